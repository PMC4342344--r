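# Independent oracles and fixture builders shared across the test files.

# Brute-force fixation probabilities by exact absorption analysis of the
# evolutionary (mutant/resident) Markov chain under the Moran rule of a
# marginal matrix: enumerate all 2^N type-strings, build the one-step
# transition matrix, and solve the absorption system. Completely
# independent of the package's linear solver (which never touches the
# 2^N state space). Usable for N <= 10 or so; intended for N <= 4.
brute_force_rho <- function(rates) {
  e <- rates$rates
  N <- nrow(e)
  B <- sum(e)
  n_states <- 2^N
  # state index s (0-based bitmask): bit i set = site i+1 is mutant
  P <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1)) {
    bits <- bitwAnd(s, bitwShiftL(1L, 0:(N - 1))) > 0
    for (i in 1:N) for (j in 1:N) {
      if (e[i, j] == 0) next
      new_bits <- bits
      new_bits[j] <- bits[i]
      s2 <- sum(bitwShiftL(1L, which(new_bits) - 1L))
      P[s + 1, s2 + 1] <- P[s + 1, s2 + 1] + e[i, j] / B
    }
  }
  all_m <- n_states   # state with every site mutant (1-based index)
  transient <- setdiff(seq_len(n_states), c(1L, all_m))
  Q <- P[transient, transient, drop = FALSE]
  r <- P[transient, all_m]
  h <- solve(diag(length(transient)) - Q, r)
  absorb <- numeric(n_states)
  absorb[all_m] <- 1
  absorb[transient] <- h
  vapply(1:N, function(i) absorb[bitwShiftL(1L, i - 1L) + 1L], numeric(1))
}

# Random non-negative 3x3 matrix adjusted on the diagonal so that site 1
# has exactly the average death rate (d_1 = B/3). Used for the sign
# analysis of the three-site clock-rate factorization.
random_n3_balanced_d1 <- function() {
  e <- matrix(runif(9, 0, 1), 3, 3)
  repeat {
    d1 <- sum(e[, 1]); B <- sum(e)
    if (abs(d1 - B / 3) < 1e-14) break
    delta <- (B - 3 * d1) / 2
    if (delta >= 0) {
      e[1, 1] <- e[1, 1] + delta       # raises d1 by delta, B by delta
    } else {
      e[2, 2] <- e[2, 2] + (3 * d1 - B)  # raises B without touching d1
    }
  }
  e
}

expect_close <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}

builtin_catalog <- function() {
  list(
    complete = builtin_structure("complete", N = 4),
    cycle = builtin_structure("cycle", N = 6, w = 0.2),
    star = builtin_structure("star", n = 3),
    asymmetric_path = builtin_structure("asymmetric_path"),
    hub_leaf = builtin_structure("hub_leaf", N = 5, a = 0.1),
    upstream_downstream = builtin_structure(
      "upstream_downstream", n_up = 2, n_down = 3,
      e_up = 0.1, e_down = 0.05, e_fwd = 0.2, e_back = 0.04),
    crypt = builtin_structure("crypt")
  )
}
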