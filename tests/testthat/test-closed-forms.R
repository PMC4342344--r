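test_that("two-site closed form matches arithmetic and the solver", {
  expect_close(fixation_n2(0.3, 0.1), c(0.75, 0.25))
  expect_close(fixation_n2(0.7, 0.7), c(0.5, 0.5))
  expect_error(fixation_n2(0, 0), "positive")
  expect_error(fixation_n2(-1, 1), "non-negative")
  set.seed(12)
  for (rep in 1:50) {
    e12 <- runif(1); e21 <- runif(1)
    m <- marginal_rates(matrix(c(runif(1), e21, e12, runif(1)), 2, 2))
    expect_close(solve_fixation(m)$site_probs, fixation_n2(e12, e21),
                 tol = 1e-12)
  }
})

test_that("two-site uniform-birth structures obey the exact slowdown identity", {
  set.seed(13)
  for (rep in 1:30) {
    e12 <- runif(1, 0, 0.5)
    e21 <- runif(1, 0, 0.5)
    e <- matrix(c(0.5 - e12, e21, e12, 0.5 - e21), 2, 2)  # b1 = b2 = 1/2
    m <- marginal_rates(e)
    rho <- overall_fixation(m)
    expect_close(rho, 0.5 - (e12 - e21)^2 / (e12 + e21), tol = 1e-12)
    expect_lte(rho, 0.5 + 1e-12)
  }
})

test_that("three-site closed form matches symmetry cases and the solver", {
  expect_close(fixation_n3(matrix(0.4, 3, 3)), rep(1 / 3, 3))
  cyc <- matrix(0, 3, 3)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 0.7
  expect_close(fixation_n3(cyc), rep(1 / 3, 3))
  expect_close(fixation_n3(cyc), brute_force_rho(marginal_rates(cyc)),
               tol = 1e-10)
  expect_error(fixation_n3(matrix(0, 3, 3)), "denominator")
  set.seed(14)
  for (rep in 1:100) {
    e <- matrix(runif(9), 3, 3)
    expect_close(solve_fixation(marginal_rates(e))$site_probs,
                 fixation_n3(e), tol = 1e-12)
  }
})

test_that("closed-form results are independent of self-replacement rates", {
  set.seed(15)
  e <- matrix(runif(9), 3, 3)
  e2 <- e; diag(e2) <- runif(3, 0, 5)
  expect_close(fixation_n3(e), fixation_n3(e2))
  expect_close(solve_fixation(marginal_rates(e2))$site_probs, fixation_n3(e),
               tol = 1e-12)
})

test_that("star closed form matches the generated structure for n = 1..30", {
  expect_close(star_rates(1)$k_over_u, 1)
  s2 <- star_rates(2)
  expect_close(c(s2$rho_hub, s2$rho_leaf, s2$k_over_u), c(1, 2, 4) / 5)
  for (n in 1:30) {
    cf <- star_rates(n)
    m <- builtin_structure("star", n = n)
    prof <- solve_fixation(m)
    expect_close(prof$site_probs[1], cf$rho_hub, tol = 1e-12)
    expect_close(prof$site_probs[-1], rep(cf$rho_leaf, n), tol = 1e-12)
    expect_close(clock_rates(m)$k_per_generation_over_u, cf$k_over_u,
                 tol = 1e-12)
  }
})

test_that("hub-leaf closed form matches the generated structure across its range", {
  expect_close(hub_leaf_rates(5, 0.25)$k_over_u, 0)
  expect_close(hub_leaf_rates(5, 0.2)$rho_overall, 0.2)
  expect_close(hub_leaf_rates(5, 0.2)$k_over_u, 1)
  expect_error(hub_leaf_rates(5, 0.3), "\\[0, 1/\\(N-1\\)\\]")
  expect_close(hub_leaf_rates(5, 0)$k_over_u, 5)  # a = 0 limit, closed form only
  for (a in c(0.05, 0.1, 0.2, 0.25)) {
    cf <- hub_leaf_rates(5, a)
    m <- builtin_structure("hub_leaf", N = 5, a = a)
    expect_close(overall_fixation(m), cf$rho_overall, tol = 1e-12)
    expect_close(clock_rates(m)$k_per_generation_over_u, cf$k_over_u,
                 tol = 1e-12)
  }
})

test_that("the two-site upstream-downstream case reduces to the N = 2 closed form", {
  ud <- updown_rates(1, 1, 0, 0, 2, 1)
  expect_close(ud$rho_up, fixation_n2(2, 1)[1])
  expect_close(ud$rho_down, fixation_n2(2, 1)[2])
})

test_that("upstream-downstream solver values equal the printed fractions", {
  set.seed(17)
  for (rep in 1:25) {
    n_up <- sample(1:3, 1); n_down <- sample(1:4, 1)
    e_up <- runif(1, 0.01, 0.3); e_down <- runif(1, 0.01, 0.3)
    e_back <- runif(1, 0, 0.1); e_fwd <- e_back + runif(1, 0.01, 0.3)
    cf <- updown_rates(n_up, n_down, e_up, e_down, e_fwd, e_back)
    m <- builtin_structure("upstream_downstream", n_up = n_up,
                           n_down = n_down, e_up = e_up, e_down = e_down,
                           e_fwd = e_fwd, e_back = e_back)
    prof <- solve_fixation(m)
    expect_close(prof$site_probs,
                 c(rep(cf$rho_up, n_up), rep(cf$rho_down, n_down)),
                 tol = 1e-12)
    k <- clock_rates(m)$k_per_generation_over_u
    expect_close(k, cf$k_over_u, tol = 1e-12)
    # acceleration exactly when upstream turnover exceeds downstream
    expect_identical(cf$accelerated, cf$d_up > cf$d_down)
    if (abs(cf$d_up - cf$d_down) > 1e-10) {
      expect_identical(k > 1, cf$d_up > cf$d_down)
    }
  }
})

test_that("unidirectional gene flow gives K = (d_up/B) N u, bounded by N/N_up", {
  for (rep in 1:10) {
    set.seed(600 + rep)
    n_up <- sample(1:3, 1); n_down <- sample(1:4, 1)
    e_up <- runif(1, 0.01, 0.3); e_down <- runif(1, 0.01, 0.3)
    e_fwd <- runif(1, 0.01, 0.3)
    cf <- updown_rates(n_up, n_down, e_up, e_down, e_fwd, 0)
    m <- builtin_structure("upstream_downstream", n_up = n_up,
                           n_down = n_down, e_up = e_up, e_down = e_down,
                           e_fwd = e_fwd, e_back = 0)
    N <- n_up + n_down
    expect_close(cf$k_over_u, N * cf$d_up / total_rate(m), tol = 1e-12)
    expect_lt(cf$k_over_u, N / n_up)
  }
})

test_that("reversed net flow is flagged but still computed", {
  expect_warning(updown_rates(2, 2, 0.1, 0.1, 0.05, 0.2), "net downstream")
})
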