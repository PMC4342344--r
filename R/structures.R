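#' Marginal replacement-rate structure
#'
#' Construct a replacement structure from an `N x N` matrix of marginal
#' replacement probabilities, where entry `(i, j)` is the per-time-step
#' probability `e[i, j]` that the offspring of site `i` replaces the
#' occupant of site `j`. Diagonal entries (self-replacement) are allowed.
#'
#' Derived quantities: birth rate `b_i = sum_j e[i, j]` (row sums), death
#' (turnover) rate `d_i = sum_j e[j, i]` (column sums), and total rate
#' `B = sum(b) = sum(d)`. A generation is defined as `N / B` time-steps,
#' so that each site is replaced once per generation on average.
#'
#' @param rates numeric `N x N` matrix with non-negative entries and at
#'   least one positive entry.
#' @param time_unit optional label (e.g. `"day"`) giving the physical
#'   meaning of one time-step, used when reporting per-time-step rates.
#' @return An object of class `"marginal_rates"` with elements `rates`,
#'   `n_sites`, `time_unit`.
#' @seealso [builtin_structure()], [random_structure()], [solve_fixation()]
#' @examples
#' m <- marginal_rates(matrix(c(0, 0.5, 0.5, 0), 2, 2))
#' birth_rates(m)
#' death_rates(m)
#' @export
marginal_rates <- function(rates, time_unit = NULL) {
  rates <- as.matrix(rates)
  if (!is.numeric(rates) || nrow(rates) != ncol(rates)) {
    stop("'rates' must be a square numeric matrix")
  }
  if (any(!is.finite(rates))) stop("'rates' must be finite")
  if (any(rates < 0)) stop("replacement rates must be non-negative")
  n <- nrow(rates)
  if (n < 1L) stop("need at least one site")
  b <- rowSums(rates)
  d <- colSums(rates)
  B <- sum(b)
  if (B <= 0) stop("total replacement rate B must be positive")
  stopifnot(abs(sum(b) - sum(d)) <= 1e-12 * max(1, B))
  dimnames(rates) <- NULL
  structure(
    list(rates = rates, n_sites = n, time_unit = time_unit),
    class = "marginal_rates"
  )
}

#' @export
print.marginal_rates <- function(x, ...) {
  cat(sprintf(
    "Replacement structure on %d sites (B = %.6g%s)\n",
    x$n_sites, total_rate(x),
    if (is.null(x$time_unit)) "" else paste0(" per ", x$time_unit)
  ))
  cat(sprintf("  birth rates b_i: %s\n",
              paste(signif(birth_rates(x), 4), collapse = " ")))
  cat(sprintf("  death rates d_i: %s\n",
              paste(signif(death_rates(x), 4), collapse = " ")))
  invisible(x)
}

#' Birth, death and total replacement rates
#'
#' `birth_rates()` returns the row sums `b_i` (expected offspring per
#' time-step), `death_rates()` the column sums `d_i` (probability of being
#' replaced per time-step), and `total_rate()` the common total
#' `B = sum(b) = sum(d)`.
#'
#' @param x a [marginal_rates()] object.
#' @return numeric vector of length `N`, or a scalar for `total_rate()`.
#' @export
birth_rates <- function(x) {
  stopifnot(inherits(x, "marginal_rates"))
  rowSums(x$rates)
}

#' @rdname birth_rates
#' @export
death_rates <- function(x) {
  stopifnot(inherits(x, "marginal_rates"))
  colSums(x$rates)
}

#' @rdname birth_rates
#' @export
total_rate <- function(x) {
  stopifnot(inherits(x, "marginal_rates"))
  sum(x$rates)
}

#' Built-in replacement structures
#'
#' Generators for the structure families used throughout the package.
#' Each returns a [marginal_rates()] object.
#'
#' * `complete(N, B)`: well-mixed population; `e[i, j] = B / N^2` for every
#'   ordered pair including self-pairs.
#' * `cycle(N, w)`: `N`-cycle with weight `w` on each of the `2N` directed
#'   neighbor edges.
#' * `star(n)`: hub plus `n` leaves (`N = n + 1`); hub feeds each leaf at
#'   rate `1/n` and each leaf feeds the hub at rate 1, so every site has
#'   birth rate 1.
#' * `asymmetric_path()`: four sites in a chain with twice as much gene
#'   flow rightward (`2c`) as leftward (`c`) and a self-loop `4c` at site
#'   1, with `c = 1/13` so that `B = 1`.
#' * `hub_leaf(N, a)`: unidirectional flow from a hub to `N - 1` leaves at
#'   weight `a` each, hub self-loop `1 - (N - 1) * a` (so `B = 1`);
#'   requires `0 <= a <= 1/(N - 1)`.
#' * `upstream_downstream(n_up, n_down, e_up, e_down, e_fwd, e_back)`: two
#'   well-mixed subpopulations; `e[i, j] = e_up` for upstream pairs
#'   (including self-pairs), `e_down` for downstream pairs, `e_fwd` from
#'   each upstream to each downstream site, `e_back` in reverse.
#' * `crypt()`: intestinal-crypt stem-cell model; `cycle(5, 0.05)` with
#'   time unit "day", so each stem cell turns over at 0.1/day.
#'
#' @param family one of `"complete"`, `"cycle"`, `"star"`,
#'   `"asymmetric_path"`, `"hub_leaf"`, `"upstream_downstream"`, `"crypt"`.
#' @param ... family parameters, see Details.
#' @return a [marginal_rates()] object. For `star` and `hub_leaf` the hub
#'   is site 1; for `upstream_downstream` sites `1:n_up` are upstream.
#' @examples
#' builtin_structure("star", n = 2)
#' builtin_structure("crypt")
#' @export
builtin_structure <- function(family, ...) {
  family <- match.arg(family, c("complete", "cycle", "star",
                                "asymmetric_path", "hub_leaf",
                                "upstream_downstream", "crypt"))
  params <- list(...)
  switch(family,
    complete = {
      N <- params$N %||% params$n
      B <- params$B %||% 1
      check_positive_int(N, "N")
      if (B <= 0) stop("B must be positive")
      marginal_rates(matrix(B / N^2, N, N))
    },
    cycle = {
      N <- params$N %||% params$n
      w <- params$w %||% 1
      check_positive_int(N, "N")
      if (N < 2) stop("cycle needs N >= 2")
      if (w <= 0) stop("w must be positive")
      e <- matrix(0, N, N)
      nxt <- c(2:N, 1)
      for (i in seq_len(N)) {
        e[i, nxt[i]] <- e[i, nxt[i]] + w
        e[nxt[i], i] <- e[nxt[i], i] + w
      }
      marginal_rates(e, time_unit = params$time_unit)
    },
    star = {
      n <- params$n
      check_positive_int(n, "n")
      N <- n + 1L
      e <- matrix(0, N, N)
      e[1, 2:N] <- 1 / n       # hub -> each leaf
      e[2:N, 1] <- 1           # each leaf -> hub
      marginal_rates(e)
    },
    asymmetric_path = {
      cc <- 1 / 13
      e <- matrix(0, 4, 4)
      e[1, 1] <- 4 * cc
      for (i in 1:3) e[i, i + 1] <- 2 * cc  # rightward
      for (i in 2:4) e[i, i - 1] <- cc      # leftward
      marginal_rates(e)
    },
    hub_leaf = {
      N <- params$N %||% params$n
      a <- params$a
      check_positive_int(N, "N")
      if (N < 2) stop("hub_leaf needs N >= 2")
      if (is.null(a) || a < 0 || a > 1 / (N - 1)) {
        stop("hub_leaf requires 0 <= a <= 1/(N-1)")
      }
      e <- matrix(0, N, N)
      e[1, 2:N] <- a
      e[1, 1] <- 1 - (N - 1) * a
      marginal_rates(e)
    },
    upstream_downstream = {
      n_up <- params$n_up %||% params$N_up
      n_down <- params$n_down %||% params$N_down
      check_positive_int(n_up, "n_up")
      check_positive_int(n_down, "n_down")
      e_up <- params$e_up; e_down <- params$e_down
      e_fwd <- params$e_fwd; e_back <- params$e_back
      for (v in list(e_up, e_down, e_fwd, e_back)) {
        if (is.null(v) || v < 0) stop("all four rates must be given and >= 0")
      }
      N <- n_up + n_down
      up <- seq_len(n_up)
      down <- n_up + seq_len(n_down)
      e <- matrix(0, N, N)
      e[up, up] <- e_up
      e[down, down] <- e_down
      e[up, down] <- e_fwd
      e[down, up] <- e_back
      marginal_rates(e)
    },
    crypt = {
      builtin_structure("cycle", N = 5, w = 0.05, time_unit = "day")
    }
  )
}

#' Random replacement structures under rate constraints
#'
#' Draws a reproducible random non-negative replacement matrix satisfying
#' one of the constraint classes used in the theory of structured neutral
#' substitution:
#'
#' * `"none"`: unconstrained sparse random weights.
#' * `"uniform_death"`: all column sums (death rates) equal.
#' * `"circulation"`: row sum equals column sum at every site
#'   (`b_i = d_i`), built as a random non-negative combination of directed
#'   cycles over random site subsets.
#' * `"uniform_birth"`: all row sums (birth rates) equal.
#'
#' Matrices are resampled until the structure is out-connected from at
#' least one vertex, so fixation is always possible.
#'
#' @param N number of sites (>= 2).
#' @param constraint one of `"none"`, `"uniform_death"`, `"circulation"`,
#'   `"uniform_birth"`.
#' @param seed integer seed; the draw is fully reproducible from it.
#' @param density expected fraction of non-zero off-diagonal entries
#'   (ignored for `"circulation"`).
#' @return a [marginal_rates()] object.
#' @examples
#' m <- random_structure(5, "circulation", seed = 2)
#' max(abs(birth_rates(m) - death_rates(m)))  # ~0
#' @export
random_structure <- function(N, constraint = c("none", "uniform_death",
                                               "circulation", "uniform_birth"),
                             seed, density = 0.7) {
  constraint <- match.arg(constraint)
  check_positive_int(N, "N")
  if (N < 2) stop("need N >= 2")
  with_local_seed(seed, random_structure_impl(N, constraint, density))
}

random_structure_impl <- function(N, constraint, density) {
  for (attempt in 1:1000) {
    e <- switch(constraint,
      none = random_raw_matrix(N, density),
      uniform_death = {
        m <- random_raw_matrix(N, density)
        # rescale columns to a common sum; resample any all-zero column
        cs <- colSums(m)
        while (any(cs == 0)) {
          m <- random_raw_matrix(N, density)
          cs <- colSums(m)
        }
        sweep(m, 2, cs, "/") * (1 / N)
      },
      circulation = {
        m <- matrix(0, N, N)
        n_cycles <- 2L + stats::rbinom(1, 2 * N, 0.5)
        for (k in seq_len(n_cycles)) {
          len <- sample(2:N, 1)
          sites <- sample.int(N, len)
          w <- runif(1, 0.1, 1)
          for (s in seq_len(len)) {
            m[sites[s], sites[if (s == len) 1 else s + 1]] <-
              m[sites[s], sites[if (s == len) 1 else s + 1]] + w
          }
        }
        m
      },
      uniform_birth = {
        m <- random_raw_matrix(N, density)
        rs <- rowSums(m)
        while (any(rs == 0)) {
          m <- random_raw_matrix(N, density)
          rs <- rowSums(m)
        }
        sweep(m, 1, rs, "/") * (1 / N)
      }
    )
    if (sum(e) > 0 && fixation_possible(marginal_rates(e))) {
      return(marginal_rates(e))
    }
  }
  stop("failed to draw an out-connected structure (should not happen)")
}

random_raw_matrix <- function(N, density) {
  e <- matrix(runif(N * N), N, N)
  mask <- matrix(runif(N * N) < density, N, N)
  e * mask
}

#' Read and write replacement-rate matrices
#'
#' Plain-text exchange format: `N` rows by `N` columns of non-negative
#' numbers, comma- or whitespace-delimited, row `i` giving the rates from
#' source site `i`. A header line is detected and skipped.
#'
#' @param path file path.
#' @param time_unit optional time-step label attached to the result.
#' @return `read_rates_matrix()` returns a [marginal_rates()] object;
#'   `write_rates_matrix()` invisibly returns `path`.
#' @export
read_rates_matrix <- function(path, time_unit = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(probe))))
  m <- as.matrix(read.table(path, sep = sep, header = header))
  storage.mode(m) <- "double"
  marginal_rates(m, time_unit = time_unit)
}

#' @rdname read_rates_matrix
#' @param x a [marginal_rates()] object.
#' @param sep field separator used when writing.
#' @export
write_rates_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "marginal_rates"))
  write.table(x$rates, path, sep = sep, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Build a structure from a named specification
#'
#' Accepts a list of the form `list(name = "star", params = list(n = 3))`
#' (the shape produced by reading a YAML/JSON config), or a flat list with
#' `name` plus parameters, and dispatches to [builtin_structure()].
#'
#' @param spec named list with `name` and family parameters.
#' @return a [marginal_rates()] object.
#' @export
structure_from_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$name))
  params <- if (!is.null(spec$params)) spec$params else spec[setdiff(names(spec), "name")]
  do.call(builtin_structure, c(list(family = spec$name), params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive_int <- function(x, label) {
  if (is.null(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop("'", label, "' must be a positive integer")
  }
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_local_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) stop("'seed' must be an integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
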