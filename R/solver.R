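#' Check that fixation is possible, and find the root sites
#'
#' A neutral mutant can fix only if the weighted digraph with edges
#' `e[i, j] > 0` is out-connected from at least one vertex: some site can
#' reach every site along positive-weight directed edges. Those sites form
#' the unique source strongly-connected component of the graph. Structures
#' violating this (e.g. two completely separate subpopulations) admit no
#' fixation and the fixation system has no valid solution.
#'
#' @param rates a [marginal_rates()] object.
#' @return `assert_fixation_possible()` returns the integer vector of root
#'   sites (members of the source strongly-connected component), or throws
#'   an error `"fixation impossible"`. `fixation_possible()` returns a
#'   logical.
#' @examples
#' assert_fixation_possible(builtin_structure("complete", N = 3))
#' @export
assert_fixation_possible <- function(rates) {
  stopifnot(inherits(rates, "marginal_rates"))
  N <- rates$n_sites
  if (N == 1L) return(1L)
  g <- igraph::graph_from_adjacency_matrix(
    (rates$rates > 0) * 1, mode = "directed", diag = FALSE
  )
  comp <- igraph::components(g, mode = "strong")
  k <- comp$no
  if (k == 1L) return(seq_len(N))
  # source SCCs = components with no incoming edge in the condensation
  memb <- comp$membership
  el <- igraph::as_edgelist(g, names = FALSE)
  cross <- memb[el[, 1]] != memb[el[, 2]]
  has_incoming <- unique(memb[el[cross, 2]])
  sources <- setdiff(seq_len(k), has_incoming)
  if (length(sources) != 1L) {
    stop("fixation impossible: no site can reach every other site ",
         "(structure has ", length(sources), " source components)")
  }
  which(memb == sources)
}

#' @rdname assert_fixation_possible
#' @export
fixation_possible <- function(rates) {
  !inherits(try(assert_fixation_possible(rates), silent = TRUE), "try-error")
}

#' Solve the site-specific fixation system
#'
#' Computes the probabilities `rho_i` that a neutral mutant arising at
#' site `i` becomes the ancestor of the whole population. These are the
#' unique solution of
#' \deqn{d_i \rho_i = \sum_j e_{ij} \rho_j \quad (i = 1, \dots, N), \qquad
#'       \sum_i \rho_i = 1,}
#' where `d_i` is the turnover (death) rate at site `i`. `rho_i` equals
#' the reproductive value of site `i`; exactly one site contains the
#' eventual ancestor, which is why the probabilities sum to one.
#'
#' The `N x N` homogeneous system is solved directly after replacing its
#' last row with the normalization; if the replaced system is numerically
#' singular the null space is extracted by singular-value decomposition
#' and renormalized. Residuals of all `N` original equations are checked
#' at tolerance `1e-10 * B`; tiny negative components (above `-1e-12`)
#' are clipped to zero and the vector renormalized.
#'
#' @param rates a [marginal_rates()] object passing
#'   [assert_fixation_possible()].
#' @return An object of class `"fixation_profile"`: a list with
#'   `site_probs` (length-`N` vector `rho_i`), `overall` (the overall
#'   fixation probability `rho = (1/B) sum_i d_i rho_i`), and `residual`
#'   (max absolute residual of the linear system at the solution).
#' @examples
#' solve_fixation(builtin_structure("star", n = 2))$site_probs  # 1/5, 2/5, 2/5
#' @export
solve_fixation <- function(rates) {
  stopifnot(inherits(rates, "marginal_rates"))
  assert_fixation_possible(rates)
  N <- rates$n_sites
  e <- rates$rates
  d <- colSums(e)
  B <- sum(d)
  A <- diag(d, nrow = N) - e      # A %*% rho = 0
  M <- A
  M[N, ] <- 1                      # normalization row
  rhs <- c(rep(0, N - 1L), 1)
  rho <- tryCatch(solve(M, rhs), error = function(err) NULL)
  if (is.null(rho) || any(!is.finite(rho)) ||
      max(abs(A %*% rho)) > 1e-10 * B) {
    # nearly reducible graphs can make the replaced system ill-conditioned;
    # fall back to the SVD null vector of the original operator
    sv <- svd(A)
    rho <- sv$v[, N]
    if (sum(rho) < 0) rho <- -rho
    rho <- rho / sum(rho)
  }
  if (min(rho) < -1e-12) {
    stop("numerical failure: fixation probabilities have negative ",
         "components (min = ", min(rho), ")")
  }
  rho <- pmax(rho, 0)
  rho <- rho / sum(rho)
  residual <- max(abs(A %*% rho))
  if (residual > 1e-10 * B) {
    stop("fixation system violates Assumption 1 or is numerically ",
         "singular (residual = ", signif(residual, 3), ")")
  }
  structure(
    list(site_probs = as.numeric(rho),
         overall = sum(d * rho) / B,
         residual = residual),
    class = "fixation_profile"
  )
}

#' @export
print.fixation_profile <- function(x, ...) {
  cat(sprintf("Fixation profile over %d sites\n", length(x$site_probs)))
  cat("  rho_i  :", paste(signif(x$site_probs, 5), collapse = " "), "\n")
  cat(sprintf("  overall rho = %.6g (residual %.2e)\n", x$overall, x$residual))
  invisible(x)
}

#' Overall fixation probability of a new mutation
#'
#' Mutations arise at site `i` in proportion to its turnover rate `d_i`
#' (each reproduction is an independent mutation opportunity), so the
#' overall fixation probability averaged over arrival sites is
#' `rho = (1/B) * sum_i d_i * rho_i`.
#'
#' @param rates a [marginal_rates()] object.
#' @param profile the [solve_fixation()] result for `rates` (solved fresh
#'   if omitted).
#' @return scalar in `[0, 1]`.
#' @export
overall_fixation <- function(rates, profile = NULL) {
  stopifnot(inherits(rates, "marginal_rates"))
  if (is.null(profile)) profile <- solve_fixation(rates)
  stopifnot(inherits(profile, "fixation_profile"),
            length(profile$site_probs) == rates$n_sites)
  d <- death_rates(rates)
  sum(d * profile$site_probs) / sum(d)
}

#' Fixation probability from an arbitrary initial mutant set
#'
#' Site-specific fixation probabilities are additive: the probability that
#' mutants initially occupying the set `S` take over the population is
#' `sum_{i in S} rho_i`, because exactly one founder site ancestors the
#' population and it must lie in `S`. The full site set gives 1, the
#' empty set 0.
#'
#' @param rates a [marginal_rates()] object.
#' @param sites integer vector of initially mutant sites (a subset of
#'   `1:N`; duplicates collapsed).
#' @param profile optional pre-computed [solve_fixation()] result.
#' @return scalar in `[0, 1]`.
#' @export
fixation_from_set <- function(rates, sites, profile = NULL) {
  stopifnot(inherits(rates, "marginal_rates"))
  sites <- unique(as.integer(sites))
  if (length(sites) > 0 &&
      (any(sites < 1L) || any(sites > rates$n_sites))) {
    stop("site index out of range 1..", rates$n_sites)
  }
  if (length(sites) == 0L) return(0)
  if (is.null(profile)) profile <- solve_fixation(rates)
  sum(profile$site_probs[sites])
}
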