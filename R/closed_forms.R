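#' Exact fixation probabilities for two sites
#'
#' For `N = 2` the fixation system solves in closed form:
#' `rho_1 = e12 / (e12 + e21)` and `rho_2 = e21 / (e12 + e21)`. The
#' result does not depend on the diagonal (self-replacement) entries.
#' These expressions are kept verbatim so they serve as an oracle that is
#' genuinely independent of the linear solver.
#'
#' @param e12,e21 off-diagonal replacement rates, not both zero.
#' @return numeric vector `c(rho1, rho2)`.
#' @examples
#' fixation_n2(0.3, 0.1)  # 0.75 0.25
#' @export
fixation_n2 <- function(e12, e21) {
  if (e12 < 0 || e21 < 0) stop("rates must be non-negative")
  if (e12 + e21 <= 0) stop("e12 + e21 must be positive (fixation impossible)")
  c(e12, e21) / (e12 + e21)
}

#' Exact fixation probabilities for three sites
#'
#' The closed-form solution of the fixation system for `N = 3`, written
#' as the printed rational expressions in the six off-diagonal rates
#' (the diagonal entries drop out):
#' \deqn{\rho_1 = (e_{12} e_{13} + e_{12} e_{23} + e_{13} e_{32})/D}
#' \deqn{\rho_2 = (e_{21} e_{13} + e_{21} e_{23} + e_{23} e_{31})/D}
#' \deqn{\rho_3 = (e_{12} e_{31} + e_{21} e_{32} + e_{31} e_{32})/D}
#' with denominator
#' `D = e12 (e13 + e23 + e31) + e13 (e21 + e32) + (e21 + e31)(e23 + e32)`.
#'
#' @param e a 3x3 matrix of rates (diagonal ignored), or a named/ordered
#'   numeric vector `c(e12, e13, e21, e23, e31, e32)`.
#' @return numeric vector `c(rho1, rho2, rho3)`.
#' @export
fixation_n3 <- function(e) {
  if (is.matrix(e)) {
    stopifnot(nrow(e) == 3, ncol(e) == 3)
    e12 <- e[1, 2]; e13 <- e[1, 3]; e21 <- e[2, 1]
    e23 <- e[2, 3]; e31 <- e[3, 1]; e32 <- e[3, 2]
  } else {
    stopifnot(length(e) == 6)
    e12 <- e[1]; e13 <- e[2]; e21 <- e[3]
    e23 <- e[4]; e31 <- e[5]; e32 <- e[6]
  }
  if (any(c(e12, e13, e21, e23, e31, e32) < 0)) {
    stop("rates must be non-negative")
  }
  denom <- e12 * (e13 + e23 + e31) + e13 * (e21 + e32) +
    (e21 + e31) * (e23 + e32)
  if (denom <= 0) {
    stop("zero denominator: structure is not out-connected from any site")
  }
  c(e12 * e13 + e12 * e23 + e13 * e32,
    e21 * e13 + e21 * e23 + e23 * e31,
    e12 * e31 + e21 * e32 + e31 * e32) / denom
}

#' Closed forms for the star structure
#'
#' A star with one hub and `n` leaves, edge weights chosen so every site
#' has birth rate 1 (hub feeds each leaf at `1/n`, each leaf feeds the
#' hub at 1). The exact solution is `rho_hub = 1 / (1 + n^2)`,
#' `rho_leaf = n / (1 + n^2)`, and `K/u = 2n / (1 + n^2)` — equal to 1
#' at `n = 1` and below 1 for `n >= 2`, an instance of the uniform-birth
#' slowdown.
#'
#' @param n number of leaves (>= 1).
#' @return list with `rho_hub`, `rho_leaf`, `k_over_u`.
#' @export
star_rates <- function(n) {
  check_positive_int(n, "n")
  list(rho_hub = 1 / (1 + n^2),
       rho_leaf = n / (1 + n^2),
       k_over_u = 2 * n / (1 + n^2))
}

#' Closed forms for the hub-and-leaves structure
#'
#' Unidirectional flow from a hub to `N - 1` leaves at weight `a` each,
#' hub self-loop `1 - (N - 1) a` (so `B = 1`). Fixation is certain from
#' the hub and impossible from leaves, hence the overall fixation
#' probability equals the hub turnover: `rho = 1 - (N - 1) a` and
#' `K/u = N (1 - (N - 1) a)`. The family sweeps out the whole admissible
#' range: `K = 0` at `a = 1/(N - 1)`, `K = u` at `a = 1/N`, and `K -> Nu`
#' as `a -> 0`.
#'
#' @param N population size (>= 2).
#' @param a hub-to-leaf weight in `[0, 1/(N - 1)]`.
#' @return list with `rho_overall`, `k_over_u`.
#' @export
hub_leaf_rates <- function(N, a) {
  check_positive_int(N, "N")
  if (N < 2) stop("need N >= 2")
  if (a < 0 || a > 1 / (N - 1)) stop("a must lie in [0, 1/(N-1)]")
  rho <- 1 - (N - 1) * a
  list(rho_overall = rho, k_over_u = N * rho)
}

#' Closed forms for the upstream-downstream structure
#'
#' Two well-mixed subpopulations of sizes `n_up`, `n_down` with
#' within-group rates `e_up`, `e_down` (self-pairs included) and
#' between-group rates `e_fwd` (upstream to downstream) and `e_back`.
#' With net downstream gene flow (`e_fwd > e_back`) the site-specific
#' fixation probabilities are
#' \deqn{\rho_\uparrow = \frac{e_\to}{N_\uparrow e_\to + N_\downarrow e_\gets},
#'       \qquad
#'       \rho_\downarrow = \frac{e_\gets}{N_\uparrow e_\to + N_\downarrow e_\gets},}
#' and the clock rate is
#' `K/u = (N/B) (n_up d_up e_fwd + n_down d_down e_back) /
#' (n_up e_fwd + n_down e_back)`, with the subpopulation turnover rates
#' `d_up`, `d_down` and total rate `B` taken from the instantiated
#' matrix (so the self-pair convention cannot silently diverge between
#' the closed form and the generator). The clock is accelerated
#' (`K > u`) exactly when the upstream population turns over faster
#' (`d_up > d_down`).
#'
#' @param n_up,n_down subpopulation sizes (>= 1).
#' @param e_up,e_down,e_fwd,e_back non-negative rates; the model assumes
#'   `e_fwd > e_back` (still computed otherwise, with a warning).
#' @return list with `rho_up`, `rho_down`, `k_over_u`, `accelerated`
#'   (logical, `K/u > 1`), `d_up`, `d_down`.
#' @export
updown_rates <- function(n_up, n_down, e_up, e_down, e_fwd, e_back) {
  if (e_fwd <= e_back) {
    warning("model assumes net downstream gene flow (e_fwd > e_back); ",
            "values computed anyway")
  }
  rates <- builtin_structure("upstream_downstream",
                             n_up = n_up, n_down = n_down,
                             e_up = e_up, e_down = e_down,
                             e_fwd = e_fwd, e_back = e_back)
  d <- death_rates(rates)
  d_up <- d[1]
  d_down <- d[n_up + 1]
  B <- total_rate(rates)
  N <- n_up + n_down
  denom <- n_up * e_fwd + n_down * e_back
  if (denom <= 0) stop("no gene flow between or within groups reaching both")
  rho_up <- e_fwd / denom
  rho_down <- e_back / denom
  k_over_u <- (N / B) * (n_up * d_up * e_fwd + n_down * d_down * e_back) /
    denom
  list(rho_up = rho_up, rho_down = rho_down, k_over_u = k_over_u,
       accelerated = k_over_u > 1, d_up = d_up, d_down = d_down)
}
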