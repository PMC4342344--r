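#' Molecular clock rates of a replacement structure
#'
#' Converts a solved fixation profile into neutral substitution rates. If
#' mutation occurs with probability `u << 1` per reproduction, mutations
#' arise at site `i` at rate proportional to its turnover `d_i`, and the
#' expected number of substitutions is
#' \deqn{K = N u \rho \text{ per generation}, \qquad
#'       \tilde K = B u \rho \text{ per time-step},}
#' with `rho` the overall fixation probability. The package reports the
#' dimensionless ratios `K/u` and `Ktilde/u`; absolute rates are filled in
#' when `u` is supplied. A generation is `N/B` time-steps.
#'
#' @param rates a [marginal_rates()] object.
#' @param u optional per-reproduction mutation probability (`0 < u << 1`;
#'   a warning is issued above 0.1 where the weak-mutation assumption is
#'   doubtful).
#' @param rel_tol relative tolerance used for the classification flags and
#'   the ternary comparison of `K` with `u`.
#' @return An object of class `"clock_report"`: list with
#'   `k_per_generation_over_u` (`= N * rho`), `k_per_timestep_over_u`
#'   (`= B * rho`), `overall_fixation`, `mutation_rate`, `k_per_generation`
#'   and `k_per_timestep` (absolute, `NA` without `u`), `time_unit`,
#'   `classification` (see [classify_structure()]) and `comparison` (one
#'   of `"K<u"`, `"K=u"`, `"K>u"`).
#' @examples
#' clock_rates(builtin_structure("crypt"), u = 1.1e-4)
#' @export
clock_rates <- function(rates, u = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(rates, "marginal_rates"))
  if (!is.null(u)) {
    if (u <= 0) stop("'u' must be positive")
    if (u > 0.1) warning("u = ", u, " is large; the clock formula assumes ",
                         "the weak-mutation regime u << 1")
  }
  profile <- solve_fixation(rates)
  N <- rates$n_sites
  B <- total_rate(rates)
  rho <- profile$overall
  k_gen <- N * rho
  cls <- classify_structure(rates, rel_tol = rel_tol, profile = profile)
  structure(
    list(
      k_per_generation_over_u = k_gen,
      k_per_timestep_over_u = B * rho,
      overall_fixation = rho,
      site_probs = profile$site_probs,
      mutation_rate = u,
      k_per_generation = if (is.null(u)) NA_real_ else N * rho * u,
      k_per_timestep = if (is.null(u)) NA_real_ else B * rho * u,
      time_unit = rates$time_unit,
      classification = cls$classification,
      comparison = cls$comparison
    ),
    class = "clock_report"
  )
}

#' @export
print.clock_report <- function(x, ...) {
  cat("Neutral substitution rates\n")
  cat(sprintf("  K/u  = %.8g per generation (%s)\n",
              x$k_per_generation_over_u, x$comparison))
  unit <- if (is.null(x$time_unit)) "time-step" else x$time_unit
  cat(sprintf("  K~/u = %.8g per %s\n", x$k_per_timestep_over_u, unit))
  if (!is.null(x$mutation_rate)) {
    cat(sprintf("  with u = %.3g: K = %.6g per generation, K~ = %.6g per %s\n",
                x$mutation_rate, x$k_per_generation, x$k_per_timestep, unit))
  }
  if (length(x$classification)) {
    cat("  structure class:", paste(x$classification, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a structure by its birth/death-rate constraints
#'
#' Three structural conditions pin down how spatial structure moves the
#' neutral clock relative to a well-mixed population:
#'
#' * uniform death rates (`d_i = B/N` for all `i`) imply `K = u`;
#' * a circulation (`b_i = d_i` at every site) implies `rho_i = 1/N` for
#'   all `i` and hence `K = u` — and conversely uniform `rho_i` implies a
#'   circulation;
#' * uniform birth rates (`b_i = B/N`) imply `K <= u`, with equality
#'   exactly when the death rates are also uniform.
#'
#' The function flags every condition the matrix satisfies (within
#' `rel_tol * B`), predicts the implied relation of `K` to `u`, computes
#' the actual relation from the solved system, and errors on an internal
#' inconsistency between the two (which would indicate a solver defect).
#'
#' @param rates a [marginal_rates()] object.
#' @param rel_tol relative tolerance for the flag and comparison tests.
#' @param profile optional pre-computed [solve_fixation()] result.
#' @return list with `classification` (character subset of
#'   `c("uniform_death", "circulation", "uniform_birth")`), `comparison`
#'   (`"K<u"`, `"K=u"` or `"K>u"`), and `k_over_u`.
#' @examples
#' classify_structure(builtin_structure("star", n = 3))
#' @export
classify_structure <- function(rates, rel_tol = 1e-9, profile = NULL) {
  stopifnot(inherits(rates, "marginal_rates"))
  b <- birth_rates(rates)
  d <- death_rates(rates)
  B <- sum(b)
  N <- rates$n_sites
  tol <- rel_tol * B
  flags <- character(0)
  if (max(abs(d - B / N)) <= tol) flags <- c(flags, "uniform_death")
  if (max(abs(b - d)) <= tol) flags <- c(flags, "circulation")
  if (max(abs(b - B / N)) <= tol) flags <- c(flags, "uniform_birth")
  if (is.null(profile)) profile <- solve_fixation(rates)
  k_over_u <- N * sum(d * profile$site_probs) / B
  comparison <- if (abs(k_over_u - 1) <= rel_tol * max(1, k_over_u)) {
    "K=u"
  } else if (k_over_u < 1) "K<u" else "K>u"
  if (("uniform_death" %in% flags || "circulation" %in% flags) &&
      comparison != "K=u") {
    stop("internal inconsistency: structure satisfies a K=u condition but ",
         "computed K/u = ", k_over_u)
  }
  if ("uniform_birth" %in% flags && comparison == "K>u") {
    stop("internal inconsistency: uniform birth rates bound K <= u but ",
         "computed K/u = ", k_over_u)
  }
  list(classification = flags, comparison = comparison, k_over_u = k_over_u)
}
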