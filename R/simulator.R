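# Monte-Carlo simulation of the evolutionary and ancestral Markov chains.
#
# The evolutionary chain tracks mutant/resident types; the ancestral chain
# tracks founder labels (site of each individual's founding ancestor) and
# absorbs when one founder's label occupies every site. One ancestral run
# therefore estimates all N site-specific fixation probabilities at once,
# an N-fold variance saving over single-mutant evolutionary runs.

# Flatten a rule's events to the vectors the C++ loop consumes.
flatten_rule <- function(rule) {
  lens <- vapply(rule$events, function(ev) length(ev$replaced), integer(1))
  list(
    probs = rule$probs,
    offsets = c(0L, cumsum(lens)),
    replaced = unlist(lapply(rule$events, function(ev) ev$replaced - 1L),
                      use.names = FALSE) %||% integer(0),
    parents = unlist(lapply(rule$events, function(ev) ev$parents - 1L),
                     use.names = FALSE) %||% integer(0)
  )
}

simulate_runs <- function(rule, initial, n_runs, seed, max_steps) {
  stopifnot(inherits(rule, "replacement_rule"))
  initial <- as.integer(initial)
  if (length(initial) != rule$n_sites) {
    stop("'initial' must assign a label to each of the ", rule$n_sites,
         " sites")
  }
  with_local_seed(seed, {
    if (rule$kind == "wright_fisher") {
      sim_wright_fisher_cpp(rule$parent_probs, initial, n_runs, max_steps)
    } else {
      fl <- flatten_rule(rule)
      sim_explicit_cpp(fl$probs, fl$offsets, fl$replaced, fl$parents,
                       initial, n_runs, max_steps)
    }
  })
}

#' Run a replacement process to absorption
#'
#' Iterates the state-update rule (`s'_i = s_i` if `i` is not replaced,
#' else the label of `alpha(i)`'s occupant) from an arbitrary labelling
#' until the population is monomorphic. Any integer labelling works: use
#' two labels for the evolutionary (mutant/resident) chain or the labels
#' `1:N` for the ancestral chain.
#'
#' @param rule a [replacement_rule()].
#' @param initial integer vector of length `N` giving each site's starting
#'   label.
#' @param seed integer seed (the run is deterministic given it).
#' @param max_steps guard against non-absorbing rules; default
#'   `1e6 * N` steps.
#' @return list with `winner` (the absorbed label) and `steps`.
#' @examples
#' rule <- moran_rule_from_marginals(builtin_structure("hub_leaf", N = 5, a = 0.1))
#' run_to_absorption(rule, initial = c(2, 1, 1, 1, 1), seed = 1)$winner  # hub wins
#' @export
run_to_absorption <- function(rule, initial, seed,
                              max_steps = 1e6 * rule$n_sites) {
  if (max_steps <= 0) stop("'max_steps' must be positive")
  res <- simulate_runs(rule, initial, n_runs = 1L, seed = seed,
                       max_steps = max_steps)
  list(winner = res$winner[1], steps = res$steps[1])
}

#' Estimate fixation probabilities by simulating the ancestral chain
#'
#' Runs the ancestral Markov chain from the canonical founding state
#' `(1, ..., N)` repeatedly; the estimate of the fixation probability from
#' site `i` is the fraction of runs in which founder `i`'s label takes
#' over the population. Exactly one founder wins each run, so the
#' estimates sum to 1 exactly.
#'
#' @param rule a [replacement_rule()].
#' @param n_runs number of independent runs (>= 1).
#' @param seed integer seed.
#' @param max_steps per-run absorption guard, default `1e6 * N`.
#' @return An object of class `"simulation_result"`: list with
#'   `estimates` (length-`N` vector of fixation-probability estimates),
#'   `standard_errors` (binomial, `sqrt(p(1-p)/n_runs)`), `n_runs`,
#'   `seed`, `mean_absorption_steps`.
#' @examples
#' rule <- moran_rule_from_marginals(builtin_structure("complete", N = 3))
#' estimate_fixation(rule, n_runs = 2000, seed = 7)
#' @export
estimate_fixation <- function(rule, n_runs, seed,
                              max_steps = 1e6 * rule$n_sites) {
  stopifnot(inherits(rule, "replacement_rule"))
  check_positive_int(n_runs, "n_runs")
  N <- rule$n_sites
  res <- simulate_runs(rule, initial = seq_len(N), n_runs = n_runs,
                       seed = seed, max_steps = max_steps)
  wins <- tabulate(res$winner, nbins = N)
  p_hat <- wins / n_runs
  structure(
    list(estimates = p_hat,
         standard_errors = sqrt(p_hat * (1 - p_hat) / n_runs),
         n_runs = as.integer(n_runs),
         seed = seed,
         mean_absorption_steps = mean(res$steps)),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Ancestral-chain fixation estimates (%d runs, seed %s)\n",
    x$n_runs, format(x$seed)))
  cat("  rho_hat:", paste(signif(x$estimates, 4), collapse = " "), "\n")
  cat("  SE     :", paste(signif(x$standard_errors, 3), collapse = " "), "\n")
  cat(sprintf("  mean steps to absorption: %.1f\n", x$mean_absorption_steps))
  invisible(x)
}

#' Estimate the fixation probability of an initial mutant set
#'
#' Simulates the evolutionary (mutant/resident) chain from a state with
#' mutants on `sites` and residents elsewhere, returning the fraction of
#' runs in which the mutant type fixed. By the additivity of site-specific
#' fixation probabilities this should match `sum(rho_i, i in sites)`.
#'
#' @param rule a [replacement_rule()].
#' @param sites integer vector of initially mutant sites.
#' @inheritParams estimate_fixation
#' @return list with `p_fix`, `se`, `n_runs`, `mean_absorption_steps`.
#' @export
estimate_fixation_from_set <- function(rule, sites, n_runs, seed,
                                       max_steps = 1e6 * rule$n_sites) {
  stopifnot(inherits(rule, "replacement_rule"))
  sites <- unique(as.integer(sites))
  N <- rule$n_sites
  if (any(sites < 1L) || any(sites > N)) stop("site index out of range")
  initial <- rep(1L, N)    # 1 = resident
  initial[sites] <- 2L     # 2 = mutant
  if (length(sites) == 0L) {
    return(list(p_fix = 0, se = 0, n_runs = n_runs,
                mean_absorption_steps = 0))
  }
  res <- simulate_runs(rule, initial, n_runs = n_runs, seed = seed,
                       max_steps = max_steps)
  p <- mean(res$winner == 2L)
  list(p_fix = p, se = sqrt(p * (1 - p) / n_runs), n_runs = n_runs,
       mean_absorption_steps = mean(res$steps))
}
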