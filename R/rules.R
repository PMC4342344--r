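#' Replacement events and replacement rules
#'
#' A replacement event is a pair `(R, alpha)`: the set `R` of sites whose
#' occupants die this time-step and the offspring-to-parent map `alpha`
#' assigning each replaced site the site of its parent. A replacement rule
#' is a finite probability distribution over such events; under neutrality
#' it does not depend on the population state.
#'
#' @param replaced integer vector of replaced site indices (the set `R`).
#' @param parents integer vector of the same length; `parents[k]` is the
#'   parent site of the offspring filling `replaced[k]`. Parents may
#'   themselves be replaced in the same event.
#' @return `replacement_event()` returns an object of class
#'   `"replacement_event"`.
#' @examples
#' replacement_event(replaced = c(2, 4, 5), parents = c(3, 4, 4))
#' @export
replacement_event <- function(replaced, parents) {
  replaced <- as.integer(replaced)
  parents <- as.integer(parents)
  if (length(replaced) != length(parents)) {
    stop("'replaced' and 'parents' must have equal length")
  }
  if (anyDuplicated(replaced)) stop("'replaced' must be a set (no duplicates)")
  if (length(replaced) > 0 && (any(replaced < 1L) || any(parents < 1L))) {
    stop("site indices must be >= 1")
  }
  structure(list(replaced = replaced, parents = parents),
            class = "replacement_event")
}

#' @rdname replacement_event
#' @param events list of [replacement_event()] objects.
#' @param probs numeric vector of event probabilities; must be
#'   non-negative and sum to 1 (tolerance `1e-12`).
#' @param n_sites number of sites `N`; inferred from the largest index
#'   mentioned if omitted.
#' @return `replacement_rule()` returns an object of class
#'   `"replacement_rule"` with elements `events`, `probs`, `n_sites`, and
#'   `kind` (`"explicit"`; see [wright_fisher_rule()] for the lazily
#'   sampled kind).
#' @export
replacement_rule <- function(events, probs, n_sites = NULL) {
  if (length(events) == 0L) stop("empty event list")
  if (length(events) != length(probs)) {
    stop("'events' and 'probs' must have equal length")
  }
  ok <- vapply(events, inherits, logical(1), "replacement_event")
  if (!all(ok)) stop("all events must be replacement_event objects")
  probs <- as.numeric(probs)
  if (any(probs < 0)) stop("event probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("event probabilities must sum to 1 (got ", sum(probs), ")")
  }
  max_idx <- max(1L, unlist(lapply(events, function(ev) {
    c(ev$replaced, ev$parents, 0L)
  })))
  if (is.null(n_sites)) n_sites <- max_idx
  if (max_idx > n_sites) stop("event references site beyond n_sites")
  structure(
    list(events = events, probs = probs, n_sites = as.integer(n_sites),
         kind = "explicit"),
    class = "replacement_rule"
  )
}

#' @export
print.replacement_rule <- function(x, ...) {
  if (x$kind == "wright_fisher") {
    cat(sprintf("Wright-Fisher replacement rule on %d sites (lazy)\n",
                x$n_sites))
  } else {
    cat(sprintf("Replacement rule on %d sites with %d events\n",
                x$n_sites, length(x$events)))
  }
  invisible(x)
}

#' Marginal replacement rates of a rule
#'
#' Collapses a replacement rule to its marginal matrix:
#' `e[i, j] = P(j in R and alpha(j) = i)`, summed over events. The
#' derived row sums equal the expected offspring counts
#' `b_i = E|alpha^-1(i)|` and the column sums equal the replacement
#' probabilities `d_i = P(i in R)`; all three definitions are computed
#' independently and cross-checked.
#'
#' @param rule a [replacement_rule()] (explicit or Wright-Fisher with
#'   `N <= 6`, for which events are enumerated).
#' @param time_unit optional time-step label for the result.
#' @return a [marginal_rates()] object.
#' @export
marginals_from_rule <- function(rule, time_unit = NULL) {
  stopifnot(inherits(rule, "replacement_rule"))
  if (rule$kind == "wright_fisher") {
    rule <- enumerate_wright_fisher(rule)
  }
  N <- rule$n_sites
  e <- matrix(0, N, N)
  b_direct <- numeric(N)  # E|alpha^-1(i)|
  d_direct <- numeric(N)  # P(i in R)
  for (k in seq_along(rule$events)) {
    ev <- rule$events[[k]]
    p <- rule$probs[k]
    if (length(ev$replaced) > 0) {
      for (m in seq_along(ev$replaced)) {
        e[ev$parents[m], ev$replaced[m]] <- e[ev$parents[m], ev$replaced[m]] + p
      }
      d_direct[ev$replaced] <- d_direct[ev$replaced] + p
      tab <- tabulate(ev$parents, nbins = N)
      b_direct <- b_direct + p * tab
    }
  }
  tol <- 1e-10 * max(1, sum(e))
  stopifnot(max(abs(rowSums(e) - b_direct)) <= tol,
            max(abs(colSums(e) - d_direct)) <= tol)
  marginal_rates(e, time_unit = time_unit)
}

#' Moran rule induced by a marginal-rate matrix
#'
#' The spatial Moran interpretation of a marginal matrix: exactly one
#' reproduction occurs per time-step, along edge `i -> j` with probability
#' `e[i, j] / B`. The marginals of the resulting rule equal `rates / B`;
#' this time rescaling leaves all fixation probabilities unchanged because
#' the fixation system is homogeneous in the rates.
#'
#' @param rates a [marginal_rates()] object with `B > 0`.
#' @return an explicit [replacement_rule()] with one single-site event per
#'   positive entry of the matrix.
#' @export
moran_rule_from_marginals <- function(rates) {
  stopifnot(inherits(rates, "marginal_rates"))
  B <- total_rate(rates)
  idx <- which(rates$rates > 0, arr.ind = TRUE)
  events <- lapply(seq_len(nrow(idx)), function(k) {
    replacement_event(replaced = idx[k, 2], parents = idx[k, 1])
  })
  replacement_rule(events, rates$rates[idx] / B, n_sites = rates$n_sites)
}

#' Wright-Fisher replacement rule
#'
#' The spatial Wright-Fisher interpretation: every site is replaced each
#' time-step (`R = {1, ..., N}`), and site `j`'s parent is drawn
#' independently from column `j` of `parent_weights` (normalized within
#' the column). For `N <= 6` the full event distribution over the `N^N`
#' parent maps can be enumerated with [marginals_from_rule()]; simulation
#' always samples parent maps lazily.
#'
#' @param parent_weights `N x N` non-negative matrix; entry `(i, j)` is
#'   the unnormalized weight with which site `i` fathers site `j`'s
#'   replacement. Every column must have positive sum.
#' @return a [replacement_rule()] of kind `"wright_fisher"`.
#' @export
wright_fisher_rule <- function(parent_weights) {
  parent_weights <- as.matrix(parent_weights)
  if (nrow(parent_weights) != ncol(parent_weights)) {
    stop("'parent_weights' must be square")
  }
  if (any(parent_weights < 0)) stop("weights must be non-negative")
  cs <- colSums(parent_weights)
  if (any(cs <= 0)) stop("every column must have positive sum")
  structure(
    list(parent_probs = sweep(parent_weights, 2, cs, "/"),
         n_sites = nrow(parent_weights),
         kind = "wright_fisher"),
    class = "replacement_rule"
  )
}

# Expand a Wright-Fisher rule into its N^N explicit events (small N only).
enumerate_wright_fisher <- function(rule, max_sites = 6L) {
  N <- rule$n_sites
  if (N > max_sites) {
    stop("refusing to enumerate ", N^N, " Wright-Fisher events; N > ",
         max_sites)
  }
  maps <- as.matrix(expand.grid(rep(list(seq_len(N)), N)))
  events <- vector("list", nrow(maps))
  probs <- numeric(nrow(maps))
  for (k in seq_len(nrow(maps))) {
    parents <- maps[k, ]
    events[[k]] <- replacement_event(replaced = seq_len(N), parents = parents)
    probs[k] <- prod(rule$parent_probs[cbind(parents, seq_len(N))])
  }
  replacement_rule(events, probs, n_sites = N)
}

#' Marginal matrix of a Wright-Fisher rule without enumeration
#'
#' For a Wright-Fisher rule the marginals have the closed form
#' `e[i, j] = parent_probs[i, j]` (site `j` is always replaced, by `i`
#' with the column-normalized weight), so `d_j = 1` for every site.
#'
#' @param rule a rule of kind `"wright_fisher"`.
#' @return a [marginal_rates()] object.
#' @export
wright_fisher_marginals <- function(rule) {
  stopifnot(inherits(rule, "replacement_rule"), rule$kind == "wright_fisher")
  marginal_rates(rule$parent_probs)
}
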