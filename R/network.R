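# Spread-of-ideas pipeline: directed follower networks -> substitution rates.
#
# A new idea is a neutral mutation: at each time-step one followee-follower
# link is chosen uniformly among the L links and the follower either copies
# the followee's idea or (with probability u << 1) innovates. This is the
# replacement structure e[i, j] = 1/L on each information-flow edge i -> j,
# so K/u depends only on the network topology.

#' Read a directed edge list
#'
#' Parses a whitespace- or tab-delimited file of integer pairs, one edge
#' per line (the SNAP ego-network `.edges` dialect). Edges are stored in
#' the direction of information flow (followee to follower) regardless of
#' the input convention; duplicate edges are collapsed and self-loops
#' dropped.
#'
#' @param path file path.
#' @param direction `"source_follows_target"` if a line `a b` means `a`
#'   follows `b` (so information flows `b -> a`; the SNAP convention), or
#'   `"source_followed_by_target"` if it means `b` follows `a` (flow
#'   `a -> b`).
#' @return An object of class `"directed_network"`: list with `node_ids`
#'   (sorted original labels), `edges` (two-column matrix of original
#'   labels, flow direction), `L` (edge count).
#' @export
read_edge_list <- function(path,
                           direction = c("source_follows_target",
                                         "source_followed_by_target")) {
  direction <- match.arg(direction)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty edge-list file: ", path)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 2L)
  if (length(bad) > 0) {
    stop("malformed edge list line ", lineno[bad[1]], " in ", path,
         ": expected two fields, got ", n_fields[bad[1]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 2, byrow = TRUE)
  if (any(is.na(m))) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("malformed edge list line ", lineno[bad], " in ", path,
         ": non-numeric field")
  }
  directed_network(src = m[, 1], dst = m[, 2], direction = direction)
}

#' @rdname read_edge_list
#' @param src,dst vectors of node labels, one edge per element.
#' @export
directed_network <- function(src, dst,
                             direction = c("source_follows_target",
                                           "source_followed_by_target")) {
  direction <- match.arg(direction)
  stopifnot(length(src) == length(dst))
  if (direction == "source_follows_target") {
    edges <- cbind(dst, src)   # flow followee -> follower
  } else {
    edges <- cbind(src, dst)
  }
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]  # self-loops out
  edges <- unique(edges)
  if (nrow(edges) == 0L) stop("no edges left after removing self-loops")
  dimnames(edges) <- NULL
  structure(
    list(node_ids = sort(unique(as.vector(edges))),
         edges = edges,
         L = nrow(edges)),
    class = "directed_network"
  )
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("Directed network: %d nodes, %d flow edges\n",
              length(x$node_ids), x$L))
  invisible(x)
}

# Eigenvector centrality on the flow digraph: a node's centrality is the
# sum of the centralities of the nodes it feeds (its followers), so
# influential sources of information score highest and the pruning root
# can reach the rest of the network via outgoing links. Power iteration
# with a uniform 1e-8 teleport term for convergence on reducible graphs;
# ties broken by the smallest original node id.
flow_eigen_centrality <- function(adj, teleport = 1e-8, tol = 1e-13,
                                  max_iter = 100000L) {
  n <- nrow(adj)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.vector(adj %*% x) + teleport * mean(x)
    s <- sum(x_new)
    if (s <= 0) return(x)  # no edges; uniform
    x_new <- x_new / s
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

#' Prune an ego network and build its replacement structure
#'
#' Applies the preprocessing used for follower-network ensembles: find the
#' node with greatest eigenvector centrality on the flow digraph, discard
#' every node not reachable from it via outgoing links (so fixation is
#' possible), then assign each surviving flow edge `i -> j` the rate
#' `e[i, j] = 1/L`, where `L` is the surviving edge count. The resulting
#' structure has total rate `B = 1` and passes
#' [assert_fixation_possible()].
#'
#' @param net a [directed_network()].
#' @return a [marginal_rates()] object with attributes `node_ids` (the
#'   retained original labels, in matrix order), `root_id` (the
#'   max-centrality node), and `n_raw` (node count before pruning).
#'   Networks reduced to a single node raise an error of class
#'   `"molclock_degenerate"` (reported and skipped by
#'   [ensemble_summary()]).
#' @export
preprocess_ego_network <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  ids <- net$node_ids
  n <- length(ids)
  idx <- match(net$edges, ids)
  dim(idx) <- dim(net$edges)
  adj <- matrix(0, n, n)
  adj[idx] <- 1
  cent <- flow_eigen_centrality(adj)
  top <- which(cent >= max(cent) - 1e-12)
  root <- top[which.min(ids[top])]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  kept <- sort(as.integer(igraph::subcomponent(g, root, mode = "out")))
  if (length(kept) < 2L) {
    stop(structure(
      class = c("molclock_degenerate", "error", "condition"),
      list(message = paste0("degenerate network: pruning from root node ",
                            ids[root], " leaves a single site"),
           call = sys.call())
    ))
  }
  sub <- adj[kept, kept, drop = FALSE]
  L <- sum(sub)
  rates <- marginal_rates(sub / L)
  attr(rates, "node_ids") <- ids[kept]
  attr(rates, "root_id") <- ids[root]
  attr(rates, "n_raw") <- n
  rates
}

#' Idea substitution rate of a preprocessed network
#'
#' For the uniform-link model (`B = 1`, `d_i` = in-degree / `L`), the
#' substitution rate per generation in units of the innovation rate `u`
#' is `K/u = N * sum_i d_i * rho_i`.
#'
#' @param rates a [marginal_rates()] object, typically from
#'   [preprocess_ego_network()].
#' @return scalar `K/u`.
#' @export
network_clock <- function(rates) {
  stopifnot(inherits(rates, "marginal_rates"))
  profile <- solve_fixation(rates)
  d <- death_rates(rates)
  rates$n_sites * sum(d * profile$site_probs) / total_rate(rates)
}

#' Ensemble statistics over a collection of networks
#'
#' Preprocesses each network (degenerate ones are skipped with a message),
#' computes `K/u` for each, and summarizes the ensemble: mean and sample
#' standard deviation of `K/u`, the count of accelerating networks
#' (`K/u > 1`, strict), the ordinary least-squares slope of `K/u` on
#' network size `N` with a seeded percentile-bootstrap confidence interval
#' (resampling networks with replacement), and the Pearson correlation.
#'
#' @param networks list of [directed_network()] objects (or already
#'   preprocessed [marginal_rates()] objects).
#' @param n_bootstrap bootstrap replicates for the slope interval.
#' @param seed integer seed for the bootstrap.
#' @param min_n drop networks with fewer than `min_n` nodes after
#'   preprocessing before summarizing (robustness check; 0 keeps all).
#' @param conf confidence level of the percentile interval.
#' @return An object of class `"ensemble_summary"`: list with
#'   `per_network` (data frame: `id`, `n_raw`, `n`, `l`, `k_over_u`),
#'   `mean_k_over_u`, `sd_k_over_u`, `n_accelerated`, `slope`,
#'   `slope_ci`, `pearson_r`, `n_networks`, `n_skipped`.
#' @export
ensemble_summary <- function(networks, n_bootstrap = 10000L, seed = 1L,
                             min_n = 0L, conf = 0.95) {
  if (!is.list(networks) || length(networks) < 2L) {
    stop("need at least 2 networks")
  }
  stopifnot(n_bootstrap >= 1L)
  ids <- names(networks) %||% as.character(seq_along(networks))
  rows <- vector("list", length(networks))
  n_skipped <- 0L
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    rates <- if (inherits(net, "marginal_rates")) {
      net
    } else {
      tryCatch(preprocess_ego_network(net),
               molclock_degenerate = function(cond) {
                 message("skipping ", ids[k], ": ", conditionMessage(cond))
                 NULL
               })
    }
    if (is.null(rates)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[k]] <- data.frame(
      id = ids[k],
      n_raw = attr(rates, "n_raw") %||% rates$n_sites,
      n = rates$n_sites,
      l = sum(rates$rates > 0),
      k_over_u = network_clock(rates)
    )
  }
  per_network <- do.call(rbind, rows)
  per_network <- per_network[per_network$n >= min_n, , drop = FALSE]
  if (is.null(per_network) || nrow(per_network) < 2L) {
    stop("need at least 2 non-degenerate networks")
  }
  k <- per_network$k_over_u
  n <- per_network$n
  fit <- lm(k ~ n)
  slope <- unname(coef(fit)[2])
  boot_slopes <- with_local_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      take <- sample.int(nrow(per_network), replace = TRUE)
      if (length(unique(n[take])) < 2L) return(NA_real_)
      unname(coef(lm(k[take] ~ n[take]))[2])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_slopes, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(
    list(per_network = per_network,
         mean_k_over_u = mean(k),
         sd_k_over_u = sd(k),
         n_accelerated = sum(k > 1),
         slope = slope,
         slope_ci = ci,
         pearson_r = if (sd(n) > 0 && sd(k) > 0) cor(n, k) else NA_real_,
         n_networks = nrow(per_network),
         n_skipped = n_skipped),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble of %d networks (%d skipped as degenerate)\n",
              x$n_networks, x$n_skipped))
  cat(sprintf("  K/u: mean %.4g, sd %.4g; %d network(s) with K/u > 1\n",
              x$mean_k_over_u, x$sd_k_over_u, x$n_accelerated))
  cat(sprintf("  slope of K/u on N: %.4g, CI (%.4g, %.4g); Pearson r %.3g\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$pearson_r))
  invisible(x)
}

#' Random ego-like directed networks
#'
#' Generates a small directed Erdos-Renyi-style graph for exercising the
#' network pipeline: each ordered pair receives an edge independently.
#' Useful for synthetic ensembles; it reproduces the format, not the
#' degree heterogeneity, of real follower networks.
#'
#' @param n_nodes node count (>= 2).
#' @param p_edge edge probability per ordered pair.
#' @param seed integer seed.
#' @return a [directed_network()] (resampled until at least one edge
#'   exists).
#' @export
random_ego_network <- function(n_nodes, p_edge = 0.25, seed) {
  check_positive_int(n_nodes, "n_nodes")
  if (n_nodes < 2) stop("need n_nodes >= 2")
  with_local_seed(seed, {
    repeat {
      a <- matrix(runif(n_nodes^2) < p_edge, n_nodes, n_nodes)
      diag(a) <- FALSE
      if (any(a)) break
    }
    idx <- which(a, arr.ind = TRUE)
    directed_network(src = idx[, 1], dst = idx[, 2],
                     direction = "source_followed_by_target")
  })
}
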