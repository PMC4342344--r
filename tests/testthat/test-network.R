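write_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".edges",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge lists are oriented followee-to-follower on read", {
  path <- write_edges(c("1 2", "2 3", "3 1"))
  net <- read_edge_list(path, direction = "source_follows_target")
  expect_setequal(paste(net$edges[, 1], net$edges[, 2]),
                  c("2 1", "3 2", "1 3"))
  net2 <- read_edge_list(path, direction = "source_followed_by_target")
  expect_setequal(paste(net2$edges[, 1], net2$edges[, 2]),
                  c("1 2", "2 3", "3 1"))
})

test_that("self-loops and duplicate edges are dropped with set semantics", {
  path <- write_edges(c("1 2", "5 5", "1 2", "2 1"))
  net <- read_edge_list(path)
  expect_equal(net$L, 2)
  expect_false(5 %in% net$node_ids)
})

test_that("malformed and empty edge files are reported precisely", {
  bad <- write_edges(c("1 2", "3", "4 5"))
  expect_error(read_edge_list(bad), "line 2")
  nonnum <- write_edges(c("1 2", "a b"))
  expect_error(read_edge_list(nonnum), "line 2")
  empty <- write_edges(character(0))
  expect_error(read_edge_list(empty), "empty")
  loops_only <- write_edges("3 3")
  expect_error(read_edge_list(loops_only), "self-loops")
})

test_that("a directed cycle keeps all nodes and runs at the well-mixed rate", {
  net <- directed_network(src = c(1, 2, 3), dst = c(2, 3, 1),
                          direction = "source_followed_by_target")
  rates <- preprocess_ego_network(net)
  expect_equal(rates$n_sites, 3)
  expect_close(rates$rates[rates$rates > 0], rep(1 / 3, 3))
  expect_close(death_rates(rates), rep(1 / 3, 3))
  expect_close(network_clock(rates), 1, tol = 1e-10)
})

test_that("an out-star is kept whole but cannot substitute ideas", {
  net <- directed_network(src = c(1, 1, 1), dst = c(2, 3, 4),
                          direction = "source_followed_by_target")
  rates <- preprocess_ego_network(net)
  expect_equal(rates$n_sites, 4)
  prof <- solve_fixation(rates)
  root_pos <- which(attr(rates, "node_ids") == 1)
  expect_close(prof$site_probs[root_pos], 1)
  expect_close(network_clock(rates), 0, tol = 1e-12)
})

test_that("pruning keeps only what the top-centrality node can reach", {
  # two disjoint dyads; only the root's component survives
  net <- directed_network(src = c(1, 2, 3, 4), dst = c(2, 1, 4, 3),
                          direction = "source_followed_by_target")
  rates <- preprocess_ego_network(net)
  expect_equal(rates$n_sites, 2)
  kept <- attr(rates, "node_ids")
  expect_true(all(kept %in% c(1, 2)) || all(kept %in% c(3, 4)))

  # a common followee feeding two followers keeps all three nodes
  lonely <- directed_network(src = c(1, 3), dst = c(2, 2),
                             direction = "source_follows_target")
  expect_equal(preprocess_ego_network(lonely)$n_sites, 3)
  chain <- directed_network(src = c(2, 1), dst = c(1, 3),
                            direction = "source_followed_by_target")
  expect_equal(preprocess_ego_network(chain)$n_sites, 3)
})

test_that("preprocessed networks always have unit total rate and solvable structure", {
  for (s in 1:15) {
    net <- random_ego_network(sample(4:12, 1), p_edge = 0.3, seed = 700 + s)
    rates <- tryCatch(preprocess_ego_network(net),
                      molclock_degenerate = function(c) NULL)
    if (is.null(rates)) next
    expect_close(total_rate(rates), 1, tol = 1e-12)
    prof <- solve_fixation(rates)
    expect_equal(sum(prof$site_probs), 1, tolerance = 1e-10)
    k <- network_clock(rates)
    expect_lt(k, rates$n_sites)
    expect_gte(k, 0)
    # uniform in-degree forces the well-mixed rate
    d <- death_rates(rates)
    if (max(abs(d - mean(d))) < 1e-12) {
      expect_close(k, 1, tol = 1e-8)
    }
  }
})

test_that("symmetric digraphs run at the well-mixed rate, asymmetric ones need not", {
  # complete digraph on 4 nodes: every ordered pair
  pairs <- expand.grid(src = 1:4, dst = 1:4)
  pairs <- pairs[pairs$src != pairs$dst, ]
  net <- directed_network(pairs$src, pairs$dst,
                          direction = "source_followed_by_target")
  expect_close(network_clock(preprocess_ego_network(net)), 1, tol = 1e-10)

  # reversing all edges changes K/u when the graph is asymmetric
  net_fwd <- directed_network(src = c(1, 1, 1, 2, 3, 4),
                              dst = c(2, 3, 4, 3, 4, 1),
                              direction = "source_followed_by_target")
  net_rev <- directed_network(src = c(2, 3, 4, 3, 4, 1),
                              dst = c(1, 1, 1, 2, 3, 4),
                              direction = "source_followed_by_target")
  k_fwd <- network_clock(preprocess_ego_network(net_fwd))
  k_rev <- network_clock(preprocess_ego_network(net_rev))
  expect_gt(abs(k_fwd - k_rev), 1e-6)
})

test_that("ensemble summaries compute the documented statistics", {
  cyc <- function() directed_network(src = c(1, 2, 3), dst = c(2, 3, 1),
                                     direction = "source_followed_by_target")
  two <- ensemble_summary(list(a = cyc(), b = cyc()), n_bootstrap = 10,
                          seed = 1)
  expect_equal(two$mean_k_over_u, 1, tolerance = 1e-10)
  expect_equal(two$sd_k_over_u, 0, tolerance = 1e-10)
  expect_equal(two$n_accelerated, 0)

  nets <- lapply(1:12, function(s) random_ego_network(4 + s %% 6, 0.35,
                                                      seed = 800 + s))
  summ <- ensemble_summary(nets, n_bootstrap = 200, seed = 5)
  expect_equal(summ$n_networks + summ$n_skipped -
                 sum(summ$per_network$n < 0), length(nets))
  expect_gte(summ$sd_k_over_u, 0)
  expect_lte(summ$slope_ci[1], summ$slope)
  expect_gte(summ$slope_ci[2], summ$slope)
  expect_equal(summ$n_accelerated, sum(summ$per_network$k_over_u > 1))
  expect_error(ensemble_summary(nets[1], n_bootstrap = 10, seed = 1),
               "at least 2")
})

test_that("ensemble summaries are reproducible bit-for-bit from the seed", {
  nets <- lapply(1:10, function(s) random_ego_network(5 + s %% 4, 0.3,
                                                      seed = 900 + s))
  s1 <- ensemble_summary(nets, n_bootstrap = 300, seed = 77)
  s2 <- ensemble_summary(nets, n_bootstrap = 300, seed = 77)
  expect_identical(s1, s2)
})

test_that("the minimum-size filter drops small networks from the summary", {
  nets <- c(
    lapply(1:6, function(s) random_ego_network(12, 0.3, seed = 1000 + s)),
    lapply(1:6, function(s) random_ego_network(4, 0.5, seed = 1100 + s))
  )
  all_nets <- ensemble_summary(nets, n_bootstrap = 50, seed = 2)
  big_only <- ensemble_summary(nets, n_bootstrap = 50, seed = 2, min_n = 10)
  expect_lt(big_only$n_networks, all_nets$n_networks)
  expect_true(all(big_only$per_network$n >= 10))
})
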