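make_toy_samples <- function(n = 5, len = 400, seed = 41) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i)
    sample(paste0("w", 1:60), len, TRUE, prob = (1:60)^-(0.5 + 0.2 * i)))
  names(out) <- paste0("U", seq_len(n), "_F1")
  out
}

test_that("consensus network accumulation equals the brute-force oracle", {
  samples <- make_toy_samples()
  net <- run_bcn(samples, sweep = c(20L, 40L), k_nn = 2L)
  expect_equal(net$weights, oracle_bcn_weights(samples, c(20, 40), 2))
  expect_equal(net$runs, 2L)

  # 3 nodes, k_nn = 1, one run: 3 directed picks fold into <= 3 edges
  s3 <- make_toy_samples(3, seed = 43)
  net3 <- run_bcn(s3, sweep = 25L, k_nn = 1L)
  n_edges <- sum(net3$weights[upper.tri(net3$weights)] > 0)
  expect_lte(n_edges, 3)
  expect_gte(n_edges, 2)
})

test_that("weight conservation holds exactly and repetition doubles weights", {
  samples <- make_toy_samples(6, seed = 47)
  k_nn <- 3L
  net <- run_bcn(samples, sweep = c(10L, 30L, 50L), k_nn = k_nn)
  expect_equal(sum(net$weights) / 2,
               net$runs * length(samples) * sum(net$rank_weights))
  # edges accumulate additively across runs: the sweep equals the sum of its
  # single-size runs, and repeating a run doubles every edge weight
  singles <- lapply(c(10L, 30L, 50L), function(sz)
    run_bcn(samples, sweep = sz, k_nn = k_nn)$weights)
  expect_equal(net$weights, Reduce(`+`, singles))

  # sweep sizes beyond the available features are skipped with a warning
  expect_warning(net3 <- run_bcn(samples, sweep = c(10L, 30L, 100000L), k_nn = 2L),
                 "skipped")
  expect_equal(net3$runs, 2L)
  expect_equal(sum(net3$weights) / 2, 2 * length(samples) * (2 + 1))

  # symmetry and no self-loops
  expect_equal(net$weights, t(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 6))
})

test_that("the edge table sorts links by weight with red-line annotation", {
  W <- matrix(0, 4, 4)
  labs <- c("U1_F1", "U1_F2", "U2_F1", "U2_F2")
  dimnames(W) <- list(labs, labs)
  W["U1_F1", "U1_F2"] <- W["U1_F2", "U1_F1"] <- 5
  W["U1_F1", "U2_F1"] <- W["U2_F1", "U1_F1"] <- 9
  net <- structure(list(weights = W, nodes = labs, runs = 1L, k_nn = 2L,
                        rank_weights = c(2, 1), sweep_used = 100L),
                   class = "costylo_bcn")
  et <- edge_table(net, parse_labels(labs))
  col <- et[et$focal == "U1_F1", ]
  expect_equal(col$other, c("U2_F1", "U1_F2"))  # manual sort by weight
  expect_equal(col$weight, c(9, 5))
  expect_equal(unique(col$red_line), 1L)        # two texts share F1
  # isolated node contributes no rows
  expect_false("U2_F2" %in% et$focal)
})

test_that("category summary tallies links and weight shares like a hand count", {
  W <- matrix(0, 4, 4)
  labs <- c("U1_F1", "U1_F2", "U2_F1", "U2_F2")
  dimnames(W) <- list(labs, labs)
  W["U1_F1", "U1_F2"] <- W["U1_F2", "U1_F1"] <- 4   # same user
  W["U1_F1", "U2_F1"] <- W["U2_F1", "U1_F1"] <- 6   # same facilitator
  W["U1_F1", "U2_F2"] <- W["U2_F2", "U1_F1"] <- 2   # neither
  net <- structure(list(weights = W, nodes = labs), class = "costylo_bcn")
  cs <- category_summary(net, parse_labels(labs))
  expect_equal(cs$links, c(1L, 1L, 1L))
  expect_equal(cs$total_weight, c(4, 6, 2))
  expect_equal(cs$weight_share, 100 * c(4, 6, 2) / 12)
  expect_equal(sum(cs$weight_share), 100)
  # one-edge network: that category has share 100
  W2 <- W * 0; W2["U1_F1", "U1_F2"] <- W2["U1_F2", "U1_F1"] <- 3
  net2 <- structure(list(weights = W2, nodes = labs), class = "costylo_bcn")
  cs2 <- category_summary(net2, parse_labels(labs))
  expect_equal(cs2$weight_share[cs2$category == "same_user"], 100)

  # realized links are bounded by the theoretical maxima
  pl <- possible_links(parse_labels(labs))
  expect_true(all(cs$links <= pl$pairs[cs$category]))
})

test_that("possible links match exhaustive pair enumeration", {
  meta <- toy_meta()
  pl <- possible_links(meta)
  # exhaustive enumeration over ordered pairs
  cnt <- c(same_user = 0L, same_facilitator = 0L, neither = 0L)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    if (meta$user[i] == meta$user[j]) cnt["same_user"] <- cnt["same_user"] + 1L
    else if (meta$facilitator[i] == meta$facilitator[j])
      cnt["same_facilitator"] <- cnt["same_facilitator"] + 1L
    else cnt["neither"] <- cnt["neither"] + 1L
  }
  expect_equal(pl$slots, cnt)
  expect_equal(sum(pl$slots), 6 * 5)
  # single-facilitator corpus of t texts: t(t-1)/2 unordered pairs
  meta1 <- parse_labels(paste0("U", 1:5, "_F1"))
  expect_equal(unname(possible_links(meta1)$pairs["same_facilitator"]),
               5 * 4 / 2)
})

test_that("graph export round-trips edges and weights", {
  samples <- make_toy_samples(5, seed = 51)
  net <- run_bcn(samples, sweep = c(15L, 30L), k_nn = 2L)
  g <- bcn_igraph(net)
  expect_equal(igraph::vcount(g), 5)
  el <- igraph::as_data_frame(g)
  for (r in seq_len(nrow(el))) {
    expect_equal(el$weight[r], net$weights[el$from[r], el$to[r]])
  }
  f <- withr::local_tempfile(fileext = ".graphml")
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_bcn(net, graphml = f, edges_csv = fcsv)
  expect_true(file.exists(f) && file.exists(fcsv))
  back <- utils::read.csv(fcsv)
  expect_equal(nrow(back), igraph::ecount(g))
})
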