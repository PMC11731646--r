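test_that("rank columns equal an exhaustive sort oracle", {
  meta <- toy_meta()
  set.seed(31)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(meta$label, meta$label)
  rt <- build_rank_table(d, meta)

  for (i in seq_len(6)) {
    col <- rt[rt$focal == meta$label[i], ]
    # brute force: sort the other distances
    dd <- d[-i, i]
    expect_equal(col$other, names(sort(dd)))
    expect_equal(col$rank, 1:5)
    expect_equal(col$distance, unname(sort(dd)))
    # red line from the focal facilitator's text count
    n_f <- sum(meta$facilitator == meta$facilitator[i])
    expect_equal(unique(col$red_line), n_f - 1L)
    # flags against direct metadata comparison
    expect_equal(col$same_user, meta$user[match(col$other, meta$label)] ==
                   meta$user[i])
  }

  # labels without metadata are a hard error
  expect_error(build_rank_table(d, meta[-1, ]), "without metadata")

  # 2-text corpus: a single rank-1 entry per column
  d2 <- d[1:2, 1:2]
  rt2 <- build_rank_table(d2, meta)
  expect_equal(nrow(rt2), 2)
  expect_equal(rt2$rank, c(1L, 1L))
})

test_that("distance ties are broken by label, deterministically", {
  meta <- toy_meta()
  d <- matrix(1, 6, 6, dimnames = list(meta$label, meta$label))
  diag(d) <- 0
  rt <- build_rank_table(d, meta)
  col <- rt[rt$focal == "U3_F3", ]
  expect_equal(col$other, sort(setdiff(meta$label, "U3_F3")))
  expect_identical(rt, build_rank_table(d, meta))
})

test_that("red-line summary equals direct enumeration on randomized rankings", {
  meta <- toy_meta()
  set.seed(55)
  for (rep in 1:10) {
    pts <- matrix(rnorm(12), 6, 2)
    d <- as.matrix(dist(pts)); dimnames(d) <- list(meta$label, meta$label)
    rt <- build_rank_table(d, meta)
    s <- red_line_summary(rt)
    brute <- 0L; t3 <- 0L
    for (i in 1:6) {
      col <- rt[rt$focal == meta$label[i], ]
      same <- which(meta$user[match(col$other, meta$label)] == meta$user[i])
      brute <- brute + sum(col$rank[same] <= col$red_line[1])
      t3 <- t3 + sum(col$rank[same] <= 3)
    }
    expect_equal(s$breaches, brute)
    expect_equal(s$top3, t3)
    expect_equal(s$denominator, 6L)  # each user has 2 texts -> 1 partner each
    expect_true(s$top3 <= s$top5 && s$top5 <= s$top10)
    expect_lte(s$breaches, s$denominator)
  }

  # all same-user texts ranked last -> zero breaches
  meta2 <- data.frame(label = c("U1_F1", "U2_F1", "U3_F1", "U1_F2"),
                      user = c("U1", "U2", "U3", "U1"),
                      facilitator = c("F1", "F1", "F1", "F2"))
  d <- matrix(c(0, 1, 2, 9,
                1, 0, 1, 9,
                2, 1, 0, 9,
                9, 9, 9, 0), 4, byrow = TRUE,
              dimnames = list(meta2$label, meta2$label))
  s <- red_line_summary(build_rank_table(d, meta2))
  expect_equal(s$breaches, 0L)
})

test_that("summary counts are invariant to distance-table permutation", {
  meta <- toy_meta()
  set.seed(77)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  dimnames(d) <- list(meta$label, meta$label)
  s1 <- red_line_summary(build_rank_table(d, meta))
  p <- sample(6)
  s2 <- red_line_summary(build_rank_table(d[p, p], meta))
  expect_equal(s1, s2)
})

test_that("the uniform-null closed form matches its hypergeometric anchors", {
  # single column with m = 2, r = 9, M = 27 -> expectation 2/3
  meta <- rbind(
    data.frame(label = paste0("U", 1:10, "_F1"), user = paste0("U", 1:10),
               facilitator = "F1"),
    data.frame(label = c("U1_F2", "U1_F3"), user = "U1",
               facilitator = c("F2", "F3")),
    data.frame(label = paste0("V", 1:16, "_G", 1:16), user = paste0("V", 1:16),
               facilitator = paste0("G", 1:16))
  )
  nn <- null_expected_breaches(meta)
  col <- nn$per_column[nn$per_column$label == "U1_F1", ]
  expect_equal(col$m, 2L)
  expect_equal(col$r, 9L)
  expect_equal(col$M, 27L)
  expect_equal(col$expectation, 2 / 3)
  # a facilitator with a single text has r = 0 and expectation 0
  col0 <- nn$per_column[nn$per_column$label == "V1_G1", ]
  expect_equal(col0$r, 0L)
  expect_equal(col0$expectation, 0)
  expect_equal(col0$variance, 0)
})

test_that("uniformly shuffled rankings reproduce the uniform-null expectation", {
  meta <- generate_corpus(center2_design(), lambda = 0, words_per_pair = 4,
                          V = 50, seed = 1)$meta
  nn <- null_expected_breaches(meta)
  set.seed(99)
  n_mc <- 2000
  totals <- numeric(n_mc)
  fac_n <- table(meta$facilitator)
  for (it in seq_len(n_mc)) {
    tot <- 0L
    for (i in seq_len(nrow(meta))) {
      m <- sum(meta$user == meta$user[i]) - 1L
      r <- fac_n[[meta$facilitator[i]]] - 1L
      M <- nrow(meta) - 1L
      pos <- sample.int(M, m)  # uniform ranks of the same-user texts
      tot <- tot + sum(pos <= r)
    }
    totals[it] <- tot
  }
  se <- sd(totals) / sqrt(n_mc)
  expect_lt(abs(mean(totals) - nn$total_expectation), 3 * se)
  expect_lt(abs(var(totals) - nn$total_variance), 0.1 * nn$total_variance)
})

test_that("the conditional null reduces to exchangeability of same-user flags", {
  meta <- toy_meta()
  set.seed(123)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  dimnames(d) <- list(meta$label, meta$label)
  rt <- build_rank_table(d, meta)
  cn <- conditional_null_breaches(rt, n_draws = 20000)
  # oracle: per column, expected breaches = m * B / C
  exp_brute <- 0
  for (f in unique(rt$focal)) {
    col <- rt[rt$focal == f, ]
    cross <- !col$same_facilitator
    B <- sum(cross & col$rank <= col$red_line)
    exp_brute <- exp_brute + sum(col$same_user) * B / sum(cross)
  }
  expect_equal(cn$expectation, exp_brute, tolerance = 1e-12)
  expect_lt(abs(mean(cn$draws) - exp_brute), 4 * sd(cn$draws) / sqrt(20000))
  expect_true(cn$interval[1] <= cn$interval[2])
})
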