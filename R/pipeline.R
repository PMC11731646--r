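#' Chunked-text clustering workflow (single-facilitator corpora)
#'
#' Runs the chunking study end to end: every pair text is cut into four
#' quarters and recombined under schemes A, B and C; each chunk corpus is
#' profiled with most-frequent words and character trigrams, z-scored,
#' turned into a cosine-delta table, clustered, and scored for same-user
#' leaf pairing. Pairs whose chunks would fall at or below `min_chunk_words`
#' tokens are excluded first (the analysis needs every half-text to clear
#' the same length floor as a full text).
#'
#' @param samples named list of token vectors, one per pair text; names are
#'   the pair labels (`<user>_<facilitator>`).
#' @param meta metadata table covering the labels.
#' @param mfw number of most frequent features (default 1000).
#' @param ngram character n-gram length (default 3).
#' @param schemes subset of `c("A","B","C")`.
#' @param modes subset of `c("word", "char_ngram")`.
#' @param linkage clustering linkage (default `"ward.D2"`).
#' @param min_chunk_words chunk length floor (strict; default 5000).
#' @param out_dir optional directory for CSV/newick/JSON outputs.
#' @return nested list: `results[[scheme]][[mode]]` each with `distance`,
#'   `hclust`, `newick`, `pairing` (from [same_user_leaf_pairing()]);
#'   plus `excluded` (labels dropped by the length filter) and
#'   `chunk_meta`.
#' @export
run_study1 <- function(samples, meta, mfw = 1000L, ngram = 3L,
                       schemes = c("A", "B", "C"),
                       modes = c("word", "char_ngram"),
                       linkage = "ward.D2", min_chunk_words = 5000L,
                       out_dir = NULL) {
  meta <- check_metadata(meta, names(samples))
  half <- vapply(samples, length, integer(1)) %/% 2L
  keep <- half > min_chunk_words
  excluded <- names(samples)[!keep]
  if (length(excluded) > 0L) {
    message("excluded from chunk analysis (chunks too short): ",
            paste(excluded, collapse = ", "))
  }
  samples <- samples[keep]
  meta <- meta[keep, , drop = FALSE]
  if (length(samples) < 2L) {
    stop(errorCondition("fewer than two pairs clear the chunk length filter",
                        class = c("costylo_empty_analysis", "error")))
  }
  results <- list()
  chunk_meta <- NULL
  for (scheme in schemes) {
    chunks <- list(); users <- character(0)
    for (i in seq_along(samples)) {
      cp <- chunk_four_way(samples[[i]], scheme)
      lab <- paste(meta$user[i], cp$labels, sep = "_")
      chunks[[lab[1L]]] <- cp$chunk1
      chunks[[lab[2L]]] <- cp$chunk2
      users <- c(users, stats::setNames(rep(meta$user[i], 2L), lab))
    }
    chunk_meta <- rbind(chunk_meta, data.frame(
      scheme = scheme, label = names(chunks),
      user = users[names(chunks)],
      word_count = vapply(chunks, length, integer(1)),
      stringsAsFactors = FALSE))
    results[[scheme]] <- list()
    for (mode in modes) {
      freq <- suppressWarnings(
        extract_features(chunks, mode = mode, k = mfw, n = ngram))
      z <- suppressMessages(zscore_matrix(freq))
      d <- cosine_delta(z)
      hc <- hcluster_delta(d, linkage)
      pairing <- same_user_leaf_pairing(hc, users)
      nwk <- as_newick(hc)
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        stem <- file.path(out_dir, paste0("study1_", scheme, "_", mode))
        write_distance_csv(d, paste0(stem, "_distance.csv"))
        writeLines(nwk, paste0(stem, ".nwk"))
      }
      results[[scheme]][[mode]] <- list(distance = d, hclust = hc,
                                        newick = nwk, pairing = pairing)
    }
  }
  out <- list(results = results, excluded = excluded, chunk_meta = chunk_meta)
  if (!is.null(out_dir)) {
    rates <- unlist(lapply(results, function(s)
      lapply(s, function(m) m$pairing$rate)))
    jsonlite::write_json(as.list(rates),
                         file.path(out_dir, "study1_pairing.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Multi-facilitator rank, group and network workflow
#'
#' The full second-study pipeline on a multi-facilitator pair corpus:
#' most-frequent-word cosine-delta distance table; per-text neighbour
#' ranking with the facilitator red line, breach/top-k summary and both
#' permutation nulls; five-group pair-relationship statistics with
#' one-sample tests (against the neutral value 1 and the corpus mean),
#' iterated equal-size subsample tests of IU against every other group, and
#' cross-validated classification of the pair distances; and the bootstrap
#' consensus network with its edge table, category summary and theoretical
#' link maxima.
#'
#' @param samples named list of token vectors, one per pair text.
#' @param meta metadata table covering the labels.
#' @param simmap similarity map (named list); required for the group
#'   analysis.
#' @param mfw most-frequent-word count for the distance table (default
#'   1000).
#' @param sweep,k_nn consensus-network sweep and neighbour count, see
#'   [run_bcn()].
#' @param linkage clustering linkage for the dendrogram.
#' @param seed integer seed controlling the subsample tests and
#'   classification folds.
#' @param out_dir optional directory for CSV/JSON/newick/GraphML outputs.
#' @return list with `distance`, `hclust`, `ranks`, `summary`, `null`
#'   (closed-form uniform null), `conditional_null`, `relations`, `groups`,
#'   `one_sample`, `iterated`, `classification`, `bcn`, `edges`,
#'   `categories`, `possible`, and `report` (flat named list of the
#'   headline statistics).
#' @export
run_study2 <- function(samples, meta, simmap, mfw = 1000L,
                       sweep = seq(100L, 5000L, by = 100L), k_nn = 3L,
                       linkage = "ward.D2", seed = 1L, out_dir = NULL) {
  meta <- check_metadata(meta, names(samples))
  freq <- suppressWarnings(extract_features(samples, mode = "word", k = mfw))
  z <- suppressMessages(zscore_matrix(freq))
  d <- cosine_delta(z)
  hc <- hcluster_delta(d, linkage)
  ranks <- build_rank_table(d, meta, simmap)
  summ <- red_line_summary(ranks)
  null <- null_expected_breaches(meta)
  cnull <- conditional_null_breaches(ranks)
  relations <- pair_relations(meta, simmap)
  groups <- group_summary(d, relations)
  vals <- attr(groups, "values")
  mu2 <- mean(unlist(vals))
  one_sample <- lapply(vals[lengths(vals) >= 2L], function(v) {
    list(mu_neutral = one_sample_test(v, 1),
         mu_average = one_sample_test(v, mu2))
  })
  others <- setdiff(names(vals)[lengths(vals) >= 2L], "IU")
  iterated <- lapply(stats::setNames(others, others), function(g) {
    iterated_subsample_test(vals$IU, vals[[g]], reps = 10L, seed = seed)
  })
  ok_class <- all(table(relations$group) >= 5L)
  classification <- if (ok_class) {
    dv <- d[cbind(relations$other, relations$focal)]
    list(
      weighted_knn = classify_relations(dv, relations$group,
                                        "weighted-knn", seed = seed),
      svm = classify_relations(dv, relations$group, "svm", seed = seed)
    )
  } else NULL
  bcn <- suppressWarnings(run_bcn(samples, sweep = sweep, k_nn = k_nn))
  edges <- edge_table(bcn, meta, simmap)
  esum <- red_line_summary(edges)
  categories <- category_summary(bcn, meta)
  possible <- possible_links(meta)
  report <- list(
    n_texts = nrow(meta),
    breaches = summ$breaches, top3 = summ$top3, top5 = summ$top5,
    top10 = summ$top10, denominator = summ$denominator,
    first_among_facilitator = summ$first_among_facilitator,
    null_expected_breaches = null$total_expectation,
    conditional_null_expectation = cnull$expectation,
    bcn_breaches = esum$breaches, bcn_top3 = esum$top3,
    bcn_top5 = esum$top5,
    bcn_links = sum(categories$links),
    same_user_links = categories$links[categories$category == "same_user"],
    same_facilitator_links =
      categories$links[categories$category == "same_facilitator"],
    neither_links = categories$links[categories$category == "neither"],
    same_user_weight_share =
      categories$weight_share[categories$category == "same_user"],
    group_counts = stats::setNames(as.list(groups$n), groups$group),
    group_means = stats::setNames(as.list(groups$mean), groups$group),
    mu_average = mu2,
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_distance_csv(d, file.path(out_dir, "study2_distance.csv"))
    writeLines(as_newick(hc), file.path(out_dir, "study2.nwk"))
    write_rank_csv(ranks, file.path(out_dir, "study2_ranks_wide.csv"),
                   file.path(out_dir, "study2_ranks_long.csv"))
    utils::write.csv(groups, file.path(out_dir, "study2_groups.csv"),
                     row.names = FALSE)
    write_bcn(bcn, graphml = file.path(out_dir, "study2_bcn.graphml"),
              edges_csv = file.path(out_dir, "study2_bcn_edges.csv"))
    utils::write.csv(categories, file.path(out_dir, "study2_categories.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "study2_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(distance = d, hclust = hc, ranks = ranks, summary = summ, null = null,
       conditional_null = cnull, relations = relations, groups = groups,
       one_sample = one_sample, iterated = iterated,
       classification = classification, bcn = bcn, edges = edges,
       bcn_summary = esum, categories = categories, possible = possible,
       report = report)
}
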