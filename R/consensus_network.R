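#' Bootstrap consensus network over a feature-size sweep
#'
#' Repeats the distance analysis across a sweep of most-frequent-feature
#' vector sizes and accumulates, for every text, weighted links to its
#' nearest neighbours: at each sweep size the features are extracted,
#' z-scored and turned into a cosine-delta table, and each node adds weight
#' `w_j = k_nn + 1 - j` to the undirected edge with its j-th nearest
#' neighbour (ties broken by label). Edges accumulate across runs, so link
#' weight measures how persistently two texts are close, independent of any
#' single feature-vector size.
#'
#' @param samples named list of token vectors (or texts), as for
#'   [extract_features()].
#' @param sweep increasing vector of feature-vector sizes (default
#'   `seq(100, 5000, by = 100)`). Sizes exceeding the number of available
#'   distinct features are skipped with a warning.
#' @param k_nn neighbours per node per run (default 3).
#' @param weights per-rank weights, positive non-increasing; default
#'   `k_nn + 1 - j`.
#' @param mode,n feature mode and n-gram length, see [extract_features()].
#' @return object of class `costylo_bcn`: list with `weights` (symmetric
#'   node-by-node weight matrix, zero diagonal), `nodes`, `runs` (number of
#'   sweep sizes actually run), `k_nn`, `rank_weights`, `sweep_used`.
#' @export
run_bcn <- function(samples, sweep = seq(100L, 5000L, by = 100L),
                    k_nn = 3L, weights = NULL, mode = "word", n = 3L) {
  stopifnot(length(sweep) >= 1L, all(diff(sweep) > 0), k_nn >= 1L,
            length(samples) >= k_nn + 1L)
  if (is.null(weights)) weights <- k_nn + 1L - seq_len(k_nn)
  stopifnot(length(weights) == k_nn, all(weights > 0), all(diff(weights) <= 0))
  kmax <- max(sweep)
  freq <- suppressWarnings(
    extract_features(samples, mode = mode, k = kmax, n = n))
  avail <- ncol(freq)
  usable <- sweep[sweep <= avail]
  skipped <- sweep[sweep > avail]
  if (length(skipped) > 0L) {
    warning(sprintf("%d sweep size(s) exceed the %d available features; skipped",
                    length(skipped), avail))
  }
  nodes <- rownames(freq)
  nn <- length(nodes)
  W <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  for (size in usable) {
    z <- suppressMessages(zscore_matrix(freq[, seq_len(size), drop = FALSE]))
    d <- cosine_delta(z)
    for (i in seq_len(nn)) {
      others <- setdiff(seq_len(nn), i)
      ord <- others[order(d[others, i], nodes[others], method = "radix")]
      for (j in seq_len(k_nn)) {
        a <- i; b <- ord[j]
        W[a, b] <- W[a, b] + weights[j]
        W[b, a] <- W[b, a] + weights[j]
      }
    }
  }
  structure(list(weights = W, nodes = nodes, runs = length(usable),
                 k_nn = k_nn, rank_weights = weights, sweep_used = usable),
            class = "costylo_bcn")
}

#' Per-node ranked link table of a consensus network
#'
#' For each node, its linked texts sorted by descending accumulated weight
#' (ties broken by label), annotated with the same red-line convention as
#' the distance-table rank analysis: the line sits at `n - 1` where `n` is
#' the number of texts written with the node's facilitator.
#'
#' @param net a `costylo_bcn` object.
#' @param meta metadata table covering every node.
#' @param simmap optional similarity map for the `similar_user` flag.
#' @return long data.frame: `focal`, `other`, `rank`, `weight`,
#'   `other_user`, `other_facilitator`, `same_user`, `same_facilitator`,
#'   `similar_user`, `red_line`. Nodes without links contribute no rows.
#' @export
edge_table <- function(net, meta, simmap = NULL) {
  W <- net$weights
  meta <- check_metadata(meta, net$nodes)
  fac_n <- table(meta$facilitator)
  rows <- lapply(seq_along(net$nodes), function(i) {
    linked <- which(W[, i] > 0)
    linked <- setdiff(linked, i)
    if (length(linked) == 0L) return(NULL)
    ord <- linked[order(-W[linked, i], net$nodes[linked], method = "radix")]
    u <- meta$user[i]; f <- meta$facilitator[i]
    data.frame(
      focal = net$nodes[i],
      other = net$nodes[ord],
      rank = seq_along(ord),
      weight = W[ord, i],
      other_user = meta$user[ord],
      other_facilitator = meta$facilitator[ord],
      same_user = meta$user[ord] == u,
      same_facilitator = meta$facilitator[ord] == f,
      similar_user = if (is.null(simmap)) NA else meta$user[ord] %in% simmap[[u]],
      red_line = as.integer(fac_n[[f]]) - 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("costylo_ranks", "data.frame")
  out
}

#' Link and weight summary by relationship category
#'
#' Assigns every realized (weight > 0) undirected edge to exactly one of
#' three categories — same user, same facilitator, or neither — with
#' same-user taking precedence (in the reference design the two cannot
#' co-occur, since each user-facilitator pairing yields one text), and
#' reports link counts, total weight, weight share and mean weight per
#' category.
#'
#' @param net a `costylo_bcn` object.
#' @param meta metadata covering every node.
#' @return data.frame with one row per category: `category`, `links`,
#'   `total_weight`, `weight_share` (percent, summing to 100), `mean_weight`.
#' @export
category_summary <- function(net, meta) {
  W <- net$weights
  meta <- check_metadata(meta, net$nodes)
  nn <- length(net$nodes)
  ij <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  cat <- ifelse(meta$user[ij[, 1]] == meta$user[ij[, 2]], "same_user",
         ifelse(meta$facilitator[ij[, 1]] == meta$facilitator[ij[, 2]],
                "same_facilitator", "neither"))
  w <- W[ij]
  tot <- sum(w)
  out <- do.call(rbind, lapply(c("same_user", "same_facilitator", "neither"),
    function(g) {
      sel <- cat == g
      data.frame(category = g, links = sum(sel), total_weight = sum(w[sel]),
                 weight_share = if (tot > 0) 100 * sum(w[sel]) / tot else NA_real_,
                 mean_weight = if (any(sel)) mean(w[sel]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  out
}

#' Theoretical maximum links per relationship category
#'
#' Counts, from the design alone, how many links each category could in
#' principle realize. The primary counts are per-text link slots (each text
#' counted against every other text it could link to, i.e. ordered pairs:
#' a facilitator with `m` texts offers each of them `m - 1` same-facilitator
#' partners, contributing `m(m-1)` slots); unordered pair counts are given
#' alongside.
#'
#' @param meta metadata table (`label`, `user`, `facilitator`).
#' @return list with `slots` (named vector of ordered counts: `same_user`,
#'   `same_facilitator`, `neither`), `pairs` (unordered counts) and
#'   `per_facilitator` (ordered same-facilitator slots by facilitator).
#' @export
possible_links <- function(meta) {
  n <- nrow(meta)
  fac_n <- table(meta$facilitator)
  user_n <- table(meta$user)
  same_f_by_fac <- fac_n * (fac_n - 1)
  slots <- c(
    same_user = sum(user_n * (user_n - 1)),
    same_facilitator = sum(same_f_by_fac),
    neither = n * (n - 1) - sum(user_n * (user_n - 1)) - sum(same_f_by_fac)
  )
  list(slots = slots, pairs = slots / 2,
       per_facilitator = same_f_by_fac)
}

#' Convert a consensus network to an igraph object
#'
#' @param net a `costylo_bcn` object.
#' @return weighted undirected `igraph` graph.
#' @export
bcn_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write a consensus network to GraphML and/or an edge-list CSV
#'
#' @param net a `costylo_bcn` object.
#' @param graphml,edges_csv output paths (either may be `NULL`).
#' @export
write_bcn <- function(net, graphml = NULL, edges_csv = NULL) {
  g <- bcn_igraph(net)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges_csv)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("source", "target", "weight")
    utils::write.csv(el, edges_csv, row.names = FALSE)
  }
  invisible(g)
}
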