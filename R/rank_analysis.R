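#' Per-text neighbour ranking with the facilitator red line
#'
#' For every text (column) of a distance table, ranks all other texts by
#' ascending distance (ties broken by label, so the table is deterministic)
#' and annotates each neighbour with whether it shares the focal text's user
#' or facilitator and whether its user is stylistically similar to the focal
#' user. The "red line" of a column is `r = n - 1`, where `n` is the number
#' of texts written with the focal text's facilitator: under the hypothesis
#' that the facilitator is the sole stylistic source, only those `n - 1`
#' same-facilitator texts should occupy the first `n - 1` positions, and
#' same-user texts should rank randomly below the line. A same-user text at
#' rank `<= r` is a breach of that barrier.
#'
#' @param d distance matrix with labelled rows/columns.
#' @param meta data.frame mapping every label to `user` and `facilitator`
#'   (see [parse_labels()]).
#' @param simmap optional similarity map (named list, as
#'   [center2_similarity()]); when `NULL` the `similar_user` flag is `NA`.
#' @return long data.frame of class `costylo_ranks` with one row per
#'   (focal, neighbour) pair: `focal`, `other`, `rank`, `distance`,
#'   `same_user`, `same_facilitator`, `similar_user`, `red_line`.
#' @export
build_rank_table <- function(d, meta, simmap = NULL) {
  labels <- rownames(d)
  stopifnot(!is.null(labels), identical(labels, colnames(d)))
  meta <- check_metadata(meta, labels)
  fac_n <- table(meta$facilitator)
  rows <- lapply(seq_along(labels), function(i) {
    others <- setdiff(seq_along(labels), i)
    ord <- others[order(d[others, i], labels[others], method = "radix")]
    u <- meta$user[i]; f <- meta$facilitator[i]
    sim <- if (is.null(simmap)) NA else meta$user[ord] %in% simmap[[u]]
    data.frame(
      focal = labels[i],
      other = labels[ord],
      rank = seq_along(ord),
      distance = d[ord, i],
      other_user = meta$user[ord],
      other_facilitator = meta$facilitator[ord],
      same_user = meta$user[ord] == u,
      same_facilitator = meta$facilitator[ord] == f,
      similar_user = sim,
      red_line = as.integer(fac_n[[f]]) - 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("costylo_ranks", "data.frame")
  out
}

#' Red-line breach and top-rank summary
#'
#' Aggregates, over all same-user rank observations, how often texts of the
#' same user (written with a different facilitator) rank above the focal
#' column's facilitator line (`breaches`) and how often they land in the
#' first 1, 3, 5 and 10 positions. Also computes the first-among-facilitator
#' statistic: for every facilitator the focal text's user also wrote with,
#' whether that user's own text outranks all other texts sharing that
#' facilitator.
#'
#' @param ranks a rank table from [build_rank_table()].
#' @return list with `breaches`, `top1`, `top3`, `top5`, `top10`,
#'   `denominator` (number of same-user observations),
#'   `first_among_facilitator` and `first_denominator`.
#' @export
red_line_summary <- function(ranks) {
  su <- ranks$same_user
  res <- list(
    breaches = sum(su & ranks$rank <= ranks$red_line),
    top1 = sum(su & ranks$rank <= 1L),
    top3 = sum(su & ranks$rank <= 3L),
    top5 = sum(su & ranks$rank <= 5L),
    top10 = sum(su & ranks$rank <= 10L),
    denominator = sum(su)
  )
  # Fig-8-style statistic: within each foreign facilitator group of each
  # column, is the focal user's text the best-ranked member of that group?
  first <- 0L; denom <- 0L
  for (f in unique(ranks$focal)) {
    col <- ranks[ranks$focal == f, , drop = FALSE]
    foreign <- unique(col$other_facilitator[col$same_user])
    for (g in foreign) {
      grp <- col[col$other_facilitator == g, , drop = FALSE]
      denom <- denom + 1L
      if (grp$same_user[which.min(grp$rank)]) first <- first + 1L
    }
  }
  res$first_among_facilitator <- first
  res$first_denominator <- denom
  res
}

#' Expected red-line breaches under the uniform-ranking null
#'
#' Formalizes "texts rank at random" as a uniformly random permutation of
#' every column: with `M` non-focal texts of which `m` share the focal
#' text's user and a red line at `r`, the number of same-user texts in the
#' first `r` positions is hypergeometric with mean `m r / M` and variance
#' `m (r/M) (1 - r/M) (M - m) / (M - 1)`. Column expectations and the
#' totals over all columns are returned. Note that this null ignores the
#' facilitator structure of the distances; see
#' [conditional_null_breaches()] for the facilitator-conditioned null that
#' matches the "sole stylistic source" hypothesis.
#'
#' @param meta metadata table (`label`, `user`, `facilitator`), one row per
#'   text.
#' @return list with `per_column` (data.frame of `label`, `m`, `r`, `M`,
#'   `expectation`, `variance`) and `total_expectation`, `total_variance`.
#' @export
null_expected_breaches <- function(meta) {
  n <- nrow(meta)
  fac_n <- table(meta$facilitator)
  user_n <- table(meta$user)
  M <- n - 1L
  m <- as.integer(user_n[meta$user]) - 1L
  r <- as.integer(fac_n[meta$facilitator]) - 1L
  expectation <- m * r / M
  variance <- m * (r / M) * (1 - r / M) * (M - m) / (M - 1)
  list(
    per_column = data.frame(label = meta$label, m = m, r = r, M = M,
                            expectation = expectation, variance = variance,
                            stringsAsFactors = FALSE),
    total_expectation = sum(expectation),
    total_variance = sum(variance)
  )
}

#' Permutation null for breaches conditional on facilitator structure
#'
#' The facilitator-only hypothesis says the user identity attached to a text
#' is stylistically meaningless, while the facilitator signal in the
#' distances is real. Its permutation null therefore holds each column's
#' observed ranking fixed and treats the same-user flags as exchangeable
#' among the cross-facilitator neighbours: in a column with `C`
#' cross-facilitator texts of which `B` happen to rank above the red line,
#' the null breach count is hypergeometric in `(B, C - B, m)`. Column draws
#' are summed by Monte Carlo to give the null distribution of the corpus
#' total.
#'
#' @param ranks rank table from [build_rank_table()].
#' @param n_draws Monte-Carlo draws for the total (default 4000).
#' @param level central interval coverage (default 0.95).
#' @return list with `observed` total breaches, `expectation`, `interval`
#'   (central `level` interval of the null total) and `draws`.
#' @export
conditional_null_breaches <- function(ranks, n_draws = 4000L, level = 0.95) {
  totals <- numeric(n_draws)
  expectation <- 0
  for (f in unique(ranks$focal)) {
    col <- ranks[ranks$focal == f, , drop = FALSE]
    cross <- !col$same_facilitator
    C <- sum(cross)
    B <- sum(cross & col$rank <= col$red_line)
    m <- sum(col$same_user)
    if (m == 0L || C == 0L) next
    expectation <- expectation + m * B / C
    totals <- totals + stats::rhyper(n_draws, B, C - B, m)
  }
  alpha <- (1 - level) / 2
  list(
    observed = sum(ranks$same_user & ranks$rank <= ranks$red_line),
    expectation = expectation,
    interval = stats::quantile(totals, c(alpha, 1 - alpha), names = FALSE,
                               type = 1L),
    draws = totals
  )
}

#' Write a rank table in wide (column-per-focal-text) and long formats
#'
#' @param ranks rank table.
#' @param file_wide,file_long output CSV paths (either may be `NULL`).
#' @export
write_rank_csv <- function(ranks, file_wide = NULL, file_long = NULL) {
  if (!is.null(file_long)) utils::write.csv(ranks, file_long, row.names = FALSE)
  if (!is.null(file_wide)) {
    focals <- unique(ranks$focal)
    wide <- do.call(cbind, lapply(focals, function(f) {
      col <- ranks[ranks$focal == f, ]
      col$other[order(col$rank)]
    }))
    colnames(wide) <- focals
    utils::write.csv(wide, file_wide, row.names = TRUE)
  }
  invisible(NULL)
}
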