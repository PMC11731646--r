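#' Cosine delta distance table
#'
#' The workhorse stylometric distance: one minus the cosine similarity of
#' the z-scored feature vectors, `d(a,b) = 1 - z_a.z_b / (|z_a||z_b|)`.
#' Values lie in `[0, 2]`: 0 for identical profiles, 1 for orthogonal ones,
#' 2 for antipodal ones.
#'
#' @param z z-score matrix from [zscore_matrix()] (samples in rows).
#' @return symmetric distance matrix with zero diagonal and the sample
#'   labels as dimnames; attribute `"metric"` is `"cosine_delta"`.
#' @export
cosine_delta <- function(z) {
  stopifnot(is.matrix(z), nrow(z) >= 2L)
  norms <- sqrt(rowSums(z^2))
  if (any(norms == 0)) {
    stop(errorCondition(
      paste("degenerate sample(s) with all-zero z-scores:",
            paste(rownames(z)[norms == 0], collapse = ", ")),
      class = c("costylo_degenerate_sample", "error")))
  }
  zn <- z / norms
  d <- 1 - tcrossprod(zn)
  d <- (d + t(d)) / 2          # enforce exact symmetry
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  attr(d, "metric") <- "cosine_delta"
  d
}

#' Burrows (classical) delta distance table
#'
#' The mean absolute difference of z-scored feature frequencies,
#' `d(a,b) = mean_f |z_af - z_bf|`; kept as an alternative metric and as an
#' independent cross-check on the cosine variant.
#'
#' @inheritParams cosine_delta
#' @return symmetric distance matrix; attribute `"metric"` is
#'   `"burrows_delta"`.
#' @export
burrows_delta <- function(z) {
  stopifnot(is.matrix(z), nrow(z) >= 2L)
  d <- as.matrix(stats::dist(z, method = "manhattan")) / ncol(z)
  attr(d, "metric") <- "burrows_delta"
  d
}

#' Hierarchical clustering of a distance table
#'
#' Agglomerative clustering via [stats::hclust()] on the given distance
#' table. The default linkage is Ward on the delta distances (`"ward.D2"`),
#' configurable to `"complete"` or `"average"`; the leaf-pairing statistic's
#' sensitivity to linkage is part of the test suite.
#'
#' @param d square distance matrix (e.g. from [cosine_delta()]).
#' @param linkage linkage method accepted by [stats::hclust()].
#' @return an `hclust` object.
#' @export
hcluster_delta <- function(d, linkage = "ward.D2") {
  stopifnot(is.matrix(d), nrow(d) >= 2L, isTRUE(all.equal(d, t(d))))
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram as a newick string
#'
#' Merge heights become branch heights; labels are sanitized by replacing
#' characters that are illegal in newick (`,();:[]` and whitespace) with
#' underscores.
#'
#' @param hc an `hclust` object.
#' @param file optional path; if given the tree is also written there.
#' @return newick string (invisibly if `file` is given).
#' @export
as_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  phy$tip.label <- gsub("[][,();:[:space:]]", "_", phy$tip.label)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Same-user leaf pairing rate of a dendrogram
#'
#' Two texts are "paired at the leaves" when their first merge in the
#' dendrogram is with each other (a leaf-leaf merge). For each sample the
#' sibling is that first merge partner if one exists; samples first absorbed
#' into a multi-leaf cluster have no sibling and count against the rate. The
#' rate is the fraction of samples whose sibling exists and shares the same
#' user.
#'
#' @param hc an `hclust` object whose labels identify the texts.
#' @param users character vector of user ids, one per label in `hc$labels`
#'   order, or a named vector indexed by label.
#' @return list with `rate`, `exceptions` (labels without a same-user
#'   sibling) and `siblings` (named character vector, `NA` where none).
#' @export
same_user_leaf_pairing <- function(hc, users) {
  labels <- hc$labels
  if (!is.null(names(users))) {
    if (!all(labels %in% names(users))) stop("users must cover all labels")
    users <- users[labels]
  }
  stopifnot(length(users) == length(labels))
  sib <- rep(NA_integer_, length(labels))
  leaf_rows <- which(hc$merge[, 1L] < 0 & hc$merge[, 2L] < 0)
  for (r in leaf_rows) {
    a <- -hc$merge[r, 1L]; b <- -hc$merge[r, 2L]
    sib[a] <- b; sib[b] <- a
  }
  ok <- !is.na(sib) & users == users[ifelse(is.na(sib), 1L, sib)]
  siblings <- ifelse(is.na(sib), NA_character_, labels[sib])
  names(siblings) <- labels
  list(rate = mean(ok), exceptions = labels[!ok], siblings = siblings)
}

#' Write a distance table to CSV
#'
#' @param d distance matrix.
#' @param file output path.
#' @export
write_distance_csv <- function(d, file) {
  utils::write.csv(as.data.frame(d), file, row.names = TRUE)
}
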