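#' Classify an ordered text pair into a relationship group
#'
#' The five groups partition the ordered pairs of texts by what the two
#' texts share: `IU` — same user; `FU` — same facilitator and stylistically
#' similar users; `F` — same facilitator only; `RU` — similar users only;
#' `NR` — neither. Similarity is read from the map directionally by default
#' (the focal text's user lists the other text's user), because the map
#' itself is directional — not all listed similarities are mutual; set
#' `symmetric = TRUE` to accept either direction.
#'
#' @param user_a,facilitator_a metadata of the focal text (vectorized).
#' @param user_b,facilitator_b metadata of the other text.
#' @param simmap similarity map (named list); required, since FU and RU are
#'   undefined without it.
#' @param symmetric apply the similarity test in both directions.
#' @return factor with levels `IU`, `FU`, `F`, `RU`, `NR`.
#' @export
assign_relation <- function(user_a, facilitator_a, user_b, facilitator_b,
                            simmap, symmetric = FALSE) {
  if (missing(simmap) || is.null(simmap)) {
    stop("a similarity map is required: FU and RU are undefined without it")
  }
  n <- length(user_a)
  stopifnot(length(user_b) == n, length(facilitator_a) == n,
            length(facilitator_b) == n)
  lists <- function(a, b) {
    mapply(function(x, y) y %in% simmap[[x]], a, b, USE.NAMES = FALSE)
  }
  sim <- lists(user_a, user_b)
  if (symmetric) sim <- sim | lists(user_b, user_a)
  same_u <- user_a == user_b
  same_f <- facilitator_a == facilitator_b
  out <- ifelse(same_u, "IU",
         ifelse(same_f & sim, "FU",
         ifelse(same_f, "F",
         ifelse(sim, "RU", "NR"))))
  factor(out, levels = c("IU", "FU", "F", "RU", "NR"))
}

#' Relationship group of every ordered pair of texts
#'
#' Every ordered pair of distinct texts contributes one observation (so `N`
#' texts give `N(N-1)` rows), matching the counting convention under which
#' each column of the distance table is read independently.
#'
#' @param meta metadata table (`label`, `user`, `facilitator`).
#' @inheritParams assign_relation
#' @return data.frame with `focal`, `other`, `group`.
#' @export
pair_relations <- function(meta, simmap, symmetric = FALSE) {
  n <- nrow(meta)
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))  # i = focal, varies slowest
  idx <- idx[idx$i != idx$j, c("i", "j")]
  data.frame(
    focal = meta$label[idx$i],
    other = meta$label[idx$j],
    group = assign_relation(meta$user[idx$i], meta$facilitator[idx$i],
                            meta$user[idx$j], meta$facilitator[idx$j],
                            simmap, symmetric),
    stringsAsFactors = FALSE
  )
}

#' Distance statistics per relationship group
#'
#' @param d distance matrix.
#' @param relations data.frame from [pair_relations()].
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`
#'   (sample SD; `NA` for groups with fewer than two values). Empty groups
#'   are reported with `n = 0`.
#' @export
group_summary <- function(d, relations) {
  vals <- d[cbind(relations$other, relations$focal)]
  out <- do.call(rbind, lapply(levels(relations$group), function(g) {
    v <- vals[relations$group == g]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "values") <- split(vals, relations$group)
  out
}

#' One-sample t-test of group distances against a reference value
#'
#' Used with `mu = 1` (the neutral cosine-delta value, halfway between the
#' metric's bounds 0 and 2) and with `mu` equal to the corpus-average
#' distance, to ask whether a group's distances sit above or below each
#' reference.
#'
#' @param values numeric distance values (>= 2).
#' @param mu reference value.
#' @param alpha significance level for the `reject` flag.
#' @return list with `statistic`, `p_value`, `reject`, `mean`, `n`.
#' @export
one_sample_test <- function(values, mu, alpha = 0.05) {
  stopifnot(length(values) >= 2L)
  if (stats::sd(values) == 0) {
    stop(errorCondition("zero-variance sample: t-test undefined",
                        class = c("costylo_degenerate_sample", "error")))
  }
  tt <- stats::t.test(values, mu = mu)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       reject = tt$p.value < alpha, mean = mean(values), n = length(values))
}

#' Iterated equal-size subsample t-test between two groups
#'
#' The groups are heavily unbalanced, so each repetition subsamples both
#' groups without replacement down to the smaller group's size, runs an
#' unpaired two-sample t-test on the equalized samples, and the p-values are
#' averaged over the repetitions. Seed-controlled and reproducible.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param reps number of repetitions (default 10).
#' @param seed integer seed.
#' @param alpha significance level for the decision on the mean p-value.
#' @return list with `mean_p`, `p_values`, `reject`, `means` and the inputs'
#'   sizes.
#' @export
iterated_subsample_test <- function(a, b, reps = 10L, seed = 1L,
                                    alpha = 0.05) {
  m <- min(length(a), length(b))
  if (m < 2L) stop("each group needs at least 2 values")
  set.seed(seed)
  p <- vapply(seq_len(reps), function(i) {
    sa <- if (length(a) > m) sample(a, m) else a
    sb <- if (length(b) > m) sample(b, m) else b
    stats::t.test(sa, sb)$p.value
  }, numeric(1))
  list(mean_p = mean(p), p_values = p, reject = mean(p) < alpha,
       means = c(mean(a), mean(b)), n = c(length(a), length(b)),
       subsample_size = m, reps = reps, seed = seed)
}

## internal: distance-weighted k-nearest-neighbour prediction on a scalar
## (or multivariate) feature; weights are inverse distances, with an exact
## match taking the whole vote.
weighted_knn_predict <- function(train_x, train_y, test_x, k = 10L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  lv <- levels(train_y)
  k <- min(k, nrow(train_x))
  apply(test_x, 1L, function(x) {
    dd <- sqrt(colSums((t(train_x) - x)^2))
    nn <- order(dd)[seq_len(k)]
    w <- 1 / pmax(dd[nn], .Machine$double.eps)
    votes <- tapply(w, factor(train_y[nn], levels = lv), sum, default = 0)
    lv[which.max(votes)]
  })
}

#' Supervised classification of pair distances into relationship groups
#'
#' Cross-validated classification of each ordered pair's scalar distance
#' value into its relationship group, with a distance-weighted KNN or an
#' SVM (radial kernel, via \pkg{e1071}). Folds are stratified by group so
#' every class appears in training. The scalar distance is the only feature,
#' which is the quantity the group analysis attaches to each observation;
#' accuracy therefore measures how separable the groups' distance
#' distributions are, nothing more.
#'
#' @param values numeric distances, one per observation.
#' @param groups factor of group labels.
#' @param method `"weighted-knn"` or `"svm"`.
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param k neighbours for the KNN method.
#' @return list with `accuracy`, `confusion` (true x predicted), `method`,
#'   `folds`, `seed`.
#' @export
classify_relations <- function(values, groups,
                               method = c("weighted-knn", "svm"),
                               folds = 5L, seed = 1L, k = 10L) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  if (any(table(groups) < folds)) {
    stop(errorCondition("a class has fewer observations than folds",
                        class = c("costylo_stratification_error", "error")))
  }
  set.seed(seed)
  fold <- integer(length(groups))
  for (g in levels(groups)) {
    ix <- which(groups == g)
    fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  pred <- character(length(groups))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (method == "weighted-knn") {
      pred[!tr] <- weighted_knn_predict(values[tr], groups[tr], values[!tr], k)
    } else {
      df <- data.frame(x = values[tr], y = groups[tr])
      fit <- e1071::svm(y ~ x, data = df)
      pred[!tr] <- as.character(stats::predict(fit,
                                               data.frame(x = values[!tr])))
    }
  }
  pred <- factor(pred, levels = levels(groups))
  list(accuracy = mean(pred == groups),
       confusion = table(true = groups, predicted = pred),
       method = method, folds = folds, seed = seed)
}
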