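# Independent oracles, kept deliberately naive (explicit loops, closed
# forms) so they share no code path with the implementation they check.

# cosine delta by explicit dot products
oracle_cosine_delta <- function(z) {
  n <- nrow(z)
  d <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(z[i, ] * z[j, ])
    d[i, j] <- 1 - num / (sqrt(sum(z[i, ]^2)) * sqrt(sum(z[j, ]^2)))
  }
  d
}

# Burrows delta by explicit mean absolute difference
oracle_burrows_delta <- function(z) {
  n <- nrow(z)
  d <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- mean(abs(z[i, ] - z[j, ]))
  }
  d
}

# per-feature standardization with population SD, by explicit loops
oracle_zscore <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    sdp <- sqrt(mean((m[, j] - mu)^2))
    out[, j] <- (m[, j] - mu) / sdp
  }
  out
}

# exhaustive nearest-pair agglomeration under complete linkage; returns the
# sets merged at each step
oracle_complete_agglomeration <- function(d) {
  clusters <- as.list(rownames(d))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best_h)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# fixed toy frequency matrices used by several tests
toy_freq_3 <- function() {
  m <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2", "f3")))
  m
}

toy_freq <- function(n_samples, n_features, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_samples * n_features), n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("f", seq_len(n_features))))
  m / rowSums(m)
}

# brute-force consensus-network accumulation: recompute features, z-scores
# and distances per sweep size with explicit loops
oracle_bcn_weights <- function(samples, sweep, k_nn) {
  labs <- names(samples)
  W <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (size in sweep) {
    freq <- suppressWarnings(extract_features(samples, "word", k = size))
    z <- suppressMessages(zscore_matrix(freq))
    d <- oracle_cosine_delta(z)
    for (i in seq_along(labs)) {
      dd <- d[, i]; dd[i] <- Inf
      ord <- order(dd, labs)
      for (j in seq_len(k_nn)) {
        b <- ord[j]
        W[i, b] <- W[i, b] + (k_nn + 1 - j)
        W[b, i] <- W[b, i] + (k_nn + 1 - j)
      }
    }
  }
  W
}

# small multi-facilitator design for combinatorial toys
toy_meta <- function() {
  data.frame(
    label = c("U1_F1", "U1_F2", "U2_F1", "U2_F2", "U3_F1", "U3_F3"),
    user = c("U1", "U1", "U2", "U2", "U3", "U3"),
    facilitator = c("F1", "F2", "F1", "F2", "F1", "F3"),
    stringsAsFactors = FALSE
  )
}
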