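#' Tokenize text into lowercase word tokens
#'
#' Lowercases the input and extracts maximal runs of Unicode letters; digits
#' and punctuation are discarded. Italian elision apostrophes are treated as
#' token boundaries. Under the default `elision = "attach"` dialect the
#' apostrophe stays attached to the elided article, so `"l'anima"` yields the
#' two tokens `"l'"` and `"anima"`; under `elision = "split"` the apostrophe
#' is dropped entirely (`"l"`, `"anima"`). Accented letters are preserved, so
#' \emph{sì} and \emph{si} remain distinct types.
#'
#' @param text character vector; elements are concatenated in order.
#' @param elision apostrophe handling dialect, `"attach"` (default) or
#'   `"split"`.
#' @return character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("Sì, sì!")
#' tokenize("l'anima bella")
tokenize <- function(text, elision = c("attach", "split")) {
  elision <- match.arg(elision)
  text <- tolower(as.character(text))
  rx <- if (elision == "attach") "\\p{L}+[’']?" else "\\p{L}+"
  m <- gregexpr(rx, text, perl = TRUE)
  out <- unlist(regmatches(text, m), use.names = FALSE)
  if (is.null(out)) character(0) else out
}

#' Lexical statistics of a token stream
#'
#' @param tokens character vector of tokens (as from [tokenize()]).
#' @return list with `tokens` (total occurrences), `types` (distinct forms),
#'   `hapax` (forms occurring exactly once) and `type_token_ratio`
#'   (`NA` for an empty stream).
#' @export
lexical_stats <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) {
    return(list(tokens = 0L, types = 0L, hapax = 0L, type_token_ratio = NA_real_))
  }
  tab <- table(tokens)
  list(
    tokens = n,
    types = length(tab),
    hapax = sum(tab == 1L),
    type_token_ratio = length(tab) / n
  )
}

## internal: character n-grams over the space-joined token stream
## (single-space separators, spaces included as characters)
char_ngrams <- function(tokens, n) {
  s <- paste(tokens, collapse = " ")
  nc <- nchar(s)
  if (nc < n) return(character(0))
  substring(s, 1:(nc - n + 1L), n:nc)
}

#' Most-frequent-feature relative-frequency matrix
#'
#' Builds the classical stylometric feature matrix: the `k` features (word
#' forms or character n-grams) with the highest summed count across the whole
#' corpus under analysis, ties broken lexicographically, with each cell the
#' feature's relative frequency within the sample (count divided by the
#' sample's total token or n-gram count, not just the count over the retained
#' features).
#'
#' @param samples a named list; each element either a character vector of
#'   tokens or a length-one string (which is passed through [tokenize()]).
#' @param mode `"word"` or `"char_ngram"`.
#' @param k number of top features to retain. If `k` exceeds the number of
#'   distinct features available the matrix is truncated with a warning.
#' @param n n-gram length for `mode = "char_ngram"` (default 3, trigrams).
#' @param elision tokenizer dialect, see [tokenize()].
#' @return numeric matrix, samples in rows (named), features in columns in
#'   corpus-frequency order; attribute `"mode"` records the feature mode.
#' @export
extract_features <- function(samples, mode = c("word", "char_ngram"),
                             k = 1000L, n = 3L, elision = "attach") {
  mode <- match.arg(mode)
  stopifnot(length(samples) >= 2L, k >= 1L, n >= 1L)
  if (is.null(names(samples)) || anyNA(names(samples)) || any(names(samples) == "")) {
    stop("`samples` must be a fully named list")
  }
  units <- lapply(samples, function(x) {
    # a length-one element is a raw text; longer vectors are token streams
    toks <- if (length(x) == 1L) tokenize(x, elision) else x
    if (mode == "char_ngram") char_ngrams(toks, n) else toks
  })
  all_units <- unlist(units, use.names = FALSE)
  vocab <- sort(unique(all_units), method = "radix")
  if (length(vocab) == 0L) stop("no features found in any sample")
  counts <- t(vapply(units, function(u) {
    tabulate(match(u, vocab), nbins = length(vocab))
  }, integer(length(vocab))))
  totals <- colSums(counts)
  ord <- order(-totals, vocab, method = "radix")
  if (k > length(vocab)) {
    warning(sprintf("only %d distinct features available (k = %d); truncating",
                    length(vocab), k))
    k <- length(vocab)
  }
  keep <- ord[seq_len(k)]
  denom <- vapply(units, length, integer(1))
  rel <- counts[, keep, drop = FALSE] / denom
  dimnames(rel) <- list(names(samples), vocab[keep])
  attr(rel, "mode") <- mode
  rel
}

#' Z-score a frequency matrix per feature
#'
#' Standardizes each feature (column) across samples using the population
#' standard deviation, the convention under which Burrows' delta equals the
#' mean absolute z-score difference. Features with zero variance across the
#' samples carry no information and are dropped; their names are recorded in
#' the `"dropped"` attribute and reported via `message()`.
#'
#' @param freq matrix from [extract_features()] (or any sample-by-feature
#'   numeric matrix with at least two rows).
#' @return matrix of z-scores with the same row names; attribute `"dropped"`
#'   holds the names of removed zero-variance features.
#' @export
zscore_matrix <- function(freq) {
  if (!is.matrix(freq) || nrow(freq) < 2L) {
    stop("need a matrix with at least two samples to standardize")
  }
  mu <- colMeans(freq)
  centered <- sweep(freq, 2L, mu)
  sdp <- sqrt(colMeans(centered^2))
  drop <- sdp == 0
  if (any(drop)) {
    message(sprintf("dropping %d zero-variance feature(s)", sum(drop)))
  }
  z <- sweep(centered[, !drop, drop = FALSE], 2L, sdp[!drop], "/")
  attr(z, "dropped") <- colnames(freq)[drop]
  z
}
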