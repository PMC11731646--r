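#' Build Zipfian style profiles for a set of authors
#'
#' The generative model behind the synthetic corpora: a shared vocabulary of
#' `V` word forms carries a Zipfian base distribution `p_i` proportional to
#' `i^-s`, and each author's unigram profile perturbs it multiplicatively,
#' `q_i` proportional to `p_i * exp(sigma * e_i)` with `e_i` standard
#' normal, renormalized. `sigma` controls how far author fingerprints
#' diverge (`sigma = 0` gives identical profiles); `s = 0` gives a uniform
#' base. Vocabulary words are letter-only strings (bijective base-26
#' encodings) so they survive the tokenizer and the caps-lock dialogue
#' format round trip.
#'
#' @param authors character vector of author ids.
#' @param V vocabulary size (default 10000).
#' @param s Zipf exponent (default 1).
#' @param sigma per-author log-normal perturbation scale (default 0.4).
#' @return list with `vocab` (character), `base` (base probabilities) and
#'   `profiles` (author-by-vocabulary probability matrix, rows sum to 1).
#'   Draws from the current RNG stream.
#' @export
make_profiles <- function(authors, V = 10000L, s = 1, sigma = 0.4) {
  stopifnot(V >= 2L, length(authors) >= 1L, sigma >= 0)
  base <- (seq_len(V))^(-s)
  base <- base / sum(base)
  profiles <- t(vapply(authors, function(a) {
    q <- base * exp(sigma * stats::rnorm(V))
    q / sum(q)
  }, numeric(V)))
  rownames(profiles) <- authors
  list(vocab = int2word(seq_len(V)), base = base, profiles = profiles)
}

## internal: bijective base-26 encoding, 1 -> "a", 26 -> "z", 27 -> "aa", ...
int2word <- function(i) {
  vapply(as.integer(i), function(x) {
    s <- character(0)
    while (x > 0L) {
      r <- (x - 1L) %% 26L
      s <- c(letters[r + 1L], s)
      x <- (x - 1L) %/% 26L
    }
    paste(s, collapse = "")
  }, "")
}

## internal: draw L token ids from a probability vector (inverse-CDF)
sample_token_ids <- function(prob, L) {
  cum <- cumsum(prob)
  cum[length(cum)] <- 1
  findInterval(stats::runif(L), cum, rightmost.closed = TRUE) + 1L
}

#' Generate one pair text from the user/facilitator mixture model
#'
#' Each of the `L` tokens is drawn independently from the user's profile
#' with probability `lambda` and from the facilitator's profile otherwise.
#' `lambda = 0` realizes the facilitator-only null (the facilitator is the
#' sole stylistic agent); `lambda = 1` a pure user text. The per-token
#' source labels are returned as ground truth.
#'
#' @param user_prob,facilitator_prob probability vectors over the shared
#'   vocabulary.
#' @param lambda mixing weight in `[0, 1]`.
#' @param L number of tokens.
#' @return list with `ids` (integer token ids) and `source` (character,
#'   `"user"`/`"facilitator"` per token). Draws from the current RNG stream.
#' @export
generate_pair_text <- function(user_prob, facilitator_prob, lambda, L) {
  stopifnot(lambda >= 0, lambda <= 1, L >= 1L)
  from_user <- stats::runif(L) < lambda
  ids <- integer(L)
  if (any(from_user)) {
    ids[from_user] <- sample_token_ids(user_prob, sum(from_user))
  }
  if (any(!from_user)) {
    ids[!from_user] <- sample_token_ids(facilitator_prob, sum(!from_user))
  }
  list(ids = ids, source = ifelse(from_user, "user", "facilitator"))
}

#' Generate a full synthetic corpus with known stylistic structure
#'
#' Builds user and facilitator profiles, then one pair text per row of the
#' design matrix. Defaults are the reference study conditions: vocabulary
#' `V = 10000` with Zipf exponent 1, perturbation `sigma = 0.4`, 20000
#' words per pairing, mixing weight `lambda = 0.5`.
#'
#' @param design data.frame with `user` and `facilitator` columns (see
#'   [center1_design()], [center2_design()]).
#' @param lambda mixing weight.
#' @param words_per_pair tokens per pair text; either a scalar or one value
#'   per design row (a word-budget column).
#' @param V,s,sigma profile model parameters, see [make_profiles()].
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `costylo_synth`: list with `samples` (named list
#'   of token character vectors), `meta` (label/user/facilitator/word_count),
#'   `truth` (profiles, lambda, per-pair user-token counts, seed).
#' @export
generate_corpus <- function(design, lambda = 0.5, words_per_pair = 20000L,
                            V = 10000L, s = 1, sigma = 0.4, seed = 1L) {
  stopifnot(nrow(design) >= 1L, all(c("user", "facilitator") %in% names(design)))
  L <- rep_len(as.integer(words_per_pair), nrow(design))
  set.seed(seed)
  users <- sort(unique(design$user))
  facs <- sort(unique(design$facilitator))
  up <- make_profiles(users, V = V, s = s, sigma = sigma)
  fp_profiles <- t(vapply(facs, function(a) {
    q <- up$base * exp(sigma * stats::rnorm(V))
    q / sum(q)
  }, numeric(V)))
  rownames(fp_profiles) <- facs
  labels <- paste(design$user, design$facilitator, sep = "_")
  samples <- vector("list", nrow(design))
  src_user <- integer(nrow(design))
  for (i in seq_len(nrow(design))) {
    g <- generate_pair_text(up$profiles[design$user[i], ],
                            fp_profiles[design$facilitator[i], ],
                            lambda, L[i])
    samples[[i]] <- up$vocab[g$ids]
    src_user[i] <- sum(g$source == "user")
  }
  names(samples) <- labels
  meta <- data.frame(label = labels, user = design$user,
                     facilitator = design$facilitator,
                     word_count = L, stringsAsFactors = FALSE)
  structure(list(
    samples = samples, meta = meta,
    truth = list(lambda = lambda, sigma = sigma, V = V, s = s, seed = seed,
                 user_profiles = up$profiles, facilitator_profiles = fp_profiles,
                 vocab = up$vocab, user_token_counts = src_user)
  ), class = "costylo_synth")
}

#' Render a pair's tokens as caps-lock dialogue session files
#'
#' Splits the user token stream into `sessions` session transcripts, each a
#' sequence of short user lines interleaved with uppercase facilitator
#' prompt lines, i.e. the on-disk dialogue format the parser consumes.
#' Because prompts are all-caps and user lines all-lowercase,
#' [split_dialogue()] recovers the user token stream exactly.
#'
#' @param tokens character vector of (lowercase) user tokens.
#' @param sessions number of session files to spread the tokens over.
#' @param words_per_line user tokens per line.
#' @param prompt_vocab words the facilitator prompts are sampled from.
#' @param prompt_every insert a prompt line before every this-many user
#'   lines.
#' @return list of character vectors, one per session (the file lines).
#'   Draws from the current RNG stream (prompt composition only).
#' @export
render_sessions <- function(tokens, sessions = 3L, words_per_line = 10L,
                            prompt_vocab = c("come", "stai", "oggi", "cosa",
                                             "vuoi", "dire", "racconta"),
                            prompt_every = 4L) {
  stopifnot(sessions >= 1L, length(tokens) >= sessions)
  bounds <- floor(seq(0, length(tokens), length.out = sessions + 1L))
  lapply(seq_len(sessions), function(sidx) {
    toks <- tokens[(bounds[sidx] + 1L):bounds[sidx + 1L]]
    starts <- seq(1L, length(toks), by = words_per_line)
    user_lines <- vapply(starts, function(s) {
      paste(toks[s:min(s + words_per_line - 1L, length(toks))], collapse = " ")
    }, "")
    out <- character(0)
    for (i in seq_along(user_lines)) {
      if ((i - 1L) %% prompt_every == 0L) {
        prompt <- toupper(paste(
          sample(prompt_vocab, min(3L, length(prompt_vocab))), collapse = " "))
        out <- c(out, prompt)
      }
      out <- c(out, user_lines[i])
    }
    out
  })
}

#' Write a synthetic corpus to disk in the session-file layout
#'
#' Emits the directory tree [read_session_dir()] consumes
#' (`dir/<user>/<facilitator>_<session>.txt`) plus `manifest.csv` and a
#' ground-truth `truth.json` (seed, lambda, per-pair user-token counts).
#'
#' @param corpus a `costylo_synth` object.
#' @param dir output directory (created if needed).
#' @param sessions_per_pair sessions per pairing.
#' @return invisibly, the manifest data.frame.
#' @export
write_corpus <- function(corpus, dir, sessions_per_pair = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (i in seq_len(nrow(corpus$meta))) {
    u <- corpus$meta$user[i]; f <- corpus$meta$facilitator[i]
    dir.create(file.path(dir, u), showWarnings = FALSE)
    ses <- render_sessions(corpus$samples[[i]], sessions = sessions_per_pair)
    for (sidx in seq_along(ses)) {
      fn <- sprintf("%s_%03d.txt", f, sidx)
      writeLines(ses[[sidx]], file.path(dir, u, fn), useBytes = TRUE)
      man[[length(man) + 1L]] <- data.frame(
        file = file.path(u, fn), user_id = u, facilitator_id = f,
        order = sidx, stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, man)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = corpus$truth$seed, lambda = corpus$truth$lambda,
         sigma = corpus$truth$sigma, V = corpus$truth$V, s = corpus$truth$s,
         user_token_counts = stats::setNames(
           as.list(corpus$truth$user_token_counts), corpus$meta$label)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(man)
}
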