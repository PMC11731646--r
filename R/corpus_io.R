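#' Split a dialogue transcript into user and facilitator text
#'
#' In the session files this pipeline targets, facilitator turns are typed in
#' caps lock while the user's typed output is lowercase/mixed case. A line is
#' attributed to the facilitator when the fraction of its alphabetic
#' characters that are uppercase is at least `caps_threshold`; the threshold
#' (rather than an exact all-caps test) tolerates punctuation, digits and
#' accented letters. Lines with no alphabetic characters cannot carry the
#' caps-lock marking and are assigned to the user.
#'
#' @param raw_lines character vector of transcript lines (UTF-8).
#' @param caps_threshold minimum uppercase fraction for a facilitator line.
#' @return list with `user` and `facilitator`, each the newline-joined
#'   concatenation of that speaker's lines in original order, plus `speaker`,
#'   the per-non-empty-line attribution.
#' @export
split_dialogue <- function(raw_lines, caps_threshold = 0.8) {
  stopifnot(is.character(raw_lines), caps_threshold > 0, caps_threshold <= 1)
  keep <- trimws(raw_lines) != ""
  lines <- raw_lines[keep]
  if (length(lines) == 0L) {
    stop(errorCondition("transcript contains no non-empty lines",
                        class = c("costylo_empty_document", "error")))
  }
  letters_only <- gsub("[^\\p{L}]", "", lines, perl = TRUE)
  upper <- nchar(gsub("[^\\p{Lu}]", "", lines, perl = TRUE))
  n_alpha <- nchar(letters_only)
  frac <- ifelse(n_alpha > 0, upper / n_alpha, 0)
  speaker <- ifelse(frac >= caps_threshold, "facilitator", "user")
  list(
    user = paste(lines[speaker == "user"], collapse = "\n"),
    facilitator = paste(lines[speaker == "facilitator"], collapse = "\n"),
    speaker = speaker
  )
}

#' Remove literal names from a text
#'
#' Case-insensitive whole-word removal of every name in `name_list`, used to
#' strip references to users' and facilitators' names before analysis.
#'
#' @param text character scalar.
#' @param name_list character vector of literal names (no regular
#'   expressions); an empty list returns the text unchanged.
#' @return the text with all occurrences removed and whitespace collapsed.
#' @export
strip_names <- function(text, name_list) {
  stopifnot(is.character(text))
  for (nm in name_list) {
    pat <- paste0("(?<![\\p{L}])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", nm),
                  "(?![\\p{L}])")
    text <- gsub(pat, " ", text, perl = TRUE, ignore.case = TRUE)
  }
  trimws(gsub("[ \t]+", " ", text))
}

#' Read a directory tree of session transcripts
#'
#' Expected layout: one UTF-8 `.txt` file per session, either
#' `dir/<user>/<facilitator>_<session>.txt` (folder encodes the user) or a
#' flat `dir/<user>_<facilitator>_<session>.txt`. An optional manifest
#' (CSV with columns `file`, `user_id`, `facilitator_id` and optionally
#' `order`) overrides the naming convention. Within a pairing, sessions are
#' ordered chronologically, taken to be lexicographic filename order unless
#' the manifest supplies `order`.
#'
#' @param dir root directory.
#' @param manifest optional path to a manifest CSV.
#' @param caps_threshold passed to [split_dialogue()].
#' @return data.frame with one row per session: `session_id`, `user_id`,
#'   `facilitator_id`, `user_text`, `facilitator_text`, ordered for
#'   [assemble_pairs()].
#' @export
read_session_dir <- function(dir, manifest = NULL, caps_threshold = 0.8) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("file", "user_id", "facilitator_id") %in% names(man)))
    files <- file.path(dir, man$file)
    user <- man$user_id
    fac <- man$facilitator_id
    ord <- if ("order" %in% names(man)) order(user, fac, man$order) else
      order(user, fac, man$file, method = "radix")
  } else {
    files <- list.files(dir, pattern = "\\.txt$", recursive = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no .txt session files under ", dir)
    rel <- list.files(dir, pattern = "\\.txt$", recursive = TRUE)
    base <- sub("\\.txt$", "", basename(rel))
    in_subdir <- dirname(rel) != "."
    user <- ifelse(in_subdir, basename(dirname(rel)),
                   sub("^([^_]+)_.*$", "\\1", base))
    fac <- ifelse(in_subdir,
                  sub("^([^_]+)_.*$", "\\1", base),
                  sub("^[^_]+_([^_]+)_.*$", "\\1", base))
    ord <- order(user, fac, rel, method = "radix")
  }
  files <- files[ord]; user <- user[ord]; fac <- fac[ord]
  if (any(user == "") || any(fac == "")) {
    stop(errorCondition("could not derive user/facilitator ids for all files",
                        class = c("costylo_malformed_metadata", "error")))
  }
  rows <- lapply(seq_along(files), function(i) {
    sp <- split_dialogue(readLines(files[i], encoding = "UTF-8", warn = FALSE),
                         caps_threshold)
    data.frame(session_id = basename(files[i]), user_id = user[i],
               facilitator_id = fac[i], user_text = sp$user,
               facilitator_text = sp$facilitator, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble per-pairing texts from parsed sessions
#'
#' Concatenates the user-side text of every session belonging to the same
#' (user, facilitator) pairing, in the order the sessions appear, and counts
#' tokens. The pair text is the unit of all downstream analyses.
#'
#' @param sessions data.frame as returned by [read_session_dir()].
#' @param elision tokenizer dialect, see [tokenize()].
#' @return data.frame with `label` (`<user>_<facilitator>`), `user_id`,
#'   `facilitator_id`, `text`, `word_count`, `n_sessions`.
#' @export
assemble_pairs <- function(sessions, elision = "attach") {
  need <- c("session_id", "user_id", "facilitator_id", "user_text")
  if (!all(need %in% names(sessions))) {
    stop(errorCondition("sessions table is missing required columns",
                        class = c("costylo_malformed_metadata", "error")))
  }
  key <- paste(sessions$user_id, sessions$facilitator_id, sep = "_")
  idx <- split(seq_len(nrow(sessions)), factor(key, levels = unique(key)))
  rows <- lapply(names(idx), function(k) {
    i <- idx[[k]]
    txt <- paste(sessions$user_text[i], collapse = "\n")
    data.frame(label = k,
               user_id = sessions$user_id[i[1L]],
               facilitator_id = sessions$facilitator_id[i[1L]],
               text = txt,
               word_count = length(tokenize(txt, elision)),
               n_sessions = length(i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter pair texts by a minimum word count
#'
#' Retains pairs whose `word_count` is strictly greater than `threshold`
#' (a text of exactly `threshold` words is excluded). Excluded labels are
#' reported with a message and attached as the `"excluded"` attribute.
#'
#' @param pairs data.frame from [assemble_pairs()] (needs `label` and
#'   `word_count`).
#' @param threshold minimum length in tokens; default 5000.
#' @return the filtered data.frame.
#' @export
filter_min_words <- function(pairs, threshold = 5000L) {
  keep <- pairs$word_count > threshold
  if (any(!keep)) {
    message("excluding short pair(s): ",
            paste(pairs$label[!keep], collapse = ", "))
  }
  out <- pairs[keep, , drop = FALSE]
  attr(out, "excluded") <- pairs$label[!keep]
  out
}

#' Split a pair text into two recombined half-texts
#'
#' The token stream is cut into four consecutive quarters of near-equal
#' length (remainder tokens go to the earliest quarters, so quarter lengths
#' differ by at most one and chunk lengths by at most 3 tokens), then the
#' quarters are recombined under one of three schemes:
#' scheme A pairs quarters 1+2 against 3+4, scheme B pairs 1+3 against 2+4,
#' and scheme C pairs 1+4 against 2+3. Running all three schemes guards the
#' downstream clustering against artefacts of any one cut.
#'
#' @param tokens character vector of tokens, or a single string to tokenize.
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @return list with `chunk1`, `chunk2` (token vectors) and `labels`
#'   (e.g. `c("1-2", "3-4")`), following the `U1_1-2` naming convention.
#' @export
chunk_four_way <- function(tokens, scheme = c("A", "B", "C")) {
  scheme <- match.arg(scheme)
  if (length(tokens) == 1L) tokens <- tokenize(tokens)
  n <- length(tokens)
  if (n < 4L) {
    stop(errorCondition("need at least 4 tokens to form quarters",
                        class = c("costylo_degenerate_input", "error")))
  }
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  extra <- n %% 4L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-4L] + 1L)
  q <- lapply(1:4, function(i) tokens[starts[i]:ends[i]])
  combo <- switch(scheme,
    A = list(c(1L, 2L), c(3L, 4L)),
    B = list(c(1L, 3L), c(2L, 4L)),
    C = list(c(1L, 4L), c(2L, 3L))
  )
  list(
    chunk1 = c(q[[combo[[1L]][1L]]], q[[combo[[1L]][2L]]]),
    chunk2 = c(q[[combo[[2L]][1L]]], q[[combo[[2L]][2L]]]),
    labels = vapply(combo, function(ix) paste(ix, collapse = "-"), ""),
    quarter_sizes = sizes
  )
}
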