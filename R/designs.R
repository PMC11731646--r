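#' Reference study designs
#'
#' The two FC-center corpus designs the pipeline is built around.
#' `center1_design()` is the single-facilitator center: seven users (U1-U7)
#' all assisted by the same facilitator. `center2_design()` is the
#' multi-facilitator center: 28 user-facilitator pairings over ten users
#' (U8-U17) and seven facilitators, with F1 assisting all ten users, F2 six,
#' F3 four, F4 and F5 two each, F7 one and F8 three. Every pairing is the
#' unit of one analysed text.
#'
#' @return data.frame with columns `user` and `facilitator`, one row per
#'   pairing.
#' @export
center2_design <- function() {
  pairs <- list(
    U8  = c("F1", "F2", "F3"),
    U9  = c("F1", "F2", "F4"),
    U10 = c("F1", "F2", "F4", "F8"),
    U11 = c("F1", "F2"),
    U12 = c("F1", "F2", "F5", "F7", "F8"),
    U13 = c("F1", "F3"),
    U14 = c("F1", "F5"),
    U15 = c("F1", "F3"),
    U16 = c("F1", "F2", "F3"),
    U17 = c("F1", "F8")
  )
  data.frame(
    user = rep(names(pairs), lengths(pairs)),
    facilitator = unlist(pairs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname center2_design
#' @export
center1_design <- function() {
  data.frame(user = paste0("U", 1:7), facilitator = "F1",
             stringsAsFactors = FALSE)
}

#' Inter-user stylistic similarity map for the multi-facilitator center
#'
#' For each user, the (at most two) other users with a similar stylistic
#' fingerprint, as extracted from the cluster analyses. The map is
#' directional: U15 lists U16 but not vice versa, so not all relationships
#' are mutual, and the pair-relationship rules honour that direction by
#' default (see [assign_relation()]).
#'
#' @return named list: for each user id, a character vector of similar users.
#' @export
center2_similarity <- function() {
  list(
    U8  = c("U16", "U14"),
    U9  = "U11",
    U10 = c("U11", "U12"),
    U11 = c("U10", "U12"),
    U12 = c("U10", "U11"),
    U13 = c("U14", "U8"),
    U14 = c("U13", "U8"),
    U15 = "U16",
    U16 = c("U8", "U14"),
    U17 = c("U8", "U16")
  )
}

#' Build a metadata table from pair labels
#'
#' Labels follow the `<user>_<facilitator>` convention (e.g. `"U8_F1"`);
#' chunked texts append the quarter code (`"U8_1-2"`), in which case the
#' facilitator must be supplied separately.
#'
#' @param labels character vector of text labels.
#' @return data.frame with `label`, `user`, `facilitator`.
#' @export
parse_labels <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("labels not of the form <user>_<facilitator>: ",
                     paste(labels[bad], collapse = ", "))
  data.frame(label = labels,
             user = vapply(parts, `[`, "", 1L),
             facilitator = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

## internal: validate a metadata frame against a set of labels
check_metadata <- function(meta, labels) {
  stopifnot(all(c("label", "user", "facilitator") %in% names(meta)))
  missing <- setdiff(labels, meta$label)
  if (length(missing) > 0L) {
    stop("labels without metadata: ", paste(missing, collapse = ", "))
  }
  meta[match(labels, meta$label), , drop = FALSE]
}
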