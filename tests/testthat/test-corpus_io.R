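test_that("caps-lock lines go to the facilitator, lowercase to the user", {
  sp <- split_dialogue(c("COME STAI OGGI", "bene grazie"))
  expect_equal(sp$user, "bene grazie")
  expect_equal(sp$facilitator, "COME STAI OGGI")

  # threshold tolerates punctuation and digits among uppercase letters
  sp <- split_dialogue(c("COME STAI, OGGI? 123", "Bene davvero"))
  expect_equal(sp$speaker, c("facilitator", "user"))

  # mostly-uppercase line crosses the 0.8 default threshold
  sp <- split_dialogue(c("COME STAi", "tutto BENE"))
  expect_equal(sp$speaker, c("facilitator", "user"))
})

test_that("an all-blank transcript raises the empty-document condition", {
  expect_error(split_dialogue(c("", "   ")), class = "costylo_empty_document")
})

test_that("split_dialogue partitions the non-empty lines without loss", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    is_fac <- stats::runif(n) < 0.3
    lines <- replicate(n, paste(sample(letters, 8, TRUE), collapse = ""))
    lines[is_fac] <- toupper(lines[is_fac])
    sp <- split_dialogue(lines)
    expect_equal(sp$speaker, ifelse(is_fac, "facilitator", "user"))
    back <- c(strsplit(sp$user, "\n")[[1]], strsplit(sp$facilitator, "\n")[[1]])
    expect_setequal(back, lines)
    expect_length(back, n)
  }
})

test_that("strip_names removes whole words case-insensitively, counted exactly", {
  expect_equal(strip_names("ciao NAME come stai", "NAME"), "ciao come stai")
  expect_equal(strip_names("testo invariato", character(0)), "testo invariato")
  # planted names drop the token count by exactly their number
  base <- rep("parola", 50)
  pos <- c(3, 9, 17, 22, 30, 41, 48)
  base[pos] <- c("Anna", "ANNA", "anna", "Marco", "marco", "Anna", "MARCO")
  txt <- paste(base, collapse = " ")
  out <- strip_names(txt, c("anna", "marco"))
  expect_equal(length(tokenize(out)), 50 - length(pos))
  # names inside longer words are untouched
  expect_equal(strip_names("annata di marcotte", c("anna", "marco")),
               "annata di marcotte")
})

test_that("assemble_pairs builds one text per distinct pairing, in order", {
  sess <- data.frame(
    session_id = paste0("s", 1:5),
    user_id = c("U1", "U1", "U1", "U1", "U1"),
    facilitator_id = c("F1", "F1", "F2", "F1", "F2"),
    user_text = c("uno", "due", "tre", "quattro", "cinque"),
    stringsAsFactors = FALSE
  )
  pairs <- assemble_pairs(sess)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$label, c("U1_F1", "U1_F2"))
  expect_equal(pairs$text[1], "uno\ndue\nquattro")  # session order preserved
  expect_equal(pairs$word_count, c(3L, 2L))
  expect_equal(pairs$n_sessions, c(3L, 2L))
  expect_error(assemble_pairs(sess[, 1:2]),
               class = "costylo_malformed_metadata")
})

test_that("the length filter is a strict inequality at the threshold", {
  pairs <- data.frame(label = c("a", "b", "c"),
                      word_count = c(5000L, 5001L, 120L))
  out <- suppressMessages(filter_min_words(pairs))
  expect_equal(out$label, "b")
  expect_equal(attr(out, "excluded"), c("a", "c"))
})

test_that("four-way chunking recombines quarters per scheme and partitions tokens", {
  toks <- letters[1:8]
  a <- chunk_four_way(toks, "A")
  expect_equal(a$chunk1, c("a", "b", "c", "d"))
  expect_equal(a$chunk2, c("e", "f", "g", "h"))
  expect_equal(a$labels, c("1-2", "3-4"))
  cc <- chunk_four_way(toks, "C")
  expect_equal(cc$chunk1, c("a", "b", "g", "h"))
  expect_equal(cc$chunk2, c("c", "d", "e", "f"))
  b <- chunk_four_way(toks, "B")
  expect_equal(b$chunk1, c("a", "b", "e", "f"))

  expect_error(chunk_four_way(letters[1:3], "A"),
               class = "costylo_degenerate_input")

  # remainder bookkeeping: 10007 tokens -> quarters 2502/2502/2502/2501
  toks <- rep("x", 10007)
  cp <- chunk_four_way(toks, "A")
  expect_equal(cp$quarter_sizes, c(2502L, 2502L, 2502L, 2501L))

  # property: for every scheme and ragged length, the chunks partition the
  # parent multiset and differ by at most 3 tokens
  set.seed(11)
  for (n in c(4, 7, 10, 41, 1003)) {
    toks <- sample(letters, n, TRUE)
    for (sch in c("A", "B", "C")) {
      cp <- chunk_four_way(toks, sch)
      expect_equal(sort(c(cp$chunk1, cp$chunk2)), sort(toks))
      expect_lte(abs(length(cp$chunk1) - length(cp$chunk2)), 3)
    }
  }
})

test_that("a rendered synthetic corpus round-trips through the parser", {
  corp <- generate_corpus(center1_design()[1:3, ], lambda = 0.5,
                          words_per_pair = 600, V = 200, seed = 5)
  dir <- withr::local_tempdir()
  man <- write_corpus(corp, dir, sessions_per_pair = 3)
  expect_equal(nrow(man), 9)

  sess <- read_session_dir(dir, manifest = file.path(dir, "manifest.csv"))
  pairs <- assemble_pairs(sess)
  expect_equal(sort(pairs$label), sort(corp$meta$label))
  for (i in seq_len(nrow(pairs))) {
    got <- tokenize(pairs$text[i])
    expect_identical(got, corp$samples[[pairs$label[i]]])
  }

  # same result from the naming convention alone (no manifest)
  pairs2 <- assemble_pairs(read_session_dir(dir))
  expect_equal(pairs2$word_count[order(pairs2$label)],
               pairs$word_count[order(pairs$label)])
})
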