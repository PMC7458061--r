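test_that("read_pubtator parses documents, expands composites, drops -1", {
  txt <- paste(
    "6203632|t|Hydralazine and lupus syndrome.",
    "6203632|a|A case with hemolytic anemia is reported after hepatitis.",
    "6203632\t0\t11\tHydralazine\tChemical\tD007545",
    "6203632\t16\t21\tlupus\tDisease\tD006332",
    "6203632\t44\t60\themolytic anemia\tDisease\tD006965|D006984",
    "6203632\t79\t88\thepatitis\tDisease\t-1",
    "6203632\tCID\tD007545\tD006332",
    sep = "\n")
  docs <- read_pubtator(txt)
  expect_length(docs, 1L)
  d <- docs[[1]]
  expect_equal(d$doc_id, "6203632")
  expect_setequal(d$mentions$concept_id,
                  c("D007545", "D006332", "D006965", "D006984"))
  expect_equal(sum(d$mentions$concept_id %in% c("D006965", "D006984")), 2L)
  expect_equal(nrow(d$relations), 1L)
  expect_equal(d$text, paste("Hydralazine and lupus syndrome.",
                             "A case with hemolytic anemia is reported after hepatitis."))
})

test_that("read_pubtator handles empty input, errors, and duplicates", {
  expect_equal(read_pubtator(""), list())
  expect_error(read_pubtator("garbage line without pipes"), "line 1")
  bad <- paste("1|t|Title here", "1|a|Abstract.", "1\t100\t110\tx\tChemical\tD1",
               sep = "\n")
  expect_error(read_pubtator(bad), "outside text")
  dup <- paste("1|t|T", "1|a|A", "1\tCID\tD1\tD2", "1\tCID\tD1\tD2", sep = "\n")
  withr::with_options(list(docgraphre.verbose = TRUE),
                      expect_message(docs <- read_pubtator(dup), "duplicate"))
  expect_equal(nrow(docs[[1]]$relations), 1L)
})

test_that("PubTator round trip is lossless and deterministic", {
  docs <- generate_corpus(small_spec(10L, seed = 3L))
  txt <- write_pubtator(docs)
  expect_identical(write_pubtator(docs), txt)          # byte-identical rerun
  docs2 <- read_pubtator(txt)
  expect_identical(write_pubtator(docs2), txt)         # write . read == id
  expect_equal(length(docs2), length(docs))
  for (k in seq_along(docs)) {
    expect_equal(docs2[[k]]$text, docs[[k]]$text)
    expect_equal(docs2[[k]]$relations, docs[[k]]$relations)
    expect_equal(docs2[[k]]$mentions$concept_id, docs[[k]]$mentions$concept_id)
  }
})

test_that("read_conllu attaches tokens/parses and validates trees", {
  doc <- new_document("9", "aa bb cc")
  cu <- paste("1\taa\t_\tNOUN\t_\t_\t2\tnsubj\t_\t_",
              "2\tbb\t_\tVERB\t_\t_\t0\troot\t_\t_",
              "3\tcc\t_\tNOUN\t_\t_\t2\tobj\t_\t_", sep = "\n")
  d <- read_conllu(cu, doc)
  expect_equal(which(d$parses[[1]]$head == 0L), 2L)
  expect_equal(d$tokens$pos_tag, c("NOUN", "VERB", "NOUN"))
  expect_equal(d$tokens$char_start, c(0L, 3L, 6L))

  cyc <- paste("1\taa\t_\tN\t_\t_\t2\tdep\t_\t_",
               "2\tbb\t_\tN\t_\t_\t1\tdep\t_\t_",
               "3\tcc\t_\tN\t_\t_\t2\tdep\t_\t_", sep = "\n")
  expect_error(read_conllu(cyc, doc), "root|cycle")
  mism <- paste("1\txx\t_\tN\t_\t_\t0\troot\t_\t_", sep = "\n")
  expect_error(read_conllu(mism, doc), "does not match")
})

test_that("CoNLL-U round trip through attach_parses is byte-identical", {
  docs <- generate_corpus(small_spec(8L, seed = 5L))
  cu <- write_conllu(docs)
  stripped <- read_pubtator(write_pubtator(docs))
  back <- attach_parses(stripped, cu)
  expect_identical(write_conllu(back), cu)
  for (d in back) {
    for (p in d$parses) expect_true(oracle_is_tree(p$head))
  }
})

test_that("align_mentions fills spans; multi-token and cross-boundary cases", {
  doc <- make_doc(
    list(chain_sentence(c("sinus", "bradycardia", "and", "atrioventricular",
                          "block", "occurred"))),
    list(list(type = "Disease", concept = "D054537", sentence = 1, tok = 4:5),
         list(type = "Disease", concept = "D001919", sentence = 1, tok = 2)))
  m <- doc$mentions
  expect_equal(m$tok_end[1] - m$tok_start[1] + 1L, 2L)  # two-token span
  expect_equal(m$tok_end[2] - m$tok_start[2] + 1L, 1L)
  # detokenised span text reproduces the mention text
  expect_equal(paste(doc$tokens$surface[m$tok_start[1]:m$tok_end[1]],
                     collapse = " "), m$text[1])
})

test_that("aligned spans cover the mention characters on random corpora", {
  docs <- generate_corpus(small_spec(15L, seed = 8L))
  for (d in docs) {
    m <- d$mentions
    for (i in seq_len(nrow(m))) {
      toks <- d$tokens[m$tok_start[i]:m$tok_end[i], ]
      expect_lte(min(toks$char_start), m$char_start[i])
      expect_gte(max(toks$char_end), m$char_end[i])
      expect_equal(paste(toks$surface, collapse = " "), m$text[i])
    }
  }
})
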