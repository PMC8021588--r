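test_that("base-pair classification matches the five-class table", {
  expected <- list(
    "0" = list(c("A", "T"), c("T", "A")),
    "1" = list(c("C", "G"), c("G", "C")),
    "2" = list(c("A", "A"), c("A", "G"), c("G", "A"), c("G", "G"),
               c("C", "C")),
    "3" = list(c("T", "T"), c("T", "C"), c("C", "T")),
    "4" = list(c("C", "A"), c("A", "C"), c("G", "T"), c("T", "G")))
  for (cls in names(expected)) {
    for (pr in expected[[cls]]) {
      expect_equal(classify_base_pair(pr[1], pr[2]), as.integer(cls))
    }
  }
  expect_error(classify_base_pair("A", "N"))
})

test_that("region encoding picks the context letter set and case", {
  expect_equal(encode_region(c(0L, 1L), "initial_forward"), "ab")
  expect_equal(encode_region(1L, "hairpin_dimer"), "l")
  expect_equal(encode_region(c(0L, 0L, 1L), "initial_forward",
                             priming = TRUE), "AAB")
  expect_equal(encode_region(c(0L, 1L, 2L, 3L, 4L), "initial_reverse"),
               "fghij")
  expect_equal(encode_region(c(0L, 1L, 2L, 3L, 4L), "middle_forward"),
               "pqrst")
  expect_equal(encode_region(c(0L, 1L, 2L, 3L, 4L), "middle_reverse"),
               "uvwxy")
  expect_equal(encode_region(integer(0), "initial_forward"), "")
})

test_that("word chunking repeats 3'-proximal chunks and drops short remainders", {
  expect_equal(words_from_region("aabbbaabbaab"),
               c("bbaab", "bbaab", "bbbaa"))
  expect_equal(words_from_region("abcde"), "abcde")
  expect_equal(words_from_region("abcd"), character(0))
  expect_equal(words_from_region(""), character(0))
  # total multiplicity is n(n+1)/2 for n chunks
  set.seed(9)
  for (len in c(5L, 9L, 10L, 17L, 25L, 32L)) {
    letters5 <- paste(sample(c("a", "b", "c", "d", "e"), len,
                             replace = TRUE), collapse = "")
    n <- len %/% 5L
    expect_length(words_from_region(letters5), n * (n + 1L) / 2L)
  }
})

test_that("the pentacode vocabulary counts 5^5 words per context and case", {
  expect_equal(vocabulary_size(), 31250L)
  vocab <- enumerate_vocabulary()
  expect_equal(length(unique(vocab)), 31250L)
  expect_true(all(nchar(vocab) == 5L))
})

test_that("nonsense sentences are reproducible and uniform over the vocabulary", {
  expect_length(nonsense_sentence(0L)$tokens, 0L)
  a <- nonsense_sentence(50L, seed = 123L)
  b <- nonsense_sentence(50L, seed = 123L)
  expect_identical(a$tokens, b$tokens)
  big <- nonsense_sentence(1e5, seed = 7L)
  vocab <- enumerate_vocabulary()
  counts <- table(factor(big$tokens, levels = vocab))
  p <- suppressWarnings(stats::chisq.test(as.vector(counts)))$p.value
  expect_gt(p, 0.001)
})

test_that("pseudo-sentences are deterministic and mark priming sites uppercase", {
  set.seed(10)
  fx <- planted_fixture(tpl_len = 320L, span = 150L)
  s1 <- build_pseudo_sentence(fx$pair, fx$template)
  s2 <- build_pseudo_sentence(fx$pair, fx$template)
  expect_identical(s1$tokens, s2$tokens)
  expect_false(is.na(s1$dG_fwd))
  expect_false(is.na(s1$dG_rev))
  # both selected sites appear as uppercase initial-stage words
  upper <- s1$tokens[grepl("^[A-Z]+$", s1$tokens)]
  expect_true(any(grepl("^[A-E]+$", upper)))  # forward priming site
  expect_true(any(grepl("^[F-J]+$", upper)))  # reverse priming site
  # middle-stage words for the perfect primer-product duplex
  expect_true(any(grepl("^[pq]+$", s1$tokens)))
  expect_true(any(grepl("^[uv]+$", s1$tokens)))
})

test_that("token order is hairpins, dimers, then template position", {
  set.seed(12)
  fx <- planted_fixture(tpl_len = 320L, span = 150L)
  # force a hairpin and a cross-dimer by engineering the primer tails
  pair <- fx$pair
  s <- build_pseudo_sentence(pair, fx$template)
  kinds <- ifelse(grepl("^[k-o]+$", s$tokens), "structure",
                  ifelse(grepl("^[a-jA-J]+$", s$tokens), "initial",
                         "middle"))
  first_initial <- match("initial", kinds)
  if (!is.na(first_initial) && any(kinds == "structure")) {
    expect_true(max(which(kinds == "structure")) < first_initial)
  }
  # every token is in the enumerated vocabulary
  expect_true(all(s$tokens %in% enumerate_vocabulary()))
})

test_that("template-stage words walk the forward strand by candidate start", {
  set.seed(13)
  fx <- planted_fixture(tpl_len = 400L, span = 150L)
  s <- build_pseudo_sentence(fx$pair, fx$template)
  # the uppercase forward-site words must precede the uppercase
  # reverse-site words (selection is ordered along the template)
  fw_up <- grep("^[A-E]+$", s$tokens)
  rv_up <- grep("^[F-J]+$", s$tokens)
  if (length(fw_up) && length(rv_up)) {
    expect_lt(min(fw_up), min(rv_up))
  }
})

test_that("empty sentences arise when nothing binds", {
  pair <- list(pair_id = "p", fwd_name = "f",
               fwd_seq = "CCCCCCCCCCCCCCCCCCCC",
               rev_name = "r", rev_seq = "CCCCCCCCCCCCCCCCCCCC")
  tpl <- list(id = "t", seq = strrep("A", 200))
  s <- build_pseudo_sentence(pair, tpl)
  expect_length(s$tokens, 0L)
  expect_true(is.na(s$dG_fwd))
})

test_that("corpus files round-trip sentences exactly", {
  set.seed(14)
  fx <- planted_fixture()
  s <- build_pseudo_sentence(fx$pair, fx$template)
  s$label <- 1L
  empty <- new_pseudo_sentence("p2", "t2")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(list(s, empty), f)
  back <- read_corpus(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$tokens, s$tokens)
  expect_equal(back[[1]]$label, 1L)
  expect_equal(back[[1]]$dG_fwd, s$dG_fwd, tolerance = 1e-8)
  expect_true(is.na(back[[2]]$label))
  expect_length(back[[2]]$tokens, 0L)
})
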