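test_that("a planted perfect site yields one full-length candidate per strand sense", {
  set.seed(21)
  tpl <- random_dna(120)
  primer <- substr(tpl, 41, 50)  # primer text matches the forward strand
  cands <- find_3prime_matches(primer, tpl, primer_id = "p")
  full <- cands[cands$length == 10L, ]
  fw <- full[full$orientation == "forward", ]
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$tpl_start, 40L)
  expect_equal(fw$tpl_end, 50L)
  expect_equal(fw$match_count, 10L)
  # a template containing the reverse complement is bound on the forward
  # strand itself: reverse orientation
  tpl2 <- paste0(substr(tpl, 1, 60), reverse_complement(primer),
                 substr(tpl, 61, 120))
  cands2 <- find_3prime_matches(primer, tpl2, primer_id = "p")
  expect_true(any(cands2$orientation == "reverse" & cands2$length == 10L &
                    cands2$match_count == 10L))
})

test_that("hopeless sequences produce no candidates", {
  expect_equal(nrow(find_3prime_matches("CCCCCCCCCC",
                                        "AAAAAAAAAAAAAAAAAAAA")), 0L)
})

test_that("the 80% identity rule follows ceil(0.8 L) exactly", {
  # suffix of 10 with exactly 8 matches: accepted (ceil(8) = 8)
  tpl_core <- "ACGTACGTAC"
  primer10 <- "TTGTACGTAC"                # 2 mismatches at the 5' end
  tpl <- paste0("GGGGGGGGGG", tpl_core, "GGGGGGGGGG")
  got <- find_3prime_matches(primer10, tpl, primer_id = "p")
  ora <- oracle_3prime_matches(primer10, tpl)
  expect_equal(got[order(got$orientation, got$tpl_start, got$length),
                   c("orientation", "tpl_start", "tpl_end", "length",
                     "match_count")],
               ora, ignore_attr = TRUE)
  expect_true(any(got$length == 10L & got$match_count == 8L))
  # 7 of 10 with no shorter qualifying suffix: rejected everywhere
  primer7 <- "TTTGTTCGAC"   # mismatches spread so no 5..10 suffix reaches 80%
  ora7 <- oracle_3prime_matches(primer7, tpl_core)
  got7 <- find_3prime_matches(primer7, tpl_core)
  expect_equal(nrow(got7), nrow(ora7))
})

test_that("optimized candidate search agrees with brute-force enumeration", {
  set.seed(33)
  for (case in 1:12) {
    primer <- random_dna(sample(8:22, 1))
    tpl <- random_dna(sample(60:200, 1))
    got <- find_3prime_matches(primer, tpl, primer_id = "p")
    got <- got[order(got$orientation, got$tpl_start, got$length),
               c("orientation", "tpl_start", "tpl_end", "length",
                 "match_count")]
    expect_equal(got, oracle_3prime_matches(primer, tpl),
                 ignore_attr = TRUE)
  }
})

test_that("reported candidates always satisfy their invariants", {
  set.seed(34)
  for (case in 1:8) {
    primer <- random_dna(sample(10:22, 1))
    tpl <- random_dna(150)
    c <- find_3prime_matches(primer, tpl, primer_id = "p")
    if (!nrow(c)) next
    expect_true(all(c$length >= 5L & c$length <= 22L))
    expect_true(all(nchar(c$classes) == c$length))
    expect_true(all(c$match_count >= ceiling(0.8 * c$length)))
    expect_true(all(c$tpl_end - c$tpl_start == c$length))
  }
})

test_that("reverse-orientation candidates equal forward candidates on the rc template", {
  set.seed(35)
  primer <- random_dna(18)
  tpl <- random_dna(140)
  n <- nchar(tpl)
  all_c <- find_3prime_matches(primer, tpl, primer_id = "p")
  rev_c <- all_c[all_c$orientation == "reverse", ]
  on_rc <- find_3prime_matches(primer, reverse_complement(tpl),
                               primer_id = "p")
  fw_rc <- on_rc[on_rc$orientation == "forward", ]
  # map rc-template forward coordinates back to the original strand
  mapped <- data.frame(tpl_start = n - fw_rc$tpl_end,
                       tpl_end = n - fw_rc$tpl_start,
                       length = fw_rc$length,
                       match_count = fw_rc$match_count)
  o1 <- rev_c[order(rev_c$tpl_start),
              c("tpl_start", "tpl_end", "length", "match_count")]
  o2 <- mapped[order(mapped$tpl_start), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("hairpin detection finds the canonical stem-loop and honors thresholds", {
  hp <- find_hairpins("GGGGGAAAACCCCC")
  expect_length(hp, 1L)
  expect_equal(hp[[1]]$stem_length, 5L)
  expect_true(hp[[1]]$three_prime_annealed)
  expect_false(hp[[1]]$three_prime_recessed)  # no 5' overhang to copy
  expect_equal(find_hairpins("AAAAAAAAAAAA"), list())
  # stem of only 4 pairs is below the detection threshold
  expect_equal(find_hairpins("GGGGAAACCCC"), list())
})

test_that("a 3'-recessed hairpin yields the self-extension product", {
  # TTTTT overhang, then stem GGGGG..CCCCC with the 3' end in the stem
  p <- "TTTTTGGGGGAAAACCCCC"
  hp <- find_hairpins(p)
  rec <- Filter(function(h) h$three_prime_recessed, hp)
  expect_length(rec, 1L)
  expect_equal(extend_from_duplex(rec[[1]]),
               paste0(p, reverse_complement("TTTTT")))
})

test_that("dimer detection: full-length, impossible, and mutual 3' overlap", {
  set.seed(36)
  a <- random_dna(16)
  d_full <- find_dimers(a, reverse_complement(a))
  expect_true(any(vapply(d_full, function(d) d$stem_length, 0L) == 16L))
  expect_equal(find_dimers("AAAAAAAA", "AAAAAAAA"), list())
  # 3'-terminal 5-base mutual overlap with both 5' overhangs
  x <- "TTTTTTTGCAGC"           # 3' end GCAGC
  y <- paste0("AAAAAAA", reverse_complement("GCAGC"))  # 3' end GCTGC
  dd <- find_dimers(x, y, ids = c("x", "y"))
  both <- Filter(function(d) all(d$three_prime_recessed), dd)
  expect_length(both, 1L)
  ext <- extend_from_duplex(both[[1]])
  expect_setequal(ext, c(paste0(x, reverse_complement("AAAAAAA")),
                         paste0(y, reverse_complement("TTTTTTT"))))
})

test_that("blunt duplexes do not extend", {
  a <- "GCAGCTTTTT"
  d <- find_dimers(a, reverse_complement(a))
  full <- Filter(function(s) s$stem_length == 10L, d)
  expect_true(length(full) >= 1L)
  expect_equal(extend_from_duplex(full[[1]]), character(0))
})

test_that("primer-set expansion adds fill-in products and reaches a fixed point", {
  # pair with no self-structures at all
  quiet <- list(fwd_name = "f", fwd_seq = "AAAAAAAAAAAAAAAAAAAA",
                rev_name = "r", rev_seq = "AGAGAGAGAGAGAGAGAGAG")
  expect_equal(nrow(expand_primer_set(quiet)), 2L)
  # planted extensible 3' overlap between fwd and rev
  hot <- list(fwd_name = "f", fwd_seq = "TTGACTTCAATTTTTGCAGC",
              rev_name = "r",
              rev_seq = paste0("CAACCAA", reverse_complement("GCAGC")))
  ex1 <- expand_primer_set(hot, rounds = 1L)
  expect_gt(nrow(ex1), 2L)
  expect_equal(ex1$seq[1:2], c(hot$fwd_seq, hot$rev_seq))
  # if a further round adds nothing the set is a fixed point
  ex2 <- expand_primer_set(hot, rounds = 2L)
  ex1_again <- expand_primer_set(hot, rounds = 1L)
  if (nrow(ex2) == nrow(ex1)) expect_equal(ex2$seq, ex1_again$seq)
  expect_lte(nrow(expand_primer_set(hot, rounds = 5L)), 16L)
})
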