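# Duplex search: 3'-anchored partial primer-template duplexes, primer
# hairpins, primer-primer dimers, and simulated polymerase fill-in
# products that are added back to the primer set.
#
# Orientation convention: "forward" means the primer anneals to the
# reverse-complement strand (its text matches the template forward
# strand) so extension proceeds along the forward strand; "reverse"
# means the primer anneals to the forward strand itself.  Coordinates
# are always 0-based half-open on the forward strand.

# Forward-orientation scan of one primer against one template strand
# given as a character string whose letters the primer must match
# one-for-one.  Returns, per 3' anchor, the maximal qualifying suffix.
# Anchors are 1-based template indices of the primer's 3'-terminal base.
.scan_suffixes <- function(primer, tpl, min_len, max_len, identity) {
  plen <- nchar(primer)
  n <- nchar(tpl)
  kmax <- min(plen, max_len)
  if (plen < min_len || n < min_len) {
    return(list(anchor = integer(0), len = integer(0), count = integer(0)))
  }
  pv <- utf8ToInt(primer)
  tv <- utf8ToInt(tpl)
  # cum[k, a] = matches among the k 3'-terminal primer bases aligned with
  # the primer 3' end at template position a (needs a >= k)
  cum <- matrix(0L, nrow = kmax, ncol = n)
  run <- integer(n)
  for (k in seq_len(kmax)) {
    pb <- pv[plen - k + 1L]
    eq <- integer(n)
    eq[k:n] <- as.integer(tv[1:(n - k + 1L)] == pb)
    run <- run + eq
    cum[k, ] <- run
  }
  best_len <- integer(n)
  best_cnt <- integer(n)
  for (L in min_len:kmax) {
    thr <- ceiling(identity * L)
    ok <- seq_len(n) >= L & cum[L, ] >= thr
    best_len[ok] <- L          # ascending L: longer qualifying suffix wins
    best_cnt[ok] <- cum[L, ok]
  }
  sel <- which(best_len > 0L)
  list(anchor = sel, len = best_len[sel], count = best_cnt[sel])
}

.empty_candidates <- function() {
  data.frame(primer_id = character(0), orientation = character(0),
             tpl_start = integer(0), tpl_end = integer(0),
             length = integer(0), match_count = integer(0),
             classes = character(0), stringsAsFactors = FALSE)
}

#' Find 3'-anchored partial primer-template duplexes
#'
#' Every 3'-terminal primer suffix of length `min_len` to `max_len` is
#' slid over both template strands; a binding candidate is emitted
#' wherever the Watson-Crick match count reaches
#' `ceiling(identity * length)`.  Only maximal candidates are kept: a
#' qualifying suffix wholly contained in a longer qualifying suffix at
#' the same 3' anchor and strand is suppressed.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param template Template as a list/row with fields `id` and `seq`
#'   (forward strand), or a plain sequence string.
#' @param min_len,max_len Suffix length bounds (defaults 5 and 22).
#' @param identity Required match fraction (default 0.8).
#' @param primer_id Identifier recorded in the output.
#' @return A data.frame of candidates with columns `primer_id`,
#'   `orientation`, `tpl_start`, `tpl_end` (0-based half-open, forward
#'   strand), `length`, `match_count` and `classes` (digit string of
#'   base-pair classes, 5'->3' along the primer).
#' @export
find_3prime_matches <- function(primer, template, min_len = 5L,
                                max_len = 22L, identity = 0.8,
                                primer_id = "primer") {
  tpl <- if (is.list(template)) template$seq else template
  .check_dna(primer, "primer")
  .check_dna(tpl, "template")
  plen <- nchar(primer)
  if (plen < min_len) stop("primer shorter than min_len", call. = FALSE)
  n <- nchar(tpl)
  pv <- .chars(primer)
  out <- list()

  # forward orientation: primer text matches the forward strand;
  # the primer pairs with the complement of the forward-strand base
  fw <- .scan_suffixes(primer, tpl, min_len, max_len, identity)
  if (length(fw$anchor)) {
    tv <- .chars(tpl)
    comp <- chartr("ACGT", "TGCA", tv)
    rows <- lapply(seq_along(fw$anchor), function(i) {
      a <- fw$anchor[i]; L <- fw$len[i]
      suff <- pv[(plen - L + 1L):plen]
      partner <- comp[(a - L + 1L):a]
      cls <- .classify_pairs(suff, partner)
      data.frame(primer_id = primer_id, orientation = "forward",
                 tpl_start = a - L, tpl_end = a, length = L,
                 match_count = fw$count[i],
                 classes = paste(cls, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    out <- c(out, rows)
  }

  # reverse orientation: scan against the reverse-complement strand and
  # map coordinates back; the primer pairs with forward-strand bases
  rc <- reverse_complement(tpl)
  rv <- .scan_suffixes(primer, rc, min_len, max_len, identity)
  if (length(rv$anchor)) {
    rcv <- .chars(rc)
    comp_rc <- chartr("ACGT", "TGCA", rcv)  # = forward-strand bases
    rows <- lapply(seq_along(rv$anchor), function(i) {
      a <- rv$anchor[i]; L <- rv$len[i]
      suff <- pv[(plen - L + 1L):plen]
      partner <- comp_rc[(a - L + 1L):a]
      cls <- .classify_pairs(suff, partner)
      data.frame(primer_id = primer_id, orientation = "reverse",
                 tpl_start = n - a, tpl_end = n - a + L, length = L,
                 match_count = rv$count[i],
                 classes = paste(cls, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    out <- c(out, rows)
  }
  if (!length(out)) return(.empty_candidates())
  do.call(rbind, out)
}

.new_self_structure <- function(kind, primer_ids, stem_length, pair_classes,
                                three_prime_annealed, three_prime_recessed,
                                extension_products) {
  structure(list(kind = kind, primer_ids = primer_ids,
                 stem_length = stem_length, pair_classes = pair_classes,
                 three_prime_annealed = three_prime_annealed,
                 three_prime_recessed = three_prime_recessed,
                 extension_products = extension_products),
            class = "self_structure")
}

.wc_match <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Find hairpin structures within a primer
#'
#' Searches maximal antiparallel self-complementary stems of at least
#' `min_stem` contiguous Watson-Crick pairs with a loop of at least
#' `min_loop` bases.  A stem whose 3' arm ends at the primer 3' terminus
#' is flagged as 3'-annealed; when a 5' overhang exists upstream of the
#' 5' arm, the structure is 3'-recessed and carries the simulated
#' fill-in extension product.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param min_stem Minimum stem length (default 5).
#' @param min_loop Minimum loop length (default 3, the physical minimum).
#' @param primer_id Identifier recorded in the output.
#' @return A list of `self_structure` objects.
#' @export
find_hairpins <- function(primer, min_stem = 5L, min_loop = 3L,
                          primer_id = "primer") {
  .check_dna(primer, "primer")
  n <- nchar(primer)
  if (n < 2L * min_stem + min_loop) return(list())
  p <- .chars(primer)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (!.wc_match(p[i], p[j])) next
      # run start only: no extension outward
      if (i > 1L && j < n && .wc_match(p[i - 1L], p[j + 1L])) next
      L <- 0L
      while (i + L <= n && j - L >= 1L &&
             (j - L) - (i + L) - 1L >= min_loop &&
             .wc_match(p[i + L], p[j - L])) {
        L <- L + 1L
      }
      if (L < min_stem) next
      cls <- .classify_pairs(p[i:(i + L - 1L)], p[j:(j - L + 1L)])
      annealed <- (j == n)
      recessed <- annealed && i > 1L
      ext <- character(0)
      if (recessed) {
        ext <- paste0(primer,
                      reverse_complement(substr(primer, 1L, i - 1L)))
      }
      res[[length(res) + 1L]] <-
        .new_self_structure("hairpin", primer_id, L, cls,
                            annealed, recessed, ext)
    }
  }
  res
}

#' Find dimer structures between two primers
#'
#' Enumerates antiparallel alignments of primers `a` and `b` and reports
#' maximal contiguous Watson-Crick runs of at least `min_len` pairs.
#' For each run, a 3' end lying inside the duplex with a 5' overhang on
#' the partner is 3'-recessed; the simulated fill-in product (the strand
#' extended with the complement of the partner overhang) is recorded.
#'
#' @param a,b Primer sequences, 5'->3' (use the same sequence twice for a
#'   self-dimer).
#' @param min_len Minimum duplex length (default 5).
#' @param ids Character vector of length 2 with the two primer ids.
#' @return A list of `self_structure` objects.
#' @export
find_dimers <- function(a, b, min_len = 5L, ids = c("a", "b")) {
  .check_dna(a, "primer a")
  .check_dna(b, "primer b")
  la <- nchar(a); lb <- nchar(b)
  av <- .chars(a); bv <- .chars(b)
  res <- list()
  # antiparallel: a[i] pairs b[j] with i + j = s constant
  for (s in 2L:(la + lb)) {
    i_lo <- max(1L, s - lb)
    i_hi <- min(la, s - 1L)
    if (i_hi - i_lo + 1L < min_len) next
    ii <- i_lo:i_hi
    m <- .wc_match(av[ii], bv[s - ii])
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      if (!r$values[q] || r$lengths[q] < min_len) next
      i0 <- ii[starts[q]]; i1 <- ii[ends[q]]
      L <- i1 - i0 + 1L
      j_at_i1 <- s - i1   # b index paired with a's most-3' run base
      j_at_i0 <- s - i0
      cls <- .classify_pairs(av[i0:i1], bv[s - (i0:i1)])
      a_annealed <- (i1 == la)
      a_recessed <- a_annealed && j_at_i1 > 1L
      b_annealed <- (j_at_i0 == lb)
      b_recessed <- b_annealed && i0 > 1L
      ext <- character(0)
      if (a_recessed) {
        ext <- c(ext, paste0(a, reverse_complement(
          substr(b, 1L, j_at_i1 - 1L))))
      }
      if (b_recessed) {
        ext <- c(ext, paste0(b, reverse_complement(
          substr(a, 1L, i0 - 1L))))
      }
      res[[length(res) + 1L]] <-
        .new_self_structure("dimer", ids, L, cls,
                            c(a = a_annealed, b = b_annealed),
                            c(a = a_recessed, b = b_recessed),
                            ext)
    }
  }
  res
}

#' Extension products of a hairpin or dimer
#'
#' Returns the simulated polymerase fill-in products for a structure
#' detected by [find_hairpins()] or [find_dimers()]: each 3'-recessed
#' strand concatenated with the complement of its partner's 5' overhang.
#' One fill-in only; no strand displacement.
#'
#' @param structure A `self_structure` object.
#' @return Character vector of extended sequences (length 0 when no 3'
#'   end is recessed, up to 2 for a dimer with both ends recessed).
#' @export
extend_from_duplex <- function(structure) {
  stopifnot(inherits(structure, "self_structure"))
  structure$extension_products
}

#' Expand a primer set with hairpin/dimer extension products
#'
#' Starting from the forward and reverse primer, each round searches
#' hairpins in every member and dimers between every member combination
#' (including self-dimers), simulates fill-in extension, and adds the
#' deduplicated products back to the set.  Capped at `rounds` iterations
#' and `max_members` members to guarantee termination.
#'
#' @param pair A primer pair (list/row with `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq`).
#' @param rounds Number of expansion rounds (default 1).
#' @param min_stem Minimum paired length for detection/extension
#'   (default 5).
#' @param max_members Hard cap on set size (default 16).
#' @return A data.frame with columns `id` and `seq`; the first two rows
#'   are the original forward and reverse primer.
#' @export
expand_primer_set <- function(pair, rounds = 1L, min_stem = 5L,
                              max_members = 16L) {
  stopifnot(rounds >= 0L)
  ids <- c(if (!is.null(pair$fwd_name)) pair$fwd_name else "fwd",
           if (!is.null(pair$rev_name)) pair$rev_name else "rev")
  seqs <- c(pair$fwd_seq, pair$rev_seq)
  for (r in seq_len(rounds)) {
    new_seqs <- character(0)
    for (i in seq_along(seqs)) {
      for (h in find_hairpins(seqs[i], min_stem = min_stem,
                              primer_id = ids[i])) {
        new_seqs <- c(new_seqs, h$extension_products)
      }
    }
    for (i in seq_along(seqs)) {
      for (j in i:length(seqs)) {
        for (d in find_dimers(seqs[i], seqs[j], min_len = min_stem,
                              ids = c(ids[i], ids[j]))) {
          new_seqs <- c(new_seqs, d$extension_products)
        }
      }
    }
    new_seqs <- setdiff(unique(new_seqs), seqs)
    if (!length(new_seqs)) break
    room <- max_members - length(seqs)
    if (room <= 0L) break
    new_seqs <- new_seqs[seq_len(min(room, length(new_seqs)))]
    seqs <- c(seqs, new_seqs)
    ids <- c(ids, paste0("ext", r, "_", seq_along(new_seqs)))
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}
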