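# Pseudo-sentence assembly: the full encoding pipeline for one
# primer-pair x template combination.
#
# Token order: hairpin words first, then dimer words (both in the
# hairpin/dimer letter set), then, walking the template forward strand
# by candidate start, the initial-stage words of every binding
# candidate; each of the two selected priming sites is uppercased and
# immediately followed by its middle-stage words encoding the perfect
# primer-product duplex.

#' Construct a pseudo-sentence object
#'
#' @param pair_id,template_id Identifiers.
#' @param tokens Character vector of 5-letter words.
#' @param label 0, 1 or NA (unknown).
#' @param dG_fwd,dG_rev Priming-site Gibbs energies (kcal/mol) or NA.
#' @return A `pseudo_sentence` object.
#' @export
new_pseudo_sentence <- function(pair_id, template_id,
                                tokens = character(0), label = NA_integer_,
                                dG_fwd = NA_real_, dG_rev = NA_real_) {
  stopifnot(all(nchar(tokens) == 5L))
  structure(list(pair_id = as.character(pair_id),
                 template_id = as.character(template_id),
                 tokens = tokens,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 dG_fwd = dG_fwd, dG_rev = dG_rev),
            class = "pseudo_sentence")
}

#' @export
print.pseudo_sentence <- function(x, ...) {
  cat("<pseudo_sentence> ", x$pair_id, " x ", x$template_id,
      ": ", length(x$tokens), " tokens, label=",
      ifelse(is.na(x$label), "?", x$label), "\n", sep = "")
  invisible(x)
}

#' Encoder configuration
#'
#' Bundles every tunable of the encoding pipeline.  `extension_min` is
#' the paired-length threshold at which hairpins/dimers are assumed to
#' prime fill-in synthesis (5), `structure_word_min` the longer
#' threshold at which they are lettered into words (6).
#'
#' @param min_len,max_len 3'-suffix length bounds for template search.
#' @param identity Required match fraction for a binding candidate.
#' @param extension_min Minimum paired bases for fill-in extension.
#' @param structure_word_min Minimum paired bases for hairpin/dimer
#'   lettering.
#' @param rounds Primer-set expansion rounds.
#' @param thermo A [thermo_config()].
#' @param nn An [nn_table()] (loaded lazily when NULL).
#' @return A `sentence_config` list.
#' @export
sentence_config <- function(min_len = 5L, max_len = 22L, identity = 0.8,
                            extension_min = 5L, structure_word_min = 6L,
                            rounds = 1L, thermo = thermo_config(),
                            nn = NULL) {
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len), identity = identity,
                 extension_min = as.integer(extension_min),
                 structure_word_min = as.integer(structure_word_min),
                 rounds = as.integer(rounds), thermo = thermo, nn = nn),
            class = "sentence_config")
}

# words for the middle stage: the primer on the fully complementary PCR
# product, every pair Watson-Crick
.middle_words <- function(primer_seq, orientation) {
  pv <- .chars(primer_seq)
  cls <- .classify_pairs(pv, chartr("ACGT", "TGCA", pv))
  ctx <- if (orientation == "forward") "middle_forward" else "middle_reverse"
  words_from_region(encode_region(cls, ctx, priming = FALSE))
}

#' Build the pseudo-sentence for one primer pair and template
#'
#' Orchestrates the full encoding: primer-set expansion with
#' hairpin/dimer fill-in products, hairpin and dimer words, 3'-anchored
#' template binding candidates with nearest-neighbor energies,
#' minimum-energy priming-site selection (uppercased words), and
#' middle-stage words for the selected sites.
#'
#' @param pair Primer pair (list/row with `pair_id`, `fwd_name`,
#'   `fwd_seq`, `rev_name`, `rev_seq`).
#' @param template Template (list/row with `id`, `seq`).
#' @param cfg A [sentence_config()].
#' @return A `pseudo_sentence` (label NA; attach labels separately).
#' @export
build_pseudo_sentence <- function(pair, template, cfg = sentence_config()) {
  nn <- if (is.null(cfg$nn)) nn_table() else cfg$nn
  members <- expand_primer_set(pair, rounds = cfg$rounds,
                               min_stem = cfg$extension_min)
  tokens <- character(0)

  # (1) hairpin words, members in set order
  for (i in seq_len(nrow(members))) {
    for (h in find_hairpins(members$seq[i],
                            min_stem = cfg$structure_word_min,
                            primer_id = members$id[i])) {
      tokens <- c(tokens, words_from_region(
        encode_region(h$pair_classes, "hairpin_dimer")))
    }
  }
  # (2) dimer words, member combinations in set order (incl. self)
  for (i in seq_len(nrow(members))) {
    for (j in i:nrow(members)) {
      for (d in find_dimers(members$seq[i], members$seq[j],
                            min_len = cfg$structure_word_min,
                            ids = c(members$id[i], members$id[j]))) {
        tokens <- c(tokens, words_from_region(
          encode_region(d$pair_classes, "hairpin_dimer")))
      }
    }
  }

  # (3) template binding candidates, all members, both strands
  cand_list <- lapply(seq_len(nrow(members)), function(i) {
    find_3prime_matches(members$seq[i], template,
                        min_len = cfg$min_len, max_len = cfg$max_len,
                        identity = cfg$identity,
                        primer_id = members$id[i])
  })
  cands <- do.call(rbind, cand_list)
  dG_fwd <- NA_real_; dG_rev <- NA_real_
  sel_keys <- character(0)
  if (nrow(cands)) {
    seq_of <- stats::setNames(members$seq, members$id)
    cands$dG <- vapply(seq_len(nrow(cands)), function(i) {
      candidate_delta_g(cands[i, ], seq_of[[cands$primer_id[i]]],
                        template, nn, cfg$thermo)
    }, numeric(1))
    is_f <- cands$orientation == "forward"
    sel <- select_priming_sites(cands[is_f, , drop = FALSE],
                                cands[!is_f, , drop = FALSE],
                                cands$dG[is_f], cands$dG[!is_f],
                                cfg$thermo)
    if (!is.null(sel)) {
      dG_fwd <- sel$dG_fwd
      dG_rev <- sel$dG_rev
      key <- function(r) paste(r$primer_id, r$orientation, r$tpl_start,
                               r$tpl_end, sep = "|")
      sel_keys <- c(key(sel$fwd), key(sel$rev))
    }
    ord <- order(cands$tpl_start, cands$primer_id, cands$orientation,
                 cands$length)
    cands <- cands[ord, , drop = FALSE]
    for (i in seq_len(nrow(cands))) {
      r <- cands[i, ]
      cls <- as.integer(.chars(r$classes))
      ctx <- if (r$orientation == "forward") "initial_forward"
             else "initial_reverse"
      k <- paste(r$primer_id, r$orientation, r$tpl_start, r$tpl_end,
                 sep = "|")
      priming <- k %in% sel_keys
      tokens <- c(tokens, words_from_region(
        encode_region(cls, ctx, priming = priming)))
      if (priming) {
        tokens <- c(tokens, .middle_words(seq_of[[r$primer_id]],
                                          r$orientation))
      }
    }
  }

  new_pseudo_sentence(pair_id = pair$pair_id, template_id = template$id,
                      tokens = tokens, dG_fwd = dG_fwd, dG_rev = dG_rev)
}

#' Build the corpus for all primer-pair x template combinations
#'
#' @param pairs Primer table as from [parse_primer_table()].
#' @param templates Template table as from [read_fasta()].
#' @param labels Optional label table as from [parse_label_table()];
#'   combinations without an entry keep label NA.
#' @param cfg A [sentence_config()].
#' @param progress Print a progress line every `progress` sentences
#'   (0 = silent).
#' @return A list of `pseudo_sentence` objects, pairs varying slowest.
#' @export
make_corpus <- function(pairs, templates, labels = NULL,
                        cfg = sentence_config(), progress = 0L) {
  if (is.null(cfg$nn)) cfg$nn <- nn_table()
  lab_key <- NULL
  if (!is.null(labels)) {
    lab_key <- stats::setNames(labels$label,
                               paste(labels$pair_id, labels$template_id,
                                     sep = "\r"))
  }
  out <- vector("list", nrow(pairs) * nrow(templates))
  n <- 0L
  for (i in seq_len(nrow(pairs))) {
    pair <- as.list(pairs[i, ])
    for (j in seq_len(nrow(templates))) {
      tpl <- list(id = templates$id[j], seq = templates$seq[j])
      s <- build_pseudo_sentence(pair, tpl, cfg)
      if (!is.null(lab_key)) {
        lb <- lab_key[paste(pair$pair_id, tpl$id, sep = "\r")]
        if (!is.na(lb)) s$label <- as.integer(lb)
      }
      n <- n + 1L
      out[[n]] <- s
      if (progress > 0L && n %% progress == 0L) {
        message(n, " sentences encoded")
      }
    }
  }
  out
}

#' Write a corpus file
#'
#' One sample per line: tab-delimited `pair_id`, `template_id`, `label`
#' (`?` when unknown), `dG_fwd`, `dG_rev`, then the space-separated
#' tokens.
#'
#' @param corpus List of `pseudo_sentence` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  fmt_g <- function(x) ifelse(is.na(x), "NA", format(x, digits = 10))
  lines <- vapply(corpus, function(s) {
    paste(s$pair_id, s$template_id,
          ifelse(is.na(s$label), "?", s$label),
          fmt_g(s$dG_fwd), fmt_g(s$dG_rev),
          paste(s$tokens, collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(c("pair_id\ttemplate_id\tlabel\tdG_fwd\tdG_rev\ttokens",
               lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus file
#'
#' @param path Corpus file written by [write_corpus()].
#' @return A list of `pseudo_sentence` objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) return(list())
  if (startsWith(lines[1], "pair_id\t")) lines <- lines[-1]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed corpus line: ", ln, call. = FALSE)
    tokens <- if (length(f) >= 6L && nzchar(f[6])) {
      strsplit(f[6], " ", fixed = TRUE)[[1]]
    } else character(0)
    new_pseudo_sentence(
      pair_id = f[1], template_id = f[2],
      label = if (f[3] == "?") NA_integer_ else as.integer(f[3]),
      dG_fwd = suppressWarnings(as.numeric(f[4])),
      dG_rev = suppressWarnings(as.numeric(f[5])),
      tokens = tokens)
  })
}
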