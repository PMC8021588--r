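# Synthetic data generator.
#
# Emulates the study design: ~450 bp double-stranded templates, 19-22 nt
# primers with ~100-150 bp amplicons, and binary PCR labels driven by
# the Gibbs energy of the selected priming sites.  Labels deliberately
# derive from the same thermodynamic engine the encoder uses: synthetic
# runs test that the label signal is representable in the
# pseudo-language, not biological truth.

#' Synthetic dataset configuration
#'
#' Defaults mirror the study conditions: 31 templates of 435-481 bases,
#' 72 primer pairs of 19-22 nt with amplicons of 100-150 bp, and about a
#' quarter of the pairs planted as exact matches (the observed positive
#' fraction per matched pair's own template).
#'
#' @param n_templates Number of templates (default 31).
#' @param template_len_range Template length range (default c(435, 481)).
#' @param gc_range GC-fraction interval templates are drawn from
#'   (default c(0.4, 0.6), typical for 16S fragments).
#' @param n_pairs Number of primer pairs (default 72).
#' @param primer_len_range Primer length range (default c(19, 22)).
#' @param amplicon_range Planted amplicon span (default c(100, 150)).
#' @param matched_fraction Fraction of pairs planted as exact matches
#'   (default 0.25).
#' @param degraded_fraction Fraction of pairs planted as mutated matches
#'   (default 0.25; the remainder is random).
#' @param mutation_rate Per-base mutation rate for degraded primers,
#'   never touching the 3'-terminal 5 bases (default 0.08).
#' @param dg_threshold Gibbs-energy threshold tau (kcal/mol): label 1
#'   iff a priming selection exists with both site energies below tau
#'   (default -12, between a perfect ~20-mer duplex (about -15 to -25
#'   at 56 C) and spurious partial bindings (above about -8)).
#' @param label_noise Probability a label is flipped (default 0.05).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_templates = 31L,
                         template_len_range = c(435L, 481L),
                         gc_range = c(0.4, 0.6),
                         n_pairs = 72L,
                         primer_len_range = c(19L, 22L),
                         amplicon_range = c(100L, 150L),
                         matched_fraction = 0.25,
                         degraded_fraction = 0.25,
                         mutation_rate = 0.08,
                         dg_threshold = -12,
                         label_noise = 0.05,
                         seed = 1L) {
  stopifnot(label_noise >= 0, label_noise < 0.5,
            template_len_range[1] <= template_len_range[2],
            primer_len_range[1] <= primer_len_range[2],
            amplicon_range[1] <= amplicon_range[2])
  structure(list(n_templates = as.integer(n_templates),
                 template_len_range = as.integer(template_len_range),
                 gc_range = gc_range,
                 n_pairs = as.integer(n_pairs),
                 primer_len_range = as.integer(primer_len_range),
                 amplicon_range = as.integer(amplicon_range),
                 matched_fraction = matched_fraction,
                 degraded_fraction = degraded_fraction,
                 mutation_rate = mutation_rate,
                 dg_threshold = dg_threshold,
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one random template
#'
#' Draws a uniform-random ACGT sequence with length in
#' `template_len_range` and GC content targeted within `gc_range`
#' (uses the current RNG state).
#'
#' @param cfg A [synth_config()].
#' @param id Template identifier.
#' @return A list with `id` and `seq`.
#' @export
generate_template <- function(cfg = synth_config(), id = "t1") {
  len <- sample(cfg$template_len_range[1]:cfg$template_len_range[2], 1L)
  gc <- stats::runif(1, cfg$gc_range[1], cfg$gc_range[2])
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  list(id = id,
       seq = paste(sample(.DNA_BASES, len, replace = TRUE, prob = p),
                   collapse = ""))
}

.mutate_outside_3prime <- function(seq, rate, protect = 5L) {
  v <- .chars(seq)
  n <- length(v)
  if (n <= protect) return(seq)
  for (i in seq_len(n - protect)) {
    if (stats::runif(1) < rate) {
      v[i] <- sample(setdiff(.DNA_BASES, v[i]), 1L)
    }
  }
  paste(v, collapse = "")
}

#' Generate a primer pair for a template
#'
#' `matched` pairs copy a template substring as the forward primer and
#' the reverse complement of a downstream substring as the reverse
#' primer, with the amplicon span drawn from `amplicon_range`.
#' `degraded` pairs start matched and mutate bases at `mutation_rate`
#' everywhere except the 3'-terminal 5 bases (the positions whose
#' complementarity dominates whether extension starts).  `random` pairs
#' are uniform sequences.
#'
#' @param template A template (list with `id`, `seq`).
#' @param mode One of `"matched"`, `"degraded"`, `"random"`.
#' @param cfg A [synth_config()].
#' @param pair_id Identifier for the pair.
#' @return A list with `pair_id`, `fwd_name`, `fwd_seq`, `rev_name`,
#'   `rev_seq` and (for planted modes) `planted_start`, `planted_end`
#'   (0-based half-open forward-strand amplicon span).
#' @export
generate_primer_pair <- function(template, mode = c("matched", "degraded",
                                                    "random"),
                                 cfg = synth_config(), pair_id = "p1") {
  mode <- match.arg(mode)
  lf <- sample(cfg$primer_len_range[1]:cfg$primer_len_range[2], 1L)
  lr <- sample(cfg$primer_len_range[1]:cfg$primer_len_range[2], 1L)
  if (mode == "random") {
    rand <- function(l) paste(sample(.DNA_BASES, l, replace = TRUE),
                              collapse = "")
    return(list(pair_id = pair_id, fwd_name = paste0(pair_id, "_f"),
                fwd_seq = rand(lf), rev_name = paste0(pair_id, "_r"),
                rev_seq = rand(lr)))
  }
  n <- nchar(template$seq)
  span <- sample(cfg$amplicon_range[1]:cfg$amplicon_range[2], 1L)
  if (n < span) stop("template too short for the amplicon range",
                     call. = FALSE)
  start <- sample.int(n - span + 1L, 1L)        # 1-based amplicon start
  fwd <- substr(template$seq, start, start + lf - 1L)
  rev_tpl <- substr(template$seq, start + span - lr, start + span - 1L)
  rev <- reverse_complement(rev_tpl)
  if (mode == "degraded") {
    fwd <- .mutate_outside_3prime(fwd, cfg$mutation_rate)
    rev <- .mutate_outside_3prime(rev, cfg$mutation_rate)
  }
  list(pair_id = pair_id, fwd_name = paste0(pair_id, "_f"),
       fwd_seq = fwd, rev_name = paste0(pair_id, "_r"), rev_seq = rev,
       planted_start = start - 1L, planted_end = start + span - 1L)
}

#' Simulate a PCR label from duplex thermodynamics
#'
#' Runs the same binding-site machinery the encoder uses (3'-anchored
#' candidate search on both primers, nearest-neighbor energies,
#' minimum-energy site selection) and sets the base label to 1 iff a
#' priming selection exists whose forward and reverse site energies are
#' both below `tau`.  The label is then flipped with probability `eps`
#' using the current RNG.
#'
#' @param pair Primer pair (list with `fwd_seq`, `rev_seq`).
#' @param template Template (list with `id`, `seq`).
#' @param tau Gibbs-energy threshold (kcal/mol).
#' @param eps Flip probability.
#' @param scfg A [sentence_config()] (thermodynamic settings and NN
#'   table).
#' @return Integer 0/1.
#' @export
simulate_pcr_label <- function(pair, template, tau = -12, eps = 0,
                               scfg = sentence_config()) {
  nn <- if (is.null(scfg$nn)) nn_table() else scfg$nn
  cands <- rbind(
    find_3prime_matches(pair$fwd_seq, template, min_len = scfg$min_len,
                        max_len = scfg$max_len, identity = scfg$identity,
                        primer_id = "fwd"),
    find_3prime_matches(pair$rev_seq, template, min_len = scfg$min_len,
                        max_len = scfg$max_len, identity = scfg$identity,
                        primer_id = "rev"))
  label <- 0L
  if (nrow(cands)) {
    seq_of <- c(fwd = pair$fwd_seq, rev = pair$rev_seq)
    dG <- vapply(seq_len(nrow(cands)), function(i) {
      candidate_delta_g(cands[i, ], seq_of[[cands$primer_id[i]]],
                        template, nn, scfg$thermo)
    }, numeric(1))
    is_f <- cands$orientation == "forward"
    sel <- select_priming_sites(cands[is_f, , drop = FALSE],
                                cands[!is_f, , drop = FALSE],
                                dG[is_f], dG[!is_f], scfg$thermo)
    if (!is.null(sel) && sel$dG_fwd < tau && sel$dG_rev < tau) label <- 1L
  }
  if (eps > 0 && stats::runif(1) < eps) label <- 1L - label
  label
}

#' Generate a full synthetic dataset
#'
#' Generates templates, primer pairs (planted matched/degraded pairs
#' target templates round-robin; the rest are random), and a complete
#' pair x template label table, all reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param scfg A [sentence_config()] used for label simulation.
#' @return A list with `templates` (data.frame id/seq), `pairs`
#'   (data.frame with primer columns plus `mode`, `target_template`),
#'   and `labels` (data.frame pair_id/template_id/label).
#' @export
generate_dataset <- function(cfg = synth_config(),
                             scfg = sentence_config()) {
  if (is.null(scfg$nn)) scfg$nn <- nn_table()
  .with_seed(cfg$seed, {
    templates <- do.call(rbind, lapply(seq_len(cfg$n_templates), function(i) {
      t <- generate_template(cfg, id = sprintf("t%02d", i))
      data.frame(id = t$id, seq = t$seq, stringsAsFactors = FALSE)
    }))
    n_matched <- round(cfg$matched_fraction * cfg$n_pairs)
    n_degraded <- round(cfg$degraded_fraction * cfg$n_pairs)
    modes <- c(rep("matched", n_matched), rep("degraded", n_degraded),
               rep("random", cfg$n_pairs - n_matched - n_degraded))
    pairs <- list()
    for (i in seq_len(cfg$n_pairs)) {
      ti <- ((i - 1L) %% cfg$n_templates) + 1L
      tpl <- list(id = templates$id[ti], seq = templates$seq[ti])
      p <- generate_primer_pair(tpl, modes[i], cfg,
                                pair_id = sprintf("p%03d", i))
      pairs[[i]] <- data.frame(pair_id = p$pair_id,
                               fwd_name = p$fwd_name, fwd_seq = p$fwd_seq,
                               rev_name = p$rev_name, rev_seq = p$rev_seq,
                               mode = modes[i],
                               target_template = if (modes[i] == "random")
                                 NA_character_ else tpl$id,
                               stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pairs)
    labels <- expand.grid(pair_id = pairs$pair_id,
                          template_id = templates$id,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    labels <- labels[order(match(labels$pair_id, pairs$pair_id),
                           match(labels$template_id, templates$id)), ]
    rownames(labels) <- NULL
    labels$label <- vapply(seq_len(nrow(labels)), function(r) {
      p <- as.list(pairs[match(labels$pair_id[r], pairs$pair_id), ])
      ti <- match(labels$template_id[r], templates$id)
      simulate_pcr_label(p, list(id = templates$id[ti],
                                 seq = templates$seq[ti]),
                         tau = cfg$dg_threshold, eps = cfg$label_noise,
                         scfg = scfg)
    }, integer(1))
    list(templates = templates, pairs = pairs, labels = labels)
  })
}
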