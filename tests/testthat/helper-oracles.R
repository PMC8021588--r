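# Independent brute-force oracles used to validate the optimized
# implementations, plus small fixture builders.

rc <- function(s) pcrlingo::reverse_complement(s)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive enumeration of every (suffix length, strand, offset) alignment;
# per (strand, anchor) only the longest qualifying suffix is kept
oracle_3prime_matches <- function(primer, tpl, min_len = 5L, max_len = 22L,
                                  identity = 0.8) {
  plen <- nchar(primer)
  n <- nchar(tpl)
  out <- list()
  for (ori in c("forward", "reverse")) {
    target <- if (ori == "forward") tpl else rc(tpl)
    best <- list()
    for (L in min_len:min(plen, max_len)) {
      suffix <- substr(primer, plen - L + 1L, plen)
      sv <- strsplit(suffix, "")[[1]]
      for (a in L:n) {
        win <- strsplit(substr(target, a - L + 1L, a), "")[[1]]
        m <- sum(sv == win)
        if (m >= ceiling(identity * L)) {
          key <- as.character(a)
          prev <- best[[key]]
          if (is.null(prev) || L > prev$L) best[[key]] <- list(L = L, m = m)
        }
      }
    }
    for (key in names(best)) {
      a <- as.integer(key); L <- best[[key]]$L
      s0 <- a - L; e0 <- a
      if (ori == "reverse") { tmp <- s0; s0 <- n - e0; e0 <- n - tmp }
      out[[length(out) + 1L]] <- data.frame(
        orientation = ori, tpl_start = s0, tpl_end = e0, length = L,
        match_count = best[[key]]$m, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(orientation = character(0), tpl_start = integer(0),
                      tpl_end = integer(0), length = integer(0),
                      match_count = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$orientation, df$tpl_start, df$length), , drop = FALSE]
}

# exhaustive enumeration for priming-site selection
oracle_select <- function(fwd, rev, dGf, dGr, min_sep = 100L) {
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      if (rev$tpl_end[j] - fwd$tpl_start[i] < min_sep) next
      tot <- dGf[i] + dGr[j]
      if (is.null(best) || tot < best$tot - 1e-12 ||
          (abs(tot - best$tot) <= 1e-12 &&
           (dGf[i] < best$dGf - 1e-12 ||
            (abs(dGf[i] - best$dGf) <= 1e-12 &&
             fwd$tpl_start[i] < best$fs)))) {
        best <- list(i = i, j = j, tot = tot, dGf = dGf[i],
                     fs = fwd$tpl_start[i])
      }
    }
  }
  best
}

# independent nearest-neighbor sum reading the shipped table directly
oracle_delta_g <- function(top, bottom, temperature_K = 329.15) {
  raw <- read.delim(system.file("extdata", "nn_stacks.tsv",
                                package = "pcrlingo"),
                    stringsAsFactors = FALSE)
  lut <- setNames(Map(c, raw$dH_kcal, raw$dS_cal), raw$stack)
  flip <- function(k) {
    paste0(substr(k, 5, 5), substr(k, 4, 4), "/",
           substr(k, 2, 2), substr(k, 1, 1))
  }
  tv <- strsplit(top, "")[[1]]
  bv <- strsplit(bottom, "")[[1]]
  total <- 0
  for (i in seq_len(length(tv) - 1L)) {
    k <- paste0(tv[i], tv[i + 1L], "/", bv[i], bv[i + 1L])
    par <- lut[[k]]
    if (is.null(par)) par <- lut[[flip(k)]]
    if (is.null(par)) stop("oracle: stack not in raw table: ", k)
    total <- total + par[1] - temperature_K * par[2] * 1e-3
  }
  total
}

# a template with a planted perfect primer pair at known coordinates
planted_fixture <- function(tpl_len = 300L, span = 150L, lf = 20L,
                            lr = 20L, start = 40L) {
  tpl <- random_dna(tpl_len)
  list(template = list(id = "tpl1", seq = tpl),
       pair = list(pair_id = "pp1",
                   fwd_name = "pp1_f",
                   fwd_seq = substr(tpl, start, start + lf - 1L),
                   rev_name = "pp1_r",
                   rev_seq = rc(substr(tpl, start + span - lr,
                                       start + span - 1L))),
       start0 = start - 1L, end0 = start + span - 1L)
}

# labeled sentences over two disjoint token sets (linearly separable)
separable_sentences <- function(n_pos, n_neg, len_range = c(4L, 12L)) {
  vocab <- pcrlingo::enumerate_vocabulary()
  pos_tokens <- vocab[1:50]
  neg_tokens <- vocab[101:150]
  mk <- function(i, tokens, label) {
    pcrlingo::new_pseudo_sentence(
      pair_id = paste0("p", i), template_id = paste0("t", i %% 7),
      tokens = sample(tokens, sample(len_range[1]:len_range[2], 1L),
                      replace = TRUE),
      label = label)
  }
  c(lapply(seq_len(n_pos), mk, tokens = pos_tokens, label = 1L),
    lapply(seq_len(n_neg) + n_pos, mk, tokens = neg_tokens, label = 0L))
}

# base-wise complement without reversal (aligned bottom strand)
.complement_str <- function(s) chartr("ACGT", "TGCA", s)
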