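# Nearest-neighbor duplex thermodynamics.
#
# Duplex stability is the sum over adjacent base-pair stacks of
# dG = dH - T * dS, with dH in kcal/mol and dS in cal/(mol K) (converted
# by 1e-3).  No initiation, terminal or salt corrections are applied:
# the model is the bare stack sum evaluated at the annealing
# temperature.  Watson-Crick stacks come from the unified
# nearest-neighbor set; single-mismatch stacks from the published
# single-mismatch series; any stack still undefined after
# symmetrization is filled with the arithmetic mean of defined stacks
# carrying the same mismatch class(es).

.WC_PAIRS <- c("AT", "TA", "CG", "GC")

# a stack key is "XY/WZ": top strand X Y read 5'->3' over bottom strand
# W Z read 3'->5'; the same physical stack read from the other strand is
# "ZW/YX"
.stack_symmetric <- function(key) {
  paste0(substr(key, 5, 5), substr(key, 4, 4), "/",
         substr(key, 2, 2), substr(key, 1, 1))
}

# unordered mismatch types present in a stack key (character vector of
# length 0, 1 or 2, e.g. "GT" with G < T sorted)
.stack_mismatches <- function(key) {
  pairs <- c(paste0(substr(key, 1, 1), substr(key, 4, 4)),
             paste0(substr(key, 2, 2), substr(key, 5, 5)))
  mm <- pairs[!(pairs %in% .WC_PAIRS)]
  vapply(mm, function(p) {
    paste(sort(c(substr(p, 1, 1), substr(p, 2, 2))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.nn_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor stack parameter table
#'
#' Reads a TSV with columns `stack` (e.g. `"AA/TT"`: top dinucleotide
#' 5'->3' over bottom dinucleotide 3'->5'), `dH_kcal`, `dS_cal` and
#' optionally `source_tag`.  The table is symmetrized (a stack and its
#' opposite-strand reading share parameters) and completed over all 256
#' stacks: stacks not listed get the arithmetic mean of the listed
#' stacks carrying the same mismatch class(es).
#'
#' @param path Path to the parameter file; defaults to the table shipped
#'   with the package.
#' @return An `nn_table` object: list with named numeric vectors `dH`
#'   and `dS` over all 256 stack keys, and a `source_tag` string.
#' @export
nn_table <- function(path = system.file("extdata", "nn_stacks.tsv",
                                        package = "pcrlingo")) {
  if (!is.null(.nn_cache[[path]])) return(.nn_cache[[path]])
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stack", "dH_kcal", "dS_cal") %in% names(raw)))
  bases <- .DNA_BASES
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                      stringsAsFactors = FALSE)
  keys <- paste0(grid$b1, grid$b2, "/", grid$b3, grid$b4)
  dH <- stats::setNames(rep(NA_real_, length(keys)), keys)
  dS <- dH
  for (i in seq_len(nrow(raw))) {
    k <- raw$stack[i]
    if (!k %in% keys) stop("malformed stack key: ", k, call. = FALSE)
    dH[k] <- raw$dH_kcal[i]
    dS[k] <- raw$dS_cal[i]
  }
  # symmetrize: copy onto the opposite-strand reading where missing
  for (k in keys) {
    s <- .stack_symmetric(k)
    if (is.na(dH[k]) && !is.na(dH[s])) { dH[k] <- dH[s]; dS[k] <- dS[s] }
  }
  # mean-fill by mismatch class
  mm_of <- lapply(keys, .stack_mismatches)
  defined <- !is.na(dH)
  mm_mean <- function(type) {
    sel <- defined & vapply(mm_of, function(m) type %in% m, logical(1))
    if (!any(sel)) stop("no defined stacks for mismatch class ", type,
                        call. = FALSE)
    c(dH = mean(dH[sel]), dS = mean(dS[sel]))
  }
  types <- unique(unlist(mm_of))
  means <- lapply(stats::setNames(types, types), mm_mean)
  for (idx in which(!defined)) {
    mm <- mm_of[[idx]]
    if (!length(mm)) stop("undefined Watson-Crick stack: ", keys[idx],
                          call. = FALSE)
    vals <- vapply(mm, function(t) means[[t]], numeric(2))
    dH[idx] <- mean(vals["dH", ])
    dS[idx] <- mean(vals["dS", ])
  }
  # enforce exact symmetry (mean the two readings if they ever differ)
  for (k in keys) {
    s <- .stack_symmetric(k)
    h <- (dH[k] + dH[s]) / 2; sv <- (dS[k] + dS[s]) / 2
    dH[k] <- h; dH[s] <- h; dS[k] <- sv; dS[s] <- sv
  }
  tab <- structure(list(dH = dH, dS = dS,
                        source_tag = if ("source_tag" %in% names(raw)) {
                          paste(unique(raw$source_tag), collapse = "+")
                        } else "user"),
                   class = "nn_table")
  .nn_cache[[path]] <- tab
  tab
}

#' Thermodynamic configuration
#'
#' @param temperature_K Absolute temperature in kelvin; the default
#'   329.15 K corresponds to the 56 degree C annealing temperature.
#' @param min_separation Minimum forward-to-reverse priming-site span in
#'   bases (default 100).
#' @return A `thermo_config` list.
#' @export
thermo_config <- function(temperature_K = 329.15, min_separation = 100L) {
  stopifnot(temperature_K > 0, min_separation >= 0)
  structure(list(temperature_K = temperature_K,
                 min_separation = as.integer(min_separation)),
            class = "thermo_config")
}

#' Gibbs energy of an aligned duplex
#'
#' `top` and `bottom` are aligned base-by-base (top 5'->3', bottom
#' 3'->5'); the return value is the sum over all adjacent stacks of
#' dH - T * dS.  A single base pair has no stack and scores 0.
#'
#' @param top,bottom Aligned DNA strings of equal length >= 1.
#' @param table An [nn_table()].
#' @param cfg A [thermo_config()].
#' @return Gibbs energy in kcal/mol.
#' @examples
#' duplex_delta_g("AA", "TT")
#' @export
duplex_delta_g <- function(top, bottom, table = nn_table(),
                           cfg = thermo_config()) {
  .check_dna(top, "top strand")
  .check_dna(bottom, "bottom strand")
  n <- nchar(top)
  if (n != nchar(bottom)) stop("strands must have equal length",
                               call. = FALSE)
  if (n < 1L) stop("duplex must have at least one base pair",
                   call. = FALSE)
  if (n == 1L) return(0)
  tv <- .chars(top)
  bv <- .chars(bottom)
  keys <- paste0(tv[-n], tv[-1L], "/", bv[-n], bv[-1L])
  sum(table$dH[keys] - cfg$temperature_K * table$dS[keys] * 1e-3)
}

#' Gibbs energy of a binding candidate
#'
#' Reconstructs the aligned duplex for a candidate reported by
#' [find_3prime_matches()] (the primer 3' suffix over the template
#' strand it anneals to) and returns its [duplex_delta_g()].
#'
#' @param cand One candidate (single-row data.frame or list with fields
#'   `orientation`, `tpl_start`, `tpl_end`, `length`).
#' @param primer_seq The primer sequence the candidate came from.
#' @param template Template (list/row with `seq`, or plain string).
#' @param table An [nn_table()].
#' @param cfg A [thermo_config()].
#' @return Gibbs energy in kcal/mol.
#' @export
candidate_delta_g <- function(cand, primer_seq, template,
                              table = nn_table(), cfg = thermo_config()) {
  tpl <- if (is.list(template) && !is.data.frame(template)) {
    template$seq
  } else if (is.data.frame(template)) template$seq else template
  L <- as.integer(cand$length)
  plen <- nchar(primer_seq)
  if (L > plen || cand$tpl_end - cand$tpl_start != L ||
      cand$tpl_start < 0L || cand$tpl_end > nchar(tpl)) {
    stop("candidate coordinates inconsistent with primer/template",
         call. = FALSE)
  }
  top <- substr(primer_seq, plen - L + 1L, plen)
  region <- substr(tpl, cand$tpl_start + 1L, cand$tpl_end)
  bottom <- if (cand$orientation == "forward") {
    .complement(region)   # primer pairs the reverse-complement strand
  } else {
    paste(rev(.chars(region)), collapse = "")  # primer pairs the forward strand
  }
  duplex_delta_g(top, bottom, table, cfg)
}

#' Select the minimum-energy priming-site pair
#'
#' Exhaustively evaluates all forward x reverse candidate combinations
#' whose span (`rev$tpl_end - fwd$tpl_start`) is at least
#' `cfg$min_separation` bases, and returns the pair minimizing the
#' summed Gibbs energy.  Ties break on lower forward-site energy, then
#' smaller forward start.
#'
#' @param fwd_cands,rev_cands Candidate data.frames (forward / reverse
#'   orientation).
#' @param dG_fwd,dG_rev Numeric vectors of candidate energies, matching
#'   the candidate rows.
#' @param cfg A [thermo_config()].
#' @return A `priming_selection` list (`fwd`, `rev`, `dG_fwd`, `dG_rev`,
#'   `total_dG`, `fwd_index`, `rev_index`), or `NULL` when no pair
#'   satisfies the separation constraint.
#' @export
select_priming_sites <- function(fwd_cands, rev_cands, dG_fwd, dG_rev,
                                 cfg = thermo_config()) {
  nf <- nrow(fwd_cands); nr <- nrow(rev_cands)
  if (!nf || !nr) return(NULL)
  stopifnot(length(dG_fwd) == nf, length(dG_rev) == nr)
  best <- NULL
  for (i in seq_len(nf)) {
    span <- rev_cands$tpl_end - fwd_cands$tpl_start[i]
    ok <- which(span >= cfg$min_separation)
    if (!length(ok)) next
    tot <- dG_fwd[i] + dG_rev[ok]
    j <- ok[which.min(tot)]
    cand_total <- dG_fwd[i] + dG_rev[j]
    better <- is.null(best) ||
      cand_total < best$total_dG - 1e-12 ||
      (abs(cand_total - best$total_dG) <= 1e-12 &&
         (dG_fwd[i] < best$dG_fwd - 1e-12 ||
            (abs(dG_fwd[i] - best$dG_fwd) <= 1e-12 &&
               fwd_cands$tpl_start[i] < best$fwd$tpl_start)))
    if (better) {
      best <- structure(list(fwd = fwd_cands[i, , drop = FALSE],
                             rev = rev_cands[j, , drop = FALSE],
                             dG_fwd = dG_fwd[i], dG_rev = dG_rev[j],
                             total_dG = cand_total,
                             fwd_index = i, rev_index = j),
                        class = "priming_selection")
    }
  }
  best
}
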