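# Shared low-level helpers (loaded first).

.DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single non-NA string", call. = FALSE)
  }
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGT]", seq))
    stop(what, " contains non-ACGT symbol '", bad, "'", call. = FALSE)
  }
  invisible(seq)
}

# fast complement (no reversal) used internally
.complement <- function(seq) chartr("ACGT", "TGCA", seq)

# split a DNA string into a character vector of single bases
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
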