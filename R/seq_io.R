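# Sequence and table input/output.
#
# Templates are plain forward-strand DNA (5'->3') over {A,C,G,T}; every
# record implicitly carries its reverse complement as the second strand.

#' Read DNA templates from a FASTA file
#'
#' Record ids are taken from the header up to the first whitespace and
#' sequences are uppercased.  Any symbol other than A, C, G or T after
#' normalization (including U, N and other IUPAC ambiguity codes) is a
#' format error naming the offending record.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A data.frame with columns `id` and `seq`, one row per record,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 first", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      stop("empty sequence in record '", ids[i], "'", call. = FALSE)
    }
    if (grepl("[^ACGT]", seqs[i])) {
      stop("record '", ids[i], "' contains a non-ACGT symbol after ",
           "normalization", call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate template id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write templates to a FASTA file
#'
#' @param templates A data.frame with columns `id` and `seq` as returned
#'   by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(templates, path) {
  set <- Biostrings::DNAStringSet(templates$seq)
  names(set) <- templates$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.sniff_delim <- function(header) {
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Parse a primer-pair table
#'
#' Reads a delimited text table (TSV by default; a CSV dialect is
#' auto-detected from the header line) with columns `pair_id`,
#' `fwd_name`, `fwd_seq`, `rev_name`, `rev_seq`.  Sequences are
#' uppercased and validated as pure ACGT.
#'
#' @param path Path to the primer table.
#' @return A data.frame with the five columns above, one row per pair.
#' @export
parse_primer_table <- function(path) {
  if (!file.exists(path)) stop("primer table not found: ", path, call. = FALSE)
  delim <- .sniff_delim(readLines(path, n = 1L))
  tab <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("pair_id", "fwd_name", "fwd_seq", "rev_name", "rev_seq")
  if (!all(need %in% names(tab))) {
    stop("primer table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$fwd_seq <- toupper(tab$fwd_seq)
  tab$rev_seq <- toupper(tab$rev_seq)
  for (i in seq_len(nrow(tab))) {
    for (col in c("fwd_seq", "rev_seq")) {
      s <- tab[[col]][i]
      if (nchar(s) == 0L || grepl("[^ACGT]", s)) {
        stop("row ", i, " (pair_id '", tab$pair_id[i], "'): ", col,
             " is not a valid DNA sequence", call. = FALSE)
      }
    }
  }
  if (anyDuplicated(tab$pair_id)) {
    stop("duplicate pair_id: ", tab$pair_id[duplicated(tab$pair_id)][1],
         call. = FALSE)
  }
  tab
}

#' Parse a PCR label table
#'
#' Columns `pair_id`, `template_id`, `label`; labels must be 0 or 1
#' (0 = no PCR product, 1 = PCR product confirmed).
#'
#' @param path Path to the label table (TSV/CSV).
#' @return A data.frame with columns `pair_id`, `template_id` (character)
#'   and `label` (integer).
#' @export
parse_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path, call. = FALSE)
  delim <- .sniff_delim(readLines(path, n = 1L))
  tab <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("pair_id", "template_id", "label")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$pair_id <- as.character(tab$pair_id)
  tab$template_id <- as.character(tab$template_id)
  if (!all(tab$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  tab$label <- as.integer(tab$label)
  if (anyDuplicated(tab[, c("pair_id", "template_id")])) {
    stop("duplicate (pair_id, template_id) entry in label table",
         call. = FALSE)
  }
  tab
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over ACGT (the empty string is allowed).
#' @return The Watson-Crick reverse complement, 5'->3'.
#' @examples
#' reverse_complement("GTCCA")  # "TGGAC"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
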