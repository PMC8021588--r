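# The pentacode alphabet.
#
# Every base pair (primer base against the template-strand base it faces)
# falls into one of five stability classes; each class maps to one letter
# per context.  Contexts distinguish where the interaction happens:
# initial-stage binding to the original template (forward / reverse
# primer orientation), middle-stage binding to the fully complementary
# PCR product (forward / reverse), and intra-/inter-primer structures
# (hairpins and dimers).  Letters at the two selected priming sites are
# uppercased; everything else stays lowercase.

# class index by (primer base, template base); classes:
# 0: A-T, T-A           (weak Watson-Crick)
# 1: C-G, G-C           (strong Watson-Crick)
# 2: A-A, A-G, G-A, G-G, C-C
# 3: T-T, T-C, C-T
# 4: C-A, A-C, G-T, T-G
.CLASS_MATRIX <- local({
  m <- matrix(NA_integer_, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
  m["A", "T"] <- 0L; m["T", "A"] <- 0L
  m["C", "G"] <- 1L; m["G", "C"] <- 1L
  m["A", "A"] <- 2L; m["A", "G"] <- 2L; m["G", "A"] <- 2L
  m["G", "G"] <- 2L; m["C", "C"] <- 2L
  m["T", "T"] <- 3L; m["T", "C"] <- 3L; m["C", "T"] <- 3L
  m["C", "A"] <- 4L; m["A", "C"] <- 4L; m["G", "T"] <- 4L; m["T", "G"] <- 4L
  m
})

.CONTEXTS <- c("initial_forward", "initial_reverse",
               "middle_forward", "middle_reverse", "hairpin_dimer")

.CONTEXT_LETTERS <- list(
  initial_forward = c("a", "b", "c", "d", "e"),
  initial_reverse = c("f", "g", "h", "i", "j"),
  middle_forward  = c("p", "q", "r", "s", "t"),
  middle_reverse  = c("u", "v", "w", "x", "y"),
  hairpin_dimer   = c("k", "l", "m", "n", "o")
)

#' The pentacode alphabet
#'
#' Returns the base-pair class table and the per-context letter sets:
#' five base-pair classes, five contexts (initial-stage forward/reverse,
#' middle-stage forward/reverse, hairpin/dimer) and two cases, for
#' 25 distinct lowercase letters plus their uppercase forms.
#'
#' @return A list with elements `class_of` (4x4 integer matrix indexed by
#'   primer and template base), `contexts` and `letters` (list of
#'   5-letter sets per context).
#' @export
pentacode_alphabet <- function() {
  list(class_of = .CLASS_MATRIX,
       contexts = .CONTEXTS,
       letters = .CONTEXT_LETTERS)
}

#' Classify a single base pair
#'
#' @param p Primer base (one of A, C, G, T).
#' @param t Template-strand base the primer base faces.
#' @return Integer class index 0-4.
#' @examples
#' classify_base_pair("A", "T")  # 0
#' classify_base_pair("G", "G")  # 2
#' @export
classify_base_pair <- function(p, t) {
  if (!(p %in% .DNA_BASES) || !(t %in% .DNA_BASES)) {
    stop("bases must be one of A, C, G, T", call. = FALSE)
  }
  .CLASS_MATRIX[p, t]
}

# vectorized class lookup over two equal-length base vectors
.classify_pairs <- function(pv, tv) {
  .CLASS_MATRIX[cbind(match(pv, .DNA_BASES), match(tv, .DNA_BASES))]
}

#' Encode a run of base-pair classes as letters
#'
#' One letter per class, 5'->3' along the primer, drawn from the
#' context's letter set; uppercased when the region is a selected
#' priming site.
#'
#' @param classes Integer vector of class indices 0-4.
#' @param context One of `"initial_forward"`, `"initial_reverse"`,
#'   `"middle_forward"`, `"middle_reverse"`, `"hairpin_dimer"`.
#' @param priming Logical; uppercase the letters?
#' @return A single letter string.
#' @export
encode_region <- function(classes, context, priming = FALSE) {
  context <- match.arg(context, .CONTEXTS)
  if (length(classes) == 0L) return("")
  if (any(classes < 0L | classes > 4L)) {
    stop("class indices must be in 0..4", call. = FALSE)
  }
  s <- paste(.CONTEXT_LETTERS[[context]][classes + 1L], collapse = "")
  if (priming) toupper(s) else s
}

#' Split a letter string into repeated pentacode words
#'
#' Five-letter chunks are taken from the 3' end stepping by 5; a 5'
#' remainder shorter than 5 letters is dropped.  With `n` resulting
#' chunks, the chunk at chunk-distance `d` from the 3' end is emitted
#' `n - d` times, so the 3'-most chunk is the most repeated (total words
#' `n(n+1)/2`).  Output lists the 3'-most chunk group first.
#'
#' @param letters Letter string, 5'->3'.
#' @return Character vector of 5-letter words (possibly empty).
#' @examples
#' words_from_region("aabbbaabbaab")
#' @export
words_from_region <- function(letters) {
  n <- nchar(letters)
  nchunks <- n %/% 5L
  if (nchunks == 0L) return(character(0))
  out <- character(0)
  for (d in seq_len(nchunks) - 1L) {
    start <- n - 5L * (d + 1L) + 1L
    word <- substr(letters, start, start + 4L)
    out <- c(out, rep(word, nchunks - d))
  }
  out
}

# all distinct pentacodes expressible under the single-context,
# single-case-per-word constraint
.vocab_cache <- new.env(parent = emptyenv())

#' Enumerate the full pentacode vocabulary
#'
#' @param alphabet Alphabet as returned by [pentacode_alphabet()].
#' @return Character vector of all distinct 5-letter words.
#' @export
enumerate_vocabulary <- function(alphabet = pentacode_alphabet()) {
  key <- paste(unlist(alphabet$letters), collapse = "")
  if (!is.null(.vocab_cache[[key]])) return(.vocab_cache[[key]])
  words <- character(0)
  for (ctx in names(alphabet$letters)) {
    set <- alphabet$letters[[ctx]]
    for (case in c("lower", "upper")) {
      ls <- if (case == "upper") toupper(set) else set
      grid <- expand.grid(ls, ls, ls, ls, ls, stringsAsFactors = FALSE)
      words <- c(words, do.call(paste0, grid))
    }
  }
  words <- unique(words)
  .vocab_cache[[key]] <- words
  words
}

#' Size of the pentacode vocabulary
#'
#' Counts the distinct 5-letter words expressible when each word uses a
#' single context letter set and a single case: five classes to the
#' fifth power, times five contexts, times two cases.
#'
#' @param alphabet Alphabet as returned by [pentacode_alphabet()].
#' @return Integer word count (31250 for the default alphabet).
#' @export
vocabulary_size <- function(alphabet = pentacode_alphabet()) {
  length(enumerate_vocabulary(alphabet))
}

#' Generate a nonsense pseudo-sentence
#'
#' Words are sampled uniformly from the full vocabulary; used as the
#' no-signal negative control for the classifier.
#'
#' @param n_tokens Number of words.
#' @param seed Integer seed (the sentence is reproducible per seed).
#' @param alphabet Alphabet as returned by [pentacode_alphabet()].
#' @return A `pseudo_sentence` object with unknown label.
#' @export
nonsense_sentence <- function(n_tokens, seed = NULL,
                              alphabet = pentacode_alphabet()) {
  stopifnot(n_tokens >= 0)
  vocab <- enumerate_vocabulary(alphabet)
  tokens <- if (n_tokens == 0L) character(0) else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    sample(vocab, n_tokens, replace = TRUE)
  }
  new_pseudo_sentence(pair_id = "nonsense", template_id = "nonsense",
                      tokens = tokens)
}
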