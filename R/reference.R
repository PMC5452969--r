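#' Load a single-sequence mitochondrial reference from FASTA
#'
#' Reads a FASTA file that must contain exactly one sequence record (an
#' rCRS-like mitochondrial reference, but any single-sequence DNA FASTA is
#' accepted). The sequence is uppercased and RNA-style `U` is mapped to `T`.
#' All genome positions in this package are 1-based and refer to this
#' sequence, matching rCRS variant nomenclature (C150T = position 150).
#'
#' @param path Path to a FASTA file with exactly one record.
#' @return An object of class `ReferenceGenome`: a list with elements
#'   `name` (record identifier), `sequence` (uppercase character string over
#'   A/C/G/T/N) and `length` (number of bases).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "acgtACGT"), fa)
#' ref <- load_reference(fa)
#' ref$length
#' @export
load_reference <- function(path) {
  # read without alphabet validation so U and IUPAC codes survive for
  # explicit normalization below (DNA readers silently drop invalid codes)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("reference FASTA is empty: ", path)
  if (length(set) != 1L)
    stop("expected exactly one sequence in the reference FASTA, found ",
         length(set), " records")
  seq <- toupper(as.character(set[[1L]]))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (grepl("[RYSWKMBDHV]", seq)) {
    n_amb <- nchar(gsub("[^RYSWKMBDHV]", "", seq))
    message("load_reference: ", n_amb,
            " IUPAC ambiguity code(s) in the reference mapped to N")
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  }
  if (grepl("[^ACGTN]", seq))
    stop("reference contains characters outside the DNA alphabet: ",
         paste(unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1L]]),
               collapse = " "))
  ref <- list(
    name     = sub("\\s.*$", "", names(set)[1L]),
    sequence = seq,
    length   = nchar(seq)
  )
  class(ref) <- "ReferenceGenome"
  ref
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", x$name, "(", x$length, "bp )\n")
  invisible(x)
}

#' Construct a reference genome from an in-memory sequence
#'
#' Convenience constructor used by the simulator and in tests; applies the
#' same normalization as [load_reference()].
#'
#' @param sequence DNA string.
#' @param name Sequence name.
#' @return A `ReferenceGenome`.
#' @export
reference_genome <- function(sequence, name = "ref") {
  seq <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (nchar(seq) == 0L) stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", seq)) stop("reference sequence contains non-ACGTN characters")
  structure(list(name = name, sequence = seq, length = nchar(seq)),
            class = "ReferenceGenome")
}

# Vector of single characters for a reference (internal helper).
ref_chars <- function(ref) strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
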