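# Amino-acid sequences over the standard 20-letter alphabet.

#' The 20 standard one-letter amino-acid codes
#'
#' Alphabetical order; this is also the row/column order of
#' \code{\link{potential_table}} matrices.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an amino-acid sequence
#'
#' @param x a single string (e.g. \code{"ACDK"}) or a character vector of
#'   one-letter codes. Lower case is accepted and uppercased.
#' @return An object of class \code{"aa_seq"}: a character vector of
#'   residues with the chain length in \code{length()}.
#' @examples
#' s <- aa_sequence("ACDEFG")
#' length(s)
#' @export
aa_sequence <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  if (length(x) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- which(!(x %in% AA_ALPHABET))
  if (length(bad))
    stop(sprintf("invalid residue code(s) %s at position(s) %s",
                 paste(unique(x[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(x, class = "aa_seq")
}

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("Amino-acid sequence, n = %d\n  %s\n", length(x),
              paste(unclass(x), collapse = "")))
  invisible(x)
}

# 0-based indices into the alphabet, for the compiled core
seq_index0 <- function(seq) {
  match(unclass(seq), AA_ALPHABET) - 1L
}

as_aa_seq <- function(x) {
  if (inherits(x, "aa_seq")) x else aa_sequence(x)
}
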