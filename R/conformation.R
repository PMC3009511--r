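# Conformations: the injective map from residues to FCC lattice points.

#' Construct a conformation
#'
#' A conformation places residue i of the sequence at row i of
#' \code{positions}. It is valid when all points are FCC points, consecutive
#' points are lattice-adjacent and no point is used twice (a self-avoiding
#' walk).
#'
#' @param seq an \code{\link{aa_sequence}} (or string coercible to one).
#' @param positions integer matrix, n x 3, one lattice point per residue.
#' @param validate check the invariants (default \code{TRUE}).
#' @return An object of class \code{"fcc_conformation"} with fields
#'   \code{seq} and \code{positions}.
#' @export
conformation <- function(seq, positions, validate = TRUE) {
  seq <- as_aa_seq(seq)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("'positions' must be an n x 3 integer matrix", call. = FALSE)
  if (any(positions != round(positions)))
    stop("'positions' must be integer lattice coordinates", call. = FALSE)
  storage.mode(positions) <- "integer"
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  if (nrow(positions) != length(seq))
    stop(sprintf("sequence has %d residues but positions has %d rows",
                 length(seq), nrow(positions)), call. = FALSE)
  conf <- structure(list(seq = seq, positions = positions),
                    class = "fcc_conformation")
  if (validate) validate_conformation(conf)
  conf
}

#' Validate conformation invariants
#'
#' Checks FCC parity of every point, adjacency of consecutive points and
#' injectivity (self-avoidance). Errors name the first offending residue.
#'
#' @param conf an \code{"fcc_conformation"}.
#' @return The conformation, invisibly, if valid.
#' @export
validate_conformation <- function(conf) {
  pos <- conf$positions
  n <- nrow(pos)
  parity <- rowSums(pos) %% 2L
  if (any(parity != 0L))
    stop(sprintf("residue %d is not on the FCC lattice (odd coordinate sum)",
                 which(parity != 0L)[1L]), call. = FALSE)
  if (n > 1L) {
    d <- abs(pos[-1L, , drop = FALSE] - pos[-n, , drop = FALSE])
    ok <- rowSums(d) == 2L & apply(d, 1L, max) <= 1L
    if (any(!ok))
      stop(sprintf("residues %d and %d are not lattice-adjacent",
                   which(!ok)[1L], which(!ok)[1L] + 1L), call. = FALSE)
  }
  key <- paste(pos[, 1L], pos[, 2L], pos[, 3L])
  if (anyDuplicated(key))
    stop(sprintf("residue %d reuses an occupied lattice point (overlap)",
                 anyDuplicated(key)), call. = FALSE)
  invisible(conf)
}

#' @export
print.fcc_conformation <- function(x, ...) {
  n <- nrow(x$positions)
  ext <- apply(x$positions, 2L, function(v) diff(range(v)))
  cat(sprintf("FCC conformation: %d residues, bounding box %d x %d x %d\n",
              n, ext[1L] + 1L, ext[2L] + 1L, ext[3L] + 1L))
  invisible(x)
}
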