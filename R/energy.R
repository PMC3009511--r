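# Contact detection and the pairwise contact-potential energy function.
#
# Two residues are in contact when they are non-adjacent in sequence
# (|i - j| > 1) and their lattice points are at L1 distance exactly 2. Note
# the deliberately plain distance criterion: offsets like (2, 0, 0) count as
# contacts even though they are not lattice-adjacent. `strict = TRUE`
# restricts contacts to lattice-adjacent pairs instead.

#' Construct a contact-potential table
#'
#' A symmetric 20 x 20 matrix of dimensionless pair energies indexed by the
#' one-letter codes in \code{\link{AA_ALPHABET}} order (all 210 unordered
#' pairs are covered). No temperature scaling is applied.
#'
#' @param entries numeric 20 x 20 matrix; symmetry is required to within
#'   \code{tol}. Row/column names, if present, must be a permutation of the
#'   alphabet and are used to reorder.
#' @param source_label free-text provenance, stored with the table.
#' @param tol symmetry tolerance (default 1e-9).
#' @return An object of class \code{"contact_potential"}.
#' @export
potential_table <- function(entries, source_label = "user", tol = 1e-9) {
  entries <- as.matrix(entries)
  if (!is.numeric(entries) || any(dim(entries) != c(20L, 20L)))
    stop("'entries' must be a numeric 20 x 20 matrix", call. = FALSE)
  if (!is.null(rownames(entries))) {
    if (!setequal(rownames(entries), AA_ALPHABET) ||
        !setequal(colnames(entries), AA_ALPHABET))
      stop("dimnames must be the 20 one-letter amino-acid codes",
           call. = FALSE)
    entries <- entries[AA_ALPHABET, AA_ALPHABET]
  }
  if (max(abs(entries - t(entries))) > tol)
    stop(sprintf("potential table is not symmetric (max asymmetry %.3g)",
                 max(abs(entries - t(entries)))), call. = FALSE)
  entries <- (entries + t(entries)) / 2
  dimnames(entries) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(entries = entries, source_label = source_label),
            class = "contact_potential")
}

#' @export
print.contact_potential <- function(x, ...) {
  cat(sprintf("Contact potential table (20 x 20, source: %s)\n",
              x$source_label))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$entries), max(x$entries)))
  invisible(x)
}

#' Uniform and HP-style fixture potentials
#'
#' \code{uniform_potential} gives every residue pair the same energy;
#' \code{hp_potential} gives hydrophobic-hydrophobic pairs the energy
#' \code{value} and everything else zero (an HP-model-style collapse of the
#' 20-letter alphabet).
#'
#' @param value pair energy (default -1, attractive).
#' @param hydrophobic one-letter codes treated as hydrophobic.
#' @return A \code{"contact_potential"}.
#' @export
uniform_potential <- function(value = -1) {
  m <- matrix(value, 20L, 20L)
  potential_table(m, source_label = sprintf("uniform(%g)", value))
}

#' @rdname uniform_potential
#' @export
hp_potential <- function(value = -1,
                         hydrophobic = c("A", "C", "F", "I", "L", "M",
                                         "V", "W", "Y")) {
  m <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[hydrophobic, hydrophobic] <- value
  potential_table(m, source_label = sprintf("hp(%g)", value))
}

#' Look up the symmetric pair energy of two residues
#'
#' @param table a \code{"contact_potential"}.
#' @param a,b one-letter residue codes.
#' @return The (commutative) table entry.
#' @export
pair_energy <- function(table, a, b) {
  stopifnot(inherits(table, "contact_potential"))
  for (r in c(a, b))
    if (!(r %in% AA_ALPHABET))
      stop(sprintf("unknown residue code '%s'", r), call. = FALSE)
  table$entries[a, b]
}

#' Contact test for a residue pair of a conformation
#'
#' Residues i and j are in contact iff \code{|i - j| > 1} and their lattice
#' points are at L1 distance 2 (with \code{strict = TRUE}, iff additionally
#' lattice-adjacent). Indices are 1-based.
#'
#' @param conf an \code{"fcc_conformation"}.
#' @param i,j residue indices in \code{1..n}.
#' @param strict restrict contacts to lattice-adjacent pairs.
#' @return logical.
#' @export
in_contact <- function(conf, i, j, strict = FALSE) {
  n <- nrow(conf$positions)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop(sprintf("residue index out of range 1..%d", n), call. = FALSE)
  if (abs(i - j) <= 1L) return(FALSE)
  d <- abs(conf$positions[i, ] - conf$positions[j, ])
  sum(d) == 2L && (!strict || all(d <= 1L))
}

#' All residue contacts of a conformation
#'
#' @param conf an \code{"fcc_conformation"}.
#' @param strict restrict contacts to lattice-adjacent pairs.
#' @return Integer matrix with columns \code{i}, \code{j} (\code{i < j}),
#'   rows sorted lexicographically; zero rows when there are no contacts.
#' @export
contact_list <- function(conf, strict = FALSE) {
  pos <- conf$positions
  n <- nrow(pos)
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  if (n < 3L) return(empty)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] > 1L, , drop = FALSE]
  d <- abs(pos[idx[, 1L], , drop = FALSE] - pos[idx[, 2L], , drop = FALSE])
  keep <- rowSums(d) == 2L
  if (strict) keep <- keep & apply(d, 1L, max) <= 1L
  out <- idx[keep, , drop = FALSE]
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Contact energy of a conformation
#'
#' The sum over all contact pairs (i < j) of the pair energy of the two
#' residues; the quantity minimized by both search modes. Translation of all
#' points and lattice symmetries leave it unchanged.
#'
#' @param conf an \code{"fcc_conformation"}.
#' @param table a \code{"contact_potential"} covering the sequence alphabet.
#' @param strict restrict contacts to lattice-adjacent pairs.
#' @return The total energy (0 for a contact-free conformation).
#' @export
conformation_energy <- function(conf, table, strict = FALSE) {
  stopifnot(inherits(table, "contact_potential"))
  cl <- contact_list(conf, strict = strict)
  if (nrow(cl) == 0L) return(0)
  s <- unclass(conf$seq)
  sum(table$entries[cbind(s[cl[, 1L]], s[cl[, 2L]])])
}
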