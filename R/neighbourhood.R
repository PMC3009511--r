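# CSP-as-neighbourhood generator: pick a random subchain, dilate its box
# domains around the current positions, exhaustively enumerate feasible
# re-placements with both flanks fixed, and return the best one.

#' Construct a subchain perturbation policy
#'
#' Each row pairs a subchain length l with a domain dilation b (1 <= b <= 3)
#' and a selection probability. The default policy draws l from
#' {7, 9, 11, 13} with probabilities 0.5, 0.3, 0.15 and 0.05 and dilations
#' 3, 2, 1, 1: short subchains keep each CSP phase cheap, while the rarer
#' long ones let the search escape local minima. Probabilities are
#' normalized defensively; rows with zero probability are dropped.
#'
#' @param l integer vector of subchain lengths (each >= 1).
#' @param b integer vector of dilations in 1..3, recycled to
#'   \code{length(l)}.
#' @param p non-negative selection weights, at least one positive.
#' @return An object of class \code{"perturbation_policy"}: a data frame
#'   with columns \code{l}, \code{b}, \code{p} (normalized).
#' @export
perturbation_policy <- function(l, b, p) {
  if (length(b) == 1L) b <- rep(b, length(l))
  if (length(l) != length(b) || length(l) != length(p))
    stop("'l', 'b' and 'p' must have matching lengths", call. = FALSE)
  if (any(l < 1L) || any(l != round(l)))
    stop("subchain lengths 'l' must be positive integers", call. = FALSE)
  if (any(b < 1L) || any(b > 3L))
    stop("domain dilation 'b' must lie in 1..3", call. = FALSE)
  if (any(p < 0) || sum(p) <= 0)
    stop("selection weights 'p' must be non-negative with positive sum",
         call. = FALSE)
  keep <- p > 0
  d <- data.frame(l = as.integer(l[keep]), b = as.integer(b[keep]),
                  p = p[keep] / sum(p[keep]))
  if (anyDuplicated(d$l))
    stop("duplicate subchain lengths in policy", call. = FALSE)
  structure(d, class = c("perturbation_policy", "data.frame"))
}

#' @rdname perturbation_policy
#' @export
default_policy <- function() {
  perturbation_policy(l = c(7L, 9L, 11L, 13L), b = c(3L, 2L, 1L, 1L),
                      p = c(0.5, 0.3, 0.15, 0.05))
}

#' Sample a subchain perturbation
#'
#' Draws a subchain length (and its dilation) from the policy after
#' discarding rows too long for the chain (rows with \code{l + 2 > n}) and
#' renormalizing, then draws the anchor i uniformly from \code{0..n-l}: the
#' perturbed window is residues \code{i+1 .. i+l}. Anchors at the extreme
#' ends are permitted, leaving one flank empty, so terminal residues can
#' move. Uses R's global RNG; seed upstream for reproducibility.
#'
#' @param policy a \code{\link{perturbation_policy}}.
#' @param n chain length.
#' @return A list with \code{anchor}, \code{length}, \code{dilation}
#'   (class \code{"perturbation"}).
#' @export
sample_perturbation <- function(policy, n) {
  stopifnot(inherits(policy, "perturbation_policy"))
  ok <- policy$l + 2L <= n
  if (!any(ok))
    stop(sprintf(paste0("no policy row fits a chain of length %d; add a ",
                        "shorter subchain length or fold a longer chain"),
                 n), call. = FALSE)
  rows <- policy[ok, , drop = FALSE]
  k <- if (nrow(rows) == 1L) 1L else
    sample.int(nrow(rows), 1L, prob = rows$p)
  l <- rows$l[k]
  anchor <- sample.int(n - l + 1L, 1L) - 1L  # uniform on 0..n-l
  structure(list(anchor = anchor, length = l, dilation = rows$b[k]),
            class = "perturbation")
}

#' Dilated box domains for a perturbation
#'
#' Window residues get the cube of half-width b around their current point
#' (so the current position always lies inside its box); every other
#' residue gets the singleton box at its current point.
#'
#' @param conf current \code{"fcc_conformation"}.
#' @param pert a perturbation from \code{\link{sample_perturbation}}.
#' @return An n x 6 integer matrix of boxes
#'   (xlo, ylo, zlo, xhi, yhi, zhi).
#' @export
dilate_domains <- function(conf, pert) {
  pos <- conf$positions
  n <- nrow(pos)
  w <- pert$anchor + seq_len(pert$length)
  if (pert$anchor < 0L || max(w) > n)
    stop("perturbation window out of range", call. = FALSE)
  b <- cbind(pos, pos)
  colnames(b) <- c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi")
  b[w, 1:3] <- b[w, 1:3] - pert$dilation
  b[w, 4:6] <- b[w, 4:6] + pert$dilation
  b
}

#' Best re-placement of a subchain (one large-neighbourhood move)
#'
#' Builds the subchain CSP (flanks fixed at their current points, window
#' boxes dilated by b), exhaustively enumerates every feasible complete
#' conformation, and returns the minimum-energy one. The current
#' conformation is itself always feasible for this CSP (its points lie in
#' every dilated box), which is asserted on every call; consequently the
#' minimum enumerated energy never exceeds the current energy.
#'
#' By default the proposal is the best solution \emph{distinct} from the
#' current conformation (ties broken by enumeration order) so that the
#' annealing layer's acceptance test retains its role; when the current
#' conformation is the unique feasible solution it is returned unchanged
#' with \code{unchanged = TRUE}. With \code{strict_greedy = TRUE} the
#' literal minimum over all enumerated solutions (possibly the current one)
#' is returned.
#'
#' @param conf current \code{"fcc_conformation"}.
#' @param pert a perturbation (anchor, length, dilation).
#' @param table a \code{"contact_potential"}.
#' @param strict_greedy include the current conformation in the minimum.
#' @param strict_contacts restrict contacts to lattice-adjacent pairs.
#' @param max_nodes enumeration guard (search nodes).
#' @return A list with \code{conformation}, \code{energy} (its full contact
#'   energy), \code{count} (number of enumerated solutions),
#'   \code{current_energy} and \code{unchanged}.
#' @export
best_neighbour <- function(conf, pert, table, strict_greedy = FALSE,
                           strict_contacts = FALSE, max_nodes = 5e8) {
  stopifnot(inherits(table, "contact_potential"))
  if (pert$length > 15L)
    stop("subchain length above the exhaustive-enumeration guard (15)",
         call. = FALSE)
  boxes <- dilate_domains(conf, pert)
  ws <- pert$anchor + 1L
  wlen <- pert$length
  res <- cpp_best_window(conf$positions, seq_index0(conf$seq),
                         table$entries, ws, wlen,
                         boxes[ws:(ws + wlen - 1L), , drop = FALSE],
                         strict_contacts, strict_greedy, max_nodes)
  if (!isTRUE(res$found_current))
    stop("internal error: current conformation not found among enumerated ",
         "solutions", call. = FALSE)
  if (!isTRUE(res$have_best)) {
    # current conformation is the unique feasible solution
    return(list(conformation = conf, energy = res$current_energy,
                count = res$count, current_energy = res$current_energy,
                unchanged = TRUE))
  }
  pos <- conf$positions
  pos[ws:(ws + wlen - 1L), ] <- res$best_window
  unchanged <- all(pos == conf$positions)
  list(conformation = conformation(conf$seq, pos, validate = FALSE),
       energy = res$best_energy, count = res$count,
       current_energy = res$current_energy, unchanged = unchanged)
}
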