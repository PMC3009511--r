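# Finite-domain lattice CSP with box domains and binary L1-distance
# constraints, solved by backtracking + propagation with complete
# enumeration over a small set of free variables.
#
# A domain is an axis-aligned integer box [lower, upper]; it is admissible
# when it contains at least one FCC point and ground when it is a single FCC
# point. A model carries one lattice variable per residue, the chain
# adjacency constraint for every consecutive pair (L1 == 2 with the
# per-coordinate <= 1 cap) and the non-overlap constraint (L1 >= 2) for
# every pair with |i - j| > 1. Because distinct FCC points are always at L1
# distance >= 2 (parity), non-overlap is equivalent to all-different; the
# printed >= 2 form is what gets encoded.

#' Construct a box domain
#'
#' @param lower,upper integer triples; the domain is the closed box
#'   \code{[lower, upper]}.
#' @return A length-6 named integer vector (class \code{"box_domain"}).
#' @export
box_domain <- function(lower, upper) {
  lower <- check_point(lower, "lower"); upper <- check_point(upper, "upper")
  structure(c(lower, upper),
            names = c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi"),
            class = "box_domain")
}

box_mat <- function(boxes) {
  # boxes: list of box_domain (or length-6 vectors) -> n x 6 integer matrix
  m <- do.call(rbind, lapply(boxes, function(b) as.integer(unclass(b))))
  colnames(m) <- c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi")
  m
}

#' Box-domain admissibility and groundness
#'
#' A box is admissible when it is non-empty and contains at least one FCC
#' point (only a degenerate single-cell box of odd parity fails the latter);
#' it is ground when it is a single valid FCC point.
#'
#' @param box a \code{\link{box_domain}} or length-6 vector
#'   (xlo, ylo, zlo, xhi, yhi, zhi).
#' @return logical.
#' @export
box_is_admissible <- function(box) {
  b <- as.integer(unclass(box))
  if (any(b[1:3] > b[4:6])) return(FALSE)
  if (all(b[1:3] == b[4:6]) && sum(b[1:3]) %% 2L != 0L) return(FALSE)
  TRUE
}

#' @rdname box_is_admissible
#' @export
box_is_ground <- function(box) {
  b <- as.integer(unclass(box))
  all(b[1:3] == b[4:6]) && sum(b[1:3]) %% 2L == 0L
}

#' All FCC points inside a box domain
#'
#' @param box a \code{\link{box_domain}}.
#' @return Integer matrix (k x 3) of the FCC points of the box, in
#'   lexicographic order.
#' @export
box_fcc_points <- function(box) {
  b <- as.integer(unclass(box))
  g <- expand.grid(z = b[3]:b[6], y = b[2]:b[5], x = b[1]:b[4])
  g <- g[(g$x + g$y + g$z) %% 2L == 0L, c("x", "y", "z")]
  g <- g[order(g$x, g$y, g$z), ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  storage.mode(m) <- "integer"
  m
}

new_csp <- function(n, boxes, constraints, seq = NULL, table = NULL,
                    feasible = TRUE) {
  structure(list(n = n, boxes = boxes, constraints = constraints,
                 seq = seq, table = table, feasible = feasible),
            class = "fcc_csp")
}

#' @export
print.fcc_csp <- function(x, ...) {
  ng <- sum(csp_ground(x))
  cat(sprintf("FCC lattice CSP: %d variables (%d ground), %d constraints%s\n",
              x$n, ng, nrow(x$constraints),
              if (x$feasible) "" else " [INFEASIBLE]"))
  invisible(x)
}

# logical vector: which variables are ground (singleton FCC boxes)
csp_ground <- function(model) {
  b <- model$boxes
  all_eq <- b[, 1L] == b[, 4L] & b[, 2L] == b[, 5L] & b[, 3L] == b[, 6L]
  all_eq & (b[, 1L] + b[, 2L] + b[, 3L]) %% 2L == 0L
}

# n x 3 matrix of ground assignments (garbage rows for free variables)
csp_points <- function(model) {
  model$boxes[, 1:3, drop = FALSE]
}

#' Test whether a (pruned) model is still feasible
#'
#' @param model an \code{"fcc_csp"}.
#' @return logical; \code{FALSE} after \code{\link{prune_domains}} proves a
#'   constraint unsatisfiable or a domain empty.
#' @export
is_feasible <- function(model) isTRUE(model$feasible)

#' Construct a lattice CSP from boxes and explicit constraints
#'
#' Lower-level companion of \code{\link{build_folding_csp}} for arbitrary
#' binary L1-distance constraint sets (useful for experimentation and
#' randomized testing of the solver).
#'
#' @param boxes list of \code{\link{box_domain}}s (one per variable).
#' @param constraints data frame with columns \code{i}, \code{j} (1-based
#'   variable indices), \code{d} (distance) and \code{kind} (one of
#'   \code{"adj"} — L1 distance 2 with the per-coordinate cap, \code{"eq"}
#'   — L1 == d, \code{"ge"} — L1 >= d).
#' @return An \code{"fcc_csp"} model.
#' @export
lattice_csp <- function(boxes, constraints) {
  bm <- box_mat(boxes)
  n <- nrow(bm)
  for (i in seq_len(n))
    if (!box_is_admissible(bm[i, ]))
      stop(sprintf("box domain of variable V%d is inadmissible", i),
           call. = FALSE)
  stopifnot(is.data.frame(constraints),
            all(c("i", "j", "d", "kind") %in% names(constraints)))
  if (nrow(constraints)) {
    stopifnot(all(constraints$kind %in% c("adj", "eq", "ge")),
              all(constraints$i != constraints$j),
              all(constraints$i >= 1L), all(constraints$j <= n),
              all(constraints$d >= 0L))
  }
  new_csp(n, bm, constraints)
}

#' Build the protein-folding CSP for a sequence and per-residue box domains
#'
#' One lattice variable per residue; chain adjacency (L1 distance 2 with the
#' per-coordinate cap) for all n - 1 consecutive pairs; non-overlap (L1
#' distance >= 2) for every pair with |i - j| > 1. The constraint set is
#' fixed once built: search never adds constraints.
#'
#' @param seq an \code{\link{aa_sequence}}.
#' @param boxes list of \code{\link{box_domain}}s, one per residue, all
#'   admissible.
#' @param table optional \code{"contact_potential"} kept as the objective.
#' @return An \code{"fcc_csp"} model.
#' @export
build_folding_csp <- function(seq, boxes, table = NULL) {
  seq <- as_aa_seq(seq)
  n <- length(seq)
  if (length(boxes) != n)
    stop(sprintf("need one box per residue: %d boxes for n = %d",
                 length(boxes), n), call. = FALSE)
  bm <- box_mat(boxes)
  for (i in seq_len(n))
    if (!box_is_admissible(bm[i, ]))
      stop(sprintf("box domain of variable V%d is inadmissible", i),
           call. = FALSE)
  cons <- NULL
  if (n >= 2L)
    cons <- data.frame(i = 1:(n - 1L), j = 2:n, d = 2L, kind = "adj",
                       stringsAsFactors = FALSE)
  if (n >= 3L) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pr <- pr[pr[, 2L] - pr[, 1L] > 1L, , drop = FALSE]
    cons <- rbind(cons, data.frame(i = pr[, 1L], j = pr[, 2L], d = 2L,
                                   kind = "ge", stringsAsFactors = FALSE))
  }
  if (is.null(cons))
    cons <- data.frame(i = integer(0), j = integer(0), d = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
  new_csp(n, bm, cons, seq = seq, table = table)
}

# interval bounds on the L1 distance achievable between two boxes
box_l1_bounds <- function(bi, bj) {
  lo <- 0L; hi <- 0L
  for (c in 1:3) {
    l1c <- max(0L, bi[c] - bj[c + 3L], bj[c] - bi[c + 3L])
    h1c <- max(bi[c + 3L] - bj[c], bj[c + 3L] - bi[c])
    lo <- lo + l1c; hi <- hi + h1c
  }
  c(lo, hi)
}

#' Prune box domains by bounds consistency
#'
#' Shrinks boxes without removing any solution and detects proven
#' infeasibility. For every chain-adjacency constraint with one side ground
#' at point p, the free side's box is intersected with the +-1 cube around
#' p; every constraint is bounds-checked via interval arithmetic on the box
#' coordinates (minimum/maximum achievable L1 distance). Runs to a fixpoint,
#' so pruning twice equals pruning once.
#'
#' @param model an \code{"fcc_csp"}.
#' @return The pruned model; check \code{\link{is_feasible}} on the result
#'   (infeasibility is a return state, not an error).
#' @export
prune_domains <- function(model) {
  stopifnot(inherits(model, "fcc_csp"))
  b <- model$boxes
  cons <- model$constraints
  n <- model$n
  repeat {
    changed <- FALSE
    ground <- b[, 1L] == b[, 4L] & b[, 2L] == b[, 5L] & b[, 3L] == b[, 6L]
    # box emptiness of FCC points
    for (i in seq_len(n)) {
      if (any(b[i, 1:3] > b[i, 4:6]) ||
          (ground[i] && sum(b[i, 1:3]) %% 2L != 0L))
        return(new_csp(n, b, cons, model$seq, model$table, feasible = FALSE))
    }
    for (k in seq_len(nrow(cons))) {
      i <- cons$i[k]; j <- cons$j[k]; d <- cons$d[k]; kind <- cons$kind[k]
      bnd <- box_l1_bounds(b[i, ], b[j, ])
      bad <- switch(kind,
        adj = bnd[1L] > 2L || bnd[2L] < 2L ||
              any(pmax(0L, pmax(b[i, 1:3] - b[j, 4:6],
                                b[j, 1:3] - b[i, 4:6])) > 1L),
        eq  = bnd[1L] > d || bnd[2L] < d,
        ge  = bnd[2L] < d)
      if (bad)
        return(new_csp(n, b, cons, model$seq, model$table, feasible = FALSE))
      if (kind == "adj") {
        for (side in 1:2) {
          g <- if (side == 1L) i else j
          f <- if (side == 1L) j else i
          if (ground[g] && sum(b[g, 1:3]) %% 2L == 0L) {
            p <- b[g, 1:3]
            newlo <- pmax(b[f, 1:3], p - 1L)
            newhi <- pmin(b[f, 4:6], p + 1L)
            if (any(newlo != b[f, 1:3]) || any(newhi != b[f, 4:6])) {
              b[f, 1:3] <- newlo; b[f, 4:6] <- newhi
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  new_csp(n, b, cons, model$seq, model$table, feasible = TRUE)
}

#' Exhaustively enumerate all solutions of a lattice CSP
#'
#' Complete backtracking search: free variables are labeled left to right by
#' index, candidate FCC points inside each box in lexicographic order, and
#' every constraint is checked against already-labeled variables. Every
#' yielded assignment satisfies all constraints; the order is deterministic.
#'
#' @param model an \code{"fcc_csp"} (pruned or not).
#' @param max_solutions guard on the number of stored solutions.
#' @param max_free guard on the number of non-ground variables; exhaustive
#'   search above it is refused (default 15).
#' @return A list of n x 3 integer matrices, one per solution (empty list
#'   when the model has no solution).
#' @export
enumerate_solutions <- function(model, max_solutions = 1e5, max_free = 15L) {
  stopifnot(inherits(model, "fcc_csp"))
  if (!is_feasible(model)) return(list())
  ground <- csp_ground(model)
  if (sum(!ground) > max_free)
    stop(sprintf(paste0("%d free variables exceed the exhaustive-search ",
                        "guard of %d"), sum(!ground), max_free),
         call. = FALSE)
  kind_code <- c(adj = 0L, eq = 1L, ge = 2L)
  consm <- cbind(model$constraints$i, model$constraints$j,
                 model$constraints$d,
                 kind_code[model$constraints$kind])
  if (nrow(model$constraints) == 0L) consm <- matrix(0L, 0L, 4L)
  storage.mode(consm) <- "integer"
  res <- cpp_enumerate_csp(model$boxes, ground, csp_points(model), consm,
                           max_solutions)
  sols <- res$solutions
  lapply(seq_len(nrow(sols)), function(r) {
    m <- matrix(sols[r, ], ncol = 3L, byrow = TRUE)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
}

#' Pure constraint-programming search for a minimum-energy conformation
#'
#' Complete branch-and-bound enumeration of self-avoiding chains. To remove
#' translational and one rotational degree of freedom, residue 1 is anchored
#' at the origin and residue 2 at (1, 1, 0) (any conformation can be mapped
#' onto this anchoring by a lattice symmetry, which leaves the energy
#' unchanged); the remaining residues range over a cube of half-width
#' \code{box_halfwidth} centred at the origin. Within that anchored space
#' the search is exhaustive: pruning uses only an admissible bound on the
#' contacts the remaining residues could still close, plus a
#' symmetry-representative filter at the first free level, so the returned
#' energy is the exact optimum of the space whenever \code{complete} is
#' \code{TRUE}. If the time limit expires first, the incumbent is returned
#' with \code{complete = FALSE}.
#'
#' Because the box is finite, energies are exact optima of the anchored
#' space; for compact optima (attractive potentials) a box comfortably
#' larger than the chain's compact extent suffices.
#'
#' @param seq an \code{\link{aa_sequence}}.
#' @param table a \code{"contact_potential"}.
#' @param time_limit wall-clock budget in seconds (default 60).
#' @param box_halfwidth cube half-width (default \code{ceiling(n/2)}).
#' @param strict restrict contacts to lattice-adjacent pairs.
#' @return A list with \code{conformation}, \code{energy}, \code{complete}
#'   (TRUE iff the tree was exhausted) and \code{nodes} searched.
#' @export
solve_pure_cp <- function(seq, table, time_limit = 60,
                          box_halfwidth = NULL, strict = FALSE) {
  seq <- as_aa_seq(seq)
  stopifnot(inherits(table, "contact_potential"), time_limit > 0)
  n <- length(seq)
  if (is.null(box_halfwidth)) box_halfwidth <- ceiling(n / 2)
  res <- cpp_solve_pure(seq_index0(seq), table$entries,
                        as.integer(box_halfwidth), as.numeric(time_limit),
                        strict)
  conf <- NULL
  if (n <= 2L || isTRUE(res$have))
    conf <- conformation(seq, res$positions)
  list(conformation = conf, energy = res$energy,
       complete = isTRUE(res$complete), nodes = res$nodes)
}
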