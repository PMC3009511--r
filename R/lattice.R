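# FCC lattice geometry: points, adjacency, angles, self-avoiding walks.
#
# Lattice points are integer triples (x, y, z) with x + y + z even; each has
# exactly 12 nearest neighbours (the permutations of (+-1, +-1, 0)).
# Coordinates are unbounded signed integers; boxes only exist in the CSP
# layer. Points compare by value and iterate in lexicographic (x, y, z)
# order throughout the package.

# the 12 unit steps, lexicographic order (kept in sync with the C++ core)
fcc_steps <- function() {
  steps <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  steps <- steps[abs(steps$x) + abs(steps$y) + abs(steps$z) == 2, ]
  m <- as.matrix(steps[order(steps$x, steps$y, steps$z), ])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  storage.mode(m) <- "integer"
  m
}

check_point <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) != 3L || anyNA(p) || any(p != round(p)))
    stop(sprintf("'%s' must be an integer triple", arg), call. = FALSE)
  as.integer(p)
}

#' Test whether an integer triple is an FCC lattice point
#'
#' A point belongs to the face-centered-cubic lattice iff its coordinate sum
#' is even.
#'
#' @param p integer vector of length 3.
#' @return \code{TRUE} iff \code{sum(p)} is even.
#' @examples
#' is_fcc_point(c(0, 0, 0))  # TRUE
#' is_fcc_point(c(1, 0, 0))  # FALSE
#' @export
is_fcc_point <- function(p) {
  p <- check_point(p)
  sum(p) %% 2L == 0L
}

check_fcc <- function(p, arg = "p") {
  p <- check_point(p, arg)
  if (sum(p) %% 2L != 0L)
    stop(sprintf("'%s' is not an FCC point (coordinate sum is odd)", arg),
         call. = FALSE)
  p
}

#' L1 (Manhattan) distance between two lattice points
#'
#' @param p,q FCC lattice points.
#' @return Non-negative integer. For distinct FCC points the distance is
#'   always even and at least 2 (a parity consequence).
#' @export
l1_distance <- function(p, q) {
  p <- check_fcc(p, "p"); q <- check_fcc(q, "q")
  sum(abs(p - q))
}

#' FCC adjacency test
#'
#' Two FCC points are adjacent iff every per-coordinate absolute difference
#' is at most 1 and their sum is exactly 2. Adjacency implies L1 distance 2
#' but not conversely: (0,0,0) and (2,0,0) are at distance 2 yet not
#' adjacent.
#'
#' @param p,q FCC lattice points.
#' @return logical.
#' @export
are_adjacent <- function(p, q) {
  p <- check_fcc(p, "p"); q <- check_fcc(q, "q")
  d <- abs(p - q)
  all(d <= 1L) && sum(d) == 2L
}

#' The 12 lattice neighbours of an FCC point
#'
#' @param p an FCC lattice point.
#' @return A 12 x 3 integer matrix, rows in lexicographic order.
#' @export
fcc_neighbors <- function(p) {
  p <- check_fcc(p)
  sweep(fcc_steps(), 2L, p, "+")
}

#' Bond angle formed by three consecutive chain points
#'
#' Reports the angle at \code{p2} between the bonds \code{p1-p2} and
#' \code{p2-p3}: a straight continuation (equal step directions) is 180
#' degrees. On the FCC lattice only 60, 90, 120 and 180 degrees can occur.
#' The degenerate reversal \code{p3 == p1} is rejected because a chain may
#' not revisit a point.
#'
#' @param p1,p2,p3 FCC points with \code{p1-p2} and \code{p2-p3} adjacent.
#' @return The angle in degrees, one of 60, 90, 120, 180.
#' @export
bond_angle <- function(p1, p2, p3) {
  p1 <- check_fcc(p1, "p1"); p2 <- check_fcc(p2, "p2"); p3 <- check_fcc(p3, "p3")
  if (!are_adjacent(p1, p2) || !are_adjacent(p2, p3))
    stop("bond_angle needs two consecutive adjacent bonds", call. = FALSE)
  if (all(p1 == p3))
    stop("degenerate triple: p3 equals p1 (chain reversal)", call. = FALSE)
  # angle between vectors p2->p1 and p2->p3; both have length sqrt(2)
  ca <- sum((p1 - p2) * (p3 - p2)) / 2
  round(acos(pmin(1, pmax(-1, ca))) * 180 / pi)
}

#' Count directed self-avoiding walks on the FCC lattice
#'
#' Exact count, by exhaustive depth-first search, of directed self-avoiding
#' walks of a given number of steps starting from a fixed origin (walks
#' related by lattice symmetry are counted separately, the standard
#' convention for SAW counts). One step gives 12, two steps 132.
#'
#' @param steps number of steps (walk visits \code{steps + 1} points).
#' @param max_steps_cap runtime guard; counting is exponential in
#'   \code{steps}, so requests above the cap are refused (default 8).
#' @return The exact walk count as a double.
#' @export
count_saws <- function(steps, max_steps_cap = 8L) {
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != round(steps))
    stop("'steps' must be a positive integer", call. = FALSE)
  if (steps > max_steps_cap)
    stop(sprintf(paste0("refusing to count %d-step walks: exhaustive DFS is ",
                        "exponential and the cap is %d steps (raise ",
                        "'max_steps_cap' explicitly if you mean it)"),
                 as.integer(steps), as.integer(max_steps_cap)), call. = FALSE)
  cpp_count_saws(as.integer(steps))
}
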