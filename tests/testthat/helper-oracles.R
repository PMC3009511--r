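# Independent brute-force oracles used across the suite. Deliberately naive
# and written from the definitions only: no shared code with the package's
# search paths.

# all FCC points of a box given as c(xlo, ylo, zlo, xhi, yhi, zhi)
oracle_box_points <- function(b) {
  pts <- list()
  for (x in b[1]:b[4]) for (y in b[2]:b[5]) for (z in b[3]:b[6])
    if ((x + y + z) %% 2 == 0) pts[[length(pts) + 1L]] <- c(x, y, z)
  pts
}

oracle_l1 <- function(p, q) sum(abs(p - q))

oracle_adjacent <- function(p, q) {
  d <- abs(p - q)
  all(d <= 1) && sum(d) == 2
}

# directed self-avoiding walk count by naive recursion
oracle_saw_count <- function(steps) {
  steps12 <- list()
  for (x in -1:1) for (y in -1:1) for (z in -1:1)
    if (abs(x) + abs(y) + abs(z) == 2)
      steps12[[length(steps12) + 1L]] <- c(x, y, z)
  recur <- function(walk) {
    if (length(walk) == steps + 1L) return(1)
    cur <- walk[[length(walk)]]
    tot <- 0
    for (s in steps12) {
      nxt <- cur + s
      if (!any(vapply(walk, function(w) all(w == nxt), logical(1))))
        tot <- tot + recur(c(walk, list(nxt)))
    }
    tot
  }
  recur(list(c(0, 0, 0)))
}

# contact energy straight from the definition (double loop over pairs)
oracle_energy <- function(pos, seq, table, strict = FALSE) {
  n <- nrow(pos)
  e <- 0
  if (n < 3) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i <= 1) next
    d <- abs(pos[i, ] - pos[j, ])
    if (sum(d) != 2) next
    if (strict && any(d > 1)) next
    e <- e + table$entries[unclass(seq)[i], unclass(seq)[j]]
  }
  e
}

# one constraint checked directly
oracle_cons_ok <- function(kind, d, p, q) {
  dd <- oracle_l1(p, q)
  switch(kind,
         adj = oracle_adjacent(p, q),
         eq = dd == d,
         ge = dd >= d)
}

# full cartesian-product enumeration of a lattice CSP: every FCC point of
# every free box against every constraint; returns solutions as a character
# vector of canonical keys (one per full assignment)
oracle_enumerate_keys <- function(model) {
  n <- model$n
  b <- model$boxes
  ground <- b[, 1] == b[, 4] & b[, 2] == b[, 5] & b[, 3] == b[, 6] &
    (b[, 1] + b[, 2] + b[, 3]) %% 2 == 0
  cand <- vector("list", n)
  for (i in seq_len(n))
    cand[[i]] <- if (ground[i]) list(b[i, 1:3]) else
      oracle_box_points(b[i, ])
  cons <- model$constraints
  keys <- character(0)
  assign <- vector("list", n)
  recur <- function(v) {
    if (v > n) {
      for (k in seq_len(nrow(cons)))
        if (!oracle_cons_ok(cons$kind[k], cons$d[k],
                            assign[[cons$i[k]]], assign[[cons$j[k]]]))
          return(invisible(NULL))
      keys[[length(keys) + 1L]] <<-
        paste(unlist(assign), collapse = ",")
      return(invisible(NULL))
    }
    for (p in cand[[v]]) {
      assign[[v]] <<- p
      recur(v + 1L)
    }
  }
  recur(1L)
  keys
}

# minimum energy over all anchored self-avoiding chains within a cube, by
# naive recursion (independent of the branch-and-bound path)
oracle_anchored_min <- function(seq, table, halfwidth, strict = FALSE) {
  n <- length(seq)
  if (n <= 2) return(0)
  steps12 <- list()
  for (x in -1:1) for (y in -1:1) for (z in -1:1)
    if (abs(x) + abs(y) + abs(z) == 2)
      steps12[[length(steps12) + 1L]] <- c(x, y, z)
  best <- Inf
  pos <- matrix(0L, n, 3)
  pos[2, ] <- c(1L, 1L, 0L)
  recur <- function(i) {
    if (i > n) {
      e <- oracle_energy(pos, seq, table, strict)
      if (e < best) best <<- e
      return(invisible(NULL))
    }
    for (s in steps12) {
      p <- pos[i - 1, ] + s
      if (any(abs(p) > halfwidth)) next
      clash <- FALSE
      for (j in 1:(i - 1)) if (all(pos[j, ] == p)) { clash <- TRUE; break }
      if (clash) next
      pos[i, ] <<- p
      recur(i + 1L)
    }
  }
  recur(3L)
  best
}

# brute-force best re-placement of a window: enumerate all self-avoiding
# re-placements of residues ws..we inside the given boxes with flanks
# fixed, scoring each full conformation with oracle_energy. Returns the
# count of feasible re-placements and the minimum energy among those
# distinct from the current window (NA if none).
oracle_window <- function(conf, ws, we, boxes, table, strict = FALSE) {
  pos <- conf$positions
  n <- nrow(pos)
  fixed <- setdiff(seq_len(n), ws:we)
  count <- 0L
  best_distinct <- NA_real_
  work <- pos
  recur <- function(g) {
    if (g > we) {
      count <<- count + 1L
      if (!all(work[ws:we, ] == pos[ws:we, ])) {
        e <- oracle_energy(work, conf$seq, table, strict)
        if (is.na(best_distinct) || e < best_distinct) best_distinct <<- e
      }
      return(invisible(NULL))
    }
    b <- boxes[g, ]
    for (p in oracle_box_points(b)) {
      if (g > 1 && !oracle_adjacent(work[g - 1, ], p)) next
      if (g == we && we < n && !oracle_adjacent(p, pos[we + 1, ])) next
      clash <- FALSE
      for (j in fixed) if (all(pos[j, ] == p)) { clash <- TRUE; break }
      if (!clash && g > ws)
        for (j in ws:(g - 1)) if (all(work[j, ] == p)) { clash <- TRUE; break }
      if (clash) next
      work[g, ] <<- p
      recur(g + 1L)
    }
  }
  recur(ws)
  list(count = count, best_distinct = best_distinct)
}

# fixture: the tetrahedral 4-chain with all three non-consecutive contacts
tetra_conf <- function(seq = aa_sequence("ACDE")) {
  conformation(seq, rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
}

# fixture: a planar zigzag chain of length n (contact-poor)
zigzag_conf <- function(n, seq = NULL) {
  if (is.null(seq)) seq <- aa_sequence(rep("A", n))
  pos <- matrix(0L, n, 3)
  for (i in seq_len(n)[-1])
    pos[i, ] <- pos[i - 1, ] + c(1L, if (i %% 2 == 0) 1L else -1L, 0L)
  conformation(seq, pos)
}

# random admissible small CSP instance for oracle-equivalence testing;
# keeps the cartesian search space below `cap` so the naive oracle stays
# tractable. Returns an fcc_csp.
random_small_csp <- function(cap = 2e5) {
  repeat {
    nv <- sample(3:6, 1)
    nfree <- sample(1:4, 1)
    free <- sort(sample(seq_len(nv), min(nfree, nv)))
    boxes <- vector("list", nv)
    for (i in seq_len(nv)) {
      if (i %in% free) {
        ctr <- c(sample(-3:3, 1), sample(-3:3, 1), sample(-3:3, 1))
        side <- sample(1:5, 3, replace = TRUE)
        lo <- ctr - (side - 1) %/% 2
        hi <- lo + side - 1
        # guarantee at least one FCC point
        if (all(side == 1) && sum(lo) %% 2 != 0) { lo[1] <- lo[1] + 1; hi <- lo }
        boxes[[i]] <- box_domain(lo, hi)
      } else {
        p <- c(sample(-3:3, 1), sample(-3:3, 1), sample(-3:3, 1))
        if (sum(p) %% 2 != 0) p[1] <- p[1] + 1
        boxes[[i]] <- box_domain(p, p)
      }
    }
    # search-space size for the naive oracle
    sz <- prod(vapply(boxes, function(b) {
      b <- unclass(b)
      if (all(b[1:3] == b[4:6])) 1 else length(oracle_box_points(b))
    }, numeric(1)))
    if (sz > cap || sz == 0) next
    cons <- data.frame(i = integer(0), j = integer(0), d = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(nv - 1))
      if (runif(1) < 0.7)
        cons <- rbind(cons, data.frame(i = i, j = i + 1, d = 2L,
                                       kind = "adj"))
    pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (j - i > 1 && runif(1) < 0.5)
        cons <- rbind(cons, data.frame(i = i, j = j, d = 2L, kind = "ge"))
      else if (runif(1) < 0.1)
        cons <- rbind(cons, data.frame(i = i, j = j,
                                       d = sample(c(2L, 4L), 1),
                                       kind = "eq"))
    }
    if (nrow(cons) == 0) next
    return(lattice_csp(boxes, cons))
  }
}

solutions_to_keys <- function(sols) {
  vapply(sols, function(m) paste(as.vector(t(m)), collapse = ","),
         character(1))
}
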