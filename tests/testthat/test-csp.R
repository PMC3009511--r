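test_that("box domains know admissibility, groundness and their FCC points", {
  expect_true(box_is_admissible(box_domain(c(0, 0, 0), c(1, 1, 1))))
  expect_false(box_is_admissible(box_domain(c(1, 0, 0), c(0, 0, 0))))
  # single odd-parity cell: no FCC point
  expect_false(box_is_admissible(box_domain(c(1, 0, 0), c(1, 0, 0))))
  expect_true(box_is_ground(box_domain(c(1, 1, 0), c(1, 1, 0))))
  expect_false(box_is_ground(box_domain(c(0, 0, 0), c(1, 1, 1))))
  pts <- box_fcc_points(box_domain(c(-1, -1, -1), c(1, 1, 1)))
  expect_equal(nrow(pts), 13L)  # origin + 12 neighbours
  expect_true(all(rowSums(pts) %% 2 == 0))
})

test_that("the folding CSP carries adjacency and non-overlap constraints", {
  mk <- function(n) {
    boxes <- replicate(n, box_domain(c(-5, -5, -5), c(5, 5, 5)),
                       simplify = FALSE)
    build_folding_csp(aa_sequence(rep("A", n)), boxes)
  }
  m3 <- mk(3)
  expect_equal(sum(m3$constraints$kind == "adj"), 2L)
  expect_equal(sum(m3$constraints$kind == "ge"), 1L)
  m5 <- mk(5)
  expect_equal(sum(m5$constraints$kind == "adj"), 4L)
  expect_equal(sum(m5$constraints$kind == "ge"), 6L)
  m1 <- mk(1)
  expect_equal(nrow(m1$constraints), 0L)
  expect_error(build_folding_csp(aa_sequence("ACD"),
                                 list(box_domain(c(0, 0, 0), c(0, 0, 0)),
                                      box_domain(c(1, 0, 0), c(1, 0, 0)),
                                      box_domain(c(0, 0, 0), c(1, 1, 1)))),
               "V2")
})

test_that("non-overlap (L1 >= 2) is equivalent to all-different on the lattice", {
  # parity forces distinct FCC points to L1 distance >= 2
  set.seed(13)
  for (k in 1:300) {
    p <- sample(-8:8, 3, replace = TRUE)
    q <- sample(-8:8, 3, replace = TRUE)
    if (sum(p) %% 2 != 0) p[1] <- p[1] + 1L
    if (sum(q) %% 2 != 0) q[1] <- q[1] + 1L
    expect_equal(sum(abs(p - q)) >= 2, !all(p == q))
  }
})

test_that("pruning shrinks boxes soundly and detects infeasibility", {
  # free variable adjacent to a ground origin: box shrinks to the +-1 cube
  boxes <- list(box_domain(c(0, 0, 0), c(0, 0, 0)),
                box_domain(c(-50, -50, -50), c(50, 50, 50)))
  m <- lattice_csp(boxes, data.frame(i = 1L, j = 2L, d = 2L, kind = "adj"))
  pr <- prune_domains(m)
  expect_true(is_feasible(pr))
  expect_equal(unname(pr$boxes[2, ]), c(-1L, -1L, -1L, 1L, 1L, 1L))
  # two ground points at distance 4 under an adjacency constraint
  boxes <- list(box_domain(c(0, 0, 0), c(0, 0, 0)),
                box_domain(c(2, 2, 0), c(2, 2, 0)))
  m2 <- lattice_csp(boxes, data.frame(i = 1L, j = 2L, d = 2L, kind = "adj"))
  expect_false(is_feasible(prune_domains(m2)))
  # ge constraint that no pair of box points can satisfy
  boxes <- list(box_domain(c(0, 0, 0), c(1, 1, 1)),
                box_domain(c(0, 0, 0), c(1, 1, 1)))
  m3 <- lattice_csp(boxes, data.frame(i = 1L, j = 2L, d = 10L, kind = "ge"))
  expect_false(is_feasible(prune_domains(m3)))
})

test_that("pruning is idempotent and never removes a solution", {
  set.seed(101)
  for (k in 1:25) {
    m <- random_small_csp(cap = 5e4)
    p1 <- prune_domains(m)
    p2 <- prune_domains(p1)
    expect_equal(p1$boxes, p2$boxes)
    expect_equal(is_feasible(p1), is_feasible(p2))
    before <- sort(solutions_to_keys(enumerate_solutions(m)))
    after <- if (is_feasible(p1))
      sort(solutions_to_keys(enumerate_solutions(p1))) else character(0)
    expect_equal(after, before)
  }
})

test_that("enumeration yields exactly the free-middle placements", {
  # V2 free between ground (0,0,0) and (2,0,0): the four mid points
  boxes <- list(box_domain(c(0, 0, 0), c(0, 0, 0)),
                box_domain(c(-9, -9, -9), c(9, 9, 9)),
                box_domain(c(2, 0, 0), c(2, 0, 0)))
  m <- lattice_csp(boxes, data.frame(i = c(1L, 2L, 1L), j = c(2L, 3L, 3L),
                                     d = 2L, kind = c("adj", "adj", "ge")))
  sols <- enumerate_solutions(m)
  expect_length(sols, 4L)
  mids <- t(vapply(sols, function(s) s[2, ], integer(3)))
  expect_equal(mids[order(mids[, 1], mids[, 2], mids[, 3]), ],
               rbind(c(1L, -1L, 0L), c(1L, 0L, -1L), c(1L, 0L, 1L),
                     c(1L, 1L, 0L)), ignore_attr = TRUE)
  # all ground and satisfied: exactly one solution
  g <- list(box_domain(c(0, 0, 0), c(0, 0, 0)),
            box_domain(c(1, 1, 0), c(1, 1, 0)))
  mg <- lattice_csp(g, data.frame(i = 1L, j = 2L, d = 2L, kind = "adj"))
  expect_length(enumerate_solutions(mg), 1L)
})

test_that("enumeration matches the cartesian brute-force oracle on random models", {
  set.seed(202)
  for (k in 1:50) {
    m <- random_small_csp(cap = 2e5)
    got <- sort(solutions_to_keys(enumerate_solutions(m,
                                                      max_solutions = 3e5)))
    want <- sort(oracle_enumerate_keys(m))
    expect_equal(got, want)
  }
})

test_that("every enumerated assignment satisfies every constraint", {
  set.seed(303)
  for (k in 1:10) {
    m <- random_small_csp(cap = 5e4)
    sols <- enumerate_solutions(m)
    for (s in utils::head(sols, 50)) {
      for (r in seq_len(nrow(m$constraints)))
        expect_true(oracle_cons_ok(m$constraints$kind[r], m$constraints$d[r],
                                   s[m$constraints$i[r], ],
                                   s[m$constraints$j[r], ]))
    }
  }
})

test_that("the free-variable guard refuses oversized exhaustive searches", {
  boxes <- replicate(20, box_domain(c(-2, -2, -2), c(2, 2, 2)),
                     simplify = FALSE)
  m <- build_folding_csp(aa_sequence(rep("A", 20)), boxes)
  expect_error(enumerate_solutions(m), "guard")
})

test_that("pure CP search is exact against the anchored-space oracle", {
  u <- uniform_potential(-1)
  # n = 4: the tetrahedral placement realizes all 3 possible contacts
  r4 <- solve_pure_cp(aa_sequence("ACDE"), u, time_limit = 30)
  expect_true(r4$complete)
  expect_equal(r4$energy, -3)
  expect_silent(validate_conformation(r4$conformation))
  # n = 2: no contact pairs exist
  r2 <- solve_pure_cp(aa_sequence("AC"), u, time_limit = 5)
  expect_true(r2$complete)
  expect_equal(r2$energy, 0)
  # n = 5 and 6, uniform and random tables, versus the naive recursion
  set.seed(77)
  m <- matrix(rnorm(400), 20, 20); m <- (m + t(m)) / 2
  rnd <- potential_table(m)
  for (n in c(5, 6)) {
    s <- random_sequence(n)
    for (tab in list(u, rnd)) {
      r <- solve_pure_cp(s, tab, time_limit = 120, box_halfwidth = 3)
      expect_true(r$complete)
      expect_equal(r$energy, oracle_anchored_min(s, tab, halfwidth = 3))
      expect_equal(conformation_energy(r$conformation, tab), r$energy)
    }
  }
})
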