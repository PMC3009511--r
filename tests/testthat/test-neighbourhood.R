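test_that("policy construction normalizes weights and validates rows", {
  p <- default_policy()
  expect_equal(p$l, c(7L, 9L, 11L, 13L))
  expect_equal(p$b, c(3L, 2L, 1L, 1L))
  expect_equal(p$p, c(0.5, 0.3, 0.15, 0.05))
  expect_equal(sum(p$p), 1)
  # weights are normalized, zero-weight rows dropped
  p2 <- perturbation_policy(l = c(3L, 5L), b = 1L, p = c(2, 0))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$p, 1)
  expect_error(perturbation_policy(1L, 4L, 1), "1..3")
  expect_error(perturbation_policy(c(3L, 3L), 1L, c(0.5, 0.5)), "duplicate")
  expect_error(perturbation_policy(3L, 1L, -1), "non-negative")
})

test_that("subchain lengths are drawn with the policy frequencies", {
  set.seed(55)
  n <- 80L
  draws <- replicate(10000, sample_perturbation(default_policy(), n),
                     simplify = FALSE)
  ls <- vapply(draws, `[[`, integer(1), "length")
  freq <- table(factor(ls, levels = c(7, 9, 11, 13))) / length(ls)
  for (k in seq_len(4)) {
    p <- default_policy()$p[k]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(freq[k] - p), 3 * se + 1e-12)
  }
  # the dilation always comes from the selected row
  bs <- vapply(draws, `[[`, integer(1), "dilation")
  expect_equal(unname(c(b7 = unique(bs[ls == 7]), b13 = unique(bs[ls == 13]))),
               c(3L, 1L))
})

test_that("infeasible rows are excluded and anchors stay in range", {
  # single-row degenerate policy
  p1 <- perturbation_policy(7L, 3L, 1)
  set.seed(8)
  d <- sample_perturbation(p1, 30L)
  expect_equal(d$length, 7L)
  expect_equal(d$dilation, 3L)
  # n = 10: only l = 7 fits the default policy
  set.seed(9)
  for (k in 1:1000) {
    d <- sample_perturbation(default_policy(), 10L)
    expect_equal(d$length, 7L)
    expect_gte(d$anchor, 0L)
    expect_lte(d$anchor + d$length, 10L)
  }
  expect_error(sample_perturbation(default_policy(), 5L), "shorter")
})

test_that("domain dilation builds +-b cubes around the window only", {
  conf <- initial_conformation(20)
  pert <- structure(list(anchor = 4L, length = 5L, dilation = 3L),
                    class = "perturbation")
  b <- dilate_domains(conf, pert)
  w <- 5:9
  expect_equal(unname(b[w, 1:3]), unname(conf$positions[w, ] - 3L))
  expect_equal(unname(b[w, 4:6]), unname(conf$positions[w, ] + 3L))
  out <- setdiff(1:20, w)
  expect_equal(unname(b[out, 1:3]), unname(conf$positions[out, ]))
  expect_equal(unname(b[out, 4:6]), unname(conf$positions[out, ]))
  # b = 1 gives side-3 boxes; the current point is inside its box
  pert1 <- structure(list(anchor = 0L, length = 3L, dilation = 1L),
                     class = "perturbation")
  b1 <- dilate_domains(conf, pert1)
  expect_true(all(b1[1:3, 4:6] - b1[1:3, 1:3] == 2L))
  expect_true(all(b1[, 1:3] <= conf$positions & conf$positions <= b1[, 4:6]))
})

test_that("best_neighbour matches the brute-force window oracle", {
  u <- uniform_potential(-1)
  set.seed(121)
  for (k in 1:8) {
    n <- sample(5:9, 1)
    conf <- initial_conformation(n, seq = random_sequence(n))
    l <- sample(2:3, 1)
    anchor <- sample(0:(n - l), 1)
    pert <- structure(list(anchor = anchor, length = l,
                           dilation = sample(1:2, 1)),
                      class = "perturbation")
    res <- best_neighbour(conf, pert, u)
    boxes <- dilate_domains(conf, pert)
    orc <- oracle_window(conf, anchor + 1L, anchor + l, boxes, u)
    expect_equal(res$count, orc$count)
    if (!is.na(orc$best_distinct)) {
      expect_false(res$unchanged)
      expect_equal(res$energy, orc$best_distinct)
    } else {
      expect_true(res$unchanged)
    }
    # returned conformation is valid and equals the claimed energy
    expect_silent(validate_conformation(res$conformation))
    expect_equal(conformation_energy(res$conformation, u), res$energy)
    # untouched residues are bit-identical
    out <- setdiff(seq_len(n), (anchor + 1):(anchor + l))
    expect_identical(res$conformation$positions[out, ],
                     conf$positions[out, ])
  }
})

test_that("the current conformation is always feasible for its own CSP", {
  u <- uniform_potential(-1)
  set.seed(131)
  conf <- initial_conformation(16, seq = random_sequence(16))
  for (k in 1:50) {
    pert <- sample_perturbation(perturbation_policy(c(3L, 5L), 1L,
                                                    c(0.7, 0.3)), 16L)
    res <- best_neighbour(conf, pert, u)
    expect_gte(res$count, 1)
    # min enumerated energy never exceeds the current energy
    expect_lte(min(res$energy, res$current_energy),
               conformation_energy(conf, u))
    expect_equal(res$current_energy, conformation_energy(conf, u))
    if (!res$unchanged) conf <- res$conformation
  }
})

test_that("strict greedy mode may return the current conformation", {
  u <- uniform_potential(-1)
  # a 4-chain where the window cannot improve: greedy keeps it
  tet <- tetra_conf()
  pert <- structure(list(anchor = 1L, length = 2L, dilation = 1L),
                    class = "perturbation")
  res <- best_neighbour(tet, pert, u, strict_greedy = TRUE)
  expect_lte(res$energy, res$current_energy)
})

test_that("enumerated solution sets grow with the dilation parameter", {
  u <- uniform_potential(-1)
  set.seed(141)
  conf <- initial_conformation(9, seq = random_sequence(9))
  counts <- vapply(1:3, function(b) {
    pert <- structure(list(anchor = 3L, length = 3L, dilation = b),
                      class = "perturbation")
    best_neighbour(conf, pert, u)$count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
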