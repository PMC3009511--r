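test_that("pair energies are symmetric table lookups with validation", {
  u <- uniform_potential(-1)
  expect_equal(pair_energy(u, "A", "C"), -1)
  tab <- u$entries
  tab["A", "A"] <- 0
  t2 <- potential_table(tab)
  expect_equal(pair_energy(t2, "A", "A"), 0)
  set.seed(3)
  m <- matrix(rnorm(400), 20, 20)
  m <- (m + t(m)) / 2
  t3 <- potential_table(m)
  for (k in 1:20) {
    ab <- sample(AA_ALPHABET, 2)
    expect_equal(pair_energy(t3, ab[1], ab[2]), pair_energy(t3, ab[2], ab[1]))
  }
  expect_error(pair_energy(u, "X", "A"), "unknown residue code 'X'")
  expect_error(potential_table(m + diag(1e-3, 20)), NA)  # still symmetric
  m2 <- m; m2[1, 2] <- m2[1, 2] + 1
  expect_error(potential_table(m2), "not symmetric")
})

test_that("contacts require sequence separation > 1 and L1 distance 2", {
  conf <- conformation("ACD", rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1)))
  expect_true(in_contact(conf, 1, 3))
  expect_false(in_contact(conf, 1, 2))
  expect_false(in_contact(conf, 2, 3))
  expect_error(in_contact(conf, 0, 3), "out of range")
  expect_error(in_contact(conf, 1, 4), "out of range")
  # pair at L1 distance 4 is not a contact
  zz <- zigzag_conf(4)
  expect_equal(l1_distance(zz$positions[1, ], zz$positions[4, ]), 4)
  expect_false(in_contact(zz, 1, 4))
})

test_that("contact lists match a brute-force pair scan", {
  expect_equal(nrow(contact_list(conformation("AC", rbind(c(0, 0, 0),
                                                          c(1, 1, 0))))), 0)
  tet <- tetra_conf()
  expect_equal(contact_list(tet),
               cbind(i = c(1L, 1L, 2L), j = c(3L, 4L, 4L)))
  zz <- zigzag_conf(4)
  expect_equal(contact_list(zz), cbind(i = c(1L, 2L), j = c(3L, 4L)))
  # property: agreement with the naive double loop on random chains
  set.seed(19)
  for (k in 1:10) {
    f <- run_hybrid(random_sequence(12), uniform_potential(-1),
                    anneal_config(iterations = 10L, seed = k,
                                  policy = perturbation_policy(3L, 1L, 1)))
    conf <- f$best_conformation
    cl <- contact_list(conf)
    manual <- NULL
    n <- nrow(conf$positions)
    for (i in 1:(n - 2)) for (j in (i + 2):n)
      if (sum(abs(conf$positions[i, ] - conf$positions[j, ])) == 2)
        manual <- rbind(manual, c(i, j))
    expect_equal(unname(cl), unname(manual))
  }
})

test_that("strict contact mode drops the non-adjacent (2,0,0)-type pairs", {
  zz <- zigzag_conf(4)  # residues 1,3 sit at offset (2,0,0)
  expect_true(in_contact(zz, 1, 3))
  expect_false(in_contact(zz, 1, 3, strict = TRUE))
  expect_equal(nrow(contact_list(zz, strict = TRUE)), 0)
  tet <- tetra_conf()  # tetrahedral contacts are lattice-adjacent
  expect_equal(contact_list(tet, strict = TRUE), contact_list(tet))
})

test_that("conformation energy is the sum of pair energies over contacts", {
  u <- uniform_potential(-1)
  tet <- tetra_conf()
  expect_equal(conformation_energy(tet, u), -3)
  expect_equal(conformation_energy(conformation("AC", rbind(c(0, 0, 0),
                                                            c(1, 1, 0))),
                                   u), 0)
  set.seed(5)
  m <- matrix(rnorm(400), 20, 20); m <- (m + t(m)) / 2
  tab <- potential_table(m)
  expect_equal(conformation_energy(tet, tab),
               oracle_energy(tet$positions, tet$seq, tab))
  # uniform table: energy = value * contact count
  zz <- zigzag_conf(9)
  expect_equal(conformation_energy(zz, uniform_potential(-2.5)),
               -2.5 * nrow(contact_list(zz)))
})

test_that("energy is invariant under translation and lattice symmetry", {
  set.seed(23)
  m <- matrix(rnorm(400), 20, 20); m <- (m + t(m)) / 2
  tab <- potential_table(m)
  f <- run_hybrid(random_sequence(14), tab,
                  anneal_config(iterations = 20L, seed = 4,
                                policy = perturbation_policy(3L, 1L, 1)))
  conf <- f$best_conformation
  e0 <- conformation_energy(conf, tab)
  # translations by FCC vectors
  for (off in list(c(2, 0, 0), c(1, 1, 0), c(-3, 1, 2))) {
    shifted <- conformation(conf$seq,
                            sweep(conf$positions, 2, as.integer(off), "+"))
    expect_equal(conformation_energy(shifted, tab), e0)
  }
  # signed permutations of the axes preserve the lattice and the energy
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  signs <- list(c(1, 1, 1), c(-1, 1, 1), c(-1, -1, 1), c(1, -1, -1))
  for (pr in perms) for (sg in signs) {
    pp <- sweep(conf$positions[, pr, drop = FALSE], 2, sg, "*")
    rot <- conformation(conf$seq, pp)
    expect_equal(conformation_energy(rot, tab), e0)
  }
})

test_that("potential table text round-trips, full and lower-triangle", {
  set.seed(31)
  m <- matrix(round(rnorm(400), 4), 20, 20); m <- (m + t(m)) / 2
  tab <- potential_table(m, source_label = "random-fixture")
  f <- tempfile(fileext = ".txt")
  write_potential(tab, f)
  back <- read_potential(f)
  expect_equal(back$entries, tab$entries)
  # lower-triangle form
  f2 <- tempfile(fileext = ".txt")
  lines <- paste(AA_ALPHABET, collapse = " ")
  for (i in 1:20)
    lines <- c(lines, paste(format(tab$entries[i, 1:i], digits = 10,
                                   trim = TRUE), collapse = " "))
  writeLines(lines, f2)
  expect_equal(read_potential(f2)$entries, tab$entries)
  # asymmetric full matrix is rejected
  f3 <- tempfile(fileext = ".txt")
  m2 <- m; m2[1, 2] <- m2[1, 2] + 0.5
  lines <- c(paste(AA_ALPHABET, collapse = " "),
             apply(m2, 1, function(r) paste(format(r, digits = 10,
                                                   trim = TRUE),
                                            collapse = " ")))
  writeLines(lines, f3)
  expect_error(read_potential(f3), "symmetric")
})
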