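test_that("default truth is a pure function with covalent-radius widths", {
  t1 <- default_truth(c("Na", "Cl"))
  t2 <- default_truth(c("Na", "Cl"))
  expect_identical(t1, t2)
  expect_equal(unname(t1$electro$sigma[c("Na", "Cl")]),
               covalent_radius(c("Na", "Cl"), "bohr"))
  expect_error(default_truth(c("A", "B", "C", "D")), "1-3")
  expect_error(default_truth(c("Na", "Na")), "duplicate")
})

test_that("ground-truth labels are self-consistent", {
  truth <- default_truth(c("Na", "Cl"))
  # isolated neutral atom: everything zero
  r0 <- label_structure(truth, atoms("Na", matrix(0, 1, 3)))
  expect_equal(r0$energy, 0)
  expect_true(all(r0$forces == 0))
  expect_equal(r0$charges, 0)
  # equilateral homonuclear trimer at +1: perfect symmetry
  ta <- default_truth("Ag")
  d <- 2.9
  tri <- atoms(rep("Ag", 3),
               rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0)),
               total_charge = 1)
  rt <- label_structure(ta, tri)
  expect_equal(rt$charges, rep(1 / 3, 3), tolerance = 1e-12)
  # forces are the exact gradient of the labelled energy
  set.seed(6)
  st <- random_cluster(6, seed = 61, box = 5, total_charge = 1)
  lab <- label_structure(truth, st)
  expect_lt(abs(sum(lab$charges) - 1), 1e-12)
  ba <- units_au$bohr_ang
  worst <- 0
  for (k in c(1, 3, 6)) {
    for (a in 1:3) {
      sp <- st; sm <- st
      sp$positions[k, a] <- sp$positions[k, a] + 1e-4 * ba
      sm$positions[k, a] <- sm$positions[k, a] - 1e-4 * ba
      fd <- -(label_structure(truth, sp, forces = FALSE)$energy -
                label_structure(truth, sm, forces = FALSE)$energy) / 2e-4
      worst <- max(worst, abs(fd - lab$forces[k, a]))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("truth Qeq matrices are positive definite on the constraint subspace", {
  for (spec in list(list(el = "Ag", name = "trimer_ions"),
                    list(el = c("C", "H"), name = "chain_protonation"),
                    list(el = c("Na", "Cl"), name = "cluster_vacancy"))) {
    truth <- default_truth(spec$el)
    tmpl <- hdnnp:::.scenario_templates(spec$name, truth)
    for (tp in tmpl) {
      st <- tp$st
      coordchi <- rep(0, st$n_atoms)
      sys <- qeq_system(st, coordchi, truth$electro)
      n <- st$n_atoms
      # project A onto the zero-sum subspace and check eigenvalues
      P <- diag(n) - matrix(1 / n, n, n)
      ev <- eigen(P %*% sys$A %*% P, symmetric = TRUE)$values
      expect_gt(min(ev[seq_len(n - 1)]), 0)
    }
  }
})

test_that("scenario generation is deterministic and correctly tagged", {
  truth <- default_truth("Ag")
  sc <- scenario("trimer_ions", n = 3, seed = 21)
  r1 <- generate_scenario(sc, truth)
  r2 <- generate_scenario(sc, truth)
  expect_identical(r1, r2)
  expect_length(r1, 6)   # n per sub-population
  pops <- vapply(r1, function(r) r$structure$info$population, "")
  expect_equal(sum(pops == "cation"), 3)
  expect_equal(sum(pops == "anion"), 3)
  expect_error(scenario("unknown_thing"), "arg")
})

test_that("trimer populations are descriptor-identical but charge-distinct", {
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 2, seed = 5), truth)
  p <- acsf_params("Ag", cutoff = 8)
  for (k in c(1, 3)) {
    cation <- recs[[k]]; anion <- recs[[k + 1]]
    expect_identical(cation$structure$positions, anion$structure$positions)
    dc <- acsf_compute(cation$structure, p, gradients = FALSE)$values
    da <- acsf_compute(anion$structure, p, gradients = FALSE)$values
    expect_identical(dc, da)
    expect_gt(max(abs(cation$charges - anion$charges)), 0.1)
  }
})

test_that("cluster vacancy redistributes the charge globally", {
  truth <- default_truth(c("Na", "Cl"))
  recs <- generate_scenario(scenario("cluster_vacancy", n = 1, sigma = 0,
                                     seed = 2), truth)
  full <- recs[[1]]; vac <- recs[[2]]
  expect_equal(full$structure$n_atoms, 17)
  expect_equal(vac$structure$n_atoms, 16)
  expect_lt(abs(sum(full$charges) - 1), 1e-12)
  expect_lt(abs(sum(vac$charges) - 1), 1e-12)
  # the retained atoms carry different charges in the two populations
  expect_gt(max(abs(full$charges[1:16] - vac$charges)), 1e-3)
  # the discriminating feature is far outside the descriptor cutoff of
  # the probe end (non-local by construction)
  probe_gap <- sqrt(sum((full$structure$positions[17, ] -
                           full$structure$positions[1, ])^2))
  expect_gt(probe_gap, 2 * acsf_params(c("Na", "Cl"), cutoff = 8)$cutoff)
})

test_that("doped slab is periodic, neutral and distantly discriminated", {
  truth <- default_truth(c("Mg", "O", "Al"))
  recs <- generate_scenario(scenario("doped_slab", n = 1, seed = 3), truth,
                            forces = FALSE)
  expect_length(recs, 2)
  pure <- recs[[1]]$structure; doped <- recs[[2]]$structure
  expect_true(all(pure$pbc))
  expect_identical(pure$total_charge, 0)
  expect_equal(sum(doped$species == "Al"), 3)  # dopant + 2 adsorbate atoms
  expect_equal(sum(pure$species == "Al"), 2)
  # dopant sits outside the adsorbate descriptor cutoff
  idop <- which(doped$species != pure$species)
  ads <- doped$n_atoms - 1:0
  dmin <- min(sqrt(rowSums((doped$positions[ads, , drop = FALSE] -
                              matrix(doped$positions[idop, ], 2, 3,
                                     byrow = TRUE))^2)))
  expect_gt(dmin, acsf_params("Al", cutoff = 8)$cutoff)
})
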