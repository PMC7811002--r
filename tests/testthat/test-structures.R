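test_that("extended-XYZ round trip is lossless for all field combinations", {
  set.seed(1)
  st1 <- random_cluster(5, total_charge = 1)
  st1$info <- list(scenario = "unit", population = "a")
  rec1 <- reference_record(st1, energy = -1.2345678901234,
                           forces = matrix(rnorm(15), 5, 3),
                           charges = c(0.4, 0.3, 0.2, 0.05, 0.05))
  st2 <- atoms(c("Na", "Cl"), rbind(c(0, 0, 0), c(2.8, 0.1, -0.3)),
               cell = diag(3) * 9.1, pbc = TRUE, total_charge = 0)
  rec2 <- reference_record(st2, energy = 0.5)   # no forces/charges
  tmp <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(list(rec1, rec2), tmp)
  back <- read_extxyz(tmp)

  expect_length(back, 2)
  expect_equal(back[[1]]$structure$positions, st1$positions, tolerance = 1e-11)
  expect_equal(back[[1]]$structure$species, st1$species)
  expect_identical(back[[1]]$structure$info$population, "a")
  expect_equal(back[[1]]$energy, rec1$energy, tolerance = 1e-11)
  expect_equal(back[[1]]$forces, rec1$forces, tolerance = 1e-11)
  expect_equal(back[[1]]$charges, rec1$charges, tolerance = 1e-11)
  # exact charge round trip
  expect_identical(back[[1]]$structure$total_charge, 1)
  # optional fields stay absent, cell/pbc round-trip
  expect_null(back[[2]]$forces)
  expect_null(back[[2]]$charges)
  expect_equal(back[[2]]$structure$cell, st2$cell, tolerance = 1e-11)
  expect_true(all(back[[2]]$structure$pbc))
  # frame without Lattice key for non-periodic structures
  expect_false(any(grepl("Lattice", readLines(tmp)[2])))
})

test_that("malformed extended-XYZ input is rejected with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "total_charge=0", "H 0 0 0", "H 1 0 0"), tmp)
  expect_error(read_extxyz(tmp), "truncated|expected")
  writeLines(c("2", "total_charge=0", "H 0 0 0", "H 1 0"), tmp)
  expect_error(read_extxyz(tmp), "line 4")
  writeLines(c("2", "total_charge=0", "H 0 0 0", "H 1 0 zz"), tmp)
  expect_error(read_extxyz(tmp), "non-numeric")
  expect_error(read_extxyz(file.path(tempdir(), "nope.xyz")), "not found")
})

test_that("missing total_charge defaults to 0 with a warning", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", 'Properties=species:S:1:pos:R:3', "H 0 0 0"), tmp)
  expect_warning(r <- read_extxyz(tmp), "total_charge")
  expect_identical(r[[1]]$structure$total_charge, 0)
})

test_that("structure invariants are enforced", {
  expect_error(atoms("H", matrix(0, 1, 2)), "n x 3")
  expect_error(atoms(c("H", "H"), matrix(0, 1, 3)), "atom count")
  expect_error(atoms("H", matrix(0, 1, 3), pbc = TRUE), "cell")
  expect_error(atoms("H", matrix(0, 1, 3), cell = matrix(0, 3, 3),
                     pbc = TRUE), "singular")
  expect_error(atoms("H", matrix(0, 1, 3), total_charge = NaN), "finite")
  expect_warning(
    reference_record(atoms("H", matrix(0, 1, 3)), charges = 0.5),
    "deviates")
})

test_that("neighbor lists match direct distance computation", {
  st <- atoms(c("H", "H"), rbind(c(0, 0, 0), c(3, 0, 0)))
  nl <- neighbor_list(st, 4)
  expect_length(nl$i, 1)
  expect_equal(nl$r, 3)
  expect_length(neighbor_list(st, 2.9)$i, 0)
  expect_error(neighbor_list(st, -1), "cutoff")
})

test_that("periodic neighbor lists agree with a brute-force supercell oracle", {
  brute_pairs <- function(st, cutoff, nimg = 5) {
    cnt <- 0
    n <- st$n_atoms
    for (a in -nimg:nimg) for (b in -nimg:nimg) for (cc in -nimg:nimg) {
      L <- c(a, b, cc) %*% st$cell
      for (i in 1:n) for (j in 1:n) {
        d <- sqrt(sum((st$positions[j, ] + L - st$positions[i, ])^2))
        if (d > 1e-12 && d <= cutoff) cnt <- cnt + 1
      }
    }
    cnt / 2   # unordered
  }
  # single atom in a small cubic cell, cutoff beyond the cell
  st1 <- atoms("Na", matrix(0.3, 1, 3), cell = diag(3) * 3, pbc = TRUE)
  expect_equal(length(neighbor_list(st1, 3.5)$i), brute_pairs(st1, 3.5))
  # random structures incl. a triclinic cell
  set.seed(42)
  for (k in 1:5) {
    cell <- diag(3) * runif(1, 3.5, 5) + matrix(runif(9, -0.4, 0.4), 3, 3)
    n <- sample(2:4, 1)
    st <- atoms(rep("Na", n), matrix(runif(3 * n, 0, 3), n, 3),
                cell = cell, pbc = TRUE)
    cutoff <- runif(1, 3, 6)
    nl <- neighbor_list(st, cutoff)
    expect_equal(length(nl$i), brute_pairs(st, cutoff, nimg = 4))
    # distances accurate against direct recomputation from shifts
    d2 <- sqrt(rowSums((st$positions[nl$j, , drop = FALSE] +
                          nl$shift %*% st$cell -
                          st$positions[nl$i, , drop = FALSE])^2))
    expect_lt(max(abs(d2 - nl$r)), 1e-10)
  }
})

test_that("perturb_structure is deterministic Gaussian noise", {
  st <- random_cluster(4, seed = 3)
  expect_identical(perturb_structure(st, 0, seed = 1)$positions, st$positions)
  p1 <- perturb_structure(st, 0.05, seed = 9)
  p2 <- perturb_structure(st, 0.05, seed = 9)
  expect_identical(p1$positions, p2$positions)
  expect_identical(p1$total_charge, st$total_charge)
  expect_error(perturb_structure(st, -0.1), "sigma")
  # law of large numbers: sample sd within 3% of sigma
  big <- atoms(rep("H", 3334), matrix(0, 3334, 3))
  disp <- perturb_structure(big, 0.05, seed = 4)$positions
  expect_lt(abs(sd(as.vector(disp)) - 0.05) / 0.05, 0.03)
})
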