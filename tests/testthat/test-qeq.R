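test_that("qeq matrix elements follow the Gaussian-charge closed forms", {
  el <- element_electro("Na", hardness = 0.2, width = 1.0)
  st <- atoms("Na", matrix(0, 1, 3))
  sys <- qeq_system(st, chi = 0.1, electro = el)
  expect_equal(sys$A[1, 1], 0.2 + 1 / sqrt(pi), tolerance = 1e-14)
  # gamma combination rule
  el2 <- element_electro(c("A1", "B1"), hardness = 0.3, width = c(0.3, 0.4))
  # use two placeholder element names via explicit widths
  st2 <- atoms(c("A1", "B1"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  sys2 <- qeq_system(st2, chi = c(0, 0), electro = el2)
  expect_equal(sys2$gamma[1, 2], 0.5, tolerance = 1e-14)
  expect_equal(sys2$A, t(sys2$A), tolerance = 1e-12)
  # overlapping atoms
  st3 <- atoms(c("A1", "B1"), matrix(0, 2, 3))
  expect_error(qeq_system(st3, c(0, 0), el2), "overlapping|coincident")
})

test_that("pair kernel has the right limits and is monotone", {
  expect_equal(pair_kernel(100, 1), 1 / 100, tolerance = 1e-12)
  # r -> 0 limit against the erf Taylor series
  g <- 0.73
  r <- 1e-9
  series <- sqrt(2 / pi) / g * (1 - r^2 / (6 * g^2))
  expect_equal(pair_kernel(r, g), series, tolerance = 1e-10)
  expect_equal(pair_kernel(0, g), sqrt(2 / pi) / g, tolerance = 1e-12)
  grid <- pair_kernel(10^seq(-3, 3, length.out = 400), g)
  expect_true(all(diff(grid) < 0))
  expect_error(pair_kernel(1, -1), "gamma")
})

test_that("constrained solve reproduces the closed-form dimer", {
  el <- element_electro(c("Na", "Cl"), hardness = c(0.3, 0.45))
  st <- atoms(c("Na", "Cl"), rbind(c(0, 0, 0), c(2.3, 0, 0)),
              total_charge = 0.4)
  chi <- c(-0.1, 0.25)
  sys <- qeq_system(st, chi, el)
  sol <- qeq_solve(sys)
  d1 <- sys$A[1, 1]; d2 <- sys$A[2, 2]; k <- sys$A[1, 2]
  q1 <- ((chi[2] - chi[1]) + 0.4 * (d2 - k)) / (d1 + d2 - 2 * k)
  expect_equal(sol$charges[1], q1, tolerance = 1e-12)
  expect_equal(sum(sol$charges), 0.4, tolerance = 1e-12)
  # stationarity residual
  expect_lt(max(abs(sys$A %*% sol$charges + chi + sol$lagrange)), 1e-10)
  # atom with larger chi gets the more negative charge
  expect_lt(sol$charges[2], sol$charges[1])
  # homonuclear symmetric dimer splits the charge evenly
  sth <- atoms(c("Na", "Na"), rbind(c(0, 0, 0), c(2.3, 0, 0)),
               total_charge = 1)
  solh <- qeq_solve(qeq_system(sth, c(0.1, 0.1), el))
  expect_equal(solh$charges, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("solution minimizes the Qeq energy on the constraint surface", {
  set.seed(31)
  el <- test_electro()
  for (k in 1:5) {
    n <- sample(3:12, 1)
    st <- random_cluster(n, seed = 100 + k, box = 7,
                         total_charge = sample(c(-1, 0, 1), 1))
    chi <- rnorm(n, 0, 0.2)
    sys <- qeq_system(st, chi, el)
    sol <- qeq_solve(sys)
    e0 <- qeq_energy(sys, sol$charges)
    expect_equal(e0, sol$e_qeq, tolerance = 1e-12)
    rand <- replicate(1000, {
      dq <- rnorm(n); dq <- dq - mean(dq)
      qeq_energy(sys, sol$charges + 0.1 * dq / max(abs(dq)))
    })
    expect_true(all(rand >= e0 - 1e-12))
  }
})

test_that("implicit derivatives match finite differences", {
  set.seed(17)
  el <- test_electro()
  st <- random_cluster(8, seed = 55, box = 7, total_charge = 1)
  chi <- rnorm(8, 0, 0.2)
  sys <- qeq_system(st, chi, el)
  sol <- qeq_solve(sys)
  der <- qeq_derivatives(sys, sol, st)
  # chi sensitivities
  fd <- matrix(0, 8, 8)
  for (k in 1:8) {
    cp <- chi; cm <- chi
    cp[k] <- cp[k] + 1e-6; cm[k] <- cm[k] - 1e-6
    fd[, k] <- (qeq_solve(qeq_system(st, cp, el))$charges -
                  qeq_solve(qeq_system(st, cm, el))$charges) / 2e-6
  }
  expect_lt(max(abs(fd - der$dq_dchi)), 1e-6)
  # gauge invariance: uniform chi shift leaves charges unchanged
  expect_lt(max(abs(rowSums(der$dq_dchi))), 1e-12)
  # hardness sensitivity (element-wise)
  eps <- 1e-6
  Jp <- el; Jp$J[["Na"]] <- Jp$J[["Na"]] + eps
  Jm <- el; Jm$J[["Na"]] <- Jm$J[["Na"]] - eps
  fdJ <- (qeq_solve(qeq_system(st, chi, Jp))$charges -
            qeq_solve(qeq_system(st, chi, Jm))$charges) / (2 * eps)
  expect_lt(max(abs(fdJ - der$dq_dJ[, "Na"])), 1e-6)
  # position sensitivities (relative to charge scale ~1)
  ba <- units_au$bohr_ang
  h <- 1e-5
  worst <- 0
  for (k in c(1, 4, 8)) {
    for (a in 1:3) {
      sp <- st; sm <- st
      sp$positions[k, a] <- sp$positions[k, a] + h * ba
      sm$positions[k, a] <- sm$positions[k, a] - h * ba
      fdv <- (qeq_solve(qeq_system(sp, chi, el))$charges -
                qeq_solve(qeq_system(sm, chi, el))$charges) / (2 * h)
      worst <- max(worst, max(abs(fdv - der$dq_dR[, k, a])))
    }
  }
  expect_lt(worst, 1e-6)
  # rigid translation leaves charges unchanged
  expect_lt(max(abs(apply(der$dq_dR, c(1, 3), sum))), 1e-12)
})

test_that("charge conservation holds to 1e-10 for every solve", {
  set.seed(77)
  el <- test_electro()
  for (k in 1:50) {
    n <- sample(2:10, 1)
    qt <- runif(1, -2, 2)
    st <- random_cluster(n, seed = 500 + k, total_charge = qt)
    sol <- qeq_solve(qeq_system(st, rnorm(n, 0, 0.3), el))
    expect_lt(abs(sum(sol$charges) - qt), 1e-10)
  }
})

test_that("pathological parameters are rejected with advice", {
  # construct an exactly singular constrained system: for a homonuclear
  # dimer the curvature on the constraint surface is 2 (d - k) with
  # d = J + 1/(sigma sqrt(pi)) and k the pair kernel; pick J so d = k
  sigma <- covalent_radius("Na", "bohr")
  r_bohr <- 2.0 / units_au$bohr_ang
  k <- pair_kernel(r_bohr, sqrt(2) * sigma)
  Jcrit <- k - 1 / (sigma * sqrt(pi))
  el <- element_electro("Na", hardness = Jcrit)
  st <- atoms(c("Na", "Na"), rbind(c(0, 0, 0), c(2.0, 0, 0)))
  sys <- qeq_system(st, c(0.1, -0.1), el)
  expect_error(qeq_solve(sys), "ill-conditioned|singular")
})
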