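test_that("model assembly enforces the generation contracts", {
  m2 <- test_model("2G")
  expect_null(m2$electro)
  expect_null(m2$charge_nets$Na)
  expect_error(predict_charges(m2, random_cluster(3, seed = 1)),
               "no charges in 2G")
  m4 <- test_model("4G")
  nd <- acsf_count(m4$acsf, "Na")
  expect_equal(m4$energy_nets$Na$sizes[1], nd + 1)   # charge input
  expect_equal(m4$charge_nets$Na$sizes[1], nd)
  m3 <- test_model("3G")
  expect_equal(m3$energy_nets$Na$sizes[1], nd)
  ac <- acsf_params("Na", cutoff = 8)
  expect_error(potential_model("4G", ac), "electro")
  expect_error(total_energy(m4, atoms("O", matrix(0, 1, 3))), "O")
})

test_that("4G charges conserve the total charge and see the charge state", {
  m4 <- test_model("4G")
  st <- random_cluster(6, seed = 9, total_charge = 1)
  q1 <- predict_charges(m4, st)
  expect_lt(abs(sum(q1) - 1), 1e-10)
  st2 <- st; st2$total_charge <- -1
  q2 <- predict_charges(m4, st2)
  expect_lt(abs(sum(q2) + 1), 1e-10)
  expect_gt(sqrt(sum((q1 - q2)^2)), 0.1)
  # 3G unscaled: identical local environments force identical charges
  m3 <- test_model("3G")
  m3$charge_mode <- "unscaled"
  expect_identical(predict_charges(m3, st), predict_charges(m3, st2))
  # 3G scaled obeys the uniform-correction formula
  m3s <- test_model("3G")
  qs <- predict_charges(m3s, st)
  qu <- predict_charges(m3, st)
  expect_equal(qs, qu + (1 - sum(qu)) / 6, tolerance = 1e-12)
  expect_lt(abs(sum(qs) - 1), 1e-12)
})

test_that("energy decomposition and invariances hold", {
  m4 <- test_model("4G")
  st <- random_cluster(5, seed = 12, total_charge = 1)
  # zeroed energy nets: total energy reduces to the electrostatic part
  mz <- m4
  for (el in names(mz$energy_nets)) {
    th <- net_flatten(mz$energy_nets[[el]])
    mz$energy_nets[[el]] <- net_unflatten(mz$energy_nets[[el]], th * 0)
  }
  te <- total_energy(mz, st)
  expect_equal(te$energy, te$e_elec, tolerance = 1e-14)
  # 2G is blind to the total charge
  m2 <- test_model("2G")
  st_p <- st; st_p$total_charge <- 1
  st_m <- st; st_m$total_charge <- -1
  expect_identical(total_energy(m2, st_p)$energy,
                   total_energy(m2, st_m)$energy)
  expect_false(isTRUE(all.equal(total_energy(m4, st_p)$energy,
                                total_energy(m4, st_m)$energy)))
  # rigid rotation + translation leave every generation invariant
  qr_ <- qr(matrix(c(0.3, -1, 0.2, 0.8, 0.1, -0.5, 0.4, 0.9, 1), 3, 3))
  R <- qr.Q(qr_) * sign(det(qr.Q(qr_)))
  for (m in list(m2, test_model("3G"), m4)) {
    str_ <- st
    str_$positions <- st$positions %*% R + 2.5
    expect_lt(abs(total_energy(m, str_)$energy -
                    total_energy(m, st)$energy), 1e-10)
  }
})

test_that("analytic forces match finite differences for all generations", {
  st <- random_cluster(5, seed = 23, total_charge = 1)
  stp <- random_cluster(5, seed = 24, box = 5, cell = diag(3) * 7,
                        pbc = TRUE, total_charge = 0)
  for (gen in c("2G", "3G", "4G")) {
    m <- test_model(gen)
    expect_lt(force_fd_dev(m, st), 1e-6)
    expect_lt(force_fd_dev(m, stp), 1e-6)
    f <- forces(m, st)
    expect_lt(max(abs(colSums(f))), 1e-9)   # translational sum rule
  }
})

test_that("dropping the dE_short/dQ chain breaks force consistency", {
  m4 <- test_model("4G")
  st <- random_cluster(6, seed = 31, total_charge = 1)
  f_full <- forces(m4, st)
  f_drop <- forces(m4, st, drop_charge_force_terms = TRUE)
  expect_gt(max(abs(f_full - f_drop)), 1e-6)
})

test_that("energy is continuous across descriptor and screening cutoffs", {
  m4 <- test_model("4G")
  rc <- m4$acsf$cutoff
  mk <- function(r) atoms(c("Na", "Cl", "Na"),
                          rbind(c(0, 0, 0), c(2.3, 0, 0), c(r, 0, 0)),
                          total_charge = 1)
  for (r0 in c(rc, m4$screening$outer)) {
    eps <- 5e-7   # Angstrom straddle around the crossing
    e1 <- total_energy(m4, mk(r0 - eps))$energy
    e2 <- total_energy(m4, mk(r0 + eps))$energy
    # remove the smooth first-order variation (analytic force at the
    # crossing): what remains bounds any genuine discontinuity
    f_mid <- forces(m4, mk(r0))[3, 1] / units_au$bohr_ang  # Ha/Angstrom
    expect_lt(abs(e2 - e1 + f_mid * 2 * eps), 1e-8)
  }
})

test_that("geometry optimization descends and respects its contracts", {
  skip_if_not_installed("withr")
  # synthetic-truth-driven 2G dimer model: train briefly on Morse data so
  # the model PES has a well-defined minimum
  truth <- default_truth("Ag")
  # stiffen the dimer well: the 1e-4 Ha/Bohr force threshold localizes a
  # minimum to fmax/k, so k must exceed ~1 Ha/Bohr^2 for a 1e-4 Bohr match
  truth$morse[["Ag-Ag"]] <- list(D = 0.4, a = 2.8, r0 = 2.9)
  set.seed(4)
  base <- atoms(c("Ag", "Ag"), rbind(c(0, 0, 0), c(2.9, 0, 0)))
  recs <- lapply(seq_len(120), function(k) {
    st <- base
    st$positions[2, 1] <- runif(1, 2.3, 3.6)
    label_structure(truth, st)
  })
  m <- test_model("2G", elements = "Ag")
  fit <- fit_short_range_stage(m, recs,
                               train_config(epochs = 250, w_E = 1, w_F = 10,
                                            seed = 1))
  m <- fit$model
  st0 <- base; st0$positions[2, 1] <- 3.1
  res <- geometry_optimize(m, st0, fmax = 1e-4, max_steps = 500)
  expect_true(res$converged)
  # energies along accepted steps are non-increasing
  expect_true(all(diff(res$energies) <= 1e-12))
  # golden-section oracle on the same model PES
  ecurve <- function(d) {
    s <- base; s$positions[2, 1] <- d
    total_energy(m, s)$energy
  }
  gold <- optimize(ecurve, c(2.3, 3.6), tol = 1e-9)
  d_opt <- res$structure$positions[2, 1] - res$structure$positions[1, 1]
  expect_lt(abs(d_opt - gold$minimum) / units_au$bohr_ang, 1e-4)  # Bohr
  # restarting from the converged minimum takes zero steps
  res2 <- geometry_optimize(m, res$structure, fmax = 1e-4)
  expect_equal(res2$steps, 0)
  # non-convergence is flagged, not thrown
  res3 <- geometry_optimize(m, st0, fmax = 1e-12, max_steps = 3)
  expect_false(res3$converged)
  expect_error(geometry_optimize(m, st0, fmax = -1), "fmax")
})
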