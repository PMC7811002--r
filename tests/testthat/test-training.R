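test_that("dataset splitting is deterministic, disjoint and stratified", {
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 5, seed = 1), truth,
                            forces = FALSE)
  sp <- split_dataset(recs, 0.9, seed = 3)
  expect_length(sp$train, 9)
  expect_length(sp$test, 1)
  sp2 <- split_dataset(recs, 0.9, seed = 3)
  expect_identical(sp, sp2)
  # disjoint + exhaustive
  key <- function(r) paste(r$structure$info$population,
                           paste(r$structure$positions, collapse = ","),
                           r$structure$total_charge)
  all_keys <- vapply(recs, key, "")
  got <- c(vapply(sp$train, key, ""), vapply(sp$test, key, ""))
  expect_setequal(got, all_keys)
  # stratification: both populations in the train split
  sp3 <- split_dataset(recs, 0.8, seed = 1)
  pops <- vapply(sp3$train, function(r) r$structure$info$population, "")
  expect_setequal(unique(pops), c("cation", "anion"))
  expect_error(split_dataset(recs[1], 0.9), "at least 2")
  expect_error(split_dataset(recs, 1.2), "fraction")
})

test_that("evaluate_model computes the advertised metrics", {
  m <- test_model("4G")
  st <- random_cluster(4, seed = 41, total_charge = 1)
  ev <- hdnnp:::.eval_potential(m, st, need_forces = TRUE)
  self <- reference_record(st, energy = ev$energy, forces = ev$forces,
                           charges = ev$charges)
  met <- evaluate_model(m, list(self))
  expect_lt(met$energy_rmse, 1e-9)
  expect_lt(met$force_rmse, 1e-9)
  expect_lt(met$charge_rmse, 1e-9)
  # hand-computed two-record metric
  r1 <- reference_record(st, energy = ev$energy + 4 * 0.001,
                         forces = ev$forces, charges = ev$charges)
  r2 <- reference_record(st, energy = ev$energy - 4 * 0.003,
                         forces = ev$forces, charges = ev$charges)
  met2 <- evaluate_model(m, list(r1, r2))
  expected_rmse <- sqrt(mean(c(0.001, 0.003)^2)) * units_au$hartree_ev * 1000
  expected_mae <- mean(c(0.001, 0.003)) * units_au$hartree_ev * 1000
  expect_equal(met2$energy_rmse, expected_rmse, tolerance = 1e-12)
  expect_equal(met2$energy_mae, expected_mae, tolerance = 1e-12)
  # homogeneity: doubling every force error doubles the force RMSE
  r3 <- reference_record(st, energy = ev$energy,
                         forces = ev$forces + 0.01, charges = ev$charges)
  r4 <- reference_record(st, energy = ev$energy,
                         forces = ev$forces + 0.02, charges = ev$charges)
  expect_equal(2 * evaluate_model(m, list(r3))$force_rmse,
               evaluate_model(m, list(r4))$force_rmse, tolerance = 1e-9)
  expect_error(evaluate_model(m, list()), "empty")
})

test_that("zero-epoch charge fit reports initial metrics, model unchanged", {
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 6, seed = 2), truth,
                            forces = FALSE)
  m <- test_model("4G", elements = "Ag")
  before <- net_flatten(m$charge_nets$Ag)
  fit <- fit_charge_stage(m, recs, train_config(epochs = 0, seed = 1))
  expect_identical(net_flatten(fit$model$charge_nets$Ag), before)
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_charge_rmse))
  expect_error(fit_charge_stage(test_model("2G"), recs), "2G")
})

test_that("stage 2 reduces the loss and never touches the charge model", {
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 30, seed = 8), truth)
  m <- test_model("4G", elements = "Ag")
  s1 <- fit_charge_stage(m, recs, train_config(epochs = 60, seed = 1))
  m <- s1$model
  chk_net <- net_flatten(m$charge_nets$Ag)
  chk_J <- m$electro$J
  s2 <- fit_short_range_stage(m, recs,
                              train_config(epochs = 150, seed = 1))
  expect_identical(net_flatten(s2$model$charge_nets$Ag), chk_net)
  expect_identical(s2$model$electro$J, chk_J)
  h <- s2$history
  expect_lt(h$train_energy_rmse[nrow(h)], h$train_energy_rmse[1])
  # w_F = 0: pure energy fitting still reduces the energy error
  s3 <- fit_short_range_stage(m, recs,
                              train_config(epochs = 80, w_F = 0, seed = 1))
  h3 <- s3$history
  expect_lt(h3$train_energy_rmse[nrow(h3)], h3$train_energy_rmse[1])
  expect_true(all(is.na(h3$train_force_rmse)))
})

test_that("training is bit-for-bit deterministic for a fixed config", {
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 15, seed = 4), truth)
  run <- function() {
    m <- test_model("4G", elements = "Ag", seed = 7)
    cfg <- train_config(epochs = 40, seed = 9)
    m <- fit_charge_stage(m, recs, cfg)$model
    m <- fit_short_range_stage(m, recs, cfg)$model
    c(net_flatten(m$charge_nets$Ag), net_flatten(m$energy_nets$Ag),
      unname(m$electro$J), unname(m$e_shift))
  }
  expect_identical(run(), run())
})

test_that("4G resolves what a direct local charge fit cannot", {
  # identical environments, two total charges: the direct (3G-style) fit
  # is bounded below by half the inter-population charge gap, while the
  # Qeq-based 4G fit distributes the total charge and fits both states
  truth <- default_truth("Ag")
  recs <- generate_scenario(scenario("trimer_ions", n = 25, sigma = 0,
                                     seed = 6), truth, forces = FALSE)
  qgap <- abs(recs[[1]]$charges[1] - recs[[2]]$charges[1])
  m4 <- test_model("4G", elements = "Ag")
  f4 <- fit_charge_stage(m4, recs, train_config(epochs = 150, seed = 1))
  rmse4 <- utils::tail(f4$history$train_charge_rmse, 1)
  expect_lt(rmse4, 1e-3)
  m3 <- test_model("3G", elements = "Ag")
  f3 <- fit_charge_stage(m3, recs, train_config(epochs = 150, seed = 1))
  rmse3 <- utils::tail(f3$history$train_charge_rmse, 1)
  expect_gt(rmse3, 0.999 * qgap / 2)
})
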