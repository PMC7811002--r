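# Shared fixtures: everything is generated in code at test time.

# random non-overlapping cluster of n atoms drawn from `elements`
random_cluster <- function(n, elements = c("Na", "Cl"), box = 6,
                           min_dist = 1.8, total_charge = 0, seed = NULL,
                           cell = NULL, pbc = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    pos <- matrix(stats::runif(3 * n, 0.2, box), n, 3)
    if (n == 1 || min(stats::dist(pos)) >= min_dist) break
  }
  atoms(sample(elements, n, replace = TRUE), pos, cell = cell, pbc = pbc,
        total_charge = total_charge)
}

# standard two-element test electro table
test_electro <- function(elements = c("Na", "Cl")) {
  element_electro(elements, hardness = c(0.4, 0.5, 0.45)[seq_along(elements)])
}

# small model factory shared across test files
test_model <- function(generation, elements = c("Na", "Cl"), seed = 5,
                       screening = TRUE, n_radial = 3) {
  ac <- acsf_params(elements, cutoff = 8, n_radial = n_radial)
  potential_model(generation, ac, electro = test_electro(elements),
                  screening = if (screening) screening_spec(1.3, ac$cutoff)
                              else NULL,
                  seed = seed)
}

# max deviation between analytic forces and central finite differences
force_fd_dev <- function(model, st, h = 1e-4) {
  ba <- units_au$bohr_ang
  f <- forces(model, st)
  maxd <- 0
  for (k in seq_len(st$n_atoms)) {
    for (a in 1:3) {
      sp <- st; sm <- st
      sp$positions[k, a] <- sp$positions[k, a] + h * ba
      sm$positions[k, a] <- sm$positions[k, a] - h * ba
      fd <- -(total_energy(model, sp)$energy -
                total_energy(model, sm)$energy) / (2 * h)
      maxd <- max(maxd, abs(fd - f[k, a]))
    }
  }
  maxd
}

# lazily computed shared training results for the acceptance tests
.acc_cache <- new.env(parent = emptyenv())

acc_get <- function(key, fn) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- fn()
  .acc_cache[[key]]
}
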