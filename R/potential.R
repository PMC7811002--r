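#' Construct a neural network potential model
#'
#' Assembles a 2G/3G/4G high-dimensional neural network potential:
#' \itemize{
#' \item 2G: total energy is a sum of environment-local atomic energies.
#' \item 3G: adds electrostatics from environment-local charges predicted
#'   by a second set of atomic networks (optionally rescaled uniformly so
#'   the total charge is exact).
#' \item 4G: the second networks predict atomic electronegativities; a
#'   constrained charge equilibration distributes the total charge
#'   globally, the resulting charges enter both the electrostatic energy
#'   and (as one extra input) the short-range atomic networks.
#' }
#'
#' @param generation `"2G"`, `"3G"` or `"4G"`.
#' @param acsf an [acsf_params()] object.
#' @param electro an [element_electro()] (required for 3G/4G).
#' @param screening a [screening_spec()] or `NULL` (applies to the
#'   electrostatic energy partition only, never to the Qeq matrix).
#' @param hidden hidden-layer widths of all atomic networks.
#' @param seed RNG seed for weight initialization.
#' @param charge_mode for 3G: `"scaled"` (uniform correction enforcing the
#'   total charge) or `"unscaled"`.
#' @param accuracy Ewald accuracy target for periodic systems (Ha).
#' @return object of class `"potential_model"`.
#' @export
potential_model <- function(generation = c("4G", "3G", "2G"), acsf,
                            electro = NULL, screening = NULL,
                            hidden = c(15, 15), seed = 1,
                            charge_mode = c("scaled", "unscaled"),
                            accuracy = 1e-6) {
  generation <- match.arg(toupper(generation), c("4G", "3G", "2G"))
  charge_mode <- match.arg(charge_mode)
  stopifnot(inherits(acsf, "acsf_params"))
  elements <- acsf$elements
  if (generation != "2G") {
    if (is.null(electro)) stop(generation, " model requires electro parameters")
    missing_el <- setdiff(elements, electro$elements)
    if (length(missing_el)) stop("electro lacks element(s): ",
                                 paste(missing_el, collapse = ", "))
  } else {
    electro <- NULL
    screening <- NULL
  }
  energy_nets <- list(); charge_nets <- list()
  for (i in seq_along(elements)) {
    el <- elements[i]
    nd <- acsf_count(acsf, el)
    extra <- if (generation == "4G") 1L else 0L
    energy_nets[[el]] <- init_network(nd + extra, hidden, seed = seed + 101 * i)
    if (generation != "2G") {
      charge_nets[[el]] <- init_network(nd, hidden, seed = seed + 101 * i + 50)
    }
  }
  base::structure(
    list(generation = generation, acsf = acsf, electro = electro,
         screening = screening, energy_nets = energy_nets,
         charge_nets = charge_nets, charge_mode = charge_mode,
         e_shift = stats::setNames(rep(0, length(elements)), elements),
         accuracy = accuracy),
    class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<%s-HDNNP: elements %s, %d descriptors/element, cutoff %.3f A%s>\n",
              x$generation, paste(x$acsf$elements, collapse = " "),
              acsf_count(x$acsf, x$acsf$elements[1]), x$acsf$cutoff,
              if (is.null(x$screening)) ""
              else sprintf(", screening %.2f-%.2f A", x$screening$inner,
                           x$screening$outer)))
  invisible(x)
}

# stack per-atom descriptor vectors into per-element matrices
.element_groups <- function(species, elements) {
  lapply(stats::setNames(elements, elements), function(el)
    which(species == el))
}

# Core evaluator: energy, charges, electrostatic energy and (optionally)
# analytic forces for any generation.  `drop_charge_force_terms` is a
# diagnostic switch that discards the dE_short/dQ force contributions of a
# 4G model (used by tests guarding the chain rule, never in production).
.eval_potential <- function(model, structure, need_forces = TRUE,
                            drop_charge_force_terms = FALSE) {
  gen <- model$generation
  n <- structure$n_atoms
  spec <- structure$species
  unknown <- setdiff(unique(spec), model$acsf$elements)
  if (length(unknown)) stop("element(s) unknown to the model: ",
                            paste(unknown, collapse = ", "))
  ds <- acsf_compute(structure, model$acsf, gradients = need_forces)
  groups <- .element_groups(spec, model$acsf$elements)
  ba <- units_au$bohr_ang

  charges <- NULL; e_elec <- NULL
  chi <- NULL; dchi_dG <- vector("list", n)
  dq_raw_dG <- vector("list", n)
  cache <- NULL; sysq <- NULL; solq <- NULL

  if (gen != "2G") {
    cache <- .electro_cache(structure, model$electro,
                            screening = model$screening,
                            accuracy = model$accuracy,
                            derivatives = need_forces)
  }
  if (gen == "4G") {
    chi <- numeric(n)
    for (el in names(groups)) {
      idx <- groups[[el]]
      if (!length(idx)) next
      X <- do.call(rbind, ds$values[idx])
      fw <- .net_fwd(model$charge_nets[[el]], X)
      chi[idx] <- fw$y
      if (need_forces) {
        Gx <- .net_gradx(model$charge_nets[[el]], X, fw)$G
        for (u in seq_along(idx)) dchi_dG[[idx[u]]] <- Gx[u, ]
      }
    }
    sysq <- qeq_system(structure, chi, model$electro,
                       accuracy = model$accuracy, cache = cache)
    solq <- qeq_solve(sysq)
    charges <- solq$charges
    e_elec <- 0.5 * drop(charges %*% cache$Phi_s %*% charges)
  } else if (gen == "3G") {
    qraw <- numeric(n)
    for (el in names(groups)) {
      idx <- groups[[el]]
      if (!length(idx)) next
      X <- do.call(rbind, ds$values[idx])
      fw <- .net_fwd(model$charge_nets[[el]], X)
      qraw[idx] <- fw$y
      if (need_forces) {
        Gx <- .net_gradx(model$charge_nets[[el]], X, fw)$G
        for (u in seq_along(idx)) dq_raw_dG[[idx[u]]] <- Gx[u, ]
      }
    }
    charges <- if (model$charge_mode == "scaled")
      qraw + (structure$total_charge - sum(qraw)) / n else qraw
    if (any(structure$pbc) && abs(sum(charges)) > 1e-6) {
      stop("periodic 3G electrostatics requires (re)scaled neutral charges")
    }
    e_elec <- 0.5 * drop(charges %*% cache$Phi_s %*% charges)
  }

  # short-range energy and per-atom input gradients
  e_short <- 0
  dE_dG <- vector("list", n)   # gradient w.r.t. descriptor part
  dEs_dQ <- numeric(n)         # 4G: gradient w.r.t. the charge input
  for (el in names(groups)) {
    idx <- groups[[el]]
    if (!length(idx)) next
    X <- do.call(rbind, ds$values[idx])
    if (gen == "4G") X <- cbind(X, charges[idx])
    fw <- .net_fwd(model$energy_nets[[el]], X)
    e_short <- e_short + sum(fw$y) + length(idx) * model$e_shift[[el]]
    if (need_forces) {
      Gx <- .net_gradx(model$energy_nets[[el]], X, fw)$G
      nd <- ncol(X) - if (gen == "4G") 1L else 0L
      for (u in seq_along(idx)) {
        dE_dG[[idx[u]]] <- Gx[u, seq_len(nd)]
        if (gen == "4G") dEs_dQ[idx[u]] <- Gx[u, nd + 1L]
      }
    }
  }
  energy <- e_short + if (is.null(e_elec)) 0 else e_elec

  out <- list(energy = energy, charges = charges, e_elec = e_elec,
              e_short = e_short, chi = chi, forces = NULL)
  if (!need_forces) return(out)

  ## ------------------------------------------------------------------ forces
  dE_dR <- matrix(0, n, 3)  # Ha/Bohr

  # electrostatic direct term at fixed charges: 0.5 q' Phi_s q
  if (gen != "2G") {
    for (a in 1:3) {
      dE_dR[, a] <- dE_dR[, a] + charges * (cache$dPhi_s[, , a] %*% charges)
    }
  }

  # effective descriptor weights: start with the short-range part
  w <- dE_dG

  if (gen == "4G") {
    # total dE/dQ, then adjoint through the augmented Qeq system
    b <- drop(cache$Phi_s %*% charges)
    if (!drop_charge_force_terms) b <- b + dEs_dQ
    p <- drop(solq$Kinv[seq_len(n), seq_len(n)] %*% b)
    # dA/dR contraction: + sum_j dPhi[k,j,a] (p_k q_j + p_j q_k), with a
    # minus from the implicit solve
    for (a in 1:3) {
      dE_dR[, a] <- dE_dR[, a] -
        (p * (cache$dPhi[, , a] %*% charges) +
           charges * (cache$dPhi[, , a] %*% p))
    }
    # chi path: -p_i folds into the descriptor chain of the charge nets
    for (i in seq_len(n)) {
      w[[i]] <- w[[i]] - p[i] * dchi_dG[[i]]
    }
  } else if (gen == "3G") {
    b <- drop(cache$Phi_s %*% charges)          # dE/dQ_i
    beff <- if (model$charge_mode == "scaled") b - mean(b) else b
    for (i in seq_len(n)) {
      w[[i]] <- w[[i]] + beff[i] * dq_raw_dG[[i]]
    }
  }

  # descriptor chain rule (gradients are Angstrom^-1; convert to Bohr^-1)
  for (i in seq_len(n)) {
    gl <- ds$gradients[[i]]
    if (!length(gl)) next
    wi <- w[[i]]
    for (key in names(gl)) {
      k <- as.integer(key)
      dE_dR[k, ] <- dE_dR[k, ] + drop(wi %*% gl[[key]]) * ba
    }
  }

  out$forces <- -dE_dR
  out
}

#' Predict atomic charges
#'
#' 4G: electronegativities from the charge networks feed the constrained
#' charge equilibration; the result sums exactly to the total charge and
#' depends on the global composition and charge state.  3G: charges come
#' directly from local networks (`"scaled"` adds the uniform correction
#' `(Q_tot - sum Q_j) / N`); identical local environments then force
#' identical charges regardless of the global state.
#'
#' @param model a [potential_model()].
#' @param structure an [atoms()] object.
#' @return numeric vector of per-atom charges (e).
#' @export
predict_charges <- function(model, structure) {
  if (model$generation == "2G") stop("no charges in 2G")
  .eval_potential(model, structure, need_forces = FALSE)$charges
}

#' Total energy of a structure
#'
#' `E_total = E_elec + E_short` (3G/4G) or the plain sum of atomic
#' energies (2G).  The screened electrostatic energy uses the model's
#' screening switch; short-range atomic networks of a 4G model receive
#' the equilibrated charge as an extra input.
#'
#' @inheritParams predict_charges
#' @return list with `energy` (Ha), `charges` (e, or `NULL` for 2G) and
#'   `e_elec` (Ha, or `NULL` for 2G).
#' @export
total_energy <- function(model, structure) {
  r <- .eval_potential(model, structure, need_forces = FALSE)
  list(energy = r$energy, charges = r$charges, e_elec = r$e_elec)
}

#' Analytic atomic forces
#'
#' `F = -dE_total/dR` assembled analytically: descriptor chain rule for
#' all generations; for 3G additionally the charge-network chain; for 4G
#' the full charge-transfer path
#' `(dE_short/dQ + dE_elec/dQ) dQ/dR` obtained by one adjoint solve of
#' the augmented charge-equilibration system.
#'
#' @inheritParams predict_charges
#' @param drop_charge_force_terms diagnostic switch (tests only): discard
#'   the `dE_short/dQ` contribution of a 4G model.
#' @return `n x 3` matrix of forces (Ha/Bohr).
#' @export
forces <- function(model, structure, drop_charge_force_terms = FALSE) {
  .eval_potential(model, structure, need_forces = TRUE,
                  drop_charge_force_terms = drop_charge_force_terms)$forces
}

#' Gradient-descent geometry optimization
#'
#' Steepest descent with backtracking step control: the trial displacement
#' moves every (mobile) atom along the force with maximum displacement
#' equal to the current step; the step halves when the energy would
#' increase and grows by 1.1 on success.  Converged when the largest
#' (mobile-atom) force component magnitude drops to `fmax`.
#' Non-convergence is flagged on the result, not raised.
#'
#' @param model a [potential_model()] or a [default_truth()] ground
#'   truth (the latter lets tests optimize on the exact surrogate surface).
#' @param structure an [atoms()] object.
#' @param fmax force threshold (Ha/Bohr), default `1e-4`.
#' @param max_steps maximum accepted steps.
#' @param mobile integer indices of atoms allowed to move (`NULL` = all);
#'   mirrors fixed-substrate relaxations.
#' @param step0 initial maximum displacement (Bohr).
#' @return list with `structure` (optimized), `energies` (per accepted
#'   step, Ha, starting energy first), `converged`, `steps`.
#' @export
geometry_optimize <- function(model, structure, fmax = 1e-4,
                              max_steps = 1000L, mobile = NULL,
                              step0 = 1e-2) {
  if (fmax <= 0) stop("fmax must be > 0")
  if (is.null(mobile)) mobile <- seq_len(structure$n_atoms)
  ba <- units_au$bohr_ang
  evaluator <- if (inherits(model, "ground_truth")) {
    function(st) {
      lab <- label_structure(model, st, forces = TRUE)
      list(energy = lab$energy, forces = lab$forces)
    }
  } else {
    function(st) .eval_potential(model, st, need_forces = TRUE)
  }
  cur <- structure
  ev <- evaluator(cur)
  energies <- ev$energy
  step <- step0
  accepted <- 0L
  repeat {
    f <- ev$forces
    f[setdiff(seq_len(structure$n_atoms), mobile), ] <- 0
    fmx <- max(abs(f))
    if (fmx <= fmax) {
      return(list(structure = cur, energies = energies, converged = TRUE,
                  steps = accepted))
    }
    if (accepted >= max_steps) break
    moved <- FALSE
    while (step > 1e-12) {
      trial <- cur
      trial$positions <- cur$positions + (step / fmx) * f * ba
      evt <- evaluator(trial)
      if (evt$energy <= ev$energy) {
        cur <- trial; ev <- evt
        energies <- c(energies, ev$energy)
        accepted <- accepted + 1L
        step <- step * 1.1
        moved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!moved) break
  }
  list(structure = cur, energies = energies, converged = FALSE,
       steps = accepted)
}
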