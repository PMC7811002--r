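#' Build a charge-equilibration system
#'
#' Assembles the symmetric interaction matrix `A` with diagonal
#' `J_i + 1/(sigma_i sqrt(pi))` and off-diagonal
#' `erf(r_ij / (sqrt(2) gamma_ij)) / r_ij`,
#' `gamma_ij = sqrt(sigma_i^2 + sigma_j^2)` (lattice-summed for periodic
#' neutral cells).  Screening never enters `A`: the equilibrated charges
#' must stay smooth in the geometry and match the reference-charge
#' training convention.
#'
#' @param structure an [atoms()] object.
#' @param chi per-atom electronegativities (Ha/e).
#' @param electro an [element_electro()] object.
#' @param accuracy Ewald accuracy target (periodic case).
#' @param cache optional precomputed `.electro_cache` result (internal reuse).
#' @return object of class `"qeq_system"`: `A`, `chi`, `q_total`, `gamma`,
#'   `n`, plus the electrostatic cache.
#' @export
qeq_system <- function(structure, chi, electro, accuracy = 1e-6,
                       cache = NULL) {
  n <- structure$n_atoms
  if (length(chi) != n) stop("chi must have one entry per atom")
  if (any(structure$pbc) && abs(structure$total_charge) > 1e-6) {
    stop("charged periodic cells are not supported")
  }
  if (is.null(cache)) {
    cache <- .electro_cache(structure, electro, screening = NULL,
                            accuracy = accuracy, derivatives = FALSE)
  }
  J <- unname(electro$J[structure$species])
  A <- cache$Phi + diag(J, n)
  gam <- sqrt(outer(cache$sigma^2, cache$sigma^2, "+"))
  base::structure(
    list(A = A, chi = as.numeric(chi), q_total = structure$total_charge,
         gamma = gam, n = n, J = J, sigma = cache$sigma, cache = cache,
         species = structure$species),
    class = "qeq_system")
}

#' Solve the constrained charge equilibration
#'
#' Minimizes
#' \eqn{E_{Qeq} = E_{elec} + \sum_i (\chi_i Q_i + J_i Q_i^2 / 2)}
#' subject to \eqn{\sum_i Q_i = Q_{tot}} by solving the augmented
#' saddle-point system
#' \deqn{\begin{pmatrix} A & 1 \\ 1^T & 0\end{pmatrix}
#'       \begin{pmatrix} Q \\ \lambda \end{pmatrix} =
#'       \begin{pmatrix} -\chi \\ Q_{tot} \end{pmatrix}}
#' with one dense solve.  The inverse of the augmented matrix is retained
#' so derivative solves ([qeq_derivatives()]) reuse it.
#'
#' @param system a [qeq_system()] object.
#' @return object of class `"qeq_solution"`: `charges`, `lagrange`,
#'   `e_elec` (unscreened electrostatic energy, Ha), `e_qeq` (the
#'   minimized objective), and `Kinv`.
#' @export
qeq_solve <- function(system) {
  stopifnot(inherits(system, "qeq_system"))
  n <- system$n
  K <- rbind(cbind(system$A, rep(1, n)), c(rep(1, n), 0))
  rc <- rcond(K)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("augmented Qeq matrix is singular or ill-conditioned ",
         "(condition estimate > 1e12); review hardness/width parameters")
  }
  Kinv <- solve(K)
  sol <- Kinv %*% c(-system$chi, system$q_total)
  q <- sol[seq_len(n)]
  lambda <- sol[n + 1]
  e_elec <- 0.5 * drop(q %*% system$cache$Phi %*% q)
  e_qeq <- e_elec + sum(system$chi * q + 0.5 * system$J * q^2)
  base::structure(
    list(charges = q, lagrange = lambda, e_elec = e_elec, e_qeq = e_qeq,
         Kinv = Kinv),
    class = "qeq_solution")
}

#' Qeq objective at arbitrary charges
#'
#' Evaluates \eqn{E_{Qeq}(Q)} for a given charge vector (used by the
#' minimization-property tests).
#'
#' @param system a [qeq_system()] object.
#' @param charges charge vector.
#' @return energy (Ha).
#' @export
qeq_energy <- function(system, charges) {
  0.5 * drop(charges %*% system$A %*% charges) + sum(system$chi * charges)
}

#' Derivatives of the equilibrated charges
#'
#' Implicit differentiation of the augmented linear system: one extra
#' solve per right-hand side, reusing the stored inverse; no finite
#' differences.  `dq_dchi` is the full `N x N` sensitivity (rows sum to
#' zero: a uniform electronegativity shift leaves the charges unchanged),
#' `dq_dJ` holds one column per element, and `dq_dR` is `N x N x 3` with
#' `[i, k, ]` the derivative of `Q_i` with respect to the position of atom
#' `k` in Bohr^-1, at fixed electronegativities.
#'
#' @param system a [qeq_system()] object.
#' @param solution the matching [qeq_solve()] result.
#' @param structure the [atoms()] object the system was built from.
#' @return list with `dq_dchi`, `dq_dJ`, `dq_dR`.
#' @export
qeq_derivatives <- function(system, solution, structure) {
  stopifnot(inherits(solution, "qeq_solution"))
  if (is.null(solution$Kinv)) stop("solution carries no factorization")
  n <- system$n
  Kqq <- solution$Kinv[seq_len(n), seq_len(n), drop = FALSE]
  q <- solution$charges
  # d(A q + chi + lambda 1) = 0 and sum dq = 0:
  #   K [dq; dlambda] = [-dA q - dchi; 0]
  dq_dchi <- -Kqq
  elems <- unique(system$species)
  dq_dJ <- vapply(elems, function(el) {
    mask <- as.numeric(system$species == el)
    -drop(Kqq %*% (mask * q))
  }, numeric(n))
  if (is.null(system$cache$dPhi)) {
    cache <- .electro_cache(structure, system_electro(system),
                            derivatives = TRUE)
    dPhi <- cache$dPhi
  } else {
    dPhi <- system$cache$dPhi
  }
  dq_dR <- array(0, c(n, n, 3))
  for (k in seq_len(n)) {
    # rhs_i = - sum_j (dA_ij / dR_k) q_j; A_ij depends on r_i, r_j only
    rhs <- matrix(0, n, 3)
    for (a in 1:3) {
      # derivative w.r.t. position of atom k:
      # row k: sum_j dPhi[k, j, a] q_j; row i != k: dPhi[i, k, a]... with
      # dPhi[i, j, ] = d Phi_ij / d r_i and d Phi_ij / d r_j = -dPhi... only
      # for clusters; in general d Phi_ij / d r_j = dPhi[j, i, ] by symmetry.
      rhs[k, a] <- -sum(dPhi[k, , a] * q)
      rhs[-k, a] <- -dPhi[k, -k, a] * q[k]
    }
    dq_dR[, k, ] <- Kqq %*% rhs
  }
  list(dq_dchi = dq_dchi, dq_dJ = dq_dJ, dq_dR = dq_dR)
}

# reconstruct an element_electro from a qeq_system (internal)
system_electro <- function(system) {
  elems <- unique(system$species)
  idx <- match(elems, system$species)
  element_electro(elems, hardness = system$J[idx], width = system$sigma[idx])
}
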