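#' Per-element electrostatic parameters
#'
#' Element-specific hardness `J` (Ha/e^2) and Gaussian charge-density
#' width `sigma` (Bohr).  Widths default to the covalent radii; hardness
#' defaults to 0.5 Ha/e^2 and is typically refined during training.
#'
#' @param elements character vector of element symbols.
#' @param hardness numeric vector (recycled) of hardness values (Ha/e^2).
#' @param width numeric vector (recycled) of Gaussian widths (Bohr);
#'   `NULL` uses [covalent_radius()].
#' @return object of class `"element_electro"`: named lists `J`, `sigma`.
#' @export
element_electro <- function(elements, hardness = 0.5, width = NULL) {
  stopifnot(length(elements) >= 1)
  J <- rep_len(hardness, length(elements))
  sigma <- if (is.null(width)) covalent_radius(elements, "bohr")
           else rep_len(width, length(elements))
  if (any(sigma <= 0)) stop("Gaussian widths must be > 0")
  base::structure(list(elements = elements,
                       J = stats::setNames(J, elements),
                       sigma = stats::setNames(sigma, elements)),
                  class = "element_electro")
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Screened Coulomb kernel of two Gaussian charges
#'
#' \eqn{\phi(r) = \mathrm{erf}(r / (\sqrt{2}\gamma)) / r} with
#' \eqn{\gamma = \sqrt{\sigma_i^2 + \sigma_j^2}}; finite at the origin
#' with limit \eqn{\sqrt{2/\pi}/\gamma} (evaluated analytically below
#' `r = 1e-8`), smooth, positive, and monotonically decreasing.
#'
#' @param r distance (Bohr), vectorized.
#' @param gamma combined Gaussian width (Bohr).
#' @return interaction in Ha e^-2.
#' @export
pair_kernel <- function(r, gamma) {
  if (any(gamma <= 0)) stop("gamma must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  small <- r < 1e-8
  out <- numeric(length(r))
  if (any(!small)) {
    rr <- r[!small]
    out[!small] <- .erf(rr / (sqrt(2) * gamma)) / rr
  }
  if (any(small)) {
    # series: erf(x)/r = sqrt(2/pi)/gamma * (1 - r^2/(6*gamma^2) + ...)
    rr <- r[small]
    out[small] <- sqrt(2 / pi) / gamma * (1 - rr^2 / (6 * gamma^2))
  }
  out
}

# d/dr of pair_kernel
.pair_kernel_deriv <- function(r, gamma) {
  small <- r < 1e-8
  out <- numeric(length(r))
  if (any(!small)) {
    rr <- r[!small]
    x <- rr / (sqrt(2) * gamma)
    out[!small] <- sqrt(2 / pi) / gamma * exp(-x^2) / rr - .erf(x) / rr^2
  }
  out[small] <- 0  # kernel has zero slope at the origin
  out
}

#' Short-range screening switch
#'
#' Cosine ramp attenuating the electrostatic pair kernel at short range
#' so close-range physics is absorbed by the short-range networks:
#' `S(r) = 0` for `r <= inner`,
#' `S(r) = 0.5 * (1 - cos(pi (r - inner)/(outer - inner)))` between, and
#' `S(r) = 1` beyond `outer`.  Self-interaction terms are never screened.
#'
#' @param inner inner radius (Angstrom), `> 0`.
#' @param outer outer radius (Angstrom), `> inner`; conventionally the
#'   symmetry-function cutoff.
#' @return object of class `"screening_spec"`.
#' @export
screening_spec <- function(inner, outer) {
  if (!(inner > 0 && outer > inner)) stop("need 0 < inner < outer")
  base::structure(list(inner = inner, outer = outer), class = "screening_spec")
}

# value and derivative of the switch; r must be in the same unit as the radii
.screen_switch <- function(r, spec) {
  if (is.null(spec)) {
    return(list(value = rep(1, length(r)), deriv = rep(0, length(r))))
  }
  u <- (r - spec$inner) / (spec$outer - spec$inner)
  v <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  d <- ifelse(u <= 0 | u >= 1, 0,
              0.5 * pi / (spec$outer - spec$inner) * sin(pi * u))
  list(value = v, deriv = d)
}

# ---------------------------------------------------------------------------
# Interaction matrices.
#
# .electro_cache computes, in Bohr/Hartree units:
#   Phi     : N x N symmetric matrix with Phi_ij the (unscreened) Gaussian
#             interaction (lattice-summed when periodic) and
#             Phi_ii = 1/(sigma_i sqrt(pi)) (+ periodic self-image terms);
#             so E_elec = 0.5 q' Phi q and the Qeq matrix is Phi + diag(J).
#   Phi_s   : same with the short-range screening switch applied to the
#             pair part (self terms untouched).
#   dPhi, dPhi_s : N x N x 3 arrays, [i, j, ] = d Phi_ij / d r_i (Bohr^-1).
# For periodic systems the Ewald splitting width `eta` is chosen from the
# accuracy target unless given explicitly.
.electro_cache <- function(structure, electro, screening = NULL,
                           eta = NULL, accuracy = 1e-6,
                           derivatives = TRUE) {
  n <- structure$n_atoms
  unknown <- setdiff(unique(structure$species), electro$elements)
  if (length(unknown)) {
    stop("element(s) without electrostatic parameters: ",
         paste(unknown, collapse = ", "))
  }
  sigma <- unname(electro$sigma[structure$species])
  pos <- structure$positions / units_au$bohr_ang   # Bohr
  periodic <- any(structure$pbc)
  scr_bohr <- if (is.null(screening)) NULL else
    screening_spec(screening$inner / units_au$bohr_ang,
                   screening$outer / units_au$bohr_ang)
  Phi <- matrix(0, n, n)
  diag(Phi) <- 1 / (sigma * sqrt(pi))
  Phi_s <- Phi
  dPhi <- if (derivatives) array(0, c(n, n, 3)) else NULL
  dPhi_s <- dPhi

  gam <- sqrt(outer(sigma^2, sigma^2, "+"))

  if (!periodic) {
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d <- pos[i, ] - pos[j, ]
          r <- sqrt(sum(d^2))
          if (r < 1e-6) stop("overlapping atoms (r < 1e-6 Bohr): atoms ",
                             i, " and ", j)
          k <- pair_kernel(r, gam[i, j])
          kp <- .pair_kernel_deriv(r, gam[i, j])
          s <- .screen_switch(r, scr_bohr)
          Phi[i, j] <- Phi[j, i] <- k
          Phi_s[i, j] <- Phi_s[j, i] <- s$value * k
          if (derivatives) {
            u <- d / r
            dPhi[i, j, ] <- kp * u
            dPhi[j, i, ] <- -kp * u
            ksp <- s$deriv * k + s$value * kp
            dPhi_s[i, j, ] <- ksp * u
            dPhi_s[j, i, ] <- -ksp * u
          }
        }
      }
    }
    return(list(Phi = Phi, Phi_s = Phi_s, dPhi = dPhi, dPhi_s = dPhi_s,
                sigma = sigma, periodic = FALSE))
  }

  ## periodic: Ewald sum of the Gaussian interaction
  if (!all(structure$pbc)) {
    stop("periodic electrostatics requires pbc in all three directions")
  }
  cell <- structure$cell / units_au$bohr_ang
  vol <- abs(det(cell))
  xs <- sqrt(-log(accuracy * 1e-2))          # dimensionless decay margin
  if (is.null(eta)) eta <- min(.cell_widths(cell)) / (2 * sqrt(2) * xs)
  gmax <- max(gam)
  rcut <- sqrt(2) * xs * max(eta, gmax)
  if (!is.null(scr_bohr)) rcut <- max(rcut, scr_bohr$outer)
  kcut <- sqrt(2) * xs / eta

  # real-space images
  stb <- structure
  stb$positions <- pos
  stb$cell <- cell
  nlb <- neighbor_list(stb, rcut)            # Bohr in, Bohr out

  # reciprocal lattice (rows)
  B <- 2 * pi * t(solve(cell))
  wB <- .cell_widths(B)
  mm <- pmax(1L, ceiling(kcut / wB))
  mg <- as.matrix(expand.grid(-mm[1]:mm[1], -mm[2]:mm[2], -mm[3]:mm[3]))
  K <- mg %*% B
  k2 <- rowSums(K^2)
  keep <- k2 > 1e-12 & k2 <= kcut^2
  K <- K[keep, , drop = FALSE]; k2 <- k2[keep]
  kfac <- 4 * pi / vol * exp(-eta^2 * k2 / 2) / k2   # per k-vector

  # reciprocal-space pair sums (includes i = j)
  # Phi_recip_ij = sum_k kfac * cos(k . (r_i - r_j))
  KR <- pos %*% t(K)                         # n x nk
  Ck <- cos(KR); Sk <- sin(KR)
  Phi_rec <- Ck %*% (kfac * t(Ck)) + Sk %*% (kfac * t(Sk))
  Phi <- Phi + Phi_rec
  diag(Phi) <- diag(Phi) - 2 / (sqrt(2 * pi) * eta)
  if (derivatives) {
    # d Phi_rec_ij / d r_i = - sum_k kfac k sin(k.(r_i - r_j))
    for (a in 1:3) {
      kf <- kfac * K[, a]
      M <- Sk %*% (kf * t(Ck)) - Ck %*% (kf * t(Sk))  # sin(k.(ri-rj)) sums
      dPhi[, , a] <- -M
    }
  }
  Phi_s <- Phi
  if (derivatives) dPhi_s <- dPhi

  # real-space part: Delta kernel over images within rcut,
  # screening correction subtracts (1 - S(r)) * full Gaussian kernel
  if (length(nlb$i)) {
    for (p in seq_along(nlb$i)) {
      i <- nlb$i[p]; j <- nlb$j[p]
      r <- nlb$r[p]
      if (i != j && r < 1e-6) stop("overlapping atoms (r < 1e-6 Bohr)")
      g <- gam[i, j]
      kg <- pair_kernel(r, g)
      ke <- pair_kernel(r, eta)
      dk <- kg - ke
      s <- .screen_switch(r, scr_bohr)
      corr <- (1 - s$value) * kg
      # vec convention: nlb$vec = r_j + L - r_i, so d r / d r_i = -vec / r
      u <- -nlb$vec[p, ] / r
      kgp <- .pair_kernel_deriv(r, g)
      kep <- .pair_kernel_deriv(r, eta)
      corrp <- -s$deriv * kg + (1 - s$value) * kgp
      add <- function(M, i, j, v) { M[i, j] <- M[i, j] + v; M }
      Phi <- add(Phi, i, j, dk); Phi_s <- add(Phi_s, i, j, dk - corr)
      if (i != j) {
        Phi <- add(Phi, j, i, dk); Phi_s <- add(Phi_s, j, i, dk - corr)
      } else {
        # self-image pairs stored once per +/- pair: count both directions
        Phi <- add(Phi, i, i, dk); Phi_s <- add(Phi_s, i, i, dk - corr)
      }
      if (derivatives && i != j) {
        dPhi[i, j, ] <- dPhi[i, j, ] + (kgp - kep) * u
        dPhi[j, i, ] <- dPhi[j, i, ] - (kgp - kep) * u
        dPhi_s[i, j, ] <- dPhi_s[i, j, ] + (kgp - kep - corrp) * u
        dPhi_s[j, i, ] <- dPhi_s[j, i, ] - (kgp - kep - corrp) * u
      }
    }
  }
  list(Phi = Phi, Phi_s = Phi_s, dPhi = dPhi, dPhi_s = dPhi_s,
       sigma = sigma, periodic = TRUE, eta = eta, rcut = rcut, kcut = kcut)
}

#' Electrostatic energy of Gaussian charges
#'
#' Cluster case:
#' \eqn{E = \sum_{i<j} S(r_{ij}) \phi_{ij}(r_{ij}) Q_i Q_j +
#' \sum_i Q_i^2 / (2 \sigma_i \sqrt{\pi})} with screening switch `S`
#' (identically 1 when `screening` is `NULL`).  Periodic case: the
#' Ewald-summed equivalent (neutral cells only), with the screening
#' correction applied to real-space pairs within the switch range.
#'
#' @param structure an [atoms()] object.
#' @param charges per-atom charges (e).
#' @param electro an [element_electro()] object.
#' @param screening a [screening_spec()] or `NULL`.
#' @param accuracy Ewald accuracy target (Ha), periodic case only.
#' @param eta optional explicit Ewald splitting width (Bohr).
#' @return energy in Ha.
#' @export
electrostatic_energy <- function(structure, charges, electro,
                                 screening = NULL, accuracy = 1e-6,
                                 eta = NULL) {
  if (length(charges) != structure$n_atoms) {
    stop("charges must have one entry per atom")
  }
  if (any(structure$pbc) &&
      abs(sum(charges)) > 1e-6) {
    stop("periodic electrostatics supports neutral cells only")
  }
  ec <- .electro_cache(structure, electro, screening = screening,
                       eta = eta, accuracy = accuracy, derivatives = FALSE)
  0.5 * drop(charges %*% ec$Phi_s %*% charges)
}

#' Ewald energy of Gaussian charges in a periodic cell
#'
#' Real-/reciprocal-space split with the splitting width chosen from the
#' accuracy target (overridable); the result is independent of the
#' splitting width to within the target.  Requires full periodicity and a
#' neutral cell.
#'
#' @inheritParams electrostatic_energy
#' @return energy in Ha.
#' @export
ewald_energy <- function(structure, charges, electro, accuracy = 1e-6,
                         eta = NULL) {
  if (accuracy <= 0) stop("accuracy must be > 0")
  if (!all(structure$pbc)) stop("ewald_energy requires pbc in all directions")
  if (abs(sum(charges)) > 1e-6) stop("ewald_energy requires a neutral cell")
  ec <- .electro_cache(structure, electro, screening = NULL, eta = eta,
                       accuracy = accuracy, derivatives = FALSE)
  0.5 * drop(charges %*% ec$Phi %*% charges)
}
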