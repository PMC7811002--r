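#' Cosine cutoff function
#'
#' Smooth cutoff \eqn{f_c(r) = 0.5[\cos(\pi r/R_c) + 1]} for `r <= R_c`,
#' zero beyond, continuously differentiable at `R_c`.  Used by all
#' radial/angular symmetry functions and by the synthetic ground truth's
#' coordination counts.
#'
#' @param r distances (any length), same unit as `cutoff`.
#' @param cutoff cutoff radius `R_c > 0`.
#' @return list with `value` and `deriv` (d f_c / d r), vectorized over `r`.
#' @examples
#' cutoff_cosine(c(0, 2, 4), 4)$value  # 1, 0.5, 0
#' @export
cutoff_cosine <- function(r, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  inside <- r <= cutoff
  v <- ifelse(inside, 0.5 * (cos(pi * r / cutoff) + 1), 0)
  d <- ifelse(inside, -0.5 * pi / cutoff * sin(pi * r / cutoff), 0)
  list(value = v, deriv = d)
}

#' Atom-centered symmetry function parameters
#'
#' Defines, per center element, the radial (`G2`) and angular (`G4`)
#' function sets.  The default set uses, per neighbor element, radial
#' eta values log-spaced between `~0` and a value focusing on the first
#' coordination shell (all with `r_shift = 0`, and always including
#' `eta = 0`, whose `G2` is exactly the smooth coordination number), plus
#' angular functions with `zeta` in `{1, 4}` and `lambda = +/-1`.
#'
#' @param elements character vector of element symbols covered.
#' @param cutoff cutoff radius in Bohr (mirroring the conventional 8-10
#'   Bohr choice); converted to Angstrom internally.
#' @param n_radial number of radial functions per element pair (>= 2).
#' @param angular logical: include angular functions.
#' @param eta_max largest radial eta (Angstrom^-2).
#' @return object of class `"acsf_params"`: list with `elements`,
#'   `cutoff` (Angstrom) and per-element lists `radial` (data frames with
#'   columns `neighbor`, `eta`, `r_shift`) and `angular` (data frames with
#'   columns `n1`, `n2`, `eta`, `zeta`, `lambda`).
#' @export
acsf_params <- function(elements, cutoff = 8, n_radial = 4, angular = TRUE,
                        eta_max = 0.8) {
  stopifnot(length(elements) >= 1, cutoff > 0, n_radial >= 2)
  rc_ang <- cutoff * units_au$bohr_ang
  etas <- c(0, exp(seq(log(0.03), log(eta_max), length.out = n_radial - 1)))
  radial <- do.call(rbind, lapply(elements, function(nb)
    data.frame(neighbor = nb, eta = etas, r_shift = 0)))
  ang <- NULL
  if (angular) {
    pairs <- t(combn2_with_rep(elements))
    ang <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
      expand.grid(n1 = pairs[k, 1], n2 = pairs[k, 2],
                  eta = c(0.0, 0.06), zeta = c(1, 4), lambda = c(-1, 1),
                  stringsAsFactors = FALSE)))
  }
  per_elem <- lapply(elements, function(el) list(radial = radial, angular = ang))
  names(per_elem) <- elements
  n_desc <- nrow(radial) + if (is.null(ang)) 0L else nrow(ang)
  if (n_desc < 1 || n_desc > 128) {
    stop("descriptor count per element out of range: ", n_desc)
  }
  base::structure(list(elements = elements, cutoff = rc_ang, sets = per_elem),
                  class = "acsf_params")
}

# unordered pairs with repetition
combn2_with_rep <- function(x) {
  idx <- which(upper.tri(diag(length(x)), diag = TRUE), arr.ind = TRUE)
  rbind(x[idx[, 1]], x[idx[, 2]])
}

#' Number of descriptors per element
#' @param params an [acsf_params()] object.
#' @param element element symbol.
#' @return integer count.
#' @export
acsf_count <- function(params, element) {
  s <- params$sets[[element]]
  if (is.null(s)) stop("element not covered by descriptor set: ", element)
  nrow(s$radial) + if (is.null(s$angular)) 0L else nrow(s$angular)
}

#' Compute atom-centered symmetry functions
#'
#' Radial part \eqn{G^2_i = \sum_j \exp(-\eta (r_{ij}-r_s)^2) f_c(r_{ij})}
#' over neighbors of the requested element, and angular part
#' \eqn{G^4_i = 2^{1-\zeta} \sum_{j<k} (1+\lambda\cos\theta_{ijk})^\zeta
#' \exp(-\eta(r_{ij}^2+r_{ik}^2+r_{jk}^2)) f_c(r_{ij}) f_c(r_{ik}) f_c(r_{jk})}
#' over element-matched neighbor pairs, with analytic gradients with
#' respect to every involved atomic position.
#'
#' Values are invariant under rigid rotations, translations and
#' permutation of like atoms; gradients are exact derivatives of the
#' implemented expressions.
#'
#' @param structure an [atoms()] object.
#' @param params an [acsf_params()] object.
#' @param nl optional precomputed [neighbor_list()] at `params$cutoff`.
#' @param gradients logical: also compute position gradients.
#' @return object of class `"descriptor_set"`: `values` is an
#'   `n_atoms`-list of numeric vectors; `gradients` (if requested) an
#'   `n_atoms`-list of lists keyed by the atom index `k` (as character)
#'   holding `n_desc x 3` matrices `dG_i/dR_k` in Angstrom^-1.
#' @export
acsf_compute <- function(structure, params, nl = NULL, gradients = TRUE) {
  stopifnot(inherits(structure, "atoms"), inherits(params, "acsf_params"))
  unknown <- setdiff(unique(structure$species), params$elements)
  if (length(unknown)) {
    stop("element(s) not covered by descriptor set: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(nl)) nl <- neighbor_list(structure, params$cutoff)
  n <- structure$n_atoms
  rc <- params$cutoff
  spec <- structure$species

  # full (symmetrized) neighbor table per center atom
  ctr <- c(nl$i, nl$j)
  nbr <- c(nl$j, nl$i)
  vec <- rbind(nl$vec, -nl$vec)
  r <- c(nl$r, nl$r)
  by_center <- split(seq_along(ctr), factor(ctr, levels = seq_len(n)))

  values <- vector("list", n)
  grads <- if (gradients) vector("list", n) else NULL

  for (ia in seq_len(n)) {
    set <- params$sets[[spec[ia]]]
    nrad <- nrow(set$radial)
    nang <- if (is.null(set$angular)) 0L else nrow(set$angular)
    nd <- nrad + nang
    g <- numeric(nd)
    idx <- by_center[[ia]]
    gr <- new.env(parent = emptyenv())
    addg <- function(atom, rows, mat3) {
      key <- as.character(atom)
      cur <- if (is.null(gr[[key]])) matrix(0, nd, 3) else gr[[key]]
      cur[rows, ] <- cur[rows, , drop = FALSE] + mat3
      gr[[key]] <- cur
    }
    if (length(idx)) {
      rj <- r[idx]; vj <- vec[idx, , drop = FALSE]; sj <- spec[nbr[idx]]
      fc <- cutoff_cosine(rj, rc)
      # radial
      for (q in seq_len(nrad)) {
        sel <- sj == set$radial$neighbor[q]
        if (!any(sel)) next
        eta <- set$radial$eta[q]; rs <- set$radial$r_shift[q]
        rr <- rj[sel]
        ex <- exp(-eta * (rr - rs)^2)
        term <- ex * fc$value[sel]
        g[q] <- sum(term)
        if (gradients) {
          # d term / d r, direction vj/r applied to neighbor, minus to center
          dterm <- ex * (fc$deriv[sel] - 2 * eta * (rr - rs) * fc$value[sel])
          dir <- vj[sel, , drop = FALSE] / rr
          contrib <- dir * dterm
          nbrs <- nbr[idx][sel]
          for (u in seq_along(nbrs)) {
            addg(nbrs[u], q, contrib[u, , drop = FALSE])
            addg(ia, q, -contrib[u, , drop = FALSE])
          }
        }
      }
      # angular
      if (nang > 0 && length(idx) >= 2) {
        np <- length(idx)
        for (jj in seq_len(np - 1)) {
          for (kk in (jj + 1):np) {
            e1 <- sj[jj]; e2 <- sj[kk]
            rij <- rj[jj]; rik <- rj[kk]
            vij <- vj[jj, ]; vik <- vj[kk, ]
            vjk <- vik - vij
            rjk <- sqrt(sum(vjk^2))
            if (rjk > rc || rjk < 1e-10) next
            match1 <- set$angular$n1 == e1 & set$angular$n2 == e2
            match2 <- set$angular$n1 == e2 & set$angular$n2 == e1
            rows <- which(match1 | match2)
            if (!length(rows)) next
            cosq <- sum(vij * vik) / (rij * rik)
            fcj <- cutoff_cosine(rij, rc); fck <- cutoff_cosine(rik, rc)
            fcl <- cutoff_cosine(rjk, rc)
            fffc <- fcj$value * fck$value * fcl$value
            eta <- set$angular$eta[rows]
            zeta <- set$angular$zeta[rows]
            lam <- set$angular$lambda[rows]
            base <- 1 + lam * cosq
            ok <- base > 0
            pw <- ifelse(ok, base^zeta, 0)
            ex <- exp(-eta * (rij^2 + rik^2 + rjk^2))
            pref <- 2^(1 - zeta)
            g[nrad + rows] <- g[nrad + rows] + pref * pw * ex * fffc
            if (gradients) {
              # derivative pieces: d/dr terms and d cos / dR
              dpw <- ifelse(ok & base > 1e-300, zeta * base^(zeta - 1), 0)
              # dcos/dRj etc (j = neighbor jj atom, k = neighbor kk atom)
              dcos_j <- vik / (rij * rik) - cosq * vij / rij^2
              dcos_k <- vij / (rij * rik) - cosq * vik / rik^2
              dcos_i <- -dcos_j - dcos_k
              # scalar radial-derivative factors
              # w.r.t. rij: -2 eta rij * ex * fffc + ex * dfcj * fck * fcl
              A <- pref * pw * ex
              drij <- A * (-2 * eta * rij * fffc +
                             fcj$deriv * fck$value * fcl$value)
              drik <- A * (-2 * eta * rik * fffc +
                             fcj$value * fck$deriv * fcl$value)
              drjk <- A * (-2 * eta * rjk * fffc +
                             fcj$value * fck$value * fcl$deriv)
              B <- pref * dpw * lam * ex * fffc
              uij <- vij / rij; uik <- vik / rik; ujk <- vjk / rjk
              # gradient w.r.t. neighbor j position
              gj <- outer(drij, uij) + outer(drjk, -ujk) + outer(B, dcos_j)
              gk <- outer(drik, uik) + outer(drjk, ujk) + outer(B, dcos_k)
              gi <- -(gj + gk)
              addg(nbr[idx][jj], nrad + rows, gj)
              addg(nbr[idx][kk], nrad + rows, gk)
              addg(ia, nrad + rows, gi)
            }
          }
        }
      }
    }
    values[[ia]] <- g
    if (gradients) grads[[ia]] <- as.list(gr)
  }
  base::structure(list(values = values, gradients = grads,
                       species = spec, params = params),
                  class = "descriptor_set")
}

#' Finite-difference validation of descriptor gradients
#'
#' Returns the maximum absolute deviation between analytic gradients and
#' central finite differences over all atoms, descriptor entries and
#' Cartesian components.  Intended for the test suite.
#'
#' @param structure an [atoms()] object.
#' @param params an [acsf_params()] object.
#' @param step finite-difference step in Angstrom (between 1e-6 and 1e-3).
#' @return maximum deviation (Angstrom^-1).
#' @export
acsf_gradient_check <- function(structure, params, step = 1e-4) {
  if (step < 1e-6 || step > 1e-3) stop("step must lie in [1e-6, 1e-3]")
  ds <- acsf_compute(structure, params, gradients = TRUE)
  n <- structure$n_atoms
  maxdev <- 0
  for (k in seq_len(n)) {
    for (comp in 1:3) {
      sp <- structure; sm <- structure
      sp$positions[k, comp] <- sp$positions[k, comp] + step
      sm$positions[k, comp] <- sm$positions[k, comp] - step
      dp <- acsf_compute(sp, params, gradients = FALSE)$values
      dm <- acsf_compute(sm, params, gradients = FALSE)$values
      for (i in seq_len(n)) {
        fd <- (dp[[i]] - dm[[i]]) / (2 * step)
        an <- ds$gradients[[i]][[as.character(k)]]
        if (is.null(an)) an <- matrix(0, length(fd), 3)
        maxdev <- max(maxdev, max(abs(fd - an[, comp])))
      }
    }
  }
  maxdev
}
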