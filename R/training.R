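#' Training configuration
#'
#' @param lr Adam learning rate (ignored by L-BFGS).
#' @param epochs maximum full-batch epochs (Adam) or iterations (L-BFGS).
#' @param w_E,w_F loss weights of the per-atom energy and the force terms
#'   in stage 2 (forces dominate per-atom-normalized energies otherwise).
#' @param optimizer `"lbfgs"` (default; deterministic quasi-Newton, much
#'   faster on these small full-batch least-squares problems) or
#'   `"adam"`.
#' @param patience early-stopping patience for Adam (epochs without
#'   validation improvement); `Inf` disables early stopping.
#' @param val_fraction fraction of the training records held out
#'   internally for validation.
#' @param seed RNG seed (validation split).
#' @param lr_decay multiplicative Adam learning-rate decay per epoch.
#' @param verbose print progress.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(lr = 0.02, epochs = 300L, w_E = 1, w_F = 10,
                         optimizer = c("lbfgs", "adam"),
                         patience = Inf, val_fraction = 0.1, seed = 1,
                         lr_decay = 1, verbose = FALSE) {
  if (w_E < 0 || w_F < 0) stop("loss weights must be >= 0")
  optimizer <- match.arg(optimizer)
  base::structure(list(lr = lr, epochs = as.integer(epochs), w_E = w_E,
                       w_F = w_F, optimizer = optimizer, patience = patience,
                       val_fraction = val_fraction, seed = as.integer(seed),
                       lr_decay = lr_decay, verbose = verbose),
                  class = "train_config")
}

#' Split a dataset into train and test parts
#'
#' Deterministic, disjoint and exhaustive; stratified by the
#' `population` tag when every record carries one, so each charge
#' state/sub-population appears in both splits.
#'
#' @param records list of [reference_record()].
#' @param fraction train fraction (default 0.9).
#' @param seed integer seed.
#' @return list with `train` and `test` record lists.
#' @export
split_dataset <- function(records, fraction = 0.9, seed = 1) {
  n <- length(records)
  if (n < 2) stop("need at least 2 records")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  pops <- vapply(records, function(r) {
    p <- r$structure$info$population
    if (is.null(p)) NA_character_ else p
  }, "")
  strata <- if (anyNA(pops)) rep("all", n) else pops
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr <- logical(n)
  # apportion round(fraction * n) train slots across strata by largest
  # remainder so the overall fraction is honored exactly
  levs <- unique(strata)
  target <- round(fraction * n)
  quota <- fraction * table(factor(strata, levels = levs))
  k_str <- floor(quota)
  rem <- target - sum(k_str)
  if (rem > 0) {
    order_rem <- order(quota - k_str, decreasing = TRUE)
    k_str[order_rem[seq_len(rem)]] <- k_str[order_rem[seq_len(rem)]] + 1
  }
  for (s in seq_along(levs)) {
    idx <- which(strata == levs[s])
    tr[sample(idx)[seq_len(k_str[s])]] <- TRUE
  }
  if (!any(tr) || all(tr)) stop("fraction yields an empty split")
  list(train = records[tr], test = records[!tr])
}

## ---------------------------------------------------------------------------
## optimizers (full batch, deterministic)

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, theta, grad, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---------------------------------------------------------------------------
## stage 1: charges

# Geometry-dependent precompute for the charge stage.  Atoms are indexed
# globally (record by record); per element we keep the stacked descriptor
# matrix and the global ids of its rows.
.charge_stage_data <- function(model, records) {
  elements <- model$acsf$elements
  nrec <- length(records)
  n_per <- vapply(records, function(r) r$structure$n_atoms, 0L)
  ntot <- sum(n_per)
  vals <- vector("list", ntot)
  spec_glob <- character(ntot)
  recs <- vector("list", nrec)
  off <- 0L
  for (r in seq_len(nrec)) {
    rec <- records[[r]]
    if (is.null(rec$charges)) stop("record ", r, " carries no reference charges")
    st <- rec$structure
    ds <- acsf_compute(st, model$acsf, gradients = FALSE)
    n <- st$n_atoms
    vals[off + seq_len(n)] <- ds$values
    spec_glob[off + seq_len(n)] <- st$species
    Phi <- if (model$generation == "4G")
      .electro_cache(st, model$electro, derivatives = FALSE)$Phi else NULL
    recs[[r]] <- list(n = n, glob = off + seq_len(n), Phi = Phi,
                      qref = rec$charges, q_total = st$total_charge,
                      species = st$species)
    off <- off + n
  }
  ids_el <- lapply(stats::setNames(elements, elements),
                   function(el) which(spec_glob == el))
  Xel <- lapply(ids_el, function(ids)
    if (length(ids)) do.call(rbind, vals[ids]) else NULL)
  list(Xel = Xel, ids_el = ids_el, recs = recs, n_atoms_total = ntot)
}

# charge loss (mean squared per-atom error) and its gradients
.charge_epoch <- function(model, data, theta_J = NULL, want_grad = TRUE) {
  elements <- model$acsf$elements
  gen <- model$generation
  fwd_el <- list()
  chi_glob <- numeric(data$n_atoms_total)
  for (el in elements) {
    if (is.null(data$Xel[[el]])) next
    fwd_el[[el]] <- .net_fwd(model$charge_nets[[el]], data$Xel[[el]])
    chi_glob[data$ids_el[[el]]] <- fwd_el[[el]]$y
  }
  Ntot <- data$n_atoms_total
  sse <- 0
  coef_glob <- numeric(Ntot)
  gJ <- stats::setNames(numeric(length(elements)), elements)
  Jval <- if (gen == "4G") .softplus(theta_J) else NULL
  for (rc in data$recs) {
    chi <- chi_glob[rc$glob]
    if (gen == "4G") {
      A <- rc$Phi + diag(unname(Jval[rc$species]), rc$n)
      K <- rbind(cbind(A, rep(1, rc$n)), c(rep(1, rc$n), 0))
      Kinv <- tryCatch(solve(K), error = function(e)
        stop("Qeq solve failed during training: ", conditionMessage(e)))
      q <- drop(Kinv %*% c(-chi, rc$q_total))[seq_len(rc$n)]
    } else {
      q <- chi   # 3G: the nets output raw charges directly
    }
    res <- q - rc$qref
    sse <- sse + sum(res^2)
    if (!want_grad) next
    if (gen == "4G") {
      Kqq <- Kinv[seq_len(rc$n), seq_len(rc$n), drop = FALSE]
      coef_glob[rc$glob] <- -drop(Kqq %*% res) * (2 / Ntot)
      for (el in unique(rc$species)) {
        mask <- as.numeric(rc$species == el)
        gJ[el] <- gJ[el] - (2 / Ntot) * sum(res * drop(Kqq %*% (mask * q)))
      }
    } else {
      coef_glob[rc$glob] <- (2 / Ntot) * res
    }
  }
  out <- list(loss = sse / Ntot, rmse = sqrt(sse / Ntot))
  if (want_grad) {
    gnet <- list()
    for (el in elements) {
      if (is.null(data$Xel[[el]])) {
        gnet[[el]] <- numeric(length(net_flatten(model$charge_nets[[el]])))
        next
      }
      gnet[[el]] <- .net_gradw(model$charge_nets[[el]], data$Xel[[el]],
                               coef_glob[data$ids_el[[el]]], fwd_el[[el]])
    }
    out$gnet <- gnet
    if (gen == "4G") out$gJ <- gJ * .sigmoid(theta_J)
  }
  out
}

#' Stage 1: fit the charge model
#'
#' 4G: minimizes the mean squared per-atom charge error of the
#' equilibrated charges over the electronegativity-network weights and
#' the per-element hardness (kept positive through a softplus
#' reparameterization); the gradient flows through the constrained Qeq
#' solve by implicit differentiation.  3G: plain regression of the
#' charge-network outputs onto the reference charges.
#'
#' @param model a 3G or 4G [potential_model()].
#' @param records training records with reference charges.
#' @param config a [train_config()].
#' @param val optional validation records; `NULL` splits
#'   `config$val_fraction` off `records`.
#' @return list with `model` (updated) and `history` (data frame with
#'   per-epoch/-iteration train charge RMSE in e, and the validation RMSE
#'   where tracked; a zero-epoch run reports the initial parameters).
#' @export
fit_charge_stage <- function(model, records, config = train_config(),
                             val = NULL) {
  if (model$generation == "2G") stop("2G models carry no charge model")
  if (is.null(val)) {
    sp <- split_dataset(records, 1 - config$val_fraction, seed = config$seed)
    records <- sp$train; val <- sp$test
  }
  elements <- model$acsf$elements
  gen <- model$generation
  data <- .charge_stage_data(model, records)
  # input standardization (set once, from the training design)
  for (el in elements) {
    if (is.null(model$charge_nets[[el]]$center) &&
        !is.null(data$Xel[[el]])) {
      model$charge_nets[[el]] <- net_set_scaling(model$charge_nets[[el]],
                                                 data$Xel[[el]])
    }
  }
  vdata <- .charge_stage_data(model, val)

  lens <- vapply(elements, function(el)
    length(net_flatten(model$charge_nets[[el]])), 0L)
  theta <- c(unlist(lapply(elements, function(el)
    net_flatten(model$charge_nets[[el]])), use.names = FALSE),
    if (gen == "4G") .softplus_inv(unname(model$electro$J[elements])))
  nJ <- if (gen == "4G") length(elements) else 0L
  unpack <- function(th) {
    pos <- 0L
    for (el in elements) {
      model$charge_nets[[el]] <<- net_unflatten(model$charge_nets[[el]],
                                                th[pos + seq_len(lens[[el]])])
      pos <- pos + lens[[el]]
    }
    if (gen == "4G") {
      model$electro$J[elements] <<- .softplus(th[pos + seq_len(nJ)])
    }
  }
  theta_J_of <- function(th) if (gen == "4G")
    stats::setNames(th[length(th) - nJ + seq_len(nJ)], elements) else NULL

  if (config$epochs == 0L) {
    tr <- .charge_epoch(model, data, theta_J_of(theta), want_grad = FALSE)$rmse
    va <- .charge_epoch(model, vdata, theta_J_of(theta), want_grad = FALSE)$rmse
    return(list(model = model,
                history = data.frame(epoch = 0L, train_charge_rmse = tr,
                                     val_charge_rmse = va)))
  }

  hist_tr <- numeric(0); hist_va <- numeric(0)
  if (config$optimizer == "lbfgs") {
    fn <- function(th) {
      unpack(th)
      .charge_epoch(model, data, theta_J_of(th), want_grad = FALSE)$loss
    }
    gr <- function(th) {
      unpack(th)
      res <- .charge_epoch(model, data, theta_J_of(th), want_grad = TRUE)
      hist_tr <<- c(hist_tr, res$rmse)
      c(unlist(res$gnet[elements], use.names = FALSE),
        if (gen == "4G") unname(res$gJ[elements]))
    }
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$epochs, factr = 10, lmm = 25))
    theta <- opt$par
    unpack(theta)
    hist_va <- rep(NA_real_, length(hist_tr))
    if (length(hist_va)) {
      hist_va[length(hist_va)] <-
        .charge_epoch(model, vdata, theta_J_of(theta), want_grad = FALSE)$rmse
    }
  } else {
    ad <- .adam_init(length(theta))
    best <- list(theta = theta, val = Inf, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      res <- .charge_epoch(model, data, theta_J_of(theta), want_grad = TRUE)
      vres <- .charge_epoch(model, vdata, theta_J_of(theta), want_grad = FALSE)
      hist_tr <- c(hist_tr, res$rmse); hist_va <- c(hist_va, vres$rmse)
      if (vres$rmse < best$val) best <- list(theta = theta, val = vres$rmse,
                                             epoch = ep)
      if (ep - best$epoch >= config$patience) break
      grad <- c(unlist(res$gnet[elements], use.names = FALSE),
                if (gen == "4G") unname(res$gJ[elements]))
      stp <- .adam_step(ad, theta, grad, config$lr * config$lr_decay^ep)
      theta <- stp$theta; ad <- stp$state
      unpack(theta)
      if (config$verbose && ep %% 50 == 0) {
        message(sprintf("charge stage epoch %d: train %.3e val %.3e e",
                        ep, res$rmse, vres$rmse))
      }
    }
    theta <- best$theta
    unpack(theta)
  }
  list(model = model,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_charge_rmse = hist_tr,
                            val_charge_rmse = hist_va))
}

## ---------------------------------------------------------------------------
## stage 2: energies and forces

# Precompute, with the charge model frozen: network inputs, the fixed
# electrostatic energy/forces and the global sparse map D_all from
# per-atom network input-gradients to all force components
# (descriptor chain + total dQ/dR chain).  Global orderings:
#   atoms: record by record; force components: atom-major x,y,z;
#   input slots: atom-major, nin slots per atom.
.short_stage_data <- function(model, records) {
  elements <- model$acsf$elements
  gen <- model$generation
  ba <- units_au$bohr_ang
  nrec <- length(records)
  use_forces <- !is.null(records[[1]]$forces)

  vals <- list(); spec_glob <- character(0)
  n_per <- integer(nrec)
  trip_i <- vector("list", nrec); trip_j <- vector("list", nrec)
  trip_x <- vector("list", nrec)
  e_elec_vec <- numeric(nrec); e_ref_vec <- numeric(nrec)
  f_ref_all <- vector("list", nrec); f_fix_all <- vector("list", nrec)
  atom_rec <- integer(0)
  off_slot <- 0L; off_f <- 0L

  for (r in seq_len(nrec)) {
    rec <- records[[r]]
    st <- rec$structure
    n <- st$n_atoms
    ds <- acsf_compute(st, model$acsf, gradients = use_forces)
    q <- NULL; e_elec <- 0; dq_tot <- NULL
    F_fixed <- if (use_forces) matrix(0, n, 3) else NULL
    if (gen != "2G") {
      cache <- .electro_cache(st, model$electro, screening = model$screening,
                              accuracy = model$accuracy,
                              derivatives = use_forces)
      chi_or_q <- numeric(n); dnet_dG <- vector("list", n)
      for (i in seq_len(n)) {
        cn <- model$charge_nets[[st$species[i]]]
        X1 <- matrix(ds$values[[i]], 1)
        fw <- .net_fwd(cn, X1)
        chi_or_q[i] <- fw$y
        if (use_forces) dnet_dG[[i]] <- drop(.net_gradx(cn, X1, fw)$G)
      }
      if (gen == "4G") {
        sysq <- qeq_system(st, chi_or_q, model$electro,
                           accuracy = model$accuracy, cache = cache)
        solq <- qeq_solve(sysq)
        q <- solq$charges
      } else {
        q <- if (model$charge_mode == "scaled")
          chi_or_q + (st$total_charge - sum(chi_or_q)) / n else chi_or_q
      }
      e_elec <- 0.5 * drop(q %*% cache$Phi_s %*% q)
      if (use_forces) {
        dchi_dR <- array(0, c(n, n, 3))
        for (m in seq_len(n)) {
          gl <- ds$gradients[[m]]
          for (key in names(gl)) {
            k <- as.integer(key)
            dchi_dR[m, k, ] <- dchi_dR[m, k, ] +
              drop(dnet_dG[[m]] %*% gl[[key]]) * ba
          }
        }
        if (gen == "4G") {
          Kqq <- solq$Kinv[seq_len(n), seq_len(n), drop = FALSE]
          dq_tot <- array(0, c(n, n, 3))
          for (k in seq_len(n)) {
            rhs <- matrix(0, n, 3)
            for (a in 1:3) {
              rhs[k, a] <- -sum(cache$dPhi[k, , a] * q)
              rhs[-k, a] <- -cache$dPhi[k, -k, a] * q[k]
              rhs[, a] <- rhs[, a] - dchi_dR[, k, a]
            }
            dq_tot[, k, ] <- Kqq %*% rhs
          }
        } else {
          dq_tot <- dchi_dR
          if (model$charge_mode == "scaled") {
            for (a in 1:3) {
              M <- dq_tot[, , a]
              dq_tot[, , a] <- M - matrix(colMeans(M), n, n, byrow = TRUE)
            }
          }
        }
        b0 <- drop(cache$Phi_s %*% q)
        for (a in 1:3) {
          F_fixed[, a] <- -(q * (cache$dPhi_s[, , a] %*% q)) -
            drop(b0 %*% dq_tot[, , a])
        }
      }
    }
    nin <- integer(n)
    nvals <- vector("list", n)
    for (i in seq_len(n)) {
      xi <- ds$values[[i]]
      if (gen == "4G") xi <- c(xi, q[i])
      nvals[[i]] <- xi
      nin[i] <- length(xi)
    }
    vals <- c(vals, nvals)
    spec_glob <- c(spec_glob, st$species)
    atom_rec <- c(atom_rec, rep.int(r, n))
    if (use_forces) {
      slot0 <- off_slot
      ti <- list(); tj <- list(); tx <- list()
      for (i in seq_len(n)) {
        nd <- nin[i] - if (gen == "4G") 1L else 0L
        gl <- ds$gradients[[i]]
        for (key in names(gl)) {
          k <- as.integer(key)
          M <- gl[[key]] * ba
          nz <- which(M != 0, arr.ind = TRUE)
          if (nrow(nz)) {
            ti[[length(ti) + 1L]] <- slot0 + nz[, 1]
            tj[[length(tj) + 1L]] <- off_f + 3L * (k - 1L) + nz[, 2]
            tx[[length(tx) + 1L]] <- M[nz]
          }
        }
        if (gen != "2G") {
          dq_row <- as.vector(t(dq_tot[i, , ]))
          nzq <- which(dq_row != 0)
          if (gen == "4G" && length(nzq)) {
            ti[[length(ti) + 1L]] <- rep.int(slot0 + nin[i], length(nzq))
            tj[[length(tj) + 1L]] <- off_f + nzq
            tx[[length(tx) + 1L]] <- dq_row[nzq]
          }
        }
        slot0 <- slot0 + nin[i]
      }
      trip_i[[r]] <- unlist(ti); trip_j[[r]] <- unlist(tj)
      trip_x[[r]] <- unlist(tx)
      f_ref_all[[r]] <- as.vector(t(rec$forces))
      f_fix_all[[r]] <- as.vector(t(F_fixed))
    }
    e_elec_vec[r] <- e_elec; e_ref_vec[r] <- rec$energy
    n_per[r] <- n
    off_slot <- off_slot + sum(nin)
    off_f <- off_f + 3L * n
  }
  ntot <- length(vals)
  ids_el <- lapply(stats::setNames(elements, elements),
                   function(el) which(spec_glob == el))
  Xel <- lapply(ids_el, function(ids)
    if (length(ids)) do.call(rbind, vals[ids]) else NULL)
  nin_el <- vapply(elements, function(el)
    if (is.null(Xel[[el]])) 0L else ncol(Xel[[el]]), 0L)
  # permutation: global slot order (atom-major) <- stacked per-element t(Gx)
  nin_glob <- lengths(vals)
  slot_of_atom <- c(0L, cumsum(nin_glob))[seq_len(ntot)]
  conc_len <- vapply(elements, function(el)
    length(ids_el[[el]]) * nin_el[[el]], 0L)
  conc_off <- stats::setNames(c(0L, cumsum(conc_len))[seq_along(elements)],
                              elements)
  perm <- integer(sum(nin_glob))
  for (e in seq_along(elements)) {
    el <- elements[e]
    ids <- ids_el[[el]]
    if (!length(ids)) next
    base <- conc_off[[el]] + (seq_along(ids) - 1L) * nin_el[[el]]
    for (d in seq_len(nin_el[[el]])) {
      perm[slot_of_atom[ids] + d] <- base + d
    }
  }
  D_all <- NULL
  if (use_forces) {
    D_all <- Matrix::sparseMatrix(
      i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
      dims = c(sum(nin_glob), 3L * ntot))
  }
  counts <- do.call(rbind, lapply(seq_len(nrec), function(r)
    as.numeric(table(factor(spec_glob[atom_rec == r], levels = elements)))))
  list(Xel = Xel, ids_el = ids_el, perm = perm, D_all = D_all,
       e_elec = e_elec_vec, e_ref = e_ref_vec,
       f_ref = if (use_forces) unlist(f_ref_all) else NULL,
       f_fix = if (use_forces) unlist(f_fix_all) else NULL,
       atom_rec = atom_rec, n_per = n_per, nrec = nrec,
       n_atoms_total = ntot, nin_el = nin_el, conc_off = conc_off,
       use_forces = use_forces,
       n_force_comp = if (use_forces) 3L * ntot else 0L,
       counts = counts)
}

# loss/gradient of one stage-2 epoch (fully vectorized)
.short_epoch <- function(model, data, config, want_grad = TRUE) {
  elements <- model$acsf$elements
  fwd_el <- list(); Gx_el <- list()
  y_glob <- numeric(data$n_atoms_total)
  for (el in elements) {
    if (is.null(data$Xel[[el]])) next
    fwd_el[[el]] <- .net_fwd(model$energy_nets[[el]], data$Xel[[el]])
    y_glob[data$ids_el[[el]]] <- fwd_el[[el]]$y
    if (data$use_forces && config$w_F > 0) {
      Gx_el[[el]] <- .net_gradx(model$energy_nets[[el]], data$Xel[[el]],
                                fwd_el[[el]])$G
    }
  }
  shift_per_rec <- drop(data$counts %*% unname(model$e_shift[elements]))
  e_pred <- data$e_elec + shift_per_rec +
    drop(rowsum(y_glob, data$atom_rec, reorder = TRUE))
  rE <- (e_pred - data$e_ref) / data$n_per
  sseE <- sum(rE^2)
  out <- list(rmse_e = sqrt(sseE / data$nrec), rmse_f = NA_real_)
  loss <- config$w_E * sseE / data$nrec
  coef_glob <- if (want_grad) (2 * config$w_E / data$nrec) *
    (rE / data$n_per)[data$atom_rec] else NULL
  V_conc <- NULL
  if (data$use_forces && config$w_F > 0) {
    conc <- unlist(lapply(elements, function(el)
      if (is.null(Gx_el[[el]])) numeric(0) else as.vector(t(Gx_el[[el]]))),
      use.names = FALSE)
    g_all <- conc[data$perm]   # perm: global slot -> concat index
    f_pred <- data$f_fix - as.numeric(Matrix::crossprod(data$D_all, g_all))
    rF <- f_pred - data$f_ref
    sseF <- sum(rF^2)
    loss <- loss + config$w_F * sseF / data$n_force_comp
    out$rmse_f <- sqrt(sseF / data$n_force_comp)
    if (want_grad) {
      dg_all <- -(2 * config$w_F / data$n_force_comp) *
        as.numeric(data$D_all %*% rF)
      V_conc <- numeric(length(conc))
      V_conc[data$perm] <- dg_all
    }
  }
  out$loss <- loss
  if (want_grad) {
    gnet <- list()
    for (el in elements) {
      np <- length(net_flatten(model$energy_nets[[el]]))
      if (is.null(data$Xel[[el]])) { gnet[[el]] <- numeric(np); next }
      g <- .net_gradw(model$energy_nets[[el]], data$Xel[[el]],
                      coef_glob[data$ids_el[[el]]], fwd_el[[el]])
      if (!is.null(V_conc)) {
        nr <- length(data$ids_el[[el]]); nc <- data$nin_el[[el]]
        V <- matrix(V_conc[data$conc_off[[el]] + seq_len(nr * nc)],
                    nrow = nr, ncol = nc, byrow = TRUE)
        g <- g + .net_gradx_vjp(model$energy_nets[[el]], data$Xel[[el]],
                                V, rep(1, nr), fwd_el[[el]])
      }
      gnet[[el]] <- g
    }
    out$gnet <- gnet
  }
  out
}

#' Stage 2: fit the short-range energy networks
#'
#' With the charge model frozen, minimizes
#' `w_E * mean[(E_total - E_ref)/N_at]^2 + w_F * mean |F_total - F_ref|^2`
#' over the energy-network weights.  The electrostatic energy (screened
#' kernel) and its forces are constants of the fit; the force-term
#' gradient includes every chain-rule path of [forces()], in particular
#' the mixed second derivatives through the charge input of 4G energy
#' networks.  Per-element energy shifts are set beforehand by least
#' squares on the training energies.  Stage 2 never touches the charge
#' networks or the hardness.
#'
#' @param model a [potential_model()]; for 3G/4G the charge stage should
#'   have been fitted first.
#' @param records training records with energies (and ideally forces).
#' @param config a [train_config()]; `w_F = 0` reduces to pure energy
#'   fitting.
#' @param val optional validation records.
#' @return list with `model` and `history` (per-epoch train energy RMSE
#'   in Ha/atom and force RMSE in Ha/Bohr; validation columns where
#'   tracked).
#' @export
fit_short_range_stage <- function(model, records, config = train_config(),
                                  val = NULL) {
  if (is.null(val)) {
    sp <- split_dataset(records, 1 - config$val_fraction, seed = config$seed)
    records <- sp$train; val <- sp$test
  }
  elements <- model$acsf$elements
  data <- .short_stage_data(model, records)
  for (el in elements) {
    if (is.null(model$energy_nets[[el]]$center) &&
        !is.null(data$Xel[[el]])) {
      model$energy_nets[[el]] <- net_set_scaling(model$energy_nets[[el]],
                                                 data$Xel[[el]])
    }
  }
  # per-element energy shifts from composition least squares
  sh <- qr.coef(qr(data$counts), data$e_ref - data$e_elec)
  sh[is.na(sh)] <- 0
  model$e_shift[elements] <- sh
  vdata <- .short_stage_data(model, val)

  lens <- vapply(elements, function(el)
    length(net_flatten(model$energy_nets[[el]])), 0L)
  unpack <- function(th) {
    pos <- 0L
    for (el in elements) {
      model$energy_nets[[el]] <<- net_unflatten(model$energy_nets[[el]],
                                                th[pos + seq_len(lens[[el]])])
      pos <- pos + lens[[el]]
    }
  }
  theta <- unlist(lapply(elements, function(el)
    net_flatten(model$energy_nets[[el]])), use.names = FALSE)
  hist <- NULL
  if (config$epochs == 0L) {
    return(list(model = model, history = hist))
  }
  if (config$optimizer == "lbfgs") {
    fn <- function(th) {
      unpack(th)
      .short_epoch(model, data, config, want_grad = FALSE)$loss
    }
    gr <- function(th) {
      unpack(th)
      res <- .short_epoch(model, data, config, want_grad = TRUE)
      hist <<- rbind(hist, data.frame(
        epoch = if (is.null(hist)) 1L else nrow(hist) + 1L,
        train_energy_rmse = res$rmse_e, train_force_rmse = res$rmse_f,
        val_energy_rmse = NA_real_, val_force_rmse = NA_real_))
      unlist(res$gnet[elements], use.names = FALSE)
    }
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$epochs, factr = 10, lmm = 25))
    unpack(opt$par)
    vres <- .short_epoch(model, vdata, config, want_grad = FALSE)
    if (!is.null(hist)) {
      hist[nrow(hist), c("val_energy_rmse", "val_force_rmse")] <-
        c(vres$rmse_e, vres$rmse_f)
    }
  } else {
    ad <- .adam_init(length(theta))
    best <- list(theta = theta, val = Inf, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      res <- .short_epoch(model, data, config, want_grad = TRUE)
      vres <- .short_epoch(model, vdata, config, want_grad = FALSE)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_energy_rmse = res$rmse_e,
        train_force_rmse = res$rmse_f,
        val_energy_rmse = vres$rmse_e, val_force_rmse = vres$rmse_f))
      if (vres$loss < best$val) best <- list(theta = theta, val = vres$loss,
                                             epoch = ep)
      if (ep - best$epoch >= config$patience) break
      grad <- unlist(res$gnet[elements], use.names = FALSE)
      stp <- .adam_step(ad, theta, grad, config$lr * config$lr_decay^ep)
      theta <- stp$theta; ad <- stp$state
      unpack(theta)
      if (config$verbose && ep %% 50 == 0) {
        message(sprintf(
          "short-range epoch %d: E %.3e Ha/atom, F %.3e Ha/Bohr (val %.3e/%.3e)",
          ep, res$rmse_e, res$rmse_f, vres$rmse_e, vres$rmse_f))
      }
    }
    unpack(best$theta)
  }
  list(model = model, history = hist)
}

#' Error metrics of a model on a dataset
#'
#' Energy errors in meV/atom, force errors in eV/Angstrom, charge errors
#' in 1e-3 e; both RMSE and MAE are always reported (conventions differ
#' on which "mean error" means).
#'
#' @param model a [potential_model()].
#' @param records list of [reference_record()].
#' @return list with fields `energy_rmse`, `energy_mae` (meV/atom),
#'   `force_rmse`, `force_mae` (eV/A), `charge_rmse`, `charge_mae`
#'   (1e-3 e; `NA` when not applicable) and `n_records`.
#' @export
evaluate_model <- function(model, records) {
  if (!length(records)) stop("empty record list")
  dE <- c(); dF <- c(); dQ <- c()
  has_q <- model$generation != "2G"
  for (rec in records) {
    need_f <- !is.null(rec$forces)
    ev <- .eval_potential(model, rec$structure, need_forces = need_f)
    if (!is.null(rec$energy)) {
      dE <- c(dE, (ev$energy - rec$energy) / rec$structure$n_atoms)
    }
    if (need_f) dF <- c(dF, as.vector(ev$forces - rec$forces))
    if (has_q && !is.null(rec$charges)) dQ <- c(dQ, ev$charges - rec$charges)
  }
  ev2mev <- units_au$hartree_ev * 1000
  f2eva <- units_au$ha_bohr_ev_ang
  list(
    energy_rmse = if (length(dE)) sqrt(mean(dE^2)) * ev2mev else NA_real_,
    energy_mae = if (length(dE)) mean(abs(dE)) * ev2mev else NA_real_,
    force_rmse = if (length(dF)) sqrt(mean(dF^2)) * f2eva else NA_real_,
    force_mae = if (length(dF)) mean(abs(dF)) * f2eva else NA_real_,
    charge_rmse = if (length(dQ)) sqrt(mean(dQ^2)) * 1000 else NA_real_,
    charge_mae = if (length(dQ)) mean(abs(dQ)) * 1000 else NA_real_,
    n_records = length(records))
}
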