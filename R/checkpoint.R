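#' Save a potential model checkpoint
#'
#' Versioned JSON container holding the generation tag, descriptor
#' definitions, per-element networks for every role (energy and, for
#' 3G/4G, charge/electronegativity), hardness and Gaussian widths,
#' screening radii, energy shifts and scaling constants.  Plain text, so
#' checkpoints diff and ship cleanly.
#'
#' @param model a [potential_model()].
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  ser_net <- function(np) list(sizes = np$sizes, theta = net_flatten(np),
                               center = np$center, scale = np$scale)
  acsf <- model$acsf
  obj <- list(
    format = "hdnnp-checkpoint",
    version = 1L,
    package_version = as.character(utils::packageVersion("hdnnp")),
    generation = model$generation,
    charge_mode = model$charge_mode,
    accuracy = model$accuracy,
    e_shift = as.list(model$e_shift),
    acsf = list(
      elements = acsf$elements,
      cutoff_ang = acsf$cutoff,
      sets = lapply(acsf$sets, function(s)
        list(radial = s$radial, angular = s$angular))),
    electro = if (is.null(model$electro)) NULL else list(
      elements = model$electro$elements,
      J = as.list(model$electro$J),
      sigma = as.list(model$electro$sigma)),
    screening = if (is.null(model$screening)) NULL else
      list(inner = model$screening$inner, outer = model$screening$outer),
    energy_nets = lapply(model$energy_nets, ser_net),
    charge_nets = lapply(model$charge_nets, ser_net))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a potential model checkpoint
#'
#' @param path checkpoint file written by [save_model()].
#' @return a [potential_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hdnnp-checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  de_net <- function(s) {
    sizes <- as.integer(s$sizes)
    np <- init_network(sizes[1], hidden = sizes[-c(1, length(sizes))], seed = 0)
    np <- net_unflatten(np, as.numeric(s$theta))
    if (!is.null(s$center)) {
      np$center <- as.numeric(s$center)
      np$scale <- as.numeric(s$scale)
    }
    np
  }
  sets <- lapply(obj$acsf$sets, function(s) {
    ang <- s$angular
    if (!is.null(ang) && !is.data.frame(ang)) ang <- as.data.frame(ang)
    list(radial = as.data.frame(s$radial), angular = ang)
  })
  acsf <- base::structure(
    list(elements = obj$acsf$elements, cutoff = obj$acsf$cutoff_ang,
         sets = sets),
    class = "acsf_params")
  electro <- if (is.null(obj$electro)) NULL else
    element_electro(obj$electro$elements,
                    hardness = unlist(obj$electro$J[obj$electro$elements]),
                    width = unlist(obj$electro$sigma[obj$electro$elements]))
  screening <- if (is.null(obj$screening)) NULL else
    screening_spec(obj$screening$inner, obj$screening$outer)
  model <- base::structure(
    list(generation = obj$generation, acsf = acsf, electro = electro,
         screening = screening,
         energy_nets = lapply(obj$energy_nets, de_net),
         charge_nets = if (length(obj$charge_nets))
           lapply(obj$charge_nets, de_net) else list(),
         charge_mode = obj$charge_mode,
         e_shift = unlist(obj$e_shift),
         accuracy = obj$accuracy),
    class = "potential_model")
  model
}
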