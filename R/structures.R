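#' Atomic structure
#'
#' Container for one atomic configuration: element symbols, Cartesian
#' coordinates in Angstrom, an optional periodic cell and the net charge
#' of the system.  The total charge is part of the structure because for
#' charge-equilibration potentials it is a physical input on the same
#' footing as the positions.
#'
#' @param species character vector of element symbols (length `n`).
#' @param positions numeric `n x 3` matrix of Cartesian coordinates (Angstrom).
#' @param cell optional `3 x 3` matrix of lattice vectors as rows (Angstrom).
#' @param pbc logical, length 1 or 3: periodic boundary flags.
#' @param total_charge net charge of the system (e).
#' @param info optional named list of free-form frame metadata (round-tripped
#'   through extended-XYZ comment lines).
#' @return An object of class `"atoms"` with fields `species`, `positions`,
#'   `cell`, `pbc`, `total_charge`, `n_atoms`, `info`.
#' @examples
#' a <- atoms(c("Na", "Cl"), rbind(c(0, 0, 0), c(2.4, 0, 0)), total_charge = 0)
#' a$n_atoms
#' @export
atoms <- function(species, positions, cell = NULL, pbc = FALSE,
                  total_charge = 0, info = list()) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3) {
    stop("positions must be an n x 3 matrix")
  }
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 1) stop("structure must contain at least one atom")
  species <- as.character(species)
  if (length(species) != n) stop("species and positions disagree on atom count")
  pbc <- rep_len(as.logical(pbc), 3L)
  if (any(pbc)) {
    if (is.null(cell)) stop("periodic structure requires a cell")
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3, 3))) stop("cell must be a 3 x 3 matrix")
    storage.mode(cell) <- "double"
    if (abs(det(cell)) < 1e-10) stop("cell is singular")
  } else if (!is.null(cell)) {
    cell <- as.matrix(cell)
    storage.mode(cell) <- "double"
  }
  if (!is.finite(total_charge)) stop("total_charge must be finite")
  structure(
    list(species = species, positions = positions, cell = cell, pbc = pbc,
         total_charge = as.numeric(total_charge), n_atoms = n, info = info),
    class = "atoms")
}

#' @export
print.atoms <- function(x, ...) {
  comp <- table(x$species)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(sprintf("<atoms %s, %d atoms, Q_tot = %+g e, %s>\n", formula,
              x$n_atoms, x$total_charge,
              if (any(x$pbc)) "periodic" else "non-periodic"))
  invisible(x)
}

#' Reference record
#'
#' One labelled sample: a structure plus (optionally) reference total
#' energy, per-atom forces and per-atom charges.  Internal energy unit is
#' Hartree and forces are Hartree/Bohr; [read_extxyz()]/[write_extxyz()]
#' convert from/to the eV and eV/Angstrom used in files.
#'
#' @param structure an [atoms()] object.
#' @param energy total reference energy (Hartree) or `NULL`.
#' @param forces `n x 3` matrix of reference forces (Hartree/Bohr) or `NULL`.
#' @param charges length-`n` vector of reference atomic charges (e) or `NULL`.
#' @return An object of class `"ref_record"`.
#' @export
reference_record <- function(structure, energy = NULL, forces = NULL,
                             charges = NULL) {
  stopifnot(inherits(structure, "atoms"))
  n <- structure$n_atoms
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == c(n, 3))) stop("forces must be n x 3")
  }
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n) stop("charges must have one entry per atom")
    if (abs(sum(charges) - structure$total_charge) > 1e-6) {
      warning(sprintf(
        "sum of charges (%.8f) deviates from total_charge (%.8f) by > 1e-6 e",
        sum(charges), structure$total_charge))
    }
  }
  if (!is.null(energy) && !is.finite(energy)) stop("energy must be finite")
  base::structure(
    list(structure = structure, energy = energy, forces = forces,
         charges = charges),
    class = "ref_record")
}

#' @export
print.ref_record <- function(x, ...) {
  cat("<ref_record ")
  print(x$structure)
  cat(sprintf("  energy: %s  forces: %s  charges: %s>\n",
              if (is.null(x$energy)) "-" else sprintf("%.6f Ha", x$energy),
              if (is.null(x$forces)) "-" else "yes",
              if (is.null(x$charges)) "-" else "yes"))
  invisible(x)
}

## ---------------------------------------------------------------------------
## extended XYZ

# Tokenize one extended-XYZ comment line into a named character vector.
# Values may be bare or double-quoted; quoted values may contain spaces.
.parse_kv_line <- function(line, lineno) {
  out <- character(0)
  rest <- trimws(line)
  pat <- '^([A-Za-z_][A-Za-z0-9_:-]*)=("([^"]*)"|\\S*)\\s*'
  while (nzchar(rest)) {
    m <- regexec(pat, rest)[[1]]
    if (m[1] == -1) stop(sprintf("malformed key=value pair on line %d", lineno))
    g <- regmatches(rest, regexec(pat, rest))[[1]]
    key <- g[2]
    val <- if (nzchar(g[4]) || grepl('^"', g[3])) g[4] else g[3]
    out[key] <- val
    rest <- substr(rest, attr(m, "match.length")[1] + 1L, nchar(rest))
    rest <- trimws(rest, which = "left")
  }
  out
}

.parse_properties <- function(spec) {
  toks <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(toks) %% 3 != 0) stop("malformed Properties string: ", spec)
  n <- length(toks) / 3
  data.frame(name = toks[3 * seq_len(n) - 2],
             type = toks[3 * seq_len(n) - 1],
             ncol = as.integer(toks[3 * seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Read an extended-XYZ file
#'
#' Parses one or more frames.  Recognized comment-line keys:
#' `Lattice="ax ay az bx by bz cx cy cz"` (Angstrom, row-major),
#' `Properties=species:S:1:pos:R:3[:forces:R:3][:charge:R:1]`,
#' `energy=<eV>`, `total_charge=<e>`, `pbc="T T T"`.  Any further keys
#' are kept in the structure's `info` list.  Energies and forces are
#' converted to Hartree and Hartree/Bohr on input.  A frame without a
#' `total_charge` key is assigned charge 0 with a warning.
#'
#' @param path file path.
#' @return list of [reference_record()] objects.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  records <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("expected atom count on line %d, got '%s'", ln, lines[ln]))
    }
    if (ln + 1L + nat > length(lines) + 1L ||
        ln + 1L > length(lines)) {
      stop(sprintf("frame starting on line %d truncated (%d atom lines expected)",
                   ln, nat))
    }
    kv <- .parse_kv_line(lines[ln + 1L], ln + 1L)
    props <- .parse_properties(
      if ("Properties" %in% names(kv)) kv[["Properties"]] else "species:S:1:pos:R:3")
    atom_lines <- lines[(ln + 2L):(ln + 1L + nat)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    nfield <- sum(props$ncol)
    bad <- which(lengths(fields) != nfield)
    if (length(bad)) {
      stop(sprintf("line %d: expected %d columns, found %d",
                   ln + 1L + bad[1], nfield, lengths(fields)[bad[1]]))
    }
    tab <- do.call(rbind, fields)
    col <- 1L
    cols <- list()
    for (k in seq_len(nrow(props))) {
      idx <- col:(col + props$ncol[k] - 1L)
      cols[[props$name[k]]] <-
        if (props$type[k] == "S") tab[, idx, drop = FALSE]
        else {
          m <- suppressWarnings(matrix(as.numeric(tab[, idx]), nrow = nat))
          if (anyNA(m)) stop(sprintf(
            "non-numeric value in field '%s' of frame starting line %d",
            props$name[k], ln))
          m
        }
      col <- col + props$ncol[k]
    }
    if (is.null(cols$species) || is.null(cols$pos)) {
      stop("frame must provide species and pos columns (line ", ln, ")")
    }
    cell <- NULL; pbc <- FALSE
    if ("Lattice" %in% names(kv)) {
      v <- as.numeric(strsplit(trimws(kv[["Lattice"]]), "\\s+")[[1]])
      if (length(v) != 9) stop("Lattice must contain 9 numbers (line ", ln + 1L, ")")
      cell <- matrix(v, nrow = 3, byrow = TRUE)
      pbc <- TRUE
    }
    if ("pbc" %in% names(kv)) {
      pbc <- toupper(strsplit(trimws(kv[["pbc"]]), "\\s+")[[1]]) %in% c("T", "TRUE")
    }
    if ("total_charge" %in% names(kv)) {
      qtot <- as.numeric(kv[["total_charge"]])
    } else {
      warning(sprintf("frame on line %d has no total_charge; assuming 0", ln))
      qtot <- 0
    }
    reserved <- c("Lattice", "Properties", "energy", "total_charge", "pbc")
    info <- as.list(kv[setdiff(names(kv), reserved)])
    st <- atoms(species = as.character(cols$species), positions = cols$pos,
                cell = cell, pbc = pbc, total_charge = qtot, info = info)
    rec <- reference_record(
      st,
      energy = if ("energy" %in% names(kv))
        as.numeric(kv[["energy"]]) / units_au$hartree_ev else NULL,
      forces = if (!is.null(cols$forces))
        cols$forces / units_au$ha_bohr_ev_ang else NULL,
      charges = if (!is.null(cols$charge)) drop(cols$charge) else NULL)
    records[[length(records) + 1L]] <- rec
    ln <- ln + 2L + nat
  }
  if (!length(records)) stop("no frames found in ", path)
  records
}

.fmt <- function(x) sprintf("%.12g", x)

#' Write an extended-XYZ file
#'
#' Inverse of [read_extxyz()]; numbers are printed with 12 significant
#' digits so a read/write round trip is lossless to that precision.
#' Energies/forces are written in eV and eV/Angstrom.
#'
#' @param records list of [reference_record()] (or [atoms()]) objects.
#' @param path output file path.
#' @export
write_extxyz <- function(records, path) {
  if (inherits(records, "ref_record") || inherits(records, "atoms")) {
    records <- list(records)
  }
  if (!length(records)) stop("records must be non-empty")
  out <- character(0)
  for (rec in records) {
    if (inherits(rec, "atoms")) rec <- reference_record(rec)
    st <- rec$structure
    props <- "species:S:1:pos:R:3"
    if (!is.null(rec$forces)) props <- paste0(props, ":forces:R:3")
    if (!is.null(rec$charges)) props <- paste0(props, ":charge:R:1")
    kv <- character(0)
    if (any(st$pbc)) {
      kv <- c(kv, sprintf('Lattice="%s"', paste(.fmt(t(st$cell)), collapse = " ")),
              sprintf('pbc="%s"', paste(ifelse(st$pbc, "T", "F"), collapse = " ")))
    }
    kv <- c(kv, sprintf("Properties=%s", props),
            sprintf("total_charge=%s", .fmt(st$total_charge)))
    if (!is.null(rec$energy)) {
      kv <- c(kv, sprintf("energy=%s", .fmt(rec$energy * units_au$hartree_ev)))
    }
    for (key in names(st$info)) {
      val <- as.character(st$info[[key]])
      if (grepl("\\s", val)) val <- sprintf('"%s"', val)
      kv <- c(kv, sprintf("%s=%s", key, val))
    }
    body <- st$species
    body <- paste(body, apply(st$positions, 1, function(p)
      paste(.fmt(p), collapse = " ")))
    if (!is.null(rec$forces)) {
      fv <- rec$forces * units_au$ha_bohr_ev_ang
      body <- paste(body, apply(fv, 1, function(p) paste(.fmt(p), collapse = " ")))
    }
    if (!is.null(rec$charges)) body <- paste(body, .fmt(rec$charges))
    out <- c(out, as.character(st$n_atoms), paste(kv, collapse = " "), body)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## neighbor lists

# Perpendicular widths of the cell: distance between opposite faces.
.cell_widths <- function(cell) {
  v <- abs(det(cell))
  areas <- c(sqrt(sum(.cross3(cell[2, ], cell[3, ])^2)),
             sqrt(sum(.cross3(cell[3, ], cell[1, ])^2)),
             sqrt(sum(.cross3(cell[1, ], cell[2, ])^2)))
  v / areas
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a neighbor list
#'
#' All pairs with distance `0 < r <= cutoff`, including periodic images
#' (the cutoff may exceed the cell size; integer image bounds are derived
#' from the cell's perpendicular widths).  Each pair is stored once:
#' same-image pairs with `i < j` and shift `(0,0,0)`; image pairs with the
#' explicit integer shift, keeping the representative whose first nonzero
#' shift component is positive.  Consumers symmetrize.  The displacement
#' convention is `vec = positions[j,] + shift %*% cell - positions[i,]`.
#'
#' @param structure an [atoms()] object.
#' @param cutoff cutoff radius (Angstrom).
#' @return object of class `"neighbor_list"`: list with integer vectors
#'   `i`, `j`, integer matrix `shift`, numeric `r` (Angstrom), matrix
#'   `vec`, and `cutoff`.
#' @export
neighbor_list <- function(structure, cutoff) {
  stopifnot(inherits(structure, "atoms"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  pos <- structure$positions
  n <- structure$n_atoms
  periodic <- any(structure$pbc)
  empty <- list(i = integer(0), j = integer(0),
                shift = matrix(0L, 0, 3), r = numeric(0),
                vec = matrix(0, 0, 3), cutoff = cutoff)
  if (!periodic) {
    if (n < 2) return(base::structure(empty, class = "neighbor_list"))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    vec <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    r <- sqrt(rowSums(vec^2))
    keep <- r <= cutoff
    if (any(r[keep] < 1e-10)) stop("coincident atoms in structure")
    out <- list(i = i[keep], j = j[keep],
                shift = matrix(0L, sum(keep), 3), r = r[keep],
                vec = vec[keep, , drop = FALSE], cutoff = cutoff)
    return(base::structure(out, class = "neighbor_list"))
  }
  cell <- structure$cell
  if (abs(det(cell)) < 1e-10) stop("cell is singular")
  w <- .cell_widths(cell)
  mmax <- ifelse(structure$pbc, floor(cutoff / w + 0.5) + 1L, 0L)
  grid <- as.matrix(expand.grid(a = -mmax[1]:mmax[1], b = -mmax[2]:mmax[2],
                                c = -mmax[3]:mmax[3]))
  # all ordered pairs (i <= j); for each, wrap the base displacement and
  # scan candidate integer shifts
  res_i <- integer(0); res_j <- integer(0); res_s <- NULL
  res_r <- numeric(0); res_v <- NULL
  inv_cell <- solve(cell)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dr <- pos[j, ] - pos[i, ]
      f0 <- round((dr %*% inv_cell)[1, ] * structure$pbc)
      shifts <- sweep(grid, 2, f0, "-")
      disp <- matrix(dr, nrow(grid), 3, byrow = TRUE) + shifts %*% cell
      r <- sqrt(rowSums(disp^2))
      keep <- r <= cutoff & r > 0
      if (i == j) {
        # self-image pairs: keep canonical half (first nonzero shift > 0)
        s <- shifts
        canon <- (s[, 1] > 0) | (s[, 1] == 0 & s[, 2] > 0) |
          (s[, 1] == 0 & s[, 2] == 0 & s[, 3] > 0)
        keep <- keep & canon
      } else if (any(r[keep] < 1e-10)) {
        stop("coincident atoms (possibly via periodic image)")
      }
      if (any(keep)) {
        nk <- sum(keep)
        res_i <- c(res_i, rep.int(i, nk)); res_j <- c(res_j, rep.int(j, nk))
        res_s <- rbind(res_s, shifts[keep, , drop = FALSE])
        res_r <- c(res_r, r[keep])
        res_v <- rbind(res_v, disp[keep, , drop = FALSE])
      }
    }
  }
  if (is.null(res_s)) return(base::structure(empty, class = "neighbor_list"))
  storage.mode(res_s) <- "integer"
  base::structure(list(i = res_i, j = res_j, shift = res_s, r = res_r,
                 vec = res_v, cutoff = cutoff),
            class = "neighbor_list")
}

#' Randomly displace a structure
#'
#' Adds independent Gaussian noise of standard deviation `sigma` to every
#' Cartesian coordinate (the sampling protocol used to generate reference
#' data around template geometries).  Cell, species and total charge are
#' unchanged; deterministic for a given seed.
#'
#' @param structure an [atoms()] object.
#' @param sigma displacement standard deviation (Angstrom), `>= 0`.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return a new [atoms()] object.
#' @export
perturb_structure <- function(structure, sigma, seed = NULL) {
  stopifnot(inherits(structure, "atoms"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  disp <- matrix(stats::rnorm(3 * structure$n_atoms, sd = sigma),
                 ncol = 3)
  out <- structure
  out$positions <- structure$positions + disp
  out
}
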