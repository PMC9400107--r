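# Applying a bank to a structure: transfer averaged parameters to matched
# atoms (the TAAM step), evaluate model densities on grids, and read/write
# per-atom instance parameter files for bank building.

#' Build a pseudoatom model from a structure and a bank
#'
#' Assigns atom types, builds each matched atom's local frame from its
#' entry's frame definition, and attaches the entry's mean multipole
#' parameters and the bank's radial settings.  Unmatched atoms are kept as
#' neutral spherical atoms (their element defaults) when
#' `neutral_unassigned` is `TRUE`, otherwise an error is raised.
#'
#' @param structure A `molecular_structure`.
#' @param bank A `bank` object.
#' @param a Cubic cell edge for scattering (default from the structure's
#'   cell, else the bounding box plus 10 Angstrom).
#' @param neutral_unassigned Keep unmatched atoms as neutral spherical
#'   atoms instead of failing.
#' @return A [pseudoatom_model()]; the assignment is attached as attribute
#'   `assignment`.
#' @export
apply_bank <- function(structure, bank, a = NULL,
                       neutral_unassigned = TRUE) {
  if (is.null(structure$bonds)) structure <- build_connectivity(structure)
  if (is.null(structure$rings)) structure <- perceive_rings(structure)
  as_ <- assign_types(structure, bank)
  if (is.null(a)) {
    a <- if (!is.null(structure$cell)) structure$cell[1L]
         else max(apply(structure$xyz, 2L, function(x) diff(range(x)))) + 10
  }
  entries <- stats::setNames(bank$entries,
                             vapply(bank$entries, `[[`, "", "type_id"))
  sites <- vector("list", length(structure$z))
  for (k in seq_along(as_$atom)) {
    i <- as_$atom[k]
    tid <- as_$type_id[k]
    z <- structure$z[i]
    if (is.na(tid)) {
      if (!neutral_unassigned)
        stop("atom ", structure$labels[i], " has no matching atom type")
      lm <- if (z == 1L) 2L else 4L
      sites[[i]] <- list(
        params = multipole_parameters(n_valence(z), 1, 1, plm_zero(lm),
                                      l_max = lm),
        frame = local_frame(origin = structure$xyz[i, ]),
        symmetry = "no")
      next
    }
    e <- entries[[tid]]
    fr <- build_frame(structure, i, e$frame, as_$mappings[[k]])
    rad <- bank$radial[[element_symbol(z)]]
    p <- e$params
    plm <- p$plm_mean
    attr(plm, "l_max") <- p$l_max
    sites[[i]] <- list(
      params = multipole_parameters(p$p_val[1L], p$kappa[1L],
                                    p$kappa_prime[1L], plm,
                                    l_max = p$l_max),
      frame = fr,
      radial = if (!is.null(rad)) radial_model(z, n_l = rad$n_l,
                                               zeta = rad$zeta),
      sph = if (!is.null(rad))
        spherical_atom_density(z, valence_shell = list(n_pow = rad$val_n,
                                                       zeta = rad$val_zeta)),
      symmetry = e$symmetry)
  }
  # shared kappa for atoms assigned the same hydrogen type
  groups <- seq_along(sites)
  htypes <- unique(stats::na.omit(as_$type_id[structure$z[as_$atom] == 1L]))
  for (t in htypes) {
    idx <- as_$atom[!is.na(as_$type_id) & as_$type_id == t]
    groups[idx] <- idx[1L]
  }
  model <- pseudoatom_model(structure, a = a, sites = sites,
                            kappa_groups = match(groups, unique(groups)))
  attr(model, "assignment") <- as_
  model
}

#' Total model electron density on a regular grid
#'
#' @param model A [pseudoatom_model()].
#' @param step Grid step in Angstrom.
#' @param margin Padding around the structure's bounding box (Angstrom).
#' @param include_core Include the frozen-core densities.
#' @return List with `origin`, `step`, `dims` and `values` (3d array,
#'   e/Angstrom^3).
#' @export
density_grid <- function(model, step = 0.2, margin = 2,
                         include_core = TRUE) {
  xyz <- model$structure$xyz
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / step)) + 1L)
  gx <- lo[1] + (seq_len(dims[1]) - 1) * step
  gy <- lo[2] + (seq_len(dims[2]) - 1) * step
  gz <- lo[3] + (seq_len(dims[3]) - 1) * step
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rho <- numeric(nrow(pts))
  for (s in model$sites)
    rho <- rho + hc_density(s$params, s$sph, s$radial, s$frame, pts,
                            include_core = include_core)
  list(origin = lo, step = step, dims = dims,
       values = array(rho, dim = dims))
}

#' Write a density grid in Gaussian cube format
#'
#' @param grid Result of [density_grid()].
#' @param model The model (atom records of the cube header).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, model, path) {
  z <- model$structure$z
  xyz <- model$structure$xyz / BOHR
  stepb <- grid$step / BOHR
  lines <- c("taamkit model density",
             "cube: outer loop x, middle y, inner z",
             sprintf("%5d %11.6f %11.6f %11.6f", length(z),
                     grid$origin[1] / BOHR, grid$origin[2] / BOHR,
                     grid$origin[3] / BOHR),
             sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[1], stepb, 0, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[2], 0, stepb, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[3], 0, 0, stepb),
             sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  # cube order: x outer, y middle, z inner, 6 values per line
  nz <- grid$dims[3]
  out <- character(0)
  for (ix in seq_len(grid$dims[1])) for (iy in seq_len(grid$dims[2])) {
    row <- grid$values[ix, iy, ]
    row <- row * BOHR^3
    for (k in seq(1L, nz, by = 6L))
      out <- c(out, paste(sprintf("%13.5e", row[k:min(k + 5L, nz)]),
                          collapse = " "))
  }
  writeLines(out, con)
  invisible(path)
}

# --- instance parameter files ----------------------------------------------

#' Write per-atom instance parameters (bank-builder input)
#'
#' One block per refined atom: source identifiers, matched type, the local
#' frame used during refinement, and the single-atom parameter values.
#'
#' @param instances List of `parameter_instance` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  out <- character(0)
  for (ins in instances) {
    p <- ins$params
    out <- c(out,
             paste("INSTANCE", ins$source, "TYPE", ins$type_id),
             paste("FRAME", paste(sprintf("%.17g", ins$frame$rotation),
                                  collapse = " ")),
             paste("PVAL", sprintf("%.6f", p$p_val)),
             paste("KAPPA", sprintf("%.6f", p$kappa)),
             paste("KPRIME", sprintf("%.6f", p$kappa_prime)))
    if (p$l_max != 4L) out <- c(out, paste("LMAX", p$l_max))
    idx <- plm_indices(p$l_max)
    for (i in seq_len(nrow(idx))) {
      v <- plm_get(p$plm, idx[i, "l"], idx[i, "m"])
      if (v != 0)
        out <- c(out, paste("PLM", idx[i, "l"], idx[i, "m"],
                            sprintf("%.6f", v)))
    }
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read per-atom instance parameters
#'
#' @param path File written by [write_instances()].
#' @return List of `parameter_instance` objects.
#' @export
read_instances <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(ln)) next
    t <- strsplit(ln, "\\s+")[[1L]]
    switch(toupper(t[1L]),
      INSTANCE = {
        cur <- list(source = t[2L], type_id = t[4L], plm = plm_zero(),
                    l_max = 4L, frame = local_frame())
      },
      FRAME = { cur$frame <- local_frame(rotation = matrix(
        as.numeric(t[-1L]), 3L, 3L)) },
      PVAL = { cur$p_val <- as.numeric(t[2L]) },
      KAPPA = { cur$kappa <- as.numeric(t[2L]) },
      KPRIME = { cur$kappa_prime <- as.numeric(t[2L]) },
      LMAX = { cur$l_max <- as.integer(t[2L]) },
      PLM = { cur$plm <- plm_set(cur$plm, as.integer(t[2L]),
                                 as.integer(t[3L]), as.numeric(t[4L])) },
      END = {
        attr(cur$plm, "l_max") <- cur$l_max
        out[[length(out) + 1L]] <- structure(
          list(source = cur$source, type_id = cur$type_id,
               params = multipole_parameters(cur$p_val, cur$kappa,
                                             cur$kappa_prime, cur$plm,
                                             l_max = cur$l_max),
               frame = cur$frame),
          class = "parameter_instance")
        cur <- NULL
      },
      stop("bad instance record: ", ln))
  }
  out
}

#' Build a bank from instance parameters and type definitions
#'
#' Groups instances by matched type, reorients each into the type frame,
#' averages, applies the symmetry selection rules and reports the
#' transferability verdicts.
#'
#' @param instances List of `parameter_instance` objects.
#' @param definitions A `bank` whose entries define the target types
#'   (their parameter blocks are replaced by the averages).
#' @param thresholds From [quality_thresholds()].
#' @return List with `bank` (averaged) and `report` (data frame `type_id`,
#'   `n`, `pass`, `n_violations`).
#' @export
build_bank <- function(instances, definitions,
                       thresholds = quality_thresholds()) {
  ids <- vapply(instances, `[[`, "", "type_id")
  entries <- list()
  rep_rows <- list()
  for (e in definitions$entries) {
    ins <- instances[ids == e$type_id]
    if (!length(ins)) { entries[[length(entries) + 1L]] <- e; next }
    avg <- average_type(ins, e)
    qc <- quality_check(avg, thresholds)
    entries[[length(entries) + 1L]] <- avg
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(type_id = e$type_id, n = length(ins), pass = qc$pass,
                 n_violations = nrow(qc$violations))
  }
  list(bank = bank(entries, radial = definitions$radial,
                   version = definitions$version),
       report = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame(type_id = character(0), n = integer(0),
                                pass = logical(0),
                                n_violations = integer(0)))
}
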