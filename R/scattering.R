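# Valence-only structure factors of a pseudoatom model on the theoretical
# P1 grid: reflection generation, aspherical atomic form factors, and the
# Fourier summation over atoms.

#' Generate the theoretical reflection grid
#'
#' All integer reflections of a cubic P1 cell with
#' `0 < sin(theta)/lambda < s_max`, in lexicographic (h, k, l) order.  The
#' convention is `sin(theta)/lambda = |h*| / 2` with
#' `|h*| = sqrt(h^2+k^2+l^2) / a`.
#'
#' @param a Cubic cell edge in Angstrom (default 30).
#' @param s_max Resolution cutoff in Angstrom^-1 (default 1.1).
#' @return A `reflection_set`: list with `a`, `hkl` (n x 3 integer matrix),
#'   `s` (per-reflection sin(theta)/lambda), `H` (`= 2 s`), `s_max`, and
#'   unique-value lookups `H_unique` / `H_idx` for radial caching.
#' @export
generate_reflections <- function(a = 30, s_max = 1.1) {
  stopifnot(a > 0, s_max > 0)
  hmax <- floor(2 * a * s_max)
  rng <- -hmax:hmax
  hkl <- as.matrix(expand.grid(l = rng, k = rng, h = rng))[, 3:1]
  n2 <- rowSums(hkl^2)
  keep <- n2 > 0 & sqrt(n2) / (2 * a) < s_max
  hkl <- hkl[keep, , drop = FALSE]
  n2 <- n2[keep]
  ord <- order(hkl[, 1L], hkl[, 2L], hkl[, 3L])
  hkl <- hkl[ord, , drop = FALSE]
  n2 <- n2[ord]
  dimnames(hkl) <- list(NULL, c("h", "k", "l"))
  u2 <- sort(unique(n2))
  structure(list(a = a, hkl = hkl, s = sqrt(n2) / (2 * a),
                 H = sqrt(n2) / a, s_max = s_max,
                 H_unique = sqrt(u2) / a, H_idx = match(n2, u2)),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat("<reflection_set>", nrow(x$hkl), "reflections, a =", x$a,
      "Angstrom, sin(theta)/lambda <", x$s_max, "Angstrom^-1\n")
  invisible(x)
}

#' Aspherical (valence-only) atomic form factor
#'
#' Fourier transform of the pseudoatom valence density:
#' `f(h) = P_val f_val(H / kappa) + sum_l i^l 4 pi <j_l>(H; kappa')
#' sum_m P_lm d_lm(h_unit)`, with the direction taken in the atom's local
#' frame.  The frozen core is excluded (add [core_form_factor()] for full
#' scattering).
#'
#' @param params A [multipole_parameters()] object.
#' @param radial A [radial_model()].
#' @param sph A [spherical_atom_density()].
#' @param s_vector Reciprocal vector(s), `n x 3` Cartesian Angstrom^-1
#'   with length `|h*| = 2 sin(theta)/lambda`, expressed in the atom's
#'   local frame.
#' @return Complex vector of form-factor values (electrons).
#' @export
atomic_form_factor <- function(params, radial, sph, s_vector) {
  if (!is.matrix(s_vector)) s_vector <- matrix(s_vector, ncol = 3L)
  H <- sqrt(rowSums(s_vector^2))
  u <- s_vector
  pos <- H > 0
  u[pos, ] <- u[pos, , drop = FALSE] / H[pos]
  if (any(!pos)) u[!pos, ] <- matrix(c(0, 0, 1), sum(!pos), 3L,
                                     byrow = TRUE)
  f <- complex(real = params$p_val *
                 valence_form_factor(sph, H, params$kappa),
               imaginary = numeric(length(H)))
  for (l in 0:params$l_max) {
    pl <- params$plm[l + 1L, (5L - l):(5L + l)]
    if (all(pl == 0)) next
    ang <- numeric(length(H))
    for (m in seq.int(-l, l)) {
      p <- unname(pl[m + l + 1L])
      if (p != 0) ang <- ang + p * real_spherical_harmonic(l, m, u)
    }
    jl <- slater_jl(l, H, radial, params$kappa_prime)
    f <- f + (1i)^l * 4 * pi * jl * ang
  }
  f
}

#' Assemble a pseudoatom model for scattering
#'
#' @param structure A `molecular_structure` placed inside a cubic cell.
#' @param a Cubic cell edge (Angstrom); taken from `structure$cell` when
#'   present.
#' @param sites List with one entry per atom:
#'   `list(params, frame, radial, sph, symmetry)`; `frame` defaults to the
#'   identity frame at the atom position, `radial`/`sph` to the element
#'   defaults, `symmetry` to `"no"`.
#' @param kappa_groups,kappa_prime_groups Integer vectors (length = atom
#'   count) labelling atoms that share a common `kappa` / `kappa'`
#'   (chemically equivalent hydrogens, typically).  Defaults: every atom
#'   its own group.
#' @return A `pseudoatom_model`.
#' @export
pseudoatom_model <- function(structure, a = NULL, sites,
                             kappa_groups = NULL,
                             kappa_prime_groups = NULL) {
  n <- length(structure$z)
  if (is.null(a)) {
    if (is.null(structure$cell)) stop("no cell edge given")
    a <- structure$cell[1L]
  }
  stopifnot(length(sites) == n)
  for (i in seq_len(n)) {
    s <- sites[[i]]
    if (is.null(s$frame))
      s$frame <- local_frame(origin = structure$xyz[i, ])
    if (is.null(s$radial)) s$radial <- radial_model(structure$z[i])
    if (is.null(s$sph)) s$sph <- spherical_atom_density(structure$z[i])
    if (is.null(s$symmetry)) s$symmetry <- "no"
    sites[[i]] <- s
  }
  if (is.null(kappa_groups)) kappa_groups <- seq_len(n)
  if (is.null(kappa_prime_groups)) kappa_prime_groups <- kappa_groups
  # shared-kappa groups must agree on the stored values
  for (g in unique(kappa_groups)) {
    idx <- which(kappa_groups == g)
    k <- vapply(sites[idx], function(s) s$params$kappa, 0)
    if (max(k) - min(k) > 1e-12)
      stop("atoms in kappa group ", g, " carry different kappa values")
  }
  structure(list(structure = structure, a = a, sites = sites,
                 kappa_groups = as.integer(kappa_groups),
                 kappa_prime_groups = as.integer(kappa_prime_groups)),
            class = "pseudoatom_model")
}

# Per-atom precomputation shared by structure factors and refinement:
# phases, local-frame reflection directions, d_lm value matrices.
.sf_precompute <- function(model, refl) {
  n <- length(model$structure$z)
  xf <- model$structure$xyz / model$a
  svec <- refl$hkl / model$a          # Cartesian reciprocal vectors (cubic)
  H <- refl$H
  pos <- H > 0
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    s <- model$sites[[i]]
    phase <- exp(2i * pi * drop(refl$hkl %*% xf[i, ]))
    ul <- svec %*% s$frame$rotation
    ul[pos, ] <- ul[pos, , drop = FALSE] / H[pos]
    if (any(!pos)) ul[!pos, ] <- matrix(c(0, 0, 1), sum(!pos), 3L,
                                        byrow = TRUE)
    lmax <- s$params$l_max
    dvals <- list()
    for (l in 0:lmax)
      dvals[[l + 1L]] <- dlm_basis(l, ul)
    pre[[i]] <- list(phase = phase, dvals = dvals)
  }
  pre
}

# Valence-only form-factor contribution of atom i on the reflection set,
# using precomputed angular values; returns complex vector.
.sf_atom_f <- function(model, refl, pre, i) {
  s <- model$sites[[i]]
  p <- s$params
  fu <- valence_form_factor(s$sph, refl$H_unique, p$kappa)
  f <- complex(real = p$p_val * fu[refl$H_idx],
               imaginary = numeric(length(refl$H)))
  for (l in 0:p$l_max) {
    pl <- p$plm[l + 1L, (5L - l):(5L + l)]
    if (all(pl == 0)) next
    ang <- drop(pre[[i]]$dvals[[l + 1L]] %*% pl)
    jl <- slater_jl(l, refl$H_unique, s$radial, p$kappa_prime)[refl$H_idx]
    f <- f + (1i)^l * 4 * pi * jl * ang
  }
  f
}

#' Valence-only structure factors of a pseudoatom model
#'
#' `F(h) = sum_atoms f_atom(h) exp(2 pi i h . x_frac)` for a static model
#' (no thermal motion, occupancies 1); each atom's form factor is evaluated
#' with the reflection direction rotated into its local frame.
#'
#' @param model A [pseudoatom_model()].
#' @param refl A [generate_reflections()] set (same cell edge).
#' @return Complex vector, one structure factor per reflection.
#' @export
structure_factors <- function(model, refl) {
  if (abs(model$a - refl$a) > 1e-9)
    stop("model and reflection set disagree on the cell edge")
  pre <- .sf_precompute(model, refl)
  FF <- complex(real = numeric(nrow(refl$hkl)))
  for (i in seq_along(model$sites))
    FF <- FF + .sf_atom_f(model, refl, pre, i) * pre[[i]]$phase
  FF
}
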