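# Real spherical harmonics in the density-normalized (pseudoatom) convention,
# rotation of multipole populations, and point-group selection rules.

# Multipliers converting unit-normalized real spherical harmonics Y_lm to the
# density-normalized functions d_lm used by pseudoatom models:
#   d_00 = 1/(4*pi)            (integrates to 1 over the sphere)
#   int |d_lm| dOmega = 2      (l >= 1; one electron moved from lobe to lobe
#                               per unit population)
# Frozen from one-off adaptive quadrature of int |Y_lm| dOmega.
.dlm_norm <- c(
  "0_0" = 0.282094791773878,
  "1_0" = 0.651470015870560, "1_1" = 0.651470015870560,
  "2_0" = 0.655529058355247, "2_1" = 0.686468424647827,
  "2_2" = 0.686468424647827,
  "3_0" = 0.656134211147438, "3_1" = 0.700877439327093,
  "3_2" = 0.691895136958641, "3_3" = 0.719291233434385,
  "4_0" = 0.656209911548885, "4_1" = 0.708474654616271,
  "4_2" = 0.698795568665500, "4_3" = 0.706162517109064,
  "4_4" = 0.748998456701370
)

# Unit-normalized real spherical harmonics as Cartesian polynomials on the
# unit sphere.  u is an n x 3 matrix of unit vectors; returns a length-n
# vector.  m >= 0 are cosine-type, m < 0 sine-type.
.ylm <- function(l, m, u) {
  x <- u[, 1L]; y <- u[, 2L]; z <- u[, 3L]
  key <- paste0(l, abs(m))
  switch(key,
    "00" = rep(sqrt(1 / (4 * pi)), nrow(u)),
    "10" = sqrt(3 / (4 * pi)) * z,
    "11" = sqrt(3 / (4 * pi)) * (if (m > 0) x else y),
    "20" = sqrt(5 / (16 * pi)) * (3 * z^2 - 1),
    "21" = sqrt(15 / (4 * pi)) * z * (if (m > 0) x else y),
    "22" = if (m > 0) 0.25 * sqrt(15 / pi) * (x^2 - y^2)
           else       0.50 * sqrt(15 / pi) * x * y,
    "30" = 0.25 * sqrt(7 / pi) * (5 * z^3 - 3 * z),
    "31" = 0.25 * sqrt(21 / (2 * pi)) * (5 * z^2 - 1) *
             (if (m > 0) x else y),
    "32" = if (m > 0) 0.25 * sqrt(105 / pi) * z * (x^2 - y^2)
           else       0.50 * sqrt(105 / pi) * z * x * y,
    "33" = 0.25 * sqrt(35 / (2 * pi)) *
             (if (m > 0) x * (x^2 - 3 * y^2) else y * (3 * x^2 - y^2)),
    "40" = (3 / 16) * sqrt(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
    "41" = 0.75 * sqrt(5 / (2 * pi)) * z * (7 * z^2 - 3) *
             (if (m > 0) x else y),
    "42" = if (m > 0) (3 / 8) * sqrt(5 / pi) * (7 * z^2 - 1) * (x^2 - y^2)
           else       0.75  * sqrt(5 / pi) * (7 * z^2 - 1) * x * y,
    "43" = 0.75 * sqrt(35 / (2 * pi)) * z *
             (if (m > 0) x * (x^2 - 3 * y^2) else y * (3 * x^2 - y^2)),
    "44" = if (m > 0) (3 / 16) * sqrt(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4)
           else       0.75  * sqrt(35 / pi) * x * y * (x^2 - y^2),
    stop("unsupported (l, m): (", l, ", ", m, ")")
  )
}

#' Density-normalized real spherical harmonic
#'
#' Evaluates the angular deformation function `d_lm` of the pseudoatom
#' (Hansen-Coppens) model.  The functions are density-normalized:
#' `d_00` integrates to 1 over the sphere and the absolute value of every
#' `d_lm` with `l >= 1` integrates to 2, so that a unit population moves one
#' electron from the negative to the positive lobe.  Functions with
#' `m >= 0` carry `cos(m*phi)`, those with `m < 0` carry `sin(|m|*phi)`.
#'
#' @param l Angular momentum quantum number, 0 to 4.
#' @param m Order, `-l` to `l` (sign selects sine/cosine type).
#' @param direction A unit 3-vector, or an `n x 3` matrix of unit vectors.
#' @return Numeric vector of function values, one per direction.
#' @examples
#' real_spherical_harmonic(0, 0, c(0, 0, 1))   # 1/(4*pi)
#' real_spherical_harmonic(1, 0, c(0, 0, 1))   # 1/pi
#' @export
real_spherical_harmonic <- function(l, m, direction) {
  if (!is.matrix(direction)) direction <- matrix(direction, ncol = 3L)
  if (abs(m) > l || l < 0L || l > 4L)
    stop("require |m| <= l <= 4, got l = ", l, ", m = ", m)
  nk <- .dlm_norm[[paste0(l, "_", abs(m))]]
  nk * .ylm(l, m, direction)
}

# n x (2l+1) matrix of d_lm values; columns ordered m = -l .. +l.
dlm_basis <- function(l, u) {
  ms <- seq.int(-l, l)
  vapply(ms, function(m) real_spherical_harmonic(l, m, u), numeric(nrow(u)))
}

# --- multipole population tables -------------------------------------------

#' Empty multipole population table
#'
#' Populations are stored as a 5 x 9 matrix: rows `l = 0..4`, columns
#' `m = -4..4`.  Entries with `|m| > l` are structurally zero.
#'
#' @param l_max Highest multipole order carried (4 for non-hydrogen
#'   pseudoatoms, 2 for hydrogen).
#' @return A zero matrix with dimnames `l0..l4` / `m-4..m4` and attribute
#'   `l_max`.
#' @export
plm_zero <- function(l_max = 4L) {
  m <- matrix(0, nrow = 5L, ncol = 9L,
              dimnames = list(paste0("l", 0:4), paste0("m", -4:4)))
  attr(m, "l_max") <- as.integer(l_max)
  m
}

#' Set one population on a `plm` table
#' @param plm Table from [plm_zero()].
#' @param l,m Multipole index.
#' @param value Population (electrons).
#' @return The updated table.
#' @export
plm_set <- function(plm, l, m, value) {
  plm[l + 1L, m + 5L] <- value
  plm
}

#' Read one population from a `plm` table
#' @inheritParams plm_set
#' @return The population value.
#' @export
plm_get <- function(plm, l, m) plm[l + 1L, m + 5L]

#' Valid multipole indices up to `l_max`
#' @param l_max Highest order.
#' @return Integer matrix with columns `l`, `m`.
#' @export
plm_indices <- function(l_max = 4L) {
  do.call(rbind, lapply(0:l_max, function(l)
    cbind(l = l, m = seq.int(-l, l))))
}

# --- rotation of populations -----------------------------------------------

# Fixed quasi-uniform sample directions (golden spiral); enough to make the
# per-l Gram systems well conditioned.
.dlm_dirs <- local({
  n <- 64L
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
})

.dlm_qr_cache <- new.env(parent = emptyenv())

.dlm_basis_qr <- function(l) {
  key <- as.character(l)
  if (is.null(.dlm_qr_cache[[key]]))
    .dlm_qr_cache[[key]] <- qr(dlm_basis(l, .dlm_dirs))
  .dlm_qr_cache[[key]]
}

# (2l+1) x (2l+1) matrix D with d_m(t(R) %*% u) = sum_k D[k, m] d_k(u).
# Valid for any orthogonal R (proper or improper); obtained by collocation
# on the fixed direction set, exact to solver precision because the d_lm
# span an invariant function space per l.
plm_rotation_block <- function(l, rotation) {
  if (l == 0L) return(matrix(1, 1L, 1L))
  b0 <- .dlm_basis_qr(l)
  b1 <- dlm_basis(l, .dlm_dirs %*% rotation)
  qr.coef(b0, b1)
}

#' Rotate multipole populations between local frames
#'
#' Returns populations `P'` such that the deformation density is unchanged:
#' `sum_m P'_lm d_lm(u) = sum_m P_lm d_lm(R^T u)` for every direction `u`.
#' Rotation mixes populations only within each `l` block.
#'
#' @param plm Population table from [plm_zero()].
#' @param rotation A proper (det +1) orthonormal 3 x 3 matrix.
#' @return Rotated population table of the same shape.
#' @export
rotate_plm <- function(plm, rotation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("improper rotation (det = -1); mirrors are handled by the ",
         "symmetry projector, not by population rotation")
  out <- plm
  for (l in 1:4) {
    idx <- (5L - l):(5L + l)
    p <- plm[l + 1L, idx]
    if (any(p != 0))
      out[l + 1L, idx] <- drop(plm_rotation_block(l, rotation) %*% p)
  }
  out
}

# --- point groups and selection rules --------------------------------------

.rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

# Close a generator set into a finite group of orthogonal matrices.
.group_closure <- function(generators, max_order = 200L) {
  elems <- list(diag(3))
  keyof <- function(M) paste(round(M, 8L), collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(keyof(diag(3)), TRUE, envir = seen)
  queue <- generators
  while (length(queue)) {
    g <- queue[[1L]]; queue <- queue[-1L]
    k <- keyof(g)
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    elems[[length(elems) + 1L]] <- g
    for (h in elems) {
      queue <- c(queue, list(g %*% h), list(h %*% g))
      if (length(elems) > max_order) stop("group closure did not terminate")
    }
  }
  elems
}

.sigma_xz <- diag(c(1, -1, 1))
.sigma_h  <- diag(c(1, 1, -1))

# Generators per supported point-group symbol, in the standard orientation
# of this package: principal axis along z, one mirror through the xz plane,
# cubic groups with 4/S4 axes along the Cartesian axes and the 3-fold along
# (1,1,1).  "cyl" is conical site symmetry (infinite rotation axis + vertical
# mirrors), "cylinf" the centrosymmetric cylinder; both are represented by a
# 16-fold proxy rotation, exact for l <= 4.
.point_group_generators <- function(symbol) {
  C2z <- .rot_axis(c(0, 0, 1), pi)
  C3z <- .rot_axis(c(0, 0, 1), 2 * pi / 3)
  C4z <- .rot_axis(c(0, 0, 1), pi / 2)
  C3d <- .rot_axis(c(1, 1, 1), 2 * pi / 3)
  C16 <- .rot_axis(c(0, 0, 1), 2 * pi / 16)
  switch(symbol,
    "no"   = list(),
    "m"    = list(.sigma_xz),
    "mm2"  = list(C2z, .sigma_xz),
    "3m"   = list(C3z, .sigma_xz),
    "-43m" = list(C4z %*% .sigma_h, C3d),
    "-62m" = list(C3z, .sigma_h, diag(c(1, -1, -1))),
    "m3m"  = list(C4z, C3d, -diag(3)),
    "cyl"    = list(C16, .sigma_xz),
    "cylinf" = list(C16, .sigma_xz, .sigma_h),
    stop("unknown point-group symbol: '", symbol, "'")
  )
}

#' Supported point-group symbols
#' @return Character vector of canonical symbols.
#' @export
point_group_symbols <- function() {
  c("no", "m", "mm2", "3m", "-43m", "-62m", "m3m", "cyl", "cylinf")
}

# Cache of group elements per symbol.
.pg_cache <- new.env(parent = emptyenv())
point_group_elements <- function(symbol) {
  if (is.null(.pg_cache[[symbol]]))
    .pg_cache[[symbol]] <- .group_closure(.point_group_generators(symbol))
  .pg_cache[[symbol]]
}

# Group-averaging projector for one l: average of the (possibly improper)
# representation matrices of all group elements in the d_lm basis.
symmetry_projector_block <- function(l, symbol) {
  ops <- point_group_elements(symbol)
  n <- 2L * l + 1L
  acc <- matrix(0, n, n)
  for (g in ops) acc <- acc + plm_rotation_block(l, g)
  acc / length(ops)
}

#' Symmetry-allowed multipole indices
#'
#' Computes which populations `P_lm` may be nonzero for a pseudoatom whose
#' local frame is oriented canonically for the given point group.  The set
#' is obtained from the group-averaging projector: an index is allowed when
#' `d_lm` has a nonzero projection onto the subspace invariant under every
#' group operation (mirrors and rotoinversions included).
#'
#' @param point_group Symbol from [point_group_symbols()]: `"no"`, `"m"`,
#'   `"mm2"`, `"3m"`, `"-43m"`, `"-62m"`, `"m3m"`, `"cyl"`, `"cylinf"`.
#' @param l_max Highest multipole order considered.
#' @return Integer matrix with columns `l`, `m`, one row per allowed index,
#'   ordered by `l` then `m`.
#' @export
allowed_indices <- function(point_group, l_max = 4L) {
  point_group <- normalize_point_group(point_group)
  rows <- list(c(l = 0L, m = 0L))   # d_00 is invariant under any group
  for (l in seq_len(l_max)) {
    P <- symmetry_projector_block(l, point_group)
    keep <- which(sqrt(colSums(P^2)) > 1e-8)
    for (k in keep)
      rows[[length(rows) + 1L]] <- c(l = l, m = k - l - 1L)
  }
  out <- do.call(rbind, rows)
  out[order(out[, "l"], out[, "m"]), , drop = FALSE]
}

#' Canonical point-group symbol
#'
#' Maps common spellings (including Unicode overbar forms like the
#' rotoinversion tetrahedral symbol) onto the canonical ASCII symbols used
#' throughout the package.
#'
#' @param symbol A point-group spelling.
#' @return Canonical symbol from [point_group_symbols()].
#' @export
normalize_point_group <- function(symbol) {
  s <- gsub("̅", "", symbol)      # combining overline
  s <- gsub("̄", "", s)           # combining macron
  s <- chartr("‾", "-", s)
  aliases <- c("4-3m" = "-43m", "43m" = "-43m", "6-2m" = "-62m",
               "62m" = "-62m", "1" = "no", "none" = "no",
               "cyl-inf" = "cylinf", "cyl8" = "cylinf")
  if (s %in% names(aliases)) s <- aliases[[s]]
  if (!s %in% point_group_symbols())
    stop("unknown point-group symbol: '", symbol, "'")
  s
}

#' Project a population table onto its symmetry-allowed components
#'
#' Applies the group-averaging projector of the given point group to every
#' `l` block; used when validating and averaging bank entries.
#'
#' @param plm Population table from [plm_zero()].
#' @param point_group Point-group symbol.
#' @param l_max Highest order retained (populations above it are zeroed).
#' @return The projected table.
#' @export
project_plm <- function(plm, point_group, l_max = attr(plm, "l_max") %||% 4L) {
  point_group <- normalize_point_group(point_group)
  out <- plm
  for (l in 1:4) {
    idx <- (5L - l):(5L + l)
    p <- plm[l + 1L, idx]
    if (l > l_max) { out[l + 1L, idx] <- 0; next }
    if (any(p != 0))
      out[l + 1L, idx] <- drop(symmetry_projector_block(l, point_group) %*% p)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
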