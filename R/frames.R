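# Per-atom local coordinate systems.  Multipole populations are expressed
# in a right-handed frame anchored to bonded neighbors; the frame definition
# travels with the atom-type entry.

#' Local frame specification
#'
#' Two named axes define the frame: the first points at its target (an atom
#' label, or the centroid of several labels written `avg(L1,L2)`), the
#' second is orthogonalized against the first, and the remaining axis
#' completes a right-handed triad.
#'
#' @param axis1_name,axis2_name Axis letters, distinct members of
#'   `c("X", "Y", "Z")`.
#' @param axis1_target,axis2_target Character vector of one or more labels;
#'   several labels mean "toward their centroid".
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(axis1_name, axis1_target, axis2_name, axis2_target) {
  axis1_name <- toupper(axis1_name); axis2_name <- toupper(axis2_name)
  stopifnot(axis1_name %in% c("X", "Y", "Z"),
            axis2_name %in% c("X", "Y", "Z"))
  if (axis1_name == axis2_name) stop("frame axes must be distinct")
  structure(list(axis1 = list(axis = axis1_name, target = axis1_target),
                 axis2 = list(axis = axis2_name, target = axis2_target)),
            class = "frame_spec")
}

.axis_index <- c(X = 1L, Y = 2L, Z = 3L)

# Direction from the central atom toward a target (centroid of labels).
.frame_target_dir <- function(structure, origin, target, mapping) {
  idx <- mapping[target]
  if (anyNA(idx)) stop("frame target label(s) not resolved: ",
                       paste(target[is.na(idx)], collapse = ", "))
  centroid <- colMeans(structure$xyz[idx, , drop = FALSE])
  v <- centroid - origin
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("frame target coincides with the central atom")
  v / nv
}

#' Build a local frame for one atom
#'
#' @param structure A `molecular_structure`.
#' @param atom Index of the central atom.
#' @param spec A [frame_spec()].
#' @param mapping Named integer vector resolving entry labels to atom
#'   indices in `structure`.
#' @return A `local_frame`: list with `origin` (Angstrom) and `rotation`
#'   (orthonormal 3 x 3, det +1, columns = local X, Y, Z in global
#'   coordinates).
#' @export
build_frame <- function(structure, atom, spec, mapping) {
  origin <- structure$xyz[atom, ]
  e1 <- .frame_target_dir(structure, origin, spec$axis1$target, mapping)
  v2 <- .frame_target_dir(structure, origin, spec$axis2$target, mapping)
  v2p <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(v2p^2))
  if (n2 < 1e-6) stop("degenerate frame: axis targets are collinear")
  e2 <- v2p / n2
  i1 <- .axis_index[[spec$axis1$axis]]
  i2 <- .axis_index[[spec$axis2$axis]]
  R <- matrix(0, 3L, 3L)
  R[, i1] <- e1
  R[, i2] <- e2
  i3 <- setdiff(1:3, c(i1, i2))
  # right-handed completion: X = Y x Z, Y = Z x X, Z = X x Y
  nxt <- function(i) (i %% 3L) + 1L
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  R[, i3] <- cross(R[, nxt(i3)], R[, nxt(nxt(i3))])
  structure(list(origin = origin, rotation = R), class = "local_frame")
}

#' Construct a local frame directly
#' @param origin Frame origin (Angstrom).
#' @param rotation Proper orthonormal 3 x 3 matrix (columns = local X, Y,
#'   Z axes in global coordinates).
#' @return A `local_frame` object.
#' @export
local_frame <- function(origin = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-10,
            abs(det(rotation) - 1) < 1e-10)
  structure(list(origin = origin, rotation = rotation),
            class = "local_frame")
}
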