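# Molecular structures: atoms with Cartesian coordinates (Angstrom),
# optional unit cell, covalent bonds, asymmetric-unit flags.  Readers for
# XYZ, small-molecule CIF and SHELX res files.

#' Construct a molecular structure
#'
#' @param symbols Character vector of element symbols (or atomic numbers).
#' @param xyz `n x 3` matrix of Cartesian coordinates in Angstrom.
#' @param labels Optional atom labels (default: symbol + running number).
#' @param cell Optional unit cell `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees).
#' @param in_asu Logical vector flagging asymmetric-unit membership
#'   (default all `TRUE`).
#' @param bonds Optional 2-column integer matrix of bonded atom pairs.
#' @return An object of class `molecular_structure`.
#' @export
molecular_structure <- function(symbols, xyz, labels = NULL, cell = NULL,
                                in_asu = NULL, bonds = NULL) {
  z <- if (is.numeric(symbols)) as.integer(symbols) else element_number(symbols)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  stopifnot(nrow(xyz) == length(z), all(is.finite(xyz)))
  if (is.null(labels)) {
    sym <- element_symbol(z)
    labels <- paste0(sym, stats::ave(seq_along(z), sym, FUN = seq_along))
  }
  if (is.null(in_asu)) in_asu <- rep(TRUE, length(z))
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (any(bonds < 1L | bonds > length(z))) stop("bond index out of range")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bonds are not allowed")
  }
  structure(list(labels = as.character(labels), z = z, xyz = xyz,
                 cell = cell, in_asu = in_asu, bonds = bonds,
                 rings = NULL),
            class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat("<molecular_structure> ", length(x$z), " atoms",
      if (!is.null(x$bonds)) paste0(", ", nrow(x$bonds), " bonds"),
      if (!is.null(x$cell)) paste0(", cell ",
                                   paste(signif(x$cell, 6), collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

n_atoms <- function(structure) length(structure$z)

# Fractional -> Cartesian orthogonalization matrix (standard setting:
# a along x, b in the xy plane).
frac_to_cart_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c_ * cos(be),
           0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c_ * v / sin(ga)), nrow = 3L, byrow = TRUE)
}

#' Read a molecular or crystal structure
#'
#' Supports plain XYZ, small-molecule CIF (fractional `_atom_site` loop plus
#' cell) and SHELX `.res`/`.ins` files.  Coordinates are returned Cartesian
#' in Angstrom; fractional coordinates are converted through the unit cell.
#' All atoms are flagged as belonging to the asymmetric unit.
#'
#' @param path File path.
#' @param format One of `"xyz"`, `"cif"`, `"res"`; guessed from the file
#'   extension when omitted.
#' @return A `molecular_structure` (without bonds; see
#'   [build_connectivity()]).
#' @export
read_structure <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", cif = "cif", res = "res", ins = "res",
                     stop("cannot guess structure format from '", ext, "'"))
  }
  switch(match.arg(format, c("xyz", "cif", "res")),
         xyz = .read_xyz(path), cif = .read_cif(path), res = .read_res(path))
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
  molecular_structure(sym, xyz)
}

.strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  getval <- function(tag) {
    i <- grep(paste0("^\\s*", tag, "\\b"), lines)
    if (!length(i)) return(NA_real_)
    .strip_su(strsplit(trimws(lines[i[1L]]), "\\s+")[[1L]][2L])
  }
  cell <- c(getval("_cell_length_a"), getval("_cell_length_b"),
            getval("_cell_length_c"), getval("_cell_angle_alpha"),
            getval("_cell_angle_beta"), getval("_cell_angle_gamma"))
  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    tags <- character(0); i <- ls + 1L
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_atom_site_fract_x", tags))) next
    body <- character(0)
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(loop_|_|data_)", ln)) break
      body <- c(body, ln); i <- i + 1L
    }
    rows <- strsplit(body, "\\s+")
    col <- function(tag) {
      j <- match(tag, tags)
      if (is.na(j)) return(NULL)
      vapply(rows, `[[`, "", j)
    }
    lab <- col("_atom_site_label")
    sym <- col("_atom_site_type_symbol")
    if (is.null(sym)) sym <- sub("^([A-Za-z]{1,2}).*$", "\\1", lab)
    sym <- sub("[0-9+-]+$", "", sym)
    frac <- cbind(.strip_su(col("_atom_site_fract_x")),
                  .strip_su(col("_atom_site_fract_y")),
                  .strip_su(col("_atom_site_fract_z")))
    if (anyNA(cell)) stop("CIF has fractional coordinates but no complete ",
                          "unit cell")
    xyz <- frac %*% t(frac_to_cart_matrix(cell))
    return(molecular_structure(sym, xyz, labels = lab, cell = cell))
  }
  stop("no _atom_site loop with fractional coordinates found in ", path)
}

.shelx_keywords <- c(
  "TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "UNIT", "TEMP", "L.S.",
  "LS", "BOND", "FMAP", "PLAN", "ACTA", "CONF", "HTAB", "WGHT", "FVAR",
  "HKLF", "END", "REM", "MORE", "AFIX", "PART", "EQIV", "EXTI", "SWAT",
  "OMIT", "TWIN", "BASF", "ANIS", "SIZE", "SHEL", "DFIX", "DANG", "SADI",
  "SAME", "FLAT", "SIMU", "DELU", "RIGU", "ISOR", "EADP", "EXYZ", "MPLA",
  "GRID", "MOLE", "SPEC", "RESI", "STIR", "ABIN", "ANSC", "ANSR", "BIND",
  "BLOC", "BUMP", "CGLS", "CHIV", "CONN", "DAMP", "DISP", "FEND", "FRAG",
  "LAUE", "LIST", "MERG", "NCSY", "NEUT", "PRIG", "SLIM", "SUMP", "TWST",
  "WIGL", "WPDB", "XNPD", "REST"
)

.read_res <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- NULL; sfac <- character(0)
  sym <- character(0); lab <- character(0); frac <- NULL
  for (ln in lines) {
    t <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!length(t) || t[1L] == "") next
    key <- toupper(t[1L])
    if (key == "CELL") {
      cell <- as.numeric(t[3:8])
    } else if (key == "SFAC") {
      sfac <- c(sfac, t[-1L])
    } else if (key == "HKLF" || key == "END") {
      break
    } else if (key %in% .shelx_keywords) {
      next
    } else if (length(t) >= 5L && !is.na(suppressWarnings(as.integer(t[2L])))) {
      si <- as.integer(t[2L])
      if (si < 1L || si > length(sfac)) next
      lab <- c(lab, t[1L]); sym <- c(sym, sfac[si])
      frac <- rbind(frac, as.numeric(t[3:5]))
    }
  }
  if (is.null(cell)) stop("SHELX file without CELL record: ", path)
  if (is.null(frac)) stop("no atom records found in ", path)
  # SHELX fixed-coordinate convention: values offset by 10 mean "fixed"
  frac <- ifelse(frac > 5, frac - 10, frac)
  xyz <- frac %*% t(frac_to_cart_matrix(cell))
  molecular_structure(sym, xyz, labels = lab, cell = cell)
}

#' Write a structure as XYZ
#'
#' @param structure A `molecular_structure`.
#' @param path Output path.
#' @param comment Second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  sym <- element_symbol(structure$z)
  lines <- c(length(structure$z), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", sym,
                     structure$xyz[, 1], structure$xyz[, 2],
                     structure$xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}
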