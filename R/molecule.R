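#' Construct a molecule
#'
#' A molecule is the sole physical input of the pipeline: element symbols,
#' Cartesian coordinates in Angstrom, and the integer total charge.
#'
#' @param symbols character vector of element symbols; must all belong to
#'   the supported set `H, C, N, O, F, Si, P, S, Cl, Br, I`.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param charge integer total charge of the solute (e).
#' @return An object of class `gb_molecule` with fields `symbols`,
#'   `coords`, and `charge`.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' n_atoms(h2)
#' @export
molecule <- function(symbols, coords, charge = 0L) {
  symbols <- normalize_symbols(symbols)
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  if (length(symbols) < 1) stop("a molecule needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(symbols)) {
    stop("coords rows (", nrow(coords), ") must match number of symbols (",
         length(symbols), ")", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (abs(charge - round(charge)) > 1e-9) {
    stop("total charge must be an integer", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(symbols = symbols, coords = coords,
                 charge = as.integer(round(charge))),
            class = "gb_molecule")
}

normalize_symbols <- function(symbols) {
  symbols <- as.character(symbols)
  idx <- match(toupper(symbols), toupper(GB_ELEMENTS))
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(GB_ELEMENTS, collapse = " "), call. = FALSE)
  }
  GB_ELEMENTS[idx]
}

#' @export
print.gb_molecule <- function(x, ...) {
  cat(sprintf("<gb_molecule> %d atoms, charge %+d\n", n_atoms(x), x$charge))
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `gb_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' Interatomic distance matrix
#' @param mol a `gb_molecule`.
#' @return symmetric n x n matrix of pair distances (Angstrom).
#' @export
distance_matrix <- function(mol) {
  as.matrix(stats::dist(mol$coords))
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `symbol x y z` row per atom (Angstrom).  The total charge is taken from
#' a `charge=<int>` token anywhere in the comment line and defaults to 0.
#'
#' @param path path to an XYZ file.
#' @return a [molecule()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed XYZ file (fewer than 3 lines): ", path,
                              call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 1) {
    stop("malformed XYZ count line: '", lines[[1]], "'", call. = FALSE)
  }
  if (length(lines) < 2 + n) {
    stop("XYZ file declares ", n, " atoms but has only ", length(lines) - 2,
         " atom rows", call. = FALSE)
  }
  charge <- 0L
  m <- regmatches(lines[[2]], regexec("charge=(-?[0-9]+)", lines[[2]]))[[1]]
  if (length(m) == 2) charge <- as.integer(m[[2]])
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "[[:space:]]+")
  bad <- vapply(rows, length, 0L) < 4
  if (any(bad)) {
    stop("malformed XYZ atom row: '", lines[2 + which(bad)[1]], "'",
         call. = FALSE)
  }
  symbols <- vapply(rows, `[[`, "", 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (!all(is.finite(coords))) stop("non-numeric coordinates in ", path,
                                    call. = FALSE)
  molecule(symbols, coords, charge)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a `gb_molecule`.
#' @param path output path.
#' @param charges optional numeric per-atom column (e.g. EE charges)
#'   appended after the coordinates.
#' @param comment extra text for the comment line; the `charge=` token is
#'   always included so the file round-trips.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, charges = NULL, comment = "") {
  n <- n_atoms(mol)
  header <- sprintf("charge=%d %s", mol$charge, comment)
  if (!is.null(charges)) {
    stopifnot(length(charges) == n)
    rows <- sprintf("%-2s %14.8f %14.8f %14.8f %12.6f", mol$symbols,
                    mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], charges)
  } else {
    rows <- sprintf("%-2s %14.8f %14.8f %14.8f", mol$symbols,
                    mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  }
  writeLines(c(as.character(n), trimws(header, "right"), rows), path)
  invisible(path)
}

#' van der Waals (Bondi) radii
#'
#' Standard literature van der Waals radii, used unmodified as the Born
#' radii of the generalized-Born features and for the surface/volume
#' estimates.
#'
#' @param path optional custom table (tsv with columns element, radius).
#' @return named numeric vector, Angstrom.
#' @export
bondi_radii <- function(path = NULL) {
  load_radius_table(if (is.null(path)) extdata_path("bondi_radii.tsv") else path,
                    cache_key = if (is.null(path)) "bondi" else NULL)
}

#' Covalent radii used for bond detection
#' @param path optional custom table (tsv with columns element, radius).
#' @return named numeric vector, Angstrom.
#' @export
covalent_radii <- function(path = NULL) {
  load_radius_table(if (is.null(path)) extdata_path("covalent_radii.tsv") else path,
                    cache_key = if (is.null(path)) "covalent" else NULL)
}

load_radius_table <- function(path, cache_key = NULL) {
  if (!is.null(cache_key) && !is.null(.gbsolv_cache[[cache_key]])) {
    return(.gbsolv_cache[[cache_key]])
  }
  tab <- read_tsv_table(path)
  radii <- setNames(as.numeric(tab$radius), tab$element)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("radii must be finite and strictly positive: ", path, call. = FALSE)
  }
  missing <- setdiff(GB_ELEMENTS, names(radii))
  if (length(missing)) {
    stop("radius table ", path, " lacks element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cache_key)) .gbsolv_cache[[cache_key]] <- radii
  radii
}

#' Look up a van der Waals radius
#' @param symbol element symbol.
#' @param table named radius vector, default [bondi_radii()].
#' @return radius in Angstrom.
#' @export
lookup_radius <- function(symbol, table = bondi_radii()) {
  symbol <- normalize_symbols(symbol)
  r <- table[symbol]
  if (anyNA(r)) {
    stop("no radius tabulated for element(s): ",
         paste(symbol[is.na(r)], collapse = ", "), call. = FALSE)
  }
  unname(r)
}

#' Coordination numbers by covalent-radius cutoff
#'
#' Atom J counts as bonded to atom I when
#' `r_IJ <= tolerance * (r_cov(I) + r_cov(J))`.  The raw neighbor count is
#' then clamped into the coordination-number ranges the charge-model
#' parameter table actually covers for that element (an isolated atom falls
#' back to the lowest listed range, an over-coordinated atom to the nearest
#' listed range), so that every atom resolves to exactly one parameter row.
#'
#' @param mol a `gb_molecule`.
#' @param radii covalent radii (named vector), default [covalent_radii()].
#' @param tolerance dimensionless cutoff factor, default 1.2.
#' @param params the `gb_ee_params` whose CN ranges define the clamping;
#'   `NULL` returns the raw neighbor counts.
#' @return integer vector of per-atom coordination numbers.
#' @export
coordination_numbers <- function(mol, radii = covalent_radii(),
                                 tolerance = 1.2, params = ee_parameters()) {
  stopifnot(tolerance > 0)
  n <- n_atoms(mol)
  rc <- radii[mol$symbols]
  if (anyNA(rc)) {
    stop("no covalent radius for element(s): ",
         paste(unique(mol$symbols[is.na(rc)]), collapse = ", "), call. = FALSE)
  }
  if (n == 1) {
    cn <- 0L
  } else {
    d <- distance_matrix(mol)
    cutoff <- tolerance * outer(rc, rc, `+`)
    diag(d) <- Inf
    cn <- as.integer(rowSums(d <= cutoff))
  }
  if (is.null(params)) return(cn)
  vapply(seq_len(n), function(i) clamp_cn(mol$symbols[i], cn[i], params),
         integer(1))
}

# clamp a raw CN into the nearest range listed for the element
clamp_cn <- function(element, cn, params) {
  rows <- params$entries[params$entries$element == element, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no charge-model parameters for element ", element, call. = FALSE)
  }
  covered <- cn >= rows$cn_min & cn <= rows$cn_max
  if (any(covered)) return(as.integer(cn))
  # distance from cn to each [cn_min, cn_max] interval; tie -> lower range
  d <- pmax(rows$cn_min - cn, cn - rows$cn_max, 0)
  row <- rows[which.min(d), ]
  as.integer(if (cn < row$cn_min) max(row$cn_min, 1) else min(row$cn_max, cn))
}
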