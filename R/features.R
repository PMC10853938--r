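# Generalized-Born feature construction.  Every electrostatic feature
# carries the dielectric factor (1 - 1/eps) and the Coulomb constant
# 332.06 kcal*A/(mol*e^2); one constant, defined once in gbsolv-package.R.

#' All possible element pairs for the Born pair terms
#' @return data.frame of the 45 unordered pairs of the nine feature
#'   elements, columns `el1`, `el2`, in canonical order.
#' @export
all_element_pairs <- function() {
  k <- length(FEATURE_ELEMENTS)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(el1 = FEATURE_ELEMENTS[i], el2 = FEATURE_ELEMENTS[i:k],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default retained pair list
#'
#' The 36 element pairs kept for the pair-energy features; the remaining 9
#' (halogen-halogen and S-Br/S-I) are dropped as rare in organic solutes.
#' Any subset of the 45 pairs in the same two-column layout is accepted.
#'
#' @param path optional custom pair-list file.
#' @return data.frame with columns `el1`, `el2`.
#' @export
default_element_pairs <- function(path = NULL) {
  tab <- read_tsv_table(if (is.null(path)) extdata_path("pairs_default.tsv") else path)
  validate_pairs(tab)
}

validate_pairs <- function(tab) {
  stopifnot(all(c("el1", "el2") %in% names(tab)))
  ok <- tab$el1 %in% FEATURE_ELEMENTS & tab$el2 %in% FEATURE_ELEMENTS
  if (!all(ok)) {
    stop("pair list contains non-feature elements: ",
         paste(unique(c(tab$el1[!ok], tab$el2[!ok])), collapse = ", "),
         call. = FALSE)
  }
  key <- pair_key(tab$el1, tab$el2)
  if (anyDuplicated(key)) stop("duplicate pairs in pair list", call. = FALSE)
  tab
}

# order-independent key for an element pair
pair_key <- function(el1, el2) {
  i <- match(el1, FEATURE_ELEMENTS)
  j <- match(el2, FEATURE_ELEMENTS)
  paste(FEATURE_ELEMENTS[pmin(i, j)], FEATURE_ELEMENTS[pmax(i, j)], sep = "-")
}

#' Feature schema
#'
#' Fixes the layout of the raw descriptor vector: 4 global features
#' (atom count, total charge, total volume, total surface), 9 per-element
#' surface sums, 9 Born self terms, the retained Born pair terms (36 by
#' default), and for nonaqueous schemas the 3 solvent descriptors.  The
#' default layouts are 58 (aqueous) and 61 (nonaqueous) features long.
#'
#' @param aqueous logical; aqueous schemas omit the solvent block.
#' @param pairs retained pair list, default [default_element_pairs()];
#'   `NULL` keeps all 45.
#' @return object of class `gb_schema` with fields `aqueous`, `pairs`,
#'   `length`, and `names` (one label per feature slot).
#' @export
gb_schema <- function(aqueous = TRUE, pairs = default_element_pairs()) {
  if (is.null(pairs)) pairs <- all_element_pairs()
  pairs <- validate_pairs(pairs)
  nm <- c("n_atoms", "q_tot", "v_tot", "s_tot",
          paste0("S_", FEATURE_ELEMENTS),
          paste0("E1_", FEATURE_ELEMENTS),
          paste0("E2_", pair_key(pairs$el1, pairs$el2)))
  if (!aqueous) nm <- c(nm, "solv_eps", "solv_bp", "solv_heavy")
  structure(list(aqueous = aqueous, pairs = pairs,
                 length = length(nm), names = nm),
            class = "gb_schema")
}

#' @export
print.gb_schema <- function(x, ...) {
  cat(sprintf("<gb_schema> %s, %d features (%d pair terms)\n",
              if (x$aqueous) "aqueous" else "nonaqueous",
              x$length, nrow(x$pairs)))
  invisible(x)
}

#' Generalized-Born pair function
#'
#' The smooth interpolation between the Coulomb limit at large separation
#' and the Born self-term at coincidence:
#' `f_IJ = sqrt(r^2 + R_I R_J exp(-r^2 / (c R_I R_J)))`, with `c = 4`.
#'
#' @param r interatomic distance(s), Angstrom, >= 0.
#' @param R_I,R_J Born (van der Waals) radii, Angstrom, > 0.
#' @param c dimensionless shape constant, default 4.
#' @return `f_IJ` in Angstrom; `f(0) = sqrt(R_I R_J)`, `f -> r` as
#'   `r -> Inf`.
#' @export
pair_function <- function(r, R_I, R_J, c = 4) {
  if (any(R_I <= 0) || any(R_J <= 0)) {
    stop("Born radii must be positive", call. = FALSE)
  }
  if (any(r < 0)) stop("distance must be non-negative", call. = FALSE)
  sqrt(r^2 + R_I * R_J * exp(-r^2 / (c * R_I * R_J)))
}

# dielectric prefactor in kcal/mol per e^2/Angstrom
born_prefactor <- function(epsilon) {
  if (any(epsilon <= 1)) stop("dielectric constant must exceed 1", call. = FALSE)
  COULOMB_KCAL * (1 - 1 / epsilon)
}

#' Born self-energy terms grouped by element
#'
#' `E1(L) = 332.06 (1 - 1/eps) * sum_{I in L} Q_I^2 / R_I` for the nine
#' feature elements L; the monatomic limit is the Born expression for a
#' spherical ion.  Si and P atoms carry charge but no element-resolved
#' feature and contribute nothing here.
#'
#' @param charges a `gb_charges` (or numeric vector of per-atom charges).
#' @param mol a `gb_molecule`.
#' @param radii named Born radius vector, default [bondi_radii()].
#' @param epsilon solvent dielectric constant, > 1.
#' @return named numeric vector over the nine feature elements (kcal/mol);
#'   absent elements map to 0.
#' @export
born_self_terms <- function(charges, mol, radii = bondi_radii(), epsilon) {
  q <- if (inherits(charges, "gb_charges")) charges$charges else charges
  stopifnot(length(q) == n_atoms(mol))
  R <- lookup_radius(mol$symbols, radii)
  contrib <- born_prefactor(epsilon) * q^2 / R
  out <- setNames(numeric(length(FEATURE_ELEMENTS)), FEATURE_ELEMENTS)
  keep <- mol$symbols %in% FEATURE_ELEMENTS
  if (any(keep)) {
    sums <- tapply(contrib[keep], mol$symbols[keep], sum)
    out[names(sums)] <- sums
  }
  out
}

#' Born pair-energy terms grouped by element pair
#'
#' `E2(L1, L2) = 332.06 (1 - 1/eps) * sum Q_I Q_J / f_IJ` over unordered
#' atom pairs I < J whose elements form the pair `{L1, L2}`; only pairs in
#' the schema's retained list are reported.
#'
#' @inheritParams born_self_terms
#' @param schema a `gb_schema` (its pair list selects the reported terms).
#' @param c shape constant of [pair_function()].
#' @return named numeric vector over the schema's pairs (kcal/mol).
#' @export
born_pair_terms <- function(charges, mol, radii = bondi_radii(), epsilon,
                            schema = gb_schema(), c = 4) {
  q <- if (inherits(charges, "gb_charges")) charges$charges else charges
  n <- n_atoms(mol)
  stopifnot(length(q) == n)
  keys <- pair_key(schema$pairs$el1, schema$pairs$el2)
  out <- setNames(numeric(length(keys)), keys)
  if (n < 2) return(out)
  R <- lookup_radius(mol$symbols, radii)
  d <- distance_matrix(mol)
  pref <- born_prefactor(epsilon)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (!(mol$symbols[i] %in% FEATURE_ELEMENTS) ||
          !(mol$symbols[j] %in% FEATURE_ELEMENTS)) next
      key <- pair_key(mol$symbols[i], mol$symbols[j])
      if (!key %in% keys) next
      f <- pair_function(d[i, j], R[i], R[j], c = c)
      out[key] <- out[key] + pref * q[i] * q[j] / f
    }
  }
  out
}

#' Total generalized-Born electrostatic energy
#'
#' `-332.06/2 * (1 - 1/eps) * sum_{I,J} Q_I Q_J / f_IJ` (double sum
#' including I = J, with `f_II = R_I`): the polarization energy of the
#' charge distribution, negative for any net-charged solute.  Used as the
#' dielectric-scalable electrostatic share in ionic data augmentation.
#'
#' @inheritParams born_self_terms
#' @param c shape constant of [pair_function()].
#' @return energy in kcal/mol.
#' @export
gb_electrostatic <- function(charges, mol, radii = bondi_radii(), epsilon,
                             c = 4) {
  q <- if (inherits(charges, "gb_charges")) charges$charges else charges
  n <- n_atoms(mol)
  stopifnot(length(q) == n)
  R <- lookup_radius(mol$symbols, radii)
  d <- if (n > 1) distance_matrix(mol) else matrix(0, 1, 1)
  f <- matrix(pair_function(as.numeric(d), rep(R, times = n),
                            rep(R, each = n), c = c), n, n)
  -born_prefactor(epsilon) / 2 * sum(outer(q, q) / f)
}

#' Assemble the raw feature vector
#'
#' Concatenates, in fixed schema order: atom count, total charge, total
#' volume, total surface, the 9 per-element surface sums, the 9 Born self
#' terms, the retained Born pair terms, and (nonaqueous only) the solvent
#' dielectric constant, boiling point, and heavy-atom count.
#'
#' @param mol a `gb_molecule`.
#' @param charges a `gb_charges` for `mol`.
#' @param surfvol a `gb_surfvol` for `mol`.
#' @param epsilon dielectric constant used for the Born terms.
#' @param solvent a `gb_solvent`; required (and its `epsilon` must match)
#'   for nonaqueous schemas.
#' @param schema a `gb_schema`.
#' @param radii named Born radius vector.
#' @return named numeric feature vector of length `schema$length`.
#' @export
assemble_features <- function(mol, charges, surfvol, epsilon,
                              solvent = NULL, schema = gb_schema(),
                              radii = bondi_radii()) {
  if (!schema$aqueous && is.null(solvent)) {
    stop("nonaqueous schema requires a solvent descriptor", call. = FALSE)
  }
  S_L <- setNames(numeric(length(FEATURE_ELEMENTS)), FEATURE_ELEMENTS)
  keep <- mol$symbols %in% FEATURE_ELEMENTS
  if (any(keep)) {
    sums <- tapply(surfvol$S[keep], mol$symbols[keep], sum)
    S_L[names(sums)] <- sums
  }
  vec <- c(n_atoms(mol), mol$charge, surfvol$V_tot, surfvol$S_tot, S_L,
           born_self_terms(charges, mol, radii, epsilon),
           born_pair_terms(charges, mol, radii, epsilon, schema))
  if (!schema$aqueous) {
    vec <- c(vec, solvent$epsilon, solvent$bp, solvent$heavy_atoms)
  }
  if (!all(is.finite(vec))) stop("non-finite feature value", call. = FALSE)
  setNames(vec, schema$names)
}

#' Compute the feature vector straight from a geometry
#'
#' Convenience wrapper: coordination numbers, EE charges, surfaces and
#' volumes, then [assemble_features()].
#'
#' @param mol a `gb_molecule`.
#' @param solvent a `gb_solvent` (or solvent name to look up); for an
#'   aqueous schema defaults to water.
#' @param schema a `gb_schema`; default chosen by the solvent (aqueous for
#'   water, nonaqueous otherwise).
#' @param params a `gb_ee_params`.
#' @param radii named Born radius vector.
#' @return named numeric feature vector.
#' @export
compute_features <- function(mol, solvent = "water", schema = NULL,
                             params = ee_parameters(), radii = bondi_radii()) {
  if (is.character(solvent)) solvent <- lookup_solvent(solvent)
  if (is.null(schema)) schema <- gb_schema(aqueous = solvent$aqueous)
  charges <- solve_charges(mol, params = params)
  sv <- surface_volume(mol, radii)
  assemble_features(mol, charges, sv, epsilon = solvent$epsilon,
                    solvent = if (schema$aqueous) NULL else solvent,
                    schema = schema, radii = radii)
}

#' Write feature vectors to CSV
#' @param features numeric vector or matrix (rows = records) of features.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  m <- if (is.null(dim(features))) t(as.matrix(features)) else features
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
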