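# Ionic data augmentation across dielectric constants and boiling points,
# plus a deterministic synthetic-molecule generator so the whole pipeline
# is exercisable without external databases.

# augmentation windows for the dielectric constant and boiling point
EPS_RANGE <- c(10, 200)
BP_RANGE <- c(40, 210)

#' Construct a solvation record
#'
#' One training observation: a solute geometry, a solvent descriptor, a
#' reference solvation free energy, a loss weight, and a provenance tag.
#'
#' @param mol a `gb_molecule` (may be NULL when only solvent/target fields
#'   matter, e.g. in augmentation unit tests).
#' @param solvent a `gb_solvent` or solvent name.
#' @param dG_ref reference solvation free energy, kcal/mol.
#' @param weight non-negative loss weight, default 1.
#' @param origin one of `measured`, `extrapolated`, `replicated`,
#'   `synthetic`.
#' @return object of class `gb_record`.
#' @export
solvation_record <- function(mol, solvent, dG_ref, weight = 1,
                             origin = c("measured", "extrapolated",
                                        "replicated", "synthetic")) {
  origin <- match.arg(origin)
  if (is.character(solvent)) solvent <- lookup_solvent(solvent)
  stopifnot(is.finite(dG_ref), weight >= 0)
  structure(list(mol = mol, solvent = solvent, dG_ref = dG_ref,
                 weight = weight, origin = origin),
            class = "gb_record")
}

#' Extrapolate an ionic record to a new dielectric constant
#'
#' Rescales the electrostatic share of the reference solvation energy by
#' the Born dielectric factor while holding the nonelectrostatic remainder
#' fixed:
#' `dG_new = dG_ref + E_elst * ((1 - 1/eps_new) / (1 - 1/eps_real) - 1)`.
#' The electrostatic share is the record's generalized-Born total at its
#' real dielectric constant (see [gb_electrostatic()]), the only
#' dielectric-dependent quantity available before any model is trained.
#' The identity holds at `eps_new = eps_real` and whenever the
#' electrostatic part is zero.
#'
#' @param record a `gb_record` for an ionic solute.
#' @param epsilon_new target dielectric constant, in (10, 200).
#' @param electrostatic_part electrostatic share of `dG_ref` at the
#'   record's real dielectric constant, kcal/mol; computed from the
#'   record's geometry with [gb_electrostatic()] when NULL.
#' @return a new `gb_record` with origin `extrapolated` and a fictitious
#'   solvent whose dielectric constant is `epsilon_new`.
#' @export
extrapolate_ionic <- function(record, epsilon_new, electrostatic_part = NULL) {
  if (epsilon_new <= EPS_RANGE[1] || epsilon_new >= EPS_RANGE[2]) {
    stop("epsilon_new must lie within (", EPS_RANGE[1], ", ", EPS_RANGE[2],
         ")", call. = FALSE)
  }
  if (is.null(record$mol) && is.null(electrostatic_part)) {
    stop("electrostatic_part required when the record has no geometry",
         call. = FALSE)
  }
  charge <- if (!is.null(record$mol)) record$mol$charge else NA_integer_
  if (!is.na(charge) && charge == 0) {
    stop("only ionic records are extrapolated across dielectric constants",
         call. = FALSE)
  }
  eps_real <- record$solvent$epsilon
  if (is.null(electrostatic_part)) {
    q <- solve_charges(record$mol)
    electrostatic_part <- gb_electrostatic(q, record$mol, epsilon = eps_real)
  }
  scale <- (1 - 1 / epsilon_new) / (1 - 1 / eps_real) - 1
  out <- record
  out$solvent$epsilon <- epsilon_new
  out$solvent$name <- sprintf("%s[eps=%.3g]", record$solvent$name, epsilon_new)
  out$dG_ref <- record$dG_ref + electrostatic_part * scale
  out$origin <- "extrapolated"
  out
}

#' Replicate a record across a boiling-point grid
#'
#' Copies the record once per grid point, changing only the solvent
#' boiling point; geometry, charge, and target are untouched.
#'
#' @param record a `gb_record`.
#' @param bp_grid boiling points in degrees C, all within (40, 210).
#' @return list of `gb_record`s with origin `replicated` (a single-point
#'   grid equal to the record's own boiling point returns the record
#'   unchanged).
#' @export
replicate_boiling_points <- function(record, bp_grid) {
  if (any(bp_grid <= BP_RANGE[1] | bp_grid >= BP_RANGE[2])) {
    stop("boiling points must lie within (", BP_RANGE[1], ", ", BP_RANGE[2],
         ") C", call. = FALSE)
  }
  lapply(bp_grid, function(bp) {
    if (isTRUE(all.equal(bp, record$solvent$bp)) && length(bp_grid) == 1) {
      return(record)
    }
    out <- record
    out$solvent$bp <- bp
    out$origin <- "replicated"
    out
  })
}

#' Generate a random small molecule
#'
#' Grows a connected cluster atom by atom: each new atom attaches to a
#' randomly chosen existing atom at a bond length drawn within 10% of the
#' covalent-radius sum, in a random direction, rejecting placements that
#' collide with earlier atoms.  Elements are drawn from the supported set
#' with weights favoring H/C/N/O chemistry; the total charge is drawn from
#' {-1, 0, +1} unless given.  Deterministic per seed.
#'
#' @param seed integer seed.
#' @param size_range inclusive atom-count range, within 1..30.
#' @param element_weights named sampling weights over the supported
#'   elements.
#' @param charge fixed total charge, or NULL to sample.
#' @return a `gb_molecule`.
#' @export
random_molecule <- function(seed, size_range = c(3, 12),
                            element_weights = NEUTRAL_ELEMENT_WEIGHTS,
                            charge = NULL) {
  stopifnot(size_range[1] >= 1, size_range[2] <= 30,
            size_range[1] <= size_range[2])
  elements <- names(element_weights)
  normalize_symbols(elements)
  rc <- covalent_radii()
  with_seed(seed, {
    n <- sample(seq(size_range[1], size_range[2]), 1)
    symbols <- sample(elements, n, replace = TRUE,
                      prob = element_weights / sum(element_weights))
    # hydrogen can only terminate; keep at least one non-H anchor
    if (n > 1 && all(symbols == "H")) symbols[1] <- "C"
    coords <- matrix(0, n, 3)
    if (n > 1) {
      for (i in 2:n) {
        anchors <- which(symbols[seq_len(i - 1)] != "H")
        if (!length(anchors)) anchors <- seq_len(i - 1)
        best_pos <- NULL
        best_clearance <- -Inf
        for (attempt in 1:200) {
          j <- if (length(anchors) == 1) anchors else sample(anchors, 1)
          bond <- (rc[symbols[i]] + rc[symbols[j]]) * runif(1, 0.9, 1.1)
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2))
          pos <- coords[j, ] + bond * u
          d <- sqrt(rowSums((coords[seq_len(i - 1), , drop = FALSE] -
                               matrix(pos, i - 1, 3, byrow = TRUE))^2))
          min_ok <- 0.8 * (rc[symbols[i]] + rc[symbols[seq_len(i - 1)]])
          min_ok[j] <- 0  # the bonded partner sits at bond length
          clearance <- min(d - min_ok)
          if (clearance > best_clearance) {
            best_clearance <- clearance
            best_pos <- pos
          }
          if (clearance >= 0) break
        }
        # a crowded cluster may leave no collision-free direction; keep the
        # least-crowded candidate (clearance is then only slightly negative)
        coords[i, ] <- best_pos
      }
    }
    if (is.null(charge)) charge <- sample(c(-1L, 0L, 1L), 1,
                                          prob = c(0.1, 0.8, 0.1))
    molecule(symbols, coords, charge)
  })
}

# default element mixes of the generator: heteroatom-rich neutrals (so
# every retained Born pair is decently represented, as a curated training
# database would ensure) and H/C/N/O/S ion chemistry (protonated amines,
# carboxylates, and the like; halogen-rich ions are not realistic solutes)
NEUTRAL_ELEMENT_WEIGHTS <- c(H = 30, C = 25, N = 10, O = 12, F = 6, S = 5,
                             Cl = 6, Br = 3, I = 3)
ION_ELEMENT_WEIGHTS <- c(H = 35, C = 30, N = 12, O = 15, S = 4)

# linear label rule on the standardized raw features: a crude solvation
# energy built from the compact physical descriptors (size, surface,
# volume, net charge, solvent polarity); entries absent from a schema
# (the solvent block, for aqueous layouts) are simply not used
LABEL_RULE_RAW_COEF <- c(n_atoms = -0.8, v_tot = -0.7, s_tot = -0.5,
                         q_tot = 1.2, solv_eps = -0.9, solv_bp = -0.3,
                         S_O = -0.4, S_C = 0.3)
LABEL_RULE_INTERCEPT <- -3

#' Generate a synthetic solvation dataset
#'
#' Desk-scale stand-in for a solvation database: random small molecules in
#' randomly drawn solvents, with ground-truth labels generated from a
#' declared linear function of the reduced features plus Gaussian noise,
#' so that training and prediction can be validated by recovery.
#'
#' The declared label rule mimics a crude solvation energy: a fixed linear
#' functional of the standardized compact descriptors (atom count, volume,
#' surface, net charge, solvent polarity and boiling point, O/C surface
#' shares) projected onto the retained principal components — hence exactly
#' linear in the reduced features, with the coefficient vector reported in
#' `truth$coef`.  Ionic records are generated small (3-7 atoms, as typical
#' ionic solutes are) and carry an elevated loss weight, mirroring the
#' emphasis that ionic augmentation places on the scarce class.
#'
#' @param n number of records.
#' @param seed integer seed; the dataset is fully reproducible from
#'   `(seed, arguments)`.
#' @param schema a `gb_schema`; nonaqueous by default so solvent features
#'   vary.
#' @param solvents candidate solvent names; defaults to a spread of
#'   dielectric constants from the registry (water only, for aqueous
#'   schemas).
#' @param size_range atom-count range of the generated neutral molecules
#'   (ions use `ion_size_range`).
#' @param ion_size_range atom-count range for ionic records.
#' @param class_mix proportions of neutral/cation/anion records; the
#'   default emulates an ion-augmented training table.
#' @param sigma Gaussian label noise, kcal/mol.
#' @param ion_weight loss weight given to ionic records (neutrals get 1).
#' @param label_rule optional function `(reduced_matrix) -> numeric`
#'   overriding the built-in linear rule.
#' @return list of class `gb_dataset`: `raw` (feature matrix), `reduced`,
#'   `y` (noisy labels), `meta` (data.frame with solvent, epsilon, charge
#'   class, origin), `weights`, `molecules`, `transform`, `schema`, and
#'   `truth` (the reduced-space coefficients, intercept, noise-free
#'   labels, and sigma of the generating rule).
#' @export
make_dataset <- function(n, seed = 1, schema = gb_schema(aqueous = FALSE),
                         solvents = NULL, size_range = c(3, 12),
                         ion_size_range = c(3, 7),
                         class_mix = c(neutral = 0.6, cation = 0.2,
                                       anion = 0.2),
                         sigma = 0.5, ion_weight = 3, label_rule = NULL) {
  stopifnot(n >= 1)
  if (is.null(solvents)) {
    solvents <- if (schema$aqueous) "water" else
      c("methanol", "ethanol", "octanol", "acetonitrile",
        "dimethyl sulfoxide", "chloroform", "benzene", "hexane")
  }
  class_mix <- class_mix / sum(class_mix)
  counts <- round(n * class_mix)
  counts["neutral"] <- n - sum(counts[c("cation", "anion")])
  charges <- rep(c(0L, 1L, -1L), counts[c("neutral", "cation", "anion")])
  mol_seeds <- with_seed(seed, sample.int(2^30, n))
  solvent_idx <- with_seed(seed + 1, sample(length(solvents), n, replace = TRUE))
  mols <- lapply(seq_len(n), function(i) {
    if (charges[i] == 0L) {
      random_molecule(mol_seeds[i], size_range = size_range,
                      element_weights = NEUTRAL_ELEMENT_WEIGHTS, charge = 0L)
    } else {
      random_molecule(mol_seeds[i], size_range = ion_size_range,
                      element_weights = ION_ELEMENT_WEIGHTS,
                      charge = charges[i])
    }
  })
  descriptors <- lapply(solvents, lookup_solvent)
  raw <- t(vapply(seq_len(n), function(i) {
    compute_features(mols[[i]], descriptors[[solvent_idx[i]]], schema = schema)
  }, numeric(schema$length)))
  # small samples cannot carry the full 9-drop projection (rank is at most
  # n - 1, and rare-pair columns may be identically zero); keep what the
  # standardized matrix supports
  s <- apply(raw, 2, stats::sd)
  s[s < .Machine$double.eps] <- 1
  rank <- qr(sweep(sweep(raw, 2, colMeans(raw)), 2, s, `/`))$rank
  n_drop_eff <- max(9, schema$length - rank)
  transform <- fit_transform(raw, n_drop = n_drop_eff)
  reduced <- apply_transform(transform, raw)
  if (is.null(label_rule)) {
    a <- setNames(numeric(schema$length), schema$names)
    keep <- intersect(names(LABEL_RULE_RAW_COEF), schema$names)
    a[keep] <- LABEL_RULE_RAW_COEF[keep]
    coef <- drop(crossprod(transform$rotation, a)) * transform$post_scale
    y_true <- drop(reduced %*% coef) + LABEL_RULE_INTERCEPT
    truth <- list(coef = coef, intercept = LABEL_RULE_INTERCEPT,
                  raw_coef = a, sigma = sigma)
  } else {
    y_true <- label_rule(reduced)
    truth <- list(rule = label_rule, sigma = sigma)
  }
  y <- y_true + with_seed(seed + 3, rnorm(n, sd = sigma))
  truth$y_true <- y_true
  meta <- data.frame(
    solvent = vapply(descriptors[solvent_idx], `[[`, "", "name"),
    epsilon = vapply(descriptors[solvent_idx], `[[`, 0, "epsilon"),
    charge = charges,
    class = c("neutral", "cation", "anion")[match(charges, c(0L, 1L, -1L))],
    origin = "synthetic",
    stringsAsFactors = FALSE)
  structure(list(raw = raw, reduced = reduced, y = y, meta = meta,
                 molecules = mols, transform = transform, schema = schema,
                 truth = truth,
                 weights = ifelse(charges == 0L, 1, ion_weight)),
            class = "gb_dataset")
}

#' @export
print.gb_dataset <- function(x, ...) {
  cat(sprintf("<gb_dataset> %d records (%s), %d raw -> %d reduced features\n",
              length(x$y), paste(table(x$meta$class), collapse = "/"),
              ncol(x$raw), ncol(x$reduced)))
  invisible(x)
}

#' Write a dataset's training table to CSV
#'
#' The training-table layout: one row per record with the solvent fields,
#' charge, reference energy, and weight, followed by the raw feature
#' columns.
#'
#' @param dataset a `gb_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  out <- cbind(dataset$meta,
               dG_ref = dataset$y,
               weight = dataset$weights,
               as.data.frame(dataset$raw))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
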