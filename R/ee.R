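# Electronegativity equalization: all atoms share one equalized
# electronegativity chi at the solution of a single linear system with a
# total-charge constraint.  Parameters depend on element AND coordination
# number; two global lengths kappa, kappa2 shape the off-diagonal coupling.

# electronegativity is d/dQ of (A*Q + B*Q^2), hence the diagonal is 2*B
EE_DIAGONAL_FACTOR <- 2

#' Electronegativity-equalization parameter set
#'
#' Loads the bundled element- and coordination-number dependent parameter
#' table: per (element, CN-range) an electronegativity-like parameter `A`
#' and a hardness-like parameter `B`, plus the two global coupling lengths
#' `kappa` and `kappa2` (Angstrom) read from the file header.
#'
#' @param path optional custom parameter file (same tsv layout as the
#'   bundled `ee_params.tsv`, `# kappa` / `# kappa2` header lines).
#' @return object of class `gb_ee_params`: `entries` (data.frame with
#'   columns element, cn_min, cn_max, A, B), `kappa`, `kappa2`.
#' @export
ee_parameters <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gbsolv_cache$ee_params)) return(.gbsolv_cache$ee_params)
  file <- if (default) extdata_path("ee_params.tsv") else path
  lines <- readLines(file, warn = FALSE)
  kv <- regmatches(lines, regexec("^#\\s*(kappa2?)\\s+([0-9.]+)", lines))
  kv <- Filter(function(m) length(m) == 3, kv)
  globals <- setNames(vapply(kv, function(m) as.numeric(m[[3]]), 0),
                      vapply(kv, `[[`, "", 2L))
  entries <- read_tsv_table(file)
  entries$cn_min <- as.numeric(entries$cn_min)
  entries$cn_max <- as.numeric(entries$cn_max)
  out <- ee_parameter_set(entries, kappa = globals[["kappa"]],
                          kappa2 = globals[["kappa2"]])
  if (default) .gbsolv_cache$ee_params <- out
  out
}

#' Assemble a parameter set from its parts
#' @param entries data.frame with columns element, cn_min, cn_max, A, B.
#' @param kappa,kappa2 global coupling lengths (Angstrom), both > 0.
#' @return `gb_ee_params` object.
#' @export
ee_parameter_set <- function(entries, kappa, kappa2) {
  stopifnot(is.data.frame(entries),
            all(c("element", "cn_min", "cn_max", "A", "B") %in% names(entries)))
  if (any(entries$B <= 0)) stop("hardness parameters B must be positive",
                                call. = FALSE)
  if (!isTRUE(kappa > 0) || !isTRUE(kappa2 > 0)) {
    stop("kappa and kappa2 must be positive", call. = FALSE)
  }
  structure(list(entries = entries, kappa = kappa, kappa2 = kappa2),
            class = "gb_ee_params")
}

#' @export
print.gb_ee_params <- function(x, ...) {
  cat(sprintf("<gb_ee_params> %d (element, CN-range) rows; kappa=%.3f A, kappa2=%.3f A\n",
              nrow(x$entries), x$kappa, x$kappa2))
  invisible(x)
}

#' Serialize a parameter set to a plain-text table
#' @param params a `gb_ee_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ee_parameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kappa\t%.6g", params$kappa),
               sprintf("# kappa2\t%.6g", params$kappa2)), con)
  write.table(params$entries, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# index of the parameter row covering (element, cn); nearest range fallback
ee_row_index <- function(params, element, cn) {
  e <- params$entries
  rows <- which(e$element == element)
  if (!length(rows)) {
    stop("no EE parameters for element ", element, call. = FALSE)
  }
  covered <- cn >= e$cn_min[rows] & cn <= e$cn_max[rows]
  if (any(covered)) return(rows[which(covered)[1]])
  d <- pmax(e$cn_min[rows] - cn, cn - e$cn_max[rows], 0)
  rows[which.min(d)]
}

#' Off-diagonal coupling of the equalization system
#'
#' The geometry-dependent coupling between two atoms a distance `r` apart:
#' `Y(r) = 1 / (r + kappa * exp(-r / kappa2))`.  Symmetric in the pair,
#' strictly positive, finite at short range, and Coulombic (proportional to
#' `1/r`) at large separation.
#'
#' @param r interatomic distance(s), Angstrom; must be > 0.
#' @param params a `gb_ee_params` supplying `kappa` and `kappa2`.
#' @return coupling value(s), 1/Angstrom.
#' @export
offdiag_coupling <- function(r, params = ee_parameters()) {
  if (any(r <= 0) || any(!is.finite(r))) {
    stop("interatomic distance must be positive and finite", call. = FALSE)
  }
  1 / (r + params$kappa * exp(-r / params$kappa2))
}

#' Solve for electronegativity-equalization charges
#'
#' Builds and solves the (N+1) x (N+1) linear system: one equalization row
#' per atom, `2 B_I Q_I + sum_J Y_IJ Q_J - chi = -A_I`, plus the constraint
#' row `sum_I Q_I = Q_tot`.  One step of iterative refinement keeps the
#' residual (and hence charge conservation) at machine precision.
#'
#' @param mol a `gb_molecule`.
#' @param cn per-atom coordination numbers, default computed from the
#'   geometry with [coordination_numbers()].
#' @param params a `gb_ee_params`.
#' @return object of class `gb_charges`: `charges` (per-atom, e) and `chi`
#'   (the equalized electronegativity).
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' solve_charges(h2)$charges   # 0 0 by symmetry
#' @export
solve_charges <- function(mol, cn = NULL, params = ee_parameters()) {
  n <- n_atoms(mol)
  if (is.null(cn)) cn <- coordination_numbers(mol, params = params)
  stopifnot(length(cn) == n)
  rows <- vapply(seq_len(n),
                 function(i) ee_row_index(params, mol$symbols[i], cn[i]),
                 integer(1))
  A <- params$entries$A[rows]
  B <- params$entries$B[rows]
  M <- matrix(0, n + 1, n + 1)
  if (n > 1) {
    d <- distance_matrix(mol)
    Y <- offdiag_coupling(pmax(d, .Machine$double.eps), params)
    diag(Y) <- 0
    M[seq_len(n), seq_len(n)] <- Y
  }
  diag(M)[seq_len(n)] <- EE_DIAGONAL_FACTOR * B
  M[seq_len(n), n + 1] <- -1
  M[n + 1, seq_len(n)] <- 1
  b <- c(-A, mol$charge)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-13) {
    stop(sprintf("equalization system is numerically singular (reciprocal condition number %.3e, condition number %.3e)",
                 rc, kappa(M, exact = FALSE)), call. = FALSE)
  }
  x <- solve(M, b)
  x <- x + solve(M, b - M %*% x)  # one refinement step
  structure(list(charges = as.numeric(x[seq_len(n)]), chi = as.numeric(x[n + 1])),
            class = "gb_charges")
}

#' @export
print.gb_charges <- function(x, ...) {
  cat(sprintf("<gb_charges> %d atoms, sum=%.3e e, chi=%.4f\n",
              length(x$charges), sum(x$charges), x$chi))
  invisible(x)
}

# pack the fitted degrees of freedom (A linear, B/kappa/kappa2 on log scale
# to keep them positive under the simplex) and the inverse
ee_pack <- function(params, rows, fit_kappa) {
  v <- c(rbind(params$entries$A[rows], log(params$entries$B[rows])))
  if (fit_kappa) v <- c(v, log(params$kappa), log(params$kappa2))
  v
}

ee_unpack <- function(v, params, rows, fit_kappa) {
  k <- length(rows)
  params$entries$A[rows] <- v[seq(1, 2 * k, by = 2)]
  params$entries$B[rows] <- exp(v[seq(2, 2 * k, by = 2)])
  if (fit_kappa) {
    params$kappa <- exp(v[2 * k + 1])
    params$kappa2 <- exp(v[2 * k + 2])
  }
  params
}

# RMSE between solved and target charges, all atoms weighted equally
ee_charge_rmse <- function(params, training) {
  se <- 0
  m <- 0
  for (rec in training) {
    q <- solve_charges(rec$mol, cn = rec$cn, params = params)$charges
    se <- se + sum((q - rec$targets)^2)
    m <- m + length(q)
  }
  sqrt(se / m)
}

#' Refit equalization parameters against target charges
#'
#' Derivative-free least-squares refinement of the `(A, B)` rows used by
#' the training molecules, jointly with `kappa` and `kappa2`, by the
#' downhill simplex (Nelder-Mead) algorithm.  The objective is the RMSE
#' between solved and target charges over all atoms of all molecules
#' (atoms weighted equally).
#'
#' @param training list of records, each a list with fields `mol` (a
#'   `gb_molecule`), optional `cn` (precomputed coordination numbers), and
#'   `targets` (per-atom target charges summing to the molecule's total
#'   charge).
#' @param initial starting `gb_ee_params`.
#' @param max_iter maximum simplex iterations.
#' @param tol relative convergence tolerance on the RMSE.
#' @param fit_kappa also optimize the global lengths kappa, kappa2.
#' @return list with `params` (refitted `gb_ee_params`), `rmse` (final
#'   charge RMSE, e), `initial_rmse`, and `convergence` (0 = converged).
#'   Non-convergence at `max_iter` raises a warning and returns the best
#'   point found.
#' @export
fit_ee_parameters <- function(training, initial = ee_parameters(),
                              max_iter = 2000, tol = 1e-6, fit_kappa = TRUE) {
  stopifnot(length(training) >= 1)
  for (rec in training) {
    if (abs(sum(rec$targets) - rec$mol$charge) > 1e-6) {
      stop("target charges must sum to the molecule's total charge",
           call. = FALSE)
    }
  }
  # parameter rows actually exercised by the training molecules
  used <- integer(0)
  training <- lapply(training, function(rec) {
    if (is.null(rec$cn)) rec$cn <- coordination_numbers(rec$mol, params = initial)
    rec
  })
  for (rec in training) {
    used <- c(used, vapply(seq_len(n_atoms(rec$mol)), function(i) {
      ee_row_index(initial, rec$mol$symbols[i], rec$cn[i])
    }, integer(1)))
  }
  rows <- sort(unique(used))
  objective <- function(v) {
    ee_charge_rmse(ee_unpack(v, initial, rows, fit_kappa), training)
  }
  v0 <- ee_pack(initial, rows, fit_kappa)
  rmse0 <- objective(v0)
  opt <- optim(v0, objective, method = "Nelder-Mead",
               control = list(maxit = max_iter, reltol = tol))
  if (opt$convergence != 0) {
    warning("simplex did not converge within ", max_iter,
            " iterations; returning best parameters found", call. = FALSE)
  }
  best <- if (opt$value <= rmse0) opt$par else v0
  list(params = ee_unpack(best, initial, rows, fit_kappa),
       rmse = min(opt$value, rmse0),
       initial_rmse = rmse0,
       convergence = opt$convergence)
}
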