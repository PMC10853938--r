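#' Load the solvent registry
#'
#' The registry supplies the three bulk solvent descriptors used as input
#' features for nonaqueous predictions: dielectric constant, normal boiling
#' point, and the number of non-hydrogen atoms per solvent molecule.  The
#' bundled table covers common laboratory solvents; any file in the same
#' four-column tsv layout can be substituted.
#'
#' @param path optional custom registry file.
#' @return data.frame with columns `name`, `epsilon`, `bp_c`, `heavy_atoms`.
#' @export
load_solvents <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.gbsolv_cache$solvents)) return(.gbsolv_cache$solvents)
  tab <- read_tsv_table(if (default) extdata_path("solvents.tsv") else path)
  needed <- c("name", "epsilon", "bp_c", "heavy_atoms")
  if (!all(needed %in% names(tab))) {
    stop("solvent registry must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$epsilon <= 1)) stop("solvent epsilon must exceed 1", call. = FALSE)
  if (any(tab$heavy_atoms < 1)) stop("heavy_atoms must be >= 1", call. = FALSE)
  if (default) .gbsolv_cache$solvents <- tab
  tab
}

#' Write a solvent registry file
#' @param table data.frame in the [load_solvents()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solvents <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a solvent descriptor
#'
#' Case-insensitive match against the registry.  Water is flagged as the
#' aqueous model's solvent; everything else routes to the nonaqueous model.
#'
#' @param name solvent name.
#' @param table registry data.frame, default [load_solvents()].
#' @return object of class `gb_solvent`: `name`, `epsilon`, `bp`,
#'   `heavy_atoms`, `aqueous`.
#' @export
lookup_solvent <- function(name, table = load_solvents()) {
  idx <- match(tolower(trimws(name)), tolower(table$name))
  if (is.na(idx)) {
    stop("unknown solvent '", name, "'; available: ",
         paste(sort(table$name), collapse = ", "), call. = FALSE)
  }
  structure(list(name = table$name[idx],
                 epsilon = table$epsilon[idx],
                 bp = table$bp_c[idx],
                 heavy_atoms = as.integer(table$heavy_atoms[idx]),
                 aqueous = tolower(table$name[idx]) == "water"),
            class = "gb_solvent")
}

#' @export
print.gb_solvent <- function(x, ...) {
  cat(sprintf("<gb_solvent> %s: eps=%.2f, bp=%.1f C, heavy atoms=%d%s\n",
              x$name, x$epsilon, x$bp, x$heavy_atoms,
              if (x$aqueous) " (aqueous)" else ""))
  invisible(x)
}
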