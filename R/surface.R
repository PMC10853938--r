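# Per-atom exposed van der Waals surface areas and volumes by pairwise
# spherical-cap subtraction.  Exact for isolated and pairwise-overlapping
# spheres; an estimate (deliberately simple) under multiple overlap.

#' Buried spherical-cap geometry for two overlapping spheres
#'
#' For spheres of radii `R_I`, `R_J` whose centers are `r_IJ` apart, the
#' crossing plane sits at signed offset `a = (r_IJ^2 + R_I^2 - R_J^2) /
#' (2 r_IJ)` from center I (negative when the plane lies behind it).  The
#' cap of sphere I buried inside J has height `h = R_I - a`, clamped to
#' `[0, 2 R_I]`, area `2 pi R_I h` and volume `pi h^2 (3 R_I - h) / 3`.
#' Non-overlapping spheres give zero; full burial gives the whole sphere.
#'
#' @param R_I,R_J sphere radii (Angstrom), > 0.
#' @param r_IJ center separation (Angstrom), > 0; vectorized.
#' @return list with numeric fields `a` (Angstrom), `dS` (Angstrom^2),
#'   `dV` (Angstrom^3).
#' @examples
#' cap_geometry(1.7, 1.7, 1.7)  # two equal spheres at r = R
#' @export
cap_geometry <- function(R_I, R_J, r_IJ) {
  if (any(R_I <= 0) || any(R_J <= 0)) {
    stop("sphere radii must be positive", call. = FALSE)
  }
  if (any(r_IJ <= 0) || any(!is.finite(r_IJ))) {
    stop("center separation must be positive and finite", call. = FALSE)
  }
  a <- (r_IJ^2 + R_I^2 - R_J^2) / (2 * r_IJ)
  h <- pmin(pmax(R_I - a, 0), 2 * R_I)
  # no geometric overlap -> no buried cap, regardless of the formal h
  h[r_IJ >= R_I + R_J] <- 0
  # sphere I entirely inside J
  h[r_IJ + R_I <= R_J] <- 2 * R_I
  list(a = a, dS = 2 * pi * R_I * h, dV = pi * h^2 * (3 * R_I - h) / 3)
}

#' Exposed atomic surface areas and volumes
#'
#' `S_I = max(0, 4 pi R_I^2 - sum_J dS_IJ)` and
#' `V_I = max(0, 4/3 pi R_I^3 - sum_J dV_IJ)`, the sums running over all
#' atoms J whose van der Waals sphere overlaps atom I's
#' (`r_IJ < R_I + R_J`); a `bonded` mode restricts the sum to covalently
#' bonded neighbors for sensitivity checks.  Negative values arising from
#' heavy multiple overlap are clamped at zero.
#'
#' @param mol a `gb_molecule`.
#' @param radii named van der Waals radius vector, default [bondi_radii()].
#' @param adjacency `"overlap"` (default) or `"bonded"`.
#' @param clamp clamp negative per-atom values at 0 (default TRUE).
#' @param tolerance covalent cutoff factor for `adjacency = "bonded"`.
#' @return object of class `gb_surfvol`: per-atom `S` (Angstrom^2) and `V`
#'   (Angstrom^3) plus totals `S_tot`, `V_tot`.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' surface_volume(h2)
#' @export
surface_volume <- function(mol, radii = bondi_radii(),
                           adjacency = c("overlap", "bonded"),
                           clamp = TRUE, tolerance = 1.2) {
  adjacency <- match.arg(adjacency)
  n <- n_atoms(mol)
  R <- lookup_radius(mol$symbols, radii)
  S <- 4 * pi * R^2
  V <- 4 / 3 * pi * R^3
  if (n > 1) {
    d <- distance_matrix(mol)
    adjacent <- d < outer(R, R, `+`)
    if (adjacency == "bonded") {
      rc <- covalent_radii()[mol$symbols]
      adjacent <- adjacent & (d <= tolerance * outer(rc, rc, `+`))
    }
    diag(adjacent) <- FALSE
    for (i in seq_len(n)) {
      js <- which(adjacent[i, ])
      if (length(js)) {
        cap <- cap_geometry(R[i], R[js], d[i, js])
        S[i] <- S[i] - sum(cap$dS)
        V[i] <- V[i] - sum(cap$dV)
      }
    }
    if (clamp) {
      S <- pmax(S, 0)
      V <- pmax(V, 0)
    }
  }
  structure(list(S = S, V = V, S_tot = sum(S), V_tot = sum(V)),
            class = "gb_surfvol")
}

#' @export
print.gb_surfvol <- function(x, ...) {
  cat(sprintf("<gb_surfvol> %d atoms: S_tot=%.2f A^2, V_tot=%.2f A^3\n",
              length(x$S), x$S_tot, x$V_tot))
  invisible(x)
}

#' Per-atom exposed surface areas
#' @inheritParams surface_volume
#' @param ... passed on to [surface_volume()].
#' @return numeric vector of per-atom areas (Angstrom^2).
#' @export
atomic_surfaces <- function(mol, radii = bondi_radii(), ...) {
  surface_volume(mol, radii, ...)$S
}

#' Per-atom exposed volumes
#' @inheritParams surface_volume
#' @param ... passed on to [surface_volume()].
#' @return numeric vector of per-atom volumes (Angstrom^3).
#' @export
atomic_volumes <- function(mol, radii = bondi_radii(), ...) {
  surface_volume(mol, radii, ...)$V
}
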