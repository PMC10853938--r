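# geometries and independent oracles shared across the suite

fix_h2 <- function() {
  molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
}

fix_hcl <- function() {
  molecule(c("H", "Cl"), rbind(c(0, 0, 0), c(1.27, 0, 0)))
}

fix_water <- function() {
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0), c(-0.757, 0.586, 0), c(0.757, 0.586, 0)))
}

fix_methane <- function() {
  a <- 0.629
  molecule(c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(a, a, a), c(-a, -a, a), c(-a, a, -a),
                 c(a, -a, -a)))
}

rotate_mol <- function(mol, axis = c(1, 2, 2), angle = 0.7,
                       shift = c(1.5, -2, 0.5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  molecule(mol$symbols,
           sweep(mol$coords %*% t(R), 2, shift, `+`),
           mol$charge)
}

# Monte-Carlo estimate of the cap area of sphere I buried inside sphere J:
# uniform points on sphere I's surface, fraction falling inside J
mc_cap_area <- function(R_I, R_J, r, n = 1e5, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(3 * n), n, 3)
  p <- R_I * p / sqrt(rowSums(p^2))
  inside <- (p[, 1] - r)^2 + p[, 2]^2 + p[, 3]^2 < R_J^2
  frac <- mean(inside)
  list(value = frac * 4 * pi * R_I^2,
       se = 4 * pi * R_I^2 * sqrt(frac * (1 - frac) / n))
}

# Monte-Carlo estimate of the lens (intersection) volume of two spheres:
# uniform points in sphere I, fraction also inside J.  The lens decomposes
# into the cap of I buried in J plus the cap of J buried in I, so the
# analytic counterpart is dV_IJ + dV_JI.
mc_lens_volume <- function(R_I, R_J, r, n = 1e5, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- R_I * runif(n)^(1 / 3)
  p <- u * rad
  inside <- (p[, 1] - r)^2 + p[, 2]^2 + p[, 3]^2 < R_J^2
  frac <- mean(inside)
  vol <- 4 / 3 * pi * R_I^3
  list(value = frac * vol, se = vol * sqrt(frac * (1 - frac) / n))
}

# Monte-Carlo exposed-surface estimate for a whole molecule
mc_exposed_surface <- function(mol, radii = bondi_radii(), n = 2e4,
                               seed = 1) {
  set.seed(seed)
  R <- lookup_radius(mol$symbols, radii)
  vapply(seq_len(n_atoms(mol)), function(i) {
    p <- matrix(rnorm(3 * n), n, 3)
    p <- sweep(R[i] * p / sqrt(rowSums(p^2)), 2, mol$coords[i, ], `+`)
    exposed <- rep(TRUE, n)
    for (j in seq_len(n_atoms(mol))[-i]) {
      d2 <- rowSums(sweep(p, 2, mol$coords[j, ])^2)
      exposed <- exposed & d2 >= R[j]^2
    }
    mean(exposed) * 4 * pi * R[i]^2
  }, numeric(1))
}

# closed-form solution of the two-atom equalization system by symbolic
# elimination: 2*B1*Q1 + Y*Q2 - chi = -A1 ; Y*Q1 + 2*B2*Q2 - chi = -A2 ;
# Q1 + Q2 = Qtot.  Subtracting the first two rows and substituting the
# constraint gives one linear equation in Q1.
ee_oracle_2atoms <- function(A, B, Y, Qtot) {
  # (2*B1 - Y)*Q1 - (2*B2 - Y)*Q2 = A2 - A1 with Q2 = Qtot - Q1
  q1 <- ((A[2] - A[1]) + (2 * B[2] - Y) * Qtot) /
    ((2 * B[1] - Y) + (2 * B[2] - Y))
  q2 <- Qtot - q1
  chi <- A[1] + 2 * B[1] * q1 + Y * q2
  list(charges = c(q1, q2), chi = chi)
}

# three-atom oracle via Cramer's rule on the explicitly written 4x4 system
ee_oracle_3atoms <- function(A, B, Y12, Y13, Y23, Qtot) {
  M <- rbind(c(2 * B[1], Y12, Y13, -1),
             c(Y12, 2 * B[2], Y23, -1),
             c(Y13, Y23, 2 * B[3], -1),
             c(1, 1, 1, 0))
  b <- c(-A, Qtot)
  detM <- det(M)
  x <- vapply(1:4, function(k) {
    Mk <- M
    Mk[, k] <- b
    det(Mk) / detM
  }, numeric(1))
  list(charges = x[1:3], chi = x[4])
}

# ee-parameter helpers used by solver tests
ee_AB_for <- function(mol, params = ee_parameters()) {
  cn <- coordination_numbers(mol, params = params)
  rows <- vapply(seq_len(n_atoms(mol)), function(i) {
    gbsolv:::ee_row_index(params, mol$symbols[i], cn[i])
  }, integer(1))
  list(A = params$entries$A[rows], B = params$entries$B[rows])
}
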