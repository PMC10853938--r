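test_that("the molecule generator is deterministic, respects size bounds, and builds plausible clusters", {
  m1 <- random_molecule(42)
  m2 <- random_molecule(42)
  expect_identical(m1$symbols, m2$symbols)
  expect_identical(m1$coords, m2$coords)
  expect_identical(m1$charge, m2$charge)

  single <- random_molecule(7, size_range = c(1, 1))
  expect_equal(n_atoms(single), 1)

  rc <- covalent_radii()
  for (s in 1:60) {
    m <- random_molecule(s, size_range = c(2, 12))
    d <- distance_matrix(m)
    diag(d) <- Inf
    # connected: every atom has a neighbor within 1.1 * 1.2 covalent sums
    cut <- outer(rc[m$symbols], rc[m$symbols], `+`)
    expect_true(all(apply(d <= 1.15 * cut, 1, any)))
    # no fused atoms
    expect_true(all(d[upper.tri(d)] >= 0.75 * cut[upper.tri(cut)]))
    expect_true(m$charge %in% -1:1)
  }
})

test_that("generated geometries always yield finite features end to end", {
  solv <- lookup_solvent("acetonitrile")
  schema <- gb_schema(aqueous = FALSE)
  for (s in seq(1, 400, by = 4)) {
    m <- random_molecule(s, size_range = c(1, 14))
    f <- compute_features(m, solv, schema = schema)
    expect_true(all(is.finite(f)))
  }
})

test_that("dielectric extrapolation obeys its identities and monotonicity", {
  base <- solvation_record(mol = NULL, solvent = "dimethyl sulfoxide",
                           dG_ref = -60)
  eps_real <- base$solvent$epsilon
  # identity at eps_new = eps_real
  same <- extrapolate_ionic(base, eps_real, electrostatic_part = -45)
  expect_equal(same$dG_ref, -60, tolerance = 1e-12)
  expect_identical(same$origin, "extrapolated")
  # pure-nonelectrostatic limit: no dependence on the new dielectric
  for (e in c(12, 60, 150)) {
    expect_equal(extrapolate_ionic(base, e, electrostatic_part = 0)$dG_ref, -60)
  }
  # negative electrostatic part: |target| grows with eps_new
  eps_grid <- c(15, 30, 60, 120, 190)
  targets <- vapply(eps_grid, function(e) {
    extrapolate_ionic(base, e, electrostatic_part = -45)$dG_ref
  }, numeric(1))
  expect_true(all(diff(targets) < 0))
  expect_error(extrapolate_ionic(base, 5, electrostatic_part = -45), "within")
  expect_error(extrapolate_ionic(base, 250, electrostatic_part = -45), "within")
})

test_that("extrapolation computes the electrostatic share from the geometry when not supplied", {
  ion <- random_molecule(11, size_range = c(3, 5), charge = -1L,
                         element_weights = c(H = 2, C = 2, O = 2))
  rec <- solvation_record(ion, "dimethyl sulfoxide", dG_ref = -65)
  out <- extrapolate_ionic(rec, 100)
  elst <- gb_electrostatic(solve_charges(ion), ion,
                           epsilon = rec$solvent$epsilon)
  scale <- (1 - 1 / 100) / (1 - 1 / rec$solvent$epsilon) - 1
  expect_equal(out$dG_ref, -65 + elst * scale, tolerance = 1e-10)
  # geometry and charge are untouched by augmentation
  expect_identical(out$mol$coords, ion$coords)
  expect_identical(out$mol$charge, ion$charge)
  # neutral records are refused
  neut <- solvation_record(random_molecule(3, charge = 0L), "methanol", -5)
  expect_error(extrapolate_ionic(neut, 50), "ionic")
})

test_that("boiling-point replication copies records without touching targets", {
  rec <- solvation_record(mol = NULL, solvent = "acetonitrile", dG_ref = -55)
  one <- replicate_boiling_points(rec, rec$solvent$bp)
  expect_length(one, 1)
  expect_identical(one[[1]], rec)
  grid <- c(50, 90, 130, 170)
  out <- replicate_boiling_points(rec, grid)
  expect_length(out, 4)
  expect_equal(vapply(out, function(r) r$solvent$bp, numeric(1)), grid)
  expect_true(all(vapply(out, function(r) r$dG_ref, numeric(1)) == -55))
  expect_true(all(vapply(out, function(r) r$origin, "") == "replicated"))
  expect_error(replicate_boiling_points(rec, c(90, 300)), "within")
})

test_that("dataset generation is reproducible and reproduces the class mix", {
  d1 <- make_dataset(60, seed = 5)
  d2 <- make_dataset(60, seed = 5)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$raw, d2$raw)
  mix <- make_dataset(100, seed = 6,
                      class_mix = c(neutral = 0.8, cation = 0.1, anion = 0.1))
  counts <- table(mix$meta$class)
  expect_lte(abs(counts[["neutral"]] - 80), 1)
  expect_lte(abs(counts[["cation"]] - 10), 1)
  expect_lte(abs(counts[["anion"]] - 10), 1)
  # declared truth: labels are exactly linear in the reduced features
  expect_equal(drop(mix$reduced %*% mix$truth$coef) + mix$truth$intercept,
               mix$truth$y_true, tolerance = 1e-10)
  # ionic records carry the elevated default weight
  expect_true(all(mix$weights[mix$meta$class != "neutral"] == 3))
})

test_that("a constant label rule trains to a constant predictor", {
  ds <- make_dataset(200, seed = 2, label_rule = function(z) rep(-5, nrow(z)),
                     sigma = 0)
  suppressWarnings(
    fit <- train_network(ds$reduced, ds$y,
                         config = training_config(epochs = 400,
                                                  batch_size = 64, seed = 1),
                         hidden = c(14, 7)))
  pred <- predict(fit$net, ds$reduced)
  expect_lt(abs(mean(pred) + 5), 0.2)
  expect_lt(median(abs(pred + 5)), 0.15)
})

test_that("the dataset training table round-trips to CSV in the training layout", {
  ds <- make_dataset(25, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 25)
  expect_true(all(c("solvent", "class", "dG_ref", "weight") %in% names(tab)))
  expect_true(all(ds$schema$names %in% names(tab)))
  expect_equal(tab$dG_ref, ds$y, tolerance = 1e-10)
})
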