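# End-to-end solvation model: feature transform + dense network + schema,
# trained and serialized together.

#' Train a solvation model from raw feature vectors
#'
#' Fits the dimensionality-reducing transform on the raw feature matrix,
#' then trains the dense network on the reduced features.  Hidden sizes
#' default to the aqueous architecture `(16, 8)` for aqueous schemas and
#' `(14, 7)` otherwise.
#'
#' @param raw numeric matrix of raw feature vectors (rows = records).
#' @param y solvation free energies, kcal/mol.
#' @param schema the `gb_schema` the features were assembled with.
#' @param weights per-record loss weights.
#' @param config a [training_config()].
#' @param n_drop components dropped by the transform, default 9.
#' @param hidden hidden layer sizes; NULL picks the schema default.
#' @param l2 L2 regularization strength.
#' @param strata optional stratification factor for the validation split
#'   (e.g. solute charge class).
#' @return object of class `gb_solvation_model`: `transform`, `net`,
#'   `schema`, `metrics_train`, `metrics_val`, `history`.
#' @export
train_solvation_model <- function(raw, y, schema, weights = NULL,
                                  config = training_config(), n_drop = 9,
                                  hidden = NULL, l2 = 0.01, strata = NULL) {
  raw <- as.matrix(raw)
  if (ncol(raw) != schema$length) {
    stop("raw feature width ", ncol(raw), " does not match schema length ",
         schema$length, call. = FALSE)
  }
  if (is.null(hidden)) hidden <- if (schema$aqueous) c(16, 8) else c(14, 7)
  transform <- fit_transform(raw, n_drop = n_drop)
  reduced <- apply_transform(transform, raw)
  fit <- train_network(reduced, y, weights = weights, config = config,
                       hidden = hidden, l2 = l2, strata = strata)
  structure(list(transform = transform, net = fit$net, schema = schema,
                 metrics_train = fit$metrics_train,
                 metrics_val = fit$metrics_val,
                 history = fit$history),
            class = "gb_solvation_model")
}

#' @export
print.gb_solvation_model <- function(x, ...) {
  cat(sprintf("<gb_solvation_model> %s, %d -> %d features, net %s\n",
              if (x$schema$aqueous) "aqueous" else "nonaqueous",
              x$schema$length, x$transform$reduced_dim,
              paste(x$net$sizes, collapse = "-")))
  if (!is.null(x$metrics_val)) {
    cat(sprintf("  validation RMSE %.3f kcal/mol\n", x$metrics_val[["rmse"]]))
  }
  invisible(x)
}

#' Predict a solvation free energy
#'
#' Runs the whole pipeline for one geometry: coordination numbers, EE
#' charges, surfaces/volumes, Born terms, feature transform, network
#' forward pass.
#'
#' @param model a `gb_solvation_model`.
#' @param mol a `gb_molecule` (or path to an XYZ file).
#' @param solvent a `gb_solvent` or solvent name.
#' @param params a `gb_ee_params`.
#' @return predicted solvation free energy, kcal/mol.
#' @export
predict_solvation <- function(model, mol, solvent = "water",
                              params = ee_parameters()) {
  if (is.character(mol)) mol <- read_xyz(mol)
  if (is.character(solvent)) solvent <- lookup_solvent(solvent)
  raw <- compute_features(mol, solvent, schema = model$schema, params = params)
  predict(model$net, apply_transform(model$transform, raw))
}

#' Serialize a solvation model to a portable text archive
#'
#' JSON container holding the schema, transform, and network weights at
#' full double precision.
#'
#' @param model a `gb_solvation_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "gbsolv-model",
    version = 1L,
    schema = list(aqueous = model$schema$aqueous,
                  pair_el1 = model$schema$pairs$el1,
                  pair_el2 = model$schema$pairs$el2),
    transform = list(center = model$transform$center,
                     scale = model$transform$scale,
                     rotation = model$transform$rotation,
                     post_scale = model$transform$post_scale),
    net = list(sizes = model$net$sizes, l2 = model$net$l2,
               layers = lapply(model$net$layers,
                               function(l) list(W = l$W, b = l$b))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a solvation model archive
#' @param path path written by [save_model()].
#' @return a `gb_solvation_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "gbsolv-model")) {
    stop(path, " is not a gbsolv model archive", call. = FALSE)
  }
  schema <- gb_schema(aqueous = p$schema$aqueous,
                      pairs = data.frame(el1 = unlist(p$schema$pair_el1),
                                         el2 = unlist(p$schema$pair_el2),
                                         stringsAsFactors = FALSE))
  rotation <- as.matrix(p$transform$rotation)
  transform <- structure(list(center = as.numeric(p$transform$center),
                              scale = as.numeric(p$transform$scale),
                              rotation = rotation,
                              post_scale = as.numeric(p$transform$post_scale),
                              reduced_dim = ncol(rotation)),
                         class = "gb_transform")
  layers <- lapply(p$net$layers, function(l) {
    W <- as.matrix(l$W)
    list(W = W, b = as.numeric(l$b))
  })
  net <- structure(list(sizes = as.integer(p$net$sizes), l2 = p$net$l2,
                        layers = layers),
                   class = "gb_network")
  structure(list(transform = transform, net = net, schema = schema,
                 metrics_train = NULL, metrics_val = NULL, history = NULL),
            class = "gb_solvation_model")
}
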