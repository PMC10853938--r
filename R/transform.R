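# Dimensionality reduction: z-score the raw features, project onto the
# leading principal components (raw dim minus n_drop of them), then whiten
# each component so the network sees unit-variance inputs.

#' Fit the dimensionality-reducing feature transform
#'
#' Standardizes each raw feature (constant columns get unit scale) and
#' computes the principal components by singular value decomposition,
#' retaining the leading `raw_dim - n_drop` of them.  Component signs are
#' fixed by making the largest-absolute loading of each component
#' positive, so the transform is deterministic.
#'
#' @param raw numeric matrix, rows = records, columns = raw features
#'   (length 58 aqueous / 61 nonaqueous for the default schemas).
#' @param n_drop number of trailing components to drop, default 9.
#' @param whiten also divide each retained component by its standard
#'   deviation.  Off by default, matching the usual PCA convention of
#'   projecting standardized data without rescaling the scores; the
#'   `post_scale` divisors are then all 1.
#' @return object of class `gb_transform`: `center`, `scale` (per raw
#'   feature), `rotation` (raw_dim x reduced_dim), `post_scale` (per
#'   component divisors applied after projection), `reduced_dim`.
#' @export
fit_transform <- function(raw, n_drop = 9, whiten = FALSE) {
  raw <- as.matrix(raw)
  p <- ncol(raw)
  k <- p - n_drop
  if (k < 1) stop("n_drop leaves no components", call. = FALSE)
  center <- colMeans(raw)
  scale <- apply(raw, 2, sd)
  scale[scale < .Machine$double.eps] <- 1
  z <- sweep(sweep(raw, 2, center), 2, scale, `/`)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < k || pc$sdev[k] < 1e-10) {
    stop("feature matrix has rank below the target dimension ", k,
         call. = FALSE)
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-absolute loading positive
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  structure(list(center = center, scale = scale, rotation = rot,
                 post_scale = if (whiten) pc$sdev[seq_len(k)] else rep(1, k),
                 reduced_dim = k),
            class = "gb_transform")
}

#' @export
print.gb_transform <- function(x, ...) {
  cat(sprintf("<gb_transform> %d -> %d features\n",
              length(x$center), x$reduced_dim))
  invisible(x)
}

#' Apply the feature transform
#'
#' `reduced = diag(1/post_scale) %*% t(rotation) %*% ((raw - center) /
#' scale)`: an affine map, linear and deterministic.
#'
#' @param transform a `gb_transform`.
#' @param raw numeric vector of raw features, or a matrix with one record
#'   per row.
#' @return reduced feature vector (or matrix with `reduced_dim` columns).
#' @export
apply_transform <- function(transform, raw) {
  vec <- is.null(dim(raw))
  m <- if (vec) t(as.matrix(raw)) else as.matrix(raw)
  if (ncol(m) != length(transform$center)) {
    stop("raw feature length ", ncol(m), " does not match transform input ",
         length(transform$center), call. = FALSE)
  }
  z <- sweep(sweep(m, 2, transform$center), 2, transform$scale, `/`)
  out <- sweep(z %*% transform$rotation, 2, transform$post_scale, `/`)
  if (vec) drop(out) else out
}
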