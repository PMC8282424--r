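# Structure-preserving H&E color normalization by sparse stain separation.
#
# The model: a pixel's transmitted intensity I relates to stain
# concentration through Beer-Lambert, X = -log(I / I0), and the OD image
# factorizes as X ~ W L with W (3 x r) the per-stain color-appearance
# (absorbance) matrix and L (r x n) the nonnegative stain-density map.
# W and L are estimated by minimizing
#
#   0.5 * ||X - W L||_F^2 + lambda * sum_j ||L[j, ]||_1,   W, L >= 0
#
# with exact cyclic coordinate-descent block updates, which makes the
# objective non-increasing at every iteration. Normalization rescales each
# source density row to the target's 99% pseudo-maximum and recombines with
# the target's color matrix, so tissue structure (the spatial pattern of L)
# is preserved while color appearance is transferred.

#' Configuration for stain separation and normalization
#'
#' @param I0 illumination level (white point), default 255
#' @param lambda sparsity weight on the density map, default 0.1
#' @param r number of stains, default 2 (hematoxylin + eosin)
#' @param pseudo_max_percentile quantile used as the robust per-stain
#'   density maximum, default 0.99
#' @param od_background_threshold OD norm below which a pixel is treated as
#'   glass/background and excluded from fitting, default 0.15
#' @param seed integer seed (controls the fitting subsample)
#' @param max_iter maximum alternations of the W/L updates
#' @param tol relative objective change for convergence
#' @param max_pixels tissue-pixel subsample size used to learn W
#' @return an object of class `norm_config`
#' @export
norm_config <- function(I0 = 255, lambda = 0.1, r = 2,
                        pseudo_max_percentile = 0.99,
                        od_background_threshold = 0.15,
                        seed = 1L, max_iter = 200, tol = 1e-4,
                        max_pixels = 20000) {
  assert_scalar_number(I0, "I0", lower = 1)
  assert_scalar_number(lambda, "lambda", lower = 0)
  assert_scalar_number(r, "r", lower = 1)
  assert_scalar_number(pseudo_max_percentile, "pseudo_max_percentile",
                       lower = 1e-9, upper = 1)
  structure(list(I0 = I0, lambda = lambda, r = as.integer(r),
                 pseudo_max_percentile = pseudo_max_percentile,
                 od_background_threshold = od_background_threshold,
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 tol = tol, max_pixels = as.integer(max_pixels)),
            class = "norm_config")
}

#' Convert an RGB image to optical density
#'
#' X = -log(max(I, 1) / I0) per channel (intensities are clipped to >= 1 so
#' OD stays finite).
#'
#' @param image RGB array (height x width x 3)
#' @param config a [norm_config()]
#' @return object of class `od_image`: list with `X` (3 x n_pixels matrix),
#'   `shape` (height, width) and `I0`
#' @export
rgb_to_od <- function(image, config = norm_config()) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  X <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  X <- -log(pmax(X, 1) / config$I0)
  structure(list(X = X, shape = c(h, w), I0 = config$I0), class = "od_image")
}

#' Convert an optical-density image back to RGB
#'
#' Inverse of [rgb_to_od()]: I = round(I0 * exp(-X)), clipped to 8 bits.
#'
#' @param od an `od_image` (or a bare 3 x n matrix plus `shape`)
#' @param shape (height, width); taken from `od` when omitted
#' @param I0 illumination level; taken from `od` when omitted
#' @return RGB array
#' @export
od_to_rgb <- function(od, shape = NULL, I0 = NULL) {
  if (inherits(od, "od_image")) {
    X <- od$X; shape <- shape %||% od$shape; I0 <- I0 %||% od$I0
  } else {
    X <- od
    if (is.null(shape) || is.null(I0)) stop("shape and I0 required")
  }
  img <- array(0, c(shape, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(pmin(pmax(round(I0 * exp(-X[ch, ])), 0), 255),
                          shape[1], shape[2])
  }
  img
}

#' Robust per-stain density maximum
#'
#' The empirical `percentile` quantile (linear interpolation) of a density
#' row; at percentile 1 this is the row maximum.
#'
#' @param L_row nonnegative numeric vector
#' @param percentile fraction in (0, 1]
#' @return scalar quantile
#' @export
pseudo_max <- function(L_row, percentile = 0.99) {
  if (length(L_row) == 0) stop("empty density row", call. = FALSE)
  assert_scalar_number(percentile, "percentile", lower = 1e-9, upper = 1)
  stats::quantile(L_row, percentile, names = FALSE, type = 7)
}

# The optimizer works on the scale-invariant form of the objective,
#
#   f(W, L) = 0.5 * ||X - W L||_F^2 + lambda * sum_j ||W_j||_2 ||L_j||_1 ,
#
# which equals the unit-norm-constrained objective at ||W_j|| = 1 and is
# unchanged by the rescaling (W_j, L_j) -> (a W_j, L_j / a). Every block
# update below is an exact minimizer, so f is non-increasing per pass, and
# the final column normalization leaves f (and W L) untouched.

# one exact cyclic coordinate-descent pass over the rows of L
# (nonnegative lasso given fixed W); vectorized across pixels
cd_L_pass <- function(X, W, L, lambda) {
  G <- crossprod(W)              # r x r
  B <- crossprod(W, X)           # r x n
  wnorm <- sqrt(diag(G))
  r <- nrow(L)
  for (j in seq_len(r)) {
    if (G[j, j] <= 1e-12) next
    resid <- B[j, ] - if (r > 1) G[j, -j, drop = FALSE] %*% L[-j, , drop = FALSE] else 0
    L[j, ] <- pmax(0, (resid - lambda * wnorm[j]) / G[j, j])
  }
  L
}

# exact cyclic coordinate-descent pass over the columns of W: each column
# solves a nonnegative group-soft-threshold problem
#   min_{w >= 0} 0.5 ||L_j||^2 ||w||^2 - <R_j L_j', w> + lambda ||L_j||_1 ||w||
cd_W_pass <- function(X, W, L, lambda) {
  H <- tcrossprod(L)             # r x r
  C <- tcrossprod(X, L)          # 3 x r
  l1 <- rowSums(L)
  r <- ncol(W)
  for (j in seq_len(r)) {
    if (H[j, j] <= 1e-12) next
    a <- C[, j] - if (r > 1) W[, -j, drop = FALSE] %*% H[-j, j, drop = FALSE] else 0
    a <- pmax(as.vector(a), 0)
    na <- sqrt(sum(a^2))
    scale <- if (na > 1e-12) max(0, na - lambda * l1[j]) / (H[j, j] * na) else 0
    W[, j] <- a * scale
  }
  W
}

stain_objective <- function(X, W, L, lambda) {
  0.5 * sum((X - W %*% L)^2) +
    lambda * sum(sqrt(colSums(W^2)) * rowSums(abs(L)))
}

# deterministic two-stain initialization: project tissue OD directions onto
# the top-2 eigenplane and take the 1%/99% angular extremes (for r > 2, an
# angular grid over the same plane). Operates on lexicographically sorted
# pixels so the result is invariant to pixel order.
init_stain_vectors <- function(Xt, r) {
  e <- eigen(tcrossprod(Xt), symmetric = TRUE)
  V <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- crossprod(V, Xt)
  phi <- atan2(proj[2, ], proj[1, ])
  qs <- if (r == 2) c(0.01, 0.99) else seq(0.01, 0.99, length.out = r)
  ang <- stats::quantile(phi, qs, names = FALSE, type = 7)
  W0 <- sapply(ang, function(a) {
    v <- V %*% c(cos(a), sin(a))
    v <- pmax(as.vector(v), 1e-6)
    v / sqrt(sum(v^2))
  })
  matrix(W0, nrow = 3)
}

#' Fit the sparse stain-separation model
#'
#' Alternates exact nonnegative-lasso updates of the density map L with
#' exact nonnegative least-squares updates of the color matrix W until the
#' objective's relative change falls below `config$tol`. W is learned on a
#' seeded subsample of at most `config$max_pixels` tissue pixels (pixels
#' whose OD norm exceeds the background threshold), then the returned
#' density map is solved for every pixel with W held fixed. Columns of the
#' returned W have unit Euclidean norm and are ordered so the first stain is
#' the more blue-absorbing (hematoxylin-like) one.
#'
#' @param od an `od_image` from [rgb_to_od()]
#' @param config a [norm_config()]
#' @return object of class `stain_model`: `W` (3 x r, unit-norm columns),
#'   `L` (r x n_pixels), `lambda`, `r`, `objective` (per-iteration trace),
#'   `tissue` (logical vector marking fitted pixels) and `shape`
#' @export
fit_stain_model <- function(od, config = norm_config()) {
  stopifnot(inherits(od, "od_image"))
  X <- od$X
  odnorm <- sqrt(colSums(X^2))
  tissue <- odnorm > config$od_background_threshold
  if (sum(tissue) < config$r) {
    stop("no tissue pixels above OD threshold", call. = FALSE)
  }
  Xt <- X[, tissue, drop = FALSE]
  # lexicographic sort makes the fit invariant to pixel permutation
  ord <- order(Xt[1, ], Xt[2, ], Xt[3, ])
  Xt <- Xt[, ord, drop = FALSE]
  if (ncol(Xt) > config$max_pixels) {
    keep <- with_seed(derive_seed(config$seed, "stain-subsample"),
                      sort(sample.int(ncol(Xt), config$max_pixels)))
    Xt <- Xt[, keep, drop = FALSE]
  }

  W <- init_stain_vectors(Xt, config$r)
  L <- matrix(0, config$r, ncol(Xt))
  L <- cd_L_pass(Xt, W, L, config$lambda)
  obj <- stain_objective(Xt, W, L, config$lambda)
  trace <- obj
  for (it in seq_len(config$max_iter)) {
    W <- cd_W_pass(Xt, W, L, config$lambda)
    for (s in 1:3) L <- cd_L_pass(Xt, W, L, config$lambda)
    obj_new <- stain_objective(Xt, W, L, config$lambda)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= config$tol * max(obj, 1e-12)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }

  # normalize columns to unit norm; the scale-invariant objective (and the
  # product W L) are unchanged by this
  norms <- sqrt(colSums(W^2))
  norms[norms < 1e-12] <- 1
  W <- sweep(W, 2, norms, "/")
  L <- L * norms
  # hematoxylin first: nuclei absorb strongly in red relative to green,
  # eosin almost only in green, so order by red/green absorbance ratio
  ratio <- (W[1, ] + 1e-6) / (W[2, ] + 1e-6)
  ordc <- order(ratio, decreasing = TRUE)
  W <- W[, ordc, drop = FALSE]

  # final density map for every pixel of the image, W fixed
  L_full <- stain_densities(od, W, lambda = config$lambda)

  structure(list(W = W, L = L_full, lambda = config$lambda, r = config$r,
                 objective = trace, tissue = tissue, shape = od$shape),
            class = "stain_model")
}

#' Solve the per-pixel stain densities for a fixed color matrix
#'
#' Convex nonnegative lasso per pixel (exact coordinate descent to
#' convergence). With `lambda = 0` this is plain nonnegative least squares,
#' the solve used when applying a normalization transform.
#'
#' @param od an `od_image`, or a bare 3 x n OD matrix
#' @param W 3 x r color-appearance matrix
#' @param lambda sparsity weight (default 0)
#' @param max_sweeps cap on coordinate sweeps
#' @return r x n density matrix
#' @export
stain_densities <- function(od, W, lambda = 0, max_sweeps = 100) {
  X <- if (inherits(od, "od_image")) od$X else od
  r <- ncol(W)
  L <- matrix(0, r, ncol(X))
  for (s in seq_len(max_sweeps)) {
    L_old <- L
    L <- cd_L_pass(X, W, L, lambda)
    if (max(abs(L - L_old)) < 1e-9) break
  }
  L
}

#' Normalize the color appearance of a source image to a target image
#'
#' Both images are stain-separated; every source density row is rescaled by
#' the ratio of the target's to the source's pseudo-maximum (computed on
#' tissue pixels); the scaled densities are recombined with the **target's**
#' color matrix and exponentiated back to RGB. The spatial structure of the
#' source densities is preserved up to that per-row scaling.
#'
#' @param source,target RGB arrays
#' @param config a [norm_config()]
#' @return normalized RGB array with attribute `stain_info` (fitted models,
#'   per-stain pseudo-maxima and scale factors)
#' @export
normalize_to_target <- function(source, target, config = norm_config()) {
  assert_rgb(source, "source"); assert_rgb(target, "target")
  od_s <- rgb_to_od(source, config)
  od_t <- rgb_to_od(target, config)
  fit_s <- fit_stain_model(od_s, config)
  fit_t <- fit_stain_model(od_t, config)

  Ls <- stain_densities(od_s, fit_s$W, lambda = 0)
  Lt <- stain_densities(od_t, fit_t$W, lambda = 0)
  pm_s <- apply(Ls[, fit_s$tissue, drop = FALSE], 1, pseudo_max,
                percentile = config$pseudo_max_percentile)
  pm_t <- apply(Lt[, fit_t$tissue, drop = FALSE], 1, pseudo_max,
                percentile = config$pseudo_max_percentile)
  factors <- ifelse(pm_s > 1e-8, pm_t / pm_s, 1)

  L_norm <- Ls * factors
  X_norm <- fit_t$W %*% L_norm
  out <- od_to_rgb(X_norm, shape = dim(source)[1:2], I0 = config$I0)
  attr(out, "stain_info") <- list(model_source = fit_s, model_target = fit_t,
                                  pseudo_max_source = pm_s,
                                  pseudo_max_target = pm_t,
                                  factors = factors)
  out
}
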