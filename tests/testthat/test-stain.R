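# Stain separation and normalization: OD round trips, the sparse
# factorization contract, pseudo-maximum quantiles, and the
# structure-preserving normalization transform.

test_that("OD conversion is the Beer-Lambert log with exact special cases", {
  cfg <- norm_config()
  img <- array(255, c(4, 4, 3))          # pure white -> OD 0
  expect_equal(rgb_to_od(img, cfg)$X, matrix(0, 3, 16))
  img_e <- array(255 / exp(1), c(2, 2, 3))
  expect_equal(rgb_to_od(img_e, cfg)$X, matrix(1, 3, 4), tolerance = 1e-12)

  # round trip within one gray level on a random image
  set.seed(8)
  rnd <- array(sample(1:255, 5 * 7 * 3, replace = TRUE), c(5, 7, 3))
  back <- od_to_rgb(rgb_to_od(rnd, cfg))
  expect_lte(max(abs(back - rnd)), 1)
  expect_error(rgb_to_od(array(1, c(4, 4, 2))), "3")
})

test_that("pseudo_max is the linear-interpolation quantile", {
  row <- 0:100
  expect_equal(pseudo_max(row, 0.99), 99)
  expect_equal(pseudo_max(rep(3.7, 50), 0.5), 3.7)
  expect_equal(pseudo_max(c(5, 1, 9, 2), 1.0), 9)
  expect_error(pseudo_max(numeric(0)), "empty")
})

test_that("fit_stain_model recovers synthesis stain vectors", {
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (s in 1:3) {
    g <- he_fixture(seed = s)
    fit <- fit_stain_model(rgb_to_od(g$image), norm_config(seed = 7))
    Wt <- sweep(g$stain_vectors, 2, sqrt(colSums(g$stain_vectors^2)), "/")
    expect_gte(cos_sim(fit$W[, 1], Wt[, 1]), 0.95)
    expect_gte(cos_sim(fit$W[, 2], Wt[, 2]), 0.95)
    # invariants: nonnegative factors, unit-norm columns, monotone objective
    expect_true(all(fit$W >= 0) && all(fit$L >= 0))
    expect_equal(colSums(fit$W^2), rep(1, 2), tolerance = 1e-9)
    expect_true(all(diff(fit$objective) <= 1e-9))
    # reconstruction quality on a two-stain image
    od <- rgb_to_od(g$image)
    rel <- sqrt(sum((od$X - fit$W %*% fit$L)^2) / sum(od$X^2))
    expect_lte(rel, 0.25)
  }
})

test_that("restarts land within 5% of the best objective", {
  g <- he_fixture(seed = 12)
  od <- rgb_to_od(g$image)
  objs <- vapply(1:5, function(s) {
    f <- fit_stain_model(od, norm_config(seed = s, max_pixels = 4000))
    utils::tail(f$objective, 1)
  }, numeric(1))
  expect_lte(max(objs), min(objs) * 1.05)
})

test_that("rank-2 data fits no worse with r = 3 than r = 2 (lambda = 0)", {
  g <- he_fixture(seed = 21)
  od <- rgb_to_od(g$image)
  res <- vapply(c(2L, 3L), function(r) {
    f <- fit_stain_model(od, norm_config(lambda = 0, r = r, seed = 3))
    sqrt(sum((od$X - f$W %*% f$L)^2))
  }, numeric(1))
  expect_lte(res[2], res[1] + 1e-6)
})

test_that("a single-stain image concentrates density on one row", {
  # all pixels along one OD direction
  v <- c(0.55, 0.75, 0.35); v <- v / sqrt(sum(v^2))
  set.seed(5)
  dens <- runif(900, 0.3, 1.2)
  X <- v %o% dens
  img <- od_to_rgb(X, shape = c(30, 30), I0 = 255)
  fit <- fit_stain_model(rgb_to_od(img), norm_config(seed = 2))
  mass <- rowSums(fit$L)
  expect_gte(max(mass) / sum(mass), 0.9)
})

test_that("all-background images are rejected", {
  blank <- array(250, c(16, 16, 3))
  expect_error(fit_stain_model(rgb_to_od(blank)), "no tissue pixels")
})

test_that("self-normalization is near identity and idempotent", {
  g <- he_fixture(seed = 31)
  cfg <- norm_config(seed = 7)
  out <- normalize_to_target(g$image, g$image, cfg)
  tis <- fit_stain_model(rgb_to_od(g$image), cfg)$tissue
  tis3 <- array(rep(matrix(tis, 96, 96), 3), c(96, 96, 3))
  mae <- mean(abs(out - g$image)[tis3])
  expect_lte(mae, 3)

  # normalize(normalize(s, t), t) ~ normalize(s, t)
  t_img <- he_fixture(seed = 32)$image
  once <- normalize_to_target(g$image, t_img, cfg)
  twice <- normalize_to_target(once, t_img, cfg)
  expect_lte(mean(abs(twice - once)), 3)
  # shape conserved
  expect_identical(dim(once), dim(g$image))
})

test_that("normalization transfers the target color appearance", {
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  src <- generate_he_image(synthetic_image_spec(
    width = 96, height = 96, n_nuclei = 40, stain_perturbation = 0.15,
    seed = 41))
  tgt <- he_fixture(seed = 42)
  cfg <- norm_config(seed = 7)
  out <- normalize_to_target(src$image, tgt$image, cfg)
  W_t <- attr(out, "stain_info")$model_target$W
  refit <- fit_stain_model(rgb_to_od(out), cfg)
  for (j in 1:2) expect_gte(cos_sim(refit$W[, j], W_t[, j]), 0.95)
})

test_that("background pixels stay near white through normalization", {
  g <- he_fixture(seed = 51)
  src <- g$image
  src[1:12, 1:12, ] <- 254          # a glass patch of near-white pixels
  t_img <- he_fixture(seed = 52)$image
  cfg <- norm_config(seed = 7)
  out <- normalize_to_target(src, t_img, cfg)
  od <- rgb_to_od(src, cfg)
  near_white <- sqrt(colSums(od$X^2)) < 0.05
  expect_gt(sum(near_white), 100)
  for (ch in 1:3) {
    src_ch <- matrix(src[, , ch], ncol = 1)[near_white]
    out_ch <- matrix(out[, , ch], ncol = 1)[near_white]
    expect_lte(max(abs(out_ch - src_ch)), 5)
  }
})
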