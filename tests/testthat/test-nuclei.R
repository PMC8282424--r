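# Segmentation training protocol (schedule, loss, gradients) and both
# segmentation backends.

test_that("polynomial schedule matches its closed form and decreases", {
  cfg <- training_config(lr0 = 0.001, N = 80)
  expect_identical(poly_lr(0, cfg), 0.001)
  expect_identical(poly_lr(80, cfg), 0)
  expect_equal(poly_lr(40, cfg), 0.001 * 0.5^0.9, tolerance = 1e-15)
  lrs <- vapply(0:80, poly_lr, numeric(1), config = cfg)
  expect_true(all(diff(lrs) < 0))
  # lr_i / lr0 independent of lr0
  cfg2 <- training_config(lr0 = 0.5, N = 80)
  expect_equal(vapply(0:80, poly_lr, numeric(1), config = cfg2) / 0.5,
               lrs / 0.001, tolerance = 1e-12)
  expect_error(poly_lr(81, cfg), "epoch index")
  expect_error(poly_lr(-1, cfg), "epoch index")
})

test_that("cross-entropy has its closed-form values and brute-force sum", {
  onehot <- diag(2)[c(1, 2, 2, 1), ]
  expect_equal(cross_entropy_loss(onehot, onehot), 0)
  unif <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(onehot, unif), log(2))
  set.seed(3)
  p <- diag(3)[sample(1:3, 20, replace = TRUE), ]
  qraw <- matrix(runif(60, 0.05, 1), 20, 3)
  q <- qraw / rowSums(qraw)
  brute <- mean(vapply(1:20, function(i) -sum(p[i, ] * log(q[i, ])),
                       numeric(1)))
  expect_equal(cross_entropy_loss(p, q), brute, tolerance = 1e-12)
  # zero predicted probability against p > 0 is clamped, with a message
  qz <- q; qz[1, which(p[1, ] == 1)] <- 0
  expect_message(v <- cross_entropy_loss(p, qz), "clamped")
  expect_true(is.finite(v))
})

test_that("network gradients match finite differences", {
  params <- gliopipe:::init_unet_params(3L, 2L, 2L, 2L, seed = 5)
  set.seed(1)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  onehot <- cbind(rep(c(1, 0), 32), rep(c(0, 1), 32))
  lossfn <- function(p) {
    fw <- gliopipe:::unet_forward(p, x)
    gliopipe:::softmax_ce(matrix(fw$logits, ncol = 2), onehot)$loss
  }
  fw <- gliopipe:::unet_forward(params, x)
  ce <- gliopipe:::softmax_ce(matrix(fw$logits, ncol = 2), onehot)
  g <- gliopipe:::unet_backward(params, fw$caches,
                                array(ce$dlogits, dim(fw$logits)))
  eps <- 1e-5
  paths <- list(c("final", "W"), c("enc", "1", "c1", "W"),
                c("bott", "c2", "W"), c("dec", "2", "c1", "W"),
                c("dec", "1", "c2", "b"))
  for (pth in paths) {
    getter <- function(pl) {
      for (k in pth) pl <- if (grepl("^[0-9]+$", k)) pl[[as.integer(k)]] else pl[[k]]
      pl
    }
    setter <- function(pl, idx, delta) {
      ref <- function(node, depth) {
        if (depth > length(pth)) {
          node[idx] <- node[idx] + delta
          return(node)
        }
        k <- pth[depth]
        kk <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
        node[[kk]] <- ref(node[[kk]], depth + 1)
        node
      }
      ref(pl, 1)
    }
    arr <- getter(params); garr <- getter(g)
    for (idx in seq_len(min(2, length(arr)))) {
      num <- (lossfn(setter(params, idx, eps)) -
                lossfn(setter(params, idx, -eps))) / (2 * eps)
      expect_equal(garr[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("one epoch means one loss entry and the logged schedule", {
  imgs <- lapply(1:2, function(s) he_fixture(seed = s, n = 10, side = 32)$image)
  msks <- lapply(1:2, function(s) he_fixture(seed = s, n = 10, side = 32)$mask)
  cfg <- training_config(N = 1, seed = 2, depth = 2, base_width = 2)
  m <- train_unet(imgs, msks, cfg)
  expect_length(m$loss_history, 1)
  cfg3 <- training_config(N = 3, seed = 2, depth = 2, base_width = 2)
  m3 <- train_unet(imgs, msks, cfg3)
  expect_equal(m3$lr_history, vapply(0:2, poly_lr, numeric(1), config = cfg3))
  expect_error(train_unet(imgs[1], msks[1]), ">= 2")
  expect_error(train_unet(imgs, list(msks[[1]], matrix(0L, 5, 5))),
               "mismatch at pair 2")
})

test_that("training loss decreases over the first epochs (seeded)", {
  imgs <- lapply(1:4, function(s) he_fixture(seed = s, n = 15, side = 48)$image)
  msks <- lapply(1:4, function(s) he_fixture(seed = s, n = 15, side = 48)$mask)
  cfg <- training_config(lr0 = 0.03, N = 5, seed = 7, depth = 2,
                         base_width = 4)
  m <- train_unet(imgs, msks, cfg)
  expect_true(all(diff(m$loss_history) < 0))
})

test_that("classical backend segments synthetic nuclei cleanly", {
  for (s in 1:3) {
    g <- generate_he_image(synthetic_image_spec(
      width = 128, height = 128, n_nuclei = 30,
      nucleus_radius_range = c(3, 4.5), allow_overlap = FALSE, seed = s))
    m <- segment(g$image, "classical")
    expect_gte(dice_coefficient(m, g$mask), 0.8)
    expect_lte(abs(count_nuclei(m) - 30), 2)
  }
  # blank slide -> empty mask
  expect_identical(segment(array(255, c(32, 32, 3)), "classical"),
                   matrix(0L, 32, 32))
  expect_error(segment(he_fixture(seed = 1)$image, "unet", model = NULL),
               "unet")
})

test_that("classical segmentation is equivariant to 90-degree rotation", {
  g <- he_fixture(seed = 9, n = 15, side = 64)
  m1 <- segment(g$image, "classical")
  m2 <- segment(rotate90_rgb(g$image), "classical")
  expect_identical(m2, rotate90(m1))
})

test_that("model checkpoints round-trip through JSON", {
  imgs <- lapply(1:2, function(s) he_fixture(seed = s, n = 8, side = 32)$image)
  msks <- lapply(1:2, function(s) he_fixture(seed = s, n = 8, side = 32)$mask)
  m <- train_unet(imgs, msks, training_config(N = 2, seed = 3, depth = 2,
                                              base_width = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_unet_model(m, path)
  m2 <- load_unet_model(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_identical(predict_unet(m2, imgs[[1]]), predict_unet(m, imgs[[1]]))
  expect_equal(m2$loss_history, m$loss_history)
})
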