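# Cascaded two-stage glioma grading. A multi-class (II / III / IV) problem
# is posed as stepwise binary classification: stage 1, a plain
# convolutional network, separates HGG (grade IV) from LGG; stage 2, a
# deeper residual network, separates LGG II from LGG III. Both stages fuse
# the image pathway with a 4-marker molecular vector (IDH, ATRX, 1p/19q,
# MGMT) and the cellularity scalar, concatenated into the first dense
# layer. Evaluation is stratified, case-level, 5-fold cross-validation.

#' Configuration for the cascade classifiers
#'
#' @param patch_size side of the square patches tiled from each ROI
#' @param features character subset of `c("intensity", "molecular",
#'   "cellularity")`: the feature blocks fused into the dense head
#' @param stage1_blocks number of conv(+pool) blocks in the stage-1 CNN
#' @param stage2_blocks number of residual blocks in the stage-2 network
#'   (each block holds two convolutions; keep >= `stage1_blocks` so stage 2
#'   is the deeper model)
#' @param base_width channels of the first convolution
#' @param epochs training epochs
#' @param batch_size patches per minibatch
#' @param lr0 initial Adam learning rate (polynomial decay over epochs)
#' @param hidden units of the fusion dense layer
#' @param augment_training apply random rotation/flip/scale augmentation to
#'   training patches (fresh draws each epoch)?
#' @param seed integer seed
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(patch_size = 512,
                              features = c("intensity", "molecular",
                                           "cellularity"),
                              stage1_blocks = 4, stage2_blocks = 6,
                              base_width = 16, epochs = 20, batch_size = 8,
                              lr0 = 0.001, hidden = 16,
                              augment_training = TRUE, seed = 1L) {
  if (length(features) == 0L) stop("no active feature block", call. = FALSE)
  features <- match.arg(features, c("intensity", "molecular", "cellularity"),
                        several.ok = TRUE)
  structure(list(patch_size = as.integer(patch_size), features = features,
                 stage1_blocks = as.integer(stage1_blocks),
                 stage2_blocks = as.integer(stage2_blocks),
                 base_width = as.integer(base_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 hidden = as.integer(hidden),
                 augment_training = isTRUE(augment_training),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Tile an ROI into square patches
#'
#' Minimal evenly spaced covering grid: per axis,
#' n = ceiling((dim - patch_size)/patch_size) + 1 windows whose offsets are
#' evenly spread from 0 to dim - patch_size (so a 1000 x 1000 ROI yields a
#' 2 x 2 grid of 512 x 512 patches with stride 488; an exact multiple tiles
#' without overlap).
#'
#' @param roi RGB array, at least `patch_size` in both dimensions
#' @param patch_size patch side in pixels
#' @return list of RGB arrays of size patch_size x patch_size
#' @export
make_patches <- function(roi, patch_size = 512) {
  assert_rgb(roi, "roi")
  h <- dim(roi)[1]; w <- dim(roi)[2]
  if (h < patch_size || w < patch_size) {
    stop(sprintf("ROI (%d x %d) smaller than patch_size %d", h, w,
                 patch_size), call. = FALSE)
  }
  offsets <- function(d) {
    n <- ceiling((d - patch_size) / patch_size) + 1
    unique(round(seq(0, d - patch_size, length.out = n)))
  }
  out <- list()
  for (r0 in offsets(h)) {
    for (c0 in offsets(w)) {
      out[[length(out) + 1L]] <-
        roi[(r0 + 1):(r0 + patch_size), (c0 + 1):(c0 + patch_size), ,
            drop = FALSE]
    }
  }
  out
}

rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rot90_img <- function(img, k) {
  k <- k %% 4
  if (k == 0) return(img)
  for (i in seq_len(k)) {
    out <- array(0, c(dim(img)[2], dim(img)[1], dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- rot90_mat(img[, , ch])
    img <- out
  }
  img
}

#' Apply a fixed augmentation transform to a patch
#'
#' Deterministic building block of [augment()]: rotation by a multiple of
#' 90 degrees, an optional axis flip, and isotropic rescaling with a center
#' crop (scale > 1) or edge-replicating pad (scale < 1) back to the
#' original size.
#'
#' @param patch RGB array (square when rotation is 90 or 270)
#' @param rotation one of 0, 90, 180, 270 (degrees)
#' @param flip `"none"`, `"horizontal"` or `"vertical"`
#' @param scale isotropic scale factor
#' @return transformed RGB array, same dimensions as the input
#' @export
apply_augmentation <- function(patch, rotation = 0, flip = "none",
                               scale = 1) {
  assert_rgb(patch, "patch")
  h <- dim(patch)[1]; w <- dim(patch)[2]
  if (rotation %in% c(90, 270) && h != w) {
    stop("90/270-degree rotation requires a square patch", call. = FALSE)
  }
  img <- rot90_img(patch, rotation / 90)
  if (flip == "horizontal") img <- img[, ncol(img[, , 1]):1, , drop = FALSE]
  if (flip == "vertical") img <- img[nrow(img[, , 1]):1, , , drop = FALSE]
  nh <- round(scale * h); nw <- round(scale * w)
  if (nh != h || nw != w) {
    eb <- EBImage::resize(to_ebimage(img), w = nw, h = nh)
    img <- from_ebimage(eb)
    if (nh >= h) {               # center crop
      r0 <- floor((nh - h) / 2); c0 <- floor((nw - w) / 2)
      img <- img[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE]
    } else {                     # edge-replicating pad
      ridx <- pmin(pmax(seq_len(h) - floor((h - nh) / 2), 1), nh)
      cidx <- pmin(pmax(seq_len(w) - floor((w - nw) / 2), 1), nw)
      img <- img[ridx, cidx, , drop = FALSE]
    }
  }
  img
}

#' Randomly augment a training patch
#'
#' Samples an independent rotation from {0, 90, 180, 270} degrees, a flip
#' from {none, horizontal, vertical} and a scale factor uniform in
#' [0.95, 1.1], then applies them via [apply_augmentation()]. Deterministic
#' given `seed`; output dimensions always equal input dimensions.
#'
#' @param patch square RGB array
#' @param seed integer seed
#' @return augmented RGB array
#' @export
augment <- function(patch, seed) {
  draws <- with_seed(seed, list(
    rotation = sample(c(0, 90, 180, 270), 1),
    flip = sample(c("none", "horizontal", "vertical"), 1),
    scale = stats::runif(1, 0.95, 1.1)))
  apply_augmentation(patch, draws$rotation, draws$flip, draws$scale)
}

#' Stratified fold assignment at the case level
#'
#' Cases are shuffled within each grade and dealt round-robin into k folds,
#' so every case is tested exactly once and each fold's test set holds
#' ~1/k of every grade (the 8:2 train/test split at k = 5).
#'
#' @param records cohort data.frame with a `grade` column
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of test-fold ids (1..k), one per record
#' @export
split_folds <- function(records, k = 5, seed = 1L) {
  stopifnot(is.data.frame(records))
  grades <- unique(records$grade)
  counts <- table(records$grade)
  if (any(counts < k)) {
    stop(sprintf("class %s has %d cases, fewer than k = %d",
                 names(counts)[which.min(counts)], min(counts), k),
         call. = FALSE)
  }
  folds <- integer(nrow(records))
  for (g in grades) {
    idx <- which(records$grade == g)
    perm <- with_seed(derive_seed(seed, paste0("fold-", g)),
                      sample(idx))
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

# ---- feature plumbing ----------------------------------------------------

molecular_vector <- function(record) {
  c(idh = as.numeric(record$idh == "MT"),
    atrx = as.numeric(record$atrx == "MT"),
    codel = as.numeric(record$codel_1p19q == "CD"),
    mgmt = as.numeric(record$mgmt == "ML"))
}

side_features <- function(record, features) {
  z <- numeric(0)
  if ("molecular" %in% features) z <- c(z, molecular_vector(record))
  if ("cellularity" %in% features) {
    if (is.null(record$cellularity) || is.na(record$cellularity)) {
      stop("record ", record$case_id, " lacks cellularity but the model ",
           "fuses the cellularity block", call. = FALSE)
    }
    z <- c(z, cellularity = record$cellularity)
  }
  z
}

# ---- stage networks ------------------------------------------------------

init_stage_params <- function(arch, config, n_side) {
  with_seed(derive_seed(config$seed, paste0(arch, "-init")), {
    use_img <- "intensity" %in% config$features
    p <- list(arch = arch, use_img = use_img, n_side = n_side)
    gap_w <- 0L
    if (use_img) {
      if (arch == "plain") {
        widths <- pmin(config$base_width * 2^(seq_len(config$stage1_blocks) - 1),
                       64L)
        convs <- list()
        prev <- 3L
        for (i in seq_along(widths)) {
          convs[[i]] <- new_conv_params(3L, prev, widths[i])
          prev <- widths[i]
        }
        p$convs <- convs
        gap_w <- prev
      } else {
        wdt <- config$base_width
        p$stem <- new_conv_params(3L, 3L, wdt)
        p$blocks <- lapply(seq_len(config$stage2_blocks), function(i) {
          list(c1 = new_conv_params(3L, wdt, wdt),
               c2 = new_conv_params(3L, wdt, wdt))
        })
        gap_w <- wdt
      }
    }
    p$dense1 <- new_dense_params(gap_w + n_side, config$hidden)
    p$dense2 <- new_dense_params(config$hidden, 2L)
    p$dense2$W <- p$dense2$W * 0.1
    p
  })
}

stage_forward <- function(params, patch, side, config) {
  cache <- list()
  feat <- numeric(0)
  if (params$use_img) {
    cur <- patch / 255 - 0.5
    if (params$arch == "plain") {
      cache$convs <- vector("list", length(params$convs))
      for (i in seq_along(params$convs)) {
        cr <- conv_relu_fwd(cur, params$convs[[i]])
        mp <- maxpool_fwd(cr$out)
        cache$convs[[i]] <- list(cr = cr$cache, mp = mp$cache)
        cur <- mp$out
      }
    } else {
      st <- conv_relu_fwd(cur, params$stem)
      cache$stem <- st$cache
      cur <- st$out
      cache$blocks <- vector("list", length(params$blocks))
      for (i in seq_along(params$blocks)) {
        a <- conv_relu_fwd(cur, params$blocks[[i]]$c1)
        b <- conv_fwd(a$out, params$blocks[[i]]$c2)
        sum_rl <- relu_fwd(cur + b$out)       # identity shortcut
        pooled <- if (dim(sum_rl$out)[1] >= 8) maxpool_fwd(sum_rl$out) else
          list(out = sum_rl$out, cache = NULL)
        cache$blocks[[i]] <- list(a = a$cache, b = b$cache,
                                  rl = sum_rl$cache, mp = pooled$cache)
        cur <- pooled$out
      }
    }
    gp <- gap_fwd(cur)
    cache$gap <- gp$cache
    feat <- gp$out
  }
  z <- c(feat, side)
  d1 <- dense_fwd(z, params$dense1)
  r1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(r1$out, params$dense2)
  cache$z <- z; cache$d1 <- d1$cache; cache$r1 <- r1$cache
  cache$d2 <- d2$cache; cache$n_img_feat <- length(feat)
  list(logits = d2$out, cache = cache)
}

stage_backward <- function(params, cache, dlogits) {
  g <- list()
  b2 <- dense_bwd(dlogits, params$dense2, cache$d2)
  g$dense2 <- list(W = b2$dW, b = b2$db)
  dr1 <- relu_bwd(b2$dx, cache$r1)
  b1 <- dense_bwd(dr1, params$dense1, cache$d1)
  g$dense1 <- list(W = b1$dW, b = b1$db)
  if (params$use_img) {
    dfeat <- b1$dx[seq_len(cache$n_img_feat)]
    dcur <- gap_bwd(dfeat, cache$gap)
    if (params$arch == "plain") {
      g$convs <- vector("list", length(params$convs))
      for (i in rev(seq_along(params$convs))) {
        dmp <- maxpool_bwd(dcur, cache$convs[[i]]$mp)
        cb <- conv_relu_bwd(dmp, params$convs[[i]], cache$convs[[i]]$cr)
        g$convs[[i]] <- list(W = cb$dW, b = cb$db)
        dcur <- cb$dx
      }
    } else {
      g$blocks <- vector("list", length(params$blocks))
      for (i in rev(seq_along(params$blocks))) {
        cc <- cache$blocks[[i]]
        if (!is.null(cc$mp)) dcur <- maxpool_bwd(dcur, cc$mp)
        dsum <- relu_bwd(dcur, cc$rl)
        bb <- conv_bwd(dsum, params$blocks[[i]]$c2, cc$b)
        ba <- conv_relu_bwd(bb$dx, params$blocks[[i]]$c1, cc$a)
        g$blocks[[i]] <- list(c1 = list(W = ba$dW, b = ba$db),
                              c2 = list(W = bb$dW, b = bb$db))
        dcur <- dsum + ba$dx                 # shortcut gradient
      }
      sb <- conv_relu_bwd(dcur, params$stem, cache$stem)
      g$stem <- list(W = sb$dW, b = sb$db)
    }
  }
  g
}

# shared training loop over case records
train_stage <- function(records, positive, arch, config) {
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  y <- positive(records)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  n_side <- length(side_features(records[1, ], config$features))
  if (!("intensity" %in% config$features) && n_side == 0L) {
    stop("no active feature block", call. = FALSE)
  }
  params <- init_stage_params(arch, config, n_side)
  opt <- adam_init(params)

  # z-score the fused side features on the training set (stored with the
  # model) so the scalar cellularity block competes on equal footing with
  # the convolutional features
  side_mat <- if (n_side > 0) {
    t(vapply(seq_len(nrow(records)),
             function(i) side_features(records[i, ], config$features),
             numeric(n_side)))
  } else matrix(0, nrow(records), 0)
  side_mu <- if (n_side > 0) colMeans(side_mat) else numeric(0)
  side_sd <- if (n_side > 0) pmax(apply(side_mat, 2, stats::sd), 1e-6) else
    numeric(0)

  patches <- list(); labels <- integer(0); sides <- list()
  for (i in seq_len(nrow(records))) {
    pats <- if ("intensity" %in% config$features) {
      make_patches(records$image[[i]], config$patch_size)
    } else list(array(0, c(2, 2, 3)))    # image pathway inactive
    sd <- if (n_side > 0) (side_mat[i, ] - side_mu) / side_sd else numeric(0)
    for (p in pats) {
      patches[[length(patches) + 1L]] <- p
      sides[[length(sides) + 1L]] <- sd
      labels <- c(labels, y[i])
    }
  }
  n_pat <- length(patches)
  sched <- training_config(lr0 = config$lr0, N = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed)
  loss_hist <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- poly_lr(epoch, sched)
    ord <- with_seed(derive_seed(config$seed, paste0(arch, "-ep", epoch)),
                     sample.int(n_pat))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      g_acc <- NULL
      b_loss <- 0
      for (ix in bt) {
        x <- patches[[ix]]
        if (config$augment_training && "intensity" %in% config$features) {
          x <- augment(x, derive_seed(config$seed,
                                      paste0(arch, "-aug", epoch, "-", ix)))
        }
        fw <- stage_forward(params, x, sides[[ix]], config)
        onehot <- matrix(c(1 - labels[ix], labels[ix]), 1)
        ce <- softmax_ce(matrix(fw$logits, 1), onehot)
        b_loss <- b_loss + ce$loss
        g <- stage_backward(params, fw$cache, as.vector(ce$dlogits))
        g_acc <- grad_add(g_acc, g)
      }
      g_acc <- grad_scale(g_acc, 1 / length(bt))
      # params holds non-numeric metadata; update only parameter entries
      meta <- params[c("arch", "use_img", "n_side")]
      pp <- params[setdiff(names(params), names(meta))]
      st <- adam_step(pp, g_acc[names(pp)], opt, lr)
      params <- c(st$params, meta)
      opt <- st$state
      ep_loss <- ep_loss + b_loss / length(bt)
    }
    loss_hist[epoch + 1L] <- ep_loss / length(batches)
  }
  structure(list(params = params, config = config, arch = arch,
                 features = config$features, side_mu = side_mu,
                 side_sd = side_sd, loss_history = loss_hist),
            class = "stage_model")
}

#' Train the stage-1 classifier (HGG vs LGG, plain CNN)
#'
#' A plain convolutional network (no residual connections) over ROI
#' patches; the molecular vector and cellularity are concatenated into the
#' first dense layer when their feature blocks are active. The positive
#' class is HGG (grade IV).
#'
#' @param train_records cohort data.frame (must contain both HGG and LGG)
#' @param config a [classifier_config()]
#' @return a `stage_model`
#' @export
train_stage1 <- function(train_records, config = classifier_config()) {
  train_stage(train_records, function(r) as.integer(r$grade == "IV"),
              "plain", config)
}

#' Train the stage-2 classifier (LGG II vs III, residual network)
#'
#' A deeper residual-block network with the same fusion mechanism; only
#' grade II/III records are admitted. The positive class is grade III.
#'
#' @param train_records cohort data.frame of LGG (grade II/III) cases only
#' @param config a [classifier_config()]
#' @return a `stage_model`
#' @export
train_stage2 <- function(train_records, config = classifier_config()) {
  if (any(!train_records$grade %in% c("II", "III"))) {
    stop("stage 2 accepts only grade II/III records", call. = FALSE)
  }
  train_stage(train_records, function(r) as.integer(r$grade == "III"),
              "resnet", config)
}

# mean positive-class probability over a case's patches
case_probability <- function(model, record) {
  cfg <- model$config
  pats <- if ("intensity" %in% cfg$features) {
    make_patches(record$image[[1]], cfg$patch_size)
  } else list(array(0, c(2, 2, 3)))
  sd <- side_features(record, cfg$features)
  if (length(sd) > 0) sd <- (sd - model$side_mu) / model$side_sd
  probs <- vapply(pats, function(p) {
    fw <- stage_forward(model$params, p, sd, cfg)
    softmax_rows(matrix(fw$logits, 1))[1, 2]
  }, numeric(1))
  mean(probs)
}

#' Predict a grade with the two-stage cascade
#'
#' Stage 1 decides HGG vs LGG on the case-level mean patch probability at
#' threshold 0.5 (ties resolved to the higher grade); an HGG verdict
#' returns grade IV without invoking stage 2, otherwise stage 2 decides II
#' vs III the same way.
#'
#' @param record one cohort row (data.frame of one row)
#' @param stage1,stage2 trained `stage_model`s
#' @return list with `grade` ("II", "III" or "IV"), `stage1_prob` and
#'   `stage2_prob` (NA when stage 2 was not consulted)
#' @export
predict_cascade <- function(record, stage1, stage2) {
  if (!identical(stage1$features, stage2$features)) {
    stop("stage 1 and stage 2 were trained with different feature blocks",
         call. = FALSE)
  }
  p1 <- case_probability(stage1, record)
  if (p1 >= 0.5) {
    return(list(grade = "IV", stage1_prob = p1, stage2_prob = NA_real_))
  }
  p2 <- case_probability(stage2, record)
  list(grade = if (p2 >= 0.5) "III" else "II",
       stage1_prob = p1, stage2_prob = p2)
}

#' Cross-validated evaluation of the grading classifiers
#'
#' Stratified case-level k-fold cross-validation of one task:
#' `"HGGvsLGG"` (stage 1 alone), `"LGGIIvsIII"` (stage 2 alone, on LGG
#' records) or `"cascade"` (both stages composed into the 3-class grade).
#' Accuracy is case-level; the report carries per-fold accuracies, their
#' mean and sample standard deviation, and the pooled confusion matrix.
#'
#' @param records cohort data.frame
#' @param task one of `"HGGvsLGG"`, `"LGGIIvsIII"`, `"cascade"`
#' @param config a [classifier_config()]
#' @param k number of folds
#' @return object of class `cv_report`
#' @export
evaluate_cv <- function(records, task = c("HGGvsLGG", "LGGIIvsIII",
                                          "cascade"),
                        config = classifier_config(), k = 5) {
  task <- match.arg(task)
  if (task == "LGGIIvsIII") {
    records <- records[records$grade %in% c("II", "III"), , drop = FALSE]
  }
  folds <- split_folds(records, k = k, seed = config$seed)
  lvls <- if (task == "HGGvsLGG") c("LGG", "HGG") else
    if (task == "LGGIIvsIII") c("II", "III") else c("II", "III", "IV")
  conf <- matrix(0L, length(lvls), length(lvls),
                 dimnames = list(truth = lvls, predicted = lvls))
  accs <- numeric(k)
  preds <- data.frame(case_id = records$case_id,
                      truth = records$grade,
                      predicted = NA_character_,
                      stage1_prob = NA_real_, stage2_prob = NA_real_,
                      fold = folds, stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    tr <- records[folds != f, , drop = FALSE]
    te <- records[folds == f, , drop = FALSE]
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("cvfold-", f))
    if (task == "HGGvsLGG") {
      m1 <- train_stage1(tr, fold_cfg)
      truth <- ifelse(te$grade == "IV", "HGG", "LGG")
      pred <- character(nrow(te)); p1s <- numeric(nrow(te))
      for (i in seq_len(nrow(te))) {
        p1s[i] <- case_probability(m1, te[i, ])
        pred[i] <- if (p1s[i] >= 0.5) "HGG" else "LGG"
      }
      preds$stage1_prob[folds == f] <- p1s
    } else if (task == "LGGIIvsIII") {
      m2 <- train_stage2(tr, fold_cfg)
      truth <- te$grade
      pred <- character(nrow(te)); p2s <- numeric(nrow(te))
      for (i in seq_len(nrow(te))) {
        p2s[i] <- case_probability(m2, te[i, ])
        pred[i] <- if (p2s[i] >= 0.5) "III" else "II"
      }
      preds$stage2_prob[folds == f] <- p2s
    } else {
      m1 <- train_stage1(tr, fold_cfg)
      m2 <- train_stage2(tr[tr$grade %in% c("II", "III"), , drop = FALSE],
                         fold_cfg)
      truth <- te$grade
      pred <- character(nrow(te))
      for (i in seq_len(nrow(te))) {
        pc <- predict_cascade(te[i, ], m1, m2)
        pred[i] <- pc$grade
        preds$stage1_prob[folds == f][i] <- pc$stage1_prob
        preds$stage2_prob[folds == f][i] <- pc$stage2_prob
      }
    }
    preds$predicted[folds == f] <- pred
    accs[f] <- mean(pred == truth)
    for (i in seq_along(truth)) {
      conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
    }
  }
  structure(list(task = task, per_fold_accuracy = accs,
                 mean_accuracy = mean(accs),
                 std_accuracy = stats::sd(accs),
                 confusion_matrix = conf, predictions = preds,
                 n_cases = nrow(records)),
            class = "cv_report")
}

#' @export
format.cv_report <- function(x, ...) {
  sprintf("%s: %.2f%% +/- %.2f%% (%d cases, %d folds)", x$task,
          100 * x$mean_accuracy, 100 * x$std_accuracy, x$n_cases,
          length(x$per_fold_accuracy))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(format(x), "\n")
  cat("per-fold accuracy:",
      paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " "), "\n")
  print(x$confusion_matrix)
  invisible(x)
}

#' Molecular-status classification from image-derived and clinical features
#'
#' Predicts IDH, 1p/19q-codeletion or ATRX status with a small single-
#' hidden-layer neural network (via \pkg{nnet}) on tabular features:
#' image-derived summaries (per-channel mean/sd of the ROI, nuclei count,
#' mean nucleus area), cellularity, one-hot histology and grade — any
#' subset. Repeated stratified 5-fold cross-validation.
#'
#' @param records cohort data.frame (needs `mask` or precomputed image
#'   summaries for the image feature group)
#' @param target `"idh"`, `"codel_1p19q"` or `"atrx"`
#' @param features character subset of `c("image", "cellularity",
#'   "histology", "grade")`
#' @param k folds per repeat
#' @param repeats number of repeated CV rounds
#' @param hidden hidden-layer size of the network
#' @param seed integer seed
#' @return object of class `cv_report` (per-fold accuracies pooled over
#'   repeats)
#' @export
classify_molecular <- function(records,
                               target = c("idh", "codel_1p19q", "atrx"),
                               features = c("image", "cellularity",
                                            "histology", "grade"),
                               k = 5, repeats = 10, hidden = 8, seed = 1L) {
  target <- match.arg(target)
  if (length(features) == 0L) stop("no active feature group", call. = FALSE)
  features <- match.arg(features,
                        c("image", "cellularity", "histology", "grade"),
                        several.ok = TRUE)
  y <- factor(records[[target]])
  if (nlevels(droplevels(y)) < 2L) {
    stop("target has a single class", call. = FALSE)
  }
  X <- NULL
  if ("image" %in% features) {
    imfeat <- t(vapply(seq_len(nrow(records)), function(i) {
      im <- records$image[[i]]
      msk <- records$mask[[i]]
      cnt <- count_nuclei(msk)
      c(mean_r = mean(im[, , 1]), mean_g = mean(im[, , 2]),
        mean_b = mean(im[, , 3]), sd_r = stats::sd(im[, , 1]),
        sd_g = stats::sd(im[, , 2]), sd_b = stats::sd(im[, , 3]),
        n_nuclei = cnt,
        mean_area = if (cnt > 0) sum(msk) / cnt else 0)
    }, numeric(8)))
    X <- cbind(X, imfeat)
  }
  if ("cellularity" %in% features) X <- cbind(X, cellularity = records$cellularity)
  if ("histology" %in% features) {
    X <- cbind(X, stats::model.matrix(~ histology - 1,
                                      data.frame(histology = factor(
                                        records$histology,
                                        c("AA", "OA", "OD", "GBM")))))
  }
  if ("grade" %in% features) {
    X <- cbind(X, stats::model.matrix(~ grade - 1,
                                      data.frame(grade = factor(
                                        records$grade, c("II", "III", "IV")))))
  }
  X <- scale(X)
  X[is.na(X)] <- 0   # zero-variance columns
  accs <- numeric(0)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), predicted = levels(y)))
  for (rep_i in seq_len(repeats)) {
    folds <- integer(nrow(records))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      perm <- with_seed(derive_seed(seed, paste0("mol-", rep_i, "-", lv)),
                        sample(idx))
      folds[perm] <- rep_len(seq_len(k), length(perm))
    }
    for (f in seq_len(k)) {
      tr <- folds != f; te <- folds == f
      fit <- with_seed(derive_seed(seed, paste0("mol-fit-", rep_i, "-", f)),
                       nnet::nnet(X[tr, , drop = FALSE],
                                  stats::model.matrix(~ y - 1)[tr, ],
                                  size = hidden, decay = 0.1, maxit = 200,
                                  trace = FALSE, softmax = TRUE))
      pr_mat <- predict(fit, X[te, , drop = FALSE])
      pr <- levels(y)[max.col(pr_mat, ties.method = "first")]
      accs <- c(accs, mean(pr == as.character(y[te])))
      truth_te <- as.character(y[te])
      for (i in seq_along(pr)) {
        conf[truth_te[i], pr[i]] <- conf[truth_te[i], pr[i]] + 1L
      }
    }
  }
  structure(list(task = paste0("molecular:", target),
                 per_fold_accuracy = accs, mean_accuracy = mean(accs),
                 std_accuracy = stats::sd(accs), confusion_matrix = conf,
                 n_cases = nrow(records)),
            class = "cv_report")
}
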