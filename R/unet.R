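# Nuclei segmentation network: a small U-Net-style encoder-decoder with
# skip connections, trained with softmax cross-entropy, Adam and a
# polynomial learning-rate decay. Depth and width are configurable so the
# same code runs desk-scale (reduced width, few epochs) and larger.

#' Training configuration for the segmentation network
#'
#' Defaults follow the training protocol used for H&E nuclei segmentation:
#' Adam with initial learning rate 0.001, minibatch 2, up to 80 epochs and
#' a polynomial decay of power 0.9.
#'
#' @param lr0 initial learning rate
#' @param N total number of epochs
#' @param batch_size minibatch size
#' @param power exponent of the polynomial learning-rate schedule
#' @param seed integer seed (weight init and batch shuffling)
#' @param optimizer optimizer name; only "Adam" is implemented
#' @param depth number of encoder levels (each halves resolution)
#' @param base_width channel count of the first encoder level
#' @return an object of class `training_config`
#' @export
training_config <- function(lr0 = 0.001, N = 80, batch_size = 2, power = 0.9,
                            seed = 1L, optimizer = "Adam", depth = 3,
                            base_width = 8) {
  assert_scalar_number(lr0, "lr0", lower = 1e-12)
  assert_scalar_number(N, "N", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  if (!identical(optimizer, "Adam")) {
    stop("only the Adam optimizer is implemented", call. = FALSE)
  }
  structure(list(lr0 = lr0, N = as.integer(N),
                 batch_size = as.integer(batch_size), power = power,
                 seed = as.integer(seed), optimizer = optimizer,
                 depth = as.integer(depth), base_width = as.integer(base_width)),
            class = "training_config")
}

#' Polynomial learning-rate schedule
#'
#' lr_i = lr0 * (1 - i/N)^power: strictly decreasing in the epoch index,
#' reaching exactly 0 at i = N.
#'
#' @param i epoch index, 0 <= i <= N
#' @param config a [training_config()]
#' @return the learning rate for epoch `i`
#' @export
poly_lr <- function(i, config = training_config()) {
  if (!is.numeric(i) || length(i) != 1L || i < 0 || i > config$N) {
    stop(sprintf("epoch index must be in [0, %d]", config$N), call. = FALSE)
  }
  config$lr0 * (1 - i / config$N)^config$power
}

#' Cross-entropy between true and predicted class distributions
#'
#' loss = -sum_x p(x) log q(x), averaged over items (pixels). Zero exactly
#' when q = p and p is one-hot. Predicted probabilities of 0 facing p > 0
#' are clamped at 1e-7 (a message is emitted).
#'
#' @param p true distribution: matrix (items x classes) or array
#'   (h, w, classes); rows on the simplex
#' @param q predicted distribution, same shape, rows summing to 1
#' @return mean cross-entropy (scalar)
#' @export
cross_entropy_loss <- function(p, q) {
  if (is.array(p) && length(dim(p)) == 3L) p <- matrix(p, ncol = dim(p)[3])
  if (is.array(q) && length(dim(q)) == 3L) q <- matrix(q, ncol = dim(q)[3])
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(all(dim(p) == dim(q)))
  if (any(q < 0)) stop("q must be nonnegative", call. = FALSE)
  bad <- q < 1e-7 & p > 0
  if (any(bad)) {
    message("cross_entropy_loss: clamped ", sum(bad),
            " zero predicted probabilities at 1e-7")
    q[bad] <- 1e-7
  }
  mean(rowSums(-p * ifelse(p > 0, log(q), 0)))
}

# ---- U-Net definition ----------------------------------------------------

init_unet_params <- function(in_c, depth, base, n_classes, seed) {
  with_seed(seed, {
    widths <- base * 2^(seq_len(depth) - 1)
    enc <- vector("list", depth)
    prev <- in_c
    for (i in seq_len(depth)) {
      enc[[i]] <- list(c1 = new_conv_params(3L, prev, widths[i]),
                       c2 = new_conv_params(3L, widths[i], widths[i]))
      prev <- widths[i]
    }
    bott_w <- base * 2^depth
    bott <- list(c1 = new_conv_params(3L, prev, bott_w),
                 c2 = new_conv_params(3L, bott_w, bott_w))
    dec <- vector("list", depth)
    up_c <- bott_w
    for (i in rev(seq_len(depth))) {
      dec[[i]] <- list(c1 = new_conv_params(3L, up_c + widths[i], widths[i]),
                       c2 = new_conv_params(3L, widths[i], widths[i]))
      up_c <- widths[i]
    }
    final <- new_conv_params(1L, widths[1], n_classes)
    # damp the classification head so initial logits are near zero: training
    # starts in the linear (non-saturated) regime of the softmax
    final$W <- final$W * 0.1
    list(enc = enc, bott = bott, dec = dec, final = final)
  })
}

conv_relu_fwd <- function(x, par) {
  cv <- conv_fwd(x, par)
  rl <- relu_fwd(cv$out)
  list(out = rl$out, cache = list(conv = cv$cache, relu = rl$cache))
}

conv_relu_bwd <- function(dout, par, cache) {
  dout <- relu_bwd(dout, cache$relu)
  conv_bwd(dout, par, cache$conv)
}

unet_forward <- function(params, x) {
  depth <- length(params$enc)
  caches <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    a <- conv_relu_fwd(cur, params$enc[[i]]$c1)
    b <- conv_relu_fwd(a$out, params$enc[[i]]$c2)
    skips[[i]] <- b$out
    mp <- maxpool_fwd(b$out)
    caches$enc[[i]] <- list(a = a$cache, b = b$cache, mp = mp$cache)
    cur <- mp$out
  }
  a <- conv_relu_fwd(cur, params$bott$c1)
  b <- conv_relu_fwd(a$out, params$bott$c2)
  caches$bott <- list(a = a$cache, b = b$cache)
  cur <- b$out
  for (i in rev(seq_len(depth))) {
    up <- upsample_fwd(cur)
    n_up <- dim(up)[3]
    cat_in <- array(c(up, skips[[i]]), c(dim(up)[1], dim(up)[2],
                                         n_up + dim(skips[[i]])[3]))
    a <- conv_relu_fwd(cat_in, params$dec[[i]]$c1)
    b <- conv_relu_fwd(a$out, params$dec[[i]]$c2)
    caches$dec[[i]] <- list(a = a$cache, b = b$cache, n_up = n_up)
    cur <- b$out
  }
  fin <- conv_fwd(cur, params$final)
  caches$final <- fin$cache
  list(logits = fin$out, caches = caches)
}

unet_backward <- function(params, caches, dlogits) {
  depth <- length(params$enc)
  grads <- list(enc = vector("list", depth), bott = NULL,
                dec = vector("list", depth), final = NULL)
  fb <- conv_bwd(dlogits, params$final, caches$final)
  grads$final <- list(W = fb$dW, b = fb$db)
  dcur <- fb$dx
  dskips <- vector("list", depth)
  for (i in seq_len(depth)) {   # decoder levels, innermost-out order = 1..depth
    cc <- caches$dec[[i]]
    b <- conv_relu_bwd(dcur, params$dec[[i]]$c2, cc$b)
    a <- conv_relu_bwd(b$dx, params$dec[[i]]$c1, cc$a)
    grads$dec[[i]] <- list(c1 = list(W = a$dW, b = a$db),
                           c2 = list(W = b$dW, b = b$db))
    n_up <- cc$n_up
    dcat <- a$dx
    dup <- dcat[, , seq_len(n_up), drop = FALSE]
    dskips[[i]] <- dcat[, , -seq_len(n_up), drop = FALSE]
    dcur <- upsample_bwd(dup)
  }
  b <- conv_relu_bwd(dcur, params$bott$c2, caches$bott$b)
  a <- conv_relu_bwd(b$dx, params$bott$c1, caches$bott$a)
  grads$bott <- list(c1 = list(W = a$dW, b = a$db),
                     c2 = list(W = b$dW, b = b$db))
  dcur <- a$dx
  for (i in rev(seq_len(depth))) {
    dpool <- maxpool_bwd(dcur, caches$enc[[i]]$mp)
    dpool <- dpool + dskips[[i]]
    b <- conv_relu_bwd(dpool, params$enc[[i]]$c2, caches$enc[[i]]$b)
    a <- conv_relu_bwd(b$dx, params$enc[[i]]$c1, caches$enc[[i]]$a)
    grads$enc[[i]] <- list(c1 = list(W = a$dW, b = a$db),
                           c2 = list(W = b$dW, b = b$db))
    dcur <- a$dx
  }
  grads
}

# caches$dec is indexed by level i but filled in reverse traversal; keep the
# backward traversal consistent with how unet_forward filled it.

#' Train the nuclei-segmentation U-Net
#'
#' Encoder-decoder with skip connections, softmax cross-entropy loss, Adam,
#' and the polynomial learning-rate schedule evaluated once per epoch.
#' Deterministic given `config$seed`.
#'
#' @param images list of RGB arrays (all the same even-sized shape)
#' @param masks list of 0/1 matrices matching `images`
#' @param config a [training_config()]
#' @param restarts number of independent training restarts; the model with
#'   the lowest final training loss is returned (restart seeds derive
#'   deterministically from `config$seed`). At the short, desk-scale
#'   schedules an occasional unlucky initialization stalls at the
#'   class-prior solution; best-of-k restarts by training loss removes
#'   that failure mode without touching held-out data. Default 1 (the
#'   plain protocol).
#' @return object of class `unet_model` with the trained parameters,
#'   per-epoch `loss_history` and `lr_history`
#' @export
train_unet <- function(images, masks, config = training_config(),
                       restarts = 1) {
  if (length(images) < 2L || length(images) != length(masks)) {
    stop("need >= 2 image/mask pairs of equal count", call. = FALSE)
  }
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]])[1:2] == dim(masks[[i]]))) {
      stop(sprintf("image/mask shape mismatch at pair %d: %s vs %s", i,
                   paste(dim(images[[i]])[1:2], collapse = "x"),
                   paste(dim(masks[[i]]), collapse = "x")), call. = FALSE)
    }
  }
  if (restarts > 1) {
    best <- NULL
    for (r in seq_len(restarts)) {
      cfg_r <- config
      if (r > 1) cfg_r$seed <- derive_seed(config$seed, paste0("restart-", r))
      m <- train_unet(images, masks, cfg_r, restarts = 1)
      if (is.null(best) ||
          utils::tail(m$loss_history, 1) < utils::tail(best$loss_history, 1)) {
        best <- m
      }
    }
    return(best)
  }
  params <- init_unet_params(3L, config$depth, config$base_width, 2L,
                             derive_seed(config$seed, "unet-init"))
  opt <- adam_init(params)
  n <- length(images)
  loss_hist <- numeric(config$N)
  lr_hist <- numeric(config$N)
  xs <- lapply(images, function(im) im / 255 - 0.5)
  onehots <- lapply(masks, function(m) {
    cbind(1 - as.vector(m), as.vector(m))
  })
  for (epoch in seq_len(config$N) - 1L) {
    lr <- poly_lr(epoch, config)
    lr_hist[epoch + 1L] <- lr
    ord <- with_seed(derive_seed(config$seed, paste0("epoch-", epoch)),
                     sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      g_acc <- NULL
      b_loss <- 0
      for (ix in bt) {
        fw <- unet_forward(params, xs[[ix]])
        lmat <- matrix(fw$logits, ncol = 2L)
        ce <- softmax_ce(lmat, onehots[[ix]])
        b_loss <- b_loss + ce$loss
        dlog <- array(ce$dlogits, dim(fw$logits))
        g <- unet_backward(params, fw$caches, dlog)
        g_acc <- grad_add(g_acc, g)
      }
      g_acc <- grad_scale(g_acc, 1 / length(bt))
      st <- adam_step(params, g_acc, opt, lr)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + b_loss / length(bt)
    }
    loss_hist[epoch + 1L] <- ep_loss / length(batches)
  }
  structure(list(params = params, config = config,
                 loss_history = loss_hist, lr_history = lr_hist),
            class = "unet_model")
}

#' Predict a nuclei mask with a trained U-Net
#'
#' @param model a `unet_model` from [train_unet()]
#' @param image RGB array (even-sized, compatible with the model's depth)
#' @return 0/1 matrix: softmax argmax per pixel
#' @export
predict_unet <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  fw <- unet_forward(model$params, image / 255 - 0.5)
  probs <- softmax_rows(matrix(fw$logits, ncol = 2L))
  matrix(as.integer(probs[, 2] > probs[, 1]), dim(image)[1], dim(image)[2])
}

# recursively flatten a nested parameter list to (dim, data) records and back,
# so checkpoints are plain JSON
params_to_json <- function(p) {
  if (is.list(p)) return(lapply(p, params_to_json))
  list(.dim = dim(p) %||% length(p), .data = as.vector(p))
}

params_from_json <- function(p) {
  if (is.list(p) && !is.null(p$.data)) {
    d <- unlist(p$.dim)
    x <- as.numeric(unlist(p$.data))
    return(if (length(d) > 1) array(x, d) else x)
  }
  lapply(p, params_from_json)
}

#' Save a trained segmentation model as a JSON checkpoint
#'
#' Weights, training configuration and loss/learning-rate histories are
#' written as plain JSON (configuration sidecar included in the same
#' file), so checkpoints are portable text.
#'
#' @param model a `unet_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_unet_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  jsonlite::write_json(
    list(params = params_to_json(model$params),
         config = unclass(model$config),
         loss_history = model$loss_history,
         lr_history = model$lr_history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a segmentation model from a JSON checkpoint
#'
#' @param path file written by [save_unet_model()]
#' @return a `unet_model`
#' @export
load_unet_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfgl <- lapply(x$config, unlist)
  cfg <- do.call(training_config, cfgl)
  structure(list(params = params_from_json(x$params), config = cfg,
                 loss_history = as.numeric(unlist(x$loss_history)),
                 lr_history = as.numeric(unlist(x$lr_history))),
            class = "unet_model")
}
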