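# Region-of-interest selection from whole-slide images: thumbnail the
# slide, over-segment it into superpixels, rank superpixels by mean gray
# intensity (darker = denser tissue), keep the low-intensity percentile,
# and map the winning centroid back to full resolution for cropping.

#' Configuration for ROI selection
#'
#' @param thumbnail_max_dim longest side of the working thumbnail, px
#' @param n_superpixels target number of superpixels on the thumbnail
#' @param compactness SLIC-style spatial weight; larger values give more
#'   compact, grid-like superpixels
#' @param percentile fraction of darkest superpixels kept as candidates
#'   (inclusive lower quantile), default 0.10
#' @param roi_size side of the square crop at full resolution, default 1000
#' @param background_threshold gray level above which a superpixel is
#'   treated as glass background and excluded from ranking (bright side
#'   only; dark superpixels are never filtered), default 240
#' @return an object of class `roi_config`
#' @export
roi_config <- function(thumbnail_max_dim = 512, n_superpixels = 400,
                       compactness = 10, percentile = 0.10, roi_size = 1000,
                       background_threshold = 240) {
  assert_scalar_number(thumbnail_max_dim, "thumbnail_max_dim", lower = 64)
  assert_scalar_number(n_superpixels, "n_superpixels", lower = 2)
  assert_scalar_number(percentile, "percentile", lower = 1e-9, upper = 1)
  assert_scalar_number(roi_size, "roi_size", lower = 1)
  structure(list(thumbnail_max_dim = as.integer(thumbnail_max_dim),
                 n_superpixels = as.integer(n_superpixels),
                 compactness = compactness, percentile = percentile,
                 roi_size = as.integer(roi_size),
                 background_threshold = background_threshold),
            class = "roi_config")
}

#' Downscale a slide image to a working thumbnail
#'
#' @param wsi RGB array, or a path to a PNG file
#' @param config a [roi_config()]
#' @return list with `thumbnail` (RGB array, longest side <=
#'   `thumbnail_max_dim`, aspect preserved) and `scale_factor`
#'   (full resolution / thumbnail resolution; 1 when no shrink was needed)
#' @export
make_thumbnail <- function(wsi, config = roi_config()) {
  if (is.character(wsi)) wsi <- read_image(wsi)
  assert_rgb(wsi, "wsi")
  h <- dim(wsi)[1]; w <- dim(wsi)[2]
  md <- config$thumbnail_max_dim
  if (max(h, w) <= md) {
    return(list(thumbnail = wsi, scale_factor = 1))
  }
  if (h >= w) {
    th <- md; tw <- max(1L, as.integer(round(w * md / h)))
  } else {
    tw <- md; th <- max(1L, as.integer(round(h * md / w)))
  }
  eb <- EBImage::resize(to_ebimage(wsi), w = tw, h = th)
  list(thumbnail = from_ebimage(eb), scale_factor = max(h, w) / md)
}

#' Over-segment a thumbnail into superpixels
#'
#' SLIC-style clustering: k-means over the joint feature
#' (row * m/S, col * m/S, R, G, B) with centers seeded on a regular grid
#' (S = sqrt(n_pixels / n_superpixels), m = compactness), followed by a
#' connectivity pass that splits clusters into connected components and
#' merges fragments smaller than S^2/4 into their dominant neighbor.
#'
#' @param thumbnail RGB array
#' @param config a [roi_config()]
#' @return integer label matrix (same height/width); labels 1..K, every
#'   pixel assigned exactly one contiguous label
#' @export
oversegment <- function(thumbnail, config = roi_config()) {
  assert_rgb(thumbnail, "thumbnail")
  h <- dim(thumbnail)[1]; w <- dim(thumbnail)[2]
  n <- h * w
  k <- min(config$n_superpixels, n)
  S <- sqrt(n / k)
  m <- config$compactness

  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  feat <- cbind(rows * m / S, cols * m / S,
                as.vector(thumbnail[, , 1]),
                as.vector(thumbnail[, , 2]),
                as.vector(thumbnail[, , 3]))

  # grid seeding
  ky <- max(1L, round(h / S)); kx <- max(1L, round(w / S))
  cy <- (seq_len(ky) - 0.5) * h / ky
  cx <- (seq_len(kx) - 0.5) * w / kx
  grid <- expand.grid(row = cy, col = cx)
  centers <- cbind(grid$row * m / S, grid$col * m / S,
                   t(vapply(seq_len(nrow(grid)), function(i) {
                     r <- pmin(pmax(round(grid$row[i]), 1), h)
                     c <- pmin(pmax(round(grid$col[i]), 1), w)
                     thumbnail[r, c, ]
                   }, numeric(3))))
  centers <- unique(centers)
  if (nrow(centers) < 2L || stats::sd(feat[, 3]) + stats::sd(feat[, 4]) +
        stats::sd(feat[, 5]) < 1e-9) {
    # degenerate/constant image: spatial grid only
    if (stats::sd(feat[, 3]) + stats::sd(feat[, 4]) + stats::sd(feat[, 5]) < 1e-9) {
      warning("constant-color image: superpixels fall back to a spatial grid")
    }
  }
  km <- suppressWarnings(stats::kmeans(feat, centers = centers,
                                       iter.max = 10, algorithm = "Lloyd"))
  lab <- matrix(km$cluster, h, w)

  lab <- enforce_connectivity(lab, min_size = max(4, floor(S * S / 4)))
  lab
}

# split every cluster into connected components, then iteratively merge
# components smaller than min_size into the neighboring label they share
# the longest border with
enforce_connectivity <- function(lab, min_size) {
  h <- nrow(lab); w <- ncol(lab)
  # relabel into connected components
  comp <- matrix(0L, h, w)
  nxt <- 0L
  for (cl in sort(unique(as.vector(lab)))) {
    bw <- EBImage::bwlabel(matrix(as.integer(lab == cl), h, w))
    bw <- matrix(as.integer(bw), h, w)
    idx <- bw > 0L
    comp[idx] <- bw[idx] + nxt
    nxt <- nxt + max(bw)
  }
  for (pass in seq_len(10L)) {
    sizes <- tabulate(comp, nbins = max(comp))
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0L || length(sizes[sizes > 0]) <= 1L) break
    # neighbor pairs via 4-neighbor shifts
    right <- cbind(as.vector(comp[, -w]), as.vector(comp[, -1]))
    down <- cbind(as.vector(comp[-h, ]), as.vector(comp[-1, ]))
    pairs <- rbind(right, down, right[, 2:1], down[, 2:1])
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    merged <- FALSE
    for (s in small) {
      nb <- pairs[pairs[, 1] == s, 2]
      if (length(nb) == 0L) next
      target <- as.integer(names(which.max(table(nb))))
      comp[comp == s] <- target
      pairs[pairs == s] <- target
      merged <- TRUE
    }
    if (!merged) break
  }
  # consecutive labels
  u <- sort(unique(as.vector(comp)))
  out <- matrix(match(comp, u), h, w)
  storage.mode(out) <- "integer"
  out
}

#' Rank superpixels by mean intensity and select the darkest percentile
#'
#' Computes each superpixel's mean gray level (luma), drops near-white glass
#' superpixels (mean above `background_threshold`; dark superpixels are
#' never dropped), then keeps every superpixel whose mean is less than or
#' equal to the `percentile` quantile of the remaining means. Candidates are
#' sorted ascending by mean intensity; ties broken by larger area, then
#' lower label id. Centroids are mapped to full resolution through
#' `scale_factor`.
#'
#' @param label_map integer label matrix from [oversegment()]
#' @param thumbnail RGB array of the same size
#' @param config a [roi_config()]
#' @param scale_factor thumbnail-to-slide scale from [make_thumbnail()]
#' @param exclude_mask optional 0/1 matrix (thumbnail coordinates); any
#'   superpixel with more than half its area inside the mask is excluded
#'   (e.g. a user-drawn pen-mark exclusion)
#' @return data.frame of ROI candidates: superpixel_id, mean_intensity,
#'   area, centroid_row, centroid_col, centroid_wsi_row, centroid_wsi_col
#' @export
rank_and_select <- function(label_map, thumbnail, config = roi_config(),
                            scale_factor = 1, exclude_mask = NULL) {
  assert_rgb(thumbnail, "thumbnail")
  if (!all(dim(label_map) == dim(thumbnail)[1:2])) {
    stop("label_map and thumbnail shapes differ", call. = FALSE)
  }
  labs <- as.vector(label_map)
  if (length(unique(labs)) == 0L) stop("empty label map", call. = FALSE)
  gray <- as.vector(rgb_to_gray(thumbnail))

  msum <- rowsum(gray, labs)
  area <- as.vector(rowsum(rep(1, length(labs)), labs))
  means <- as.vector(msum) / area
  rows <- rep(seq_len(nrow(label_map)), times = ncol(label_map))
  cols <- rep(seq_len(ncol(label_map)), each = nrow(label_map))
  cen_r <- as.vector(rowsum(rows, labs)) / area
  cen_c <- as.vector(rowsum(cols, labs)) / area
  ids <- as.integer(rownames(msum))

  keep <- means <= config$background_threshold
  if (!is.null(exclude_mask)) {
    ex_frac <- as.vector(rowsum(as.numeric(exclude_mask), labs)) / area
    keep <- keep & ex_frac <= 0.5
  }
  if (!any(keep)) keep <- rep(TRUE, length(ids))  # blank slide: rank everything

  q <- stats::quantile(means[keep], config$percentile, names = FALSE, type = 7)
  sel <- keep & means <= q
  ord <- order(means[sel], -area[sel], ids[sel])
  out <- data.frame(superpixel_id = ids[sel][ord],
                    mean_intensity = means[sel][ord],
                    area = area[sel][ord],
                    centroid_row = cen_r[sel][ord],
                    centroid_col = cen_c[sel][ord])
  out$centroid_wsi_row <- as.integer(round(out$centroid_row * scale_factor))
  out$centroid_wsi_col <- as.integer(round(out$centroid_col * scale_factor))
  out
}

#' Crop a square ROI around a candidate centroid
#'
#' The window is centered on the candidate's full-resolution centroid and
#' shifted (never padded) to fit inside the slide, so the output is always
#' exactly `roi_size` x `roi_size`.
#'
#' @param wsi RGB array (full resolution) or path to a PNG
#' @param candidate one row of the data.frame from [rank_and_select()]
#' @param config a [roi_config()]
#' @return RGB array of size roi_size x roi_size
#' @export
crop_roi <- function(wsi, candidate, config = roi_config()) {
  if (is.character(wsi)) wsi <- read_image(wsi)
  assert_rgb(wsi, "wsi")
  h <- dim(wsi)[1]; w <- dim(wsi)[2]
  rs <- config$roi_size
  if (h < rs || w < rs) {
    stop(sprintf("slide (%d x %d) smaller than roi_size %d", h, w, rs),
         call. = FALSE)
  }
  r0 <- as.integer(round(candidate$centroid_wsi_row - rs / 2))
  c0 <- as.integer(round(candidate$centroid_wsi_col - rs / 2))
  r0 <- min(max(r0, 0L), h - rs)
  c0 <- min(max(c0, 0L), w - rs)
  wsi[(r0 + 1):(r0 + rs), (c0 + 1):(c0 + rs), , drop = FALSE]
}

#' Select ROIs from a slide in one call
#'
#' Convenience wrapper: thumbnail, over-segment, rank, and crop the top
#' `n_roi` candidates.
#'
#' @param wsi RGB array or PNG path
#' @param config a [roi_config()]
#' @param n_roi number of ROIs to crop (default 1, the top candidate)
#' @param exclude_mask optional thumbnail-coordinate 0/1 exclusion mask
#' @return list with `rois` (list of RGB arrays), `candidates` (data.frame)
#'   and `scale_factor`
#' @export
select_rois <- function(wsi, config = roi_config(), n_roi = 1,
                        exclude_mask = NULL) {
  if (is.character(wsi)) wsi <- read_image(wsi)
  th <- make_thumbnail(wsi, config)
  lab <- oversegment(th$thumbnail, config)
  cand <- rank_and_select(lab, th$thumbnail, config,
                          scale_factor = th$scale_factor,
                          exclude_mask = exclude_mask)
  n <- min(n_roi, nrow(cand))
  rois <- lapply(seq_len(n), function(i) crop_roi(wsi, cand[i, ], config))
  list(rois = rois, candidates = cand, scale_factor = th$scale_factor)
}
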