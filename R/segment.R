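# Nuclei segmentation front-end with two backends: the trainable
# encoder-decoder network (production path) and a fully deterministic
# classical pipeline (stain-separate, Otsu-threshold the hematoxylin
# density, fill holes, drop specks), used wherever GPU-scale training is
# out of reach. Touching-nuclei splitting by distance-transform watershed
# is applied when counting objects, not to the binary mask itself.

#' Segment nuclei in an H&E image
#'
#' Classical backend: the image is stain-separated (sparse non-negative
#' factorization), the hematoxylin density row is thresholded by Otsu,
#' holes are filled and objects smaller than `min_object_px` pixels are
#' removed. The whole path is deterministic and equivariant to 90-degree
#' rotation. A blank (all-background) image yields an empty mask.
#'
#' @param image RGB array
#' @param backend `"classical"` or `"unet"`
#' @param model a `unet_model`, required for the unet backend
#' @param config a [norm_config()] for the classical stain separation
#' @param min_object_px minimum object size kept, in pixels
#' @return 0/1 nuclei mask matrix of the image's height x width
#' @export
segment <- function(image, backend = c("classical", "unet"), model = NULL,
                    config = norm_config(), min_object_px = 10) {
  assert_rgb(image)
  backend <- match.arg(backend)
  if (backend == "unet") {
    if (!inherits(model, "unet_model")) {
      stop("unet backend requires a trained `unet_model`", call. = FALSE)
    }
    return(predict_unet(model, image))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  od <- rgb_to_od(image, config)
  odnorm <- sqrt(colSums(od$X^2))
  if (sum(odnorm > config$od_background_threshold) < config$r) {
    return(matrix(0L, h, w))   # blank slide: nothing to segment
  }
  fit <- fit_stain_model(od, config)
  hem <- matrix(fit$L[1, ], h, w)
  hmax <- max(hem)
  if (hmax <= 0) return(matrix(0L, h, w))
  thr <- EBImage::otsu(hem / hmax, range = c(0, 1), levels = 256) * hmax
  bin <- matrix(as.integer(hem > thr), h, w)
  bin <- matrix(as.integer(EBImage::fillHull(bin)), h, w)
  # drop specks
  lab <- matrix(as.integer(EBImage::bwlabel(bin)), h, w)
  if (max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    drop <- which(sizes < min_object_px)
    if (length(drop)) bin[lab %in% drop] <- 0L
  }
  storage.mode(bin) <- "integer"
  bin
}

#' Count nuclei in a binary mask
#'
#' Connected components, optionally split at necks between touching nuclei
#' by a distance-transform watershed.
#'
#' @param mask 0/1 matrix
#' @param split_touching apply the watershed split?
#' @return integer object count
#' @export
count_nuclei <- function(mask, split_touching = TRUE) {
  assert_mask(mask)
  if (sum(mask) == 0) return(0L)
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    ws <- EBImage::watershed(dm, tolerance = 1)
    return(as.integer(max(ws)))
  }
  as.integer(max(EBImage::bwlabel(mask)))
}

#' Dice overlap between two binary masks
#'
#' 2|A intersect B| / (|A| + |B|); defined as 1 when both masks are empty.
#'
#' @param a,b 0/1 matrices of equal shape
#' @return Dice coefficient in [0, 1]
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a == 1); sb <- sum(b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}
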