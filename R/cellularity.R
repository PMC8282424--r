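# Tumor cellularity: the fraction of image area covered by (optionally
# dilated) segmented nuclei. Dilation with a small structuring element
# accounts for the cytoplasm surrounding each nucleus; sizes around 11-12
# px are the convention in the cellularity literature, with 0 (no dilation)
# a common baseline.

#' Configuration for cellularity computation
#'
#' @param dilation_size structuring-element diameter in pixels; 0 disables
#'   dilation. Even sizes are reduced to the next odd size (a disk needs a
#'   center pixel); a message reports the adjustment.
#' @param element_shape `"disk"` (default) or `"square"`
#' @return an object of class `cellularity_config`
#' @export
cellularity_config <- function(dilation_size = 0,
                               element_shape = c("disk", "square")) {
  assert_scalar_number(dilation_size, "dilation_size", lower = 0)
  structure(list(dilation_size = as.integer(dilation_size),
                 element_shape = match.arg(element_shape)),
            class = "cellularity_config")
}

#' Structuring element for morphological dilation
#'
#' Disk of diameter `size`: offsets (i, j) with i^2 + j^2 <= r^2 for
#' r = (size - 1)/2. Square: the full size x size block.
#'
#' @param size odd element diameter (side) in pixels
#' @param shape `"disk"` or `"square"`
#' @return 0/1 kernel matrix of dim (size, size)
#' @export
structuring_element <- function(size, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  stopifnot(size >= 1, size %% 2 == 1)
  if (shape == "square") return(matrix(1, size, size))
  r <- (size - 1) / 2
  off <- seq(-r, r)
  outer(off, off, function(i, j) as.numeric(i^2 + j^2 <= r^2))
}

#' Compute cellularity of a nuclei mask
#'
#' cellularity = foreground pixels / total pixels, after optional
#' morphological dilation of the mask with the configured structuring
#' element. Always in [0, 1] and non-decreasing in the dilation size.
#'
#' @param mask 0/1 nuclei mask matrix
#' @param config a [cellularity_config()]
#' @return object of class `cellularity_result`: list with `cellularity`,
#'   `foreground_pixels`, `total_pixels`, `dilation_size`
#' @export
compute_cellularity <- function(mask, config = cellularity_config()) {
  assert_mask(mask)
  size <- config$dilation_size
  if (size > 0 && size %% 2 == 0) {
    message("even dilation_size ", size, " reduced to ", size - 1,
            " (disk elements need a center pixel)")
    size <- size - 1L
  }
  m <- mask
  if (size >= 3) {
    kern <- structuring_element(size, config$element_shape)
    m <- matrix(as.integer(EBImage::dilate(mask, kern) > 0),
                nrow(mask), ncol(mask))
  }
  fg <- sum(m == 1)
  structure(list(cellularity = fg / length(m),
                 foreground_pixels = fg,
                 total_pixels = length(m),
                 dilation_size = config$dilation_size),
            class = "cellularity_result")
}

#' Stratified cellularity summary over a cohort
#'
#' Per-stratum mean, sample variance and count of case cellularity, with
#' strata defined by grade or by grade x IDH status. Strata with no records
#' are omitted with a warning.
#'
#' @param records a cohort data.frame with columns `cellularity`, `grade`
#'   and (for `by = "grade_idh"`) `idh`, plus `case_id`
#' @param by `"grade"` or `"grade_idh"`
#' @return data.frame with columns stratum, n, mean_cellularity,
#'   var_cellularity
#' @export
stratified_summary <- function(records, by = c("grade", "grade_idh")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(records))
  if (is.null(records$cellularity) || anyNA(records$cellularity)) {
    bad <- if (is.null(records$cellularity)) records$case_id else
      records$case_id[is.na(records$cellularity)]
    stop("missing cellularity for case(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  strata <- if (by == "grade") records$grade else
    paste(records$grade, records$idh, sep = ":")
  levels_all <- if (by == "grade") c("II", "III", "IV") else
    as.vector(outer(c("II", "III", "IV"), c("MT", "WT"), paste, sep = ":"))
  out <- do.call(rbind, lapply(levels_all, function(s) {
    x <- records$cellularity[strata == s]
    if (length(x) == 0L) return(NULL)
    data.frame(stratum = s, n = length(x), mean_cellularity = mean(x),
               var_cellularity = if (length(x) > 1) stats::var(x) else 0)
  }))
  empty <- setdiff(levels_all, out$stratum)
  if (length(empty) > 0) {
    warning("strata with no records omitted: ", paste(empty, collapse = ", "))
  }
  out
}
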