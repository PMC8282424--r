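# Synthetic H&E histology: seed-controlled generation of stained-tissue
# images with exact ground-truth nuclei masks, mock whole-slide thumbnails
# with optional pen-mark artifacts, and molecular/grade cohorts.
#
# Synthesis follows the Beer-Lambert transmission model used throughout the
# package: a per-pixel optical-density field is composed from a hematoxylin
# absorbance vector (nuclei) and an eosin absorbance vector (background
# tissue), then exponentiated against illumination I0 = 255 and quantized to
# 8 bits. Because synthesis and stain separation share the same OD
# convention, the separation module can be validated against known ground
# truth stain vectors.

#' Specification of a synthetic H&E image
#'
#' @param width,height image size in pixels
#' @param n_nuclei number of elliptical nuclei to place
#' @param nucleus_radius_range length-2 vector, min/max semi-major axis in px
#' @param nucleus_eccentricity_range length-2 vector in [0, 1)
#' @param hematoxylin_od_vector 3-vector of per-channel optical densities for
#'   the nuclear stain (default: the Ruifrok reference hematoxylin vector)
#' @param eosin_od_vector 3-vector for the cytoplasm/stroma stain
#'   (default: the Ruifrok reference eosin vector)
#' @param background_intensity 8-bit level of the brightest channel of the
#'   eosin background
#' @param stain_perturbation nonnegative scale of the random perturbation
#'   applied to both stain vectors (0 = exact reference vectors)
#' @param allow_overlap may nuclei overlap (the default, as in real tissue)?
#'   When FALSE, rejection sampling keeps nuclei disjoint, for tests that
#'   need a known object count
#' @param seed integer seed; identical specs produce bit-identical output
#' @return an object of class `synthetic_image_spec`
#' @export
synthetic_image_spec <- function(width = 96, height = 96, n_nuclei = 40,
                                 nucleus_radius_range = c(3, 5),
                                 nucleus_eccentricity_range = c(0, 0.7),
                                 hematoxylin_od_vector = c(0.65, 0.70, 0.29),
                                 eosin_od_vector = c(0.07, 0.99, 0.11),
                                 background_intensity = 210,
                                 stain_perturbation = 0,
                                 allow_overlap = TRUE,
                                 seed = 1L) {
  assert_scalar_number(width, "width", lower = 0)
  assert_scalar_number(height, "height", lower = 0)
  assert_scalar_number(n_nuclei, "n_nuclei", lower = 0)
  stopifnot(length(nucleus_radius_range) == 2L,
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            nucleus_radius_range[1] > 0,
            length(nucleus_eccentricity_range) == 2L,
            all(nucleus_eccentricity_range >= 0),
            all(nucleus_eccentricity_range < 1))
  for (v in list(hematoxylin_od_vector, eosin_od_vector)) {
    if (length(v) != 3L || any(v < 0) || all(v == 0)) {
      stop("stain OD vectors must be nonnegative, nonzero 3-vectors",
           call. = FALSE)
    }
  }
  assert_scalar_number(background_intensity, "background_intensity", 1, 255)
  assert_scalar_number(stain_perturbation, "stain_perturbation", lower = 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 nucleus_eccentricity_range = as.numeric(nucleus_eccentricity_range),
                 hematoxylin_od_vector = as.numeric(hematoxylin_od_vector),
                 eosin_od_vector = as.numeric(eosin_od_vector),
                 background_intensity = as.numeric(background_intensity),
                 stain_perturbation = as.numeric(stain_perturbation),
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# evaluate expr under a temporary RNG state so generators never disturb the
# caller's random stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rasterize a filled ellipse into a binary matrix
#'
#' A pixel (i, j) belongs to the ellipse when its center satisfies the
#' point-in-ellipse inequality for semi-axes `a = radius` and
#' `b = radius * sqrt(1 - ecc^2)` rotated by `angle`.
#'
#' @param height,width matrix size
#' @param center length-2 (row, col) ellipse center (may be fractional)
#' @param radius semi-major axis in pixels
#' @param ecc eccentricity in [0, 1)
#' @param angle rotation in radians
#' @return integer 0/1 matrix of dim (height, width)
#' @export
draw_ellipse_mask <- function(height, width, center, radius, ecc = 0,
                              angle = 0) {
  stopifnot(radius > 0, ecc >= 0, ecc < 1)
  a <- radius
  b <- radius * sqrt(1 - ecc^2)
  m <- matrix(0L, height, width)
  r0 <- max(1L, floor(center[1] - a)); r1 <- min(height, ceiling(center[1] + a))
  c0 <- max(1L, floor(center[2] - a)); c1 <- min(width, ceiling(center[2] + a))
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - center[1], length(rows), length(cols))
  dx <- matrix(cols - center[2], length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m[rows, cols] <- m[rows, cols] | inside
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic H&E image with its ground-truth nuclei mask
#'
#' Nuclei are placed by uniform rejection sampling (overlaps allowed; a
#' nucleus must fit inside the frame, with up to 100 attempts each).
#' Foreground pixels receive a hematoxylin-dominant optical density,
#' background pixels an eosin density chosen so the brightest background
#' channel matches `background_intensity`; the RGB image is
#' `round(255 * exp(-OD))` clipped to 8 bits.
#'
#' @param spec a [synthetic_image_spec()]
#' @return list with elements `image` (height x width x 3 array),
#'   `mask` (0/1 matrix), `od` (3 x n_pixels pre-exponentiation OD field) and
#'   `stain_vectors` (3 x 2 matrix of the possibly perturbed H/E vectors)
#' @export
generate_he_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  h <- spec$height; w <- spec$width
  if (h == 0L || w == 0L) stop("zero-area image requested", call. = FALSE)
  rmax <- spec$nucleus_radius_range[2]
  rmean <- mean(spec$nucleus_radius_range)
  exp_cover <- spec$n_nuclei * pi * rmean^2 / (h * w)
  if (exp_cover > 0.95) {
    stop(sprintf(paste0("n_nuclei = %d would cover ~%.0f%% of the image; ",
                        "expected nuclei coverage must stay below 95%%"),
                 spec$n_nuclei, 100 * exp_cover), call. = FALSE)
  }

  with_seed(spec$seed, {
    # perturb stain vectors (simulates scanner/stain variability)
    perturb <- function(v) {
      if (spec$stain_perturbation <= 0) return(v)
      v2 <- v * (1 + spec$stain_perturbation * stats::rnorm(1)) +
        spec$stain_perturbation * 0.3 * stats::rnorm(3)
      v2 <- pmax(v2, 1e-3)
      v2 / sqrt(sum(v2^2)) * sqrt(sum(v^2))
    }
    hv <- perturb(spec$hematoxylin_od_vector)
    ev <- perturb(spec$eosin_od_vector)

    mask <- matrix(0L, h, w)
    hdens <- matrix(0, h, w)            # hematoxylin density map
    placed_at <- matrix(NA_real_, 0, 3) # (row, col, radius) of placed nuclei
    if (spec$n_nuclei > 0L) {
      for (k in seq_len(spec$n_nuclei)) {
        placed <- FALSE
        for (attempt in seq_len(100L)) {
          r <- stats::runif(1, spec$nucleus_radius_range[1], rmax)
          if (2 * r + 1 > min(h, w)) next
          ecc <- stats::runif(1, spec$nucleus_eccentricity_range[1],
                              spec$nucleus_eccentricity_range[2])
          ang <- stats::runif(1, 0, pi)
          cr <- stats::runif(1, r + 1, h - r)
          cc <- stats::runif(1, r + 1, w - r)
          if (!spec$allow_overlap && nrow(placed_at) > 0 &&
              any(sqrt((placed_at[, 1] - cr)^2 + (placed_at[, 2] - cc)^2) <
                    placed_at[, 3] + r + 2)) next
          ell <- draw_ellipse_mask(h, w, c(cr, cc), r, ecc, ang)
          dens <- stats::runif(1, 0.85, 1.25)
          mask <- pmax(mask, ell)
          hdens <- pmax(hdens, ell * dens)
          placed_at <- rbind(placed_at, c(cr, cc, r))
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("failed to place a nucleus within 100 attempts; ",
               "nucleus_radius_range too large for the image", call. = FALSE)
        }
      }
    }
    storage.mode(mask) <- "integer"

    # eosin background density: brightest eosin channel hits background_intensity
    d_bg <- -log(spec$background_intensity / 255) / max(ev)
    edens <- matrix(d_bg, h, w) *
      matrix(1 + 0.05 * stats::rnorm(h * w), h, w)
    edens <- pmax(edens, 0)
    # nuclei retain some surrounding eosin signal (cytoplasm under/around them)
    edens <- edens * (1 - 0.5 * mask)

    X <- rbind(hv[1] * as.vector(hdens) + ev[1] * as.vector(edens),
               hv[2] * as.vector(hdens) + ev[2] * as.vector(edens),
               hv[3] * as.vector(hdens) + ev[3] * as.vector(edens))
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- matrix(X[ch, ], h, w)
    img <- round(255 * exp(-img))
    img <- pmin(pmax(img, 0), 255)

    list(image = img, mask = mask, od = X,
         stain_vectors = cbind(hematoxylin = hv, eosin = ev))
  })
}

#' Generate a mock whole-slide thumbnail with known tissue regions
#'
#' A bright glass background (mean level > 240, so the ROI ranking's glass
#' filter applies) holds `n_tissue_regions` dark elliptical tissue blobs.
#' With `with_pen_mark = TRUE`, a near-black ink polyline of width 15 px is
#' drawn disjoint from every tissue region; its extreme darkness reproduces
#' the documented failure mode of intensity-ranked ROI selection on
#' pen-annotated slides.
#'
#' @param n_tissue_regions number of tissue blobs (>= 1)
#' @param with_pen_mark add a pen-mark artifact?
#' @param seed integer seed
#' @param height,width image size in pixels
#' @return list with `image`, `regions` (data.frame of bounding boxes:
#'   region_id, row_min, row_max, col_min, col_max), and `pen_mask`
#'   (0/1 matrix, or NULL when no pen mark was drawn)
#' @export
generate_mock_wsi <- function(n_tissue_regions, with_pen_mark = FALSE,
                              seed = 1L, height = 360, width = 480) {
  assert_scalar_number(n_tissue_regions, "n_tissue_regions", lower = 1)
  n_tissue_regions <- as.integer(n_tissue_regions)
  with_seed(seed, {
    h <- height; w <- width
    img <- array(0, c(h, w, 3))
    bg <- 244 + matrix(2 * stats::rnorm(h * w), h, w)
    for (ch in 1:3) img[, , ch] <- bg

    # place non-overlapping tissue blobs
    centers <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    boxes <- NULL
    tissue_mask <- matrix(0L, h, w)
    for (k in seq_len(n_tissue_regions)) {
      ok <- FALSE
      for (attempt in seq_len(400L)) {
        r <- stats::runif(1, 0.09, 0.14) * min(h, w)
        cr <- stats::runif(1, r + 5, h - r - 5)
        cc <- stats::runif(1, r + 5, w - r - 5)
        if (nrow(centers) > 0 &&
            any(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) <
                (radii + r + 12))) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place ", n_tissue_regions,
                    " disjoint tissue regions", call. = FALSE)
      centers <- rbind(centers, c(cr, cc))
      radii <- c(radii, r)
      ecc <- stats::runif(1, 0, 0.5)
      blob <- draw_ellipse_mask(h, w, c(cr, cc), r, ecc, stats::runif(1, 0, pi))
      tissue_mask <- pmax(tissue_mask, blob)
      idx <- which(blob == 1L)
      # dark purple-pink tissue texture
      base <- c(125, 85, 135)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- base[ch] + 12 * stats::rnorm(length(idx))
        img[, , ch] <- plane
      }
      rows <- ((idx - 1) %% h) + 1; cols <- ((idx - 1) %/% h) + 1
      boxes <- rbind(boxes, data.frame(region_id = k,
                                       row_min = min(rows), row_max = max(rows),
                                       col_min = min(cols), col_max = max(cols)))
    }

    pen_mask <- NULL
    if (isTRUE(with_pen_mark)) {
      # pick a column band away from all tissue blobs
      margin <- 12 + 8   # half pen width + clearance
      free <- setdiff(seq(20, w - 20),
                      unlist(lapply(seq_len(n_tissue_regions), function(k) {
                        lo <- floor(centers[k, 2] - radii[k] - margin)
                        hi <- ceiling(centers[k, 2] + radii[k] + margin)
                        seq(max(1, lo), min(w, hi))
                      })))
      if (length(free) == 0) stop("no room for a pen mark", call. = FALSE)
      x0 <- free[sample.int(length(free), 1)]
      pts <- cbind(row = c(0.12, 0.5, 0.88) * h,
                   col = x0 + c(0, stats::runif(1, -4, 4), stats::runif(1, -4, 4)))
      pen_mask <- matrix(0L, h, w)
      half <- 7.5  # stroke width 15 px
      for (s in 1:2) {
        p <- pts[s, ]; q <- pts[s + 1, ]
        steps <- ceiling(sqrt(sum((q - p)^2)))
        for (t in seq(0, 1, length.out = steps + 1)) {
          ctr <- p + t * (q - p)
          pen_mask <- pmax(pen_mask,
                           draw_ellipse_mask(h, w, ctr, half, 0, 0))
        }
      }
      storage.mode(pen_mask) <- "integer"
      idx <- which(pen_mask == 1L)
      ink <- c(18, 18, 60)   # near-black blue ink
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- ink[ch] + 3 * stats::rnorm(length(idx))
        img[, , ch] <- plane
      }
    }

    img <- pmin(pmax(round(img), 0), 255)
    list(image = img, regions = boxes, pen_mask = pen_mask)
  })
}

#' Specification of a synthetic molecular/grade cohort
#'
#' Grade is encoded in nuclei density (higher-grade tumors are more
#' cellular), and molecular marker probabilities are grade-conditional, so a
#' downstream classifier has a recoverable signal with known ground truth.
#'
#' @param n_cases_per_class named counts for grades II, III and IV
#' @param density_by_grade named list; per grade a c(mean, sd) of the nuclei
#'   count per image
#' @param molecular_priors named list; per grade a named vector of
#'   probabilities c(idh, atrx, codel, mgmt) for IDH MT, ATRX MT, 1p/19q CD
#'   and MGMT ML respectively
#' @param image_width,image_height per-case ROI image size
#' @param nucleus_radius_range passed to [synthetic_image_spec()]
#' @param stain_perturbation per-case stain variability
#' @param seed integer seed
#' @return an object of class `synthetic_cohort_spec`
#' @export
synthetic_cohort_spec <- function(
    n_cases_per_class = c(II = 15, III = 15, IV = 15),
    density_by_grade = list(II = c(mean = 12, sd = 2.5),
                            III = c(mean = 21, sd = 3.5),
                            IV = c(mean = 38, sd = 5)),
    molecular_priors = list(
      II = c(idh = 0.85, atrx = 0.60, codel = 0.40, mgmt = 0.80),
      III = c(idh = 0.75, atrx = 0.55, codel = 0.35, mgmt = 0.70),
      IV = c(idh = 0.10, atrx = 0.10, codel = 0.02, mgmt = 0.40)),
    image_width = 64, image_height = 64,
    nucleus_radius_range = c(3, 5),
    stain_perturbation = 0.02,
    seed = 1L) {
  grades <- c("II", "III", "IV")
  stopifnot(all(grades %in% names(n_cases_per_class)),
            all(grades %in% names(density_by_grade)),
            all(grades %in% names(molecular_priors)))
  if (any(n_cases_per_class < 1)) {
    stop("every grade class needs at least one case", call. = FALSE)
  }
  for (g in grades) {
    d <- density_by_grade[[g]]
    if (d[["mean"]] <= 0 || d[["sd"]] < 0) {
      stop("densities must be positive", call. = FALSE)
    }
    p <- molecular_priors[[g]]
    if (any(p < 0) || any(p > 1)) {
      stop("molecular priors must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_cases_per_class = n_cases_per_class[grades],
                 density_by_grade = density_by_grade[grades],
                 molecular_priors = molecular_priors[grades],
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 stain_perturbation = as.numeric(stain_perturbation),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic case cohort
#'
#' Each case carries a grade-conditional H&E ROI image, its exact nuclei
#' mask, a molecular profile sampled from the grade's priors, a histology
#' label (grade IV is always GBM) and the ground-truth-mask cellularity
#' (undilated). Class counts match the spec exactly.
#'
#' @param spec a [synthetic_cohort_spec()]
#' @return a data.frame of class `glio_cohort` with list-columns `image` and
#'   `mask` plus case_id, grade, histology, idh, atrx, codel_1p19q, mgmt,
#'   n_nuclei and cellularity
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  grades <- names(spec$n_cases_per_class)
  rows <- list()
  idx <- 0L
  for (g in grades) {
    n <- spec$n_cases_per_class[[g]]
    dens <- spec$density_by_grade[[g]]
    pri <- spec$molecular_priors[[g]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      cseed <- derive_seed(spec$seed, paste0("case-", g, "-", i))
      draws <- with_seed(cseed, {
        list(n_nuclei = max(0L, as.integer(round(stats::rnorm(
               1, dens[["mean"]], dens[["sd"]])))),
             idh = stats::runif(1) < pri[["idh"]],
             atrx = stats::runif(1) < pri[["atrx"]],
             codel = stats::runif(1) < pri[["codel"]],
             mgmt = stats::runif(1) < pri[["mgmt"]],
             hist_u = stats::runif(1))
      })
      histology <- if (g == "IV") "GBM" else if (draws$codel) {
        if (draws$hist_u < 0.8) "OD" else "OA"
      } else {
        if (draws$hist_u < 0.55) "AA" else if (draws$hist_u < 0.8) "OA" else "OD"
      }
      ispec <- synthetic_image_spec(
        width = spec$image_width, height = spec$image_height,
        n_nuclei = draws$n_nuclei,
        nucleus_radius_range = spec$nucleus_radius_range,
        stain_perturbation = spec$stain_perturbation,
        seed = derive_seed(cseed, "image"))
      gen <- generate_he_image(ispec)
      rows[[idx]] <- list(
        case_id = sprintf("case_%03d", idx), grade = g, histology = histology,
        idh = if (draws$idh) "MT" else "WT",
        atrx = if (draws$atrx) "MT" else "WT",
        codel_1p19q = if (draws$codel) "CD" else "NC",
        mgmt = if (draws$mgmt) "ML" else "UM",
        n_nuclei = draws$n_nuclei,
        cellularity = mean(gen$mask),
        image = gen$image, mask = gen$mask)
    }
  }
  df <- data.frame(
    case_id = vapply(rows, `[[`, "", "case_id"),
    grade = vapply(rows, `[[`, "", "grade"),
    histology = vapply(rows, `[[`, "", "histology"),
    idh = vapply(rows, `[[`, "", "idh"),
    atrx = vapply(rows, `[[`, "", "atrx"),
    codel_1p19q = vapply(rows, `[[`, "", "codel_1p19q"),
    mgmt = vapply(rows, `[[`, "", "mgmt"),
    n_nuclei = vapply(rows, `[[`, 0L, "n_nuclei"),
    cellularity = vapply(rows, `[[`, 0, "cellularity"),
    stringsAsFactors = FALSE)
  df$image <- lapply(rows, `[[`, "image")
  df$mask <- lapply(rows, `[[`, "mask")
  class(df) <- c("glio_cohort", "data.frame")
  df
}

#' Write a cohort to disk (PNG images/masks + CSV table)
#'
#' @param cohort a `glio_cohort` data.frame from [generate_cohort()]
#' @param dir output directory (created if missing)
#' @return path of the written CSV, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glio_cohort") || is.data.frame(cohort))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_paths <- file.path(dir, paste0(cohort$case_id, ".png"))
  mask_paths <- file.path(dir, paste0(cohort$case_id, "_mask.png"))
  for (i in seq_len(nrow(cohort))) {
    write_image(cohort$image[[i]], img_paths[i])
    write_mask(cohort$mask[[i]], mask_paths[i])
  }
  tab <- cohort[, c("case_id", "grade", "histology", "idh", "atrx",
                    "codel_1p19q", "mgmt", "cellularity")]
  tab$image_path <- img_paths
  tab$mask_path <- mask_paths
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param csv path to the cohort CSV
#' @param load_images also load images and masks into memory?
#' @return a `glio_cohort` data.frame
#' @export
read_cohort <- function(csv, load_images = TRUE) {
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  if (load_images) {
    tab$image <- lapply(tab$image_path, read_image)
    tab$mask <- lapply(tab$mask_path, read_mask)
  }
  class(tab) <- c("glio_cohort", "data.frame")
  tab
}
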