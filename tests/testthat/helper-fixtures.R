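# Shared fixtures, memoized so expensive objects (cohorts, CV runs) are
# built once per test session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# a modest two-stain H&E image with ground truth
he_fixture <- function(seed = 3, n = 40, side = 96) {
  generate_he_image(synthetic_image_spec(width = side, height = side,
                                         n_nuclei = n, seed = seed))
}

# desk-scale classifier configuration used across cascade tests
desk_classifier_config <- function(seed = 3, ...) {
  classifier_config(patch_size = 32, stage1_blocks = 2, stage2_blocks = 3,
                    base_width = 8, epochs = 4, batch_size = 8, lr0 = 0.01,
                    seed = seed, ...)
}

# ROI configuration matched to the mock-WSI scale
desk_roi_config <- function(...) {
  roi_config(thumbnail_max_dim = 160, n_superpixels = 120, roi_size = 80, ...)
}

# default 150-case study cohort (grade encoded by nuclei density)
default_cohort_150 <- function() {
  fixture("cohort150", function() {
    generate_cohort(synthetic_cohort_spec(
      n_cases_per_class = c(II = 50, III = 50, IV = 50), seed = 5))
  })
}

small_cohort <- function() {
  fixture("cohort30", function() {
    generate_cohort(synthetic_cohort_spec(
      n_cases_per_class = c(II = 10, III = 10, IV = 10), seed = 11))
  })
}

# cross-validated accuracy of the grading stages on the default cohort,
# for a given feature set; memoized because each run trains 5 folds
cohort_cv <- function(task, features = c("intensity", "molecular",
                                         "cellularity")) {
  key <- paste0("cv-", task, "-", paste(features, collapse = "+"))
  fixture(key, function() {
    evaluate_cv(default_cohort_150(), task,
                desk_classifier_config(features = features))
  })
}

# independent brute-force dilation oracle: explicit per-pixel neighborhood
# OR over the structuring element's offsets
brute_force_dilate <- function(mask, size, shape = "disk") {
  if (size %% 2 == 0) size <- size - 1
  if (size < 3) return(mask)
  kern <- structuring_element(size, shape)
  r <- (size - 1) / 2
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 1) {
        for (di in -r:r) {
          for (dj in -r:r) {
            if (kern[di + r + 1, dj + r + 1] == 1) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- 1L
            }
          }
        }
      }
    }
  }
  out
}

# centroid-in-box helper for mock-WSI oracles
in_any_box <- function(row, col, boxes) {
  any(row >= boxes$row_min & row <= boxes$row_max &
        col >= boxes$col_min & col <= boxes$col_max)
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
rotate90_rgb <- function(img) {
  out <- array(0, c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) out[, , ch] <- rotate90(img[, , ch])
  out
}
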