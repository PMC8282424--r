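# Synthetic histology generator: determinism, geometric ground truth,
# Beer-Lambert consistency, cohort structure.

test_that("ellipse rasterization matches a brute-force point-in-ellipse test", {
  cases <- list(list(center = c(50.5, 50.5), radius = 10, ecc = 0, angle = 0),
                list(center = c(20, 70), radius = 7, ecc = 0.6, angle = 0.8),
                list(center = c(5, 5), radius = 4, ecc = 0.3, angle = 2))
  for (cs in cases) {
    m <- draw_ellipse_mask(100, 100, cs$center, cs$radius, cs$ecc, cs$angle)
    a <- cs$radius; b <- cs$radius * sqrt(1 - cs$ecc^2)
    expected <- matrix(0L, 100, 100)
    for (i in 1:100) {
      for (j in 1:100) {
        dx <- j - cs$center[2]; dy <- i - cs$center[1]
        u <- dx * cos(cs$angle) + dy * sin(cs$angle)
        v <- -dx * sin(cs$angle) + dy * cos(cs$angle)
        if ((u / a)^2 + (v / b)^2 <= 1) expected[i, j] <- 1L
      }
    }
    expect_identical(m, expected)
  }
})

test_that("H&E synthesis honors its contract", {
  # no nuclei: empty mask, zero cellularity
  g0 <- generate_he_image(synthetic_image_spec(width = 40, height = 40,
                                               n_nuclei = 0, seed = 1))
  expect_identical(sum(g0$mask), 0L)
  expect_equal(compute_cellularity(g0$mask)$cellularity, 0)

  # determinism: same spec (incl. seed) -> bit-identical outputs
  spec <- synthetic_image_spec(width = 64, height = 64, n_nuclei = 25,
                               seed = 42)
  g1 <- generate_he_image(spec)
  g2 <- generate_he_image(spec)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$mask, g2$mask)

  # image values are 8-bit, nuclei darker than background
  expect_true(all(g1$image >= 0 & g1$image <= 255))
  gray <- rgb_to_gray(g1$image)
  expect_lt(mean(gray[g1$mask == 1]), mean(gray[g1$mask == 0]))

  # mask/OD consistency: every foreground pixel has positive hematoxylin
  # contribution, visible as extra red-channel OD above the eosin floor
  hv <- spec$hematoxylin_od_vector
  od_red <- matrix(g1$od[1, ], 64, 64)
  expect_true(all(od_red[g1$mask == 1] > max(od_red[g1$mask == 0]) * 0.5))
})

test_that("synthesis rejects impossible requests", {
  expect_error(generate_he_image(synthetic_image_spec(width = 0, height = 10)),
               "zero-area")
  expect_error(generate_he_image(
    synthetic_image_spec(width = 20, height = 20, n_nuclei = 500,
                         nucleus_radius_range = c(3, 5))),
    "95")
  expect_error(synthetic_image_spec(nucleus_radius_range = c(5, 3)))
  expect_error(synthetic_image_spec(hematoxylin_od_vector = c(0, 0, 0)))
})

test_that("mock WSI places dark tissue in bright glass, pen mark darkest", {
  mw <- generate_mock_wsi(2, with_pen_mark = FALSE, seed = 4)
  expect_equal(nrow(mw$regions), 2)
  gray <- rgb_to_gray(mw$image)
  expect_gt(mean(gray), 200)              # mostly glass
  # region boxes really contain dark tissue
  b <- mw$regions[1, ]
  expect_lt(mean(gray[b$row_min:b$row_max, b$col_min:b$col_max]), 200)

  mp <- generate_mock_wsi(2, with_pen_mark = TRUE, seed = 4)
  expect_false(is.null(mp$pen_mask))
  grayp <- rgb_to_gray(mp$image)
  darkest <- which(grayp == min(grayp), arr.ind = TRUE)[1, ]
  expect_equal(mp$pen_mask[darkest[1], darkest[2]], 1L)
  # pen stroke disjoint from tissue boxes
  for (k in seq_len(nrow(mp$regions))) {
    bb <- mp$regions[k, ]
    expect_equal(sum(mp$pen_mask[bb$row_min:bb$row_max,
                                 bb$col_min:bb$col_max]), 0L)
  }
  expect_error(generate_mock_wsi(0), "n_tissue_regions")
})

test_that("cohort generation matches class counts and priors", {
  coh <- small_cohort()
  expect_s3_class(coh, "glio_cohort")
  expect_equal(unname(table(coh$grade)[c("II", "III", "IV")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_true(all(coh$histology[coh$grade == "IV"] == "GBM"))
  expect_true(all(coh$idh %in% c("MT", "WT")))
  expect_true(all(coh$codel_1p19q %in% c("CD", "NC")))

  # degenerate prior: P(IDH MT | II) = 1 forces every II record to MT
  pri1 <- list(II = c(idh = 1, atrx = 0.5, codel = 0.3, mgmt = 0.5),
               III = c(idh = 0.5, atrx = 0.5, codel = 0.3, mgmt = 0.5),
               IV = c(idh = 0, atrx = 0.1, codel = 0.02, mgmt = 0.4))
  cdg <- generate_cohort(synthetic_cohort_spec(
    n_cases_per_class = c(II = 8, III = 3, IV = 3),
    molecular_priors = pri1, seed = 2))
  expect_true(all(cdg$idh[cdg$grade == "II"] == "MT"))
  expect_true(all(cdg$idh[cdg$grade == "IV"] == "WT"))
  expect_error(synthetic_cohort_spec(n_cases_per_class = c(II = 0, III = 1,
                                                           IV = 1)))
})

test_that("cohort molecular marginals converge to the priors", {
  # 3-standard-error agreement at n = 500 per class on one marker/grade
  n <- 500L
  coh <- generate_cohort(synthetic_cohort_spec(
    n_cases_per_class = c(II = n, III = 2, IV = 2),
    density_by_grade = list(II = c(mean = 4, sd = 1), III = c(mean = 4, sd = 1),
                            IV = c(mean = 6, sd = 1)),
    image_width = 16, image_height = 16,
    nucleus_radius_range = c(1.5, 2.5), seed = 77))
  p_hat <- mean(coh$idh[coh$grade == "II"] == "MT")
  p <- 0.85
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("cohorts round-trip through PNG + CSV on disk", {
  coh <- generate_cohort(synthetic_cohort_spec(
    n_cases_per_class = c(II = 2, III = 2, IV = 2), seed = 6))
  dir <- withr::local_tempdir()
  csv <- write_cohort(coh, dir)
  back <- read_cohort(csv)
  expect_equal(back$grade, coh$grade)
  expect_identical(back$mask[[1]], coh$mask[[1]])
  expect_identical(back$image[[3]], coh$image[[3]])
})
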