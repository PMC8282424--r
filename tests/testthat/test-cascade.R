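# Cascade classifier plumbing: patch tiling, augmentation, fold
# bookkeeping, fusion configuration, cascade decision rule, molecular
# classification.

test_that("patch tiling follows the covering-grid rule", {
  mk <- function(side) array(seq_len(side * side * 3) %% 251, c(side, side, 3))
  expect_length(make_patches(mk(1024), 512), 4)
  p1000 <- make_patches(mk(1000), 512)
  expect_length(p1000, 4)
  # stride 488: the last patch ends exactly at the ROI edge
  roi <- mk(1000)
  expect_identical(p1000[[4]], roi[489:1000, 489:1000, , drop = FALSE])
  # exact fit: a single identity patch
  roi512 <- mk(512)
  p512 <- make_patches(roi512, 512)
  expect_length(p512, 1)
  expect_identical(p512[[1]], roi512)
  expect_error(make_patches(mk(100), 512), "smaller")
  # patches tile content exactly (array-slice oracle)
  p64 <- make_patches(mk(64), 32)
  expect_identical(p64[[1]], mk(64)[1:32, 1:32, , drop = FALSE])
})

test_that("augmentation transforms are exact and deterministic", {
  patch <- he_fixture(seed = 2, n = 10, side = 32)$image
  # 180-degree rotation is an involution
  r180 <- apply_augmentation(patch, rotation = 180)
  expect_identical(apply_augmentation(r180, rotation = 180), patch)
  # no-op path is the identity
  expect_identical(apply_augmentation(patch, 0, "none", 1), patch)
  # flips are involutions
  fh <- apply_augmentation(patch, flip = "horizontal")
  expect_identical(apply_augmentation(fh, flip = "horizontal"), patch)
  # shape contract for any seed, incl. scaling
  for (s in c(1, 2, 3, 10)) {
    out <- augment(patch, seed = s)
    expect_identical(dim(out), dim(patch))
  }
  expect_identical(augment(patch, seed = 5), augment(patch, seed = 5))
  expect_false(identical(augment(patch, seed = 5), augment(patch, seed = 6)))
  rect <- array(0, c(16, 32, 3))
  expect_error(apply_augmentation(rect, rotation = 90), "square")
})

test_that("fold splits are stratified, disjoint and reproducible", {
  coh <- small_cohort()
  f <- split_folds(coh, k = 5, seed = 3)
  expect_length(f, 30)
  # each fold tests 6 cases, 2 per grade
  for (k in 1:5) {
    expect_equal(sum(f == k), 6)
    expect_equal(unname(table(coh$grade[f == k])), c(2L, 2L, 2L),
                 ignore_attr = TRUE)
  }
  expect_identical(split_folds(coh, k = 5, seed = 3), f)
  expect_false(identical(split_folds(coh, k = 5, seed = 4), f))
  tiny <- coh[c(1:3, 11:13, 21:23), ]
  expect_error(split_folds(tiny, k = 5), "fewer than k")
})

test_that("training rejects degenerate inputs", {
  coh <- small_cohort()
  expect_error(train_stage1(coh[coh$grade == "II", ],
                            desk_classifier_config()), "single class")
  expect_error(train_stage2(coh, desk_classifier_config()),
               "only grade II/III")
  expect_error(classifier_config(features = character(0)),
               "no active feature block")
})

test_that("stage-2 network is the deeper model by configuration", {
  cfg <- classifier_config()
  expect_gte(cfg$stage2_blocks, cfg$stage1_blocks)
})

test_that("the cascade short-circuits on an HGG verdict and breaks ties up", {
  coh <- small_cohort()
  cfg <- desk_classifier_config(seed = 8)
  cfg$epochs <- 3L
  m1 <- train_stage1(coh, cfg)
  m2 <- train_stage2(coh[coh$grade %in% c("II", "III"), ], cfg)
  hgg_case <- coh[which(coh$grade == "IV")[1], ]
  pred <- predict_cascade(hgg_case, m1, m2)
  if (pred$stage1_prob >= 0.5) {
    expect_equal(pred$grade, "IV")
    expect_true(is.na(pred$stage2_prob))    # stage 2 never consulted
  }
  lgg_case <- coh[which(coh$grade == "II")[1], ]
  pred2 <- predict_cascade(lgg_case, m1, m2)
  if (pred2$stage1_prob < 0.5) expect_false(is.na(pred2$stage2_prob))

  # mismatched feature configuration is refused
  cfg_nc <- desk_classifier_config(seed = 8,
                                   features = c("intensity", "molecular"))
  cfg_nc$epochs <- 2L
  m2b <- train_stage2(coh[coh$grade %in% c("II", "III"), ], cfg_nc)
  expect_error(predict_cascade(hgg_case, m1, m2b), "feature")
})

test_that("CV reports are internally consistent", {
  coh <- small_cohort()
  cfg <- desk_classifier_config(seed = 4)
  cfg$epochs <- 2L
  rep <- evaluate_cv(coh, "HGGvsLGG", cfg)
  expect_equal(rep$mean_accuracy, mean(rep$per_fold_accuracy))
  expect_equal(rep$std_accuracy, sd(rep$per_fold_accuracy))
  expect_equal(sum(rep$confusion_matrix), nrow(coh))
  # row sums equal per-class test counts
  expect_equal(unname(rowSums(rep$confusion_matrix)),
               unname(c(sum(coh$grade != "IV"), sum(coh$grade == "IV"))))
  # case-level integrity: every case tested exactly once
  expect_setequal(rep$predictions$case_id, coh$case_id)
  expect_false(anyNA(rep$predictions$predicted))
  # reporting format mirrors the "mean% +/- std%" convention
  expect_match(format(rep), "%")
})

test_that("cascade accuracy respects the per-stage composition bound", {
  coh <- small_cohort()
  cfg <- desk_classifier_config(seed = 6)
  r1 <- evaluate_cv(coh, "HGGvsLGG", cfg)
  r2 <- evaluate_cv(coh, "LGGIIvsIII", cfg)
  rc <- evaluate_cv(coh, "cascade", cfg)
  expect_gte(rc$mean_accuracy,
             r1$mean_accuracy * r2$mean_accuracy - 0.05)
})

test_that("molecular classification exploits grade-conditional priors", {
  coh <- fixture("mol_cohort", function() {
    generate_cohort(synthetic_cohort_spec(
      n_cases_per_class = c(II = 20, III = 20, IV = 20),
      molecular_priors = list(
        II = c(idh = 0.9, atrx = 0.6, codel = 0.4, mgmt = 0.8),
        III = c(idh = 0.9, atrx = 0.55, codel = 0.35, mgmt = 0.7),
        IV = c(idh = 0.1, atrx = 0.1, codel = 0.02, mgmt = 0.4)),
      seed = 17))
  })
  rep <- classify_molecular(coh, "idh", features = "grade", repeats = 3,
                            seed = 2)
  prior <- max(mean(coh$idh == "MT"), mean(coh$idh == "WT"))
  expect_gt(rep$mean_accuracy, prior)

  # adding histology + grade never hurts much relative to cellularity alone
  base <- classify_molecular(coh, "idh", features = "cellularity",
                             repeats = 3, seed = 2)
  rich <- classify_molecular(coh, "idh",
                             features = c("cellularity", "histology",
                                          "grade"),
                             repeats = 3, seed = 2)
  expect_gte(rich$mean_accuracy, base$mean_accuracy - 0.02)

  expect_error(classify_molecular(coh, "idh", features = character(0)),
               "feature")
  one_class <- coh; one_class$idh <- "MT"
  expect_error(classify_molecular(one_class, "idh"), "single class")
})
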