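test_that("the feature matrix has one row per individual, features by task", {
  sf <- study_features()
  fm <- build_feature_matrix(sf$ft)
  expect_equal(dim(fm$X), c(80L, 30L))
  expect_equal(levels(fm$y), c("non_autistic", "mixed"))
  expect_false(anyDuplicated(fm$participant_id) > 0)
  # both members of a dyad share the label
  for (d in unique(fm$dyad_id))
    expect_length(unique(fm$y[fm$dyad_id == d]), 1L)
  # dropping one task for one individual excludes them with a warning
  ft2 <- sf$ft[!(sf$ft$participant_id == sf$ft$participant_id[1] &
                 sf$ft$task == "meal_planning"), ]
  expect_warning(fm2 <- build_feature_matrix(ft2), "missing a task")
  expect_equal(nrow(fm2$X), 79L)
  # relabelling the tasks swaps the column blocks but not the values
  ft3 <- sf$ft
  ft3$task <- ifelse(ft3$task == "hobbies", "meal_planning", "hobbies")
  fm3 <- build_feature_matrix(ft3)
  feats <- sub("\\.(hobbies|meal_planning)$", "", colnames(fm$X))
  tasks <- sub("^.*\\.", "", colnames(fm$X))
  swapped <- paste(feats, ifelse(tasks == "hobbies", "meal_planning",
                                 "hobbies"), sep = ".")
  expect_equal(fm3$X[, swapped], fm$X, ignore_attr = TRUE)
})

test_that("the CV plan stratifies 26/14 dyads over 7 folds as 6,6,6,6,6,5,5", {
  dy <- sprintf("D%02d", 1:40)
  lab <- rep(c("mixed", "non_autistic"), c(26, 14))
  plan <- make_cv_plan(dy, lab, seed = 3)
  expect_length(plan$perms, 10L)
  for (pp in plan$perms) {
    sizes <- as.vector(table(pp$outer))
    expect_equal(sort(sizes), c(5, 5, 6, 6, 6, 6, 6))
    mixed_per_fold <- as.vector(table(pp$outer[lab == "mixed"]))
    expect_true(all(mixed_per_fold %in% 3:4))
    # every dyad appears in exactly one outer fold
    expect_equal(sort(names(pp$outer)), sort(dy))
    # inner folds partition the outer training dyads
    for (f in 1:7)
      expect_equal(sort(names(pp$inner[[f]])), sort(dy[pp$outer != f]))
  }
  # deterministic given the seed
  expect_identical(plan, make_cv_plan(dy, lab, seed = 3))
  expect_false(identical(plan, make_cv_plan(dy, lab, seed = 4)))
})

test_that("infeasible stratifications are rejected with a message", {
  expect_error(make_cv_plan(sprintf("D%d", 1:10),
                            rep(c("mixed", "non_autistic"), c(6, 4))),
               "stratification infeasible")
  expect_error(make_cv_plan(sprintf("D%d", 1:14), rep("mixed", 14)),
               "stratification infeasible")
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(0.738, 0.786), 0.762)
  expect_equal(balanced_accuracy(1, 1), 1)
  expect_equal(balanced_accuracy(0, 1), 0.5)
  expect_error(balanced_accuracy(1.2, 0.5), "\\[0, 1\\]")
  expect_error(balanced_accuracy(0.5, -0.1), "\\[0, 1\\]")
})

test_that("separable dyad-structured data is classified almost perfectly", {
  fm <- gaussian_fm(n_mixed = 10, n_non = 10, shift = 2.5, seed = 11)
  dy <- unique(fm$dyad_id)
  lab <- as.character(fm$y)[match(dy, fm$dyad_id)]
  plan <- make_cv_plan(dy, lab, outer_perms = 2, seed = 5)
  rep <- fit_predict_nested(fm, plan, grid = 2^(-2:2))
  expect_gte(rep$balanced_accuracy, 0.9)
  expect_gte(rep$auc, 0.95)
  expect_equal(rep$balanced_accuracy,
               (rep$sensitivity + rep$specificity) / 2)
})

test_that("training-derived parameters ignore the test rows (no leakage)", {
  fm <- gaussian_fm(n_mixed = 7, n_non = 7, shift = 1, seed = 21)
  dy <- unique(fm$dyad_id)
  lab <- as.character(fm$y)[match(dy, fm$dyad_id)]
  plan <- make_cv_plan(dy, lab, outer_perms = 1, seed = 9)
  r1 <- fit_predict_nested(fm, plan, grid = c(0.5, 2), details = TRUE)
  # corrupt one dyad's rows wildly; folds where that dyad is in the test
  # partition must keep identical training-derived parameters
  target <- dy[1]
  fm2 <- fm
  fm2$X[fm2$dyad_id == target, ] <- fm2$X[fm2$dyad_id == target, ] + 1e3
  r2 <- fit_predict_nested(fm2, plan, grid = c(0.5, 2), details = TRUE)
  f_test <- plan$perms[[1]]$outer[[target]]
  d1 <- Filter(function(d) d$fold == f_test, r1$details)[[1]]
  d2 <- Filter(function(d) d$fold == f_test, r2$details)[[1]]
  expect_identical(d1$C, d2$C)
  expect_identical(d1$threshold, d2$threshold)
  expect_identical(d1$lo, d2$lo)
  expect_identical(d1$hi, d2$hi)
  expect_identical(d1$median, d2$median)
})

test_that("duplicating every row while halving the penalty refits identically", {
  fm <- gaussian_fm(n_mixed = 5, n_non = 5, shift = 1, seed = 31)
  y <- fm$y
  m1 <- dyadsync:::svm_l2l2_fit(fm$X, y, C = 1)
  idx <- rep(seq_len(nrow(fm$X)), each = 2)
  m2 <- dyadsync:::svm_l2l2_fit(fm$X[idx, ], y[idx], C = 0.5)
  expect_equal(m1$w, m2$w, tolerance = 1e-4)
  expect_equal(m1$b, m2$b, tolerance = 1e-4)
})

test_that("the squared-hinge SVM agrees with a reference linear SVM", {
  skip_if_not_installed("e1071")
  fm <- gaussian_fm(n_mixed = 10, n_non = 10, shift = 3, seed = 41)
  mod <- dyadsync:::svm_l2l2_fit(fm$X, fm$y, C = 1)
  pred <- ifelse(dyadsync:::svm_decision(mod, fm$X) > 0, "mixed",
                 "non_autistic")
  ref <- e1071::svm(fm$X, fm$y, kernel = "linear", cost = 1, scale = FALSE)
  ref_pred <- as.character(predict(ref, fm$X))
  expect_gte(mean(pred == ref_pred), 0.95)
})

test_that("zero-variance features are pruned, all-constant input errors", {
  fm <- gaussian_fm(n_mixed = 7, n_non = 7, shift = 1, seed = 51)
  fm$X[, 2] <- 5                       # constant column
  dy <- unique(fm$dyad_id)
  lab <- as.character(fm$y)[match(dy, fm$dyad_id)]
  plan <- make_cv_plan(dy, lab, outer_perms = 1, seed = 2)
  r <- fit_predict_nested(fm, plan, grid = 1, details = TRUE)
  expect_true(all(vapply(r$details, function(d) !d$keep[2], logical(1))))
  fm$X[] <- 3
  expect_error(fit_predict_nested(fm, plan, grid = 1), "all features pruned")
})

test_that("the permutation p honours the +1 bound and config errors", {
  fm <- gaussian_fm(n_mixed = 7, n_non = 7, shift = 2.5, seed = 61)
  dy <- unique(fm$dyad_id)
  lab <- as.character(fm$y)[match(dy, fm$dyad_id)]
  plan <- make_cv_plan(dy, lab, outer_perms = 1, seed = 3)
  pt <- label_permutation_test(fm, plan, n_perm = 30, grid = 1, seed = 4,
                               optimize_threshold = FALSE)
  expect_gte(pt$p_value, 1 / 31)
  expect_lte(pt$p_value, 1)
  # strong separation at n_perm = 30 reaches the minimum attainable p
  expect_equal(pt$p_value, 1 / 31, tolerance = 1e-12)
  expect_error(label_permutation_test(fm, plan, n_perm = 0), "n_perm")
})

test_that("single-class labels propagate a stratification error", {
  fm <- gaussian_fm(n_mixed = 7, n_non = 7, seed = 71)
  fm$y <- factor(rep("mixed", length(fm$y)),
                 levels = c("non_autistic", "mixed"))
  expect_error(fit_predict_nested(fm, plan = NULL), "stratification")
})
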