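test_that("perfectly separated scores give AUC 1 and a perfect threshold", {
  r <- roc_analysis(c(0, 1, 2, 3), c("NL", "NL", "AD", "AD"))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_sens, 1)
  expect_equal(r$optimal_spec, 1)
  expect_gt(r$optimal_threshold, 1)
  expect_lt(r$optimal_threshold, 2)
})

test_that("trapezoidal AUC equals brute-force pair counting, with ties", {
  for (s in 1:40) {
    set.seed(s)
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    # integer scores force plenty of ties
    pos <- sample(0:5, n1, replace = TRUE)
    neg <- sample(0:5, n0, replace = TRUE)
    r <- roc_analysis(c(pos, neg), rep(c("AD", "NL"), c(n1, n0)))
    expect_equal(r$auc, pair_count_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("threshold ties break toward higher specificity", {
  # sens x spec is 0.5 at two thresholds; the higher-specificity one wins
  r <- roc_analysis(c(1, 3, 2, 4), c("NL", "NL", "AD", "AD"))
  candidates <- r$sensitivities * r$specificities
  expect_equal(max(candidates), r$optimal_sens * r$optimal_spec)
  alt <- which(candidates == max(candidates))
  expect_equal(r$optimal_spec, max(r$specificities[alt]))
})

test_that("agreement with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  sc <- rnorm(60)
  lb <- rep(c("NL", "AD"), 30)
  sc[lb == "AD"] <- sc[lb == "AD"] + 1
  ours <- roc_analysis(sc, lb)
  ref <- pROC::roc(lb, sc, levels = c("NL", "AD"), direction = "<",
                   quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("fold assignment is a seeded stratified partition", {
  labels <- rep(c("NL", "AD"), c(23, 17))
  f <- fdgpattern:::stratified_folds(labels, 10, seed = 4)
  expect_length(f, 40)
  expect_true(all(f %in% 1:10))
  for (g in c("NL", "AD")) {
    counts <- tabulate(f[labels == g], 10)
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(f, fdgpattern:::stratified_folds(labels, 10, seed = 4))
  expect_error(fdgpattern:::stratified_folds(rep("NL", 5), 10, 1),
               class = "fdgpattern_bad_k")
})

test_that("a hugely separable effect yields perfect pooled CV metrics", {
  set.seed(92)
  n <- 20; p <- 15
  vals <- matrix(exp(rnorm(n * p, 0, 0.05)), n, p)
  vals[11:20, 1:5] <- vals[11:20, 1:5] * 5
  vm <- proportional_scale(
    toy_matrix(vals, rep(c("NL", "AD"), each = 10), scaled = FALSE))
  cv <- kfold_cv(vm, method = "GLM", k = 10, seed = 3)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$auc, 1)
  # every subject held out exactly once
  expect_equal(sort(cv$pooled_scores$subject_id), sort(vm$subject_ids))
})

test_that("training folds are unaffected by their own held-out subjects", {
  vm <- random_positive_matrix(n = 30, p = 40, seed = 93)
  cv1 <- kfold_cv(vm, method = "GLM", k = 5, seed = 7)
  target_fold <- cv1$fold_assignment[3]
  # corrupt subject 3 (a test subject of its fold): the fold's
  # training-derived threshold must not change
  vm2 <- vm
  vm2$values[3, ] <- vm2$values[3, ] * 50
  cv2 <- kfold_cv(vm2, method = "GLM", k = 5, seed = 7)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_equal(cv1$per_fold_models[[target_fold]]$z_threshold,
               cv2$per_fold_models[[target_fold]]$z_threshold)
})

test_that("cohort reports count designations per group in x-of-n form", {
  set.seed(94)
  n <- 24; p <- 20
  vals <- matrix(exp(rnorm(n * p, 0, 0.1)), n, p)
  vals[13:24, 1:6] <- vals[13:24, 1:6] * 3
  vm <- proportional_scale(
    toy_matrix(vals, rep(c("NL", "AD"), each = 12), scaled = FALSE))
  m <- suppressWarnings(train_svm(vm, config = svm_config("SMO",
                                                          outlier_fraction = 0)))
  rep1 <- apply_to_cohort(m, vm, positive_groups = "AD",
                          negative_groups = "NL")
  expect_equal(sum(rep1$by_group$n), n)
  expect_true(all(grepl("^\\d+ of \\d+$", rep1$by_group$label)))
  expect_equal(rep1$sens_x_spec, rep1$sensitivity * rep1$specificity)
  # SVM separated training perfectly here: all AD designated AD
  expect_equal(rep1$by_group$label[rep1$by_group$group == "AD"], "12 of 12")

  # empty factor levels are dropped with a warning
  expect_warning(apply_to_cohort(m, vm,
                                 labels = factor(vm$labels,
                                                 levels = c("NL", "AD",
                                                            "PDD"))),
                 class = "fdgpattern_empty_group")
})

test_that("topographic similarity is exact for self and negated maps", {
  set.seed(95)
  spec <- cohort_spec(grid = c(12, 12, 12), n_control = 4, n_disease = 4,
                      seed = 95)
  co <- generate_cohort(spec)
  mask <- compute_mask(co$volumes)
  idx <- which(mask$include)
  arr <- array(rnorm(12^3), c(12, 12, 12))
  a <- fdgpattern:::smooth_gaussian_3d(arr, 8, 4)[idx]

  self <- topographic_similarity(a, a, mask, n_surrogates = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p_corrected, 1 / 100)

  neg <- topographic_similarity(a, -a, mask, n_surrogates = 99, seed = 1)
  expect_equal(neg$r, -1)

  expect_error(topographic_similarity(rep(1, length(a)), a, mask,
                                      n_surrogates = 99),
               class = "fdgpattern_constant_pattern")
  expect_error(topographic_similarity(a[-1], a, mask, n_surrogates = 99),
               class = "fdgpattern_mask_mismatch")
  expect_error(topographic_similarity(a, a, mask, n_surrogates = 10),
               class = "fdgpattern_bad_config")
})

test_that("surrogate maps preserve the amplitude spectrum", {
  set.seed(96)
  box <- fdgpattern:::smooth_gaussian_3d(array(rnorm(10^3), c(10, 10, 10)),
                                         8, 4)
  surr <- fdgpattern:::phase_randomize(box)
  expect_equal(Mod(fft(surr)), Mod(fft(box)), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(surr, box)))
})
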