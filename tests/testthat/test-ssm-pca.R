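test_that("log double-centering removes subject and voxel means", {
  # logs are [[1,3],[3,5]]: row-centering gives [[-1,1],[-1,1]],
  # column means (-1,1) become the GMP, centered residual is zero
  vm <- toy_matrix(rbind(c(exp(1), exp(3)), c(exp(3), exp(5))),
                   labels = c("NL", "AD"))
  dec <- log_double_center(vm)
  expect_equal(dec$gmp, c(-1, 1))
  expect_true(all(abs(dec$centered) < 1e-12))

  const <- toy_matrix(matrix(2.5, 3, 4), labels = c("NL", "NL", "AD"))
  expect_true(all(abs(log_double_center(const)$centered) < 1e-12))

  vm2 <- random_positive_matrix(n = 25, p = 60, seed = 21)
  c2 <- log_double_center(vm2)$centered
  expect_lt(max(abs(rowMeans(c2))), 1e-12)
  expect_lt(max(abs(colMeans(c2))), 1e-12)

  neg <- toy_matrix(rbind(c(1, -2), c(1, 1)), labels = c("NL", "AD"))
  expect_error(log_double_center(neg),
               class = "fdgpattern_nonpositive_value")
})

test_that("SVD components match an independent eigendecomposition", {
  vm <- random_positive_matrix(n = 30, p = 100, seed = 33)
  dec <- ssm_svd(log_double_center(vm), k = 10)

  expect_lt(max(abs(crossprod(dec$pcs) - diag(10))), 1e-8)
  sc <- crossprod(dec$subject_scores)
  expect_lt(max(abs(sc - diag(diag(sc)))), 1e-8)
  expect_true(all(diff(dec$vaf) <= 1e-12))
  expect_lte(sum(dec$vaf), 1 + 1e-12)

  # oracle: eigenvectors of the voxel covariance
  ev <- eigen(crossprod(dec$centered), symmetric = TRUE)$vectors[, 1:10]
  for (j in 1:10) {
    agreement <- abs(sum(dec$pcs[, j] * ev[, j]))
    expect_gt(agreement, 1 - 1e-8)
  }

  expect_error(ssm_svd(log_double_center(vm), k = 30),
               class = "fdgpattern_k_too_large")
})

test_that("a rank-one centered matrix yields its direction as PC1", {
  u <- c(1, -2, 1); u <- u - mean(u)
  set.seed(3); v <- rnorm(40); v <- v - mean(v)
  dec <- structure(list(centered = u %o% v, gmp = rep(0, 40)),
                   class = "ssm_decomposition")
  out <- ssm_svd(dec, k = 1)
  expect_equal(out$vaf[1], 1)
  expect_gt(abs(sum(out$pcs[, 1] * v / sqrt(sum(v^2)))), 1 - 1e-10)
})

test_that("the best-discriminating PC is selected and disease-oriented", {
  set.seed(17)
  n <- 40
  code <- rep(c(0, 1), each = n / 2)
  S <- matrix(rnorm(n * 5), n, 5)
  S[, 2] <- S[, 2] + code * 3   # only PC2 separates the groups
  dec <- synthetic_decomp(S, labels = ifelse(code == 1, "AD", "NL"))
  m <- select_best_pc(dec)
  expect_equal(m$extras$selected_pcs, 2)
  expect_equal(m$method, "SSM1")

  # orientation: disease group expresses the pattern positively
  st <- prospective_score_on_centered(m, dec)
  expect_gt(mean(st[code == 1]), mean(st[code == 0]))
})

test_that("PC1 is selected when one dominant effect is planted", {
  dec <- phantom_decomp()
  m <- select_best_pc(dec)
  expect_equal(m$extras$selected_pcs, 1)
})

test_that("stepwise combination retains the informative component", {
  reps <- 60
  exact <- 0; has_informative <- 0
  for (r in seq_len(reps)) {
    set.seed(400 + r)
    n <- 80; k <- 10
    code <- rep(c(0, 1), each = n / 2)
    S <- matrix(rnorm(n * k), n, k)
    S[, 1] <- S[, 1] + code * 1.5
    dec <- synthetic_decomp(S, p = 150, seed = 500 + r,
                            labels = ifelse(code == 1, "AD", "NL"))
    m <- suppressWarnings(stepwise_combine(dec))
    sel <- m$extras$selected_pcs
    if (1 %in% sel) has_informative <- has_informative + 1
    if (length(sel) == 1 && sel == 1) exact <- exact + 1
  }
  expect_equal(has_informative, reps)
  # forward entry at p < .05 over 9 null candidates admits a noise PC with
  # probability ~ 1 - 0.95^9, so the exact-set rate sits near 0.63
  expect_gt(exact / reps, 0.45)
})

test_that("stepwise falls back to the best single PC when nothing enters", {
  set.seed(55)
  n <- 24
  S <- matrix(rnorm(n * 4), n, 4)
  # make all PC scores orthogonal to the label
  code <- rep(c(0, 1), each = n / 2)
  cc <- code - mean(code)
  for (j in 1:4) S[, j] <- S[, j] - cc * sum(S[, j] * cc) / sum(cc^2)
  dec <- synthetic_decomp(S, p = 80, seed = 56,
                          labels = ifelse(code == 1, "AD", "NL"))
  expect_warning(m <- stepwise_combine(dec),
                 class = "fdgpattern_stepwise_empty")
  expect_equal(m$method, "SSM2")
  expect_length(m$extras$selected_pcs, 1)
})

test_that("the PC combination is reported in conventional notation", {
  mask <- toy_matrix(matrix(1, 1, 4), "NL")$mask
  m <- fdgpattern:::pattern_model("SSM2", rep(0.5, 4), 0, mask,
                                  ref_mean = 0, ref_sd = 1,
                                  extras = list(selected_pcs = c(1, 3, 7),
                                                weights = c(1.372, 0.851,
                                                            -0.204)))
  expect_equal(format_pc_combination(m),
               "1.372 x PC1 + 0.851 x PC3 - 0.204 x PC7")
})

test_that("prospective scoring agrees with SVD-derived training scores", {
  dec <- phantom_decomp()
  vm <- phantom_vm()
  m1 <- select_best_pc(dec)
  m1$z_threshold <- 0
  st <- prospective_score(m1, vm)
  svd_scores <- as.numeric(dec$centered %*% m1$pattern)
  expect_gt(cor(st$raw_score, svd_scores), 0.999)
  expect_lt(max(abs(st$raw_score - svd_scores)), 1e-6)
})

test_that("SSM scores are invariant to global rescaling of a scan", {
  dec <- ssm_svd(log_double_center(random_positive_matrix(16, 40, 61)), 5)
  m <- select_best_pc(dec)
  m$z_threshold <- 0
  vm <- random_positive_matrix(16, 40, 61)
  base <- prospective_score(m, vm)$raw_score
  vm$values[4, ] <- vm$values[4, ] * 3.7
  rescaled <- prospective_score(m, vm)$raw_score
  expect_lt(abs(rescaled[4] - base[4]), 1e-9)
  expect_equal(rescaled[-4], base[-4])
})

test_that("a scan equal to exp(gmp + constant) scores exactly zero", {
  dec <- phantom_decomp()
  m <- select_best_pc(dec)
  m$z_threshold <- 0
  vm <- phantom_vm()
  flat <- vm
  flat$values <- matrix(exp(dec$gmp + 2), 1, length(dec$gmp))
  flat$subject_ids <- "flat"
  flat$labels <- "NL"
  st <- prospective_score(m, flat)
  expect_lt(abs(st$raw_score), 1e-9)
})
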