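test_that("the two-point maximal-margin problem is solved in closed form", {
  X <- rbind(c(1, 0), c(-1, 0)); y <- c(1, -1)
  r <- fdgpattern:::smo_solve_cpp(tcrossprod(X), y, 10, 1e-6, 1e6)
  expect_true(r$converged)
  expect_equal(r$alpha, c(0.5, 0.5), tolerance = 1e-8)
  w <- colSums(r$alpha * y * X)
  expect_equal(w, c(1, 0), tolerance = 1e-8)
  expect_lt(abs(r$bias), 1e-8)
})

test_that("a single-subject ISDA problem has the analytic solution", {
  # one subject, K11 = 1 + offset, y = +1: alpha = min(C, 1/K11)
  K <- matrix(1.1, 1, 1)
  r <- fdgpattern:::isda_solve_cpp(K, 1, 10, 0, 1e6)
  expect_equal(r$alpha, 1 / 1.1, tolerance = 1e-9)
  r2 <- fdgpattern:::isda_solve_cpp(K, 1, 0.5, 0, 1e6)
  expect_equal(r2$alpha, 0.5, tolerance = 1e-12)
})

test_that("single ISDA coordinate steps never decrease the dual", {
  set.seed(71)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c(1, -1), each = n / 2)
  st <- svm_dual_state(tcrossprod(X) + 0.1, y, C = 1)
  obj <- svm_dual_objective(st)
  for (rep in 1:5) for (i in seq_len(n)) {
    st <- isda_step(st, i)
    newobj <- svm_dual_objective(st)
    expect_gte(newobj, obj - 1e-12)
    obj <- newobj
  }
  # an already-optimal coordinate is a fixed point
  st2 <- isda_step(st, 1)
  st3 <- isda_step(st2, 1)
  expect_equal(st3$alpha, st2$alpha)
})

test_that("SMO pair steps preserve the equality constraint", {
  set.seed(72)
  n <- 24
  X <- matrix(rnorm(n * 3), n, 3)
  X[1:12, 1] <- X[1:12, 1] + 1
  y <- rep(c(1, -1), each = n / 2)
  st <- svm_dual_state(tcrossprod(X), y, C = 1)
  obj <- svm_dual_objective(st)
  for (k in 1:100) {
    st <- smo_step(st)
    if (isTRUE(st$converged)) break
    expect_lt(abs(sum(st$alpha * st$y)), 1e-8)
    newobj <- svm_dual_objective(st)
    expect_gte(newobj, obj - 1e-12)
    obj <- newobj
  }
  expect_true(isTRUE(st$converged))
  # a converged state reports convergence immediately
  expect_true(isTRUE(smo_step(st)$converged))
})

test_that("both solvers match a generic convex-QP dual solution", {
  skip_if_not_installed(c("kernlab"))
  set.seed(2)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(1, -1), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 1.2
  C <- 1

  # SMO vs interior-point QP with the equality constraint
  K <- tcrossprod(X)
  rs <- fdgpattern:::smo_solve_cpp(K, y, C, 1e-6, 1e6)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 9,
                       maxiter = 300)
  a <- kernlab::primal(sol)
  w <- colSums(a * y * X)
  sv <- which(a > 1e-5 & a < C - 1e-5)
  b <- mean(y[sv] - X[sv, ] %*% w)
  f_qp <- as.numeric(X %*% w + b)
  f_smo <- as.numeric(X %*% colSums(rs$alpha * y * X)) + rs$bias
  expect_lt(max(abs(f_smo - f_qp)), 1e-4)

  # ISDA vs box-constrained quasi-Newton on the offset-kernel dual
  K2 <- tcrossprod(X) + 0.1
  ri <- fdgpattern:::isda_solve_cpp(K2, y, C, 0, 1e6)
  Q2 <- (y %o% y) * K2
  o <- optim(rep(0, n), function(a) 0.5 * sum(a * (Q2 %*% a)) - sum(a),
             function(a) as.numeric(Q2 %*% a) - 1, method = "L-BFGS-B",
             lower = 0, upper = C, control = list(maxit = 5000, factr = 1))
  f_ib <- as.numeric(X %*% colSums(o$par * y * X)) + 0.1 * sum(o$par * y)
  f_isda <- as.numeric(X %*% colSums(ri$alpha * y * X)) +
    0.1 * sum(ri$alpha * y)
  expect_lt(max(abs(f_isda - f_ib)), 1e-4)
})

test_that("trained models satisfy dual feasibility and reconstruction", {
  set.seed(77)
  n <- 30; p <- 12
  vals <- matrix(exp(rnorm(n * p, 0, 0.3)), n, p)
  vals[16:30, 1:4] <- vals[16:30, 1:4] * 1.6
  vm <- proportional_scale(
    toy_matrix(vals, rep(c("NL", "AD"), each = 15), scaled = FALSE))
  for (solver in c("ISDA", "SMO")) {
    cfg <- svm_config(solver, outlier_fraction = 0)
    m <- suppressWarnings(train_svm(vm, config = cfg))
    a <- m$extras$alphas
    expect_true(all(a >= -1e-12 & a <= cfg$C + 1e-12))
    code <- as.integer(vm$labels == "AD")
    yv <- ifelse(code == 1, 1, -1)
    w <- as.numeric(crossprod(vm$values, a * yv))
    expect_lt(max(abs(w - m$pattern)), 1e-8)
    if (solver == "SMO") expect_lt(abs(sum(a * yv)), 1e-8)
    st <- score_subjects(m, vm)
    expect_identical(st$designation,
                     ifelse(st$raw_score > 0, "AD", "non-AD"))
  }
})

test_that("robust learning removes the stated fraction of training scans", {
  set.seed(78)
  n <- 40; p <- 10
  vals <- matrix(exp(rnorm(n * p, 0, 0.3)), n, p)
  vals[21:40, 1:3] <- vals[21:40, 1:3] * 1.5
  vm <- proportional_scale(
    toy_matrix(vals, rep(c("NL", "AD"), each = 20), scaled = FALSE))
  m <- suppressWarnings(train_svm(vm, config = svm_config("SMO")))
  expect_length(m$extras$removed_outliers, ceiling(0.05 * n))
  expect_true(all(m$extras$removed_outliers %in% vm$subject_ids))
  expect_length(m$extras$alphas, n - ceiling(0.05 * n))
})

test_that("ISDA and SMO agree on designations for a separable phantom", {
  spec <- cohort_spec(grid = c(16, 16, 16), n_control = 20, n_disease = 20,
                      d = 4, seed = 301)
  co <- generate_cohort(spec)
  mask <- compute_mask(co$volumes)
  vm <- proportional_scale(extract_matrix(co$volumes, mask,
                                          co$manifest$group))
  test_spec <- cohort_spec(grid = c(16, 16, 16), n_control = 50,
                           n_disease = 50, d = 4, seed = 302)
  te <- generate_cohort(test_spec)
  vte <- proportional_scale(extract_matrix(te$volumes, mask,
                                           te$manifest$group))
  m_isda <- suppressWarnings(train_svm(vm, config = svm_config("ISDA")))
  m_smo <- suppressWarnings(train_svm(vm, config = svm_config("SMO")))
  d_isda <- score_subjects(m_isda, vte)$designation
  d_smo <- score_subjects(m_smo, vte)$designation
  expect_identical(d_isda, d_smo)
})

test_that("rescaling features with a compensating C keeps decision signs", {
  set.seed(80)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(1, -1), each = n / 2)
  X[y == 1, ] <- X[y == 1, ] + 2.5
  r1 <- fdgpattern:::smo_solve_cpp(tcrossprod(X), y, 1, 1e-6, 1e6)
  f1 <- as.numeric(X %*% colSums(r1$alpha * y * X)) + r1$bias
  X2 <- 2 * X
  r2 <- fdgpattern:::smo_solve_cpp(tcrossprod(X2), y, 1 / 4, 1e-6, 1e6)
  f2 <- as.numeric(X2 %*% colSums(r2$alpha * y * X2)) + r2$bias
  expect_identical(sign(f1), sign(f2))
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(svm_config("ISDA", C = 0), class = "fdgpattern_bad_config")
  expect_error(svm_config("SMO", outlier_fraction = 0.6),
               class = "fdgpattern_bad_config")
  cfg <- svm_config("ISDA")
  expect_equal(cfg$kernel_offset, 0.1)
  expect_equal(cfg$kkt_tolerance, 0)
  cfg2 <- svm_config("SMO")
  expect_equal(cfg2$kernel_offset, 0)
  expect_equal(cfg2$kkt_tolerance, 0.001)
  expect_equal(cfg2$max_iterations, 1e6)
  expect_equal(cfg2$outlier_fraction, 0.05)
})
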