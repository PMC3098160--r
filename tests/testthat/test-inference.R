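test_that("squared error matches closed forms", {
  # constant data with w = 0, b = 0: derivatives vanish, error is zero
  const <- fixture_series(matrix(2, 2, 30), matrix(0, 2, 30))
  expect_equal(sqe(matrix(0, 2, 2), const, b = c(0, 0)), 0)

  # one gene, x(t) = exp(-t): dx/dt = -x, so w = -1, b = 0 fits exactly
  tt <- seq(0, 4, length.out = 120)
  x <- matrix(exp(-tt), 1)
  series <- fixture_series(x, -x, t_max = 4)
  expect_lt(sqe(matrix(-1, 1, 1), series, b = 0), 1e-12)
  # with w = 0 the error is the summed squared derivative
  manual <- 0
  for (k in seq_len(120)) manual <- manual + exp(-tt[k])^2
  expect_equal(sqe(matrix(0, 1, 1), series, b = 0), manual)
})

test_that("objective distance is the masked Euclidean norm", {
  w <- matrix(0, 3, 3)
  O <- matrix(0, 3, 3)
  O[1, 2] <- 3
  O[2, 3] <- 4
  term <- grn_objective(O)
  expect_equal(objective_distance(O, term), 0)
  expect_equal(objective_distance(w, term), 5) # 3-4-5 triangle
  # random seeded instance against an explicit double loop
  set.seed(12)
  w2 <- matrix(rnorm(25), 5)
  O2 <- matrix(rnorm(25), 5)
  term2 <- grn_objective(O2)
  acc <- 0
  for (i in 1:5) {
    for (j in 1:5) if (i != j) acc <- acc + (w2[i, j] - O2[i, j])^2
  }
  expect_equal(objective_distance(w2, term2), sqrt(acc))
  # empty mask warns and returns 0
  empty <- grn_objective(O, mask = matrix(FALSE, 3, 3))
  expect_warning(d0 <- objective_distance(w, empty), "mask")
  expect_equal(d0, 0)
})

test_that("SOO matches the closed-form least-squares solution", {
  inst <- fixture_linear_instance(n = 6, seed = 3, noise = 0.3)
  fit <- soo_fit(inst$series, init_seed = 7)
  # oracle: independent closed-form fit via lm.fit on the stacked design
  A <- cbind(t(inst$series$values), 1)
  ref <- sum(lm.fit(A, t(inst$series$derivatives))$residuals^2)
  expect_lt(abs(fit$sqe - ref) / ref, 1e-4)
  # well-conditioned noiseless instance: recovers the generating model
  clean <- fixture_linear_instance(n = 6, seed = 4, noise = 0)
  cfit <- soo_fit(clean$series, init_seed = 7)
  expect_equal(unname(cfit$w), clean$w, tolerance = 1e-3)
  expect_equal(unname(cfit$b), clean$b, tolerance = 1e-3)
})

test_that("SOO attains zero error on constant data and is init-independent there", {
  const <- fixture_series(matrix(c(1, 2), 2, 40), matrix(0, 2, 40))
  fit <- soo_fit(const, init_seed = 1)
  expect_lt(fit$sqe, 1e-10)
  f1 <- soo_fit(fixture_linear_instance(seed = 5, noise = 0.2)$series, init_seed = 1)
  f2 <- soo_fit(fixture_linear_instance(seed = 5, noise = 0.2)$series, init_seed = 99)
  expect_lt(abs(f1$sqe - f2$sqe) / f1$sqe, 1e-6) # convex problem
})

test_that("goal attainment with the SOO solution as objective returns it", {
  inst <- fixture_linear_instance(n = 5, seed = 8, noise = 0.2)
  soo <- soo_fit(inst$series, init_seed = 3)
  term <- grn_objective(soo$w, goal = 0, weight = 1, label = "custom")
  fit <- moo_fit(inst$series, term, init_seed = 4)
  off <- which(diag(5) == 0)
  expect_equal(fit$w[off], soo$w[off], tolerance = 1e-3)
})

test_that("goal attainment degenerates to SOO without data terms", {
  inst <- fixture_linear_instance(n = 5, seed = 9, noise = 0.2)
  soo <- soo_fit(inst$series, init_seed = 2)
  moo <- moo_fit(inst$series, list(), init_seed = 2)
  expect_equal(moo$role, "moo")
  expect_lt(abs(moo$sqe - soo$sqe) / soo$sqe, 1e-4)
})

test_that("exact and augmented-Lagrangian solvers agree", {
  inst <- fixture_linear_instance(n = 5, seed = 10, noise = 0.3)
  set.seed(44)
  O <- matrix(rnorm(25, sd = 0.5), 5)
  term <- scale_objective(grn_objective(O, label = "custom"))
  fe <- moo_fit(inst$series, term, init_seed = 6, solver = "exact")
  fa <- moo_fit(inst$series, term, init_seed = 6, solver = "alm")
  Fe <- fe$attainment$F[2]
  Fa <- fa$attainment$F[2]
  expect_lt(abs(Fe - Fa) / Fe, 0.05)
  expect_lte(Fe, Fa * (1 + 1e-6)) # the exact path attains at least as good a goal
  expect_gt(cor(fe$w[term$mask], fa$w[term$mask]), 0.95)
  # both honour the squared-error cap
  cap <- fe$provenance$sqe_min * 1.05
  expect_lt(fe$sqe, cap * 1.01)
  expect_lt(fa$sqe, cap * 1.05)
})

test_that("weights trade attainment monotonically between goals", {
  # in the goal-attainment constraint F_k - theta_k * gamma <= J_k with
  # gamma >= 0, a larger theta_k slackens goal k: its attained F_k - J_k
  # can only grow, while the competing goal's attainment can only improve
  inst <- fixture_linear_instance(n = 4, seed = 11, noise = 0.3)
  set.seed(5)
  O1 <- matrix(rnorm(16, sd = 0.4), 4)
  O2 <- matrix(rnorm(16, sd = 0.4), 4)
  res <- sapply(c(0.5, 1, 2, 4), function(th) {
    terms <- list(
      grn_objective(O1, weight = 1, label = "custom"),
      grn_objective(O2, weight = th, label = "custom")
    )
    fit <- moo_fit(inst$series, terms, init_seed = 3)
    fit$attainment$slack[2:3]
  })
  expect_true(all(diff(res[2, ]) >= -1e-6)) # slackened goal drifts up
  expect_true(all(diff(res[1, ]) <= 1e-6)) # fixed-weight goal improves
})

test_that("hard data goals are enforced or reported infeasible", {
  inst <- fixture_linear_instance(n = 4, seed = 12, noise = 0.2)
  soo <- soo_fit(inst$series, init_seed = 1)
  # a hard goal that the SOO solution itself satisfies is achievable
  term <- grn_objective(soo$w, goal = 0.5, weight = 0, label = "custom")
  fit <- moo_fit(inst$series, term, init_seed = 2, solver = "alm")
  expect_lt(objective_distance(fit, term), 0.5 + 1e-3)
  # an impossible hard goal errors with the offending term
  far <- matrix(100, 4, 4)
  bad <- grn_objective(far, goal = 1e-6, weight = 0, label = "custom")
  expect_error(moo_fit(inst$series, bad, init_seed = 2, solver = "alm"), "infeasible")
})

test_that("ensemble combination takes magnitudes and signs from its parents", {
  w_r <- grn_fit(matrix(c(0, 0.5, 0, 0.3), 2, 2), c(0, 0), "ratio_fit")
  w_c <- grn_fit(matrix(c(1, -0.2, -1, 0), 2, 2), c(0, 0), "correlation_fit")
  ens <- ensemble_combine(w_r, w_c)
  expect_equal(ens$role, "ensemble")
  expect_equal(unname(ens$w[2, 1]), -0.5) # magnitude 0.5, sign from -0.2
  expect_equal(unname(ens$w[1, 2]), 0) # zero magnitude stays zero
  expect_equal(unname(ens$w[2, 2]), 0.3) # sign donor 0 -> positive tie rule
  wrong <- grn_fit(matrix(0, 3, 3), rep(0, 3), "correlation_fit")
  expect_error(ensemble_combine(w_r, wrong), "shape")
})

test_that("tidy and glance summarize fits as tibbles", {
  w <- matrix(c(0, 2, -1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  fit <- grn_fit(w, c(0.1, 0.2), "soo", sqe = 3.5)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(td$weight[1], 2) # ranked by |weight|
  expect_equal(td$regulator[1], "A")
  expect_equal(td$target[1], "B")
  gl <- glance(fit)
  expect_equal(gl$sqe, 3.5)
  expect_equal(gl$role, "soo")
})
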