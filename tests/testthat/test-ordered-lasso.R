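test_that("a large penalty returns the all-zero solution and network", {
  set.seed(71)
  ts <- expression_ts(matrix(rnorm(4 * 30), 4, 30))
  z <- senemod:::standardize_rows(ts$values)
  d <- senemod:::lagged_design(z, 1, 2)
  lam_max <- max(abs(crossprod(d$X, d$y)))
  fit <- ordered_lasso_fit(ts, 1, l_max = 2, lambda = lam_max * 1.01)
  expect_true(all(fit$w == 0))
  adj <- infer_network(ts, l_max = 2, lambda = lam_max * 2)
  expect_true(all(adj == 0))
})

test_that("an AR(1) series recovers its coefficient against the OLS oracle", {
  set.seed(73)
  Tn <- 500
  x <- numeric(Tn)
  for (t in 2:Tn) x[t] <- 0.5 * x[t - 1] + rnorm(1, 0, 0.01)
  ts <- expression_ts(matrix(x, 1), dt = 1)
  fit <- ordered_lasso_fit(ts, 1, l_max = 1, lambda = 0)
  z <- senemod:::standardize_rows(ts$values)
  d <- senemod:::lagged_design(z, 1, 1)
  w_ols <- sum(d$X * d$y) / sum(d$X^2)
  expect_lt(abs(fit$w[1, 1] - w_ols), 1e-6)
  expect_lt(abs(fit$w[1, 1] - 0.5), 0.02)
})

test_that("lag monotonicity binds and matches a brute-force grid search", {
  # single gene, two lags, a penalty strong enough to engage the constraint
  set.seed(73)
  found_violation <- FALSE
  for (try in 1:10) {
    z <- matrix(rnorm(30), 1, 30)
    ts <- expression_ts(z)
    zs <- senemod:::standardize_rows(z)
    d <- senemod:::lagged_design(zs, 1, 2)
    w_ols <- qr.solve(d$X, d$y)
    if (abs(w_ols[1]) >= abs(w_ols[2])) next  # need an active constraint
    found_violation <- TRUE
    lam <- 0.3
    fit <- ordered_lasso_fit(ts, 1, l_max = 2, lambda = lam)
    expect_gte(abs(fit$w[1, 1]), abs(fit$w[1, 2]) - 1e-10)
    # exhaustive grid oracle at step 1e-3
    grid <- seq(-1.5, 1.5, by = 1e-3)
    best <- NULL
    for (w1 in grid) {
      w2s <- grid[abs(grid) <= abs(w1)]
      obj <- 0.5 * colSums((d$y - d$X[, 1] * w1 -
                              outer(d$X[, 2], w2s))^2) +
        lam * (abs(w1) + abs(w2s))
      i <- which.min(obj)
      if (is.null(best) || obj[i] < best$obj) {
        best <- list(w = c(w1, w2s[i]), obj = obj[i])
      }
    }
    expect_lt(max(abs(best$w - fit$w[1, ])), 2e-3)
    break
  }
  expect_true(found_violation)
})

test_that("every fit satisfies the monotonicity constraint at machine tolerance", {
  set.seed(74)
  ts <- expression_ts(matrix(rnorm(5 * 40), 5, 40))
  for (lam in c(0, 0.5, 2, 8)) {
    for (target in 1:5) {
      fit <- ordered_lasso_fit(ts, target, l_max = 3, lambda = lam)
      mono <- apply(abs(fit$w), 1, function(a) all(diff(a) <= 1e-10))
      expect_true(all(mono))
    }
  }
})

test_that("active predictor blocks shrink monotonically along a lambda path", {
  prog <- example_grn6()
  dat <- gen_expression_from_network(prog, 60, noise_sd = 0.05,
                                     noise = "process", seed = 75)
  lams <- c(0.1, 0.5, 2, 5, 10, 20, 40)
  n_active <- vapply(lams, function(l) {
    adj <- infer_network(dat$ts, l_max = 2, lambda = l, zero_tol = 1e-6)
    sum(adj)
  }, numeric(1))
  expect_true(all(diff(n_active) <= 0))
})

test_that("a constant gene emits no outgoing edges at positive penalty", {
  set.seed(76)
  vals <- rbind(rep(3, 25), matrix(rnorm(3 * 25), 3, 25))
  rownames(vals) <- c("const", "a", "b", "c")
  ts <- expression_ts(vals)
  adj <- infer_network(ts, l_max = 2, lambda = 0.5, zero_tol = 1e-6)
  expect_true(all(adj["const", ] == 0))
})

test_that("insufficient time points raise an informative error", {
  ts <- expression_ts(matrix(rnorm(3 * 4), 3, 4))
  expect_error(ordered_lasso_fit(ts, 1, l_max = 3, lambda = 0),
               "insufficient data")
})

test_that("stage-wise reconstruction marks short windows and converges to the full fit", {
  prog <- example_grn6()
  dat <- gen_expression_from_network(prog, 39, noise_sd = 0.05,
                                     noise = "process", seed = 77)
  stages <- rep(c("GS10", "GS30", "GS50", "GS70", "GS90"), each = 8)
  ts <- expression_ts(dat$ts$values, stages = stages)
  nets <- stagewise_networks(ts, min_timepoints = 10, l_max = 2, lambda = 4)
  expect_s3_class(nets[["GS10"]], "not_reconstructable")
  expect_false(inherits(nets[["GS90"]], "not_reconstructable"))
  full <- infer_network(expression_ts(dat$ts$values), l_max = 2, lambda = 4)
  expect_equal(unclass(nets[["GS90"]])[, ], unclass(full)[, ])
  expect_error(stagewise_networks(ts, stages = "GS55"), "unknown stage")
})

test_that("the hub gene tops the out-degree ranking on hub-structured data", {
  hub <- regulatory_program(
    factors = lapply(1:6, function(i)
      program_factor(sprintf("f%d", i), c(0.5, 0.4, 0.5, 0.6, 0.3, 0.45)[i])),
    genes = list(
      program_gene("g1", "f1", list(el_constitutive(0.4))),
      program_gene("g2", "f2", list(el_activate("f1", 1.6, 0.8))),
      program_gene("g3", "f3", list(el_activate("f1", 1.6, 0.8))),
      program_gene("g4", "f4", list(el_constitutive(1.3),
                                    el_repress("f1", 1.6, 0.8))),
      program_gene("g5", "f5", list(el_activate("f1", 1.6, 0.8))),
      program_gene("g6", "f6", list(el_constitutive(0.3)))
    )
  )
  hits <- 0
  for (s in 1:10) {
    dat <- gen_expression_from_network(hub, 80, noise_sd = 0.05,
                                       noise = "process", seed = 200 + s)
    adj <- infer_network(dat$ts, l_max = 2, lambda = "cv", nlambda = 15)
    diag(adj) <- 0L
    if (which.max(rowSums(adj)) == 1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("reconstruction metrics agree with a brute-force confusion count", {
  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(evaluate_reconstruction(a, a)$precision, 1)
  expect_equal(evaluate_reconstruction(a, a)$recall, 1)
  zero <- a * 0L
  ev <- evaluate_reconstruction(a, zero)
  expect_equal(ev$precision, 0)
  expect_equal(ev$recall, 0)
  set.seed(78)
  for (rep in 1:20) {
    t5 <- matrix(rbinom(25, 1, 0.3), 5, 5)
    r5 <- matrix(rbinom(25, 1, 0.3), 5, 5)
    ev <- evaluate_reconstruction(t5, r5)
    tp <- fp <- fn <- 0
    for (i in 1:5) for (j in 1:5) {
      if (t5[i, j] & r5[i, j]) tp <- tp + 1
      if (!t5[i, j] & r5[i, j]) fp <- fp + 1
      if (t5[i, j] & !r5[i, j]) fn <- fn + 1
    }
    expect_equal(ev$tp, tp); expect_equal(ev$fp, fp); expect_equal(ev$fn, fn)
  }
  expect_error(evaluate_reconstruction(a, matrix(0, 3, 3)), "dimension")
})
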