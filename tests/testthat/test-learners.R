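test_that("forest degenerate and range behaviour", {
  # constant response: every prediction is the log-scale constant
  fit <- constant_fit(2.5)
  covs <- data.frame(a = rnorm(15), b = rnorm(15))
  pred <- predict_sites(fit, manual_sites(covs))
  expect_equal(pred, rep(log(2.5), 15), tolerance = 1e-9)

  # forest predictions are averages of training values: range oracle
  sites <- tiny_sites(n = 40, seed = 8)
  rf <- fit_random_forest(sites, seed = 1, ntree = 100)
  new_sites <- tiny_sites(n = 40, seed = 9)
  p <- predict_sites(rf, new_sites)
  yr <- range(log(sites$phytolith_pct))
  expect_true(all(p >= yr[1] - 1e-12 & p <= yr[2] + 1e-12))

  expect_error(fit_random_forest(sites, vars = "temp_01"), "2 covariates")
})

test_that("forest learns a noiseless step response (OOB R2)", {
  set.seed(31)
  covs <- data.frame(xx = runif(200), noise = rnorm(200))
  y <- exp(ifelse(covs$xx > 0.5, 1, -1))
  sites <- manual_sites(covs, phytolith = y)
  rf <- fit_random_forest(sites, seed = 7, ntree = 500)
  expect_gt(rf$state$oob_r2, 0.9)
})

test_that("forest is deterministic given its seed", {
  sites <- tiny_sites(n = 30, seed = 3)
  f1 <- fit_random_forest(sites, seed = 5, ntree = 50)
  f2 <- fit_random_forest(sites, seed = 5, ntree = 50)
  f3 <- fit_random_forest(sites, seed = 6, ntree = 50)
  probe <- tiny_sites(n = 20, seed = 4)
  expect_identical(predict_sites(f1, probe), predict_sites(f2, probe))
  expect_false(identical(predict_sites(f1, probe), predict_sites(f3, probe)))
})

test_that("lasso shrinkage limits: full shrinkage and lambda = 0", {
  set.seed(12)
  covs <- as.data.frame(matrix(rnorm(60 * 4), 60,
                               dimnames = list(NULL, c("a", "b", "c", "d"))))
  y <- exp(0.5 + 1.5 * covs$a - covs$c + rnorm(60, 0, 0.2))
  sites <- manual_sites(covs, phytolith = y)

  big <- fit_lasso(sites, lambda = 100)
  beta_big <- big$state$beta
  expect_equal(unname(beta_big[-1]), rep(0, 4))
  expect_equal(unname(beta_big[1]), mean(log(y)))

  zero <- fit_lasso(sites, lambda = 0)
  oracle <- ols_brute(as.matrix(covs), log(y))
  expect_equal(unname(zero$state$beta), oracle, tolerance = 1e-6)
})

test_that("lasso on an orthonormal design equals soft thresholding", {
  set.seed(2)
  n <- 40; p <- 5
  Q <- qr.Q(qr(matrix(rnorm(n * p), n)))  # Q'Q = I
  X <- Q * sqrt(n)                        # X'X / n = I
  colnames(X) <- paste0("v", seq_len(p))
  beta_true <- c(2, -1.5, 0.8, 0, 0)
  y <- exp(as.numeric(X %*% beta_true))   # noiseless, no intercept
  sites <- manual_sites(as.data.frame(X), phytolith = y)
  lambda <- 0.5
  fit <- fit_lasso(sites, lambda = lambda, standardize = FALSE,
                   intercept = FALSE)
  b_ols <- as.numeric(crossprod(X, log(y)) / n)
  expect_equal(unname(fit$state$beta[-1]), soft_threshold(b_ols, lambda),
               tolerance = 1e-6)
})

test_that("lasso drops zero-variance covariates with a warning", {
  set.seed(3)
  covs <- data.frame(a = rnorm(20), b = rnorm(20), flat = rep(1, 20))
  sites <- manual_sites(covs, phytolith = exp(covs$a))
  expect_warning(fit <- fit_lasso(sites, lambda = 0.01), "flat")
  expect_setequal(fit$vars, c("a", "b"))
})

test_that("GAM reduces to OLS on linear truth and handles degenerate input", {
  set.seed(4)
  covs <- data.frame(xx = runif(80, -2, 2), u = rnorm(80))
  y <- exp(0.3 + 0.8 * covs$xx) # noiseless linear truth
  sites <- manual_sites(covs, phytolith = y)
  g <- suppressWarnings(fit_gam(sites, vars = "xx")) # noiseless: REML may
  ols_pred <- cbind(1, covs$xx) %*% ols_brute(matrix(covs$xx), log(y))
  rmse <- sqrt(mean((predict_sites(g, sites) - ols_pred)^2))
  expect_lt(rmse, 1e-3)

  # constant response: all smooth contributions shrink to nothing
  const <- manual_sites(covs, phytolith = rep(1.7, 80))
  gc <- suppressWarnings(fit_gam(const, vars = c("xx", "u")))
  expect_equal(predict_sites(gc, const), rep(log(1.7), 80),
               tolerance = 1e-6)

  expect_error(fit_gam(sites, vars = "nope"), "nope")
  expect_error(fit_gam(sites, vars = character(0)), "non-empty")
})

test_that("GAM captures a smooth nonlinear signal", {
  set.seed(5)
  covs <- data.frame(xx = runif(300, -pi, pi))
  y <- exp(sin(covs$xx) + rnorm(300, 0, 0.1))
  sites <- manual_sites(covs, phytolith = y)
  g <- fit_gam(sites, vars = "xx")
  obs <- log(y); pred <- predict_sites(g, sites)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_gt(r2, 0.8)
})

test_that("few-distinct-value covariates fall back to linear terms", {
  set.seed(6)
  covs <- data.frame(cont = rnorm(50), binary = rep(c(0, 1), 25))
  sites <- manual_sites(covs, phytolith = exp(covs$cont + 0.5 * covs$binary))
  g <- suppressWarnings(fit_gam(sites, vars = c("cont", "binary")))
  expect_identical(g$settings$linear_fallback, "binary")
})

test_that("importance scaling and learner-specific scores", {
  # lasso with exactly one active coefficient
  set.seed(7)
  covs <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  sites <- manual_sites(covs, phytolith = exp(3 * covs$a + rnorm(50, 0, .1)))
  la <- fit_lasso(sites, lambda = 1)
  imp <- variable_importance(la)
  expect_equal(imp$scaled[imp$variable == "a"], 1)
  expect_equal(imp$scaled[imp$variable != "a"], c(0, 0))
  expect_equal(imp$sign[imp$variable == "a"], 1)

  # forest: the sole informative covariate tops the ranking
  rf <- fit_random_forest(sites, seed = 2, ntree = 200)
  rf_imp <- variable_importance(rf)
  expect_equal(rf_imp$variable[which.max(rf_imp$scaled)], "a")
  expect_equal(max(rf_imp$scaled), 1)
  expect_equal(sum(rf_imp$scaled >= 1), 1L)

  # GAM: a shrunk-to-null term scores ~0 on the refit-deviance scale
  g <- fit_gam(sites, vars = c("a", "b"))
  g_imp <- variable_importance(g, sites)
  expect_lt(g_imp$scaled[g_imp$variable == "b"], 0.05)
  expect_equal(g_imp$scaled[g_imp$variable == "a"], 1)
})

test_that("raster predictions agree with site predictions cell by cell", {
  cfg <- tiny_landscape(seed = 13, rows = 10, cols = 10)
  stk <- generate_landscape(cfg)
  sites <- simulate_response(sample_sites(stk, 30, seed = 13), cfg)
  probe <- sample_sites(stk, 100, seed = 1) # every cell

  for (fit in list(fit_random_forest(sites, seed = 1, ntree = 60),
                   fit_lasso(sites, seed = 1),
                   fit_gam(sites, vars = c("temp_01", "precip_01")))) {
    map <- predict_raster(fit, stk)
    sp <- predict_sites(fit, probe)
    for (i in c(1, 37, 100)) {
      col <- (probe$x[i] - stk$xmin) / stk$cellsize + 0.5
      row <- (stk$ymax - probe$y[i]) / stk$cellsize + 0.5
      expect_equal(map$values[row, col], sp[i], tolerance = 1e-9)
    }
  }

  # fully masked stack -> fully masked map
  masked <- covariate_stack(stk$layers, cellsize = stk$cellsize,
                            mask = matrix(FALSE, 10, 10))
  rf <- fit_random_forest(sites, seed = 1, ntree = 30)
  expect_true(all(is.na(predict_raster(rf, masked)$values)))

  # forest raster range oracle
  map <- predict_raster(rf, stk)
  yr <- range(log(sites$phytolith_pct))
  expect_true(all(map$values >= yr[1] - 1e-12 & map$values <= yr[2] + 1e-12))

  # missing layer -> configuration error
  drop <- stk$layers[setdiff(names(stk$layers), "temp_01")]
  stk2 <- covariate_stack(drop, cellsize = stk$cellsize)
  expect_error(predict_raster(rf, stk2), "temp_01")
})
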