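test_that("knn weights: tie-breaks, small cases, brute-force oracle", {
  # 3 collinear equally spaced sites, k = 1: the middle site's two
  # candidates tie; the documented tie-break picks the earlier record
  sw <- knn_weights(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)), k = 1)
  expect_equal(sw$neighbors[[2]], 1L)

  # k = 2, n = 3: every other site is a neighbour with weight 0.5
  sw2 <- knn_weights(data.frame(x = c(0, 1, 5), y = c(0, 0, 0)), k = 2)
  for (i in 1:3) {
    expect_setequal(sw2$neighbors[[i]], setdiff(1:3, i))
    expect_equal(sw2$weights[[i]], c(0.5, 0.5))
  }

  # random 20-site set vs all-pairs distance sort
  set.seed(20)
  xy <- data.frame(x = runif(20), y = runif(20))
  sw3 <- knn_weights(xy, k = 4)
  d <- as.matrix(dist(xy))
  for (i in 1:20) {
    others <- setdiff(1:20, i)
    expect_equal(sw3$neighbors[[i]], others[order(d[i, others])][1:4])
  }
  expect_error(knn_weights(xy, k = 20), "k")
})

test_that("Moran's I: exact toy value and brute-force equivalence", {
  # unit square, rook neighbours row-standardized, alternating values -> -1
  W <- rbind(c(0, .5, 0, .5), c(.5, 0, .5, 0),
             c(0, .5, 0, .5), c(.5, 0, .5, 0))
  expect_equal(morans_i(c(1, -1, 1, -1), W), -1)

  # brute-force double-sum oracle on random instances, n <= 25
  set.seed(21)
  for (n in c(8, 17, 25)) {
    xy <- data.frame(x = runif(n), y = runif(n))
    sw <- knn_weights(xy, k = 3)
    v <- rnorm(n)
    expect_equal(morans_i(v, sw), morans_brute(v, weights_matrix(sw)),
                 tolerance = 1e-12)
  }

  expect_error(morans_i(rep(1, 10), knn_weights(
    data.frame(x = 1:10, y = 0), k = 2)), "constant")
})

test_that("permutation test: null expectation, bounds, power, invariance", {
  set.seed(22)
  xy <- data.frame(x = runif(30), y = runif(30))
  sw <- knn_weights(xy, k = 5)
  v <- rnorm(30)
  mc <- morans_mc(v, sw, n_sim = 999, seed = 5)
  # mean permuted I ~ -1/(n-1) within Monte-Carlo error
  se <- sd(mc$i_sim) / sqrt(mc$n_sim)
  expect_lt(abs(mean(mc$i_sim) - (-1 / 29)), 4 * se)
  expect_gte(mc$p_value, 1 / 1000)
  expect_lte(mc$p_value, 1)

  # strongly clustered values: value = x coordinate on a 30-site grid
  grid <- expand.grid(x = 1:6, y = 1:5)
  swg <- knn_weights(grid, k = 5)
  clustered <- morans_mc(grid$x, swg, n_sim = 999, seed = 6)
  expect_lte(clustered$p_value, 0.01)

  # p-value invariant to adding a constant to all values
  shifted <- morans_mc(v + 100, sw, n_sim = 199, seed = 7)
  base <- morans_mc(v, sw, n_sim = 199, seed = 7)
  expect_equal(shifted$p_value, base$p_value)
  expect_equal(shifted$i_observed, base$i_observed, tolerance = 1e-9)
})

test_that("residual correlations: identity, symmetry, orthogonality", {
  sites <- tiny_sites(n = 40, seed = 23)
  rf <- fit_random_forest(sites, seed = 1, ntree = 60)
  rc <- residual_correlation(list(a = rf, b = rf), sites)
  expect_equal(rc["a", "b"], 1)

  # orthogonal construction: y = q1 + q2 over an orthonormal, mean-zero
  # basis; OLS on (q1, q3) leaves exactly q2 as residual and OLS on
  # (q2, q4) leaves exactly q1, and cor(q1, q2) = 0 by construction
  set.seed(24)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 4), 100))))[, -1]
  colnames(Q) <- paste0("q", 1:4)
  sites2 <- manual_sites(as.data.frame(Q),
                         phytolith = exp(Q[, "q1"] + Q[, "q2"]))
  f1 <- fit_lasso(sites2, lambda = 0, vars = c("q1", "q3"))
  f2 <- fit_lasso(sites2, lambda = 0, vars = c("q2", "q4"))
  rc2 <- residual_correlation(list(f1 = f1, f2 = f2), sites2)
  expect_equal(rc2, t(rc2), tolerance = 1e-12)
  expect_lt(abs(rc2["f1", "f2"]), 1e-6)
  expect_error(residual_correlation(list(rf), sites), "2 fits")
})

test_that("novelty distance: degenerate zeros and brute-force oracle", {
  cfg <- tiny_landscape(seed = 25, rows = 8, cols = 8)
  stk <- generate_landscape(cfg)
  sites <- sample_sites(stk, 12, seed = 25)

  # a cell whose covariates equal a site's, k_near = 1 -> distance 0
  nov1 <- env_pc_distance(stk, sites, n_ref = 64, n_pc = 3, k_near = 1,
                          seed = 1)
  col <- (sites$x[1] - stk$xmin) / stk$cellsize + 0.5
  row <- (stk$ymax - sites$y[1]) / stk$cellsize + 0.5
  expect_equal(nov1$map$values[row, col], 0, tolerance = 1e-9)

  # identical covariates everywhere, one site -> distance 0 everywhere
  flat <- covariate_stack(list(a = matrix(2, 5, 5), b = matrix(7, 5, 5)))
  fsites <- site_table(data.frame(site_id = "s1", x = 0.5, y = 0.5,
                                  a = 2, b = 7))
  nov_flat <- suppressWarnings(
    env_pc_distance(flat, fsites, n_ref = 25, n_pc = 2, k_near = 1,
                    seed = 1))
  expect_equal(as.vector(nov_flat$map$values), rep(0, 25), tolerance = 1e-9)

  # 2 covariates, 3 sites, 4-cell stack vs eigen-decomposition oracle
  toy <- covariate_stack(list(u = matrix(c(1, 2, 3, 4), 2, 2),
                              v = matrix(c(0.5, -1, 2, 0), 2, 2)))
  tsites <- site_table(data.frame(site_id = c("a", "b", "c"),
                                  x = c(0.5, 1.5, 0.5),
                                  y = c(1.5, 1.5, 0.5),
                                  u = c(1, 3, 2), v = c(0.5, 2, -1)))
  nov_toy <- env_pc_distance(toy, tsites, n_ref = 4, n_pc = 2, k_near = 2,
                             seed = 3)
  cells <- as.matrix(stack_to_df(toy)[, c("u", "v")])
  oracle <- novelty_brute(cells, cells,
                          as.matrix(as.data.frame(tsites)[, c("u", "v")]),
                          n_pc = 2, k_near = 2)
  expect_equal(as.vector(t(nov_toy$map$values)), oracle, tolerance = 1e-9)

  # retained-variance report: in [0,1], non-increasing, sums to 1
  nov <- env_pc_distance(stk, sites, n_ref = 64, n_pc = 3, k_near = 3,
                         seed = 2)
  ve <- nov$var_explained
  expect_true(all(ve >= 0 & ve <= 1))
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-9)

  expect_error(env_pc_distance(stk, sites, n_pc = 100), "n_pc")
})

test_that("novelty distance is invariant to layer and site order", {
  cfg <- tiny_landscape(seed = 26, rows = 6, cols = 6)
  stk <- generate_landscape(cfg)
  sites <- sample_sites(stk, 10, seed = 26)
  nov <- env_pc_distance(stk, sites, n_ref = 36, seed = 4)

  shuffled_layers <- covariate_stack(rev(stk$layers), xmin = stk$xmin,
                                     ymax = stk$ymax,
                                     cellsize = stk$cellsize)
  nov_l <- env_pc_distance(shuffled_layers, sites, n_ref = 36, seed = 4)
  expect_equal(nov_l$map$values, nov$map$values, tolerance = 1e-9)

  perm <- site_table(as.data.frame(sites)[sample(nrow(sites)), ])
  nov_s <- env_pc_distance(stk, perm, n_ref = 36, seed = 4)
  expect_equal(nov_s$map$values, nov$map$values, tolerance = 1e-9)
})

test_that("masking is thresholded, counted, idempotent", {
  pred <- grid_map(matrix(c(10, 20, 30, 40), 2, 2))
  nov <- grid_map(matrix(c(1, 2, 4, 5), 2, 2))

  expect_identical(apply_novelty_mask(pred, nov, threshold = Inf)$values,
                   pred$values)
  expect_true(all(is.na(apply_novelty_mask(pred, nov, 0)$values)))

  m3 <- apply_novelty_mask(pred, nov, threshold = 3)
  expect_equal(sum(is.na(m3$values)), 2L)
  expect_identical(m3$values[c(1, 2)], pred$values[c(1, 2)])

  # idempotent
  expect_identical(apply_novelty_mask(m3, nov, threshold = 3)$values,
                   m3$values)
  expect_error(apply_novelty_mask(pred, grid_map(matrix(1, 3, 3))),
               "geometry")
})

test_that("NPP detrending removes exactly the linear trend", {
  npp <- grid_map(matrix(runif(25, 100, 900), 5, 5))
  linear <- grid_map(matrix(0.002 * npp$values + 1, 5, 5))
  res <- npp_detrend(linear, npp)
  expect_lt(max(abs(res$values)), 1e-9)

  expect_error(npp_detrend(linear, grid_map(matrix(5, 5, 5))), "constant")

  # 5-cell toy against the normal-equations oracle
  nppv <- c(1, 2, 3, 4, 5); predv <- c(2.0, 2.4, 3.1, 3.2, 4.4)
  toy_n <- grid_map(matrix(c(nppv, NA), 2, 3))
  toy_p <- grid_map(matrix(c(predv, NA), 2, 3))
  res2 <- npp_detrend(toy_p, toy_n)
  ab <- ols_brute(matrix(nppv), predv)
  expect_equal(res2$values[1:5], predv - (ab[1] + ab[2] * nppv),
               tolerance = 1e-12)
  expect_true(is.na(res2$values[6]))
})

test_that("variable clustering follows correlation distance", {
  set.seed(27)
  base <- rnorm(200)
  covs <- data.frame(a = base, nega = -base, ind = rnorm(200))
  sites <- manual_sites(covs, phytolith = exp(rnorm(200)))
  vc <- variable_cluster(sites)
  # a variable and its negation: distance 0, merged first
  dm <- as.matrix(vc$dist)
  expect_equal(dm["a", "nega"], 0, tolerance = 1e-12)
  expect_equal(sort(vc$hclust$labels[-vc$hclust$merge[1, ]]),
               c("a", "nega"))
  # independent variables: distance near 1
  expect_gt(dm["a", "ind"], 0.85)

  # 3-variable toy vs hand-computed average linkage
  x1 <- as.numeric(scale(rnorm(100)))
  e2 <- as.numeric(scale(residuals(lm(rnorm(100) ~ x1))))
  e3r <- rnorm(100)
  e3 <- as.numeric(scale(residuals(lm(e3r ~ x1 + e2))))
  covs3 <- data.frame(p = x1,
                      q = 0.9 * x1 + sqrt(1 - 0.81) * e2,
                      r = 0.3 * x1 + sqrt(1 - 0.09) * e3)
  sites3 <- manual_sites(covs3, phytolith = exp(rnorm(100)))
  vc3 <- variable_cluster(sites3)
  oracle <- average_linkage_brute(vc3$dist)
  expect_equal(vc3$hclust$height, oracle$heights, tolerance = 1e-9)
  # first merge joins the tightly correlated pair p, q
  expect_equal(oracle$merges[[1]], c(1, 2))

  # constant covariate excluded with a warning
  covs_c <- cbind(covs, flat = 1)
  expect_warning(vcc <- variable_cluster(
    manual_sites(covs_c, phytolith = exp(rnorm(200)))), "flat")
  expect_equal(vcc$excluded, "flat")
})
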