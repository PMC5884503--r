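# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (double loops, normal
# equations, eigen-decomposition) rather than calling the package's own code
# paths.

pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Moran's I by explicit double sum over the dense weight matrix.
morans_brute <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  }
  (n / sum(W)) * num / sum(z^2)
}

# OLS by normal equations (with intercept).
ols_brute <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(crossprod(Xi), crossprod(Xi, y)))
}

soft_threshold <- function(t, lambda) sign(t) * pmax(abs(t) - lambda, 0)

# PCA novelty distance by eigen-decomposition and explicit pairwise
# distances: standardize by reference stats, project, mean distance to the
# k nearest site projections in the first n_pc components.
novelty_brute <- function(ref, cells, sites, n_pc, k_near) {
  mu <- colMeans(ref)
  sdev <- apply(ref, 2, sd)
  sdev[sdev == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sdev, "/")
  S <- cov(zs(ref)) * (nrow(ref) - 1) / nrow(ref) # scale-free for eigenvectors
  ev <- eigen(S, symmetric = TRUE)$vectors[, seq_len(n_pc), drop = FALSE]
  cp <- zs(cells) %*% ev
  sp <- zs(sites) %*% ev
  vapply(seq_len(nrow(cp)), function(i) {
    d <- vapply(seq_len(nrow(sp)), function(j) {
      sqrt(sum((cp[i, ] - sp[j, ])^2))
    }, numeric(1))
    mean(sort(d)[seq_len(k_near)])
  }, numeric(1))
}

# Average-linkage agglomeration over a small distance matrix, by hand.
# Returns merge heights in order and the member sets merged at each step.
average_linkage_brute <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Small synthetic fixtures ----------------------------------------------------

tiny_landscape <- function(seed = 1, rows = 24, cols = 24, noise_sd = 0.3,
                           coefficients = list(temp_01 = -1, precip_01 = 0.5),
                           ...) {
  landscape_config(rows = rows, cols = cols, cellsize = 1, n_temp = 4,
                   n_precip = 3, block_cor = 0.5, field_range = 3,
                   coefficients = coefficients, noise_sd = noise_sd,
                   baseline = -1.2, seed = seed, ...)
}

tiny_sites <- function(n = 60, seed = 1, ...) {
  cfg <- tiny_landscape(seed = seed, ...)
  stk <- generate_landscape(cfg)
  simulate_response(sample_sites(stk, n, seed = seed), cfg)
}

# A site table from raw columns (covariates given directly, no landscape).
manual_sites <- function(covs, phytolith = NULL, x = NULL, y = NULL) {
  n <- nrow(covs)
  df <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                   x = if (is.null(x)) seq_len(n) else x,
                   y = if (is.null(y)) rep(0, n) else y)
  df <- cbind(df, covs)
  if (!is.null(phytolith)) df$phytolith_pct <- phytolith
  site_table(df)
}

# A fit whose predictions are a known constant: a forest trained on a
# constant response never splits, so every prediction equals log(value).
constant_fit <- function(value, vars = c("a", "b"), n = 12) {
  covs <- as.data.frame(matrix(seq_len(n * length(vars)), n,
                               dimnames = list(NULL, vars)))
  fit_random_forest(manual_sites(covs, phytolith = rep(value, n)),
                    seed = 1, ntree = 20, mtry = 2)
}
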