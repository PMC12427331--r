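test_that("the GRM matches hand arithmetic and structural expectations", {
  # 2 individuals, 1 SNP: X = (0, 2), p = 0.5, Z = (-1, 1), denom = 0.5
  G <- compute_grm(matrix(c(0, 2), 2, 1,
                          dimnames = list(c("a", "b"), "s1")))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  # identical individuals produce identical rows
  X <- matrix(rbinom(40, 2, 0.4), 4, 10,
              dimnames = list(letters[1:4], NULL))
  X[2, ] <- X[1, ]
  G2 <- compute_grm(X)
  expect_equal(G2[1, ], G2[2, ])
  expect_equal(G2[1, 1], G2[1, 2])
  expect_true(isSymmetric(unname(G2)))
  # monomorphic columns contribute nothing
  X3 <- cbind(X, 2L)
  expect_equal(unname(compute_grm(X3)), unname(G2))
  expect_error(compute_grm(matrix(2, 5, 3)), "monomorphic")
})

test_that("the GRM diagonal centres near 1 in an equilibrium population", {
  out <- simulate_population(sim_config(
    n_founders = 500, n_generations = 0, offspring_per_generation = 1,
    n_blocks = 50, block_size = 6, seed = 41))
  G <- compute_grm(impute_and_discretize(recode_to_minor(out$genotypes))$mean)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
})

test_that("fixed-h2 GBLUP equals a direct dense mixed-model solve", {
  set.seed(42)
  X <- matrix(rbinom(7 * 30, 2, 0.35), 7, 30,
              dimnames = list(paste0("i", 1:7), NULL))
  y <- stats::setNames(rnorm(5), paste0("i", 1:5))
  G <- compute_grm(X)
  fit <- fit_gblup(G, y, method = "fixed_h2", h2 = 0.5)
  expect_equal(fit$lambda, 1)
  # dense oracle: mu by GLS, then (G_train + lambda I) omega = y - mu
  Vi <- solve(G[1:5, 1:5] + fit$lambda * diag(5))
  mu <- sum(Vi %*% y) / sum(Vi)
  omega <- Vi %*% (y - mu)
  want <- as.numeric(G[6:7, 1:5] %*% omega + mu)
  got <- unname(predict(fit, G, ids = c("i6", "i7")))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("GBLUP prediction is exactly ridge regression on centred dosages", {
  set.seed(43)
  X <- matrix(rbinom(12 * 40, 2, 0.3), 12, 40,
              dimnames = list(paste0("i", 1:12), NULL))
  train <- paste0("i", 1:9); test <- paste0("i", 10:12)
  y <- stats::setNames(rnorm(9) + 0.3 * rowSums(X[train, 1:3]), train)
  G <- compute_grm(X)
  denom <- attr(G, "denom")
  fit <- fit_gblup(G, y, method = "fixed_h2", h2 = 0.4)
  got <- unname(predict(fit, G, ids = test))
  # ridge oracle on Z = X - 2p with penalty lambda * denom
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  R <- solve(crossprod(Z[train, ]) + fit$lambda * denom * diag(ncol(Z)))
  beta <- R %*% crossprod(Z[train, ], y - fit$mu)
  want <- as.numeric(Z[test, ] %*% beta + fit$mu)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("limiting behaviour: huge lambda reverts to the mean, order does not matter", {
  set.seed(44)
  X <- matrix(rbinom(10 * 30, 2, 0.3), 10, 30,
              dimnames = list(paste0("i", 1:10), NULL))
  y <- stats::setNames(rnorm(8), paste0("i", 1:8))
  G <- compute_grm(X)
  fit <- fit_gblup(G, y, method = "fixed_h2", h2 = 1e-9)
  preds <- predict(fit, G, ids = c("i9", "i10"))
  expect_lt(max(abs(preds - fit$mu)), 1e-6)
  # permuting the training order leaves predictions unchanged
  fit2 <- fit_gblup(G, y[sample(names(y))], method = "fixed_h2", h2 = 0.4)
  fit1 <- fit_gblup(G, y, method = "fixed_h2", h2 = 0.4)
  expect_equal(predict(fit1, G, ids = c("i9", "i10")),
               predict(fit2, G, ids = c("i9", "i10")), tolerance = 1e-10)
})

test_that("REML finds no genetic variance in a pure-noise trait", {
  out <- simulate_population(sim_config(
    n_founders = 150, n_generations = 2, offspring_per_generation = 150,
    n_blocks = 40, h2_additive = 0, seed = 45))
  y <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
  split <- forward_split(out$pedigree)
  G <- compute_grm(impute_and_discretize(recode_to_minor(out$genotypes))$mean)
  fit <- fit_gblup(G, y[split$train], method = "reml")
  expect_lt(fit$h2, 0.1)
  preds <- predict(fit, G, ids = split$test)
  expect_lt(sd(preds), 0.1 * sd(y))
})

test_that("GBLUP is blind to purely epistatic genetic signal", {
  r2 <- vapply(1:3, function(seed) {
    out <- simulate_population(sim_config(
      n_founders = 150, n_generations = 2, offspring_per_generation = 150,
      n_blocks = 40, h2_additive = 0, epistasis_frac = 0.5,
      n_causal_pairs = 30, seed = seed))
    y <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
    split <- forward_split(out$pedigree)
    G <- compute_grm(impute_and_discretize(recode_to_minor(out$genotypes))$mean)
    fit <- fit_gblup(G, y[split$train], method = "reml")
    compute_metrics(y[split$test], predict(fit, G, ids = split$test))$r2
  }, 1)
  expect_lt(mean(r2), 0.05)
})

test_that("lasso respects its penalty limits and recovers strong signal", {
  set.seed(46)
  # infinite penalty: intercept-only model at the training mean
  X <- matrix(rbinom(60 * 15, 2, 0.3), 60, 15)
  y <- rnorm(60) + X[, 1]
  f_inf <- fit_lasso(X[1:40, ], y[1:40], X[41:60, ], y[41:60],
                     penalties = c(1e6))
  expect_true(all(f_inf$coefficients == 0))
  expect_equal(unname(f_inf$intercept), mean(y[1:40]), tolerance = 1e-10)
  expect_equal(unname(predict(f_inf, X[41:60, ])),
               rep(mean(y[1:40]), 20), tolerance = 1e-10)

  # zero penalty on a well-conditioned problem matches least squares
  f0 <- suppressWarnings(
    fit_lasso(X[1:40, 1:5], y[1:40], X[41:60, 1:5], y[41:60],
              penalties = c(0)))
  ols <- lm(y[1:40] ~ X[1:40, 1:5])
  expect_equal(unname(f0$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-6)

  # planted large effects are recovered up to within-block LD proxies
  out <- simulate_population(sim_config(
    n_founders = 300, n_generations = 2, offspring_per_generation = 400,
    n_blocks = 20, h2_additive = 0.8, n_causal_add = 5, seed = 47))
  y2 <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
  split <- forward_split(out$pedigree)
  Xs <- impute_and_discretize(recode_to_minor(out$genotypes))$mean
  fit <- fit_lasso(Xs[split$train, ], y2[split$train],
                   Xs[split$validation, ], y2[split$validation])
  chosen <- names(fit$coefficients)[fit$coefficients != 0]
  chosen_blocks <- unique(sub("_s\\d+$", "", chosen))
  eff <- dplyr::filter(out$causal_effects, component == "additive")
  top <- eff$snp_a[order(-abs(eff$effect))][1:3]
  top_blocks <- sub("_s\\d+$", "", top)
  expect_true(all(top_blocks %in% chosen_blocks))
  expect_error(fit_lasso(X[1:40, ], y[1:40], X[41:60, ], y[41:60],
                         penalties = numeric(0)), "empty")
})
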