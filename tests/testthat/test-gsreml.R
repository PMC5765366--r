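test_that("REML on balanced data matches the one-way ANOVA closed form", {
  for (seed in c(42L, 7L, 99L)) {
    t <- balanced_trial(g = 20L, r = 2L, s2g = 2, s2r = 1, seed = seed)
    fit <- gsreml(t, "y")
    y <- t$y; geno <- t$genotype
    ym <- tapply(y, geno, mean)
    g <- 20L; r <- 2L
    mse <- sum((y - ym[geno])^2) / (g * (r - 1))
    msg <- r * sum((tapply(y, geno, mean) - mean(y))^2) / (g - 1)
    expect_true(fit$converged)
    expect_equal(fit$varcomp[["residual"]], mse, tolerance = 1e-5)
    expect_equal(fit$varcomp[["g"]], (msg - mse) / r, tolerance = 1e-5)
    expect_equal(fit$mu, mean(y), tolerance = 1e-8)
  }
})

test_that("constant response collapses to the degenerate fit", {
  d <- data.frame(plot_id = paste0("p", 1:8), range = 1:8, column = 1,
                  genotype = rep(c("a", "b"), 4), y = 5)
  t <- trial_table(d, traits = "y")
  fit <- gsreml(t, "y")
  expect_equal(fit$mu, 5)
  expect_equal(unname(fit$varcomp[c("g", "residual")]), c(0, 0))
  expect_true(fit$converged)
})

test_that("solver llk beats a dense grid search on small instances", {
  withr_seed(101)
  pd <- plot_dim(2, 1)
  for (inst in 1:5) {
    n <- sample(18:28, 1)
    d <- data.frame(plot_id = paste0("p", 1:n),
                    range = rep_len(1:5, n), column = rep(1:6, each = 5)[1:n],
                    genotype = sample(sprintf("g%d", 1:7), n, TRUE))
    d$y <- rnorm(7)[as.integer(factor(d$genotype))] + rnorm(n) * 1.5
    t <- trial_table(d, traits = "y")
    ker <- spatial_kernel(plot_dist(t, pd, "isotropic"), "gaussian", 3)
    fit <- gsreml(t, "y", spatial = ker)
    vy <- var(t$y)
    grid <- vy * exp(seq(log(0.005), log(5), length.out = 12))
    best <- -Inf
    for (a in grid) for (b in grid) for (cc in grid) {
      ll <- tryCatch(reml_loglik(t, "y", spatial = ker,
                                 varcomps = c(g = a, s = b, residual = cc)),
                     error = function(e) -Inf)
      if (ll > best) best <- ll
    }
    expect_gte(fit$loglik, best - 1e-4)
  }
})

test_that("restricted log-likelihood matches the single-component closed form", {
  withr_seed(13)
  n <- 15
  y <- rnorm(n, mean = 3)
  d <- data.frame(plot_id = paste0("p", 1:n), range = 1:n, column = 1,
                  genotype = rep(c("a", "b", "c"), 5), y = y)
  t <- trial_table(d, traits = "y")
  for (s2 in c(0.4, 1, 2.7)) {
    ll <- reml_loglik(t, "y", varcomps = c(g = 0, residual = s2))
    rss <- sum((y - mean(y))^2)
    closed <- -0.5 * ((n - 1) * log(2 * pi * s2) + rss / s2 + log(n))
    expect_equal(ll, closed, tolerance = 1e-10)
  }
})

test_that("scaling the response scales the variance-component optimum by c^2", {
  t <- balanced_trial(g = 15L, r = 2L, seed = 3L)
  fit1 <- gsreml(t, "y")
  d <- as.data.frame(t); d$y <- 3 * d$y
  fit3 <- gsreml(trial_table(d, traits = "y"), "y")
  expect_equal(fit3$varcomp[["g"]] / fit1$varcomp[["g"]], 9, tolerance = 1e-3)
  expect_equal(fit3$varcomp[["residual"]] / fit1$varcomp[["residual"]], 9,
               tolerance = 1e-3)
})

test_that("the likelihood is invariant to consistent plot permutation", {
  withr_seed(8)
  n <- 16
  d <- data.frame(plot_id = paste0("p", 1:n), range = rep(1:4, 4),
                  column = rep(1:4, each = 4),
                  genotype = sample(c("a", "b", "c", "d"), n, TRUE),
                  y = rnorm(n))
  t <- trial_table(d, traits = "y")
  ker <- spatial_kernel(plot_dist(t, plot_dim(2, 1), "isotropic"),
                        "power", 0.5)
  vc <- c(g = 0.7, s = 0.4, residual = 1.1)
  ll1 <- reml_loglik(t, "y", spatial = ker, varcomps = vc)
  perm <- sample(n)
  t2 <- trial_table(d[perm, ], traits = "y")
  # the kernel is indexed by plot id, so it realigns automatically
  ll2 <- reml_loglik(t2, "y", spatial = ker, varcomps = vc)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("fitted effects plus residual reproduce the training response", {
  withr_seed(21)
  lay <- small_layout(n_test = 40L, n_checks = 3L, check_reps = 3L,
                      n_columns = 7L)
  t <- null_phenotype(lay, seed = 2L)
  ker <- spatial_kernel(plot_dist(t, attr(lay, "plot_dim"), "isotropic"),
                        "gaussian", 4)
  fit <- gsreml(t, "y", spatial = ker, extraneous = "range")
  rebuilt <- fit$mu + fit$blup$g[t$genotype] + fit$blup$s[t$plot_id] +
    fit$blup$range[as.character(t$range)] + fit$residuals
  expect_lt(max(abs(rebuilt - t$y)), 1e-8)
})

test_that("variance components are never negative and boundaries are flagged", {
  withr_seed(31)
  for (i in 1:5) {
    t <- balanced_trial(g = 12L, r = 2L, s2g = 0.01, s2r = 1,
                        seed = 200L + i)
    ker <- spatial_kernel(plot_dist(t, plot_dim(2, 1), "isotropic"),
                          "gaussian", 3)
    fit <- gsreml(t, "y", spatial = ker)
    expect_true(all(fit$varcomp >= 0))
    expect_true(all(fit$varcomp[fit$boundary] == 0))
  }
})

test_that("LRT reproduces the printed mixture thresholds and contracts", {
  t <- balanced_trial(seed = 42L)
  fit <- gsreml(t, "y")
  l0 <- lrt(fit, fit, extra_df = 1L)
  expect_equal(l0$statistic, 0)
  expect_false(l0$significant)
  expect_equal(round(lrt(fit, fit, extra_df = 1L)$threshold, 3), 2.706)
  expect_equal(round(lrt(fit, fit, extra_df = 2L)$threshold, 3), 4.605)
  # statistic invariant to adding a constant to the response
  ker <- spatial_kernel(plot_dist(t, plot_dim(2, 1), "isotropic"),
                        "gaussian", 2)
  m1 <- gsreml(t, "y", spatial = ker)
  s1 <- lrt(m1, fit)$statistic
  d <- as.data.frame(t); d$y <- d$y + 100
  t2 <- trial_table(d, traits = "y")
  s2 <- lrt(gsreml(t2, "y", spatial = ker), gsreml(t2, "y"))$statistic
  expect_equal(s1, s2, tolerance = 1e-4)
  # mismatched observation counts are rejected
  t3 <- trial_table(as.data.frame(t)[1:30, ], traits = "y")
  expect_error(lrt(gsreml(t3, "y"), fit), "different numbers")
})

test_that("Cullis heritability formula and closed-form agreement", {
  # PEV = 0: perfect information, h2 = 1
  fake <- structure(list(varcomp = c(g = 2), pev_g = matrix(0, 4, 4)),
                    class = "gsreml")
  expect_equal(cullis_h2(fake), 1)
  # mean pairwise PEV difference equal to 2 sigma2_g: h2 = 0
  fake2 <- structure(list(varcomp = c(g = 1), pev_g = diag(2, 4)),
                     class = "gsreml")
  # VbarDelta = 2 * (4*8 - 8) / 12 = 4 = 2 sigma2_g * 2 ... compute directly
  g <- 4; P <- diag(2, 4)
  vbar <- 2 * (g * sum(diag(P)) - sum(P)) / (g * (g - 1))
  expect_equal(cullis_h2(fake2), 1 - vbar / 2)
  # balanced design, K = I: matches classical line-mean heritability
  t <- balanced_trial(g = 25L, r = 2L, seed = 5L)
  fit <- gsreml(t, "y")
  s2g <- fit$varcomp[["g"]]; s2r <- fit$varcomp[["residual"]]
  expect_equal(cullis_h2(fit), 1 - 1 / (1 + 2 * s2g / s2r),
               tolerance = 1e-6)
  # zero genotypic variance: undefined with warning
  fake3 <- structure(list(varcomp = c(g = 0), pev_g = diag(4)),
                     class = "gsreml")
  expect_warning(h <- cullis_h2(fake3), "undefined")
  expect_true(is.na(h))
})

test_that("prediction follows yhat = mu + g + s with kriged spatial term", {
  withr_seed(17)
  lay <- small_layout(n_test = 30L, n_checks = 3L, check_reps = 3L,
                      n_columns = 6L)
  t <- null_phenotype(lay, seed = 9L)
  K <- identity_kinship(t$genotype)
  test_idx <- t$genotype %in% unique(t$genotype)[1:5]
  train <- trial_table(as.data.frame(t)[!test_idx, ], traits = "y")
  test <- as.data.frame(t)[test_idx, ]
  # base model: prediction is mu + g only
  fb <- gsreml(train, "y", kinship = K)
  pb <- predict(fb, test)
  expect_equal(unname(pb), unname(fb$mu + fb$blup$g[test$genotype]))
  # spatial fit with sigma2_s fixed at zero: s BLUP vanishes everywhere
  ker <- spatial_kernel(plot_dist(t, attr(lay, "plot_dim"), "isotropic"),
                        "gaussian", 3)
  f0 <- gsreml(train, "y", kinship = K, spatial = ker,
               varcomps = c(g = 1, s = 0, residual = 1))
  expect_true(all(f0$blup$s == 0))
  expect_equal(unname(predict(f0, test)), unname(pb), tolerance = 0.5)
  # genotype absent from K is a hard error
  test_bad <- test; test_bad$genotype[1] <- "not-a-genotype"
  expect_error(predict(fb, test_bad), "absent")
})

test_that("spherical kriging transfers the spatial BLUP to coincident plots", {
  # plot pairs 1 m apart within a pair, pairs far apart; spherical phi
  # slightly above 1 m gives within-pair correlation near 1 and zero
  # correlation between pairs, so a held-out plot inherits (almost) the
  # spatial BLUP of its coincident training partner
  n_pair <- 6
  d <- data.frame(
    plot_id = paste0("p", 1:(2 * n_pair)),
    range = rep(seq(1, by = 50, length.out = n_pair), each = 2) +
      rep(c(0, 1), n_pair),
    column = 1,
    genotype = c(rbind(sprintf("tr%d", 1:n_pair),
                       sprintf("te%d", 1:n_pair))))
  withr_seed(23)
  d$y <- rnorm(2 * n_pair, sd = 2)
  t <- trial_table(d, traits = "y")
  K <- identity_kinship(t$genotype)
  D <- plot_dist(t, plot_dim(1, 1), "isotropic")
  ker <- spatial_kernel(D, "spherical", 1.05)
  train <- trial_table(d[d$genotype %in% sprintf("tr%d", 1:n_pair), ],
                       traits = "y")
  fit <- gsreml(train, "y", kinship = K, spatial = ker,
                varcomps = c(g = 0.5, s = 2, residual = 0.5))
  s <- fit$blup$s
  within_corr <- ker[1, 2]   # correlation at 1 m
  for (i in seq_len(n_pair)) {
    held <- s[paste0("p", 2 * i)]
    obs <- s[paste0("p", 2 * i - 1)]
    expect_equal(unname(held), unname(within_corr * obs), tolerance = 1e-8)
  }
})
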