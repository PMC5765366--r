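test_that("folds partition genotypes with near-equal sizes", {
  p100 <- make_folds(sprintf("g%03d", 1:100), k = 10, n_repeats = 2,
                     seed = 1)
  sizes <- table(p100$assignments[[1]])
  expect_equal(unname(sizes), rep(10L, 10L), ignore_attr = TRUE)
  p101 <- make_folds(sprintf("g%03d", 1:101), k = 10, n_repeats = 1,
                     seed = 1)
  sizes101 <- sort(table(p101$assignments[[1]]))
  expect_equal(unname(sizes101), c(rep(10L, 9L), 11L), ignore_attr = TRUE)
  # every repeat covers every genotype exactly once
  for (r in 1:2)
    expect_setequal(names(p100$assignments[[r]]), sprintf("g%03d", 1:100))
  expect_error(make_folds(letters, k = 1), "at least 2")
  expect_error(make_folds(letters[1:3], k = 10), "fewer genotypes")
})

test_that("fold assignment is deterministic given the seed", {
  a <- make_folds(letters, k = 5, n_repeats = 3, seed = 77)
  b <- make_folds(letters, k = 5, n_repeats = 3, seed = 77)
  expect_identical(a, b)
  c2 <- make_folds(letters, k = 5, n_repeats = 3, seed = 78)
  expect_false(identical(a$assignments, c2$assignments))
})

test_that("train and test never share a genotype; plots follow genotypes", {
  lay <- small_layout()
  t <- null_phenotype(lay, seed = 4L)
  plan <- make_folds(t$genotype, k = 10, n_repeats = 5, seed = 42)
  for (r in seq_len(plan$n_repeats)) {
    fold_of <- plan$assignments[[r]]
    for (f in seq_len(plan$k)) {
      test_geno <- names(fold_of)[fold_of == f]
      is_test <- t$genotype %in% test_geno
      expect_length(intersect(unique(t$genotype[is_test]),
                              unique(t$genotype[!is_test])), 0L)
    }
    # replicated checks: all plots of one check are on the same side
    chk <- unique(t$genotype[t$is_check])
    for (g in chk)
      expect_length(unique(fold_of[g]), 1L)
  }
})

test_that("cross_validate is deterministic and reports sane metrics", {
  lay <- small_layout(n_test = 60L, n_checks = 4L, check_reps = 4L,
                      n_columns = 10L)
  gt <- gblup_trial(lay, h2 = 0.6, seed = 12L)
  plan <- make_folds(gt$trial$genotype, k = 5, n_repeats = 2, seed = 9)
  cv1 <- cross_validate(gt$trial, "y", kinship = gt$K, plan = plan)
  cv2 <- cross_validate(gt$trial, "y", kinship = gt$K, plan = plan)
  expect_equal(cv1$pRMSE, cv2$pRMSE)
  expect_equal(cv1$pCOR, cv2$pCOR)
  expect_equal(nrow(cv1$per_fold), 10L)
  expect_equal(cv1$n_failed_fits, 0L)
  # held-out genotypes are predictable through the marker kinship
  expect_true(cv1$pCOR > 0.2)
})

test_that("zero genotypic signal gives near-zero prediction accuracy", {
  lay <- small_layout(n_test = 120L, n_checks = 5L, check_reps = 4L,
                      n_columns = 14L)
  # pure noise response: no genotypic variance at all
  d <- as.data.frame(lay)
  withr_seed(55)
  d$y <- rnorm(nrow(d))
  t <- trial_table(d, traits = "y")
  plan <- make_folds(t$genotype, k = 10, n_repeats = 5, seed = 6)
  cv <- cross_validate(t, "y", plan = plan)
  expect_lt(abs(cv$pCOR), 0.1)
})

test_that("constant predictions are recorded as pCOR 0 with a warning", {
  d <- data.frame(plot_id = paste0("p", 1:40), range = rep(1:8, 5),
                  column = rep(1:5, each = 8),
                  genotype = rep(sprintf("g%02d", 1:20), 2), y = 3)
  t <- trial_table(d, traits = "y")
  plan <- make_folds(t$genotype, k = 5, n_repeats = 1, seed = 2)
  expect_warning(cv <- cross_validate(t, "y", plan = plan), "constant")
  expect_equal(cv$pCOR, 0)
})

test_that("relative metrics follow the ratio formulas, in percent", {
  mk <- function(prmse, pcor)
    structure(list(pRMSE = prmse, pCOR = pcor), class = "cv_result")
  m <- relative_metrics(mk(10, 0.5), mk(9, 0.6))
  expect_equal(unname(m["rel_pcor_increase"]), 20)
  expect_equal(unname(m["rel_prmse_decrease"]), 10)
  same <- relative_metrics(mk(10, 0.5), mk(10, 0.5))
  expect_equal(unname(same), c(0, 0))
  expect_error(relative_metrics(mk(0, 0.5), mk(1, 0.6)), "zero")
})

test_that("ties in pRMSE are broken toward higher pCOR, then the base model", {
  tab <- data.frame(family = c("none", "gaussian"),
                    direction = c("none", "isotropic"),
                    param = c(NA, 3), pRMSE = c(1, 1), pCOR = c(0.5, 0.5))
  expect_equal(spatGBLUP:::pick_best(tab), 1L)
  tab$pCOR[2] <- 0.6
  expect_equal(spatGBLUP:::pick_best(tab), 2L)
  tab2 <- data.frame(family = c("none", "gaussian", "gaussian"),
                     direction = "isotropic", param = c(NA, 5, 2),
                     pRMSE = c(1, 0.9, 0.9), pCOR = 0.5)
  expect_equal(spatGBLUP:::pick_best(tab2), 3L)  # smaller parameter wins
})

test_that("selection recovers a simulated spatial signal and its LRT fires", {
  # strong range-directional gaussian field variation
  lay <- small_layout(n_test = 60L, n_checks = 4L, check_reps = 4L,
                      n_columns = 10L)
  pd <- attr(lay, "plot_dim")
  wins <- lrt_sig <- logical(4)
  for (i in seq_along(wins)) {
    sim <- simulate_trial(
      sim_config(genotypic_ratio = 0.4, fra_sp = 0.8, family = "gaussian",
                 param = 8, scenario = "checks_only", seed = 400L + i),
      layout = lay)
    t <- sim$trial
    plan <- make_folds(t$genotype, k = 5, n_repeats = 2, seed = i)
    sel <- suppressWarnings(select_spatial_model(
      t, "y", dim = pd, plan = plan,
      families = "gaussian", directions = c("isotropic", "range"),
      grids = list(gaussian = c(2, 8, 20))))
    wins[i] <- !is.null(sel$best_spec$spatial)
    lrt_sig[i] <- !is.null(sel$lrt) && sel$lrt$significant
  }
  expect_gte(sum(wins), 3L)
  expect_gte(sum(lrt_sig), 3L)
})

test_that("a pure Column step effect is picked up by the Model 2 extension", {
  lay <- small_layout(n_test = 60L, n_checks = 4L, check_reps = 4L,
                      n_columns = 10L)
  pd <- attr(lay, "plot_dim")
  picked <- logical(3)
  for (i in seq_along(picked)) {
    withr_seed(500L + i)
    genos <- unique(lay$genotype)
    g <- stats::setNames(rnorm(length(genos)), genos)
    cl_eff <- stats::setNames(rnorm(max(lay$column), sd = 1.5),
                              seq_len(max(lay$column)))
    d <- as.data.frame(lay)
    d$y <- g[d$genotype] + cl_eff[as.character(d$column)] +
      rnorm(nrow(d), sd = 0.7)
    t <- trial_table(d, traits = "y")
    plan <- make_folds(t$genotype, k = 5, n_repeats = 2, seed = i)
    sel <- suppressWarnings(select_spatial_model(
      t, "y", dim = pd, plan = plan, families = "gaussian",
      directions = "isotropic", grids = list(gaussian = c(2, 8))))
    m2 <- suppressWarnings(extend_extraneous(sel, t, "y"))
    picked[i] <- m2$best_extraneous %in% c("column", "both")
  }
  expect_gte(sum(picked), 2L)
})

test_that("degenerate layouts skip the matching extraneous candidate", {
  # single Range: the range and both extensions are skipped with warnings
  d <- data.frame(plot_id = paste0("p", 1:30), range = 1L, column = 1:30,
                  genotype = rep(sprintf("g%02d", 1:15), 2))
  withr_seed(61)
  d$y <- rnorm(15)[as.integer(factor(d$genotype))] + rnorm(30, sd = 0.5)
  t <- trial_table(d, traits = "y")
  plan <- make_folds(t$genotype, k = 5, n_repeats = 1, seed = 3)
  sel <- suppressWarnings(select_spatial_model(
    t, "y", dim = plot_dim(2, 1), plan = plan, families = "gaussian",
    directions = "column", grids = list(gaussian = c(4))))
  expect_warning(m2 <- extend_extraneous(sel, t, "y"), "single level")
  expect_false(any(m2$table$extraneous %in% c("range", "both")))
})

test_that("every candidate in a selection shares the same CV plan", {
  t <- balanced_trial(g = 20L, r = 2L, seed = 30L)
  plan <- make_folds(t$genotype, k = 5, n_repeats = 1, seed = 8)
  sel <- suppressWarnings(select_spatial_model(
    t, "y", dim = plot_dim(2, 1), plan = plan, families = "power",
    directions = "range", grids = list(power = c(0.3, 0.6))))
  expect_identical(sel$plan, plan)
  expect_equal(sel$base$plan_seed, plan$seed)
})
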