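#' Default simulated field layout
#'
#' A synthetic stand-in for a breeding-trial field: 829 genotypes of which
#' 11 are replicated check genotypes, laid out on a regular grid of 26
#' Ranges x 34 Columns (884 plots: 818 unreplicated test genotypes plus 6
#' plots for each check, interleaved evenly through the field in serpentine
#' order). The associated plot dimension is 2 x 1 m (length x width), so
#' adjacent Ranges are 1 m apart and adjacent Columns 2 m apart. Any
#' user-supplied layout with the same columns can be used instead.
#'
#' @param n_test number of unreplicated test genotypes, default 818.
#' @param n_checks number of check genotypes, default 11.
#' @param check_reps plots per check genotype, default 6.
#' @param n_columns number of field Columns, default 34.
#' @return a [trial_table] skeleton (no trait columns) with attribute
#'   `plot_dim` holding the 2 x 1 [plot_dim].
#' @export
default_layout <- function(n_test = 818L, n_checks = 11L, check_reps = 6L,
                           n_columns = 34L) {
  n_plots <- n_test + n_checks * check_reps
  n_ranges <- ceiling(n_plots / n_columns)
  grid <- expand.grid(column = seq_len(n_columns), range = seq_len(n_ranges))
  # serpentine order: reverse column order in even ranges
  ord <- order(grid$range, ifelse(grid$range %% 2L == 0L,
                                  -grid$column, grid$column))
  grid <- grid[ord, ][seq_len(n_plots), ]
  checks <- sprintf("CHK%02d", seq_len(n_checks))
  tests <- sprintf("G%04d", seq_len(n_test))
  geno <- rep(NA_character_, n_plots)
  # spread check plots evenly through the serpentine order, cycling checks
  check_pos <- round(seq(1, n_plots, length.out = n_checks * check_reps))
  check_pos <- unique(check_pos)
  while (length(check_pos) < n_checks * check_reps)
    check_pos <- sort(unique(c(check_pos, sample.int(n_plots, 1L))))
  geno[check_pos] <- rep(checks, length.out = length(check_pos))
  geno[is.na(geno)] <- tests
  d <- data.frame(plot_id = paste0("R", grid$range, "C", grid$column),
                  range = grid$range, column = grid$column,
                  genotype = geno, is_check = geno %in% checks,
                  stringsAsFactors = FALSE)
  out <- trial_table(d, traits = character(0))
  attr(out, "plot_dim") <- plot_dim(2, 1)
  out
}

#' Apply a genotype-replication scenario to a layout
#'
#' Three replication scenarios: `"checks_only"` leaves every test genotype
#' on a single plot (minimum replication); `"half_replicated"` gives a
#' seeded random 50% of the test genotypes a second plot;
#' `"fully_replicated"` gives every test genotype a second plot. New plots
#' are appended in fresh Ranges beyond the existing field, so coordinates
#' stay unique.
#'
#' @param layout a [trial_table] skeleton (e.g. [default_layout]).
#' @param scenario replication scenario.
#' @param seed integer seed for the half-replicated subset.
#' @return a [trial_table] skeleton, with `plot_dim` attribute preserved.
#' @export
apply_replication <- function(layout,
                              scenario = c("checks_only", "half_replicated",
                                           "fully_replicated"),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(layout, "trial_table"))
  if (scenario == "checks_only") return(layout)
  tests <- unique(layout$genotype[!layout$is_check])
  extra <- if (scenario == "fully_replicated") tests else
    with_seed(seed, sort(sample(tests, floor(length(tests) / 2))))
  n_columns <- max(layout$column)
  n_new <- length(extra)
  start_range <- max(layout$range)
  grid <- expand.grid(column = seq_len(n_columns),
                      range = start_range + seq_len(ceiling(n_new / n_columns)))
  grid <- grid[seq_len(n_new), ]
  add <- data.frame(plot_id = paste0("R", grid$range, "C", grid$column),
                    range = grid$range, column = grid$column,
                    genotype = extra, is_check = FALSE,
                    stringsAsFactors = FALSE)
  out <- trial_table(rbind(as.data.frame(layout), add),
                     traits = character(0))
  attr(out, "plot_dim") <- attr(layout, "plot_dim")
  out
}

#' Simulation settings
#'
#' @param genotypic_ratio genotypic share of total phenotypic variance,
#'   strictly in (0, 1). Genotypic effects have unit variance, so the total
#'   error variance is `(1 - h) / h` with `h = genotypic_ratio`.
#' @param fra_sp spatial share of the total error variance, strictly in
#'   (0, 1).
#' @param family spatial kernel family used to generate the field trend
#'   (`"power"` or `"gaussian"`, the two most dissimilar structures;
#'   `"spherical"` is allowed for completeness).
#' @param param standardizing parameter of the generating kernel.
#' @param scenario replication scenario, see [apply_replication].
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genotypic_ratio = 0.5, fra_sp = 0.5,
                       family = c("gaussian", "power", "spherical"),
                       param = 10.5,
                       scenario = c("checks_only", "half_replicated",
                                    "fully_replicated"),
                       seed = 1L) {
  family <- match.arg(family)
  scenario <- match.arg(scenario)
  stopifnot(genotypic_ratio > 0, genotypic_ratio < 1,
            fra_sp > 0, fra_sp < 1)
  structure(list(genotypic_ratio = genotypic_ratio, fra_sp = fra_sp,
                 family = family, param = param, scenario = scenario,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a field trial with genotypic, spatial and residual effects
#'
#' Generates one phenotype per plot as
#' `y = g(genotype) + s(plot) + r(plot)` with
#' `g ~ N(0, 1)` i.i.d. per genotype (no relationship matrix is used in
#' the generation), `s ~ MVN(0, sigma2_s * S)` where `S` is the configured
#' kernel on the isotropic distance matrix of the (replication-extended)
#' layout, and `r ~ N(0, sigma2_r)` i.i.d. The genotypic ratio `h`
#' determines the total error variance `sigma2_e = (1 - h) / h`, which
#' `fra_sp` partitions into `sigma2_s = fra_sp * sigma2_e` and
#' `sigma2_r = (1 - fra_sp) * sigma2_e`.
#'
#' @param cfg a [sim_config].
#' @param layout a [trial_table] skeleton with a `plot_dim` attribute;
#'   default [default_layout].
#' @return object of class `sim_trial`: `$trial` (a [trial_table] with
#'   trait `y`), `$true_g`, `$true_s`, `$true_r`, `$config`, `$variances`
#'   (the target `sigma2` values) and `$kernel`.
#' @export
simulate_trial <- function(cfg, layout = default_layout()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(layout, "trial_table"))
  dim <- attr(layout, "plot_dim")
  if (is.null(dim)) dim <- plot_dim(2, 1)
  layout <- apply_replication(layout, cfg$scenario, seed = cfg$seed)
  h <- cfg$genotypic_ratio
  s2e <- (1 - h) / h
  s2s <- cfg$fra_sp * s2e
  s2r <- (1 - cfg$fra_sp) * s2e
  D <- plot_dist(layout, dim, "isotropic")
  S <- spatial_kernel(D, cfg$family, cfg$param)
  n <- nrow(layout)
  genos <- unique(layout$genotype)
  L <- tryCatch(chol(unclass(S) + diag(1e-8, n)), error = function(e)
    stop("spatial kernel is not positive semidefinite after repair"))
  sim <- with_seed(cfg$seed, {
    g <- stats::setNames(stats::rnorm(length(genos)), genos)
    s <- sqrt(s2s) * drop(crossprod(L, stats::rnorm(n)))
    r <- stats::rnorm(n, sd = sqrt(s2r))
    list(g = g, s = s, r = r)
  })
  names(sim$s) <- names(sim$r) <- layout$plot_id
  d <- as.data.frame(layout)
  d$y <- sim$g[d$genotype] + sim$s + sim$r
  trial <- trial_table(d, traits = "y")
  attr(trial, "plot_dim") <- dim
  structure(list(trial = trial, true_g = sim$g, true_s = sim$s,
                 true_r = sim$r, config = cfg,
                 variances = c(g = 1, s = s2s, r = s2r), kernel = S),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Simulated trial:", nrow(x$trial), "plots,",
      length(x$true_g), "genotypes\n")
  cat("  generator:", x$config$family, "param", x$config$param,
      "| h =", x$config$genotypic_ratio, "fraSp =", x$config$fra_sp,
      "|", x$config$scenario, "\n")
  invisible(x)
}

#' Evaluate competing models on a simulated trial
#'
#' Fits each candidate model to all plots of the simulated trial with an
#' identity relationship matrix on the genotype labels (matching how the
#' genotypic effects were generated) and scores it by the recovery of the
#' *true* genotypic effects: `rmse_g = RMSE(true_g, g_hat)` and
#' `cor_g = cor(true_g, g_hat)` over all genotypes. The best model has the
#' lowest RMSE (and is cross-checked against the highest accuracy). Failed
#' fits are kept in the table but excluded from the ranking.
#'
#' @param sim a [sim_trial].
#' @param candidates named list of model specifications; each element is a
#'   list with `family`, `direction`, `param`, or `NULL` for the base
#'   model. Default: base plus the three kernel families, isotropic, at
#'   the generating parameter.
#' @param control solver settings.
#' @return a data frame, one row per candidate: `model`, `family`,
#'   `direction`, `param`, `rmse_g`, `cor_g`, the estimated variance
#'   components, `converged` and `best`.
#' @export
evaluate_models <- function(sim, candidates = NULL,
                            control = gsreml_control()) {
  stopifnot(inherits(sim, "sim_trial"))
  t <- sim$trial
  dim <- attr(t, "plot_dim")
  if (is.null(candidates)) {
    candidates <- list(
      base = NULL,
      power = list(family = "power", direction = "isotropic",
                   param = if (sim$config$family == "power")
                     sim$config$param else 0.5),
      gaussian = list(family = "gaussian", direction = "isotropic",
                      param = if (sim$config$family == "gaussian")
                        sim$config$param else 10.5),
      spherical = list(family = "spherical", direction = "isotropic",
                       param = if (sim$config$family == "spherical")
                         sim$config$param else 10.5))
  }
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  D_cache <- list()
  rows <- lapply(names(candidates), function(nm) {
    spec <- candidates[[nm]]
    ker <- NULL
    if (!is.null(spec)) {
      dir <- spec$direction %||% "isotropic"
      if (is.null(D_cache[[dir]]))
        D_cache[[dir]] <<- plot_dist(t, dim, dir)
      ker <- tryCatch(spatial_kernel(D_cache[[dir]], spec$family, spec$param),
                      error = function(e) NULL)
      if (is.null(ker))
        return(data.frame(model = nm, family = spec$family, direction = dir,
                          param = spec$param, rmse_g = NA, cor_g = NA,
                          s2_g = NA, s2_s = NA, s2_r = NA,
                          converged = FALSE))
    }
    fit <- tryCatch(
      gsreml(t, "y", kinship = NULL, spatial = ker, pev = FALSE,
             control = control),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged))
      return(data.frame(model = nm,
                        family = spec$family %||% "none",
                        direction = spec$direction %||% "none",
                        param = spec$param %||% NA_real_,
                        rmse_g = NA, cor_g = NA,
                        s2_g = NA, s2_s = NA, s2_r = NA, converged = FALSE))
    ghat <- fit$blup$g[names(sim$true_g)]
    data.frame(model = nm,
               family = if (is.null(spec)) "none" else spec$family,
               direction = if (is.null(spec)) "none" else
                 spec$direction %||% "isotropic",
               param = if (is.null(spec)) NA_real_ else spec$param,
               rmse_g = sqrt(mean((sim$true_g - ghat)^2)),
               cor_g = stats::cor(sim$true_g, ghat),
               s2_g = fit$varcomp[["g"]],
               s2_s = if ("s" %in% names(fit$varcomp))
                 fit$varcomp[["s"]] else NA_real_,
               s2_r = fit$varcomp[["residual"]],
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  ok <- which(out$converged & is.finite(out$rmse_g))
  if (length(ok)) out$best[ok[which.min(out$rmse_g[ok])]] <- TRUE
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a grid of simulation scenarios
#'
#' Executes the Cartesian product of genotypic ratios, spatial fractions,
#' generating kernels, replication scenarios and seeds, evaluating each
#' simulated trial with [evaluate_models]. Per-cell seeds are derived
#' deterministically from `master_seed`, so identical calls give identical
#' tables. The long-format result is suitable for ANOVA-style summaries of
#' which model wins where.
#'
#' @param h_grid genotypic ratios, default `c(0.3, 0.5, 0.7, 0.9)`.
#' @param fra_grid spatial fractions of error variance, same default.
#' @param kernel_grid data frame with columns `family` and `param`;
#'   default power theta in \{0.2, 0.5, 0.8\} and gaussian phi in
#'   \{0.5, 10.5, 30.5, 60.5\}.
#' @param scenarios replication scenarios to include.
#' @param n_seeds simulation replicates per cell, default 20.
#' @param master_seed integer master seed.
#' @param layout field layout skeleton, default [default_layout].
#' @param candidates passed to [evaluate_models]; default base + three
#'   isotropic kernels at the generating parameter.
#' @param control solver settings.
#' @return long-format data frame, one row per (cell, seed, model):
#'   generator settings, seed, model description, `rmse_g`, `cor_g`,
#'   estimated variance components and convergence flag.
#' @export
run_sim_grid <- function(h_grid = c(0.3, 0.5, 0.7, 0.9),
                         fra_grid = c(0.3, 0.5, 0.7, 0.9),
                         kernel_grid = default_kernel_grid(),
                         scenarios = "checks_only",
                         n_seeds = 20L, master_seed = 20170307L,
                         layout = default_layout(), candidates = NULL,
                         control = gsreml_control()) {
  stopifnot(length(h_grid) > 0, length(fra_grid) > 0, nrow(kernel_grid) > 0)
  cells <- expand.grid(h = h_grid, fra_sp = fra_grid,
                       kid = seq_len(nrow(kernel_grid)),
                       scenario = scenarios, stringsAsFactors = FALSE)
  seeds <- with_seed(master_seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       nrow(cells) * n_seeds),
                            nrow = nrow(cells)))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    fam <- kernel_grid$family[cells$kid[i]]
    par <- kernel_grid$param[cells$kid[i]]
    for (j in seq_len(n_seeds)) {
      cfg <- sim_config(genotypic_ratio = cells$h[i],
                        fra_sp = cells$fra_sp[i],
                        family = fam, param = par,
                        scenario = cells$scenario[i],
                        seed = seeds[i, j])
      tab <- tryCatch(
        evaluate_models(simulate_trial(cfg, layout), candidates,
                        control = control),
        error = function(e) NULL)
      if (is.null(tab)) next
      out[[length(out) + 1L]] <- data.frame(
        kernel_family_true = fam, param_true = par,
        h = cells$h[i], fra_sp = cells$fra_sp[i],
        scenario = cells$scenario[i], seed = seeds[i, j],
        tab, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname run_sim_grid
#' @export
default_kernel_grid <- function() {
  rbind(data.frame(family = "power", param = c(0.2, 0.5, 0.8)),
        data.frame(family = "gaussian", param = c(0.5, 10.5, 30.5, 60.5)))
}
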