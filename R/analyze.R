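#' End-to-end spatial-GBLUP analysis of a field trial
#'
#' The full exploratory pipeline for one or more traits: drop missing
#' values, match genotypes against the relationship matrix, fit the base
#' model, remove outlier plots (residual beyond `outlier_sd` residual
#' standard deviations), search for the best spatial kernel by repeated
#' cross-validation ([select_spatial_model]), optionally extend with
#' extraneous Range/Column effects ([extend_extraneous]), and write the
#' results as delimited text files.
#'
#' Files written per trait into `out_dir` (when not `NULL`):
#' `<trait>_genotype_blups.csv`, `<trait>_spatial_blups.csv` (plot id,
#' coordinates, observation, spatial BLUP, residuals of the selected and
#' base models — a grid export for external heat-map visualization),
#' `<trait>_cv_table.csv` (one row per candidate with pRMSE/pCOR/failure
#' counts) and `<trait>_summary.txt` (selected structure, variance
#' components, heritability, LRT, relative metrics, failed-model count).
#' A `manifest.txt` echoing the configuration and seed makes the run
#' reproducible.
#'
#' @param t a [trial_table] (e.g. from [read_trial]).
#' @param kinship genomic relationship matrix, e.g. [vanraden_kinship] on
#'   [read_markers] output; `NULL` uses an identity relationship.
#' @param dim a [plot_dim].
#' @param traits traits to analyze; default all traits of `t`.
#' @param out_dir output directory (created if absent), or `NULL` to skip
#'   file output.
#' @param folds,repeats,seed cross-validation settings.
#' @param skip_model2 do not try Range/Column extensions.
#' @param skip_outlier_removal keep all plots.
#' @param outlier_sd outlier threshold in residual standard deviations.
#' @param ... further arguments passed to [select_spatial_model]
#'   (`families`, `directions`, `grids`, `control`).
#' @return invisibly, a named list per trait with elements `selection`,
#'   `model2` (or `NULL`), `fit`, `h2`, `n_outliers`, `n_unmatched`,
#'   `n_failed_fits`.
#' @export
analyze_trial <- function(t, kinship = NULL, dim, traits = NULL,
                          out_dir = NULL, folds = 10L, repeats = 5L,
                          seed = 20170307L, skip_model2 = FALSE,
                          skip_outlier_removal = FALSE, outlier_sd = 2.5,
                          ...) {
  stopifnot(inherits(t, "trial_table"), inherits(dim, "plot_dim"))
  if (is.null(traits)) traits <- attr(t, "traits")
  if (!length(traits)) stop("no traits to analyze")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  failures <- character(0)
  for (tr in traits) {
    res <- tryCatch(
      analyze_one_trait(t, kinship, dim, tr, out_dir, folds, repeats,
                        seed, skip_model2, skip_outlier_removal,
                        outlier_sd, ...),
      error = function(e) {
        message("trait '", tr, "' failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) failures <- c(failures, tr) else results[[tr]] <- res
  }
  if (!is.null(out_dir)) {
    writeLines(c(
      paste0("spatGBLUP analyze_trial manifest"),
      paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste0("seed: ", seed),
      paste0("folds: ", folds, "  repeats: ", repeats),
      paste0("plot_dim: ", dim$length_m, " x ", dim$width_m),
      paste0("traits: ", paste(traits, collapse = ", ")),
      paste0("failed_traits: ", if (length(failures))
        paste(failures, collapse = ", ") else "none"),
      paste0("skip_model2: ", skip_model2,
             "  skip_outlier_removal: ", skip_outlier_removal),
      paste0("outlier_sd: ", outlier_sd)),
      file.path(out_dir, "manifest.txt"))
  }
  if (length(failures) && !length(results))
    stop("every trait failed: ", paste(failures, collapse = ", "))
  attr(results, "failed_traits") <- failures
  invisible(results)
}

analyze_one_trait <- function(t, kinship, dim, tr, out_dir, folds, repeats,
                              seed, skip_model2, skip_outlier_removal,
                              outlier_sd, ...) {
  message("trait '", tr, "': preprocessing")
  tt <- drop_missing_for_trait(t, tr)
  n_unmatched <- 0L
  if (!is.null(kinship)) {
    tt <- match_genotypes(tt, kinship)
    n_unmatched <- attr(tt, "n_unmatched")
  }
  base0 <- gsreml(tt, tr, kinship = kinship)
  n_outliers <- 0L
  if (!skip_outlier_removal) {
    tt <- remove_outliers(tt, tr, base0, c_sd = outlier_sd)
    n_outliers <- attr(tt, "n_outliers")
    if (n_outliers > 0)
      message("trait '", tr, "': removed ", n_outliers, " outlier plot(s)")
  }
  plan <- make_folds(tt$genotype, k = folds, n_repeats = repeats,
                     seed = seed)
  message("trait '", tr, "': spatial model search")
  sel <- select_spatial_model(tt, tr, kinship = kinship, dim = dim,
                              plan = plan, ...)
  m2 <- NULL
  if (!skip_model2) {
    message("trait '", tr, "': extraneous-effect extension")
    m2 <- extend_extraneous(sel, tt, tr, kinship = kinship)
  }
  fit <- if (!is.null(m2)) m2$fit_best else sel$fit_best
  # refit with PEV for heritability if the kept fit lacks it
  h2 <- tryCatch(suppressWarnings(cullis_h2(fit)), error = function(e) NA_real_)
  n_failed <- sum(sel$table$n_failed) +
    if (!is.null(m2)) sum(m2$table$n_failed) else 0L
  if (!is.null(out_dir))
    write_trait_outputs(out_dir, tr, tt, sel, m2, fit, h2, n_failed)
  list(selection = sel, model2 = m2, fit = fit, h2 = h2,
       n_outliers = n_outliers, n_unmatched = n_unmatched,
       n_failed_fits = n_failed, data = tt)
}

write_trait_outputs <- function(out_dir, tr, tt, sel, m2, fit, h2,
                                n_failed) {
  g <- fit$blup$g
  utils::write.csv(data.frame(genotype = names(g), blup = unname(g)),
                   file.path(out_dir, paste0(tr, "_genotype_blups.csv")),
                   row.names = FALSE)
  s <- fit$blup$s
  grid <- data.frame(plot_id = tt$plot_id, range = tt$range,
                     column = tt$column, genotype = tt$genotype,
                     observed = tt[[tr]],
                     spatial_blup = if (is.null(s)) 0 else
                       unname(s[tt$plot_id]),
                     residual_model = unname(fit$residuals[tt$plot_id]),
                     residual_base = unname(
                       sel$fit_base$residuals[tt$plot_id]))
  utils::write.csv(grid,
                   file.path(out_dir, paste0(tr, "_spatial_blups.csv")),
                   row.names = FALSE)
  utils::write.csv(sel$table,
                   file.path(out_dir, paste0(tr, "_cv_table.csv")),
                   row.names = FALSE)
  bs <- sel$best_spec$spatial
  lines <- c(
    paste0("trait: ", tr),
    paste0("n_plots: ", nrow(tt)),
    paste0("selected_model: ", if (is.null(bs)) "Base" else
      paste0(bs$family, "-", bs$direction, " (param ",
             signif(bs$param, 6), ")")),
    paste0("extraneous: ", if (is.null(m2)) "not tested" else
      m2$best_extraneous),
    paste0("varcomp: ", paste(sprintf("%s=%.6g", names(fit$varcomp),
                                      fit$varcomp), collapse = "  ")),
    paste0("boundary: ", paste(names(fit$varcomp)[fit$boundary],
                               collapse = " ")),
    paste0("heritability_cullis: ", signif(h2, 6)),
    paste0("restricted_loglik: ", signif(fit$loglik, 10)),
    paste0("base_pRMSE: ", signif(sel$base$pRMSE, 6),
           "  base_pCOR: ", signif(sel$base$pCOR, 6)),
    paste0("best_pRMSE: ", signif(sel$best$pRMSE, 6),
           "  best_pCOR: ", signif(sel$best$pCOR, 6)),
    paste0("rel_pcor_increase_pct: ",
           signif(sel$rel_metrics[["rel_pcor_increase"]], 6)),
    paste0("rel_prmse_decrease_pct: ",
           signif(sel$rel_metrics[["rel_prmse_decrease"]], 6)),
    if (!is.null(sel$lrt))
      paste0("lrt_model1_vs_base: chi2=", signif(sel$lrt$statistic, 6),
             " threshold=", signif(sel$lrt$threshold, 4),
             " significant=", sel$lrt$significant,
             " mixture_p=", signif(sel$lrt$p_value, 4)),
    if (!is.null(m2) && !is.null(m2$lrt))
      paste0("lrt_model2: chi2=", signif(m2$lrt$statistic, 6),
             " threshold=", signif(m2$lrt$threshold, 4),
             " significant=", m2$lrt$significant),
    paste0("n_failed_models: ", n_failed))
  writeLines(lines, file.path(out_dir, paste0(tr, "_summary.txt")))
}

#' Run a simulation study and write its results table
#'
#' Thin file-writing wrapper around [run_sim_grid]: writes the long-format
#' results table and a manifest (grids, seeds, package version) to
#' `out_dir`.
#'
#' @inheritParams run_sim_grid
#' @param out_dir output directory.
#' @return invisibly, the results data frame.
#' @export
simulate_study <- function(out_dir, h_grid = c(0.3, 0.5, 0.7, 0.9),
                           fra_grid = c(0.3, 0.5, 0.7, 0.9),
                           kernel_grid = default_kernel_grid(),
                           scenarios = "checks_only", n_seeds = 20L,
                           master_seed = 20170307L,
                           layout = default_layout(), ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- run_sim_grid(h_grid = h_grid, fra_grid = fra_grid,
                      kernel_grid = kernel_grid, scenarios = scenarios,
                      n_seeds = n_seeds, master_seed = master_seed,
                      layout = layout, ...)
  utils::write.csv(res, file.path(out_dir, "simulation_results.csv"),
                   row.names = FALSE)
  writeLines(c(
    "spatGBLUP simulate_study manifest",
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("package_version: ",
           as.character(utils::packageVersion("spatGBLUP"))),
    paste0("master_seed: ", master_seed),
    paste0("n_seeds: ", n_seeds),
    paste0("h_grid: ", paste(h_grid, collapse = ", ")),
    paste0("fra_grid: ", paste(fra_grid, collapse = ", ")),
    paste0("kernels: ", paste(paste0(kernel_grid$family, "(",
                                     kernel_grid$param, ")"),
                              collapse = ", ")),
    paste0("scenarios: ", paste(scenarios, collapse = ", ")),
    paste0("layout_plots: ", nrow(layout))),
    file.path(out_dir, "manifest.txt"))
  invisible(res)
}
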