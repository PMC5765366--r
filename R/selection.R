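# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cross-validation plan over genotypes
#'
#' Builds `n_repeats` independent random partitions of the genotype set
#' into `k` folds of near-equal size (sizes differ by at most one).
#' Training and test sets never share a genotype: every plot follows its
#' genotype, so replicated genotypes contribute all their plots to the same
#' side of the split.
#'
#' @param genotypes character vector of genotype identifiers (duplicates
#'   ignored).
#' @param k number of folds, default 10.
#' @param n_repeats number of repeats, default 5.
#' @param seed integer seed; the same seed always yields the same plan.
#' @return object of class `cv_plan`: a list of per-repeat named integer
#'   vectors mapping genotype to fold.
#' @export
make_folds <- function(genotypes, k = 10L, n_repeats = 5L, seed = 20170307L) {
  genotypes <- unique(as.character(genotypes))
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (length(genotypes) < k)
    stop("fewer genotypes (", length(genotypes), ") than folds (", k, ")")
  assignments <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    fold <- rep(seq_len(k), length.out = length(genotypes))
    stats::setNames(fold[sample.int(length(genotypes))], genotypes)
  }))
  structure(list(k = k, n_repeats = as.integer(n_repeats), seed = seed,
                 assignments = assignments),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("CV plan: ", x$k, "-fold x ", x$n_repeats, " repeats over ",
      length(x$assignments[[1L]]), " genotypes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Cross-validated predictability of one model specification
#'
#' For every repeat and fold of the plan: fit the model on the training
#' plots, predict the held-out plots with [predict.gsreml], and record the
#' root-mean-squared error (pRMSE) and Pearson correlation (pCOR) between
#' observed and predicted phenotypes. Fold-fits that error or fail to
#' converge are trapped, skipped and counted. A fold whose predictions are
#' constant has no defined correlation; it is recorded as 0 with a warning.
#'
#' @param t a [trial_table] with no missing values for `trait`.
#' @param trait trait to fit.
#' @param kinship genomic relationship matrix (or `NULL` for identity).
#' @param spatial optional [spatial_kernel] covering all plots of `t`.
#' @param extraneous `"none"`, `"range"`, `"column"` or `"both"`.
#' @param plan a [cv_plan] covering all genotypes of `t`.
#' @param control solver settings.
#' @return object of class `cv_result`: mean `pRMSE`, mean `pCOR`,
#'   `per_fold` data frame, `n_failed_fits`, and the model description.
#' @export
cross_validate <- function(t, trait, kinship = NULL, spatial = NULL,
                           extraneous = "none", plan,
                           control = gsreml_control()) {
  stopifnot(inherits(t, "trial_table"), inherits(plan, "cv_plan"))
  genos <- unique(t$genotype)
  if (!all(genos %in% names(plan$assignments[[1L]])))
    stop("CV plan does not cover every genotype of the trial")
  if (is.null(kinship)) {
    # identity relationship over the whole trial, so held-out genotypes
    # exist in K (their BLUP is then shrunk to zero)
    kinship <- diag(length(genos))
    dimnames(kinship) <- list(sort(genos), sort(genos))
  }
  # NB: fold-fits are cold-started on purpose. Warm-starting from the
  # full-data optimum leaks information about the held-out folds into the
  # training fit through the (nearly flat) likelihood surface near a
  # variance boundary, and measurably biases selection toward spatial
  # candidates on null fields.
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(plan$n_repeats)) {
    fold_of <- plan$assignments[[r]]
    for (f in seq_len(plan$k)) {
      test_geno <- names(fold_of)[fold_of == f]
      is_test <- t$genotype %in% test_geno
      if (!any(is_test) || all(is_test)) next
      train <- restitch(t[!is_test, , drop = FALSE], t)
      test <- t[is_test, , drop = FALSE]
      fit <- tryCatch(
        gsreml(train, trait, kinship = kinship, spatial = spatial,
               extraneous = extraneous, pev = FALSE,
               control = control),
        error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        n_failed <- n_failed + 1L
        next
      }
      yhat <- tryCatch(predict(fit, test), error = function(e) NULL)
      if (is.null(yhat)) { n_failed <- n_failed + 1L; next }
      obs <- test[[trait]]
      prmse <- sqrt(mean((obs - yhat)^2))
      pcor <- if (stats::sd(yhat) == 0 || stats::sd(obs) == 0) {
        warning("constant predictions in a fold; pCOR recorded as 0")
        0
      } else stats::cor(obs, yhat)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, pRMSE = prmse, pCOR = pcor)
    }
  }
  total <- plan$n_repeats * plan$k
  if (n_failed > total / 2)
    stop("more than half of the fold-fits failed (",
         n_failed, "/", total, ") for model: ",
         describe_spec(spatial, extraneous))
  per_fold <- do.call(rbind, rows)
  structure(list(
    pRMSE = mean(per_fold$pRMSE), pCOR = mean(per_fold$pCOR),
    per_fold = per_fold, n_failed_fits = n_failed,
    model = list(spatial = if (is.null(spatial)) NULL else
      list(family = attr(spatial, "family"),
           direction = attr(spatial, "direction"),
           param = attr(spatial, "param")),
      extraneous = extraneous),
    plan_seed = plan$seed), class = "cv_result")
}

describe_spec <- function(spatial, extraneous) {
  s <- if (is.null(spatial)) "Base" else
    paste0(attr(spatial, "family"), "-", attr(spatial, "direction"),
           " (", signif(attr(spatial, "param"), 4), ")")
  if (!identical(extraneous, "none")) s <- paste0(s, " + ", extraneous)
  s
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CV predictability: pRMSE =", signif(x$pRMSE, 5),
      " pCOR =", signif(x$pCOR, 4),
      " (", x$n_failed_fits, "failed fold-fits )\n")
  invisible(x)
}

#' Relative predictability change of a model over the base model
#'
#' Relative increase in prediction accuracy
#' `(pCOR_model - pCOR_base) / (1 - pCOR_base)` and relative decrease in
#' prediction error `(pRMSE_base - pRMSE_model) / pRMSE_base`, both in
#' percent.
#'
#' @param base,model [cv_result] objects computed under the same plan.
#' @return named vector `c(rel_pcor_increase, rel_prmse_decrease)` in
#'   percent.
#' @export
relative_metrics <- function(base, model) {
  stopifnot(inherits(base, "cv_result"), inherits(model, "cv_result"))
  if (base$pCOR >= 1) stop("base pCOR must be below 1")
  if (base$pRMSE == 0) stop("base pRMSE is zero; relative decrease undefined")
  c(rel_pcor_increase = 100 * (model$pCOR - base$pCOR) / (1 - base$pCOR),
    rel_prmse_decrease = 100 * (base$pRMSE - model$pRMSE) / base$pRMSE)
}

#' Exploratory search for the best spatial structure (Model 1)
#'
#' Evaluates the base GBLUP model and every candidate spatial kernel
#' (family x direction x standardizing parameter) under one shared
#' cross-validation plan, so all comparisons are paired. The best model is
#' the one with the lowest pRMSE; ties go to the higher pCOR, then to the
#' base model, then to the smaller standardizing parameter. A full-data
#' likelihood-ratio test of the best spatial candidate against the base
#' model (1 added variance component) is reported whichever model wins
#' the CV.
#'
#' @param t a [trial_table] with no missing values for `trait`.
#' @param trait trait name.
#' @param kinship genomic relationship matrix (or `NULL` for identity).
#' @param dim a [plot_dim].
#' @param plan a [cv_plan]; default 10-fold x 5 repeats.
#' @param families kernel families to try.
#' @param directions distance directions to try.
#' @param grids optional named list (`power`, `gaussian`, `spherical`) of
#'   parameter vectors overriding [parameter_grid]. Gaussian/spherical
#'   grids may also be direction-specific via `grids[[family]][[direction]]`.
#' @param alpha significance level of the reported LRT.
#' @param control solver settings.
#' @return object of class `gs_selection`: `table` (one row per candidate),
#'   `base` and `best` [cv_result]s, `best_spec`, `rel_metrics`, `lrt`,
#'   and the fitted full-data models `fit_base`, `fit_best`.
#' @export
select_spatial_model <- function(t, trait, kinship = NULL, dim,
                                 plan = NULL,
                                 families = c("power", "gaussian", "spherical"),
                                 directions = c("isotropic", "range", "column"),
                                 grids = NULL, alpha = 0.1,
                                 control = gsreml_control()) {
  stopifnot(inherits(t, "trial_table"), inherits(dim, "plot_dim"))
  if (is.null(plan)) plan <- make_folds(t$genotype)
  dists <- lapply(stats::setNames(directions, directions),
                  function(dir) plot_dist(t, dim, dir))
  base_cv <- cross_validate(t, trait, kinship = kinship, plan = plan,
                            control = control)
  cand <- list()
  tab <- data.frame(family = "none", direction = "none", param = NA_real_,
                    pRMSE = base_cv$pRMSE, pCOR = base_cv$pCOR,
                    n_failed = base_cv$n_failed_fits,
                    stringsAsFactors = FALSE)
  for (fam in families) for (dir in directions) {
    pg <- grids[[fam]]
    if (is.list(pg)) pg <- pg[[dir]]
    if (is.null(pg)) pg <- parameter_grid(fam, dists[[dir]])
    for (p in pg) {
      ker <- tryCatch(spatial_kernel(dists[[dir]], fam, p),
                      error = function(e) NULL)
      if (is.null(ker)) next
      cv <- tryCatch(
        cross_validate(t, trait, kinship = kinship, spatial = ker,
                       plan = plan, control = control),
        error = function(e) NULL)
      if (is.null(cv)) next
      cand[[length(cand) + 1L]] <- list(cv = cv, kernel = ker)
      tab <- rbind(tab, data.frame(
        family = fam, direction = dir, param = p,
        pRMSE = cv$pRMSE, pCOR = cv$pCOR, n_failed = cv$n_failed_fits,
        stringsAsFactors = FALSE))
    }
  }
  pick <- pick_best(tab)
  best_is_base <- pick == 1L
  best_cv <- if (best_is_base) base_cv else cand[[pick - 1L]]$cv
  best_kernel <- if (best_is_base) NULL else cand[[pick - 1L]]$kernel
  # full-data LRT of the best *spatial* candidate against base
  fit_base <- gsreml(t, trait, kinship = kinship, control = control)
  lrt_res <- NULL; fit_best <- fit_base
  if (length(cand)) {
    sp_rows <- which(tab$family != "none")
    sp_pick <- sp_rows[pick_best(tab[sp_rows, , drop = FALSE])]
    sp_kernel <- cand[[sp_pick - 1L]]$kernel
    fit_sp <- tryCatch(
      gsreml(t, trait, kinship = kinship, spatial = sp_kernel,
             control = control), error = function(e) NULL)
    if (!is.null(fit_sp) && fit_sp$converged)
      lrt_res <- lrt(fit_sp, fit_base, extra_df = 1L, alpha = alpha)
    fit_best <- if (best_is_base) fit_base else fit_sp
    if (!best_is_base &&
        (is.null(fit_best) ||
         !identical(attr(best_kernel, "param"), attr(sp_kernel, "param")) ||
         !identical(attr(best_kernel, "family"), attr(sp_kernel, "family")) ||
         !identical(attr(best_kernel, "direction"), attr(sp_kernel, "direction"))))
      fit_best <- gsreml(t, trait, kinship = kinship, spatial = best_kernel,
                         control = control)
  }
  structure(list(
    table = tab, base = base_cv, best = best_cv,
    best_spec = list(
      spatial = if (best_is_base) NULL else
        list(family = attr(best_kernel, "family"),
             direction = attr(best_kernel, "direction"),
             param = attr(best_kernel, "param")),
      extraneous = "none"),
    best_kernel = best_kernel,
    rel_metrics = relative_metrics(base_cv, best_cv),
    lrt = lrt_res, fit_base = fit_base, fit_best = fit_best,
    plan = plan), class = "gs_selection")
}

# row index of the best model in a candidate table: lowest pRMSE, ties by
# higher pCOR, then base ("none") preferred, then smaller parameter
pick_best <- function(tab) {
  ord <- order(tab$pRMSE, -tab$pCOR, tab$family != "none",
               tab$param, na.last = FALSE)
  ord[1L]
}

#' @export
print.gs_selection <- function(x, ...) {
  cat("Spatial model selection over", nrow(x$table) - 1L, "candidates\n")
  cat("  Base:  pRMSE", signif(x$base$pRMSE, 5), " pCOR",
      signif(x$base$pCOR, 4), "\n")
  bs <- x$best_spec$spatial
  if (is.null(bs)) {
    cat("  Best:  Base model (no spatial kernel)\n")
  } else {
    cat("  Best: ", bs$family, "-", bs$direction,
        " (param ", signif(bs$param, 4), "): pRMSE ",
        signif(x$best$pRMSE, 5), " pCOR ", signif(x$best$pCOR, 4),
        "\n", sep = "")
    cat(sprintf("  relative pCOR increase %.2f%%, pRMSE decrease %.2f%%\n",
                x$rel_metrics[["rel_pcor_increase"]],
                x$rel_metrics[["rel_prmse_decrease"]]))
  }
  if (!is.null(x$lrt)) print(x$lrt)
  invisible(x)
}

#' Extend the selected model with extraneous Range/Column effects (Model 2)
#'
#' Starting from the winner of [select_spatial_model] (base or spatial),
#' evaluates the addition of random Range effects, Column effects, and
#' both, under the same cross-validation plan, to capture extraneous field
#' variation (e.g. tillage direction) that the smooth spatial kernel does
#' not fit. The likelihood-ratio test of the selected extension against
#' the starting model uses as many degrees of freedom as components added
#' (thresholds 2.706 for one, 4.605 for two at `alpha = 0.1`). Degenerate
#' candidates (a single Range or Column in the field) are skipped with a
#' warning.
#'
#' @param selection a `gs_selection` from [select_spatial_model].
#' @param t,trait,kinship,control as in [select_spatial_model].
#' @param alpha significance level for the LRT.
#' @return object of class `gs_selection2`: candidate `table`, `best_cv`,
#'   `best_extraneous` (`"none"` if no extension wins), `lrt` of the best
#'   extension vs. the starting model, and the full-data `fit_best`.
#' @export
extend_extraneous <- function(selection, t, trait, kinship = NULL,
                              alpha = 0.1, control = gsreml_control()) {
  stopifnot(inherits(selection, "gs_selection"))
  plan <- selection$plan
  ker <- selection$best_kernel
  start_cv <- selection$best
  tab <- data.frame(extraneous = "none", pRMSE = start_cv$pRMSE,
                    pCOR = start_cv$pCOR,
                    n_failed = start_cv$n_failed_fits,
                    stringsAsFactors = FALSE)
  cands <- c("range", "column", "both")
  ok <- list()
  for (ex in cands) {
    if ((ex %in% c("range", "both") && length(unique(t$range)) < 2L) ||
        (ex %in% c("column", "both") && length(unique(t$column)) < 2L)) {
      warning("skipping '", ex, "' extension: single level in the field")
      next
    }
    cv <- tryCatch(
      cross_validate(t, trait, kinship = kinship, spatial = ker,
                     extraneous = ex, plan = plan, control = control),
      error = function(e) NULL)
    if (is.null(cv)) next
    ok[[ex]] <- cv
    tab <- rbind(tab, data.frame(extraneous = ex, pRMSE = cv$pRMSE,
                                 pCOR = cv$pCOR,
                                 n_failed = cv$n_failed_fits,
                                 stringsAsFactors = FALSE))
  }
  ord <- order(tab$pRMSE, -tab$pCOR, tab$extraneous != "none")
  best_ex <- tab$extraneous[ord[1L]]
  best_cv <- if (best_ex == "none") start_cv else ok[[best_ex]]
  lrt_res <- NULL
  fit_best <- selection$fit_best
  if (best_ex != "none") {
    extra <- if (best_ex == "both") 2L else 1L
    fit_ext <- tryCatch(
      gsreml(t, trait, kinship = kinship, spatial = ker,
             extraneous = best_ex, control = control),
      error = function(e) NULL)
    if (!is.null(fit_ext) && fit_ext$converged) {
      lrt_res <- lrt(fit_ext, selection$fit_best, extra_df = extra,
                     alpha = alpha)
      fit_best <- fit_ext
    }
  }
  structure(list(table = tab, best_cv = best_cv,
                 best_extraneous = best_ex, lrt = lrt_res,
                 fit_best = fit_best, plan = plan),
            class = "gs_selection2")
}

#' @export
print.gs_selection2 <- function(x, ...) {
  cat("Extraneous-effect extension (Model 2) candidates:\n")
  print(x$table, row.names = FALSE)
  cat("  Best extension:", x$best_extraneous, "\n")
  if (!is.null(x$lrt)) print(x$lrt)
  invisible(x)
}
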