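#' Control settings for the REML solver
#'
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood, default `1e-6`.
#' @param max_iter maximum Fisher-scoring iterations, default 100.
#' @param floor_frac variance components are never allowed below
#'   `floor_frac * var(y)`; a component held at this floor for three
#'   consecutive iterations is declared a boundary (zero) solution.
#' @param max_halvings maximum step-halvings per iteration.
#' @return a list of class `gsreml_control`.
#' @export
gsreml_control <- function(tol = 1e-6, max_iter = 100L,
                           floor_frac = 1e-9, max_halvings = 30L) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 floor_frac = floor_frac,
                 max_halvings = as.integer(max_halvings)),
            class = "gsreml_control")
}

# Evaluate the restricted log-likelihood and projection quantities at fixed
# variance components. X is the intercept column; the REML criterion is
#   -0.5 * [ (n-1) log(2*pi) + log|V| + log(1' V^-1 1) + y' P y ].
reml_eval <- function(y, Vlist, theta) {
  n <- length(y)
  V <- diag(theta[["residual"]], n)
  for (nm in setdiff(names(Vlist), "residual"))
    V <- V + theta[[nm]] * Vlist[[nm]]
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Vinv <- chol2inv(L)
  a <- rowSums(Vinv)                      # V^-1 1
  cc <- sum(a)                            # 1' V^-1 1
  if (cc <= 0) return(NULL)
  mu <- sum(a * y) / cc
  Py <- Vinv %*% y - a * (sum(a * y) / cc)
  Py <- drop(Py)
  llk <- -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(L))) +
                   log(cc) + sum(y * Py))
  list(llk = llk, Vinv = Vinv, a = a, cc = cc, mu = mu, Py = Py)
}

# REML scores and expected (Fisher) information at the current evaluation.
# tr(P V_i) uses elementwise products with V^-1; the information matrix
# forms P V_i once per non-residual component.
reml_score_info <- function(ev, Vlist, active) {
  P <- ev$Vinv - tcrossprod(ev$a) / ev$cc
  m <- length(active)
  score <- numeric(m); names(score) <- active
  PV <- vector("list", m); names(PV) <- active
  for (nm in active) {
    if (nm == "residual") {
      trPV <- sum(diag(ev$Vinv)) - sum(ev$a^2) / ev$cc
      qf <- sum(ev$Py^2)
      PV[[nm]] <- P
    } else {
      Vi <- Vlist[[nm]]
      trPV <- sum(ev$Vinv * Vi) - drop(crossprod(ev$a, Vi %*% ev$a)) / ev$cc
      qf <- drop(crossprod(ev$Py, Vi %*% ev$Py))
      PV[[nm]] <- P %*% Vi
    }
    score[nm] <- -0.5 * (trPV - qf)
  }
  info <- matrix(0, m, m, dimnames = list(active, active))
  for (i in seq_len(m)) for (j in i:m) {
    info[i, j] <- info[j, i] <- 0.5 * sum(PV[[i]] * t(PV[[j]]))
  }
  list(score = score, info = info, P = P)
}

reml_solve <- function(y, Vlist, control, start = NULL) {
  n <- length(y)
  comp <- names(Vlist)
  vary <- stats::var(y)
  floor <- control$floor_frac * max(vary, .Machine$double.eps)
  theta <- stats::setNames(rep(vary / length(comp), length(comp)), comp)
  if (!is.null(start) && all(comp %in% names(start)))
    theta <- stats::setNames(as.numeric(start[comp]), comp)
  theta <- pmax(theta, floor)
  boundary <- stats::setNames(rep(FALSE, length(comp)), comp)
  pinned <- stats::setNames(rep(0L, length(comp)), comp)
  ev <- reml_eval(y, Vlist, as.list(theta))
  if (is.null(ev)) stop("covariance matrix singular at starting values")
  converged <- FALSE
  # a frozen boundary component whose score is positive at the current
  # point is released: the optimum wants it strictly inside the domain
  release_check <- function() {
    frozen <- comp[boundary[comp]]
    if (!length(frozen)) return(FALSE)
    sc <- reml_score_info(ev, Vlist, frozen)$score
    hot <- names(sc)[sc > 1e-6]
    if (!length(hot)) return(FALSE)
    boundary[hot] <<- FALSE
    pinned[hot] <<- 0L
    TRUE
  }
  try_direction <- function(delta, active) {
    step <- 1
    for (h in seq_len(control$max_halvings)) {
      cand <- theta
      cand[active] <- pmax(theta[active] + step * delta, floor)
      ev2 <- reml_eval(y, Vlist, as.list(cand))
      if (!is.null(ev2) && is.finite(ev2$llk) && ev2$llk >= ev$llk - 1e-12)
        return(list(cand = cand, ev = ev2, step = step))
      step <- step / 2
    }
    NULL
  }
  n_stall <- 0L
  for (iter in seq_len(control$max_iter)) {
    active <- comp[!boundary[comp]]
    si <- reml_score_info(ev, Vlist, active)
    info <- si$info + diag(1e-10 * max(diag(si$info), 1), length(active))
    delta <- tryCatch(drop(solve(info, si$score)),
                      error = function(e) NULL)
    if (is.null(delta)) stop("singular information matrix in REML update")
    got <- try_direction(delta, active)
    if (is.null(got)) {
      # Fisher direction can be poor when the information matrix is
      # ill-conditioned near a variance boundary; fall back to the
      # diagonally preconditioned gradient before giving up
      delta2 <- si$score / pmax(diag(si$info), 1e-12)
      got <- try_direction(delta2, active)
    }
    if (is.null(got)) {              # no ascent direction in the active set
      if (release_check()) next
      converged <- TRUE
      break
    }
    dllk <- got$ev$llk - ev$llk
    theta <- got$cand
    ev <- got$ev
    at_floor <- theta <= floor * (1 + 1e-6)
    pinned <- ifelse(at_floor, pinned + 1L, 0L)
    boundary <- boundary | (pinned >= 3L)
    if (abs(dllk) < control$tol) {
      # a tiny gain after heavy step-halving is a stall, not convergence:
      # the gradient may still be large along a badly scaled direction
      if (got$step >= 0.99 || n_stall >= 5L) {
        if (release_check()) { n_stall <- 0L; next }
        converged <- TRUE
        break
      }
      n_stall <- n_stall + 1L
    } else n_stall <- 0L
  }
  boundary <- boundary | (theta <= floor * (1 + 1e-6))
  list(theta = theta, boundary = boundary, ev = ev,
       converged = converged, floor = floor, n_iter = iter)
}

#' Fit a genomic-selection mixed model with optional spatial kernel
#'
#' Fits, by restricted maximum likelihood, the plot-level mixed model
#' \deqn{y = \mu + Z g + s + Z_2\,ra + Z_3\,cl + r}
#' where \eqn{g \sim N(0, K\sigma^2_g)} are genotypic effects with
#' covariance proportional to a genomic relationship matrix,
#' \eqn{s \sim N(0, S\sigma^2_s)} are plot-level spatial effects with a
#' parametric correlation kernel \eqn{S} (see [spatial_kernel]), optional
#' \eqn{ra}/\eqn{cl} are i.i.d. random Range and Column effects capturing
#' extraneous (operational) field variation, and \eqn{r} is i.i.d.
#' residual error. Omitting `spatial` and `extraneous` gives the base
#' GBLUP model; adding the spatial kernel gives the GS-spatial model;
#' adding Range/Column effects gives its extraneous-variation extension.
#'
#' Variance components are estimated by Fisher scoring (expected
#' information) with step-halving, a non-negativity floor at
#' `floor_frac * var(y)`, and boundary detection: a component held at the
#' floor for three consecutive iterations is reported as exactly 0 with a
#' boundary flag. Genotypic BLUPs are returned for *every* genotype in the
#' relationship matrix, observed or not, so unphenotyped genotypes are
#' predicted through the kinship; spatial BLUPs are returned for every plot
#' the kernel covers, so held-out plots can be predicted by kriging.
#'
#' @param t a [trial_table] of training plots.
#' @param trait trait column to fit.
#' @param kinship genomic relationship matrix with genotype dimnames
#'   covering all genotypes of `t` (e.g. [vanraden_kinship]). `NULL` uses
#'   an identity relationship on the genotype labels of `t`.
#' @param spatial a [spatial_kernel] over the field layout (may cover more
#'   plots than `t`; rows are matched by plot id), or `NULL` for no spatial
#'   component.
#' @param extraneous `"none"`, `"range"`, `"column"` or `"both"` random
#'   Range/Column effects.
#' @param varcomps optional named numeric vector of fixed variance
#'   components (names among `g`, `s`, `range`, `column`, `residual`);
#'   when supplied no optimization is done and the model is evaluated at
#'   these values (used for likelihood profiling and oracles).
#' @param start optional named vector of starting values for the variance
#'   components (e.g. a previous fit's `varcomp`), used to warm-start the
#'   solver; ignored when incomplete.
#' @param pev compute the genotype prediction-error variance-covariance
#'   matrix (needed by [cullis_h2]); default `TRUE`. Turned off in inner
#'   cross-validation loops for speed.
#' @param control a [gsreml_control].
#' @return an object of class `gsreml` with components `mu`, `varcomp`
#'   (named vector), `boundary` (logical flags), `blup` (list with `g`,
#'   and `s`/`range`/`column` when present), `loglik`, `converged`,
#'   `n_obs`, `fitted`, `residuals`, `pev_g` and bookkeeping needed by
#'   [predict.gsreml].
#' @seealso [lrt], [cullis_h2], [select_spatial_model]
#' @export
gsreml <- function(t, trait, kinship = NULL, spatial = NULL,
                   extraneous = c("none", "range", "column", "both"),
                   varcomps = NULL, start = NULL, pev = TRUE,
                   control = gsreml_control()) {
  stopifnot(inherits(t, "trial_table"))
  extraneous <- match.arg(extraneous)
  if (!trait %in% traits(t)) stop("unknown trait: ", trait)
  y <- t[[trait]]
  if (anyNA(y)) stop("trait '", trait, "' has missing values; ",
                     "apply drop_missing_for_trait() first")
  n <- length(y)
  if (is.null(kinship)) {
    ids <- sort(unique(t$genotype))
    kinship <- diag(length(ids))
    dimnames(kinship) <- list(ids, ids)
  }
  if (is.null(rownames(kinship)))
    stop("kinship must carry genotype dimnames")
  if (!all(t$genotype %in% rownames(kinship)))
    stop("genotype(s) of the trial absent from the kinship; ",
         "apply match_genotypes() first")

  Vlist <- list(g = kinship[t$genotype, t$genotype, drop = FALSE])
  if (!is.null(spatial)) {
    stopifnot(inherits(spatial, "spatial_kernel"))
    if (!all(t$plot_id %in% rownames(spatial)))
      stop("spatial kernel does not cover all plots of the trial")
    Vlist$s <- unclass(spatial)[t$plot_id, t$plot_id, drop = FALSE]
  }
  if (extraneous %in% c("range", "both")) {
    if (length(unique(t$range)) < 2L)
      stop("cannot fit a Range effect: field has a single Range")
    Vlist$range <- outer(t$range, t$range, "==") + 0
  }
  if (extraneous %in% c("column", "both")) {
    if (length(unique(t$column)) < 2L)
      stop("cannot fit a Column effect: field has a single Column")
    Vlist$column <- outer(t$column, t$column, "==") + 0
  }
  Vlist$residual <- NULL   # handled implicitly as an identity term
  comp <- c(names(Vlist), "residual")
  Vlist$residual <- "identity"   # placeholder; reml_eval adds theta_r * I

  # degenerate input: constant response
  if (stats::var(y) < 1e-12 * max(1, mean(y)^2)) {
    vc <- stats::setNames(rep(0, length(comp)), comp)
    fit <- new_gsreml(t, trait, kinship, spatial, extraneous, vc,
                      boundary = stats::setNames(rep(TRUE, length(comp)), comp),
                      mu = mean(y), Py = rep(0, n), P = NULL,
                      loglik = NA_real_, converged = TRUE, n_iter = 0L,
                      pev = FALSE)
    return(fit)
  }

  if (!is.null(varcomps)) {
    miss <- setdiff(comp, names(varcomps))
    if (length(miss))
      stop("varcomps must name every component: missing ",
           paste(miss, collapse = ", "))
    if (any(varcomps[comp] < 0)) stop("variance components must be >= 0")
    if (all(varcomps[comp] == 0)) stop("variance components must not all be zero")
    th <- pmax(varcomps[comp], 0)
    # exact zeros are kept, provided V stays positive definite
    ev <- reml_eval(y, Vlist, as.list(th))
    if (is.null(ev)) stop("covariance matrix not positive definite at varcomps")
    sol <- list(theta = th, boundary = th == 0, ev = ev,
                converged = TRUE, n_iter = 0L)
  } else {
    sol <- reml_solve(y, Vlist, control, start = start)
  }

  theta <- sol$theta
  report <- theta
  report[sol$boundary] <- 0
  P <- sol$ev$Vinv - tcrossprod(sol$ev$a) / sol$ev$cc
  new_gsreml(t, trait, kinship, spatial, extraneous, report,
             boundary = sol$boundary, mu = sol$ev$mu, Py = sol$ev$Py,
             P = P, loglik = sol$ev$llk, converged = sol$converged,
             n_iter = sol$n_iter, pev = pev, theta_internal = theta)
}

# assemble the fitted-object: BLUPs for all genotypes/plots, PEV, residuals
new_gsreml <- function(t, trait, kinship, spatial, extraneous, vc, boundary,
                       mu, Py, P, loglik, converged, n_iter, pev,
                       theta_internal = vc) {
  n <- nrow(t)
  blup <- list()
  # genotypic BLUP for every genotype in K: g_hat = sigma2_g K Z' P y
  u <- rowsum(Py, group = t$genotype)               # Z' P y by genotype
  g_all <- theta_internal[["g"]] *
    drop(kinship[, rownames(u), drop = FALSE] %*% u)
  names(g_all) <- rownames(kinship)
  blup$g <- g_all
  fitted <- mu + g_all[t$genotype]
  if (!is.null(spatial)) {
    s_all <- theta_internal[["s"]] *
      drop(unclass(spatial)[, t$plot_id, drop = FALSE] %*% Py)
    names(s_all) <- rownames(spatial)
    blup$s <- s_all
    fitted <- fitted + s_all[t$plot_id]
  }
  if (extraneous %in% c("range", "both")) {
    ra <- theta_internal[["range"]] * drop(rowsum(Py, group = t$range))
    names(ra) <- rownames(rowsum(Py, group = t$range))
    blup$range <- ra
    fitted <- fitted + ra[as.character(t$range)]
  }
  if (extraneous %in% c("column", "both")) {
    cl <- theta_internal[["column"]] * drop(rowsum(Py, group = t$column))
    names(cl) <- rownames(rowsum(Py, group = t$column))
    blup$column <- cl
    fitted <- fitted + cl[as.character(t$column)]
  }
  resid <- theta_internal[["residual"]] * Py
  names(fitted) <- names(resid) <- t$plot_id
  pev_g <- NULL
  if (pev && !is.null(P)) {
    M <- kinship[, t$genotype, drop = FALSE]         # K Z' (g_all x n)
    pev_g <- theta_internal[["g"]] * kinship -
      theta_internal[["g"]]^2 * M %*% P %*% t(M)
    dimnames(pev_g) <- dimnames(kinship)
  }
  structure(list(
    mu = mu, varcomp = vc, boundary = boundary, blup = blup,
    loglik = loglik, converged = converged, n_iter = n_iter, n_obs = n,
    fitted = fitted, residuals = resid, pev_g = pev_g,
    trait = trait, extraneous = extraneous,
    spatial_info = if (is.null(spatial)) NULL else
      list(family = attr(spatial, "family"),
           direction = attr(spatial, "direction"),
           param = attr(spatial, "param")),
    train_plots = t$plot_id, genotypes = rownames(kinship)),
    class = "gsreml")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the REML criterion of the model defined by the arguments at a
#' given point of the variance-component space, without any optimization.
#' Used for likelihood profiling and as the objective of brute-force
#' checks of the solver.
#'
#' @inheritParams gsreml
#' @param varcomps named vector with an entry for every component of the
#'   model (`g`, optional `s`/`range`/`column`, `residual`), all `>= 0`
#'   and not all zero.
#' @return the restricted log-likelihood, a single number.
#' @export
reml_loglik <- function(t, trait, kinship = NULL, spatial = NULL,
                        extraneous = c("none", "range", "column", "both"),
                        varcomps) {
  extraneous <- match.arg(extraneous)
  fit <- gsreml(t, trait, kinship = kinship, spatial = spatial,
                extraneous = extraneous, varcomps = varcomps, pev = FALSE)
  fit$loglik
}

#' @export
print.gsreml <- function(x, ...) {
  kind <- if (!is.null(x$spatial_info)) {
    paste0("GS-spatial (", x$spatial_info$family, " ",
           x$spatial_info$direction, ", param ",
           signif(x$spatial_info$param, 4), ")")
  } else "base GBLUP"
  if (x$extraneous != "none")
    kind <- paste0(kind, " + ", x$extraneous, " effect(s)")
  cat("REML fit:", kind, "\n")
  cat("  n =", x$n_obs, "plots,", length(x$blup$g), "genotypes in K\n")
  cat("  mu =", signif(x$mu, 6), "\n  variance components:\n")
  vc <- x$varcomp
  for (nm in names(vc))
    cat(sprintf("    %-9s %.6g%s\n", nm, vc[nm],
                if (x$boundary[nm]) " (boundary)" else ""))
  cat("  restricted logLik =", signif(x$loglik, 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.gsreml <- function(object, ...) {
  h2 <- tryCatch(suppressWarnings(cullis_h2(object)), error = function(e) NA_real_)
  structure(list(fit = object, h2 = h2), class = "summary.gsreml")
}

#' @export
print.summary.gsreml <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$h2))
    cat("  Cullis generalized heritability:", signif(x$h2, 4), "\n")
  invisible(x)
}

#' @export
coef.gsreml <- function(object, ...) c(mu = object$mu)

#' @export
residuals.gsreml <- function(object, ...) object$residuals

#' @export
fitted.gsreml <- function(object, ...) object$fitted

#' @export
logLik.gsreml <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomp) + 1L,
            nobs = object$n_obs, class = "logLik")
}

#' Predict phenotypes at (held-out) plots
#'
#' Computes `yhat = mu + g_hat(genotype) + s_hat(plot) [+ range/column
#' effects]` for the plots of `newdata`. Genotypic BLUPs for genotypes
#' unobserved in training flow through the genomic relationship matrix;
#' the spatial BLUP at a held-out plot is its kriging prediction given the
#' training observations (all plot locations enter the mixed-model
#' equations, with only training rows observed). For a base-model fit the
#' spatial term is absent.
#'
#' @param object a [gsreml] fit.
#' @param newdata a [trial_table], or any data frame with columns
#'   `plot_id`, `genotype`, `range`, `column`, of plots to predict. Every
#'   genotype must be present in the fit's relationship matrix; when the
#'   fit has a spatial component, every plot id must be covered by its
#'   kernel.
#' @param ... unused.
#' @return named numeric vector of predictions, one per plot of `newdata`.
#' @export
predict.gsreml <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("plot_id", "genotype", "range", "column") %in%
                  names(newdata)))
  bad <- setdiff(unique(newdata$genotype), object$genotypes)
  if (length(bad))
    stop("genotype(s) absent from the relationship matrix: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  yhat <- object$mu + object$blup$g[newdata$genotype]
  if (!is.null(object$blup$s)) {
    missing_plot <- setdiff(newdata$plot_id, names(object$blup$s))
    if (length(missing_plot))
      stop("plot(s) not covered by the spatial kernel: ",
           paste(utils::head(missing_plot, 5L), collapse = ", "))
    yhat <- yhat + object$blup$s[newdata$plot_id]
  }
  if (!is.null(object$blup$range)) {
    e <- object$blup$range[as.character(newdata$range)]
    e[is.na(e)] <- 0
    yhat <- yhat + e
  }
  if (!is.null(object$blup$column)) {
    e <- object$blup$column[as.character(newdata$column)]
    e[is.na(e)] <- 0
    yhat <- yhat + e
  }
  stats::setNames(drop(yhat), newdata$plot_id)
}

#' Likelihood-ratio test for added variance components
#'
#' Compares a fitted model against a nested base fit on the same
#' observations: `chi2 = 2 (llk_model - llk_base)`, floored at zero.
#' Because the null value of a variance component lies on the boundary of
#' the parameter space the statistic follows a chi-square mixture
#' `0.5 chi2(0) : 0.5 chi2(df)`; the mixture p-value is reported. The
#' significance decision, however, uses the plain upper-`alpha` chi-square
#' quantile (2.706 for 1 df and 4.605 for 2 df at `alpha = 0.1`), the
#' conservative convention this package standardizes on.
#'
#' @param model,base converged [gsreml] fits on identical observations.
#' @param extra_df number of variance components added by `model`.
#' @param alpha significance level, default 0.1.
#' @return object of class `gsreml_lrt`: `statistic`, `df`, `threshold`,
#'   `significant`, `p_value` (mixture).
#' @export
lrt <- function(model, base, extra_df = 1L, alpha = 0.1) {
  stopifnot(inherits(model, "gsreml"), inherits(base, "gsreml"))
  if (!isTRUE(model$converged) || !isTRUE(base$converged))
    stop("both fits must have converged")
  if (model$n_obs != base$n_obs)
    stop("fits use different numbers of observations (",
         model$n_obs, " vs ", base$n_obs, ")")
  stat <- max(0, 2 * (model$loglik - base$loglik))
  threshold <- stats::qchisq(1 - alpha, df = extra_df)
  p_mix <- 0.5 * stats::pchisq(stat, df = extra_df, lower.tail = FALSE)
  if (stat == 0) p_mix <- 1   # point mass at zero included
  structure(list(statistic = stat, df = as.integer(extra_df),
                 threshold = threshold, significant = stat > threshold,
                 p_value = p_mix, alpha = alpha),
            class = "gsreml_lrt")
}

#' @export
print.gsreml_lrt <- function(x, ...) {
  cat(sprintf(
    "Variance-component LRT: chi2 = %.4f (df = %d), threshold %.3f at alpha = %g -> %s\n",
    x$statistic, x$df, x$threshold, x$alpha,
    if (x$significant) "significant" else "not significant"))
  cat(sprintf("  mixture p-value (0.5 chi2(0) : 0.5 chi2(%d)): %.4g\n",
              x$df, x$p_value))
  invisible(x)
}

#' Cullis generalized heritability
#'
#' `h2 = 1 - Vbar_Delta / (2 sigma2_g)`, where `Vbar_Delta` is the mean
#' over all genotype pairs of the prediction-error variance of the BLUP
#' difference `g_i - g_j`. Valid for unbalanced designs with unreplicated
#' genotypes; reduces to the classical line-mean heritability on balanced
#' replicated designs with identity kinship. The value is returned
#' unclamped, with a warning when it falls outside `[0, 1]`.
#'
#' @param fit a [gsreml] fit with `pev = TRUE` and `sigma2_g > 0`.
#' @return heritability on `[0, 1]` (unclamped), or `NA` with a warning
#'   when the genotypic variance is zero.
#' @export
cullis_h2 <- function(fit) {
  stopifnot(inherits(fit, "gsreml"))
  s2g <- fit$varcomp[["g"]]
  if (!is.finite(s2g) || s2g <= 0) {
    warning("genotypic variance is zero; heritability undefined")
    return(NA_real_)
  }
  if (is.null(fit$pev_g))
    stop("fit was produced with pev = FALSE; refit with pev = TRUE")
  P <- fit$pev_g
  g <- nrow(P)
  trP <- sum(diag(P)); sumP <- sum(P)
  vbar <- 2 * (g * trP - sumP) / (g * (g - 1))
  h2 <- 1 - vbar / (2 * s2g)
  if (h2 < 0 || h2 > 1)
    warning("Cullis heritability outside [0, 1]: ", signif(h2, 4))
  h2
}
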