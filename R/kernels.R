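#' Plot-to-plot distance matrix
#'
#' Center-to-center distances between plots, in meters, built from the
#' (Range, Column) grid indices and the physical plot dimension. The Range
#' component of the distance between two plots is `|delta range| * width_m`
#' and the Column component `|delta column| * length_m`; the isotropic
#' distance is the hypotenuse of the two. Directional matrices use only
#' their own component, so a Range-directional distance is zero between any
#' two plots in the same Range.
#'
#' @param t a [trial_table] (only coordinates and plot ids are used).
#' @param dim a [plot_dim].
#' @param direction `"isotropic"`, `"range"` or `"column"`.
#' @return a symmetric n x n matrix of class `plot_dist` with plot ids as
#'   dimnames and the direction stored as an attribute.
#' @export
plot_dist <- function(t, dim, direction = c("isotropic", "range", "column")) {
  stopifnot(inherits(t, "trial_table"), inherits(dim, "plot_dim"))
  direction <- match.arg(direction)
  dr <- abs(outer(t$range, t$range, "-")) * dim$width_m
  dc <- abs(outer(t$column, t$column, "-")) * dim$length_m
  D <- switch(direction,
              isotropic = sqrt(dr^2 + dc^2),
              range = dr,
              column = dc)
  dimnames(D) <- list(t$plot_id, t$plot_id)
  structure(D, direction = direction, class = c("plot_dist", "matrix", "array"))
}

#' Parametric spatial correlation kernel
#'
#' Applies one of three random-field correlation structures entrywise to a
#' distance matrix:
#' \describe{
#'   \item{power}{`theta^D` with `0 < theta < 1`; the generalization of the
#'     AR(1) structure to unequally spaced plots (on a unit-spaced transect
#'     it *is* AR(1) with `rho = theta`).}
#'   \item{gaussian}{`exp(-D^2 / phi^2)` with `phi > 0`; slow initial decay
#'     followed by rapid drop-off.}
#'   \item{spherical}{`1 - 1.5 (D/phi) + 0.5 (D/phi)^3` for `D <= phi`, and
#'     exactly 0 beyond the standardizing parameter `phi`.}
#' }
#' Larger standardizing parameters mean slower decay of correlation with
#' distance. Directional kernels repeat values across plots sharing a Range
#' or Column and can be numerically rank-deficient, so every kernel is
#' passed through a positive-semidefiniteness check: if the smallest
#' eigenvalue is below `-1e-8`, jitter `delta = |lambda_min| + 1e-8` is
#' added to the diagonal and the matrix rescaled back to unit diagonal.
#'
#' @param d a [plot_dist] matrix.
#' @param family `"power"`, `"gaussian"` or `"spherical"`.
#' @param param the standardizing parameter (`theta` for power in (0,1);
#'   `phi > 0` otherwise).
#' @return an object of class `spatial_kernel`: the n x n correlation
#'   matrix with `family`, `direction` and `param` attributes.
#' @export
spatial_kernel <- function(d, family = c("power", "gaussian", "spherical"),
                           param) {
  stopifnot(inherits(d, "plot_dist"))
  family <- match.arg(family)
  stopifnot(is.numeric(param), length(param) == 1L, is.finite(param))
  if (family == "power") {
    if (param <= 0 || param >= 1)
      stop("power standardizing parameter theta must lie strictly in (0, 1)")
  } else if (param <= 0) {
    stop(family, " standardizing parameter phi must be > 0")
  }
  D <- unclass(d)
  S <- switch(family,
    power = param^D,
    gaussian = exp(-(D^2) / param^2),
    spherical = {
      x <- D / param
      out <- 1 - 1.5 * x + 0.5 * x^3
      out[D > param] <- 0
      out
    })
  diag(S) <- 1
  S <- repair_psd(S)
  structure(S, family = family, direction = attr(d, "direction"),
            param = param, class = c("spatial_kernel", "matrix", "array"))
}

# add jitter and renormalize to unit diagonal when lambda_min < -1e-8
repair_psd <- function(S, tol = 1e-8) {
  lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < -tol) {
    delta <- abs(lmin) + tol
    S <- (S + diag(delta, nrow(S))) / (1 + delta)
  }
  S
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat("Spatial kernel: ", attr(x, "family"), " (", attr(x, "direction"),
      "), parameter ", attr(x, "param"), ", ", nrow(x), " plots\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix (Method 1)
#'
#' Additive relationship matrix from biallelic SNP dosages: markers with
#' minor allele frequency at or below `maf_min` are removed, missing
#' dosages are mean-imputed per marker, dosages are centered by twice the
#' allele frequency, and
#' `K = W W' / (2 * sum_j p_j (1 - p_j))`
#' where `W` is the centered dosage matrix. Under a panel near
#' Hardy--Weinberg equilibrium the mean diagonal of `K` approaches 1.
#'
#' @param m genotype x marker dosage matrix (values 0/1/2, `NA` allowed)
#'   with genotype rownames, e.g. from [read_markers].
#' @param maf_min minor-allele-frequency threshold; markers are kept only
#'   when MAF is strictly greater, default 0.01.
#' @return genotype x genotype relationship matrix with dimnames.
#' @export
vanraden_kinship <- function(m, maf_min = 0.01) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m))) stop("dosage matrix must carry genotype rownames")
  p <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(maf) & maf > maf_min
  if (!any(keep))
    stop("no marker passes the MAF > ", maf_min, " filter")
  m <- m[, keep, drop = FALSE]
  p <- p[keep]
  # per-marker mean imputation of missing dosages
  if (anyNA(m)) {
    for (j in which(colSums(is.na(m)) > 0L))
      m[is.na(m[, j]), j] <- 2 * p[j]
  }
  W <- sweep(m, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(m), rownames(m))
  K
}

#' Default standardizing-parameter grid for a kernel family
#'
#' The exploratory model search evaluates each kernel family over a grid of
#' standardizing parameters. For the power family the grid is
#' `0.1, 0.2, ..., 0.9`; for gaussian and spherical it is `n` values
#' log-spaced between the smallest nonzero and the largest distance in the
#' field, so the grid adapts to the field extent. A user-supplied grid
#' always overrides the default.
#'
#' @param family kernel family.
#' @param d a [plot_dist] matrix (used only for gaussian/spherical).
#' @param n grid size for gaussian/spherical, default 10.
#' @return numeric vector of parameter values.
#' @export
parameter_grid <- function(family = c("power", "gaussian", "spherical"),
                           d = NULL, n = 10L) {
  family <- match.arg(family)
  if (family == "power") return(seq(0.1, 0.9, by = 0.1))
  stopifnot(inherits(d, "plot_dist"))
  pos <- d[d > 0]
  if (!length(pos)) stop("distance matrix has no nonzero entries")
  lo <- min(pos); hi <- max(pos)
  if (hi <= lo) return(rep(lo, 1L))
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Write a kernel or relationship matrix as delimited text
#'
#' @param x a matrix with dimnames (spatial kernel, distance or kinship).
#' @param path output file path.
#' @param sep separator, default comma.
#' @export
write_kernel <- function(x, path, sep = ",") {
  utils::write.table(as.matrix(unclass(x)), path, sep = sep,
                     col.names = NA, quote = FALSE)
  invisible(path)
}
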