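# fixtures built in code; all randomness is locally seeded

# balanced trial: g genotypes x r reps on a grid, K = identity implied
balanced_trial <- function(g = 20L, r = 2L, s2g = 2, s2r = 1, seed = 42L) {
  withr_seed(seed)
  geno <- rep(sprintf("g%02d", seq_len(g)), each = r)
  gv <- rnorm(g, sd = sqrt(s2g))
  y <- gv[rep(seq_len(g), each = r)] + rnorm(g * r, sd = sqrt(s2r))
  trial_table(data.frame(
    plot_id = paste0("p", seq_len(g * r)),
    range = rep(seq_len(g), each = r), column = rep(seq_len(r), g),
    genotype = geno, y = y, stringsAsFactors = FALSE), traits = "y")
}

# small rectangular layout with a few replicated checks
small_layout <- function(n_test = 100L, n_checks = 4L, check_reps = 5L,
                         n_columns = 12L) {
  default_layout(n_test = n_test, n_checks = n_checks,
                 check_reps = check_reps, n_columns = n_columns)
}

# phenotype with genotypic + residual effects only (no spatial trend)
null_phenotype <- function(layout, s2g = 1, s2r = 1, seed = 1L) {
  withr_seed(seed)
  genos <- unique(layout$genotype)
  g <- stats::setNames(rnorm(length(genos), sd = sqrt(s2g)), genos)
  d <- as.data.frame(layout)
  d$y <- g[d$genotype] + rnorm(nrow(d), sd = sqrt(s2r))
  out <- trial_table(d, traits = "y")
  attr(out, "plot_dim") <- attr(layout, "plot_dim")
  attr(out, "true_g") <- g
  out
}

# identity kinship over a set of genotype labels
identity_kinship <- function(genotypes) {
  genotypes <- sort(unique(genotypes))
  K <- diag(length(genotypes))
  dimnames(K) <- list(genotypes, genotypes)
  K
}

# set.seed without leaking state into other tests
withr_seed <- function(seed) {
  set.seed(seed)
}

# trial generated under the GBLUP model: marker-derived kinship and
# genotypic values built from the same markers, so held-out genotypes are
# predictable through K
gblup_trial <- function(layout, n_markers = 300L, h2 = 0.6, seed = 1L) {
  withr_seed(seed)
  genos <- unique(layout$genotype)
  p <- runif(n_markers, 0.2, 0.8)
  M <- sapply(p, function(pj) rbinom(length(genos), 2, pj))
  rownames(M) <- genos
  K <- vanraden_kinship(M)
  a <- rnorm(n_markers)
  g <- drop(scale(M %*% a)) * sqrt(h2)
  names(g) <- genos
  d <- as.data.frame(layout)
  d$y <- g[d$genotype] + rnorm(nrow(d), sd = sqrt(1 - h2))
  t <- trial_table(d, traits = "y")
  attr(t, "plot_dim") <- attr(layout, "plot_dim")
  list(trial = t, K = K, true_g = g)
}

# a minimal object carrying residuals, enough for remove_outliers()
fake_base_fit <- function(residuals, plot_ids) {
  structure(list(residuals = stats::setNames(residuals, plot_ids)),
            class = "gsreml")
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
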