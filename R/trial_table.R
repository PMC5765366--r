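#' Construct a field-trial table
#'
#' A trial table holds one row per field plot with its Range index (the
#' North--South partition of the field), Column index (East--West), genotype
#' identifier, a check flag and one or more trait columns. It is the input
#' to all model fitting and selection functions in this package.
#'
#' @param data a data frame with columns `plot_id`, `range`, `column`,
#'   `genotype`, `is_check` and one column per trait.
#' @param traits character vector naming the trait columns of `data`.
#' @return a `trial_table`: a data frame with a `traits` attribute.
#' @details Invariants enforced: `(range, column)` pairs are unique, all
#'   non-missing trait values are finite, and at least two distinct
#'   genotypes are present. Coordinates are kept as the 1-based integers of
#'   the field layout; serpentine plot ordering carries no information once
#'   the coordinates are known and is not interpreted.
#' @export
trial_table <- function(data, traits) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("plot_id", "range", "column", "genotype")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$is_check)) data$is_check <- FALSE
  if (missing(traits) || is.null(traits))
    traits <- setdiff(names(data), c(req, "is_check"))
  bad <- setdiff(traits, names(data))
  if (length(bad))
    stop("unknown trait column(s): ", paste(bad, collapse = ", "))
  data$plot_id  <- as.character(data$plot_id)
  data$genotype <- as.character(data$genotype)
  data$range    <- as.integer(data$range)
  data$column   <- as.integer(data$column)
  data$is_check <- as.logical(data$is_check)
  if (anyNA(data$range) || anyNA(data$column))
    stop("Range/Column indices must be non-missing integers")
  if (any(data$range < 1L) || any(data$column < 1L))
    stop("Range/Column indices must be positive (1-based)")
  key <- paste(data$range, data$column, sep = ":")
  if (anyDuplicated(key)) {
    dup <- data$plot_id[key %in% key[duplicated(key)]]
    stop("duplicate (Range, Column) coordinates for plots: ",
         paste(dup, collapse = ", "))
  }
  if (anyDuplicated(data$plot_id))
    stop("duplicate plot identifiers")
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      data[[tr]] <- v
    }
    if (any(!is.na(v) & !is.finite(v)))
      stop("non-finite values in trait '", tr, "'")
  }
  if (length(unique(data$genotype)) < 2L)
    stop("a trial table needs at least two distinct genotypes")
  rownames(data) <- NULL
  structure(data, traits = traits,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Field-trial table: ", nrow(x), " plots, ",
      length(unique(x$genotype)), " genotypes (",
      sum(x$is_check), " check plots)\n", sep = "")
  cat("Layout: Ranges 1..", max(x$range), " x Columns 1..", max(x$column),
      "; traits: ", paste(attr(x, "traits"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Traits stored in a trial table
#' @param t a [trial_table].
#' @return character vector of trait column names.
#' @export
traits <- function(t) attr(t, "traits")

# rebuild the class/attributes after row subsetting
restitch <- function(data, template) {
  trial_table(as.data.frame(data), traits = attr(template, "traits"))
}

#' Plot dimension
#'
#' Physical size of a plot in meters, expressed as length x width. Length
#' runs along the Column direction (East--West) and width along the Range
#' direction (North--South), so the center-to-center distance between two
#' adjacent Ranges is `width_m` and between two adjacent Columns is
#' `length_m`. Field layouts in which plots share their longer edge across
#' Ranges therefore put adjacent Ranges closer together than adjacent
#' Columns.
#'
#' @param length_m plot extent along the Column direction, meters.
#' @param width_m plot extent along the Range direction, meters.
#' @return an object of class `plot_dim`.
#' @export
plot_dim <- function(length_m, width_m) {
  stopifnot(is.numeric(length_m), is.numeric(width_m),
            length(length_m) == 1L, length(width_m) == 1L)
  if (!is.finite(length_m) || !is.finite(width_m) ||
      length_m <= 0 || width_m <= 0)
    stop("plot dimensions must be strictly positive")
  structure(list(length_m = length_m, width_m = width_m),
            class = "plot_dim")
}

#' @export
print.plot_dim <- function(x, ...) {
  cat("Plot dimension: ", x$length_m, " x ", x$width_m,
      " m (length x width)\n", sep = "")
  invisible(x)
}

#' Read a field-trial table from delimited text
#'
#' Reads a per-plot CSV (or other delimited) file with field coordinates,
#' genotype labels and trait values, and validates it into a [trial_table].
#' Rows with missing Range or Column are dropped with a message; missing
#' trait values (empty or `NA`) are kept as `NA`.
#'
#' @param path path to the delimited file.
#' @param traits character vector of trait column names in the file; by
#'   default every column not used for coordinates/identifiers.
#' @param genotype,range,column,plot_id,check names of the corresponding
#'   columns in the file. `plot_id` and `check` may be `NULL`: plot ids then
#'   default to `"R<range>C<column>"` and no plot is a check.
#' @param sep field separator, default comma.
#' @return a [trial_table].
#' @export
read_trial <- function(path, traits = NULL,
                       genotype = "genotype", range = "range",
                       column = "column", plot_id = NULL, check = NULL,
                       sep = ",") {
  if (!file.exists(path)) stop("trial file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  need <- c(genotype, range, column, plot_id, check, traits)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("column(s) not present in ", path, ": ", paste(miss, collapse = ", "))
  keep <- !(is.na(raw[[range]]) | is.na(raw[[column]]))
  if (any(!keep))
    message("dropping ", sum(!keep), " row(s) with missing coordinates")
  raw <- raw[keep, , drop = FALSE]
  d <- data.frame(
    plot_id = if (is.null(plot_id))
      paste0("R", raw[[range]], "C", raw[[column]]) else as.character(raw[[plot_id]]),
    range = raw[[range]], column = raw[[column]],
    genotype = raw[[genotype]],
    is_check = if (is.null(check)) FALSE else as.logical(raw[[check]]),
    stringsAsFactors = FALSE)
  if (is.null(traits))
    traits <- setdiff(names(raw), c(genotype, range, column, plot_id, check))
  for (tr in traits) d[[tr]] <- suppressWarnings(as.numeric(raw[[tr]]))
  trial_table(d, traits = traits)
}

#' Read a SNP dosage matrix from delimited text
#'
#' First column genotype identifier, remaining columns biallelic marker
#' dosages coded 0/1/2 (missing allowed).
#'
#' @param path path to the delimited file.
#' @param sep field separator, default comma.
#' @return a numeric genotype x marker matrix with genotype rownames.
#' @export
read_markers <- function(path, sep = ",") {
  if (!file.exists(path)) stop("marker file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicate genotype identifiers in ", path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) stop("marker dosages must be 0, 1, 2 or missing")
  rownames(m) <- ids
  m
}

#' Drop plots with a missing trait value
#'
#' Restricts a trial to the plots carrying a finite observation for one
#' trait, the first preprocessing step before fitting that trait.
#'
#' @param t a [trial_table].
#' @param trait trait name.
#' @return the filtered [trial_table].
#' @export
drop_missing_for_trait <- function(t, trait) {
  stopifnot(inherits(t, "trial_table"))
  if (!trait %in% traits(t)) stop("unknown trait: ", trait)
  keep <- is.finite(t[[trait]])
  if (!any(keep)) stop("all values of trait '", trait, "' are missing")
  if (all(keep)) return(t)
  restitch(t[keep, , drop = FALSE], t)
}

#' Keep plots whose genotype has genomic information
#'
#' Removes plots whose genotype is absent from the relationship matrix and
#' reports how many were dropped.
#'
#' @param t a [trial_table].
#' @param K a genomic relationship matrix with genotype dimnames (see
#'   [vanraden_kinship]).
#' @return the filtered [trial_table] with attribute `n_unmatched` giving
#'   the number of removed plots.
#' @export
match_genotypes <- function(t, K) {
  stopifnot(inherits(t, "trial_table"))
  ids <- rownames(K)
  if (is.null(ids)) stop("relationship matrix must carry genotype dimnames")
  keep <- t$genotype %in% ids
  if (!any(keep)) stop("no genotype of the trial is present in the relationship matrix")
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " plot(s) removed: genotype not in relationship matrix")
  out <- if (removed > 0) restitch(t[keep, , drop = FALSE], t) else t
  attr(out, "n_unmatched") <- removed
  out
}

#' Remove outlier plots after a base-model fit
#'
#' Drops, in a single pass, every plot whose base-model residual exceeds
#' `c_sd` times the sample standard deviation of the residuals (strict
#' inequality). Outlying observations can distort the apparent spatial
#' dependency of a field, so they are screened with the no-spatial base
#' model before any spatial structure is entertained.
#'
#' @param t the [trial_table] the base model was fitted on.
#' @param trait trait name the fit used.
#' @param base_fit a [gsreml] fit of the base model on `t`.
#' @param c_sd threshold multiplier, default 2.5.
#' @return the filtered [trial_table] with attribute `n_outliers`.
#' @export
remove_outliers <- function(t, trait, base_fit, c_sd = 2.5) {
  stopifnot(inherits(t, "trial_table"), inherits(base_fit, "gsreml"))
  r <- stats::residuals(base_fit)
  if (length(r) != nrow(t) || !all(names(r) == t$plot_id))
    stop("base_fit was not produced on this trial table")
  s <- stats::sd(r)
  drop <- if (is.finite(s) && s > 0) abs(r) > c_sd * s else rep(FALSE, length(r))
  if (all(drop)) stop("outlier rule removed every plot")
  out <- if (any(drop)) restitch(t[!drop, , drop = FALSE], t) else t
  attr(out, "n_outliers") <- sum(drop)
  out
}
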