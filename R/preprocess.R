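#' Filter proteins by detection across conditions
#'
#' Keeps proteins with at least `min_valid` observed (non-missing) values in
#' at least one condition. With `min_valid = 1` this is the loose "detected
#' in at least one category" rule; with `min_valid` equal to the replicate
#' count it requires a complete triplicate in some condition. Per-condition
#' identification counts (proteins with >= `min_valid` observed values in
#' that condition) are attached as attribute `"id_counts"` for the
#' identification accounting.
#'
#' The filter is idempotent: applying it twice with the same rule changes
#' nothing.
#'
#' @param x an [lfq_matrix] at stage `raw` or `log2`.
#' @param design a [sample_design] covering the matrix columns.
#' @param min_valid minimum observed values required within a single
#'   condition (default 3).
#' @return the filtered [lfq_matrix], with attribute `id_counts` (named
#'   integer vector per condition).
#' @export
filter_detected <- function(x, design, min_valid = 3) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (!x$stage %in% c("raw", "log2"))
    stop_config("filter_detected expects a raw or log2 stage matrix, got '",
                x$stage, "'")
  design <- align_design(x, design)
  min_valid <- as.integer(min_valid)
  if (min_valid < 1) stop_config("min_valid must be >= 1")
  reps <- table(design$condition)
  if (any(min_valid > reps))
    stop_config("min_valid (", min_valid, ") exceeds the replicate count of ",
                "condition(s): ",
                paste(names(reps)[reps < min_valid], collapse = ", "))
  counts <- valid_counts(x, design)
  keep <- apply(counts >= min_valid, 1L, any)
  out <- lfq_subset(x, keep)
  attr(out, "id_counts") <- colSums(counts >= min_valid)
  out
}

# proteins x conditions matrix of observed-value counts
valid_counts <- function(x, design) {
  obs <- !is.na(x$values)
  conds <- levels(design$condition)
  counts <- vapply(conds, function(cc) {
    rowSums(obs[, design$condition == cc, drop = FALSE])
  }, numeric(nrow(obs)))
  if (nrow(obs) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(rownames(obs), conds))
  counts
}

#' Log2-transform raw intensities
#'
#' Replaces every observed intensity by its base-2 logarithm; the missing
#' mask is unchanged. Zeros must already have been coerced to missing (the
#' reader does this for raw tables); a zero or negative observed value is a
#' data error naming the offending cell.
#'
#' @param x an [lfq_matrix] at stage `raw`.
#' @return an [lfq_matrix] at stage `log2`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$stage != "raw")
    stop_config("log2_transform expects a raw stage matrix, got '", x$stage, "'")
  bad <- which(!is.na(x$values) & x$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_data("non-positive observed value at protein '",
              rownames(x$values)[bad[1, 1]], "', sample '",
              colnames(x$values)[bad[1, 2]], "'")
  out <- x
  out$values <- log2(x$values)
  out$stage <- "log2"
  out
}

#' Impute missing values from a downshifted Gaussian
#'
#' Replaces each missing cell by a draw from
#' `Normal(mean_ref - downshift * sd_ref, (width * sd_ref)^2)`, where
#' `mean_ref` and `sd_ref` are the mean and sample standard deviation
#' (`n - 1` denominator) of the *observed* log2 values in the cell's
#' reference scope: its sample column under `scope = "per_sample"` (the
#' convention for this parameterization) or the whole matrix under
#' `scope = "global"`. This emulates the missing-not-at-random mechanism of
#' label-free data, where missingness is caused by low abundance: imputed
#' values land in the left tail of the observed distribution.
#'
#' Observed cells are never altered. Missing cells are imputed in row-major
#' order from a single generator seeded once, so a fixed seed reproduces the
#' imputation exactly.
#'
#' @param x an [lfq_matrix] at stage `log2`.
#' @param width spread of the imputation distribution as a fraction of the
#'   reference standard deviation (default 0.3).
#' @param downshift left shift of its mean in units of the reference standard
#'   deviation (default 1.8).
#' @param scope `"per_sample"` (default) or `"global"`.
#' @param seed integer seed, or `NULL` to use the current generator state.
#' @return an [lfq_matrix] at stage `imputed` with an empty missing mask.
#' @export
impute_mnar <- function(x, width = 0.3, downshift = 1.8,
                        scope = c("per_sample", "global"), seed = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$stage != "log2")
    stop_config("impute_mnar expects a log2 stage matrix, got '", x$stage, "'")
  if (width <= 0) stop_config("width must be > 0")
  if (downshift < 0) stop_config("downshift must be >= 0")
  scope <- match.arg(scope)
  v <- x$values
  out <- x
  out$stage <- "imputed"
  if (!anyNA(v)) { # nothing to do; output identical to input
    out$values <- v
    return(out)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (scope == "global") {
    obs <- v[!is.na(v)]
    if (length(obs) < 2) stop_data("fewer than 2 observed values in the matrix")
    mu <- rep(mean(obs), ncol(v))
    sd_ref <- rep(stats::sd(obs), ncol(v))
  } else {
    n_obs <- colSums(!is.na(v))
    short <- colnames(v)[n_obs < 2]
    if (length(short))
      stop_data("sample column(s) with fewer than 2 observed values: ",
                paste(short, collapse = ", "))
    mu <- colMeans(v, na.rm = TRUE)
    sd_ref <- apply(v, 2L, stats::sd, na.rm = TRUE)
  }

  # row-major traversal: work on the transpose so column-major indexing of
  # t(v) enumerates the original matrix row by row
  tv <- t(v)
  miss <- which(is.na(tv))
  sample_idx <- ((miss - 1L) %% nrow(tv)) + 1L
  z <- stats::rnorm(length(miss))
  tv[miss] <- mu[sample_idx] - downshift * sd_ref[sample_idx] +
    width * sd_ref[sample_idx] * z
  out$values <- t(tv)
  out
}
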