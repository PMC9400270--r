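#' Asymmetric quartile width-adjustment normalization
#'
#' For each scope (a protein row by default), computes the first, second and
#' third quartiles (q1, q2, q3; linear-interpolation "type 7" convention),
#' subtracts the median q2 from every value, then divides positive residuals
#' by `q3 - q2` and negative residuals by `q2 - q1`. Zeros stay zero. A
#' non-degenerate scope therefore ends up with quartiles exactly
#' (-1, 0, +1): the two halves of the distribution are rescaled to equal
#' width, which removes per-protein location and asymmetric spread before
#' differential testing.
#'
#' If a side has zero width (`q3 == q2` or `q2 == q1`, e.g. heavily tied
#' values), that side's scale factor is set to 1 after median subtraction and
#' a warning names the affected scope; a fully constant scope maps to all
#' zeros.
#'
#' @param x an [lfq_matrix] at stage `imputed` (no missing cells).
#' @param scope `"protein"` (default; normalize each row over all its
#'   samples) or `"sample"` (normalize each column).
#' @return an [lfq_matrix] at stage `normalized`.
#' @export
width_adjust <- function(x, scope = c("protein", "sample")) {
  stopifnot(inherits(x, "lfq_matrix"))
  scope <- match.arg(scope)
  if (anyNA(x$values))
    stop_config("width_adjust requires a matrix without missing cells ",
                "(impute first)")
  v <- if (scope == "protein") x$values else t(x$values)
  adj <- t(apply(v, 1L, width_adjust_vec))
  degen <- rownames(v)[attr_degenerate(v)]
  if (length(degen))
    warning("degenerate quartile width in ", scope, " scope(s): ",
            paste(utils::head(degen, 5L), collapse = ", "),
            if (length(degen) > 5L) sprintf(" (and %d more)", length(degen) - 5L))
  out <- x
  out$values <- if (scope == "protein") adj else t(adj)
  dimnames(out$values) <- dimnames(x$values)
  out$stage <- "normalized"
  out
}

width_adjust_vec <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  centered <- v - q[2]
  up <- q[3] - q[2]
  dn <- q[2] - q[1]
  if (up <= 0) up <- 1
  if (dn <= 0) dn <- 1
  ifelse(centered > 0, centered / up, centered / dn)
}

attr_degenerate <- function(v) {
  qs <- t(apply(v, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE, type = 7))
  which(qs[, 3] - qs[, 2] <= 0 | qs[, 2] - qs[, 1] <= 0)
}

#' Row standardization (z-scoring)
#'
#' Centers each protein row to mean 0 and scales it to sample standard
#' deviation 1 — the display transform behind per-condition average
#' abundances in candidate tables, where the printed per-condition means of
#' a protein sum to zero. Constant rows map to all zeros with a warning.
#'
#' Idempotent: standardizing a standardized matrix changes nothing.
#'
#' @param x an [lfq_matrix] without missing cells.
#' @return an [lfq_matrix] at stage `standardized`.
#' @export
standardize_rows <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (anyNA(x$values))
    stop_config("standardize_rows requires a matrix without missing cells")
  v <- x$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  const <- sdv <= 0 | !is.finite(sdv)
  if (any(const)) {
    warning("constant row(s) standardized to zero: ",
            paste(utils::head(rownames(v)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) sprintf(" (and %d more)", sum(const) - 5L))
    sdv[const] <- 1
  }
  out <- x
  out$values <- (v - mu) / sdv
  out$values[const, ] <- 0
  out$stage <- "standardized"
  out
}

#' Pairwise replicate Pearson correlations
#'
#' Computes the Pearson correlation between every pair of sample columns on
#' observed values (pairwise-complete), the numerical content of the
#' multiscatter replicate-quality plots: within-condition replicates of a
#' well-behaved LFQ experiment correlate around 0.7-1. Zero-variance columns
#' yield `NA` correlations and are named in a warning rather than silently
#' reported as 0.
#'
#' @param x an [lfq_matrix] with at least 3 proteins.
#' @param design optional [sample_design]; when supplied, the result gains
#'   `condition_1`/`condition_2` columns for grouping.
#' @return a data frame with one row per ordered sample pair: `sample_1`,
#'   `sample_2`, `r`, and condition labels when a design is given. The full
#'   correlation matrix (symmetric, unit diagonal) is attached as attribute
#'   `"matrix"`.
#' @export
replicate_correlation <- function(x, design = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (nrow(x$values) < 3)
    stop_config("replicate_correlation needs at least 3 proteins")
  v <- x$values
  sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
  flat <- colnames(v)[!is.na(sds) & sds == 0]
  if (length(flat))
    warning("zero-variance sample column(s), correlations undefined: ",
            paste(flat, collapse = ", "))
  cm <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                    method = "pearson"))
  diag(cm) <- 1
  pairs <- expand.grid(sample_1 = colnames(v), sample_2 = colnames(v),
                       stringsAsFactors = FALSE)
  res <- data.frame(pairs, r = as.vector(cm), stringsAsFactors = FALSE)
  if (!is.null(design)) {
    design <- align_design(x, design)
    res$condition_1 <- as.character(design$condition[match(res$sample_1, design$sample)])
    res$condition_2 <- as.character(design$condition[match(res$sample_2, design$sample)])
  }
  attr(res, "matrix") <- cm
  res
}
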