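#' Per-protein one-way ANOVA across conditions
#'
#' Computes, for every protein row, the classical fixed-effects one-way
#' F statistic across the design's conditions with degrees of freedom
#' (k - 1, N - k), the upper-tail p-value from the F distribution, and
#' Benjamini-Hochberg adjusted q-values over all tested proteins. A protein
#' is flagged significant when `q < alpha`.
#'
#' Degenerate rows are handled explicitly: zero within-group variance with
#' zero between-group variance gives F = 0, p = 1; zero within-group
#' variance with non-zero between-group variance gives p = 0 and is flagged
#' in the `degenerate` column.
#'
#' The computation is vectorized over the whole matrix (explicit sums of
#' squares); it matches `oneway.test(var.equal = TRUE)` row by row.
#'
#' @param x an [lfq_matrix] without missing cells (normally the
#'   width-adjusted stage).
#' @param design a [sample_design] with >= 2 conditions and >= 2 replicates
#'   each.
#' @param alpha significance level on the q-value (default 0.05).
#' @return a data frame of class `evlfq_diff`: `protein_id`, `gene_symbol`,
#'   one `mean_<condition>` column per condition, `F`, `p`, `q`,
#'   `significant`, `degenerate`. Degrees of freedom are attached as
#'   attribute `"df"`.
#' @export
anova_oneway <- function(x, design, alpha = 0.05) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (anyNA(x$values))
    stop_config("anova_oneway requires a matrix without missing cells")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  design <- align_design(x, design)
  reps <- table(design$condition)
  if (any(reps < 2))
    stop_config("condition(s) with fewer than 2 replicates: ",
                paste(names(reps)[reps < 2], collapse = ", "))
  v <- x$values
  conds <- levels(design$condition)
  k <- length(conds)
  N <- ncol(v)

  group_means <- vapply(conds, function(cc) {
    rowMeans(v[, design$condition == cc, drop = FALSE])
  }, numeric(nrow(v)))
  if (nrow(v) == 1L)
    group_means <- matrix(group_means, 1L, k, dimnames = list(rownames(v), conds))
  n_c <- as.numeric(reps[conds])
  grand <- as.vector(group_means %*% n_c) / N

  ssb <- rowSums(sweep(sweep(group_means, 1L, grand)^2, 2L, n_c, "*"))
  fitted <- group_means[, match(design$condition, conds), drop = FALSE]
  ssw <- rowSums((v - fitted)^2)

  df1 <- k - 1
  df2 <- N - k
  eps <- 1e-300
  degenerate <- ssw <= eps & ssb > eps
  Fstat <- ifelse(ssw <= eps,
                  ifelse(ssb <= eps, 0, Inf),
                  (ssb / df1) / (ssw / df2))
  p <- ifelse(is.infinite(Fstat), 0,
              ifelse(ssw <= eps & ssb <= eps, 1,
                     stats::pf(Fstat, df1, df2, lower.tail = FALSE)))
  q <- bh_adjust(p)

  res <- data.frame(protein_id = x$proteins$protein_id,
                    gene_symbol = x$proteins$gene_symbol,
                    stringsAsFactors = FALSE)
  gm <- as.data.frame(group_means)
  names(gm) <- paste0("mean_", conds)
  res <- cbind(res, gm)
  res$F <- Fstat
  res$p <- p
  res$q <- q
  res$significant <- q < alpha
  res$degenerate <- degenerate
  rownames(res) <- NULL
  attr(res, "df") <- c(df1 = df1, df2 = df2)
  attr(res, "alpha") <- alpha
  class(res) <- c("evlfq_diff", "data.frame")
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted p-values (q-values), capped at 1 and monotone
#' non-decreasing in p-rank; values follow their p's under any permutation
#' of the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_config("p-values must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_config("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}
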