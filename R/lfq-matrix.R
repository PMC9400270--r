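#' Construct an LFQ abundance matrix
#'
#' The central container of the package: a protein-by-sample quantification
#' grid with per-protein annotation and a processing-stage tag. Missing
#' (unquantified) cells are stored as `NA`; the missing mask is therefore
#' `is.na()` of the value grid. Stages track the pipeline:
#' `raw` (linear-scale intensities), `log2`, `imputed`, `normalized`
#' (width-adjusted), `standardized` (row z-scored).
#'
#' @param values numeric matrix, proteins in rows and samples in columns.
#'   `NA` marks a missing (not quantified) cell.
#' @param proteins data frame with columns `protein_id` (unique, non-empty),
#'   `gene_symbol` and `description`; one row per matrix row. If `NULL`,
#'   annotation is derived from the matrix row names.
#' @param stage processing stage tag, one of `"raw"`, `"log2"`, `"imputed"`,
#'   `"normalized"`, `"standardized"`.
#' @return an object of class `lfq_matrix`: a list with elements `values`,
#'   `proteins` and `stage`.
#' @examples
#' m <- lfq_matrix(matrix(2^rnorm(12, 25), 4, 3,
#'                        dimnames = list(paste0("P", 1:4), paste0("S", 1:3))))
#' m
#' @export
lfq_matrix <- function(values, proteins = NULL, stage = "raw") {
  stage <- match.arg(stage, lfq_stages())
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("protein", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = rownames(values),
                           gene_symbol = rownames(values),
                           description = "",
                           stringsAsFactors = FALSE)
  }
  needed <- c("protein_id", "gene_symbol", "description")
  missing_cols <- setdiff(needed, names(proteins))
  if (length(missing_cols))
    stop_format("protein annotation lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  proteins <- as.data.frame(proteins)[, needed]
  if (nrow(proteins) != nrow(values))
    stop_consistency("annotation has ", nrow(proteins),
                     " rows but the matrix has ", nrow(values))
  dup <- unique(proteins$protein_id[duplicated(proteins$protein_id)])
  if (length(dup))
    stop_format("duplicate protein ids: ", paste(dup, collapse = ", "))
  rownames(values) <- proteins$protein_id
  rownames(proteins) <- NULL
  obj <- structure(list(values = values, proteins = proteins, stage = stage),
                   class = "lfq_matrix")
  validate_lfq_matrix(obj)
  obj
}

lfq_stages <- function() c("raw", "log2", "imputed", "normalized", "standardized")

validate_lfq_matrix <- function(x) {
  v <- x$values
  obs <- v[!is.na(v)]
  if (any(!is.finite(obs)))
    stop_data("non-finite observed values in ", x$stage, "-stage matrix")
  if (x$stage == "raw" && any(obs < 0))
    stop_data("negative raw intensities are not allowed")
  if (x$stage %in% c("imputed", "normalized", "standardized") && anyNA(v))
    stop_data(x$stage, "-stage matrix must not contain missing cells")
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Missing-value mask of an LFQ matrix
#'
#' @param x an [lfq_matrix].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  is.na(x$values)
}

#' @export
print.lfq_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<lfq_matrix> %d proteins x %d samples, stage '%s', %d missing cell%s (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$stage, n_miss,
              if (n_miss == 1) "" else "s",
              100 * n_miss / length(x$values)))
  invisible(x)
}

# Subset rows of a matrix, keeping annotation in step.
lfq_subset <- function(x, keep) {
  v <- x$values[keep, , drop = FALSE]
  out <- x
  out$values <- v
  out$proteins <- x$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  out
}

#' Construct a sample design
#'
#' Maps sample columns to condition labels and replicate indices. The design
#' defines the multi-group layout for detection filtering, per-condition
#' identification sets and the one-way ANOVA.
#'
#' @param sample character vector of sample ids (must match matrix columns).
#' @param condition condition label per sample; the factor level order (or
#'   first-appearance order for character input) is preserved throughout.
#' @param replicate optional 1-based replicate index per sample; assigned in
#'   input order within each condition when absent.
#' @return a data frame of class `sample_design` with columns `sample`,
#'   `condition` (factor) and `replicate` (integer).
#' @examples
#' sample_design(paste0("S", 1:6), rep(c("KPC", "PSC"), each = 3))
#' @export
sample_design <- function(sample, condition, replicate = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stop_consistency("duplicate sample id(s): ",
                     paste(unique(sample[duplicated(sample)]), collapse = ", "))
  if (length(condition) != length(sample))
    stop_consistency("'condition' and 'sample' lengths differ")
  if (!is.factor(condition))
    condition <- factor(condition, levels = unique(as.character(condition)))
  condition <- droplevels(condition)
  if (nlevels(condition) < 2)
    stop_config("a design needs at least 2 conditions")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(sample), condition, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  d <- data.frame(sample = sample, condition = condition,
                  replicate = replicate, stringsAsFactors = FALSE)
  tab <- table(d$condition)
  if (any(tab < 2))
    warning("condition(s) with a single replicate: ",
            paste(names(tab)[tab < 2], collapse = ", "),
            " (differential testing will refuse them)")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("<sample_design> %d samples, %d conditions (%s)\n",
              nrow(x), nlevels(x$condition),
              paste(levels(x$condition), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

# Check the design covers exactly the matrix columns; reorder design rows to
# the matrix column order.
align_design <- function(x, design) {
  stopifnot(inherits(x, "lfq_matrix"), inherits(design, "sample_design"))
  samples <- colnames(x$values)
  missing <- setdiff(samples, design$sample)
  if (length(missing))
    stop_consistency("matrix sample(s) absent from design: ",
                     paste(missing, collapse = ", "))
  extra <- setdiff(design$sample, samples)
  if (length(extra))
    stop_consistency("design sample(s) absent from matrix: ",
                     paste(extra, collapse = ", "))
  design[match(samples, design$sample), , drop = FALSE]
}
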