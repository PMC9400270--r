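#' Fit the co-culture EV differential-abundance model
#'
#' The package's main entry point: runs the full label-free differential
#' abundance analysis on a protein (or phosphoprotein) quantification matrix
#' over a multi-condition design, and returns a fitted object holding every
#' intermediate stage and result table.
#'
#' Stages, in order:
#' \enumerate{
#'   \item detection filter (>= `min_valid` observed values in at least one
#'     condition);
#'   \item log2 transform of observed intensities;
#'   \item downshifted-Gaussian imputation of missing values
#'     (width/downshift in units of the per-sample observed standard
#'     deviation);
#'   \item asymmetric quartile width-adjustment normalization per protein;
#'   \item per-protein one-way ANOVA across conditions with
#'     Benjamini-Hochberg FDR, significance gate `q < alpha`;
#'   \item row standardization of the significant subset;
#'   \item hierarchical clustering (Euclidean, average linkage) into `k`
#'     clusters with per-cluster condition profiles;
#'   \item candidate selection: the cluster most elevated in the interaction
#'     (co-culture) condition relative to the monocultures;
#'   \item top-`n` candidate ranking by interaction-condition mean.
#' }
#' Replicate Pearson correlations and per-condition identification sets with
#' their Venn decomposition are computed alongside as quality control and
#' accounting.
#'
#' The phosphoprotein arm (`arm = "phospho"`) runs the identical numerical
#' pipeline with a default of `k = 5` clusters; its candidate table is
#' computed but flagged as not used for target selection, reflecting the
#' weaker profile trends typical of phosphoproteome clusters.
#'
#' @param x an [lfq_matrix] at stage `raw` (linear intensities) or `log2`.
#' @param design a [sample_design] covering the matrix columns.
#' @param interaction the interaction/co-culture condition label ranked on
#'   (default `"CoC"`).
#' @param min_valid detection-filter threshold (default 3: a complete
#'   triplicate in at least one condition; use 1 for the loose
#'   detected-anywhere rule).
#' @param width,downshift imputation parameters (defaults 0.3 and 1.8).
#' @param impute_scope `"per_sample"` or `"global"` reference statistics for
#'   imputation.
#' @param normalize_scope scope of the width-adjustment normalization:
#'   `"sample"` (default; each sample column is centered on its median and
#'   its two quartile widths equalized, the column-wise convention of
#'   Perseus-style width adjustment, which preserves between-condition
#'   differences) or `"protein"` (each row; removes per-protein location and
#'   asymmetric spread but also compresses the very group contrast the
#'   downstream selection looks for — useful for display, not recommended
#'   before the ANOVA).
#' @param alpha FDR significance level (default 0.05).
#' @param k number of clusters; defaults to 4 for the protein arm and 5 for
#'   the phospho arm.
#' @param top_n candidate-table size (default 20).
#' @param min_valid_id identification threshold for the Venn accounting
#'   (default 1, independent of the analysis filter).
#' @param arm `"protein"` or `"phospho"`.
#' @param seed integer seed for the imputation draws.
#' @return an object of class `evome`; see Details. Key components:
#'   `diff` (per-protein F/p/q table), `model` (the `cluster_model`),
#'   `candidates` (the ranked `candidate_table`), `id_sets` and `venn`,
#'   `correlations`, plus all matrix stages under `$stages`.
#' @examples
#' sim <- simulate_lfq(sim_config(n_proteins = 300, seed = 7))
#' fit <- evome(sim$matrix, sim$design, seed = 7)
#' fit
#' head(candidates(fit))
#' @export
evome <- function(x, design, interaction = "CoC", min_valid = 3,
                  width = 0.3, downshift = 1.8,
                  impute_scope = c("per_sample", "global"),
                  normalize_scope = c("sample", "protein"),
                  alpha = 0.05, k = NULL, top_n = 20, min_valid_id = 1,
                  arm = c("protein", "phospho"), seed = 1L) {
  cl <- match.call()
  arm <- match.arg(arm)
  impute_scope <- match.arg(impute_scope)
  normalize_scope <- match.arg(normalize_scope)
  if (is.null(k)) k <- if (arm == "phospho") 5L else 4L
  stopifnot(inherits(x, "lfq_matrix"))
  design <- align_design(x, design)
  if (!interaction %in% levels(design$condition))
    stop_config("interaction condition '", interaction, "' not in the design")
  if (top_n < 1) stop_config("top_n must be >= 1")

  filtered <- filter_detected(x, design, min_valid = min_valid)
  id_sets <- identification_sets(filtered, design, min_valid = min_valid_id)
  venn <- venn_report(id_sets)

  lg <- if (filtered$stage == "raw") log2_transform(filtered) else filtered
  correlations <- replicate_correlation(lg, design)
  imputed <- impute_mnar(lg, width = width, downshift = downshift,
                         scope = impute_scope, seed = seed)
  normalized <- width_adjust(imputed, scope = normalize_scope)
  diff <- anova_oneway(normalized, design, alpha = alpha)

  sig <- diff$protein_id[diff$significant]
  model <- NULL
  candidates <- NULL
  standardized <- NULL
  candidate_cluster <- NA_integer_
  if (length(sig) == 0) {
    warning("no significant proteins at q < ", alpha,
            "; skipping clustering and candidate selection")
  } else {
    k_eff <- min(k, length(sig))
    if (k_eff < k)
      warning("only ", length(sig), " significant protein(s); using k = ", k_eff)
    sub <- lfq_subset(normalized, match(sig, normalized$proteins$protein_id))
    standardized <- standardize_rows(sub)
    model <- hierarchical_cluster(standardized, k = k_eff, design = design)
    cand_ids <- select_candidates(model, interaction = interaction)
    candidate_cluster <- attr(cand_ids, "cluster")
    candidates <- if (length(cand_ids)) {
      rank_top(cand_ids, model$condition_means, standardized$proteins,
               n = top_n, interaction = interaction)
    }
    if (is.null(candidates))
      warning("empty candidate set; no candidate table produced")
  }

  structure(list(call = cl, arm = arm, interaction = interaction,
                 design = design,
                 params = list(min_valid = min_valid, width = width,
                               downshift = downshift,
                               impute_scope = impute_scope,
                               normalize_scope = normalize_scope, alpha = alpha,
                               k = k, top_n = top_n,
                               min_valid_id = min_valid_id, seed = seed),
                 stages = list(input = x, filtered = filtered, log2 = lg,
                               imputed = imputed, normalized = normalized,
                               standardized = standardized),
                 diff = diff, model = model, candidates = candidates,
                 candidate_cluster = candidate_cluster,
                 candidates_used_for_selection = (arm == "protein"),
                 id_sets = id_sets, venn = venn,
                 correlations = correlations),
            class = "evome")
}

#' Extract the ranked candidate table
#'
#' @param fit an [evome] fit.
#' @return the `candidate_table` data frame, or `NULL` when no candidates
#'   were selected.
#' @export
candidates <- function(fit) {
  stopifnot(inherits(fit, "evome"))
  fit$candidates
}

#' @export
print.evome <- function(x, ...) {
  n_in <- nrow(x$stages$input$values)
  n_filt <- nrow(x$stages$filtered$values)
  n_sig <- sum(x$diff$significant)
  cat(sprintf("<evome fit> arm = %s, %d conditions (%s), interaction = %s\n",
              x$arm, nlevels(x$design$condition),
              paste(levels(x$design$condition), collapse = ", "),
              x$interaction))
  cat(sprintf("  proteins: %d input, %d after detection filter, %d significant (q < %g)\n",
              n_in, n_filt, n_sig, x$params$alpha))
  if (!is.null(x$model))
    cat(sprintf("  clusters: k = %d, candidate cluster %s (%d ranked candidates)\n",
                x$model$k,
                if (is.na(x$candidate_cluster)) "none" else x$candidate_cluster,
                if (is.null(x$candidates)) 0L else nrow(x$candidates)))
  invisible(x)
}

#' @export
summary.evome <- function(object, ...) {
  within_r <- NULL
  cr <- object$correlations
  if (!is.null(cr$condition_1)) {
    w <- cr$condition_1 == cr$condition_2 & cr$sample_1 != cr$sample_2
    within_r <- range(cr$r[w], na.rm = TRUE)
  }
  s <- list(arm = object$arm,
            conditions = levels(object$design$condition),
            n_input = nrow(object$stages$input$values),
            n_filtered = nrow(object$stages$filtered$values),
            id_counts = attr(object$stages$filtered, "id_counts"),
            set_sizes = vapply(object$id_sets, length, integer(1)),
            venn = object$venn,
            n_significant = sum(object$diff$significant),
            alpha = object$params$alpha,
            cluster_sizes = if (!is.null(object$model))
              table(object$model$assignment),
            profile = if (!is.null(object$model)) object$model$profile,
            candidate_cluster = object$candidate_cluster,
            candidates = object$candidates,
            within_replicate_r = within_r)
  class(s) <- "summary.evome"
  s
}

#' @export
print.summary.evome <- function(x, ...) {
  cat(sprintf("EV secretome differential-abundance fit (%s arm)\n", x$arm))
  cat(sprintf("conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("proteins: %d input -> %d filtered -> %d significant at q < %g\n",
              x$n_input, x$n_filtered, x$n_significant, x$alpha))
  cat("identification-set sizes (Venn accounting): ",
      paste(names(x$set_sizes), x$set_sizes, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$within_replicate_r))
    cat(sprintf("within-condition replicate Pearson r: %.2f to %.2f\n",
                x$within_replicate_r[1], x$within_replicate_r[2]))
  if (!is.null(x$cluster_sizes)) {
    cat("cluster sizes: ", paste(x$cluster_sizes, collapse = ", "), "\n")
    cat("cluster mean profiles:\n")
    print(round(x$profile, 3))
  }
  if (!is.null(x$candidates)) {
    cat("top candidates:\n")
    print(utils::head(as.data.frame(x$candidates), 10))
  }
  invisible(x)
}

#' Parallel-coordinate plot of cluster profiles
#'
#' Draws each cluster's per-condition mean profile (and optionally the
#' member-protein profiles behind it) as parallel coordinates, one panel per
#' cluster — the standard reading aid for expression archetypes such as
#' "elevated only in co-culture".
#'
#' @param x an [evome] fit with a cluster model.
#' @param members draw individual member profiles behind the cluster mean?
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.evome <- function(x, members = TRUE, ...) {
  if (is.null(x$model)) {
    warning("no cluster model to plot")
    return(invisible(x))
  }
  prof <- x$model$profile
  cm <- x$model$condition_means
  k <- x$model$k
  old <- graphics::par(mfrow = grDevices::n2mfrow(k), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  conds <- colnames(prof)
  for (cl in seq_len(k)) {
    ids <- names(x$model$assignment)[x$model$assignment == cl]
    ylim <- range(cm[ids, , drop = FALSE], prof)
    graphics::plot(NA, xlim = c(1, length(conds)), ylim = ylim, xaxt = "n",
                   xlab = "", ylab = "standardized abundance",
                   main = sprintf("cluster %d (n = %d)", cl, length(ids)))
    graphics::axis(1, at = seq_along(conds), labels = conds)
    if (members)
      for (id in ids)
        graphics::lines(seq_along(conds), cm[id, ], col = "grey80")
    graphics::lines(seq_along(conds), prof[cl, ], lwd = 2, col = "firebrick")
  }
  invisible(x)
}
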