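#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of protein rows (Euclidean distance, average
#' linkage by default) cut to exactly `k` clusters — the unsupervised
#' grouping behind expression heatmaps, from which profile archetypes such as
#' "elevated only in co-culture" are read off. Typical cluster counts are
#' k = 4 for protein and k = 5 for phosphoprotein secretome profiles.
#'
#' @param x an [lfq_matrix] without missing cells, normally row-standardized.
#' @param k number of clusters (1 <= k <= number of proteins).
#' @param design optional [sample_design]; when given, per-cluster
#'   per-condition mean profiles are computed.
#' @param method agglomeration method passed to [stats::hclust()].
#' @return a list of class `cluster_model`: `tree` (the `hclust` object, or
#'   `NULL` for a single protein), `k`, `assignment` (named integer vector),
#'   `profile` (k x conditions matrix of mean values, when a design is
#'   given), `condition_means` (protein x condition matrix), `method`.
#' @export
hierarchical_cluster <- function(x, k, design = NULL, method = "average") {
  stopifnot(inherits(x, "lfq_matrix"))
  if (anyNA(x$values)) stop_config("clustering requires a complete matrix")
  n <- nrow(x$values)
  k <- as.integer(k)
  if (k < 1) stop_config("k must be >= 1")
  if (k > n) stop_config("k (", k, ") exceeds the number of proteins (", n, ")")
  if (n == 1L) {
    assignment <- stats::setNames(1L, rownames(x$values))
    tree <- NULL
  } else {
    tree <- stats::hclust(stats::dist(x$values, method = "euclidean"),
                          method = method)
    assignment <- stats::cutree(tree, k = k)
  }
  model <- structure(list(tree = tree, k = k, assignment = assignment,
                          profile = NULL, condition_means = NULL,
                          method = method),
                     class = "cluster_model")
  if (!is.null(design)) {
    design <- align_design(x, design)
    model$condition_means <- condition_means(x, design)
    model$profile <- cluster_profiles(model, x, design)
  }
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d (%s linkage), sizes: %s\n", x$k,
              x$method, paste(table(x$assignment), collapse = ", ")))
  if (!is.null(x$profile)) {
    cat("cluster mean profiles:\n")
    print(round(x$profile, 3))
  }
  invisible(x)
}

# protein x condition matrix of per-condition means
condition_means <- function(x, design) {
  conds <- levels(design$condition)
  m <- vapply(conds, function(cc) {
    rowMeans(x$values[, design$condition == cc, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (nrow(x$values) == 1L)
    m <- matrix(m, 1L, length(conds),
                dimnames = list(rownames(x$values), conds))
  m
}

#' Per-cluster per-condition mean profiles
#'
#' For each cluster, the mean value per condition over its member proteins —
#' the numerical content of parallel-coordinate cluster plots. Profiles are
#' recomputable from the assignment and the matrix; this function is that
#' recomputation.
#'
#' @param model a `cluster_model`.
#' @param x the clustered [lfq_matrix].
#' @param design a [sample_design].
#' @return k x conditions numeric matrix.
#' @export
cluster_profiles <- function(model, x, design) {
  stopifnot(inherits(model, "cluster_model"), inherits(x, "lfq_matrix"))
  design <- align_design(x, design)
  cm <- condition_means(x, design)
  ids <- names(model$assignment)
  if (!all(ids %in% rownames(cm)))
    stop_consistency("cluster assignment names not all present in the matrix")
  cm <- cm[ids, , drop = FALSE]
  prof <- t(vapply(seq_len(model$k), function(cl) {
    colMeans(cm[model$assignment == cl, , drop = FALSE])
  }, numeric(ncol(cm))))
  rownames(prof) <- paste0("cluster", seq_len(model$k))
  prof
}

#' Select candidate proteins by co-culture profile contrast
#'
#' Picks the cluster whose mean profile maximizes
#' `profile[interaction] - max(profile[other conditions])`, i.e. the cluster
#' of proteins elevated in the co-culture (interaction) condition while
#' relatively low in both monocultures, and returns its members. The cluster
#' contrast operationalizes "relatively low": individual members may dip
#' slightly above zero in a monoculture and still belong.
#'
#' @param model a `cluster_model` with profiles (built with a design).
#' @param interaction label of the interaction condition (default `"CoC"`).
#' @return character vector of member protein ids, with attributes
#'   `"cluster"` (the chosen cluster id) and `"contrast"` (its profile
#'   contrast). Empty, with a warning, when no cluster has a positive mean
#'   in the interaction condition.
#' @export
select_candidates <- function(model, interaction = "CoC") {
  stopifnot(inherits(model, "cluster_model"))
  prof <- model$profile
  if (is.null(prof))
    stop_config("model has no profiles; cluster with a design first")
  if (!interaction %in% colnames(prof))
    stop_config("condition '", interaction, "' not in the profiles")
  others <- setdiff(colnames(prof), interaction)
  contrast <- prof[, interaction] - apply(prof[, others, drop = FALSE], 1L, max)
  best <- which.max(contrast)
  if (prof[best, interaction] <= 0) {
    warning("no cluster is elevated in '", interaction,
            "'; returning an empty candidate set")
    out <- character(0)
    attr(out, "cluster") <- NA_integer_
    attr(out, "contrast") <- NA_real_
    return(out)
  }
  out <- names(model$assignment)[model$assignment == best]
  attr(out, "cluster") <- unname(best)
  attr(out, "contrast") <- unname(contrast[best])
  out
}

#' Rank candidates into a top-N table
#'
#' Orders candidate proteins by their mean abundance in the interaction
#' condition, descending, ties broken alphabetically by gene symbol, and
#' returns the top `n` with per-condition average abundances — the layout of
#' a "top proteins overexpressed in co-culture" table (gene symbol,
#' description, one average per condition).
#'
#' @param candidates character vector of protein ids.
#' @param means protein x condition matrix of per-condition means (row names
#'   = protein ids), e.g. `condition_means` from the cluster model.
#' @param proteins protein annotation data frame (`protein_id`,
#'   `gene_symbol`, `description`).
#' @param n table size (default 20); fewer candidates than `n` returns all.
#' @param interaction condition ranked on (default `"CoC"`).
#' @return a data frame of class `candidate_table`: `gene_symbol`,
#'   `description`, one `mean_<condition>` column per condition (interaction
#'   condition last), sorted by the interaction mean, descending.
#' @export
rank_top <- function(candidates, means, proteins, n = 20,
                     interaction = "CoC") {
  n <- as.integer(n)
  if (n < 1) stop_config("n must be >= 1")
  if (!interaction %in% colnames(means))
    stop_config("condition '", interaction, "' not in the means matrix")
  missing <- setdiff(candidates, rownames(means))
  if (length(missing))
    stop_consistency("candidate(s) without condition means: ",
                     paste(utils::head(missing, 5L), collapse = ", "))
  idx <- match(candidates, proteins$protein_id)
  if (anyNA(idx))
    stop_consistency("candidate(s) without annotation: ",
                     paste(candidates[is.na(idx)], collapse = ", "))
  m <- means[candidates, , drop = FALSE]
  conds <- c(setdiff(colnames(means), interaction), interaction)
  tab <- data.frame(gene_symbol = proteins$gene_symbol[idx],
                    description = proteins$description[idx],
                    stringsAsFactors = FALSE)
  for (cc in conds) tab[[paste0("mean_", cc)]] <- m[, cc]
  ord <- order(-tab[[paste0("mean_", interaction)]], tab$gene_symbol)
  tab <- tab[utils::head(ord, n), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "interaction") <- interaction
  class(tab) <- c("candidate_table", "data.frame")
  tab
}

#' Export a linkage tree in Newick format
#'
#' @param model a `cluster_model` with a non-null tree.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
tree_newick <- function(model, path = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$tree)) stop_config("model has no linkage tree")
  nwk <- hclust_newick(model$tree)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

hclust_newick <- function(h) {
  lab <- h$labels
  if (is.null(lab)) lab <- as.character(seq_along(h$order))
  rec <- function(i, parent_height) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_height))
    children <- h$merge[i, ]
    height <- h$height[i]
    inner <- paste(rec(children[1], height), rec(children[2], height), sep = ",")
    sprintf("(%s):%g", inner, parent_height - height)
  }
  top <- nrow(h$merge)
  paste0("(", rec(h$merge[top, 1], h$height[top]), ",",
         rec(h$merge[top, 2], h$height[top]), ");")
}
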