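#' Run the full pipeline from files to a result bundle on disk
#'
#' Thin orchestration over [evome()]: reads the quantification matrix and
#' design (or takes in-memory objects), fits the model, and writes every
#' stage and result table to `out_dir` with a provenance header recording
#' stage, parameters and seed. Re-running with identical inputs and
#' parameters reproduces byte-identical outputs (no timestamps are written).
#'
#' Files written: `matrix_filtered.tsv`, `matrix_imputed.tsv`,
#' `matrix_normalized.tsv`, `matrix_standardized.tsv` (when significant
#' proteins exist), `diff_results.tsv`, `cluster_assignments.tsv`,
#' `cluster_profiles.tsv`, `cluster_tree.nwk`, `candidates.tsv`,
#' `replicate_correlations.tsv`, `venn.json`, `log.txt` (one structured line
#' per stage with input/output dimensions), and `overlap.json` +
#' `novel_proteins.tsv` when reference lists are supplied.
#'
#' @param matrix an [lfq_matrix], or a path readable by [read_lfq_table()].
#' @param design a [sample_design], or a path readable by [read_design()].
#' @param out_dir output directory (created if needed).
#' @param references optional list of `reference_set` objects or paths.
#' @param id_map optional path to a two-column identifier-mapping file
#'   applied to gene symbols before reference overlap.
#' @param prefix intensity-column prefix for file input.
#' @param ... further arguments passed to [evome()] (`min_valid`, `width`,
#'   `downshift`, `alpha`, `k`, `top_n`, `arm`, `seed`, ...).
#' @return the [evome] fit, invisibly, with attribute `"files"` listing the
#'   written paths.
#' @export
run_pipeline <- function(matrix, design, out_dir, references = NULL,
                         id_map = NULL, prefix = "LFQ intensity ", ...) {
  if (is.character(matrix)) matrix <- read_lfq_table(matrix, prefix = prefix)
  if (is.character(design)) design <- read_design(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- evome(matrix, design, ...)
  prov <- c(fit$params, list(arm = fit$arm, interaction = fit$interaction))
  log_lines <- character(0)
  log_stage <- function(stage, obj) {
    d <- if (inherits(obj, "lfq_matrix")) dim(obj$values) else dim(obj)
    log_lines <<- c(log_lines,
                    sprintf("stage=%s rows=%d cols=%d", stage, d[1], d[2]))
  }

  files <- character(0)
  wr <- function(name) { p <- file.path(out_dir, name); files <<- c(files, p); p }

  for (st in c("filtered", "imputed", "normalized")) {
    write_lfq_table(fit$stages[[st]], wr(paste0("matrix_", st, ".tsv")),
                    prefix = prefix, provenance = prov)
    log_stage(st, fit$stages[[st]])
  }
  if (!is.null(fit$stages$standardized)) {
    write_lfq_table(fit$stages$standardized, wr("matrix_standardized.tsv"),
                    prefix = prefix, provenance = prov)
    log_stage("standardized", fit$stages$standardized)
  }

  write_result_table(as.data.frame(fit$diff), wr("diff_results.tsv"),
                     c(list(stage = "diff"), prov))
  log_stage("diff", fit$diff)

  write_result_table(as.data.frame(fit$correlations),
                     wr("replicate_correlations.tsv"),
                     c(list(stage = "qc_correlation"), prov))

  if (!is.null(fit$model)) {
    asg <- data.frame(protein_id = names(fit$model$assignment),
                      cluster = unname(fit$model$assignment),
                      stringsAsFactors = FALSE)
    write_result_table(asg, wr("cluster_assignments.tsv"),
                       c(list(stage = "clusters"), prov))
    prof <- as.data.frame(fit$model$profile)
    prof <- cbind(cluster = rownames(fit$model$profile), prof,
                  stringsAsFactors = FALSE)
    write_result_table(prof, wr("cluster_profiles.tsv"),
                       c(list(stage = "profiles"), prov))
    if (!is.null(fit$model$tree)) tree_newick(fit$model, wr("cluster_tree.nwk"))
  }
  if (!is.null(fit$candidates)) {
    write_result_table(as.data.frame(fit$candidates), wr("candidates.tsv"),
                       c(list(stage = "candidates"), prov))
    log_stage("candidates", fit$candidates)
  }

  jsonlite::write_json(
    list(regions = as.list(fit$venn$regions),
         union_size = fit$venn$union_size,
         set_sizes = as.list(fit$venn$set_sizes)),
    wr("venn.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(references)) {
    refs <- lapply(references, function(r) {
      if (is.character(r) && length(r) == 1 && file.exists(r)) read_reference(r)
      else r
    })
    genes <- fit$stages$filtered$proteins$gene_symbol
    if (!is.null(id_map)) genes <- map_identifiers(genes, id_map)
    ov <- overlap_reference(genes, refs)
    jsonlite::write_json(
      list(study_size = ov$study_size, overlap = as.list(ov$overlap),
           novel_count = ov$novel_count),
      wr("overlap.json"), auto_unbox = TRUE, digits = NA)
    write_result_table(data.frame(gene_symbol = ov$novel,
                                  stringsAsFactors = FALSE),
                       wr("novel_proteins.tsv"),
                       c(list(stage = "novel"), prov))
  }

  writeLines(log_lines, wr("log.txt"))
  attr(fit, "files") <- files
  invisible(fit)
}

write_result_table <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(provenance), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate an experiment and write the fixture bundle to disk
#'
#' Runs [simulate_lfq()] and writes `matrix.tsv` (the raw LFQ dialect
#' [read_lfq_table()] reads), `design.tsv` and `truth.tsv` (pattern label,
#' true per-condition log2 means, realized dropout probability) with
#' provenance headers.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return the simulation list (see [simulate_lfq()]), invisibly, with
#'   attribute `"files"`.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_lfq(config)
  prov <- list(seed = config$seed, n_proteins = config$n_proteins,
               effect_size = config$effect_size,
               replicate_sd = config$replicate_sd)
  files <- c(matrix = file.path(out_dir, "matrix.tsv"),
             design = file.path(out_dir, "design.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_lfq_table(sim$matrix, files[["matrix"]], provenance = prov)
  write_design(sim$design, files[["design"]])
  write_result_table(as.data.frame(sim$truth), files[["truth"]],
                     c(list(stage = "truth"), prov))
  attr(sim, "files") <- files
  invisible(sim)
}
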