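#' Per-condition identification sets
#'
#' A protein is "identified" in a condition when it has at least `min_valid`
#' observed values among that condition's replicates. The default
#' `min_valid = 1` is the loose accounting used for per-condition
#' identification totals and Venn diagrams; it is deliberately independent of
#' the (stricter) analysis filter, since identification totals routinely
#' exceed the analysis-eligible set.
#'
#' @param x an [lfq_matrix] (raw or log2 stage; the missing mask drives
#'   membership).
#' @param design a [sample_design].
#' @param min_valid minimum observed values within the condition (default 1).
#' @return named list of class `identification_sets`, one character vector of
#'   protein ids per condition.
#' @export
identification_sets <- function(x, design, min_valid = 1) {
  stopifnot(inherits(x, "lfq_matrix"))
  design <- align_design(x, design)
  min_valid <- as.integer(min_valid)
  if (min_valid < 1) stop_config("min_valid must be >= 1")
  reps <- table(design$condition)
  if (any(min_valid > reps))
    stop_config("min_valid (", min_valid, ") exceeds the replicate count of ",
                "condition(s): ",
                paste(names(reps)[reps < min_valid], collapse = ", "))
  counts <- valid_counts(x, design)
  sets <- lapply(colnames(counts), function(cc) {
    rownames(counts)[counts[, cc] >= min_valid]
  })
  names(sets) <- colnames(counts)
  structure(sets, class = "identification_sets")
}

#' @export
print.identification_sets <- function(x, ...) {
  cat("<identification_sets>\n")
  for (nm in names(x)) cat(sprintf("  %s: %d proteins\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Venn decomposition of identification sets
#'
#' Exact region counts for every intersection pattern over the input sets,
#' by per-element membership tally. Region counts sum to the union size and
#' each set's total is the sum of the regions containing it; counts are
#' invariant to the order the sets are given in.
#'
#' @param sets a named list of character vectors (e.g.
#'   [identification_sets()]); at least 2 sets.
#' @return a list of class `venn_report`: `regions` (named integer vector
#'   over all 2^K - 1 patterns, names like `"KPC"`, `"KPC&CoC"`),
#'   `union_size`, `set_sizes`.
#' @export
venn_report <- function(sets) {
  sets <- lapply(sets, as.character)
  if (length(sets) < 2) stop_config("venn_report needs at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_config("sets must be named")
  nm <- names(sets)
  K <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L)
    member <- matrix(member, 1L, K, dimnames = list(NULL, nm))

  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), K))[-1, , drop = FALSE]
  names(patterns) <- nm
  region_name <- apply(patterns, 1L, function(p) paste(nm[as.logical(p)],
                                                       collapse = "&"))
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(row) all(row == as.logical(p))))
  })
  if (!length(universe)) counts <- rep(0L, nrow(patterns))
  regions <- stats::setNames(as.integer(counts), region_name)
  structure(list(regions = regions,
                 union_size = length(universe),
                 set_sizes = vapply(sets, length, integer(1))),
            class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat(sprintf("<venn_report> union of %d elements over %d sets\n",
              x$union_size, length(x$set_sizes)))
  cat("set sizes: ", paste(names(x$set_sizes), x$set_sizes, sep = "=",
                           collapse = ", "), "\n")
  print(x$regions)
  invisible(x)
}

#' Overlap of a study set with reference compendia
#'
#' Counts how many study identifiers appear in each reference set (e.g.
#' ExoCarta- or Vesiclepedia-style extracellular-vesicle compendium exports)
#' and lists the "novel" identifiers absent from every reference. Study
#' identifiers are uppercased to the normalization the reference reader
#' applies. Reported overlaps are snapshots of the supplied reference files;
#' compendium counts are version-dependent.
#'
#' @param study character vector of study identifiers (non-empty).
#' @param references a list of `reference_set` objects (see
#'   [read_reference()]), or character vectors.
#' @return a list of class `overlap_report`: `study_size`, `overlap` (named
#'   integer vector per reference), `overlap_fraction`, `novel` (sorted
#'   character vector), `novel_count`.
#' @export
overlap_reference <- function(study, references) {
  study <- unique(toupper(as.character(study)))
  study <- study[nzchar(study)]
  if (!length(study)) stop_config("study set is empty")
  refs <- lapply(references, function(r) {
    if (inherits(r, "reference_set")) r$members else unique(toupper(as.character(r)))
  })
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    nms <- vapply(seq_along(references), function(i) {
      r <- references[[i]]
      if (inherits(r, "reference_set")) r$name else paste0("reference", i)
    }, character(1))
    names(refs) <- nms
  }
  overlap <- vapply(refs, function(r) sum(study %in% r), integer(1))
  in_any <- study %in% unique(unlist(refs, use.names = FALSE))
  structure(list(study_size = length(study),
                 overlap = overlap,
                 overlap_fraction = overlap / length(study),
                 novel = sort(study[!in_any]),
                 novel_count = sum(!in_any)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> study set of %d identifiers\n", x$study_size))
  for (nm in names(x$overlap))
    cat(sprintf("  %s: %d (%.1f%%)\n", nm, x$overlap[[nm]],
                100 * x$overlap_fraction[[nm]]))
  cat(sprintf("  novel (in no reference): %d\n", x$novel_count))
  invisible(x)
}
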