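# Small programmatic fixtures shared across test files.

# A tiny three-condition design: k conditions x r replicates.
toy_design <- function(conditions = c("KPC", "PSC", "CoC"), reps = 3) {
  sample_design(paste0(rep(conditions, each = reps), "_", seq_len(reps)),
                rep(conditions, each = reps))
}

# An lfq_matrix from a plain numeric matrix, with stage control.
toy_matrix <- function(values, stage = "raw", ids = NULL) {
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(values)))
  rownames(values) <- ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  lfq_matrix(values, stage = stage)
}

# Matrix with prescribed observed-value counts per condition (3 reps each);
# observed cells get intensity 2^20, the rest are missing.
counts_matrix <- function(counts_per_condition, design) {
  conds <- levels(design$condition)
  n <- nrow(counts_per_condition)
  v <- matrix(NA_real_, n, nrow(design))
  colnames(v) <- design$sample
  for (i in seq_len(n)) {
    for (j in seq_along(conds)) {
      cols <- which(design$condition == conds[j])
      k <- counts_per_condition[i, j]
      if (k > 0) v[i, cols[seq_len(k)]] <- 2^20
    }
  }
  toy_matrix(v)
}

table1_path <- function() {
  system.file("extdata", "coculture_top20.tsv", package = "evlfq")
}

read_table1 <- function() {
  read_lfq_table(table1_path(), prefix = "Average ", stage = "standardized")
}

# Agreement between two labelings, maximized over label permutation
# (exact for small k): fraction of points whose labels match under the best
# one-to-one relabeling.
label_agreement <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  ka <- max(a); kb <- max(b)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(max(ka, kb)))) {
    best <- max(best, mean(p[b] == a))
  }
  best
}
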