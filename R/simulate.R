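#' Configuration for the synthetic LFQ generator
#'
#' Describes a simulated label-free quantification experiment: a three-group
#' secretome design (cancer cells, stellate cells, co-culture by default) with
#' log-normal protein intensities, archetype-patterned group effects and
#' intensity-dependent (missing-not-at-random) dropout.
#'
#' Pattern archetypes mirror the four expression-profile clusters typical of
#' co-culture secretome studies:
#' \describe{
#'   \item{cluster1}{low in the first (cancer) condition, high in the stromal
#'     and co-culture conditions}
#'   \item{cluster2}{high only in the co-culture (interaction) condition}
#'   \item{cluster3}{high only in the stromal condition}
#'   \item{cluster4}{low only in the co-culture condition}
#' }
#' Remaining proteins are `null` (no group effect).
#'
#' @param n_proteins number of simulated proteins.
#' @param conditions ordered condition labels; the third is treated as the
#'   co-culture/interaction condition by downstream defaults.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity location and
#'   spread of per-protein baselines (typical LFQ intensities live around
#'   2^25).
#' @param pattern_fractions named nonnegative fractions per archetype, summing
#'   to at most 1; the remainder of proteins is `null`. Counts are
#'   `floor(fraction * n_proteins)` per pattern, in the order given, with the
#'   remainder assigned to `null`.
#' @param effect_size log2 units added (or subtracted) per archetype.
#' @param replicate_sd within-condition replicate standard deviation (log2).
#' @param dropout_midpoint log2 intensity at which the dropout probability is
#'   1/2.
#' @param dropout_steepness logistic slope of the dropout curve (per log2
#'   unit); larger values give a sharper detection limit.
#' @param seed integer seed; identical configurations reproduce identical
#'   output bit for bit.
#' @return a list of class `sim_config`.
#' @seealso [simulate_lfq()]
#' @export
sim_config <- function(n_proteins = 1000,
                       conditions = c("KPC", "PSC", "CoC"),
                       replicates_per_condition = 3,
                       baseline_log2_mean = 25,
                       baseline_log2_sd = 2,
                       pattern_fractions = c(cluster1 = 0.1, cluster2 = 0.1,
                                             cluster3 = 0.1, cluster4 = 0.1),
                       effect_size = 1.5,
                       replicate_sd = 0.5,
                       dropout_midpoint = baseline_log2_mean - 1.5 * baseline_log2_sd,
                       dropout_steepness = 1,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              conditions = as.character(conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              pattern_fractions = pattern_fractions,
              effect_size = effect_size,
              replicate_sd = replicate_sd,
              dropout_midpoint = dropout_midpoint,
              dropout_steepness = dropout_steepness,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1) stop_config("n_proteins must be positive")
  if (length(cfg$conditions) < 2) stop_config("need at least 2 conditions")
  if (cfg$replicates_per_condition < 2)
    stop_config("replicates_per_condition must be >= 2")
  pf <- cfg$pattern_fractions
  if (length(pf)) {
    if (is.null(names(pf)) || any(!nzchar(names(pf))))
      stop_config("pattern_fractions must be named")
    if (any(pf < 0)) stop_config("pattern fractions must be nonnegative")
    if (sum(pf) > 1 + 1e-12) stop_config("pattern fractions must sum to <= 1")
    unknown <- setdiff(names(pf), sim_archetypes())
    if (length(unknown))
      stop_config("unknown pattern label(s): ", paste(unknown, collapse = ", "))
  }
  for (f in c("baseline_log2_sd", "replicate_sd", "dropout_steepness"))
    if (cfg[[f]] <= 0) stop_config(f, " must be > 0")
  if (cfg$effect_size < 0) stop_config("effect_size must be nonnegative")
  invisible(cfg)
}

sim_archetypes <- function() c("cluster1", "cluster2", "cluster3", "cluster4")

# Per-condition log2 offsets of each archetype, for conditions ordered
# (cancer, stromal, co-culture). "e" is the effect size.
archetype_offsets <- function(conditions, effect_size) {
  e <- effect_size
  k <- length(conditions)
  base <- matrix(0, nrow = 5, ncol = k,
                 dimnames = list(c(sim_archetypes(), "null"), conditions))
  # archetypes are defined on the first three conditions; extra conditions
  # (if any) stay at baseline
  base["cluster1", 1] <- -e
  base["cluster1", 2] <- e
  base["cluster1", 3] <- e
  base["cluster2", 3] <- e
  base["cluster3", 2] <- e
  base["cluster4", 3] <- -e
  base
}

#' Simulate a label-free quantification experiment with known ground truth
#'
#' Draws per-protein baseline log2 intensities from a normal distribution,
#' adds archetype group effects, adds replicate noise, and censors cells with
#' a logistic missing-not-at-random mechanism: the probability that a cell is
#' missing decreases with its true log2 intensity,
#' `P(missing) = plogis(-(x - midpoint) * steepness)`.
#' Observed cells are reported on the linear intensity scale (`2^x`), missing
#' cells as `NA`, matching the raw stage a quantification tool would emit.
#'
#' @param config a [sim_config()].
#' @return a list with elements:
#'   \describe{
#'     \item{matrix}{an [lfq_matrix] at stage `raw`}
#'     \item{design}{the matching [sample_design]}
#'     \item{truth}{data frame of class `synth_truth`: `protein_id`,
#'       `pattern`, one `true_mean_<condition>` column per condition (log2),
#'       and the realized `dropout_prob` averaged over the protein's cells}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' sim <- simulate_lfq(sim_config(n_proteins = 50, seed = 42))
#' sim$matrix
#' table(sim$truth$pattern)
#' @export
simulate_lfq <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_proteins
  conds <- config$conditions
  reps <- config$replicates_per_condition
  k <- length(conds)

  # deterministic label layout: floor(fraction * n) per pattern, in the
  # order given; remainder is null
  counts <- floor(config$pattern_fractions * n)
  labels <- rep("null", n)
  at <- 1L
  for (p in names(counts)) {
    if (counts[[p]] > 0) {
      labels[at:(at + counts[[p]] - 1L)] <- p
      at <- at + counts[[p]]
    }
  }

  offs <- archetype_offsets(conds, config$effect_size)
  set.seed(config$seed)
  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  true_means <- baseline + offs[labels, , drop = FALSE]  # n x k

  sample_ids <- paste0(rep(conds, each = reps), "_", rep(seq_len(reps), k))
  design <- sample_design(sample_ids, rep(conds, each = reps))

  true_log2 <- true_means[, rep(seq_len(k), each = reps), drop = FALSE] +
    matrix(stats::rnorm(n * k * reps, 0, config$replicate_sd), n, k * reps)
  colnames(true_log2) <- sample_ids

  p_miss <- stats::plogis(-(true_log2 - config$dropout_midpoint) *
                            config$dropout_steepness)
  miss <- matrix(stats::runif(length(p_miss)) < p_miss, n, k * reps)

  values <- 2^true_log2
  values[miss] <- NA_real_
  rownames(values) <- paste0("SYN", formatC(seq_len(n), width = nchar(n),
                                            flag = "0"))

  proteins <- data.frame(protein_id = rownames(values),
                         gene_symbol = rownames(values),
                         description = paste0("simulated ", labels, " protein"),
                         stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = rownames(values), pattern = labels,
                      stringsAsFactors = FALSE)
  tm <- as.data.frame(true_means)
  names(tm) <- paste0("true_mean_", conds)
  truth <- cbind(truth, tm)
  truth$dropout_prob <- rowMeans(p_miss)
  rownames(truth) <- NULL
  class(truth) <- c("synth_truth", "data.frame")
  attr(truth, "mean_dropout_prob") <- mean(p_miss)

  list(matrix = lfq_matrix(values, proteins, stage = "raw"),
       design = design, truth = truth, config = config)
}
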