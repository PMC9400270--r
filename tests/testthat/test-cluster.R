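test_that("two well-separated clouds are recovered at k = 2", {
  set.seed(81)
  v <- rbind(matrix(rnorm(10 * 4, 0, 0.1), 10, 4),
             matrix(rnorm(10 * 4, 50, 0.1), 10, 4))
  m <- toy_matrix(v, stage = "standardized")
  model <- hierarchical_cluster(m, k = 2)
  a <- model$assignment
  expect_length(unique(a[1:10]), 1)
  expect_length(unique(a[11:20]), 1)
  expect_false(a[1] == a[11])
})

test_that("single protein at k = 1 forms one cluster; k > n errors", {
  m <- toy_matrix(matrix(rnorm(4), 1, 4), stage = "standardized")
  model <- hierarchical_cluster(m, k = 1)
  expect_equal(unname(model$assignment), 1L)
  expect_error(hierarchical_cluster(m, k = 2), class = "evlfq_config_error")
})

test_that("archetype clusters are recovered from simulated data", {
  skip_if_not_installed("mclust")
  fr <- c(cluster1 = 0.25, cluster2 = 0.25, cluster3 = 0.25, cluster4 = 0.25)
  sim <- simulate_lfq(sim_config(n_proteins = 32, pattern_fractions = fr,
                                 dropout_midpoint = -50, seed = 1))
  lg <- log2_transform(sim$matrix)
  st <- standardize_rows(impute_mnar(lg, seed = 1))
  model <- hierarchical_cluster(st, k = 4, design = sim$design)
  truth <- sim$truth$pattern[match(names(model$assignment),
                                   sim$truth$protein_id)]
  ari <- mclust::adjustedRandIndex(model$assignment, truth)
  expect_gte(ari, 0.9)
})

test_that("clustering is invariant to row permutation up to relabeling", {
  skip_if_not_installed("mclust")
  set.seed(82)
  v <- rbind(matrix(rnorm(24, 0, 0.2), 6, 4),
             matrix(rnorm(24, 5, 0.2), 6, 4),
             matrix(rnorm(24, -5, 0.2), 6, 4))
  m <- toy_matrix(v, stage = "standardized")
  m1 <- hierarchical_cluster(m, k = 3)
  perm <- sample(nrow(v))
  mp <- lfq_subset(m, perm)
  m2 <- hierarchical_cluster(mp, k = 3)
  a1 <- m1$assignment[names(m2$assignment)]
  expect_equal(mclust::adjustedRandIndex(a1, m2$assignment), 1)
})

test_that("profiles are the means of member rows and recomputable", {
  sim <- simulate_lfq(sim_config(n_proteins = 40, seed = 83))
  st <- standardize_rows(impute_mnar(log2_transform(sim$matrix), seed = 83))
  model <- hierarchical_cluster(st, k = 3, design = sim$design)
  prof2 <- cluster_profiles(model, st, sim$design)
  expect_equal(model$profile, prof2, tolerance = 1e-12)
  cm <- model$condition_means
  for (cl in 1:3) {
    ids <- names(model$assignment)[model$assignment == cl]
    expect_equal(model$profile[cl, ],
                 colMeans(cm[ids, , drop = FALSE]), tolerance = 1e-12)
  }
  # a singleton cluster's profile equals that protein's condition means
  one <- hierarchical_cluster(lfq_subset(st, 1), k = 1, design = sim$design)
  expect_equal(unname(one$profile[1, ]), unname(one$condition_means[1, ]),
               tolerance = 1e-12)
})

test_that("candidate selection picks the co-culture-elevated cluster", {
  fr <- c(cluster1 = 0.25, cluster2 = 0.25, cluster3 = 0.25, cluster4 = 0.25)
  sim <- simulate_lfq(sim_config(n_proteins = 60, pattern_fractions = fr,
                                 dropout_midpoint = -50, seed = 2))
  st <- standardize_rows(impute_mnar(log2_transform(sim$matrix), seed = 2))
  model <- hierarchical_cluster(st, k = 4, design = sim$design)
  cand <- select_candidates(model, interaction = "CoC")
  truth2 <- sim$truth$protein_id[sim$truth$pattern == "cluster2"]
  expect_gte(sum(cand %in% truth2) / length(truth2), 0.9)
  expect_gte(mean(cand %in% truth2), 0.9)
  # planted cluster2 profile peaks at CoC
  chosen <- attr(cand, "cluster")
  expect_equal(which.max(model$profile[chosen, ]),
               which(colnames(model$profile) == "CoC"), ignore_attr = TRUE)
})

test_that("flat profiles give an empty selection with a warning", {
  v <- matrix(0, 6, 9)
  v[, 1] <- c(1e-9, -1e-9, 1e-9, -1e-9, 1e-9, -1e-9) # break constancy, keep flat
  d <- toy_design()
  colnames(v) <- d$sample
  m <- toy_matrix(v, stage = "standardized")
  model <- hierarchical_cluster(m, k = 2, design = d)
  model$profile[] <- 0
  expect_warning(cand <- select_candidates(model), "empty candidate set")
  expect_length(cand, 0)
})

test_that("ranking orders by interaction mean with alphabetical tie-break", {
  means <- rbind(A = c(KPC = -1, PSC = 0, CoC = 2),
                 B = c(-0.5, 0, 3),
                 C = c(0, -1, 2),
                 D = c(0, 0, 1))
  prot <- data.frame(protein_id = c("A", "B", "C", "D"),
                     gene_symbol = c("Zeta", "Beta", "Alpha", "Gamma"),
                     description = "", stringsAsFactors = FALSE)
  tab <- rank_top(c("A", "B", "C", "D"), means, prot, n = 3)
  expect_s3_class(tab, "candidate_table")
  # B first (3), then tie at 2 broken alphabetically: Alpha before Zeta
  expect_equal(tab$gene_symbol, c("Beta", "Alpha", "Zeta"))
  expect_equal(tab$mean_CoC, c(3, 2, 2))
  expect_true(all(diff(tab$mean_CoC) <= 0))
  expect_equal(names(tab), c("gene_symbol", "description", "mean_KPC",
                             "mean_PSC", "mean_CoC"))
  # fewer candidates than n returns all; bad n errors
  expect_equal(nrow(rank_top(c("A", "B"), means, prot, n = 20)), 2)
  expect_error(rank_top("A", means, prot, n = 0), class = "evlfq_config_error")
})

test_that("the linkage tree exports as parseable Newick", {
  set.seed(84)
  m <- toy_matrix(matrix(rnorm(20), 5, 4), stage = "standardized")
  model <- hierarchical_cluster(m, k = 2)
  nwk <- tree_newick(model)
  expect_match(nwk, "^\\(.*\\);$")
  for (id in rownames(m$values)) expect_match(nwk, id, fixed = TRUE)
})
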