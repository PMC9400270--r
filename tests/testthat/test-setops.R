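test_that("identification membership follows the min_valid rule", {
  d <- toy_design()
  counts <- rbind(c(3, 1, 0), c(1, 1, 1), c(0, 3, 3), c(2, 2, 2))
  m <- counts_matrix(counts, d)
  s1 <- identification_sets(m, d, min_valid = 1)
  expect_setequal(s1$KPC, c("P1", "P2", "P4"))
  expect_setequal(s1$PSC, c("P1", "P2", "P3", "P4"))
  expect_setequal(s1$CoC, c("P2", "P3", "P4"))
  s3 <- identification_sets(m, d, min_valid = 3)
  expect_setequal(s3$KPC, "P1")
  expect_setequal(s3$PSC, "P3")
  expect_setequal(s3$CoC, "P3")
  # a protein observed everywhere belongs to every set
  all9 <- counts_matrix(rbind(c(3, 3, 3)), d)
  s <- identification_sets(all9, d, 3)
  expect_true(all(vapply(s, function(x) "P1" %in% x, logical(1))))
  expect_error(identification_sets(m, d, 4), class = "evlfq_config_error")
})

test_that("venn regions match hand enumeration", {
  rep_ <- venn_report(list(A = c("1", "2"), B = c("2", "3"), C = c("3", "4")))
  r <- rep_$regions
  expect_equal(unname(r[["A"]]), 1)
  expect_equal(unname(r[["B"]]), 0)
  expect_equal(unname(r[["C"]]), 1)
  expect_equal(unname(r[["A&B"]]), 1)
  expect_equal(unname(r[["B&C"]]), 1)
  expect_equal(unname(r[["A&C"]]), 0)
  expect_equal(unname(r[["A&B&C"]]), 0)
  expect_equal(rep_$union_size, 4)
})

test_that("identical sets collapse into the all-sets region", {
  s <- c("x", "y", "z")
  rep_ <- venn_report(list(A = s, B = s, C = s))
  expect_equal(unname(rep_$regions[["A&B&C"]]), 3)
  expect_equal(sum(rep_$regions), rep_$union_size)
  expect_equal(unname(rep_$regions[["A"]]), 0)
})

test_that("venn counts equal a brute-force tally and respect the invariants", {
  set.seed(91)
  for (i in 1:20) {
    universe <- paste0("e", 1:40)
    sets <- list(A = sample(universe, sample(5:30, 1)),
                 B = sample(universe, sample(5:30, 1)),
                 C = sample(universe, sample(5:30, 1)))
    rep_ <- venn_report(sets)
    # brute force: per-element membership pattern tally
    pat <- vapply(unique(unlist(sets)), function(e) {
      paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    brute <- table(pat)
    for (nm in names(rep_$regions)) {
      expect_equal(unname(rep_$regions[[nm]]),
                   if (nm %in% names(brute)) unname(brute[[nm]]) else 0L)
    }
    # sums to the union; per-set total = sum of regions containing the set
    expect_equal(sum(rep_$regions), rep_$union_size)
    for (nm in names(sets)) {
      in_regions <- grepl(paste0("(^|&)", nm, "(&|$)"), names(rep_$regions))
      expect_equal(sum(rep_$regions[in_regions]),
                   length(unique(sets[[nm]])))
    }
    # permutation invariance of set order (region names follow input order)
    rep2 <- venn_report(sets[c("C", "A", "B")])
    expect_equal(unname(rep2$regions[["C&A&B"]]),
                 unname(rep_$regions[["A&B&C"]]))
    expect_equal(unname(rep2$regions[["A"]]), unname(rep_$regions[["A"]]))
    expect_equal(rep2$union_size, rep_$union_size)
  }
})

test_that("reference overlap counts and the novel list are exact", {
  ov <- overlap_reference(c("A", "B", "C"),
                          list(ref1 = "A", ref2 = c("A", "B")))
  expect_equal(unname(ov$overlap), c(1, 2))
  expect_equal(ov$novel, "C")
  expect_equal(ov$novel_count, 1)
  # accounting: novel + in-any = study size
  expect_equal(ov$novel_count + sum(c("A", "B", "C") %in% c("A", "B")),
               ov$study_size)

  # empty reference: zero overlap, everything novel
  ov0 <- overlap_reference(c("x", "y"), list(empty = character(0)))
  expect_equal(unname(ov0$overlap), 0)
  expect_equal(ov0$novel_count, 2)

  expect_error(overlap_reference(character(0), list(r = "A")),
               class = "evlfq_config_error")
})

test_that("overlap normalizes case like the reference reader", {
  ov <- overlap_reference(c("Sfrp2", "kif5b", "Novel1"),
                          list(ev = c("SFRP2", "KIF5B")))
  expect_equal(unname(ov$overlap), 2)
  expect_equal(ov$novel, "NOVEL1")
})
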