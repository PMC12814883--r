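# Redundancy census: exact bookkeeping on the hand fixture, degenerate
# cohorts, brute-force oracle agreement, and permutation invariance.

test_that("census fractions equal hand-computed values on the fixture", {
  cohort <- census_fixture()
  asn <- assign_cohort(cohort)
  cen <- repeat_spacer_census(cohort, asn)
  ov <- cen[cen$cas_type == "overall", ]
  expect_equal(ov$n_arrays, 10)
  expect_equal(ov$frac_identical_repeat, 0.6)
  expect_equal(ov$frac_spacer_overlap, 0.4)
  expect_equal(ov$frac_identical_spacers, 0.2)
  expect_equal(ov$frac_same_last_spacer, 0.4)
  expect_equal(ov$frac_loci_multi_same_repeat, 0.75)
  # per-type slice: the two I-F arrays share a repeat but no spacers
  if_row <- cen[cen$cas_type == "I-F", ]
  expect_equal(if_row$frac_identical_repeat, 1)
  expect_equal(if_row$frac_spacer_overlap, 0)
})

test_that("arrays-per-locus summary matches the fixture by hand", {
  cohort <- census_fixture()
  apl <- arrays_per_locus(cohort, assign_cohort(cohort))
  counts <- apl$per_locus$n_arrays[match(c("L1", "L2", "L3", "L4"),
                                         apl$per_locus$locus_id)]
  expect_equal(counts, c(3L, 2L, 1L, 2L))
  ov <- apl$summary[apl$summary$cas_type == "overall", ]
  expect_equal(ov$mean, 2)
  expect_equal(ov$median, 2)
  expect_equal(ov$max, 3)
  # a locus with no assigned arrays counts as zero unless excluded
  lonely <- quick_genome("G9", loci = list(list(id = "L9", type = "V-A",
                                                start = 100, end = 200)))
  cohort2 <- c(cohort, list(G9 = lonely))
  apl2 <- arrays_per_locus(cohort2, assign_cohort(cohort2))
  expect_equal(apl2$per_locus$n_arrays[apl2$per_locus$locus_id == "L9"], 0L)
  apl3 <- arrays_per_locus(cohort2, assign_cohort(cohort2),
                           include_empty = FALSE)
  expect_false("L9" %in% apl3$per_locus$locus_id)
})

test_that("identical clones give fractions 1; all-distinct repeats give 0", {
  clones <- list(G = quick_genome("G",
    loci = list(list(id = "L", type = "I-E", start = 1000, end = 2000)),
    arrays = lapply(1:3, function(i)
      list(id = paste0("A", i), start = 3000 + 2000 * i, end = 4000 + 2000 * i,
           rep = "ACGTACGT", spacers = c("s1", "s2")))))
  cen <- repeat_spacer_census(clones, assign_cohort(clones))
  ov <- cen[cen$cas_type == "overall", ]
  expect_equal(ov$frac_identical_repeat, 1)
  expect_equal(ov$frac_spacer_overlap, 1)
  expect_equal(ov$frac_identical_spacers, 1)
  expect_equal(ov$frac_same_last_spacer, 1)
  expect_equal(ov$frac_loci_multi_same_repeat, 1)

  distinct <- list(G = quick_genome("G",
    loci = list(list(id = "L", type = "I-E", start = 1000, end = 2000)),
    arrays = lapply(1:3, function(i)
      list(id = paste0("A", i), start = 3000 + 2000 * i, end = 4000 + 2000 * i,
           rep = paste(rep(c("AC", "GT", "CA")[i], 4), collapse = ""),
           spacers = c("s1", "s2")))))
  cen0 <- repeat_spacer_census(distinct, assign_cohort(distinct))
  ov0 <- cen0[cen0$cas_type == "overall", ]
  expect_equal(ov0$frac_identical_repeat, 0)
  expect_equal(ov0$frac_spacer_overlap, 0)
  expect_equal(ov0$frac_identical_spacers, 0)
  expect_equal(ov0$frac_same_last_spacer, 0)
  expect_equal(ov0$frac_loci_multi_same_repeat, 0)
})

test_that("census agrees exactly with the brute-force pair scan", {
  spec <- cohort_spec(n_genomes = 120, substitution_prob = 0.01,
                      duplication_prob = 0.3, seed = 77)
  gen <- generate_cohort(spec)
  asn <- assign_cohort(gen$cohort)
  cen <- repeat_spacer_census(gen$cohort, asn)
  ov <- cen[cen$cas_type == "overall", ]
  bf <- brute_force_census(gen$cohort)
  expect_equal(ov$frac_identical_repeat, unname(bf["identical_repeat"]))
  expect_equal(ov$frac_spacer_overlap, unname(bf["spacer_overlap"]))
  expect_equal(ov$frac_identical_spacers, unname(bf["identical_spacers"]))
  expect_equal(ov$frac_same_last_spacer, unname(bf["same_last_spacer"]))
})

test_that("census is invariant under genome and array order permutations", {
  spec <- cohort_spec(n_genomes = 60, duplication_prob = 0.4, seed = 13)
  gen <- generate_cohort(spec)
  cohort <- gen$cohort
  set.seed(1)
  shuffled <- cohort[sample(length(cohort))]
  shuffled <- lapply(shuffled, function(g) {
    if (nrow(g$arrays) > 1) g$arrays <- g$arrays[sample(nrow(g$arrays)), ]
    g
  })
  c1 <- repeat_spacer_census(cohort, assign_cohort(cohort))
  c2 <- repeat_spacer_census(shuffled, assign_cohort(shuffled))
  o1 <- c1[c1$cas_type == "overall", ]
  o2 <- c2[c2$cas_type == "overall", ]
  for (col in c("frac_identical_repeat", "frac_spacer_overlap",
                "frac_identical_spacers", "frac_same_last_spacer",
                "frac_loci_multi_same_repeat"))
    expect_equal(o1[[col]], o2[[col]])
})

test_that("length-by-proximity summaries match hand computation", {
  g <- quick_genome("G",
    loci = list(list(id = "L", type = "II-C", start = 1000000, end = 1010000)),
    arrays = list(
      list(id = "c1", start = 1011000, end = 1012000, rep = "AC",
           spacers = paste0("s", 1:10)),
      list(id = "c2", start = 1013000, end = 1014000, rep = "AC",
           spacers = paste0("t", 1:12)),
      list(id = "f1", start = 2000000, end = 2001000, rep = "GT",
           spacers = paste0("u", 1:4)),
      list(id = "f2", start = 2100000, end = 2101000, rep = "GT",
           spacers = paste0("v", 1:6))))
  cohort <- list(G = g)
  lbp <- length_by_proximity(cohort, assign_cohort(cohort))
  close_row <- lbp[lbp$cas_type == "II-C" & lbp$is_close, ]
  far_row <- lbp[lbp$cas_type == "II-C" & !lbp$is_close, ]
  expect_equal(close_row$median, 11)
  expect_equal(far_row$median, 5)
  expect_equal(close_row$n, 2L)
  # restricting to repeats seen close drops the far GT arrays
  lbp_sr <- length_by_proximity(cohort, assign_cohort(cohort),
                                same_repeat_as_close = TRUE)
  expect_false(any(!lbp_sr$is_close))
})

test_that("generator acquisition bias shows up as longer close arrays", {
  spec <- cohort_spec(n_genomes = 1100, type_freqs = c(X = 1),
                      arrays_per_locus_dist = c("2" = 1), prob_close = 0.5,
                      duplication_prob = 0, orphan_rate = 0,
                      acquisition_bias = 3, seed = 5)
  gen <- generate_cohort(spec)
  lbp <- length_by_proximity(gen$cohort, assign_cohort(gen$cohort))
  cl <- lbp[lbp$cas_type == "X" & lbp$is_close, ]
  fa <- lbp[lbp$cas_type == "X" & !lbp$is_close, ]
  expect_gte(cl$n + fa$n, 2000)
  # biased theta triples the stationary mean; difference >> 3 SE
  se <- sqrt(cl$mean / cl$n + fa$mean / fa$n)  # Poisson var = mean
  expect_gt(cl$mean - fa$mean, 3 * se)
})
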