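# Repeat similarity: edit distance vs oracles, normalization, SMACOF
# embedding, KDE marginals, and within-genome distance distributions.

test_that("edit distance matches worked examples and the recursive oracle", {
  expect_equal(edit_distance("GTTTCCC", "GTTTCCC"), 0L)
  expect_equal(edit_distance("ACGT", ""), 4L)
  expect_equal(edit_distance("", ""), 0L)
  expect_equal(edit_distance("kitten", "sitting"), 3L)
  # exhaustive binary pairs up to length 3 against top-down recursion
  strs <- binary_strings(3)
  for (a in strs) for (b in strs)
    expect_identical(edit_distance(a, b), recursive_levenshtein(a, b))
  # random DNA pairs against the independent C implementation
  set.seed(41)
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE), collapse = "")
    expect_identical(edit_distance(a, b), as.integer(utils::adist(a, b)))
  }
})

test_that("unnormalized repeat distances satisfy the metric axioms", {
  set.seed(42)
  reps <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(18:36, 1), TRUE), collapse = ""),
    character(1))
  D <- distance_matrix(data.frame(array_id = paste0("r", 1:40),
                                  consensus_repeat = reps),
                       normalization = "none")$D
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  for (i in 1:1000) {
    ijk <- sample(40, 3)
    expect_lte(D[ijk[1], ijk[3]], D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]])
  }
})

test_that("normalization divides by the per-genome or global maximum length", {
  r30 <- paste(rep("A", 30), collapse = "")
  r36 <- paste(c(rep("C", 18), rep("G", 18)), collapse = "")
  raw <- edit_distance(r30, r36)
  df <- data.frame(array_id = c("a", "b"), genome_id = "G",
                   consensus_repeat = c(r30, r36), stringsAsFactors = FALSE)
  Dg <- distance_matrix(df, normalization = "per_genome_max")$D
  expect_equal(Dg["a", "b"], raw / 36)
  r40 <- paste(rep("T", 40), collapse = "")
  df3 <- data.frame(array_id = c("a", "b", "c"),
                    consensus_repeat = c(r30, r36, r40), stringsAsFactors = FALSE)
  Dglob <- distance_matrix(df3, normalization = "global_max")$D
  expect_equal(Dglob["a", "b"], raw / 40)
  # identical repeats -> all-zero matrix; per-genome scope enforced
  same <- data.frame(array_id = c("x", "y"), genome_id = c("G1", "G2"),
                     consensus_repeat = c(r30, r30), stringsAsFactors = FALSE)
  expect_true(all(distance_matrix(same, normalization = "none")$D == 0))
  expect_error(distance_matrix(same, normalization = "per_genome_max"),
               "single genome")
  expect_error(distance_matrix(same[0, ], "none"), "no arrays")
})

test_that("SMACOF recovers exactly embeddable configurations", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  emb <- mds_embed(tri, seed = 2, n_init = 4, max_iter = 2000, tol = 1e-14)
  expect_lt(emb$stress, 1e-6)
  sq <- rbind(c(0, 1, sqrt(2), 1),
              c(1, 0, 1, sqrt(2)),
              c(sqrt(2), 1, 0, 1),
              c(1, sqrt(2), 1, 0))
  emb2 <- mds_embed(sq, seed = 2, n_init = 4, max_iter = 5000, tol = 1e-15)
  expect_lt(emb2$stress, 1e-6)
  rec <- as.matrix(stats::dist(emb2$coords))
  expect_lt(max(abs(rec - sq)), 1e-3)
  # agreement with classical scaling on an exactly embeddable set
  cmds <- stats::cmdscale(sq, k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(cmds)) - rec)), 1e-3)
})

test_that("SMACOF stress is monotonically non-increasing and inputs validated", {
  set.seed(3)
  pts <- matrix(stats::rnorm(24), ncol = 2)
  D <- as.matrix(stats::dist(pts)) + stats::runif(144, 0, 0.05)
  D <- (D + t(D)) / 2; diag(D) <- 0
  emb <- mds_embed(D, seed = 7, n_init = 3, max_iter = 200, tol = 1e-10)
  expect_true(all(diff(emb$stress_trace) <= 1e-12))
  expect_lte(emb$stress, emb$stress_trace[1])
  bad <- D; bad[1, 2] <- bad[2, 1] <- NA
  expect_error(mds_embed(bad), "non-finite")
  # degenerate single point
  one <- mds_embed(matrix(0, 1, 1))
  expect_equal(one$stress, 0)
  expect_equal(unname(one$coords), matrix(0, 1, 2))
})

test_that("the Gaussian KDE integrates to one and preserves shape", {
  set.seed(8)
  x <- stats::rnorm(400)
  kd <- kde_marginal(x, grid = seq(-6, 6, length.out = 2001))
  area <- sum(diff(kd$grid) * (utils::head(kd$density, -1) +
                                 utils::tail(kd$density, -1)) / 2)
  expect_lt(abs(area - 1), 0.01)
  expect_true(all(kd$density >= 0))
  # symmetric sample -> symmetric density about the mean
  xs <- c(x, -x)
  kds <- kde_marginal(xs, grid = seq(-6, 6, length.out = 401))
  expect_lt(max(abs(kds$density - rev(kds$density))), 1e-10)
  # two well-separated clusters -> bimodal
  xb <- c(stats::rnorm(300, -10, 0.5), stats::rnorm(300, 10, 0.5))
  kb <- kde_marginal(xb, grid = seq(-14, 14, length.out = 801))
  d <- kb$density
  maxima <- which(d > c(-Inf, utils::head(d, -1)) &
                    d > c(utils::tail(d, -1), -Inf) & d > max(d) / 10)
  expect_equal(length(maxima), 2)
  expect_error(kde_marginal(rep(1, 10)), "distinct")
})

test_that("within-genome distance distribution pools k(k-1)/2 pairs per genome", {
  cohort <- census_fixture()
  dd <- distance_distribution(cohort)
  counts <- table(dd$genome_id)
  expect_equal(as.integer(counts[c("G1", "G2", "G4", "G5")]),
               c(3L, 1L, 1L, 1L))  # k = 3,2,2,2; G3 has one array
  expect_false("G3" %in% dd$genome_id)
  expect_equal(dd$distance[dd$genome_id == "G2"], 0)  # identical repeats
  # two distant ancestral repeats co-occurring -> mass at 0 and far from 0
  spec <- cohort_spec(n_genomes = 150, type_freqs = c(A = 0.9, B = 0.9),
                      substitution_prob = 0, duplication_prob = 0.5,
                      orphan_rate = 0, seed = 19)
  gen <- generate_cohort(spec)
  dd2 <- distance_distribution(gen$cohort, normalization = "per_genome_max")
  expect_gt(mean(dd2$distance == 0), 0.05)
  expect_gt(mean(dd2$distance > 0.3), 0.05)
})
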