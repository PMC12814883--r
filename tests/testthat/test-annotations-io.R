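# Annotation I/O and array-to-locus assignment.

test_that("cohort TSV round-trip preserves every field", {
  cohort <- census_fixture()
  a1 <- tempfile(fileext = ".tsv"); l1 <- tempfile(fileext = ".tsv")
  write_cohort(cohort, a1, l1)
  back <- read_cohort(a1, l1)
  # genome without arrays or loci cannot round-trip; fixture has none such
  expect_setequal(names(back), names(cohort))
  for (gid in names(cohort)) {
    expect_equal(back[[gid]]$loci, cohort[[gid]]$loci, ignore_attr = TRUE)
    ref <- cohort[[gid]]$arrays
    got <- got0 <- back[[gid]]$arrays
    got <- got[match(ref$array_id, got$array_id), ]
    expect_equal(got$start, ref$start)
    expect_equal(got$consensus_repeat, ref$consensus_repeat)
    expect_equal(got$spacers, ref$spacers, ignore_attr = TRUE)
  }
  # write(read(x)) is byte-identical to write(x)
  a2 <- tempfile(fileext = ".tsv"); l2 <- tempfile(fileext = ".tsv")
  write_cohort(back, a2, l2)
  expect_identical(readLines(a1), readLines(a2))
  expect_identical(readLines(l1), readLines(l2))
})

test_that("reader reports file, line, and field on malformed input", {
  a <- tempfile(); l <- tempfile()
  writeLines(c(paste(c("genome_id", "seq_id", "array_id", "start", "end",
                       "orientation", "confidence", "consensus_repeat",
                       "spacers"), collapse = "\t"),
               "G1\tchr\tA1\tnot_a_number\t200\tforward\tbona-fide\tACGT\ts1,s2"),
             a)
  writeLines(paste(c("genome_id", "seq_id", "locus_id", "cas_type", "start",
                     "end"), collapse = "\t"), l)
  expect_error(read_cohort(a, l), "line 2.*start", ignore.case = TRUE)

  writeLines(c(paste(c("genome_id", "seq_id", "array_id", "start", "end",
                       "orientation", "confidence", "consensus_repeat",
                       "spacers"), collapse = "\t"),
               "G1\tchr\tA1\t100\t200\tforward\tbona-fide\tACGT\ts1",
               "G2\tchr\tA1\t100\t200\tforward\tbona-fide\tACGT\ts1"),
             a)
  expect_error(read_cohort(a, l), "duplicate array_id")

  writeLines("genome_id\tseq_id", a)
  expect_error(read_cohort(a, l), "missing required column")
})

test_that("loci-only and arrays-only genomes survive reading", {
  cohort <- list(
    quick_genome("GA", loci = list(list(id = "L1", type = "I-E",
                                        start = 100, end = 200)),
                 arrays = list(list(id = "A1", start = 300, end = 400,
                                    rep = "ACGT", spacers = "s1"))),
    quick_genome("GB", arrays = list(list(id = "B1", start = 10, end = 20,
                                          rep = "ACGT", spacers = "s1"))),
    quick_genome("GC", loci = list(list(id = "L2", type = "II-C",
                                        start = 5, end = 50))))
  a <- tempfile(); l <- tempfile()
  write_cohort(cohort, a, l)
  back <- read_cohort(a, l)
  expect_setequal(names(back), c("GA", "GB", "GC"))
  expect_equal(nrow(back$GB$loci), 0)
  expect_equal(nrow(back$GC$arrays), 0)
})

test_that("assignment follows the nearest-gap rule with the stated sides", {
  g <- quick_genome("G",
    loci = list(list(id = "L", type = "I-E", start = 10000, end = 15000)),
    arrays = list(
      list(id = "after", start = 20000, end = 21000, rep = "ACGT", spacers = "s1"),
      list(id = "overlap", start = 14000, end = 16000, rep = "ACGT", spacers = "s2"),
      list(id = "before", start = 2000, end = 3000, rep = "ACGT", spacers = "s3")))
  a <- assign_arrays(g)
  a <- a[match(c("after", "overlap", "before"), a$array_id), ]
  expect_equal(a$side, c("after", "overlap", "before"))
  expect_equal(a$signed_distance, c(5000L, 0L, -7000L))
  expect_equal(a$is_close, c(TRUE, TRUE, TRUE))
  expect_equal(a$assigned_type, rep("I-E", 3))
})

test_that("genomes without Cas loci yield orphans labelled 'no cas type'", {
  g <- quick_genome("G", arrays = list(
    list(id = "A1", start = 100, end = 200, rep = "ACGT", spacers = "s1"),
    list(id = "A2", start = 500, end = 700, rep = "ACGT", spacers = "s2")))
  a <- assign_arrays(g)
  expect_true(all(a$side == "orphan"))
  expect_true(all(a$assigned_type == "no cas type"))
  expect_true(all(is.na(a$locus_id)))
  expect_false(any(a$is_close))
})

test_that("equidistant loci are resolved to the smaller start coordinate", {
  g <- quick_genome("G",
    loci = list(list(id = "Lright", type = "A", start = 30000, end = 31000),
                list(id = "Lleft", type = "B", start = 9000, end = 10000)),
    arrays = list(list(id = "A1", start = 15000, end = 25000,
                       rep = "ACGT", spacers = "s1")))
  a <- assign_arrays(g)
  expect_equal(a$locus_id, "Lleft")
  expect_equal(a$assigned_type, "B")
})

test_that("assigned locus always minimises the gap; thresholds behave at extremes", {
  set.seed(21)
  for (rep_i in 1:20) {
    n_loc <- sample(1:4, 1)
    starts <- sort(sample(seq(1000, 900000, by = 1000), n_loc + 2))
    g <- quick_genome("G",
      loci = lapply(seq_len(n_loc), function(i)
        list(id = paste0("L", i), type = "T", start = starts[i],
             end = starts[i] + 500)),
      arrays = list(list(id = "A", start = starts[n_loc + 1],
                         end = starts[n_loc + 1] + 300,
                         rep = "ACGT", spacers = "s")))
    a <- assign_arrays(g)
    gaps <- sapply(seq_len(n_loc), function(i) {
      max(0, max(starts[n_loc + 1], starts[i]) -
            min(starts[n_loc + 1] + 300, starts[i] + 500))
    })
    expect_equal(abs(a$signed_distance), min(gaps))
    expect_true(assign_arrays(g, close_threshold_bp = Inf)$is_close)
    expect_false(assign_arrays(g, close_threshold_bp = 0)$is_close)
  }
})

test_that("distances are computed within a replicon only", {
  g <- quick_genome("G",
    loci = list(list(id = "L1", type = "I-E", start = 100, end = 200,
                     seq_id = "chr")),
    arrays = list(
      list(id = "Achr", start = 300, end = 400, rep = "ACGT",
           spacers = "s1", seq_id = "chr"),
      list(id = "Aplasmid", start = 300, end = 400, rep = "ACGT",
           spacers = "s2", seq_id = "plasmid")))
  a <- assign_arrays(g)
  expect_equal(a$side[a$array_id == "Achr"], "after")
  expect_equal(a$side[a$array_id == "Aplasmid"], "orphan")
})
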