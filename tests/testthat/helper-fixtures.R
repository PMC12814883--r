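# Shared fixtures built in code. quick_genome() assembles a genome_annotation
# from terse locus/array tuples; census_fixture() is the hand-computed
# five-genome cohort used for exact census bookkeeping checks.

quick_genome <- function(gid, loci = NULL, arrays = NULL, seq_id = "chr") {
  ldf <- NULL
  if (length(loci)) {
    ldf <- do.call(rbind, lapply(loci, function(l) {
      data.frame(locus_id = l$id, seq_id = if (!is.null(l$seq_id)) l$seq_id else seq_id,
                 cas_type = l$type, start = l$start, end = l$end,
                 stringsAsFactors = FALSE)
    }))
  }
  adf <- NULL
  if (length(arrays)) {
    adf <- do.call(rbind, lapply(arrays, function(a) {
      df <- data.frame(array_id = a$id,
                       seq_id = if (!is.null(a$seq_id)) a$seq_id else seq_id,
                       start = a$start, end = a$end,
                       orientation = if (!is.null(a$orientation)) a$orientation else "forward",
                       confidence = if (!is.null(a$confidence)) a$confidence else "bona-fide",
                       consensus_repeat = a$rep, stringsAsFactors = FALSE)
      df$spacers <- list(a$spacers)
      df
    }))
  }
  genome_annotation(gid, loci = ldf, arrays = adf)
}

# Five genomes, ten arrays. Hand-computed expectations:
#   frac_identical_repeat  = 6/10 (A1,A2,B1,B2,E1,E2)
#   frac_spacer_overlap    = 4/10 (A1,A2 share s3; B1,B2 clones)
#   frac_identical_spacers = 2/10 (B1,B2)
#   frac_same_last_spacer  = 4/10 (A1,A2 end in s3; B1,B2 end in t2)
#   loci with >=2 same-repeat arrays = 3/4 (L1, L2, L4; not L3)
#   arrays per locus: L1=3, L2=2, L3=1, L4=2 -> mean 2, median 2, max 3
census_fixture <- function() {
  g1 <- quick_genome("G1",
    loci = list(list(id = "L1", type = "I-E", start = 100000, end = 110000)),
    arrays = list(
      list(id = "A1", start = 111000, end = 112000, rep = "AAAACCCC",
           spacers = c("s1", "s2", "s3")),
      list(id = "A2", start = 95000, end = 96000, rep = "AAAACCCC",
           spacers = c("s4", "s5", "s3")),
      list(id = "A3", start = 120000, end = 121000, rep = "GGGGTTTT",
           spacers = c("s6", "s7"))))
  g2 <- quick_genome("G2",
    loci = list(list(id = "L2", type = "II-C", start = 50000, end = 60000)),
    arrays = list(
      list(id = "B1", start = 61000, end = 62000, rep = "ACACACAC",
           spacers = c("t1", "t2")),
      list(id = "B2", start = 63000, end = 64000, rep = "ACACACAC",
           spacers = c("t1", "t2"))))
  g3 <- quick_genome("G3",
    loci = list(list(id = "L3", type = "I-E", start = 10000, end = 20000)),
    arrays = list(
      list(id = "C1", start = 21000, end = 22000, rep = "TTTTGGGG",
           spacers = "u1")))
  g4 <- quick_genome("G4",
    arrays = list(
      list(id = "D1", start = 5000, end = 6000, rep = "CCCCAAAA",
           spacers = c("v1", "v2")),
      list(id = "D2", start = 9000, end = 10000, rep = "AATTCCGG",
           spacers = "v3")))
  g5 <- quick_genome("G5",
    loci = list(list(id = "L4", type = "I-F", start = 200000, end = 210000)),
    arrays = list(
      list(id = "E1", start = 211000, end = 212000, rep = "GCGCGCGC",
           spacers = c("w1", "w2")),
      list(id = "E2", start = 195000, end = 196000, rep = "GCGCGCGC",
           spacers = c("x1", "x2"))))
  list(G1 = g1, G2 = g2, G3 = g3, G4 = g4, G5 = g5)
}

# Independent brute-force recomputation of the census fractions by scanning
# all within-genome array pairs (quadratic; used as the oracle).
brute_force_census <- function(cohort) {
  arr <- do.call(rbind, lapply(cohort, function(g) {
    if (!nrow(g$arrays)) return(NULL)
    df <- data.frame(genome_id = g$genome_id, array_id = g$arrays$array_id,
                     rep = toupper(g$arrays$consensus_repeat),
                     stringsAsFactors = FALSE)
    df$spacers <- g$arrays$spacers
    df
  }))
  n <- nrow(arr)
  ir <- so <- is_ <- sl <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || arr$genome_id[i] != arr$genome_id[j]) next
      if (arr$rep[i] != arr$rep[j]) next
      ir[i] <- TRUE
      si <- arr$spacers[[i]]; sj <- arr$spacers[[j]]
      if (any(si %in% sj)) so[i] <- TRUE
      if (identical(sort(si), sort(sj))) is_[i] <- TRUE
      if (si[length(si)] == sj[length(sj)]) sl[i] <- TRUE
    }
  }
  c(identical_repeat = mean(ir), spacer_overlap = mean(so),
    identical_spacers = mean(is_), same_last_spacer = mean(sl))
}

# Memoised top-down recursive Levenshtein oracle (independent of the
# package's bottom-up implementation).
recursive_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, length(x) + 1L, length(y) + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j else if (j == 0L) i else {
      min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
          rec(i - 1L, j - 1L) + (x[i] != y[j]))
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(length(x), length(y))
}

# all binary strings of length 0..max_len
binary_strings <- function(max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("0", "1")), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}
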