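# Observed vs expected occurrence of Cas types, alone and in pairs, with
# signed fold-changes and exact binomial tests.

#' Genome-by-type presence table
#'
#' A Cas type is present in a genome iff at least one Cas locus of that type
#' is annotated there. Orphan arrays contribute no type.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @return Logical matrix, genomes x types (0 columns if no loci anywhere).
#' @export
type_presence <- function(cohort) {
  if (!length(cohort)) {
    return(matrix(logical(0), nrow = 0, ncol = 0))
  }
  types <- sort(unique(unlist(lapply(cohort, function(g) g$loci$cas_type))))
  m <- matrix(FALSE, nrow = length(cohort), ncol = length(types),
              dimnames = list(vapply(cohort, function(g) g$genome_id, character(1)),
                              types))
  for (i in seq_along(cohort)) {
    tt <- unique(cohort[[i]]$loci$cas_type)
    if (length(tt)) m[i, tt] <- TRUE
  }
  m
}

#' Expected number of genomes where two Cas types co-occur
#'
#' Under independent reshuffling of presence labels, a type present in `j` of
#' `n` genomes and another present in `k` of `n` co-occur with probability
#' `(j/n)(k/n)` per genome, i.e. an expected count of `j * k / n`.
#'
#' @param j,k Genome counts of the two types.
#' @param n Total genomes (>= 1).
#' @return Expected co-occurrence count.
#' @export
expected_pair_count <- function(j, k, n) {
  if (n < 1) stop("n must be >= 1")
  if (any(c(j, k) < 0) || any(c(j, k) > n)) stop("j and k must lie in [0, n]")
  j * k / n
}

#' Expected number of genomes where a type occurs as the only system
#'
#' Under independence the expected count of genomes containing type `t` and
#' no other type is `j_t * prod_{s != t} (1 - j_s / n)`.
#'
#' @param counts Named vector of per-type genome counts.
#' @param type Type whose solo count is wanted.
#' @param n Total genomes.
#' @return Expected solo-occurrence count.
#' @export
expected_solo_count <- function(counts, type, n) {
  if (!type %in% names(counts)) stop("unknown type: ", type)
  if (any(counts > n)) stop("counts cannot exceed n")
  others <- counts[setdiff(names(counts), type)]
  counts[[type]] * prod(1 - others / n)
}

#' Signed fold-change between observed and expected counts
#'
#' Returns `observed / expected` when observed >= expected and
#' `-(expected / observed)` otherwise, so the magnitude is always >= 1 and a
#' fold-change of -5 means the observed count is 5-fold smaller than
#' expected. `observed = 0` has no finite ratio; the value `-expected` is
#' returned as a lower-bound sentinel (the true magnitude of depletion is at
#' least `expected`-fold).
#'
#' @param observed Observed count (>= 0).
#' @param expected Expected count (> 0).
#' @return Signed fold-change (vectorised).
#' @export
fold_change <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be > 0")
  if (any(observed < 0)) stop("observed must be >= 0")
  ifelse(observed == 0, -expected,
         ifelse(observed >= expected, observed / expected, -expected / observed))
}

#' Exact binomial test of a solo-occurrence count
#'
#' Two-sided exact binomial test of `observed_solo` successes in `n` trials
#' against success probability `p_solo` (the expected solo count divided by
#' `n`), using the minimum-likelihood rule for the opposite tail.
#'
#' @param observed_solo Observed solo count.
#' @param n Number of genomes.
#' @param p_solo Null solo probability.
#' @return p-value in \[0, 1\].
#' @export
binomial_solo_test <- function(observed_solo, n, p_solo) {
  stopifnot(observed_solo >= 0, observed_solo <= n, p_solo >= 0, p_solo <= 1)
  stats::binom.test(observed_solo, n, p = p_solo,
                    alternative = "two.sided")$p.value
}

#' Observed vs expected co-occurrence of Cas types
#'
#' For every Cas type: the number of genomes where it occurs as the only
#' system, the expectation under independent reshuffling, the signed
#' fold-change, and a two-sided exact binomial p-value. For every unordered
#' type pair: observed and expected joint counts, fold-change, and (for
#' information; pairs are gated by count only) a binomial p-value. A pair
#' cell is flagged `reported` iff observed or expected reaches `min_count`; a
#' solo cell additionally requires p-value < `alpha`.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param min_count Minimum observed-or-expected count for a cell to be
#'   reported (default 50).
#' @param alpha Significance gate for solo cells (default 1e-4).
#' @return Object of class `cooccurrence_table`: a data frame with columns
#'   `kind` (`solo`/`pair`), `type_a`, `type_b`, `observed`, `expected`,
#'   `fold_change`, `fold_change_lower_bound` (TRUE when observed = 0 and
#'   the fold-change is the `-expected` sentinel), `p_value`, `reported`;
#'   attributes `n_genomes` and `type_counts`.
#' @export
cooccurrence_table <- function(cohort, min_count = 50, alpha = 0.0001) {
  if (!length(cohort)) stop("cohort is empty")
  pres <- type_presence(cohort)
  n <- nrow(pres)
  types <- colnames(pres)
  rows <- list()
  if (length(types)) {
    counts <- colSums(pres)
    n_types_per_genome <- rowSums(pres)
    for (t in types) {
      obs_solo <- sum(pres[, t] & n_types_per_genome == 1L)
      exp_solo <- expected_solo_count(counts, t, n)
      fc <- if (exp_solo > 0) fold_change(obs_solo, exp_solo) else NA_real_
      pv <- binomial_solo_test(obs_solo, n, exp_solo / n)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "solo", type_a = t, type_b = t,
        observed = obs_solo, expected = exp_solo, fold_change = fc,
        fold_change_lower_bound = obs_solo == 0 && exp_solo > 0,
        p_value = pv,
        reported = max(obs_solo, exp_solo) >= min_count && pv < alpha,
        stringsAsFactors = FALSE)
    }
    if (length(types) >= 2L) {
      joint <- crossprod(pres)  # symmetric observed pair counts
      for (i in seq_along(types)) {
        for (jdx in seq_along(types)) {
          if (jdx <= i) next
          s <- types[i]; t <- types[jdx]
          obs <- joint[s, t]
          expc <- expected_pair_count(counts[[s]], counts[[t]], n)
          fc <- if (expc > 0) fold_change(obs, expc) else NA_real_
          pv <- if (expc > 0) binomial_solo_test(obs, n, expc / n) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "pair", type_a = s, type_b = t,
            observed = obs, expected = expc, fold_change = fc,
            fold_change_lower_bound = obs == 0 && expc > 0,
            p_value = pv,
            reported = max(obs, expc) >= min_count,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), type_a = character(), type_b = character(),
               observed = numeric(), expected = numeric(),
               fold_change = numeric(), fold_change_lower_bound = logical(),
               p_value = numeric(), reported = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_genomes") <- n
  attr(out, "type_counts") <- if (length(types)) colSums(pres) else numeric(0)
  class(out) <- c("cooccurrence_table", "data.frame")
  out
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("Cas-type co-occurrence over %d genomes (%d solo, %d pair cells; %d reported)\n",
              attr(x, "n_genomes"), sum(x$kind == "solo"), sum(x$kind == "pair"),
              sum(x$reported)))
  df <- as.data.frame(x)
  for (col in c("expected", "fold_change"))
    if (col %in% names(df)) df[[col]] <- round(df[[col]], 2)
  if ("p_value" %in% names(df)) df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
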