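# Redundancy census: arrays-per-locus statistics, identical-repeat and
# spacer-sharing fractions, and array-length statistics by type and
# proximity to the Cas locus.

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1)))
}

# canonical repeat key, optionally folding reverse complements together
repeat_key <- function(repeats, reverse_complement_aware = FALSE) {
  r <- toupper(repeats)
  if (!reverse_complement_aware) return(r)
  rc <- toupper(reverse_complement(r))
  ifelse(r <= rc, r, rc)
}

summarise_counts <- function(x) {
  if (!length(x)) return(c(mean = NA_real_, median = NA_real_, max = NA_real_))
  c(mean = mean(x), median = stats::median(x), max = max(x))
}

#' Arrays-per-locus counts and summaries
#'
#' Counts, for every Cas locus, the arrays assigned to it (orphans excluded).
#' Loci with zero assigned arrays contribute a count of 0 by default.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param assignments Long assignment table from [assign_cohort()].
#' @param include_empty Include loci with no assigned array in the
#'   denominator (default TRUE).
#' @return List with `per_locus` (`genome_id`, `locus_id`, `cas_type`,
#'   `n_arrays`) and `summary` (per Cas type plus an `overall` row: `n_loci`,
#'   `mean`, `median`, `max`).
#' @export
arrays_per_locus <- function(cohort, assignments, include_empty = TRUE) {
  loci <- do.call(rbind, lapply(cohort, function(g) {
    if (!nrow(g$loci)) return(NULL)
    data.frame(genome_id = g$genome_id, locus_id = g$loci$locus_id,
               cas_type = g$loci$cas_type, stringsAsFactors = FALSE)
  }))
  if (is.null(loci)) {
    return(list(per_locus = data.frame(genome_id = character(),
                                       locus_id = character(),
                                       cas_type = character(),
                                       n_arrays = integer()),
                summary = data.frame(cas_type = character(), n_loci = integer(),
                                     mean = numeric(), median = numeric(),
                                     max = numeric())))
  }
  assigned <- assignments[assignments$side != "orphan", , drop = FALSE]
  tab <- table(assigned$locus_id)
  loci$n_arrays <- as.integer(tab[loci$locus_id])
  loci$n_arrays[is.na(loci$n_arrays)] <- 0L
  if (!include_empty) loci <- loci[loci$n_arrays > 0L, , drop = FALSE]
  groups <- split(loci$n_arrays, loci$cas_type)
  groups$overall <- loci$n_arrays
  summ <- do.call(rbind, lapply(names(groups), function(ty) {
    s <- summarise_counts(groups[[ty]])
    data.frame(cas_type = ty, n_loci = length(groups[[ty]]),
               mean = s["mean"], median = s["median"], max = s["max"],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  rownames(loci) <- NULL
  list(per_locus = loci, summary = summ)
}

# flat per-array view of a cohort used by the census and the weights module
flatten_arrays <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(g) {
    if (!nrow(g$arrays)) return(NULL)
    df <- data.frame(genome_id = g$genome_id, array_id = g$arrays$array_id,
                     consensus_repeat = g$arrays$consensus_repeat,
                     n_spacers = vapply(g$arrays$spacers, length, integer(1)),
                     stringsAsFactors = FALSE)
    df$spacers <- g$arrays$spacers
    df$last_spacer <- vapply(g$arrays$spacers, function(s) s[length(s)], character(1))
    df
  }))
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), array_id = character(),
                      consensus_repeat = character(), n_spacers = integer(),
                      last_spacer = character(), stringsAsFactors = FALSE)
    out$spacers <- list()
  }
  rownames(out) <- NULL
  out
}

#' Census of identical repeats and shared spacers
#'
#' For every array, flags whether (a) at least one other array in the same
#' genome carries a byte-identical consensus repeat; and, among such arrays,
#' whether it (b) shares at least one spacer string with a same-repeat
#' partner, (c) has a spacer multiset identical to a partner's, (d) shares
#' the leader-distal (last, oldest) spacer with a partner. All four fractions
#' use the total number of arrays as denominator, so (b)-(d) are sub-fractions
#' of (a). Additionally reports the fraction of Cas loci with at least two
#' assigned arrays of identical consensus repeat.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param assignments Long assignment table from [assign_cohort()].
#' @param reverse_complement_aware Fold reverse-complement repeats together
#'   before comparison (default FALSE: repeats are compared exactly as
#'   reported).
#' @return Object of class `census_report`: data frame with one row per
#'   assigned type plus an `overall` row, columns `n_arrays`,
#'   `frac_identical_repeat`, `frac_spacer_overlap`, `frac_identical_spacers`,
#'   `frac_same_last_spacer`, and (overall row only) `n_loci`,
#'   `frac_loci_multi_same_repeat`. Per-array flags are in the
#'   `per_array` attribute.
#' @export
repeat_spacer_census <- function(cohort, assignments,
                                 reverse_complement_aware = FALSE) {
  arr <- flatten_arrays(cohort)
  n_arr <- nrow(arr)
  if (!n_arr) stop("cohort contains no arrays")
  arr$key <- repeat_key(arr$consensus_repeat, reverse_complement_aware)
  arr$assigned_type <- assignments$assigned_type[match(arr$array_id, assignments$array_id)]

  arr$identical_repeat <- FALSE
  arr$spacer_overlap <- FALSE
  arr$identical_spacers <- FALSE
  arr$same_last_spacer <- FALSE

  for (idx in split(seq_len(n_arr), arr$genome_id)) {
    if (length(idx) < 2L) next
    keys <- arr$key[idx]
    for (grp in split(idx, keys)) {
      if (length(grp) < 2L) next
      arr$identical_repeat[grp] <- TRUE
      sorted <- lapply(arr$spacers[grp], sort)
      for (pos in seq_along(grp)) {
        i <- grp[pos]
        partners <- grp[-pos]
        sp <- arr$spacers[[i]]
        arr$spacer_overlap[i] <- any(vapply(partners, function(j) {
          any(sp %in% arr$spacers[[j]])
        }, logical(1)))
        arr$identical_spacers[i] <- any(vapply(seq_along(grp)[-pos], function(q) {
          identical(sorted[[pos]], sorted[[q]])
        }, logical(1)))
        arr$same_last_spacer[i] <- any(arr$last_spacer[partners] == arr$last_spacer[i])
      }
    }
  }

  # locus-level: >= 2 assigned arrays sharing one consensus repeat
  assigned <- assignments[assignments$side != "orphan", , drop = FALSE]
  locus_ids <- unlist(lapply(cohort, function(g) g$loci$locus_id))
  n_loci <- length(locus_ids)
  multi_same <- character(0)
  if (nrow(assigned)) {
    akey <- arr$key[match(assigned$array_id, arr$array_id)]
    per_locus <- split(akey, assigned$locus_id)
    multi_same <- names(per_locus)[vapply(per_locus, function(k) {
      any(table(k) >= 2L)
    }, logical(1))]
  }

  frac <- function(flag, rows) if (length(rows)) mean(flag[rows]) else NA_real_
  groups <- split(seq_len(n_arr), arr$assigned_type)
  groups$overall <- seq_len(n_arr)
  out <- do.call(rbind, lapply(names(groups), function(ty) {
    rows <- groups[[ty]]
    data.frame(cas_type = ty, n_arrays = length(rows),
               frac_identical_repeat = frac(arr$identical_repeat, rows),
               frac_spacer_overlap = frac(arr$spacer_overlap, rows),
               frac_identical_spacers = frac(arr$identical_spacers, rows),
               frac_same_last_spacer = frac(arr$same_last_spacer, rows),
               stringsAsFactors = FALSE)
  }))
  out$n_loci <- ifelse(out$cas_type == "overall", n_loci, NA_integer_)
  out$frac_loci_multi_same_repeat <-
    ifelse(out$cas_type == "overall" & n_loci > 0,
           length(multi_same) / max(n_loci, 1L), NA_real_)
  rownames(out) <- NULL
  per_array <- arr[, c("genome_id", "array_id", "assigned_type",
                       "identical_repeat", "spacer_overlap",
                       "identical_spacers", "same_last_spacer")]
  structure(out, per_array = per_array,
            class = c("census_report", "data.frame"))
}

#' @export
print.census_report <- function(x, ...) {
  ov <- x[x$cas_type == "overall", ]
  cat(sprintf(paste0("Redundancy census over %d arrays: %.1f%% share a repeat ",
                     "in-genome; %.1f%% spacer overlap; %.1f%% identical ",
                     "spacers; %.1f%% same last spacer\n"),
              ov$n_arrays, 100 * ov$frac_identical_repeat,
              100 * ov$frac_spacer_overlap, 100 * ov$frac_identical_spacers,
              100 * ov$frac_same_last_spacer))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Array-length summaries by type and proximity to the Cas locus
#'
#' Mean/median/max spacer counts per (assigned type, close flag) cell,
#' orphans excluded. With `same_repeat_as_close = TRUE` the table is
#' restricted to arrays whose consensus repeat matches that of at least one
#' close array in the same genome, which isolates length differences among
#' arrays sharing one repeat from differences between repeat families.
#'
#' @inheritParams repeat_spacer_census
#' @param same_repeat_as_close Restrict to arrays sharing a close array's
#'   consensus repeat (default FALSE).
#' @return `data.frame`: `cas_type` (plus `overall` rows), `is_close`, `n`,
#'   `mean`, `median`, `max`.
#' @export
length_by_proximity <- function(cohort, assignments,
                                same_repeat_as_close = FALSE) {
  arr <- flatten_arrays(cohort)
  m <- match(arr$array_id, assignments$array_id)
  arr$assigned_type <- assignments$assigned_type[m]
  arr$is_close <- assignments$is_close[m]
  arr$side <- assignments$side[m]
  arr <- arr[arr$side != "orphan", , drop = FALSE]
  if (same_repeat_as_close && nrow(arr)) {
    keep <- logical(nrow(arr))
    for (idx in split(seq_len(nrow(arr)), arr$genome_id)) {
      close_reps <- unique(arr$consensus_repeat[idx][arr$is_close[idx]])
      keep[idx] <- arr$consensus_repeat[idx] %in% close_reps
    }
    arr <- arr[keep, , drop = FALSE]
  }
  if (!nrow(arr)) {
    return(data.frame(cas_type = character(), is_close = logical(),
                      n = integer(), mean = numeric(), median = numeric(),
                      max = numeric(), stringsAsFactors = FALSE))
  }
  cells <- rbind(
    data.frame(cas_type = arr$assigned_type, is_close = arr$is_close,
               n_spacers = arr$n_spacers, stringsAsFactors = FALSE),
    data.frame(cas_type = "overall", is_close = arr$is_close,
               n_spacers = arr$n_spacers, stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(cells, list(cells$cas_type, cells$is_close),
                                     drop = TRUE), function(d) {
    s <- summarise_counts(d$n_spacers)
    data.frame(cas_type = d$cas_type[1], is_close = d$is_close[1],
               n = nrow(d), mean = s["mean"], median = s["median"],
               max = s["max"], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cas_type, !out$is_close), ]
  rownames(out) <- NULL
  out
}
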