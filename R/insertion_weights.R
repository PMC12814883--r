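# Relative insertion-rate weights under the independent deletion model and
# the neutral multinomial null. With a constant deletion rate rho, array i's
# insertion rate is theta_i = n_i * rho, so its share of the genome's total
# insertion rate is w_i = theta_i / theta = n_i / n -- the weights are pure
# length proportions and rho cancels.

#' Insertion-rate weights from array lengths
#'
#' @param lengths Integer vector of array lengths (spacer counts), all >= 1,
#'   at least two arrays.
#' @return Numeric weights `w_i = n_i / sum(n)`, order preserved, summing
#'   to 1.
#' @export
insertion_rate_weights <- function(lengths) {
  if (length(lengths) < 2L) stop("need at least two arrays (k >= 2)")
  if (any(lengths < 1)) stop("all array lengths must be >= 1")
  lengths / sum(lengths)
}

#' Select genomes for the insertion-rate weight analysis
#'
#' Keeps genomes with exactly `k_values` in-scope arrays; genomes containing
#' any orphan array are excluded entirely. With `same_repeat_only` the
#' in-scope set is the largest group of arrays in the genome sharing one
#' consensus repeat (ties broken by the largest total spacer count, then
#' lexicographically by repeat), and `k` is that group's size; with
#' `all_groups` every identical-repeat group of size >= 2 yields a record.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param assignments Long assignment table from [assign_cohort()].
#' @param k_values Admissible array counts per record (default 2:4).
#' @param same_repeat_only Restrict each genome to arrays sharing one
#'   consensus repeat (default FALSE).
#' @param all_groups With `same_repeat_only`, emit every same-repeat group of
#'   size >= 2 instead of only the largest (default FALSE).
#' @param cas_type Optional single Cas type: keep only genomes whose
#'   non-orphan arrays are all assigned this type.
#' @return Object of class `weight_records`: long data frame with one row per
#'   in-scope array: `record_id`, `genome_id`, `scope` (`all`/`same_repeat`),
#'   `k`, `n_total`, `array_id`, `length`, `weight`, `is_close`.
#' @export
select_weight_genomes <- function(cohort, assignments, k_values = c(2, 3, 4),
                                  same_repeat_only = FALSE, all_groups = FALSE,
                                  cas_type = NULL) {
  arr <- flatten_arrays(cohort)
  m <- match(arr$array_id, assignments$array_id)
  arr$side <- assignments$side[m]
  arr$is_close <- assignments$is_close[m]
  arr$assigned_type <- assignments$assigned_type[m]
  scope_label <- if (same_repeat_only) "same_repeat" else "all"

  rows <- list()
  for (idx in split(seq_len(nrow(arr)), arr$genome_id)) {
    if (any(arr$side[idx] == "orphan")) next  # genomes with orphans excluded
    if (!is.null(cas_type) && !all(arr$assigned_type[idx] == cas_type)) next
    groups <- if (same_repeat_only) {
      gs <- split(idx, arr$consensus_repeat[idx])
      gs <- gs[vapply(gs, length, integer(1)) >= 2L]
      if (!length(gs)) next
      if (!all_groups) {
        sizes <- vapply(gs, length, integer(1))
        totals <- vapply(gs, function(i) sum(arr$n_spacers[i]), numeric(1))
        ord <- order(-sizes, -totals, names(gs))
        gs[ord[1]]
      } else gs
    } else list(all = idx)
    for (gname in names(groups)) {
      grp <- groups[[gname]]
      k <- length(grp)
      if (!k %in% k_values) next
      lens <- arr$n_spacers[grp]
      rid <- if (same_repeat_only && all_groups)
        paste0(arr$genome_id[grp[1]], ":", gname) else arr$genome_id[grp[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, genome_id = arr$genome_id[grp],
        scope = scope_label, k = k, n_total = sum(lens),
        array_id = arr$array_id[grp], length = lens,
        weight = insertion_rate_weights(lens),
        is_close = arr$is_close[grp], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), genome_id = character(),
               scope = character(), k = integer(), n_total = integer(),
               array_id = character(), length = integer(), weight = numeric(),
               is_close = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("weight_records", "data.frame")
  out
}

#' One neutral draw of insertion-rate weights
#'
#' Under neutral acquisition every new spacer lands in any of the `k` arrays
#' with equal probability `1/k`, so given `n_total` spacers the array lengths
#' are one Multinomial(`n_total`, `1/k`, ..., `1/k`) draw; dividing by
#' `n_total` yields the weights.
#'
#' @param n_total Total spacer count (>= 1).
#' @param k Number of arrays (>= 2).
#' @return Numeric vector of `k` weights summing to 1.
#' @export
neutral_weight_sample <- function(n_total, k) {
  stopifnot(n_total >= 1, k >= 2)
  as.vector(stats::rmultinom(1L, n_total, rep(1 / k, k))) / n_total
}

#' Matched neutral null distribution of insertion-rate weights
#'
#' For each observed record (genome), draws exactly one neutral sample
#' matched on its `(k, n_total)`, so the null has the same number of records
#' as the data.
#'
#' @param records [select_weight_genomes()] output.
#' @param seed Optional seed for reproducibility.
#' @return `weight_records`-shaped data frame of null weights (the `is_close`
#'   column is `NA`).
#' @export
neutral_distribution <- function(records, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(split(records, records$record_id), function(r) {
    w <- neutral_weight_sample(r$n_total[1], r$k[1])
    data.frame(record_id = r$record_id, genome_id = r$genome_id,
               scope = r$scope, k = r$k, n_total = r$n_total,
               array_id = r$array_id, length = as.integer(w * r$n_total[1]),
               weight = w, is_close = NA, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else records[0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weight_records", "data.frame")
  out
}

#' Per-k summary of observed vs neutral insertion-rate weights
#'
#' For each array count `k`: the overall mean weight (identically `1/k`
#' because weights sum to 1 per genome; reported as a bookkeeping check),
#' mean/sd/count of weights of close and far arrays, the empirical weight
#' variance, and -- when a null is supplied -- the matched neutral variance
#' and the observed/null variance ratio. Variance inflation above 1 indicates
#' per-array heterogeneity of insertion rates beyond neutral sampling noise.
#'
#' @param records Observed [select_weight_genomes()] output.
#' @param null Optional matched [neutral_distribution()] output.
#' @return `data.frame` with one row per `k`.
#' @export
weight_summary <- function(records, null = NULL) {
  if (!nrow(records)) stop("no weight records")
  out <- do.call(rbind, lapply(split(records, records$k), function(r) {
    k <- r$k[1]
    cl <- r$weight[r$is_close %in% TRUE]
    fa <- r$weight[r$is_close %in% FALSE]
    data.frame(k = k,
               n_records = length(unique(r$record_id)),
               mean_weight = mean(r$weight),
               var_weight = stats::var(r$weight),
               n_close = length(cl),
               mean_close = if (length(cl)) mean(cl) else NA_real_,
               sd_close = if (length(cl) > 1) stats::sd(cl) else NA_real_,
               n_far = length(fa),
               mean_far = if (length(fa)) mean(fa) else NA_real_,
               sd_far = if (length(fa) > 1) stats::sd(fa) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(null) && nrow(null)) {
    nv <- vapply(split(null$weight, null$k), stats::var, numeric(1))
    out$null_var <- nv[as.character(out$k)]
    out$var_ratio <- out$var_weight / out$null_var
  } else {
    out$null_var <- NA_real_
    out$var_ratio <- NA_real_
  }
  rownames(out) <- NULL
  out
}
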