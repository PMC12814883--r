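# Distance and orientation distributions of arrays around their Cas loci,
# and side/orientation configurations of two-array single-type genomes.

#' Geometry records for non-orphan arrays
#'
#' One row per assigned (non-orphan) array combining its assignment (side,
#' signed distance, close flag, assigned type) with its annotated orientation.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param assignments Long assignment table from [assign_cohort()].
#' @return `data.frame`: `genome_id`, `array_id`, `assigned_type`, `side`,
#'   `signed_distance`, `orientation`, `is_close`.
#' @export
geometry_table <- function(cohort, assignments) {
  keep <- assignments$side != "orphan"
  a <- assignments[keep, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(genome_id = character(), array_id = character(),
                      assigned_type = character(), side = character(),
                      signed_distance = integer(), orientation = character(),
                      is_close = logical(), stringsAsFactors = FALSE))
  }
  ori <- do.call(c, unname(lapply(cohort, function(g) {
    stats::setNames(g$arrays$orientation, g$arrays$array_id)
  })))
  data.frame(genome_id = a$genome_id, array_id = a$array_id,
             assigned_type = a$assigned_type, side = a$side,
             signed_distance = a$signed_distance,
             orientation = unname(ori[a$array_id]),
             is_close = a$is_close, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Side/orientation configurations of two-array, single-type genomes
#'
#' Restricted to genomes with exactly one distinct Cas type and exactly two
#' arrays, classifies where the two arrays sit relative to the Cas locus
#' (`flanking`, `both_before`, `both_after`) and their joint orientation
#' (`both_forward`, `both_reverse`, `mixed`, or `unknown` if either array is
#' unoriented). An array overlapping its locus is resolved to the side
#' holding its midpoint.
#'
#' @inheritParams geometry_table
#' @return `data.frame`: `genome_id`, `cas_type`, `side_pattern`,
#'   `orientation_pattern`.
#' @export
pair_configurations <- function(cohort, assignments) {
  rows <- list()
  for (g in cohort) {
    if (nrow(g$arrays) != 2L) next
    tt <- unique(g$loci$cas_type)
    if (length(tt) != 1L) next
    a <- assignments[assignments$genome_id == g$genome_id, , drop = FALSE]
    if (nrow(a) != 2L || any(a$side == "orphan")) next
    sides <- character(2)
    for (i in 1:2) {
      if (a$side[i] != "overlap") {
        sides[i] <- a$side[i]
      } else {
        # midpoint rule
        arr <- g$arrays[g$arrays$array_id == a$array_id[i], ]
        loc <- g$loci[g$loci$locus_id == a$locus_id[i], ]
        mid_a <- (arr$start + arr$end) / 2
        mid_l <- (loc$start + loc$end) / 2
        sides[i] <- if (mid_a < mid_l) "before" else "after"
      }
    }
    side_pattern <- if (all(sides == "before")) "both_before"
      else if (all(sides == "after")) "both_after" else "flanking"
    ori <- g$arrays$orientation[match(a$array_id, g$arrays$array_id)]
    orientation_pattern <- if (any(ori == "unknown")) "unknown"
      else if (all(ori == "forward")) "both_forward"
      else if (all(ori == "reverse")) "both_reverse" else "mixed"
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g$genome_id, cas_type = tt,
      side_pattern = side_pattern, orientation_pattern = orientation_pattern,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), cas_type = character(),
               side_pattern = character(), orientation_pattern = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binned distance-to-Cas counts split by type, side, and orientation
#'
#' Bins the absolute gap of each geometry record with the supplied edges
#' (an extra open bin beyond the last edge catches the remainder; overlap
#' records form their own `overlap` bin at distance 0) and cross-tabulates
#' with assigned type, side, and orientation. Counts always sum to the number
#' of input records.
#'
#' @param records Output of [geometry_table()].
#' @param bin_edges Strictly increasing non-negative edges in bp. The default
#'   `c(0, 500, 2500, 5000, 10000)` follows the scale on which close-array
#'   positional biases are visible.
#' @return `data.frame`: `assigned_type`, `side`, `bin`, `orientation`,
#'   `count`.
#' @export
distance_histogram <- function(records, bin_edges = c(0, 500, 2500, 5000, 10000)) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(bin_edges < 0)) stop("bin_edges must be non-negative")
  if (!nrow(records)) {
    return(data.frame(assigned_type = character(), side = character(),
                      bin = character(), orientation = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  edges <- unique(c(0, bin_edges, Inf))  # leading 0 so every gap falls in a bin
  labels <- paste0("[", utils::head(edges, -1), ",",
                   ifelse(is.finite(edges[-1]), edges[-1], "Inf"), ")")
  bin <- ifelse(records$side == "overlap", "overlap",
                labels[findInterval(abs(records$signed_distance), edges,
                                    rightmost.closed = FALSE)])
  tab <- as.data.frame(table(assigned_type = records$assigned_type,
                             side = records$side, bin = bin,
                             orientation = records$orientation),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
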