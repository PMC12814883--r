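# Domain types and TSV I/O for per-genome CRISPR annotation tables, plus
# array-to-locus assignment. Coordinates are 0-based half-open [start, end)
# both in files and in memory.

ORIENTATIONS <- c("forward", "reverse", "unknown")
CONFIDENCE_LEVELS <- c("bona-fide", "possible")
NO_CAS_TYPE <- "no cas type"

ARRAY_COLUMNS <- c("genome_id", "seq_id", "array_id", "start", "end",
                   "orientation", "confidence", "consensus_repeat", "spacers")
LOCUS_COLUMNS <- c("genome_id", "seq_id", "locus_id", "cas_type", "start", "end")

empty_arrays_df <- function() {
  data.frame(array_id = character(), seq_id = character(),
             start = integer(), end = integer(),
             orientation = character(), confidence = character(),
             consensus_repeat = character(), stringsAsFactors = FALSE)
}

empty_loci_df <- function() {
  data.frame(locus_id = character(), seq_id = character(),
             cas_type = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a single-genome annotation record
#'
#' A `genome_annotation` bundles the Cas loci and spacer arrays of one genome
#' (one replicon set; multi-replicon genomes distinguish replicons via
#' `seq_id`). It is the unit on which all downstream analyses operate.
#'
#' @param genome_id Genome identifier (non-empty string).
#' @param loci `data.frame` with columns `locus_id`, `seq_id`, `cas_type`,
#'   `start`, `end`, or `NULL` for a genome without detected Cas loci.
#' @param arrays `data.frame` with columns `array_id`, `seq_id`, `start`,
#'   `end`, `orientation` (`"forward"`, `"reverse"`, `"unknown"`),
#'   `confidence` (`"bona-fide"`, `"possible"`), `consensus_repeat`, and a
#'   list column `spacers` holding one character vector per array, ordered
#'   leader-proximal first. `NULL` for a genome without arrays.
#' @param sequence_length Optional total sequence length in bp.
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, loci = NULL, arrays = NULL,
                              sequence_length = NA_integer_) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("genome_id must be a single non-empty string")
  if (is.null(loci)) loci <- empty_loci_df()
  if (is.null(arrays)) {
    arrays <- empty_arrays_df()
    arrays$spacers <- list()
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  arrays <- as.data.frame(arrays, stringsAsFactors = FALSE)
  for (col in c("start", "end")) {
    if (col %in% names(loci)) loci[[col]] <- as.integer(loci[[col]])
    if (col %in% names(arrays)) arrays[[col]] <- as.integer(arrays[[col]])
  }
  g <- structure(list(genome_id = genome_id,
                      sequence_length = as.integer(sequence_length),
                      loci = loci, arrays = arrays),
                 class = "genome_annotation")
  validate_genome_annotation(g)
  g
}

validate_genome_annotation <- function(g) {
  loci <- g$loci; arrays <- g$arrays
  need_l <- setdiff(c("locus_id", "seq_id", "cas_type", "start", "end"), names(loci))
  if (length(need_l)) stop("loci table missing column(s): ", paste(need_l, collapse = ", "))
  need_a <- setdiff(c("array_id", "seq_id", "start", "end", "orientation",
                      "confidence", "consensus_repeat", "spacers"), names(arrays))
  if (length(need_a)) stop("arrays table missing column(s): ", paste(need_a, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id within genome ", g$genome_id)
  if (anyDuplicated(arrays$array_id)) stop("duplicate array_id within genome ", g$genome_id)
  if (nrow(loci)) {
    if (any(loci$start >= loci$end)) stop("locus with start >= end in genome ", g$genome_id)
    if (any(!nzchar(loci$cas_type))) stop("empty cas_type in genome ", g$genome_id)
  }
  if (nrow(arrays)) {
    if (any(arrays$start >= arrays$end)) stop("array with start >= end in genome ", g$genome_id)
    if (!all(arrays$orientation %in% ORIENTATIONS))
      stop("invalid orientation in genome ", g$genome_id)
    if (!all(arrays$confidence %in% CONFIDENCE_LEVELS))
      stop("invalid confidence in genome ", g$genome_id)
    if (any(nchar(arrays$consensus_repeat) < 1L))
      stop("empty consensus_repeat in genome ", g$genome_id)
    ns <- vapply(arrays$spacers, length, integer(1))
    if (any(ns < 1L)) stop("array without spacers in genome ", g$genome_id)
  }
  invisible(g)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d Cas locus(i), %d array(s)\n",
              x$genome_id, nrow(x$loci), nrow(x$arrays)))
  invisible(x)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  df
}

to_int_checked <- function(x, path, field) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | !nzchar(x))
  if (length(bad))
    stop(sprintf("%s: line %d: field '%s' is not an integer (value '%s')",
                 path, bad[1] + 1L, field, x[bad[1]]))
  out
}

#' Read a cohort of genome annotations from TSV tables
#'
#' Expects the two-table schema: `arrays.tsv` with columns `genome_id`,
#' `seq_id`, `array_id`, `start`, `end`, `orientation`, `confidence`,
#' `consensus_repeat`, `spacers` (comma-separated, leader-proximal first) and
#' `loci.tsv` with columns `genome_id`, `seq_id`, `locus_id`, `cas_type`,
#' `start`, `end`. Tab-separated, UTF-8, header row required. Genomes present
#' only in the loci table are emitted with zero arrays; genomes with arrays
#' but no loci are emitted with an empty locus table (their arrays become
#' orphans upon assignment).
#'
#' @param arrays_path Path to the arrays TSV.
#' @param loci_path Path to the loci TSV.
#' @return A named list of [genome_annotation()] objects (a "cohort"), in
#'   order of first appearance across the two files.
#' @export
read_cohort <- function(arrays_path, loci_path) {
  adf <- read_tsv_checked(arrays_path, ARRAY_COLUMNS)
  ldf <- read_tsv_checked(loci_path, LOCUS_COLUMNS)

  if (nrow(adf)) {
    if (anyDuplicated(adf$array_id)) {
      dup <- adf$array_id[duplicated(adf$array_id)][1]
      stop(sprintf("%s: duplicate array_id '%s'", arrays_path, dup))
    }
    adf$start <- to_int_checked(adf$start, arrays_path, "start")
    adf$end <- to_int_checked(adf$end, arrays_path, "end")
    bad <- which(!adf$orientation %in% ORIENTATIONS)
    if (length(bad))
      stop(sprintf("%s: line %d: field 'orientation' invalid (value '%s')",
                   arrays_path, bad[1] + 1L, adf$orientation[bad[1]]))
    bad <- which(!adf$confidence %in% CONFIDENCE_LEVELS)
    if (length(bad))
      stop(sprintf("%s: line %d: field 'confidence' invalid (value '%s')",
                   arrays_path, bad[1] + 1L, adf$confidence[bad[1]]))
    bad <- which(!nzchar(adf$spacers))
    if (length(bad))
      stop(sprintf("%s: line %d: field 'spacers' is empty", arrays_path, bad[1] + 1L))
  }
  if (nrow(ldf)) {
    if (anyDuplicated(ldf$locus_id)) {
      dup <- ldf$locus_id[duplicated(ldf$locus_id)][1]
      stop(sprintf("%s: duplicate locus_id '%s'", loci_path, dup))
    }
    ldf$start <- to_int_checked(ldf$start, loci_path, "start")
    ldf$end <- to_int_checked(ldf$end, loci_path, "end")
  }

  genome_ids <- unique(c(adf$genome_id, ldf$genome_id))
  cohort <- lapply(genome_ids, function(gid) {
    ga <- adf[adf$genome_id == gid, , drop = FALSE]
    gl <- ldf[ldf$genome_id == gid, , drop = FALSE]
    arrays <- if (nrow(ga)) {
      out <- data.frame(array_id = ga$array_id, seq_id = ga$seq_id,
                        start = ga$start, end = ga$end,
                        orientation = ga$orientation, confidence = ga$confidence,
                        consensus_repeat = ga$consensus_repeat,
                        stringsAsFactors = FALSE)
      out$spacers <- strsplit(ga$spacers, ",", fixed = TRUE)
      out
    } else NULL
    loci <- if (nrow(gl)) {
      data.frame(locus_id = gl$locus_id, seq_id = gl$seq_id,
                 cas_type = gl$cas_type, start = gl$start, end = gl$end,
                 stringsAsFactors = FALSE)
    } else NULL
    genome_annotation(gid, loci = loci, arrays = arrays)
  })
  names(cohort) <- genome_ids
  cohort
}

#' Write a cohort back to the two-table TSV schema
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces `x`
#' field-for-field. Genomes with neither loci nor arrays produce no rows and
#' are therefore not recoverable from the files.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param arrays_path,loci_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, arrays_path, loci_path) {
  arows <- lapply(cohort, function(g) {
    if (!nrow(g$arrays)) return(NULL)
    data.frame(genome_id = g$genome_id, seq_id = g$arrays$seq_id,
               array_id = g$arrays$array_id,
               start = g$arrays$start, end = g$arrays$end,
               orientation = g$arrays$orientation,
               confidence = g$arrays$confidence,
               consensus_repeat = g$arrays$consensus_repeat,
               spacers = vapply(g$arrays$spacers, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  })
  lrows <- lapply(cohort, function(g) {
    if (!nrow(g$loci)) return(NULL)
    data.frame(genome_id = g$genome_id, seq_id = g$loci$seq_id,
               locus_id = g$loci$locus_id, cas_type = g$loci$cas_type,
               start = g$loci$start, end = g$loci$end,
               stringsAsFactors = FALSE)
  })
  adf <- do.call(rbind, c(arows, list(empty_cohort_arrays_tsv())))
  ldf <- do.call(rbind, c(lrows, list(empty_cohort_loci_tsv())))
  utils::write.table(adf, arrays_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(ldf, loci_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(arrays = arrays_path, loci = loci_path))
}

empty_cohort_arrays_tsv <- function() {
  df <- data.frame(genome_id = character(), seq_id = character(),
                   array_id = character(), start = integer(), end = integer(),
                   orientation = character(), confidence = character(),
                   consensus_repeat = character(), spacers = character(),
                   stringsAsFactors = FALSE)
  df
}

empty_cohort_loci_tsv <- function() {
  data.frame(genome_id = character(), seq_id = character(),
             locus_id = character(), cas_type = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

interval_gap <- function(a_start, a_end, l_start, l_end) {
  pmax(0L, pmax(a_start, l_start) - pmin(a_end, l_end))
}

#' Assign each array of a genome to its closest Cas locus
#'
#' The distance between an array and a locus is the gap between their nearest
#' feature ends, `max(0, max(start_a, start_l) - min(end_a, end_l))`;
#' overlapping intervals have distance 0 and side `"overlap"`. Each array is
#' assigned to the locus minimising this gap, restricted to loci on the same
#' `seq_id` (distances across replicons are meaningless). Ties are broken by
#' smaller locus start, then lexicographic `locus_id`, so assignment is
#' deterministic. Arrays in a genome without any Cas locus are `"orphan"` and
#' carry the type label `"no cas type"`; an array whose replicon carries no
#' locus in a genome that has loci elsewhere is likewise reported as orphan.
#'
#' @param genome A [genome_annotation()].
#' @param close_threshold_bp Arrays with gap strictly below this value are
#'   flagged `is_close` (default 10000 bp).
#' @return `data.frame` with one row per array: `array_id`, `locus_id`
#'   (`NA` for orphans), `signed_distance` (negative = array before the
#'   locus, positive = after, 0 = overlap; `NA` for orphans), `side`
#'   (`before`/`after`/`overlap`/`orphan`), `is_close`, `assigned_type`.
#' @export
assign_arrays <- function(genome, close_threshold_bp = 10000) {
  stopifnot(inherits(genome, "genome_annotation"))
  arr <- genome$arrays
  loc <- genome$loci
  n <- nrow(arr)
  if (n == 0L) {
    return(data.frame(array_id = character(), locus_id = character(),
                      signed_distance = integer(), side = character(),
                      is_close = logical(), assigned_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(array_id = arr$array_id, locus_id = NA_character_,
                    signed_distance = NA_integer_, side = "orphan",
                    is_close = FALSE, assigned_type = NO_CAS_TYPE,
                    stringsAsFactors = FALSE)
  if (nrow(loc) == 0L) return(out)

  # deterministic tie-break: order candidate loci by start, then locus_id
  ord <- order(loc$start, loc$locus_id)
  loc <- loc[ord, , drop = FALSE]

  for (i in seq_len(n)) {
    cand <- which(loc$seq_id == arr$seq_id[i])
    if (!length(cand)) next  # replicon without Cas: stays orphan
    gaps <- interval_gap(arr$start[i], arr$end[i], loc$start[cand], loc$end[cand])
    j <- cand[which.min(gaps)]  # which.min takes first minimum = tie-break order
    gap <- min(gaps)
    overlap <- arr$start[i] < loc$end[j] && loc$start[j] < arr$end[i]
    if (overlap) {
      out$side[i] <- "overlap"
      out$signed_distance[i] <- 0L
    } else if (arr$end[i] <= loc$start[j]) {
      out$side[i] <- "before"
      out$signed_distance[i] <- -gap
    } else {
      out$side[i] <- "after"
      out$signed_distance[i] <- gap
    }
    out$locus_id[i] <- loc$locus_id[j]
    out$assigned_type[i] <- loc$cas_type[j]
    out$is_close[i] <- gap < close_threshold_bp
  }
  out
}

#' Assign arrays to loci across a whole cohort
#'
#' Applies [assign_arrays()] to every genome and binds the results with a
#' `genome_id` column prepended.
#'
#' @inheritParams assign_arrays
#' @param cohort List of [genome_annotation()] objects.
#' @return Long `data.frame` of assignments.
#' @export
assign_cohort <- function(cohort, close_threshold_bp = 10000) {
  rows <- lapply(cohort, function(g) {
    a <- assign_arrays(g, close_threshold_bp = close_threshold_bp)
    if (!nrow(a)) return(NULL)
    cbind(data.frame(genome_id = g$genome_id, stringsAsFactors = FALSE), a)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), array_id = character(),
                      locus_id = character(), signed_distance = integer(),
                      side = character(), is_close = logical(),
                      assigned_type = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Drop "possible"-confidence arrays from a cohort
#'
#' Confidence is an input label from the upstream array detector; both
#' levels are analysed by default. This filter restricts the cohort to
#' "bona-fide" arrays for sensitivity analyses.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @return Filtered cohort (genomes retained even if left with no arrays).
#' @export
filter_bona_fide <- function(cohort) {
  lapply(cohort, function(g) {
    keep <- g$arrays$confidence == "bona-fide"
    g$arrays <- g$arrays[keep, , drop = FALSE]
    g
  })
}
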