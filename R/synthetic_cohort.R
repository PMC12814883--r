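# Synthetic cohort generator. Emits annotation cohorts with the statistical
# structure the downstream analyses assume -- per-genome Cas-type presence
# with optional pairwise dependence, arrays-per-locus counts, Poisson
# (theta/rho) array lengths under the independent deletion model, type-specific
# placement and orientation biases, per-type ancestral consensus repeats
# diverged by point mutation, array duplications with partial spacer sharing,
# and orphan arrays -- together with the ground truth needed for
# parameter-recovery tests.

DNA_ALPHABET <- c("A", "C", "G", "T")

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_ALPHABET, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

mutate_repeat <- function(repeat_seq, substitution_prob) {
  if (substitution_prob <= 0) return(repeat_seq)
  chars <- strsplit(repeat_seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < substitution_prob
  if (any(hit)) {
    # substitute with a different base
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_ALPHABET, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Specification of a synthetic annotation cohort
#'
#' Collects every tunable of the generator. Defaults describe a cohort with a
#' handful of common Cas types at realistic frequencies, a mean of roughly 1.5
#' arrays per locus, stationary array lengths of around 15 spacers
#' (insertion rate `theta` = 15, deletion rate `rho` = 1, stationary length
#' Poisson(theta/rho)), a strong tendency for arrays to sit close to their
#' locus, and no built-in co-occurrence enrichment or acquisition bias.
#'
#' @param n_genomes Number of genomes to simulate.
#' @param type_freqs Named vector of marginal presence probabilities per Cas
#'   type.
#' @param pair_enrichment `NULL`, or `data.frame(type_a, type_b, multiplier)`.
#'   A multiplier m rescales the joint presence probability of the pair toward
#'   `m * freq_a * freq_b` (clipped below to the feasible minimum) while
#'   preserving the marginals; `m = 1` is independence, `m = 0` exclusion.
#' @param arrays_per_locus_dist Named numeric vector: probability of 1, 2, ...
#'   arrays per Cas locus (names are the counts).
#' @param theta_per_type Named vector of per-type insertion rates
#'   `theta`; a single unnamed value is recycled to all types.
#' @param rho Deletion rate (> 0); stationary array length is
#'   Poisson(`theta`/`rho`).
#' @param prob_after,prob_forward,prob_close Per-type placement
#'   probabilities (single values are recycled): probability that an array
#'   lies after (downstream of) its locus, that it is forward oriented, and
#'   that it is placed close (gap drawn from `near_sampler`) rather than far
#'   (gap from `far_sampler`).
#' @param near_sampler,far_sampler Functions `n -> integer gaps in bp`.
#'   Defaults: near gaps exponential with mean 1500 bp truncated below
#'   10 kb (most arrays within a few hundred bp of their locus); far gaps
#'   uniform on 100 kb--1 Mb.
#' @param repeat_length Length of the per-type ancestral consensus repeats.
#' @param substitution_prob Per-site substitution probability applied
#'   independently to each array's copy of its type's ancestral repeat.
#' @param duplication_prob Probability that a locus gains one duplicated
#'   array copying the consensus repeat and a leader-distal suffix of the
#'   spacers of one of its arrays.
#' @param orphan_rate Probability that a genome gains one unassociated array
#'   with a random repeat, far from every locus.
#' @param acquisition_bias Multiplier (>= 1) on the insertion rate of arrays
#'   close to their locus; 1 = unbiased.
#' @param spacer_length Length of the random spacer strings (identity is all
#'   the analyses use).
#' @param genome_length Genome size in bp.
#' @param seed Integer seed; cohorts are reproducible given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genomes = 2000,
                        type_freqs = c("I-E" = 0.25, "I-F" = 0.15,
                                       "II-C" = 0.10, "I-C" = 0.08,
                                       "III-A" = 0.08, "II-A" = 0.06,
                                       "V-A" = 0.05),
                        pair_enrichment = NULL,
                        arrays_per_locus_dist = c("1" = 0.65, "2" = 0.22,
                                                  "3" = 0.09, "4" = 0.04),
                        theta_per_type = 15,
                        rho = 1,
                        prob_after = 0.5,
                        prob_forward = 0.8,
                        prob_close = 0.8,
                        near_sampler = function(n) pmin(as.integer(stats::rexp(n, 1 / 1500)), 9999L),
                        far_sampler = function(n) as.integer(stats::runif(n, 1e5, 1e6)),
                        repeat_length = 30,
                        substitution_prob = 0.02,
                        duplication_prob = 0.1,
                        orphan_rate = 0.1,
                        acquisition_bias = 1,
                        spacer_length = 32,
                        genome_length = 4e6,
                        seed = 1) {
  types <- names(type_freqs)
  if (is.null(types) || any(!nzchar(types)))
    stop("type_freqs must be a named vector")
  if (any(type_freqs < 0 | type_freqs > 1))
    stop("type frequencies must lie in [0, 1]")
  if (rho <= 0) stop("rho must be > 0")
  recycle <- function(x, what) {
    if (is.null(names(x)) && length(x) == 1L) x <- stats::setNames(rep(x, length(types)), types)
    if (!all(types %in% names(x))) stop(what, " must cover every type")
    x[types]
  }
  theta_per_type <- recycle(theta_per_type, "theta_per_type")
  if (any(theta_per_type <= 0)) stop("theta must be > 0")
  prob_after <- recycle(prob_after, "prob_after")
  prob_forward <- recycle(prob_forward, "prob_forward")
  prob_close <- recycle(prob_close, "prob_close")
  probs <- c(prob_after, prob_forward, prob_close,
             duplication_prob, orphan_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (acquisition_bias < 1) stop("acquisition_bias must be >= 1")
  apl <- arrays_per_locus_dist / sum(arrays_per_locus_dist)
  if (is.null(names(apl))) stop("arrays_per_locus_dist must be named by count")
  if (!is.null(pair_enrichment)) {
    pair_enrichment <- as.data.frame(pair_enrichment, stringsAsFactors = FALSE)
    stopifnot(all(c("type_a", "type_b", "multiplier") %in% names(pair_enrichment)))
    if (any(pair_enrichment$multiplier < 0)) stop("enrichment multipliers must be >= 0")
    unknown <- setdiff(c(pair_enrichment$type_a, pair_enrichment$type_b), types)
    if (length(unknown)) stop("enrichment names unknown type(s): ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(n_genomes = as.integer(n_genomes), type_freqs = type_freqs,
                 pair_enrichment = pair_enrichment,
                 arrays_per_locus_dist = apl,
                 theta_per_type = theta_per_type, rho = rho,
                 prob_after = prob_after, prob_forward = prob_forward,
                 prob_close = prob_close,
                 near_sampler = near_sampler, far_sampler = far_sampler,
                 repeat_length = as.integer(repeat_length),
                 substitution_prob = substitution_prob,
                 duplication_prob = duplication_prob,
                 orphan_rate = orphan_rate,
                 acquisition_bias = acquisition_bias,
                 spacer_length = as.integer(spacer_length),
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d genomes, %d Cas types, theta/rho = %s, seed %d\n",
              x$n_genomes, length(x$type_freqs),
              paste(unique(round(x$theta_per_type / x$rho, 2)), collapse = "/"),
              x$seed))
  invisible(x)
}

#' Draw one stationary array length under the independent deletion model
#'
#' Under independent per-spacer insertions at rate `theta` and deletions at
#' rate `rho`, the stationary array length is Poisson distributed with mean
#' `theta / rho`.
#'
#' @param theta Insertion rate (>= 0).
#' @param rho Deletion rate (> 0).
#' @param n Number of draws.
#' @return Integer vector of `n` draws from Poisson(`theta`/`rho`).
#' @export
sample_idm_length <- function(theta, rho, n = 1) {
  if (any(theta < 0)) stop("theta must be >= 0")
  if (any(rho <= 0)) stop("rho must be > 0")
  stats::rpois(n, theta / rho)
}

#' Sample per-genome Cas-type presence
#'
#' With all enrichment multipliers equal to 1 every type is present
#' independently with its marginal frequency. A multiplier `m` on a pair
#' (A, B) sets the joint presence probability to
#' `clip(m * freq_A * freq_B)` while preserving both marginals exactly, by
#' sampling B conditionally on A. Pairs are processed sequentially; when
#' pairs share a type the later adjustment conditions on the already-sampled
#' column, so marginals are preserved but three-way interactions are not
#' controlled.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of genomes (defaults to `spec$n_genomes`).
#' @return Logical matrix, genomes x types.
#' @export
sample_type_presence <- function(spec, n = spec$n_genomes) {
  stopifnot(inherits(spec, "cohort_spec"))
  types <- names(spec$type_freqs)
  p <- spec$type_freqs
  pres <- matrix(stats::runif(n * length(types)) < rep(p, each = n),
                 nrow = n, dimnames = list(NULL, types))
  pe <- spec$pair_enrichment
  if (!is.null(pe) && nrow(pe)) {
    for (r in seq_len(nrow(pe))) {
      a <- pe$type_a[r]; b <- pe$type_b[r]; m <- pe$multiplier[r]
      pa <- p[[a]]; pb <- p[[b]]
      target <- m * pa * pb
      lo <- max(0, pa + pb - 1)
      hi <- min(pa, pb)
      if (target > hi + 1e-12)
        stop(sprintf("infeasible enrichment for pair (%s, %s): joint %.4g exceeds min marginal %.4g",
                     a, b, target, hi))
      pab <- min(max(target, lo), hi)
      if (pa <= 0) next
      p_b_given_a <- pab / pa
      p_b_given_not_a <- if (pa >= 1) 0 else (pb - pab) / (1 - pa)
      u <- stats::runif(n)
      pres[, b] <- ifelse(pres[, a], u < p_b_given_a, u < p_b_given_not_a)
    }
  }
  pres
}

# Draw a positive IDM length; zero draws are redrawn (arrays must hold at
# least one spacer). Returns length and whether resampling happened.
positive_idm_length <- function(theta, rho) {
  len <- stats::rpois(1L, theta / rho)
  resampled <- FALSE
  while (len < 1L) {
    len <- stats::rpois(1L, theta / rho)
    resampled <- TRUE
  }
  list(len = len, resampled = resampled)
}

#' Generate a synthetic annotation cohort with ground truth
#'
#' Deterministic given the spec (including its seed). Per genome: a Cas-type
#' set is sampled ([sample_type_presence()]); each present type gets one Cas
#' locus; each locus gets `arrays_per_locus_dist` arrays placed by the
#' per-type placement model; array lengths are Poisson(`theta_i`/`rho`) with
#' `theta_i = theta_type * acquisition_bias` for close arrays (zero-length
#' draws are redrawn to >= 1 spacer and flagged in the truth table); spacers
#' are random distinct strings; consensus repeats are the type's ancestral
#' repeat with independent per-site substitutions; with probability
#' `duplication_prob` a locus gains a duplicate array copying the consensus
#' repeat and the leader-distal spacer plus a random suffix; with probability
#' `orphan_rate` a genome gains an unassociated array with a random repeat,
#' at least 100 kb from every locus.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `cohort` (named list of [genome_annotation()])
#'   and `truth` (list with `presence` matrix, `ancestral_repeats`, and an
#'   `arrays` data frame of per-array ground truth: source locus, true
#'   `theta_i`, close flag, duplication lineage, resampling flag).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  types <- names(spec$type_freqs)
  ancestral <- stats::setNames(random_dna(length(types), spec$repeat_length), types)
  presence <- sample_type_presence(spec)

  apl_counts <- as.integer(names(spec$arrays_per_locus_dist))
  apl_probs <- as.numeric(spec$arrays_per_locus_dist)
  glen <- spec$genome_length
  locus_region <- c(1.1e6, 2.9e6)  # leaves room for 1 Mb far placements
  min_spacing <- 50000

  cohort <- vector("list", spec$n_genomes)
  truth_rows <- vector("list", spec$n_genomes)

  for (gi in seq_len(spec$n_genomes)) {
    gid <- sprintf("G%05d", gi)
    present <- types[presence[gi, ]]

    # --- place loci, >= 50 kb apart
    n_loc <- length(present)
    loci <- NULL
    occupied <- matrix(numeric(0), ncol = 2)
    if (n_loc) {
      starts <- numeric(0)
      for (k in seq_len(n_loc)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- floor(stats::runif(1, locus_region[1], locus_region[2]))
          if (!length(starts) || all(abs(starts - s) >= min_spacing)) {
            starts <- c(starts, s); ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place loci with required spacing in genome ", gid)
      }
      widths <- floor(stats::runif(n_loc, 5000, 12000))
      loci <- data.frame(locus_id = sprintf("%s_L%d", gid, seq_len(n_loc)),
                         seq_id = "chr", cas_type = present,
                         start = as.integer(starts),
                         end = as.integer(starts + widths),
                         stringsAsFactors = FALSE)
      occupied <- cbind(starts, starts + widths)
    }

    arr_rows <- list()
    tr_rows <- list()
    aix <- 0L

    place_array <- function(locus_start, locus_end, gap, after, arr_len_bp) {
      # returns c(start, end) or NULL when it cannot be placed
      for (try in 1:20) {
        if (after) {
          s <- locus_end + gap
        } else {
          s <- locus_start - gap - arr_len_bp
        }
        e <- s + arr_len_bp
        if (s >= 0 && e <= glen &&
            (!nrow(occupied) || all(e <= occupied[, 1] | s >= occupied[, 2]))) {
          occupied <<- rbind(occupied, c(s, e))
          return(c(s, e))
        }
        gap <- gap + spec$near_sampler(1)  # nudge and retry
      }
      NULL
    }

    add_array <- function(type, locus_row, is_close, len, repeat_seq, spacers,
                          theta_i, dup_of, resampled) {
      aix <<- aix + 1L
      after <- stats::runif(1) < (if (is.na(type)) 0.5 else spec$prob_after[[type]])
      forward <- stats::runif(1) < (if (is.na(type)) 0.5 else spec$prob_forward[[type]])
      gap <- if (is.na(type)) {
        # orphan: anywhere >= 100 kb from every locus
        spec$far_sampler(1)
      } else if (is_close) spec$near_sampler(1) else spec$far_sampler(1)
      arr_bp <- len * (spec$spacer_length + spec$repeat_length) + spec$repeat_length
      if (is.na(type)) {
        pos <- NULL
        for (try in 1:50) {
          s <- floor(stats::runif(1, 0, glen - arr_bp))
          e <- s + arr_bp
          gaps <- pmax(0, pmax(s, occupied[, 1]) - pmin(e, occupied[, 2]))
          far_enough <- !nrow(occupied) || all(gaps >= 1e5)
          if (far_enough) { occupied <<- rbind(occupied, c(s, e)); pos <- c(s, e); break }
        }
        if (is.null(pos)) return(invisible(NULL))
      } else {
        pos <- place_array(locus_row$start, locus_row$end, gap, after, arr_bp)
        if (is.null(pos)) stop("could not place array after retries in genome ", gid)
      }
      arr_rows[[length(arr_rows) + 1L]] <<- data.frame(
        array_id = sprintf("%s_A%d", gid, aix), seq_id = "chr",
        start = as.integer(pos[1]), end = as.integer(pos[2]),
        orientation = if (forward) "forward" else "reverse",
        confidence = if (stats::runif(1) < 0.9) "bona-fide" else "possible",
        consensus_repeat = repeat_seq, stringsAsFactors = FALSE)
      arr_rows[[length(arr_rows)]]$spacers <<- list(spacers)
      tr_rows[[length(tr_rows) + 1L]] <<- data.frame(
        genome_id = gid, array_id = sprintf("%s_A%d", gid, aix),
        cas_type = if (is.na(type)) NO_CAS_TYPE else type,
        locus_id = if (is.null(locus_row)) NA_character_ else locus_row$locus_id,
        theta_i = theta_i, is_close_true = isTRUE(is_close),
        duplicated_from = dup_of, resampled = resampled,
        stringsAsFactors = FALSE)
      invisible(NULL)
    }

    if (n_loc) {
      for (li in seq_len(n_loc)) {
        type <- present[li]
        lrow <- loci[li, ]
        n_arr <- apl_counts[sample.int(length(apl_counts), 1L, prob = apl_probs)]
        locus_arrays <- list()
        for (ai in seq_len(n_arr)) {
          is_close <- stats::runif(1) < spec$prob_close[[type]]
          theta_i <- spec$theta_per_type[[type]] *
            (if (is_close) spec$acquisition_bias else 1)
          draw <- positive_idm_length(theta_i, spec$rho)
          spacers <- random_dna(draw$len, spec$spacer_length)
          rep_seq <- mutate_repeat(ancestral[[type]], spec$substitution_prob)
          add_array(type, lrow, is_close, draw$len, rep_seq, spacers,
                    theta_i, NA_character_, draw$resampled)
          locus_arrays[[ai]] <- list(repeat_seq = rep_seq, spacers = spacers,
                                     id = sprintf("%s_A%d", gid, aix))
        }
        if (stats::runif(1) < spec$duplication_prob) {
          # duplicate one array of this locus: same consensus repeat, shares
          # the leader-distal spacer plus a random suffix; fresh
          # leader-proximal spacers on top
          src <- locus_arrays[[sample.int(length(locus_arrays), 1L)]]
          n_src <- length(src$spacers)
          suffix_len <- sample.int(n_src, 1L)
          fresh <- stats::rpois(1L, spec$theta_per_type[[type]] / spec$rho / 2)
          spacers <- c(random_dna(fresh, spec$spacer_length),
                       utils::tail(src$spacers, suffix_len))
          is_close <- stats::runif(1) < spec$prob_close[[type]]
          add_array(type, lrow, is_close, length(spacers), src$repeat_seq,
                    spacers, spec$theta_per_type[[type]], src$id, FALSE)
        }
      }
    }
    if (stats::runif(1) < spec$orphan_rate) {
      theta_bar <- mean(spec$theta_per_type)
      draw <- positive_idm_length(theta_bar, spec$rho)
      add_array(NA_character_, NULL, FALSE, draw$len,
                random_dna(1L, spec$repeat_length),
                random_dna(draw$len, spec$spacer_length),
                theta_bar, NA_character_, draw$resampled)
    }

    arrays <- if (length(arr_rows)) do.call(rbind, arr_rows) else NULL
    cohort[[gi]] <- genome_annotation(gid, loci = loci, arrays = arrays,
                                      sequence_length = glen)
    truth_rows[[gi]] <- if (length(tr_rows)) do.call(rbind, tr_rows) else NULL
  }

  names(cohort) <- vapply(cohort, function(g) g$genome_id, character(1))
  truth_arrays <- do.call(rbind, truth_rows)
  rownames(truth_arrays) <- NULL
  rownames(presence) <- names(cohort)
  list(cohort = cohort,
       truth = list(presence = presence, ancestral_repeats = ancestral,
                    arrays = truth_arrays))
}

#' Write generator ground truth to TSV
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$arrays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
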