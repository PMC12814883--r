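# Pipeline driver: generate or read a cohort, assign arrays, run every
# analysis, and write the report TSVs plus a run manifest. All stochastic
# stages draw from stage seeds derived deterministically from the global
# seed, so a fixed config yields byte-identical outputs.

#' Pipeline configuration
#'
#' Exactly one of (`arrays_path` + `loci_path`) or `generator_spec` must be
#' supplied.
#'
#' @param out_dir Output directory (created if missing).
#' @param arrays_path,loci_path Input annotation TSVs (see [read_cohort()]).
#' @param generator_spec A [cohort_spec()] to simulate a cohort instead.
#' @param close_threshold_bp Close-to-Cas threshold in bp (default 10000).
#' @param min_count Reporting threshold for co-occurrence cells (default 50).
#' @param alpha Significance gate for solo co-occurrence cells (default
#'   1e-4).
#' @param k_values Array counts admitted to the weight analysis (default
#'   2:4).
#' @param normalization Repeat-distance normalization for the embedding
#'   (default `"global_max"`).
#' @param mds_n_init,mds_max_iter,mds_tol SMACOF controls (see
#'   [mds_embed()]).
#' @param subsample_cap Maximum number of arrays entering the distance
#'   matrix/embedding; larger inputs are subsampled stratified by assigned
#'   type (quadratic cost otherwise). Default 1000.
#' @param exclude_possible Drop "possible"-confidence arrays before any
#'   analysis (default FALSE).
#' @param include_orphans_in_repeat_space Keep orphan arrays in the
#'   repeat-distance analyses (default FALSE; they are always excluded from
#'   co-occurrence, geometry, and weights).
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            arrays_path = NULL, loci_path = NULL,
                            generator_spec = NULL,
                            close_threshold_bp = 10000,
                            min_count = 50, alpha = 0.0001,
                            k_values = c(2, 3, 4),
                            normalization = "global_max",
                            mds_n_init = 4, mds_max_iter = 300,
                            mds_tol = 1e-4,
                            subsample_cap = 1000,
                            exclude_possible = FALSE,
                            include_orphans_in_repeat_space = FALSE,
                            seed = 1) {
  from_files <- !is.null(arrays_path) || !is.null(loci_path)
  if (from_files && (is.null(arrays_path) || is.null(loci_path)))
    stop("both arrays_path and loci_path are required to read a cohort")
  if (from_files == !is.null(generator_spec))
    stop("supply exactly one of (arrays_path + loci_path) or generator_spec")
  if (close_threshold_bp <= 0 || min_count <= 0 || alpha <= 0 ||
      subsample_cap <= 0)
    stop("thresholds must be positive")
  structure(list(out_dir = out_dir, arrays_path = arrays_path,
                 loci_path = loci_path, generator_spec = generator_spec,
                 close_threshold_bp = close_threshold_bp,
                 min_count = min_count, alpha = alpha, k_values = k_values,
                 normalization = normalization, mds_n_init = mds_n_init,
                 mds_max_iter = mds_max_iter, mds_tol = mds_tol,
                 subsample_cap = subsample_cap,
                 exclude_possible = exclude_possible,
                 include_orphans_in_repeat_space = include_orphans_in_repeat_space,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

# stratified-by-type seeded subsample of the flat array table
subsample_arrays <- function(arr, cap, seed) {
  if (nrow(arr) <= cap) return(arr)
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(arr)), arr$assigned_type), function(i) {
    take <- max(1L, floor(length(i) / nrow(arr) * cap))
    sort(sample(i, min(take, length(i))))
  }))
  arr[sort(idx), , drop = FALSE]
}

#' Run the full comparative analysis pipeline
#'
#' Obtains a cohort (from TSVs or the generator), assigns arrays to Cas
#' loci, and writes to `config$out_dir`: `cooccurrence.tsv`, `geometry.tsv`,
#' `pair_config.tsv`, `census.tsv`, `weights.tsv`, `null_weights.tsv`,
#' `distances.tsv`, `embedding.tsv`, `density.tsv`, and `run_manifest.txt`
#' (plus `arrays.tsv`/`loci.tsv`/`truth.tsv` when the cohort is generated).
#' Runs with the same config produce byte-identical TSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$arrays_path)) {
    if (!file.exists(config$arrays_path)) stop("missing input: ", config$arrays_path)
    if (!file.exists(config$loci_path)) stop("missing input: ", config$loci_path)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$generator_spec)) {
    gen <- generate_cohort(config$generator_spec)
    cohort <- gen$cohort
    write_cohort(cohort, paths("arrays.tsv"), paths("loci.tsv"))
    write_truth(gen$truth, paths("truth.tsv"))
  } else {
    cohort <- read_cohort(config$arrays_path, config$loci_path)
  }
  n_arrays_in <- sum(vapply(cohort, function(g) nrow(g$arrays), integer(1)))
  if (config$exclude_possible) cohort <- filter_bona_fide(cohort)
  n_arrays <- sum(vapply(cohort, function(g) nrow(g$arrays), integer(1)))

  assignments <- assign_cohort(cohort, config$close_threshold_bp)

  cooc <- cooccurrence_table(cohort, min_count = config$min_count,
                             alpha = config$alpha)
  write_report_tsv(as.data.frame(cooc), paths("cooccurrence.tsv"))

  geom <- geometry_table(cohort, assignments)
  write_report_tsv(geom, paths("geometry.tsv"))
  write_report_tsv(pair_configurations(cohort, assignments),
                   paths("pair_config.tsv"))

  census <- repeat_spacer_census(cohort, assignments)
  apl <- arrays_per_locus(cohort, assignments)
  lbp <- length_by_proximity(cohort, assignments)
  census_df <- merge(as.data.frame(census), apl$summary, by = "cas_type",
                     all.x = TRUE, suffixes = c("", "_arrays_per_locus"))
  write_report_tsv(census_df, paths("census.tsv"))
  write_report_tsv(lbp, paths("length_by_proximity.tsv"))

  records <- select_weight_genomes(cohort, assignments,
                                   k_values = config$k_values)
  write_report_tsv(as.data.frame(records), paths("weights.tsv"))
  null <- neutral_distribution(records, seed = config$seed + 1L)
  write_report_tsv(as.data.frame(null), paths("null_weights.tsv"))

  arr <- flatten_arrays(cohort)
  arr$assigned_type <- assignments$assigned_type[match(arr$array_id,
                                                       assignments$array_id)]
  if (!config$include_orphans_in_repeat_space)
    arr <- arr[arr$assigned_type != NO_CAS_TYPE, , drop = FALSE]
  emb <- NULL
  if (nrow(arr)) {
    arr_sub <- subsample_arrays(arr, config$subsample_cap, config$seed + 2L)
    dm <- distance_matrix(arr_sub[, c("array_id", "consensus_repeat")],
                          normalization = if (config$normalization == "per_genome_max")
                            "global_max" else config$normalization)
    ut <- which(upper.tri(dm$D), arr.ind = TRUE)
    write_report_tsv(data.frame(id_a = dm$labels[ut[, 1]],
                                id_b = dm$labels[ut[, 2]],
                                distance = dm$D[ut]),
                     paths("distances.tsv"))
    emb <- mds_embed(dm, seed = config$seed + 3L, n_init = config$mds_n_init,
                     max_iter = config$mds_max_iter, tol = config$mds_tol)
    write_report_tsv(data.frame(array_id = emb$labels,
                                x = emb$coords[, 1], y = emb$coords[, 2],
                                stress = emb$stress),
                     paths("embedding.tsv"))
    dens <- rbind(cbind(coordinate = "x", kde_marginal(emb$coords[, 1])),
                  cbind(coordinate = "y", kde_marginal(emb$coords[, 2])))
    write_report_tsv(dens, paths("density.tsv"))
  }

  manifest <- c(sprintf("crisprarrays %s",
                        as.character(utils::packageVersion("crisprarrays"))),
                sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
                sprintf("seed: %d", config$seed),
                sprintf("genomes: %d", length(cohort)),
                sprintf("arrays_in: %d", n_arrays_in),
                sprintf("arrays_analysed: %d", n_arrays),
                sprintf("orphan_arrays: %d", sum(assignments$side == "orphan")),
                sprintf("close_threshold_bp: %s", config$close_threshold_bp),
                sprintf("min_count: %s", config$min_count),
                sprintf("alpha: %s", config$alpha),
                sprintf("k_values: %s", paste(config$k_values, collapse = ",")),
                sprintf("normalization: %s", config$normalization),
                sprintf("subsample_cap: %s", config$subsample_cap),
                sprintf("exclude_possible: %s", config$exclude_possible),
                sprintf("weight_records: %d", length(unique(records$record_id))))
  writeLines(manifest, paths("run_manifest.txt"))

  invisible(list(out_dir = config$out_dir, cohort = cohort,
                 assignments = assignments, cooccurrence = cooc,
                 geometry = geom, census = census, weights = records,
                 null_weights = null, embedding = emb))
}
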