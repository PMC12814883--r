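# Flat key/value config with per-type sub-tables, for driving the generator
# from the command line.

#' Read a cohort specification from a config file
#'
#' The format is `key = value` lines, `#` comments, and two kinds of
#' sections: `[type <label>]` with keys `freq`, `theta`, `prob_after`,
#' `prob_forward`, `prob_close`, and `[pair <labelA> <labelB>]` with key
#' `multiplier`. Top-level keys map to [cohort_spec()] arguments of the same
#' name (`n_genomes`, `rho`, `substitution_prob`, `duplication_prob`,
#' `orphan_rate`, `acquisition_bias`, `repeat_length`, `spacer_length`,
#' `genome_length`, `seed`, and `arrays_per_locus_dist` as
#' `count:prob` pairs separated by commas, e.g. `1:0.65,2:0.35`).
#'
#' @param path Path to the config file.
#' @return A [cohort_spec()].
#' @export
read_spec_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  top <- list()
  types <- list()
  pairs <- list()
  section <- NULL
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      hdr <- strsplit(gsub("\\[|\\]", "", ln), "[[:space:]]+")[[1]]
      section <- hdr
      if (hdr[1] == "type") types[[hdr[2]]] <- list()
      else if (hdr[1] == "pair") pairs[[paste(hdr[2], hdr[3], sep = "\r")]] <- list()
      else stop("unknown section in ", path, ": ", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed line in ", path, ": ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (is.null(section)) top[[key]] <- val
    else if (section[1] == "type") types[[section[2]]][[key]] <- val
    else pairs[[paste(section[2], section[3], sep = "\r")]][[key]] <- val
  }
  if (!length(types)) stop("config defines no [type ...] sections")

  num <- function(x) as.numeric(x)
  type_names <- names(types)
  pull <- function(field, default) {
    vapply(type_names, function(t) {
      v <- types[[t]][[field]]
      if (is.null(v)) default else num(v)
    }, numeric(1))
  }
  freqs <- pull("freq", NA)
  if (any(is.na(freqs))) stop("every [type] section needs a freq")
  pe <- NULL
  if (length(pairs)) {
    ab <- do.call(rbind, strsplit(names(pairs), "\r", fixed = TRUE))
    pe <- data.frame(type_a = ab[, 1], type_b = ab[, 2],
                     multiplier = vapply(pairs, function(p)
                       num(p$multiplier), numeric(1)),
                     stringsAsFactors = FALSE)
  }
  apl <- NULL
  if (!is.null(top$arrays_per_locus_dist)) {
    parts <- strsplit(strsplit(top$arrays_per_locus_dist, ",")[[1]], ":")
    apl <- stats::setNames(vapply(parts, function(p) num(p[2]), numeric(1)),
                           vapply(parts, function(p) trimws(p[1]), character(1)))
  }
  call_args <- list(
    type_freqs = stats::setNames(freqs, type_names),
    theta_per_type = stats::setNames(pull("theta", 15), type_names),
    prob_after = stats::setNames(pull("prob_after", 0.5), type_names),
    prob_forward = stats::setNames(pull("prob_forward", 0.8), type_names),
    prob_close = stats::setNames(pull("prob_close", 0.8), type_names),
    pair_enrichment = pe)
  if (!is.null(apl)) call_args$arrays_per_locus_dist <- apl
  for (key in c("n_genomes", "rho", "substitution_prob", "duplication_prob",
                "orphan_rate", "acquisition_bias", "repeat_length",
                "spacer_length", "genome_length", "seed")) {
    if (!is.null(top[[key]])) call_args[[key]] <- num(top[[key]])
  }
  do.call(cohort_spec, call_args)
}
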