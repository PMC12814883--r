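# Consensus-repeat similarity: Levenshtein distances, normalization, metric
# MDS by SMACOF majorization, and Gaussian KDE marginals.

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and
#' substitutions transforming `a` into `b`, computed by the standard
#' two-row dynamic programme. Alphabet-agnostic; case-sensitive.
#'
#' @param a,b Strings.
#' @return Integer distance.
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1] <- i
    sub_cost <- prev[1:m] + (x[i] != y)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, sub_cost[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Pairwise consensus-repeat distance matrix
#'
#' Levenshtein distances between the consensus repeats of a set of arrays
#' (computed in C via [utils::adist()]; [edit_distance()] is the same
#' quantity for a single pair), optionally normalized by the maximum repeat
#' length within the genome (`per_genome_max`; all arrays must then share one
#' `genome_id`) or over all input arrays (`global_max`). Sequences are
#' uppercased first; non-ACGT characters participate as ordinary symbols.
#'
#' @param arrays `data.frame` with columns `array_id` and `consensus_repeat`
#'   (a `genome_id` column is required for `per_genome_max`), or a cohort
#'   (list of [genome_annotation()]) which is flattened first.
#' @param normalization One of `"none"`, `"per_genome_max"`, `"global_max"`.
#' @return Object of class `repeat_dist`: list with `labels`, symmetric
#'   matrix `D`, `normalization`.
#' @export
distance_matrix <- function(arrays, normalization = c("none", "per_genome_max",
                                                      "global_max")) {
  normalization <- match.arg(normalization)
  if (is.list(arrays) && !is.data.frame(arrays)) arrays <- flatten_arrays(arrays)
  if (!nrow(arrays)) stop("no arrays supplied")
  reps <- toupper(arrays$consensus_repeat)
  if (normalization == "per_genome_max" &&
      (is.null(arrays$genome_id) || length(unique(arrays$genome_id)) != 1L))
    stop("per_genome_max normalization requires arrays from a single genome")
  D <- utils::adist(reps)
  L <- switch(normalization,
              none = 1,
              per_genome_max = max(nchar(reps)),
              global_max = max(nchar(reps)))
  D <- D / L
  dimnames(D) <- list(arrays$array_id, arrays$array_id)
  structure(list(labels = arrays$array_id, D = D,
                 normalization = normalization),
            class = "repeat_dist")
}

#' @export
print.repeat_dist <- function(x, ...) {
  cat(sprintf("<repeat_dist> %d repeats, normalization = %s, max distance %.3g\n",
              length(x$labels), x$normalization, max(x$D)))
  invisible(x)
}

smacof_stress <- function(delta, D) {
  sum((delta[upper.tri(delta)] - D[upper.tri(D)])^2)
}

smacof_run <- function(delta, X, max_iter, tol) {
  n <- nrow(delta)
  D <- as.matrix(stats::dist(X))
  trace <- smacof_stress(delta, D)
  for (it in seq_len(max_iter)) {
    # Guttman transform with unit weights: X <- B(X) X / n
    ratio <- matrix(0, n, n)
    pos <- D > 0
    ratio[pos] <- delta[pos] / D[pos]
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    D <- as.matrix(stats::dist(X))
    s <- smacof_stress(delta, D)
    trace <- c(trace, s)
    if (trace[it] - s < tol) break
  }
  list(X = X, stress = trace[length(trace)], trace = trace)
}

#' Metric MDS embedding by SMACOF majorization
#'
#' Projects a dissimilarity matrix into 2-D by iterating the Guttman
#' transform, which never increases the raw stress (the residual sum of
#' squares between input dissimilarities and embedded Euclidean distances).
#' The best of `n_init` random initializations is returned; results are
#' deterministic given `seed`.
#'
#' @param D A [distance_matrix()] result, a `dist`, or a square symmetric
#'   matrix.
#' @param seed Integer seed for the random initializations.
#' @param n_init Number of random starts (default 4).
#' @param max_iter Maximum Guttman iterations per start (default 300).
#' @param tol Stop a run when the stress decrease falls below this (default
#'   1e-4; tighten for high-precision embeddings).
#' @return Object of class `repeat_embedding`: `labels`, `coords` (n x 2),
#'   `stress`, `stress_trace` (per-iteration stress of the winning run),
#'   `seed`.
#' @export
mds_embed <- function(D, seed = 1, n_init = 4, max_iter = 300, tol = 1e-4) {
  labels <- NULL
  if (inherits(D, "repeat_dist")) { labels <- D$labels; D <- D$D }
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (any(!is.finite(D))) stop("D contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  if (n == 1L) {
    return(structure(list(labels = labels,
                          coords = matrix(0, 1, 2,
                                          dimnames = list(labels, c("x", "y"))),
                          stress = 0, stress_trace = 0, seed = seed),
                     class = "repeat_embedding"))
  }
  set.seed(seed)
  span <- max(D)
  if (span == 0) span <- 1
  best <- NULL
  for (i in seq_len(n_init)) {
    X0 <- matrix(stats::runif(n * 2, -span, span), n, 2)
    run <- smacof_run(D, X0, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  coords <- best$X
  coords <- sweep(coords, 2, colMeans(coords))  # centre
  dimnames(coords) <- list(labels, c("x", "y"))
  structure(list(labels = labels, coords = coords, stress = best$stress,
                 stress_trace = best$trace, seed = seed),
            class = "repeat_embedding")
}

#' @export
print.repeat_embedding <- function(x, ...) {
  cat(sprintf("<repeat_embedding> %d points in 2-D, final stress %.4g (%d iterations)\n",
              nrow(x$coords), x$stress, length(x$stress_trace) - 1L))
  invisible(x)
}

#' @export
plot.repeat_embedding <- function(x, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2], xlab = "MDS 1", ylab = "MDS 2",
                 main = sprintf("SMACOF embedding (stress %.3g)", x$stress), ...)
  invisible(x)
}

#' Gaussian kernel density estimate on a grid
#'
#' Plain Gaussian-kernel density with Scott's-rule bandwidth by default, used
#' for the marginal distributions of MDS coordinates.
#'
#' @param values Numeric sample (at least two distinct values).
#' @param grid Evaluation grid; defaults to 512 points spanning the data
#'   plus 3 bandwidths on either side.
#' @param bw Bandwidth; default Scott's rule ([stats::bw.nrd()]).
#' @return `data.frame` with columns `grid` and `density`.
#' @export
kde_marginal <- function(values, grid = NULL, bw = NULL) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("need at least two distinct values (the data-driven bandwidth is 0 ",
         "otherwise); supply a spread-out sample or an explicit bw")
  if (is.null(bw)) bw <- stats::bw.nrd(values)
  if (is.null(grid))
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = 512)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g - values, sd = bw)),
                 numeric(1))
  data.frame(grid = grid, density = dens)
}

#' Within-genome normalized repeat-distance distribution
#'
#' Pools the pairwise normalized consensus-repeat distances within each
#' genome that has at least two arrays, stratified by the genome's array
#' count. Each genome with `k` arrays contributes `k (k - 1) / 2` distances.
#'
#' @param cohort List of [genome_annotation()] objects.
#' @param normalization Passed to [distance_matrix()]; `per_genome_max` by
#'   default.
#' @return `data.frame` with columns `genome_id`, `k` (arrays in the genome),
#'   `distance`.
#' @export
distance_distribution <- function(cohort, normalization = c("per_genome_max",
                                                            "global_max",
                                                            "none")) {
  normalization <- match.arg(normalization)
  global_L <- if (normalization == "global_max") {
    max(1, unlist(lapply(cohort, function(g) nchar(g$arrays$consensus_repeat))))
  } else NA
  rows <- lapply(cohort, function(g) {
    k <- nrow(g$arrays)
    if (k < 2L) return(NULL)
    reps <- toupper(g$arrays$consensus_repeat)
    D <- utils::adist(reps)
    L <- switch(normalization, none = 1,
                per_genome_max = max(nchar(reps)),
                global_max = global_L)
    D <- D / L
    data.frame(genome_id = g$genome_id, k = k,
               distance = D[upper.tri(D)], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome_id = character(), k = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
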