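#' Plant barrier and corridor strips on a deme grid
#'
#' Builds the "true" rate field used by the synthetic-data generator:
#' a background log10 migration rate of 0 with axis-aligned rectangular
#' strips of depressed (barriers) or elevated (corridors) migration.
#' Strips must not overlap and each must contain at least one vertex.
#'
#' @param graph A [deme_grid()] object.
#' @param strips List of strips, each a list with elements `label`
#'   (`"barrier"` or `"corridor"`), `depth` (log10 offset added to the
#'   background; negative for barriers, positive for corridors), and
#'   `xlim`, `ylim` (numeric length-2 ranges in graph coordinates; either
#'   may be `NULL` for the full range).
#' @param log10_q Per-vertex log10 diversity rates (default uniform 0).
#' @return An object of class `rate_field` with per-vertex `log10_m`,
#'   `log10_q` and an `annotations` list mapping `barrier`, `corridor` and
#'   `background` to vertex index sets.
#' @examples
#' g <- deme_grid(c(0, 900, 0, 400), spacing_km = 100, mode = "planar")
#' fld <- rate_field(g, strips = list(
#'   list(label = "barrier", depth = -1, xlim = c(400, 500), ylim = NULL)))
#' table(fld$log10_m)
#' @export
rate_field <- function(graph, strips = list(), log10_q = NULL) {
  stopifnot(inherits(graph, "deme_graph"))
  nv <- nrow(graph$vertices)
  log10_m <- rep(0, nv)
  if (is.null(log10_q)) log10_q <- rep(0, nv)
  if (length(log10_q) != nv) stop("log10_q must have one entry per vertex")
  taken <- rep(FALSE, nv)
  ann <- list(barrier = integer(0), corridor = integer(0))
  for (k in seq_along(strips)) {
    s <- strips[[k]]
    if (is.null(s$label) || !s$label %in% c("barrier", "corridor"))
      stop("strip ", k, ": label must be 'barrier' or 'corridor'")
    if (is.null(s$depth) || s$depth == 0)
      stop("strip ", k, ": depth must be nonzero")
    if (s$label == "barrier" && s$depth >= 0)
      stop("strip ", k, ": barrier depth must be negative")
    if (s$label == "corridor" && s$depth <= 0)
      stop("strip ", k, ": corridor depth must be positive")
    v <- graph$vertices
    inx <- if (is.null(s$xlim)) rep(TRUE, nv)
           else v[, 1L] >= s$xlim[1L] & v[, 1L] <= s$xlim[2L]
    iny <- if (is.null(s$ylim)) rep(TRUE, nv)
           else v[, 2L] >= s$ylim[1L] & v[, 2L] <= s$ylim[2L]
    hit <- which(inx & iny)
    if (length(hit) == 0L)
      stop("strip ", k, " (", s$label, ") does not intersect the grid")
    if (any(taken[hit]))
      stop("strip ", k, " overlaps a previous strip; labels must be disjoint")
    taken[hit] <- TRUE
    log10_m[hit] <- log10_m[hit] + s$depth
    ann[[s$label]] <- sort(c(ann[[s$label]], hit))
  }
  ann$background <- which(!taken)
  structure(list(graph = graph, log10_m = log10_m, log10_q = log10_q,
                 annotations = ann), class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat(sprintf(
    "rate_field: %d vertices (%d barrier, %d corridor, %d background)\n",
    length(x$log10_m), length(x$annotations$barrier),
    length(x$annotations$corridor), length(x$annotations$background)))
  invisible(x)
}

#' Simulate stepping-stone genotype data by forward Wright-Fisher
#'
#' Generates SNP genotypes with the spatial statistical structure the
#' surface model assumes: allele frequencies evolve on the deme graph by
#' deterministic migration followed by binomial drift, then individuals
#' are sampled from their demes.  Per generation, the frequency vector of
#' each locus is multiplied by a migration matrix whose edge rates are
#' `m_base * 10^((log10_m[u] + log10_m[v]) / 2)` (geometric mean of the
#' endpoint rates, matching [rates_on_edges()]), row-normalised so the
#' diagonal holds the non-migrant fraction; then `2 * deme_size` binomial
#' draws per deme implement drift.  There is no mutation; frequencies are
#' initialised Uniform(0.1, 0.9) per locus so loci are exchangeable
#' replicates.  Genotypes are `Binomial(2, f_deme)` draws and sample
#' coordinates are the deme positions plus a small Gaussian jitter.
#'
#' @param field A [rate_field()] object.
#' @param deme_size Diploid individuals per deme (2N chromosomes for
#'   drift); default 100.
#' @param n_generations Number of forward generations; default 300.
#' @param p_snps Number of loci.
#' @param n_per_deme Diploid individuals sampled per deme.
#' @param m_base Baseline per-edge migration fraction per generation at
#'   log10 rate 0; default 0.01.
#' @param outflow_cap Maximum allowed per-deme total emigration fraction
#'   per generation; exceeding it is an error advising a rate rescale.
#' @param jitter_sd Coordinate jitter standard deviation; default 1% of
#'   the grid spacing.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A [geno_matrix()] object with attributes `assignment` (true
#'   deme index per individual), `field`, and `freqs` (final deme x locus
#'   allele frequencies).
#' @export
simulate_wf_genotypes <- function(field, p_snps, n_per_deme,
                                  deme_size = 100, n_generations = 300,
                                  m_base = 0.01, outflow_cap = 0.5,
                                  jitter_sd = NULL, seed = 1) {
  stopifnot(inherits(field, "rate_field"))
  if (p_snps < 1L || n_per_deme < 1L || deme_size < 1L || n_generations < 1L)
    stop("all counts must be positive")
  graph <- field$graph
  nv <- nrow(graph$vertices)
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, nv - igraph::vcount(ig)))
  if (igraph::components(ig)$no > 1L) stop("graph must be connected")
  if (is.null(jitter_sd)) jitter_sd <- 0.01 * graph$spacing_km
  w <- m_base * rates_on_edges(field$log10_m, graph)
  M <- matrix(0, nv, nv)
  e <- graph$edges
  M[cbind(e[, 1L], e[, 2L])] <- w
  M[cbind(e[, 2L], e[, 1L])] <- w
  out <- rowSums(M)
  if (any(out > outflow_cap))
    stop("per-deme migration outflow exceeds cap (max ",
         signif(max(out), 3), " > ", outflow_cap,
         "); rescale m_base or rate field")
  diag(M) <- 1 - out
  set.seed(as.integer(seed))
  twoN <- 2L * as.integer(deme_size)
  f <- matrix(runif(nv * p_snps, 0.1, 0.9), nv, p_snps)
  for (t in seq_len(n_generations)) {
    f <- M %*% f
    f[f < 0] <- 0; f[f > 1] <- 1   # clip floating-point rounding
    f <- matrix(rbinom(nv * p_snps, twoN, f), nv, p_snps) / twoN
  }
  assignment <- rep(seq_len(nv), each = n_per_deme)
  n <- length(assignment)
  geno <- matrix(rbinom(n * p_snps, 2L, f[assignment, ]), n, p_snps)
  coords <- graph$vertices[assignment, , drop = FALSE] +
    matrix(rnorm(2L * n, sd = jitter_sd), n, 2L)
  samples <- data.frame(
    sample_id = sprintf("ind_%04d", seq_len(n)),
    lon = coords[, 1L], lat = coords[, 2L],
    pop = sprintf("deme_%03d", assignment),
    language = NA_character_)
  snps <- data.frame(chr = 1L, id = sprintf("snp_%06d", seq_len(p_snps)),
                     pos = seq_len(p_snps) * 1000L,
                     a1 = "A", a2 = "C")
  g <- geno_matrix(geno, snps, samples)
  attr(g, "assignment") <- assignment
  attr(g, "field") <- field
  attr(g, "freqs") <- f
  g
}

#' Draw a dissimilarity matrix from the model's own likelihood
#'
#' Model-exact generator: draws the contrast-projected scatter matrix from
#' the Wishart distribution with `p` degrees of freedom and mean
#' `sigma2 * M`, where `M = -1/2 * C Delta C'` with the fixed contrast
#' basis `C` (rows `e_1 - e_{i+1}`), then back-transforms to a pairwise
#' dissimilarity matrix with zero diagonal.  The expectation of the
#' returned matrix is `sigma2 * delta`.
#'
#' @param delta Expected individual-level dissimilarity matrix (symmetric,
#'   zero diagonal); e.g. an [expected_dissimilarity()] expanded to
#'   individuals.
#' @param sigma2 Positive scale.
#' @param p Loci count (degrees of freedom, `p >= nrow(delta)`).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return Dissimilarity matrix of the same dimension as `delta`.
#' @export
simulate_model_exact <- function(delta, sigma2, p, seed = 1) {
  delta <- as.matrix(delta)
  if (!isSymmetric(unname(delta), tol = 1e-8))
    stop("delta must be symmetric")
  dd <- delta
  diag(dd) <- 0
  M <- -0.5 * contrast_project(dd)
  ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
  if (!ok) stop("implied covariance is not positive definite")
  if (p < nrow(delta)) stop("need p >= number of individuals")
  set.seed(as.integer(seed))
  W <- rWishart(1L, df = p, Sigma = sigma2 * M / p)[, , 1L]
  D <- contrast_backproject(W)
  rownames(D) <- colnames(D) <- rownames(delta)
  D
}

#' Write a synthetic dataset to disk
#'
#' Writes the genotype trio files, the sample coordinate table and a JSON
#' truth file (rate field, annotations, simulation settings) for recovery
#' scoring.
#'
#' @param g A simulated [geno_matrix()] from [simulate_wf_genotypes()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_synth_dataset <- function(g, prefix) {
  write_plink(g, prefix)
  write_coords_tsv(g, paste0(prefix, ".coords.tsv"))
  fld <- attr(g, "field")
  truth <- list(
    log10_m = fld$log10_m, log10_q = fld$log10_q,
    annotations = lapply(fld$annotations, as.integer),
    assignment = as.integer(attr(g, "assignment")))
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
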