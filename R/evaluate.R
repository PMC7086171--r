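#' Observed pairwise genetic dissimilarity
#'
#' `D_ij` is the average squared genotype difference `(g_il - g_jl)^2`
#' over loci typed in both individuals (pairwise-complete); the diagonal
#' is zero.  Units are squared allele counts.
#'
#' @param g A [geno_matrix()] object with at least 2 individuals.
#' @return Symmetric n x n matrix with sample ids as dimnames.
#' @export
observed_dissimilarity <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  gg <- g$geno
  n <- nrow(gg)
  if (n < 2L) stop("need at least 2 individuals")
  Mmask <- !is.na(gg)
  X0 <- gg; X0[!Mmask] <- 0L
  X0 <- matrix(as.numeric(X0), n)
  Mn <- matrix(as.numeric(Mmask), n)
  X2 <- X0^2
  shared <- tcrossprod(Mn)
  num <- X2 %*% t(Mn) + Mn %*% t(X2) - 2 * tcrossprod(X0)
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    w <- which(off, arr.ind = TRUE)[1L, ]
    stop("no shared typed loci for pair ", g$samples$sample_id[w[1L]],
         " / ", g$samples$sample_id[w[2L]])
  }
  D <- num / pmax(shared, 1)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(g$samples$sample_id, g$samples$sample_id)
  D
}

#' Genotype principal component analysis
#'
#' Missing calls are mean-imputed per SNP, columns are mean-centred (no
#' variance scaling by default, the common convention for genotype PCA),
#' and a truncated eigendecomposition of the sample covariance yields
#' scores and loadings.  A deterministic sign convention makes the
#' largest-magnitude loading of each PC positive.
#'
#' @param g A [geno_matrix()] object.
#' @param k Number of components, `k <= min(n - 1, p)`.
#' @param scale Also scale each SNP to unit variance (default `FALSE`).
#' @return List with `scores` (n x k), `loadings` (p x k), `eigenvalues`
#'   (variances along each PC, length k).
#' @export
pca_decompose <- function(g, k, scale = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  gg <- g$geno
  n <- nrow(gg); p <- ncol(gg)
  if (k > min(n - 1L, p))
    stop("k exceeds the maximum rank min(n - 1, p) = ", min(n - 1L, p))
  if (any(colMeans(is.na(gg)) == 1))
    stop("all-missing SNP column present")
  mu <- colMeans(gg, na.rm = TRUE)
  X <- sweep(gg, 2L, mu)
  X[is.na(X)] <- 0
  if (scale) {
    sdv <- apply(gg, 2L, sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    X <- sweep(X, 2L, sdv, `/`)
  }
  K <- tcrossprod(X)
  ee <- eigen(K, symmetric = TRUE)
  lam <- pmax(ee$values[seq_len(k)], 0)
  U <- ee$vectors[, seq_len(k), drop = FALSE]
  sv <- sqrt(lam)
  scores <- U %*% diag(sv, k)
  loadings <- crossprod(X, U)
  loadings <- sweep(loadings, 2L, pmax(sv, .Machine$double.eps), `/`)
  ## sign convention: largest-|loading| entry positive per PC
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- g$samples$sample_id
  rownames(loadings) <- g$snps$id
  list(scores = scores, loadings = loadings,
       eigenvalues = lam / (n - 1L))
}

#' Population distance matrix implied by leading PCs
#'
#' Takes the coordinatewise median of each population's individuals over
#' the first `k` PC scores and returns squared Euclidean distances
#' between the population medians.
#'
#' @param scores Score matrix from [pca_decompose()].
#' @param pops Population label per individual (row of `scores`).
#' @param k Number of components to use; conventional choices are 2, 10
#'   and 100 (capped at the available rank).
#' @return Symmetric matrix over populations (sorted unique labels).
#' @export
expected_distance_from_pcs <- function(scores, pops, k) {
  if (k > ncol(scores)) stop("k exceeds available components")
  pops <- as.character(pops)
  if (any(is.na(pops))) stop("every individual needs a population label")
  med <- t(vapply(split(seq_along(pops), pops), function(ix) {
    apply(scores[ix, seq_len(k), drop = FALSE], 2L, median)
  }, numeric(k)))
  D <- as.matrix(dist(med))^2
  dimnames(D) <- list(rownames(med), rownames(med))
  D
}

#' Population distance matrix implied by the posterior surfaces
#'
#' For each posterior draw the fitted surfaces imply an expected
#' dissimilarity between the observed demes scaled by that draw's
#' `sigma2`; averaging over draws gives the model's expected distance
#' matrix between populations (populations are mapped to their deme).
#'
#' @param fit A [migsurf()] fit.
#' @param pops Population label per individual used in the fit; default
#'   one population per observed deme.
#' @return Symmetric matrix over populations; diagonal holds the expected
#'   within-deme dissimilarity.
#' @export
expected_distance_from_posterior <- function(fit, pops = NULL) {
  stopifnot(inherits(fit, "migsurf"))
  demes <- fit$obs_demes
  idx <- match(fit$assignment, demes)
  if (is.null(pops)) pops <- sprintf("deme_%03d", fit$assignment)
  pops <- as.character(pops)
  pd <- vapply(split(idx, pops), function(ix) {
    u <- unique(ix)
    if (length(u) != 1L)
      stop("population spans multiple demes; supply per-deme labels")
    u
  }, integer(1))
  draws <- fit$draws
  nd <- length(draws$sigma2)
  acc <- 0
  for (s in seq_len(nd)) {
    w <- rates_on_edges(draws$m_vertex[s, ], fit$graph)
    R <- resistance_from_laplacian(nrow(fit$graph$vertices),
                                   fit$graph$edges, w)
    delta <- expected_dissimilarity(R, 10^draws$q_vertex[s, ], demes)
    acc <- acc + draws$sigma2[s] * as.matrix(delta)[pd, pd, drop = FALSE]
  }
  D <- acc / nd
  dimnames(D) <- list(names(pd), names(pd))
  D
}

#' Correlation between expected and observed distance matrices
#'
#' Pearson correlation over the strict upper triangle, the standard
#' summary for comparing model-implied and observed genetic distances.
#'
#' @param expected,observed Symmetric matrices with identical ordering.
#' @param method Label stored in the result (e.g. `"posterior-surface"`,
#'   `"pca-10"`).
#' @return Object of class `fit_result` with elements `method`,
#'   `pearson_r`, `n_pairs`.
#' @export
fit_correlation <- function(expected, observed, method = "expected") {
  expected <- as.matrix(expected); observed <- as.matrix(observed)
  if (!all(dim(expected) == dim(observed))) stop("shape mismatch")
  if (nrow(expected) < 3L) stop("need at least 3 populations")
  ut <- upper.tri(expected)
  x <- expected[ut]; y <- observed[ut]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in distance vector; correlation undefined")
  structure(list(method = method, pearson_r = cor(x, y),
                 n_pairs = sum(ut)), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: Pearson r = %.4f over %d pairs\n",
              x$method, x$pearson_r, x$n_pairs))
  invisible(x)
}

#' Multi-locus Weir-Cockerham FST
#'
#' The 1984 variance-component estimator: per-locus among-population (a),
#' among-individual (b) and within-individual (c) components combined as
#' a ratio of sums, `FST = sum(a) / sum(a + b + c)`.  Monomorphic loci are
#' skipped.
#'
#' @param g A [geno_matrix()] object.
#' @param pops Population label per individual; at least 2 populations
#'   with at least 2 individuals each.
#' @return Single FST estimate.
#' @export
fst_empirical <- function(g, pops) {
  stopifnot(inherits(g, "geno_matrix"))
  pops <- as.character(pops)
  tab <- table(pops)
  if (length(tab) < 2L) stop("need at least 2 populations")
  if (any(tab < 2L)) stop("each population needs at least 2 individuals")
  gg <- g$geno
  groups <- split(seq_len(nrow(gg)), pops)
  r <- length(groups)
  suma <- 0; sumall <- 0
  any_poly <- FALSE
  for (l in seq_len(ncol(gg))) {
    x <- gg[, l]
    ni <- vapply(groups, function(ix) sum(!is.na(x[ix])), numeric(1))
    if (any(ni < 1)) next
    pi <- vapply(groups, function(ix) mean(x[ix], na.rm = TRUE), numeric(1)) / 2
    hi <- vapply(groups, function(ix) mean(x[ix] == 1L, na.rm = TRUE),
                 numeric(1))
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    any_poly <- TRUE
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    suma <- suma + a
    sumall <- sumall + a + b + cc
  }
  if (!any_poly) stop("all loci are monomorphic; FST undefined")
  suma / sumall
}

#' Equilibrium stepping-stone FST from a mean migration rate
#'
#' The classic equilibrium approximation `FST = 1 / (1 + 4 M kappa)` with
#' `M = deme_size_scaling * mean_m` the effective number of migrants and
#' `kappa` a geometry constant (1 corresponds to the many-deme island
#' approximation; finite island models with d demes use `kappa =
#' d / (d - 1)` under the pairwise between-deme FST definition).  This is
#' an approximation: it ignores the full lattice geometry.
#'
#' @param mean_m Mean relative migration rate (e.g. the posterior mean on
#'   the natural scale); must be positive.
#' @param deme_size_scaling Multiplier converting the relative rate into
#'   an effective migrant number `N * m`.
#' @param kappa Geometry constant (default 1).
#' @return Theoretical FST in (0, 1).
#' @export
fst_stepping_stone <- function(mean_m, deme_size_scaling = 1, kappa = 1) {
  if (mean_m <= 0 || deme_size_scaling <= 0 || kappa <= 0)
    stop("all inputs must be positive")
  M <- deme_size_scaling * mean_m
  1 / (1 + 4 * M * kappa)
}

#' Fully connected island-model deme graph
#'
#' A complete graph over `n_demes` demes, the classic island model.  Used
#' with [simulate_wf_genotypes()] to generate data whose equilibrium FST
#' has a closed form, against which [fst_stepping_stone()] can be checked.
#'
#' @param n_demes Number of demes (at least 2).
#' @param spacing_km Nominal spacing stored on the graph (default 100).
#' @return A `deme_graph` (planar mode, demes on a circle).
#' @export
island_graph <- function(n_demes, spacing_km = 100) {
  if (n_demes < 2L) stop("need at least 2 demes")
  th <- 2 * pi * (seq_len(n_demes) - 1L) / n_demes
  r <- if (n_demes == 2L) spacing_km / 2 else
    spacing_km / (2 * sin(pi / n_demes))
  verts <- cbind(x = r * cos(th), y = r * sin(th))
  edges <- t(utils::combn(n_demes, 2L))
  structure(list(vertices = verts, edges = edges, spacing_km = spacing_km,
                 mode = "planar"), class = "deme_graph")
}

#' Partial Mantel test for language-boundary signal
#'
#' Partial correlation between a genetic distance matrix and a categorical
#' same/different-group indicator matrix, controlling for geographic
#' distance: both matrices are regressed on the geographic distances
#' (upper-triangle vectors) and the residuals correlated.  The null
#' distribution permutes population labels (rows and columns jointly) of
#' the genetic matrix; the P-value is one-sided upper,
#' `(1 + #(r_perm >= r_obs)) / (n_perm + 1)`.  Mantel-type tests are known
#' to be liberally calibrated under strong spatial autocorrelation;
#' interpret with care.
#'
#' @param D_gen Genetic distance matrix between populations.
#' @param D_lang 0/1 matrix: 1 if the populations belong to different
#'   language groups.
#' @param D_geo Geographic distance matrix (see
#'   [great_circle_matrix()]).
#' @param n_perm Number of permutations, at least 99 (default 999).
#' @param seed Integer seed.
#' @return List with `statistic` (partial r), `p_value`, `n_perm`.
#' @export
partial_mantel <- function(D_gen, D_lang, D_geo, n_perm = 999, seed = 1) {
  D_gen <- as.matrix(D_gen); D_lang <- as.matrix(D_lang)
  D_geo <- as.matrix(D_geo)
  n <- nrow(D_gen)
  if (!all(dim(D_lang) == n) || !all(dim(D_geo) == n))
    stop("matrices must have matching shapes")
  if (n_perm < 99) stop("need at least 99 permutations")
  ut <- upper.tri(D_gen)
  geo <- D_geo[ut]
  lang <- D_lang[ut]
  if (sd(lang) == 0 || sd(D_gen[ut]) == 0)
    stop("constant matrix; partial correlation undefined")
  ## simple-regression residuals in closed form (least squares on geo)
  vg <- var(geo)
  resid_on_geo <- function(v) {
    if (vg == 0) v - mean(v)
    else v - mean(v) - cov(v, geo) / vg * (geo - mean(geo))
  }
  rl <- resid_on_geo(lang)
  pr <- function(Dg) {
    rg <- resid_on_geo(Dg[ut])
    if (sd(rg) == 0 || sd(rl) == 0) return(NA_real_)
    cor(rg, rl)
  }
  r_obs <- pr(D_gen)
  set.seed(as.integer(seed))
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    r_perm[b] <- pr(D_gen[pm, pm])
  }
  p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  list(statistic = r_obs, p_value = p, n_perm = n_perm)
}
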