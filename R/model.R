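#' Create a Voronoi rate tessellation
#'
#' A piecewise-constant log10 rate surface: each seed point owns a Voronoi
#' tile, and every grid vertex takes the rate `mean + effect` of its nearest
#' seed.  Migration surfaces are relative, so their `mean` is fixed at 0;
#' the diversity surface carries a free mean level.
#'
#' @param seeds k x 2 matrix of seed coordinates (same coordinate system as
#'   the deme graph the tessellation will be evaluated on).
#' @param effects Numeric vector of per-tile log10 rate offsets.
#' @param mean Overall log10 level added to every tile (default 0).
#' @param effect_bound Maximum allowed |effect| in log10 units (default 2).
#' @return An object of class `rate_tess`.
#' @export
rate_tess <- function(seeds, effects, mean = 0, effect_bound = 2) {
  seeds <- matrix(as.numeric(seeds), ncol = 2L)
  effects <- as.numeric(effects)
  if (nrow(seeds) < 1L) stop("tessellation needs at least one tile")
  if (nrow(seeds) != length(effects))
    stop("number of seeds and effects must match")
  if (any(!is.finite(effects)) || any(abs(effects) > effect_bound))
    stop("tile effects must be finite and within +/-", effect_bound,
         " log10 units")
  structure(list(seeds = seeds, effects = effects, mean = mean,
                 effect_bound = effect_bound), class = "rate_tess")
}

#' @export
print.rate_tess <- function(x, ...) {
  cat(sprintf("rate_tess: %d tiles, mean %g, effects in [%g, %g]\n",
              nrow(x$seeds), x$mean, min(x$effects), max(x$effects)))
  invisible(x)
}

#' Evaluate a tessellated rate surface at the grid vertices
#'
#' Each vertex takes `mean + effect` of its nearest seed (ties broken by the
#' lowest seed index).  Distances are Euclidean in the graph's coordinate
#' space for planar graphs and great-circle for spherical graphs.
#'
#' @param tess A [rate_tess()] object.
#' @param graph A [deme_grid()] object.
#' @return Numeric vector of per-vertex log10 rates.
#' @export
rates_on_vertices <- function(tess, graph) {
  stopifnot(inherits(tess, "rate_tess"), inherits(graph, "deme_graph"))
  tile <- nearest_seed(graph$vertices, tess$seeds, graph$mode)
  tess$mean + tess$effects[tile]
}

nearest_seed <- function(pts, seeds, mode = "planar") {
  if (nrow(seeds) == 1L) return(rep(1L, nrow(pts)))
  d <- if (mode == "spherical") {
    great_circle_matrix(pts, seeds)
  } else {
    ## squared Euclidean distance: same nearest seed, no sqrt needed
    dx <- outer(pts[, 1L], seeds[, 1L], `-`)
    dy <- outer(pts[, 2L], seeds[, 2L], `-`)
    dx * dx + dy * dy
  }
  max.col(-d, ties.method = "first")
}

#' Edge conductances from vertex migration rates
#'
#' The conductance of edge (u, v) is the geometric mean of the endpoint
#' rates on the natural scale: `10^((log10_m[u] + log10_m[v]) / 2)`.
#'
#' @param vertex_log10_m Per-vertex log10 migration rates.
#' @param graph A [deme_grid()] object.
#' @return Numeric vector of per-edge conductances, one per row of
#'   `graph$edges`.
#' @export
rates_on_edges <- function(vertex_log10_m, graph) {
  stopifnot(inherits(graph, "deme_graph"))
  if (length(vertex_log10_m) != nrow(graph$vertices))
    stop("need one rate per vertex")
  if (any(!is.finite(vertex_log10_m))) stop("rates must be finite")
  e <- graph$edges
  10^((vertex_log10_m[e[, 1L]] + vertex_log10_m[e[, 2L]]) / 2)
}

#' Resistance distances on a weighted deme graph
#'
#' Effective electrical resistance between every pair of vertices when each
#' edge carries its conductance, computed through the pseudo-inverse of the
#' weighted graph Laplacian.  Resistance distance is the model's proxy for
#' how fast genetic dissimilarity accrues between demes.
#'
#' @param graph A [deme_grid()] object.
#' @param conductances Positive per-edge conductances (row order of
#'   `graph$edges`).
#' @return Symmetric matrix `R` with zero diagonal.
#' @export
resistance_distances <- function(graph, conductances) {
  stopifnot(inherits(graph, "deme_graph"))
  if (length(conductances) != nrow(graph$edges))
    stop("need one conductance per edge")
  if (any(!is.finite(conductances)) || any(conductances <= 0))
    stop("conductances must be positive and finite")
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(
    ig, max(0L, nrow(graph$vertices) - igraph::vcount(ig)))
  if (igraph::components(ig)$no > 1L)
    stop("graph is disconnected: resistance distances are infinite")
  resistance_from_laplacian(nrow(graph$vertices), graph$edges, conductances)
}

## fast path shared with the MCMC inner loop: no connectivity check.
## Uses (L + J/n)^{-1} = L^+ + J/n; the J/n terms cancel in
## R_uv = K_uu + K_vv - 2 K_uv.
resistance_from_laplacian <- function(nv, edges, w) {
  L <- matrix(0, nv, nv)
  iu <- edges[, 1L]; iv <- edges[, 2L]
  L[cbind(iu, iv)] <- -w
  L[cbind(iv, iu)] <- -w
  diag(L) <- -rowSums(L)
  K <- solve(L + 1 / nv)
  dK <- diag(K)
  R <- outer(dK, dK, `+`) - 2 * K
  R[R < 0] <- 0   # clip tiny negative rounding noise
  R
}

#' Expected pairwise dissimilarity between observed demes
#'
#' Combines the resistance distances with the local diversity rates:
#' for distinct demes `a != b`,
#' `Delta(a, b) = (q_a + q_b) / 2 + R(a, b) / 4`, and the diagonal holds
#' `Delta(a, a) = q_a`, the expected dissimilarity of two distinct
#' individuals sampled from the same deme.  The commute-time scaling 1/4
#' and the additive within-deme term are fixed conventions of the model;
#' the likelihood's free scale sigma^2 absorbs overall units but not the
#' balance between the q and R parts.
#'
#' @param R Vertex-level resistance distance matrix
#'   (from [resistance_distances()]).
#' @param vertex_q Per-vertex diversity rates on the natural scale (> 0).
#' @param demes Integer vector of observed deme (vertex) indices.
#' @return Symmetric matrix over `demes` with `q` on the diagonal; class
#'   `expected_dissimilarity` with attribute `demes`.
#' @export
expected_dissimilarity <- function(R, vertex_q, demes = seq_len(nrow(R))) {
  if (any(vertex_q < 0)) stop("diversity rates q must be non-negative")
  q <- vertex_q[demes]
  D <- outer(q, q, `+`) / 2 + R[demes, demes, drop = FALSE] / 4
  diag(D) <- q
  structure(D, demes = demes, class = c("expected_dissimilarity", "matrix"))
}

## ---- contrast basis and Wishart likelihood ---------------------------------

## project an n x n matrix with the fixed contrast basis C whose rows are
## e_1 - e_{i+1}: returns the (n-1) x (n-1) matrix C X C'
contrast_project <- function(X) {
  n <- nrow(X)
  X11 <- X[1L, 1L]
  r <- X[-1L, 1L]
  X11 + X[-1L, -1L, drop = FALSE] - outer(r, rep(1, n - 1L)) -
    outer(rep(1, n - 1L), X[1L, -1L])
}

## inverse of contrast_project restricted to symmetric X with zero diagonal
contrast_backproject <- function(A) {
  n <- nrow(A) + 1L
  D <- matrix(0, n, n)
  dA <- diag(A)
  D[1L, -1L] <- dA
  D[-1L, 1L] <- dA
  inner <- outer(dA, dA, `+`) - 2 * A
  diag(inner) <- 0
  D[-1L, -1L] <- inner
  D
}

## log multivariate gamma function, dimension d at argument a
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## expand a deme-level expected dissimilarity to the individual level:
## zero diagonal, q_a for same-deme pairs, Delta(a,b) otherwise
expand_to_individuals <- function(delta, deme_index) {
  Dq <- as.matrix(delta)[deme_index, deme_index, drop = FALSE]
  diag(Dq) <- 0
  Dq
}

#' Wishart log-likelihood of an observed dissimilarity matrix
#'
#' The observed individual-level dissimilarity matrix `D` is projected with
#' a fixed contrast basis `C` (rows `e_1 - e_{i+1}`) into a scatter matrix
#' `S = -1/2 * C D C' * p`, which is modelled as Wishart with `p` degrees
#' of freedom and scale `Sigma = sigma2 * (-1/2 * C Delta* C')`, where
#' `Delta*` is the individual-level expansion of the deme-level expected
#' dissimilarity (zero diagonal, same-deme pairs equal to the deme's `q`).
#' Under this convention `E[S] = p * Sigma`.  The basis affects the density
#' only through an additive constant, which cancels in all MCMC acceptance
#' ratios and Bayes-factor differences.
#'
#' @param D_obs n x n observed dissimilarity matrix
#'   (see [observed_dissimilarity()]).
#' @param delta Deme-level [expected_dissimilarity()] matrix.
#' @param assignment Either a [assign_demes()] object or an integer vector
#'   mapping each of the n individuals to a row of `delta` (i.e. to an
#'   observed deme, in the order of `attr(delta, "demes")`).
#' @param sigma2 Positive scale parameter.
#' @param p Number of loci (Wishart degrees of freedom); must satisfy
#'   `p >= n`.
#' @return The log-likelihood; `-Inf` with attribute `"npd" = TRUE` if the
#'   implied scale matrix is not positive definite.
#' @export
wishart_loglik <- function(D_obs, delta, assignment, sigma2, p) {
  D_obs <- as.matrix(D_obs)
  n <- nrow(D_obs)
  if (n < 2L) stop("need at least 2 individuals")
  if (p < n) stop("Wishart density undefined for p < n")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  idx <- deme_index_of(assignment, delta)
  S <- -0.5 * contrast_project(D_obs) * p
  M <- -0.5 * contrast_project(expand_to_individuals(delta, idx))
  d <- n - 1L
  US <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(US)) stop("observed scatter matrix is not positive definite")
  logdetS <- 2 * sum(log(diag(US)))
  UM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(UM)) {
    ll <- -Inf
    attr(ll, "npd") <- TRUE
    return(ll)
  }
  logdetM <- 2 * sum(log(diag(UM)))
  ## tr(Sigma^-1 S) = tr(M^-1 S) / sigma2 via triangular solve
  X <- forwardsolve(t(UM), t(US))
  trMS <- sum(X * X)
  (p - d - 1) / 2 * logdetS - trMS / (2 * sigma2) -
    p * d / 2 * log(2) - p / 2 * (d * log(sigma2) + logdetM) -
    lmvgamma(p / 2, d)
}

## resolve an assignment argument into indices over the rows of delta
deme_index_of <- function(assignment, delta) {
  demes <- attr(delta, "demes")
  vx <- if (inherits(assignment, "deme_assignment")) assignment$vertex
        else as.integer(assignment)
  if (!is.null(demes) && all(vx %in% demes)) {
    match(vx, demes)
  } else if (all(vx >= 1L & vx <= nrow(delta))) {
    vx
  } else {
    stop("assignment refers to demes not present in 'delta'")
  }
}

#' Write a matrix with ids as TSV
#'
#' @param m Matrix with row/col names (ids added if absent).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
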