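## shared fixtures, built once per test session and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, expr, envir = .fixture_cache)
  .fixture_cache[[name]]
}

## toy genotype panel with known metadata defects, used by the
## variant-filter tests: among the first 10 SNPs, 2 chrX, 1 A/T ambiguous,
## 1 duplicated id, 1 all-heterozygous (HWE excess), 1 high-missingness;
## 60 further clean SNPs keep the filtered panel large enough for the
## relatedness filter; 1 individual with high missingness and 1 exact
## duplicate individual
toy_filter_panel <- function() {
  set.seed(401)
  n <- 120
  p <- 70
  geno <- matrix(rbinom(n * p, 2, 0.4), n, p)
  snps <- data.frame(
    chr = c(1, 1, 2, "X", 3, "X", 4, 5, 6, 7, rep(1:22, length.out = 60)),
    id = sprintf("rs%02d", 1:p),
    pos = rep(seq(1e5, 1e6, length.out = 10), length.out = p),
    a1 = c("A", "C", "G", "A", "A", "C", "C", "C", "T", "A",
           rep("A", 60)),
    a2 = c("T", "T", "A", "C", "G", "G", "T", "T", "C", "G",
           rep("G", 60)),
    stringsAsFactors = FALSE)
  snps$id[7] <- snps$id[8] <- "rs_dup"     # duplicate id, same alleles
  geno[, 5] <- 1L                          # all heterozygous -> HWE excess
  geno[1:3, 9] <- NA_integer_              # 2.5% missing at SNP 9 (> 1%)
  geno[n, ] <- geno[1L, ]                  # exact duplicate individual
  ## one individual missing at 5 of the 64 surviving SNPs (7.8% > 5%),
  ## while each of those SNPs stays below the 1% per-SNP missingness
  ## threshold (1/120)
  geno[n - 1L, 11:15] <- NA_integer_
  samples <- data.frame(sample_id = sprintf("s%03d", 1:n),
                        lon = runif(n), lat = runif(n))
  geno_matrix(geno, snps, samples)
}

## quantile agreement within chain Monte-Carlo error: compares empirical
## deciles of an autocorrelated chain against an oracle sample, with the
## chain's own batch-means quantile standard errors setting the tolerance
## (plus a small allowance for the oracle's sampling noise)
qq_within_mc_error <- function(chain, oracle, probs = seq(0.1, 0.9, 0.1),
                               n_batch = 40, z = 4, oracle_allow = 0.02) {
  qe <- quantile(chain, probs)
  qo <- quantile(oracle, probs)
  grp <- rep(seq_len(n_batch), each = ceiling(length(chain) / n_batch),
             length.out = length(chain))
  bq <- vapply(split(chain, grp), quantile, numeric(length(probs)),
               probs = probs)
  se <- apply(bq, 1, sd) / sqrt(n_batch)
  all(abs(qe - qo) <= z * se + oracle_allow)
}

## barrier-recovery experiment shared by the inference unit tests and the
## acceptance suite: 10x5 planar grid, one vertical barrier strip of depth
## -1, 4 individuals per deme, 5000 loci, 100k iterations
recovery_experiment <- function() {
  cached("recovery", {
    g <- deme_grid(c(0, 950, 0, 350), spacing_km = 100, mode = "planar")
    fld <- rate_field(g, strips = list(
      list(label = "barrier", depth = -1, xlim = c(420, 530), ylim = NULL)))
    sim <- simulate_wf_genotypes(fld, p_snps = 5000, n_per_deme = 4,
                                 seed = 20)
    D <- observed_dissimilarity(sim)
    cfg <- migsurf_control(n_iter = 100000, burn_in = 20000, thin = 400,
                           n_pilot = 2, pilot_iter = 5000, seed = 2)
    fit <- migsurf(D, g, attr(sim, "assignment"), n_loci = 5000,
                   control = cfg)
    list(graph = g, field = fld, sim = sim, D = D, fit = fit)
  })
}

## long prior-only chain (likelihood switched off) shared by the
## prior-recovery tests
prior_chain <- function() {
  cached("prior_chain", {
    g <- deme_grid(c(0, 400, 0, 300), spacing_km = 100, mode = "planar")
    D <- matrix(0.5, 6, 6); diag(D) <- 0
    pre <- migsurf_data(D, g, rep(1:3, 2), n_loci = 10)
    cfg <- migsurf_control(n_iter = 200000, burn_in = 10000, thin = 20,
                           n_pilot = 0, seed = 5, likelihood = FALSE)
    st <- migsurf_init_state(pre, cfg)
    out <- migsurf:::run_steps(st, pre, cfg, temperature = 1,
                               n_steps = cfg$n_iter,
                               record_from = cfg$burn_in, thin = cfg$thin)
    list(pre = pre, cfg = cfg, draws = out$draws)
  })
}

## random connected weighted graph used by the resistance-distance checks
rand_graph <- function(nv, seed, p_edge = 0.3) {
  set.seed(seed)
  edges <- t(combn(nv, 2))
  keep <- runif(nrow(edges)) < p_edge
  edges <- unique(rbind(edges[keep, , drop = FALSE],
                        cbind(seq_len(nv - 1), seq_len(nv - 1) + 1)))
  structure(list(vertices = cbind(runif(nv), runif(nv)),
                 edges = edges, spacing_km = 1, mode = "planar"),
            class = "deme_graph")
}

## independent per-pair oracle: ground the last vertex and solve L x = b
resistance_oracle <- function(graph, w) {
  nv <- nrow(graph$vertices)
  L <- matrix(0, nv, nv)
  L[graph$edges] <- -w
  L[graph$edges[, c(2, 1)]] <- -w
  diag(L) <- -rowSums(L)
  R <- matrix(0, nv, nv)
  for (u in seq_len(nv - 1)) for (v in seq((u + 1), nv)) {
    b <- rep(0, nv); b[u] <- 1; b[v] <- -1
    x <- c(solve(L[-nv, -nv], b[-nv]), 0)
    R[u, v] <- R[v, u] <- sum(b * x)
  }
  R
}

## population-level mean of an individual-level dissimilarity matrix
pop_mean_matrix <- function(D, pops) {
  pops <- as.character(pops)
  ids <- sort(unique(pops))
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      out[i, j] <- out[j, i] <- mean(D[pops == ids[i], pops == ids[j]])
    }
  }
  out
}

## independent by-hand Weir-Cockerham (1984) variance components for one
## locus given per-population allele counts nA (of 2*ni genes), sample
## sizes ni (diploids) and heterozygote fractions hi
wc_by_hand <- function(nA, ni, hi) {
  r <- length(ni)
  nbar <- mean(ni)
  pi <- nA / (2 * ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

## batch-means Monte-Carlo standard error for an autocorrelated series
batch_se <- function(x, n_batch = 50) {
  bm <- tapply(x, rep(seq_len(n_batch), each = ceiling(length(x) / n_batch),
                      length.out = length(x)), mean)
  sd(bm) / sqrt(length(bm))
}

## construct a minimal fake migsurf fit with given per-vertex draw matrix,
## for testing the posterior summaries in isolation
fake_fit <- function(m_vertex, graph, raster_dim = 10) {
  cell <- migsurf:::raster_cell_map(graph, raster_dim)
  nd <- nrow(m_vertex)
  structure(list(
    draws = list(m_vertex = m_vertex, q_vertex = m_vertex * 0,
                 sigma2 = rep(1, nd), K_m = rep(1L, nd), K_q = rep(1L, nd),
                 mu_q = rep(0, nd), omega2_m = rep(0.25, nd),
                 omega2_q = rep(0.25, nd), loglik = rep(0, nd),
                 logpost = rep(0, nd)),
    acceptance = NULL, graph = graph,
    assignment = rep(1L, 3), obs_demes = 1L, n = 3L, p = 10L,
    control = migsurf_control(), cell_map = cell$map,
    raster_x = cell$x, raster_y = cell$y), class = "migsurf")
}
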