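mk_geno <- function(geno, pos = NULL) {
  p <- ncol(geno)
  geno_matrix(geno,
              data.frame(chr = 1, id = sprintf("s%04d", 1:p),
                         pos = if (is.null(pos)) 1000L * (1:p) else pos,
                         a1 = "A", a2 = "C"),
              data.frame(sample_id = sprintf("i%03d", seq_len(nrow(geno))),
                         lon = 0, lat = 0))
}

test_that("observed dissimilarity follows the pairwise-complete rule", {
  ## identical rows -> 0; single SNP 0 vs 2 -> 4
  g <- mk_geno(rbind(c(0L, 2L), c(0L, 2L), c(2L, 0L)))
  D <- observed_dissimilarity(g)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 4)
  ## missing-data case: {0, NA, 2} vs {0, 1, 2} over 2 shared loci
  g2 <- mk_geno(rbind(c(0L, NA, 2L), c(0L, 1L, 2L)))
  expect_equal(observed_dissimilarity(g2)[1, 2], 0)
  ## zero shared loci is an error naming the pair
  g3 <- mk_geno(rbind(c(0L, NA), c(NA, 1L), c(1L, 1L)))
  expect_error(observed_dissimilarity(g3), "i001|i002")
})

test_that("observed dissimilarity matches the double-loop oracle", {
  set.seed(14)
  geno <- matrix(rbinom(30 * 40, 2, 0.4), 30, 40)
  geno[sample(length(geno), 60)] <- NA
  g <- mk_geno(geno)
  D <- observed_dissimilarity(g)
  oracle <- matrix(0, 30, 30)
  for (i in 1:29) for (j in (i + 1):30) {
    ok <- !is.na(geno[i, ]) & !is.na(geno[j, ])
    oracle[i, j] <- oracle[j, i] <- mean((geno[i, ok] - geno[j, ok])^2)
  }
  expect_lt(max(abs(unname(D) - oracle)), 1e-12)
})

test_that("genotype PCA has the expected spectrum and determinism", {
  ## rank-1 matrix: PC1 carries all variance
  v <- rbinom(40, 2, 0.5)
  geno <- outer(v, rep(1L, 30))
  geno <- geno + 0L
  g <- mk_geno(geno)
  pc <- pca_decompose(g, k = 3)
  expect_gt(pc$eigenvalues[1], 1e-8)
  expect_lt(pc$eigenvalues[2] / pc$eigenvalues[1], 1e-10)
  ## deterministic across runs, including the sign rule
  set.seed(15)
  geno <- matrix(rbinom(50 * 200, 2, 0.5), 50, 200)
  geno[sample(length(geno), 100)] <- NA
  g <- mk_geno(geno)
  p1 <- pca_decompose(g, 5); p2 <- pca_decompose(g, 5)
  expect_lt(max(abs(p1$scores - p2$scores)), 1e-8)
  expect_error(pca_decompose(g, 51), "rank")
  ## two isolated populations separate completely on PC1
  gr <- island_graph(2)
  fld <- rate_field(gr)
  sim <- simulate_wf_genotypes(fld, p_snps = 500, n_per_deme = 20,
                               deme_size = 50, n_generations = 500,
                               m_base = 1e-4, seed = 16)
  pc <- pca_decompose(sim, 2)
  s1 <- pc$scores[sim$samples$pop == "deme_001", 1]
  s2 <- pc$scores[sim$samples$pop == "deme_002", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("PC-implied population distances use coordinatewise medians", {
  set.seed(18)
  scores <- matrix(rnorm(60), 20, 3)
  pops <- rep(c("a", "b"), each = 10)
  ## all individuals of a population at one point: that point is the median
  scores[pops == "a", ] <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  D <- expected_distance_from_pcs(scores, pops, k = 3)
  medb <- apply(scores[pops == "b", ], 2, median)
  expect_equal(D["a", "b"], sum((c(1, 2, 3) - medb)^2))
  expect_error(expected_distance_from_pcs(scores, pops, k = 9), "exceeds")
})

test_that("fit correlation equals the upper-triangle Pearson r", {
  set.seed(19)
  A <- matrix(runif(36), 6, 6); A <- A + t(A); diag(A) <- 0
  expect_equal(fit_correlation(A, A)$pearson_r, 1)
  expect_equal(fit_correlation(A, -A + 2)$pearson_r, -1)
  B <- matrix(1, 6, 6)
  expect_error(fit_correlation(A, B), "zero variance")
  expect_error(fit_correlation(A[1:2, 1:2], A[1:2, 1:2]), "3 populations")
})

test_that("Weir-Cockerham FST matches a by-hand computation", {
  ## 2 pops x 10 diploids, one locus, allele counts 15/20 vs 5/20
  make_geno_from_counts <- function(nA, n) {
    ## nA copies of allele A among 2n chromosomes, spread as evenly
    g <- integer(n)
    g[seq_len(nA %/% 2)] <- 2L
    if (nA %% 2) g[nA %/% 2 + 1] <- 1L
    g
  }
  g1 <- make_geno_from_counts(15, 10)   # 7 hom + 1 het
  g2 <- make_geno_from_counts(5, 10)    # 2 hom + 1 het
  g <- mk_geno(cbind(c(g1, g2)))
  pops <- rep(c("p1", "p2"), each = 10)
  fst <- fst_empirical(g, pops)
  ## independent by-hand variance components (r = 2, nbar = 10)
  r <- 2; ni <- c(10, 10); nbar <- 10
  pi <- c(15, 5) / 20
  hi <- c(mean(g1 == 1), mean(g2 == 1))
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_lt(abs(fst - a / (a + b + cc)), 1e-10)
  ## fixed opposite alleles: FST = 1
  gfix <- mk_geno(cbind(rep(c(0L, 2L), each = 5)))
  expect_equal(fst_empirical(gfix, rep(c("x", "y"), each = 5)), 1)
  ## label swap invariance (0 <-> 2 per locus)
  set.seed(23)
  geno <- matrix(rbinom(40 * 50, 2, 0.3), 40, 50)
  pops2 <- rep(c("x", "y"), each = 20)
  f1 <- fst_empirical(mk_geno(geno), pops2)
  geno2 <- geno; geno2[, 1:25] <- 2L - geno2[, 1:25]
  expect_equal(fst_empirical(mk_geno(geno2), pops2), f1, tolerance = 1e-12)
  ## identical allele frequencies: FST near zero
  big <- matrix(rbinom(400 * 300, 2, rep(runif(300, 0.2, 0.8),
                                         each = 400)), 400, 300)
  f0 <- fst_empirical(mk_geno(big), rep(c("x", "y"), each = 200))
  expect_lt(abs(f0), 0.01)
  ## monomorphic-only panel is an error
  expect_error(fst_empirical(mk_geno(matrix(1e0 * 0, 10, 3)),
                             rep(c("x", "y"), each = 5)), "monomorphic")
})

test_that("stepping-stone FST has the correct limits", {
  expect_lt(fst_stepping_stone(1e9), 1e-8)
  expect_gt(fst_stepping_stone(1e-12), 1 - 1e-8)
  expect_equal(fst_stepping_stone(1, deme_size_scaling = 25, kappa = 1),
               1 / 101)
  expect_error(fst_stepping_stone(-1), "positive")
})

test_that("great-circle distances match closed forms", {
  expect_equal(great_circle_matrix(cbind(10, 20))[1, 1], 0)
  anti <- great_circle_matrix(rbind(c(0, 0), c(180, 0)))
  expect_equal(anti[1, 2], pi * 6371, tolerance = 1e-6)
  set.seed(9)
  pts <- cbind(runif(8, -180, 180), runif(8, -80, 80))
  M <- great_circle_matrix(pts)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
})

test_that("partial Mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  n <- 15
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  D_geo <- as.matrix(dist(xy))
  grp <- rep(c(0, 1), length.out = n)
  D_lang <- outer(grp, grp, `!=`) * 1
  D_gen <- D_geo / 50 + D_lang + matrix(rnorm(n * n, sd = 0.2), n, n)
  D_gen <- (D_gen + t(D_gen)) / 2; diag(D_gen) <- 0
  res <- partial_mantel(D_gen, D_lang, D_geo, n_perm = 99, seed = 1)
  veg <- vegan::mantel.partial(as.dist(D_gen), as.dist(D_lang),
                               as.dist(D_geo), permutations = 99)
  expect_equal(res$statistic, unname(veg$statistic), tolerance = 1e-10)
})

test_that("partial Mantel detects planted language boundaries", {
  set.seed(34)
  n <- 20
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  D_geo <- as.matrix(dist(xy))
  grp <- as.numeric(xy[, 1] > 25)
  D_lang <- outer(grp, grp, `!=`) * 1
  noise <- matrix(rnorm(n * n, sd = 0.5), n, n)
  D_gen <- D_geo + 2 * D_lang + (noise + t(noise)) / 2
  diag(D_gen) <- 0
  res <- partial_mantel(D_gen, D_lang, D_geo, n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
  ## determinism
  res2 <- partial_mantel(D_gen, D_lang, D_geo, n_perm = 999, seed = 2)
  expect_identical(res$p_value, res2$p_value)
  expect_error(partial_mantel(D_gen, D_lang * 0, D_geo), "constant")
  expect_error(partial_mantel(D_gen, D_lang, D_geo, n_perm = 10), "99")
})

test_that("partial Mantel reduces to simple Mantel when geography is flat", {
  set.seed(35)
  n <- 12
  D_geo <- matrix(1, n, n); diag(D_geo) <- 0
  grp <- rep(c(0, 1), each = n / 2)
  D_lang <- outer(grp, grp, `!=`) * 1
  A <- matrix(runif(n * n), n, n); A <- A + t(A); diag(A) <- 0
  res <- partial_mantel(A, D_lang, D_geo, n_perm = 99, seed = 3)
  ut <- upper.tri(A)
  ## the geographic control is constant on the upper triangle, so the
  ## partial statistic equals the simple Mantel correlation
  expect_equal(res$statistic, cor(A[ut], D_lang[ut]), tolerance = 1e-10)
})

test_that("observed dissimilarity grows with resistance distance", {
  g <- deme_grid(c(0, 950, 0, 350), spacing_km = 100, mode = "planar")
  fld <- rate_field(g)
  sim <- simulate_wf_genotypes(fld, p_snps = 2000, n_per_deme = 2, seed = 41)
  D <- observed_dissimilarity(sim)
  asg <- attr(sim, "assignment")
  R <- resistance_distances(g, rep(1, nrow(g$edges)))
  ## population-mean dissimilarity between demes vs resistance distance
  nd <- nrow(g$vertices)
  demepairs <- which(upper.tri(R), arr.ind = TRUE)
  dvals <- apply(demepairs, 1, function(uv) {
    mean(D[asg == uv[1], asg == uv[2]])
  })
  rvals <- R[upper.tri(R)]
  expect_gt(cor(dvals, rvals, method = "spearman"), 0.8)
})
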