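test_that("the sampler control validates its schedule", {
  expect_error(migsurf_control(n_iter = 1000, burn_in = 1000), "burn_in")
  expect_error(migsurf_control(thin = 0), "thin")
  expect_error(migsurf_control(move_weights = c(effect = 1)), "move_weights")
  ## the production-scale schedule is expressible
  cfg <- migsurf_control(n_iter = 8e6, burn_in = 5e5, thin = 20000,
                         n_pilot = 4, pilot_iter = 2e6)
  expect_equal(cfg$thin, 20000)
  expect_equal(cfg$burn_in, 5e5)
})

test_that("prior-only chains recover the tile-count prior", {
  pc <- prior_chain()
  K <- pc$draws$K_m
  ## zero-truncated Poisson(10) mean
  target <- 10 / (1 - exp(-10))
  se <- batch_se(K)
  expect_lt(abs(mean(K) - target), 3 * se)
  se_q <- batch_se(pc$draws$K_q)
  expect_lt(abs(mean(pc$draws$K_q) - target), 3 * se_q)
})

test_that("prior-only chains recover the sigma2 and effect marginals", {
  pc <- prior_chain()
  ## sigma2 ~ Inverse-Gamma(1, 1): compare deciles
  s2 <- pc$draws$sigma2
  qs <- quantile(s2, seq(0.1, 0.9, 0.1))
  th <- 1 / qgamma(seq(0.9, 0.1, -0.1), 1, 1)
  expect_lt(max(abs(qs - th) / th), 0.15)
  ## a vertex's log10 m marginal equals the hierarchical effect prior
  ## (oracle: omega2 ~ U(0,1), effect ~ N(0, omega) truncated to +/-2);
  ## agreement judged against the chain's own quantile MC error
  set.seed(99)
  om <- sqrt(runif(40000))
  oracle <- rnorm(40000, 0, om)
  oracle <- oracle[abs(oracle) <= 2][1:20000]
  expect_true(qq_within_mc_error(pc$draws$m_vertex[, 1], oracle))
  ## support constraints hold everywhere
  expect_lte(max(abs(pc$draws$m_vertex)), 2)
  expect_true(all(pc$draws$omega2_m > 0 & pc$draws$omega2_m <= 1))
  expect_true(all(abs(pc$draws$mu_q) <= 6))
})

test_that("prior-only mean surface is flat at zero", {
  pc <- prior_chain()
  vm <- rowMeans(pc$draws$m_vertex)   # per-draw across-vertex mean
  se <- batch_se(vm)
  expect_lt(abs(mean(vm)), 3 * se)
})

test_that("birth/death flows satisfy detailed balance empirically", {
  pc <- prior_chain()
  pre <- pc$pre; cfg <- pc$cfg
  set.seed(17)
  st <- migsurf_init_state(pre, cfg)
  K <- integer(60000)
  for (i in seq_along(K)) {
    st <- mcmc_step(st, pre, cfg, temperature = 1)
    K[i] <- length(st$m$eff)
  }
  ## flows between adjacent K values around the mode must balance
  for (k in 9:11) {
    up <- sum(K[-length(K)] == k & K[-1] == k + 1)
    dn <- sum(K[-length(K)] == k + 1 & K[-1] == k)
    expect_lt(abs(up - dn) / sqrt(up + dn), 4)
  }
})

test_that("chains with identical seeds are byte-identical", {
  g <- deme_grid(c(0, 400, 0, 300), spacing_km = 100, mode = "planar")
  fld <- rate_field(g)
  sim <- simulate_wf_genotypes(fld, p_snps = 300, n_per_deme = 2,
                               n_generations = 30, seed = 3)
  D <- observed_dissimilarity(sim)
  cfg <- migsurf_control(n_iter = 800, burn_in = 200, thin = 20,
                         n_pilot = 1, pilot_iter = 100, seed = 42)
  f1 <- migsurf(D, g, attr(sim, "assignment"), 300, cfg)
  f2 <- migsurf(D, g, attr(sim, "assignment"), 300, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$acceptance, f2$acceptance)
  ## acceptance rates are logged and lie strictly inside (0, 1) overall
  expect_true(all(f1$acceptance[c("effect", "sigma2")] > 0))
  expect_true(all(f1$acceptance <= 1, na.rm = TRUE))
  expect_equal(sum(f1$proposals), cfg$n_iter)
  ## draw count = floor((n_iter - burn_in) / thin)
  expect_equal(length(f1$draws$sigma2), (800 - 200) %/% 20)
  ## trace serializes as TSV
  f <- tempfile(fileext = ".tsv")
  write_trace_tsv(f1, f)
  tr <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tr), length(f1$draws$sigma2))
  expect_equal(tr$sigma2, f1$draws$sigma2)
  ## final sampler state round-trips through JSON
  fs <- tempfile(fileext = ".json")
  write_model_state(f1$final_state, fs)
  st <- read_model_state(fs)
  expect_equal(st$m$eff, f1$final_state$m$eff)
  expect_equal(unname(st$q$seeds), unname(f1$final_state$q$seeds))
  expect_equal(st$sigma2, f1$final_state$sigma2)
  ## surface rasters write with a JSON header
  pfx <- tempfile()
  s <- posterior_mean_surface(f1)
  write_surface_raster(s, pfx)
  hdr <- jsonlite::read_json(paste0(pfx, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$nx, length(s$x))
  m <- as.matrix(read.table(gzfile(paste0(pfx, ".mean.tsv.gz")),
                            sep = "\t"))
  expect_equal(unname(m), unname(s$mean), ignore_attr = TRUE)
})

test_that("single MCMC moves are deterministic given the RNG state", {
  g <- deme_grid(c(0, 400, 0, 300), spacing_km = 100, mode = "planar")
  D <- matrix(0.5, 6, 6); diag(D) <- 0
  pre <- migsurf_data(D, g, rep(1:3, 2), n_loci = 10)
  cfg <- migsurf_control(likelihood = FALSE)
  st0 <- migsurf_init_state(pre, cfg)
  run <- function() {
    set.seed(7)
    st <- st0
    moves <- character(200); acc <- logical(200)
    for (i in 1:200) {
      st <- mcmc_step(st, pre, cfg)
      moves[i] <- attr(st, "move"); acc[i] <- attr(st, "accepted")
    }
    list(m = moves, a = acc, st = st)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$m, r2$m)
  expect_identical(r1$a, r2$a)
  expect_identical(r1$st$m, r2$st$m)
})

test_that("posterior mean surfaces use the sample-sd convention", {
  g <- deme_grid(c(0, 400, 0, 300), spacing_km = 100, mode = "planar")
  nv <- nrow(g$vertices)
  ## two draws at -1 and +1 everywhere: mean 0, sd sqrt(2)
  fit <- fake_fit(rbind(rep(-1, nv), rep(1, nv)), g)
  s <- posterior_mean_surface(fit)
  expect_true(all(s$mean == 0))
  expect_equal(unique(as.vector(s$sd)), sqrt(2))
  ## identical draws: sd identically zero
  fit2 <- fake_fit(rbind(rep(0.5, nv), rep(0.5, nv)), g)
  expect_true(all(posterior_mean_surface(fit2)$sd == 0))
  expect_error(posterior_mean_surface(fake_fit(matrix(0, 1, nv), g)),
               "2 posterior draws")
})

test_that("trough consensus counts draws below the per-draw mean", {
  g <- deme_grid(c(0, 400, 0, 300), spacing_km = 100, mode = "planar")
  nv <- nrow(g$vertices)
  mk <- function(n_low) {
    V <- matrix(0, 100, nv)
    V[seq_len(n_low), 1] <- -1        # vertex 1 depressed in n_low draws
    V[seq(n_low + 1, 100), 1] <- 2    # elevated otherwise
    V
  }
  fit <- fake_fit(mk(96), g)
  tr <- detect_troughs(fit, threshold = 0.95)
  v1cells <- fit$cell_map == 1
  expect_true(all(tr$labels[v1cells] == "trough"))
  expect_equal(tr$vertex_f_low[1], 0.96)
  ## 90/100 is not enough at 0.95
  tr2 <- detect_troughs(fake_fit(mk(90), g), threshold = 0.95)
  expect_true(all(tr2$labels == "neither"))
  expect_error(detect_troughs(fit, threshold = 0.4), "threshold")
  expect_error(detect_troughs(fake_fit(mk(96)[1:10, ], g)), "20")
})

test_that("fitted surfaces recover a planted barrier", {
  rec <- recovery_experiment()
  fit <- rec$fit
  truth <- rec$field$log10_m
  rho <- cor(coef(fit)$log10_m, truth, method = "spearman")
  expect_gt(rho, 0.5)
  ## summaries behave
  s <- summary(fit)
  expect_true(all(is.finite(s$table[, "mean"])))
  expect_output(print(fit), "migsurf fit")
})

test_that("recovery does not degrade with more loci", {
  ## both correlations are MCMC estimates with sampler noise, and once the
  ## barrier is localised the rank correlation saturates at its ties cap,
  ## so the monotonicity is asserted on a 3-seed mean with a small
  ## Monte-Carlo tolerance
  g <- deme_grid(c(0, 450, 0, 200), spacing_km = 100, mode = "planar")
  fld <- rate_field(g, strips = list(
    list(label = "barrier", depth = -1, xlim = c(170, 280), ylim = NULL)))
  rho <- matrix(0, 3, 2)
  for (s in 1:3) {
    sim <- simulate_wf_genotypes(fld, p_snps = 5000, n_per_deme = 4,
                                 seed = 300 + s)
    rho[s, ] <- vapply(c(500, 5000), function(p) {
      sub <- migsurf:::subset_geno(sim, j = seq_len(p))
      D <- observed_dissimilarity(sub)
      cfg <- migsurf_control(n_iter = 40000, burn_in = 10000, thin = 200,
                             n_pilot = 1, pilot_iter = 3000, seed = 4)
      fit <- migsurf(D, g, attr(sim, "assignment"), p, cfg)
      cor(coef(fit)$log10_m, fld$log10_m, method = "spearman")
    }, numeric(1))
  }
  expect_gte(mean(rho[, 2]), mean(rho[, 1]) - 0.01)
  ## and the barrier is found at both locus counts
  expect_gt(min(rho), 0.5)
})

test_that("identical models give a log Bayes factor near zero", {
  g <- deme_grid(c(0, 450, 0, 200), spacing_km = 100, mode = "planar")
  fld <- rate_field(g)
  sim <- simulate_wf_genotypes(fld, p_snps = 1000, n_per_deme = 2, seed = 31)
  D <- observed_dissimilarity(sim)
  cfg <- migsurf_control(seed = 11, n_temps = 12, bf_iter = 1200,
                         bf_burn = 400, constrain_m = TRUE)
  pre <- migsurf_data(D, g, attr(sim, "assignment"), 1000)
  a <- migsurf:::power_posterior_logml(pre, cfg, constrain_m = TRUE,
                                       seed = 21)
  b <- migsurf:::power_posterior_logml(pre, cfg, constrain_m = TRUE,
                                       seed = 22)
  expect_lt(abs(a$log_ml - b$log_ml), 4 * sqrt(a$se^2 + b$se^2) + 1)
})
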