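#' MCMC and prior settings for surface fitting
#'
#' Collects the schedule, priors and proposal scales of the
#' reversible-jump sampler.  Tile counts have zero-truncated Poisson
#' priors with mean parameter `lambda_tiles`; tile effects are Normal(0,
#' omega^2) truncated to `+/-effect_bound`; omega^2 is Uniform(0, 1); the
#' diversity mean level `mu_q` is Uniform(-6, 6); `sigma2` is
#' Inverse-Gamma(1, 1).  The migration mean level is fixed at 0: migration
#' rates are relative, and the overall scale is carried jointly by the
#' tile effects and `sigma2`.
#'
#' @param n_iter Total iterations of the final chain.
#' @param burn_in Iterations discarded before the first retained draw
#'   (must be `< n_iter`).
#' @param thin Keep every `thin`-th iteration.
#' @param n_pilot Number of pilot chains; the end state with the highest
#'   posterior log-density seeds the final chain.
#' @param pilot_iter Iterations per pilot chain.
#' @param seed Integer seed controlling all randomness.
#' @param move_weights Named weights (summing to 1) over the move types
#'   `effect`, `seed`, `birth`, `death`, `sigma2`, `omega2`, `mu_q`;
#'   `birth` and `death` must have equal weight.  Surface-specific moves
#'   choose the migration or diversity surface uniformly.
#' @param lambda_tiles Mean parameter of the zero-truncated Poisson prior
#'   on tile counts (default 10).
#' @param effect_bound Truncation bound on |tile effect|, log10 units
#'   (default 2).
#' @param effect_step_sd Random-walk sd of effect updates (default 0.1).
#' @param seed_step_sd Random-walk sd of seed moves; default the grid
#'   spacing.
#' @param omega_step_sd Random-walk sd of omega^2 updates (default 0.1).
#' @param mu_step_sd Random-walk sd of mu_q updates (default 0.1).
#' @param likelihood Set `FALSE` to sample the prior (likelihood term
#'   switched off), used for prior-recovery checks.
#' @param constrain_m Fix the migration surface at a single tile (the
#'   uniform-migration null); the diversity tessellation stays free.
#' @param n_temps,temp_exponent Power-posterior temperature ladder
#'   `t_k = (k / (n_temps - 1))^temp_exponent` for marginal-likelihood
#'   estimation (defaults 16 and 5).
#' @param bf_iter,bf_burn Iterations and burn-in per temperature rung.
#' @param raster_dim Cells per side of the surface raster (default 100).
#' @return A list of class `migsurf_control`.
#' @export
migsurf_control <- function(n_iter = 20000, burn_in = 5000, thin = 50,
                            n_pilot = 2, pilot_iter = 2000, seed = 1,
                            move_weights = NULL,
                            lambda_tiles = 10, effect_bound = 2,
                            effect_step_sd = 0.1, seed_step_sd = NULL,
                            omega_step_sd = 0.1, mu_step_sd = 0.1,
                            likelihood = TRUE, constrain_m = FALSE,
                            n_temps = 16, temp_exponent = 5,
                            bf_iter = 1500, bf_burn = 500,
                            raster_dim = 100) {
  if (is.null(move_weights))
    move_weights <- c(effect = 0.30, seed = 0.18, birth = 0.11,
                      death = 0.11, sigma2 = 0.10, omega2 = 0.10,
                      mu_q = 0.10)
  need <- c("effect", "seed", "birth", "death", "sigma2", "omega2", "mu_q")
  if (!setequal(names(move_weights), need))
    stop("move_weights must name exactly: ", paste(need, collapse = ", "))
  move_weights <- move_weights[need]
  if (abs(sum(move_weights) - 1) > 1e-8) stop("move weights must sum to 1")
  if (abs(move_weights[["birth"]] - move_weights[["death"]]) > 1e-12)
    stop("birth and death moves must have equal weight")
  if (burn_in >= n_iter)
    stop("burn_in must be smaller than n_iter (no draws otherwise)")
  if (thin < 1) stop("thin must be at least 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_pilot = n_pilot, pilot_iter = pilot_iter,
                 seed = as.integer(seed), move_weights = move_weights,
                 lambda_tiles = lambda_tiles, effect_bound = effect_bound,
                 effect_step_sd = effect_step_sd, seed_step_sd = seed_step_sd,
                 omega_step_sd = omega_step_sd, mu_step_sd = mu_step_sd,
                 likelihood = likelihood, constrain_m = constrain_m,
                 n_temps = n_temps, temp_exponent = temp_exponent,
                 bf_iter = bf_iter, bf_burn = bf_burn,
                 raster_dim = raster_dim),
            class = "migsurf_control")
}

#' Precompute the model data for the sampler
#'
#' Projects the observed dissimilarity matrix with the fixed contrast
#' basis into the scatter matrix `S = -1/2 C D C' p`, caches its Cholesky
#' factor and log-determinant, and records the deme structure.  Used by
#' [migsurf()], [mcmc_step()] and [log_bayes_factor()].
#'
#' @param D Observed individual-level dissimilarity matrix.
#' @param graph A [deme_grid()] object.
#' @param assignment A [assign_demes()] object or integer vector of vertex
#'   indices, one per individual.
#' @param n_loci Number of loci behind `D` (Wishart degrees of freedom).
#' @return A list of class `migsurf_data`.
#' @export
migsurf_data <- function(D, graph, assignment, n_loci) {
  stopifnot(inherits(graph, "deme_graph"))
  D <- as.matrix(D)
  n <- nrow(D)
  vx <- if (inherits(assignment, "deme_assignment")) assignment$vertex
        else as.integer(assignment)
  if (length(vx) != n) stop("one assignment per individual required")
  if (any(vx < 1L) || any(vx > nrow(graph$vertices)))
    stop("assignment refers to vertices outside the graph")
  if (n_loci < n) stop("need n_loci >= number of individuals")
  obs_demes <- sort(unique(vx))
  deme_index <- match(vx, obs_demes)
  d <- n - 1L
  S <- -0.5 * contrast_project(D) * n_loci
  US <- tryCatch(chol(S), error = function(e)
    stop("projected scatter matrix is not positive definite; ",
         "check that D is a valid dissimilarity matrix"))
  logdetS <- 2 * sum(log(diag(US)))
  p <- n_loci
  const <- (p - d - 1) / 2 * logdetS - p * d / 2 * log(2) -
    lmvgamma(p / 2, d)
  vr <- graph$vertices
  bbox <- c(range(vr[, 1L]), range(vr[, 2L]))
  ## a degenerate direction (single-row grids) still needs positive area
  pad <- graph$spacing_km / 2
  bbox <- bbox + c(-pad, pad, -pad, pad)
  same <- outer(deme_index, deme_index, `==`) & upper.tri(D)
  mean_within <- if (any(same)) mean(D[same])
                 else mean(D[upper.tri(D)]) / 2
  structure(list(D = D, graph = graph, assignment = vx,
                 obs_demes = obs_demes, deme_index = deme_index,
                 n = n, d = d, p = p, S = S, L_S = t(US),
                 logdetS = logdetS, const = const, bbox = bbox,
                 area = (bbox[2L] - bbox[1L]) * (bbox[4L] - bbox[3L]),
                 mean_within = mean_within),
            class = "migsurf_data")
}

## ---- state -----------------------------------------------------------------

## sufficient statistics of a state: vertex rates, resistance distances and
## the Cholesky pieces of M = -1/2 C Delta* C'.  Pass cached pieces for the
## surface that did not change.
compute_ss <- function(state, pre, cfg, vlm = NULL, R = NULL, vq = NULL) {
  if (!cfg$likelihood)
    return(list(ok = TRUE, logdetM = 0, trMS = 0,
                vlm = NULL, R = NULL, vq = NULL))
  g <- pre$graph
  if (is.null(vlm)) {
    tile <- nearest_seed(g$vertices, state$m$seeds, g$mode)
    vlm <- state$m$eff[tile]
    R <- NULL
  }
  if (is.null(R)) {
    w <- 10^((vlm[g$edges[, 1L]] + vlm[g$edges[, 2L]]) / 2)
    R <- resistance_from_laplacian(nrow(g$vertices), g$edges, w)
  }
  if (is.null(vq)) {
    tile <- nearest_seed(g$vertices, state$q$seeds, g$mode)
    vq <- 10^(state$mu_q + state$q$eff[tile])
  }
  od <- pre$obs_demes
  qd <- vq[od]
  Dd <- outer(qd, qd, `+`) / 2 + R[od, od, drop = FALSE] / 4
  diag(Dd) <- qd
  Di <- Dd[pre$deme_index, pre$deme_index, drop = FALSE]
  diag(Di) <- 0
  M <- -0.5 * contrast_project(Di)
  UM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(UM))
    return(list(ok = FALSE, logdetM = NA_real_, trMS = NA_real_,
                vlm = vlm, R = R, vq = vq))
  X <- forwardsolve(t(UM), pre$L_S)
  list(ok = TRUE, logdetM = 2 * sum(log(diag(UM))), trMS = sum(X * X),
       vlm = vlm, R = R, vq = vq)
}

ll_from_ss <- function(ss, sigma2, pre, cfg) {
  if (!cfg$likelihood) return(0)
  if (!ss$ok) return(-Inf)
  pre$const - ss$trMS / (2 * sigma2) -
    pre$p / 2 * (pre$d * log(sigma2) + ss$logdetM)
}

## log prior density of a full state (natural measure; used for pilot-run
## comparison and trace reporting; move acceptances use analytic deltas)
log_prior_state <- function(state, pre, cfg) {
  lam <- cfg$lambda_tiles
  b <- cfg$effect_bound
  ztp <- function(k) k * log(lam) - lfactorial(k) - log(expm1(lam))
  teff <- function(eff, om2) {
    om <- sqrt(om2)
    sum(dnorm(eff, 0, om, log = TRUE)) -
      length(eff) * log(pnorm(b / om) - pnorm(-b / om))
  }
  km <- length(state$m$eff); kq <- length(state$q$eff)
  ztp(km) + ztp(kq) +
    teff(state$m$eff, state$omega2_m) + teff(state$q$eff, state$omega2_q) -
    (km + kq) * log(pre$area) - log(12) -
    2 * log(state$sigma2) - 1 / state$sigma2
}

#' Initial sampler state
#'
#' Builds a single-tile state for both surfaces.  With the likelihood
#' enabled, the migration level of the single tile is chosen by a coarse
#' grid search (jointly with a moment-matched `sigma2` and a data-driven
#' diversity level), which centres the chain near the right overall scale.
#'
#' @param pre A [migsurf_data()] object.
#' @param cfg A [migsurf_control()] object.
#' @return A list of class `migsurf_state`.
#' @export
migsurf_init_state <- function(pre, cfg) {
  ctr <- c(mean(pre$bbox[1:2]), mean(pre$bbox[3:4]))
  state <- list(
    m = list(seeds = matrix(ctr, 1L, 2L), eff = 0),
    q = list(seeds = matrix(ctr, 1L, 2L), eff = 0),
    mu_q = 0, omega2_m = 0.25, omega2_q = 0.25, sigma2 = 1)
  class(state) <- "migsurf_state"
  if (cfg$likelihood) {
    state$mu_q <- clamp(log10(max(pre$mean_within, 1e-6)), -6, 6)
    egrid <- seq(-0.95, 0.95, by = 0.1) * cfg$effect_bound
    for (pass in 1:2) {
      prof <- vapply(egrid, function(e) {
        st <- state; st$m$eff <- e
        ss <- compute_ss(st, pre, cfg)
        if (!ss$ok) return(-Inf)
        ## sigma2 profiled at its conditional posterior mode
        s2 <- ss$trMS / (pre$p * pre$d)
        pre$const - pre$p * pre$d / 2 * (1 + log(s2)) -
          pre$p / 2 * ss$logdetM
      }, numeric(1))
      e0 <- egrid[which.max(prof)]
      state$m$eff <- e0
      ss0 <- compute_ss(state, pre, cfg)
      state$sigma2 <- max(ss0$trMS / (pre$p * pre$d), 1e-8)
      state$mu_q <- clamp(log10(max(pre$mean_within / state$sigma2, 1e-6)),
                          -6, 6)
    }
  }
  state
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

## truncated normal draw by rejection (bound/omega >= 2 in practice)
rtnorm <- function(sd, bound) {
  repeat {
    x <- rnorm(1L, 0, sd)
    if (abs(x) <= bound) return(x)
  }
}

## ---- single MCMC move ------------------------------------------------------

#' One reversible-jump MCMC move
#'
#' Draws one move type (tile effect update, seed move, tile birth, tile
#' death, `sigma2` update, `omega2` update or `mu_q` update), picking the
#' migration or diversity surface uniformly for surface-specific moves,
#' and applies a Metropolis-Hastings accept/reject step.  Births draw the
#' new seed uniformly over the region and the new effect from its prior,
#' so the acceptance ratio reduces to the (tempered) likelihood ratio
#' times the prior tile-count ratio; deaths are the exact reverse.
#' `sigma2` is conjugate given the rest of the state and is updated by a
#' Gibbs draw (always accepted).
#'
#' @param state A `migsurf_state` (see [migsurf_init_state()]) carrying a
#'   cached `ss` element, or a bare state (the cache is built on entry).
#' @param pre A [migsurf_data()] object.
#' @param cfg A [migsurf_control()] object.
#' @param temperature Power-posterior temperature in `[0, 1]` multiplying
#'   the log-likelihood (default 1).
#' @return The updated state; attributes `move` (type) and `accepted`.
#' @export
mcmc_step <- function(state, pre, cfg, temperature = 1) {
  if (is.null(state$ss)) {
    state$ss <- compute_ss(state, pre, cfg)
    state$ll <- ll_from_ss(state$ss, state$sigma2, pre, cfg)
  }
  seed_sd <- if (is.null(cfg$seed_step_sd)) pre$graph$spacing_km
             else cfg$seed_step_sd
  mv <- names(cfg$move_weights)[
    sample.int(7L, 1L, prob = cfg$move_weights)]
  surf <- if (runif(1L) < 0.5) "m" else "q"
  accepted <- FALSE
  t <- temperature
  b <- cfg$effect_bound
  frozen_m <- cfg$constrain_m && surf == "m"

  if (mv == "effect") {
    tess <- state[[surf]]
    j <- sample.int(length(tess$eff), 1L)
    om <- sqrt(if (surf == "m") state$omega2_m else state$omega2_q)
    enew <- tess$eff[j] + rnorm(1L, 0, cfg$effect_step_sd)
    if (abs(enew) <= b) {
      dlp <- dnorm(enew, 0, om, log = TRUE) -
        dnorm(tess$eff[j], 0, om, log = TRUE)
      st2 <- state
      st2[[surf]]$eff[j] <- enew
      ss2 <- if (surf == "m")
        compute_ss(st2, pre, cfg, vq = state$ss$vq)
      else
        compute_ss(st2, pre, cfg, vlm = state$ss$vlm, R = state$ss$R)
      ll2 <- ll_from_ss(ss2, state$sigma2, pre, cfg)
      if (log(runif(1L)) < t * (ll2 - state$ll) + dlp) {
        state <- st2; state$ss <- ss2; state$ll <- ll2
        accepted <- TRUE
      }
    }
  } else if (mv == "seed") {
    tess <- state[[surf]]
    j <- sample.int(nrow(tess$seeds), 1L)
    snew <- tess$seeds[j, ] + rnorm(2L, 0, seed_sd)
    inb <- snew[1L] >= pre$bbox[1L] && snew[1L] <= pre$bbox[2L] &&
      snew[2L] >= pre$bbox[3L] && snew[2L] <= pre$bbox[4L]
    if (inb) {
      st2 <- state
      st2[[surf]]$seeds[j, ] <- snew
      ss2 <- if (surf == "m")
        compute_ss(st2, pre, cfg, vq = state$ss$vq)
      else
        compute_ss(st2, pre, cfg, vlm = state$ss$vlm, R = state$ss$R)
      ll2 <- ll_from_ss(ss2, state$sigma2, pre, cfg)
      if (log(runif(1L)) < t * (ll2 - state$ll)) {
        state <- st2; state$ss <- ss2; state$ll <- ll2
        accepted <- TRUE
      }
    }
  } else if (mv == "birth") {
    if (!frozen_m) {
      tess <- state[[surf]]
      K <- length(tess$eff)
      om <- sqrt(if (surf == "m") state$omega2_m else state$omega2_q)
      snew <- c(runif(1L, pre$bbox[1L], pre$bbox[2L]),
                runif(1L, pre$bbox[3L], pre$bbox[4L]))
      enew <- rtnorm(om, b)
      st2 <- state
      st2[[surf]]$seeds <- rbind(tess$seeds, snew)
      st2[[surf]]$eff <- c(tess$eff, enew)
      ss2 <- if (surf == "m")
        compute_ss(st2, pre, cfg, vq = state$ss$vq)
      else
        compute_ss(st2, pre, cfg, vlm = state$ss$vlm, R = state$ss$R)
      ll2 <- ll_from_ss(ss2, state$sigma2, pre, cfg)
      ## proposal = prior for the new tile; zero-truncated Poisson count ratio
      lacc <- t * (ll2 - state$ll) + log(cfg$lambda_tiles) - log(K + 1)
      if (log(runif(1L)) < lacc) {
        state <- st2; state$ss <- ss2; state$ll <- ll2
        accepted <- TRUE
      }
    }
  } else if (mv == "death") {
    tess <- state[[surf]]
    K <- length(tess$eff)
    if (!frozen_m && K > 1L) {
      j <- sample.int(K, 1L)
      st2 <- state
      st2[[surf]]$seeds <- tess$seeds[-j, , drop = FALSE]
      st2[[surf]]$eff <- tess$eff[-j]
      ss2 <- if (surf == "m")
        compute_ss(st2, pre, cfg, vq = state$ss$vq)
      else
        compute_ss(st2, pre, cfg, vlm = state$ss$vlm, R = state$ss$R)
      ll2 <- ll_from_ss(ss2, state$sigma2, pre, cfg)
      lacc <- t * (ll2 - state$ll) + log(K) - log(cfg$lambda_tiles)
      if (log(runif(1L)) < lacc) {
        state <- st2; state$ss <- ss2; state$ll <- ll2
        accepted <- TRUE
      }
    }
  } else if (mv == "sigma2") {
    ## conjugate: tempered likelihood x IG(1, 1) prior
    shape <- 1 + t * pre$p * pre$d / 2 * as.numeric(cfg$likelihood)
    rate <- 1 + if (cfg$likelihood && state$ss$ok)
      t * state$ss$trMS / 2 else 0
    state$sigma2 <- 1 / stats::rgamma(1L, shape = shape, rate = rate)
    state$ll <- ll_from_ss(state$ss, state$sigma2, pre, cfg)
    accepted <- TRUE
  } else if (mv == "omega2") {
    om2 <- if (surf == "m") state$omega2_m else state$omega2_q
    om2new <- om2 + rnorm(1L, 0, cfg$omega_step_sd)
    if (om2new > 0 && om2new <= 1) {
      eff <- state[[surf]]$eff
      ltrunc <- function(o2) {
        o <- sqrt(o2)
        sum(dnorm(eff, 0, o, log = TRUE)) -
          length(eff) * log(pnorm(b / o) - pnorm(-b / o))
      }
      if (log(runif(1L)) < ltrunc(om2new) - ltrunc(om2)) {
        if (surf == "m") state$omega2_m <- om2new
        else state$omega2_q <- om2new
        accepted <- TRUE
      }
    }
  } else if (mv == "mu_q") {
    munew <- state$mu_q + rnorm(1L, 0, cfg$mu_step_sd)
    if (abs(munew) <= 6) {
      st2 <- state
      st2$mu_q <- munew
      ss2 <- compute_ss(st2, pre, cfg, vlm = state$ss$vlm, R = state$ss$R)
      ll2 <- ll_from_ss(ss2, state$sigma2, pre, cfg)
      if (log(runif(1L)) < t * (ll2 - state$ll)) {
        state <- st2; state$ss <- ss2; state$ll <- ll2
        accepted <- TRUE
      }
    }
  }
  attr(state, "move") <- mv
  attr(state, "accepted") <- accepted
  state
}

## run n_steps moves; optionally record thinned draws.
## Draws record vertex rates, so prior-only chains compute them lazily here.
run_steps <- function(state, pre, cfg, temperature, n_steps,
                      record_from = Inf, thin = 1L) {
  nv <- nrow(pre$graph$vertices)
  nrec <- if (is.finite(record_from))
    max(0L, (n_steps - record_from) %/% thin) else 0L
  rec <- list(
    m_vertex = matrix(NA_real_, nrec, nv),
    q_vertex = matrix(NA_real_, nrec, nv),
    sigma2 = numeric(nrec), mu_q = numeric(nrec),
    omega2_m = numeric(nrec), omega2_q = numeric(nrec),
    K_m = integer(nrec), K_q = integer(nrec),
    loglik = numeric(nrec), logpost = numeric(nrec),
    iter = integer(nrec))
  props <- accs <- setNames(numeric(7L), names(cfg$move_weights))
  if (is.null(state$ss)) {
    state$ss <- compute_ss(state, pre, cfg)
    state$ll <- ll_from_ss(state$ss, state$sigma2, pre, cfg)
  }
  g <- pre$graph
  k <- 0L
  for (i in seq_len(n_steps)) {
    state <- mcmc_step(state, pre, cfg, temperature)
    mv <- attr(state, "move")
    props[mv] <- props[mv] + 1
    accs[mv] <- accs[mv] + attr(state, "accepted")
    if (i > record_from && (i - record_from) %% thin == 0L) {
      k <- k + 1L
      vlm <- state$ss$vlm
      if (is.null(vlm))
        vlm <- state$m$eff[nearest_seed(g$vertices, state$m$seeds, g$mode)]
      vlq <- state$mu_q +
        state$q$eff[nearest_seed(g$vertices, state$q$seeds, g$mode)]
      rec$m_vertex[k, ] <- vlm
      rec$q_vertex[k, ] <- vlq
      rec$sigma2[k] <- state$sigma2
      rec$mu_q[k] <- state$mu_q
      rec$omega2_m[k] <- state$omega2_m
      rec$omega2_q[k] <- state$omega2_q
      rec$K_m[k] <- length(state$m$eff)
      rec$K_q[k] <- length(state$q$eff)
      rec$loglik[k] <- state$ll
      rec$logpost[k] <- temperature * state$ll +
        log_prior_state(state, pre, cfg)
      rec$iter[k] <- i
    }
  }
  list(state = state, draws = rec, props = props, accs = accs)
}

## ---- main fitting function -------------------------------------------------

#' Fit effective migration and diversity surfaces
#'
#' The main entry point: fits the tessellated-surface model to an observed
#' individual-level genetic dissimilarity matrix by reversible-jump MCMC.
#' Following standard practice, several short pilot chains are run first
#' and the end state with the highest posterior log-density seeds the
#' final chain; the final chain discards `burn_in` iterations and keeps
#' every `thin`-th state.
#'
#' @param D Observed dissimilarity matrix from
#'   [observed_dissimilarity()].
#' @param graph A [deme_grid()] object.
#' @param assignment A [assign_demes()] object (or integer vertex vector).
#' @param n_loci Number of loci behind `D`.
#' @param control A [migsurf_control()] object.
#' @return An object of class `migsurf` with thinned posterior draws
#'   (`draws`), per-move acceptance rates (`acceptance`), the raster cell
#'   map, and the inputs needed by the posterior summaries.  Methods:
#'   `print`, `summary`, `coef`, `plot`, `predict`, `simulate`, `logLik`.
#' @examples
#' \donttest{
#' g <- deme_grid(c(0, 500, 0, 300), spacing_km = 100, mode = "planar")
#' fld <- rate_field(g)
#' sim <- simulate_wf_genotypes(fld, p_snps = 300, n_per_deme = 2,
#'                              n_generations = 50, seed = 7)
#' D <- observed_dissimilarity(sim)
#' fit <- migsurf(D, g, attr(sim, "assignment"), n_loci = 300,
#'                control = migsurf_control(n_iter = 2000, burn_in = 500,
#'                                          thin = 10, n_pilot = 1,
#'                                          pilot_iter = 200, seed = 1))
#' fit
#' }
#' @export
migsurf <- function(D, graph, assignment, n_loci,
                    control = migsurf_control()) {
  cfg <- control
  pre <- migsurf_data(D, graph, assignment, n_loci)
  set.seed(cfg$seed)
  init <- migsurf_init_state(pre, cfg)
  state <- init
  if (cfg$n_pilot > 0L && cfg$pilot_iter > 0L) {
    best <- -Inf
    for (i in seq_len(cfg$n_pilot)) {
      set.seed(cfg$seed + i)
      out <- run_steps(init, pre, cfg, temperature = 1,
                       n_steps = cfg$pilot_iter)
      lp <- out$state$ll + log_prior_state(out$state, pre, cfg)
      if (!is.finite(best) || lp > best) {
        best <- lp
        state <- out$state
      }
    }
    if (!is.finite(best)) stop("all pilot chains have non-finite posterior")
  }
  set.seed(cfg$seed + 1000L)
  out <- run_steps(state, pre, cfg, temperature = 1,
                   n_steps = cfg$n_iter, record_from = cfg$burn_in,
                   thin = cfg$thin)
  acc <- ifelse(out$props > 0, out$accs / out$props, NA_real_)
  cell <- raster_cell_map(graph, cfg$raster_dim)
  structure(list(draws = out$draws, acceptance = acc,
                 proposals = out$props,
                 graph = graph, assignment = pre$assignment,
                 obs_demes = pre$obs_demes, n = pre$n, p = pre$p,
                 control = cfg, cell_map = cell$map,
                 raster_x = cell$x, raster_y = cell$y,
                 final_state = strip_ss(out$state)),
            class = "migsurf")
}

strip_ss <- function(state) {
  state$ss <- NULL
  state
}

#' Serialize a sampler state as JSON
#'
#' Writes the tessellations (seeds, effects), `mu_q`, `omega2` and
#' `sigma2` of a `migsurf_state` (e.g. a fit's `final_state`).
#'
#' @param state A `migsurf_state`.
#' @param path Output path.
#' @return `read_model_state` returns a `migsurf_state`;
#'   `write_model_state` returns `path` invisibly.
#' @export
write_model_state <- function(state, path) {
  obj <- list(
    m = list(seeds = unname(state$m$seeds), effects = state$m$eff),
    q = list(seeds = unname(state$q$seeds), effects = state$q$eff),
    mu_q = state$mu_q, omega2_m = state$omega2_m,
    omega2_q = state$omega2_q, sigma2 = state$sigma2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_state
#' @export
read_model_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- list(
    m = list(seeds = matrix(as.numeric(obj$m$seeds), ncol = 2L),
             eff = as.numeric(obj$m$effects)),
    q = list(seeds = matrix(as.numeric(obj$q$seeds), ncol = 2L),
             eff = as.numeric(obj$q$effects)),
    mu_q = obj$mu_q, omega2_m = obj$omega2_m, omega2_q = obj$omega2_q,
    sigma2 = obj$sigma2)
  class(st) <- "migsurf_state"
  st
}

## nearest-vertex map for a raster_dim x raster_dim lattice over the
## bounding box of the graph (cells are the graph's Voronoi cells sampled
## on a regular lattice)
raster_cell_map <- function(graph, raster_dim) {
  v <- graph$vertices
  bx <- range(v[, 1L]); by <- range(v[, 2L])
  pad <- graph$spacing_km / 2
  x <- seq(bx[1L] - pad, bx[2L] + pad, length.out = raster_dim)
  y <- seq(by[1L] - pad, by[2L] + pad, length.out = raster_dim)
  pts <- cbind(rep(x, times = raster_dim), rep(y, each = raster_dim))
  map <- integer(nrow(pts))
  block <- 2000L
  for (s in seq(1L, nrow(pts), by = block)) {
    e <- min(s + block - 1L, nrow(pts))
    d <- if (graph$mode == "spherical")
      great_circle_matrix(pts[s:e, , drop = FALSE], v)
    else plane_dist(pts[s:e, , drop = FALSE], v)
    map[s:e] <- max.col(-d, ties.method = "first")
  }
  list(map = map, x = x, y = y)
}
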