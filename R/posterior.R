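#' @export
print.migsurf <- function(x, ...) {
  nd <- length(x$draws$sigma2)
  cat(sprintf(
    "migsurf fit: %d individuals over %d observed demes, %d loci\n",
    x$n, length(x$obs_demes), x$p))
  cat(sprintf("  %d posterior draws (n_iter %d, burn-in %d, thin %d)\n",
              nd, x$control$n_iter, x$control$burn_in, x$control$thin))
  if (nd > 0)
    cat(sprintf(
      "  posterior means: K_m %.1f, K_q %.1f, sigma2 %.4g, loglik %.1f\n",
      mean(x$draws$K_m), mean(x$draws$K_q), mean(x$draws$sigma2),
      mean(x$draws$loglik)))
  invisible(x)
}

#' @export
summary.migsurf <- function(object, ...) {
  d <- object$draws
  qs <- function(v) c(mean = mean(v), quantile(v, c(0.025, 0.5, 0.975)))
  tab <- rbind(sigma2 = qs(d$sigma2), mu_q = qs(d$mu_q),
               K_m = qs(d$K_m), K_q = qs(d$K_q),
               omega2_m = qs(d$omega2_m), omega2_q = qs(d$omega2_q),
               loglik = qs(d$loglik))
  out <- list(table = tab, acceptance = object$acceptance,
              n_draws = length(d$sigma2))
  class(out) <- "summary.migsurf"
  out
}

#' @export
print.summary.migsurf <- function(x, ...) {
  cat("Posterior summaries (", x$n_draws, " draws):\n", sep = "")
  print(round(x$table, 4))
  cat("Acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' @export
coef.migsurf <- function(object, ...) {
  list(log10_m = colMeans(object$draws$m_vertex),
       log10_q = colMeans(object$draws$q_vertex),
       sigma2 = mean(object$draws$sigma2))
}

#' @export
logLik.migsurf <- function(object, ...) {
  ll <- mean(object$draws$loglik)
  attr(ll, "df") <- NA
  class(ll) <- "logLik"
  ll
}

#' Write the thinned scalar trace of a fit as TSV
#'
#' Columns: iteration, log-likelihood, tile counts, sigma2, mu_q.
#'
#' @param fit A [migsurf()] fit.
#' @param path Output path.
#' @export
write_trace_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "migsurf"))
  d <- fit$draws
  write.table(
    data.frame(iter = d$iter, loglik = d$loglik, K_m = d$K_m, K_q = d$K_q,
               sigma2 = d$sigma2, mu_q = d$mu_q),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Posterior mean and sd surface rasters
#'
#' Cellwise posterior mean and standard deviation (sample sd, denominator
#' `n - 1`) of a log10 rate surface over the raster lattice.
#'
#' @param fit A [migsurf()] fit with at least 2 draws.
#' @param surface `"m"` (migration, default) or `"q"` (diversity).
#' @return List of class `migsurf_surface`: raster coordinates `x`, `y`,
#'   matrices `mean` and `sd`, and the underlying per-vertex summaries.
#' @export
posterior_mean_surface <- function(fit, surface = c("m", "q")) {
  stopifnot(inherits(fit, "migsurf"))
  surface <- match.arg(surface)
  V <- if (surface == "m") fit$draws$m_vertex else fit$draws$q_vertex
  if (nrow(V) < 2L) stop("need at least 2 posterior draws")
  vmean <- colMeans(V)
  vsd <- apply(V, 2L, sd)
  nd <- length(fit$raster_x)
  structure(list(
    x = fit$raster_x, y = fit$raster_y,
    mean = matrix(vmean[fit$cell_map], nd, nd),
    sd = matrix(vsd[fit$cell_map], nd, nd),
    vertex_mean = vmean, vertex_sd = vsd, surface = surface),
    class = "migsurf_surface")
}

#' @export
print.migsurf_surface <- function(x, ...) {
  cat(sprintf(
    "migsurf_surface (%s): %dx%d raster, mean in [%.3f, %.3f]\n",
    x$surface, length(x$x), length(x$y), min(x$mean), max(x$mean)))
  invisible(x)
}

#' Write a surface raster with a JSON header
#'
#' The posterior mean and sd rasters go to gzip-compressed TSV matrices
#' (`<prefix>.mean.tsv.gz`, `<prefix>.sd.tsv.gz`) and the cell-grid
#' metadata to `<prefix>.json`.
#'
#' @param surface A [posterior_mean_surface()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_surface_raster <- function(surface, prefix) {
  stopifnot(inherits(surface, "migsurf_surface"))
  for (part in c("mean", "sd")) {
    con <- gzfile(sprintf("%s.%s.tsv.gz", prefix, part), "w")
    write.table(surface[[part]], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(surface = surface$surface, nx = length(surface$x),
         ny = length(surface$y), x_range = range(surface$x),
         y_range = range(surface$y)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Consensus troughs and corridors
#'
#' For each raster cell, `f_low` is the fraction of posterior draws in
#' which the cell's log10 migration rate lies below that draw's
#' across-cell mean.  Cells with `f_low >= threshold` are troughs
#' (consistently depressed migration); cells with `1 - f_low >= threshold`
#' are corridors.  Connected components (4-neighbour) of trough and
#' corridor cells are reported as features.
#'
#' @param fit A [migsurf()] fit with at least 20 draws.
#' @param threshold Consensus fraction in (0.5, 1]; the conventional
#'   choice is 0.95.
#' @return List of class `migsurf_troughs`: `labels` (raster matrix with
#'   values `"trough"`, `"corridor"`, `"neither"`), `f_low` raster,
#'   `vertex_f_low`, and `features` (lists of cell-index vectors).
#' @export
detect_troughs <- function(fit, threshold = 0.95) {
  stopifnot(inherits(fit, "migsurf"))
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  V <- fit$draws$m_vertex
  if (nrow(V) < 20L) stop("need at least 20 posterior draws")
  w <- tabulate(fit$cell_map, nbins = ncol(V))
  cellmean <- as.vector(V %*% w) / sum(w)   # per-draw across-cell mean
  below <- sweep(V, 1L, cellmean, `<`)
  f_low_vertex <- colMeans(below)
  f_low_cell <- f_low_vertex[fit$cell_map]
  lab <- ifelse(f_low_cell >= threshold, "trough",
                ifelse(1 - f_low_cell >= threshold, "corridor", "neither"))
  nd <- length(fit$raster_x)
  labm <- matrix(lab, nd, nd)
  structure(list(
    labels = labm, f_low = matrix(f_low_cell, nd, nd),
    vertex_f_low = f_low_vertex, threshold = threshold,
    n_draws = nrow(V),
    features = list(trough = grid_components(labm == "trough"),
                    corridor = grid_components(labm == "corridor"))),
    class = "migsurf_troughs")
}

#' @export
print.migsurf_troughs <- function(x, ...) {
  cat(sprintf(
    "migsurf_troughs (threshold %.2f, %d draws): %d trough cells in %d features, %d corridor cells in %d features\n",
    x$threshold, x$n_draws, sum(x$labels == "trough"),
    length(x$features$trough), sum(x$labels == "corridor"),
    length(x$features$corridor)))
  invisible(x)
}

## connected components (4-neighbour) of TRUE cells in a logical matrix;
## returns a list of cell-index vectors, largest first
grid_components <- function(mask) {
  nr <- nrow(mask); ncl <- ncol(mask)
  lab <- matrix(0L, nr, ncl)
  comp <- list()
  nextlab <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    cells <- integer(0)
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      cells <- c(cells, cur)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (nb in c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
                   if (cl > 1L) cur - nr, if (cl < ncl) cur + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nextlab
          queue <- c(queue, nb)
        }
      }
    }
    comp[[nextlab]] <- cells
  }
  if (length(comp))
    comp[order(vapply(comp, length, integer(1)), decreasing = TRUE)]
  else comp
}

#' Plot a fitted migration or diversity surface
#'
#' Posterior mean surface as a raster image with deme locations and,
#' optionally, consensus trough/corridor cells outlined.
#'
#' @param x A [migsurf()] fit.
#' @param surface `"m"` or `"q"`.
#' @param troughs Overlay consensus trough (dark) and corridor (light)
#'   cells (requires >= 20 draws).
#' @param ... Passed to [graphics::image()].
#' @export
plot.migsurf <- function(x, surface = c("m", "q"), troughs = FALSE, ...) {
  surface <- match.arg(surface)
  s <- posterior_mean_surface(x, surface)
  pal <- grDevices::hcl.colors(51, "RdYlBu", rev = FALSE)
  rng <- max(abs(s$mean - mean(s$mean)), 1e-12)
  graphics::image(s$x, s$y, s$mean, col = pal,
                  zlim = mean(s$mean) + c(-rng, rng),
                  xlab = colnames(x$graph$vertices)[1L],
                  ylab = colnames(x$graph$vertices)[2L],
                  main = sprintf("posterior mean log10 %s", surface), ...)
  graphics::points(x$graph$vertices, pch = 16, cex = 0.4)
  if (troughs) {
    tr <- detect_troughs(x)
    pts <- which(tr$labels == "trough")
    if (length(pts)) {
      r <- (pts - 1L) %% length(s$x) + 1L
      cl <- (pts - 1L) %/% length(s$x) + 1L
      graphics::points(s$x[r], s$y[cl], pch = ".", col = "black")
    }
  }
  invisible(x)
}

#' @export
plot.migsurf_surface <- function(x, ...) {
  graphics::image(x$x, x$y, x$mean,
                  col = grDevices::hcl.colors(51, "RdYlBu"),
                  main = sprintf("posterior mean log10 %s", x$surface), ...)
  invisible(x)
}

#' Expected distances from a fitted model
#'
#' `predict` returns the posterior expected population-level distance
#' matrix (see [expected_distance_from_posterior()]).
#'
#' @param object A [migsurf()] fit.
#' @param pops Optional population labels per individual.
#' @param ... Unused.
#' @export
predict.migsurf <- function(object, pops = NULL, ...) {
  expected_distance_from_posterior(object, pops)
}

#' Simulate dissimilarity matrices from the fitted model
#'
#' Draws model-exact individual-level dissimilarity matrices at the
#' posterior mean surface (see [simulate_model_exact()]).
#'
#' @param object A [migsurf()] fit.
#' @param nsim Number of matrices.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` dissimilarity matrices.
#' @export
simulate.migsurf <- function(object, nsim = 1, seed = 1, ...) {
  cf <- coef(object)
  w <- rates_on_edges(cf$log10_m, object$graph)
  R <- resistance_from_laplacian(nrow(object$graph$vertices),
                                 object$graph$edges, w)
  delta <- expected_dissimilarity(R, 10^cf$log10_q, object$obs_demes)
  idx <- match(object$assignment, object$obs_demes)
  Di <- expand_to_individuals(delta, idx)
  lapply(seq_len(nsim), function(i)
    simulate_model_exact(Di, cf$sigma2, object$p, seed = seed + i - 1L))
}
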