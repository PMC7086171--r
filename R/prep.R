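#' Exact Hardy-Weinberg test for heterozygote excess
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows the Levene-Haldane distribution; the one-sided P-value for
#' heterozygote excess sums that distribution over heterozygote counts at
#' least as large as observed (`midp = TRUE` counts the observed value at
#' half weight).  Heterozygote excess is the artifactual failure mode of
#' merged panels with strand errors, whereas a heterozygote deficit is
#' expected under population structure (Wahlund effect) and should not be
#' filtered.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Observed homozygote counts for the two alleles.
#' @param midp Use the mid-P variant (default `FALSE`).
#' @return One-sided P-value for heterozygote excess.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2, midp = FALSE) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  nA <- 2L * n_hom1 + n_het            # allele counts
  nB <- 2L * n_hom2 + n_het
  rare <- min(nA, nB)
  ## possible heterozygote counts share the parity of the rare allele count
  hs <- seq(rare %% 2L, rare, by = 2L)
  logp <- n_het_logprob(hs, rare, n)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  sel <- hs >= n_het
  p <- sum(pr[sel])
  if (midp) p <- p - pr[hs == n_het] / 2
  min(1, max(0, p))
}

## log Levene-Haldane probability (up to a constant) of h heterozygotes
## given rare-allele count nr among n diploids
n_het_logprob <- function(h, nr, n) {
  nAA <- (nr - h) / 2
  nBB <- n - nAA - h
  h * log(2) + lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) -
    lgamma(nBB + 1)
}

new_filter_report <- function(thresholds) {
  structure(list(removed = list(), thresholds = thresholds,
                 n_in = NULL, n_out = NULL), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  if (!is.null(x$n_in))
    cat(sprintf("  input:  %d individuals x %d SNPs\n", x$n_in[1], x$n_in[2]))
  for (nm in names(x$removed))
    cat(sprintf("  %-20s %d removed\n", nm, x$removed[[nm]]))
  if (!is.null(x$n_out))
    cat(sprintf("  output: %d individuals x %d SNPs\n",
                x$n_out[1], x$n_out[2]))
  if (length(x$thresholds))
    cat("  thresholds:",
        paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a filter report as JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(
    list(removed = report$removed, thresholds = report$thresholds,
         n_in = report$n_in, n_out = report$n_out),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Variant- and missingness-level panel filters
#'
#' Applies, in this fixed order: removal of non-autosomal and non-SNP
#' records; removal of strand-ambiguous A/T and G/C variants; removal of
#' duplicated SNP ids (keeping the first copy) and of SNPs whose allele
#' pair conflicts between copies (all copies dropped); a one-sided exact
#' Hardy-Weinberg test in the heterozygote-excess direction at `hwe_alpha`;
#' removal of SNPs with missingness above `snp_miss`; and removal of
#' individuals with missingness above `ind_miss`.
#'
#' @param g A [geno_matrix()] object with SNP metadata.
#' @param hwe_alpha HWE exact-test significance threshold (default `1e-5`).
#' @param snp_miss Maximum per-SNP missingness fraction (default 0.01).
#' @param ind_miss Maximum per-individual missingness fraction
#'   (default 0.05).
#' @param hwe_midp Use the mid-P HWE variant (default `FALSE`).
#' @return List with elements `geno` (filtered `geno_matrix`) and `report`
#'   (a `filter_report` whose per-rule counts reconcile exactly with the
#'   change in matrix shape).
#' @export
filter_variants <- function(g, hwe_alpha = 1e-5, snp_miss = 0.01,
                            ind_miss = 0.05, hwe_midp = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  s <- g$snps
  if (any(is.na(s$chr)) || any(is.na(s$pos)) ||
      any(is.na(s$a1)) || any(is.na(s$a2)))
    stop("SNP metadata (chr, pos, alleles) must be complete")
  rep_ <- new_filter_report(list(hwe_alpha = hwe_alpha, snp_miss = snp_miss,
                                 ind_miss = ind_miss))
  rep_$n_in <- dim(g)
  keep <- rep(TRUE, ncol(g$geno))

  chrnum <- suppressWarnings(as.integer(as.character(s$chr)))
  autosomal <- !is.na(chrnum) & chrnum >= 1L & chrnum <= 22L
  is_snp <- s$a1 %in% c("A", "C", "G", "T") & s$a2 %in% c("A", "C", "G", "T")
  drop <- keep & !(autosomal & is_snp)
  rep_$removed$non_autosomal_or_non_snp <- sum(drop)
  keep[drop] <- FALSE

  amb <- paste0(s$a1, s$a2) %in% c("AT", "TA", "GC", "CG")
  drop <- keep & amb
  rep_$removed$ambiguous_strand <- sum(drop)
  keep[drop] <- FALSE

  ## duplicate ids: identical allele pairs keep the first copy; conflicting
  ## allele pairs (different alternative alleles between sources) drop all
  n_dup <- 0L; n_mis <- 0L
  idx <- which(keep)
  if (anyDuplicated(s$id[idx])) {
    pair <- ifelse(s$a1 < s$a2, paste0(s$a1, s$a2), paste0(s$a2, s$a1))
    for (grp in split(idx, s$id[idx])) {
      if (length(grp) < 2L) next
      if (length(unique(pair[grp])) > 1L) {
        keep[grp] <- FALSE
        n_mis <- n_mis + length(grp)
      } else {
        keep[grp[-1L]] <- FALSE
        n_dup <- n_dup + length(grp) - 1L
      }
    }
  }
  rep_$removed$duplicate_id <- n_dup
  rep_$removed$allele_mismatch <- n_mis

  gg <- g$geno
  hwe_p <- vapply(which(keep), function(j) {
    x <- gg[, j]
    hwe_exact_test(sum(x == 1L, na.rm = TRUE), sum(x == 2L, na.rm = TRUE),
                   sum(x == 0L, na.rm = TRUE), midp = hwe_midp)
  }, numeric(1))
  drop <- which(keep)[hwe_p < hwe_alpha]
  rep_$removed$hwe_fail <- length(drop)
  keep[drop] <- FALSE

  smiss <- colMeans(is.na(gg))
  drop <- keep & smiss > snp_miss
  rep_$removed$snp_missingness <- sum(drop)
  keep[drop] <- FALSE

  if (!any(keep)) stop("no SNPs survive filtering: empty panel")
  g <- subset_geno(g, j = which(keep))

  imiss <- rowMeans(is.na(g$geno))
  ikeep <- imiss <= ind_miss
  rep_$removed$ind_missingness <- sum(!ikeep)
  if (!any(ikeep)) stop("no individuals survive filtering: empty panel")
  g <- subset_geno(g, i = which(ikeep))
  rep_$n_out <- dim(g)
  list(geno = g, report = rep_)
}

#' Prune closely related individuals
#'
#' Builds the standardized genotype cross-product relatedness matrix
#' (per-SNP mean-centred and variance-scaled values, averaged over loci
#' non-missing in both individuals) and greedily removes, from each pair
#' exceeding `cutoff`, the member with more missing data (ties broken by
#' the larger sample index), until no pair exceeds `cutoff`.  A cutoff of
#' 0.6 removes duplicates and close relatives.
#'
#' @param g A [geno_matrix()] object with at least 2 individuals and
#'   50 SNPs.
#' @param cutoff Relatedness cutoff in (0, 2] (default 0.6).
#' @return List with `keep` (character vector of retained sample ids),
#'   `relatedness` (the full matrix) and `report`.
#' @export
relatedness_prune <- function(g, cutoff = 0.6) {
  stopifnot(inherits(g, "geno_matrix"))
  if (cutoff <= 0 || cutoff > 2) stop("cutoff must be in (0, 2]")
  if (nrow(g$geno) < 2L) stop("need at least 2 individuals")
  if (ncol(g$geno) < 50L) stop("need at least 50 SNPs")
  gg <- g$geno
  mu <- colMeans(gg, na.rm = TRUE)
  sdv <- apply(gg, 2L, sd, na.rm = TRUE)
  poly <- which(is.finite(sdv) & sdv > 0)
  X <- sweep(sweep(gg[, poly, drop = FALSE], 2L, mu[poly]), 2L, sdv[poly], `/`)
  Mmask <- !is.na(X)
  X0 <- X; X0[!Mmask] <- 0
  num <- tcrossprod(X0)
  den <- tcrossprod(Mmask * 1)
  rel <- num / pmax(den, 1)
  ids <- g$samples$sample_id
  dimnames(rel) <- list(ids, ids)
  nmiss <- rowSums(is.na(gg))
  active <- rep(TRUE, nrow(rel))
  removed <- character(0)
  repeat {
    r <- rel
    r[!active, ] <- 0; r[, !active] <- 0
    r[lower.tri(r, diag = TRUE)] <- 0
    mx <- max(r)
    if (mx <= cutoff) break
    w <- which(r == mx, arr.ind = TRUE)[1L, ]
    i <- w[1L]; j <- w[2L]
    drop <- if (nmiss[i] > nmiss[j]) i
            else if (nmiss[j] > nmiss[i]) j
            else max(i, j)
    active[drop] <- FALSE
    removed <- c(removed, ids[drop])
  }
  rep_ <- new_filter_report(list(rel_cutoff = cutoff))
  rep_$n_in <- dim(g)
  rep_$removed$related_removed <- length(removed)
  rep_$n_out <- c(sum(active), ncol(gg))
  list(keep = ids[active], removed = removed, relatedness = rel,
       report = rep_)
}

#' Remove windows around PC-loading outlier SNPs
#'
#' Long-range LD and structural variants can concentrate extreme loadings
#' on a principal component.  This filter runs a PCA on the current panel,
#' standardises each PC's loadings by their standard deviation
#' (`outlier_score = loading / sd(loadings)`), and removes every SNP
#' within `window_bp / 2` on either side of any SNP whose |outlier_score|
#' exceeds `z_thresh` on any of the first `n_pcs` components.
#'
#' @param g A [geno_matrix()] with positions sorted within chromosome.
#' @param n_pcs Number of leading PCs to scan (default 10).
#' @param z_thresh Outlier score threshold (default 5).
#' @param window_bp Total window width in bp centred on each outlier SNP
#'   (default 200000, i.e. +/-100 kb).
#' @return List with `geno` (pruned panel) and `report`.
#' @export
loading_outlier_prune <- function(g, n_pcs = 10, z_thresh = 5,
                                  window_bp = 200000) {
  stopifnot(inherits(g, "geno_matrix"))
  for (ch in unique(g$snps$chr)) {
    ps <- g$snps$pos[g$snps$chr == ch]
    if (is.unsorted(ps)) stop("positions must be sorted within chromosome")
  }
  pca <- pca_decompose(g, k = n_pcs)
  L <- pca$loadings
  score <- sweep(L, 2L, apply(L, 2L, sd), `/`)
  outlier <- which(apply(abs(score) > z_thresh, 1L, any))
  drop <- rep(FALSE, ncol(g$geno))
  half <- window_bp / 2
  for (j in outlier) {
    same <- g$snps$chr == g$snps$chr[j] &
      abs(g$snps$pos - g$snps$pos[j]) <= half
    drop[same] <- TRUE
  }
  rep_ <- new_filter_report(list(n_pcs = n_pcs, z_thresh = z_thresh,
                                 window_bp = window_bp))
  rep_$n_in <- dim(g)
  rep_$removed$loading_outlier_snps <- sum(drop)
  g2 <- if (any(drop)) subset_geno(g, j = which(!drop)) else g
  rep_$n_out <- dim(g2)
  list(geno = g2, report = rep_)
}

#' Downsample over-represented sampling locales
#'
#' Samples sharing identical rounded coordinates form a locale; locales
#' larger than `max_per_locale` are subsampled uniformly without
#' replacement.  Used to avoid distortions from uneven sampling.
#'
#' @param samples Data frame with `sample_id`, `lon`, `lat`.
#' @param max_per_locale Maximum individuals kept per locale (default 50).
#' @param seed Integer seed (same seed, same kept set).
#' @param digits Coordinate rounding used to define locales (default 2).
#' @return Character vector of kept sample ids.
#' @export
downsample_locales <- function(samples, max_per_locale = 50, seed = 1,
                               digits = 2) {
  if (max_per_locale < 1) stop("max_per_locale must be at least 1")
  key <- paste(round(samples$lon, digits), round(samples$lat, digits))
  set.seed(as.integer(seed))
  keep <- unlist(lapply(split(seq_len(nrow(samples)), key), function(ix) {
    if (length(ix) <= max_per_locale) ix
    else sort(sample(ix, max_per_locale))
  }), use.names = FALSE)
  samples$sample_id[sort(keep)]
}
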