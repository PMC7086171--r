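#' Construct a genotype matrix object
#'
#' The container used throughout the package: an individuals x SNPs matrix
#' of allele counts (0/1/2, `NA` for missing) together with SNP metadata
#' and per-sample metadata (coordinates, population and optional language
#' labels).
#'
#' @param geno Integer matrix, individuals in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}` counting copies of allele `a1`.
#' @param snps Data frame with columns `chr`, `id`, `pos`, `a1`, `a2`
#'   (one row per SNP); an optional `source` column tags the study of
#'   origin for merged panels.
#' @param samples Data frame with columns `sample_id`, `lon`, `lat` and
#'   optionally `pop`, `language`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, snps, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snps <- as.data.frame(snps)
  samples <- as.data.frame(samples)
  need <- c("chr", "id", "pos", "a1", "a2")
  if (!all(need %in% names(snps)))
    stop("'snps' must have columns ", paste(need, collapse = ", "))
  if (!"sample_id" %in% names(samples))
    stop("'samples' must have a sample_id column")
  if (nrow(snps) != ncol(geno)) stop("one snps row per genotype column required")
  if (nrow(samples) != nrow(geno))
    stop("one samples row per genotype row required")
  if (!"pop" %in% names(samples)) samples$pop <- NA_character_
  if (!"language" %in% names(samples)) samples$language <- NA_character_
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be allele counts in {0, 1, 2} or NA")
  rownames(geno) <- samples$sample_id
  colnames(geno) <- snps$id
  structure(list(geno = geno, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

## subset a geno_matrix by individuals (i) and/or SNPs (j)
subset_geno <- function(g, i = NULL, j = NULL) {
  if (!is.null(i)) {
    g$geno <- g$geno[i, , drop = FALSE]
    g$samples <- g$samples[i, , drop = FALSE]
    rownames(g$samples) <- NULL
  }
  if (!is.null(j)) {
    g$geno <- g$geno[, j, drop = FALSE]
    g$snps <- g$snps[j, , drop = FALSE]
    rownames(g$snps) <- NULL
  }
  g
}

#' Read and write genotype trio files (.bed/.bim/.fam dialect)
#'
#' SNP-major binary genotype files in the standard trio layout: a `.bed`
#' file with the 3-byte magic header `0x6c 0x1b 0x01` and two-bit genotype
#' codes (00 = homozygous a1, 01 = missing, 10 = heterozygous,
#' 11 = homozygous a2), a `.bim` SNP table (chr, id, cM, pos, a1, a2) and a
#' `.fam` sample table.  Genotypes are stored/returned as counts of the
#' `a1` allele.
#'
#' @param g A [geno_matrix()] object.
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return `read_plink` returns a `geno_matrix` (coordinates set to `NA`
#'   unless supplied separately); `write_plink` returns `prefix` invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$geno); p <- ncol(g$geno)
  ## two-bit codes per genotype: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(1L, n, p)
  gg <- g$geno
  code[!is.na(gg) & gg == 2L] <- 0L
  code[!is.na(gg) & gg == 1L] <- 2L
  code[!is.na(gg) & gg == 0L] <- 3L
  npad <- (4L - n %% 4L) %% 4L
  if (npad > 0L) code <- rbind(code, matrix(0L, npad, p))
  dim(code) <- c(4L, length(code) / 4L)
  bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  write.table(data.frame(g$snps$chr, g$snps$id, 0,
                         format(g$snps$pos, scientific = FALSE, trim = TRUE),
                         g$snps$a1, g$snps$a2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- g$samples
  fam <- data.frame(if (!is.null(s$pop) && !all(is.na(s$pop))) s$pop else 0,
                    s$sample_id, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "character", "character"))
  bim$pos <- as.integer(bim$pos)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = "character")
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3L + ceiling(n / 4) * p)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a bed file: bad magic number")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- NULL
  perSnp <- ceiling(n / 4) * 4L
  codes <- matrix(codes, nrow = perSnp)[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_integer_, n, p)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  samples <- data.frame(sample_id = fam[[2L]], lon = NA_real_, lat = NA_real_,
                        pop = fam[[1L]], language = NA_character_)
  geno_matrix(geno, bim[, c("chr", "id", "pos", "a1", "a2")], samples)
}

#' Write a sample coordinate table as TSV
#'
#' @param g A [geno_matrix()] object.
#' @param path Output path.
#' @export
write_coords_tsv <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  write.table(g$samples[, c("sample_id", "lon", "lat", "pop", "language")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
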