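#' Genomic-matrix configuration
#'
#' Quality-control thresholds and blending weights for building the
#' genomic relationship matrix.  Defaults follow routine beef-cattle
#' practice: minor allele frequency >= 0.05, SNP and animal call rates
#' >= 0.90, Hardy-Weinberg screening by the maximum absolute difference
#' between observed and expected heterozygosity (<= 0.15), autosomes
#' 1-29 only, and G blended as 0.95 G + 0.05 A22.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param snp_callrate_min Minimum per-SNP call rate.
#' @param animal_callrate_min Minimum per-animal call rate.
#' @param hwe_max_dev Maximum |observed - expected| heterozygosity.
#' @param autosomes Integer vector of autosomal chromosome numbers.
#' @param blend_g_weight,blend_a_weight Blending weights for G and A22;
#'   must sum to 1.
#' @param tune_mean_diag Rescale G so its mean diagonal and mean
#'   off-diagonal match A22 before blending (off by default; the
#'   frequency-based scaling G = MM'/k already targets a unit mean
#'   diagonal).
#' @param filter_order Order in which SNP filters are applied, each on
#'   the set surviving the previous one.
#' @return List of class `gconfig`.
#' @export
gmatrix_config <- function(maf_min = 0.05, snp_callrate_min = 0.90,
                           animal_callrate_min = 0.90, hwe_max_dev = 0.15,
                           autosomes = 1:29,
                           blend_g_weight = 0.95, blend_a_weight = 0.05,
                           tune_mean_diag = FALSE,
                           filter_order = c("callrate", "maf", "hwe",
                                            "autosome")) {
  stopifnot(abs(blend_g_weight + blend_a_weight - 1) < 1e-12,
            maf_min > 0, maf_min < 0.5,
            snp_callrate_min > 0, snp_callrate_min <= 1,
            hwe_max_dev > 0, hwe_max_dev < 1)
  filter_order <- match.arg(filter_order,
                            c("callrate", "maf", "hwe", "autosome"),
                            several.ok = TRUE)
  structure(list(maf_min = maf_min, snp_callrate_min = snp_callrate_min,
                 animal_callrate_min = animal_callrate_min,
                 hwe_max_dev = hwe_max_dev, autosomes = autosomes,
                 blend_g_weight = blend_g_weight,
                 blend_a_weight = blend_a_weight,
                 tune_mean_diag = tune_mean_diag,
                 filter_order = filter_order),
            class = "gconfig")
}

snp_stats <- function(geno) {
  n <- nrow(geno)
  called <- colSums(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  obs_het <- colMeans(geno == 1, na.rm = TRUE)
  list(callrate = called / n, p = p, maf = pmin(p, 1 - p),
       obs_het = obs_het, exp_het = 2 * p * (1 - p))
}

#' SNP quality control
#'
#' Removes SNPs failing, in the configured order: call rate < 0.90,
#' minor allele frequency < 0.05, Hardy-Weinberg deviation
#' |observed het - 2p(1-p)| > 0.15, and non-autosomal position.  Each
#' filter is evaluated on the SNPs surviving the previous one, and
#' per-filter removal counts are reported.
#'
#' @param g A [genotype_matrix()].
#' @param cfg A [gmatrix_config()].
#' @return The filtered `genomat`, with attribute `qc_audit`: a
#'   `data.frame` (filter, threshold, removed).
#' @export
qc_snps <- function(g, cfg = gmatrix_config()) {
  stopifnot(inherits(g, "genomat"))
  keep <- rep(TRUE, ncol(g$geno))
  audit <- data.frame(filter = character(0), threshold = numeric(0),
                      removed = integer(0))
  for (f in cfg$filter_order) {
    st <- snp_stats(g$geno[, keep, drop = FALSE])
    fail <- switch(f,
      callrate = st$callrate < cfg$snp_callrate_min,
      maf      = st$maf < cfg$maf_min,
      hwe      = abs(st$obs_het - st$exp_het) > cfg$hwe_max_dev,
      autosome = !(g$map$chrom[keep] %in% cfg$autosomes))
    fail[is.na(fail)] <- TRUE
    thr <- switch(f, callrate = cfg$snp_callrate_min, maf = cfg$maf_min,
                  hwe = cfg$hwe_max_dev, autosome = NA_real_)
    audit <- rbind(audit, data.frame(filter = f, threshold = thr,
                                     removed = sum(fail)))
    keep[keep] <- !fail
  }
  if (!any(keep)) {
    stop("no SNPs survive quality control; audit:\n",
         paste(utils::capture.output(print(audit)), collapse = "\n"))
  }
  out <- genotype_matrix(g$geno[, keep, drop = FALSE],
                         g$map[keep, , drop = FALSE])
  attr(out, "qc_audit") <- audit
  out
}

#' Animal quality control
#'
#' Removes animals whose genotype call rate falls below the threshold.
#' Applied after [qc_snps()].
#'
#' @inheritParams qc_snps
#' @return The filtered `genomat` with attribute `removed_animals`.
#' @export
qc_animals <- function(g, cfg = gmatrix_config()) {
  stopifnot(inherits(g, "genomat"))
  cr <- rowMeans(!is.na(g$geno))
  drop <- cr < cfg$animal_callrate_min
  if (all(drop)) stop("no animals survive call-rate filtering")
  out <- genotype_matrix(g$geno[!drop, , drop = FALSE], g$map)
  attr(out, "removed_animals") <- rownames(g$geno)[drop]
  attr(out, "qc_audit") <- attr(g, "qc_audit")
  out
}

#' Center genotypes and compute the VanRaden scaling constant
#'
#' Computes observed allele frequencies p from the genotyped sample,
#' imputes missing calls by the column mean 2p, centers each column to
#' `count - 2p`, and returns the scaling constant `k = 2 sum p(1-p)`.
#'
#' @param g A QC'd `genomat`.
#' @return List with `M` (centered numeric matrix), `p` (named allele
#'   frequencies), `k`, and `map`.
#' @export
center_and_scale <- function(g) {
  stopifnot(inherits(g, "genomat"))
  geno <- g$geno
  p <- colMeans(geno, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP(s) reached centering (should be MAF-filtered): ",
         paste(utils::head(g$map$snp_id[p <= 0 | p >= 1], 5), collapse = ", "))
  }
  M <- sweep(geno, 2, 2 * p)
  if (anyNA(M)) M[is.na(M)] <- 0  # missing -> column mean after centering
  k <- 2 * sum(p * (1 - p))
  list(M = M, p = stats::setNames(p, g$map$snp_id), k = k, map = g$map)
}

#' Genomic relationship matrix G = M D M' / k
#'
#' VanRaden's first method with optional SNP weights: `G = M D M' / k`
#' where M holds centered allele counts, D is a diagonal matrix of SNP
#' weights (identity for the unweighted case) and `k = 2 sum p(1-p)`.
#'
#' @param M Centered genotype matrix from [center_and_scale()].
#' @param k Scaling constant from [center_and_scale()].
#' @param weights Optional per-SNP weights (recycled 1 by default).
#' @return A `relmat` of kind `"G_raw"`.
#' @export
g_matrix <- function(M, k, weights = NULL) {
  if (k <= 0) stop("scaling constant k must be positive")
  if (is.null(weights)) {
    G <- tcrossprod(M) / k
  } else {
    stopifnot(length(weights) == ncol(M), all(weights >= 0))
    G <- tcrossprod(sweep(M, 2, weights, `*`), M) / k
  }
  G <- (G + t(G)) / 2
  relmat(G, rownames(M), "G_raw")
}

#' Blend G with A22
#'
#' Guards against singular G by forming `Gb = w_g G + w_a A22`
#' (default 0.95/0.05).  With `tune_mean_diag` in the configuration, G
#' is first rescaled as `a + b G` so that its mean diagonal and mean
#' off-diagonal match those of A22.
#'
#' @param G A `relmat` of kind `"G_raw"`.
#' @param A22 A `relmat` of kind `"A22"` on the same ids.
#' @param cfg A [gmatrix_config()].
#' @return A `relmat` of kind `"G_blended"`.
#' @export
blend_g <- function(G, A22, cfg = gmatrix_config()) {
  stopifnot(inherits(G, "relmat"), inherits(A22, "relmat"))
  if (!identical(attr(G, "ids"), attr(A22, "ids"))) {
    stop("G and A22 ids are not aligned")
  }
  Gm <- unclass(G); Am <- unclass(A22)
  if (isTRUE(cfg$tune_mean_diag) && nrow(Gm) > 1) {
    md_g <- mean(diag(Gm)); mo_g <- (sum(Gm) - sum(diag(Gm))) / (length(Gm) - nrow(Gm))
    md_a <- mean(diag(Am)); mo_a <- (sum(Am) - sum(diag(Am))) / (length(Am) - nrow(Am))
    b <- (md_a - mo_a) / (md_g - mo_g)
    a <- md_a - b * md_g
    Gm <- a + b * Gm
  }
  Gb <- cfg$blend_g_weight * Gm + cfg$blend_a_weight * Am
  relmat(Gb, attr(G, "ids"), "G_blended")
}
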