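#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the GEBVs of the genotyped animals into per-SNP allele
#' substitution effects using the standard ssGWAS back-solution
#' `u = D M' Ginv a_g / k`, where M holds centered genotypes, D the
#' current SNP weights and Ginv the inverse of the genomic matrix
#' actually used in the evaluation.  With an unblended, unweighted G
#' this is the projection `u = M'(MM')^- a_g`, so `M u` reproduces
#' `a_g`.
#'
#' @param cs Centered genotypes from [center_and_scale()] (list with
#'   `M`, `k`, `p`, `map`).
#' @param G_used_inv Inverse of the genomic matrix used in evaluation
#'   (matrix over the genotyped animals, same order as rows of `M`).
#' @param gebv_genotyped Named or ordered numeric vector of GEBVs for
#'   the genotyped animals (row order of `M`).
#' @param weights Per-SNP weights (default 1).
#' @return `data.frame` of class `snp_effects`: `snp_id`, `chrom`,
#'   `pos`, `effect`, `weight`, `p`.
#' @export
backsolve_snp_effects <- function(cs, G_used_inv, gebv_genotyped,
                                  weights = NULL) {
  M <- cs$M
  if (is.null(weights)) weights <- rep(1, ncol(M))
  stopifnot(length(weights) == ncol(M))
  a <- gebv_genotyped
  if (!is.null(names(a))) {
    if (!all(rownames(M) %in% names(a))) {
      stop("GEBV vector length/names do not cover the genotyped animals")
    }
    a <- a[rownames(M)]
  }
  if (length(a) != nrow(M) || anyNA(a)) {
    stop("GEBV vector length (", length(a),
         ") does not match genotyped animals (", nrow(M), ")")
  }
  Gi <- unclass(G_used_inv)
  if (!all(dim(Gi) == nrow(M))) stop("G inverse does not conform with M")
  u <- weights * as.numeric(crossprod(M, Gi %*% a)) / cs$k
  out <- data.frame(snp_id = cs$map$snp_id, chrom = cs$map$chrom,
                    pos = cs$map$pos, effect = u, weight = weights,
                    p = as.numeric(cs$p), stringsAsFactors = FALSE)
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Update SNP weights from estimated effects
#'
#' Weighted-ssGBLUP re-weighting: the raw weight of SNP j is its
#' estimated variance contribution `u_j^2 * 2 p_j (1 - p_j)`; weights
#' are normalized to sum to the SNP count (mean 1) and floored at
#' `1e-8` of the mean so the weighted G stays invertible.
#'
#' @param effects A `snp_effects` table from
#'   [backsolve_snp_effects()].
#' @param floor_frac Weight floor as a fraction of the mean weight.
#' @return Numeric vector of weights (sum = number of SNPs).
#' @export
update_weights <- function(effects, floor_frac = 1e-8) {
  m <- nrow(effects)
  raw <- effects$effect^2 * 2 * effects$p * (1 - effects$p)
  if (all(raw < .Machine$double.eps)) {
    warning("all SNP effects are zero; weights reset to 1")
    return(rep(1, m))
  }
  w <- raw * m / sum(raw)
  w <- pmax(w, floor_frac)
  w * m / sum(w)
}

#' Run the iterative weighted single-step GWAS
#'
#' Full WssGBLUP loop: iteration 1 uses equal SNP weights; each
#' iteration builds the weighted genomic matrix `G = M D M' / k`,
#' blends it with A22, assembles H-inverse with the tau/omega scaling,
#' re-solves the mixed-model equations for GEBVs (variance components
#' held fixed), back-solves SNP effects, and re-weights.  Three
#' iterations total by default.
#'
#' @param d An `mmdesign` for the trait.
#' @param op The ordered pedigree.
#' @param cs Centered genotypes from [center_and_scale()]; row names
#'   of `cs$M` are the genotyped animal ids.
#' @param sigma2_a,sigma2_e Variance components (e.g. from
#'   [ai_reml()]); not re-estimated across weight iterations.
#' @param n_iterations Number of weight iterations (default 3:
#'   equal weights plus two re-weightings).
#' @param tau,omega H-inverse scaling factors.
#' @param cfg A [gmatrix_config()] (controls blending/tuning).
#' @return List of class `wssgwas_fit`: `iterations` (list of
#'   `snp_effects` tables, one per iteration), `effects` (final
#'   table), `gebv` (final GEBVs, all animals), `genotyped_ids`.
#' @export
run_wssgblup <- function(d, op, cs, sigma2_a, sigma2_e,
                         n_iterations = 3, tau = 1.0, omega = 0.7,
                         cfg = gmatrix_config()) {
  stopifnot(n_iterations >= 1)
  gids <- rownames(cs$M)
  ## sparse A-inverse + ancestor-pruned A22: the mixed-model equations
  ## stay sparse outside the genotyped block
  Ainv <- a_inverse_sparse(op)
  A22 <- a22_direct(op, gids)
  gidx <- match(gids, op$ids)
  w <- rep(1, ncol(cs$M))
  iters <- vector("list", n_iterations)
  sol <- NULL
  for (it in seq_len(n_iterations)) {
    G <- g_matrix(cs$M, cs$k, weights = w)
    Gb <- blend_g(G, A22$A22, cfg)
    delta <- tau * chol2inv(chol(unclass(Gb))) -
      omega * unclass(A22$A22_inverse)
    Hinv <- Ainv + Matrix::sparseMatrix(
      i = rep(gidx, times = length(gidx)),
      j = rep(gidx, each = length(gidx)),
      x = as.numeric(delta), dims = c(op$n, op$n))
    sol <- solve_mme(d, Hinv, sigma2_a, sigma2_e)
    Gbi <- chol2inv(chol(unclass(Gb)))
    ## back-solve from GEBV deviations: a mean offset is not a genetic
    ## contrast and would leak into the SNP effects through Gb-inverse
    a_g <- sol$gebv[gids]
    a_g <- a_g - mean(a_g)
    eff <- backsolve_snp_effects(cs, Gbi, a_g, weights = w)
    iters[[it]] <- eff
    if (it < n_iterations) w <- update_weights(eff)
  }
  structure(list(iterations = iters, effects = iters[[n_iterations]],
                 gebv = sol$gebv, genotyped_ids = gids),
            class = "wssgwas_fit")
}

#' Moving-window proportion of genetic variance
#'
#' Slides a window of `window_size` adjacent SNPs (step 1, never
#' crossing a chromosome boundary) along the genome and reports, for
#' each window, the percentage of the total genomic variance explained:
#' `100 * Var(M_w u_w) / Var(M u)` over the genotyped animals.
#' Chromosomes with fewer SNPs than the window emit no windows.
#'
#' @param effects A `snp_effects` table.
#' @param M Centered genotype matrix (same SNP order as `effects`).
#' @param window_size Number of adjacent SNPs per window (default 5).
#' @param distinct If `TRUE`, use non-overlapping windows instead of
#'   moving ones.
#' @return `data.frame` of class `window_scan`: `chrom`, `start_bp`,
#'   `end_bp`, `mid_bp`, `snp_first`, `snp_last`, `pct_var`.
#' @export
window_variance <- function(effects, M, window_size = 5,
                            distinct = FALSE) {
  stopifnot(nrow(effects) == ncol(M), window_size >= 1)
  ord <- order(effects$chrom, effects$pos)
  eff <- effects[ord, , drop = FALSE]
  M <- M[, ord, drop = FALSE]
  gv <- as.numeric(M %*% eff$effect)
  denom <- stats::var(gv)
  if (denom <= 0) stop("total genomic variance is zero; no signal to scan")
  rows <- list()
  for (ch in unique(eff$chrom)) {
    j <- which(eff$chrom == ch)
    if (length(j) < window_size) next
    starts <- if (distinct) {
      seq(1L, length(j) - window_size + 1L, by = window_size)
    } else {
      seq_len(length(j) - window_size + 1L)
    }
    for (s in starts) {
      w <- j[s:(s + window_size - 1L)]
      gw <- as.numeric(M[, w, drop = FALSE] %*% eff$effect[w])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = eff$pos[w[1L]],
        end_bp = eff$pos[w[window_size]],
        mid_bp = (eff$pos[w[1L]] + eff$pos[w[window_size]]) / 2,
        snp_first = eff$snp_id[w[1L]], snp_last = eff$snp_id[w[window_size]],
        pct_var = 100 * stats::var(gw) / denom)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = integer(0), start_bp = integer(0),
               end_bp = integer(0), mid_bp = numeric(0),
               snp_first = character(0), snp_last = character(0),
               pct_var = numeric(0))
  class(out) <- c("window_scan", "data.frame")
  out
}

#' Call significant genomic regions
#'
#' Windows explaining more than `threshold_pct` of the total genetic
#' variance are significant; overlapping or book-ended significant
#' windows on the same chromosome are merged into regions reporting the
#' full span and the peak window.
#'
#' @param scan A `window_scan`.
#' @param threshold_pct Variance threshold in percent (default 1).
#' @return `data.frame`: `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `peak_pct`.
#' @export
call_regions <- function(scan, threshold_pct = 1.0) {
  sig <- scan[scan$pct_var > threshold_pct, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_windows = integer(0),
                      peak_pct = numeric(0)))
  }
  sig <- sig[order(sig$chrom, sig$start_bp), , drop = FALSE]
  out <- list()
  cur <- sig[1, ]
  cur_n <- 1L
  for (i in seq_len(nrow(sig))[-1]) {
    row <- sig[i, ]
    if (row$chrom == cur$chrom && row$start_bp <= cur$end_bp + 1) {
      cur$end_bp <- max(cur$end_bp, row$end_bp)
      cur$pct_var <- max(cur$pct_var, row$pct_var)
      cur_n <- cur_n + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cur$chrom, start_bp = cur$start_bp, end_bp = cur$end_bp,
        n_windows = cur_n, peak_pct = cur$pct_var)
      cur <- row
      cur_n <- 1L
    }
  }
  out[[length(out) + 1L]] <- data.frame(
    chrom = cur$chrom, start_bp = cur$start_bp, end_bp = cur$end_bp,
    n_windows = cur_n, peak_pct = cur$pct_var)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
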