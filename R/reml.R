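#' Build design matrices for the animal model
#'
#' Constructs `y`, the fixed-effect matrix `X` (contemporary-group
#' indicators with the first level absorbed into the intercept, plus
#' mean-centered age and heterozygosity covariates) and the record-to-
#' animal map for the model
#' `y = CG + b1 (Age - mean) + b2 (H_D - mean) + a + e`.
#'
#' Records with missing heterozygosity are excluded from fitting (not
#' imputed).  Covariates that do not vary are dropped from X to keep it
#' full rank.
#'
#' @param t Cleaned phenotype `data.frame` (see [edit_phenotypes()])
#'   with columns `animal`, `trait`, `value`, `cg`, `age_days`, `hd`.
#' @param op An `orped`; every phenotyped animal must appear in it.
#' @param trait Trait to extract (one of the values in `t$trait`).
#' @param use_hd,use_age Include the covariates (default TRUE).
#' @return Object of class `mmdesign`: list with `y`, `X`,
#'   `animal_idx` (record -> position in `op$ids`), `ids` (pedigree
#'   ids), `trait`, `n`, `p`.
#' @export
build_design <- function(t, op, trait, use_hd = TRUE, use_age = TRUE) {
  stopifnot(inherits(op, "orped"),
            all(c("animal", "trait", "value", "cg", "age_days") %in% names(t)))
  d <- t[t$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait ", trait)
  if (use_hd) {
    if (!"hd" %in% names(d)) stop("phenotype table lacks an 'hd' column")
    d <- d[!is.na(d$hd), , drop = FALSE]
    if (!nrow(d)) stop("all records lack a heterozygosity coefficient")
  }
  idx <- match(as.character(d$animal), op$ids)
  if (anyNA(idx)) {
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(unique(d$animal[is.na(idx)]), collapse = ", "))
  }
  cg <- factor(d$cg)
  X <- if (nlevels(cg) > 1) {
    stats::model.matrix(~cg)
  } else {
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (use_age) {
    age_c <- d$age_days - mean(d$age_days)
    if (stats::sd(age_c) > 0) X <- cbind(X, age = age_c)
  }
  if (use_hd) {
    hd_c <- d$hd - mean(d$hd)
    if (stats::sd(hd_c) > 0) X <- cbind(X, hd = hd_c)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  structure(list(y = as.numeric(d$value), X = X, animal_idx = idx,
                 animal = as.character(d$animal), ids = op$ids,
                 trait = trait, n = nrow(d), p = ncol(X)),
            class = "mmdesign")
}

## X'W and W'y aggregates without materializing the indicator matrix W
xtw_aggregate <- function(X, idx, q) {
  p <- ncol(X)
  XtW <- matrix(0, p, q)
  agg <- rowsum(X, group = idx)
  XtW[, as.integer(rownames(agg))] <- t(agg)
  XtW
}

#' Solve the mixed-model equations
#'
#' Henderson's MME for one trait:
#' `[X'X X'W; W'X W'W + lambda Kinv] [b; a] = [X'y; W'y]` with
#' `lambda = sigma2_e / sigma2_a`, where `Kinv` is the inverse
#' relationship matrix (A-inverse for pedigree BLUP, H-inverse for
#' ssGBLUP).
#'
#' @param d An `mmdesign` from [build_design()].
#' @param Kinv `relmat` of kind `"A_inverse"` or `"H_inverse"` over the
#'   pedigree ids used in `d`.
#' @param sigma2_a,sigma2_e Additive and residual variances.
#' @return List with `beta` (named fixed-effect solutions), `gebv`
#'   (named breeding values for every pedigree animal), `lambda`, and
#'   `fitted`/`residuals` for the phenotyped records.
#' @export
solve_mme <- function(d, Kinv, sigma2_a, sigma2_e) {
  stopifnot(inherits(d, "mmdesign"), sigma2_a > 0, sigma2_e > 0)
  sparse <- methods::is(Kinv, "Matrix")
  Ki <- if (sparse) Kinv else unclass(Kinv)
  q <- length(d$ids)
  if (!all(dim(Ki) == c(q, q))) stop("Kinv dimension does not match pedigree")
  lambda <- sigma2_e / sigma2_a
  X <- d$X; y <- d$y; idx <- d$animal_idx; p <- ncol(X)
  XtX <- crossprod(X)
  XtW <- xtw_aggregate(X, idx, q)
  rhs <- c(crossprod(X, y), {
    wy <- numeric(q)
    agg <- rowsum(y, group = idx)
    wy[as.integer(rownames(agg))] <- agg
    wy
  })
  sol <- if (sparse) {
    ## sparse mixed-model equations: A-inverse contributes a sparse
    ## pattern, the genotyped block is the only dense piece
    C <- rbind(
      cbind(Matrix::Matrix(XtX), Matrix::Matrix(XtW, sparse = TRUE)),
      cbind(Matrix::t(Matrix::Matrix(XtW, sparse = TRUE)),
            Matrix::Diagonal(q, tabulate(idx, q)) + lambda * Ki))
    tryCatch(as.numeric(Matrix::solve(Matrix::forceSymmetric(C), rhs)),
             error = function(e) {
               stop("mixed-model equations are singular: ",
                    conditionMessage(e))
             })
  } else {
    WtW <- diag(tabulate(idx, q), q)
    C <- rbind(cbind(XtX, XtW), cbind(t(XtW), WtW + lambda * Ki))
    tryCatch(solve(C, rhs), error = function(e) {
      stop("mixed-model equations are singular: ", conditionMessage(e))
    })
  }
  beta <- stats::setNames(sol[seq_len(p)], colnames(X))
  gebv <- stats::setNames(sol[-seq_len(p)], d$ids)
  fit <- as.numeric(X %*% beta) + gebv[idx]
  list(beta = beta, gebv = gebv, lambda = lambda,
       fitted = fit, residuals = y - fit)
}

## eigendecomposition of the record-space covariance structure
## S = W K W' = K[idx, idx]; shared by AI-REML paths
reml_spectral <- function(d, Kinv) {
  K <- chol2inv(chol(unclass(Kinv)))
  S <- K[d$animal_idx, d$animal_idx, drop = FALSE]
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(lam = lam, yt = as.numeric(crossprod(e$vectors, d$y)),
       Xt = crossprod(e$vectors, d$X))
}

#' Variance components by average-information REML
#'
#' Fits the single-trait animal model by AI-REML.  The record-space
#' covariance `W K W'` is eigendecomposed once, which makes every
#' iteration closed-form on the rotated data; AI (Newton) updates are
#' replaced by EM steps whenever they would leave the parameter space.
#' Standard errors come from the inverse AI matrix at convergence, and
#' the heritability SE by the delta method.
#'
#' @inheritParams solve_mme
#' @param start Optional `c(sigma2_a, sigma2_e)` starting values;
#'   defaults to a 30/70 split of the fixed-effects-adjusted variance.
#' @param tol Relative parameter-change convergence bound.
#' @param ltol Relative log-likelihood-change convergence bound.
#' @param max_rounds Iteration cap; non-convergence is flagged, not an
#'   error.
#' @return Object of class `varcomp`: `sigma2_a`, `sigma2_e`, `se_a`,
#'   `se_e`, `h2`, `se_h2`, `loglik`, `n_iterations`, `converged`,
#'   `cov_theta`.
#' @export
ai_reml <- function(d, Kinv, start = NULL, tol = 1e-8, ltol = 1e-9,
                    max_rounds = 200) {
  stopifnot(inherits(d, "mmdesign"))
  sp <- reml_spectral(d, Kinv)
  lam <- sp$lam; yt <- sp$yt; Xt <- sp$Xt
  n <- length(yt)
  if (is.null(start)) {
    r0 <- stats::lm.fit(d$X, d$y)$residuals
    v0 <- stats::var(r0)
    start <- c(0.3 * v0, 0.7 * v0)
  }
  th <- pmax(start, 1e-8)
  floor_v <- 1e-10 * stats::var(d$y)
  ll_old <- -Inf
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_rounds)) {
    st <- uni_reml_inner(th, lam, yt, Xt)
    AI <- st$AI
    delta <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
    th_new <- if (!is.null(delta)) th + delta else c(NA, NA)
    if (anyNA(th_new) || any(th_new <= 0)) {
      ## EM fallback keeps the update inside the parameter space
      th_new <- c(
        th[1] + th[1]^2 / length(d$ids) * (st$quad[1] - st$trP[1]),
        th[2] + th[2]^2 / n * (st$quad[2] - st$trP[2]))
      th_new <- pmax(th_new, floor_v)
    }
    rel <- max(abs(th_new - th) / pmax(th, floor_v))
    dll <- abs(st$ll - ll_old) / (abs(st$ll) + 1e-10)
    th <- th_new
    ll_old <- st$ll
    if (rel < tol && dll < ltol) {
      converged <- TRUE
      break
    }
  }
  fin <- uni_reml_inner(th, lam, yt, Xt)
  cov_theta <- tryCatch(solve(fin$AI), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se <- sqrt(pmax(diag(cov_theta), 0))
  h2 <- th[1] / sum(th)
  gr <- c(th[2], -th[1]) / sum(th)^2
  se_h2 <- sqrt(max(drop(t(gr) %*% cov_theta %*% gr), 0))
  structure(list(sigma2_a = th[1], sigma2_e = th[2],
                 se_a = se[1], se_e = se[2],
                 h2 = h2, se_h2 = se_h2, loglik = fin$ll,
                 n_iterations = it, converged = converged,
                 cov_theta = cov_theta),
            class = "varcomp")
}

## one AI-REML evaluation on rotated data: loglik, scores, AI matrix,
## traces and quadratic forms for the EM step
uni_reml_inner <- function(th, lam, yt, Xt) {
  v <- th[1] * lam + th[2]
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  Ch <- chol(XtWX)
  Cinv <- chol2inv(Ch)
  b <- Cinv %*% crossprod(Xt, w * yt)
  r <- yt - as.numeric(Xt %*% b)
  Py <- w * r
  yPy <- sum(yt * Py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(Ch))) + yPy)
  h <- rowSums((Xt %*% Cinv) * Xt)       # x_i' (X'VinvX)^-1 x_i
  trP <- c(sum(w * lam) - sum(lam * w^2 * h),
           sum(w)       - sum(w^2 * h))
  quad <- c(sum(Py^2 * lam), sum(Py^2))
  score <- -0.5 * (trP - quad)
  Pu <- function(u) w * u - (w * Xt) %*% (Cinv %*% crossprod(Xt, w * u))
  u1 <- lam * Py; u2 <- Py
  P1 <- Pu(u1); P2 <- Pu(u2)
  AI <- 0.5 * matrix(c(sum(u1 * P1), sum(u1 * P2),
                       sum(u2 * P1), sum(u2 * P2)), 2, 2)
  AI <- (AI + t(AI)) / 2
  list(ll = ll, score = score, AI = AI, trP = trP, quad = quad)
}

#' Variance components by EM-REML (independent cross-check)
#'
#' Classical expectation-maximization REML on the mixed-model equations:
#' `sigma2_a = (a' Kinv a + sigma2_e tr(Kinv Caa)) / q` and
#' `sigma2_e = y'(y - Xb - Wa) / (n - rank X)`.  Slower than [ai_reml()]
#' but algorithmically independent of it; the two must agree at the
#' REML maximum.
#'
#' @inheritParams ai_reml
#' @return A `varcomp` (standard errors are not computed: `NA`).
#' @export
em_reml <- function(d, Kinv, start = NULL, tol = 1e-10,
                    max_rounds = 5000) {
  stopifnot(inherits(d, "mmdesign"))
  Ki <- unclass(Kinv)
  q <- length(d$ids)
  X <- d$X; y <- d$y; idx <- d$animal_idx
  n <- length(y); p <- ncol(X)
  if (is.null(start)) {
    v0 <- stats::var(stats::lm.fit(X, y)$residuals)
    start <- c(0.3 * v0, 0.7 * v0)
  }
  th <- pmax(start, 1e-8)
  XtX <- crossprod(X)
  XtW <- xtw_aggregate(X, idx, q)
  WtW <- diag(tabulate(idx, q), q)
  Wty <- numeric(q)
  agg <- rowsum(y, group = idx)
  Wty[as.integer(rownames(agg))] <- agg
  rhs <- c(crossprod(X, y), Wty)
  yty <- sum(y^2)
  converged <- FALSE
  for (it in seq_len(max_rounds)) {
    lambda <- th[2] / th[1]
    C <- rbind(cbind(XtX, XtW), cbind(t(XtW), WtW + lambda * Ki))
    Cinv <- solve(C)
    sol <- Cinv %*% rhs
    a <- sol[-seq_len(p)]
    Caa <- Cinv[-seq_len(p), -seq_len(p)]
    s2a <- (sum(a * (Ki %*% a)) + th[2] * sum(Ki * Caa)) / q
    s2e <- (yty - sum(sol * rhs)) / (n - p)
    th_new <- c(s2a, s2e)
    rel <- max(abs(th_new - th) / pmax(th, 1e-12))
    th <- th_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(sigma2_a = th[1], sigma2_e = th[2],
                 se_a = NA_real_, se_e = NA_real_,
                 h2 = th[1] / sum(th), se_h2 = NA_real_,
                 loglik = NA_real_, n_iterations = it,
                 converged = converged, cov_theta = NULL),
            class = "varcomp")
}

#' Heritability with delta-method standard error
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the SE propagates the
#' component covariance matrix when available.
#'
#' @param v A `varcomp`, or a numeric `c(sigma2_a, sigma2_e)`.
#' @param cov_theta Optional 2x2 covariance of the components (taken
#'   from `v` when it is a `varcomp`).
#' @return List with `h2` and `se`.
#' @export
heritability <- function(v, cov_theta = NULL) {
  if (inherits(v, "varcomp")) {
    th <- c(v$sigma2_a, v$sigma2_e)
    if (is.null(cov_theta)) cov_theta <- v$cov_theta
  } else {
    th <- as.numeric(v)
  }
  h2 <- th[1] / sum(th)
  se <- NA_real_
  if (!is.null(cov_theta) && !anyNA(cov_theta)) {
    gr <- c(th[2], -th[1]) / sum(th)^2
    se <- sqrt(max(drop(t(gr) %*% cov_theta %*% gr), 0))
  }
  list(h2 = h2, se = se)
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s after %d rounds):\n",
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  cat(sprintf("  sigma2_a = %.6g (SE %.3g)\n", x$sigma2_a, x$se_a))
  cat(sprintf("  sigma2_e = %.6g (SE %.3g)\n", x$sigma2_e, x$se_e))
  cat(sprintf("  h2       = %.4f (SE %.3g)\n", x$h2, x$se_h2))
  invisible(x)
}
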