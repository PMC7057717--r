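## Bivariate AI-REML for the animal model
##
## Model: y_t = X_t b_t + a_t + e_t, (a_1, a_2) ~ N(0, G0 x K),
## (e_1, e_2) ~ N(0, R0 x I) with residual covariance only between
## records on the same animal.  Parameters th = (g11, g12, g22, r11,
## r12, r22).  Two computational routes share the interface: a spectral
## route for the balanced case (both traits recorded on the same
## animals, one record each) where the eigendecomposition of K over the
## recorded animals turns V into independent 2x2 blocks, and a dense
## route for unequal record sets.

biv_theta_valid <- function(th) {
  g <- th[1] * th[3] - th[2]^2
  r <- th[4] * th[6] - th[5]^2
  th[1] > 0 && th[3] > 0 && g > 0 && th[4] > 0 && th[6] > 0 && r > 0
}

## one evaluation on the spectral (balanced) route
biv_inner_spectral <- function(th, lam, yt1, yt2, Xt1, Xt2) {
  g11 <- th[1]; g12 <- th[2]; g22 <- th[3]
  r11 <- th[4]; r12 <- th[5]; r22 <- th[6]
  V11 <- lam * g11 + r11
  V12 <- lam * g12 + r12
  V22 <- lam * g22 + r22
  dt <- V11 * V22 - V12^2
  if (any(dt <= 0) || any(V11 <= 0)) return(NULL)
  iv11 <- V22 / dt; iv22 <- V11 / dt; iv12 <- -V12 / dt
  p1 <- ncol(Xt1); p2 <- ncol(Xt2)
  C <- rbind(cbind(crossprod(Xt1, Xt1 * iv11), crossprod(Xt1, Xt2 * iv12)),
             cbind(crossprod(Xt2, Xt1 * iv12), crossprod(Xt2, Xt2 * iv22)))
  rhs <- c(crossprod(Xt1, iv11 * yt1 + iv12 * yt2),
           crossprod(Xt2, iv12 * yt1 + iv22 * yt2))
  Ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Ch)) return(NULL)
  Cinv <- chol2inv(Ch)
  b <- as.numeric(Cinv %*% rhs)
  r1 <- yt1 - as.numeric(Xt1 %*% b[seq_len(p1)])
  r2 <- yt2 - as.numeric(Xt2 %*% b[p1 + seq_len(p2)])
  Py1 <- iv11 * r1 + iv12 * r2
  Py2 <- iv12 * r1 + iv22 * r2
  yPy <- sum(yt1 * Py1 + yt2 * Py2)
  ll <- -0.5 * (sum(log(dt)) + 2 * sum(log(diag(Ch))) + yPy)

  ## parameter structure: coefficient vector c and cross-trait type
  pars <- list(list(c = lam, t = "11"), list(c = lam, t = "12"),
               list(c = lam, t = "22"), list(c = 1,   t = "11"),
               list(c = 1,   t = "12"), list(c = 1,   t = "22"))
  score <- numeric(6)
  ulist <- vector("list", 6)
  for (j in 1:6) {
    cj <- pars[[j]]$c
    quad <- switch(pars[[j]]$t,
                   "11" = sum(cj * Py1^2),
                   "12" = 2 * sum(cj * Py1 * Py2),
                   "22" = sum(cj * Py2^2))
    trv <- switch(pars[[j]]$t,
                  "11" = sum(cj * iv11),
                  "12" = 2 * sum(cj * iv12),
                  "22" = sum(cj * iv22))
    w <- switch(pars[[j]]$t,
      "11" = list(cj * iv11^2, cj * iv11 * iv12, cj * iv12^2),
      "12" = list(2 * cj * iv11 * iv12, cj * (iv11 * iv22 + iv12^2),
                  2 * cj * iv12 * iv22),
      "22" = list(cj * iv12^2, cj * iv12 * iv22, cj * iv22^2))
    Mj <- rbind(cbind(crossprod(Xt1, Xt1 * w[[1]]),
                      crossprod(Xt1, Xt2 * w[[2]])),
                cbind(crossprod(Xt2, Xt1 * w[[2]]),
                      crossprod(Xt2, Xt2 * w[[3]])))
    score[j] <- -0.5 * ((trv - sum(Cinv * Mj)) - quad)
    ulist[[j]] <- switch(pars[[j]]$t,
                         "11" = list(cj * Py1, numeric(length(Py1)) ),
                         "12" = list(cj * Py2, cj * Py1),
                         "22" = list(numeric(length(Py2)), cj * Py2))
  }
  vlist <- lapply(ulist, function(u) {
    list(iv11 * u[[1]] + iv12 * u[[2]], iv12 * u[[1]] + iv22 * u[[2]])
  })
  tlist <- lapply(vlist, function(v) {
    c(crossprod(Xt1, v[[1]]), crossprod(Xt2, v[[2]]))
  })
  AI <- matrix(0, 6, 6)
  for (j in 1:6) for (k in j:6) {
    s <- sum(ulist[[j]][[1]] * vlist[[k]][[1]] +
             ulist[[j]][[2]] * vlist[[k]][[2]]) -
      drop(t(tlist[[j]]) %*% Cinv %*% tlist[[k]])
    AI[j, k] <- AI[k, j] <- 0.5 * s
  }
  list(ll = ll, score = score, AI = AI)
}

## one evaluation on the dense (general) route
biv_inner_dense <- function(th, y, X, Qlist) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (j in seq_along(Qlist)) V <- V + th[j] * Qlist[[j]]
  Ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Ch)) return(NULL)
  Vinv <- chol2inv(Ch)
  XtVinvX <- crossprod(X, Vinv %*% X)
  Cc <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(Cc)) return(NULL)
  Cinv <- chol2inv(Cc)
  VinvX <- Vinv %*% X
  P <- Vinv - VinvX %*% Cinv %*% t(VinvX)
  Py <- as.numeric(P %*% y)
  yPy <- sum(y * Py)
  ll <- -0.5 * (2 * sum(log(diag(Ch))) + 2 * sum(log(diag(Cc))) + yPy)
  m <- length(Qlist)
  score <- numeric(m)
  us <- vector("list", m)
  for (j in seq_len(m)) {
    us[[j]] <- as.numeric(Qlist[[j]] %*% Py)
    score[j] <- -0.5 * (sum(P * Qlist[[j]]) - sum(Py * us[[j]]))
  }
  AI <- matrix(0, m, m)
  Pu <- lapply(us, function(u) as.numeric(P %*% u))
  for (j in seq_len(m)) for (k in j:m) {
    AI[j, k] <- AI[k, j] <- 0.5 * sum(us[[j]] * Pu[[k]])
  }
  list(ll = ll, score = score, AI = AI)
}

#' Bivariate variance components by AI-REML
#'
#' Estimates the 2x2 additive (G0) and residual (R0) covariance
#' matrices of two traits under `a ~ N(0, G0 x K)`,
#' `e ~ N(0, R0 x I)` (residual covariance only between records on the
#' same animal), and derives the genetic and phenotypic correlations
#' with delta-method standard errors from the inverse AI matrix.
#' AI updates that would leave the positive-definite parameter space
#' are step-halved.
#'
#' @param d1,d2 `mmdesign` objects for the two traits (record sets may
#'   differ).
#' @param Kinv Inverse relationship matrix over the shared pedigree.
#' @param start Optional length-6 start
#'   `c(g11, g12, g22, r11, r12, r22)`.
#' @param tol,ltol,max_rounds Convergence controls as in [ai_reml()].
#' @return Object of class `bivarcomp`: `G0`, `R0`, `rg`, `se_rg`,
#'   `rp`, `se_rp`, `theta`, `se_theta`, `loglik`, `n_iterations`,
#'   `converged`.
#' @export
bivariate_reml <- function(d1, d2, Kinv, start = NULL, tol = 1e-8,
                           ltol = 1e-9, max_rounds = 200) {
  stopifnot(inherits(d1, "mmdesign"), inherits(d2, "mmdesign"),
            identical(d1$ids, d2$ids))
  balanced <- identical(d1$animal_idx, d2$animal_idx) &&
    !anyDuplicated(d1$animal_idx)
  if (balanced) {
    K <- chol2inv(chol(unclass(Kinv)))
    S <- K[d1$animal_idx, d1$animal_idx, drop = FALSE]
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    U <- e$vectors
    env <- list(lam = lam,
                yt1 = as.numeric(crossprod(U, d1$y)),
                yt2 = as.numeric(crossprod(U, d2$y)),
                Xt1 = crossprod(U, d1$X), Xt2 = crossprod(U, d2$X))
    inner <- function(th) biv_inner_spectral(th, env$lam, env$yt1,
                                             env$yt2, env$Xt1, env$Xt2)
  } else {
    K <- chol2inv(chol(unclass(Kinv)))
    S11 <- K[d1$animal_idx, d1$animal_idx, drop = FALSE]
    S12 <- K[d1$animal_idx, d2$animal_idx, drop = FALSE]
    S22 <- K[d2$animal_idx, d2$animal_idx, drop = FALSE]
    n1 <- d1$n; n2 <- d2$n
    Tm <- outer(d1$animal_idx, d2$animal_idx, `==`) * 1
    zero <- function(a, b) matrix(0, a, b)
    Qlist <- list(
      rbind(cbind(S11, zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
      rbind(cbind(zero(n1, n1), S12), cbind(t(S12), zero(n2, n2))),
      rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), S22)),
      rbind(cbind(diag(n1), zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
      rbind(cbind(zero(n1, n1), Tm), cbind(t(Tm), zero(n2, n2))),
      rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), diag(n2))))
    y <- c(d1$y, d2$y)
    X <- rbind(cbind(d1$X, zero(n1, ncol(d2$X))),
               cbind(zero(n2, ncol(d1$X)), d2$X))
    inner <- function(th) biv_inner_dense(th, y, X, Qlist)
  }
  if (is.null(start)) {
    v1 <- stats::var(stats::lm.fit(d1$X, d1$y)$residuals)
    v2 <- stats::var(stats::lm.fit(d2$X, d2$y)$residuals)
    start <- c(0.3 * v1, 0.5 * 0.3 * sqrt(v1 * v2), 0.3 * v2,
               0.7 * v1, 0.5 * 0.7 * sqrt(v1 * v2), 0.7 * v2)
  }
  th <- start
  if (!biv_theta_valid(th)) stop("invalid starting covariance matrices")
  converged <- FALSE
  ll_old <- -Inf
  st <- NULL
  for (it in seq_len(max_rounds)) {
    st <- inner(th)
    if (is.null(st)) stop("variance structure became non-positive-definite")
    delta <- tryCatch(solve(st$AI, st$score), error = function(e) {
      tryCatch(solve(st$AI + diag(1e-8 * max(abs(diag(st$AI))), 6),
                     st$score), error = function(e2) rep(0, 6))
    })
    th_new <- th + delta
    halvings <- 0
    while (!biv_theta_valid(th_new) && halvings < 30) {
      delta <- delta / 2
      th_new <- th + delta
      halvings <- halvings + 1
    }
    if (!biv_theta_valid(th_new)) th_new <- th  # boundary: stay put
    rel <- max(abs(th_new - th) / pmax(abs(th), 1e-10))
    dll <- abs(st$ll - ll_old) / (abs(st$ll) + 1e-10)
    th <- th_new
    ll_old <- st$ll
    if (rel < tol && dll < ltol) {
      converged <- TRUE
      break
    }
  }
  fin <- inner(th)
  cov_theta <- tryCatch(solve(fin$AI), error = function(e) {
    matrix(NA_real_, 6, 6)
  })
  se_theta <- sqrt(pmax(diag(cov_theta), 0))
  G0 <- matrix(th[c(1, 2, 2, 3)], 2, 2)
  R0 <- matrix(th[c(4, 5, 5, 6)], 2, 2)
  rg <- th[2] / sqrt(th[1] * th[3])
  gr_g <- c(-0.5 * rg / th[1], 1 / sqrt(th[1] * th[3]),
            -0.5 * rg / th[3], 0, 0, 0)
  se_rg <- sqrt(max(drop(t(gr_g) %*% cov_theta %*% gr_g), 0))
  sp1 <- th[1] + th[4]; sp2 <- th[3] + th[6]; num <- th[2] + th[5]
  rp <- num / sqrt(sp1 * sp2)
  gr_p <- c(-0.5 * rp / sp1, 1 / sqrt(sp1 * sp2), -0.5 * rp / sp2,
            -0.5 * rp / sp1, 1 / sqrt(sp1 * sp2), -0.5 * rp / sp2)
  se_rp <- sqrt(max(drop(t(gr_p) %*% cov_theta %*% gr_p), 0))
  structure(list(G0 = G0, R0 = R0, rg = rg, se_rg = se_rg,
                 rp = rp, se_rp = se_rp, theta = th,
                 se_theta = se_theta, loglik = fin$ll,
                 n_iterations = it, converged = converged,
                 cov_theta = cov_theta, balanced = balanced),
            class = "bivarcomp")
}

#' @export
print.bivarcomp <- function(x, ...) {
  cat(sprintf("Bivariate components (%s after %d rounds):\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  genetic correlation    %.3f (SE %.3g)\n", x$rg, x$se_rg))
  cat(sprintf("  phenotypic correlation %.3f (SE %.3g)\n", x$rp, x$se_rp))
  invisible(x)
}
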