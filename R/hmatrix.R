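#' Single-step inverse relationship matrix H^-1
#'
#' Assembles the ssGBLUP matrix
#' `H^-1 = A^-1 + [0 0; 0 tau Gb^-1 - omega A22^-1]`,
#' where the nonzero block sits on the genotyped animals.  The scaling
#' factors tau and omega temper the genomic and pedigree information to
#' reduce bias; tau = 1.0 and omega = 0.7 are the defaults used for
#' composite-cattle evaluation.
#'
#' @param Ainv `relmat` of kind `"A_inverse"` over all pedigree animals.
#' @param Gb `relmat` of kind `"G_blended"` over the genotyped animals
#'   (may also be an `"A22"` for the degenerate pedigree-only check).
#' @param A22inv `relmat` of kind `"A22_inverse"`, same ids as `Gb`.
#' @param tau,omega Scaling factors (tau > 0).
#' @return `relmat` of kind `"H_inverse"` with attribute
#'   `genotyped_ids`.
#' @export
h_inverse <- function(Ainv, Gb, A22inv, tau = 1.0, omega = 0.7) {
  stopifnot(inherits(Ainv, "relmat"), tau > 0)
  ids <- attr(Ainv, "ids")
  gids <- attr(Gb, "ids")
  if (length(gids) == 0L) {
    H <- unclass(Ainv)
    out <- relmat(H, ids, "H_inverse")
    attr(out, "genotyped_ids") <- character(0)
    return(out)
  }
  stopifnot(identical(gids, attr(A22inv, "ids")))
  idx <- match(gids, ids)
  if (anyNA(idx)) stop("genotyped id(s) absent from A inverse: ",
                       paste(gids[is.na(idx)], collapse = ", "))
  Gbi <- tryCatch(chol2inv(chol(unclass(Gb))), error = function(e) {
    stop("blended G is numerically singular; increase the A22 blending ",
         "weight (see gmatrix_config)")
  })
  H <- unclass(Ainv)
  H[idx, idx] <- H[idx, idx] + tau * Gbi - omega * unclass(A22inv)
  H <- (H + t(H)) / 2
  out <- relmat(H, ids, "H_inverse")
  attr(out, "genotyped_ids") <- gids
  out
}

#' Explicit H matrix (test oracle for tau = omega = 1)
#'
#' Builds the combined relationship matrix H directly, conditioning the
#' ungenotyped animals on the genotyped block:
#' `H22 = Gb`, `H12 = A12 A22^-1 Gb`,
#' `H11 = A11 + A12 A22^-1 (Gb - A22) A22^-1 A21`.
#' Its dense inverse equals [h_inverse()] output at tau = omega = 1;
#' intended for small pedigrees as an independent check.
#'
#' @param A `relmat` of kind `"A"`.
#' @param Gb `relmat` over the genotyped ids (subset of A's ids).
#' @return `relmat` of kind `"H"`.
#' @export
h_explicit <- function(A, Gb) {
  stopifnot(inherits(A, "relmat"), inherits(Gb, "relmat"))
  ids <- attr(A, "ids")
  gids <- attr(Gb, "ids")
  idx2 <- match(gids, ids)
  if (anyNA(idx2)) stop("genotyped id(s) absent from A")
  idx1 <- setdiff(seq_along(ids), idx2)
  Am <- unclass(A); Gm <- unclass(Gb)
  H <- Am
  if (length(idx1)) {
    A12 <- Am[idx1, idx2, drop = FALSE]
    A22i <- chol2inv(chol(Am[idx2, idx2, drop = FALSE]))
    B <- A12 %*% A22i              # regression of ungenotyped on genotyped
    H[idx1, idx2] <- B %*% Gm
    H[idx2, idx1] <- t(H[idx1, idx2, drop = FALSE])
    H[idx1, idx1] <- Am[idx1, idx1, drop = FALSE] +
      B %*% (Gm - Am[idx2, idx2, drop = FALSE]) %*% t(B)
  }
  H[idx2, idx2] <- Gm
  H <- (H + t(H)) / 2
  relmat(H, ids, "H")
}
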