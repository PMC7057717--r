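#' Topologically order a pedigree
#'
#' Reorders pedigree rows so that every parent precedes its offspring
#' (founders first), producing the dense integer-indexed representation
#' that all relationship-matrix routines consume.
#'
#' @param ped A pedigree `data.frame` with columns `animal`, `sire`,
#'   `dam` (character; `NA` = unknown parent), e.g. from
#'   [read_pedigree()].
#' @return An object of class `orped`: a list with `ids` (character,
#'   topological order), `sire` and `dam` (integer indices into `ids`,
#'   `NA` for unknown), and `n`.
#' @examples
#' ped <- data.frame(animal = c("C", "F1", "F2"),
#'                   sire   = c("F1", NA, NA),
#'                   dam    = c("F2", NA, NA))
#' op <- order_pedigree(ped)
#' op$ids  # founders first
#' @export
order_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids)) {
    stop("duplicate animal id(s) in pedigree: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(ids)
  sire <- match(as.character(ped$sire), ids)
  dam  <- match(as.character(ped$dam), ids)
  if (any(sire == seq_len(n), na.rm = TRUE) ||
      any(dam == seq_len(n), na.rm = TRUE)) {
    bad <- ids[which(sire == seq_len(n) | dam == seq_len(n))]
    stop("pedigree cycle: animal is its own parent: ",
         paste(stats::na.omit(bad), collapse = ", "))
  }
  ## Kahn's algorithm on parent -> offspring edges
  indeg <- integer(n)
  for (i in seq_len(n)) {
    indeg[i] <- sum(!is.na(sire[i]), !is.na(dam[i]))
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle detected involving animal(s): ",
         paste(ids[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  pos <- integer(n); pos[ord] <- seq_len(n)
  out <- list(ids = ids[ord],
              sire = ifelse(is.na(sire[ord]), NA_integer_, pos[sire[ord]]),
              dam  = ifelse(is.na(dam[ord]),  NA_integer_, pos[dam[ord]]),
              n = n)
  class(out) <- "orped"
  out
}

#' @export
print.orped <- function(x, ...) {
  cat("Ordered pedigree:", x$n, "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  invisible(x)
}

#' Inbreeding coefficients from an ordered pedigree
#'
#' Computes Wright's inbreeding coefficient F for every animal, either by
#' the tabular method (builds A, reads `diag(A) - 1`) or by the
#' Meuwissen-Luo algorithm, which avoids materializing A and scales to
#' large pedigrees.  The two must agree exactly; `method = "auto"` picks
#' tabular for up to 2000 animals and Meuwissen-Luo beyond.
#'
#' @param op An `orped` from [order_pedigree()].
#' @param method `"auto"`, `"tabular"` or `"meuwissen-luo"`.
#' @return Named numeric vector of F in `[0, 1)`, in pedigree order.
#' @export
inbreeding <- function(op, method = c("auto", "tabular", "meuwissen-luo")) {
  stopifnot(inherits(op, "orped"))
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (op$n <= 2000L) "tabular" else "meuwissen-luo"
  }
  F <- if (method == "tabular") {
    diag(a_matrix(op)) - 1
  } else {
    inbreeding_ml(op)
  }
  names(F) <- op$ids
  F
}

## Meuwissen & Luo (1992): A_ii = sum_j L_ij^2 d_j via ancestor traversal.
inbreeding_ml <- function(op) {
  n <- op$n
  F <- numeric(n)
  d <- numeric(n)   # Mendelian-sampling variance of each animal
  for (i in seq_len(n)) {
    s <- op$sire[i]; dd <- op$dam[i]
    d[i] <- if (!is.na(s) && !is.na(dd)) {
      0.5 - 0.25 * (F[s] + F[dd])
    } else if (!is.na(s)) {
      0.75 - 0.25 * F[s]
    } else if (!is.na(dd)) {
      0.75 - 0.25 * F[dd]
    } else 1
    if (is.na(s) || is.na(dd)) {
      F[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * d[j]
      sj <- op$sire[j]; dj <- op$dam[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * L[j]
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  F
}

relmat <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  structure(values, ids = ids, kind = kind, class = c("relmat", "matrix"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat kind=%s, %d x %d>\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Numerator relationship matrix A (tabular method)
#'
#' Builds the pedigree-based additive relationship matrix by the tabular
#' recursion a(i,j) = (a(j,s_i) + a(j,d_i))/2, a(i,i) = 1 + F_i, with
#' unknown parents treated as unrelated founders.  Dense storage; intended
#' for desk-scale pedigrees (up to roughly 10^4 animals).
#'
#' @inheritParams inbreeding
#' @return A `relmat` of kind `"A"` with ids in pedigree order.
#' @export
a_matrix <- function(op) {
  stopifnot(inherits(op, "orped"))
  n <- op$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- op$sire[i]; d <- op$dam[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s, drop = TRUE] else numeric(i - 1L)
      ad_ <- if (!is.na(d)) A[j, d, drop = TRUE] else numeric(i - 1L)
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + 0.5 * asd
  }
  relmat(A, op$ids, "A")
}

#' Inverse of A by Henderson's rules
#'
#' Builds A-inverse directly from pedigree structure, with
#' Mendelian-sampling variances adjusted for parental inbreeding
#' (0.5 - 0.25(F_s + F_d) for two known parents, 0.75 - 0.25 F_p for one,
#' 1 for founders).
#'
#' @inheritParams inbreeding
#' @param F Optional precomputed inbreeding coefficients in pedigree
#'   order; computed via [inbreeding()] when `NULL`.
#' @return A `relmat` of kind `"A_inverse"`.
#' @export
a_inverse <- function(op, F = NULL) {
  stopifnot(inherits(op, "orped"))
  if (is.null(F)) F <- inbreeding(op)
  n <- op$n
  Ai <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- op$sire[i]; d <- op$dam[i]
    m <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (F[s] + F[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * F[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * F[d]
    } else 1
    if (m <= 0) stop("non-positive Mendelian-sampling variance at animal ",
                     op$ids[i])
    al <- 1 / m
    Ai[i, i] <- Ai[i, i] + al
    par <- c(s, d)
    par <- par[!is.na(par)]
    for (p in par) {
      Ai[i, p] <- Ai[i, p] - al / 2
      Ai[p, i] <- Ai[p, i] - al / 2
    }
    for (p in par) for (q in par) {
      Ai[p, q] <- Ai[p, q] + al / 4
    }
  }
  relmat(Ai, op$ids, "A_inverse")
}

#' Genotyped-subset relationship matrix A22 and its inverse
#'
#' Extracts the principal submatrix of A for the genotyped animals and
#' inverts it densely.
#'
#' @param A A `relmat` of kind `"A"`.
#' @param genotyped_ids Character vector of genotyped animal ids; must
#'   all be present in `A`.
#' @return List with `A22` and `A22_inverse`, both `relmat`s indexed by
#'   `genotyped_ids` (in the order given).
#' @export
subset_a22 <- function(A, genotyped_ids) {
  stopifnot(inherits(A, "relmat"), attr(A, "kind") == "A")
  ids <- attr(A, "ids")
  miss <- setdiff(genotyped_ids, ids)
  if (length(miss)) {
    stop("genotyped id(s) not in pedigree: ", paste(miss, collapse = ", "))
  }
  idx <- match(genotyped_ids, ids)
  A22 <- unclass(A)[idx, idx, drop = FALSE]
  A22i <- chol2inv(chol(A22))
  list(A22 = relmat(A22, genotyped_ids, "A22"),
       A22_inverse = relmat(A22i, genotyped_ids, "A22_inverse"))
}

## sparse A-inverse (Henderson's rules) as a dsCMatrix; same numbers as
## a_inverse() but stored sparse for large mixed-model equations
a_inverse_sparse <- function(op, F = NULL) {
  stopifnot(inherits(op, "orped"))
  if (is.null(F)) F <- inbreeding(op)
  n <- op$n
  k <- 0L
  tri <- matrix(0, 9L * n, 3L)
  for (i in seq_len(n)) {
    s <- op$sire[i]; d <- op$dam[i]
    m <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (F[s] + F[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * F[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * F[d]
    } else 1
    al <- 1 / m
    k <- k + 1L; tri[k, ] <- c(i, i, al)
    par <- c(s, d); par <- par[!is.na(par)]
    for (p in par) {
      k <- k + 1L; tri[k, ] <- c(i, p, -al / 2)
      k <- k + 1L; tri[k, ] <- c(p, i, -al / 2)
    }
    for (p in par) for (q in par) {
      k <- k + 1L; tri[k, ] <- c(p, q, al / 4)
    }
  }
  tri <- tri[seq_len(k), , drop = FALSE]
  out <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                              dims = c(n, n),
                              dimnames = list(op$ids, op$ids))
  Matrix::forceSymmetric(out)
}

## restrict an ordered pedigree to a set of animals plus all their
## ancestors (relationships among the subset are unchanged)
prune_to_ancestors <- function(op, ids) {
  keep <- logical(op$n)
  keep[match(ids, op$ids)] <- TRUE
  for (i in rev(seq_len(op$n))) {
    if (keep[i]) {
      for (p in c(op$sire[i], op$dam[i])) if (!is.na(p)) keep[p] <- TRUE
    }
  }
  idx <- which(keep)
  pos <- integer(op$n); pos[idx] <- seq_along(idx)
  out <- list(ids = op$ids[idx],
              sire = ifelse(is.na(op$sire[idx]), NA_integer_,
                            pos[op$sire[idx]]),
              dam = ifelse(is.na(op$dam[idx]), NA_integer_,
                           pos[op$dam[idx]]),
              n = length(idx))
  class(out) <- "orped"
  out
}

## A22 and its inverse computed on the ancestor-pruned pedigree only;
## equal to subset_a22(a_matrix(op), ids) but far cheaper when most
## animals are phenotyped descendants of the genotyped set
a22_direct <- function(op, ids) {
  sub <- prune_to_ancestors(op, ids)
  subset_a22(a_matrix(sub), ids)
}
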