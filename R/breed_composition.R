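#' Breed composition of a composite animal
#'
#' Constructor for NABC breed-composition vectors.  The four biological
#' types of the Montana Tropical Composite program are N (Zebu), A
#' (adapted Taurine), B (British Taurine) and C (Continental European
#' Taurine); the fractions of an animal must sum to one.
#'
#' @param n,a,b,c Fractions in `[0, 1]` of each biological type.
#' @return Numeric vector of class `breed_comp` with names N, A, B, C.
#' @export
breed_comp <- function(n, a, b, c) {
  v <- c(N = n, A = a, B = b, C = c)
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("breed fractions must lie in [0, 1]")
  }
  if (abs(sum(v) - 1) > 1e-9) {
    stop("breed fractions must sum to 1 (got ", format(sum(v)), ")")
  }
  structure(v, class = "breed_comp")
}

#' Parse a four-digit breed-composition code
#'
#' Herdbook composition codes such as "4444" encode the NABC fractions in
#' sixteenths, one digit group per biological type in N, A, B, C order:
#' "4444" is (1/4, 1/4, 1/4, 1/4) and "4480" is (1/4, 1/4, 1/2, 0).
#' Digits must sum to the base (16 by default).
#'
#' @param code Character scalar of four digit groups.
#' @param base Total number of parts the digits must sum to (default 16,
#'   i.e. sixteenths).
#' @return A [breed_comp()].
#' @examples
#' parse_composition_code("4444")
#' parse_composition_code("4480")
#' @export
parse_composition_code <- function(code, base = 16L) {
  code <- as.character(code)
  if (length(code) != 1L || is.na(code) || !grepl("^[0-9]+$", code)) {
    stop("composition code must be a string of digits, got: ", code)
  }
  ## single digits unless the code is longer than 4 characters, in which
  ## case split evenly into 4 groups
  nc <- nchar(code)
  if (nc %% 4L != 0L) stop("composition code length must be a multiple of 4: ", code)
  w <- nc %/% 4L
  digits <- vapply(seq_len(4L), function(i) {
    as.integer(substr(code, (i - 1L) * w + 1L, i * w))
  }, integer(1))
  if (sum(digits) != base) {
    stop("composition code '", code, "' digits sum to ", sum(digits),
         ", expected ", base)
  }
  breed_comp(digits[1] / base, digits[2] / base, digits[3] / base,
             digits[4] / base)
}

#' Format a breed composition back to its code
#'
#' Inverse of [parse_composition_code()] for compositions expressible in
#' the given base.
#'
#' @param comp A `breed_comp`.
#' @inheritParams parse_composition_code
#' @return Character code.
#' @export
format_composition_code <- function(comp, base = 16L) {
  d <- round(unclass(comp) * base)
  if (max(abs(d - unclass(comp) * base)) > 1e-6) {
    stop("composition not expressible in base ", base)
  }
  paste(d, collapse = "")
}

#' Direct heterozygosity coefficient H_D
#'
#' Expected fraction of loci at which an offspring carries alleles from
#' two different biological types, `H_D = 1 - sum_i S_i * D_i`, where
#' `S_i` and `D_i` are the sire's and dam's fractions of biological type
#' i.  Used as the heterosis covariate in the evaluation model.
#'
#' @param sire,dam `breed_comp` objects (or plain numeric 4-vectors
#'   summing to one).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' nn <- breed_comp(1, 0, 0, 0); aa <- breed_comp(0, 1, 0, 0)
#' heterozygosity_coefficient(nn, aa)  # 1: fully complementary
#' heterozygosity_coefficient(nn, nn)  # 0: identical purebreds
#' @export
heterozygosity_coefficient <- function(sire, dam) {
  s <- unclass(sire); d <- unclass(dam)
  stopifnot(length(s) == 4L, length(d) == 4L)
  hd <- 1 - sum(s * d)
  min(max(hd, 0), 1)
}

#' Montana Tropical Composite eligibility
#'
#' Applies the Montana program rules: at least three breeds in the
#' genetic composition, a minimum of 12.5% adapted Taurine (A) and 25%
#' for N and A together, and maxima of 37.5% N, 87.5% A and 75% for each
#' of B and C.
#'
#' @param comp A `breed_comp`.
#' @param n_breeds Number of distinct breeds contributing to the animal.
#'   When `NULL`, the number of nonzero NABC groups is used as a proxy
#'   (each biological type counted as one breed).
#' @return List with `eligible` (logical), `n_breeds` used, and `failed`
#'   (character vector of violated rules, empty when eligible).
#' @export
classify_montana <- function(comp, n_breeds = NULL) {
  v <- unclass(comp)
  proxy <- is.null(n_breeds)
  if (proxy) n_breeds <- sum(v > 1e-12)
  failed <- character(0)
  if (n_breeds < 3) failed <- c(failed, "fewer than 3 breeds")
  if (v["A"] < 0.125 - 1e-12) failed <- c(failed, "A below 12.5%")
  if (v["N"] + v["A"] < 0.25 - 1e-12) failed <- c(failed, "N+A below 25%")
  if (v["N"] > 0.375 + 1e-12) failed <- c(failed, "N above 37.5%")
  if (v["A"] > 0.875 + 1e-12) failed <- c(failed, "A above 87.5%")
  if (v["B"] > 0.75 + 1e-12) failed <- c(failed, "B above 75%")
  if (v["C"] > 0.75 + 1e-12) failed <- c(failed, "C above 75%")
  list(eligible = length(failed) == 0L, n_breeds = n_breeds,
       breed_count_proxy = proxy, failed = failed)
}
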