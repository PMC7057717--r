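## shared fixture builders; everything is generated in code

## random acyclic pedigree: nf founders, rest with parents among earlier
## animals (possibly one unknown)
random_pedigree <- function(n, nf = max(3L, n %/% 10L),
                            p_unknown = 0.1) {
  an <- sprintf("a%03d", seq_len(n))
  s <- d <- rep(NA_character_, n)
  for (i in (nf + 1L):n) {
    s[i] <- if (stats::runif(1) < p_unknown) NA else an[sample(i - 1L, 1)]
    d[i] <- if (stats::runif(1) < p_unknown) NA else an[sample(i - 1L, 1)]
  }
  data.frame(animal = an, sire = s, dam = d, stringsAsFactors = FALSE)
}

## independent oracle: additive relationship by recursive coancestry
## f(i,j) = kinship; a(i,j) = 2 f(i,j).  Memoized top-down recursion,
## entirely separate from the tabular code path.
coancestry_oracle <- function(op) {
  n <- op$n
  f <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (!is.na(f[i, j])) return(f[i, j])
    v <- if (i == j) {
      s <- op$sire[i]; d <- op$dam[i]
      0.5 * (1 + if (!is.na(s) && !is.na(d)) kin(s, d) else 0)
    } else {
      a <- max(i, j); b <- min(i, j)   # a is younger (later in order)
      s <- op$sire[a]; d <- op$dam[a]
      0.5 * ((if (!is.na(s)) kin(s, b) else 0) +
             (if (!is.na(d)) kin(d, b) else 0))
    }
    f[i, j] <<- v
    f[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) kin(i, j)
  2 * f
}

## small genotype fixture with given dimensions and frequency range
random_genomat <- function(n, m, n_chrom = 2, p_range = c(0.2, 0.8)) {
  p <- stats::runif(m, p_range[1], p_range[2])
  geno <- sapply(p, function(pp) {
    g <- stats::rbinom(n, 2, pp)
    while (min(g) == max(g)) g <- stats::rbinom(n, 2, pp)
    g
  })
  rownames(geno) <- sprintf("an%03d", seq_len(n))
  chrom <- sort(rep(seq_len(n_chrom), length.out = m))
  pos <- unlist(lapply(table(chrom), function(k) {
    sort(sample(seq(1e6, 9e7), k))
  }), use.names = FALSE)
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                    chrom = chrom, pos = pos)
  genotype_matrix(geno, map)
}

## phenotype rows with explicit factor columns
raw_phenotypes <- function(n, traits = "T1", n_farms = 2) {
  expand <- expand.grid(animal = sprintf("an%03d", seq_len(n)),
                        trait = traits, stringsAsFactors = FALSE)
  data.frame(expand,
             value = stats::rnorm(nrow(expand), 50, 5),
             farm = sample(sprintf("f%d", seq_len(n_farms)), nrow(expand),
                           replace = TRUE),
             birth_year = sample(2010:2011, nrow(expand), replace = TRUE),
             season = sample(c("wet", "dry"), nrow(expand), replace = TRUE),
             sex = sample(c("M", "F"), nrow(expand), replace = TRUE),
             mgmt_group = "mg1",
             age_days = round(stats::rnorm(nrow(expand), 580, 75)),
             hd = stats::runif(nrow(expand)),
             stringsAsFactors = FALSE)
}
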