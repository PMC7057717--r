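#' Simulation scenario for a composite-cattle dataset
#'
#' Bundles every tunable of the synthetic-population generator.  The
#' defaults emulate a Montana-Tropical-style composite: four founder
#' breeds (N, A, B, C) diverged at Fst 0.15, a crossing design that
#' produces fully eligible (1/4, 1/4, 1/4, 1/4) composites by
#' generation 2 and intercrosses them afterwards, ultrasound carcass
#' traits on the published scales (LMA 58.40 cm2, BFT 2.84 mm, RFT
#' 3.16 mm, MARB 3.29 score units; heritabilities 0.29/0.26/0.16/0.33),
#' scanning ages around 580 (SD 75) days, and a genotyped subset biased
#' toward sires.
#'
#' @param seed Integer seed (mandatory; all draws flow from it).
#' @param n_founders_per_breed Founders per breed (half male).
#' @param n_generations Generations after the founders (>= 2 reaches
#'   composite eligibility).
#' @param offspring_per_mating Offspring per mating pair; a vector is
#'   recycled over generations (last value reused beyond its length).
#' @param max_matings Cap on mating pairs per generation (vector
#'   recycled like `offspring_per_mating`; `Inf` = every available
#'   pair).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp Panel
#'   layout; 1 Morgan per 100 Mb.
#' @param divergence Between-breed allele-frequency Fst.
#' @param founder_history_generations Generations of random mating
#'   within each founder breed before the composite crossing begins.
#'   This equips founder haplotypes with the linkage disequilibrium a
#'   real breed carries, which is what makes window-based association
#'   mapping possible across families; 0 gives LD-free founders.
#' @param founder_history_size Effective size of the within-breed
#'   ancestral pool during those generations (defaults to the founder
#'   count).  Smaller values give stronger, longer-range breed LD, as
#'   in breeds with small effective population size.
#' @param traits,trait_means,trait_sds,h2 Trait names and scales.
#' @param rg Genetic correlation matrix between traits.
#' @param n_qtl Number of QTL per trait.
#' @param qtl_var_frac Per-QTL fraction of additive variance.
#' @param polygenic_panel_frac Fraction of the non-QTL additive
#'   variance carried by small effects at the (non-QTL) panel SNPs;
#'   the remainder is a pedigree polygenic term.  Real genetic
#'   backgrounds are genomic, so a pure pedigree residual (0) is
#'   pessimistic for marker-based analyses.
#' @param qtl_on_panel If `TRUE` (default) QTL are panel SNPs; if
#'   `FALSE`, hidden loci adjacent to panel SNPs in incomplete LD.
#' @param qtl_freq_band QTL are drawn among loci whose allele frequency
#'   lies in this band in every founder breed, so that causal variants
#'   segregate in the composite and are not distorted (excess
#'   heterozygosity, low MAF) by the crossing design.
#' @param qtl_ld_flip Allele flip probability linking a hidden QTL to
#'   its neighboring panel SNP in founders (smaller = tighter LD).
#' @param n_farms,n_seasons,n_mgmt Contemporary-group structure (plus
#'   birth year and sex).
#' @param cg_sd CG effect SD as a fraction of the trait SD.
#' @param age_mean,age_sd Age at scanning (days).
#' @param b_age Per-trait linear age slopes (trait units per day).
#' @param b_het Per-trait heterosis effects (trait units per unit H_D).
#' @param genotyping_fraction Fraction of eligible animals genotyped;
#'   sires are sampled preferentially.
#' @param genotyped_generations Generations eligible for genotyping
#'   (`NULL` = every generation from 2 on).  Restricting genotyping to
#'   parent generations with many phenotyped progeny mimics a
#'   progeny-testing scheme and raises GEBV accuracy.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(seed,
                         n_founders_per_breed = 40,
                         n_generations = 3,
                         offspring_per_mating = 4,
                         max_matings = Inf,
                         n_chromosomes = 10,
                         snps_per_chromosome = 100,
                         chromosome_length_bp = 1e8,
                         divergence = 0.15,
                         founder_history_generations = 8,
                         founder_history_size = NULL,
                         traits = c("LMA", "BFT", "RFT", "MARB"),
                         trait_means = c(58.40, 2.84, 3.16, 3.29),
                         trait_sds = c(12.79, 0.71, 1.37, 1.20),
                         h2 = c(0.29, 0.26, 0.16, 0.33),
                         rg = NULL,
                         n_qtl = 5,
                         qtl_var_frac = rep(0.04, n_qtl),
                         polygenic_panel_frac = 0.5,
                         qtl_on_panel = TRUE,
                         qtl_ld_flip = 0.05,
                         qtl_freq_band = c(0.15, 0.85),
                         n_farms = 3, n_seasons = 2, n_mgmt = 1,
                         cg_sd = 0.5,
                         age_mean = 580.27, age_sd = 75.08,
                         b_age = NULL, b_het = NULL,
                         genotyping_fraction = 0.6,
                         genotyped_generations = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  nt <- length(traits)
  if (is.null(rg)) {
    rg <- diag(nt)
    if (nt == 4) {
      ## genetic correlations typical of ultrasound carcass traits
      rg[1, 2] <- rg[2, 1] <- 0.46
      rg[1, 3] <- rg[3, 1] <- 0.29
      rg[1, 4] <- rg[4, 1] <- 0.27
      rg[2, 3] <- rg[3, 2] <- 0.97
      rg[2, 4] <- rg[4, 2] <- 0.50
      rg[3, 4] <- rg[4, 3] <- 0.47
    }
  }
  if (is.null(b_age)) b_age <- 0.005 * trait_sds  # per-day growth trend
  if (is.null(b_het)) b_het <- 0.3 * trait_sds    # heterosis at H_D = 1
  stopifnot(all(h2 > 0 & h2 < 1), sum(qtl_var_frac) < 1,
            length(trait_means) == nt, length(trait_sds) == nt,
            all(dim(rg) == nt))
  structure(as.list(environment()), class = "sim_scenario")
}

## Balding-Nichols founder frequencies + binomial haplotypes
#' Simulate purebred founder haplotypes and compositions
#'
#' Draws a common allele frequency per locus, diverges it per breed
#' under a Balding-Nichols model with the scenario's Fst, and samples
#' two haplotypes per founder.
#'
#' @param s A [sim_scenario()].
#' @param map Locus map (internal; built by
#'   [simulate_pedigree_and_genotypes()] when omitted).
#' @return List with `hap1`, `hap2` (founders x loci 0/1 matrices),
#'   `comp` (founders x 4 NABC fractions), `sex`, `breed`, `map`,
#'   `freq` (per-breed locus frequencies).
#' @export
simulate_founders <- function(s, map = NULL) {
  stopifnot(inherits(s, "sim_scenario"))
  if (is.null(map)) map <- build_locus_map(s)
  L <- nrow(map)
  p0 <- stats::runif(L, 0.1, 0.9)
  freq <- matrix(0, 4, L, dimnames = list(c("N", "A", "B", "C"), NULL))
  for (b in 1:4) {
    freq[b, ] <- if (s$divergence <= 0) p0 else {
      f <- s$divergence
      stats::rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
  }
  freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  nf <- s$n_founders_per_breed
  n <- 4 * nf
  breed <- rep(c("N", "A", "B", "C"), each = nf)
  hap1 <- matrix(0L, n, L)
  hap2 <- matrix(0L, n, L)
  for (b in 1:4) {
    rows <- which(breed == c("N", "A", "B", "C")[b])
    pb <- freq[b, ]
    hap1[rows, ] <- matrix(stats::rbinom(length(rows) * L, 1L,
                                         rep(pb, each = length(rows))),
                           length(rows), L)
    hap2[rows, ] <- matrix(stats::rbinom(length(rows) * L, 1L,
                                         rep(pb, each = length(rows))),
                           length(rows), L)
  }
  ## within-breed random mating builds up breed linkage disequilibrium;
  ## the ancestral pool may be smaller than the founder count (small
  ## effective population size), in which case the founders are drawn
  ## as offspring of the final pool generation
  if (s$founder_history_generations > 0) {
    chrom_index <- split(seq_len(nrow(map)), map$chrom)
    chrom_pos <- split(map$pos, map$chrom)
    pool_n <- if (is.null(s$founder_history_size)) nf else
      min(s$founder_history_size, nf)
    for (b in 1:4) {
      rows <- which(breed == c("N", "A", "B", "C")[b])
      keep <- rows[seq_len(pool_n)]
      h1 <- hap1[keep, , drop = FALSE]
      h2 <- hap2[keep, , drop = FALSE]
      for (g in seq_len(s$founder_history_generations)) {
        n1 <- h1; n2 <- h2
        for (i in seq_len(pool_n)) {
          par <- sample(pool_n, 2)
          n1[i, ] <- make_gamete(h1[par[1], ], h2[par[1], ], chrom_index,
                                 chrom_pos, s$chromosome_length_bp)
          n2[i, ] <- make_gamete(h1[par[2], ], h2[par[2], ], chrom_index,
                                 chrom_pos, s$chromosome_length_bp)
        }
        h1 <- n1; h2 <- n2
      }
      for (i in seq_along(rows)) {
        par <- sample(pool_n, 2)
        hap1[rows[i], ] <- make_gamete(h1[par[1], ], h2[par[1], ],
                                       chrom_index, chrom_pos,
                                       s$chromosome_length_bp)
        hap2[rows[i], ] <- make_gamete(h1[par[2], ], h2[par[2], ],
                                       chrom_index, chrom_pos,
                                       s$chromosome_length_bp)
      }
    }
  }
  comp <- matrix(0, n, 4, dimnames = list(NULL, c("N", "A", "B", "C")))
  comp[cbind(seq_len(n), match(breed, c("N", "A", "B", "C")))] <- 1
  sex <- rep(rep(c("M", "F"), length.out = nf), 4)
  list(hap1 = hap1, hap2 = hap2, comp = comp, sex = sex, breed = breed,
       map = map, freq = freq)
}

## locus map: randomly placed panel SNPs; QTL are selected later, once
## founder frequencies are known
build_locus_map <- function(s) {
  maps <- lapply(seq_len(s$n_chromosomes), function(ch) {
    pos <- sort(sample.int(s$chromosome_length_bp, s$snps_per_chromosome))
    data.frame(snp_id = sprintf("snp_%d_%d", ch, seq_along(pos)),
               chrom = ch, pos = pos, is_qtl = FALSE,
               ld_partner = NA_integer_, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  map
}

## pick QTL among loci common in every founder breed (segregate in the
## composite, low between-breed differentiation so crossing does not
## distort their Hardy-Weinberg heterozygosity), spread over chromosomes
select_qtl <- function(s, map, freq) {
  lo <- apply(freq, 2, min)
  hi <- apply(freq, 2, max)
  cand <- which(lo >= s$qtl_freq_band[1] & hi <= s$qtl_freq_band[2])
  if (length(cand) < s$n_qtl) stop("too few common loci to place QTL; ",
                                   "widen qtl_freq_band")
  by_chrom <- split(cand, map$chrom[cand])
  first <- vapply(by_chrom, function(j) if (length(j) == 1) j else
    sample(j, 1), integer(1))
  if (s$n_qtl <= length(first)) {
    sort(sample(first, s$n_qtl))
  } else {
    sort(c(first, sample(setdiff(cand, first), s$n_qtl - length(first))))
  }
}

## one recombinant gamete from a parent's two haplotypes
make_gamete <- function(h1, h2, chrom_index, chrom_pos, chrom_len) {
  out <- integer(length(h1))
  for (ci in seq_along(chrom_index)) {
    jj <- chrom_index[[ci]]
    morgans <- chrom_len / 1e8  # 1 Morgan per 100 Mb
    nx <- stats::rpois(1, morgans)
    phase0 <- stats::rbinom(1, 1, 0.5)
    if (nx == 0) {
      out[jj] <- if (phase0 == 0) h1[jj] else h2[jj]
    } else {
      xpos <- sort(stats::runif(nx, 0, chrom_len))
      seg <- findInterval(chrom_pos[[ci]], xpos)
      phase <- (phase0 + seg) %% 2
      out[jj] <- ifelse(phase == 0, h1[jj], h2[jj])
    }
  }
  out
}

#' Simulate the composite pedigree with gene dropping
#'
#' Crossing design: generation 1 mates N x A and B x C founders,
#' generation 2 mates the two F1 pools into (1/4, 1/4, 1/4, 1/4)
#' composites, and later generations intercross composites.  Gametes
#' recombine with Poisson crossover counts at 1 Morgan / 100 Mb.
#' Offspring breed composition is the mean of the parents'; a
#' genotyped subset (sires preferentially) is drawn from generations
#' >= 2.
#'
#' @param s A [sim_scenario()].
#' @return List of class `sim_population`: `ped` (pedigree
#'   `data.frame` with factors and composition codes), `hap1`, `hap2`,
#'   `map`, `comp`, `hd` (per-animal heterozygosity coefficient, `NA`
#'   founders), `sex`, `generation`, `genotyped` (ids),
#'   `genotypes` (a [genotype_matrix()] of panel SNPs).
#' @export
simulate_pedigree_and_genotypes <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  set.seed(s$seed)
  map <- build_locus_map(s)
  fo <- simulate_founders(s, map)
  qtl_snp <- select_qtl(s, map, fo$freq)
  if (s$qtl_on_panel) {
    map$is_qtl[qtl_snp] <- TRUE
  } else {
    ## hidden QTL: extra loci 1 bp past a panel SNP whose founder allele
    ## they copy with occasional flips (incomplete LD)
    extra <- map[qtl_snp, , drop = FALSE]
    extra$snp_id <- sprintf("qtl_%d", seq_along(qtl_snp))
    extra$pos <- extra$pos + 1L
    extra$is_qtl <- TRUE
    extra$ld_partner <- qtl_snp
    map <- rbind(map, extra)
    rownames(map) <- NULL
    nf4 <- nrow(fo$hap1)
    q1 <- q2 <- matrix(0L, nf4, length(qtl_snp))
    for (j in seq_along(qtl_snp)) {
      nb <- qtl_snp[j]
      fl1 <- stats::rbinom(nf4, 1L, s$qtl_ld_flip)
      fl2 <- stats::rbinom(nf4, 1L, s$qtl_ld_flip)
      q1[, j] <- ifelse(fl1 == 1L, 1L - fo$hap1[, nb], fo$hap1[, nb])
      q2[, j] <- ifelse(fl2 == 1L, 1L - fo$hap2[, nb], fo$hap2[, nb])
    }
    fo$hap1 <- cbind(fo$hap1, q1)
    fo$hap2 <- cbind(fo$hap2, q2)
    ord <- order(map$chrom, map$pos)
    newpos <- integer(nrow(map))
    newpos[ord] <- seq_len(nrow(map))
    map <- map[ord, , drop = FALSE]
    map$ld_partner <- ifelse(is.na(map$ld_partner), NA_integer_,
                             newpos[map$ld_partner])
    rownames(map) <- NULL
    fo$hap1 <- fo$hap1[, ord, drop = FALSE]
    fo$hap2 <- fo$hap2[, ord, drop = FALSE]
  }
  chrom_index <- split(seq_len(nrow(map)), map$chrom)
  chrom_pos <- split(map$pos, map$chrom)
  chrom_len <- s$chromosome_length_bp

  hap1 <- fo$hap1; hap2 <- fo$hap2
  comp <- fo$comp
  sex <- fo$sex
  gen <- rep(0L, nrow(hap1))
  sire <- rep(NA_integer_, nrow(hap1))
  dam <- rep(NA_integer_, nrow(hap1))
  hd <- rep(NA_real_, nrow(hap1))

  pair_up <- function(males, females, cap) {
    k <- min(length(males), length(females), cap)
    if (k == 0) stop("mating pool exhausted; enlarge the scenario")
    cbind(sample(males)[seq_len(k)], sample(females)[seq_len(k)])
  }
  gen_par <- function(par, g) par[min(g, length(par))]
  for (g in seq_len(s$n_generations)) {
    prev <- which(gen == g - 1L)
    cap <- gen_par(s$max_matings, g)
    opm <- gen_par(s$offspring_per_mating, g)
    if (g == 1L) {
      br <- fo$breed
      m1 <- pair_up(prev[br == "N" & sex[prev] == "M"],
                    prev[br == "A" & sex[prev] == "F"], cap)
      m2 <- pair_up(prev[br == "B" & sex[prev] == "M"],
                    prev[br == "C" & sex[prev] == "F"], cap)
      matings <- rbind(m1, m2)
    } else if (g == 2L) {
      na_pool <- which(gen == 1L & comp[, "N"] > 0)
      bc_pool <- which(gen == 1L & comp[, "B"] > 0)
      matings <- pair_up(na_pool[sex[na_pool] == "M"],
                         bc_pool[sex[bc_pool] == "F"], cap)
    } else {
      matings <- pair_up(prev[sex[prev] == "M"], prev[sex[prev] == "F"],
                         cap)
    }
    n_off <- nrow(matings) * opm
    off1 <- matrix(0L, n_off, nrow(map))
    off2 <- matrix(0L, n_off, nrow(map))
    off_comp <- matrix(0, n_off, 4, dimnames = list(NULL, colnames(comp)))
    off_sire <- integer(n_off); off_dam <- integer(n_off)
    off_hd <- numeric(n_off)
    r <- 0L
    for (mi in seq_len(nrow(matings))) {
      si <- matings[mi, 1]; di <- matings[mi, 2]
      for (o in seq_len(opm)) {
        r <- r + 1L
        off1[r, ] <- make_gamete(hap1[si, ], hap2[si, ], chrom_index,
                                 chrom_pos, chrom_len)
        off2[r, ] <- make_gamete(hap1[di, ], hap2[di, ], chrom_index,
                                 chrom_pos, chrom_len)
        off_comp[r, ] <- (comp[si, ] + comp[di, ]) / 2
        off_sire[r] <- si; off_dam[r] <- di
        off_hd[r] <- 1 - sum(comp[si, ] * comp[di, ])
      }
    }
    hap1 <- rbind(hap1, off1)
    hap2 <- rbind(hap2, off2)
    comp <- rbind(comp, off_comp)
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
    gen <- c(gen, rep(g, n_off))
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    hd <- c(hd, off_hd)
  }
  n <- nrow(hap1)
  ids <- sprintf("ID%04d", seq_len(n))
  code <- vapply(seq_len(n), function(i) {
    d16 <- comp[i, ] * 16
    if (max(abs(d16 - round(d16))) < 1e-9) {
      paste(round(d16), collapse = "")
    } else NA_character_
  }, character(1))
  ped <- data.frame(
    animal = ids,
    sire = ifelse(is.na(sire), NA_character_, ids[sire]),
    dam = ifelse(is.na(dam), NA_character_, ids[dam]),
    birth_year = 2008L + gen,
    farm = sample(sprintf("farm%d", seq_len(s$n_farms)), n, replace = TRUE),
    season = sample(sprintf("season%d", seq_len(s$n_seasons)), n,
                    replace = TRUE),
    sex = sex,
    mgmt_group = sample(sprintf("mg%d", seq_len(s$n_mgmt)), n,
                        replace = TRUE),
    composition_code = code,
    stringsAsFactors = FALSE)
  rownames(hap1) <- rownames(hap2) <- ids
  rownames(comp) <- ids

  ## genotyped subset (sires weighted 3:1)
  gg <- if (is.null(s$genotyped_generations)) {
    seq(2L, s$n_generations)
  } else s$genotyped_generations
  cand <- which(gen %in% gg)
  if (length(cand)) {
    is_parent <- seq_len(n) %in% c(sire, dam)
    wt <- ifelse(is_parent[cand], 3, 1)
    k <- max(1L, round(s$genotyping_fraction * length(cand)))
    geno_idx <- sort(sample(cand, k, prob = wt))
  } else geno_idx <- integer(0)
  panel <- which(!map$is_qtl | s$qtl_on_panel)
  geno <- (hap1 + hap2)[geno_idx, panel, drop = FALSE]
  gmap <- map[panel, c("snp_id", "chrom", "pos")]
  genotypes <- genotype_matrix(geno, gmap)

  structure(list(ped = ped, hap1 = hap1, hap2 = hap2, map = map,
                 comp = comp, hd = hd, sex = sex, generation = gen,
                 genotyped = ids[geno_idx], genotypes = genotypes),
            class = "sim_population")
}

#' Simulate phenotypes over a simulated population
#'
#' True breeding values combine QTL effects (each QTL scaled to its
#' target fraction of the additive variance for the first trait and
#' drawn with the scenario's genetic correlations across traits) and a
#' pedigree polygenic term descended by Mendelian sampling; the
#' polygenic term is rescaled so the realized TBV variance matches the
#' target additive variance.  Records follow
#' `y = mean + CG + b_age (age - mean age) + b_het (H_D - mean H_D) +
#' TBV + e` for animals of generation >= 1 (founders carry no H_D).
#'
#' @param s A [sim_scenario()].
#' @param pop A `sim_population` from
#'   [simulate_pedigree_and_genotypes()].
#' @return List: `phenotypes` (long `data.frame`: animal, trait,
#'   value, farm, birth_year, season, sex, mgmt_group, age_days, hd)
#'   and `truth` (`tbv` matrix, `qtl` table, `sigma2_a`, `sigma2_e`,
#'   `b_age`, `b_het`, `cg_effects`).
#' @export
simulate_phenotypes <- function(s, pop) {
  stopifnot(inherits(s, "sim_scenario"), inherits(pop, "sim_population"))
  nt <- length(s$traits)
  n <- nrow(pop$hap1)
  ids <- rownames(pop$hap1)
  sigma2_a <- s$h2 * s$trait_sds^2
  sigma2_e <- (1 - s$h2) * s$trait_sds^2
  if (sum(s$qtl_var_frac) >= 1) stop("QTL variance fractions must sum below 1")
  Lrg <- chol(s$rg)

  ## QTL component; effect sizes are calibrated on the composite
  ## generations (>= 2 when present) so each QTL explains its target
  ## fraction of additive variance in the population actually analyzed,
  ## not in the purebred founders
  qcol <- which(pop$map$is_qtl)
  if (length(qcol) != s$n_qtl) qcol <- qcol[seq_len(s$n_qtl)]
  Q <- (pop$hap1 + pop$hap2)[, qcol, drop = FALSE]
  ref <- if (any(pop$generation >= 2L)) which(pop$generation >= 2L)
         else seq_len(n)
  zz <- matrix(stats::rnorm(s$n_qtl * nt), s$n_qtl, nt) %*% Lrg
  beta <- matrix(0, s$n_qtl, nt)
  qtl_part <- matrix(0, n, nt)
  for (t in seq_len(nt)) {
    for (j in seq_len(s$n_qtl)) {
      sdq <- stats::sd(Q[ref, j])
      if (sdq < 1e-8) stop("monomorphic QTL in simulation; reseed or ",
                           "enlarge the founder pool")
      beta[j, t] <- sign(zz[j, t]) *
        sqrt(s$qtl_var_frac[j] * sigma2_a[t]) / sdq
    }
    qtl_part[, t] <- Q %*% beta[, t]
  }

  ## small genomic background effects at the non-QTL panel loci
  bg_part <- matrix(0, n, nt)
  if (s$polygenic_panel_frac > 0) {
    bcol <- setdiff(which(!pop$map$is_qtl), qcol)
    Mb <- pop$hap1[, bcol, drop = FALSE] + pop$hap2[, bcol, drop = FALSE]
    bsmall <- matrix(stats::rnorm(length(bcol) * nt), length(bcol),
                     nt) %*% Lrg
    bg_part <- Mb %*% bsmall
  }
  ## pedigree polygenic component
  op <- order_pedigree(pop$ped)
  Fi <- inbreeding(op)
  sigma_poly <- (1 - sum(s$qtl_var_frac)) * sigma2_a
  poly <- matrix(0, n, nt, dimnames = list(op$ids, s$traits))
  for (i in seq_len(op$n)) {
    si <- op$sire[i]; di <- op$dam[i]
    z <- as.numeric(stats::rnorm(nt) %*% Lrg)
    if (is.na(si) || is.na(di)) {
      poly[i, ] <- z * sqrt(sigma_poly)
    } else {
      msv <- 0.5 * (1 - (Fi[si] + Fi[di]) / 2)
      poly[i, ] <- (poly[si, ] + poly[di, ]) / 2 + z * sqrt(msv * sigma_poly)
    }
  }
  poly <- poly[ids, , drop = FALSE]
  tbv <- matrix(0, n, nt, dimnames = list(ids, s$traits))
  for (t in seq_len(nt)) {
    vq <- stats::var(qtl_part[, t])
    if (vq >= sigma2_a[t]) stop("QTL variance exceeds the additive target; ",
                                "infeasible partition")
    v_rest <- sigma2_a[t] - vq
    v_bg <- s$polygenic_panel_frac * v_rest
    bg_t <- if (v_bg > 0 && stats::var(bg_part[, t]) > 0) {
      (bg_part[, t] - mean(bg_part[, t])) *
        sqrt(v_bg / stats::var(bg_part[, t]))
    } else numeric(n)
    sc <- sqrt((v_rest - v_bg) / stats::var(poly[, t]))
    tbv[, t] <- qtl_part[, t] - mean(qtl_part[, t]) + bg_t +
      poly[, t] * sc
  }

  ## records for generation >= 1
  rec <- which(pop$generation >= 1L)
  age <- pmax(round(stats::rnorm(n, s$age_mean, s$age_sd)), 300)
  fac <- pop$ped[, c("farm", "birth_year", "season", "sex", "mgmt_group")]
  cg_key <- do.call(paste, c(fac, sep = ":"))
  cgs <- unique(cg_key[rec])
  rows <- vector("list", nt)
  cg_eff <- matrix(stats::rnorm(length(cgs) * nt), length(cgs), nt,
                   dimnames = list(cgs, s$traits))
  for (t in seq_len(nt)) {
    cg_eff[, t] <- cg_eff[, t] * s$cg_sd * s$trait_sds[t]
    e <- stats::rnorm(length(rec), 0, sqrt(sigma2_e[t]))
    y <- s$trait_means[t] + cg_eff[cg_key[rec], t] +
      s$b_age[t] * (age[rec] - mean(age[rec])) +
      s$b_het[t] * (pop$hd[rec] - mean(pop$hd[rec])) +
      tbv[rec, t] + e
    rows[[t]] <- data.frame(animal = ids[rec], trait = s$traits[t],
                            value = y, fac[rec, , drop = FALSE],
                            age_days = age[rec], hd = pop$hd[rec],
                            stringsAsFactors = FALSE)
  }
  phe <- do.call(rbind, rows)
  rownames(phe) <- NULL
  qtl <- data.frame(pop$map[qcol, c("snp_id", "chrom", "pos")],
                    beta, check.names = FALSE)
  names(qtl)[4:(3 + nt)] <- paste0("beta_", s$traits)
  list(phenotypes = phe,
       truth = list(tbv = tbv, qtl = qtl, sigma2_a = sigma2_a,
                    sigma2_e = sigma2_e, b_age = s$b_age,
                    b_het = s$b_het, cg_effects = cg_eff))
}

#' Simulate a complete composite-cattle dataset
#'
#' Convenience wrapper: founders, pedigree + genotypes, phenotypes and
#' the truth record in one call.
#'
#' @param s A [sim_scenario()].
#' @return List of class `sim_dataset` with `ped`, `genotypes`,
#'   `phenotypes`, `comp`, `hd`, `truth`, `population`, `scenario`.
#' @export
simulate_dataset <- function(s) {
  pop <- simulate_pedigree_and_genotypes(s)
  sim <- simulate_phenotypes(s, pop)
  structure(list(ped = pop$ped, genotypes = pop$genotypes,
                 phenotypes = sim$phenotypes, comp = pop$comp,
                 hd = pop$hd, truth = sim$truth, population = pop,
                 scenario = s),
            class = "sim_dataset")
}

#' Plant quality-control defects into a clean dataset
#'
#' Injects exactly the requested numbers of low-MAF SNPs, low-call-rate
#' SNPs, Hardy-Weinberg-deviant SNPs, low-call-rate animals, phenotype
#' outliers and sub-5-record contemporary groups, so that the QC
#' filters can be verified to remove exactly the planted records.
#'
#' @param d A `sim_dataset`.
#' @param n_low_maf,n_low_callrate_snp,n_hwe,n_low_callrate_animal,
#'   n_outlier,n_small_cg Counts of each defect (default 0).
#' @return The modified `sim_dataset`; attribute `defect_manifest`
#'   lists what was planted where.
#' @export
plant_defects <- function(d, n_low_maf = 0, n_low_callrate_snp = 0,
                          n_hwe = 0, n_low_callrate_animal = 0,
                          n_outlier = 0, n_small_cg = 0) {
  stopifnot(inherits(d, "sim_dataset"))
  geno <- d$genotypes$geno
  map <- d$genotypes$map
  n <- nrow(geno); m <- ncol(geno)
  manifest <- list()
  st <- snp_stats(geno)
  clean <- which(st$maf >= 0.10 & st$callrate == 1 &
                 abs(st$obs_het - st$exp_het) <= 0.10)
  need <- n_low_maf + n_low_callrate_snp + n_hwe
  if (need > length(clean)) stop("not enough clean SNPs to plant defects")
  pick <- sample(clean, need)
  take <- function(k) {
    out <- pick[seq_len(k)]
    pick <<- pick[-seq_len(k)]
    out
  }
  if (n_low_maf > 0) {
    cols <- take(n_low_maf)
    for (j in cols) {
      g <- stats::rbinom(n, 2, 0.02)
      if (sum(g) == 0) g[sample(n, 1)] <- 1L  # keep polymorphic, MAF << 0.05
      geno[, j] <- g
    }
    manifest$low_maf <- map$snp_id[cols]
  }
  if (n_low_callrate_snp > 0) {
    cols <- take(n_low_callrate_snp)
    k <- ceiling(0.15 * n)
    for (j in cols) geno[sample(n, k), j] <- NA
    manifest$low_callrate_snp <- map$snp_id[cols]
  }
  if (n_hwe > 0) {
    cols <- take(n_hwe)
    for (j in cols) geno[, j] <- 1L  # all heterozygous: dev = 0.5
    manifest$hwe <- map$snp_id[cols]
  }
  if (n_low_callrate_animal > 0) {
    if (n < 20) stop("need at least 20 genotyped animals to plant ",
                     "animal call-rate defects safely")
    k <- ceiling(0.15 * m)
    if (n_low_callrate_animal * k > m) {
      stop("too many animal call-rate defects for disjoint SNP sets")
    }
    rows <- sample(n, n_low_callrate_animal)
    cols_all <- sample(m, n_low_callrate_animal * k)
    for (i in seq_along(rows)) {
      geno[rows[i], cols_all[(i - 1) * k + seq_len(k)]] <- NA
    }
    manifest$low_callrate_animal <- rownames(geno)[rows]
  }
  phe <- d$phenotypes
  if (n_outlier > 0) {
    cg1 <- build_contemporary_groups(phe)
    key <- interaction(cg1$cg, cg1$trait, drop = TRUE)
    tabs <- table(key)
    big <- names(tabs)[tabs >= 20]
    if (length(big) < n_outlier) {
      stop("not enough contemporary-group cells with >= 20 records to ",
           "plant outliers")
    }
    cells <- sample(big, n_outlier)
    planted <- character(0)
    for (cell in cells) {
      ridx <- which(key == cell)
      tgt <- sample(ridx, 1)
      others <- setdiff(ridx, tgt)
      mu0 <- mean(cg1$value[others]); s0 <- stats::sd(cg1$value[others])
      nn <- length(ridx)
      ## choose c so that the planted value exceeds 3.5 SD of the cell
      ## with itself included
      zfun <- function(cc) {
        v <- mu0 + cc * s0
        vals <- c(cg1$value[others], v)
        abs(v - mean(vals)) / stats::sd(vals) - 3.8
      }
      cc <- stats::uniroot(zfun, c(3.5, 1e4))$root
      phe$value[phe$animal == cg1$animal[tgt] &
                phe$trait == cg1$trait[tgt]] <- mu0 + cc * s0
      planted <- c(planted, paste(cg1$animal[tgt], cg1$trait[tgt], sep = "/"))
    }
    manifest$outliers <- planted
  }
  if (n_small_cg > 0) {
    cg1 <- build_contemporary_groups(phe)
    tabs <- table(cg1$cg[!duplicated(cg1$animal)])
    big <- names(tabs)[tabs >= 13]
    if (length(big) < n_small_cg) {
      stop("not enough large contemporary groups to split off small ones")
    }
    groups <- sample(big, n_small_cg)
    made <- character(0)
    for (gi in seq_along(groups)) {
      an <- unique(cg1$animal[cg1$cg == groups[gi]])
      mv <- sample(an, 4)
      newmg <- sprintf("mg_planted%d", gi)
      phe$mgmt_group[phe$animal %in% mv] <- newmg
      made <- c(made, newmg)
    }
    manifest$small_cg <- made
  }
  d$genotypes <- genotype_matrix(geno, map)
  d$phenotypes <- phe
  attr(d, "defect_manifest") <- manifest
  d
}

#' Simulate a half-sib design for REML calibration
#'
#' Balanced paternal half-sib families with known heritabilities and,
#' for two or more traits, known genetic and residual correlations.
#' Every progeny carries one record per trait; dams are unknown and
#' unrelated.  This is the standard design for checking that REML
#' recovers the variance components it was given.
#'
#' @param n_sires,progeny_per_sire Family structure.
#' @param h2 Per-trait heritabilities.
#' @param rg,re Genetic and residual correlation matrices (identity
#'   default).
#' @param var_p Per-trait phenotypic variances.
#' @param traits Trait names.
#' @param n_cg Number of (random, balanced) contemporary groups.
#' @return List: `ped` (pedigree `data.frame`), `phe` (long phenotype
#'   table with constant age and hd), `truth` (`sigma2_a`, `sigma2_e`,
#'   `rg`, `re`, `tbv`).
#' @export
simulate_halfsib <- function(n_sires = 50, progeny_per_sire = 20,
                             h2 = 0.3, rg = NULL, re = NULL,
                             var_p = rep(1, length(h2)),
                             traits = paste0("T", seq_along(h2)),
                             n_cg = 5) {
  nt <- length(h2)
  if (is.null(rg)) rg <- diag(nt)
  if (is.null(re)) re <- diag(nt)
  s2a <- h2 * var_p
  s2e <- (1 - h2) * var_p
  n <- n_sires * progeny_per_sire
  sid <- sprintf("S%03d", seq_len(n_sires))
  pid <- sprintf("P%05d", seq_len(n))
  ped <- data.frame(animal = c(sid, pid),
                    sire = c(rep(NA, n_sires), rep(sid, each = progeny_per_sire)),
                    dam = NA_character_, stringsAsFactors = FALSE)
  Lg <- chol(rg); Le <- chol(re)
  tbv_s <- (matrix(stats::rnorm(n_sires * nt), n_sires, nt) %*% Lg) %*%
    diag(sqrt(s2a), nt)
  ms <- (matrix(stats::rnorm(n * nt), n, nt) %*% Lg) %*%
    diag(sqrt(0.75 * s2a), nt)
  tbv_p <- 0.5 * tbv_s[rep(seq_len(n_sires), each = progeny_per_sire), ,
                       drop = FALSE] + ms
  e <- (matrix(stats::rnorm(n * nt), n, nt) %*% Le) %*% diag(sqrt(s2e), nt)
  cg <- sample(sprintf("cg%d", seq_len(n_cg)), n, replace = TRUE)
  cg_eff <- stats::rnorm(n_cg, 0, 0.3)
  names(cg_eff) <- sprintf("cg%d", seq_len(n_cg))
  rows <- lapply(seq_len(nt), function(t) {
    data.frame(animal = pid, trait = traits[t],
               value = cg_eff[cg] + tbv_p[, t] + e[, t],
               cg = cg, age_days = 580L, hd = 0.75,
               stringsAsFactors = FALSE)
  })
  phe <- do.call(rbind, rows)
  rownames(phe) <- NULL
  tbv <- rbind(tbv_s, tbv_p)
  rownames(tbv) <- c(sid, pid)
  list(ped = ped, phe = phe,
       truth = list(sigma2_a = s2a, sigma2_e = s2e, rg = rg, re = re,
                    tbv = tbv))
}
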