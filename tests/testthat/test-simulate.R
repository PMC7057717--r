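test_that("founder simulation: divergence null and Fst calibration", {
  ## divergence 0: all breeds share frequencies
  s0 <- sim_scenario(seed = 90, divergence = 0,
                     n_founders_per_breed = 20,
                     snps_per_chromosome = 50, n_chromosomes = 2)
  set.seed(90)
  fo0 <- simulate_founders(s0)
  expect_equal(max(apply(fo0$freq, 2, stats::sd)), 0)
  ## divergence 0.15: between-breed frequency variance ~ 0.15 p(1-p)
  s1 <- sim_scenario(seed = 91, divergence = 0.15,
                     n_founders_per_breed = 20,
                     snps_per_chromosome = 500, n_chromosomes = 4)
  set.seed(91)
  fo1 <- simulate_founders(s1)
  pbar <- colMeans(fo1$freq)
  vr <- apply(fo1$freq, 2, stats::var)
  ratio <- mean(vr) / mean(pbar * (1 - pbar))
  expect_lt(abs(ratio - 0.15), 0.03)
  ## founders are purebred unit vectors
  expect_true(all(rowSums(fo1$comp) == 1))
  expect_true(all(apply(fo1$comp, 1, max) == 1))
  ## same seed, same matrix
  set.seed(91)
  fo1b <- simulate_founders(s1)
  expect_identical(fo1$hap1, fo1b$hap1)
})

test_that("gene dropping: compositions, H_D, Mendelian consistency, eligibility", {
  s <- sim_scenario(seed = 92, n_founders_per_breed = 20,
                    offspring_per_mating = 3, n_generations = 3,
                    snps_per_chromosome = 40, n_chromosomes = 3)
  pop <- simulate_pedigree_and_genotypes(s)
  gen <- pop$generation
  ## F1 of pure N x pure A: composition (1/2, 1/2, 0, 0), H_D = 1
  f1 <- which(gen == 1L & pop$comp[, "N"] > 0)
  expect_true(all(pop$comp[f1, "N"] == 0.5 & pop$comp[f1, "A"] == 0.5))
  expect_true(all(pop$hd[f1] == 1))
  ## generation-2 composites are (1/4, 1/4, 1/4, 1/4) and eligible
  g2 <- which(gen == 2L)
  expect_true(all(abs(pop$comp[g2, ] - 0.25) < 1e-12))
  elig <- vapply(g2, function(i) {
    classify_montana(breed_comp(pop$comp[i, 1], pop$comp[i, 2],
                                pop$comp[i, 3], pop$comp[i, 4]))$eligible
  }, logical(1))
  expect_true(all(elig))
  ## Mendelian consistency at every locus for every non-founder
  geno_all <- pop$hap1 + pop$hap2
  ped_idx <- match(pop$ped$animal, rownames(geno_all))
  sire_idx <- match(pop$ped$sire, pop$ped$animal)
  dam_idx <- match(pop$ped$dam, pop$ped$animal)
  ok <- TRUE
  for (i in which(!is.na(sire_idx))) {
    gs <- geno_all[sire_idx[i], ]; gd <- geno_all[dam_idx[i], ]
    go <- geno_all[i, ]
    lo <- (gs >= 1 | gs == 2) * 0  # transmissible minimum per parent
    min_o <- (gs == 2) + (gd == 2)
    max_o <- 2 - ((gs == 0) + (gd == 0))
    if (any(go < min_o | go > max_o)) { ok <- FALSE; break }
  }
  expect_true(ok)
  ## composition codes parse back to the fractions
  has_code <- which(!is.na(pop$ped$composition_code))
  i <- has_code[length(has_code)]
  cc <- parse_composition_code(pop$ped$composition_code[i])
  expect_equal(unclass(cc), pop$comp[i, ], ignore_attr = TRUE)
})

test_that("phenotype simulation hits the target variance partition and scales", {
  s <- sim_scenario(seed = 93, n_founders_per_breed = 40,
                    offspring_per_mating = 5, n_generations = 3,
                    snps_per_chromosome = 60, n_chromosomes = 5)
  d <- simulate_dataset(s)
  tr <- d$truth
  ## realized TBV variance matches each target additive variance
  for (t in seq_along(s$traits)) {
    expect_lt(abs(stats::var(tr$tbv[, t]) / tr$sigma2_a[t] - 1), 0.15)
  }
  ## realized h2 within a loose band (checks e-variance too)
  phe <- d$phenotypes
  lma <- phe[phe$trait == "LMA", ]
  tbv_rec <- tr$tbv[lma$animal, "LMA"]
  resid <- lma$value - tbv_rec
  h2_real <- stats::var(tbv_rec) /
    (stats::var(tbv_rec) + tr$sigma2_e[1])
  expect_lt(abs(h2_real - 0.29), 0.06)
  ## trait means near the configured scales
  mns <- tapply(phe$value, phe$trait, mean)
  expect_lt(max(abs(mns[s$traits] - s$trait_means) / s$trait_sds), 0.6)
  ## heterosis slope recovered by regression when planted, zero when not
  fitc <- stats::lm(value ~ hd + age_days, data = lma)
  expect_gt(stats::coef(fitc)[["hd"]], 0)
  s0 <- sim_scenario(seed = 94, n_founders_per_breed = 40,
                     offspring_per_mating = 5, n_generations = 3,
                     snps_per_chromosome = 60, n_chromosomes = 5,
                     b_het = rep(0, 4), cg_sd = 0)
  d0 <- simulate_dataset(s0)
  lma0 <- d0$phenotypes[d0$phenotypes$trait == "LMA", ]
  y_adj <- lma0$value - d0$truth$tbv[lma0$animal, "LMA"]
  fit0 <- stats::lm(y_adj ~ hd + age_days, data = lma0)
  expect_lt(abs(summary(fit0)$coefficients["hd", "t value"]), 3)
  ## infeasible QTL partition errors
  expect_error(sim_scenario(seed = 1, qtl_var_frac = rep(0.25, 5)),
               "sum")
})

test_that("datasets are reproducible from the seed", {
  s <- sim_scenario(seed = 95, n_founders_per_breed = 16,
                    offspring_per_mating = 3, n_generations = 2,
                    snps_per_chromosome = 30, n_chromosomes = 2)
  d1 <- simulate_dataset(s)
  d2 <- simulate_dataset(s)
  expect_identical(d1$genotypes$geno, d2$genotypes$geno)
  expect_identical(d1$phenotypes$value, d2$phenotypes$value)
  expect_identical(d1$truth$tbv, d2$truth$tbv)
})

test_that("hidden QTL sit beside a panel SNP in strong founder LD", {
  s <- sim_scenario(seed = 96, n_founders_per_breed = 30,
                    offspring_per_mating = 3, n_generations = 2,
                    snps_per_chromosome = 40, n_chromosomes = 3,
                    qtl_on_panel = FALSE, qtl_ld_flip = 0.05)
  pop <- simulate_pedigree_and_genotypes(s)
  qrows <- which(pop$map$is_qtl)
  expect_length(qrows, s$n_qtl)
  expect_false(any(pop$map$snp_id[qrows] %in% pop$genotypes$map$snp_id))
  for (qc in qrows) {
    nb <- pop$map$ld_partner[qc]
    expect_identical(pop$map$chrom[qc], pop$map$chrom[nb])
    r <- stats::cor(pop$hap1[, qc] + pop$hap2[, qc],
                    pop$hap1[, nb] + pop$hap2[, nb])
    expect_gt(abs(r), 0.7)
  }
})

test_that("planted defects are removed exactly by the QC filters", {
  s <- sim_scenario(seed = 97, n_founders_per_breed = 40,
                    offspring_per_mating = 6, n_generations = 3,
                    snps_per_chromosome = 60, n_chromosomes = 3,
                    genotyping_fraction = 0.9, cg_sd = 0.2,
                    n_farms = 1, n_seasons = 1)
  d <- simulate_dataset(s)
  ## ensure the base dataset is QC-clean before planting
  base <- qc_snps(d$genotypes)
  base_removed <- sum(attr(base, "qc_audit")$removed)
  dd <- plant_defects(d, n_low_maf = 3, n_low_callrate_snp = 2,
                      n_hwe = 1, n_low_callrate_animal = 2,
                      n_outlier = 1, n_small_cg = 1)
  man <- attr(dd, "defect_manifest")
  out <- qc_snps(dd$genotypes)
  audit <- attr(out, "qc_audit")
  getf <- function(a, f) a$removed[a$filter == f]
  ba <- attr(base, "qc_audit")
  ## defects were planted on clean SNPs, so the removal counts grow by
  ## exactly the planted numbers
  expect_identical(getf(audit, "maf") - getf(ba, "maf"), 3L)
  expect_identical(getf(audit, "callrate") - getf(ba, "callrate"), 2L)
  expect_identical(getf(audit, "hwe") - getf(ba, "hwe"), 1L)
  expect_true(all(man$low_maf %in%
                  setdiff(dd$genotypes$map$snp_id, out$map$snp_id)))
  ## animal call-rate
  out2 <- qc_animals(out)
  expect_setequal(attr(out2, "removed_animals"),
                  man$low_callrate_animal)
  ## phenotype outlier: exactly one more removal than the natural
  ## 3.5-SD outliers already present in Gaussian data, and the planted
  ## record is among the removed
  base_log <- attr(filter_outliers(build_contemporary_groups(
    d$phenotypes)), "edit_log")
  t1 <- build_contemporary_groups(dd$phenotypes)
  t2 <- filter_outliers(t1)
  log2 <- attr(t2, "edit_log")
  expect_identical(nrow(log2), nrow(base_log) + 1L)
  expect_true(all(man$outliers %in%
                  paste(log2$animal, log2$trait, sep = "/")))
  t3 <- filter_small_cgs(t2)
  log3 <- attr(t3, "edit_log")
  expect_true(all(grepl("mg_planted", log3$cg)))
  expect_identical(nrow(log3), 4L * length(unique(t1$trait)))
  ## empty request leaves the dataset unchanged
  d_same <- plant_defects(d)
  expect_identical(d_same$genotypes$geno, d$genotypes$geno)
  expect_identical(d_same$phenotypes$value, d$phenotypes$value)
})
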