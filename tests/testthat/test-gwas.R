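## unblended fixture: G = MM'/k is full rank (more SNPs than animals)
gwas_fixture <- function(seed = 70, n = 50, m = 100) {
  set.seed(seed)
  g <- random_genomat(n, m, n_chrom = 2, p_range = c(0.2, 0.8))
  cs <- center_and_scale(g)
  G <- g_matrix(cs$M, cs$k)
  Ginv <- chol2inv(chol(unclass(G) + diag(1e-8, n)))
  list(cs = cs, G = G, Ginv = Ginv)
}

test_that("back-solved SNP effects satisfy the projection identity", {
  fx <- gwas_fixture()
  ## column-centered M leaves the all-ones vector in G's null space, so
  ## the projection identity applies to centered GEBVs
  a <- stats::rnorm(nrow(fx$cs$M))
  a <- a - mean(a)
  names(a) <- rownames(fx$cs$M)
  eff <- backsolve_snp_effects(fx$cs, fx$Ginv, a)
  ## M u reproduces the GEBVs when G is unblended and unweighted
  expect_lt(max(abs(fx$cs$M %*% eff$effect - a)), 1e-6)
  ## zero GEBVs give zero effects
  eff0 <- backsolve_snp_effects(fx$cs, fx$Ginv, a * 0)
  expect_equal(max(abs(eff0$effect)), 0)
  expect_error(backsolve_snp_effects(fx$cs, fx$Ginv, a[-1]), "length")
})

test_that("one-SNP back-solution matches the least-squares closed form", {
  set.seed(71)
  map1 <- data.frame(snp_id = "s1", chrom = 1L, pos = 50L)
  geno <- matrix(stats::rbinom(40, 2, 0.4), 40, 1,
                 dimnames = list(sprintf("an%02d", 1:40), NULL))
  cs <- center_and_scale(genotype_matrix(geno, map1))
  m1 <- cs$M[, 1]
  a <- 0.8 * m1
  ## G = m1 m1' / k has rank 1; its Moore-Penrose inverse is
  ## k m1 m1' / |m1|^4
  Ginv <- cs$k * outer(m1, m1) / sum(m1^2)^2
  eff <- backsolve_snp_effects(cs, Ginv, stats::setNames(a, names(m1)))
  ## closed form: regression of a on the single centered column
  expect_lt(abs(eff$effect[1] - sum(m1 * a) / sum(m1^2)), 1e-10)
})

test_that("weight updates: symmetry, scale invariance, concentration", {
  eff <- data.frame(snp_id = letters[1:4], chrom = 1L, pos = 1:4,
                    effect = c(1, 1, 1, 1), weight = 1, p = 0.5)
  expect_equal(update_weights(eff), rep(1, 4))
  ## doubling effects leaves normalized weights unchanged
  eff2 <- eff; eff2$effect <- eff$effect * 2
  expect_equal(update_weights(eff), update_weights(eff2))
  ## one nonzero effect takes (almost) all the weight
  eff3 <- eff; eff3$effect <- c(2, 0, 0, 0)
  w <- update_weights(eff3)
  expect_equal(w[1], 4, tolerance = 1e-6)
  expect_true(all(w[-1] < 1e-6))
  expect_equal(sum(w), 4)
  ## all-zero effects reset with a warning
  eff4 <- eff; eff4$effect <- 0
  expect_warning(w0 <- update_weights(eff4), "zero")
  expect_equal(w0, rep(1, 4))
})

test_that("window variance: counting, whole-genome identity, localization", {
  fx <- gwas_fixture(72, n = 40, m = 60)
  eff <- backsolve_snp_effects(fx$cs, fx$Ginv,
                               stats::setNames(stats::rnorm(40),
                                               rownames(fx$cs$M)))
  scan <- window_variance(eff, fx$cs$M, window_size = 5)
  m_per_chrom <- table(eff$chrom)
  expect_identical(nrow(scan), sum(m_per_chrom - 4L))
  ## whole-genome single window is exactly 100% (one chromosome)
  set.seed(73)
  g1 <- random_genomat(30, 20, n_chrom = 1, p_range = c(0.3, 0.7))
  cs1 <- center_and_scale(g1)
  G1 <- g_matrix(cs1$M, cs1$k)
  e1 <- backsolve_snp_effects(cs1, solve(unclass(G1) + diag(1e-8, 30)),
                              stats::setNames(stats::rnorm(30),
                                              rownames(cs1$M)))
  whole <- window_variance(e1, cs1$M, window_size = 20)
  expect_identical(nrow(whole), 1L)
  expect_equal(whole$pct_var, 100)
  ## single causal SNP: windows holding it carry essentially all signal
  e_single <- e1
  e_single$effect <- ifelse(seq_len(20) == 7, 1, 0)
  scan_s <- window_variance(e_single, cs1$M, window_size = 5)
  holds7 <- scan_s$start_bp <= e1$pos[7] & scan_s$end_bp >= e1$pos[7]
  expect_true(all(scan_s$pct_var[holds7] > 99))
  expect_true(all(scan_s$pct_var[!holds7] < 1))
  ## chromosome with fewer SNPs than the window emits no windows
  small <- random_genomat(10, 8, n_chrom = 2, p_range = c(0.3, 0.7))
  cs_s <- center_and_scale(small)
  es <- backsolve_snp_effects(cs_s, diag(10),
                              stats::setNames(stats::rnorm(10),
                                              rownames(cs_s$M)))
  expect_identical(nrow(window_variance(es, cs_s$M, window_size = 5)), 0L)
})

test_that("window scan is invariant to SNP column permutation", {
  fx <- gwas_fixture(74, n = 30, m = 40)
  a <- stats::rnorm(30)
  a <- stats::setNames(a - mean(a), rownames(fx$cs$M))
  eff <- backsolve_snp_effects(fx$cs, fx$Ginv, a)
  scan <- window_variance(eff, fx$cs$M)
  set.seed(74)
  perm <- sample(ncol(fx$cs$M))
  cs_p <- fx$cs
  cs_p$M <- fx$cs$M[, perm]
  cs_p$p <- fx$cs$p[perm]
  cs_p$map <- fx$cs$map[perm, ]
  eff_p <- backsolve_snp_effects(cs_p, fx$Ginv, a)
  scan_p <- window_variance(eff_p, cs_p$M)
  expect_equal(scan$pct_var, scan_p$pct_var, tolerance = 1e-10)
})

test_that("region calling merges adjacent significant windows", {
  scan <- data.frame(chrom = c(1, 1, 1, 1, 2, 3),
                     start_bp = c(100, 200, 300, 5000, 100, 100),
                     end_bp = c(250, 350, 450, 5100, 200, 200),
                     pct_var = c(2, 1.5, 3, 0.5, 1.2, 2.5))
  class(scan) <- c("window_scan", "data.frame")
  regs <- call_regions(scan)
  expect_identical(nrow(regs), 3L)
  r1 <- regs[regs$chrom == 1, ]
  expect_identical(r1$start_bp, 100)
  expect_identical(r1$end_bp, 450)
  expect_identical(r1$n_windows, 3L)
  expect_equal(r1$peak_pct, 3)
  ## different chromosomes never merge
  expect_setequal(regs$chrom, c(1, 2, 3))
  ## nothing significant -> empty
  expect_identical(nrow(call_regions(scan, threshold_pct = 10)), 0L)
})

test_that("iterative WssGBLUP: base case, determinism, weight growth at a QTL", {
  set.seed(75)
  ## compact end-to-end population with one strong QTL
  s <- sim_scenario(seed = 75, n_founders_per_breed = 30,
                    offspring_per_mating = 4, n_generations = 3,
                    snps_per_chromosome = 60, n_chromosomes = 5,
                    n_qtl = 1, qtl_var_frac = 0.2,
                    genotyping_fraction = 0.9)
  d <- simulate_dataset(s)
  g2 <- qc_animals(qc_snps(d$genotypes))
  cs <- center_and_scale(g2)
  op <- order_pedigree(d$ped)
  phe <- edit_phenotypes(d$phenotypes)
  dd <- build_design(phe, op, "LMA")
  fit1 <- run_wssgblup(dd, op, cs, d$truth$sigma2_a[1],
                       d$truth$sigma2_e[1], n_iterations = 1)
  fit3 <- run_wssgblup(dd, op, cs, d$truth$sigma2_a[1],
                       d$truth$sigma2_e[1], n_iterations = 3)
  ## n_iterations = 1 equals the first iteration of the longer run
  expect_equal(fit1$effects$effect, fit3$iterations[[1]]$effect,
               tolerance = 1e-12)
  expect_true(all(fit1$effects$weight == 1))
  ## weight sum conserved at every iteration
  m <- nrow(fit3$effects)
  for (it in 1:3) {
    expect_equal(sum(fit3$iterations[[it]]$weight), m, tolerance = 1e-6)
  }
  ## the planted QTL gains weight from iteration 1 to 2
  qsnp <- d$truth$qtl$snp_id[1]
  j <- match(qsnp, fit3$iterations[[2]]$snp_id)
  if (!is.na(j)) {
    expect_gt(fit3$iterations[[2]]$weight[j],
              fit3$iterations[[1]]$weight[j])
  }
  ## same inputs, same tables
  fit3b <- run_wssgblup(dd, op, cs, d$truth$sigma2_a[1],
                        d$truth$sigma2_e[1], n_iterations = 3)
  expect_identical(fit3$effects$effect, fit3b$effects$effect)
})
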