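test_that("pedigree kinship has the expected relationship coefficients", {
  expect_error(simulate_pedigree(0, 4), "positive")
  expect_error(simulate_pedigree(2, -1), "positive")

  expect_equal(simulate_pedigree(1, 1)$kinship,
               matrix(1, 1, 1, dimnames = list("F0001_I1", "F0001_I1")))

  ped <- simulate_pedigree(100, 4)
  kin <- ped$kinship
  expect_true(isSymmetric(kin))
  expect_equal(unname(diag(kin)), rep(1, 400))
  # off-diagonals by relationship class: 0.5 within parent-offspring and
  # sib pairs, 0 for the founder couple and across families
  fam <- ped$samples$family_id
  founder <- is.na(ped$samples$father_id)
  for (f in sample(unique(fam), 5)) {
    i <- which(fam == f)
    blk <- kin[i, i]
    expect_equal(unname(blk[1, 2]), 0)            # founder couple
    expect_equal(unname(blk[1, 3]), 0.5)          # parent-offspring
    expect_equal(unname(blk[3, 4]), 0.5)          # full sibs
  }
  off_family <- kin[fam == "F0001", fam == "F0002"]
  expect_equal(unname(off_family), matrix(0, 4, 4))
  expect_gte(min(eigen(kin, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("gene-dropped genotypes follow Hardy-Weinberg and Mendelian rules", {
  expect_error(simulate_genotypes(simulate_pedigree(1, 1), 5, c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotypes(simulate_pedigree(1, 1), 5, c(0.1, 0.6)),
               "maf_range")

  # founders at MAF 0.5: genotype frequencies (1/4, 1/2, 1/4)
  ped1 <- simulate_pedigree(3000, 1)
  g <- simulate_genotypes(ped1, 1, c(0.5, 0.5), seed = 5)
  expect_true(all(g %in% 0:2))
  tab <- tabulate(g + 1, 3)
  expect_gt(stats::chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 1e-4)

  # offspring genotypes are composed of transmitted parental alleles:
  # a child's dosage never exceeds what the parents can transmit
  ped <- simulate_pedigree(50, 4)
  gg <- simulate_genotypes(ped, 200, seed = 6)
  kids <- which(!is.na(ped$samples$father_id))
  for (i in kids[1:20]) {
    fa <- gg[ped$samples$father_id[i], ]
    mo <- gg[ped$samples$mother_id[i], ]
    lo <- (fa == 2) + (mo == 2)
    hi <- 2 - (fa == 0) - (mo == 0)
    expect_true(all(gg[i, ] >= lo & gg[i, ] <= hi))
  }
})

test_that("methylation values stay in [0,1] with controllable correlation and variance", {
  expect_error(simulate_methylation(10, 5, 1, rep(0.05, 5)), "within_gene_corr")

  M <- simulate_methylation(500, 8, 0.3, seq(0.02, 0.1, length.out = 8), seed = 2)
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(apply(M, 2, stats::var) > 0))

  # rho = 0: empirical cross-CpG correlations near zero
  M0 <- simulate_methylation(2000, 6, 0, rep(0.05, 6), seed = 3)
  C0 <- stats::cor(M0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.08)

  # the latent construction is invertible through qlogis: exchangeable
  # correlation 0.5 is recovered
  M5 <- simulate_methylation(2000, 10, 0.5, rep(0.05, 10), seed = 4)
  CL <- stats::cor(stats::qlogis(M5))
  expect_lt(abs(mean(CL[upper.tri(CL)]) - 0.5), 0.05)

  # empirical SDs track the requested profile
  prof <- seq(0.02, 0.12, length.out = 10)
  Mv <- simulate_methylation(4000, 10, 0, prof, seed = 5)
  sds <- apply(Mv, 2, stats::sd)
  expect_equal(unname(rank(sds)), rank(prof))
  expect_true(all(abs(sds - prof) / prof < 0.2))
})

test_that("phenotype generator reproduces the mixed-model covariance", {
  ped <- simulate_pedigree(150, 4)
  n <- nrow(ped$samples)
  sf <- sample_frame(data.frame(sample_id = ped$samples$sample_id,
                                family_id = ped$samples$family_id,
                                phenotype = 0))
  vc <- variance_components(list(kin = ped$kinship), check_psd = FALSE)

  expect_error(simulate_phenotype(sf, NULL,
                                  effect_spec(numeric(1), numeric(0), 0.5, 1)),
               "psis")

  # beta = 0, T = 0, alpha = 0: iid N(0, sigma2)
  y0 <- simulate_phenotype(sf, NULL, effect_spec(0, numeric(0), 0, 2.5),
                           vc, seed = 8, n_replicates = 50)
  expect_equal(stats::var(as.vector(y0)), 2.5, tolerance = 0.05)

  # T1 = 0.5 on kinship: sib phenotype covariance = 0.5 * 0.5 = 0.25
  eff <- effect_spec(0, numeric(0), 0.5, 1)
  Y <- simulate_phenotype(sf, NULL, eff, vc, seed = 9, n_replicates = 3000)
  sib1 <- which(!is.na(ped$samples$father_id))[c(TRUE, FALSE)]
  covs <- vapply(sib1, function(i)
    stats::cov(Y[i, ], Y[i + 1, ]), numeric(1))
  expect_equal(mean(covs), 0.25, tolerance = 0.03)
})

test_that("all generators are bit-reproducible given the same seed", {
  p1 <- simulate_pedigree(5, c(2, 3, 4, 4, 5), size_probs = NULL, seed = 3)
  p2 <- simulate_pedigree(5, c(2, 3, 4, 4, 5), size_probs = NULL, seed = 3)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, 50, seed = 4)
  expect_identical(g1, simulate_genotypes(p2, 50, seed = 4))
  m1 <- simulate_methylation(20, 4, 0.2, rep(0.05, 4), seed = 5)
  expect_identical(m1, simulate_methylation(20, 4, 0.2, rep(0.05, 4), seed = 5))
  d1 <- simulate_dataset(n_families = 5, family_size = 3, n_genes = 2,
                         cpgs_per_gene = 3, m_snps = 40, seed = 6)
  d2 <- simulate_dataset(n_families = 5, family_size = 3, n_genes = 2,
                         cpgs_per_gene = 3, m_snps = 40, seed = 6)
  expect_identical(d1$samples$y, d2$samples$y)
  expect_identical(d1$methylation$values, d2$methylation$values)
  expect_identical(d1$genotypes, d2$genotypes)
})
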