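test_that("Tajima's D matches the worked case and handles degeneracy", {
  m <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  td <- tajimas_d(m)
  expect_equal(td$S, 2L)
  expect_equal(td$pi, 8 / 6)
  expect_equal(td$a1, 11 / 6)
  expect_equal(td$D, 1.8931, tolerance = 1e-4)

  same <- matrix(1, 5, 3)
  expect_true(is.na(tajimas_d(same)$D))
  expect_equal(tajimas_d(same)$S, 0L)
  expect_error(tajimas_d(matrix(0, 1, 2)), "at least 2")
})

test_that("Tajima's D equals the brute-force oracle on random matrices", {
  set.seed(51)
  for (i in 1:50) {
    mat <- random_hap_matrix()
    expect_equal(tajimas_d(mat)$D, tajima_oracle(mat), tolerance = 1e-9)
    # duplicating every haplotype changes D deterministically
    mat2 <- rbind(mat, mat)
    expect_equal(tajimas_d(mat2)$D, tajima_oracle(mat2), tolerance = 1e-9)
  }
})

test_that("the windowed scan respects bin anchoring and SNP minima", {
  set.seed(52)
  pos <- c(sort(sample.int(9999, 12)), sort(sample.int(9999, 9)) + 10000L)
  geno <- matrix(rbinom(21 * 10, 1, 0.5), nrow = 10)
  panel <- snp_panel("chrT", pos, geno, paste0("S", 1:5))
  scan <- windowed_tajima_scan(panel, scan_config())
  expect_equal(nrow(scan), 1L) # second bin has only 9 SNPs
  expect_equal(scan$bin_start, 0L)
  expect_equal(scan$n_snps, 12L)
  expect_equal(scan$D, tajimas_d(geno[, 1:12])$D)

  # a haplogroup subset equals Tajima's D of the sliced matrix
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  scan_sub <- windowed_tajima_scan(panel, scan_config(), subset = mask)
  expect_equal(scan_sub$D, tajimas_d(geno[mask, 1:12])$D)
})

test_that("empirical percentile flags use inverse-ECDF quantiles", {
  gw <- 1:100
  expect_equal(empirical_percentile_flags(gw, 3), "low5")
  expect_equal(empirical_percentile_flags(gw, 8), "low10")
  expect_equal(empirical_percentile_flags(gw, 50), "none")
  expect_equal(empirical_percentile_flags(gw, 91), "high10")
  expect_equal(empirical_percentile_flags(gw, 99), "high5")

  set.seed(53)
  gw <- rnorm(500)
  region <- rnorm(200)
  flags <- empirical_percentile_flags(gw, region)
  q <- quantile(gw, c(0.05, 0.10, 0.90, 0.95), type = 1, names = FALSE)
  oracle <- ifelse(region <= q[1], "low5",
                   ifelse(region <= q[2], "low10",
                          ifelse(region >= q[4], "high5",
                                 ifelse(region >= q[3], "high10", "none"))))
  expect_equal(flags, oracle)
})

test_that("LD statistics reproduce hand arithmetic and complete LD", {
  coupled <- snp_panel("c", c(10L, 20L),
                       cbind(rep(c(0L, 1L), each = 4),
                             rep(c(0L, 1L), each = 4)), paste0("S", 1:4))
  ld <- ld_pair_stats(coupled, 1, 2)
  expect_equal(ld$Dprime, 1)
  expect_equal(ld$r2, 1)

  # counts (3,1,1,3)/8: D = 0.125, D' = 0.5, r2 = 0.25
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 0, 0, 0)
  panel <- snp_panel("c", c(1L, 2L), cbind(a, b), paste0("S", 1:4))
  ld2 <- ld_pair_stats(panel, 1, 2)
  expect_equal(ld2$D_coef, 0.125)
  expect_equal(ld2$Dprime, 0.5)
  expect_equal(ld2$r2, 0.25)

  mono <- snp_panel("c", c(1L, 2L), cbind(rep(1L, 4), c(0L, 1L, 0L, 1L)),
                    paste0("S", 1:2))
  expect_error(ld_pair_stats(mono, 1, 2), "undefined LD")
})

test_that("r2 never exceeds D-prime on random site pairs", {
  set.seed(54)
  for (rep in 1:40) {
    a <- rbinom(60, 1, runif(1, 0.2, 0.8))
    b <- rbinom(60, 1, runif(1, 0.2, 0.8))
    if (mean(a) %in% c(0, 1) || mean(b) %in% c(0, 1)) next
    ld <- mucvntr:::ld_from_vectors(a, b)
    expect_lte(ld$r2, ld$Dprime + 1e-12)
    expect_gte(ld$Dprime, 0); expect_lte(ld$Dprime, 1)
    expect_gte(ld$r2, 0); expect_lte(ld$r2, 1)
  }
})

test_that("independent sites in a large panel have near-zero mean r2", {
  set.seed(55)
  n <- 500
  r2s <- replicate(500, {
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    mucvntr:::ld_from_vectors(a, b)$r2
  })
  expect_lt(mean(r2s), 0.02)
})

test_that("D-prime CIs match the direct-grid oracle and narrow with n", {
  perfect <- dprime_ci(c(50, 0, 0, 50))
  oracle <- dprime_ci_oracle(c(50, 0, 0, 50))
  expect_equal(perfect$lower, oracle$lower)
  expect_equal(perfect$upper, oracle$upper)
  expect_gte(perfect$lower, 0.9) # likelihood concentrates at D' = 1

  balanced <- dprime_ci(c(25, 25, 25, 25))
  expect_lt(balanced$upper, 0.9)
  expect_equal(balanced, dprime_ci_oracle(c(25, 25, 25, 25)))

  big <- dprime_ci(c(250, 250, 250, 250))
  expect_lt(big$upper - big$lower, balanced$upper - balanced$lower)

  set.seed(56)
  for (rep in 1:10) {
    counts <- as.vector(stats::rmultinom(1, 60, runif(4, 0.05, 1)))
    expect_equal(dprime_ci(counts), dprime_ci_oracle(counts))
  }
})

test_that("Gabriel blocks match the toy case and the exhaustive oracle", {
  set.seed(57)
  a <- rep(c(0L, 1L), each = 100)
  c3 <- rbinom(200, 1, 0.5)
  panel <- snp_panel("c", c(100L, 200L, 5000L), cbind(a, a, c3),
                     paste0("S", 1:100))
  blocks <- gabriel_blocks(panel)
  expect_equal(nrow(blocks), 1L)
  expect_equal(c(blocks$start_site, blocks$end_site), c(1L, 2L))

  indep <- snp_panel("c", c(100L, 200L, 300L),
                     matrix(rbinom(600, 1, 0.5), 200, 3),
                     paste0("S", 1:100))
  expect_equal(nrow(gabriel_blocks(indep)), 0L)

  for (rep in 1:20) {
    panel <- random_panel(n_hap = 40, n_sites = sample(4:8, 1))
    if (ncol(panel$geno) < 2) next
    got <- gabriel_blocks(panel)
    want <- gabriel_oracle(panel)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_site, want$i)
      expect_equal(got$end_site, want$j)
    }
  }
})

test_that("block-size percentiles flag large blocks", {
  gw <- seq_len(1000) * 1000
  out <- block_size_percentile(gw, c(990000, 500000, 920000))
  expect_equal(out$flag, c("top5", "none", "top10"))
  set.seed(58)
  gw <- runif(300, 1e3, 1e6)
  spans <- runif(50, 1e3, 1e6)
  got <- block_size_percentile(gw, spans)
  rank_frac <- vapply(spans, function(s) mean(gw <= s), numeric(1))
  expect_equal(got$flag, ifelse(rank_frac >= 0.95, "top5",
                                ifelse(rank_frac >= 0.90, "top10", "none")))
})

test_that("HWE chi-square matches hand expectations and directions", {
  exact <- hwe_chisq(c(25, 50, 25))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)

  dep <- hwe_chisq(c(30, 40, 30))
  expect_equal(dep$chi2, 4.0)
  expect_equal(dep$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(dep$direction, "het_deficit")

  expect_equal(hwe_chisq(c(0, 100, 0))$direction, "het_excess")
  mono <- hwe_chisq(c(10, 0, 0))
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)

  set.seed(59)
  for (rep in 1:30) {
    counts <- as.vector(stats::rmultinom(1, 200, c(0.3, 0.45, 0.25)))
    expect_equal(hwe_chisq(counts)$chi2, hwe_oracle(counts),
                 tolerance = 1e-9)
  }
})

test_that("contingency chi-square matches the textbook oracle", {
  flat <- contingency_chisq(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  diag <- contingency_chisq(rbind(c(30, 10), c(10, 30)))
  expect_equal(diag$chi2, 20.0)
  expect_equal(diag$df, 1)

  expect_error(contingency_chisq(rbind(c(0, 0), c(5, 5))), "marginal")

  set.seed(60)
  for (rep in 1:30) {
    r <- sample(2:4, 1); k <- sample(2:4, 1)
    tab <- matrix(sample(1:40, r * k, TRUE), r, k)
    got <- contingency_chisq(tab)
    want <- chisq_oracle(tab)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
    expect_equal(got$df, want$df)
  }
})

test_that("the tSNP scan ranks perfect tags first and applies thresholds", {
  set.seed(61)
  n <- 200
  labels <- rep(c("H1", "H2", "H3"), times = c(100, 70, 30))
  sim <- simulate_coalescent_panel(n, 5, "neutral", seed = 62,
                                   interval = c(1L, 9000L))
  panel <- plant_tag_snps(sim$panel, labels,
                          tibble::tibble(target = c("H1", "H1"),
                                         r2 = c(1, 0.5),
                                         position = c(9500L, 9600L)))
  locus <- genomic_interval("chrSim", 0L, 10000L)
  scan <- haplogroup_tsnp_scan(panel, labels, "H1", locus,
                               window = 50000, r2_threshold = 0.85)
  expect_equal(scan$position[1], 9500L)
  expect_equal(scan$r2_target[1], 1)
  expect_true(scan$is_hit[1])
  # the planted r2 = 0.5 tag is excluded at the 0.85 threshold
  partial <- scan[scan$position == 9600L, ]
  expect_false(partial$is_hit)
  expect_lt(abs(partial$r2_target - 0.5), 0.021)
  # cross-haplogroup r2 reported
  expect_true(all(c("r2_H2", "r2_H3") %in% names(scan)))

  expect_error(haplogroup_tsnp_scan(panel, rep("H1", n), "H1", locus),
               "degenerate")
})

test_that("manual r2 arithmetic matches the scan on a 90% tag", {
  labels <- rep(c("H1", "H2"), each = 100)
  ind <- as.integer(labels == "H1")
  snp <- ind
  snp[1:10] <- 0L # matches membership in 90% of target haplotypes
  panel <- snp_panel("c", c(50L, 60L), cbind(snp, rbinom(200, 1, 0.5)),
                     paste0("S", 1:100))
  got <- haplogroup_tsnp_scan(panel, labels, "H1",
                              genomic_interval("c", 0L, 100L))
  # hand 2x2 haplotype-count formula
  pA <- mean(snp); pB <- mean(ind); pAB <- mean(snp & ind)
  r2_hand <- (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(got$r2_target[got$position == 50L], r2_hand)
})
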