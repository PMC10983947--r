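cons8 <- motif_consensus(8, "aa", "TTSTTSAP")

test_that("exact tandem repeats decompose into clean instances", {
  d <- decompose_vntr(strrep("TTSTTSAP", 3), cons8)
  expect_equal(d$n_instances, 3L)
  expect_equal(d$instances$seq, rep("TTSTTSAP", 3))
  expect_false(any(d$instances$has_indel))
})

test_that("substituted and indel-bearing copies are recovered", {
  d <- decompose_vntr(paste0("TTSTTSAP", "TTSTTVAP", "TTSTTSAP"), cons8)
  expect_equal(d$instances$seq, c("TTSTTSAP", "TTSTTVAP", "TTSTTSAP"))
  expect_false(any(d$instances$has_indel))

  d2 <- decompose_vntr(paste0("TTSTTSAP", "TTSTTSA", "TTSTTSAP"), cons8)
  expect_equal(d2$n_instances, 3L)
  expect_equal(d2$instances$has_indel, c(FALSE, TRUE, FALSE))
  expect_equal(d2$instances$seq[2], "TTSTTSA")

  expect_error(decompose_vntr("TTSTT", cons8), "shorter")
})

test_that("decomposition matches the exhaustive segmentation oracle", {
  set.seed(31)
  pool <- unname(motif_pool())
  for (rep in 1:12) {
    copies <- sample(pool, 3, replace = TRUE)
    # optionally delete or insert one residue in the middle copy
    mid <- copies[2]
    kind <- sample(c("none", "del", "ins"), 1)
    if (kind == "del") {
      p <- sample(8, 1)
      mid <- paste0(substr(mid, 1, p - 1), substr(mid, p + 1, 8))
    } else if (kind == "ins") {
      p <- sample(8, 1)
      mid <- paste0(substr(mid, 1, p), "G", substr(mid, p + 1, 8))
    }
    seg <- paste0(copies[1], mid, copies[3])
    d <- decompose_vntr(seg, cons8)
    oracle <- decompose_oracle(seg, "TTSTTSAP")
    expect_equal(d$score, oracle$score)
    expect_equal(paste(d$instances$seq, collapse = ""), seg)
    expect_equal(d$n_instances, 3L)
  }
})

test_that("tiling conservation holds under heavy mutation", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    aa <- sample(mucvntr:::AA20, 8 * n, replace = TRUE)
    base <- strsplit(strrep("TTSTTSAP", n), "")[[1]]
    mutate <- runif(8 * n) < 0.15
    base[mutate] <- aa[mutate]
    seg <- paste(base, collapse = "")
    d <- decompose_vntr(seg, cons8)
    expect_equal(paste(d$instances$seq, collapse = ""), seg)
  }
})

test_that("consensus estimation picks the modal frame", {
  d <- decompose_vntr(paste0(strrep("TTSTTSAP", 5), "TTSTTVAP",
                             strrep("TTSTTSAP", 4)),
                      motif_consensus(8, "aa"))
  expect_equal(d$consensus_seq, "TTSTTSAP")
})

test_that("catalogue ids, allele strings and allele counts behave", {
  segs <- tibble::tibble(
    haplotype = c("h1", "h2", "h3"),
    domain = "TR1",
    segment = c(strrep("TTSTTSAP", 4),
                strrep("TTSTTSAP", 4),
                paste0(strrep("TTSTTSAP", 3), "TTSTTVAP")))
  decomp <- decompose_cohort(segs, cons8)
  cat <- build_catalog(decomp)
  expect_equal(cat$n_unique_motifs, 2L)
  expect_equal(cat$motifs$motif_id, c("M001", "M002"))
  expect_equal(cat$motifs$seq[1], "TTSTTSAP") # highest total count first
  expect_equal(cat$n_unique_alleles, 2L)
  expect_equal(cat$alleles$allele_string[cat$alleles$haplotype == "h1"],
               cat$alleles$allele_string[cat$alleles$haplotype == "h2"])

  identical2 <- build_catalog(decompose_cohort(segs[1:2, ], cons8))
  expect_equal(identical2$n_unique_alleles, 1L)
})

test_that("zero-rate cohorts give exactly one allele per founder", {
  loc <- toy_locus()
  sim <- simulate_vntr_cohort(loc, sizes = c(H1 = 4L, H2 = 4L, H3 = 4L),
                              sub_rate = 0, dup_rate = 0, del_rate = 0,
                              seed = 2)
  pr <- project_cohort(sim$haplotypes, loc$reference_seq, loc$model)
  segs <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
    ann <- scan_domains(pr$aa_seq[i], loc$templates, loc$consensus)
    tibble::tibble(haplotype = paste0(pr$sample_id[i], "_h",
                                      pr$hap_index[i]),
                   domain = ann$tr_segments$label,
                   segment = substring(pr$aa_seq[i], ann$tr_segments$start,
                                       ann$tr_segments$end))
  })
  cat <- build_catalog(decompose_cohort(segs, loc$consensus))
  expect_equal(cat$n_unique_alleles, 3L)
})

test_that("usage matrix normalisations follow the formulas", {
  decomp <- tibble::tibble(
    haplotype = rep(c("h1", "h2"), each = 10),
    domain = "TR1", instance = rep(1:10, 2),
    seq = c(rep("TTSTTSAP", 4), rep("TTSTTVAP", 6),
            rep("TTSTTSAP", 8), rep("TTSTTVAP", 2)),
    start = 1L, end = 8L, has_indel = FALSE)
  cat <- build_catalog(decomp)
  ln <- usage_matrix(cat, decomp, "length_norm")
  expect_equal(unname(rowSums(unclass(ln))), c(1, 1))
  expect_equal(unclass(ln)["h1", "M001"], 0.4)
  cn <- usage_matrix(cat, decomp, "column_norm")
  expect_equal(unname(unclass(cn)), matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)

  same <- dplyr::mutate(decomp, seq = "TTSTTSAP")
  cat_s <- build_catalog(same)
  cn_s <- usage_matrix(cat_s, same, "column_norm")
  expect_true(all(unclass(cn_s) == 0)) # degenerate min-max rule

  expect_error(usage_matrix(cat, decomp[0, ], "raw"), "zero")
})

test_that("UPGMA reproduces hand-derived merges and tie rules", {
  dup <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dd <- upgma_cluster(dup)
  expect_equal(dd$height[1], 0) # identical rows merge first at height 0

  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  u <- upgma_cluster(d3)
  expect_equal(u$height, c(1, 4))

  # two clean pairs then one high merge; verified against hclust average
  d4 <- matrix(c(0, 1, 9, 9.5,
                 1, 0, 9.4, 9.2,
                 9, 9.4, 0, 2,
                 9.5, 9.2, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  u4 <- upgma_cluster(d4)
  expect_equal(u4$height[1:2], c(0.5, 1))
  hc <- stats::hclust(stats::as.dist(d4), method = "average")
  expect_equal(u4$height, hc$height / 2)

  expect_error(upgma_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA trees are ultrametric and permutation-invariant", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    p <- matrix(runif(n * 3), n)
    d <- as.matrix(stats::dist(p))
    rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
    u <- upgma_cluster(d)
    # merges at non-decreasing heights, leaves at height 0: every leaf is
    # root-height from the root (ultrametric); ape agrees on the tree
    expect_true(all(diff(u$height) >= -1e-12))
    tr <- ape::read.tree(text = write_newick(u))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    # permutation invariance up to leaf order
    perm <- sample(n)
    u2 <- upgma_cluster(d[perm, perm])
    expect_equal(sort(u$height), sort(u2$height))
    t2 <- ape::read.tree(text = write_newick(u2))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(t2))), 0)
  }
})

test_that("PFM columns are distributions with the expected consensus", {
  decomp <- tibble::tibble(haplotype = "h1", domain = "TR1",
                           instance = 1:4,
                           seq = rep("TTSTTSAP", 4), start = 1L, end = 8L,
                           has_indel = FALSE)
  pfm <- position_frequency_matrix(decomp, 8)
  expect_equal(unname(colSums(pfm$pfm)), rep(1, 8))
  expect_equal(pfm$consensus, "TTSTTSAP")
  expect_true(all(apply(pfm$pfm, 2, max) == 1)) # point masses

  mix <- tibble::tibble(haplotype = "h1", domain = "TR1", instance = 1:2,
                        seq = c("TTSTTSAP", "TTSTTSVP"), start = 1L,
                        end = 8L, has_indel = FALSE)
  pfm2 <- position_frequency_matrix(mix, 8)
  expect_equal(unname(pfm2$pfm[c("A", "V"), 7]), c(0.5, 0.5))
  expect_equal(sum(pfm2$pfm[, 7]), 1)
  expect_equal(substr(pfm2$consensus, 1, 6), "TTSTTS")
  expect_equal(substr(pfm2$consensus, 7, 7), "A") # tie -> lexicographic
})
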