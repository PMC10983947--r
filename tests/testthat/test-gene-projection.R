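# single-exon toy gene: 50 bp flanks around an exon holding the CDS
toy_single_exon <- function(cds, flank_seed = 3) {
  set.seed(flank_seed)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  ref <- paste0(flank5, cds, flank3)
  model <- gene_model("toy", genomic_interval("chrT", 50, 50 + nchar(cds)),
                      tibble::tibble(start = 50, end = 50 + nchar(cds)),
                      vntr_exon_index = 1, coding_start = 50,
                      coding_end = 50 + nchar(cds))
  list(ref = ref, model = model)
}

test_that("anchor extraction takes the k-mers flanking each exon", {
  toy <- toy_single_exon("ATGAAATGA")
  a <- extract_anchor_pairs(toy$ref, toy$model, k = 15)
  expect_equal(a$left_anchor, substr(toy$ref, 36, 50))
  expect_equal(a$right_anchor, substr(toy$ref, 60, 74))

  near_edge <- gene_model("g", genomic_interval("c", 5, 20),
                          tibble::tibble(start = 5, end = 20), 1, 5, 20)
  expect_error(extract_anchor_pairs(toy$ref, near_edge, k = 15), "edge")

  n_ref <- paste0(strrep("N", 40), substr(toy$ref, 41, nchar(toy$ref)))
  expect_error(extract_anchor_pairs(n_ref, toy$model, k = 15), "N")
})

test_that("self-projection reproduces the gene model exactly", {
  loc <- toy_locus()
  anchors <- extract_anchor_pairs(loc$reference_seq, loc$model, k = 30)
  em <- locate_exons(loc$reference_seq, anchors)
  expect_true(all(em$status == "mapped"))
  expect_equal(em$start, loc$model$exons$start)
  expect_equal(em$end, loc$model$exons$end)
  expect_true(all(em$identity_left == 1 & em$identity_right == 1))
})

test_that("an insertion inside the VNTR exon lengthens only that exon", {
  loc <- toy_locus()
  ex <- loc$model$exons
  set.seed(5)
  ins <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  cut <- ex$start[3] + 60 # inside the central exon
  hap <- paste0(substr(loc$reference_seq, 1, cut), ins,
                substr(loc$reference_seq, cut + 1,
                       nchar(loc$reference_seq)))
  anchors <- extract_anchor_pairs(loc$reference_seq, loc$model, k = 30)
  em <- locate_exons(hap, anchors)
  expect_true(all(em$status == "mapped"))
  widths_ref <- ex$end - ex$start
  widths_hap <- em$end - em$start
  expect_equal(widths_hap[3], widths_ref[3] + 300)
  expect_equal(widths_hap[-3], widths_ref[-3])
  # independent check: exon 3 span by direct string search of flanks
  left <- substr(loc$reference_seq, ex$start[3] - 29, ex$start[3])
  hit <- regexpr(left, hap, fixed = TRUE)
  expect_equal(as.integer(hit) + 29L, em$start[3])
})

test_that("a deleted anchor flank yields a missing exon status", {
  loc <- toy_locus()
  ex <- loc$model$exons
  hap <- paste0(substr(loc$reference_seq, 1, ex$end[3]),
                # drop the 200 bp downstream of exon 3 (its right anchor)
                substr(loc$reference_seq, ex$end[3] + 201,
                       nchar(loc$reference_seq)))
  anchors <- extract_anchor_pairs(loc$reference_seq, loc$model, k = 30)
  em <- locate_exons(hap, anchors)
  expect_equal(em$status[3], "missing")
})

test_that("splicing and translation follow the standard genetic code", {
  toy <- toy_single_exon("ATGAAATGA")
  anchors <- extract_anchor_pairs(toy$ref, toy$model, k = 15)
  em <- locate_exons(toy$ref, anchors)
  pred <- splice_translate(toy$ref, em, toy$model)
  expect_equal(pred$aa_seq, "MK")
  expect_equal(pred$length_aa, 2L)
  expect_equal(classify_orf(pred), "complete")

  toy2 <- toy_single_exon("ATGAAATAAAAATGA")
  anchors2 <- extract_anchor_pairs(toy2$ref, toy2$model, k = 15)
  pred2 <- splice_translate(toy2$ref, locate_exons(toy2$ref, anchors2),
                            toy2$model)
  expect_equal(pred2$aa_seq, "MK")
  expect_equal(pred2$orf_status, "truncated")
  expect_equal(pred2$stop_position_aa, 3L)

  toy3 <- toy_single_exon("TTGAAATGA")
  anchors3 <- extract_anchor_pairs(toy3$ref, toy3$model, k = 15)
  pred3 <- splice_translate(toy3$ref, locate_exons(toy3$ref, anchors3),
                            toy3$model)
  expect_equal(pred3$orf_status, "no_start")
})

test_that("minus-strand projection equals the plus-strand protein", {
  loc <- toy_locus()
  L <- nchar(loc$reference_seq)
  rc <- mucvntr:::revcomp(loc$reference_seq)
  ex <- loc$model$exons
  ex_rc <- tibble::tibble(start = L - ex$end, end = L - ex$start)
  model_rc <- gene_model("toy-", genomic_interval("chrT", L - ex$end[5],
                                                  L - ex$start[1], "-"),
                         ex_rc, vntr_exon_index = 3,
                         coding_start = L - ex$end[5],
                         coding_end = L - ex$start[1])
  pred_plus <- {
    a <- extract_anchor_pairs(loc$reference_seq, loc$model, 30)
    splice_translate(loc$reference_seq,
                     locate_exons(loc$reference_seq, a), loc$model)
  }
  pred_minus <- {
    a <- extract_anchor_pairs(rc, model_rc, 30)
    splice_translate(rc, locate_exons(rc, a), model_rc)
  }
  expect_equal(pred_minus$aa_seq, pred_plus$aa_seq)
  expect_equal(pred_minus$orf_status, "complete")
})

test_that("N inside a mapped exon flags the prediction unreliable", {
  toy <- toy_single_exon("ATGAANTGA")
  anchors <- extract_anchor_pairs(toy$ref, toy$model, k = 15)
  pred <- splice_translate(toy$ref, locate_exons(toy$ref, anchors),
                           toy$model)
  expect_equal(pred$orf_status, "unreliable")
})

test_that("translation agrees with Biostrings on random CDSs", {
  set.seed(21)
  for (i in 1:300) {
    n_codons <- sample(2:60, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, TRUE),
                 collapse = "")
    mine <- paste(mucvntr:::translate_cds(cds), collapse = "")
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE))
    expect_equal(mine, bs)
  }
})

test_that("in-frame whole-motif edits shift protein length by bp/3", {
  loc <- toy_locus()
  sim <- simulate_vntr_cohort(loc, sizes = c(H1 = 6L), sub_rate = 0,
                              dup_rate = 0.15, del_rate = 0.15, seed = 9)
  pr <- project_cohort(sim$haplotypes, loc$reference_seq, loc$model)
  founder_total <- sum(lengths(loc$founders$H1$trs))
  founder_len <- sim$truth$protein_length[1] -
    (sim$truth$n_instances[1] - founder_total) * 8
  net <- sim$truth$n_dup - sim$truth$n_del
  expect_equal(pr$length_aa, founder_len + net * 8L)
  expect_equal(pr$length_aa, sim$truth$protein_length)
})
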