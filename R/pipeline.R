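#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector of enabled stages among `"simulate"`,
#'   `"project"`, `"domains"`, `"motifs"`, `"popgen"`.
#' @param sizes Cohort sizes per haplogroup (simulate stage).
#' @param sub_rate,dup_rate,del_rate VNTR mutation rates.
#' @param n_bins,panel_n,panel_theta Genome-wide background parameters
#'   (popgen stage).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(out_dir = "mucvntr_run", seed = 1,
                            stages = c("simulate", "project", "domains",
                                       "motifs", "popgen"),
                            sizes = c(H1 = 103L, H2 = 78L, H3 = 25L),
                            sub_rate = 0.002, dup_rate = 0.01,
                            del_rate = 0.01, n_bins = 50L, panel_n = 50L,
                            panel_theta = 5) {
  list(out_dir = out_dir, seed = seed, stages = stages,
       simulate = list(sizes = sizes, sub_rate = sub_rate,
                       dup_rate = dup_rate, del_rate = del_rate),
       project = list(k = 30L, min_identity = 0.9),
       motifs = list(mode = "length_norm"),
       popgen = list(n_bins = n_bins, n = panel_n, theta = panel_theta,
                     bin_width = 10000L, min_snps = 10L,
                     tsnp_window = 50000L, tsnp_r2 = 0.85))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  modifyList(cfg, user)
}

write_tsv_out <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load)
#' haplotypes, project the gene model and predict proteins, annotate
#' domains, decompose motifs and build catalogue/usage/clustering, and
#' run the population-genetic scans on a simulated background panel —
#' writing the standard output bundle (`proteins.fa`, `qc.tsv`,
#' `domains.tsv`, `decomp.tsv`, `catalog.tsv`, `usage.tsv`, `tree.nwk`,
#' `scan.tsv`, `blocks.tsv`, `tsnps.tsv`, `summary.json`, `run.log`,
#' `MANIFEST.tsv`). Reruns with unchanged configuration are
#' byte-identical. A stage failure aborts with the stage named; outputs
#' written so far stay on disk and the MANIFEST records incompleteness.
#'
#' @param cfg A [pipeline_config()] list.
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character(0)
  log_stage <- function(stage, params, n_rows) {
    hash <- substr(tools::md5sum(tempfile_with(params)), 1, 8)
    line <- sprintf("stage=%s params_md5=%s rows=%d", stage, hash, n_rows)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  tempfile_with <- function(obj) {
    f <- tempfile()
    writeLines(paste(deparse(obj), collapse = ""), f)
    f
  }
  emitted <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    if (grepl("\\.tsv$", name)) write_tsv_out(x, p)
    else if (grepl("\\.fa$", name)) write_fasta(x, p)
    else if (grepl("\\.nwk$", name)) writeLines(x, p)
    else if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    emitted <<- c(emitted, name)
    p
  }
  finish_manifest <- function(complete) {
    mf <- tibble(file = emitted,
                 md5 = unname(tools::md5sum(file.path(cfg$out_dir,
                                                      emitted))),
                 complete = complete)
    write_tsv_out(mf, file.path(cfg$out_dir, "MANIFEST.tsv"))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      finish_manifest(complete = FALSE)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  results <- list()
  locus <- toy_locus()
  summary <- list(seed = cfg$seed, stages = cfg$stages)

  if ("simulate" %in% cfg$stages) {
    results$cohort <- run_stage("simulate", function() {
      simulate_vntr_cohort(locus, sizes = cfg$simulate$sizes,
                           sub_rate = cfg$simulate$sub_rate,
                           dup_rate = cfg$simulate$dup_rate,
                           del_rate = cfg$simulate$del_rate,
                           seed = cfg$seed)
    })
    emit(select(results$cohort$truth, -dplyr::any_of("seq")), "truth.tsv")
    log_stage("simulate", cfg$simulate, nrow(results$cohort$haplotypes))
    summary$haplogroup_counts <-
      as.list(table(results$cohort$haplotypes$haplogroup))
  }

  if ("project" %in% cfg$stages) {
    if (is.null(results$cohort)) abort("project stage requires haplotypes")
    results$proteins <- run_stage("project", function() {
      project_cohort(results$cohort$haplotypes, locus$reference_seq,
                     locus$model, k = cfg$project$k,
                     min_identity = cfg$project$min_identity)
    })
    pr <- results$proteins
    emit(tibble(id = paste0(pr$sample_id, "_h", pr$hap_index),
                seq = ifelse(is.na(pr$aa_seq), "", pr$aa_seq)),
         "proteins.fa")
    emit(select(pr, -"aa_seq"), "qc.tsv")
    log_stage("project", cfg$project, nrow(pr))
    summary$orf_status_counts <- as.list(table(pr$orf_status))
    summary$protein_lengths <- pr$length_aa
  }

  if ("domains" %in% cfg$stages) {
    if (is.null(results$proteins)) abort("domains stage requires proteins")
    results$domains <- run_stage("domains", function() {
      annotate_cohort(results$proteins, locus$templates, locus$consensus,
                      locus$rules)
    })
    emit(results$domains, "domains.tsv")
    log_stage("domains", list(), nrow(results$domains))
    summary$protein_group_counts <-
      as.list(table(results$domains$group_label))
    summary$st_total_mean <- mean(results$domains$total_count_ST,
                                  na.rm = TRUE)
    summary$st_fraction_mean <- mean(results$domains$total_fraction_ST,
                                     na.rm = TRUE)
  }

  if ("motifs" %in% cfg$stages) {
    if (is.null(results$proteins)) abort("motifs stage requires proteins")
    results$motifs <- run_stage("motifs", function() {
      pr <- filter(results$proteins, .data$orf_status == "complete")
      segs <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
        ann <- scan_domains(pr$aa_seq[i], locus$templates, locus$consensus)
        if (ann$n_TR_domains == 0) return(tibble())
        tibble(haplotype = paste0(pr$sample_id[i], "_h", pr$hap_index[i]),
               domain = ann$tr_segments$label,
               segment = substring(pr$aa_seq[i], ann$tr_segments$start,
                                   ann$tr_segments$end))
      })
      decomp <- decompose_cohort(segs, locus$consensus)
      catalog <- build_catalog(decomp)
      um <- usage_matrix(catalog, decomp, mode = cfg$motifs$mode)
      dmat <- as.matrix(stats::dist(unclass(um)))
      dend <- upgma_cluster(dmat)
      pfm <- position_frequency_matrix(decomp, locus$consensus$m)
      list(decomp = decomp, catalog = catalog, usage = um, dend = dend,
           pfm = pfm)
    })
    emit(results$motifs$decomp, "decomp.tsv")
    emit(results$motifs$catalog$motifs, "catalog.tsv")
    emit(cbind(tibble(haplotype = rownames(unclass(results$motifs$usage))),
               as.data.frame(unclass(results$motifs$usage))), "usage.tsv")
    emit(write_newick(results$motifs$dend), "tree.nwk")
    log_stage("motifs", cfg$motifs, nrow(results$motifs$decomp))
    summary$n_unique_motifs <- results$motifs$catalog$n_unique_motifs
    summary$n_unique_alleles <- results$motifs$catalog$n_unique_alleles
    summary$motif_consensus <- results$motifs$pfm$consensus
  }

  if ("popgen" %in% cfg$stages) {
    results$popgen <- run_stage("popgen", function() {
      pg <- cfg$popgen
      bg <- simulate_genomewide_bins(pg$n_bins, n = pg$n,
                                     theta = pg$theta,
                                     seed = cfg$seed + 1000L,
                                     bin_width = pg$bin_width)
      scfg <- scan_config(bin_width = pg$bin_width,
                          min_snps_per_bin = pg$min_snps)
      scan <- windowed_tajima_scan(bg$panel, scfg)
      scan$flag <- empirical_percentile_flags(scan$D, scan$D)
      region <- simulate_coalescent_panel(pg$n, pg$theta, "neutral",
                                          chrom = "chrRegion")
      blocks <- gabriel_blocks(region$panel, scfg)
      labels <- rep(c("H1", "H2"), length.out = pg$n)
      tag <- plant_tag_snps(region$panel, labels,
                            tibble(target = "H1", r2 = 1,
                                   position = 10001L))
      tsnps <- haplogroup_tsnp_scan(tag, labels, "H1",
                                    genomic_interval("chrRegion", 0L,
                                                     10000L),
                                    window = pg$tsnp_window,
                                    r2_threshold = pg$tsnp_r2)
      list(scan = scan, blocks = blocks, tsnps = tsnps)
    })
    emit(results$popgen$scan, "scan.tsv")
    emit(results$popgen$blocks, "blocks.tsv")
    emit(results$popgen$tsnps, "tsnps.tsv")
    log_stage("popgen", cfg$popgen, nrow(results$popgen$scan))
    summary$scan_flag_counts <- as.list(table(results$popgen$scan$flag))
    summary$n_blocks <- nrow(results$popgen$blocks)
    summary$n_tsnp_hits <- sum(results$popgen$tsnps$is_hit)
  }

  emit(summary, "summary.json")
  finish_manifest(complete = TRUE)
  invisible(c(results, list(summary = summary)))
}
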