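#' Read a FASTA file into a tibble
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that uppercases
#' sequences, strips line wrapping, preserves record order and enforces
#' unique record ids.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("no records in ", path)))
  if (length(set) == 0) abort(paste0("no records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, seq = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA (60-column wrap)
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a single-gene BED12 gene model
#'
#' One BED12 line describes the transcript; blocks become exons (0-based
#' half-open), `thickStart`/`thickEnd` the CDS. The VNTR exon defaults to
#' the largest block (the mucin central exon), overridable with
#' `vntr_exon`.
#'
#' @param path BED12 file with one line for the gene of interest.
#' @param vntr_exon Optional 1-based transcript-order exon index of the
#'   VNTR exon; default picks the largest exon.
#' @return A [gene_model()] object.
#' @export
read_gene_model_bed12 <- function(path, vntr_exon = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0) abort("empty BED file")
  f <- strsplit(trimws(ln[1]), "[ \t]+")[[1]]
  if (length(f) < 12) abort("BED12 requires 12 fields")
  chrom <- f[1]; cstart <- as.integer(f[2]); cend <- as.integer(f[3])
  name <- f[4]; strand <- f[6]
  thick_start <- as.integer(f[7]); thick_end <- as.integer(f[8])
  n_blocks <- as.integer(f[10])
  sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
  starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
  if (length(sizes) != n_blocks || length(starts) != n_blocks) {
    abort("BED12 format error: blockCount does not match blockSizes/blockStarts")
  }
  exons <- tibble(start = cstart + starts, end = cstart + starts + sizes)
  if (any(exons$end > cend)) abort("BED12 format error: block exceeds chromEnd")
  locus <- genomic_interval(chrom, cstart, cend, strand)
  if (is.null(vntr_exon)) {
    widths <- exons$end - exons$start
    genomic_idx <- which.max(widths)
    vntr_exon <- if (strand == "-") n_blocks - genomic_idx + 1L else genomic_idx
  }
  gene_model(name, locus, exons, vntr_exon, thick_start, thick_end)
}

#' Phased biallelic SNP panel
#'
#' Container for a haplotype-by-site binary allele matrix with 1-based
#' site positions and per-haplotype sample metadata.
#'
#' @param chrom Chromosome identifier.
#' @param positions Strictly increasing 1-based positions.
#' @param geno Integer matrix, rows = haplotypes, cols = sites, entries in
#'   \{0,1\}.
#' @param sample_ids Per-sample ids; each sample spans two consecutive rows.
#' @param populations Optional per-haplotype population labels.
#' @param haplogroups Optional per-haplotype haplogroup labels.
#' @param skip_report Optional named counts of records skipped on ingest.
#'
#' @return An object of class `snp_panel`.
#' @export
snp_panel <- function(chrom, positions, geno, sample_ids,
                      populations = NULL, haplogroups = NULL,
                      skip_report = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  positions <- as.integer(positions)
  if (ncol(geno) != length(positions)) abort("ncol(geno) != length(positions)")
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    abort("positions must be strictly increasing")
  }
  if (length(positions) > 0 && !all(geno %in% c(0L, 1L))) {
    abort("panel entries must be 0/1")
  }
  structure(list(chrom = chrom, positions = positions, geno = geno,
                 sample_ids = sample_ids,
                 populations = populations, haplogroups = haplogroups,
                 skip_report = skip_report),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d haplotypes x %d sites on %s\n",
              nrow(x$geno), ncol(x$geno), x$chrom))
  invisible(x)
}

n_haplotypes <- function(panel) nrow(panel$geno)
n_sites <- function(panel) ncol(panel$geno)

#' Read a phased VCF into a `snp_panel`
#'
#' Parses with [vcfR::read.vcfR()] and keeps only biallelic SNP records
#' whose genotypes are all phased (`|` separator) and fully called.
#' Multi-allelic, indel, unphased and missing-genotype records are skipped
#' and tallied in the panel's `skip_report`. Positions stay 1-based in the
#' panel; the optional `region` filter is 0-based half-open.
#'
#' @param path VCF path (v4.2 subset; GT must be the format field).
#' @param region Optional [genomic_interval()] restricting sites.
#' @return A [snp_panel()] with a `skip_report` attribute field.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  total <- nrow(fix)
  skip <- c(multiallelic = 0L, indel = 0L, unphased_or_missing = 0L,
            outside_region = 0L, retained = 0L, total = total)
  if (total == 0) {
    return(snp_panel(chrom = NA_character_, positions = integer(),
                     geno = matrix(integer(), 0, 0), sample_ids = character(),
                     skip_report = skip))
  }
  if (ncol(v@gt) < 2) abort("VCF has no GT data")
  fmt <- v@gt[, 1]
  if (!all(grepl("^GT($|:)", fmt))) abort("GT must lead the FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, total)
  multi <- grepl(",", fix$ALT)
  skip["multiallelic"] <- sum(multi); keep[multi] <- FALSE
  indel <- !multi & (nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 |
                       fix$ALT == "." | is.na(fix$ALT))
  skip["indel"] <- sum(indel); keep[indel] <- FALSE
  phased_ok <- apply(gt, 1, function(g) {
    all(!is.na(g)) && all(grepl("^[01]\\|[01]$", g))
  })
  bad_gt <- keep & !phased_ok
  skip["unphased_or_missing"] <- sum(bad_gt); keep[bad_gt] <- FALSE
  if (!is.null(region)) {
    inside <- fix$CHROM == region$chrom & pos - 1L >= region$start &
      pos - 1L < region$end
    skip["outside_region"] <- sum(keep & !inside)
    keep <- keep & inside
  }
  skip["retained"] <- sum(keep)
  samples <- colnames(gt)
  if (sum(keep) == 0) {
    return(snp_panel(chrom = fix$CHROM[1], positions = integer(),
                     geno = matrix(integer(), 2 * length(samples), 0),
                     sample_ids = samples, skip_report = skip))
  }
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  # rows: sample1 hap1, sample1 hap2, sample2 hap1, ...
  a1 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 1, 1)))
  a2 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 3, 3)))
  geno <- matrix(0L, nrow = 2 * length(samples), ncol = sum(keep))
  geno[seq(1, 2 * length(samples), by = 2), ] <- t(a1)
  geno[seq(2, 2 * length(samples), by = 2), ] <- t(a2)
  ord <- order(pos)
  snp_panel(chrom = fix$CHROM[keep][1], positions = pos[ord],
            geno = geno[, ord, drop = FALSE], sample_ids = samples,
            skip_report = skip)
}

#' Write a `snp_panel` as a minimal phased VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT=GT with synthetic
#' A/G alleles (the panel is binary) and phased genotypes.
#'
#' @param panel A [snp_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  n_hap <- n_haplotypes(panel)
  if (n_hap %% 2 != 0) abort("panel must have an even number of haplotypes")
  samples <- panel$sample_ids
  if (length(samples) != n_hap / 2) {
    samples <- paste0("S", seq_len(n_hap / 2))
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", panel$chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(panel$positions), function(j) {
    g <- panel$geno[, j]
    gt <- paste(g[seq(1, n_hap, 2)], g[seq(2, n_hap, 2)], sep = "|")
    paste(c(panel$chrom, panel$positions[j], ".", "A", "G", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- Newick ---------------------------------------------------------------

escape_newick_label <- function(x) {
  bad <- grepl("[(),:;\\[\\]'\\s]", x, perl = TRUE)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Serialize a UPGMA dendrogram as Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0), so for an ultrametric tree every leaf is equidistant from the root.
#' Labels containing Newick metacharacters are quoted.
#'
#' @param dend A `vntr_dendrogram` from [upgma_cluster()].
#' @return A single Newick string (terminated by `;`).
#' @export
write_newick <- function(dend) {
  stopifnot(inherits(dend, "vntr_dendrogram"))
  labels <- escape_newick_label(dend$labels)
  n_merge <- nrow(dend$merge)
  if (is.null(n_merge) || n_merge == 0) {
    if (length(labels) != 1) abort("dendrogram without merges needs one leaf")
    return(paste0(labels[1], ";"))
  }
  node_height <- function(k) if (k < 0) 0 else dend$height[k]
  min_leaf <- function(k) {
    if (k < 0) return(-k)
    min(min_leaf(dend$merge[k, 1]), min_leaf(dend$merge[k, 2]))
  }
  render <- function(k) { # k: negative = leaf index, positive = merge row
    if (k < 0) return(labels[-k])
    a <- dend$merge[k, 1]; b <- dend$merge[k, 2]
    if (min_leaf(b) < min_leaf(a)) { tmp <- a; a <- b; b <- tmp }
    h <- dend$height[k]
    fmt <- function(child) {
      sprintf("%s:%s", render(child),
              format(h - node_height(child), trim = TRUE, digits = 10))
    }
    paste0("(", fmt(a), ",", fmt(b), ")")
  }
  paste0(render(n_merge), ";")
}
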