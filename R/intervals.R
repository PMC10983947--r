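#' Genomic interval in 0-based half-open coordinates
#'
#' All coordinates inside the package are 0-based half-open; 1-based formats
#' (VCF) are converted at the boundary on read/write.
#'
#' @param chrom Chromosome / sequence identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#'
#' @return A `genomic_interval` list with fields `chrom`, `start`, `end`,
#'   `strand`.
#' @export
#' @examples
#' genomic_interval("chr11", 1117952, 1272172)
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    abort("invalid interval: require 0 <= start < end")
  }
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Gene model with an identified VNTR exon
#'
#' @param name Gene name.
#' @param locus A [genomic_interval()] spanning the gene.
#' @param exons Tibble with columns `start`, `end` (0-based half-open,
#'   genomic order).
#' @param vntr_exon_index 1-based index (transcript order) of the exon
#'   holding the tandem-repeat domains.
#' @param coding_start,coding_end 0-based half-open CDS bounds on the
#'   genome.
#'
#' @return A `gene_model` object.
#' @export
gene_model <- function(name, locus, exons, vntr_exon_index,
                       coding_start, coding_end) {
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- arrange(exons, .data$start)
  if (any(exons$start >= exons$end)) abort("exon with start >= end")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort("exons overlap")
  }
  # transcript order equals genomic order on '+', reversed on '-'
  if (locus$strand == "-") exons <- exons[rev(seq_len(nrow(exons))), ]
  vntr_exon_index <- as.integer(vntr_exon_index)
  if (vntr_exon_index < 1 || vntr_exon_index > nrow(exons)) {
    abort("vntr_exon_index addresses no exon")
  }
  structure(list(name = name, locus = locus, exons = exons,
                 vntr_exon_index = vntr_exon_index,
                 coding_start = as.integer(coding_start),
                 coding_end = as.integer(coding_end)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s, %d exons (VNTR exon %d), %s:%d-%d(%s)\n",
              x$name, nrow(x$exons), x$vntr_exon_index, x$locus$chrom,
              x$locus$start, x$locus$end, x$locus$strand))
  invisible(x)
}
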