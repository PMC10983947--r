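#' Tajima's D from a binary haplotype-by-site matrix
#'
#' Contrasts mean pairwise diversity (pi) with Watterson's estimator
#' (S/a1). Negative values indicate an excess of rare variants
#' (positive-selection signature); positive values an excess of
#' intermediate-frequency variants (balancing-selection signature). With
#' no segregating sites the statistic is undefined and reported as `NA`.
#'
#' @param mat Matrix with rows = haplotypes, entries in \{0,1\}.
#' @return List of class `tajima_d`: `n`, `S`, `pi`, the 1989 constants
#'   `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`, and `D`.
#' @export
#' @examples
#' m <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
#' tajimas_d(m)$D # about +1.89
tajimas_d <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) abort("need at least 2 haplotypes")
  if (length(mat) > 0 && !all(mat %in% c(0, 1))) {
    abort("matrix entries must be 0/1")
  }
  x <- colSums(mat)
  seg <- x > 0 & x < n
  S <- sum(seg)
  pi <- if (ncol(mat) == 0) 0 else
    sum(x[seg] * (n - x[seg])) / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0) NA_real_ else
    (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(n = n, S = S, pi = pi, a1 = a1, a2 = a2, b1 = b1,
                 b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2, D = D),
            class = "tajima_d")
}

#' @export
print.tajima_d <- function(x, ...) {
  cat(sprintf("<tajima_d> n=%d S=%d pi=%.4f D=%s\n", x$n, x$S, x$pi,
              ifelse(is.na(x$D), "NA", sprintf("%.4f", x$D))))
  invisible(x)
}

#' @export
glance.tajima_d <- function(x, ...) {
  tibble(n = x$n, S = x$S, pi = x$pi, theta_w = x$S / x$a1, D = x$D)
}

#' Scan configuration for binned selection statistics
#'
#' Defaults mirror the standard genome-scan setup: 10-kbp bins anchored
#' at multiples of the bin width, at least 10 SNPs per bin, empirical
#' flags at the two-sided 90th/95th percentiles, and site filters of
#' minor allele frequency > 5% with at most 25% missing genotypes.
#'
#' @param bin_width Bin width in bp.
#' @param min_snps_per_bin Minimum SNPs for a bin to be reported.
#' @param maf_min Minor-allele-frequency filter.
#' @param max_missing Maximum per-site missing fraction.
#' @return A `scan_config` list.
#' @export
scan_config <- function(bin_width = 10000L, min_snps_per_bin = 10L,
                        maf_min = 0.05, max_missing = 0.25) {
  structure(list(bin_width = as.integer(bin_width),
                 min_snps_per_bin = as.integer(min_snps_per_bin),
                 maf_min = maf_min, max_missing = max_missing),
            class = "scan_config")
}

#' Binned Tajima's D scan over a phased panel
#'
#' Sites fall into bins aligned to multiples of `bin_width` from
#' coordinate 0 (0-based); bins with fewer than `min_snps_per_bin` SNPs
#' are omitted. An optional haplotype mask restricts rows before S and pi
#' are computed (haplogroup or population stratification).
#'
#' @param panel A [snp_panel()].
#' @param cfg A [scan_config()].
#' @param subset Optional logical/integer haplotype row mask.
#' @return Tibble of class `tajima_scan`: `bin_start`, `bin_end` (0-based
#'   half-open), `n_snps`, `D`.
#' @export
windowed_tajima_scan <- function(panel, cfg = scan_config(), subset = NULL) {
  geno <- panel$geno
  if (!is.null(subset)) geno <- geno[subset, , drop = FALSE]
  w <- cfg$bin_width
  bin <- (panel$positions - 1L) %/% w
  out <- purrr::map_dfr(sort(unique(bin)), function(b) {
    cols <- which(bin == b)
    if (length(cols) < cfg$min_snps_per_bin) return(tibble())
    td <- tajimas_d(geno[, cols, drop = FALSE])
    tibble(bin_start = b * w, bin_end = (b + 1L) * w,
           n_snps = length(cols), D = td$D)
  })
  if (nrow(out) == 0) {
    out <- tibble(bin_start = integer(), bin_end = integer(),
                  n_snps = integer(), D = numeric())
  }
  class(out) <- c("tajima_scan", class(out))
  out
}

#' Flag region bins against an empirical genome-wide distribution
#'
#' Uses inverse-ECDF (type-1) quantiles of the genome-wide values:
#' `low5` for values at or below the 5th percentile, `low10` at or below
#' the 10th, `high5` at or above the 95th, `high10` at or above the
#' 90th; `none` otherwise. The stronger flag wins.
#'
#' @param genomewide Numeric vector of background bin values (NA
#'   dropped).
#' @param region Numeric vector of region bin values.
#' @return Character vector of flags, one per region value (`NA` input
#'   gives `NA` flag).
#' @export
empirical_percentile_flags <- function(genomewide, region) {
  genomewide <- genomewide[!is.na(genomewide)]
  if (length(genomewide) == 0) abort("genomewide distribution is empty")
  q <- quantile(genomewide, c(0.05, 0.10, 0.90, 0.95), type = 1,
                names = FALSE)
  vapply(region, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v <= q[1]) "low5"
    else if (v <= q[2]) "low10"
    else if (v >= q[4]) "high5"
    else if (v >= q[3]) "high10"
    else "none"
  }, character(1))
}

#' Pairwise linkage disequilibrium between two panel sites
#'
#' Frequencies come from phased haplotype counts; `Dprime` is the LD
#' coefficient normalised by its frequency-bound maximum and `r2` the
#' squared allelic correlation.
#'
#' @param panel A [snp_panel()].
#' @param i,j Site column indices.
#' @return List with `p_A`, `p_B`, `p_AB`, `D_coef`, `Dmax`, `Dprime`,
#'   `r2`.
#' @export
ld_pair_stats <- function(panel, i, j) {
  a <- panel$geno[, i]; b <- panel$geno[, j]
  ld_from_vectors(a, b)
}

ld_from_vectors <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) abort("undefined LD: monomorphic site")
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (Dmax == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(p_A = pA, p_B = pB, p_AB = pAB, D_coef = D, Dmax = Dmax,
       Dprime = Dprime, r2 = r2)
}

#' Likelihood-grid confidence interval for D-prime
#'
#' With allele frequencies fixed at their maximum-likelihood estimates,
#' the multinomial likelihood of the four observed two-locus haplotype
#' counts is evaluated on a D-prime grid over \[0, 1\], normalised to unit
#' mass. The lower bound is the smallest grid value whose cumulative mass
#' from below reaches (1 - coverage)/2; the upper bound the largest with
#' the same mass from above (the Haploview-style construction).
#'
#' @param counts Integer vector `(n_AB, n_Ab, n_aB, n_ab)`.
#' @param coverage Interval coverage (default 0.90).
#' @param grid Grid step (default 0.001).
#' @return List with `lower`, `upper`.
#' @export
dprime_ci <- function(counts, coverage = 0.90, grid = 0.001) {
  stopifnot(length(counts) == 4)
  ntot <- sum(counts)
  if (ntot < 1) abort("need at least one haplotype")
  pA <- (counts[1] + counts[2]) / ntot
  pB <- (counts[1] + counts[3]) / ntot
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(lower = 0, upper = 1)) # monomorphic: uninformative
  }
  Dobs <- counts[1] / ntot - pA * pB
  Dmax <- if (Dobs >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dgrid <- seq(0, 1, by = grid)
  loglik <- vapply(dgrid, function(dp) {
    D <- sign(Dobs) * dp * Dmax
    if (Dobs == 0) D <- dp * Dmax
    p <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    if (any(p < -1e-12)) return(-Inf)
    p <- pmax(p, 0)
    if (any(counts > 0 & p == 0)) return(-Inf)
    sum(counts[counts > 0] * log(p[counts > 0]))
  }, numeric(1))
  lik <- exp(loglik - max(loglik))
  mass <- lik / sum(lik)
  alpha <- (1 - coverage) / 2
  cum_lo <- cumsum(mass)
  cum_hi <- rev(cumsum(rev(mass)))
  lower <- dgrid[which(cum_lo >= alpha)[1]]
  upper <- dgrid[tail(which(cum_hi >= alpha), 1)]
  list(lower = lower, upper = upper)
}

two_locus_counts <- function(a, b) {
  c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
    sum(a == 0 & b == 1), sum(a == 0 & b == 0))
}

maf_filter <- function(panel, maf_min) {
  f <- colMeans(panel$geno)
  keep <- pmin(f, 1 - f) > maf_min
  panel$positions <- panel$positions[keep]
  panel$geno <- panel$geno[, keep, drop = FALSE]
  panel
}

#' Gabriel-definition haplotype blocks
#'
#' Pairs are classified from D-prime confidence intervals: strong LD iff
#' the CI lower bound is at least `strong_ld[1]` and the upper at least
#' `strong_ld[2]`; strong recombination iff the upper bound is below
#' `recomb_upper`. A candidate block is a site interval whose outermost
#' pair is strong LD and where strong-LD pairs make up at least
#' `informative_fraction` of informative pairs. Overlapping candidates
#' are resolved greedily by bp span, ties leftmost. Sites are
#' MAF-filtered with `cfg$maf_min` first.
#'
#' @param panel A [snp_panel()].
#' @param cfg A [scan_config()] (MAF filter).
#' @param strong_ld CI thresholds `(lower, upper)`, default
#'   `c(0.70, 0.98)`.
#' @param recomb_upper Strong-recombination upper bound, default 0.90.
#' @param informative_fraction Minimum strong-LD share, default 0.95.
#' @param max_pair_bp Pairs farther apart are ignored, default 500 kbp.
#' @return Tibble of class `gabriel_blocks`: `start_site`, `end_site`
#'   (indices into the filtered site list), `start_pos`, `end_pos`
#'   (1-based), `n_snps`, `span_bp`.
#' @export
gabriel_blocks <- function(panel, cfg = scan_config(),
                           strong_ld = c(0.70, 0.98), recomb_upper = 0.90,
                           informative_fraction = 0.95,
                           max_pair_bp = 500000) {
  panel <- maf_filter(panel, cfg$maf_min)
  S <- n_sites(panel)
  empty <- tibble(start_site = integer(), end_site = integer(),
                  start_pos = integer(), end_pos = integer(),
                  n_snps = integer(), span_bp = integer())
  if (S < 2) return(structure(empty, class = c("gabriel_blocks",
                                               class(empty))))
  pos <- panel$positions
  # pair classification: 1 = strong LD, -1 = strong recomb, 0 = other
  cls <- matrix(0L, S, S)
  for (i in seq_len(S - 1)) {
    for (j in seq((i + 1), S)) {
      if (pos[j] - pos[i] > max_pair_bp) next
      ci <- dprime_ci(two_locus_counts(panel$geno[, i], panel$geno[, j]))
      if (ci$lower >= strong_ld[1] && ci$upper >= strong_ld[2]) {
        cls[i, j] <- 1L
      } else if (ci$upper < recomb_upper) {
        cls[i, j] <- -1L
      }
    }
  }
  cand <- list()
  for (i in seq_len(S - 1)) {
    for (j in seq((i + 1), S)) {
      if (cls[i, j] != 1L) next
      sub <- cls[i:j, i:j, drop = FALSE]
      n_strong <- sum(sub == 1L)
      n_recomb <- sum(sub == -1L)
      if (n_strong + n_recomb == 0) next
      if (n_strong / (n_strong + n_recomb) >= informative_fraction) {
        cand[[length(cand) + 1]] <- c(i, j, pos[j] - pos[i])
      }
    }
  }
  if (length(cand) == 0) {
    return(structure(empty, class = c("gabriel_blocks", class(empty))))
  }
  cm <- do.call(rbind, cand)
  cm <- cm[order(-cm[, 3], cm[, 1]), , drop = FALSE]
  used <- rep(FALSE, S)
  rows <- list()
  for (r in seq_len(nrow(cm))) {
    i <- cm[r, 1]; j <- cm[r, 2]
    if (any(used[i:j])) next
    used[i:j] <- TRUE
    rows[[length(rows) + 1]] <- tibble(start_site = i, end_site = j,
                                       start_pos = pos[i], end_pos = pos[j],
                                       n_snps = j - i + 1L,
                                       span_bp = pos[j] - pos[i])
  }
  out <- arrange(bind_rows(rows), .data$start_site)
  structure(out, class = c("gabriel_blocks", class(empty)))
}

#' Percentile rank of region block sizes against a genome-wide background
#'
#' @param genomewide_spans Background block spans (bp).
#' @param region_spans Region block spans (bp).
#' @return Tibble with `span_bp`, `percentile` (ECDF rank) and `flag` in
#'   \{top5, top10, none\}.
#' @export
block_size_percentile <- function(genomewide_spans, region_spans) {
  if (length(genomewide_spans) == 0) abort("genomewide spans empty")
  ec <- stats::ecdf(genomewide_spans)
  tibble(span_bp = region_spans, percentile = ec(region_spans)) |>
    mutate(flag = dplyr::case_when(.data$percentile >= 0.95 ~ "top5",
                                   .data$percentile >= 0.90 ~ "top10",
                                   TRUE ~ "none"))
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Pearson chi-square against expectations at the MLE allele frequency
#' (1 df, no continuity correction), with the direction of the
#' heterozygote departure. A monomorphic sample gives chi2 = 0, p = 1.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)`.
#' @return List with `chi2`, `p`, `direction` in \{het_excess,
#'   het_deficit, none\}.
#' @export
hwe_chisq <- function(counts) {
  stopifnot(length(counts) == 3)
  ntot <- sum(counts)
  if (ntot <= 0) abort("total genotype count must be positive")
  p <- (2 * counts[1] + counts[2]) / (2 * ntot)
  if (p %in% c(0, 1)) {
    return(list(chi2 = 0, p = 1, direction = "none"))
  }
  expd <- ntot * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expd)^2 / expd)
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  diff_het <- counts[2] - expd[2]
  direction <- if (chi2 == 0 || diff_het == 0) "none" else
    if (diff_het > 0) "het_excess" else "het_deficit"
  list(chi2 = chi2, p = pval, direction = direction)
}

#' Pearson chi-square test of independence for an r x c table
#'
#' @param table Matrix of counts with positive row and column sums.
#' @return List with `chi2`, `df`, `p`.
#' @export
contingency_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Discover haplogroup-tagging SNPs by squared correlation
#'
#' The target haplogroup is encoded as a pseudo-site (allele 1 =
#' haplotype carries the haplogroup) and r2 is computed against every
#' polymorphic SNP within `window` bp of the locus boundaries. Hits are
#' sites with r2 above `r2_threshold`; for each site the r2 against every
#' other haplogroup's indicator is also reported (specificity check).
#'
#' @param panel A [snp_panel()].
#' @param labels Per-haplotype haplogroup labels.
#' @param target Haplogroup id to tag.
#' @param locus A [genomic_interval()] for the gene.
#' @param window Scan window each side of the locus (default 50 kbp).
#' @param r2_threshold Tagging threshold (default 0.85).
#' @return Tibble sorted by `r2_target` descending: `position`,
#'   `r2_target`, `is_hit`, and one `r2_<group>` column per other
#'   haplogroup.
#' @export
haplogroup_tsnp_scan <- function(panel, labels, target, locus,
                                 window = 50000, r2_threshold = 0.85) {
  if (length(labels) != n_haplotypes(panel)) {
    abort("labels must cover all haplotypes")
  }
  if (!target %in% labels) abort("target haplogroup absent from labels")
  if (length(unique(labels)) == 1) {
    abort("degenerate encoding: all haplotypes share one label")
  }
  ind <- as.integer(labels == target)
  lo <- locus$start + 1L - window # 1-based bounds of the scan window
  hi <- locus$end + window
  in_win <- panel$positions >= lo & panel$positions <= hi
  f <- colMeans(panel$geno)
  poly <- f > 0 & f < 1
  sites <- which(in_win & poly)
  others <- setdiff(unique(labels), target)
  rows <- purrr::map_dfr(sites, function(s) {
    snp <- panel$geno[, s]
    r2t <- ld_from_vectors(snp, ind)$r2
    out <- tibble(position = panel$positions[s], r2_target = r2t,
                  is_hit = r2t > r2_threshold)
    for (g in others) {
      out[[paste0("r2_", g)]] <- ld_from_vectors(snp,
                                                 as.integer(labels == g))$r2
    }
    out
  })
  if (nrow(rows) == 0) {
    rows <- tibble(position = integer(), r2_target = numeric(),
                   is_hit = logical())
  }
  arrange(rows, desc(.data$r2_target), .data$position)
}
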