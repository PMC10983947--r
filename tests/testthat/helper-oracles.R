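# Independent oracles used across the suite. These deliberately take the
# slow, literal route (textbook formulas, exhaustive enumeration,
# Biostrings alignments) so they share no code with the implementation.

# Tajima (1989) by direct evaluation: pairwise loops, literal constants.
tajima_oracle <- function(mat) {
  n <- nrow(mat)
  S <- 0
  for (j in seq_len(ncol(mat))) {
    x <- sum(mat[, j])
    if (x > 0 && x < n) S <- S + 1
  }
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + sum(mat[i, ] != mat[j, ])
    }
  }
  pi <- total / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(NA_real_)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Affine local/global alignment score through Biostrings.
bs_align_score <- function(pattern, subject, type, match = 1,
                           mismatch = -1, gap_open = -2, gap_extend = -1) {
  alpha <- unique(c(strsplit(pattern, "")[[1]], strsplit(subject, "")[[1]]))
  sm <- matrix(mismatch, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- match
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = type,
    substitutionMatrix = sm, gapOpening = abs(gap_open),
    gapExtension = abs(gap_extend), scoreOnly = TRUE))
}

# Exhaustive decomposition: best segmentation into parts of length within
# m +/- slack, each part scored by global alignment against the consensus.
decompose_oracle <- function(segment, consensus_seq, slack = 2,
                             match = 2, mismatch = -2, gap_open = -4,
                             gap_extend = -1) {
  m <- nchar(consensus_seq)
  L <- nchar(segment)
  best <- list(score = -Inf, parts = NULL)
  lens <- seq(max(1, m - slack), m + slack)
  recurse <- function(start, parts, score) {
    if (start > L) {
      if (score > best$score) best <<- list(score = score, parts = parts)
      return(invisible())
    }
    for (l in lens) {
      if (start + l - 1 > L) next
      part <- substr(segment, start, start + l - 1)
      s <- bs_align_score(part, consensus_seq, "global", match, mismatch,
                          gap_open, gap_extend)
      recurse(start + l, c(parts, part), score + s)
    }
  }
  recurse(1, character(0), 0)
  best
}

# Gabriel definition evaluated naively over all intervals, with a
# separately-coded greedy resolution.
gabriel_oracle <- function(panel, maf_min = 0.05, strong_ld = c(0.70, 0.98),
                           recomb_upper = 0.90, frac = 0.95,
                           max_pair_bp = 500000) {
  f <- colMeans(panel$geno)
  keep <- pmin(f, 1 - f) > maf_min
  pos <- panel$positions[keep]
  g <- panel$geno[, keep, drop = FALSE]
  S <- ncol(g)
  if (S < 2) return(data.frame())
  classify <- function(i, j) {
    if (pos[j] - pos[i] > max_pair_bp) return(0L)
    cnt <- c(sum(g[, i] == 1 & g[, j] == 1), sum(g[, i] == 1 & g[, j] == 0),
             sum(g[, i] == 0 & g[, j] == 1), sum(g[, i] == 0 & g[, j] == 0))
    ci <- dprime_ci(cnt)
    if (ci$lower >= strong_ld[1] && ci$upper >= strong_ld[2]) return(1L)
    if (ci$upper < recomb_upper) return(-1L)
    0L
  }
  cand <- data.frame()
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      if (classify(i, j) != 1L) next
      ns <- 0L; nr <- 0L
      for (a in i:(j - 1)) for (b in (a + 1):j) {
        cl <- classify(a, b)
        if (cl == 1L) ns <- ns + 1L
        if (cl == -1L) nr <- nr + 1L
      }
      if (ns + nr > 0 && ns / (ns + nr) >= frac) {
        cand <- rbind(cand, data.frame(i = i, j = j, span = pos[j] - pos[i]))
      }
    }
  }
  if (nrow(cand) == 0) return(data.frame())
  chosen <- data.frame()
  remaining <- cand[order(-cand$span, cand$i), ]
  blocked <- rep(FALSE, S)
  for (r in seq_len(nrow(remaining))) {
    i <- remaining$i[r]; j <- remaining$j[r]
    if (!any(blocked[i:j])) {
      blocked[i:j] <- TRUE
      chosen <- rbind(chosen, remaining[r, ])
    }
  }
  chosen[order(chosen$i), ]
}

# D' CI by direct multinomial evaluation on the grid (stats::dmultinom).
dprime_ci_oracle <- function(counts, coverage = 0.90, grid = 0.001) {
  ntot <- sum(counts)
  pA <- (counts[1] + counts[2]) / ntot
  pB <- (counts[1] + counts[3]) / ntot
  Dobs <- counts[1] / ntot - pA * pB
  sgn <- if (Dobs >= 0) 1 else -1
  Dmax <- if (Dobs >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dgrid <- seq(0, 1, by = grid)
  lik <- vapply(dgrid, function(dp) {
    p <- c(pA * pB + sgn * dp * Dmax, pA * (1 - pB) - sgn * dp * Dmax,
           (1 - pA) * pB - sgn * dp * Dmax,
           (1 - pA) * (1 - pB) + sgn * dp * Dmax)
    if (any(p < -1e-12)) return(0)
    p <- pmax(p, 0)
    if (any(counts > 0 & p == 0)) return(0)
    stats::dmultinom(counts, prob = p)
  }, numeric(1))
  mass <- lik / sum(lik)
  alpha <- (1 - coverage) / 2
  lower <- dgrid[which(cumsum(mass) >= alpha)[1]]
  upper <- dgrid[max(which(rev(cumsum(rev(mass))) >= alpha))]
  list(lower = lower, upper = upper)
}

# Pearson chi-square by the textbook formula.
chisq_oracle <- function(tab) {
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  list(chi2 = sum((tab - expd)^2 / expd),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

hwe_oracle <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum((counts - expd)^2 / expd)
}

# random binary haplotype matrix with at least one segregating column
random_hap_matrix <- function(n_max = 20, s_max = 50) {
  n <- sample(4:n_max, 1)
  S <- sample(1:s_max, 1)
  mat <- matrix(rbinom(n * S, 1, runif(1, 0.1, 0.9)), n, S)
  mat
}

# small random phased panel for LD/block tests
random_panel <- function(n_hap = 40, n_sites = 8, span = 50000) {
  pos <- sort(sample.int(span, n_sites))
  # mixture of correlated neighbours and independent sites
  g <- matrix(0L, n_hap, n_sites)
  base <- rbinom(n_hap, 1, 0.5)
  for (j in seq_len(n_sites)) {
    if (runif(1) < 0.5) {
      flip <- rbinom(n_hap, 1, 0.1)
      g[, j] <- as.integer(xor(base, flip))
    } else {
      g[, j] <- rbinom(n_hap, 1, runif(1, 0.2, 0.8))
    }
  }
  keep <- colMeans(g) > 0 & colMeans(g) < 1
  snp_panel("chrT", pos[keep], g[, keep, drop = FALSE],
            paste0("S", seq_len(n_hap / 2)))
}
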