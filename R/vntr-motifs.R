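#' Consensus-period motif description
#'
#' @param m Period length (aa or bp), >= 2.
#' @param alphabet `"aa"` or `"nt"`.
#' @param consensus_seq Optional consensus string of length `m`; when
#'   absent, [decompose_vntr()] estimates it from the segment.
#' @return A `motif_consensus` list.
#' @export
motif_consensus <- function(m, alphabet = c("aa", "nt"),
                            consensus_seq = NULL) {
  alphabet <- match.arg(alphabet)
  m <- as.integer(m)
  if (m < 2) abort("period m must be >= 2")
  if (!is.null(consensus_seq) && nchar(consensus_seq) != m) {
    abort("consensus_seq length must equal m")
  }
  structure(list(m = m, alphabet = alphabet, consensus_seq = consensus_seq),
            class = "motif_consensus")
}

# modal m-mer of the non-overlapping frames, maximizing total identity to
# all frames; ties broken lexicographically
estimate_consensus <- function(segment, m) {
  n_frames <- floor(nchar(segment) / m)
  frames <- substring(segment, m * (seq_len(n_frames) - 1) + 1,
                      m * seq_len(n_frames))
  cand <- sort(unique(frames))
  frame_mat <- do.call(rbind, strsplit(frames, "", fixed = TRUE))
  score <- vapply(cand, function(cc) {
    cv <- strsplit(cc, "", fixed = TRUE)[[1]]
    sum(t(frame_mat) == cv)
  }, numeric(1))
  cand[which.max(score)] # which.max takes the first (lexicographic) tie
}

#' Decompose a degenerate VNTR segment into consensus-period motifs
#'
#' Period-constrained wraparound dynamic programming aligns the segment
#' against unbounded tandem copies of the consensus; instance boundaries
#' fall where the motif phase wraps. The instances tile the segment, so
#' concatenating them reproduces the input byte for byte.
#' Substitution-only instances have length `m`; instances touched by an
#' insertion or deletion are flagged `has_indel`.
#'
#' @param segment Amino-acid or nucleotide string, `nchar(segment) >= m`.
#' @param consensus A [motif_consensus()].
#' @param scoring Numeric vector `(match, mismatch, gap_open, gap_extend)`,
#'   default `c(2, -2, -4, -1)`.
#' @return Object of class `motif_decomposition`: fields `segment`,
#'   `consensus_seq`, `m`, `score` and `instances` (tibble with `seq`,
#'   `start`, `end` 1-based inclusive, `has_indel`). `n_instances` equals
#'   `nrow(instances)`.
#' @export
decompose_vntr <- function(segment, consensus,
                           scoring = c(2, -2, -4, -1)) {
  stopifnot(inherits(consensus, "motif_consensus"))
  m <- consensus$m
  if (nchar(segment) < m) abort("segment shorter than the motif period")
  cseq <- consensus$consensus_seq %||% estimate_consensus(segment, m)
  res <- .wraparound_decompose_cpp(segment, cseq,
                                   as.integer(scoring[1]),
                                   as.integer(scoring[2]),
                                   as.integer(scoring[3]),
                                   as.integer(scoring[4]))
  idx <- res$motif_index
  copies <- sort(unique(idx))
  instances <- purrr::map_dfr(copies, function(cp) {
    pos <- which(idx == cp)
    tibble(seq = substr(segment, min(pos), max(pos)),
           start = min(pos), end = max(pos),
           has_indel = (max(pos) - min(pos) + 1L != m) ||
             res$n_del[cp] > 0 || res$n_ins[cp] > 0)
  })
  structure(list(segment = segment, consensus_seq = cseq, m = m,
                 score = res$score, instances = instances,
                 n_instances = nrow(instances)),
            class = "motif_decomposition")
}

#' @export
print.motif_decomposition <- function(x, ...) {
  cat(sprintf("<motif_decomposition> %d instances of period %d (%d with indel)\n",
              x$n_instances, x$m, sum(x$instances$has_indel)))
  invisible(x)
}

#' @export
tidy.motif_decomposition <- function(x, ...) {
  mutate(x$instances, instance = dplyr::row_number(), .before = 1)
}

#' Decompose every TR segment of a cohort
#'
#' @param segments Tibble with columns `haplotype`, `domain`, `segment`.
#' @param consensus A [motif_consensus()].
#' @param scoring Passed to [decompose_vntr()].
#' @return Long tibble: `haplotype`, `domain`, `instance`, `seq`, `start`,
#'   `end`, `has_indel`.
#' @export
decompose_cohort <- function(segments, consensus,
                             scoring = c(2, -2, -4, -1)) {
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    d <- decompose_vntr(segments$segment[i], consensus, scoring)
    mutate(tidy(d), haplotype = segments$haplotype[i],
           domain = segments$domain[i], .before = 1)
  })
}

#' Build the cohort-wide unique-motif catalogue and allele strings
#'
#' Unique full-length (indel-free) motif instances receive stable ids
#' ordered by descending total count, ties lexicographic. Indel-bearing
#' instances are kept out of the catalogue but retained in allele strings
#' under the reserved id `IND`. The allele string of a haplotype is the
#' ordered id sequence with `|` between TR domains; the number of unique
#' allele strings is the unique-allele count.
#'
#' @param decomp Long tibble from [decompose_cohort()].
#' @return Object of class `motif_catalog` with `motifs` (tibble
#'   `motif_id`, `seq`, `total_count`), `alleles` (tibble `haplotype`,
#'   `allele_string`), `n_unique_motifs`, `n_unique_alleles`.
#' @export
build_catalog <- function(decomp) {
  full <- filter(decomp, !.data$has_indel)
  tab <- full |>
    dplyr::count(.data$seq, name = "total_count") |>
    arrange(desc(.data$total_count), .data$seq) |>
    mutate(motif_id = sprintf("M%03d", dplyr::row_number()))
  id_of <- setNames(tab$motif_id, tab$seq)
  decomp2 <- decomp |>
    mutate(motif_id = ifelse(.data$has_indel, "IND",
                             unname(id_of[.data$seq])))
  alleles <- decomp2 |>
    group_by(.data$haplotype) |>
    dplyr::arrange(.data$domain, .data$instance, .by_group = TRUE) |>
    summarise(allele_string = {
      paste(tapply(.data$motif_id, .data$domain, paste, collapse = "-"),
            collapse = "|")
    }, .groups = "drop")
  structure(list(motifs = select(tab, "motif_id", "seq", "total_count"),
                 alleles = alleles,
                 n_unique_motifs = nrow(tab),
                 n_unique_alleles = dplyr::n_distinct(alleles$allele_string)),
            class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog> %d unique motifs, %d unique alleles (%d haplotypes)\n",
              x$n_unique_motifs, x$n_unique_alleles, nrow(x$alleles)))
  invisible(x)
}

#' @export
tidy.motif_catalog <- function(x, ...) x$motifs

#' @export
glance.motif_catalog <- function(x, ...) {
  tibble(n_unique_motifs = x$n_unique_motifs,
         n_unique_alleles = x$n_unique_alleles,
         n_haplotypes = nrow(x$alleles))
}

#' Haplotype-by-motif usage matrix
#'
#' `raw` counts motif instances per haplotype; `length_norm` divides each
#' row by the haplotype's total instance count (including indel-bearing
#' instances), so rows sum to 1 when no indel instances exist;
#' `column_norm` min-max scales each `length_norm` column (a column with
#' identical values maps to all zeros).
#'
#' @param catalog A [build_catalog()] result.
#' @param decomp The long decomposition tibble the catalogue was built
#'   from.
#' @param mode One of `"raw"`, `"length_norm"`, `"column_norm"`.
#' @return A numeric matrix (rows = haplotypes, cols = motif ids) of class
#'   `usage_matrix`.
#' @export
usage_matrix <- function(catalog, decomp,
                         mode = c("length_norm", "raw", "column_norm")) {
  mode <- match.arg(mode)
  haps <- unique(decomp$haplotype)
  totals <- table(decomp$haplotype)[haps]
  if (length(haps) == 0 || any(totals == 0)) {
    abort("haplotype with zero motif instances")
  }
  id_of <- setNames(catalog$motifs$motif_id, catalog$motifs$seq)
  full <- filter(decomp, !.data$has_indel)
  counts <- matrix(0, nrow = length(haps), ncol = nrow(catalog$motifs),
                   dimnames = list(haps, catalog$motifs$motif_id))
  tab <- full |> dplyr::count(.data$haplotype, .data$seq)
  for (i in seq_len(nrow(tab))) {
    counts[tab$haplotype[i], id_of[[tab$seq[i]]]] <- tab$n[i]
  }
  out <- switch(mode,
    raw = counts,
    length_norm = counts / as.numeric(totals),
    column_norm = {
      ln <- counts / as.numeric(totals)
      apply(ln, 2, function(col) {
        rng <- max(col) - min(col)
        if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
      })
    })
  structure(out, class = c("usage_matrix", class(out)), mode = mode)
}

#' @export
tidy.usage_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(haplotype = rep(rownames(m), times = ncol(m)),
         motif_id = rep(colnames(m), each = nrow(m)),
         value = as.vector(m))
}

#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group method with arithmetic mean: the distance from a
#' merged cluster to any other is the size-weighted mean of its members'
#' distances, and each merge sits at half the merge distance so the tree
#' is ultrametric. Ties are broken by the smallest (row, col) index pair.
#'
#' @param dist_mat Symmetric non-negative matrix with zero diagonal.
#' @param labels Optional leaf labels (defaults to rownames).
#' @return Object of class `vntr_dendrogram` (hclust-compatible fields
#'   `merge`, `height`, `labels`, `order`).
#' @export
upgma_cluster <- function(dist_mat, labels = NULL) {
  dist_mat <- as.matrix(dist_mat)
  if (!isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-12))) {
    abort("distance matrix must be symmetric")
  }
  if (any(dist_mat < 0)) abort("distances must be non-negative")
  n <- nrow(dist_mat)
  labels <- labels %||% rownames(dist_mat) %||% paste0("L", seq_len(n))
  if (n == 1) {
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          labels = labels, order = 1L, method = "upgma"),
                     class = "vntr_dendrogram"))
  }
  d <- dist_mat
  active <- seq_len(n)
  cluster_id <- -seq_len(n)     # hclust convention: negative leaf ids
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    a <- cluster_id[i]; b <- cluster_id[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    height[step] <- best_d / 2
    new_row <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    members[[length(members) + 1]] <- c(members[[active[i]]],
                                        members[[active[j]]])
    active <- c(active[keep], length(members))
    cluster_id <- c(cluster_id[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  ord <- walk(n - 1)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, method = "upgma"),
            class = "vntr_dendrogram")
}

#' @export
print.vntr_dendrogram <- function(x, ...) {
  cat(sprintf("<vntr_dendrogram> %d leaves, UPGMA\n", length(x$labels)))
  invisible(x)
}

#' @export
tidy.vntr_dendrogram <- function(x, ...) {
  if (nrow(x$merge) == 0) {
    return(tibble(step = integer(), left = integer(), right = integer(),
                  height = numeric()))
  }
  tibble(step = seq_len(nrow(x$merge)), left = x$merge[, 1],
         right = x$merge[, 2], height = x$height)
}

#' @export
as.hclust.vntr_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Position frequency matrix and consensus of catalogued motifs
#'
#' Builds an instance-weighted residue frequency matrix over motif
#' positions 1..m from all full-length instances; each column sums to 1.
#' The consensus takes the most frequent residue per column, ties broken
#' lexicographically.
#'
#' @param decomp Long decomposition tibble ([decompose_cohort()]).
#' @param m Motif period.
#' @return Object of class `motif_pfm`: fields `pfm` (residues x
#'   positions) and `consensus`.
#' @export
position_frequency_matrix <- function(decomp, m) {
  full <- filter(decomp, !.data$has_indel)
  if (nrow(full) == 0) abort("no full-length instances")
  mat <- do.call(rbind, strsplit(full$seq, "", fixed = TRUE))
  residues <- sort(unique(as.vector(mat)))
  pfm <- vapply(seq_len(m), function(j) {
    tab <- table(factor(mat[, j], levels = residues))
    as.numeric(tab) / nrow(mat)
  }, numeric(length(residues)))
  rownames(pfm) <- residues
  colnames(pfm) <- seq_len(m)
  consensus <- paste(vapply(seq_len(m), function(j) {
    residues[which.max(pfm[, j])] # residues sorted: ties -> lexicographic
  }, character(1)), collapse = "")
  structure(list(pfm = pfm, consensus = consensus, n_instances = nrow(mat)),
            class = "motif_pfm")
}

#' @export
print.motif_pfm <- function(x, ...) {
  cat(sprintf("<motif_pfm> consensus %s from %d instances\n",
              x$consensus, x$n_instances))
  invisible(x)
}

#' @export
tidy.motif_pfm <- function(x, ...) {
  tibble(residue = rep(rownames(x$pfm), times = ncol(x$pfm)),
         position = rep(seq_len(ncol(x$pfm)), each = nrow(x$pfm)),
         freq = as.vector(x$pfm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
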