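AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# lexicographically smallest codon per amino acid: a fixed, deterministic
# reverse translation so nucleotide output is reproducible
fixed_codons <- function() {
  gc <- codon_table()
  aa <- unique(unname(gc))
  setNames(vapply(aa, function(a) min(names(gc)[gc == a]), character(1)), aa)
}

reverse_translate <- function(aa_seq) {
  tab <- fixed_codons()
  paste(tab[strsplit(aa_seq, "", fixed = TRUE)[[1]]], collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic cysteine-rich domain templates
#'
#' Deterministic 40-aa stand-ins for the five mucin cys-domain types.
#' These are synthetic sequences with a mucin-like cysteine spacing, not
#' curated biological templates.
#'
#' @return Template tibble as from [read_domain_templates()].
#' @export
synthetic_cys_templates <- function() {
  types <- c("I", "II", "III", "IV", "V")
  purrr::map_dfr(seq_along(types), function(t) {
    set.seed(8800 + t)
    aa <- sample(setdiff(AA20, "C"), 40, replace = TRUE)
    aa[seq(1, 40, by = 4)] <- "C" # cys every 4th position
    tibble(name = paste0("cys", types[t], "_syn"), domain_class = "cys",
           cys_type = types[t], aa_seq = paste(aa, collapse = ""))
  })
}

# patterned founder motif-id string: base id with substitutions at fixed
# positions
founder_string <- function(n, base = "A", subs = c()) {
  s <- rep(base, n)
  for (p in names(subs)) s[as.integer(p)] <- subs[[p]]
  s
}

#' Motif variant pool of the synthetic MUC5AC-like 8-mer repeat
#'
#' @return Named character vector of period-8 amino-acid motifs; variant
#'   `A` is the TTSTTSAP consensus.
#' @export
motif_pool <- function() {
  c(A = "TTSTTSAP", B = "TTSTTVAP", C = "TTSTTSAA", D = "PTSTTSAP",
    E = "TTSTTSTP", F = "TSSTTSAP", G = "TTSTPSAP", H = "TTSTTSVP",
    I = "ATSTTSAP", J = "TTSSTSAP")
}

founder_architectures <- function() {
  list(
    H1 = list( # P1-like: deletion of cys II/III before the first TR
      cys_before = c("I", "IV", "V"),
      inter_cys = c("I", "II", "III"), terminal_cys = "IV",
      trs = list(TR1 = founder_string(18, subs = c("3" = "B", "9" = "C")),
                 TR2 = founder_string(20, subs = c("5" = "E")),
                 TR3 = founder_string(15, subs = c("2" = "F", "11" = "B")),
                 TR4 = founder_string(22, subs = c("7" = "H")))),
    H2 = list( # P2-like: canonical five cys before the first TR
      cys_before = c("I", "II", "III", "IV", "V"),
      inter_cys = c("I", "II", "III"), terminal_cys = "IV",
      trs = list(TR1 = founder_string(25, subs = c("4" = "C", "12" = "D")),
                 TR2 = founder_string(20, subs = c("5" = "E", "15" = "G")),
                 TR3 = founder_string(15, subs = c("2" = "F")),
                 TR4 = founder_string(22, subs = c("7" = "H", "20" = "J")))),
    H3 = list( # P4-like: extra central TR of 11 copies plus an extra cys
      cys_before = c("I", "II", "III", "IV", "V"),
      inter_cys = c("I", "V", "II", "III"), terminal_cys = "IV",
      trs = list(TR1 = founder_string(28, subs = c("4" = "C", "21" = "I")),
                 TR2 = founder_string(20, subs = c("5" = "E")),
                 TRc = founder_string(11, subs = c("6" = "B")),
                 TR3 = founder_string(15, subs = c("2" = "F", "8" = "J")),
                 TR4 = founder_string(22, subs = c("7" = "H"))))
  )
}

PREFIX_AA <- "MGKADLWQREHGFNVKLDAQYREWGMDKLHF" # 31 aa, exons 1-2
TAIL_AA <- "GKLDNQWREHAFMVYKLDGQ"               # 20 aa, exons 4-5

assemble_protein <- function(arch, tr_strings, templates, pool) {
  tmpl_of <- setNames(templates$aa_seq, templates$cys_type)
  tr_aa <- vapply(tr_strings, function(ids) {
    paste(pool[ids], collapse = "")
  }, character(1))
  central <- paste0(paste(tmpl_of[arch$cys_before], collapse = ""))
  n_tr <- length(tr_aa)
  stopifnot(length(arch$inter_cys) == n_tr - 1)
  for (i in seq_len(n_tr)) {
    central <- paste0(central, tr_aa[i])
    if (i < n_tr) central <- paste0(central, tmpl_of[arch$inter_cys[i]])
  }
  central <- paste0(central, tmpl_of[arch$terminal_cys])
  paste0(PREFIX_AA, central, TAIL_AA)
}

protein_to_cds <- function(protein) paste0(reverse_translate(protein), "TAA")

# fixed CDS split: exon1 45 nt + exon2 48 nt cover the 31-aa prefix;
# exon4 30 nt + exon5 33 nt cover the 20-aa tail plus stop; exon3 is the
# variable central exon
cds_exon_pieces <- function(cds) {
  L <- nchar(cds)
  list(e1 = substr(cds, 1, 45), e2 = substr(cds, 46, 93),
       e3 = substr(cds, 94, L - 63),
       e4 = substr(cds, L - 62, L - 33), e5 = substr(cds, L - 32, L))
}

#' Build the synthetic mucin-like reference locus
#'
#' Constructs a deterministic desk-scale locus: a five-exon gene whose
#' large central exon carries the cys/TR architecture, a reference
#' scaffold with unique exon-flank anchors, the synthetic cys template
#' library, the repeat motif pool, founder architectures for three
#' haplogroups (H1 P1-like, H2 P2-like, H3 P4-like with a central TR of
#' 11 copies), and the protein-group rule table. The reference allele is
#' the H2 founder.
#'
#' @param seed Seed for the intron/flank scaffold sequence.
#' @return List with `reference_seq`, `model` ([gene_model()]),
#'   `templates`, `pool`, `founders`, `consensus`
#'   ([motif_consensus()]), `rules`.
#' @export
toy_locus <- function(seed = 4211) {
  templates <- synthetic_cys_templates()
  pool <- motif_pool()
  founders <- founder_architectures()
  ref_protein <- assemble_protein(founders$H2, founders$H2$trs, templates,
                                  pool)
  cds <- protein_to_cds(ref_protein)
  pieces <- cds_exon_pieces(cds)
  for (attempt in 0:24) {
    set.seed(seed + attempt)
    flank5 <- random_dna(200); flank3 <- random_dna(200)
    introns <- replicate(4, random_dna(150))
    seq_parts <- c(flank5, pieces$e1, introns[1], pieces$e2, introns[2],
                   pieces$e3, introns[3], pieces$e4, introns[4], pieces$e5,
                   flank3)
    reference_seq <- paste(seq_parts, collapse = "")
    lens <- nchar(seq_parts)
    offs <- cumsum(c(0, lens))
    exon_idx <- c(2, 4, 6, 8, 10)
    exons <- tibble(start = offs[exon_idx], end = offs[exon_idx + 1])
    # anchors (k = 30) must be unique in the scaffold
    anchors_ok <- all(vapply(seq_len(5), function(i) {
      l <- substr(reference_seq, exons$start[i] - 29, exons$start[i])
      r <- substr(reference_seq, exons$end[i] + 1, exons$end[i] + 30)
      count_l <- length(gregexpr(l, reference_seq, fixed = TRUE)[[1]])
      count_r <- length(gregexpr(r, reference_seq, fixed = TRUE)[[1]])
      count_l == 1 && count_r == 1
    }, logical(1)))
    if (anchors_ok) break
  }
  if (!anchors_ok) abort("could not build a scaffold with unique anchors")
  model <- gene_model("MUCSYN", genomic_interval("chrSyn", exons$start[1],
                                                 exons$end[5], "+"),
                      exons, vntr_exon_index = 3,
                      coding_start = exons$start[1],
                      coding_end = exons$end[5])
  list(reference_seq = reference_seq, model = model, templates = templates,
       pool = pool, founders = founders,
       consensus = motif_consensus(8, "aa", "TTSTTSAP"),
       rules = default_group_rules())
}

#' Default protein-group rule table
#'
#' Encodes the shipped fixture
#' (`inst/extdata/protein_group_rules.tsv`): P1 lacks two cys before the
#' first TR; P2/P3 split a canonical four-TR architecture by first-TR
#' copy number; P4/P6 carry five TR domains with a central TR of 11
#' copies; P5/P6 carry a cys duplication (seven cys before the first TR).
#'
#' @return Rule tibble as from [read_group_rules()].
#' @export
default_group_rules <- function() {
  tibble(group = c("P1", "P2", "P3", "P4", "P5", "P6"),
         min_tr = c(4L, 4L, 4L, 5L, 4L, 5L),
         max_tr = c(4L, 4L, 4L, 5L, 4L, 5L),
         min_cys_before = c(3L, 5L, 5L, 5L, 7L, 7L),
         max_cys_before = c(3L, 5L, 5L, 5L, 7L, 7L),
         central_tr_copies = c(NA, NA, NA, 11L, NA, 11L),
         tr1_min = c(NA, NA, 27L, NA, NA, NA),
         tr1_max = c(NA, 26L, NA, NA, NA, NA))
}

mutate_tr_strings <- function(tr_strings, pool, sub_rate, dup_rate,
                              del_rate) {
  n_dup <- 0L; n_del <- 0L; n_sub <- 0L
  out <- lapply(tr_strings, function(ids) {
    seqs <- unname(pool[ids])
    kept <- list()
    for (s in seqs) { # whole-motif events, per-copy Bernoulli
      if (runif(1) < del_rate) { n_del <<- n_del + 1L; next }
      kept[[length(kept) + 1]] <- s
      if (runif(1) < dup_rate) {
        n_dup <<- n_dup + 1L
        kept[[length(kept) + 1]] <- s
      }
    }
    vapply(kept, function(s) { # per-residue substitutions
      aa <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- runif(length(aa)) < sub_rate
      if (any(hit)) {
        n_sub <<- n_sub + sum(hit)
        aa[hit] <- vapply(aa[hit], function(old) {
          sample(setdiff(AA20, old), 1)
        }, character(1))
      }
      paste(aa, collapse = "")
    }, character(1))
  })
  list(tr_seqs = out, n_dup = n_dup, n_del = n_del, n_sub = n_sub)
}

#' Simulate a haplogroup-structured VNTR cohort
#'
#' Per haplotype: the founder motif strings of its haplogroup are copied;
#' whole-motif deletions and duplications are applied per copy
#' (Bernoulli), then per-residue amino-acid substitutions at
#' `sub_rate` (replacement drawn uniformly from the other 19 residues, so
#' reverse translation can never create a stop codon); the mutated
#' central exon is spliced into the reference scaffold. Identical
#' arguments and seed give byte-identical output.
#'
#' @param locus A [toy_locus()] (or compatible list).
#' @param sizes Named haplotype counts per haplogroup; the default is the
#'   206-haplotype composition H1 = 103, H2 = 78, H3 = 25.
#' @param sub_rate Per-residue substitution probability (default 0.002).
#' @param dup_rate,del_rate Per-copy whole-motif duplication/deletion
#'   probabilities (default 0.01 each).
#' @param seed RNG seed.
#' @return List with `haplotypes` (tibble `sample_id`, `hap_index`,
#'   `population`, `haplogroup`, `seq`) and `truth` (per-haplotype
#'   generator record: final motif strings, per-TR copy numbers, protein
#'   length, event counts, truth group label).
#' @export
simulate_vntr_cohort <- function(locus,
                                 sizes = c(H1 = 103L, H2 = 78L, H3 = 25L),
                                 sub_rate = 0.002, dup_rate = 0.01,
                                 del_rate = 0.01, seed = 1) {
  set.seed(seed)
  pops <- c("AFR", "EUR", "EAS", "SAS", "AMR")
  groups <- rep(names(sizes), times = sizes)
  n_hap <- length(groups)
  ref_pieces <- strsplit_scaffold(locus)
  rows <- vector("list", n_hap)
  truth <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    g <- groups[h]
    arch <- locus$founders[[g]]
    mut <- mutate_tr_strings(arch$trs, locus$pool, sub_rate, dup_rate,
                             del_rate)
    protein <- assemble_protein_seqs(arch, mut$tr_seqs, locus$templates)
    cds <- protein_to_cds(protein)
    pieces <- cds_exon_pieces(cds)
    hap_seq <- paste0(ref_pieces$before, pieces$e3, ref_pieces$after)
    sample_id <- sprintf("S%03d", (h + 1) %/% 2)
    rows[[h]] <- tibble(sample_id = sample_id,
                        hap_index = 2L - (h %% 2L),
                        population = pops[((h - 1) %/% 2) %% 5 + 1],
                        haplogroup = g, seq = hap_seq)
    copy_numbers <- lengths(mut$tr_seqs)
    truth[[h]] <- tibble(
      sample_id = sample_id, hap_index = 2L - (h %% 2L), haplogroup = g,
      allele_string = paste(vapply(mut$tr_seqs, paste, character(1),
                                   collapse = "-"), collapse = "|"),
      tr_copy_numbers = paste(copy_numbers, collapse = ","),
      n_instances = sum(copy_numbers),
      protein_length = nchar(protein),
      n_dup = mut$n_dup, n_del = mut$n_del, n_sub = mut$n_sub,
      group_truth = truth_group(arch, copy_numbers, locus$rules))
  }
  list(haplotypes = bind_rows(rows), truth = bind_rows(truth))
}

assemble_protein_seqs <- function(arch, tr_seqs, templates) {
  tmpl_of <- setNames(templates$aa_seq, templates$cys_type)
  tr_aa <- vapply(tr_seqs, paste, character(1), collapse = "")
  central <- paste(tmpl_of[arch$cys_before], collapse = "")
  n_tr <- length(tr_aa)
  for (i in seq_len(n_tr)) {
    central <- paste0(central, tr_aa[i])
    if (i < n_tr) central <- paste0(central, tmpl_of[arch$inter_cys[i]])
  }
  central <- paste0(central, tmpl_of[arch$terminal_cys])
  paste0(PREFIX_AA, central, TAIL_AA)
}

truth_group <- function(arch, copy_numbers, rules) {
  ann <- structure(list(n_TR_domains = length(copy_numbers),
                        n_cys_before_first_TR = length(arch$cys_before),
                        per_TR_motif_counts = unname(copy_numbers)),
                   class = "domain_annotation")
  classify_protein_group(ann, rules)
}

strsplit_scaffold <- function(locus) {
  ex <- locus$model$exons
  list(before = substr(locus$reference_seq, 1, ex$start[3]),
       after = substr(locus$reference_seq, ex$end[3] + 1,
                      nchar(locus$reference_seq)))
}

# ---- coalescent panels ----------------------------------------------------

# neutral Hudson genealogy: returns branches (length + leaf-descendant
# sets) and tree height, times in coalescent units of 2N generations
neutral_genealogy <- function(n) {
  times <- rep(0, n)
  desc <- lapply(seq_len(n), identity)
  t_now <- 0
  branches_len <- numeric(0)
  branches_desc <- list()
  while (length(desc) > 1) {
    k <- length(desc)
    t_now <- t_now + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (p in pair) {
      branches_len <- c(branches_len, t_now - times[p])
      branches_desc[[length(branches_desc) + 1]] <- desc[[p]]
    }
    merged <- c(desc[[pair[1]]], desc[[pair[2]]])
    desc <- c(desc[-pair], list(merged))
    times <- c(times[-pair], t_now)
  }
  list(branch_len = branches_len, branch_desc = branches_desc,
       height = t_now)
}

star_genealogy <- function(n, tau) {
  list(branch_len = rep(tau, n), branch_desc = lapply(seq_len(n), identity),
       height = tau)
}

balanced_genealogy <- function(n, tau, max_tries = 1000) {
  if (n %% 2 != 0) abort("balanced shape requires even n")
  half <- n / 2
  for (try in seq_len(max_tries)) {
    g1 <- neutral_genealogy(half)
    g2 <- neutral_genealogy(half)
    if (g1$height < tau && g2$height < tau) {
      desc2 <- lapply(g2$branch_desc, function(d) d + half)
      return(list(
        branch_len = c(g1$branch_len, g2$branch_len, tau - g1$height,
                       tau - g2$height),
        branch_desc = c(g1$branch_desc, desc2, list(seq_len(half)),
                        list(seq_len(half) + half)),
        height = tau))
    }
  }
  abort("balanced genealogy: clade height exceeded tau in every try")
}

#' Simulate a phased SNP panel under a coalescent genealogy
#'
#' Neutral: Hudson coalescent without recombination (inter-coalescence
#' times Exp(k(k-1)/2) in units of 2N generations). Star: all n lineages
#' join at `tau`, so every mutation is a singleton (excess of rare
#' variation). Balanced: two neutral clades of n/2 joined at `tau`
#' (excess of intermediate-frequency variation). Mutations follow the
#' infinite-sites model, Poisson(theta/2 x total branch length), dropped
#' uniformly on branches; site positions are uniform without replacement
#' on `interval`.
#'
#' @param n Number of haplotypes.
#' @param theta Population mutation rate (4N mu for the simulated
#'   stretch).
#' @param shape `"neutral"`, `"star"`, or `"balanced"`.
#' @param tau Clade-join time in coalescent units; defaults to 1 (star)
#'   or 5 (balanced).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param chrom Chromosome label for the panel.
#' @param interval 1-based closed interval for site positions.
#' @return List with `panel` ([snp_panel()]), `S`, `tree_length`,
#'   `shape`.
#' @export
simulate_coalescent_panel <- function(n, theta,
                                      shape = c("neutral", "star",
                                                "balanced"),
                                      tau = NULL, seed = NULL,
                                      chrom = "chrSim",
                                      interval = c(1L, 10000L)) {
  shape <- match.arg(shape)
  if (n < 2) abort("n must be >= 2")
  if (theta <= 0) abort("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tau <- tau %||% switch(shape, star = 1, balanced = 5, neutral = NULL)
  gen <- switch(shape,
                neutral = neutral_genealogy(n),
                star = star_genealogy(n, tau),
                balanced = balanced_genealogy(n, tau))
  total_len <- sum(gen$branch_len)
  S <- rpois(1, theta / 2 * total_len)
  width <- interval[2] - interval[1] + 1
  if (S > width) abort("more mutations than available positions")
  if (S == 0) {
    panel <- snp_panel(chrom, integer(), matrix(0L, n, 0),
                       paste0("S", seq_len(ceiling(n / 2))))
    return(list(panel = panel, S = 0L, tree_length = total_len,
                shape = shape))
  }
  branch <- sample.int(length(gen$branch_len), S, replace = TRUE,
                       prob = gen$branch_len)
  pos <- sort(sample.int(width, S) + interval[1] - 1L)
  geno <- matrix(0L, n, S)
  for (s in seq_len(S)) geno[gen$branch_desc[[branch[s]]], s] <- 1L
  panel <- snp_panel(chrom, pos, geno, paste0("S", seq_len(ceiling(n / 2))))
  list(panel = panel, S = S, tree_length = total_len, shape = shape)
}

#' Plant tagging SNPs in known LD with haplogroup labels
#'
#' Each planted site starts as the exact membership indicator of its
#' target haplogroup (r2 = 1) and single-haplotype flips are applied
#' greedily until the realised r2 is within 0.02 of the requested value.
#'
#' @param panel A [snp_panel()].
#' @param labels Per-haplotype haplogroup labels.
#' @param spec Tibble with columns `target`, `r2`, `position`.
#' @return The panel with planted sites inserted (positions sorted); the
#'   realised r2 values are recorded in `attr(panel, "planted")`.
#' @export
plant_tag_snps <- function(panel, labels, spec) {
  if (length(labels) != n_haplotypes(panel)) {
    abort("labels must cover all haplotypes")
  }
  planted <- list()
  for (r in seq_len(nrow(spec))) {
    target <- spec$target[r]; want <- spec$r2[r]
    position <- as.integer(spec$position[r])
    if (want <= 0 || want > 1) abort("desired r2 must be in (0, 1]")
    if (position %in% panel$positions) {
      abort(sprintf("position collision at %d", position))
    }
    ind <- as.integer(labels == target)
    if (all(ind == 0)) abort("target haplogroup absent")
    allele <- ind
    realised <- 1
    n_flips <- 0L
    while (abs(realised - want) > 0.02) {
      cand <- vapply(seq_along(allele), function(h) {
        flipped <- allele
        flipped[h] <- 1L - flipped[h]
        if (all(flipped == 0) || all(flipped == 1)) return(NA_real_)
        ld_from_vectors(flipped, ind)$r2
      }, numeric(1))
      gain <- abs(cand - want)
      if (all(is.na(gain)) || min(gain, na.rm = TRUE) >=
            abs(realised - want)) {
        abort(sprintf(
          "unachievable r2 %.3f for %s; nearest achievable %.3f",
          want, target, realised))
      }
      h <- which.min(gain) # deterministic: lowest index on ties
      allele[h] <- 1L - allele[h]
      realised <- cand[h]
      n_flips <- n_flips + 1L
    }
    at <- findInterval(position, panel$positions)
    panel$positions <- append(panel$positions, position, after = at)
    panel$geno <- cbind(panel$geno[, seq_len(at), drop = FALSE], allele,
                        panel$geno[, setdiff(seq_len(ncol(panel$geno) - 1),
                                             seq_len(at)),
                                   drop = FALSE])
    planted[[length(planted) + 1]] <- tibble(target = target,
                                             position = position,
                                             desired_r2 = want,
                                             realised_r2 = realised,
                                             n_flips = n_flips)
  }
  # rebuild to revalidate ordering and entries
  out <- snp_panel(panel$chrom, panel$positions, panel$geno,
                   panel$sample_ids, panel$populations, panel$haplogroups,
                   panel$skip_report)
  attr(out, "planted") <- bind_rows(planted)
  out
}

#' Simulate a multi-bin genome-wide background panel
#'
#' Each bin is an independent coalescent panel placed in consecutive
#' 10-kbp windows; selected bins can be overridden with star or balanced
#' genealogies to plant selection signatures.
#'
#' @param n_bins Number of bins.
#' @param n,theta Per-bin coalescent parameters.
#' @param planted Optional tibble with columns `bin`, `shape` (and
#'   optional `tau`) overriding specific bins.
#' @param seed RNG seed.
#' @param bin_width Bin width in bp (default 10 kbp).
#' @param chrom Chromosome label.
#' @return List with `panel` (all bins concatenated) and `truth` (tibble
#'   `bin`, `shape`, `S`).
#' @export
simulate_genomewide_bins <- function(n_bins, n = 50, theta = 5,
                                     planted = NULL, seed = 1,
                                     bin_width = 10000L,
                                     chrom = "chrAuto") {
  set.seed(seed)
  if (!is.null(planted) && any(planted$bin > n_bins)) {
    abort("planted bin index exceeds n_bins")
  }
  shapes <- rep("neutral", n_bins)
  taus <- rep(NA_real_, n_bins)
  if (!is.null(planted)) {
    shapes[planted$bin] <- planted$shape
    if ("tau" %in% names(planted)) taus[planted$bin] <- planted$tau
  }
  pos_all <- integer(0)
  geno_all <- vector("list", n_bins)
  truth <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1L) * bin_width + 1L
    sim <- simulate_coalescent_panel(
      n, theta, shapes[b],
      tau = if (is.na(taus[b])) NULL else taus[b],
      chrom = chrom, interval = c(lo, lo + bin_width - 1L))
    pos_all <- c(pos_all, sim$panel$positions)
    geno_all[[b]] <- sim$panel$geno
    truth[[b]] <- tibble(bin = b, shape = shapes[b], S = sim$S)
  }
  geno <- do.call(cbind, geno_all)
  panel <- snp_panel(chrom, pos_all, geno,
                     paste0("S", seq_len(ceiling(n / 2))))
  list(panel = panel, truth = bind_rows(truth))
}
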