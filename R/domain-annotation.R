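#' Read a domain template library from FASTA
#'
#' Template ids follow the convention `name|class|type`, e.g.
#' `cys1a|cys|I` or `linker1|other|NA`. The shipped library
#' (`system.file("extdata", "cys_templates_synthetic.fa", package =
#' "mucvntr")`) contains synthetic stand-ins for the five mucin
#' cysteine-rich domain types, not curated biological sequences.
#'
#' @param path FASTA of amino-acid templates.
#' @return Tibble with columns `name`, `domain_class`, `cys_type`,
#'   `aa_seq`.
#' @export
read_domain_templates <- function(path) {
  fa <- read_fasta(path)
  parts <- strsplit(fa$id, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    abort(paste0("template ids must be name|class|type: ",
                 paste(fa$id[bad], collapse = ", ")))
  }
  out <- tibble(name = vapply(parts, `[`, "", 1),
                domain_class = vapply(parts, `[`, "", 2),
                cys_type = vapply(parts, `[`, "", 3),
                aa_seq = fa$seq)
  out$cys_type[out$domain_class != "cys"] <- NA_character_
  if (any(out$domain_class == "cys" & is.na(out$cys_type))) {
    abort("cys templates require a cys_type")
  }
  out
}

#' Segment a predicted protein into cys and tandem-repeat domains
#'
#' Every local-alignment hit of a cys template with identity >=
#' `min_identity` (matches / template length) over >= `min_coverage` of
#' the template becomes a candidate cys call; overlaps are resolved by
#' highest identity, then leftmost start. Maximal inter-cys segments
#' whose motif decomposition yields at least `tr_min_instances` tandem
#' instances at adequate similarity to the consensus become TR domains
#' numbered left to right.
#'
#' @param protein Amino-acid string.
#' @param templates Template tibble from [read_domain_templates()].
#' @param consensus A [motif_consensus()] for the repeat motif.
#' @param min_identity Cys-call identity threshold (default 0.8).
#' @param min_coverage Minimum aligned fraction of the template (default
#'   0.8).
#' @param tr_min_instances Minimum tandem instances to call a TR domain
#'   (default 3); guards against degenerate linkers.
#' @param min_motif_identity Minimum mean per-position identity of a
#'   segment's instances to the consensus (default 0.5).
#' @return Object of class `domain_annotation`: `calls` tibble (`label`,
#'   `start`, `end` 1-based inclusive aa coordinates, `identity`),
#'   `n_cys_before_first_TR`, `n_TR_domains`, `per_TR_motif_counts`, and
#'   `tr_segments` (tibble of TR intervals and decompositions).
#' @export
scan_domains <- function(protein, templates, consensus,
                         min_identity = 0.8, min_coverage = 0.8,
                         tr_min_instances = 3, min_motif_identity = 0.5) {
  if (nrow(templates) == 0) abort("templates must be non-empty")
  cys_tmpl <- filter(templates, .data$domain_class == "cys")
  hits <- purrr::map_dfr(seq_len(nrow(cys_tmpl)), function(t) {
    tl <- nchar(cys_tmpl$aa_seq[t])
    min_raw <- max(1L, as.integer(floor(0.3 * tl)))
    h <- .sw_hits_cpp(protein, cys_tmpl$aa_seq[t], 1L, -1L, -2L, -1L,
                      min_score = min_raw, max_hits = 64L)
    if (nrow(h) == 0) return(tibble())
    tibble(cys_type = cys_tmpl$cys_type[t],
           start = unname(h[, "sub_start"]) + 1L,
           end = unname(h[, "sub_end"]),
           identity = unname(h[, "n_match"]) / tl,
           coverage = unname(h[, "q_aligned"]) / tl)
  })
  if (nrow(hits) > 0) {
    hits <- filter(hits, .data$identity >= min_identity,
                   .data$coverage >= min_coverage)
  }
  calls <- tibble(label = character(), start = integer(), end = integer(),
                  identity = numeric())
  if (nrow(hits) > 0) {
    hits <- arrange(hits, desc(.data$identity), .data$start)
    taken <- rep(FALSE, nchar(protein))
    for (i in seq_len(nrow(hits))) {
      span <- seq(hits$start[i], hits$end[i])
      if (!any(taken[span])) {
        taken[span] <- TRUE
        calls <- bind_rows(calls, tibble(label = hits$cys_type[i],
                                         start = hits$start[i],
                                         end = hits$end[i],
                                         identity = hits$identity[i]))
      }
    }
    calls <- arrange(calls, .data$start)
  }
  # maximal inter-cys segments
  bounds <- rbind(c(0L, 0L), cbind(calls$start, calls$end),
                  c(nchar(protein) + 1L, nchar(protein) + 1L))
  segs <- purrr::map_dfr(seq_len(nrow(bounds) - 1), function(i) {
    s <- bounds[i, 2] + 1L; e <- bounds[i + 1, 1] - 1L
    if (e - s + 1L >= consensus$m) tibble(start = s, end = e) else tibble()
  })
  tr_rows <- list(); tr_calls <- list(); tr_idx <- 0L
  for (i in seq_len(nrow(segs))) {
    seg <- substr(protein, segs$start[i], segs$end[i])
    dec <- decompose_vntr(seg, consensus)
    full <- dec$instances[!dec$instances$has_indel, ]
    mean_id <- if (nrow(full) == 0) 0 else {
      cv <- strsplit(dec$consensus_seq, "", fixed = TRUE)[[1]]
      mean(vapply(full$seq, function(s) {
        mean(strsplit(s, "", fixed = TRUE)[[1]] == cv)
      }, numeric(1)))
    }
    if (nrow(full) >= tr_min_instances && mean_id >= min_motif_identity) {
      tr_idx <- tr_idx + 1L
      lab <- paste0("TR", tr_idx)
      tr_calls[[tr_idx]] <- tibble(label = lab, start = segs$start[i],
                                   end = segs$end[i], identity = mean_id)
      tr_rows[[tr_idx]] <- tibble(label = lab, start = segs$start[i],
                                  end = segs$end[i],
                                  n_instances = dec$n_instances,
                                  decomposition = list(dec))
    }
  }
  calls <- arrange(bind_rows(calls, bind_rows(tr_calls)), .data$start)
  tr_segments <- bind_rows(tr_rows)
  first_tr <- if (nrow(tr_segments) > 0) min(tr_segments$start) else Inf
  n_cys_before <- sum(calls$end < first_tr & !grepl("^TR", calls$label))
  structure(list(calls = calls,
                 n_cys_before_first_TR = n_cys_before,
                 n_TR_domains = nrow(tr_segments),
                 per_TR_motif_counts = if (nrow(tr_segments)) {
                   tr_segments$n_instances
                 } else integer(),
                 tr_segments = tr_segments),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("<domain_annotation> %d calls: %s\n", nrow(x$calls),
              paste(x$calls$label, collapse = " ")))
  invisible(x)
}

#' @export
tidy.domain_annotation <- function(x, ...) x$calls

#' Read the protein-group rule table
#'
#' The shipped rule fixture (`system.file("extdata",
#' "protein_group_rules.tsv", package = "mucvntr")`) encodes
#' architecture-based groups P1-P6 as ranges over the number of TR
#' domains, the number of cys domains preceding the first TR, the central
#' TR's motif copy number and the first TR's copy number. `NA` leaves a
#' predicate unconstrained. Rules are data, not code, because group
#' boundaries are a curation choice.
#'
#' @param path TSV with header `group, min_tr, max_tr, min_cys_before,
#'   max_cys_before, central_tr_copies, tr1_min, tr1_max`.
#' @return Tibble of rules.
#' @export
read_group_rules <- function(path) {
  rules <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("group", "min_tr", "max_tr", "min_cys_before",
            "max_cys_before", "central_tr_copies", "tr1_min", "tr1_max")
  if (!all(need %in% names(rules))) {
    abort(paste0("rule table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  as_tibble(rules)
}

rule_matches <- function(rule, ann) {
  in_range <- function(x, lo, hi) {
    (is.na(lo) || x >= lo) && (is.na(hi) || x <= hi)
  }
  n_tr <- ann$n_TR_domains
  if (!in_range(n_tr, rule$min_tr, rule$max_tr)) return(FALSE)
  if (!in_range(ann$n_cys_before_first_TR, rule$min_cys_before,
                rule$max_cys_before)) return(FALSE)
  if (!is.na(rule$central_tr_copies)) {
    if (n_tr %% 2 == 0) return(FALSE) # no single central TR
    central <- ann$per_TR_motif_counts[(n_tr + 1) / 2]
    if (central != rule$central_tr_copies) return(FALSE)
  }
  if (!is.na(rule$tr1_min) || !is.na(rule$tr1_max)) {
    if (n_tr == 0) return(FALSE)
    if (!in_range(ann$per_TR_motif_counts[1], rule$tr1_min, rule$tr1_max)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Classify a domain annotation into a protein group
#'
#' Applies the rule table in order; the label of the first matching rule
#' is returned, `"unclassified"` if none matches. More than one matching
#' rule is a configuration error: the fixture rules must be mutually
#' exclusive.
#'
#' @param ann A [scan_domains()] result.
#' @param rules Rule tibble from [read_group_rules()].
#' @return The group label.
#' @export
classify_protein_group <- function(ann, rules) {
  stopifnot(inherits(ann, "domain_annotation"))
  matches <- vapply(seq_len(nrow(rules)), function(i) {
    rule_matches(rules[i, ], ann)
  }, logical(1))
  if (sum(matches) > 1) {
    abort(paste0("overlapping protein-group rules: ",
                 paste(rules$group[matches], collapse = ", ")))
  }
  if (!any(matches)) return("unclassified")
  rules$group[which(matches)[1]]
}

#' Serine/threonine content of TR domains
#'
#' S/T residues are the candidate O-glycosylation sites of mucin repeats;
#' absolute count tracks VNTR length while the fraction measures
#' glycosylation density.
#'
#' @param ann A [scan_domains()] result with at least one TR call.
#' @param protein The annotated protein string.
#' @return List with `per_tr` tibble (`label`, `count_ST`,
#'   `fraction_ST`) and totals `total_count_ST`, `total_fraction_ST`
#'   (over the combined TR length).
#' @export
st_content <- function(ann, protein) {
  stopifnot(inherits(ann, "domain_annotation"))
  if (ann$n_TR_domains == 0) abort("annotation has no TR domains")
  per_tr <- purrr::map_dfr(seq_len(nrow(ann$tr_segments)), function(i) {
    seg <- substr(protein, ann$tr_segments$start[i], ann$tr_segments$end[i])
    cnt <- sum(strsplit(seg, "", fixed = TRUE)[[1]] %in% c("S", "T"))
    tibble(label = ann$tr_segments$label[i], count_ST = cnt,
           fraction_ST = cnt / nchar(seg))
  })
  total_len <- sum(ann$tr_segments$end - ann$tr_segments$start + 1)
  list(per_tr = per_tr, total_count_ST = sum(per_tr$count_ST),
       total_fraction_ST = sum(per_tr$count_ST) / total_len)
}

#' Annotate a cohort of predicted proteins
#'
#' @param proteins Tibble with columns `sample_id`, `hap_index`,
#'   `aa_seq` (rows with `NA` or non-complete ORFs are skipped, mirroring
#'   the complete-ORF requirement for domain curation), plus optional
#'   metadata columns carried through.
#' @param templates,consensus,rules See [scan_domains()] and
#'   [classify_protein_group()].
#' @param ... Passed to [scan_domains()].
#' @return Tibble with per-haplotype domain-architecture columns:
#'   `calls` (comma-joined labels), `n_cys_before_first_TR`,
#'   `n_TR_domains`, `tr_copy_numbers` (comma-joined),
#'   `group_label`, `total_count_ST`, `total_fraction_ST`.
#' @export
annotate_cohort <- function(proteins, templates, consensus, rules, ...) {
  keep <- !is.na(proteins$aa_seq)
  if ("orf_status" %in% names(proteins)) {
    keep <- keep & proteins$orf_status == "complete"
  }
  proteins <- proteins[keep, , drop = FALSE]
  meta_cols <- intersect(c("population", "haplogroup"), names(proteins))
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    ann <- scan_domains(proteins$aa_seq[i], templates, consensus, ...)
    st <- if (ann$n_TR_domains > 0) st_content(ann, proteins$aa_seq[i]) else
      list(total_count_ST = NA_integer_, total_fraction_ST = NA_real_)
    out <- tibble(sample_id = proteins$sample_id[i],
                  hap_index = proteins$hap_index[i])
    for (mc in meta_cols) out[[mc]] <- proteins[[mc]][i]
    out$calls <- paste(ann$calls$label, collapse = ",")
    out$n_cys_before_first_TR <- ann$n_cys_before_first_TR
    out$n_TR_domains <- ann$n_TR_domains
    out$tr_copy_numbers <- paste(ann$per_TR_motif_counts, collapse = ",")
    out$group_label <- classify_protein_group(ann, rules)
    out$total_count_ST <- st$total_count_ST
    out$total_fraction_ST <- st$total_fraction_ST
    out
  })
}
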