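#' Extract exon-flank anchor pairs from a reference sequence
#'
#' For each exon the k-mer immediately upstream of the exon start and the
#' k-mer immediately downstream of the exon end (reference coordinates,
#' genomic strand) are recorded. These anchors localise exons on haplotype
#' assemblies without whole-genome alignment: mucin exon flanks are unique
#' at k >= 15.
#'
#' @param reference_seq Reference nucleotide string containing the locus.
#' @param model A [gene_model()].
#' @param k Anchor length in bp (default 30).
#' @return Tibble with columns `exon_index` (transcript order),
#'   `left_anchor`, `right_anchor`, `k`.
#' @export
extract_anchor_pairs <- function(reference_seq, model, k = 30) {
  k <- as.integer(k)
  if (k < 15) abort("anchor length k must be >= 15")
  L <- nchar(reference_seq)
  exons <- model$exons # transcript order
  out <- purrr::map_dfr(seq_len(nrow(exons)), function(i) {
    s <- exons$start[i]; e <- exons$end[i]
    if (s - k < 0 || e + k > L) {
      abort(sprintf("exon %d lies closer than k=%d bp to the reference edge",
                    i, k))
    }
    left <- substr(reference_seq, s - k + 1, s)       # ref[s-k, s)
    right <- substr(reference_seq, e + 1, e + k)      # ref[e, e+k)
    if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
      abort(sprintf("anchor flank of exon %d contains N", i))
    }
    tibble(exon_index = i, left_anchor = left, right_anchor = right, k = k)
  })
  out
}

place_anchor <- function(hap_seq, anchor, min_identity) {
  k <- nchar(anchor)
  hits <- .sw_hits_cpp(hap_seq, anchor, 1L, -1L, -2L, -1L,
                       min_score = max(1L, as.integer(floor(k / 2))),
                       max_hits = 2L)
  if (nrow(hits) == 0) {
    return(list(status = "missing", start = NA_integer_, end = NA_integer_,
                score = NA_integer_, identity = NA_real_))
  }
  identity <- hits[1, "n_match"] / k
  if (identity < min_identity) {
    return(list(status = "missing", start = NA_integer_, end = NA_integer_,
                score = hits[1, "score"], identity = identity))
  }
  ambiguous <- nrow(hits) > 1 && hits[2, "score"] >= hits[1, "score"] - 1L
  list(status = if (ambiguous) "ambiguous" else "mapped",
       start = unname(hits[1, "sub_start"]), end = unname(hits[1, "sub_end"]),
       score = unname(hits[1, "score"]), identity = unname(identity))
}

#' Locate exons on a haplotype sequence by anchor alignment
#'
#' Each anchor is placed by best affine-gap local alignment (match +1,
#' mismatch -1, gap open -2, gap extend -1). An exon maps to the span
#' between its left anchor's end and its right anchor's start. A placement
#' whose runner-up ties within 1 score unit is `ambiguous`; an anchor with
#' identity below `min_identity` is `missing`.
#'
#' @param hap_seq Haplotype nucleotide string.
#' @param anchors Output of [extract_anchor_pairs()].
#' @param min_identity Minimum anchor identity (matches / k), default 0.9.
#' @return Tibble (one row per exon, transcript order) with columns
#'   `exon_index`, `start`, `end` (0-based half-open on the haplotype),
#'   `score_left`, `score_right`, `identity_left`, `identity_right`,
#'   `status` in \{mapped, ambiguous, missing\}.
#' @export
locate_exons <- function(hap_seq, anchors, min_identity = 0.9) {
  purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
    left <- place_anchor(hap_seq, anchors$left_anchor[i], min_identity)
    right <- place_anchor(hap_seq, anchors$right_anchor[i], min_identity)
    status <- if (left$status == "missing" || right$status == "missing") {
      "missing"
    } else if (left$status == "ambiguous" || right$status == "ambiguous") {
      "ambiguous"
    } else if (left$end > right$start) {
      "missing" # anchors crossed: no valid exon span
    } else {
      "mapped"
    }
    tibble(exon_index = anchors$exon_index[i],
           start = if (status == "missing") NA_integer_ else left$end,
           end = if (status == "missing") NA_integer_ else right$start,
           score_left = left$score, score_right = right$score,
           identity_left = left$identity, identity_right = right$identity,
           status = status)
  })
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_cds <- function(cds) {
  n_codon <- floor(nchar(cds) / 3)
  if (n_codon == 0) return(character(0))
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  tab <- codon_table()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X" # codons containing N or other ambiguity
  unname(aa)
}

#' Splice mapped exons and translate the coding sequence
#'
#' Exon sequences are concatenated in transcript order (the spliced
#' sequence is reverse-complemented first for minus-strand genes) and
#' translated with the standard genetic code from the model's coding
#' offset. A trailing stop is removed; an internal stop truncates the
#' protein and is reported via `stop_position_aa`. Exons containing N are
#' not guessed at: the prediction is flagged `unreliable`.
#'
#' @param hap_seq Haplotype nucleotide string.
#' @param exon_map Output of [locate_exons()]; all exons must be `mapped`.
#' @param model The [gene_model()] used for anchoring.
#' @return List of class `protein_prediction` with fields `aa_seq`,
#'   `length_aa`, `orf_status` in \{complete, truncated, no_start,
#'   unreliable\}, `stop_position_aa`, `cds`.
#' @export
splice_translate <- function(hap_seq, exon_map, model) {
  if (any(exon_map$status != "mapped")) {
    abort(paste0("unmapped exons: ",
                 paste(exon_map$exon_index[exon_map$status != "mapped"],
                       collapse = ", ")))
  }
  # transcript order rows; genomic order for extraction
  em <- arrange(exon_map, .data$start)
  pieces <- substring(hap_seq, em$start + 1, em$end)
  tx <- paste(pieces, collapse = "")
  if (model$locus$strand == "-") tx <- revcomp(tx)
  offset <- coding_offset(model)
  cds <- substr(tx, offset + 1, nchar(tx))
  if (nchar(cds) < 3) abort("spliced coding sequence shorter than one codon")
  aa <- translate_cds(cds)
  pred <- build_prediction(aa)
  pred$cds <- cds
  pred
}

# transcript-coordinate offset of the CDS start, computed on the reference
coding_offset <- function(model) {
  exons <- model$exons # transcript order
  if (model$locus$strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      s <- exons$start[i]; e <- exons$end[i]
      if (model$coding_start >= s && model$coding_start < e) {
        return(off + model$coding_start - s)
      }
      off <- off + (e - s)
    }
  } else {
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      s <- exons$start[i]; e <- exons$end[i]
      if (model$coding_end > s && model$coding_end <= e) {
        return(off + e - model$coding_end)
      }
      off <- off + (e - s)
    }
  }
  abort("coding_start lies in no exon")
}

build_prediction <- function(aa) {
  if (any(aa == "X")) {
    return(structure(list(aa_seq = paste(aa[aa != "*"], collapse = ""),
                          length_aa = sum(aa != "*"),
                          orf_status = "unreliable",
                          stop_position_aa = NA_integer_),
                     class = "protein_prediction"))
  }
  stops <- which(aa == "*")
  internal_stop <- length(stops) > 0 && stops[1] < length(aa)
  trailing_stop <- length(stops) > 0 && stops[1] == length(aa)
  aa_seq <- if (length(stops) > 0) {
    paste(aa[seq_len(stops[1] - 1)], collapse = "")
  } else {
    paste(aa, collapse = "")
  }
  # truncation takes precedence over a missing start codon
  status <- if (internal_stop) {
    "truncated"
  } else if (length(aa) == 0 || aa[1] != "M") {
    "no_start"
  } else {
    "complete"
  }
  structure(list(aa_seq = aa_seq, length_aa = nchar(aa_seq),
                 orf_status = status,
                 stop_position_aa = if (internal_stop) stops[1] else
                   NA_integer_),
            class = "protein_prediction")
}

#' Classify a protein prediction's ORF status
#'
#' `complete` iff the protein starts with M and has no internal stop
#' before the annotated end; `truncated` iff an internal stop occurs
#' (including within the final codons before the annotated stop);
#' `no_start` otherwise. `unreliable` marks predictions over exons
#' containing N.
#'
#' @param pred A `protein_prediction` from [splice_translate()].
#' @return The status string.
#' @export
classify_orf <- function(pred) {
  stopifnot(inherits(pred, "protein_prediction"))
  pred$orf_status
}

#' Project a gene model across a cohort of haplotypes
#'
#' Runs [extract_anchor_pairs()], [locate_exons()] and
#' [splice_translate()] per haplotype and returns one row per haplotype.
#'
#' @param haplotypes Tibble with columns `sample_id`, `hap_index`, `seq`
#'   (plus optional `population`, `haplogroup`, carried through).
#' @param reference_seq Reference nucleotide string.
#' @param model A [gene_model()].
#' @param k Anchor length (default 30).
#' @param min_identity Anchor identity threshold (default 0.9).
#' @return Tibble with per-haplotype `orf_status`, `length_aa`, `aa_seq`,
#'   `exon_status` (comma-joined per-exon statuses) and VNTR-exon
#'   coordinates `vntr_start`, `vntr_end` on the haplotype.
#' @export
project_cohort <- function(haplotypes, reference_seq, model, k = 30,
                           min_identity = 0.9) {
  anchors <- extract_anchor_pairs(reference_seq, model, k)
  meta_cols <- intersect(c("population", "haplogroup"), names(haplotypes))
  purrr::map_dfr(seq_len(nrow(haplotypes)), function(i) {
    em <- locate_exons(haplotypes$seq[i], anchors, min_identity)
    all_mapped <- all(em$status == "mapped")
    if (all_mapped) {
      pred <- splice_translate(haplotypes$seq[i], em, model)
      vr <- em[em$exon_index == model$vntr_exon_index, ]
      res <- tibble(orf_status = pred$orf_status,
                    length_aa = pred$length_aa, aa_seq = pred$aa_seq,
                    vntr_start = vr$start, vntr_end = vr$end)
    } else {
      res <- tibble(orf_status = "unmapped", length_aa = NA_integer_,
                    aa_seq = NA_character_, vntr_start = NA_integer_,
                    vntr_end = NA_integer_)
    }
    out <- tibble(sample_id = haplotypes$sample_id[i],
                  hap_index = haplotypes$hap_index[i])
    for (mc in meta_cols) out[[mc]] <- haplotypes[[mc]][i]
    out$exon_status <- paste(em$status, collapse = ",")
    dplyr::bind_cols(out, res)
  })
}
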