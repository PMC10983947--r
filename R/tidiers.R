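#' @export
tidy.snp_panel <- function(x, ...) {
  if (n_sites(x) == 0) {
    return(tibble(haplotype = integer(), position = integer(),
                  allele = integer()))
  }
  tibble(haplotype = rep(seq_len(n_haplotypes(x)), times = n_sites(x)),
         position = rep(x$positions, each = n_haplotypes(x)),
         allele = as.vector(x$geno))
}

#' @export
glance.snp_panel <- function(x, ...) {
  f <- if (n_sites(x) > 0) colMeans(x$geno) else numeric(0)
  tibble(n_haplotypes = n_haplotypes(x), n_sites = n_sites(x),
         n_segregating = sum(f > 0 & f < 1),
         mean_maf = if (length(f)) mean(pmin(f, 1 - f)) else NA_real_)
}
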