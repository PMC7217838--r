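#' Packaged HLA class I allele counts: AD cohort vs general population
#'
#' Published allele counts at two-field resolution for loci A, B and C in
#' a 54-patient Alzheimer cohort (108 chromosomes per locus) and a
#' Taiwanese general-population reference (2150 / 2180 / 2178
#' chromosomes for A / B / C). Frequencies are computed against the
#' published per-locus chromosome totals; the general-population counts
#' for rare alleles were not all published, so the listed counts need
#' not sum exactly to the totals.
#'
#' @param locus optional subset, any of `"A"`, `"B"`, `"C"`.
#' @return `data.frame` with columns `locus`, `allele`, `ad_count`,
#'   `ad_total`, `gp_count`, `gp_total`, `ad_freq`, `gp_freq`.
#' @export
hlaReferenceFrequencies <- function(locus = c("A", "B", "C")) {
  locus <- match.arg(locus, several.ok = TRUE)
  path <- system.file("extdata", "hla_class1_reference_counts.csv",
                      package = "SelfAntigenLoad", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$locus %in% locus, ]
  df$ad_freq <- df$ad_count / df$ad_total
  df$gp_freq <- df$gp_count / df$gp_total
  rownames(df) <- NULL
  df
}

# Default per-locus allele frequency tables for the simulator: the
# general-population columns, renormalized within each locus.
#' @noRd
defaultAlleleFreqTable <- function() {
  ref <- hlaReferenceFrequencies()
  out <- lapply(split(ref, ref$locus), function(d) {
    p <- d$gp_count / sum(d$gp_count)
    stats::setNames(p, d$allele)
  })
  out[c("A", "B", "C")]
}
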