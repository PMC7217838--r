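# HLA class I allele-frequency tabulation and cohort comparison.
# Frequency tables use chromosome (dosage) counting — a homozygote
# contributes two — so a locus typed in n individuals totals 2n alleles.
# The patient-level early/late contrast uses carrier counting instead
# (>= 1 copy), which is what published per-allele onset contrasts imply.

#' Tabulate allele counts at one locus
#'
#' @param genotypes long-format genotype `data.frame`.
#' @param locus `"A"`, `"B"` or `"C"`.
#' @return list of class `AlleleFrequencyTable`: `locus`, `rows`
#'   (`data.frame` allele / count / frequency, descending count),
#'   `total_alleles` (= 2 x individuals typed at the locus).
#' @export
tabulateAlleleCounts <- function(genotypes, locus) {
  locus <- match.arg(locus, c("A", "B", "C"))
  samples <- unique(genotypes$sample_id)
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  missing <- setdiff(samples, g$sample_id)
  if (length(missing))
    stop("sample(s) without locus ", locus, " genotype: ",
         paste(missing, collapse = ", "))
  copies <- ifelse(g$homozygous, 2L, 1L)
  counts <- tapply(copies, g$allele, sum)
  total <- sum(copies)
  rows <- data.frame(allele = names(counts),
                     count = as.integer(counts),
                     frequency = as.numeric(counts) / total,
                     stringsAsFactors = FALSE)
  rows <- rows[order(-rows$count, rows$allele), ]
  rownames(rows) <- NULL
  structure(list(locus = locus, rows = rows,
                 total_alleles = as.integer(total)),
            class = "AlleleFrequencyTable")
}

#' @export
print.AlleleFrequencyTable <- function(x, ...) {
  cat("HLA-", x$locus, " allele frequencies (", x$total_alleles,
      " chromosomes)\n", sep = "")
  print(transform(x$rows, frequency = sprintf("%.1f%%", 100 * frequency)),
        row.names = FALSE)
  invisible(x)
}

#' @noRd
asFreqTable <- function(x) {
  if (inherits(x, "AlleleFrequencyTable")) return(x)
  # accept a data.frame with allele/count columns plus a known total
  stop("expected an AlleleFrequencyTable (see tabulateAlleleCounts)")
}

#' Build an AlleleFrequencyTable from explicit counts
#'
#' For published tables whose counts are known but whose genotypes are
#' not (e.g. the packaged general-population reference).
#'
#' @param locus `"A"`, `"B"` or `"C"`.
#' @param counts named integer vector, allele -> chromosome count.
#' @param total_alleles total chromosomes (default `sum(counts)`;
#'   published tables may omit rare alleles, making the total larger).
#' @return an `AlleleFrequencyTable`.
#' @export
alleleFrequencyTable <- function(locus, counts, total_alleles = sum(counts)) {
  if (any(counts < 0) || total_alleles < sum(counts))
    stop("counts must be non-negative and sum to at most total_alleles")
  rows <- data.frame(allele = names(counts), count = as.integer(counts),
                     frequency = as.numeric(counts) / total_alleles,
                     stringsAsFactors = FALSE)
  rows <- rows[order(-rows$count, rows$allele), ]
  rownames(rows) <- NULL
  structure(list(locus = locus, rows = rows,
                 total_alleles = as.integer(total_alleles)),
            class = "AlleleFrequencyTable")
}

#' Compare allele frequencies between two cohorts
#'
#' `per_allele_fisher` runs, for each allele in either table, a 2x2
#' Fisher exact test of allele vs all-other chromosomes, with the
#' cross-product odds ratio. `overall_chi_square` runs one chi-square
#' test on the allele x cohort count table, pooling alleles whose
#' overall expected count is below 1 into `"other"`.
#'
#' @param table1,table2 `AlleleFrequencyTable`s for the same locus.
#' @param mode `"per_allele_fisher"` or `"overall_chi_square"`.
#' @return for `per_allele_fisher`, a `data.frame` with one row per
#'   allele (counts, frequencies, odds ratio, p); for
#'   `overall_chi_square`, a list with the pooled count matrix,
#'   `statistic`, `df` and `p_value`.
#' @export
compareAlleleFrequencies <- function(table1, table2,
                                     mode = c("per_allele_fisher",
                                              "overall_chi_square")) {
  mode <- match.arg(mode)
  t1 <- asFreqTable(table1); t2 <- asFreqTable(table2)
  if (!nrow(t1$rows) || !nrow(t2$rows)) stop("empty allele table")
  alleles <- sort(union(t1$rows$allele, t2$rows$allele))
  c1 <- setNames(rep(0L, length(alleles)), alleles)
  c1[t1$rows$allele] <- t1$rows$count
  c2 <- setNames(rep(0L, length(alleles)), alleles)
  c2[t2$rows$allele] <- t2$rows$count
  if (mode == "per_allele_fisher") {
    rows <- lapply(alleles, function(a) {
      ft <- fisherExact2x2(matrix(c(c1[[a]], t1$total_alleles - c1[[a]],
                                    c2[[a]], t2$total_alleles - c2[[a]]),
                                  2L, byrow = TRUE))
      data.frame(allele = a,
                 count1 = c1[[a]], total1 = t1$total_alleles,
                 freq1 = c1[[a]] / t1$total_alleles,
                 count2 = c2[[a]], total2 = t2$total_alleles,
                 freq2 = c2[[a]] / t2$total_alleles,
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 degenerate = ft$degenerate, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  # overall chi-square with pooling of alleles whose expected overall
  # count (under the pooled margin) is below 1
  n1 <- t1$total_alleles; n2 <- t2$total_alleles
  expected <- (c1 + c2) * min(n1, n2) / (n1 + n2)
  pool <- expected < 1
  m <- rbind(cohort1 = c(c1[!pool], other = sum(c1[pool])),
             cohort2 = c(c2[!pool], other = sum(c2[pool])))
  if (!any(pool)) m <- m[, colnames(m) != "other", drop = FALSE]
  chi <- suppressWarnings(chisq.test(m))
  list(counts = m, statistic = unname(chi$statistic),
       df = unname(chi$parameter), p_value = chi$p.value)
}

#' Patient-level carrier contrast for one allele
#'
#' Builds the 2x2 of carriers (>= 1 copy) vs non-carriers by onset
#' group and runs a two-sided Fisher exact test.
#'
#' @param genotypes long-format genotype `data.frame`.
#' @param phenotypes phenotype `data.frame` (supplies `onset_group`).
#' @param allele two-field allele name, e.g. `"A*02:01"`.
#' @return list of class `AlleleComparison`: carrier counts and
#'   frequencies per group, `odds_ratio` (cross-product), `p_value`,
#'   `degenerate`, `test_used = "fisher_carrier"`.
#' @export
carrierContrast <- function(genotypes, phenotypes, allele) {
  allele <- normalizeAllele(allele)
  carriers <- unique(genotypes$sample_id[genotypes$allele == allele])
  grp <- phenotypes$onset_group
  isc <- phenotypes$sample_id %in% carriers
  a <- sum(grp == "early" & isc); b <- sum(grp == "early" & !isc)
  c_ <- sum(grp == "late" & isc); d <- sum(grp == "late" & !isc)
  ft <- fisherExact2x2(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
  structure(list(
    allele = allele,
    carriers_early = a, n_early = a + b,
    freq_early = if (a + b) a / (a + b) else NaN,
    carriers_late = c_, n_late = c_ + d,
    freq_late = if (c_ + d) c_ / (c_ + d) else NaN,
    odds_ratio = ft$odds_ratio, p_value = ft$p_value,
    degenerate = ft$degenerate || (a + c_ == 0L),
    test_used = "fisher_carrier"
  ), class = "AlleleComparison")
}

#' @export
print.AlleleComparison <- function(x, ...) {
  cat("Carrier contrast for ", x$allele, "\n", sep = "")
  cat(sprintf("  early: %d/%d (%.1f%%)   late: %d/%d (%.1f%%)\n",
              x$carriers_early, x$n_early, 100 * x$freq_early,
              x$carriers_late, x$n_late, 100 * x$freq_late))
  cat(sprintf("  OR = %.3g, two-sided Fisher p = %.3g%s\n", x$odds_ratio,
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
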