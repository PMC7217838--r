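# Shared fixtures and independent oracles. The oracles are deliberately
# naive (enumeration / brute force) and never call the code paths they
# check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptides <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(AA, k, replace = TRUE), collapse = ""), character(1))
}

randomProtein <- function(L) paste(sample(AA, L, replace = TRUE),
                                   collapse = "")

# brute-force enumeration of window substrings covering the mutant site
bruteKmers <- function(peptide, mutant_offset, ks, require_span = TRUE) {
  n <- nchar(peptide)
  out <- character()
  for (k in ks) {
    if (k > n) next
    for (s in seq_len(n - k + 1)) {
      covers <- s <= mutant_offset && mutant_offset <= s + k - 1
      if (!require_span || covers)
        out <- c(out, substr(peptide, s, s + k - 1))
    }
  }
  out
}

# exhaustive two-sided Fisher p: sum hypergeometric probabilities of all
# tables at the observed margins that are no more likely than observed
enumFisherP <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by full enumeration of the group
# assignment (tie-free data): doubled smaller tail of the U distribution
enumMwuP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) {
    xx <- vals[i]; yy <- vals[-i]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  uobs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(1, 2 * min(mean(us <= uobs), mean(us >= uobs)))
}

# pairwise-comparison AUC (probability a positive outranks a negative,
# ties one half)
aucPairs <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

crossOR <- function(a, b, c_, d) (a * d) / (b * c_)

# small allele-frequency table for fast simulation tests
tinyAlleleTable <- function() {
  list(A = c("A*11:01" = 0.5, "A*02:01" = 0.5),
       B = c("B*40:01" = 0.6, "B*46:01" = 0.4),
       C = c("C*07:02" = 0.5, "C*01:02" = 0.5))
}

# small, fast cohort config for pipeline-level tests
tinyCohortConfig <- function(seed = 1L, mean_early = 4, mean_late = 4,
                             n_early = 22L, n_late = 32L) {
  cohortConfig(n_early = n_early, n_late = n_late,
               mean_variants_early = mean_early,
               mean_variants_late = mean_late,
               allele_freq_table = tinyAlleleTable(),
               proteome_size = 8L, protein_length_range = c(40L, 60L),
               seed = seed)
}

# one pipeline-lite replicate for calibration/propagation tests:
# cohort -> 9-mers -> surrogate calls -> loads
tinyLoads <- function(config) {
  co <- simulateCohort(config)
  ps <- buildPeptideSet(variants(co), proteins(co), length_set = 9)
  calls <- predictBinding(ps, genotypes(co))
  ld <- selfAntigenLoads(calls, sample_ids = phenotypes(co)$sample_id)
  merge(phenotypes(co), ld, by = "sample_id")
}
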