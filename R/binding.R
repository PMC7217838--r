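# Peptide-HLA binding layer. Binding strength comes either from a
# parsed external prediction table or from the built-in surrogate
# predictor: a deterministic allele-specific position-weight score whose
# percentile rank is taken against a fixed reference distribution of
# pseudo-random peptides keyed by (allele, length) — never by run — so
# identical inputs give identical outputs across sessions and platforms.

# Session cache for position-weight matrices and reference score
# distributions; contents are pure functions of their keys.
.surrogate_cache <- new.env(parent = emptyenv())

#' @noRd
alleleCheck <- function(allele) {
  ok <- grepl("^[ABC]\\*[0-9]{2,3}:[0-9]{2,3}$", allele)
  if (!all(ok))
    stop("malformed HLA allele name(s): ",
         paste(unique(allele[!ok]), collapse = ", "))
  invisible(allele)
}

# Allele- and length-specific position weight matrix (20 x k), standard
# normal entries drawn from a stream keyed by a string hash of
# (allele, k).
#' @noRd
surrogatePwm <- function(allele, k) {
  key <- paste0("pwm/", allele, "/", k)
  if (is.null(.surrogate_cache[[key]]))
    .surrogate_cache[[key]] <- withLocalSeed(
      keyedSeed("pwm", allele, k), matrix(rnorm(20L * k), nrow = 20L))
  .surrogate_cache[[key]]
}

# Sorted reference score distribution for (allele, k): scores of
# `ref_size` pseudo-random peptides under the same PWM, drawn from a
# stream keyed by (allele, k) so the distribution is a constant of the
# allele, not of the run.
#' @noRd
surrogateReference <- function(allele, k, ref_size = 100000L) {
  key <- paste0("ref/", allele, "/", k, "/", ref_size)
  if (is.null(.surrogate_cache[[key]])) {
    pwm <- surrogatePwm(allele, k)
    scores <- withLocalSeed(keyedSeed("ref", allele, k, ref_size), {
      res <- matrix(sample.int(20L, ref_size * k, replace = TRUE),
                    nrow = ref_size)
      sc <- numeric(ref_size)
      for (j in seq_len(k)) sc <- sc + pwm[res[, j], j]
      sc / k
    })
    .surrogate_cache[[key]] <- sort(scores)
  }
  .surrogate_cache[[key]]
}

#' @noRd
surrogateScore <- function(peptides, allele, k) {
  pwm <- surrogatePwm(allele, k)
  res <- matrix(aaIndex(unlist(strsplit(peptides, "", fixed = TRUE))),
                nrow = length(peptides), byrow = TRUE)
  sc <- numeric(length(peptides))
  for (j in seq_len(k)) sc <- sc + pwm[res[, j], j]
  sc / k
}

#' Deterministic surrogate binding predictor
#'
#' Scores each (peptide, allele) pair with an allele-specific
#' position-weight model and converts the score to an empirical
#' percentile rank against that allele's fixed reference distribution
#' (lower rank = stronger predicted binder, as in standard presentation
#' predictors). The pseudo-affinity in nM is a fixed monotone transform
#' of the rank. This is a reproducibility device with the statistical
#' behaviour of a real predictor (allele-specific, length-aware, ranks
#' uniform for random peptides), not a trained binding model.
#'
#' @param peptides character vector of 8-14-mers.
#' @param alleles two-field HLA class I allele names, recycled against
#'   `peptides` if scalar (and vice versa).
#' @param ref_size reference-distribution size per (allele, length).
#' @return `data.frame`: `peptide`, `allele`, `affinity_nM`,
#'   `percentile_rank` (in (0, 100]).
#' @export
surrogateAffinity <- function(peptides, alleles, ref_size = 100000L) {
  n <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, n)
  alleles <- rep_len(alleles, n)
  alleleCheck(alleles)
  k <- nchar(peptides)
  if (any(k < 8L | k > 14L))
    stop("peptide length outside 8-14: ",
         paste(unique(peptides[k < 8L | k > 14L]), collapse = ", "))
  rank <- numeric(n)
  grp <- split(seq_len(n), paste(alleles, k))
  for (idx in grp) {
    al <- alleles[idx[1]]; kk <- k[idx[1]]
    ref <- surrogateReference(al, kk, ref_size)
    sc <- surrogateScore(peptides[idx], al, kk)
    nle <- findInterval(sc, ref)              # reference scores <= sc
    r <- 100 * (length(ref) - nle) / length(ref)
    rank[idx] <- pmax(r, 100 / length(ref))   # keep rank in (0, 100]
  }
  data.frame(peptide = peptides, allele = alleles,
             affinity_nM = rankToAffinity(rank),
             percentile_rank = rank, stringsAsFactors = FALSE)
}

# Monotone rank -> pseudo-affinity map, anchored so the conventional
# strong-binder region (rank <= 0.5) falls near/below 50 nM.
#' @noRd
rankToAffinity <- function(rank) {
  round(50000 * (rank / 100)^1.3, 2)
}

#' Binder classification thresholds
#'
#' Percentile-rank bounds for strong and weak binders (boundaries
#' inclusive), plus an absolute-affinity alternative used when
#' `mode = "affinity"` in [classifyBinder()]. The defaults (0.5 / 2.0
#' rank, 50 nM) are the conventional defaults of widely used class I
#' presentation predictors; the source study does not state its numeric
#' threshold.
#'
#' @param strong_rank_max percentile rank at or below which a call is
#'   `strong`.
#' @param weak_rank_max rank at or below which a non-strong call is
#'   `weak`.
#' @param affinity_strong_nM absolute affinity bound for `strong` in
#'   affinity mode.
#' @return class `BinderThresholds`.
#' @export
binderThresholds <- function(strong_rank_max = 0.5, weak_rank_max = 2.0,
                             affinity_strong_nM = 50) {
  if (!(strong_rank_max > 0 && strong_rank_max < weak_rank_max))
    stop("need 0 < strong_rank_max < weak_rank_max")
  structure(list(strong_rank_max = strong_rank_max,
                 weak_rank_max = weak_rank_max,
                 affinity_strong_nM = affinity_strong_nM),
            class = "BinderThresholds")
}

#' Classify binding calls
#'
#' Rank mode (default): `strong` if rank <= `strong_rank_max`, else
#' `weak` if rank <= `weak_rank_max`, else `non`; boundaries inclusive.
#' Affinity mode: `strong` if affinity <= `affinity_strong_nM`, else
#' `non`.
#'
#' @param percentile_rank numeric vector of ranks (or, in affinity mode,
#'   affinities in nM).
#' @param thresholds a [binderThresholds()].
#' @param mode `"rank"` or `"affinity"`.
#' @return character vector in `{strong, weak, non}`.
#' @export
classifyBinder <- function(percentile_rank,
                           thresholds = binderThresholds(),
                           mode = c("rank", "affinity")) {
  mode <- match.arg(mode)
  if (mode == "rank")
    ifelse(percentile_rank <= thresholds$strong_rank_max, "strong",
           ifelse(percentile_rank <= thresholds$weak_rank_max, "weak", "non"))
  else
    ifelse(percentile_rank <= thresholds$affinity_strong_nM, "strong", "non")
}

#' Predict binding for a peptide set against patient genotypes
#'
#' One call per unique peptide sequence x distinct patient allele
#' (alleles deduplicated per locus first: a homozygous allele is a
#' presentation capability, not a dosage). With
#' `predictor = "external"`, calls are looked up in a parsed
#' NetMHC-style table ([readNetmhcTable()]) and every required
#' (peptide, allele) pair must be present.
#'
#' @param peptide_set a [buildPeptideSet()] result or a k-mer
#'   `data.frame` with columns `sample_id`, `kmer`.
#' @param genotypes long-format genotype `data.frame`.
#' @param predictor `"surrogate"` or `"external"`.
#' @param binding_table parsed external calls (required for
#'   `"external"`).
#' @param thresholds a [binderThresholds()].
#' @param mode classification mode passed to [classifyBinder()].
#' @param ref_size surrogate reference size.
#' @return `data.frame` of calls: `sample_id`, `peptide`, `allele`,
#'   `affinity_nM`, `percentile_rank`, `binder_class`.
#' @export
predictBinding <- function(peptide_set, genotypes,
                           predictor = c("surrogate", "external"),
                           binding_table = NULL,
                           thresholds = binderThresholds(),
                           mode = c("rank", "affinity"),
                           ref_size = 100000L) {
  predictor <- match.arg(predictor)
  mode <- match.arg(mode)
  km <- if (inherits(peptide_set, "PeptideSet")) peptide_set$kmers
        else peptide_set
  empty <- data.frame(sample_id = character(), peptide = character(),
                      allele = character(), affinity_nM = numeric(),
                      percentile_rank = numeric(), binder_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(km) == 0L) return(empty)
  pairs <- unique(km[, c("sample_id", "kmer")])
  names(pairs) <- c("sample_id", "peptide")
  al <- unique(genotypes[, c("sample_id", "allele")])
  calls <- merge(pairs, al, by = "sample_id")
  if (nrow(calls) == 0L) return(empty)
  if (predictor == "surrogate") {
    pred <- surrogateAffinity(calls$peptide, calls$allele,
                              ref_size = ref_size)
    calls$affinity_nM <- pred$affinity_nM
    calls$percentile_rank <- pred$percentile_rank
  } else {
    if (is.null(binding_table))
      stop("binding_table is required for the external predictor")
    key <- paste(calls$peptide, calls$allele)
    tkey <- paste(binding_table$peptide, binding_table$allele)
    i <- match(key, tkey)
    if (anyNA(i)) {
      missing <- unique(key[is.na(i)])
      stop("external table lacks ", length(missing),
           " required (peptide, allele) pair(s), e.g. ",
           paste(utils::head(missing, 3), collapse = "; "))
    }
    calls$affinity_nM <- binding_table$affinity_nM[i]
    calls$percentile_rank <- binding_table$percentile_rank[i]
  }
  basis <- if (mode == "rank") calls$percentile_rank else calls$affinity_nM
  calls$binder_class <- classifyBinder(basis, thresholds, mode = mode)
  calls <- calls[order(calls$sample_id, calls$peptide, calls$allele), ]
  rownames(calls) <- NULL
  calls
}

#' Aggregate the self-antigen load
#'
#' The load is the number of strong binders among a patient's calls —
#' by default the number of distinct peptide sequences that are strong
#' for at least one of the patient's alleles (`unique_peptide`), units =
#' peptide number; `peptide_allele_pairs` counts strong
#' (peptide, allele) calls instead.
#'
#' @param calls binding-call `data.frame` for one patient (a
#'   `sample_id` column, if present, must be constant).
#' @param counting_mode `"unique_peptide"` or `"peptide_allele_pairs"`.
#' @return non-negative integer.
#' @export
computeSelfAntigenLoad <- function(calls,
                                   counting_mode = c("unique_peptide",
                                                     "peptide_allele_pairs")) {
  counting_mode <- match.arg(counting_mode)
  if (!is.null(calls$sample_id) && length(unique(calls$sample_id)) > 1L)
    stop("calls span multiple samples; use selfAntigenLoads()")
  strong <- calls[calls$binder_class == "strong", , drop = FALSE]
  if (counting_mode == "unique_peptide")
    length(unique(strong$peptide))
  else
    nrow(strong)
}

#' Per-patient load table
#'
#' Applies [computeSelfAntigenLoad()] per sample; samples listed in
#' `phenotypes` (or `sample_ids`) but absent from `calls` get load 0.
#'
#' @param calls binding-call `data.frame` with a `sample_id` column.
#' @param sample_ids samples to report (default: those present in
#'   `calls`).
#' @inheritParams computeSelfAntigenLoad
#' @return `data.frame` with columns `sample_id`,
#'   `self_antigen_load`.
#' @export
selfAntigenLoads <- function(calls, sample_ids = NULL,
                             counting_mode = c("unique_peptide",
                                               "peptide_allele_pairs")) {
  counting_mode <- match.arg(counting_mode)
  if (is.null(sample_ids)) sample_ids <- unique(calls$sample_id)
  by <- split(calls, factor(calls$sample_id, levels = sample_ids))
  loads <- vapply(by, computeSelfAntigenLoad, integer(1),
                  counting_mode = counting_mode)
  data.frame(sample_id = sample_ids,
             self_antigen_load = as.integer(unname(loads)),
             stringsAsFactors = FALSE)
}
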