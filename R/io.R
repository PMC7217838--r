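# Readers/writers for the external formats the pipeline touches. All
# readers validate strictly: every line either becomes a record or raises
# a located error; nothing is silently dropped.

#' Read a protein FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Sequences must use the 20-letter amino-acid alphabet plus `X`.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet], possibly empty.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  dup <- unique(names(aa)[duplicated(names(aa))])
  if (length(dup))
    stop("duplicate protein identifier(s): ", paste(dup, collapse = ", "))
  seqs <- as.character(aa)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for: ",
         paste(names(aa)[nchar(seqs) == 0L], collapse = ", "))
  ok <- paste(c(AA20, "X"), collapse = "")
  for (i in seq_along(seqs)) {
    bad <- regexpr(paste0("[^", ok, "]"), seqs[[i]])
    if (bad > 0L)
      stop("illegal residue '", substr(seqs[[i]], bad, bad), "' at position ",
           bad, " of ", names(aa)[i])
  }
  aa
}

#' Write proteins to FASTA
#'
#' @param proteins an `AAStringSet` (or named character vector).
#' @param path output path.
#' @export
writeProteinFasta <- function(proteins, path) {
  if (!methods::is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' @noRd
parseAaChange <- function(token) {
  m <- regmatches(token, regexec("^(?:p\\.)?([A-Z])([0-9]+)([A-Z])$", token))[[1]]
  if (length(m) != 4L)
    stop("unparsable amino-acid change: '", token, "'")
  ref <- m[2]; alt <- m[4]; pos <- as.integer(m[3])
  if (!(ref %in% AA20) || !(alt %in% AA20))
    stop("unparsable amino-acid change: '", token,
         "' (non-standard residue letter)")
  if (pos < 1L) stop("position must be >= 1 in '", token, "'")
  if (ref == alt)
    stop("synonymous change rejected: '", token, "'")
  list(position = pos, ref_aa = ref, alt_aa = alt)
}

#' Read an annotated-variant table
#'
#' Tab-separated with header columns `sample_id`, `protein_id`,
#' `aa_change`. Amino-acid changes are accepted in compact (`R331W`) or
#' HGVS-p shorthand (`p.R331W`) notation; synonymous rows are rejected.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample_id`, `protein_id`,
#'   `position`, `ref_aa`, `alt_aa`.
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("sample_id", "protein_id", "aa_change"), names(df))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(sample_id = character(), protein_id = character(),
                      position = integer(), ref_aa = character(),
                      alt_aa = character(), stringsAsFactors = FALSE))
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parseAaChange(df$aa_change[i]),
             error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  data.frame(
    sample_id  = df$sample_id,
    protein_id = df$protein_id,
    position   = vapply(parsed, `[[`, integer(1), "position"),
    ref_aa     = vapply(parsed, `[[`, character(1), "ref_aa"),
    alt_aa     = vapply(parsed, `[[`, character(1), "alt_aa"),
    stringsAsFactors = FALSE
  )
}

#' Write an annotated-variant table
#'
#' Inverse of [readVariantTable()]; emits compact `R331W` notation.
#'
#' @param variants variant `data.frame`.
#' @param path output path.
#' @export
writeVariantTable <- function(variants, path) {
  out <- data.frame(
    sample_id  = variants$sample_id,
    protein_id = variants$protein_id,
    aa_change  = paste0(variants$ref_aa, variants$position, variants$alt_aa),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalize one allele name to two-field star-colon form, or error.
# Accepts "A*02:01", "a*02:01:01" (extra fields truncated) and the
# lowercase underscore form "hla_a_02_01[_suffix...]".
#' @noRd
normalizeAllele <- function(token) {
  token <- trimws(token)
  t2 <- tolower(token)
  if (grepl("^hla_[a-z]_", t2)) {
    parts <- strsplit(t2, "_", fixed = TRUE)[[1]]
    if (length(parts) < 4L)
      stop("cannot normalize HLA allele token '", token,
           "' (need locus, group and protein fields)")
    locus <- toupper(parts[2])
    group <- parts[3]; prot <- parts[4]
  } else {
    m <- regmatches(t2, regexec("^([a-z])\\*([0-9]+):([0-9]+)", t2))[[1]]
    if (length(m) != 4L)
      stop("cannot normalize HLA allele token '", token, "'")
    locus <- toupper(m[2]); group <- m[3]; prot <- m[4]
  }
  if (!(locus %in% c("A", "B", "C")))
    stop("HLA locus '", locus, "' is not a class I locus (A, B or C)")
  sprintf("%s*%s:%s", locus, group, prot)
}

#' @noRd
emptyGenotypes <- function() {
  data.frame(sample_id = character(), locus = character(),
             allele = character(), homozygous = logical(),
             stringsAsFactors = FALSE)
}

# Collapse per-sample, per-locus allele pairs to the long dedup format.
#' @noRd
collapseLocus <- function(sample_id, locus, alleles) {
  if (length(alleles) < 1L || length(alleles) > 2L)
    stop("sample ", sample_id, " locus ", locus, ": expected 1-2 alleles, got ",
         length(alleles))
  uq <- unique(alleles)
  data.frame(sample_id = sample_id, locus = locus, allele = uq,
             homozygous = rep(length(uq) == 1L && length(alleles) == 2L,
                              length(uq)),
             stringsAsFactors = FALSE)
}

#' Read HLA class I genotypes
#'
#' Two dialects are supported. `"tsv"` is the canonical internal format:
#' columns `sample_id`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2`, each cell an
#' allele name such as `A*02:01` (deeper fields are truncated to
#' two-field resolution). `"winners"` is the conventional per-sample
#' HLA-typing output: one file per sample, one line per locus, e.g.
#' `HLA-A<TAB>hla_a_02_01<TAB>hla_a_11_01`; the tool's exact layout is
#' not standardized, so this dialect is an explicit assumption of this
#' package.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"winners"`.
#' @param sample_id sample name for the winners dialect (default: file
#'   name without extension).
#' @return long-format genotype `data.frame` (columns `sample_id`,
#'   `locus`, `allele`, `homozygous`); homozygous loci appear once with
#'   the flag set.
#' @export
readHlaGenotypes <- function(path, dialect = c("tsv", "winners"),
                             sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- read.delim(path, colClasses = "character", check.names = FALSE)
    cols <- c("A1", "A2", "B1", "B2", "C1", "C2")
    miss <- setdiff(c("sample_id", cols), names(df))
    if (length(miss))
      stop("genotype TSV missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(df) == 0L) return(emptyGenotypes())
    out <- lapply(seq_len(nrow(df)), function(i) {
      do.call(rbind, lapply(c("A", "B", "C"), function(loc) {
        al <- vapply(df[i, paste0(loc, 1:2)], normalizeAllele, character(1))
        if (any(substr(al, 1, 1) != loc))
          stop("sample ", df$sample_id[i], ": allele ",
               al[substr(al, 1, 1) != loc][1], " listed under locus ", loc)
        collapseLocus(df$sample_id[i], loc, al)
      }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out)
  }
  # winners dialect: one sample per file
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyGenotypes())
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("line ", i, ": expected a locus label and two allele fields")
    lab <- toupper(trimws(fields[1]))
    locus <- sub("^HLA-", "", lab)
    if (!(locus %in% c("A", "B", "C")))
      stop("line ", i, ": locus '", lab, "' is not HLA class I (A, B or C)")
    al <- vapply(fields[-1], normalizeAllele, character(1), USE.NAMES = FALSE)
    if (any(substr(al, 1, 1) != locus))
      stop("line ", i, ": allele ", al[substr(al, 1, 1) != locus][1],
           " does not belong to locus ", locus)
    collapseLocus(sample_id, locus, al)
  })
  loci <- vapply(out, function(d) d$locus[1], character(1))
  if (anyDuplicated(loci))
    stop("locus ", loci[duplicated(loci)][1], " repeated across lines in ",
         path)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write HLA genotypes to the canonical TSV
#'
#' Inverse of `readHlaGenotypes(dialect = "tsv")`; homozygous loci are
#' expanded back to two identical columns.
#'
#' @param genotypes long-format genotype `data.frame`.
#' @param path output path.
#' @export
writeHlaGenotypes <- function(genotypes, path) {
  samples <- unique(genotypes$sample_id)
  rows <- lapply(samples, function(s) {
    g <- genotypes[genotypes$sample_id == s, ]
    cells <- lapply(c("A", "B", "C"), function(loc) {
      al <- g$allele[g$locus == loc]
      if (length(al) == 0L)
        stop("sample ", s, " has no alleles at locus ", loc)
      if (length(al) == 1L) al <- rep(al, 2L)
      al[1:2]
    })
    c(sample_id = s, unlist(cells))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "A1", "A2", "B1", "B2", "C1", "C2")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a NetMHC-style binding table
#'
#' Tab-separated export with columns `peptide`, `allele`, `affinity_nM`
#' (alias `nM`) and `percentile_rank` (alias `rank` / `%Rank`). The
#' binder class is always recomputed from `thresholds`, never trusted
#' from the file.
#'
#' @param path input TSV.
#' @param thresholds a [binderThresholds()] object.
#' @return `data.frame` of binding calls: `peptide`, `allele`,
#'   `affinity_nM`, `percentile_rank`, `binder_class`.
#' @export
readNetmhcTable <- function(path, thresholds = binderThresholds()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  alias <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  cols <- c(peptide = alias("peptide"), allele = alias("allele"),
            affinity_nM = alias(c("affinity_nM", "nM", "Affinity(nM)")),
            percentile_rank = alias(c("percentile_rank", "rank", "%Rank")))
  if (anyNA(cols))
    stop("binding table missing column(s): ",
         paste(names(cols)[is.na(cols)], collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(peptide = character(), allele = character(),
                      affinity_nM = numeric(), percentile_rank = numeric(),
                      binder_class = character(), stringsAsFactors = FALSE))
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop("non-numeric ", what, " at row ", which(is.na(v))[1])
    v
  }
  out <- data.frame(
    peptide = df[[cols["peptide"]]],
    allele = vapply(df[[cols["allele"]]], normalizeAllele, character(1),
                    USE.NAMES = FALSE),
    affinity_nM = num(df[[cols["affinity_nM"]]], "affinity"),
    percentile_rank = num(df[[cols["percentile_rank"]]], "percentile rank"),
    stringsAsFactors = FALSE
  )
  out$binder_class <- classifyBinder(out$percentile_rank, thresholds)
  out
}

#' Read a phenotype table
#'
#' CSV with header `sample_id, onset_group, gender, education_years,
#' apoe_e4, baseline_cdr`.
#'
#' @param path input CSV.
#' @return validated phenotype `data.frame`.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "onset_group", "gender", "education_years",
                    "apoe_e4", "baseline_cdr"), names(df))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  validatePhenotypes(df)
}

#' @noRd
validatePhenotypes <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$onset_group %in% c("early", "late")))
    stop("onset_group must be 'early' or 'late'")
  if (!all(df$gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  if (!is.numeric(df$education_years) || any(df$education_years < 0))
    stop("education_years must be non-negative numbers")
  df$apoe_e4 <- as.logical(df$apoe_e4)
  if (anyNA(df$apoe_e4)) stop("apoe_e4 must be logical")
  if (!all(df$baseline_cdr %in% c(0.5, 1, 2, 3)))
    stop("baseline_cdr must be one of 0.5, 1, 2, 3")
  df
}

#' Write a phenotype table
#' @param phenotypes phenotype `data.frame`.
#' @param path output CSV path.
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a directory written by [writeCohort()]
#'
#' @param dir directory containing `proteins.fasta`, `variants.tsv`,
#'   `genotypes.tsv` and `phenotypes.csv`.
#' @return a [SelfAntigenCohort-class].
#' @export
readCohort <- function(dir) {
  newCohort(
    proteins   = readProteinFasta(file.path(dir, "proteins.fasta")),
    variants   = readVariantTable(file.path(dir, "variants.tsv")),
    genotypes  = readHlaGenotypes(file.path(dir, "genotypes.tsv"), "tsv"),
    phenotypes = readPhenotypes(file.path(dir, "phenotypes.csv"))
  )
}

#' Write a cohort's four input files (plus a config echo) to a directory
#'
#' @param cohort a [SelfAntigenCohort-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteinFasta(proteins(cohort), file.path(dir, "proteins.fasta"))
  writeVariantTable(variants(cohort), file.path(dir, "variants.tsv"))
  writeHlaGenotypes(genotypes(cohort), file.path(dir, "genotypes.tsv"))
  writePhenotypes(phenotypes(cohort), file.path(dir, "phenotypes.csv"))
  if (length(cohort@config)) {
    cfg <- cohort@config
    cfg$allele_freq_table <- NULL  # tabular; echoed separately if needed
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
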