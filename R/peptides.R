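# Mutant-centered window extraction and k-mer enumeration. A missense
# variant at residue p of a protein of length L defines the window
# [max(1, p-13), min(L, p+13)] — 13 flanking residues on each side, 27
# residues when untruncated — carrying the ALT residue at the mutant
# site. Candidate HLA class I epitopes are all 8-14-mers of that window
# that span the mutant residue (a k-mer avoiding it is identical to
# unmutated self and carries no variant information).

#' Extract mutant-centered windows
#'
#' @param variants variant `data.frame` (columns `sample_id`,
#'   `protein_id`, `position`, `ref_aa`, `alt_aa`).
#' @param proteins an `AAStringSet` (or named character vector) covering
#'   every `protein_id`.
#' @param flank residues kept on each side of the mutant site.
#' @return `data.frame`: the variant columns plus `start`, `end`
#'   (1-based inclusive protein coordinates), `peptide` (with the ALT
#'   residue substituted) and `mutant_offset` (1-based position of the
#'   mutant residue within `peptide`).
#' @export
extractWindows <- function(variants, proteins, flank = 13L) {
  seqs <- if (methods::is(proteins, "AAStringSet")) as.character(proteins)
          else proteins
  if (nrow(variants) == 0L) {
    out <- variants
    out$start <- integer(); out$end <- integer()
    out$peptide <- character(); out$mutant_offset <- integer()
    return(out)
  }
  unknown <- setdiff(variants$protein_id, names(seqs))
  if (length(unknown))
    stop("protein(s) not supplied: ", paste(unique(unknown), collapse = ", "))
  s <- seqs[variants$protein_id]
  L <- nchar(s)
  p <- variants$position
  if (any(p < 1L | p > L)) {
    i <- which(p < 1L | p > L)[1]
    stop("variant position ", p[i], " out of range for ",
         variants$protein_id[i], " (length ", L[i], ")")
  }
  found <- substr(s, p, p)
  if (any(found != variants$ref_aa)) {
    i <- which(found != variants$ref_aa)[1]
    stop("reference mismatch at ", variants$protein_id[i], " position ",
         p[i], ": expected ", variants$ref_aa[i], ", found ", found[i])
  }
  start <- pmax(1L, p - flank)
  end <- pmin(L, p + flank)
  pep <- substr(s, start, end)
  off <- p - start + 1L
  substr(pep, off, off) <- variants$alt_aa
  out <- variants
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  out$peptide <- unname(pep)
  out$mutant_offset <- as.integer(off)
  out
}

#' Extract a single mutant window
#'
#' Convenience wrapper around [extractWindows()] for one variant.
#'
#' @param variant one-row variant `data.frame` or a list with fields
#'   `protein_id`, `position`, `ref_aa`, `alt_aa` (and optionally
#'   `sample_id`).
#' @param protein the protein sequence (character scalar or length-1
#'   `AAStringSet`).
#' @inheritParams extractWindows
#' @return one-row window `data.frame`.
#' @export
extractWindow <- function(variant, protein, flank = 13L) {
  v <- as.data.frame(variant[c("protein_id", "position", "ref_aa", "alt_aa")],
                     stringsAsFactors = FALSE)
  v$sample_id <- if (!is.null(variant[["sample_id"]]))
    variant[["sample_id"]] else NA_character_
  s <- if (methods::is(protein, "AAStringSet")) as.character(protein)[1]
       else as.character(protein)[1]
  names(s) <- v$protein_id
  extractWindows(v, s, flank = flank)
}

#' Enumerate candidate k-mers spanning the mutant residue
#'
#' All contiguous substrings of the window peptide with length in
#' `length_set` whose span includes the mutant offset; one row per
#' (start, k). Sequence duplicates are retained here — deduplication is
#' a load-stage policy. For an untruncated 27-residue window and the
#' default lengths 8-14 this yields 77 k-mers (k of them for each k <=
#' 13, and 14 for k = 14).
#'
#' @param windows window `data.frame` from [extractWindows()].
#' @param length_set integer k-mer lengths, each within 8-14.
#' @param require_span if `FALSE`, emit all k-mers of the window, not
#'   only those covering the mutant site.
#' @return `data.frame`: parent-window columns `sample_id`,
#'   `protein_id`, `position`, plus `kmer`, `k` and `start_in_window`.
#' @export
enumerateMutantKmers <- function(windows, length_set = 8:14,
                                 require_span = TRUE) {
  length_set <- sort(unique(as.integer(length_set)))
  if (!length(length_set)) stop("length_set must be non-empty")
  if (any(length_set < 8L | length_set > 14L))
    stop("k-mer lengths must lie within 8-14")
  empty <- data.frame(sample_id = character(), protein_id = character(),
                      position = integer(), kmer = character(), k = integer(),
                      start_in_window = integer(), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows$peptide[i]
    m <- windows$mutant_offset[i]
    n <- nchar(w)
    per_k <- lapply(length_set, function(k) {
      if (k > n) return(NULL)
      s <- if (require_span) seq.int(max(1L, m - k + 1L), min(m, n - k + 1L))
           else seq_len(n - k + 1L)
      if (!length(s) || s[1] > s[length(s)]) return(NULL)
      data.frame(sample_id = windows$sample_id[i],
                 protein_id = windows$protein_id[i],
                 position = windows$position[i],
                 kmer = substring(w, s, s + k - 1L),
                 k = k, start_in_window = as.integer(s),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_k)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Build the full peptide set for a variant collection
#'
#' Windows plus mutant-spanning k-mers for every variant.
#'
#' @inheritParams extractWindows
#' @inheritParams enumerateMutantKmers
#' @return list with elements `windows` and `kmers` (class
#'   `PeptideSet`).
#' @export
buildPeptideSet <- function(variants, proteins, length_set = 8:14,
                            flank = 13L, require_span = TRUE) {
  windows <- extractWindows(variants, proteins, flank = flank)
  kmers <- enumerateMutantKmers(windows, length_set = length_set,
                                require_span = require_span)
  structure(list(windows = windows, kmers = kmers,
                 length_set = sort(unique(as.integer(length_set)))),
            class = "PeptideSet")
}

#' @export
print.PeptideSet <- function(x, ...) {
  cat("PeptideSet: ", nrow(x$windows), " windows, ", nrow(x$kmers),
      " k-mers (k in ", paste(range(x$length_set), collapse = "-"), ")\n",
      sep = "")
  invisible(x)
}

#' Write candidate peptides for an external predictor
#'
#' `writePeptideTsv()` writes the k-mer table; `writePeptideFasta()`
#' writes one FASTA record per k-mer with header
#' `sample|protein|change|k|start`.
#'
#' @param peptide_set a [buildPeptideSet()] result (or a k-mer
#'   `data.frame`).
#' @param path output path.
#' @name peptide-export
#' @export
writePeptideTsv <- function(peptide_set, path) {
  km <- if (inherits(peptide_set, "PeptideSet")) peptide_set$kmers
        else peptide_set
  write.table(km, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname peptide-export
#' @param windows the window `data.frame` (needed to reconstruct the
#'   amino-acid change in headers); defaults to the one in
#'   `peptide_set`.
#' @export
writePeptideFasta <- function(peptide_set, path, windows = NULL) {
  km <- if (inherits(peptide_set, "PeptideSet")) peptide_set$kmers
        else peptide_set
  if (is.null(windows) && inherits(peptide_set, "PeptideSet"))
    windows <- peptide_set$windows
  key <- paste(km$sample_id, km$protein_id, km$position)
  wkey <- paste(windows$sample_id, windows$protein_id, windows$position)
  i <- match(key, wkey)
  change <- paste0(windows$ref_aa[i], windows$position[i], windows$alt_aa[i])
  aa <- Biostrings::AAStringSet(km$kmer)
  names(aa) <- paste(km$sample_id, km$protein_id, change, km$k,
                     km$start_in_window, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
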