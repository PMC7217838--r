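#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats rnorm rpois rbinom runif dbinom quantile median
#'   fisher.test wilcox.test chisq.test glm binomial coef vcov qnorm
#'   complete.cases sd setNames
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
NULL

#' Container for a complete self-antigen analysis cohort
#'
#' Bundles the four inputs the pipeline consumes — a proteome, annotated
#' nonsynonymous variants, HLA class I genotypes and patient phenotypes —
#' together with the configuration and seed that produced them (for
#' simulated cohorts) so a run is fully reproducible.
#'
#' @slot proteins an [Biostrings::AAStringSet] of protein sequences, one
#'   per distinct protein identifier.
#' @slot variants `data.frame` with columns `sample_id`, `protein_id`,
#'   `position` (1-based residue index), `ref_aa`, `alt_aa`.
#' @slot genotypes long-format `data.frame` with columns `sample_id`,
#'   `locus` (A/B/C), `allele` (two-field, e.g. `A*02:01`) and
#'   `homozygous` (logical; a homozygous locus is stored once,
#'   flagged, and contributes two chromosomes to dosage counts).
#' @slot phenotypes `data.frame` with columns `sample_id`, `onset_group`
#'   (`early`/`late`), `gender` (`male`/`female`), `education_years`,
#'   `apoe_e4` (logical), `baseline_cdr` (0.5, 1, 2 or 3).
#' @slot config the [cohortConfig()] echo (empty list for ingested data).
#' @slot seed integer seed used for simulation (`NA` for ingested data).
#'
#' @seealso [simulateCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("SelfAntigenCohort",
  slots = c(
    proteins   = "AAStringSet",
    variants   = "data.frame",
    genotypes  = "data.frame",
    phenotypes = "data.frame",
    config     = "list",
    seed       = "integer"
  )
)

setValidity("SelfAntigenCohort", function(object) {
  msgs <- character()
  v <- object@variants
  ph <- object@phenotypes
  g <- object@genotypes
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      msgs <<- c(msgs, paste0(what, " missing column(s): ",
                              paste(miss, collapse = ", ")))
    length(miss) == 0L
  }
  okv <- need(v, c("sample_id", "protein_id", "position", "ref_aa", "alt_aa"),
              "variants")
  okg <- need(g, c("sample_id", "locus", "allele", "homozygous"), "genotypes")
  okp <- need(ph, c("sample_id", "onset_group", "gender", "education_years",
                    "apoe_e4", "baseline_cdr"), "phenotypes")
  if (okp && anyDuplicated(ph$sample_id))
    msgs <- c(msgs, "duplicate sample_id in phenotypes")
  if (okv && nrow(v)) {
    unknown <- setdiff(v$protein_id, names(object@proteins))
    if (length(unknown))
      msgs <- c(msgs, paste0("variant protein_id not in proteome: ",
                             paste(unique(unknown), collapse = ", ")))
    else {
      seqs <- as.character(object@proteins)[v$protein_id]
      found <- substr(seqs, v$position, v$position)
      bad <- which(found != v$ref_aa)
      if (length(bad))
        msgs <- c(msgs, paste0(length(bad),
          " variant(s) whose ref_aa does not match the protein sequence"))
    }
  }
  if (okp && okg && nrow(ph)) {
    nog <- setdiff(ph$sample_id, g$sample_id)
    if (length(nog))
      msgs <- c(msgs, paste0("samples without genotypes: ",
                             paste(nog, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Accessors for SelfAntigenCohort components
#'
#' @param x a [SelfAntigenCohort-class] object.
#' @return `proteins()` the `AAStringSet`; the others the corresponding
#'   `data.frame` (see the class documentation for columns).
#' @aliases proteins variants genotypes phenotypes
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname cohort-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname cohort-accessors
setMethod("proteins", "SelfAntigenCohort", function(x) x@proteins)
#' @rdname cohort-accessors
setMethod("variants", "SelfAntigenCohort", function(x) x@variants)
#' @rdname cohort-accessors
setMethod("genotypes", "SelfAntigenCohort", function(x) x@genotypes)
#' @rdname cohort-accessors
setMethod("phenotypes", "SelfAntigenCohort", function(x) x@phenotypes)

setMethod("show", "SelfAntigenCohort", function(object) {
  ph <- object@phenotypes
  cat("SelfAntigenCohort\n")
  cat("  proteins:  ", length(object@proteins), "\n", sep = "")
  cat("  variants:  ", nrow(object@variants), " (",
      length(unique(object@variants$sample_id)), " samples)\n", sep = "")
  cat("  samples:   ", nrow(ph), sep = "")
  if (nrow(ph))
    cat(" (", sum(ph$onset_group == "early"), " early / ",
        sum(ph$onset_group == "late"), " late)", sep = "")
  cat("\n")
  if (!is.na(object@seed))
    cat("  simulated with seed ", object@seed, "\n", sep = "")
})

#' @noRd
newCohort <- function(proteins, variants, genotypes, phenotypes,
                      config = list(), seed = NA_integer_) {
  methods::new("SelfAntigenCohort",
               proteins = proteins, variants = variants,
               genotypes = genotypes, phenotypes = phenotypes,
               config = config, seed = as.integer(seed))
}
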