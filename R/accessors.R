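#' Construct a SummaryStats object
#'
#' @param stats data.frame carrying the summary-statistic column contract
#'   (see \linkS4class{SummaryStats}).
#' @param trait,cohort optional labels.
#' @return A \linkS4class{SummaryStats}.
#' @export
SummaryStats <- function(stats, trait = NA_character_, cohort = NA_character_) {
  stats <- as.data.frame(stats)
  rownames(stats) <- NULL
  new("SummaryStats", stats = stats, trait = trait, cohort = cohort)
}

#' Construct an LDMatrix from a signed correlation matrix
#'
#' @param r square symmetric matrix of signed correlations with SNP ids as
#'   dimnames (supplied via \code{snpIds} if absent).
#' @param snpIds optional SNP ids to place on the dimnames.
#' @return An \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(r, snpIds = NULL) {
  r <- as.matrix(r)
  if (!is.null(snpIds)) dimnames(r) <- list(snpIds, snpIds)
  new("LDMatrix", r = r)
}

#' Construct a GenotypePanel
#'
#' @param dosage samples x SNPs numeric matrix with dosages in [0, 2].
#' @param variants data.frame with snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf matching the dosage columns.
#' @return A \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(dosage, variants) {
  variants <- as.data.frame(variants)
  rownames(variants) <- NULL
  new("GenotypePanel", dosage = as.matrix(dosage), variants = variants)
}

#' Construct QC thresholds
#'
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hwePMin minimum Hardy-Weinberg equilibrium p-value (default 1e-20).
#' @param missingMax maximum missing call rate (default 0.05).
#' @param infoMin minimum imputation info score (default 0.8).
#' @return A \linkS4class{QCThresholds}.
#' @export
qcThresholds <- function(mafMin = 0.01, hwePMin = 1e-20, missingMax = 0.05,
                         infoMin = 0.8) {
  new("QCThresholds", mafMin = mafMin, hwePMin = hwePMin,
      missingMax = missingMax, infoMin = infoMin)
}

#' Construct summary-level MR input
#'
#' @param snpIds SNP identifiers.
#' @param bzx,sezx exposure effects (per protein SD) and SEs.
#' @param bzy,sezy outcome effects (log-odds) and SEs.
#' @param ld signed LD matrix (or \linkS4class{LDMatrix}); identity if omitted.
#' @param pzx exposure p-values; derived from the normal Wald statistic if
#'   omitted.
#' @return An \linkS4class{MRInput}.
#' @export
mrInput <- function(snpIds, bzx, sezx, bzy, sezy, ld = NULL, pzx = NULL) {
  L <- length(snpIds)
  if (is.null(ld)) ld <- diag(L)
  if (is(ld, "LDMatrix")) ld <- ld@r
  ld <- as.matrix(ld)
  if (is.null(pzx)) pzx <- 2 * pnorm(-abs(bzx / sezx))
  new("MRInput", snpIds = as.character(snpIds), bzx = as.numeric(bzx),
      sezx = as.numeric(sezx), bzy = as.numeric(bzy), sezy = as.numeric(sezy),
      pzx = as.numeric(pzx), ld = ld)
}

#' Build MRInput from an InstrumentSet, optionally against new outcome stats
#'
#' With \code{outcome = NULL} the outcome effects stored at selection time are
#' used. Supplying a \linkS4class{SummaryStats} for another disease
#' re-harmonizes the set's SNPs to that table (allele flips applied, SNPs
#' absent from the table raise an error).
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param outcome optional \linkS4class{SummaryStats} of a disease scan.
#' @return An \linkS4class{MRInput} whose LD matrix is the outcome-cohort one.
#' @export
asMRInput <- function(set, outcome = NULL) {
  d <- set@data
  if (is.null(outcome)) {
    if (!all(c("b_zy", "se_zy") %in% names(d)))
      stop("instrument set carries no outcome effects; supply `outcome`")
    zy <- d[, c("b_zy", "se_zy")]
  } else {
    st <- summaryTable(outcome)
    idx <- match(d$snp_id, st$snp_id)
    if (anyNA(idx))
      stop("SNPs missing from the outcome table: ",
           paste(d$snp_id[is.na(idx)], collapse = ", "))
    o <- st[idx, ]
    flip <- o$effect_allele == d$other_allele & o$other_allele == d$effect_allele
    same <- o$effect_allele == d$effect_allele & o$other_allele == d$other_allele
    if (any(!flip & !same))
      stop("irreconcilable alleles for: ",
           paste(d$snp_id[!flip & !same], collapse = ", "))
    zy <- data.frame(b_zy = ifelse(flip, -o$beta, o$beta), se_zy = o$se)
  }
  mrInput(d$snp_id, d$b_zx, d$se_zx, zy$b_zy, zy$se_zy,
          ld = set@ldOutcome, pzx = d$p_zx)
}

# --- small accessors -------------------------------------------------------

#' Accessors for pipeline objects
#'
#' \code{summaryTable} returns the data.frame inside a
#' \linkS4class{SummaryStats}; \code{ldMatrix} the numeric matrix inside an
#' \linkS4class{LDMatrix}; \code{dosages} and \code{variantInfo} the slots of
#' a \linkS4class{GenotypePanel}; \code{instrumentData} and
#' \code{heidiCapable} those of an \linkS4class{InstrumentSet};
#' \code{gridResults} and \code{mTests} those of an \linkS4class{MRGrid};
#' \code{studyTruth} the \linkS4class{SimulationTruth} of a
#' \linkS4class{PairedStudy}; \code{isRejected} tests for an
#' \linkS4class{InstrumentRejection}.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
summaryTable <- function(x) x@stats

#' @rdname accessors
#' @export
ldMatrix <- function(x) x@r

#' @rdname accessors
#' @export
dosages <- function(x) x@dosage

#' @rdname accessors
#' @export
variantInfo <- function(x) x@variants

#' @rdname accessors
#' @export
instrumentData <- function(x) x@data

#' @rdname accessors
#' @export
heidiCapable <- function(x) x@heidiCapable

#' @rdname accessors
#' @export
gridResults <- function(x) x@results

#' @rdname accessors
#' @export
mTests <- function(x) x@mTests

#' @rdname accessors
#' @export
studyTruth <- function(x) x@truth

#' @rdname accessors
#' @export
isRejected <- function(x) is(x, "InstrumentRejection")

# --- show methods ----------------------------------------------------------

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %d SNPs, trait=%s, cohort=%s\n",
              nrow(object@stats), object@trait, object@cohort))
  if (nrow(object@stats) > 0) print(utils::head(object@stats, 4L))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix over %d SNPs (signed r)\n", nrow(object@r)))
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d samples x %d SNPs\n",
              nrow(object@dosage), ncol(object@dosage)))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf(
    "InstrumentSet for %s: %d instruments (p<%.2g, r2<=%.2g)%s\n",
    object@proteinId, nrow(object@data),
    object@params$pThresh, object@params$r2Thresh,
    if (object@heidiCapable) "" else " [HEIDI disabled: <5 SNPs]"))
})

setMethod("show", "InstrumentRejection", function(object) {
  cat(sprintf("InstrumentRejection for %s: %s (n=%d)\n",
              object@proteinId, object@reason, object@nSelected))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]: OR %.2f (%.2f-%.2f), p=%.2g, IVs %d/%d\n",
              object@method, object@or_, object@ciLow, object@ciHigh,
              object@p, object@nIvUsed, object@nIvInitial))
  if (object@method == "egger")
    cat(sprintf("  intercept %.3g (p=%.2g)\n",
                object@eggerIntercept, object@eggerInterceptP))
})

setMethod("show", "MRGrid", function(object) {
  cat(sprintf("MRGrid: %d cells (m=%d), %d significant at FDR<%.2g\n",
              nrow(object@results), object@mTests,
              sum(object@results$significant, na.rm = TRUE),
              object@params$fdrAlpha %||% 0.05))
})

setMethod("show", "PairedStudy", function(object) {
  cat(sprintf(
    "PairedStudy: exposure n=%d, outcome n=%d (%d cases), %d SNPs, true b=%.3f\n",
    nrow(object@exposurePanel@dosage), nrow(object@outcomePanel@dosage),
    sum(object@caseLabels), ncol(object@exposurePanel@dosage),
    object@truth@trueB))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: n_exp=%d, n_out=%d (%d cases), blocks=%s, h2=%.2f, trueB=%.3f\n",
    object@nExposure, object@nOutcome, object@nCases,
    paste(object@nSnpsPerBlock, collapse = "+"), object@h2Target, object@trueB))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
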