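#' @import methods
#' @importFrom stats cor pchisq pnorm pt qnorm rbinom rnorm runif sd
#'   uniroot var plogis binomial p.adjust
#' @importFrom utils read.delim write.table head
NULL

.SUMMARY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "p", "n")

#' Per-SNP association summary statistics for one trait in one cohort
#'
#' Thin S4 container around a data.frame of GWAS summary statistics with the
#' column contract used throughout the pipeline: \code{snp_id}, \code{chrom},
#' \code{pos} (1-based), \code{effect_allele}, \code{other_allele}, \code{eaf},
#' \code{beta} (per SD of the INT-transformed protein for exposure scans,
#' log-odds per dosage unit for disease scans), \code{se}, \code{p}, \code{n}.
#'
#' @slot stats data.frame with the columns above, one row per SNP.
#' @slot trait single character, the phenotype scanned.
#' @slot cohort single character, the cohort label.
#' @export
setClass("SummaryStats",
  representation(stats = "data.frame", trait = "character", cohort = "character"),
  prototype(trait = NA_character_, cohort = NA_character_))

setValidity("SummaryStats", function(object) {
  st <- object@stats
  miss <- setdiff(.SUMMARY_COLS, names(st))
  if (length(miss) > 0)
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(st$snp_id))
    return("duplicated snp_id")
  if (nrow(st) > 0) {
    if (any(!is.na(st$se) & st$se <= 0))
      return("se must be strictly positive")
    if (any(!is.na(st$p) & (st$p <= 0 | st$p > 1)))
      return("p must lie in (0, 1]")
  }
  TRUE
})

#' Signed LD correlation matrix over an ordered SNP set
#'
#' @slot r numeric matrix of signed correlations, symmetric with unit
#'   diagonal; SNP ids on both dimnames.
#' @export
setClass("LDMatrix", representation(r = "matrix"))

setValidity("LDMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("matrix must be square")
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("SNP ids required on both dimnames")
  if (!identical(rownames(r), colnames(r)))
    return("row and column SNP ids differ")
  if (nrow(r) > 0) {
    if (max(abs(r - t(r))) > 1e-8) return("matrix not symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) return("diagonal must be 1")
    if (max(abs(r)) > 1 + 1e-8) return("|r| must not exceed 1")
  }
  TRUE
})

#' Individual-level genotype dosages plus variant annotation
#'
#' @slot dosage numeric matrix, samples x SNPs, entries in [0, 2]; rownames are
#'   sample ids, colnames SNP ids.
#' @slot variants data.frame with snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, aligned to the dosage columns.
#' @export
setClass("GenotypePanel",
  representation(dosage = "matrix", variants = "data.frame"))

setValidity("GenotypePanel", function(object) {
  d <- object@dosage
  v <- object@variants
  if (!identical(colnames(d), v$snp_id))
    return("dosage colnames must equal variants$snp_id in order")
  if (is.null(rownames(d))) return("sample ids required as dosage rownames")
  if (length(d) > 0 && (min(d) < -1e-9 || max(d) > 2 + 1e-9))
    return("dosages must lie in [0, 2]")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "eaf")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    return(paste("variants missing columns:", paste(miss, collapse = ", ")))
  TRUE
})

#' Generating parameters for a synthetic paired-cohort study
#'
#' Defines the statistical structure the MR pipeline assumes: an exposure
#' cohort with a rank-INT protein driven by a handful of cis SNPs, a large
#' case-control outcome cohort sharing the SNP set and LD but with disjoint
#' individuals, a true log-odds causal effect of the protein, and an optional
#' fraction of horizontally pleiotropic instruments.
#'
#' @slot seed integer RNG seed.
#' @slot nExposure exposure-cohort size (default 872).
#' @slot nOutcome outcome-cohort size.
#' @slot nCases expected number of cases (< nOutcome).
#' @slot nSnpsPerBlock integer vector of LD-block sizes.
#' @slot blockRho AR(1) within-block correlation, one per block or scalar,
#'   each in [0, 1).
#' @slot eafRange length-2 effect-allele-frequency sampling interval in (0, 1).
#' @slot nCausal number of true cis-pQTL SNPs.
#' @slot h2Target fraction of protein variance explained by the causal SNPs,
#'   in (0, 1).
#' @slot trueB causal log-odds effect of the protein (per SD of its INT level)
#'   on disease.
#' @slot pleioFraction fraction of causal instruments given direct SNP-disease
#'   effects.
#' @slot pleioEffectMean,pleioEffectSd mean and SD of the direct log-odds
#'   effects (mean nonzero gives directional pleiotropy).
#' @slot nPCs number of standardized principal-component-like covariates
#'   (sex and age are always generated).
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nExposure = "integer", nOutcome = "integer",
    nCases = "integer", nSnpsPerBlock = "integer", blockRho = "numeric",
    eafRange = "numeric", nCausal = "integer", h2Target = "numeric",
    trueB = "numeric", pleioFraction = "numeric", pleioEffectMean = "numeric",
    pleioEffectSd = "numeric", nPCs = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nCases >= object@nOutcome) return("nCases must be < nOutcome")
  if (object@h2Target <= 0 || object@h2Target >= 1)
    return("h2Target must lie in (0, 1)")
  if (object@pleioFraction < 0 || object@pleioFraction > 1)
    return("pleioFraction must lie in [0, 1]")
  if (any(object@blockRho < 0 | object@blockRho >= 1))
    return("blockRho must lie in [0, 1)")
  if (any(object@nSnpsPerBlock < 1)) return("block sizes must be >= 1")
  if (length(object@eafRange) != 2 || any(object@eafRange <= 0) ||
      any(object@eafRange >= 1) || diff(object@eafRange) < 0)
    return("eafRange must be an interval inside (0, 1)")
  if (object@nCausal > sum(object@nSnpsPerBlock))
    return("nCausal exceeds the total SNP count")
  TRUE
})

#' Ground truth kept alongside a synthetic study for recovery tests
#'
#' @slot trueB causal log-odds per protein SD.
#' @slot causalSnps ids of the SNPs with nonzero protein effects.
#' @slot pleiotropicSnps ids of SNPs with direct disease effects (may overlap
#'   causalSnps: a causal pQTL can also be pleiotropic).
#' @slot perSnpEffects named numeric, protein-scale betas per causal SNP.
#' @slot pleioEffects named numeric, direct log-odds effects.
#' @slot realizedH2 protein variance fraction the causal SNPs explain in the
#'   generated exposure cohort.
#' @export
setClass("SimulationTruth",
  representation(trueB = "numeric", causalSnps = "character",
    pleiotropicSnps = "character", perSnpEffects = "numeric",
    pleioEffects = "numeric", realizedH2 = "numeric"))

setValidity("SimulationTruth", function(object) {
  if (object@realizedH2 < 0 || object@realizedH2 > 1)
    return("realizedH2 must lie in [0, 1]")
  TRUE
})

#' A generated two-sample study: exposure and outcome cohorts plus truth
#'
#' @slot exposurePanel,outcomePanel \linkS4class{GenotypePanel}s sharing SNP
#'   identities and LD structure but with disjoint individuals.
#' @slot protein named numeric, raw protein level per exposure sample (unit
#'   variance by construction; INT is applied at scan time).
#' @slot caseLabels named integer 0/1 disease status per outcome sample.
#' @slot exposureCovariates,outcomeCovariates data.frames with sex, age and
#'   PC columns.
#' @slot truth \linkS4class{SimulationTruth}.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("PairedStudy",
  representation(exposurePanel = "GenotypePanel", protein = "numeric",
    outcomePanel = "GenotypePanel", caseLabels = "integer",
    exposureCovariates = "data.frame", outcomeCovariates = "data.frame",
    truth = "SimulationTruth", config = "SimulationConfig"))

setValidity("PairedStudy", function(object) {
  if (length(intersect(rownames(object@exposurePanel@dosage),
                       rownames(object@outcomePanel@dosage))) > 0)
    return("exposure and outcome sample ids must be disjoint (two-sample design)")
  TRUE
})

#' Variant QC thresholds
#'
#' Defaults follow the conventional biobank imputed-data filter: minor allele
#' frequency >= 0.01, Hardy-Weinberg p >= 1e-20, missing call rate <= 0.05,
#' imputation info score >= 0.8.
#'
#' @slot mafMin,hwePMin,missingMax,infoMin numeric thresholds in [0, 1].
#' @export
setClass("QCThresholds",
  representation(mafMin = "numeric", hwePMin = "numeric",
    missingMax = "numeric", infoMin = "numeric"))

setValidity("QCThresholds", function(object) {
  v <- c(object@mafMin, object@hwePMin, object@missingMax, object@infoMin)
  if (any(v < 0 | v > 1)) return("all thresholds must lie in [0, 1]")
  TRUE
})

#' A harmonized, LD-pruned instrument set for one protein
#'
#' Rows are SNPs aligned to a common effect allele, carrying exposure effects
#' (b_zx, per SD of INT protein) and, when selection was run against an
#' outcome table, outcome effects (b_zy, log-odds). Both cohorts' signed LD
#' sub-matrices over the selected SNPs are retained; estimation uses the
#' outcome-cohort one.
#'
#' @slot proteinId protein identifier.
#' @slot data data.frame with snp_id, chrom, pos, effect_allele, other_allele,
#'   eaf, b_zx, se_zx, p_zx and optionally b_zy, se_zy, p_zy.
#' @slot ldExposure,ldOutcome signed r matrices, order-matched to data.
#' @slot params list: pThresh, r2Thresh, windowBp, minIv.
#' @slot heidiCapable FALSE when fewer than 5 instruments survive selection,
#'   in which case HEIDI outlier removal is disabled downstream.
#' @export
setClass("InstrumentSet",
  representation(proteinId = "character", data = "data.frame",
    ldExposure = "matrix", ldOutcome = "matrix", params = "list",
    heidiCapable = "logical"))

setValidity("InstrumentSet", function(object) {
  d <- object@data
  if (nrow(d) < 1) return("an instrument set needs at least one SNP")
  if (!identical(rownames(object@ldOutcome), d$snp_id) ||
      !identical(rownames(object@ldExposure), d$snp_id))
    return("LD matrix order must match the SNP order")
  pt <- object@params$pThresh
  if (!is.null(pt) && any(d$p_zx >= pt))
    return("all exposure p-values must fall below pThresh")
  r2t <- object@params$r2Thresh
  if (!is.null(r2t) && nrow(d) > 1) {
    for (m in list(object@ldExposure, object@ldOutcome)) {
      off <- m[upper.tri(m)]
      if (any(off^2 > r2t + 1e-12))
        return("pairwise r^2 exceeds r2Thresh in a stored LD matrix")
    }
  }
  TRUE
})

#' Rejection record for a protein with too few instruments
#'
#' @slot proteinId protein identifier.
#' @slot reason human-readable reason, e.g. "n_selected < min_iv".
#' @slot nSelected how many instruments survived selection.
#' @slot params the selection parameters used.
#' @export
setClass("InstrumentRejection",
  representation(proteinId = "character", reason = "character",
    nSelected = "integer", params = "list"))

#' Summary-level input to the MR estimators
#'
#' @slot snpIds SNP identifiers.
#' @slot bzx,sezx exposure effects and SEs (per SD of INT protein).
#' @slot bzy,sezy outcome effects and SEs (log-odds).
#' @slot pzx exposure p-values (identify the top SNP for HEIDI).
#' @slot ld signed LD matrix, order-matched.
#' @export
setClass("MRInput",
  representation(snpIds = "character", bzx = "numeric", sezx = "numeric",
    bzy = "numeric", sezy = "numeric", pzx = "numeric", ld = "matrix"))

setValidity("MRInput", function(object) {
  L <- length(object@snpIds)
  if (L < 1) return("at least one instrument required")
  lens <- c(length(object@bzx), length(object@sezx), length(object@bzy),
            length(object@sezy), length(object@pzx))
  if (any(lens != L)) return("all effect vectors must have equal length")
  if (any(object@sezx <= 0) || any(object@sezy <= 0))
    return("standard errors must be strictly positive")
  if (!identical(dim(object@ld), c(L, L)))
    return("LD matrix dimension must match the instrument count")
  if (L > 0 && max(abs(object@ld - t(object@ld))) > 1e-8)
    return("LD matrix must be symmetric")
  if (L > 0 && max(abs(diag(object@ld) - 1)) > 1e-8)
    return("LD matrix must have unit diagonal")
  TRUE
})

#' A causal-effect estimate from one MR method
#'
#' @slot method one of "gsmr", "ivw", "egger", "wmedian", "wald".
#' @slot b,se,p log-odds causal effect per protein SD, its SE and p-value.
#' @slot or_,ciLow,ciHigh odds ratio with 95 percent confidence bounds.
#' @slot nIvInitial,nIvUsed instrument counts before/after outlier removal.
#' @slot removedSnps ids removed as HEIDI outliers.
#' @slot heidiApplied whether outlier removal ran.
#' @slot eggerIntercept,eggerInterceptP pleiotropy intercept test (egger only).
#' @slot phi random-effect residual inflation, floored at 1 (ivw/egger only).
#' @slot bootstrapSeed seed used for the bootstrap SE (wmedian only).
#' @export
setClass("MREstimate",
  representation(method = "character", b = "numeric", se = "numeric",
    p = "numeric", or_ = "numeric", ciLow = "numeric", ciHigh = "numeric",
    nIvInitial = "integer", nIvUsed = "integer", removedSnps = "character",
    heidiApplied = "logical", eggerIntercept = "numeric",
    eggerInterceptP = "numeric", phi = "numeric", bootstrapSeed = "integer"),
  prototype(removedSnps = character(0), heidiApplied = FALSE,
    eggerIntercept = NA_real_, eggerInterceptP = NA_real_, phi = NA_real_,
    bootstrapSeed = NA_integer_))

setValidity("MREstimate", function(object) {
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@or_ + 1e-12 && object@or_ <= object@ciHigh + 1e-12))
    return("confidence bounds must bracket the odds ratio")
  if (!is.na(object@nIvUsed) && !is.na(object@nIvInitial) &&
      object@nIvUsed > object@nIvInitial)
    return("nIvUsed cannot exceed nIvInitial")
  TRUE
})

#' Protein-by-disease MR grid with FDR control
#'
#' @slot results one row per (protein, disease) cell: per-method estimates,
#'   the main-analysis (GSMR) raw p, its BH-adjusted value over all attempted
#'   cells, the significance call, heat-map category and flags.
#' @slot mTests number of cells attempted (the BH denominator).
#' @slot params list of run parameters (methods, alpha levels, seeds).
#' @export
setClass("MRGrid",
  representation(results = "data.frame", mTests = "integer", params = "list"))

setValidity("MRGrid", function(object) {
  res <- object@results
  if (nrow(res) > 0 && all(c("raw_p", "fdr_p") %in% names(res))) {
    ok <- is.na(res$raw_p) | is.na(res$fdr_p) |
      (res$fdr_p >= res$raw_p - 1e-12 & res$fdr_p <= 1 + 1e-12)
    if (!all(ok)) return("fdr_p must lie in [raw_p, 1]")
  }
  TRUE
})
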