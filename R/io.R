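#' Read and write summary-statistic tables
#'
#' The on-disk layout is a TSV with the GCTA-COJO-compatible column set
#' \code{SNP, A1, A2, freq, b, se, p, N} plus \code{CHR} and \code{POS}
#' (1-based). On read, each row's p-value is checked against the two-sided
#' normal tail of b/se and a warning names SNPs deviating by more than 10
#' percent relative (t-based and sentinel rows excepted via \code{se = Inf}).
#'
#' @param path file path.
#' @param trait,cohort labels stored on the object.
#' @return \code{readSummaryStats}: a \linkS4class{SummaryStats}.
#' @export
readSummaryStats <- function(path, trait = NA_character_, cohort = NA_character_) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "POS", "A1", "A2", "freq", "b", "se", "p", "N")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("summary-statistics file lacks columns: ", paste(miss, collapse = ", "))
  st <- data.frame(snp_id = d$SNP, chrom = as.character(d$CHR), pos = d$POS,
                   effect_allele = d$A1, other_allele = d$A2, eaf = d$freq,
                   beta = d$b, se = d$se, p = d$p, n = d$N)
  expected <- 2 * pnorm(-abs(st$beta / st$se))
  chk <- is.finite(st$se) & expected > 0
  bad <- chk & abs(st$p - expected) / expected > 0.10
  if (any(bad))
    warning("p-values inconsistent with beta/se (>10% relative) for: ",
            paste(st$snp_id[bad], collapse = ", "))
  SummaryStats(st, trait = trait, cohort = cohort)
}

#' @param x the object to write.
#' @rdname readSummaryStats
#' @export
writeSummaryStats <- function(x, path) {
  st <- x@stats
  out <- data.frame(SNP = st$snp_id, CHR = st$chrom, POS = st$pos,
                    A1 = st$effect_allele, A2 = st$other_allele,
                    freq = st$eaf, b = st$beta, se = st$se, p = st$p,
                    N = st$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write signed LD matrices
#'
#' Square TSV of signed r with SNP ids as both header and first column.
#'
#' @param path file path.
#' @return \code{readLDMatrix}: an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  d <- read.delim(path, sep = "\t", row.names = 1, check.names = FALSE)
  LDMatrix(as.matrix(d))
}

#' @param x the \linkS4class{LDMatrix} to write.
#' @rdname readLDMatrix
#' @export
writeLDMatrix <- function(x, path) {
  r <- x@r
  out <- data.frame(SNP = rownames(r), r, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the individual-level pieces of a paired study
#'
#' Emits dosage TSVs (samples x SNPs with a header row of SNP ids and sample
#' ids in the first column), phenotype/covariate TSVs, a variant-annotation
#' TSV (SNP, CHR, POS, A1, A2, EAF), both cohorts' LD estimates, and the
#' simulation truth as YAML.
#'
#' @param study a \linkS4class{PairedStudy}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wDos <- function(panel, path) {
    d <- data.frame(sample_id = rownames(panel@dosage), panel@dosage,
                    check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wDos(study@exposurePanel, file.path(dir, "exposure_dosage.tsv"))
  wDos(study@outcomePanel, file.path(dir, "outcome_dosage.tsv"))
  expPh <- data.frame(sample_id = names(study@protein),
                      protein = study@protein, study@exposureCovariates,
                      check.names = FALSE)
  write.table(expPh, file.path(dir, "exposure_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  outPh <- data.frame(sample_id = names(study@caseLabels),
                      case = study@caseLabels, study@outcomeCovariates,
                      check.names = FALSE)
  write.table(outPh, file.path(dir, "outcome_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  v <- study@exposurePanel@variants
  write.table(data.frame(SNP = v$snp_id, CHR = v$chrom, POS = v$pos,
                         A1 = v$effect_allele, A2 = v$other_allele,
                         EAF = v$eaf),
              file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLDMatrix(estimateLD(study@exposurePanel), file.path(dir, "ld_exposure.tsv"))
  writeLDMatrix(estimateLD(study@outcomePanel), file.path(dir, "ld_outcome.tsv"))
  tr <- study@truth
  yaml::write_yaml(list(
    true_b = tr@trueB, causal_snp_ids = as.list(tr@causalSnps),
    pleiotropic_snp_ids = as.list(tr@pleiotropicSnps),
    per_snp_effects = as.list(tr@perSnpEffects),
    pleio_effects = as.list(tr@pleioEffects),
    realized_h2 = tr@realizedH2), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read gene annotations from TSV or BED
#'
#' TSV input carries \code{gene_id, chrom, start, end} with 1-based inclusive
#' coordinates; BED input (detected by the \code{.bed} extension, no header,
#' columns chrom/start/end/name) uses 0-based half-open coordinates and is
#' converted to 1-based inclusive on read.
#'
#' @param path file path.
#' @return data.frame with gene_id, chrom, start, end (1-based inclusive).
#' @export
readGeneAnnotations <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    d <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("BED input needs chrom/start/end/name columns")
    data.frame(gene_id = d[[4]], chrom = as.character(d[[1]]),
               start = d[[2]] + 1L, end = d[[3]])
  } else {
    d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(d))
    if (length(miss) > 0)
      stop("gene annotation lacks columns: ", paste(miss, collapse = ", "))
    d$chrom <- as.character(d$chrom)
    d[, need]
  }
}

#' Write and read an instrument set (TSV + YAML parameter sidecar)
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param dir output directory; files are named after the protein id.
#' @return \code{writeInstrumentSet}: invisibly, the paths written.
#' @export
writeInstrumentSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, set@proteinId)
  d <- set@data
  for (j in seq_along(d)) if (is.numeric(d[[j]]))
    d[[j]] <- formatC(d[[j]], digits = 17, format = "g")
  write.table(d, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLDMatrix(LDMatrix(set@ldExposure), paste0(base, ".ld_exposure.tsv"))
  writeLDMatrix(LDMatrix(set@ldOutcome), paste0(base, ".ld_outcome.tsv"))
  yaml::write_yaml(c(set@params,
                     list(protein_id = set@proteinId,
                          heidi_capable = set@heidiCapable)),
                   paste0(base, ".yaml"))
  invisible(paste0(base, c(".tsv", ".ld_exposure.tsv", ".ld_outcome.tsv", ".yaml")))
}

#' @param proteinId protein whose files to read back.
#' @rdname writeInstrumentSet
#' @export
readInstrumentSet <- function(dir, proteinId) {
  base <- file.path(dir, proteinId)
  d <- read.delim(paste0(base, ".tsv"), sep = "\t", stringsAsFactors = FALSE)
  d$chrom <- as.character(d$chrom)
  pars <- yaml::read_yaml(paste0(base, ".yaml"))
  hc <- isTRUE(pars$heidi_capable)
  pars <- pars[c("pThresh", "r2Thresh", "windowBp", "minIv")]
  pars$minIv <- as.integer(pars$minIv)
  new("InstrumentSet", proteinId = proteinId, data = d,
      ldExposure = readLDMatrix(paste0(base, ".ld_exposure.tsv"))@r,
      ldOutcome = readLDMatrix(paste0(base, ".ld_outcome.tsv"))@r,
      params = pars, heidiCapable = hc)
}

#' Printed main-analysis p-values bundled with the package
#'
#' Raw GSMR p-values for the 15 biomarker-disease pairs reported by a
#' published two-sample MR screen of 21 inflammatory protein biomarkers
#' against 18 inflammatory diseases (main setting: instrument p < 1e-6,
#' LD r-squared < 0.6), together with the published FDR-adjusted values.
#' Used by the worked FDR examples and the acceptance checks.
#'
#' @return data.frame with biomarker, disease, p and published_fdr columns.
#' @export
mainAnalysisPvalues <- function() {
  path <- system.file("extdata", "main_mr_pvalues.tsv", package = "proteoMR",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
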