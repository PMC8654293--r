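#' Cis-regulatory window around a protein-coding gene
#'
#' The interval between the gene end points extended by \code{windowBp} on
#' each side, 1-based and inclusive at both ends, clamped at position 1.
#'
#' @param gene list or one-row data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param windowBp flank size in base pairs (default 2 Mb).
#' @return A length-one \code{GRanges}.
#' @export
cisWindow <- function(gene, windowBp = 2000000) {
  gene <- as.list(gene)
  if (gene$start > gene$end) stop("gene start must not exceed end")
  GenomicRanges::GRanges(
    seqnames = as.character(gene$chrom),
    ranges = IRanges::IRanges(start = max(1, gene$start - windowBp),
                              end = gene$end + windowBp),
    gene_id = gene$gene_id)
}

.PALINDROMES <- c(A = "T", T = "A", C = "G", G = "C")

#' Intersect two cohorts' summary statistics and harmonize alleles
#'
#' Keeps SNPs present in both tables. Strand-ambiguous (palindromic A/T or
#' C/G) SNPs are excluded by default since their orientation cannot be
#' verified between cohorts. Where the outcome's allele pair is the swap of
#' the exposure's, the outcome beta's sign is flipped and its EAF replaced by
#' 1 - EAF; irreconcilable allele pairs are excluded with reason.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects (or their
#'   data.frames) carrying alleles. Duplicate snp_ids raise an error.
#' @param excludePalindromic drop strand-ambiguous SNPs (default TRUE).
#' @return List with \code{data}, a merged data.frame carrying
#'   snp_id/chrom/pos/alleles/eaf from the exposure plus b_zx/se_zx/p_zx and
#'   harmonized b_zy/se_zy/p_zy/eaf_zy, and \code{excluded}, a data.frame of
#'   (snp_id, reason).
#' @export
intersectAndHarmonize <- function(exposure, outcome, excludePalindromic = TRUE) {
  ex <- if (is(exposure, "SummaryStats")) exposure@stats else as.data.frame(exposure)
  ou <- if (is(outcome, "SummaryStats")) outcome@stats else as.data.frame(outcome)
  if (anyDuplicated(ex$snp_id)) stop("duplicate snp_id in the exposure table")
  if (anyDuplicated(ou$snp_id)) stop("duplicate snp_id in the outcome table")
  excluded <- data.frame(snp_id = character(0), reason = character(0))
  note <- function(ids, why) {
    if (length(ids) > 0)
      excluded <<- rbind(excluded, data.frame(snp_id = ids, reason = why))
  }
  absent <- setdiff(ex$snp_id, ou$snp_id)
  note(absent, "absent from outcome")
  ex <- ex[ex$snp_id %in% ou$snp_id, , drop = FALSE]
  idx <- match(ex$snp_id, ou$snp_id)
  ou <- ou[idx, , drop = FALSE]

  pal <- toupper(ex$effect_allele) == .PALINDROMES[toupper(ex$other_allele)]
  pal[is.na(pal)] <- FALSE
  if (excludePalindromic) {
    note(ex$snp_id[pal], "palindromic")
    ex <- ex[!pal, , drop = FALSE]
    ou <- ou[!pal, , drop = FALSE]
  }
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  bad <- !(same | swap)
  note(ex$snp_id[bad], "allele mismatch")
  ex <- ex[!bad, , drop = FALSE]
  ou <- ou[!bad, , drop = FALSE]
  swap <- swap[!bad]

  data <- data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = ex$eaf,
    b_zx = ex$beta, se_zx = ex$se, p_zx = ex$p, n_zx = ex$n,
    b_zy = ifelse(swap, -ou$beta, ou$beta),
    se_zy = ou$se, p_zy = ou$p, n_zy = ou$n,
    eaf_zy = ifelse(swap, 1 - ou$eaf, ou$eaf),
    flipped = swap)
  rownames(data) <- NULL
  list(data = data, excluded = excluded)
}

# r^2 between one SNP and a set, from a signed-r matrix; errors on absences
.r2With <- function(ld, snp, others) {
  missing <- setdiff(c(snp, others), rownames(ld))
  if (length(missing) > 0)
    stop("SNP(s) missing from an LD matrix: ", paste(missing, collapse = ", "))
  ld[snp, others]^2
}

#' Greedy dual-cohort LD pruning of instrument candidates
#'
#' Iterates the selection loop: (i) pick the candidate with the lowest
#' exposure p-value (ties: smaller position, then lexicographic snp_id);
#' (ii) remove every remaining candidate in LD (r-squared strictly above
#' \code{r2Thresh}) with the pick in either cohort's LD matrix; (iii) repeat
#' until no candidate remains. The returned set is pairwise below the
#' threshold in both cohorts.
#'
#' @param candidates data.frame with snp_id, pos, p_zx, all already inside
#'   the cis window with p_zx below the selection threshold.
#' @param ldExposure,ldOutcome \linkS4class{LDMatrix} (or matrices) covering
#'   all candidates; a missing SNP raises an error.
#' @param r2Thresh LD pruning threshold on r-squared (default 0.6).
#' @return Character vector of selected snp_ids, in selection order.
#' @export
greedyPrune <- function(candidates, ldExposure, ldOutcome, r2Thresh = 0.6) {
  if (is(ldExposure, "LDMatrix")) ldExposure <- ldExposure@r
  if (is(ldOutcome, "LDMatrix")) ldOutcome <- ldOutcome@r
  cand <- as.data.frame(candidates)
  if (nrow(cand) == 0) return(character(0))
  missing <- setdiff(cand$snp_id, intersect(rownames(ldExposure), rownames(ldOutcome)))
  if (length(missing) > 0)
    stop("SNP(s) missing from an LD matrix: ", paste(missing, collapse = ", "))
  ord <- order(cand$p_zx, cand$pos, cand$snp_id)
  cand <- cand[ord, , drop = FALSE]
  selected <- character(0)
  remaining <- cand$snp_id
  while (length(remaining) > 0) {
    pick <- remaining[1]
    selected <- c(selected, pick)
    rest <- setdiff(remaining, pick)
    if (length(rest) > 0) {
      drop <- .r2With(ldExposure, pick, rest) > r2Thresh |
              .r2With(ldOutcome, pick, rest) > r2Thresh
      remaining <- rest[!drop]
    } else remaining <- character(0)
  }
  selected
}

#' Select the instrument set for one protein
#'
#' Composes the selection pipeline: restrict the exposure scan to the cis
#' window of the protein-coding gene, intersect with the outcome cohort and
#' harmonize alleles, keep SNPs with exposure p below \code{pThresh}, and
#' greedily prune to pairwise LD r-squared at most \code{r2Thresh} in both
#' cohorts. Proteins ending with fewer than \code{minIv} instruments return
#' an \linkS4class{InstrumentRejection}; sets of exactly 4 instruments are
#' flagged HEIDI-incapable (outlier removal needs at least 5 SNPs).
#'
#' @param proteinId protein identifier.
#' @param gene gene annotation (see \code{\link{cisWindow}}).
#' @param exposure,outcome \linkS4class{SummaryStats} for the protein scan
#'   and the disease scan.
#' @param ldExposure,ldOutcome signed LD sources covering the candidates.
#' @param pThresh exposure p-value threshold (default 1e-6).
#' @param r2Thresh LD threshold (default 0.6).
#' @param windowBp cis flank (default 2 Mb).
#' @param minIv minimum instrument count (default 4).
#' @param excludePalindromic drop strand-ambiguous SNPs (default TRUE).
#' @return An \linkS4class{InstrumentSet} or \linkS4class{InstrumentRejection}.
#' @export
selectInstruments <- function(proteinId, gene, exposure, outcome,
                              ldExposure, ldOutcome,
                              pThresh = 1e-6, r2Thresh = 0.6,
                              windowBp = 2000000, minIv = 4L,
                              excludePalindromic = TRUE) {
  if (is(ldExposure, "LDMatrix")) ldExposure <- ldExposure@r
  if (is(ldOutcome, "LDMatrix")) ldOutcome <- ldOutcome@r
  params <- list(pThresh = pThresh, r2Thresh = r2Thresh,
                 windowBp = windowBp, minIv = as.integer(minIv))
  win <- cisWindow(gene, windowBp)
  harm <- intersectAndHarmonize(exposure, outcome,
                                excludePalindromic = excludePalindromic)
  d <- harm$data
  inWin <- d$chrom == as.character(GenomicRanges::seqnames(win)) &
    d$pos >= GenomicRanges::start(win) & d$pos <= GenomicRanges::end(win)
  d <- d[inWin & d$p_zx < pThresh, , drop = FALSE]
  sel <- greedyPrune(d, ldExposure, ldOutcome, r2Thresh = r2Thresh)
  if (length(sel) < minIv)
    return(new("InstrumentRejection", proteinId = proteinId,
               reason = "n_selected < min_iv",
               nSelected = length(sel), params = params))
  d <- d[match(sel, d$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  # orient the outcome-cohort LD signs to the common (exposure) effect allele
  s <- ifelse(d$flipped, -1, 1)
  ldo <- ldOutcome[sel, sel, drop = FALSE] * tcrossprod(s)
  diag(ldo) <- 1
  dimnames(ldo) <- list(sel, sel)
  new("InstrumentSet", proteinId = proteinId, data = d,
      ldExposure = ldExposure[sel, sel, drop = FALSE],
      ldOutcome = ldo,
      params = params, heidiCapable = length(sel) >= 5L)
}
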