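#' Rank-based inverse normal transformation
#'
#' Maps values within each group to normal quantiles of their (average, for
#' ties) ranks: \eqn{\Phi^{-1}((rank - 0.5)/n)}. The output is invariant to
#' any strictly increasing transform of the input, has mean 0 within each
#' group, and SD slightly below 1 in finite samples. Missing values are left
#' missing and do not consume ranks.
#'
#' @param values numeric vector.
#' @param groups optional grouping factor (e.g. assay plate); the transform
#'   is applied within each group.
#' @param offset rank offset c in (rank - c)/n; 0.5 by default (symmetric).
#' @return Numeric vector of the same length.
#' @export
rankInverseNormal <- function(values, groups = NULL, offset = 0.5) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  if (length(groups) != length(values))
    stop("groups must match values in length")
  out <- rep(NA_real_, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(values))
    if (length(idx) < 2)
      stop("group '", g, "' has fewer than 2 non-missing values")
    r <- rank(values[idx], ties.method = "average")
    out[idx] <- qnorm((r - offset) / length(idx))
  }
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square comparison of observed genotype counts
#' with the counts expected under HWE at the sample allele frequency.
#' Returns 1 when any expected count is zero (monomorphic site). Vectorized.
#'
#' @param nAA,nAa,naa genotype counts (effect-allele homozygote,
#'   heterozygote, other homozygote).
#' @return p-value(s) in (0, 1].
#' @export
hweTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (any(n <= 0)) stop("total genotype count must be positive")
  p <- (2 * nAA + nAa) / (2 * n)
  eAA <- n * p^2
  eAa <- n * 2 * p * (1 - p)
  eaa <- n * (1 - p)^2
  chi <- ifelse(eAA == 0 | eAa == 0 | eaa == 0, 0,
                (nAA - eAA)^2 / eAA + (nAa - eAa)^2 / eAa + (naa - eaa)^2 / eaa)
  pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Variant QC filter
#'
#' Removes variants failing any of the thresholds, recording one reason per
#' removed variant, the first failing rule in the fixed order
#' MAF, HWE, missingness, info. Columns \code{hwe_p}, \code{missing} and
#' \code{info} are each optional; absent columns skip the corresponding rule.
#' The filter is idempotent.
#'
#' @param variants data.frame with at least \code{snp_id} and \code{eaf}
#'   (minor allele frequency is \code{pmin(eaf, 1 - eaf)}), optionally
#'   \code{hwe_p}, \code{missing}, \code{info}.
#' @param thresholds a \linkS4class{QCThresholds}.
#' @return List with \code{kept} (filtered data.frame) and \code{removed}
#'   (data.frame of snp_id, reason).
#' @export
qcFilterVariants <- function(variants, thresholds = qcThresholds()) {
  stopifnot(is(thresholds, "QCThresholds"))
  variants <- as.data.frame(variants)
  if (!all(c("snp_id", "eaf") %in% names(variants)))
    stop("variants must carry snp_id and eaf")
  reason <- rep(NA_character_, nrow(variants))
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  reason[is.na(reason) & maf < thresholds@mafMin] <- "MAF"
  if ("hwe_p" %in% names(variants))
    reason[is.na(reason) & variants$hwe_p < thresholds@hwePMin] <- "HWE"
  if ("missing" %in% names(variants))
    reason[is.na(reason) & variants$missing > thresholds@missingMax] <- "missingness"
  if ("info" %in% names(variants))
    reason[is.na(reason) & variants$info < thresholds@infoMin] <- "info"
  keep <- is.na(reason)
  list(kept = variants[keep, , drop = FALSE],
       removed = data.frame(snp_id = variants$snp_id[!keep],
                            reason = reason[!keep]))
}

# shared per-SNP scan scaffolding: builds the summary table skeleton
.scanTable <- function(panel, beta, se, p, n) {
  v <- panel@variants
  SummaryStats(data.frame(
    snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    eaf = colMeans(panel@dosage) / 2,
    beta = beta, se = se, p = p, n = n))
}

#' Per-SNP linear association scan
#'
#' Ordinary least squares of the phenotype on each SNP's dosage plus the
#' covariates (with intercept), reporting the dosage coefficient, its SE and
#' a t-distribution p-value with residual degrees of freedom. Computed via
#' Frisch-Waugh residualization against the covariate design, which is exact
#' OLS. A constant dosage column is reported with an infinite-SE sentinel and
#' p = 1 rather than dropped.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param phenotype numeric response, one value per sample. Supply it already
#'   INT-transformed, or set \code{int = TRUE} to apply
#'   \code{\link{rankInverseNormal}} here.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param int apply the rank-based inverse normal transform first.
#' @param trait,cohort labels stored on the result.
#' @return A \linkS4class{SummaryStats} with betas per SD of the (INT)
#'   phenotype per dosage unit.
#' @export
linearScan <- function(panel, phenotype, covariates = NULL, int = FALSE,
                       trait = NA_character_, cohort = NA_character_) {
  D <- panel@dosage
  n <- nrow(D)
  if (length(phenotype) != n) stop("phenotype length must match sample count")
  if (int) phenotype <- rankInverseNormal(phenotype)
  C <- cbind(rep(1, n))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))
  qc <- qr(C)
  yr <- qr.resid(qc, phenotype)
  Dr <- qr.resid(qc, D)
  ssx <- colSums(Dr^2)
  df <- n - qc$rank - 1L
  xy <- colSums(Dr * yr)
  beta <- ifelse(ssx > 1e-12, xy / ssx, NA_real_)
  rss <- pmax(sum(yr^2) - beta^2 * ssx, 0)
  se <- sqrt(rss / df / ssx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = df)
  const <- ssx <= 1e-12
  beta[const] <- 0
  se[const] <- Inf
  p[const] <- 1
  .scanTable(panel, beta, se, p, n)
}

#' Per-SNP logistic association scan
#'
#' Maximum-likelihood logistic regression of case status on each SNP's
#' dosage plus covariates, reporting the log-odds per dosage unit with Wald
#' SE and normal p-value. Non-converged fits or fits showing separation
#' (exploding coefficient or SE) are flagged with sentinel values
#' (beta 0, se Inf, p 1) rather than dropped.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param labels 0/1 case status per sample; both classes must be present.
#' @param covariates optional numeric matrix/data.frame.
#' @param trait,cohort labels stored on the result.
#' @return A \linkS4class{SummaryStats}.
#' @export
logisticScan <- function(panel, labels, covariates = NULL,
                         trait = NA_character_, cohort = NA_character_) {
  D <- panel@dosage
  n <- nrow(D)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match sample count")
  if (length(unique(labels)) < 2)
    stop("both cases and controls are required")
  C <- cbind(rep(1, n))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))
  M <- ncol(D)
  beta <- se <- numeric(M)
  for (j in seq_len(M)) {
    X <- cbind(C[, 1, drop = FALSE], D[, j], C[, -1, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, labels, family = stats::binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged && !anyNA(fit$coefficients)
    if (ok) {
      b <- fit$coefficients[2]
      # Wald SE from the unscaled inverse Fisher information
      R <- fit$qr$qr[seq_len(ncol(X)), , drop = FALSE]
      cov <- tryCatch(chol2inv(R), error = function(e) NULL)
      s <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
      if (!is.finite(b) || !is.finite(s) || abs(b) > 20 || s > 100) ok <- FALSE
      else { beta[j] <- b; se[j] <- s }
    }
    if (!ok) { beta[j] <- 0; se[j] <- Inf }
  }
  p <- ifelse(is.finite(se), 2 * pnorm(-abs(beta / se)), 1)
  .scanTable(panel, beta, se, p, n)
}

#' Variance in a phenotype explained by SNP subsets
#'
#' Per-SNP R-squared is the incremental R-squared of adding that SNP alone to
#' the covariate-only model; the joint value adds the whole subset at once.
#' Aliased (linearly dependent) SNPs are dropped from the joint fit with a
#' warning.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param phenotype numeric response.
#' @param covariates optional numeric matrix/data.frame.
#' @param snps character vector of SNP ids (non-empty).
#' @return List with \code{perSnp} (named numeric) and \code{joint} (scalar),
#'   both fractions in [0, 1].
#' @export
varianceExplained <- function(panel, phenotype, covariates = NULL, snps) {
  if (length(snps) == 0) stop("snps must be non-empty")
  D <- panel@dosage
  if (!all(snps %in% colnames(D)))
    stop("unknown SNP ids: ", paste(setdiff(snps, colnames(D)), collapse = ", "))
  n <- nrow(D)
  C <- cbind(rep(1, n))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))
  qc <- qr(C)
  yr <- qr.resid(qc, phenotype)
  tss <- sum(yr^2)
  rssOf <- function(X) {
    Xr <- qr.resid(qc, X)
    q2 <- qr(Xr)
    sum(qr.resid(q2, yr)^2)
  }
  perSnp <- vapply(snps, function(s) {
    (tss - rssOf(D[, s, drop = FALSE])) / tss
  }, numeric(1))
  X <- D[, snps, drop = FALSE]
  q2 <- qr(qr.resid(qc, X))
  if (q2$rank < length(snps)) {
    kept <- snps[q2$pivot[seq_len(q2$rank)]]
    warning("dropping aliased SNPs from the joint fit: ",
            paste(setdiff(snps, kept), collapse = ", "))
    X <- D[, kept, drop = FALSE]
  }
  joint <- (tss - rssOf(X)) / tss
  list(perSnp = pmin(pmax(perSnp, 0), 1), joint = min(max(joint, 0), 1))
}
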