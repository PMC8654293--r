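#' Configure a synthetic paired-cohort study
#'
#' Defaults mirror the study setting the pipeline was built for: an exposure
#' cohort of 872 individuals with a unit-variance protein whose genetics
#' explain 30 percent of its variance through 10 cis SNPs in two AR(1) LD
#' blocks, and an outcome cohort of 20,000 individuals with 2,000 expected
#' cases and a protective causal odds ratio of 0.84 per protein SD.
#'
#' @param seed integer RNG seed.
#' @param nExposure,nOutcome,nCases cohort sizes (cases in expectation).
#' @param nSnpsPerBlock integer vector of LD-block sizes.
#' @param blockRho within-block AR(1) correlation(s) in [0, 1).
#' @param eafRange effect-allele-frequency sampling interval in (0, 1).
#' @param nCausal number of SNPs with nonzero protein effects (taken from the
#'   start of the SNP list, spread over blocks in order).
#' @param h2Target protein variance fraction explained by the causal SNPs.
#' @param trueB causal log-odds effect per SD of INT protein level.
#' @param pleioFraction fraction of causal instruments receiving direct
#'   disease effects.
#' @param pleioEffectMean,pleioEffectSd mean/SD of the direct log-odds effects.
#' @param nPCs number of standardized PC-like covariates.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nExposure = 872L, nOutcome = 20000L,
                             nCases = 2000L, nSnpsPerBlock = c(5L, 5L),
                             blockRho = 0.3, eafRange = c(0.15, 0.85),
                             nCausal = 10L, h2Target = 0.3,
                             trueB = log(0.84), pleioFraction = 0,
                             pleioEffectMean = 0, pleioEffectSd = 0.05,
                             nPCs = 2L) {
  new("SimulationConfig", seed = as.integer(seed),
      nExposure = as.integer(nExposure), nOutcome = as.integer(nOutcome),
      nCases = as.integer(nCases), nSnpsPerBlock = as.integer(nSnpsPerBlock),
      blockRho = rep_len(blockRho, length(nSnpsPerBlock)),
      eafRange = eafRange, nCausal = as.integer(nCausal),
      h2Target = h2Target, trueB = trueB, pleioFraction = pleioFraction,
      pleioEffectMean = pleioEffectMean, pleioEffectSd = pleioEffectSd,
      nPCs = as.integer(nPCs))
}

#' Block-diagonal AR(1) LD matrix
#'
#' Within block \eqn{k} of size \eqn{m_k}, the signed correlation between
#' SNPs \eqn{i} and \eqn{j} is \eqn{\rho_k^{|i-j|}}; cross-block entries are
#' zero. The result is symmetric, unit-diagonal and positive definite for
#' \eqn{\rho \in [0, 1)}.
#'
#' @param config a \linkS4class{SimulationConfig}, or an integer vector of
#'   block sizes (with \code{blockRho} then read from the second argument).
#' @param blockRho per-block correlation decay, used when \code{config} is a
#'   plain vector of block sizes.
#' @param snpIds optional SNP ids; defaults to "snp_1", ...
#' @return An \linkS4class{LDMatrix}.
#' @export
simulateLDMatrix <- function(config, blockRho = NULL, snpIds = NULL) {
  if (is(config, "SimulationConfig")) {
    sizes <- config@nSnpsPerBlock
    rhos <- config@blockRho
  } else {
    sizes <- as.integer(config)
    if (is.null(blockRho)) stop("blockRho required with plain block sizes")
    rhos <- rep_len(blockRho, length(sizes))
  }
  if (any(rhos < 0 | rhos >= 1)) stop("blockRho must lie in [0, 1)")
  if (any(sizes < 1)) stop("block sizes must be >= 1")
  M <- sum(sizes)
  r <- matrix(0, M, M)
  at <- 0L
  for (k in seq_along(sizes)) {
    idx <- at + seq_len(sizes[k])
    r[idx, idx] <- rhos[k]^abs(outer(seq_len(sizes[k]), seq_len(sizes[k]), "-"))
    at <- at + sizes[k]
  }
  if (is.null(snpIds)) snpIds <- paste0("snp_", seq_len(M))
  LDMatrix(r, snpIds = snpIds)
}

#' Simulate HWE genotype dosages with a target LD structure
#'
#' Gaussian-copula scheme: per individual, two independent multivariate
#' normal latent vectors with correlation matrix \code{ld} are drawn (one per
#' haplotype) and thresholded at the normal quantile of each SNP's effect
#' allele frequency; the haplotype indicators are summed to a 0/1/2 dosage.
#' Marginals are Binomial(2, eaf) and Hardy-Weinberg holds by construction;
#' dosage correlations approximate (slightly attenuate) the latent \code{ld}.
#'
#' @param ld an \linkS4class{LDMatrix} (or plain correlation matrix).
#' @param eafs effect-allele frequencies in (0, 1), one per SNP.
#' @param n number of individuals (>= 2).
#' @param seed optional integer seed for reproducibility.
#' @param sampleIds optional sample ids; default "S1", ...
#' @param variants optional variant annotation data.frame; a default one
#'   (chromosome 1, 5-kb spacing, A/G alleles) is built if omitted.
#' @return A \linkS4class{GenotypePanel}.
#' @export
simulateGenotypes <- function(ld, eafs, n, seed = NULL, sampleIds = NULL,
                              variants = NULL) {
  if (is(ld, "LDMatrix")) {
    snpIds <- rownames(ld@r)
    R <- ld@r
  } else {
    R <- as.matrix(ld)
    snpIds <- rownames(R) %||% paste0("snp_", seq_len(nrow(R)))
  }
  M <- nrow(R)
  if (length(eafs) != M) stop("length(eafs) must match the LD dimension")
  if (any(eafs <= 0 | eafs >= 1)) stop("eafs must lie in (0, 1)")
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  U <- chol(R)
  thr <- qnorm(eafs)  # haplotype carries the effect allele when latent < thr
  hap <- function() {
    Z <- matrix(rnorm(n * M), n, M) %*% U
    sweep(Z, 2, thr, "<") + 0
  }
  dos <- hap() + hap()
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
  dimnames(dos) <- list(sampleIds, snpIds)
  if (is.null(variants))
    variants <- data.frame(snp_id = snpIds, chrom = "1",
                           pos = 1000000L + (seq_len(M) - 1L) * 5000L,
                           effect_allele = "A", other_allele = "G",
                           eaf = as.numeric(eafs))
  GenotypePanel(dos, variants)
}

#' Signed LD estimated from a genotype panel
#'
#' Pairwise Pearson correlation of dosages, the empirical analogue of the
#' outcome-cohort LD estimate used in the causal-effect covariance model.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @return An \linkS4class{LDMatrix}.
#' @export
estimateLD <- function(panel) {
  r <- cor(panel@dosage)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  LDMatrix(r, snpIds = colnames(panel@dosage))
}

#' Generate a paired exposure/outcome study
#'
#' Exposure cohort: dosages from the copula model; protein level =
#' sum(effect_j x dosage_j) + covariate effects + Gaussian noise, with
#' per-SNP effects scaled so the causal SNPs explain \code{h2Target} of the
#' (unit) protein variance and the noise variance set to
#' 1 - h2 - Var(covariate part), so log-odds per protein SD is the natural
#' effect scale. Outcome cohort: disjoint, independently drawn individuals
#' sharing SNP identities, EAFs and LD; case labels are Bernoulli draws from
#' a logistic model whose linear predictor is an intercept tuned so the
#' expected case count equals \code{nCases}, plus \code{trueB} times the
#' protein-scale genetic value, direct effects for pleiotropic SNPs, and
#' covariate effects.
#'
#' Pleiotropic SNPs are sampled among the causal SNPs excluding the
#' largest-effect (sentinel) SNP whenever \code{pleioFraction < 1}, emulating
#' a cis architecture whose lead variant acts through the protein.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{PairedStudy}.
#' @export
generatePairedStudy <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  M <- sum(config@nSnpsPerBlock)
  ld <- simulateLDMatrix(config)
  eafs <- runif(M, config@eafRange[1], config@eafRange[2])
  snpIds <- rownames(ld@r)

  # covariate effect sizes on the protein (standardized-covariate scale)
  covBetaProt <- c(sex = 0.10, age = 0.05, rep(0.03, config@nPCs))
  covBetaDis <- c(sex = 0.10, age = 0.20, rep(0.05, config@nPCs))
  # sex is Bernoulli(0.5) (variance 0.25); age and PCs standardized (variance 1)
  covVar <- covBetaProt[1]^2 * 0.25 + sum(covBetaProt[-1]^2)
  if (config@h2Target + covVar >= 1)
    stop("h2Target plus covariate variance must stay below 1")

  makeCovariates <- function(n, prefix) {
    d <- data.frame(sex = rbinom(n, 1L, 0.5),
                    age = round(runif(n, 35, 70)))
    for (k in seq_len(config@nPCs)) d[[paste0("PC", k)]] <- rnorm(n)
    rownames(d) <- paste0(prefix, seq_len(n))
    d
  }
  covMatrix <- function(d) {
    m <- cbind(sex = d$sex, age = as.numeric(scale(d$age)))
    for (k in seq_len(config@nPCs)) m <- cbind(m, d[[paste0("PC", k)]])
    m
  }

  # exposure cohort ---------------------------------------------------------
  expPanel <- simulateGenotypes(ld, eafs, config@nExposure,
                                sampleIds = paste0("EXP", seq_len(config@nExposure)))
  causal <- snpIds[seq_len(config@nCausal)]
  # per-SNP effect magnitudes: roughly equal h2 shares with mild jitter,
  # random signs; rescaled on the realized genetic value to hit h2Target
  shares <- runif(config@nCausal, 0.5, 1.5)
  u <- sample(c(-1, 1), config@nCausal, replace = TRUE) * sqrt(shares)
  gExp <- drop(expPanel@dosage[, causal, drop = FALSE] %*% u)
  u <- u * sqrt(config@h2Target / var(gExp))
  names(u) <- causal
  gExp <- drop(expPanel@dosage[, causal, drop = FALSE] %*% u)
  expCov <- makeCovariates(config@nExposure, "EXP")
  noiseVar <- 1 - config@h2Target - covVar
  protein <- gExp + drop(covMatrix(expCov) %*% covBetaProt) +
    rnorm(config@nExposure, sd = sqrt(noiseVar))
  names(protein) <- rownames(expPanel@dosage)
  # realized h2: incremental R2 of the causal dosages over covariates
  realizedH2 <- varianceExplained(expPanel, protein,
                                  covariates = covMatrix(expCov),
                                  snps = causal)$joint
  realizedH2 <- min(max(realizedH2, 0), 1)

  # pleiotropic SNPs --------------------------------------------------------
  nPleio <- round(config@pleioFraction * config@nCausal)
  pleioIds <- character(0)
  pleioEff <- numeric(0)
  if (nPleio > 0) {
    pool <- if (config@pleioFraction < 1 && config@nCausal > 1)
      setdiff(causal, causal[which.max(abs(u))]) else causal
    nPleio <- min(nPleio, length(pool))
    pleioIds <- sort(sample(pool, nPleio))
    pleioEff <- rnorm(nPleio, config@pleioEffectMean, config@pleioEffectSd)
    names(pleioEff) <- pleioIds
  }

  # outcome cohort ----------------------------------------------------------
  outPanel <- simulateGenotypes(ld, eafs, config@nOutcome,
                                sampleIds = paste0("OUT", seq_len(config@nOutcome)))
  outCov <- makeCovariates(config@nOutcome, "OUT")
  gOut <- drop(outPanel@dosage[, causal, drop = FALSE] %*% u)
  lp <- config@trueB * gOut + drop(covMatrix(outCov) %*% covBetaDis)
  if (length(pleioIds) > 0)
    lp <- lp + drop(outPanel@dosage[, pleioIds, drop = FALSE] %*% pleioEff)
  target <- config@nCases / config@nOutcome
  alpha0 <- uniroot(function(a) mean(plogis(a + lp)) - target,
                    interval = c(-30, 30), tol = 1e-10)$root
  labels <- rbinom(config@nOutcome, 1L, plogis(alpha0 + lp))
  names(labels) <- rownames(outPanel@dosage)

  truth <- new("SimulationTruth", trueB = config@trueB, causalSnps = causal,
               pleiotropicSnps = pleioIds, perSnpEffects = u,
               pleioEffects = pleioEff, realizedH2 = realizedH2)
  new("PairedStudy", exposurePanel = expPanel, protein = protein,
      outcomePanel = outPanel, caseLabels = labels,
      exposureCovariates = expCov, outcomeCovariates = outCov,
      truth = truth, config = config)
}

#' Run both cohort association scans on a generated study
#'
#' Convenience pipeline step: INT-transforms the protein and scans it
#' linearly in the exposure cohort, scans case status logistically in the
#' outcome cohort (both adjusted for sex, standardized age and the PC
#' covariates), estimates signed LD in the outcome cohort, and assembles the
#' summary-level MR input over the requested SNPs.
#'
#' @param study a \linkS4class{PairedStudy}.
#' @param snps SNPs to include in the MR input (default: the causal SNPs).
#' @return List with \code{exposure} and \code{outcome}
#'   (\linkS4class{SummaryStats}), \code{ld} (\linkS4class{LDMatrix},
#'   outcome cohort) and \code{input} (\linkS4class{MRInput}).
#' @export
scanStudy <- function(study, snps = NULL) {
  stopifnot(is(study, "PairedStudy"))
  covm <- function(d) {
    m <- cbind(sex = d$sex, age = as.numeric(scale(d$age)))
    pcs <- grep("^PC", names(d), value = TRUE)
    for (k in pcs) m <- cbind(m, d[[k]])
    m
  }
  exposure <- linearScan(study@exposurePanel, study@protein,
                         covariates = covm(study@exposureCovariates),
                         int = TRUE, trait = "protein", cohort = "exposure")
  outcome <- logisticScan(study@outcomePanel, study@caseLabels,
                          covariates = covm(study@outcomeCovariates),
                          trait = "disease", cohort = "outcome")
  ld <- estimateLD(study@outcomePanel)
  if (is.null(snps)) snps <- study@truth@causalSnps
  ex <- exposure@stats[match(snps, exposure@stats$snp_id), ]
  ou <- outcome@stats[match(snps, outcome@stats$snp_id), ]
  input <- mrInput(snps, ex$beta, ex$se, ou$beta, ou$se,
                   ld = ld@r[snps, snps, drop = FALSE], pzx = ex$p)
  list(exposure = exposure, outcome = outcome, ld = ld, input = input)
}
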