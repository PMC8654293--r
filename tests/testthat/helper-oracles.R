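# Independent oracle implementations used to cross-check the package.
# Each is written from the mathematical definition, sharing no code with R/.

# O(m^2) Benjamini-Hochberg from the step-up definition: the adjusted value
# of the k-th smallest p is min over j >= k of m * p_(j) / j, capped at 1.
oracleBH <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  n <- length(ps)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    best <- 1
    for (j in k:n) best <- min(best, m * ps[j] / j)
    adj[k] <- best
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# textbook BH step-up rejection count at level alpha (m = length)
oracleBHRejections <- function(p, alpha) {
  ps <- sort(p)
  m <- length(ps)
  k <- which(ps <= alpha * seq_len(m) / m)
  if (length(k) == 0) 0L else max(k)
}

# brute-force re-implementation of the dual-cohort greedy pruning loop:
# repeatedly take the remaining candidate with smallest (p, pos, id) and
# discard everything correlated above the threshold in either cohort.
oraclePrune <- function(cand, ldx, ldy, r2t) {
  picked <- character(0)
  alive <- rep(TRUE, nrow(cand))
  key <- order(cand$p_zx, cand$pos, cand$snp_id)
  rankOf <- integer(nrow(cand))
  rankOf[key] <- seq_len(nrow(cand))
  while (any(alive)) {
    i <- which(alive)[which.min(rankOf[alive])]
    s <- cand$snp_id[i]
    picked <- c(picked, s)
    alive[i] <- FALSE
    for (j in which(alive)) {
      t <- cand$snp_id[j]
      if (ldx[s, t]^2 > r2t || ldy[s, t]^2 > r2t) alive[j] <- FALSE
    }
  }
  picked
}

# GLS estimate of the causal effect by explicit matrix inversion, in the
# canonical orientation (every exposure effect positive, LD signs flipped)
oracleGLS <- function(bzx, sezx, bzy, sezy, R) {
  S <- diag(ifelse(bzx < 0, -1, 1), length(bzx))
  bzx <- drop(S %*% bzx)
  bzy <- drop(S %*% bzy)
  R <- S %*% R %*% S
  ratio <- bzy / bzx
  v <- (sezy^2 + ratio^2 * sezx^2) / bzx^2
  V <- R * outer(sqrt(v), sqrt(v))
  diag(V) <- v
  Vi <- solve(V)
  one <- rep(1, length(ratio))
  denom <- drop(t(one) %*% Vi %*% one)
  b <- drop(t(one) %*% Vi %*% ratio) / denom
  list(b = b, se = sqrt(1 / denom))
}

# scalar inverse-variance-weighted mean of Wald ratios (identity-LD oracle)
oracleScalarIVW <- function(bzx, sezx, bzy, sezy) {
  ratio <- bzy / bzx
  v <- (sezy^2 + ratio^2 * sezx^2) / bzx^2
  w <- 1 / v
  list(b = sum(w * ratio) / sum(w), se = sqrt(1 / sum(w)))
}

# random positive-definite correlation matrix with SNP ids
randomCorr <- function(L, ids = paste0("rs", seq_len(L))) {
  A <- matrix(rnorm(L * L), L)
  S <- crossprod(A) + diag(L) * 0.5
  r <- stats::cov2cor(S)
  dimnames(r) <- list(ids, ids)
  r
}

# summary-level two-sample MR data with optional pleiotropy: exposure betas
# drawn around fixed true effects, outcome betas b * bzx + direct effects,
# observation noise at the stated SEs (LD-correlated on both sides)
simSummary <- function(L = 10, b = log(0.84), sezx = 0.02, sezy = 0.03,
                       R = diag(L), pleio = numeric(L), bzx0 = NULL) {
  if (is.null(bzx0)) bzx0 <- seq(0.25, 0.45, length.out = L) * rep(c(1, -1), length.out = L)
  U <- chol(R)
  corrNoise <- function(se) drop(crossprod(U, rnorm(L))) * se
  bzx <- bzx0 + corrNoise(sezx)
  bzy <- b * bzx0 + pleio + corrNoise(sezy)
  proteoMR::mrInput(paste0("rs", seq_len(L)), bzx, rep(sezx, L), bzy,
                    rep(sezy, L), ld = R,
                    pzx = 2 * pnorm(-abs(bzx / sezx)))
}

# shared selection fixture: 12 cis SNPs with tiered exposure p-values and
# two LD blocks, plus an outcome table with matching alleles
selectionFixture <- function() {
  ids <- paste0("rs", 1:12)
  pos <- 3e6 + (0:11) * 2e4
  pzx <- c(1e-9, 1e-8, 1e-7, 2e-7, 5e-7, 8e-7, 1e-12, 3e-10, 6e-8, 2e-9,
           4e-7, 9e-7)
  beta <- qnorm(pzx / 2, lower.tail = FALSE) * 0.03
  ld <- matrix(0.05, 12, 12, dimnames = list(ids, ids))
  diag(ld) <- 1
  # one tight block (r ~ .9), one moderate block (r ~ .5)
  for (blk in list(1:4, 5:8)) {
    rho <- if (blk[1] == 1) 0.9 else 0.5
    ld[blk, blk] <- rho^abs(outer(blk, blk, "-"))
    diag(ld) <- 1
  }
  exposure <- proteoMR::SummaryStats(data.frame(
    snp_id = ids, chrom = "1", pos = pos, effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = beta, se = 0.03, p = pzx, n = 872))
  outcome <- proteoMR::SummaryStats(data.frame(
    snp_id = ids, chrom = "1", pos = pos, effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = beta * log(0.9), se = 0.01,
    p = 2 * pnorm(-abs(beta * log(0.9)) / 0.01), n = 3e5))
  gene <- list(gene_id = "GENE1", chrom = "1", start = 3e6, end = 3.1e6)
  list(exposure = exposure, outcome = outcome, gene = gene, ld = ld, ids = ids)
}

# covariate design used by the scans, mirroring scanStudy()
covDesign <- function(d) {
  m <- cbind(sex = d$sex, age = as.numeric(scale(d$age)))
  for (k in grep("^PC", names(d), value = TRUE)) m <- cbind(m, d[[k]])
  m
}
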