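#' Per-SNP Wald ratio with delta-method variance
#'
#' The per-instrument causal estimate \eqn{\beta_i = b_{zy,i}/b_{zx,i}} with
#' first-order variance \eqn{(se_{zy}^2 + \beta^2 se_{zx}^2)/b_{zx}^2}.
#' Vectorized.
#'
#' @param bzx,sezx exposure effect(s) and SE(s); bzx must be nonzero.
#' @param bzy,sezy outcome effect(s) and SE(s).
#' @return List with \code{ratio} and \code{variance}.
#' @export
waldRatio <- function(bzx, sezx, bzy, sezy) {
  if (any(bzx == 0)) stop("undefined Wald ratio: b_zx is zero")
  ratio <- bzy / bzx
  variance <- (sezy^2 + ratio^2 * sezx^2) / bzx^2
  list(ratio = ratio, variance = variance)
}

#' 95 percent odds-ratio interval from a log-odds estimate
#'
#' @param b log-odds estimate.
#' @param se its standard error (>= 0).
#' @return List with \code{or_}, \code{ciLow}, \code{ciHigh}.
#' @export
toOddsRatio <- function(b, se) {
  if (any(se < 0)) stop("se must be non-negative")
  z <- 1.959964
  list(or_ = exp(b), ciLow = exp(b - z * se), ciHigh = exp(b + z * se))
}

# canonical orientation: flip each SNP so its exposure effect is positive
# (negating both betas and the LD signs); Wald ratios are invariant, and the
# ratio covariance r_ij sqrt(v_i v_j) is sign-correct only in this coding
.orientInput <- function(input) {
  s <- ifelse(input@bzx < 0, -1, 1)
  if (all(s == 1)) return(input)
  ld <- input@ld * tcrossprod(s)
  diag(ld) <- 1
  initialize(input, bzx = s * input@bzx, bzy = s * input@bzy, ld = ld)
}

# covariance of Wald ratios under LD: V_ij = r_ij sqrt(v_i v_j), diag v_i
.ratioCovariance <- function(v, R) {
  s <- sqrt(v)
  V <- R * tcrossprod(s)
  diag(V) <- v
  V
}

# guarded Cholesky solve; cnd is the 2-norm condition estimate
.cholSolve <- function(A, B) {
  cnd <- kappa(A, exact = FALSE)
  if (!is.finite(cnd) || cnd > 1e12)
    stop("covariance matrix numerically singular (condition number > 1e12); ",
         "consider a stricter LD r^2 threshold for instrument selection")
  U <- chol(A)
  backsolve(U, forwardsolve(t(U), B))
}

.mkEstimate <- function(method, b, se, p, nInit, nUsed, ...) {
  orci <- toOddsRatio(b, se)
  new("MREstimate", method = method, b = b, se = se, p = max(p, .Machine$double.xmin),
      or_ = orci$or_, ciLow = orci$ciLow, ciHigh = orci$ciHigh,
      nIvInitial = as.integer(nInit), nIvUsed = as.integer(nUsed), ...)
}

#' GSMR-style GLS causal estimate over correlated instruments
#'
#' Combines per-SNP Wald ratios by generalized least squares under the
#' first-order ratio covariance \eqn{V_{ij} = r_{ij}\sqrt{v_i v_j}}, giving
#' \eqn{\hat b = (1'V^{-1}\hat\beta)/(1'V^{-1}1)} with
#' \eqn{se = (1'V^{-1}1)^{-1/2}} (fixed-effect convention, no inflation) and
#' a 1-df chi-square p-value for \eqn{(\hat b/se)^2}. At a single instrument
#' this collapses exactly to the Wald ratio.
#'
#' @param input an \linkS4class{MRInput}; all b_zx must be nonzero.
#' @return An \linkS4class{MREstimate} with method "gsmr".
#' @export
glsCausalEstimate <- function(input) {
  validObject(input)
  input <- .orientInput(input)
  w <- waldRatio(input@bzx, input@sezx, input@bzy, input@sezy)
  V <- .ratioCovariance(w$variance, input@ld)
  one <- rep(1, length(w$ratio))
  Vi1 <- .cholSolve(V, cbind(one, w$ratio))
  denom <- sum(Vi1[, 1])
  b <- sum(Vi1[, 2]) / denom
  se <- 1 / sqrt(denom)
  p <- pchisq((b / se)^2, df = 1, lower.tail = FALSE)
  .mkEstimate("gsmr", b, se, p, length(one), length(one))
}

#' HEIDI outlier removal
#'
#' Heterogeneity-in-dependent-instruments screen for horizontally pleiotropic
#' instruments. The SNP with the smallest exposure p-value serves as the
#' reference; for every other SNP the deviation of its Wald ratio from the
#' reference ratio, \eqn{d_i = \hat\beta_i - \hat\beta_{ref}}, is tested with
#' variance \eqn{v_i + v_{ref} - 2 r_{i,ref}\sqrt{v_i v_{ref}}} against a
#' 1-df chi-square; SNPs with p below \code{alpha} are removed in a single
#' pass. With fewer than 5 instruments the procedure is switched off and the
#' input returned unchanged.
#'
#' @param input an \linkS4class{MRInput}.
#' @param alpha outlier significance threshold (default 0.01).
#' @param passes number of removal passes (default 1; the reference is
#'   re-chosen among survivors on later passes).
#' @return List with \code{input} (possibly filtered \linkS4class{MRInput}),
#'   \code{removed} (character ids) and \code{applied} (logical).
#' @export
heidiOutlier <- function(input, alpha = 0.01, passes = 1L) {
  validObject(input)
  if (length(input@snpIds) < 5)
    return(list(input = input, removed = character(0), applied = FALSE))
  cur <- input
  removed <- character(0)
  for (pass in seq_len(passes)) {
    L <- length(cur@snpIds)
    if (L < 2) break
    ori <- .orientInput(cur)
    w <- waldRatio(ori@bzx, ori@sezx, ori@bzy, ori@sezy)
    ref <- which.min(ori@pzx)
    d <- w$ratio - w$ratio[ref]
    vd <- w$variance + w$variance[ref] -
      2 * ori@ld[, ref] * sqrt(w$variance * w$variance[ref])
    vd <- pmax(vd, .Machine$double.eps)
    pHet <- pchisq(d^2 / vd, df = 1, lower.tail = FALSE)
    pHet[ref] <- 1
    out <- pHet < alpha
    if (!any(out)) break
    removed <- c(removed, cur@snpIds[out])
    keep <- which(!out)
    cur <- mrInput(cur@snpIds[keep], cur@bzx[keep], cur@sezx[keep],
                   cur@bzy[keep], cur@sezy[keep],
                   ld = cur@ld[keep, keep, drop = FALSE], pzx = cur@pzx[keep])
  }
  list(input = cur, removed = removed, applied = TRUE)
}

#' GSMR estimate with HEIDI outlier removal
#'
#' Runs \code{\link{heidiOutlier}} (automatically disabled below 5
#' instruments) and then \code{\link{glsCausalEstimate}} on the remainder,
#' recording the removed SNPs and instrument counts.
#'
#' @param input an \linkS4class{MRInput}.
#' @param heidi run the outlier screen (default TRUE).
#' @param heidiAlpha outlier threshold (default 0.01).
#' @return An \linkS4class{MREstimate} with method "gsmr".
#' @export
gsmrEstimate <- function(input, heidi = TRUE, heidiAlpha = 0.01) {
  nInit <- length(input@snpIds)
  removed <- character(0)
  applied <- FALSE
  if (heidi) {
    h <- heidiOutlier(input, alpha = heidiAlpha)
    input <- h$input
    removed <- h$removed
    applied <- h$applied
  }
  est <- glsCausalEstimate(input)
  est@nIvInitial <- as.integer(nInit)
  est@nIvUsed <- length(input@snpIds)
  est@removedSnps <- removed
  est@heidiApplied <- applied
  est
}

# GLS regression of y on X with covariance Omega; returns coef, cov, resid
.glsFit <- function(X, y, Omega) {
  Oi <- .cholSolve(Omega, cbind(X, y))
  OiX <- Oi[, seq_len(ncol(X)), drop = FALSE]
  Oiy <- Oi[, ncol(X) + 1]
  XtOX <- crossprod(X, OiX)
  coefCov <- solve(XtOX)
  coefs <- drop(coefCov %*% crossprod(X, Oiy))
  resid <- y - drop(X %*% coefs)
  list(coef = coefs, cov = coefCov, resid = resid)
}

#' Correlated-instrument inverse-variance weighted estimate
#'
#' GLS regression of the outcome effects on the exposure effects through the
#' origin, with the outcome-side covariance
#' \eqn{\Omega_{ij} = r_{ij} se_{zy,i} se_{zy,j}}. Under the random-effect
#' convention the SE is inflated by the residual standard error
#' \eqn{\phi = \max(1, \sqrt{r'\Omega^{-1}r/(L-1)})}; with identity LD the
#' estimate reduces to the classic IVW weighted formula.
#'
#' @param input an \linkS4class{MRInput} with at least 2 instruments.
#' @param randomEffects apply the SE floor-at-one inflation (default TRUE).
#' @param allowSingle permit L = 1 (test use only; the fixed-effect estimate
#'   then equals the Wald ratio).
#' @return An \linkS4class{MREstimate} with method "ivw" (slot \code{phi}
#'   carries the inflation factor).
#' @export
ivwCorrelated <- function(input, randomEffects = TRUE, allowSingle = FALSE) {
  validObject(input)
  L <- length(input@snpIds)
  if (L < 2 && !allowSingle) stop("IVW requires at least 2 instruments")
  Omega <- .ratioCovariance(input@sezy^2, input@ld)
  fit <- .glsFit(cbind(input@bzx), input@bzy, Omega)
  b <- fit$coef[1]
  phi <- if (randomEffects && L > 1) {
    rOir <- drop(crossprod(fit$resid, .cholSolve(Omega, fit$resid)))
    max(1, sqrt(rOir / (L - 1)))
  } else 1
  se <- phi * sqrt(fit$cov[1, 1])
  p <- 2 * pnorm(-abs(b / se))
  .mkEstimate("ivw", b, se, p, L, L, phi = phi)
}

#' Correlated-instrument MR-Egger estimate
#'
#' Each SNP is first oriented so its exposure effect is non-negative
#' (negating both effects and the corresponding LD signs), then outcome
#' effects are GLS-regressed on [1, b_zx] with the same outcome-side
#' covariance as IVW. The slope is the causal estimate; a nonzero intercept
#' indicates directional pleiotropy. Random-effect SEs use the residual
#' standard error floored at one with L - 2 degrees of freedom.
#'
#' @param input an \linkS4class{MRInput} with at least 3 instruments.
#' @param randomEffects apply the SE floor-at-one inflation (default TRUE).
#' @return An \linkS4class{MREstimate} with method "egger" carrying
#'   \code{eggerIntercept} and \code{eggerInterceptP}.
#' @export
eggerCorrelated <- function(input, randomEffects = TRUE) {
  validObject(input)
  L <- length(input@snpIds)
  if (L < 3) stop("MR-Egger requires >=3 instruments")
  s <- ifelse(input@bzx < 0, -1, 1)
  x <- s * input@bzx
  y <- s * input@bzy
  R <- input@ld * tcrossprod(s)
  Omega <- .ratioCovariance(input@sezy^2, R)
  fit <- .glsFit(cbind(1, x), y, Omega)
  phi <- if (randomEffects) {
    rOir <- drop(crossprod(fit$resid, .cholSolve(Omega, fit$resid)))
    max(1, sqrt(rOir / (L - 2)))
  } else 1
  b <- fit$coef[2]
  se <- phi * sqrt(fit$cov[2, 2])
  i0 <- fit$coef[1]
  i0se <- phi * sqrt(fit$cov[1, 1])
  .mkEstimate("egger", b, se, 2 * pnorm(-abs(b / se)), L, L,
              eggerIntercept = i0,
              eggerInterceptP = 2 * pnorm(-abs(i0 / i0se)),
              phi = phi)
}

# weighted median of ratios with cumulative-weight interpolation
.weightedMedian <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  S <- cumsum(w) - w / 2
  if (S[1] >= 0.5) return(ratio[1])
  n <- length(ratio)
  if (S[n] <= 0.5) return(ratio[n])
  k <- max(which(S < 0.5))
  ratio[k] + (ratio[k + 1] - ratio[k]) * (0.5 - S[k]) / (S[k + 1] - S[k])
}

#' Weighted median causal estimate with bootstrap SE
#'
#' Per-SNP Wald ratios weighted by inverse variance; the estimate linearly
#' interpolates the weighted median of the ordered ratios, consistent as long
#' as instruments carrying at least half the weight are valid. The SE is the
#' standard deviation of the estimate over parametric resamples
#' (effects drawn independently around their estimates; LD between
#' instruments is ignored in the bootstrap).
#'
#' @param input an \linkS4class{MRInput} with at least 3 instruments.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed optional integer seed, recorded on the result.
#' @return An \linkS4class{MREstimate} with method "wmedian".
#' @export
weightedMedian <- function(input, nBoot = 1000L, seed = NULL) {
  validObject(input)
  L <- length(input@snpIds)
  if (L < 3) stop("the weighted median requires >=3 instruments")
  if (!is.null(seed)) set.seed(seed)
  w0 <- waldRatio(input@bzx, input@sezx, input@bzy, input@sezy)
  b <- .weightedMedian(w0$ratio, 1 / w0$variance)
  boots <- vapply(seq_len(nBoot), function(i) {
    bx <- rnorm(L, input@bzx, input@sezx)
    by <- rnorm(L, input@bzy, input@sezy)
    bx[bx == 0] <- .Machine$double.eps
    r <- by / bx
    v <- (input@sezy^2 + r^2 * input@sezx^2) / bx^2
    .weightedMedian(r, 1 / v)
  }, numeric(1))
  se <- sd(boots)
  p <- 2 * pnorm(-abs(b / se))
  .mkEstimate("wmedian", b, se, p, L, L,
              bootstrapSeed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
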