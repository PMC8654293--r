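test_that("Wald ratios carry delta-method variances", {
  w <- waldRatio(0.5, 0, -0.1, 0.05)
  expect_equal(w$ratio, -0.2)
  expect_equal(w$variance, 0.01)
  # unit denominator passes the outcome effect through
  expect_equal(waldRatio(1, 0.02, 0.37, 0.05)$ratio, 0.37)
  expect_error(waldRatio(0, 0.1, 0.2, 0.1), "zero")

  # variance oracle: one million sampled ratios at strong-instrument noise
  set.seed(71)
  bx <- rnorm(1e6, 1, 0.05)
  by <- rnorm(1e6, 0.3, 0.02)
  mc <- var(by / bx)
  expect_lt(abs(waldRatio(1, 0.05, 0.3, 0.02)$variance - mc) / mc, 0.10)
})

test_that("odds-ratio conversion matches the normal-quantile oracle", {
  o <- toOddsRatio(0, 0.1)
  expect_equal(round(c(o$or_, o$ciLow, o$ciHigh), 2), c(1.00, 0.82, 1.22))
  # a published-style cell: b = ln 0.84 with CI (0.80, 0.88) after rounding
  se <- log(0.88 / 0.80) / (2 * 1.959964)
  o2 <- toOddsRatio(log(0.84), se)
  expect_equal(formatOrCi(o2$or_, o2$ciLow, o2$ciHigh), "0.84 (0.80–0.88)")
  o3 <- toOddsRatio(0.5, 0)
  expect_equal(c(o3$ciLow, o3$or_, o3$ciHigh), rep(exp(0.5), 3))
  expect_error(toOddsRatio(0, -1), "non-negative")
})

test_that("GLS causal estimation collapses and matches linear algebra", {
  # L = 1: identical to the Wald ratio with a chi-square(1) p
  one <- mrInput("rs1", 0.4, 0.03, -0.08, 0.02)
  est <- glsCausalEstimate(one)
  w <- waldRatio(0.4, 0.03, -0.08, 0.02)
  expect_equal(est@b, w$ratio, tolerance = 1e-14)
  expect_equal(est@se, sqrt(w$variance), tolerance = 1e-14)
  expect_equal(est@p, pchisq((est@b / est@se)^2, 1, lower.tail = FALSE))

  # two independent equal-variance ratios average (negligible exposure noise
  # keeps the delta-method variances equal across the two ratios)
  est2 <- glsCausalEstimate(mrInput(c("a", "b"), c(1, 1), c(1e-9, 1e-9),
                                    c(0.1, 0.3), c(0.05, 0.05)))
  expect_equal(est2@b, 0.2, tolerance = 1e-12)

  # L = 5 AR(1) r = 0.6 against the explicit-inverse oracle
  set.seed(72)
  for (i in 1:40) {
    L <- sample(2:8, 1)
    R <- randomCorr(L)
    bzx <- runif(L, 0.2, 0.6) * sample(c(-1, 1), L, replace = TRUE)
    sezx <- runif(L, 0.01, 0.05)
    bzy <- rnorm(L, -0.17 * bzx, 0.03)
    sezy <- runif(L, 0.01, 0.05)
    inp <- mrInput(rownames(R), bzx, sezx, bzy, sezy, ld = R)
    est <- glsCausalEstimate(inp)
    orc <- oracleGLS(bzx, sezx, bzy, sezy, R)
    expect_equal(est@b, orc$b, tolerance = 1e-10)
    expect_equal(est@se, orc$se, tolerance = 1e-10)
  }
  ar <- simulateLDMatrix(5L, blockRho = 0.6)
  inp5 <- mrInput(rownames(ldMatrix(ar)), rep(0.4, 5), rep(0.02, 5),
                  rnorm(5, -0.07, 0.01), rep(0.02, 5), ld = ar)
  orc5 <- oracleGLS(inp5@bzx, inp5@sezx, inp5@bzy, inp5@sezy, ldMatrix(ar))
  expect_equal(glsCausalEstimate(inp5)@b, orc5$b, tolerance = 1e-10)

  # numerically singular ratio covariance is refused with advice
  dup <- matrix(1, 2, 2)
  dimnames(dup) <- list(c("a", "b"), c("a", "b"))
  expect_error(glsCausalEstimate(mrInput(c("a", "b"), c(0.4, 0.4),
                                         c(0.02, 0.02), c(0.1, 0.1),
                                         c(0.03, 0.03), ld = dup)),
               "stricter")
})

test_that("HEIDI removes planted outliers and respects the <5-SNP rule", {
  # identical ratios: nothing removed
  same <- mrInput(paste0("rs", 1:6), rep(0.5, 6), rep(0.02, 6),
                  rep(0.1, 6), rep(0.03, 6))
  h <- heidiOutlier(same)
  expect_true(h$applied)
  expect_length(h$removed, 0)

  # L = 4: switched off entirely
  four <- mrInput(paste0("rs", 1:4), rep(0.5, 4), rep(0.02, 4),
                  c(0.1, 0.1, 0.1, 5), rep(0.03, 4))
  h4 <- heidiOutlier(four)
  expect_false(h4$applied)
  expect_identical(h4$input, four)

  # planted displacement of 8 sd(d_i) is caught in >= 95% of replicates
  set.seed(73)
  caught <- vapply(1:200, function(i) {
    inp <- simSummary(L = 8, b = -0.17, sezx = 0.02, sezy = 0.03)
    w <- waldRatio(inp@bzx, inp@sezx, inp@bzy, inp@sezy)
    ref <- which.min(inp@pzx)
    j <- if (ref == 8) 7 else 8
    shift <- 8 * sqrt(w$variance[j] + w$variance[ref]) * inp@bzx[j]
    inp@bzy[j] <- inp@bzy[j] + shift
    paste0("rs", j) %in% heidiOutlier(inp)$removed
  }, logical(1))
  expect_gte(mean(caught), 0.95)

  # gsmrEstimate records the removal bookkeeping
  inp <- simSummary(L = 8, b = -0.17)
  inp@bzy[3] <- inp@bzy[3] + 1
  est <- gsmrEstimate(inp)
  expect_true(est@heidiApplied)
  expect_true("rs3" %in% est@removedSnps)
  expect_equal(est@nIvInitial, 8L)
  expect_equal(est@nIvUsed, 8L - length(est@removedSnps))
})

test_that("correlated IVW reduces to the classic estimator at identity LD", {
  # collinear input: exact slope, zero residuals, no inflation
  col <- mrInput(c("a", "b"), c(0.5, 0.4), c(0.01, 0.01), c(0.1, 0.08),
                 c(0.05, 0.05))
  est <- ivwCorrelated(col)
  expect_equal(est@b, 0.2, tolerance = 1e-12)
  expect_equal(est@phi, 1)

  set.seed(74)
  for (i in 1:20) {
    L <- sample(3:10, 1)
    bzx <- runif(L, 0.2, 0.6)
    bzy <- rnorm(L, 0.2 * bzx, 0.02)
    sezy <- runif(L, 0.02, 0.06)
    inp <- mrInput(paste0("rs", 1:L), bzx, rep(0.01, L), bzy, sezy)
    fe <- ivwCorrelated(inp, randomEffects = FALSE)
    classic <- sum(bzx * bzy / sezy^2) / sum(bzx^2 / sezy^2)
    expect_equal(fe@b, classic, tolerance = 1e-10)
    expect_equal(fe@se, 1 / sqrt(sum(bzx^2 / sezy^2)), tolerance = 1e-10)
  }

  # the random-effect residual SE never deflates below one
  expect_gte(ivwCorrelated(col, randomEffects = TRUE)@phi, 1)
  expect_error(ivwCorrelated(mrInput("a", 0.5, 0.1, 0.1, 0.1)), "2")
  # single-instrument collapse permitted in test-only mode
  soloIvw <- ivwCorrelated(mrInput("a", 0.5, 0.1, 0.1, 0.1),
                           randomEffects = FALSE, allowSingle = TRUE)
  expect_equal(soloIvw@b, 0.2, tolerance = 1e-12)
})

test_that("MR-Egger fits an intercept and canonicalizes orientation", {
  x <- seq(0.2, 0.8, length.out = 6)
  y <- 0.05 + 0.2 * x
  line <- mrInput(paste0("rs", 1:6), x, rep(1e-4, 6), y, rep(1e-4, 6))
  est <- eggerCorrelated(line)
  expect_equal(est@eggerIntercept, 0.05, tolerance = 1e-8)
  expect_equal(est@b, 0.2, tolerance = 1e-8)

  # negating alleles (x, y and LD signs) leaves the fit unchanged
  set.seed(75)
  R <- randomCorr(6)
  inp <- mrInput(paste0("rs", 1:6), x * c(1, -1, 1, -1, 1, 1),
                 rep(0.01, 6), rnorm(6, 0.1, 0.05), rep(0.03, 6), ld = R)
  s <- c(-1, 1, -1, 1, 1, -1)
  flip <- mrInput(inp@snpIds, s * inp@bzx, inp@sezx, s * inp@bzy,
                  inp@sezy, ld = R * tcrossprod(s), pzx = inp@pzx)
  a <- eggerCorrelated(inp)
  b <- eggerCorrelated(flip)
  expect_equal(a@b, b@b, tolerance = 1e-12)
  expect_equal(a@se, b@se, tolerance = 1e-12)
  expect_equal(a@eggerIntercept, b@eggerIntercept, tolerance = 1e-12)

  expect_error(eggerCorrelated(mrInput(c("a", "b"), c(1, 1), c(0.1, 0.1),
                                       c(0.1, 0.1), c(0.1, 0.1))), ">=3")
})

test_that("the weighted median interpolates and bootstraps reproducibly", {
  inp <- mrInput(paste0("rs", 1:3), c(1, 1, 1), rep(1e-9, 3), c(1, 2, 3),
                 rep(0.05, 3))
  est <- weightedMedian(inp, nBoot = 50, seed = 1)
  expect_equal(est@b, 2, tolerance = 1e-12)

  estA <- weightedMedian(inp, nBoot = 200, seed = 42)
  estB <- weightedMedian(inp, nBoot = 200, seed = 42)
  expect_identical(estA@se, estB@se)
  expect_equal(estA@bootstrapSeed, 42L)

  # breakdown: under 50% of weight displaced by +1 leaves the estimate near
  # the truth
  set.seed(76)
  L <- 30
  bzx <- runif(L, 0.3, 0.5)
  bzy <- 0.1 * bzx
  bad <- 1:13                      # 13/30 of roughly equal weight invalid
  bzy[bad] <- bzy[bad] + 1 * bzx[bad]
  inp2 <- mrInput(paste0("rs", 1:L), bzx, rep(1e-3, L), bzy, rep(1e-3, L))
  expect_lt(abs(weightedMedian(inp2, nBoot = 50, seed = 2)@b - 0.1), 0.05)

  expect_error(weightedMedian(mrInput(c("a", "b"), c(1, 1), c(0.1, 0.1),
                                      c(0.1, 0.1), c(0.1, 0.1))), ">=3")
})

test_that("estimators are invariant to SNP permutation and allele flips", {
  set.seed(77)
  L <- 7
  R <- randomCorr(L)
  inp <- mrInput(rownames(R), runif(L, 0.2, 0.6), runif(L, 0.01, 0.03),
                 rnorm(L, -0.1, 0.05), runif(L, 0.02, 0.04), ld = R)
  perm <- sample(L)
  pinp <- mrInput(inp@snpIds[perm], inp@bzx[perm], inp@sezx[perm],
                  inp@bzy[perm], inp@sezy[perm], ld = R[perm, perm],
                  pzx = inp@pzx[perm])
  s <- sample(c(-1, 1), L, replace = TRUE)
  finp <- mrInput(inp@snpIds, s * inp@bzx, inp@sezx, s * inp@bzy,
                  inp@sezy, ld = R * tcrossprod(s), pzx = inp@pzx)
  for (fn in list(glsCausalEstimate, ivwCorrelated, eggerCorrelated)) {
    a <- fn(inp); b <- fn(pinp); d <- fn(finp)
    expect_equal(a@b, b@b, tolerance = 1e-12)
    expect_equal(a@se, b@se, tolerance = 1e-12)
    expect_equal(a@b, d@b, tolerance = 1e-12)
    expect_equal(a@se, d@se, tolerance = 1e-12)
  }
  wa <- weightedMedian(inp, nBoot = 10, seed = 9)
  wb <- weightedMedian(pinp, nBoot = 10, seed = 9)
  expect_equal(wa@b, wb@b, tolerance = 1e-12)
})
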