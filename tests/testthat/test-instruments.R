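test_that("cis windows extend gene end points by the flank, clamped at 1", {
  win <- cisWindow(list(gene_id = "G", chrom = "7",
                        start = 3000000, end = 3100000))
  expect_equal(GenomicRanges::start(win), 1000000)
  expect_equal(GenomicRanges::end(win), 5100000)
  expect_equal(as.character(GenomicRanges::seqnames(win)), "7")

  near <- cisWindow(list(gene_id = "G", chrom = "1", start = 500000,
                         end = 600000))
  expect_equal(GenomicRanges::start(near), 1)
  expect_error(cisWindow(list(gene_id = "G", chrom = "1", start = 10,
                              end = 5)), "start")
})

test_that("harmonization flips swapped alleles and logs exclusions", {
  ex <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                   pos = 1:4, effect_allele = c("A", "A", "A", "C"),
                   other_allele = c("G", "C", "T", "T"),
                   eaf = c(0.3, 0.2, 0.5, 0.4),
                   beta = c(0.3, 0.2, 0.1, 0.4), se = 0.05,
                   p = 1e-8, n = 872)
  ou <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs9"), chrom = "1",
                   pos = c(1:4, 9), effect_allele = c("G", "A", "A", "C", "A"),
                   other_allele = c("A", "C", "T", "G", "G"),
                   eaf = c(0.65, 0.2, 0.5, 0.4, 0.5),
                   beta = c(0.1, 0.2, 0.3, 0.4, 0.1), se = 0.02, p = 1e-4,
                   n = 3e5)
  ou$effect_allele[4] <- "T"  # irreconcilable with exposure C/G
  out <- intersectAndHarmonize(ex, ou)
  expect_equal(out$data$snp_id, c("rs1", "rs2"))
  # rs1 alleles are swapped: sign flip and EAF complement
  expect_equal(out$data$b_zy[1], -0.1)
  expect_equal(out$data$eaf_zy[1], 0.35)
  expect_true(out$data$flipped[1])
  expect_equal(out$data$b_zy[2], 0.2)
  expect_equal(out$excluded$reason[out$excluded$snp_id == "rs3"],
               "palindromic")
  expect_equal(out$excluded$reason[out$excluded$snp_id == "rs4"],
               "allele mismatch")
  # palindromic exclusion is configurable
  keepPal <- intersectAndHarmonize(ex[-4, ], ou[-4, ],
                                   excludePalindromic = FALSE)
  expect_true("rs3" %in% keepPal$data$snp_id)

  expect_error(intersectAndHarmonize(rbind(ex, ex[1, ]), ou), "duplicate")

  # involution: a table harmonized against itself keeps every sign
  self <- intersectAndHarmonize(ex[ex$other_allele != "T", ],
                                ex[ex$other_allele != "T", ])
  expect_equal(self$data$b_zy, self$data$b_zx)
  expect_false(any(self$data$flipped))
})

test_that("greedy pruning follows the dual-cohort loop", {
  ids <- c("A", "B", "C")
  cand <- data.frame(snp_id = ids, pos = 1:3, p_zx = c(1e-9, 1e-8, 1e-7))
  base <- diag(3)
  dimnames(base) <- list(ids, ids)
  offd <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  ldA <- offd(base, "A", "B", sqrt(0.7))
  # r^2(A,B) = 0.7 in the exposure source only: B still removed
  expect_equal(greedyPrune(cand, ldA, base, r2Thresh = 0.6), c("A", "C"))
  # same but only in the outcome source
  expect_equal(greedyPrune(cand, base, ldA, r2Thresh = 0.6), c("A", "C"))
  # below threshold nothing is removed; r^2 must strictly exceed it
  ldEq <- offd(base, "A", "B", 0.774)  # r^2 = 0.599
  expect_equal(greedyPrune(cand, ldEq, base, r2Thresh = 0.6),
               c("A", "B", "C"))
  expect_equal(greedyPrune(cand[0, ], base, base), character(0))
  expect_error(greedyPrune(cand, base[1:2, 1:2], base), "missing")
  # ties on p break by position then id
  tie <- data.frame(snp_id = c("Z", "Y"), pos = c(5, 2),
                    p_zx = c(1e-8, 1e-8))
  m2 <- diag(2); dimnames(m2) <- list(c("Z", "Y"), c("Z", "Y"))
  expect_equal(greedyPrune(tie, m2, m2)[1], "Y")
})

test_that("greedy pruning matches a brute-force re-implementation", {
  set.seed(61)
  for (i in 1:60) {
    L <- sample(2:12, 1)
    ids <- paste0("rs", seq_len(L))
    cand <- data.frame(snp_id = ids, pos = sample(1e6, L),
                       p_zx = 10^runif(L, -12, -6))
    ldx <- randomCorr(L, ids)
    ldy <- randomCorr(L, ids)
    r2t <- runif(1, 0.1, 0.8)
    expect_identical(greedyPrune(cand, ldx, ldy, r2Thresh = r2t),
                     oraclePrune(cand, ldx, ldy, r2t))
  }
})

test_that("instrument selection applies thresholds and the >=4 rule", {
  fx <- selectionFixture()
  set <- selectInstruments("P1", fx$gene, fx$exposure, fx$outcome,
                           fx$ld, fx$ld)
  expect_s4_class(set, "InstrumentSet")
  d <- instrumentData(set)
  expect_true(all(d$p_zx < 1e-6))
  offr2 <- set@ldOutcome[upper.tri(set@ldOutcome)]^2
  expect_true(all(offr2 <= 0.6))
  expect_identical(greedyPrune(d, fx$ld, fx$ld, 0.6), d$snp_id)
  expect_true(heidiCapable(set))

  # determinism
  set2 <- selectInstruments("P1", fx$gene, fx$exposure, fx$outcome,
                            fx$ld, fx$ld)
  expect_identical(instrumentData(set2), d)

  # cis-window boundary is inclusive: a SNP exactly at end + 2 Mb survives
  exB <- summaryTable(fx$exposure)
  exB$pos[exB$snp_id == "rs12"] <- 5100000
  ouB <- summaryTable(fx$outcome)
  ouB$pos[ouB$snp_id == "rs12"] <- 5100000
  setB <- selectInstruments("P1", fx$gene, SummaryStats(exB),
                            SummaryStats(ouB), fx$ld, fx$ld)
  expect_true("rs12" %in% instrumentData(setB)$snp_id)
  exB$pos[exB$snp_id == "rs12"] <- 5100001
  setC <- selectInstruments("P1", fx$gene, SummaryStats(exB),
                            SummaryStats(ouB), fx$ld, fx$ld)
  expect_false("rs12" %in% instrumentData(setC)$snp_id)

  # too few instruments: rejection record mirroring the inclusion rule
  exFew <- summaryTable(fx$exposure)
  exFew$p[4:12] <- 0.5  # only rs1..rs3 stay below threshold
  rej <- selectInstruments("P1", fx$gene, SummaryStats(exFew), fx$outcome,
                           fx$ld, fx$ld)
  expect_true(isRejected(rej))
  expect_equal(rej@reason, "n_selected < min_iv")
  expect_lte(rej@nSelected, 3L)

  # exactly 4 instruments: accepted but HEIDI-incapable
  exFour <- summaryTable(fx$exposure)
  exFour$p[c(3, 4, 5, 6, 9, 11, 12)] <- 0.5  # keep rs1 rs2 rs7 rs8 rs10
  exFour$p[2] <- 0.5                          # drop rs2 too -> 4 left
  setFour <- selectInstruments("P1", fx$gene, SummaryStats(exFour),
                               fx$outcome, fx$ld, fx$ld)
  expect_s4_class(setFour, "InstrumentSet")
  expect_equal(nrow(instrumentData(setFour)), 4)
  expect_false(heidiCapable(setFour))

  # non-default thresholds are accepted and recorded on the set
  strict <- selectInstruments("P1", fx$gene, fx$exposure, fx$outcome,
                              fx$ld, fx$ld, pThresh = 5e-8, r2Thresh = 0.2,
                              minIv = 1L)
  expect_equal(strict@params$pThresh, 5e-8)
  expect_equal(strict@params$r2Thresh, 0.2)
  expect_true(all(instrumentData(strict)$p_zx < 5e-8))
})

test_that("stricter selection settings choose subsets on the fixed fixture", {
  fx <- selectionFixture()
  base <- instrumentData(selectInstruments("P1", fx$gene, fx$exposure,
                                           fx$outcome, fx$ld, fx$ld))$snp_id
  for (pars in list(c(5e-8, 0.6), c(1e-6, 0.2), c(5e-8, 0.2))) {
    got <- selectInstruments("P1", fx$gene, fx$exposure, fx$outcome,
                             fx$ld, fx$ld, pThresh = pars[1],
                             r2Thresh = pars[2], minIv = 1L)
    expect_true(all(instrumentData(got)$snp_id %in% base))
    expect_lt(nrow(instrumentData(got)), length(base) + 1)
  }
})

test_that("instrument sets round trip through TSV + YAML sidecars", {
  fx <- selectionFixture()
  set <- selectInstruments("P1", fx$gene, fx$exposure, fx$outcome,
                           fx$ld, fx$ld)
  dir <- withr::local_tempdir()
  writeInstrumentSet(set, dir)
  back <- readInstrumentSet(dir, "P1")
  expect_equal(instrumentData(back), instrumentData(set), tolerance = 1e-15)
  expect_equal(back@ldOutcome, set@ldOutcome, tolerance = 1e-15)
  expect_equal(back@params, set@params)
  expect_equal(heidiCapable(back), heidiCapable(set))
})

test_that("gene annotations read from TSV and BED agree", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "genes.tsv")
  writeLines(c("gene_id\tchrom\tstart\tend", "G1\t1\t1001\t2000"), tsv)
  bed <- file.path(dir, "genes.bed")
  writeLines("1\t1000\t2000\tG1", bed)  # 0-based half-open
  expect_equal(readGeneAnnotations(tsv), readGeneAnnotations(bed))
})
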