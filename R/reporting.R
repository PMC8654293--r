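#' Benjamini-Hochberg step-up FDR adjustment with an explicit test count
#'
#' Wraps \code{stats::p.adjust(method = "BH")} with the total number of tests
#' \code{m} passed through, so a printed subset of a larger family can be
#' adjusted against the family's full size (a protein-by-disease grid passes
#' proteins x diseases). Adjusted values are the running minima of
#' \eqn{m\,p_{(k)}/k} capped at 1, returned in the original order; ties share
#' the better adjusted value.
#'
#' @param p numeric p-values in [0, 1].
#' @param m total number of tests (defaults to \code{length(p)}).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (m < sum(!is.na(p))) stop("m must be at least the number of p-values")
  stats::p.adjust(p, method = "BH", n = m)
}

.SHADE_BREAKS <- c(0, 1e-4, 1e-3, 1e-2, 0.05)
.SHADE_LABELS <- c("dark", "medium dark", "medium light", "light")

#' Heat-map category for one grid cell
#'
#' Direction is protective (OR below 1) or harmful; raw p-values below 0.05
#' fall into four shade bins (light: [0.01, 0.05), medium light:
#' [0.001, 0.01), medium dark: [0.0001, 0.001), dark: below 0.0001); cells
#' with raw p at or above 0.05 are "white". The star flags FDR significance.
#'
#' @param rawP raw (unadjusted) p-value.
#' @param or_ odds ratio of the estimate.
#' @param significant logical FDR < 0.05 call.
#' @return List with \code{direction}, \code{shade}, \code{star} and a
#'   combined \code{category} string such as "protective/light".
#' @export
categorizeCell <- function(rawP, or_, significant = FALSE) {
  if (is.na(rawP) || rawP >= 0.05) {
    return(list(direction = NA_character_, shade = "white",
                star = isTRUE(significant), category = "white"))
  }
  direction <- if (or_ < 1) "protective" else "harmful"
  bin <- findInterval(rawP, .SHADE_BREAKS, rightmost.closed = FALSE)
  shade <- .SHADE_LABELS[bin]
  list(direction = direction, shade = shade, star = isTRUE(significant),
       category = paste0(direction, "/", shade,
                         if (isTRUE(significant)) "*" else ""))
}

#' Format an odds ratio with its 95 percent interval
#'
#' @param or_,ciLow,ciHigh the interval, printed at 2 decimals as
#'   "0.84 (0.80-0.88)".
#' @return Character vector.
#' @export
formatOrCi <- function(or_, ciLow, ciHigh) {
  sprintf("%.2f (%.2f–%.2f)", or_, ciLow, ciHigh)
}

.METHOD_FUNS <- c("gsmr", "ivw", "egger", "wmedian")

# run every requested method on one harmonized cell; failures per method
# become NA columns rather than aborting the cell
.estimateCell <- function(input, methods, heidiAlpha, nBoot, seed) {
  out <- list()
  for (m in methods) {
    est <- tryCatch(switch(m,
      gsmr = gsmrEstimate(input, heidi = TRUE, heidiAlpha = heidiAlpha),
      ivw = ivwCorrelated(input),
      egger = eggerCorrelated(input),
      wmedian = weightedMedian(input, nBoot = nBoot, seed = seed),
      stop("unknown method: ", m)), error = function(e) e)
    out[[m]] <- est
  }
  out
}

#' Run the protein-by-disease MR grid with FDR control
#'
#' For every (instrument set, disease) cell the set's SNPs are harmonized to
#' that disease's outcome scan, HEIDI outlier removal runs when the set has
#' at least 5 instruments, and each requested method is estimated. The
#' main-analysis (GSMR) raw p-values are BH-adjusted over the total number of
#' attempted cells; sensitivity-method p-values are reported unadjusted.
#' Cells whose SNPs are missing from a disease table are marked failed but
#' still count toward the adjustment denominator.
#'
#' @param instrumentSets list of \linkS4class{InstrumentSet}s (rejections may
#'   be included and are skipped with a message).
#' @param outcomeStats named list of \linkS4class{SummaryStats}, one per
#'   disease.
#' @param methods subset of c("gsmr", "ivw", "egger", "wmedian"); the first
#'   must be "gsmr", whose p-value drives the FDR column.
#' @param heidiAlpha HEIDI outlier threshold (default 0.01).
#' @param fdrAlpha significance level on the adjusted p (default 0.05).
#' @param nBoot,seed weighted-median bootstrap controls.
#' @return An \linkS4class{MRGrid}.
#' @export
runGrid <- function(instrumentSets, outcomeStats,
                    methods = c("gsmr", "ivw", "egger", "wmedian"),
                    heidiAlpha = 0.01, fdrAlpha = 0.05,
                    nBoot = 1000L, seed = NULL) {
  stopifnot(length(instrumentSets) >= 1, length(outcomeStats) >= 1)
  methods <- match.arg(methods, .METHOD_FUNS, several.ok = TRUE)
  if (methods[1] != "gsmr")
    stop("the main analysis method must be gsmr")
  sets <- Filter(function(s) is(s, "InstrumentSet"), instrumentSets)
  if (length(sets) < length(instrumentSets))
    message(length(instrumentSets) - length(sets),
            " rejected protein(s) excluded from the grid")
  if (length(sets) == 0)
    stop("no instrument sets left to analyze (all proteins rejected)")
  if (is.null(names(outcomeStats)))
    names(outcomeStats) <- paste0("disease_", seq_along(outcomeStats))

  rows <- list()
  for (set in sets) {
    for (dz in names(outcomeStats)) {
      row <- list(protein_id = set@proteinId, disease_id = dz,
                  status = "ok", reason = "",
                  n_iv_initial = nrow(set@data), n_iv_used = NA_integer_,
                  removed_snps = "",
                  heidi_disabled_flag = !set@heidiCapable,
                  few_iv_flag = FALSE)
      input <- tryCatch(asMRInput(set, outcomeStats[[dz]]),
                        error = function(e) e)
      if (inherits(input, "error")) {
        row$status <- "failed"
        row$reason <- conditionMessage(input)
        for (m in methods)
          row[paste0(m, c("_b", "_se", "_p", "_or", "_ci_low", "_ci_high"))] <-
            NA_real_
        row[c("egger_intercept", "egger_intercept_p")] <- NA_real_
        row$raw_p <- NA_real_
        rows[[length(rows) + 1L]] <- row
        next
      }
      ests <- .estimateCell(input, methods, heidiAlpha, nBoot, seed)
      for (m in methods) {
        e <- ests[[m]]
        cols <- paste0(m, c("_b", "_se", "_p", "_or", "_ci_low", "_ci_high"))
        if (inherits(e, "error")) {
          row[cols] <- NA_real_
          if (m == "gsmr") { row$status <- "failed"; row$reason <- conditionMessage(e) }
        } else {
          row[cols] <- list(e@b, e@se, e@p, e@or_, e@ciLow, e@ciHigh)
          if (m == "gsmr") {
            row$n_iv_used <- e@nIvUsed
            row$removed_snps <- paste(e@removedSnps, collapse = ",")
            row$few_iv_flag <- e@nIvUsed < 4L
            row$heidi_disabled_flag <- !e@heidiApplied
          }
          if (m == "egger") {
            row$egger_intercept <- e@eggerIntercept
            row$egger_intercept_p <- e@eggerInterceptP
          }
        }
      }
      if (!"egger" %in% methods)
        row[c("egger_intercept", "egger_intercept_p")] <- NA_real_
      row$raw_p <- if (is.null(row$gsmr_p)) NA_real_ else row$gsmr_p
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(res) <- NULL
  mT <- nrow(res)
  res$fdr_p <- bhAdjust(res$raw_p, m = mT)
  res$significant <- !is.na(res$fdr_p) & res$fdr_p < fdrAlpha
  cats <- mapply(function(p, o, s) categorizeCell(p, o, s)$category,
                 res$raw_p, res$gsmr_or, res$significant)
  res$category <- as.character(cats)
  new("MRGrid", results = res, mTests = as.integer(mT),
      params = list(methods = methods, heidiAlpha = heidiAlpha,
                    fdrAlpha = fdrAlpha, nBoot = as.integer(nBoot),
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Write a grid report to disk
#'
#' Emits \code{results.tsv} (full-precision per-method estimates plus
#' formatted "OR (95\% CI)" columns), \code{figure1_categories.tsv} (the
#' machine-readable heat-map analogue), \code{params.yaml} and
#' \code{run.log}. \code{\link{readReport}} round-trips the grid exactly.
#'
#' @param grid an \linkS4class{MRGrid}.
#' @param outDir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(grid, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- grid@results
  main <- res
  if (nrow(main) > 0 && all(c("gsmr_or", "gsmr_ci_low", "gsmr_ci_high") %in% names(main)))
    main$gsmr_or_ci <- ifelse(is.na(main$gsmr_or), "NA",
      formatOrCi(main$gsmr_or, main$gsmr_ci_low, main$gsmr_ci_high))
  fmt <- function(df) {
    for (j in seq_along(df)) if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
    df
  }
  paths <- file.path(outDir, c("results.tsv", "figure1_categories.tsv",
                               "params.yaml", "run.log"))
  write.table(fmt(main), paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  catCols <- intersect(c("protein_id", "disease_id", "raw_p", "fdr_p",
                         "significant", "category", "few_iv_flag",
                         "heidi_disabled_flag"), names(res))
  write.table(fmt(res[, catCols, drop = FALSE]), paths[2], sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(grid@params, list(m_tests = grid@mTests)), paths[3])
  writeLines(c(sprintf("cells: %d", nrow(res)),
               sprintf("m_tests: %d", grid@mTests),
               sprintf("significant: %d", sum(res$significant, na.rm = TRUE)),
               sprintf("failed: %d", sum(res$status == "failed"))), paths[4])
  invisible(paths)
}

#' Read a grid report back from disk
#'
#' @param outDir directory written by \code{\link{writeReport}}.
#' @return An \linkS4class{MRGrid} equal to the one written.
#' @export
readReport <- function(outDir) {
  res <- read.delim(file.path(outDir, "results.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
  res$gsmr_or_ci <- NULL
  for (col in c("reason", "removed_snps"))
    if (col %in% names(res)) res[[col]][is.na(res[[col]])] <- ""
  for (col in c("n_iv_initial", "n_iv_used"))
    if (col %in% names(res)) res[[col]] <- as.integer(res[[col]])
  pars <- yaml::read_yaml(file.path(outDir, "params.yaml"))
  mT <- as.integer(pars$m_tests)
  pars$m_tests <- NULL
  pars$nBoot <- as.integer(pars$nBoot)
  pars$seed <- as.integer(pars$seed)
  new("MRGrid", results = res, mTests = mT, params = pars)
}
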