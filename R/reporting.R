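#' Packaged study fixtures
#'
#' `libraryTotalsFixture()` returns the per-replicate DeepSAGE library totals
#' of the field study (three cultivars, 2008 weeks 9/12/15/18/21 and 2009
#' weeks 9/11, biological triplicates with a few missing libraries) in long
#' form. `yieldFixture()` returns the agronomic yield table (tuber yield in
#' hkg/ha, starch content in % fresh weight); the cultivar-to-value
#' assignment follows the running text, which is authoritative over the
#' row-shifted table layout of the printed sample-statistics table.
#'
#' @return `libraryTotalsFixture()`: `data.frame(cultivar, year, week,
#'   replicate, total, combined_printed)` with `NA` totals for missing
#'   libraries and the printed combined total repeated per group;
#'   `yieldFixture()`: `data.frame(cultivar, tuber_yield, starch_percent)`.
#' @export
libraryTotalsFixture <- function() {
  path <- system.file("extdata", "library_totals.tsv",
                      package = "StarchSAGE", mustWork = TRUE)
  wide <- read.delim(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(cultivar = wide$cultivar, year = wide$year, week = wide$week,
               replicate = r, total = wide[[paste0("replicate", r)]],
               combined_printed = wide$combined, stringsAsFactors = FALSE)
  }))
  long[order(long$cultivar, long$year, long$week, long$replicate), ,
       drop = FALSE]
}

#' @rdname libraryTotalsFixture
#' @export
yieldFixture <- function() {
  read.delim(system.file("extdata", "cultivar_yield.tsv",
                         package = "StarchSAGE", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Summarize replicate library totals
#'
#' Combined totals are within-group sums over the available replicates
#' (missing replicates are simply absent from the sum). The replicate-level
#' mean is computed per year series over non-missing replicate libraries;
#' min/max are taken over the combined totals per year series.
#'
#' @param totals Long table with columns `cultivar`, `year`, `week`,
#'   `replicate`, `total` (`NA` for missing libraries).
#' @return List with `combined` (`cultivar`, `year`, `week`, `n_replicates`,
#'   `combined_total`) and `per_year` (`year`, `n_replicate_libraries`,
#'   `replicate_mean`, `combined_min`, `combined_max`,
#'   `n_combined_libraries`).
#' @export
librarySummary <- function(totals) {
  need <- c("cultivar", "year", "week", "replicate", "total")
  if (!all(need %in% names(totals)))
    stop("totals needs columns: ", paste(need, collapse = ", "))
  if (!nrow(totals)) stop("empty series")
  if (any(totals$total < 0, na.rm = TRUE)) stop("totals must be >= 0")
  key <- totals[, c("cultivar", "year", "week")]
  combined <- do.call(rbind, lapply(
    split(totals, interaction(key, drop = TRUE)), function(g) {
      data.frame(cultivar = g$cultivar[1], year = g$year[1], week = g$week[1],
                 n_replicates = sum(!is.na(g$total)),
                 combined_total = sum(g$total, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  combined <- combined[order(combined$cultivar, combined$year, combined$week), ]
  rownames(combined) <- NULL
  per_year <- do.call(rbind, lapply(split(totals, totals$year), function(g) {
    comb <- combined[combined$year == g$year[1], ]
    data.frame(year = g$year[1],
               n_replicate_libraries = sum(!is.na(g$total)),
               replicate_mean = mean(g$total, na.rm = TRUE),
               combined_min = min(comb$combined_total),
               combined_max = max(comb$combined_total),
               n_combined_libraries = nrow(comb), stringsAsFactors = FALSE)
  }))
  rownames(per_year) <- NULL
  list(combined = combined, per_year = per_year)
}

#' Percent increase in starch mass yield over a baseline cultivar
#'
#' Starch mass yield is `tuber_yield * starch_percent / 100` (hkg starch per
#' ha); the increase over the baseline cultivar is reported as a
#' nearest-integer percentage (half away from zero).
#'
#' @param records `data.frame(cultivar, tuber_yield, starch_percent)`.
#' @param baseline Baseline cultivar name (must be present with non-zero
#'   starch yield).
#' @return `data.frame(cultivar, starch_yield, increase_pct)`.
#' @examples
#' starchYieldComparison(yieldFixture(), "Jutlandia")
#' @export
starchYieldComparison <- function(records, baseline) {
  if (!baseline %in% records$cultivar)
    stop(sprintf("baseline cultivar '%s' not present", baseline))
  sy <- records$tuber_yield * records$starch_percent / 100
  base <- sy[records$cultivar == baseline][1]
  if (base == 0) stop("baseline starch yield is zero")
  data.frame(cultivar = records$cultivar, starch_yield = sy,
             increase_pct = roundHalfUp((sy / base - 1) * 100),
             stringsAsFactors = FALSE)
}

#' Assemble a run report from pipeline stage outputs
#'
#' Collects the outputs of a full synthetic or real run — read dispositions,
#' PCA quality-control flags, the differential-expression table, biochemistry
#' results, the configuration echo and seeds — into a plain-text report and a
#' machine-readable JSON twin. Identical inputs give byte-identical reports.
#'
#' @param stages Named list; recognized entries: `dispositions`
#'   (data.frame), `pca` ([PCAReport-class]), `de` (from [deScan()]),
#'   `rates` (from [computeRates()]), `ratios` (from [g1pG6pRatio()]),
#'   `library_summary` (from [librarySummary()]), `config` (a
#'   [generatorConfig()]), `seed` (integer).
#' @param file Optional path prefix; when given, `<file>.txt` and
#'   `<file>.json` are written.
#' @return Invisibly, a list with `text` (character vector of report lines)
#'   and `data` (the JSON-serializable payload).
#' @export
runReport <- function(stages, file = NULL) {
  if (!length(stages)) stop("at least one stage output is required")
  txt <- c("StarchSAGE run report", "=====================")
  data <- list()
  if (!is.null(stages$seed)) {
    txt <- c(txt, sprintf("seed: %d", stages$seed))
    data$seed <- stages$seed
  }
  if (!is.null(stages$config)) {
    cfg <- stages$config
    txt <- c(txt, sprintf(
      "config: %d genes (%d starch), %d samples, mean depth %g, seed %d",
      cfg$n_genes, cfg$n_starch_genes, nrow(cfg$samples), cfg$mean_depth,
      cfg$seed))
    data$config <- cfg[c("n_genes", "n_starch_genes", "mean_depth",
                         "dilinker_fraction", "no_anchor_fraction",
                         "replicate_cv", "seed")]
  }
  if (!is.null(stages$dispositions)) {
    d <- stages$dispositions
    txt <- c(txt, sprintf(
      "reads: %d productive, %d no-anchor, %d too-short, %d ambiguous-base, %d unmatched",
      sum(d$productive), sum(d$no_anchor), sum(d$too_short),
      sum(d$ambiguous_base), sum(d$unmatched)))
    data$dispositions <- d
  }
  if (!is.null(stages$library_summary)) {
    data$library_summary <- stages$library_summary
    py <- stages$library_summary$per_year
    txt <- c(txt, sprintf(
      "libraries %d: %d replicate-level (mean %s tags), combined %s..%s",
      py$year, py$n_replicate_libraries,
      format(roundHalfUp(py$replicate_mean), big.mark = ","),
      format(py$combined_min, big.mark = ","),
      format(py$combined_max, big.mark = ",")))
  }
  if (!is.null(stages$pca)) {
    out <- outliers(stages$pca)
    txt <- c(txt, if (length(out))
      paste("PCA outliers:", paste(out, collapse = ", "))
      else "PCA: no outliers identified")
    data$pca <- as.data.frame(pcaScores(stages$pca))
  }
  if (!is.null(stages$de)) {
    de <- stages$de
    flagged <- unique(de[de$step_flagged,
                         c("step_name", "year", "week"), drop = FALSE])
    txt <- c(txt, if (nrow(flagged))
      sprintf("significant steps: %s",
              paste(sprintf("%s (%d wk%d)", flagged$step_name, flagged$year,
                            flagged$week), collapse = "; "))
      else "no significant steps")
    data$de <- de
  }
  if (!is.null(stages$rates)) {
    txt <- c(txt, sprintf("enzyme activities: %d samples, mean %.4g A340/min",
                          nrow(stages$rates), mean(stages$rates$activity)))
    data$rates <- stages$rates
  }
  if (!is.null(stages$ratios)) {
    s <- stages$ratios$summary
    if (!is.null(s))
      txt <- c(txt, sprintf("G1P/G6P %s wk%d: %.3g +/- %.2g (n=%d)",
                            s$cultivar, s$week, s$mean_ratio, s$sem, s$n))
    data$ratios <- stages$ratios$ratios
  }
  if (!is.null(file)) {
    writeLines(txt, paste0(file, ".txt"))
    jsonlite::write_json(data, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }
  invisible(list(text = txt, data = data))
}
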