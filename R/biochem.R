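#' Enzyme activity from paired sample/control absorbance traces
#'
#' Fits ordinary least-squares slopes to the A340-versus-time series of the
#' assay sample and of the no-sample control, subtracts the control slope and
#' converts to the reporting unit: `(slope_sample - slope_control) * 60 *
#' dilution_factor`, in A340/min. A negative net slope is clipped to 0 and
#' flagged.
#'
#' @param sample `data.frame(time_s, a340)` for the assay sample, plus a
#'   `dilution` column (or pass `dilution`); >= 3 points, strictly increasing
#'   times.
#' @param control Same layout for the no-sample control; its time window must
#'   overlap the sample's.
#' @param dilution Dilution factor override (defaults to
#'   `sample$dilution[1]`, else 1).
#' @return One-row `data.frame(activity, slope_sample, slope_control,
#'   clipped)`; `activity` in A340/min.
#' @examples
#' t <- 0:9 * 30
#' s <- data.frame(time_s = t, a340 = 0.05 + 0.002 * t)
#' ctl <- data.frame(time_s = t, a340 = 0.05 + 0.0005 * t)
#' computeRate(s, ctl, dilution = 5)
#' @export
computeRate <- function(sample, control, dilution = NULL) {
  slope1 <- .traceSlope(sample, "sample")
  slope0 <- .traceSlope(control, "control")
  if (max(sample$time_s) < min(control$time_s) ||
      max(control$time_s) < min(sample$time_s))
    stop("sample and control traces do not cover overlapping time windows")
  if (is.null(dilution))
    dilution <- if ("dilution" %in% names(sample)) sample$dilution[1] else 1
  net <- slope1 - slope0
  clipped <- net < 0
  if (clipped) net <- 0
  data.frame(activity = net * 60 * dilution, slope_sample = slope1,
             slope_control = slope0, clipped = clipped)
}

.traceSlope <- function(trace, what) {
  if (nrow(trace) < 3L)
    stop(sprintf("%s trace needs at least 3 points", what))
  if (any(diff(trace$time_s) <= 0))
    stop(sprintf("%s trace times must be strictly increasing", what))
  unname(coef(lm(a340 ~ time_s, data = trace))[2L])
}

#' Compute activities for every sample trace in a run
#'
#' Splits a long trace table into per-sample traces, pairs each with the
#' control trace (`is_control == TRUE`) and applies [computeRate()].
#'
#' @param traces Long `data.frame` as produced by [simulateAssayTraces()]:
#'   `time_s`, `a340`, `sample_id`, `dilution`, `is_control`, plus any
#'   annotation columns (e.g. `cultivar`, `replicate`) carried through.
#' @return `data.frame` with one row per sample and columns `sample_id`,
#'   annotation columns, `activity`, `slope_sample`, `slope_control`,
#'   `clipped`.
#' @export
computeRates <- function(traces) {
  ctl <- traces[traces$is_control, ]
  if (!nrow(ctl)) stop("no control trace (is_control == TRUE) found")
  smp <- traces[!traces$is_control, ]
  out <- lapply(split(smp, smp$sample_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    r <- computeRate(tr, ctl[order(ctl$time_s), ])
    ann <- tr[1L, setdiff(names(tr), c("time_s", "a340", "is_control")),
              drop = FALSE]
    cbind(ann, r, row.names = NULL)
  })
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}

#' Fit a linear standard curve for one analyte
#'
#' Ordinary least squares of peak area on concentration over reference
#' standards.
#'
#' @param concentration,area Numeric vectors of calibration points; at least
#'   two distinct concentrations.
#' @param analyte Analyte label.
#' @return A [StandardCurve-class].
#' @examples
#' fitStandardCurve(c(0.5, 1, 2), c(50, 100, 200), "G1P")
#' @export
fitStandardCurve <- function(concentration, area, analyte = "analyte") {
  if (length(unique(concentration)) < 2L)
    stop("standard curve needs at least 2 distinct concentrations")
  fit <- lm(area ~ concentration)
  tss <- sum((area - mean(area))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  new("StandardCurve", analyte = analyte,
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      r_squared = min(max(r2, 0), 1), n = length(area))
}

#' Convert a peak area into tissue concentration
#'
#' Back-calculates the extract concentration from the calibration line and
#' scales by the extraction geometry:
#' `conc = (area - intercept) / slope * reconstitution_volume / 1000 /
#' (tissue_mass * extract_fraction)`, i.e. micromol per g tissue when the
#' curve is in mM and the volume in microlitre. Negative back-calculated
#' concentrations are floored at 0 and flagged.
#'
#' @param area Peak area(s).
#' @param curve A [StandardCurve-class].
#' @param tissue_mass Tissue mass in g (> 0).
#' @param reconstitution_volume Reconstitution volume in microlitre.
#' @param extract_fraction Fraction of the extract carried through the
#'   partial-volume transfers of the protocol (default 1).
#' @return `data.frame(conc_per_g, clipped)`.
#' @export
quantifyAnalyte <- function(area, curve, tissue_mass,
                            reconstitution_volume = 100,
                            extract_fraction = 1) {
  stopifnot(is(curve, "StandardCurve"))
  if (any(tissue_mass <= 0)) stop("tissue_mass must be > 0")
  conc_mM <- (area - curve@intercept) / curve@slope
  clipped <- conc_mM < 0
  conc_mM[clipped] <- 0
  data.frame(conc_per_g = conc_mM * (reconstitution_volume / 1000) /
               (tissue_mass * extract_fraction),
             clipped = clipped)
}

#' Per-chromatogram G1P/G6P ratios with group statistics
#'
#' Because both hexose phosphates are measured in the same chromatogram, the
#' ratio of their concentrations cancels shared sample-preparation and
#' loading variation; the ratio is therefore formed per chromatogram *before*
#' any averaging. Chromatograms with a non-positive G6P concentration are
#' excluded with a flag. Group means and standard errors are computed over
#' the per-chromatogram ratios; cross-cultivar comparisons can be run on the
#' returned ratios with [ttestStep()].
#'
#' @param peaks Peak table (`sample_id`, `analyte`, `peak_area`,
#'   `tissue_mass`, plus grouping columns `cultivar`, `week` if present).
#' @param curves Named list of [StandardCurve-class] objects containing
#'   `G1P` and `G6P`.
#' @param reconstitution_volume,extract_fraction Passed to
#'   [quantifyAnalyte()].
#' @return List with `ratios` (one row per chromatogram: grouping columns,
#'   `g1p`, `g6p`, `ratio`, `excluded`) and `summary` (per (cultivar, week):
#'   `n`, `mean_ratio`, `sem`).
#' @export
g1pG6pRatio <- function(peaks, curves, reconstitution_volume = 100,
                        extract_fraction = 1) {
  stopifnot(all(c("G1P", "G6P") %in% names(curves)))
  per <- lapply(split(peaks, peaks$sample_id), function(p) {
    g1 <- p[p$analyte == "G1P", ]
    g6 <- p[p$analyte == "G6P", ]
    if (nrow(g1) != 1L || nrow(g6) != 1L)
      stop(sprintf("chromatogram '%s' must contain exactly one G1P and one G6P peak",
                   p$sample_id[1]))
    c1 <- quantifyAnalyte(g1$peak_area, curves$G1P, g1$tissue_mass,
                          reconstitution_volume, extract_fraction)$conc_per_g
    c6 <- quantifyAnalyte(g6$peak_area, curves$G6P, g6$tissue_mass,
                          reconstitution_volume, extract_fraction)$conc_per_g
    ann <- g1[1L, intersect(c("sample_id", "cultivar", "week", "replicate"),
                            names(g1)), drop = FALSE]
    usable <- c6 > 1e-12  # zero up to back-calculation round-off
    cbind(ann, data.frame(g1p = c1, g6p = c6,
                          ratio = if (usable) c1 / c6 else NA_real_,
                          excluded = !usable), row.names = NULL)
  })
  ratios <- do.call(rbind, c(unname(per), list(make.row.names = FALSE)))
  summary <- NULL
  if (all(c("cultivar", "week") %in% names(ratios))) {
    keep <- !ratios$excluded
    summary <- do.call(rbind, lapply(
      split(ratios[keep, ], paste(ratios$cultivar, ratios$week)[keep]),
      function(g) data.frame(cultivar = g$cultivar[1], week = g$week[1],
                             n = nrow(g), mean_ratio = mean(g$ratio),
                             sem = if (nrow(g) > 1L)
                               sd(g$ratio) / sqrt(nrow(g)) else NA_real_,
                             stringsAsFactors = FALSE)))
    rownames(summary) <- NULL
  }
  list(ratios = ratios, summary = summary)
}

#' Equilibrium ratio of the phosphoglucomutase reaction
#'
#' For the conversion G1P -> G6P with standard free-energy change
#' `delta_G0` (kJ/mol), the equilibrium constant is
#' `Keq = [G6P]/[G1P] = exp(-delta_G0 * 1000 / (R * T))`. A negative
#' `delta_G0` gives `Keq > 1`: the equilibrium lies towards G6P.
#'
#' @param delta_G0 Standard Gibbs free-energy change in kJ/mol (the PGM
#'   reaction value is -7.28 kJ/mol).
#' @param temperature Absolute temperature in kelvin (> 0; default 298.15).
#' @param gas_constant Gas constant in J/(mol K).
#' @return The equilibrium ratio `[G6P]/[G1P]`.
#' @examples
#' equilibriumRatio(-7.28)  # about 18.9: equilibrium far towards G6P
#' @export
equilibriumRatio <- function(delta_G0, temperature = 298.15,
                             gas_constant = 8.314) {
  if (any(temperature <= 0)) stop("temperature must be > 0 K")
  exp(-delta_G0 * 1000 / (gas_constant * temperature))
}
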