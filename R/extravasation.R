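#' Fit a linear fluorescence standard curve
#'
#' Ordinary least-squares regression of plate-reader fluorescence on dye
#' concentration over a standard dilution series (classical calibration:
#' reading on concentration, inverted for prediction).
#'
#' @param standards Data frame with columns `conc_ng_ml` and `reading`, or a
#'   numeric vector of concentrations if `reading` is supplied separately.
#' @param reading Optional numeric vector of readings.
#' @return An object of class `"eb_calibration"` with `slope` (fluorescence
#'   units per ng/ml), `intercept`, `r2` and the standards; warns if
#'   r2 < 0.98.
#' @examples
#' std <- data.frame(conc_ng_ml = c(0, 50, 100, 200, 400, 800, 1600))
#' std$reading <- 5 + 3 * std$conc_ng_ml
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, reading = NULL) {
  if (is.data.frame(standards)) {
    if (!all(c("conc_ng_ml", "reading") %in% names(standards)))
      stop("`standards` must have columns `conc_ng_ml` and `reading`")
    conc <- standards$conc_ng_ml
    reading <- standards$reading
  } else {
    conc <- standards
    if (is.null(reading)) stop("supply `reading` with vector standards")
  }
  stopifnot(is.numeric(conc), is.numeric(reading),
            length(conc) == length(reading))
  if (length(unique(conc)) < 2)
    stop("need >= 2 distinct standard concentrations to fit a curve")
  fit <- stats::lm(reading ~ conc)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope is not positive; check the standard series")
  ss_tot <- sum((reading - mean(reading))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (r2 < 0.98)
    warning("standard curve r2 = ", signif(r2, 3),
            " < 0.98; calibration may be unreliable")
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]), r2 = r2,
         standards = data.frame(conc_ng_ml = conc, reading = reading)),
    class = "eb_calibration"
  )
}

#' @export
print.eb_calibration <- function(x, ...) {
  cat("Evans blue calibration curve:",
      sprintf("reading = %.4g + %.4g x conc (ng/ml), r2 = %.4f",
              x$intercept, x$slope, x$r2), "\n")
  invisible(x)
}

#' @export
coef.eb_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Invert the calibration: fluorescence reading to concentration
#'
#' @param object An `"eb_calibration"` object.
#' @param reading Fluorescence reading(s).
#' @param ... Unused.
#' @return Concentration(s) in ng/ml (may be negative for readings below
#'   the intercept; see [quantify_tissue()] for clipping).
#' @export
predict.eb_calibration <- function(object, reading, ...) {
  (reading - object$intercept) / object$slope
}

#' @export
plot.eb_calibration <- function(x, ...) {
  graphics::plot(x$standards$conc_ng_ml, x$standards$reading,
                 xlab = "Evans blue (ng/ml)", ylab = "Fluorescence",
                 main = "Standard curve", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Evans blue content of a tissue sample
#'
#' Converts a plate fluorescence reading to dye concentration through the
#' standard curve, then to tissue content:
#' `content = concentration * extract_volume / tissue_mass` (ng dye per mg
#' tissue). Readings below the curve intercept give small negative
#' concentrations from plate noise; these are clipped to zero and flagged.
#'
#' @param reading Fluorescence reading(s).
#' @param tissue_mass Tissue wet mass(es), mg (> 0).
#' @param curve An `"eb_calibration"` object.
#' @param extract_volume Formamide extraction volume, ml.
#' @return Numeric vector of ng/mg with a logical attribute `"clipped"`.
#' @examples
#' curve <- fit_standard_curve(data.frame(conc_ng_ml = c(0, 100, 200, 400),
#'                                        reading = c(0, 100, 200, 400)))
#' quantify_tissue(400, tissue_mass = 40, curve = curve)  # 5 ng/mg
#' @export
quantify_tissue <- function(reading, tissue_mass, curve, extract_volume = 0.5) {
  stopifnot(inherits(curve, "eb_calibration"))
  if (any(tissue_mass <= 0)) stop("`tissue_mass` must be > 0")
  if (any(extract_volume <= 0)) stop("`extract_volume` must be > 0")
  conc <- predict(curve, reading)
  clipped <- conc < 0
  if (any(clipped)) {
    warning(sum(clipped),
            " reading(s) below the calibration intercept clipped to 0 ng/mg")
    conc[clipped] <- 0
  }
  structure(conc * extract_volume / tissue_mass, clipped = clipped)
}

#' Fold-change of group means versus sham
#'
#' Ratio of each irradiated group's mean to the sham (0 Gy) mean within
#' each stratum, with a seeded bootstrap percentile confidence interval.
#'
#' @param table Long data frame with a dose column, a value column and the
#'   stratifying columns.
#' @param value Name of the value column.
#' @param dose Name of the dose column; sham is `dose == 0`.
#' @param by Character vector of stratifying columns (only those present in
#'   `table` are used).
#' @param n_boot Bootstrap resamples for the percentile interval.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with the stratum columns, `dose_gy`, `fold`,
#'   `ci_lower`, `ci_upper`, `n_dose`, `n_sham`.
#' @export
fold_change_vs_sham <- function(table, value = "value", dose = "dose_gy",
                                by = c("age_group", "region", "timepoint"),
                                n_boot = 2000, conf = 0.95, seed = 1) {
  stopifnot(value %in% names(table), dose %in% names(table))
  by <- intersect(by, names(table))
  set.seed(seed)
  strata <- if (length(by)) {
    split(table, table[by], drop = TRUE)
  } else list(all = table)

  one_stratum <- function(st) {
    sham <- st[[value]][st[[dose]] == 0]
    if (!length(sham))
      stop("no sham (dose 0) observations in stratum; cannot form fold-change")
    doses <- sort(unique(st[[dose]][st[[dose]] != 0]))
    out <- lapply(doses, function(d) {
      trt <- st[[value]][st[[dose]] == d]
      fold <- mean(trt) / mean(sham)
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(sample(trt, replace = TRUE)) / mean(sample(sham, replace = TRUE))
      }, numeric(1))
      ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
      cbind(st[1, by, drop = FALSE],
            data.frame(dose_gy = d, fold = fold, ci_lower = ci[1],
                       ci_upper = ci[2], n_dose = length(trt),
                       n_sham = length(sham)))
    })
    do.call(rbind, out)
  }
  res <- do.call(rbind, lapply(strata, one_stratum))
  rownames(res) <- NULL
  res
}
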