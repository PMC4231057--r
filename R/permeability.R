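#' Cleared volume of a transwell sample
#'
#' The cleared volume is the luminal (donor) volume equivalent from which
#' tracer has been completely transferred to the abluminal (receiver)
#' compartment: `C_abluminal * V_abluminal / C_luminal`.
#'
#' @param abluminal_conc Receiver concentration, ug/ml (>= 0, vectorized).
#' @param abluminal_volume Receiver volume, ul.
#' @param luminal_conc Donor concentration entering the formula, ug/ml (> 0).
#' @return Cleared volume(s) in ul.
#' @examples
#' compute_clearance(0.2, 530, 10)   # 10.6 ul
#' @export
compute_clearance <- function(abluminal_conc, abluminal_volume, luminal_conc) {
  if (any(luminal_conc <= 0)) stop("`luminal_conc` must be > 0")
  if (any(abluminal_conc < 0) || any(abluminal_volume < 0))
    stop("concentrations and volumes must be >= 0")
  abluminal_conc * abluminal_volume / luminal_conc
}

#' Permeability-surface product from a clearance time course
#'
#' Ordinary least-squares slope of cumulative cleared volume against time;
#' the slope is the permeability-surface product PS (ul/min). The origin
#' (0, 0) is prepended unless a t = 0 sample is already supplied, and an
#' intercept is still estimated: only the slope is used, which makes the
#' fit robust to a nonzero lag without forcing the line through the origin.
#'
#' @param times Sampling times, min.
#' @param cumulative_cleared Cumulative cleared volumes at `times`, ul.
#' @return A list with `slope` (ul/min), `r2` and `intercept`.
#' @examples
#' fit_ps(c(20, 40, 60), c(2, 4, 6))  # slope 0.1, r2 = 1
#' @export
fit_ps <- function(times, cumulative_cleared) {
  stopifnot(is.numeric(times), is.numeric(cumulative_cleared),
            length(times) == length(cumulative_cleared))
  if (!any(times == 0)) {
    times <- c(0, times)
    cumulative_cleared <- c(0, cumulative_cleared)
  }
  if (length(unique(times)) < 2)
    stop("need >= 2 distinct time points to fit PS")
  fit <- stats::lm(cumulative_cleared ~ times)
  ss_tot <- sum((cumulative_cleared - mean(cumulative_cleared))^2)
  r2 <- if (ss_tot == 0) NA_real_ else
    1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2)
}

#' Series-conductance correction for the cell-free insert
#'
#' The measured total conductance is the series combination of the
#' endothelial monolayer and the bare coated filter:
#' `1/PS_endothelial = 1/PS_total - 1/PS_insert`.
#'
#' @param ps_total Total PS of insert plus monolayer, ul/min.
#' @param ps_insert PS of the cell-free insert, ul/min.
#' @return Endothelial PS in ul/min (always >= `ps_total`).
#' @examples
#' correct_for_insert(1, 2)  # 2
#' @export
correct_for_insert <- function(ps_total, ps_insert) {
  if (any(ps_total <= 0) || any(ps_insert <= 0))
    stop("PS values must be > 0")
  if (any(ps_total >= ps_insert))
    stop("series-model violation: ps_total >= ps_insert ",
         "(a monolayer cannot be more conductive than the bare filter)")
  1 / (1 / ps_total - 1 / ps_insert)
}

#' Endothelial permeability coefficient
#'
#' Converts the endothelial permeability-surface product from ul/min to
#' cm3/s and divides by the membrane area, reporting Pe on the
#' 10^-6 cm/s scale.
#'
#' @param ps_endothelial Endothelial PS, ul/min.
#' @param area Membrane area, cm2 (> 0).
#' @return Pe in units of 10^-6 cm/s.
#' @examples
#' compute_pe(4.158e-3, 0.33)  # 0.21
#' @export
compute_pe <- function(ps_endothelial, area) {
  if (any(area <= 0)) stop("`area` must be > 0")
  if (any(ps_endothelial < 0)) stop("`ps_endothelial` must be >= 0")
  ps_to_pe(ps_endothelial, area)
}

#' Normalized transendothelial electrical resistance
#'
#' Scales a raw resistance reading by the insert area and subtracts the
#' resistance-area product of an empty coated insert. Negative results are
#' clipped to zero and flagged.
#'
#' @param raw_resistance Raw meter reading(s), ohm (>= 0).
#' @param area Insert area, cm2.
#' @param blank Blank insert TEER, ohm cm2.
#' @return A data frame with columns `raw_resistance`, `area`, `blank`,
#'   `teer` (ohm cm2) and `clipped`.
#' @examples
#' compute_teer(515.15, 0.33, 70)  # TEER 100 ohm cm2
#' @export
compute_teer <- function(raw_resistance, area = 0.33, blank = 70) {
  if (any(raw_resistance < 0)) stop("`raw_resistance` must be >= 0")
  if (any(area <= 0)) stop("`area` must be > 0")
  if (any(blank < 0)) stop("`blank` must be >= 0")
  teer <- raw_resistance * area - blank
  clipped <- teer < 0
  if (any(clipped)) {
    warning(sum(clipped), " TEER value(s) below the blank were clipped to 0")
    teer[clipped] <- 0
  }
  data.frame(raw_resistance = raw_resistance, area = area, blank = blank,
             teer = teer, clipped = clipped)
}

#' Fit endothelial permeability coefficients from a transwell plate
#'
#' Runs the full estimation chain on a long table of per-insert interval
#' readings: cleared volumes per sampling interval are cumulated and
#' regressed on time to give total PS per insert; the cell-free inserts for
#' each tracer are pooled (mean PS) to give the filter conductance; each
#' cell-bearing insert is then corrected for the filter in series and
#' converted to a permeability coefficient Pe (10^-6 cm/s). Inserts whose
#' total PS reaches or exceeds the filter PS violate the series model and
#' are excluded with a warning.
#'
#' @param data Data frame with columns `insert_id`, `dose_gy`, `day`,
#'   `tracer`, `cell_free` (logical), `interval_end_min`, `abluminal_conc`
#'   and `luminal_conc_nominal` (the donor concentration used in the
#'   clearance formula).
#' @param abluminal_volume Receiver volume, ul.
#' @param insert_area Membrane area, cm2.
#' @param ps_insert Optional named numeric vector of filter PS per tracer
#'   (ul/min), overriding the pooled cell-free estimate.
#' @return An object of class `"perm_fit"` with components
#'   \describe{
#'     \item{results}{per-insert data frame: `insert_id`, `dose_gy`, `day`,
#'       `tracer`, `ps_total`, `ps_insert`, `ps_endothelial`, `pe`,
#'       `fit_r2`, `excluded`.}
#'     \item{ps_insert}{named vector of filter PS per tracer (ul/min).}
#'     \item{clearances}{per-insert cumulative cleared volumes used in the
#'       regressions.}
#'   }
#' @examples
#' sim <- simulate_permeability_dataset(default_kinetics(doses = 0, days = 1),
#'                                      n_inserts = 3, seed = 1)
#' fit <- fit_permeability(sim$permeability)
#' summary(fit)
#' @export
fit_permeability <- function(data, abluminal_volume = 530, insert_area = 0.33,
                             ps_insert = NULL) {
  required <- c("insert_id", "tracer", "cell_free", "interval_end_min",
                "abluminal_conc", "luminal_conc_nominal")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("`data` is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"dose_gy" %in% names(data)) data$dose_gy <- NA_real_
  if (!"day" %in% names(data)) data$day <- NA_real_
  if (!any(!data$cell_free))
    stop("no cell-bearing inserts in `data`")

  per_insert_ps <- function(rows) {
    rows <- rows[order(rows$interval_end_min), ]
    cleared <- compute_clearance(rows$abluminal_conc, abluminal_volume,
                                 rows$luminal_conc_nominal)
    cum <- cumsum(cleared)
    fit <- fit_ps(rows$interval_end_min, cum)
    list(ps = fit$slope, r2 = fit$r2,
         clearance = data.frame(insert_id = rows$insert_id[1],
                                tracer = rows$tracer[1],
                                time_min = rows$interval_end_min,
                                cumulative_cleared = cum))
  }

  key <- interaction(data$insert_id, data$tracer, drop = TRUE)
  pieces <- lapply(split(data, key), per_insert_ps)
  meta <- data[!duplicated(key), c("insert_id", "dose_gy", "day", "tracer",
                                   "cell_free")]
  meta <- meta[match(levels(key), key[!duplicated(key)]), ]
  meta$ps_total <- vapply(pieces, `[[`, numeric(1), "ps")
  meta$fit_r2 <- vapply(pieces, `[[`, numeric(1), "r2")

  # pooled filter conductance per tracer
  tracers <- unique(meta$tracer[!meta$cell_free])
  if (is.null(ps_insert)) {
    cf <- meta[meta$cell_free, ]
    missing_cf <- setdiff(tracers, unique(cf$tracer))
    if (length(missing_cf))
      stop("no cell-free inserts for tracer(s): ",
           paste(missing_cf, collapse = ", "),
           "; supply `ps_insert` or include cell-free inserts")
    ps_insert <- tapply(cf$ps_total, cf$tracer, mean)
    ps_insert <- stats::setNames(as.numeric(ps_insert), names(ps_insert))
  } else {
    missing_cf <- setdiff(tracers, names(ps_insert))
    if (length(missing_cf))
      stop("`ps_insert` has no entry for tracer(s): ",
           paste(missing_cf, collapse = ", "))
  }

  res <- meta[!meta$cell_free, ]
  res$ps_insert <- ps_insert[res$tracer]
  res$excluded <- res$ps_total >= res$ps_insert | res$ps_total <= 0
  if (any(res$excluded))
    warning(sum(res$excluded), " insert(s) violate the series model ",
            "(ps_total >= ps_insert or <= 0) and were excluded")
  res$ps_endothelial <- NA_real_
  ok <- !res$excluded
  res$ps_endothelial[ok] <- correct_for_insert(res$ps_total[ok],
                                               res$ps_insert[ok])
  res$pe <- NA_real_
  res$pe[ok] <- compute_pe(res$ps_endothelial[ok], insert_area)
  rownames(res) <- NULL

  structure(
    list(
      results = res[, c("insert_id", "dose_gy", "day", "tracer", "ps_total",
                        "ps_insert", "ps_endothelial", "pe", "fit_r2",
                        "excluded")],
      ps_insert = ps_insert,
      clearances = do.call(rbind, lapply(pieces, `[[`, "clearance")),
      abluminal_volume = abluminal_volume,
      insert_area = insert_area,
      call = match.call()
    ),
    class = "perm_fit"
  )
}

#' @export
print.perm_fit <- function(x, ...) {
  cat("Transwell permeability fit:", nrow(x$results), "cell-bearing insert(s),",
      sum(x$results$excluded), "excluded\n")
  cat("Filter PS (ul/min):",
      paste(names(x$ps_insert), signif(x$ps_insert, 4), sep = " = ",
            collapse = ", "), "\n")
  print(utils::head(x$results, 10))
  if (nrow(x$results) > 10) cat("...", nrow(x$results) - 10, "more row(s)\n")
  invisible(x)
}

#' Group summary of a permeability fit
#'
#' @param object A `"perm_fit"` object.
#' @param ... Unused.
#' @return A data frame of mean, SD and n of Pe per tracer, dose and day.
#' @export
summary.perm_fit <- function(object, ...) {
  res <- object$results[!object$results$excluded, ]
  agg <- stats::aggregate(pe ~ tracer + dose_gy + day, data = res,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[c("tracer", "dose_gy", "day")],
                    mean_pe = agg$pe[, "mean"], sd_pe = agg$pe[, "sd"],
                    n = agg$pe[, "n"])
  out[order(out$tracer, out$dose_gy, out$day), ]
}

#' @export
coef.perm_fit <- function(object, ...) {
  stats::setNames(object$results$pe,
                  paste(object$results$insert_id, object$results$tracer,
                        sep = ":"))
}

#' Plot group mean permeability coefficients by day and dose
#'
#' @param x A `"perm_fit"` object.
#' @param tracer Which tracer to plot (default: first present).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.perm_fit <- function(x, tracer = NULL, ...) {
  s <- summary(x)
  if (is.null(tracer)) tracer <- s$tracer[1]
  s <- s[s$tracer == tracer, ]
  wide <- stats::reshape(s[, c("dose_gy", "day", "mean_pe")],
                         idvar = "day", timevar = "dose_gy",
                         direction = "wide")
  wide <- wide[order(wide$day), ]
  mat <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$day, mat, type = "b", pch = 19, lty = 1,
                    xlab = "Day post-irradiation",
                    ylab = expression(P[e] ~ (10^-6 ~ cm/s)),
                    main = paste("Endothelial permeability:", tracer), ...)
  graphics::legend("topright",
                   legend = sub("mean_pe\\.", "", colnames(wide)[-1]),
                   col = seq_len(ncol(mat)), lty = 1, pch = 19,
                   title = "Dose (Gy)", bty = "n")
  invisible(x)
}
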