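#' Significance star codes
#'
#' @param p Numeric p-value(s).
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
star_code <- function(p) {
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns")))
}

check_cells <- function(data, factors) {
  tab <- table(lapply(factors, function(f) data[[f]]))
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ",
         paste(factors, mapply(function(f, i) dimnames(tab)[[f]][i],
                               seq_along(factors), empty),
               sep = " = ", collapse = ", "))
  }
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Dose-by-timepoint ANOVA with Type III sums of squares under sum-to-zero
#' contrasts (equivalent to the textbook decomposition on balanced data).
#'
#' @param data Data frame of grouped measurements.
#' @param response Name of the value column.
#' @param factors Length-2 character vector naming the two factor columns.
#' @return An object of class `"dose_anova"`: `anova_table` (factor, F,
#'   df1, df2, p), the underlying `lm` fit, residual mean square and
#'   degrees of freedom, and the factor/response names.
#' @examples
#' eff <- default_effects()
#' cnt <- simulate_count_assays(eff, seed = 7)
#' dens <- cnt[cnt$assay == "cell_density", ]
#' dens$value <- cell_density(dens$numerator, dens$denominator)
#' two_way_anova(dens, response = "value", factors = c("dose_gy", "timepoint"))
#' @export
two_way_anova <- function(data, response = "value",
                          factors = c("dose_gy", "timepoint")) {
  stopifnot(length(factors) == 2, response %in% names(data),
            all(factors %in% names(data)))
  data <- data[, c(response, factors)]
  data[[1]] <- as.numeric(data[[1]])
  if (any(!is.finite(data[[1]]))) stop("response values must be finite")
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(factors, function(f) nlevels(data[[f]]), 1L) < 2))
    stop("both factors need >= 2 levels")
  check_cells(data, factors)
  form <- stats::as.formula(paste(response, "~", factors[1], "*", factors[2]))
  contr <- stats::setNames(rep(list("contr.sum"), 2), factors)
  fit <- stats::lm(form, data = data, contrasts = contr)
  if (fit$df.residual < 1)
    stop("no residual degrees of freedom: need replicate observations")
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  df2 <- a3["Residuals", "Df"]
  tab <- data.frame(
    factor = rownames(a3)[keep],
    F = a3[keep, "F value"],
    df1 = a3[keep, "Df"],
    df2 = df2,
    p = a3[keep, "Pr(>F)"],
    row.names = NULL
  )
  structure(
    list(anova_table = tab, fit = fit,
         mse = sum(stats::residuals(fit)^2) / fit$df.residual,
         df_residual = fit$df.residual,
         response = response, factors = factors, data = data),
    class = "dose_anova"
  )
}

#' One-way fixed-effects ANOVA with Bonferroni comparisons vs control
#'
#' Standard one-way F test plus Bonferroni-adjusted pairwise comparisons of
#' each group against the control group, using the pooled error variance.
#'
#' @param data Data frame of grouped measurements.
#' @param response Name of the value column.
#' @param group Name of the grouping column.
#' @param control Control level (default `"0"`, the sham group).
#' @return A `"dose_anova"` object whose `comparisons` table holds the
#'   control-vs-group tests (mean difference, raw and adjusted p, stars).
#' @export
one_way_anova <- function(data, response = "value", group = "dose_gy",
                          control = "0") {
  stopifnot(response %in% names(data), group %in% names(data))
  data <- data[, c(response, group)]
  data[[1]] <- as.numeric(data[[1]])
  if (any(!is.finite(data[[1]]))) stop("response values must be finite")
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 2) stop("need >= 2 groups")
  sizes <- table(data[[group]])
  if (any(sizes < 2)) stop("every group needs >= 2 observations")
  if (!control %in% levels(data[[group]]))
    stop("control level '", control, "' not present")
  form <- stats::as.formula(paste(response, "~", group))
  fit <- stats::lm(form, data = data)
  an <- stats::anova(fit)
  tab <- data.frame(factor = group, F = an[1, "F value"], df1 = an[1, "Df"],
                    df2 = an[2, "Df"], p = an[1, "Pr(>F)"], row.names = NULL)
  mse <- an[2, "Mean Sq"]
  df2 <- an[2, "Df"]

  others <- setdiff(levels(data[[group]]), control)
  m <- length(others)
  comps <- do.call(rbind, lapply(others, function(g) {
    x <- data[[response]][data[[group]] == g]
    y <- data[[response]][data[[group]] == control]
    diff <- mean(x) - mean(y)
    se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
    tstat <- if (se == 0) 0 else diff / se
    p_raw <- 2 * stats::pt(-abs(tstat), df2)
    data.frame(group = g, control = control, mean_diff = diff, t = tstat,
               df = df2, p_raw = p_raw, p_adj = min(1, m * p_raw))
  }))
  comps$stars <- star_code(comps$p_adj)
  structure(
    list(anova_table = tab, comparisons = comps, fit = fit, mse = mse,
         df_residual = df2, family_size = m, response = response,
         factors = group, data = data),
    class = "dose_anova"
  )
}

#' Bonferroni post-tests of each dose against sham at matched timepoints
#'
#' For every timepoint, each dose group is compared to the sham (0 Gy)
#' group by a t statistic using the pooled error variance of the ANOVA fit.
#' Raw p-values are multiplied by the family size and capped at 1. The
#' default family contains all dose-vs-sham comparisons across timepoints;
#' `family = "per_timepoint"` restricts the family to the comparisons
#' within each timepoint.
#'
#' @param anova A `"dose_anova"` object from [two_way_anova()] whose first
#'   factor is dose and second is timepoint.
#' @param family Bonferroni family definition.
#' @param control Sham level of the dose factor.
#' @return Data frame with `timepoint`, `dose`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_adj`, `stars`.
#' @export
bonferroni_vs_sham <- function(anova,
                               family = c("dose_by_time", "per_timepoint"),
                               control = "0") {
  stopifnot(inherits(anova, "dose_anova"), length(anova$factors) == 2)
  family <- match.arg(family)
  data <- anova$data
  dose_f <- anova$factors[1]
  time_f <- anova$factors[2]
  response <- anova$response
  if (!control %in% levels(data[[dose_f]]))
    stop("sham level '", control, "' not present in factor ", dose_f)
  doses <- setdiff(levels(data[[dose_f]]), control)
  times <- levels(data[[time_f]])
  for (tp in times)
    if (!any(data[[dose_f]] == control & data[[time_f]] == tp))
      stop("sham group missing at timepoint ", tp)
  m <- if (family == "dose_by_time") length(doses) * length(times)
       else length(doses)

  grid <- expand.grid(dose = doses, timepoint = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  comps <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$dose[i]; tp <- grid$timepoint[i]
    x <- data[[response]][data[[dose_f]] == d & data[[time_f]] == tp]
    y <- data[[response]][data[[dose_f]] == control & data[[time_f]] == tp]
    diff <- mean(x) - mean(y)
    se <- sqrt(anova$mse * (1 / length(x) + 1 / length(y)))
    tstat <- if (se == 0) 0 else diff / se
    p_raw <- 2 * stats::pt(-abs(tstat), anova$df_residual)
    data.frame(timepoint = tp, dose = d, mean_diff = diff, t = tstat,
               df = anova$df_residual, p_raw = p_raw,
               p_adj = min(1, m * p_raw))
  }))
  comps$stars <- star_code(comps$p_adj)
  attr(comps, "family_size") <- m
  comps
}

#' @export
print.dose_anova <- function(x, ...) {
  cat("Fixed-effects ANOVA (", paste(x$factors, collapse = " x "), ")\n",
      sep = "")
  print(transform(x$anova_table, F = signif(F, 5), p = signif(p, 4)),
        row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nBonferroni comparisons vs control (family size ",
        x$family_size, "):\n", sep = "")
    print(transform(x$comparisons, mean_diff = signif(mean_diff, 4),
                    t = signif(t, 4), p_raw = signif(p_raw, 4),
                    p_adj = signif(p_adj, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.dose_anova <- function(object, ...) {
  means <- stats::aggregate(
    object$data[[object$response]],
    by = lapply(object$factors, function(f) object$data[[f]]),
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  names(means)[seq_along(object$factors)] <- object$factors
  out <- data.frame(means[object$factors], mean = means$x[, "mean"],
                    sd = means$x[, "sd"], n = means$x[, "n"])
  out
}
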