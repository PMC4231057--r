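#' Endothelial progenitor colony rate
#'
#' Colony-forming units per 10^5 peripheral blood mononuclear cells.
#'
#' @param colonies Colony count(s) (>= 0).
#' @param pbmc PBMC count(s) plated (> 0).
#' @return CFU per 10^5 PBMC.
#' @examples
#' cep_rate(12, 6e5)  # 2
#' @export
cep_rate <- function(colonies, pbmc) {
  if (any(pbmc <= 0)) stop("`pbmc` must be > 0")
  if (any(colonies < 0)) stop("`colonies` must be >= 0")
  colonies / pbmc * 1e5
}

#' Senescent cell percentage with exact binomial confidence interval
#'
#' Percentage of SA-beta-gal-positive cells on a coverslip, with the
#' Clopper-Pearson exact interval computed from beta quantiles.
#'
#' @param positive Positive cell count(s).
#' @param total Total cells counted (>= 1).
#' @param conf_level Confidence level of the exact interval.
#' @return Data frame with `positive`, `total`, `percent`, `ci_lower`,
#'   `ci_upper` (all percentages).
#' @examples
#' senescence_fraction(120, 400)  # 30%
#' @export
senescence_fraction <- function(positive, total, conf_level = 0.95) {
  if (any(total < 1)) stop("`total` must be >= 1")
  if (any(positive < 0) || any(positive > total))
    stop("`positive` must lie in [0, total]")
  alpha <- 1 - conf_level
  lower <- ifelse(positive == 0, 0,
                  stats::qbeta(alpha / 2, positive, total - positive + 1))
  upper <- ifelse(positive == total, 1,
                  stats::qbeta(1 - alpha / 2, positive + 1, total - positive))
  data.frame(positive = positive, total = total,
             percent = 100 * positive / total,
             ci_lower = 100 * lower, ci_upper = 100 * upper)
}

#' Cell density of a microscope field
#'
#' @param cells Cell count(s) (>= 0).
#' @param field_area Field area(s), mm2 (> 0).
#' @return Cells per mm2.
#' @examples
#' cell_density(50, 0.25)  # 200
#' @export
cell_density <- function(cells, field_area) {
  if (any(field_area <= 0)) stop("`field_area` must be > 0")
  if (any(cells < 0)) stop("`cells` must be >= 0")
  cells / field_area
}

#' Otsu's threshold for a grayscale image
#'
#' Exhaustive search over the observed gray levels for the threshold that
#' maximizes the between-class variance of the below/above split (Otsu's
#' criterion). Pixels with value <= threshold form the background class.
#' Ties are broken toward the lowest threshold.
#'
#' @param x Numeric matrix or vector of non-negative intensities with at
#'   least two distinct values.
#' @return The threshold value (one of the gray levels present).
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  if (any(v < 0)) stop("intensities must be non-negative")
  levels <- sort(unique(v))
  if (length(levels) < 2)
    stop("degenerate threshold: image has constant intensity")
  counts <- tabulate(match(v, levels))
  n <- length(v)
  cw <- cumsum(counts)                # pixels <= level
  cm <- cumsum(counts * levels)       # intensity mass <= level
  total <- cm[length(cm)]
  k <- seq_len(length(levels) - 1)    # candidate split points
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- cm[k] / cw[k]
  mu1 <- (total - cm[k]) / (n - cw[k])
  between <- w0 * w1 * (mu0 - mu1)^2
  levels[k[which.max(between)]]
}

#' Background-subtracted stain intensity of an image field
#'
#' Reproduces a thresholded intensity quantification: the stained area is
#' identified by a global threshold (Otsu's method by default), the
#' background level is estimated as the mean of sub-threshold
#' (non-expressing) pixels and subtracted from every pixel (floored at
#' zero), and the mean of the above-threshold pixels after subtraction is
#' returned.
#'
#' @param pixels Numeric matrix of non-negative gray values, at least
#'   64 x 64 pixels, with non-constant intensity.
#' @param threshold Optional manual threshold overriding Otsu's method.
#' @return A list with `mean_intensity` (background-subtracted mean of the
#'   stained area), `threshold`, `background` and `stained_fraction`.
#' @examples
#' img <- matrix(10, 64, 64); img[1:32, 1:32] <- 110
#' quantify_intensity(img)$mean_intensity  # 100
#' @export
quantify_intensity <- function(pixels, threshold = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(dim(pixels) < 64))
    stop("image fields must be at least 64 x 64 pixels")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (length(unique(as.numeric(pixels))) < 2)
    stop("degenerate threshold: image has constant intensity")
  if (is.null(threshold)) threshold <- otsu_threshold(pixels)
  bg_mask <- pixels <= threshold
  if (!any(bg_mask) || all(bg_mask))
    stop("threshold leaves an empty stained or background class")
  background <- mean(pixels[bg_mask])
  corrected <- pmax(pixels - background, 0)
  list(mean_intensity = mean(corrected[!bg_mask]),
       threshold = threshold,
       background = background,
       stained_fraction = mean(!bg_mask))
}
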