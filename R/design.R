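#' Transwell assay design
#'
#' Describes the geometry, tracer dose and sampling schedule of a transwell
#' permeability experiment: a luminal (upper, donor) compartment separated
#' from an abluminal (lower, receiver) compartment by a membrane insert
#' carrying the endothelial monolayer. Defaults reproduce a 24-well format
#' insert assay (70 ul luminal / 530 ul abluminal, 0.33 cm2 membrane) with
#' the insert transferred to a fresh well at 20, 40 and 60 min.
#'
#' @param luminal_volume Donor compartment volume in ul.
#' @param abluminal_volume Receiver compartment volume in ul.
#' @param insert_area Membrane surface area in cm2.
#' @param sample_times Times (min) at which the insert is moved to a fresh
#'   receiver well and both compartments are sampled; strictly increasing.
#' @param donor_concentration Initial tracer concentration in the luminal
#'   compartment, ug/ml (10 for fluorescein, 165 for Evans blue-albumin).
#' @param tracer_label One of `"fluorescein"` or `"eb_albumin"`.
#' @return An object of class `"assay_design"` (a named list).
#' @examples
#' assay_design()
#' assay_design(donor_concentration = 165, tracer_label = "eb_albumin")
#' @export
assay_design <- function(luminal_volume = 70,
                         abluminal_volume = 530,
                         insert_area = 0.33,
                         sample_times = c(20, 40, 60),
                         donor_concentration = 10,
                         tracer_label = c("fluorescein", "eb_albumin")) {
  tracer_label <- match.arg(tracer_label)
  stopifnot(
    is.numeric(luminal_volume), length(luminal_volume) == 1, luminal_volume > 0,
    is.numeric(abluminal_volume), length(abluminal_volume) == 1, abluminal_volume > 0,
    is.numeric(insert_area), length(insert_area) == 1, insert_area > 0,
    is.numeric(donor_concentration), length(donor_concentration) == 1,
    donor_concentration > 0,
    is.numeric(sample_times), length(sample_times) >= 1
  )
  if (any(sample_times <= 0) || any(diff(sample_times) <= 0))
    stop("`sample_times` must be strictly increasing and positive")
  structure(
    list(
      luminal_volume = luminal_volume,
      abluminal_volume = abluminal_volume,
      insert_area = insert_area,
      sample_times = sample_times,
      donor_concentration = donor_concentration,
      tracer_label = tracer_label
    ),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Transwell assay design (", x$tracer_label, ")\n", sep = "")
  cat("  luminal/abluminal volume: ", x$luminal_volume, " / ",
      x$abluminal_volume, " ul\n", sep = "")
  cat("  insert area: ", x$insert_area, " cm2\n", sep = "")
  cat("  donor concentration: ", x$donor_concentration, " ug/ml\n", sep = "")
  cat("  sample times: ", paste(x$sample_times, collapse = ", "), " min\n",
      sep = "")
  invisible(x)
}

#' Default paired tracer designs
#'
#' The two designs used when both paracellular (fluorescein) and
#' transcellular (Evans blue-albumin) markers are assayed in parallel on the
#' same inserts.
#'
#' @return A named list of two [assay_design()] objects.
#' @export
default_designs <- function() {
  list(
    fluorescein = assay_design(donor_concentration = 10,
                               tracer_label = "fluorescein"),
    eb_albumin  = assay_design(donor_concentration = 165,
                               tracer_label = "eb_albumin")
  )
}

#' True kinetic parameters for the forward simulator
#'
#' Ground-truth endothelial permeability coefficients, cell-free insert
#' permeabilities and TEER values from which synthetic plates are generated.
#'
#' @param pe_endothelial Data frame with columns `tracer`, `dose_gy`, `day`,
#'   `pe` giving the true endothelial permeability coefficient
#'   (10^-6 cm/s) per tracer, dose and post-irradiation day.
#' @param pe_insert Named numeric vector: permeability (10^-6 cm/s) of the
#'   cell-free coated membrane per tracer.
#' @param teer Data frame with columns `dose_gy`, `day`, `teer`: true TEER
#'   (ohm cm2) per dose and day.
#' @param blank_teer Resistance-area product of an empty coated insert
#'   (ohm cm2), subtracted during TEER normalization.
#' @return An object of class `"true_kinetics"`.
#' @seealso [default_kinetics()] for the study-default parameter set.
#' @export
true_kinetics <- function(pe_endothelial, pe_insert, teer, blank_teer = 70) {
  stopifnot(is.data.frame(pe_endothelial),
            all(c("tracer", "dose_gy", "day", "pe") %in% names(pe_endothelial)),
            is.numeric(pe_insert), !is.null(names(pe_insert)),
            is.data.frame(teer),
            all(c("dose_gy", "day", "teer") %in% names(teer)),
            is.numeric(blank_teer), length(blank_teer) == 1, blank_teer >= 0)
  if (any(pe_endothelial$pe <= 0)) stop("all endothelial Pe must be > 0")
  if (any(pe_insert <= 0)) stop("all insert permeabilities must be > 0")
  if (any(teer$teer < 0)) stop("true TEER must be >= 0")
  missing_tracer <- setdiff(unique(pe_endothelial$tracer), names(pe_insert))
  if (length(missing_tracer))
    stop("no insert permeability given for tracer(s): ",
         paste(missing_tracer, collapse = ", "))
  structure(
    list(pe_endothelial = pe_endothelial, pe_insert = pe_insert,
         teer = teer, blank_teer = blank_teer),
    class = "true_kinetics"
  )
}

#' Study-default kinetic parameters
#'
#' The default ground truth used by the simulator: sham Pe of 0.21 (fluorescein)
#' and 0.043 (Evans blue-albumin) x10^-6 cm/s, sham TEER 382.6 ohm cm2,
#' blank insert 70 ohm cm2, and a dose-by-day effect structure in which
#' permeability rises from day 2 at 2 and 10 Gy (peaking at day 2) and from
#' day 3 at 0.1 Gy for fluorescein only, while TEER falls 30% at 10 Gy on
#' day 2 only. Cell-free insert permeabilities default to 20 (fluorescein)
#' and 5 (Evans blue-albumin) x10^-6 cm/s.
#'
#' @param doses Radiation doses (Gy) to include.
#' @param days Post-irradiation days to include.
#' @return A `"true_kinetics"` object.
#' @export
default_kinetics <- function(doses = c(0, 0.1, 2, 10), days = c(1, 2, 3, 5)) {
  # multiplicative Pe effects relative to sham, per dose x day
  pe_mult <- function(tracer, dose, day) {
    if (dose == 0 || day == 1) return(1)
    if (dose == 0.1) {
      if (tracer != "fluorescein") return(1)       # low dose: paracellular only
      return(if (day >= 3) 1.5 else 1)
    }
    if (day == 2) return(if (dose == 10) 3.0 else 2.5)
    if (dose == 10) 2.5 else 2.0
  }
  base_pe <- c(fluorescein = 0.21, eb_albumin = 0.043)
  grid <- expand.grid(tracer = names(base_pe), dose_gy = doses, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$pe <- mapply(function(tr, d, dy) base_pe[[tr]] * pe_mult(tr, d, dy),
                    grid$tracer, grid$dose_gy, grid$day)
  teer <- expand.grid(dose_gy = doses, day = days, KEEP.OUT.ATTRS = FALSE)
  teer$teer <- ifelse(teer$dose_gy == 10 & teer$day == 2,
                      382.6 * 0.7, 382.6)
  true_kinetics(
    pe_endothelial = grid,
    pe_insert = c(fluorescein = 20, eb_albumin = 5),
    teer = teer,
    blank_teer = 70
  )
}

#' Effect model for the grouped in vivo and count assays
#'
#' Baseline endpoint levels, multiplicative dose-by-timepoint effects,
#' noise levels and group sizes used by [simulate_in_vivo_dataset()] and
#' [simulate_count_assays()].
#'
#' @param baseline Named numeric: mean sham level per endpoint
#'   (`evans_blue` in ng/mg tissue, `senescence` as a fraction in (0,1),
#'   `cep` as colonies per 10^5 PBMC, `cell_density` in cells/mm2).
#' @param multipliers Data frame with columns `endpoint`, `dose_gy`,
#'   `timepoint`, `multiplier` (and optionally `age_group`); effect factor
#'   applied to the baseline for that group.
#' @param noise_cv Named numeric: between-subject coefficient of variation
#'   per endpoint.
#' @param group_sizes Named numeric: subjects (animals, coverslips, fields)
#'   per dose-by-timepoint cell, per endpoint.
#' @return An object of class `"effect_model"`.
#' @seealso [default_effects()]
#' @export
effect_model <- function(baseline, multipliers, noise_cv, group_sizes) {
  stopifnot(is.numeric(baseline), !is.null(names(baseline)),
            is.data.frame(multipliers),
            all(c("endpoint", "dose_gy", "timepoint", "multiplier") %in%
                  names(multipliers)),
            is.numeric(noise_cv), !is.null(names(noise_cv)),
            is.numeric(group_sizes), !is.null(names(group_sizes)))
  if (any(multipliers$multiplier <= 0)) stop("multipliers must be > 0")
  if (any(noise_cv < 0)) stop("noise_cv must be >= 0")
  if (any(group_sizes < 2))
    stop("group_sizes must be >= 2 for any group entering statistics")
  structure(
    list(baseline = baseline, multipliers = multipliers,
         noise_cv = noise_cv, group_sizes = group_sizes),
    class = "effect_model"
  )
}

#' Study-default effect structure
#'
#' Default effect patterns for the grouped endpoints: Evans blue
#' extravasation doubles at 1 week in adults at every dose (the infant
#' response is shifted to 4 weeks) and recovers fully by 26 weeks;
#' circulating endothelial progenitor colonies drop at day 1 after 0.1 and
#' 2 Gy and recover by 26 weeks; endothelial/glial cell density falls at 2
#' and 10 Gy from day 3; the SA-beta-gal-positive fraction rises 30% and 40%
#' above the 25% sham level at 2 and 10 Gy on day 5.
#'
#' @return An `"effect_model"` object.
#' @export
default_effects <- function() {
  rbindf <- function(...) do.call(rbind, list(...))
  grid_mult <- function(endpoint, timepoints, doses, mult, age_group = NA) {
    g <- expand.grid(dose_gy = doses, timepoint = timepoints,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$endpoint <- endpoint
    g$age_group <- age_group
    g$multiplier <- mult(g$dose_gy, g$timepoint)
    g[, c("endpoint", "age_group", "dose_gy", "timepoint", "multiplier")]
  }
  doses <- c(0, 0.1, 2, 10)
  invivo_tp <- c("1d", "1w", "4w", "26w")
  eb_adult <- grid_mult("evans_blue", invivo_tp, doses, age_group = "adult",
    mult = function(d, tp) ifelse(d > 0 & tp == "1w", 2.0,
                           ifelse(d == 10 & tp == "4w", 1.4, 1.0)))
  eb_infant <- grid_mult("evans_blue", invivo_tp, doses, age_group = "infant",
    mult = function(d, tp) ifelse(d >= 2 & tp == "1w", 1.5,
                           ifelse(d > 0 & tp == "4w", 2.0, 1.0)))
  cep <- grid_mult("cep", invivo_tp, doses,
    mult = function(d, tp) {
      m <- rep(1, length(d))
      m[d %in% c(0.1, 2) & tp == "1d"] <- 0.5
      m[d == 2 & tp %in% c("1w", "4w")] <- 0.6
      m[d == 0.1 & tp == "1w"] <- 0.8
      m
    })
  dens <- grid_mult("cell_density", c("1", "2", "3", "5"), doses,
    mult = function(d, tp) ifelse(d >= 2 & tp %in% c("3", "5"),
                                  ifelse(d == 10, 0.6, 0.7), 1.0))
  sen <- grid_mult("senescence", "5", doses,
    mult = function(d, tp) ifelse(d == 10, 1.4, ifelse(d == 2, 1.3, 1.0)))
  effect_model(
    baseline = c(evans_blue = 15, senescence = 0.25, cep = 2.0,
                 cell_density = 400),
    multipliers = rbindf(eb_adult, eb_infant, cep, dens, sen),
    noise_cv = c(evans_blue = 0.2, senescence = 0, cep = 0.15,
                 cell_density = 0.1),
    group_sizes = c(evans_blue = 12, senescence = 19, cep = 6,
                    cell_density = 6)
  )
}
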