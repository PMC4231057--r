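# mean-one multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a transwell permeability plate with TEER readings
#'
#' Forward-simulates the interval-transfer transwell protocol: tracer is
#' loaded into the luminal compartment; at each sampling time the insert is
#' moved to a fresh receiver well, so the receiver concentration resets to
#' zero while the donor concentration carries over. Within each interval
#' concentrations follow the exact two-compartment solution with total
#' conductance given by the series combination of the endothelial and
#' filter permeabilities (`1/PS_total = 1/PS_e + 1/PS_f`). Cell-free
#' inserts are simulated with the filter conductance alone. Measured
#' abluminal concentrations receive multiplicative mean-one lognormal noise;
#' raw resistance readings `(TEER_true + blank)/area` receive additive
#' Gaussian noise with SD `noise_cv * TEER_true / area`.
#'
#' @param kinetics A [true_kinetics()] object.
#' @param designs Named list of [assay_design()] objects, one per tracer in
#'   `kinetics` (default [default_designs()] restricted to those tracers).
#' @param n_inserts Cell-bearing inserts per dose-by-day group.
#' @param n_cell_free Cell-free inserts per tracer.
#' @param noise_cv Coefficient of variation of measurement noise.
#' @param seed Integer seed; required, simulations are reproducible.
#' @return A list with data frames `permeability` (columns `insert_id`,
#'   `dose_gy`, `day`, `tracer`, `cell_free`, `interval_end_min`,
#'   `abluminal_conc`, `luminal_conc_nominal`), `teer` (`insert_id`,
#'   `dose_gy`, `day`, `raw_ohm`), and a `provenance` list (seed and
#'   parameter snapshot).
#' @examples
#' sim <- simulate_permeability_dataset(default_kinetics(), seed = 42)
#' head(sim$permeability)
#' @export
simulate_permeability_dataset <- function(kinetics,
                                          designs = NULL,
                                          n_inserts = 3,
                                          n_cell_free = 3,
                                          noise_cv = 0.1,
                                          seed) {
  stopifnot(inherits(kinetics, "true_kinetics"), n_inserts >= 1,
            n_cell_free >= 1, noise_cv >= 0)
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: simulated datasets must be reproducible")
  set.seed(seed)
  tracers <- unique(kinetics$pe_endothelial$tracer)
  if (is.null(designs)) designs <- default_designs()[tracers]
  if (!all(tracers %in% names(designs)))
    stop("`designs` must contain one design per tracer")

  simulate_insert <- function(design, ps_total, insert_id, dose, day,
                              cell_free) {
    times <- design$sample_times
    starts <- c(0, times[-length(times)])
    donor <- design$donor_concentration
    receiver_true <- numeric(length(times))
    for (i in seq_along(times)) {
      sol <- two_compartment_solution(design, ps_total, times[i] - starts[i],
                                      donor, receiver_start = 0)
      receiver_true[i] <- sol$receiver
      donor <- sol$donor
    }
    measured <- receiver_true * lognormal_noise(length(times), noise_cv)
    data.frame(insert_id = insert_id, dose_gy = dose, day = day,
               tracer = design$tracer_label, cell_free = cell_free,
               interval_end_min = times, abluminal_conc = measured,
               luminal_conc_nominal = design$donor_concentration)
  }

  rows <- list()
  for (tr in tracers) {
    design <- designs[[tr]]
    ps_f <- pe_to_ps(kinetics$pe_insert[[tr]], design$insert_area)
    pe_tab <- kinetics$pe_endothelial[kinetics$pe_endothelial$tracer == tr, ]
    for (r in seq_len(nrow(pe_tab))) {
      ps_e <- pe_to_ps(pe_tab$pe[r], design$insert_area)
      ps_total <- 1 / (1 / ps_e + 1 / ps_f)
      for (k in seq_len(n_inserts)) {
        id <- sprintf("%s_d%g_day%g_i%02d", tr, pe_tab$dose_gy[r],
                      pe_tab$day[r], k)
        rows[[length(rows) + 1]] <- simulate_insert(
          design, ps_total, id, pe_tab$dose_gy[r], pe_tab$day[r], FALSE)
      }
    }
    for (k in seq_len(n_cell_free)) {
      id <- sprintf("%s_cellfree_i%02d", tr, k)
      rows[[length(rows) + 1]] <- simulate_insert(design, ps_f, id, 0, 0, TRUE)
    }
  }
  permeability <- do.call(rbind, rows)
  rownames(permeability) <- NULL

  area <- designs[[1]]$insert_area
  teer_rows <- kinetics$teer[rep(seq_len(nrow(kinetics$teer)),
                                 each = n_inserts), ]
  raw <- (teer_rows$teer + kinetics$blank_teer) / area +
    stats::rnorm(nrow(teer_rows), 0, noise_cv * teer_rows$teer / area)
  teer <- data.frame(
    insert_id = sprintf("teer_d%g_day%g_i%02d", teer_rows$dose_gy,
                        teer_rows$day,
                        sequence(rep(n_inserts, nrow(kinetics$teer)))),
    dose_gy = teer_rows$dose_gy, day = teer_rows$day,
    raw_ohm = pmax(raw, 0))
  rownames(teer) <- NULL

  list(permeability = permeability, teer = teer,
       provenance = list(seed = seed, n_inserts = n_inserts,
                         n_cell_free = n_cell_free, noise_cv = noise_cv,
                         kinetics = kinetics))
}

#' Simulate the in vivo Evans blue extravasation study
#'
#' Draws per-animal brain tissue Evans blue content lognormally around
#' `baseline * multiplier` for each age-by-dose-by-timepoint group, converts
#' it to plate-reader fluorescence through an invertible linear calibration,
#' and emits the 7-point standard dilution series alongside. Each animal
#' contributes one cerebrum and one cerebellum sample.
#'
#' @param effects An [effect_model()]; multipliers for endpoint
#'   `"evans_blue"` must cover every requested age-by-dose-by-timepoint cell.
#' @param regions Brain regions sampled per animal.
#' @param ages Age groups simulated.
#' @param seed Integer seed (required).
#' @return A list with data frames `invivo` (`animal_id`, `age_group`,
#'   `region`, `dose_gy`, `timepoint`, `reading`, `tissue_mass_mg`,
#'   `extract_volume_ml`), `standards` (`conc_ng_ml`, `reading`) and a
#'   `provenance` list (including the true calibration slope/intercept).
#' @export
simulate_in_vivo_dataset <- function(effects,
                                     regions = c("cerebrum", "cerebellum"),
                                     ages = c("adult", "infant"),
                                     seed) {
  stopifnot(inherits(effects, "effect_model"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: simulated datasets must be reproducible")
  set.seed(seed)
  mult <- effects$multipliers[effects$multipliers$endpoint == "evans_blue", ]
  baseline <- effects$baseline[["evans_blue"]]
  cv <- effects$noise_cv[["evans_blue"]]
  n <- effects$group_sizes[["evans_blue"]]
  slope_true <- 0.85     # fluorescence units per ng/ml
  intercept_true <- 50   # plate background
  extract_volume <- 0.5  # ml formamide per sample
  mass_mean <- c(cerebrum = 180, cerebellum = 55)  # mg

  rows <- list()
  cells <- unique(mult[, c("dose_gy", "timepoint")])
  for (age in ages) {
    m_age <- mult[is.na(mult$age_group) | mult$age_group == age, ]
    for (r in seq_len(nrow(cells))) {
      d <- cells$dose_gy[r]; tp <- cells$timepoint[r]
      fac <- m_age$multiplier[m_age$dose_gy == d & m_age$timepoint == tp]
      if (length(fac) != 1)
        stop("effect multiplier missing or ambiguous for evans_blue, age ",
             age, ", dose ", d, " Gy, timepoint ", tp)
      for (k in seq_len(n)) {
        content <- baseline * fac * lognormal_noise(length(regions), cv)
        mass <- stats::rnorm(length(regions), mass_mean[regions],
                             0.1 * mass_mean[regions])
        conc <- content * mass / extract_volume   # ng/ml in the extract
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = sprintf("%s_d%g_%s_a%02d", age, d, tp, k),
          age_group = age, region = regions, dose_gy = d, timepoint = tp,
          reading = intercept_true + slope_true * conc,
          tissue_mass_mg = mass, extract_volume_ml = extract_volume)
      }
    }
  }
  invivo <- do.call(rbind, rows)
  rownames(invivo) <- NULL

  standards <- data.frame(conc_ng_ml = c(0, 250, 500, 1000, 2500, 5000, 10000))
  standards$reading <- intercept_true + slope_true * standards$conc_ng_ml

  list(invivo = invivo, standards = standards,
       provenance = list(seed = seed, slope = slope_true,
                         intercept = intercept_true, baseline = baseline,
                         noise_cv = cv, group_size = n))
}

#' Simulate count-based cellular assays
#'
#' Generates endothelial progenitor colony counts
#' (`colonies ~ Poisson(rate * PBMC / 1e5)`), senescence coverslip counts
#' (`positives ~ Binomial(n_counted in [400, 500], p * multiplier)`) and
#' cells-per-field counts (`cells ~ Poisson(density * field_area)`) for
#' every dose-by-timepoint cell of the effect model.
#'
#' @param effects An [effect_model()].
#' @param field_area_mm2 Microscope field area for cell-density counts, mm2.
#' @param pbmc_mean Mean PBMC count plated per progenitor assay.
#' @param seed Integer seed (required).
#' @return A data frame with columns `subject_id`, `dose_gy`, `timepoint`,
#'   `assay` (`"cep"`, `"senescence"`, `"cell_density"`), `numerator`
#'   (colonies / positive cells / cells) and `denominator` (PBMC count /
#'   cells counted / field area in mm2).
#' @export
simulate_count_assays <- function(effects, field_area_mm2 = 0.145,
                                  pbmc_mean = 6e5, seed) {
  stopifnot(inherits(effects, "effect_model"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: simulated datasets must be reproducible")
  set.seed(seed)
  mlt <- effects$multipliers
  rows <- list()

  sim_cells <- function(assay, fun) {
    m <- mlt[mlt$endpoint == assay, ]
    n <- effects$group_sizes[[assay]]
    for (r in seq_len(nrow(m))) {
      for (k in seq_len(n)) {
        rows[[length(rows) + 1]] <<- data.frame(
          subject_id = sprintf("%s_d%g_%s_s%02d", assay, m$dose_gy[r],
                               m$timepoint[r], k),
          dose_gy = m$dose_gy[r], timepoint = m$timepoint[r], assay = assay,
          fun(m$multiplier[r]))
      }
    }
  }

  if (any(mlt$endpoint == "cep")) {
    base_rate <- effects$baseline[["cep"]]
    cv <- effects$noise_cv[["cep"]]
    sim_cells("cep", function(fac) {
      pbmc <- round(pbmc_mean * lognormal_noise(1, cv))
      rate <- base_rate * fac
      data.frame(numerator = stats::rpois(1, rate * pbmc / 1e5),
                 denominator = pbmc)
    })
  }
  if (any(mlt$endpoint == "senescence")) {
    p0 <- effects$baseline[["senescence"]]
    sim_cells("senescence", function(fac) {
      p <- p0 * fac
      if (p > 1) stop("senescence probability p * multiplier exceeds 1")
      counted <- sample(400:500, 1)
      data.frame(numerator = stats::rbinom(1, counted, p),
                 denominator = counted)
    })
  }
  if (any(mlt$endpoint == "cell_density")) {
    dens0 <- effects$baseline[["cell_density"]]
    cv <- effects$noise_cv[["cell_density"]]
    sim_cells("cell_density", function(fac) {
      lambda <- dens0 * fac * lognormal_noise(1, cv) * field_area_mm2
      data.frame(numerator = stats::rpois(1, lambda),
                 denominator = field_area_mm2)
    })
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  counts
}
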