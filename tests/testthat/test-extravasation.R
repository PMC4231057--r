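test_that("standard curve fitting matches the OLS oracle", {
  conc <- c(0, 50, 100, 200, 400, 800, 1600)
  exact <- fit_standard_curve(data.frame(conc_ng_ml = conc,
                                         reading = 3 * conc + 5))
  expect_equal(exact$slope, 3)
  expect_equal(exact$intercept, 5)
  expect_equal(exact$r2, 1)

  set.seed(42)
  noisy <- 3 * conc + 5 + rnorm(length(conc), 0, 4)
  fit <- fit_standard_curve(conc, noisy)
  ora <- ols_oracle(conc, noisy)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, ora$intercept, tolerance = 1e-12)

  expect_error(fit_standard_curve(rep(100, 7), rnorm(7)), "distinct")
  expect_error(fit_standard_curve(conc, 5 - 3 * conc), "not positive")
  expect_warning(fit_standard_curve(c(0, 1, 2, 3, 4, 5, 6),
                                    c(0, 5, 1, 6, 2, 7, 3)), "0.98")
})

test_that("tissue quantification follows the calibration algebra", {
  curve <- fit_standard_curve(data.frame(conc_ng_ml = c(0, 200, 400, 800),
                                         reading = c(0, 200, 400, 800)))
  # 400 ng/ml in 0.5 ml over 40 mg -> 5 ng/mg
  expect_equal(as.numeric(quantify_tissue(400, 40, curve)), 5)
  expect_equal(as.numeric(quantify_tissue(curve$intercept, 40, curve)), 0)
  # linear in reading above the intercept, scale-inverse in mass
  r <- c(100, 200, 400)
  q <- as.numeric(quantify_tissue(r, 40, curve))
  expect_equal(q / q[1], r / r[1])
  expect_equal(as.numeric(quantify_tissue(400, 80, curve)), 2.5)
  expect_warning(q0 <- quantify_tissue(-5, 40, curve), "clipped")
  expect_equal(as.numeric(q0), 0)
  expect_error(quantify_tissue(10, 0, curve), "tissue_mass")
})

test_that("calibration round trip is the identity on noise-free data", {
  eff <- default_effects()
  eff$noise_cv[["evans_blue"]] <- 0
  sim <- simulate_in_vivo_dataset(eff, ages = "adult", seed = 44)
  curve <- fit_standard_curve(sim$standards)
  content <- quantify_tissue(sim$invivo$reading, sim$invivo$tissue_mass_mg,
                             curve, extract_volume = 0.5)
  truth <- merge(
    sim$invivo,
    eff$multipliers[eff$multipliers$endpoint == "evans_blue" &
                      eff$multipliers$age_group == "adult", ],
    by = c("dose_gy", "timepoint"))
  expect_equal(nrow(truth), nrow(sim$invivo))
  recovered <- as.numeric(content)[match(paste(truth$animal_id, truth$region),
                                         paste(sim$invivo$animal_id,
                                               sim$invivo$region))]
  expect_equal(recovered, 15 * truth$multiplier, tolerance = 1e-9)
})

test_that("fold changes vs sham behave at the identities", {
  tab <- data.frame(dose_gy = rep(c(0, 2), each = 6),
                    timepoint = "1w",
                    value = rep(c(4, 5, 6), 4))
  f <- fold_change_vs_sham(tab, n_boot = 50, seed = 3)
  expect_equal(f$fold, 1)       # identical groups
  tab$value[tab$dose_gy == 2] <- 2 * tab$value[tab$dose_gy == 2]
  f2 <- fold_change_vs_sham(tab, n_boot = 50, seed = 3)
  expect_equal(f2$fold, 2)
  expect_error(fold_change_vs_sham(tab[tab$dose_gy > 0, ], n_boot = 10),
               "sham")
})

test_that("fold-change estimates recover a known multiplier within 15%", {
  eff <- default_effects()   # n = 12, CV 20%, week-1 doubling in adults
  folds <- vapply(1:6, function(rep_seed) {
    sim <- simulate_in_vivo_dataset(eff, ages = "adult",
                                    regions = "cerebrum", seed = 100 + rep_seed)
    curve <- fit_standard_curve(sim$standards)
    sim$invivo$value <- as.numeric(quantify_tissue(
      sim$invivo$reading, sim$invivo$tissue_mass_mg, curve))
    wk1 <- sim$invivo[sim$invivo$timepoint == "1w", ]
    mean(fold_change_vs_sham(wk1, n_boot = 100, seed = 1)$fold)
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2) / 2, 0.15)
})

test_that("bootstrap intervals are seeded and cover the point estimate", {
  tab <- data.frame(dose_gy = rep(c(0, 10), each = 8), timepoint = "1w",
                    value = c(rnorm(8, 10, 1), rnorm(8, 20, 2)))
  f1 <- fold_change_vs_sham(tab, n_boot = 500, seed = 7)
  f2 <- fold_change_vs_sham(tab, n_boot = 500, seed = 7)
  expect_identical(f1, f2)
  expect_true(f1$ci_lower < f1$fold & f1$fold < f1$ci_upper)
})
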