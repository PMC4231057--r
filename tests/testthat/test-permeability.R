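test_that("cleared volume follows the clearance formula", {
  expect_equal(compute_clearance(0, 530, 10), 0)
  expect_equal(compute_clearance(0.2, 530, 10), 10.6)
  expect_equal(compute_clearance(10, 530, 10), 530)  # full equilibration
  expect_error(compute_clearance(0.2, 530, 0), "luminal_conc")
  expect_error(compute_clearance(-1, 530, 10), ">= 0")
})

test_that("PS regression recovers exact and noisy slopes", {
  exact <- fit_ps(c(0, 20, 40, 60), c(0, 2, 4, 6))
  expect_equal(exact$slope, 0.1)
  expect_equal(exact$r2, 1)

  x <- c(0, 20, 40, 60); y <- c(0, 2.1, 3.9, 6.0)
  fit <- fit_ps(x, y)
  expect_equal(fit$slope, ols_oracle(x, y)$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, ols_oracle(x, y)$intercept, tolerance = 1e-12)

  flat <- fit_ps(c(0, 20, 40, 60), c(5, 5, 5, 5))
  expect_equal(flat$slope, 0)

  # the origin is prepended when no t = 0 sample is given
  anchored <- fit_ps(c(20, 40, 60), c(2, 4, 6))
  expect_equal(anchored$slope, 0.1)
  expect_error(fit_ps(numeric(0), numeric(0)), "distinct time points")
})

test_that("series correction obeys its algebra, bounds and limits", {
  expect_equal(correct_for_insert(1, 2), 2)
  expect_error(correct_for_insert(2, 1), "series-model violation")
  expect_error(correct_for_insert(2, 2), "series-model violation")
  expect_error(correct_for_insert(0, 2), "> 0")

  # filter limit: correction tends to the identity as ps_insert grows;
  # the exact relative excess is r/(1 - r) with r = ps_total/ps_insert
  ps_t <- 0.004
  excess <- vapply(c(0.4, 4, 400, 4e6), function(ps_f) {
    ps_e <- correct_for_insert(ps_t, ps_f)
    expect_gte(ps_e, ps_t)                       # series bound
    r <- ps_t / ps_f
    expect_lt(abs((ps_e / ps_t - 1) - r / (1 - r)), 1e-12)
    ps_e / ps_t - 1
  }, numeric(1))
  expect_true(all(diff(excess) < 0))             # vanishes in the filter limit
  expect_lt(excess[length(excess)], 1e-8)
})

test_that("Pe conversion matches the unit-conversion oracle", {
  expect_equal(compute_pe(0, 0.33), 0)
  expect_equal(compute_pe(4.158e-3, 0.33), 0.21)
  expect_equal(compute_pe(2 * 4.158e-3, 0.33), 2 * 0.21)  # linearity
  expect_error(compute_pe(1, 0), "area")
})

test_that("TEER normalization subtracts the blank after area scaling", {
  expect_equal(compute_teer(515.15, 0.33, 70)$teer, 100, tolerance = 1e-5)
  expect_equal(compute_teer(1371.5, 0.33, 70)$teer, 382.595)
  expect_equal(compute_teer(70 / 0.33, 0.33, 70)$teer, 0)
  expect_warning(res <- compute_teer(50, 0.33, 70), "clipped")
  expect_equal(res$teer, 0)
  expect_true(res$clipped)
  expect_error(compute_teer(-1), ">= 0")
})

test_that("the permeability pipeline needs both insert types", {
  kin <- default_kinetics(doses = 0, days = 1)
  sim <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 2)
  tab <- sim$permeability
  expect_error(fit_permeability(tab[!tab$cell_free, ]), "cell-free")
  expect_error(fit_permeability(tab[tab$cell_free, ]), "cell-bearing")
  expect_error(fit_permeability(tab[, c("insert_id", "tracer")]),
               "missing column")
})

test_that("the pipeline is deterministic and supports a filter override", {
  kin <- default_kinetics(doses = c(0, 2), days = c(1, 2))
  sim <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 5)
  f1 <- fit_permeability(sim$permeability)
  f2 <- fit_permeability(sim$permeability)
  expect_identical(f1$results, f2$results)

  ps_override <- f1$ps_insert * 1.05
  f3 <- fit_permeability(sim$permeability, ps_insert = ps_override)
  expect_equal(unname(f3$ps_insert), unname(ps_override))
  expect_false(isTRUE(all.equal(f1$results$pe, f3$results$pe)))
})

test_that("series-model violating inserts are flagged and excluded", {
  kin <- default_kinetics(doses = 0, days = 1)
  sim <- simulate_permeability_dataset(kin, n_inserts = 2, noise_cv = 0,
                                       seed = 6)
  tab <- sim$permeability
  # force one cell insert to out-conduct the filter
  hot <- tab$insert_id == tab$insert_id[!tab$cell_free][1]
  tab$abluminal_conc[hot] <- tab$abluminal_conc[hot] * 500
  expect_warning(fit <- fit_permeability(tab), "series model")
  expect_equal(sum(fit$results$excluded), 1)
  expect_true(all(is.na(fit$results$pe[fit$results$excluded])))
  expect_true(all(!is.na(fit$results$pe[!fit$results$excluded])))
})

test_that("clearance, PS and Pe are invariant to joint concentration scaling", {
  kin <- default_kinetics(doses = c(0, 10), days = 2)
  sim <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 10)
  tab <- sim$permeability
  scaled <- tab
  scaled$abluminal_conc <- scaled$abluminal_conc * 7.5
  scaled$luminal_conc_nominal <- scaled$luminal_conc_nominal * 7.5
  f1 <- fit_permeability(tab)
  f2 <- fit_permeability(scaled)
  expect_equal(f1$results$pe, f2$results$pe, tolerance = 1e-12)
  expect_equal(f1$ps_insert, f2$ps_insert, tolerance = 1e-12)
})

test_that("series bound holds on every fitted insert", {
  kin <- default_kinetics()
  sim <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 13)
  fit <- fit_permeability(sim$permeability)
  ok <- !fit$results$excluded
  expect_true(all(fit$results$ps_endothelial[ok] >= fit$results$ps_total[ok]))
})

test_that("mean recovered Pe at CV 10% is within 10% of truth for both tracers", {
  kin <- default_kinetics(doses = 0, days = 1)
  sim <- simulate_permeability_dataset(kin, n_inserts = 48, noise_cv = 0.1,
                                       seed = 17)
  fit <- fit_permeability(sim$permeability)
  s <- summary(fit)
  expect_equal(s$mean_pe[s$tracer == "fluorescein"], 0.21, tolerance = 0.10)
  expect_equal(s$mean_pe[s$tracer == "eb_albumin"], 0.043, tolerance = 0.10)
})

test_that("perm_fit methods expose the fitted coefficients", {
  kin <- default_kinetics(doses = 0, days = 1)
  sim <- simulate_permeability_dataset(kin, n_inserts = 3, seed = 19)
  fit <- fit_permeability(sim$permeability)
  expect_s3_class(fit, "perm_fit")
  expect_output(print(fit), "Transwell permeability fit")
  expect_length(coef(fit), nrow(fit$results))
  s <- summary(fit)
  expect_true(all(c("mean_pe", "sd_pe", "n") %in% names(s)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
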