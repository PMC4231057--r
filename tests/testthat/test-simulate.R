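test_that("all generators are bit-identical under a fixed seed", {
  kin <- default_kinetics(doses = c(0, 10), days = c(1, 2))
  eff <- default_effects()
  s1 <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 11)
  s2 <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 11)
  expect_identical(s1$permeability, s2$permeability)
  expect_identical(s1$teer, s2$teer)
  v1 <- simulate_in_vivo_dataset(eff, seed = 5)
  v2 <- simulate_in_vivo_dataset(eff, seed = 5)
  expect_identical(v1$invivo, v2$invivo)
  expect_identical(v1$standards, v2$standards)
  c1 <- simulate_count_assays(eff, seed = 9)
  c2 <- simulate_count_assays(eff, seed = 9)
  expect_identical(c1, c2)
  # and a different seed changes the draws
  s3 <- simulate_permeability_dataset(kin, n_inserts = 2, seed = 12)
  expect_false(identical(s1$permeability$abluminal_conc,
                         s3$permeability$abluminal_conc))
})

test_that("generators refuse to run without a seed", {
  kin <- default_kinetics(doses = 0, days = 1)
  eff <- default_effects()
  expect_error(simulate_permeability_dataset(kin), "seed")
  expect_error(simulate_in_vivo_dataset(eff), "seed")
  expect_error(simulate_count_assays(eff), "seed")
})

test_that("permeability table row accounting matches the design", {
  kin <- default_kinetics()   # 4 doses x 4 days x 2 tracers
  sim <- simulate_permeability_dataset(kin, n_inserts = 3, n_cell_free = 3,
                                       seed = 3)
  cell_rows <- sum(!sim$permeability$cell_free)
  expect_equal(cell_rows, 3 * 4 * 4 * 2 * 3)
  expect_equal(sum(sim$permeability$cell_free), 3 * 2 * 3)
  expect_equal(nrow(sim$teer), 3 * 4 * 4)
})

test_that("noise-free simulated plates invert to the true Pe within 1%", {
  kin <- default_kinetics()
  sim <- simulate_permeability_dataset(kin, n_inserts = 1, n_cell_free = 1,
                                       noise_cv = 0, seed = 1)
  fit <- fit_permeability(sim$permeability)
  res <- merge(fit$results, kin$pe_endothelial,
               by = c("tracer", "dose_gy", "day"),
               suffixes = c("", "_true"))
  expect_equal(nrow(res), nrow(fit$results))
  expect_true(all(abs(res$pe / res$pe_true - 1) < 0.01))
})

test_that("null in vivo effects give fold-changes near one", {
  eff <- default_effects()
  eff$multipliers$multiplier[eff$multipliers$endpoint == "evans_blue"] <- 1
  sim <- simulate_in_vivo_dataset(eff, ages = "adult", seed = 21)
  curve <- fit_standard_curve(sim$standards)
  sim$invivo$value <- as.numeric(quantify_tissue(
    sim$invivo$reading, sim$invivo$tissue_mass_mg, curve))
  folds <- fold_change_vs_sham(sim$invivo, n_boot = 200, seed = 2)
  expect_true(all(abs(folds$fold - 1) < 0.35))
  expect_lt(abs(mean(folds$fold) - 1), 0.1)
})

test_that("a two-fold in vivo multiplier is recovered downstream", {
  eff <- default_effects()
  sim <- simulate_in_vivo_dataset(eff, ages = "adult", seed = 31)
  curve <- fit_standard_curve(sim$standards)
  sim$invivo$value <- as.numeric(quantify_tissue(
    sim$invivo$reading, sim$invivo$tissue_mass_mg, curve))
  wk1 <- sim$invivo[sim$invivo$timepoint == "1w", ]
  folds <- fold_change_vs_sham(wk1, n_boot = 200, seed = 2)
  expect_lt(abs(mean(folds$fold) - 2), 0.3)
})

test_that("count assay distributions follow their sampling models", {
  eff <- default_effects()
  # zero colony rate -> all colony counts zero
  eff0 <- eff
  eff0$baseline[["cep"]] <- 1e-12
  cnt0 <- simulate_count_assays(eff0, seed = 4)
  expect_true(all(cnt0$numerator[cnt0$assay == "cep"] == 0))

  # binomial expectation: p = 0.25 x 1.4 over many coverslips -> 0.35
  eff2 <- eff
  eff2$group_sizes[["senescence"]] <- 400
  cnt <- simulate_count_assays(eff2, seed = 8)
  sen <- cnt[cnt$assay == "senescence" & cnt$dose_gy == 10, ]
  expect_equal(nrow(sen), 400)
  expect_true(all(sen$denominator >= 400 & sen$denominator <= 500))
  expect_equal(mean(sen$numerator / sen$denominator), 0.35, tolerance = 0.01)

  # impossible probability is a configuration error
  eff_bad <- eff
  eff_bad$baseline[["senescence"]] <- 0.9
  expect_error(simulate_count_assays(eff_bad, seed = 1), "exceeds 1")
})

test_that("missing effect-model cells raise a configuration error", {
  eff <- default_effects()
  keep <- !(eff$multipliers$endpoint == "evans_blue" &
              eff$multipliers$timepoint == "4w" &
              eff$multipliers$dose_gy == 2 &
              eff$multipliers$age_group == "adult")
  eff$multipliers <- eff$multipliers[keep, ]
  expect_error(simulate_in_vivo_dataset(eff, ages = "adult", seed = 1),
               "multiplier missing")
})

test_that("effect model validates its invariants", {
  eff <- default_effects()
  bad <- eff$multipliers
  bad$multiplier[1] <- -1
  expect_error(effect_model(eff$baseline, bad, eff$noise_cv,
                            eff$group_sizes), "> 0")
  expect_error(effect_model(eff$baseline, eff$multipliers, eff$noise_cv,
                            c(evans_blue = 1)), ">= 2")
})
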