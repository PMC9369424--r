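test_that("the generator is fully deterministic in its seed", {
  cfg <- cci_config(seed = 99)
  r1 <- simulate_cci_study(cfg)
  r2 <- simulate_cci_study(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_behavior_records(r1, p1)
  write_behavior_records(r2, p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical CSV
  r3 <- simulate_cci_study(cci_config(seed = 100))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("emitted raw values respect the assay bounds", {
  recs <- simulate_cci_study(cci_config(seed = 8, noise_sd = 25))
  pwt <- recs[recs$assay == "mechanical_pwt", ]
  expect_true(all(pwt$pre_drug >= 0.2 & pwt$pre_drug <= 6.84))
  expect_true(all(pwt$post_drug >= 0.2 & pwt$post_drug <= 6.84))
  ac <- recs[recs$assay == "acetone", ]
  expect_true(all(ac$post_drug >= 0 & ac$post_drug == round(ac$post_drug)))
  expect_true(all(ac$pre_drug >= 1))
  expect_true(all(recs$post_drug[recs$assay == "rotarod"] <= 300))
  expect_true(all(recs$post_drug[recs$assay == "bar"] <= 120))
  of <- recs[recs$assay == "open_field", ]
  expect_true(all(of$post_drug >= 0 & of$post_drug == round(of$post_drug)))
})

test_that("the study design is mirrored: group sizes, doses, one arm per animal", {
  cfg <- cci_config(seed = 4, assays = c("mechanical_pwt", "acetone"))
  recs <- simulate_cci_study(cfg)
  per_animal <- dplyr::distinct(recs, .data$animal_id, .data$group,
                                .data$drug_a_dose_nmol, .data$drug_b_dose_nmol)
  expect_equal(nrow(per_animal), dplyr::n_distinct(recs$animal_id))
  counts <- dplyr::count(per_animal, .data$group,
                         total = .data$drug_a_dose_nmol + .data$drug_b_dose_nmol)
  expect_true(all(counts$n == cfg$n_per_group))
  expect_setequal(counts$total[counts$group == "THC"], cfg$doses)
  comb <- per_animal[per_animal$group == "THC:CBD", ]
  expect_equal(comb$drug_a_dose_nmol, comb$drug_b_dose_nmol) # 1:1 ray
})

test_that("noiseless generation closes the loop: fits recover the truth", {
  cfg <- cci_config(seed = 1, noise_sd = 0, assays = "mechanical_pwt")
  recs <- simulate_cci_study(cfg)
  thc <- fit_hill(mpe_dose_response(recs, "mechanical_pwt", group = "THC"))
  cbd <- fit_hill(mpe_dose_response(recs, "mechanical_pwt", group = "CBD"))
  tr <- cfg$truth$mechanical_pwt
  expect_equal(c(thc$emax, thc$ed50, thc$hill), unname(tr$thc), tolerance = 1e-4)
  expect_equal(c(cbd$emax, cbd$ed50, cbd$hill), unname(tr$cbd), tolerance = 1e-4)
  res <- run_combination(recs, "mechanical_pwt")
  expect_equal(res$experimental$ed50, res$predicted$ed50, tolerance = 1e-2)
  expect_identical(res$synergy$verdict, "additive")
})

test_that("normalizing generated records returns the latent effect up to clipping", {
  cfg <- cci_config(seed = 12, noise_sd = 0, assays = "mechanical_pwt",
                    timepoints = 1)
  recs <- simulate_cci_study(cfg)
  thc <- recs[recs$group == "THC" & recs$drug_b_dose_nmol == 56, ]
  latent <- hill_effect(56, 85, 14, 2.6)
  expect_equal(add_mpe(thc)$mpe, rep(latent, nrow(thc)), tolerance = 1e-9)
})

test_that("a synergistic truth shifts the combination left of the additive prediction", {
  recs <- simulate_cci_study(cci_config(seed = 6, assays = "mechanical_pwt",
                                        interaction_shift = 0.5, noise_sd = 0))
  res <- run_combination(recs, "mechanical_pwt")
  expect_lt(res$experimental$ed50, res$predicted$ed50)
  expect_equal(res$experimental$ed50, res$predicted$ed50 * 0.5, tolerance = 0.05)
})

test_that("vehicle stability reflects the generator's zero-effect contract", {
  noiseless <- simulate_cci_study(cci_config(seed = 3, noise_sd = 0,
                                             assays = "mechanical_pwt"))
  veh <- add_mpe(noiseless)
  veh <- veh$mpe[veh$group == "vehicle"]
  expect_equal(veh, rep(0, length(veh))) # exactly zero without noise
  expect_true(vehicle_stability_check(noiseless))
  noisy <- simulate_cci_study(cci_config(seed = 3, assays = "mechanical_pwt"))
  expect_true(vehicle_stability_check(noisy))
  shifted <- simulate_cci_study(cci_config(seed = 3, n_per_group = 40,
                                           assays = "mechanical_pwt",
                                           vehicle_shift = 30))
  expect_false(vehicle_stability_check(shifted))
})

test_that("allodynia is present: post-CCI baselines sit below healthy levels", {
  recs <- simulate_cci_study(cci_config(seed = 10))
  pre_cci <- attr(recs, "pre_cci")
  m <- dplyr::inner_join(
    dplyr::distinct(recs, .data$animal_id, .data$assay, .data$pre_drug),
    pre_cci, by = c("animal_id", "assay")
  )
  pwt <- m[m$assay == "mechanical_pwt", ]
  expect_lt(mean(pwt$pre_drug), mean(pwt$pre_cci)) # thresholds drop after CCI
  ac <- m[m$assay == "acetone", ]
  expect_gt(mean(ac$pre_drug), mean(ac$pre_cci)) # cold responses increase
})

test_that("invalid configurations are rejected up front", {
  expect_error(cci_config(n_per_group = 1))
  expect_error(cci_config(interaction_shift = 0))
  expect_error(cci_config(doses = c(0, 10)))
  expect_error(cci_config(ratio = c(0.6, 0.6)))
  bad <- default_baselines()
  bad$mechanical_pwt["pre_drug_mean"] <- 7.2
  expect_error(cci_config(baselines = bad), "cut-off")
})

test_that("the Poisson acetone mode still yields fit-recoverable structure", {
  recs <- simulate_cci_study(cci_config(seed = 5, assays = "acetone",
                                        acetone_mode = "poisson"))
  fit <- fit_hill(mpe_dose_response(recs, "acetone", group = "THC"))
  expect_gt(fit$emax, 30)
  expect_lt(abs(log(fit$ed50 / 21)), log(2.5)) # within 2.5-fold of truth
})
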