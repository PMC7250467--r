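# Prediction assembly, least-squares fitting, RMSE, parameter round trip.

test_that("zero weights reduce predictions to the random-coil baseline", {
  p <- default_params_cached()
  for (nuc in c("CA", "CB", "C", "HN", "N", "HA"))
    p$weights[[nuc]] <- list(contact = 0, hbond = 0, ani = 0, ring = 0,
                             dihedral = 0)
  st <- build_peptide("AFKEW", c(-57, -47))
  tab <- predict_shifts(st, params = p, mode = "batched")
  rc <- vapply(seq_len(nrow(tab)), function(i)
    p$random_coil[[tab$res_name[i]]][[tab$nucleus[i]]], numeric(1))
  expect_equal(tab$shift_ppm, rc)
})

test_that("prediction is affine in any single weight", {
  p <- default_params_cached()
  st <- build_peptide("AAFAAA", c(-57, -47))
  sel <- clear_protons(get_select(st), st)
  d <- compute_descriptors(st, sel, p, "batched")
  t0 <- predict_shifts(st, sel, p, "batched")
  delta <- 0.37
  p2 <- p
  p2$weights$CA$contact <- p$weights$CA$contact + delta
  t1 <- predict_shifts(st, sel, p2, "batched")
  ca <- t0$nucleus == "CA"
  dca <- d$contact[match(t0$atom[ca], d$atom)]
  expect_equal(t1$shift_ppm[ca] - t0$shift_ppm[ca], delta * dca,
               tolerance = 1e-9)
  expect_equal(t1$shift_ppm[!ca], t0$shift_ppm[!ca])
})

test_that("reference and batched predictions agree row by row", {
  st <- build_peptide(strrep("AFKEW", 4), c(-57, -47))
  sel <- clear_protons(get_select(st), st)
  p <- default_params_cached()
  tr <- predict_shifts(st, sel, p, "reference")
  tb <- predict_shifts(st, sel, p, "batched")
  expect_equal(tb$shift_ppm, tr$shift_ppm, tolerance = 1e-10)
  expect_identical(tb[, c("chain", "res_seq", "nucleus")],
                   tr[, c("chain", "res_seq", "nucleus")])
})

test_that("rmse_shifts implements the RMSE formula and max error", {
  st <- helix10()
  tab <- predict_shifts(st, params = default_params_cached(),
                        mode = "batched")
  expect_equal(rmse_shifts(tab, tab, "CA")$rmse, 0)
  # constant residual c -> RMSE = |c|
  shifted <- tab
  shifted$shift_ppm <- shifted$shift_ppm - 0.7
  r <- rmse_shifts(tab, shifted, "CA")
  expect_equal(r$rmse, 0.7, tolerance = 1e-12)
  expect_equal(r$max_error, 0.7, tolerance = 1e-12)
  # hand-computed residual vector (1, 2, 2) -> sqrt(3)
  pred <- data.frame(chain = "A", res_seq = 1:3, res_name = "ALA",
                     nucleus = "CA", shift_ppm = c(1, 2, 2))
  obs <- data.frame(chain = "A", res_seq = 1:3, res_name = "ALA",
                    nucleus = "CA", shift_ppm = c(0, 0, 0))
  r2 <- rmse_shifts(pred, obs, "CA")
  expect_equal(r2$rmse, sqrt(3), tolerance = 1e-12)
  expect_equal(r2$max_error, 2)
  expect_lte(r2$rmse, r2$max_error)
  expect_error(rmse_shifts(pred, obs[obs$res_seq > 10, ], "CA"),
               "empty comparison")
})

test_that("fit recovers generating weights exactly from noise-free data", {
  base <- default_params_cached()
  for (nuc in names(base$fourier))
    base$fourier[[nuc]] <- list(phi = c(0.5, -0.2, 0.1, 0.3, 0, 0),
                                psi = c(-0.4, 0.1, 0, 0.2, 0, 0))
  truth <- base
  w_true <- list(contact = 0.3, hbond = -2.0, ani = 1.5, ring = 4.0,
                 dihedral = 0.8)
  for (nuc in names(truth$weights)) truth$weights[[nuc]] <- w_true
  sts <- build_validation_set(3, 40, seed = 17)
  training <- lapply(sts, function(s)
    list(structure = s, observed = predict_shifts(s, NULL, truth, "batched")))
  fitted <- fit_parameters(training, base)
  for (nuc in c("HN", "HA")) # protons exercise every family
    for (fam in names(w_true))
      expect_equal(fitted$weights[[nuc]][[fam]], w_true[[fam]],
                   tolerance = 1e-8)
  for (nuc in c("CA", "N"))  # heavy nuclei have no anisotropy column
    for (fam in c("contact", "hbond", "ring", "dihedral"))
      expect_equal(fitted$weights[[nuc]][[fam]], w_true[[fam]],
                   tolerance = 1e-8)
  expect_true(all(attr(fitted, "training_rmse") < 1e-8))
})

test_that("fit recovers weights within 3 standard errors under noise", {
  base <- default_params_cached()
  for (nuc in names(base$fourier))
    base$fourier[[nuc]] <- list(phi = c(0.5, -0.2, 0.1, 0.3, 0, 0),
                                psi = c(-0.4, 0.1, 0, 0.2, 0, 0))
  truth <- base
  w_true <- list(contact = 0.3, hbond = -2.0, ani = 1.5, ring = 4.0,
                 dihedral = 0.8)
  for (nuc in names(truth$weights)) truth$weights[[nuc]] <- w_true
  sts <- build_validation_set(5, 50, seed = 23)
  set.seed(23)
  training <- lapply(sts, function(s) {
    obs <- predict_shifts(s, NULL, truth, "batched")
    obs$shift_ppm <- obs$shift_ppm + rnorm(nrow(obs), 0, 0.1)
    list(structure = s, observed = obs)
  })
  fitted <- fit_parameters(training, base)
  info <- attr(fitted, "fit")
  for (nuc in c("CA", "HN")) {
    tab <- info[[nuc]]
    for (k in seq_len(nrow(tab))) {
      fam <- tab$term[k]
      expect_lt(abs(tab$estimate[k] - w_true[[fam]]),
                3 * tab$std_error[k] + 1e-12)
    }
  }
})

test_that("under-determined fits fail naming the nucleus", {
  base <- default_params_cached()
  st <- build_peptide("AA", c(-57, -47))
  obs <- predict_shifts(st, NULL, base, "batched")
  obs <- obs[obs$nucleus == "CA", ][1, ]
  expect_error(
    fit_parameters(list(list(structure = st, observed = obs)), base),
    "under-determined.*CA")
})

test_that("parameter files round-trip losslessly through YAML", {
  p <- default_params_cached()
  p$weights$CA$contact <- 0.123456789012345
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  back <- read_params(f)
  expect_equal(back$weights, p$weights, tolerance = 1e-15)
  expect_equal(back$random_coil, p$random_coil)
  expect_equal(back$cutoffs, p$cutoffs)
  expect_equal(back$fourier, p$fourier)
  # identical predictions from the round-tripped set
  st <- build_peptide("AFA", c(-57, -47))
  expect_equal(predict_shifts(st, NULL, back, "batched")$shift_ppm,
               predict_shifts(st, NULL, p, "batched")$shift_ppm)
})
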