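test_that("the weighted combined CSP matches hand evaluation", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.1, 0), 0.1)
  # oracle: sqrt(0.03^2 + (0.2 * 0.154)^2)
  expect_equal(combined_csp(0.03, 0.2), sqrt(0.03^2 + (0.2 * 0.154)^2),
               tolerance = 1e-12)
  expect_equal(combined_csp(0.03, 0.2), 0.0430, tolerance = 1e-4 / 0.043)
  # symmetric in the sign of either component
  expect_equal(combined_csp(-0.03, 0.2), combined_csp(0.03, -0.2))
  expect_error(combined_csp(NA, 1), class = "dynsel_invalid_argument")
})

test_that("the depletion isotherm matches hand evaluation and its limits", {
  # oracle: 0.1 * (3.1 - sqrt(3.1^2 - 4)) / (2 * 0.5)
  byhand <- 0.1 * (3.1 - sqrt(3.1^2 - 4 * 0.5 * 2)) / (2 * 0.5)
  expect_equal(isotherm_csp(0.5, 2.0, 0.6, 0.1), byhand, tolerance = 1e-12)
  expect_equal(isotherm_csp(0.5, 2.0, 0.6, 0.1), 0.07315, tolerance = 1e-5 / 0.073)

  expect_equal(isotherm_csp(0.5, 0, 0.6, 0.1), 0)
  sat <- isotherm_csp(0.5, 1e6 * 0.6, 0.6, 0.1)
  expect_lt(abs(sat - 0.1) / 0.1, 1e-3)

  expect_error(isotherm_csp(0, 1, 1, 1), class = "dynsel_invalid_argument")
  expect_error(isotherm_csp(1, -1, 1, 1), class = "dynsel_invalid_argument")
})

test_that("the isotherm is monotone in L and decreasing in KD", {
  L <- seq(0, 40, by = 0.5)
  for (P in c(0.4, 0.7)) {
    for (kd in c(0.1, 0.6, 2.8, 14)) {
      csp <- isotherm_csp(P, L, kd, 1)
      expect_true(all(diff(csp) > 0))
      expect_true(all(csp >= 0 & csp <= 1))
    }
    # dCSP/dKD < 0 at fixed L > 0
    for (l in c(0.5, 2, 8)) {
      grid <- vapply(c(0.1, 0.3, 1, 3, 10), function(kd)
        isotherm_csp(P, l, kd, 1), 0)
      expect_true(all(diff(grid) < 0))
    }
  }
})

test_that("the weak-binding regime reduces to the hyperbolic form", {
  # for KD >= 20 P the depletion solution tracks L / (L + KD) to within
  # 1% of the saturation amplitude
  L <- seq(0, 50, by = 0.25)
  for (P in c(0.4, 0.5, 0.7)) {
    kd <- 20 * P
    expect_lt(max(abs(isotherm_csp(P, L, kd, 1) - L / (L + kd))), 0.01)
  }
})

test_that("binder selection applies a strict threshold on the grid", {
  truth <- quick_truth(n_bind = 5, n_null = 5)
  set <- simulate_titration_set(truth, 2)
  expect_identical(sort(select_binders(set, 2, 0.05)), paste0("r", 1:5))

  # residue sitting exactly at the threshold is excluded
  csp_at <- combined_csp(0.05, 0)
  one <- structure(list(P = 0.5, L = c(0, 1, 2),
                        data = data.frame(residue = "r1",
                                          ligand_mM = c(0, 1, 2),
                                          ddH_ppm = c(0, 0.03, 0.05),
                                          ddN_ppm = 0)),
                   class = "titration_set")
  expect_length(select_binders(one, 2, threshold = csp_at), 0)
  expect_identical(select_binders(one, 2, threshold = csp_at - 1e-9), "r1")

  expect_error(select_binders(set, at_ligand = 3), class = "dynsel_invalid_argument")

  empty <- simulate_titration_set(quick_truth(n_bind = 0, n_null = 4), 1)
  expect_length(select_binders(empty, 2), 0)
})

test_that("noiseless global fits recover planted KD and amplitudes exactly", {
  for (kd in c(0.1, 0.3, 0.6, 2.8, 14, 20)) {
    truth <- quick_truth(kd = kd, n_bind = 10, n_null = 0, noise = 0,
                         seed = round(kd * 10) + 1)
    set <- simulate_titration_set(truth, 7)
    fit <- fit_global(set, names(truth$delta0))
    expect_lt(abs(fit$kd - kd) / kd, 1e-4)
    expect_lt(max(abs(fit$delta0 - truth$delta0) / truth$delta0), 1e-4)
    expect_lt(fit$convergence$deviance, 1e-16)
  }
})

test_that("fits under realistic noise stay accurate and report uncertainty", {
  truth <- quick_truth(kd = 0.6, n_bind = 10, n_null = 0,
                       noise = 0.02 * 0.4, seed = 77,
                       L = c(0, 0.25, 0.5, 1, 2, 4, 8, 16))
  set <- simulate_titration_set(truth, 123)
  fit <- fit_global(set, names(truth$delta0), n_boot = 50, boot_seed = 9)
  expect_lt(abs(fit$kd - 0.6) / 0.6, 0.25)
  expect_gt(fit$kd_se, 0)
  expect_gt(fit$kd_se_boot, 0)
  # the two uncertainty estimators agree in order of magnitude
  expect_lt(abs(log10(fit$kd_se / fit$kd_se_boot)), 1)
})

test_that("underdetermined designs are rejected", {
  truth <- quick_truth(n_bind = 1, n_null = 0, L = c(0, 1, 2))
  set <- simulate_titration_set(truth, 3)
  set$data <- set$data[set$data$ligand_mM < 2, ]
  set$L <- c(0, 1)
  expect_error(fit_global(set, "r1"), class = "dynsel_invalid_argument")
  expect_error(fit_global(simulate_titration_set(truth, 3), character(0)),
               class = "dynsel_invalid_argument")
  expect_error(fit_global(simulate_titration_set(truth, 3), c("r1", "zz")),
               class = "dynsel_invalid_argument")
})

test_that("display normalisation reproduces the single master curve", {
  truth <- quick_truth(kd = 1.2, n_bind = 6, n_null = 0, noise = 0)
  set <- simulate_titration_set(truth, 11)
  fit <- fit_global(set, names(truth$delta0))
  norm <- normalize_for_plot(fit)

  # noiseless normalised points lie on the fitted unit-amplitude curve
  expected <- isotherm_csp(set$P, norm$points$ligand_mM, fit$kd, 1)
  expect_equal(norm$points$mean_norm_csp, expected, tolerance = 1e-9)
  expect_lt(max(norm$points$sd), 1e-10)

  # the curve saturates at 1
  expect_lt(abs(isotherm_csp(set$P, 1e6 * fit$kd, fit$kd, 1) - 1), 1e-3)

  # sd equals the population sd of the per-residue normalised values
  noisy <- simulate_titration_set(quick_truth(kd = 1.2, n_bind = 6, n_null = 0,
                                              noise = 0.005), 13)
  nfit <- fit_global(noisy, paste0("r", 1:6))
  nn <- normalize_for_plot(nfit)
  at <- nn$points$ligand_mM[4]
  rows <- nfit$data[nfit$data$ligand_mM == at, ]
  vals <- rows$csp / nfit$delta0[rows$residue]
  expect_equal(nn$points$sd[4], sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)

  # zero-amplitude residues are excluded from the display with a warning
  truth0 <- quick_truth(kd = 1.2, n_bind = 3, n_null = 1, noise = 0)
  set0 <- simulate_titration_set(truth0, 5)
  fit0 <- fit_global(set0, names(truth0$delta0))
  expect_warning(normalize_for_plot(fit0), "zero saturation")
})
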