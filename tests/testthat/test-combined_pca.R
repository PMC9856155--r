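# Small aligned trajectory used for the brute-force oracle comparisons.
oracle_traj <- function(n_atoms = 5, frames = 10, seed = 4) {
  set.seed(seed)
  X <- matrix(rnorm(frames * 3 * n_atoms, sd = 2), frames)
  tr <- trajectory(data.frame(chain = "A", resid = seq_len(n_atoms), name = "CA"),
                   X, system = rep(c("s1", "s2"), length.out = frames))
  tr$aligned <- TRUE   # oracle comparison needs the raw coordinates untouched
  tr
}

test_that("PCA requires an aligned trajectory and handles zero variance", {
  tr <- oracle_traj()
  tr$aligned <- FALSE
  expect_error(fit_pca(tr), class = "dynsel_state_error")

  flat <- trajectory(data.frame(chain = "A", resid = 1:4, name = "CA"),
                     matrix(rep(rnorm(12), each = 6), 6, byrow = FALSE),
                     aligned = TRUE)
  flat$xyz <- matrix(rep(rnorm(12), 6), 6, byrow = TRUE)
  model <- fit_pca(flat)
  expect_true(all(model$lambda < 1e-20))
})

test_that("eigenpairs match a brute-force dense covariance eigendecomposition", {
  tr <- oracle_traj(5, 10)
  model <- fit_pca(tr)

  # independent oracle: explicit covariance assembly + dense eigensolve
  C <- sweep(tr$xyz, 2, colMeans(tr$xyz))
  cov <- crossprod(C) / nrow(C)
  eig <- eigen(cov, symmetric = TRUE)
  k <- min(nrow(tr$xyz) - 1, ncol(tr$xyz))
  expect_equal(model$lambda[1:k], eig$values[1:k], tolerance = 1e-8)

  # eigenvalue sum equals the total coordinate variance
  expect_equal(sum(model$lambda), model$total_var, tolerance = 1e-8)
  expect_equal(sum(model$lambda), sum(diag(cov)), tolerance = 1e-8)

  # |projections| agree with the oracle basis (signs are conventions)
  p_mine <- abs(C %*% model$vectors[, 1:3])
  p_orac <- abs(C %*% eig$vectors[, 1:3])
  expect_equal(p_mine, p_orac, tolerance = 1e-8, ignore_attr = TRUE)

  # orthonormality of the returned eigenvectors
  expect_lt(max(abs(crossprod(model$vectors) - diag(ncol(model$vectors)))), 1e-8)
})

test_that("projections satisfy the PCA identities", {
  tr <- oracle_traj(6, 20)
  model <- fit_pca(tr)
  series <- project_trajectory(tr, model, 1:5)

  # combined projections have zero mean and variance lambda on each PC
  for (pc in 1:5) {
    p <- series$projection[series$pc == pc]
    expect_lt(abs(mean(p)), 1e-8)
    expect_equal(mean(p^2), model$lambda[pc], tolerance = 1e-8)
  }

  # the mean structure projects to zero everywhere
  mean_tr <- trajectory(tr$atoms, matrix(model$mean, 1), aligned = TRUE)
  pm <- project_trajectory(mean_tr, model, 1:5)
  expect_lt(max(abs(pm$projection)), 1e-10)

  # a frame displaced along v_3 projects to its displacement on PC 3 only
  shifted <- trajectory(tr$atoms,
                        matrix(model$mean + 2.5 * model$vectors[, 3], 1),
                        aligned = TRUE)
  ps <- project_trajectory(shifted, model, 1:5)
  expect_equal(ps$projection[ps$pc == 3], 2.5, tolerance = 1e-10)
  expect_lt(max(abs(ps$projection[ps$pc != 3])), 1e-10)

  expect_error(project_trajectory(oracle_traj(4), model),
               class = "dynsel_invalid_argument")
  expect_error(project_trajectory(tr, model, pcs = 999),
               class = "dynsel_invalid_argument")
})

test_that("per-system statistics use the system's own mean", {
  series <- data.frame(frame = 1:2, system = "s", pc = 1L,
                       projection = c(1, -1))
  class(series) <- c("projection_series", "data.frame")
  st <- system_stats(series)
  expect_equal(st$avg_proj, 0)
  expect_equal(st$rmsf, 1)   # population sd of {1, -1}

  # frame-weighted mean of per-system averages vanishes (combined mean)
  tr <- oracle_traj(6, 30)
  model <- fit_pca(tr)
  s <- project_trajectory(tr, model, 1:3)
  st <- system_stats(s)
  counts <- table(tr$system)[st$system[st$pc == 1]]
  for (pc in 1:3) {
    w <- st$avg_proj[st$pc == pc] * as.numeric(counts)
    expect_lt(abs(sum(w) / sum(counts)), 1e-8)
  }
})

test_that("pseudo-trajectories are straight lines over the observed span", {
  tr <- oracle_traj(5, 12)
  model <- fit_pca(tr)

  two <- pseudo_trajectory(model, 1, n_frames = 2)
  s <- attr(two, "s")
  expect_equal(n_frames(two), 2)
  expect_equal(s, unname(model$proj_range[1, ]), ignore_attr = TRUE)

  # observed span equals [min, max] of the concatenated projections
  series <- project_trajectory(tr, model, 1)
  expect_equal(min(series$projection), s[1], tolerance = 1e-10)
  expect_equal(max(series$projection), s[2], tolerance = 1e-10)

  # each pseudo-frame re-projects to its own s_j, and to 0 off-mode
  ps <- pseudo_trajectory(model, 2, n_frames = 7)
  pr <- project_trajectory(ps, model, 1:4)
  expect_equal(pr$projection[pr$pc == 2], attr(ps, "s"), tolerance = 1e-9)
  expect_lt(max(abs(pr$projection[pr$pc != 2])), 1e-9)

  # sigma span is symmetric about the mean
  sg <- pseudo_trajectory(model, 1, n_frames = 5, span = "sigma", k = 2)
  expect_equal(attr(sg, "s")[1], -2 * sqrt(model$lambda[1]), tolerance = 1e-10)

  # zero-variance PC has no observed span
  flat <- trajectory(tr$atoms, matrix(rep(rnorm(15), 4), 4, byrow = TRUE),
                     aligned = TRUE)
  fmodel <- fit_pca(flat)
  expect_error(pseudo_trajectory(fmodel, 1), class = "dynsel_degenerate_span")
})

test_that("residue r.m.s.f. within a mode is normalised and localised", {
  tr <- oracle_traj(8, 15)
  model <- fit_pca(tr)
  for (pc in 1:3) {
    r <- residue_rmsf_in_mode(model, pc)
    expect_length(r, 8)
    expect_equal(sum(r^2) / model$lambda[pc], 1, tolerance = 1e-10)
  }

  # a planted smooth mode concentrates r.m.s.f. on its largest components
  st <- tiny_structure(40)
  m <- tiny_modes(st, n_modes = 1, seed = 9,
                  systems = list(X = list(mu = 0, amp = 2)))
  sim <- simulate_system_trajectory(st, m, "X", 800, 13)
  sim$aligned <- TRUE   # planted modes are internal; no rigid drift to remove
  pmodel <- fit_pca(sim)
  got <- residue_rmsf_in_mode(pmodel, 1)
  planted <- sqrt(rowSums(matrix(m$vectors[, 1], ncol = 3, byrow = TRUE)^2))
  expect_gt(cor(got, planted, method = "spearman"), 0.95)
})

test_that("pca models persist as plain text", {
  tr <- oracle_traj(5, 10)
  model <- fit_pca(tr)
  prefix <- withr::local_tempfile()
  paths <- write_pca_model(model, prefix, n_pcs = 3)
  expect_true(all(file.exists(paths)))
  ev <- read.delim(paths[1])
  expect_equal(ev$lambda_A2, model$lambda[1:3], tolerance = 1e-6)
})
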