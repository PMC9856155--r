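#' Generate a compact self-avoiding C-alpha scaffold
#'
#' Builds one or more identical C-alpha-only chains as self-avoiding
#' random walks with 3.8 Angstrom steps, compacted by a radius-of-gyration
#' cap so the fold has protein-like dimensions.  Chains are identical
#' copies related by a rigid translation (a toy homodimer).
#'
#' @param n_residues_per_chain Residues per chain (>= 4).
#' @param n_chains Number of chains (>= 1).
#' @param seed Integer seed; output is bitwise reproducible per seed.
#' @return A `toy_structure`: list with `atoms` (chain, resid, name,
#'   element) and `xyz` (n x 3 matrix, Angstrom).
#' @export
make_toy_structure <- function(n_residues_per_chain, n_chains, seed) {
  if (!is.numeric(n_residues_per_chain) || n_residues_per_chain < 4 ||
      !is.numeric(n_chains) || n_chains < 1) {
    abort_invalid("need n_residues_per_chain >= 4 and n_chains >= 1")
  }
  n <- as.integer(n_residues_per_chain)
  step <- 3.8          # Calpha-Calpha virtual bond, Angstrom
  clash <- 3.0         # minimum non-bonded Calpha separation
  r_cap <- max(12, 3.2 * n^(1/3) * 1.3)   # compactness cap on |r|
  chain_xyz <- with_seed(seed, {
    for (attempt in 1:100) {
      xyz <- matrix(NA_real_, n, 3L)
      xyz[1L, ] <- 0
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:500) {
          dir <- stats::rnorm(3)
          cand <- xyz[i - 1L, ] + step * dir / sqrt(sum(dir^2))
          if (sqrt(sum(cand^2)) > r_cap) next
          if (i > 2L) {
            d2 <- rowSums(sweep(xyz[1:(i - 2L), , drop = FALSE], 2L, cand)^2)
            if (min(d2) < clash^2) next
          }
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) abort_invalid("failed to generate a self-avoiding chain; try another seed")
    xyz
  })
  offset <- 2 * r_cap + 10
  xyz <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    sweep(chain_xyz, 2L, -c(offset * (c - 1L), 0, 0))
  }))
  atoms <- data.frame(
    chain = rep(LETTERS[seq_len(n_chains)], each = n),
    resid = rep(seq_len(n), n_chains),
    name = "CA",
    element = "C",
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, xyz = xyz), class = "toy_structure")
}

rigid_body_basis <- function(xyz) {
  n <- nrow(xyz)
  cen <- sweep(xyz, 2L, colMeans(xyz))
  basis <- matrix(0, 3L * n, 6L)
  for (a in 1:3) basis[seq(a, 3L * n, by = 3L), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(cen, 1L, function(r) c(
      axes[a, 2] * r[3] - axes[a, 3] * r[2],
      axes[a, 3] * r[1] - axes[a, 1] * r[3],
      axes[a, 1] * r[2] - axes[a, 2] * r[1]
    )))
    basis[, 3L + a] <- as.numeric(t(rot))
  }
  qr.Q(qr(basis))
}

#' Plant an orthonormal set of smooth collective modes
#'
#' Draws random displacement fields with low-frequency spatial correlation
#' along the chain (sums of the first few chain harmonics), projects out
#' the six rigid-body degrees of freedom (so the planted motions are
#' internal and survive superposition), and Gram-Schmidt-orthonormalises
#' the result.  Per-system mean displacements and amplitudes are attached
#' afterwards with [set_system_modes()].
#'
#' @param structure A `toy_structure` (typically a single subunit).
#' @param n_modes Number of modes (<= 3N - 6).
#' @param seed Integer seed.
#' @param sigma_noise Isotropic coordinate noise sd (Angstrom) used by
#'   [simulate_system_trajectory()].
#' @return A `mode_set`: `vectors` (3N x K, orthonormal columns),
#'   `n_atoms`, `sigma_noise` and an initially empty `params` list.
#' @export
make_mode_set <- function(structure, n_modes, seed, sigma_noise = 0) {
  n <- nrow(structure$atoms)
  if (n_modes > 3L * n - 6L || n_modes < 1L) {
    abort_invalid(sprintf("n_modes must be in [1, %d] for %d atoms", 3L * n - 6L, n))
  }
  rigid <- rigid_body_basis(structure$xyz)
  vecs <- with_seed(seed, {
    V <- matrix(0, 3L * n, n_modes)
    got <- 0L
    idx <- seq_len(n)
    harmonics <- 1:4
    while (got < n_modes) {
      raw <- matrix(0, n, 3L)
      for (ax in 1:3) {
        for (h in harmonics) {
          ph <- pi * h * (idx - 1L) / max(1L, n - 1L)
          raw[, ax] <- raw[, ax] + stats::rnorm(1) * cos(ph) + stats::rnorm(1) * sin(ph)
        }
      }
      v <- as.numeric(t(raw))
      v <- v - rigid %*% crossprod(rigid, v)
      if (got > 0L) {
        W <- V[, seq_len(got), drop = FALSE]
        v <- v - W %*% crossprod(W, v)
      }
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) next
      got <- got + 1L
      V[, got] <- v / nv
    }
    V
  })
  structure(
    list(vectors = vecs, n_atoms = n, sigma_noise = sigma_noise,
         params = list()),
    class = "mode_set"
  )
}

#' Attach per-system mode statistics to a mode set
#'
#' @param modes A `mode_set`.
#' @param system System tag.
#' @param mu Planted mean displacement per mode (Angstrom), length K.
#' @param amp Planted fluctuation amplitude per mode (Angstrom), length K.
#' @return The updated `mode_set`.
#' @export
set_system_modes <- function(modes, system, mu, amp) {
  k <- ncol(modes$vectors)
  if (length(mu) != k || length(amp) != k) {
    abort_invalid(sprintf("mu and amp must have length %d (one per mode)", k))
  }
  if (any(amp < 0)) abort_invalid("amplitudes must be non-negative")
  modes$params[[system]] <- list(mu = as.numeric(mu), amp = as.numeric(amp))
  modes
}

#' Simulate a trajectory with planted collective modes
#'
#' Frame `t` is `x_ref + sum_k (mu_k + a_k z_tk) v_k + eps_t`, with `z`
#' i.i.d. standard normal per frame and mode and `eps` isotropic Gaussian
#' coordinate noise of sd `sigma_noise`.  When the structure has several
#' identical chains and the mode set was built on a single subunit, the
#' modes are applied chain-locally with independent coefficients per
#' chain (equivalently: a block-diagonal orthonormal mode set over the
#' full structure sharing `mu`/`a` across chain copies), so every subunit
#' trajectory carries the planted per-mode statistics.
#'
#' @param structure A `toy_structure`.
#' @param modes A `mode_set` with parameters for `system_tag`
#'   ([set_system_modes()]).
#' @param system_tag System label stamped on every frame.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A [trajectory()].
#' @export
simulate_system_trajectory <- function(structure, modes, system_tag, n_frames, seed) {
  par <- modes$params[[system_tag]]
  if (is.null(par)) {
    abort_config(sprintf("mode set carries no mu/amp for system '%s'", system_tag))
  }
  n_struct <- nrow(structure$atoms)
  n_mode <- modes$n_atoms
  if (n_struct == n_mode) {
    blocks <- list(seq_len(n_struct))
  } else {
    chains <- unique(structure$atoms$chain)
    blocks <- lapply(chains, function(ch) which(structure$atoms$chain == ch))
    if (!all(lengths(blocks) == n_mode)) {
      abort_config(sprintf(
        "mode set dimension (%d atoms) matches neither the structure (%d) nor its chains",
        n_mode, n_struct
      ))
    }
  }
  K <- ncol(modes$vectors)
  ref <- as.numeric(t(structure$xyz))
  xyz <- with_seed(seed, {
    disp <- matrix(0, n_frames, 3L * n_struct)
    for (b in blocks) {
      Z <- matrix(stats::rnorm(n_frames * K), n_frames, K)
      coef <- sweep(Z, 2L, par$amp, `*`)
      coef <- sweep(coef, 2L, par$mu, `+`)
      cols <- as.vector(rbind(3L * b - 2L, 3L * b - 1L, 3L * b))
      disp[, cols] <- coef %*% t(modes$vectors)
    }
    if (modes$sigma_noise > 0) {
      disp <- disp + modes$sigma_noise * matrix(
        stats::rnorm(n_frames * 3L * n_struct), n_frames
      )
    }
    sweep(disp, 2L, -ref)
  })
  trajectory(structure$atoms[, c("chain", "resid", "name")], xyz,
             system = system_tag)
}

#' Ground truth for a synthetic titration experiment
#'
#' Holds the planted dissociation constant, per-residue saturation CSPs,
#' the per-residue angle splitting the combined CSP into 1H and 15N
#' components, and the measurement design.
#'
#' @param kd Dissociation constant (mM), > 0.
#' @param delta0 Named numeric vector of per-residue saturation CSPs
#'   (ppm), >= 0; names are residue ids.
#' @param P Protein concentration (mM), > 0.
#' @param L Ligand concentrations (mM), non-negative and strictly
#'   increasing.
#' @param noise_sd Additive Gaussian noise on each shift component (ppm).
#' @param theta Optional per-residue split angle (radians, in `[0, pi/2]`);
#'   drawn uniformly per residue from `seed` when omitted, since only
#'   combined CSPs are ever reported.
#' @param seed Seed for drawing `theta` when it is omitted.
#' @return A `titration_ground_truth` list.
#' @export
titration_ground_truth <- function(kd, delta0, P = 0.5,
                                   L = c(0, 0.25, 0.5, 1, 2, 4, 8),
                                   noise_sd = 0, theta = NULL, seed = 1) {
  if (kd <= 0 || P <= 0) abort_invalid("kd and P must be positive")
  if (any(delta0 < 0)) abort_invalid("delta0 must be non-negative")
  if (any(L < 0) || any(diff(L) <= 0)) {
    abort_invalid("L must be non-negative and strictly increasing")
  }
  if (is.null(names(delta0))) names(delta0) <- as.character(seq_along(delta0))
  if (is.null(theta)) {
    theta <- with_seed(seed, stats::runif(length(delta0), 0, pi / 2))
  }
  names(theta) <- names(delta0)
  structure(
    list(kd = kd, delta0 = delta0, theta = theta, P = P, L = L,
         noise_sd = noise_sd),
    class = "titration_ground_truth"
  )
}

#' Simulate a titration set from planted ground truth
#'
#' For residue `r` at ligand concentration `L` the target combined CSP is
#' the one-site depletion isotherm [isotherm_csp()]; the emitted component
#' shifts are `ddH = c cos(theta_r)/W_H`, `ddN = c sin(theta_r)/W_N`
#' (plus noise at `L > 0`), so the noise-free weighted combination
#' reproduces the target exactly.  Shifts at `L = 0` are exactly zero by
#' definition (differences from the free state).
#'
#' @param truth A [titration_ground_truth()].
#' @param seed Integer seed for the measurement noise.
#' @param weights [csp_weights()] used to split the combined CSP.
#' @return A `titration_set`: list with `P` (mM), `L` (mM grid) and
#'   `data` (residue, ligand_mM, ddH_ppm, ddN_ppm).
#' @export
simulate_titration_set <- function(truth, seed, weights = csp_weights()) {
  res <- names(truth$delta0)
  grid <- expand.grid(residue = res, ligand_mM = truth$L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  csp <- isotherm_csp(truth$P, grid$ligand_mM, truth$kd,
                      truth$delta0[grid$residue])
  th <- truth$theta[grid$residue]
  ddH <- csp * cos(th) / weights$wh
  ddN <- csp * sin(th) / weights$wn
  if (truth$noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2L * nrow(grid), 0,
                                                 truth$noise_sd), ncol = 2L))
    pos <- grid$ligand_mM > 0
    ddH[pos] <- ddH[pos] + noise[pos, 1L]
    ddN[pos] <- ddN[pos] + noise[pos, 2L]
  }
  structure(
    list(P = truth$P, L = truth$L,
         data = data.frame(residue = grid$residue,
                           ligand_mM = grid$ligand_mM,
                           ddH_ppm = as.numeric(ddH),
                           ddN_ppm = as.numeric(ddN),
                           stringsAsFactors = FALSE)),
    class = "titration_set"
  )
}

#' Simulate a stationary interatomic distance series
#'
#' I.i.d. normal draws truncated at zero (exact inverse-CDF truncation),
#' as a fixture for the distance-distribution analysis.
#'
#' @param mean Mean distance (Angstrom), > 0.
#' @param sd Standard deviation (Angstrom), >= 0.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return Numeric vector of distances (Angstrom).
#' @export
simulate_distance_series <- function(mean, sd, n_frames, seed) {
  if (mean <= 0 || sd < 0) abort_invalid("need mean > 0 and sd >= 0")
  if (sd == 0) return(rep(mean, n_frames))
  with_seed(seed, {
    u <- stats::runif(n_frames, stats::pnorm(0, mean, sd), 1)
    stats::qnorm(u, mean, sd)
  })
}

#' Write / read a titration set as tab-separated text
#'
#' Format: header `residue ligand_mM ddH_ppm ddN_ppm` (tab-separated),
#' protein concentration recorded on a `# P_mM=` comment line.
#'
#' @param set A `titration_set`.
#' @param path Output path.
#' @return Invisibly, `path` (write) or the `titration_set` (read).
#' @export
write_titration_set <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# P_mM=%.10g", set$P), con)
  utils::write.table(set$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_set
#' @export
read_titration_set <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# P_mM=", first)) {
    abort_parse("titration file lacks the '# P_mM=' header line")
  }
  P <- as.numeric(sub("^# P_mM=", "", first))
  data <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  data$residue <- as.character(data$residue)
  structure(list(P = P, L = sort(unique(data$ligand_mM)), data = data),
            class = "titration_set")
}

#' Write / read a ground-truth sidecar as plain key-value text
#'
#' @param truth A [titration_ground_truth()].
#' @param path Output path.
#' @return Invisibly, `path` (write) or the ground truth (read).
#' @export
write_ground_truth <- function(truth, path) {
  lines <- c(
    sprintf("kd_mM=%.12g", truth$kd),
    sprintf("P_mM=%.12g", truth$P),
    sprintf("noise_sd_ppm=%.12g", truth$noise_sd),
    sprintf("L_mM=%s", paste(sprintf("%.12g", truth$L), collapse = ",")),
    sprintf("delta0_%s=%.12g", names(truth$delta0), truth$delta0),
    sprintf("theta_%s=%.12g", names(truth$theta), truth$theta)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  pick <- function(k) vals[keys == k]
  d0 <- grepl("^delta0_", keys)
  th <- grepl("^theta_", keys)
  delta0 <- as.numeric(vals[d0]); names(delta0) <- sub("^delta0_", "", keys[d0])
  theta <- as.numeric(vals[th]); names(theta) <- sub("^theta_", "", keys[th])
  titration_ground_truth(
    kd = as.numeric(pick("kd_mM")), delta0 = delta0,
    P = as.numeric(pick("P_mM")),
    L = as.numeric(strsplit(pick("L_mM"), ",")[[1L]]),
    noise_sd = as.numeric(pick("noise_sd_ppm")), theta = theta
  )
}

#' Write a toy structure or trajectory snapshot as PDB
#'
#' @param structure A `toy_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  tr <- trajectory(structure$atoms[, c("chain", "resid", "name")],
                   matrix(as.numeric(t(structure$xyz)), nrow = 1L))
  write_trajectory(tr, path)
}
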