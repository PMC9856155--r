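#' Amide chemical-shift weighting factors
#'
#' Weights for combining amide 1H and 15N chemical shift changes into a
#' single perturbation value; the conventional 15N weight accounts for
#' the narrower 15N shift dispersion of backbone amides.
#'
#' @param wh,wn Positive weights for the 1H and 15N dimensions.
#' @return A `csp_weights` list.
#' @export
csp_weights <- function(wh = 1, wn = 0.154) {
  if (wh <= 0 || wn <= 0) abort_invalid("weights must be positive")
  structure(list(wh = wh, wn = wn), class = "csp_weights")
}

#' Weighted combined chemical shift perturbation
#'
#' `CSP = sqrt((ddH * W_H)^2 + (ddN * W_N)^2)`, in ppm.  Non-negative and
#' symmetric in the sign of either component.
#'
#' @param ddH,ddN Amide 1H and 15N chemical shift differences (ppm)
#'   between free and bound states; vectorised.
#' @param weights A [csp_weights()].
#' @return Combined CSP (ppm).
#' @export
combined_csp <- function(ddH, ddN, weights = csp_weights()) {
  if (!all(is.finite(ddH)) || !all(is.finite(ddN))) {
    abort_invalid("shift differences must be finite")
  }
  sqrt((ddH * weights$wh)^2 + (ddN * weights$wn)^2)
}

#' One-site binding isotherm with ligand depletion
#'
#' The exact solution of the one-site equilibrium at comparable protein
#' and ligand concentrations (no excess-ligand approximation):
#' `CSP = Delta0 * (P + L + KD - sqrt((P + L + KD)^2 - 4 P L)) / (2 P)`.
#' Zero at `L = 0`, monotonically increasing in `L`, saturating at
#' `Delta0`.
#'
#' @param P Protein concentration (mM), > 0.
#' @param L Ligand concentration(s) (mM), >= 0.
#' @param kd Dissociation constant (mM), > 0.
#' @param delta0 Combined CSP at saturation (ppm); vectorised with `L`.
#' @return CSP (ppm).
#' @export
isotherm_csp <- function(P, L, kd, delta0) {
  if (P <= 0 || kd <= 0 || any(L < 0)) {
    abort_invalid("need P > 0, kd > 0 and L >= 0")
  }
  s <- P + L + kd
  frac <- (s - sqrt(s^2 - 4 * P * L)) / (2 * P)
  delta0 * frac
}

#' Select binding residues by CSP threshold
#'
#' Residues whose combined CSP at a given ligand concentration strictly
#' exceeds the threshold (a residue sitting exactly at the threshold is
#' excluded).
#'
#' @param set A `titration_set`.
#' @param at_ligand Ligand concentration (mM); must be on the set's
#'   concentration grid.
#' @param threshold CSP threshold (ppm); default 0.05.
#' @param weights A [csp_weights()].
#' @return Character vector of residue ids.
#' @export
select_binders <- function(set, at_ligand = 2, threshold = 0.05,
                           weights = csp_weights()) {
  if (!any(abs(set$L - at_ligand) < 1e-9)) {
    abort_invalid(sprintf("ligand concentration %g mM is not on the titration grid",
                          at_ligand))
  }
  rows <- set$data[abs(set$data$ligand_mM - at_ligand) < 1e-9, , drop = FALSE]
  csp <- combined_csp(rows$ddH_ppm, rows$ddN_ppm, weights)
  unique(rows$residue[csp > threshold])
}

#' Global one-site dissociation-constant fit
#'
#' Simultaneous nonlinear least squares over the raw combined CSPs of all
#' selected residues, with one shared dissociation constant and one
#' saturation amplitude per residue, using the exact ligand-depletion
#' isotherm ([isotherm_csp()]).  Levenberg-Marquardt optimisation with a
#' multi-start over a log-spaced KD grid when no initial guess is given;
#' asymptotic standard errors come from the Jacobian covariance at the
#' optimum, with an optional seeded residual bootstrap.
#'
#' @param set A `titration_set`.
#' @param binders Character vector of residue ids to fit (>= 1); the
#'   design must offer at least 3 ligand concentrations and more points
#'   than parameters.
#' @param init Optional named list `list(kd =, delta0 =)` initial values.
#' @param weights A [csp_weights()].
#' @param n_boot Number of residual-bootstrap resamples for the optional
#'   bootstrap standard error (0 disables it).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `binding_fit`: `kd`, `kd_se`, `delta0`, `delta0_se`,
#'   `kd_se_boot` (if requested), `residuals`, `fitted`, `data`,
#'   `convergence`.
#' @export
fit_global <- function(set, binders, init = NULL, weights = csp_weights(),
                       n_boot = 0L, boot_seed = 1L) {
  if (length(binders) < 1L) abort_invalid("need at least one binder residue")
  if (length(set$L) < 3L) abort_invalid("need at least 3 ligand concentrations")
  dat <- set$data[set$data$residue %in% binders, , drop = FALSE]
  if (!setequal(unique(dat$residue), binders)) {
    abort_invalid("some binder residues are absent from the titration set")
  }
  dat$csp <- combined_csp(dat$ddH_ppm, dat$ddN_ppm, weights)
  res_ids <- unique(dat$residue)
  n_par <- 1L + length(res_ids)
  if (nrow(dat) <= n_par) {
    abort_invalid(sprintf(
      "underdetermined fit: %d points for %d parameters", nrow(dat), n_par
    ))
  }
  ridx <- match(dat$residue, res_ids)
  resid_fn <- function(par) {
    kd <- par[1L]
    d0 <- par[-1L]
    dat$csp - isotherm_csp(set$P, dat$ligand_mM, kd, d0[ridx])
  }
  lmax <- max(set$L)
  fit_once <- function(kd0) {
    frac <- isotherm_csp(set$P, lmax, kd0, 1)
    d0_init <- vapply(res_ids, function(r) {
      max(dat$csp[dat$residue == r]) / max(frac, 1e-6)
    }, 0)
    minpack.lm::nls.lm(
      par = c(kd0, d0_init), fn = resid_fn,
      lower = c(1e-8, rep(0, length(res_ids))),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14
      )
    )
  }
  fits <- if (is.null(init)) {
    lapply(10^seq(-1.5, 1.8, length.out = 7), fit_once)
  } else {
    list(minpack.lm::nls.lm(
      par = c(init$kd, rep_len(init$delta0, length(res_ids))), fn = resid_fn,
      lower = c(1e-8, rep(0, length(res_ids))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ))
  }
  dev <- vapply(fits, function(f) sum(resid_fn(f$par)^2), 0)
  best <- fits[[which.min(dev)]]
  if (best$info == 0L) {
    abort_fit(sprintf("global fit failed: %s", best$message))
  }
  if (best$info == 5L) {
    warning(sprintf("global fit hit the iteration cap; best candidate returned (%s)",
                    best$message))
  }
  par <- best$par
  # asymptotic covariance from a forward-difference Jacobian at the optimum
  J <- jacobian_fd(function(p) -resid_fn(p), par)
  dof <- nrow(dat) - n_par
  s2 <- sum(resid_fn(par)^2) / max(dof, 1L)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * s2),
                 error = function(e) rep(NA_real_, n_par))
  out <- structure(
    list(
      kd = unname(par[1L]), kd_se = unname(se[1L]),
      delta0 = stats::setNames(par[-1L], res_ids),
      delta0_se = stats::setNames(se[-1L], res_ids),
      residuals = resid_fn(par),
      fitted = dat$csp - resid_fn(par),
      data = dat, P = set$P, L = set$L, weights = weights,
      convergence = list(info = best$info, message = best$message,
                         deviance = min(dev), niter = best$niter)
    ),
    class = "binding_fit"
  )
  if (n_boot > 0L) {
    r0 <- out$residuals
    f0 <- out$fitted
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- f0 + sample(r0, replace = TRUE)
        fb <- minpack.lm::nls.lm(
          par = par,
          fn = function(p) yb - isotherm_csp(set$P, dat$ligand_mM, p[1L],
                                             p[-1L][ridx]),
          lower = c(1e-8, rep(0, length(res_ids))),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
        fb$par[1L]
      }, 0)
    })
    out$kd_se_boot <- stats::sd(boots)
  }
  out
}

jacobian_fd <- function(fn, par, eps = 1e-7) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> KD = %.4g +/- %.2g mM; %d residues; deviance %.3g (%s)\n",
    x$kd, x$kd_se, length(x$delta0), x$convergence$deviance,
    x$convergence$message
  ))
  invisible(x)
}

#' Saturation-normalised averaged binding curve
#'
#' For display: each residue's CSPs are normalised by its fitted
#' saturation value, then averaged over residues per ligand point, with
#' one-standard-deviation error bars (population sd over residues).
#' Residues with a zero fitted saturation amplitude are excluded with a
#' warning.  The fitted curve (which is common to all residues after
#' normalisation) is evaluated on a dense concentration grid.
#'
#' @param fit A `binding_fit`.
#' @param n_dense Points in the dense fitted curve.
#' @return List with `points` (`ligand_mM`, `mean_norm_csp`, `sd`) and
#'   `curve` (`ligand_mM`, `norm_csp`).
#' @export
normalize_for_plot <- function(fit, n_dense = 200L) {
  keep <- names(fit$delta0)[fit$delta0 > 0]
  if (length(keep) < length(fit$delta0)) {
    warning(sprintf("excluding %d residue(s) with zero saturation amplitude",
                    length(fit$delta0) - length(keep)))
  }
  dat <- fit$data[fit$data$residue %in% keep, , drop = FALSE]
  norm <- dat$csp / fit$delta0[dat$residue]
  by_l <- split(norm, dat$ligand_mM)
  lg <- as.numeric(names(by_l))
  o <- order(lg)
  dense <- seq(min(fit$L), max(fit$L), length.out = n_dense)
  list(
    points = data.frame(
      ligand_mM = lg[o],
      mean_norm_csp = vapply(by_l, mean, 0)[o],
      sd = vapply(by_l, function(v) sqrt(mean((v - mean(v))^2)), 0)[o],
      row.names = NULL
    ),
    curve = data.frame(ligand_mM = dense,
                       norm_csp = isotherm_csp(fit$P, dense, fit$kd, 1))
  )
}

#' Write a binding-fit report as tab-separated text
#'
#' @param fit A `binding_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# KD_mM=%.10g\tKD_se_mM=%.10g\tdeviance=%.10g",
                     fit$kd, fit$kd_se, fit$convergence$deviance), con)
  utils::write.table(
    data.frame(residue = names(fit$delta0), delta0_ppm = fit$delta0,
               delta0_se_ppm = fit$delta0_se, row.names = NULL),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
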