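## Equilibrium binding-curve fits (one-site with Hill slope, fluorescence
## polarization) and mass-photometry calibration / peak fitting /
## stoichiometry assignment.

#' Fit a one-site binding curve with Hill slope
#'
#' Nonlinear least squares of
#' `response = baseline + amplitude * c^h / (Kd^h + c^h)` via
#' Levenberg-Marquardt, with multi-start initialization: Kd is started at
#' the concentration nearest half-maximal response and at geometric
#' quartiles of the concentration range; the Hill coefficient at 0.5, 1 and
#' 2 (unless constrained). The best residual sum of squares wins.
#'
#' @param curve A [titration_curve()] with at least 5 points.
#' @param constrain_hill Optional fixed Hill coefficient (e.g. 1 for short
#'   duplexes or FP data); `NULL` fits it freely.
#' @return A `BindingFit` with `Kd`, `hill`, `amplitude`, `baseline`, `rss`,
#'   `converged`. When no start converges, or the fitted amplitude is
#'   negligible relative to the response spread (Kd unidentifiable),
#'   `converged` is `FALSE` and the best-effort parameters are returned.
#' @export
fit_one_site_hill <- function(curve, constrain_hill = NULL) {
  stopifnot(inherits(curve, "TitrationCurve"))
  conc <- curve$concentration; resp <- curve$response
  if (length(conc) < 5L) stop("need at least 5 titration points for fitting")
  pos <- conc[conc > 0]
  if (length(pos) < 3L) stop("need at least 3 positive concentrations")
  base0 <- min(resp); amp0 <- max(resp) - min(resp)
  half <- base0 + amp0 / 2
  kd_half <- conc[which.min(abs(resp - half))]
  qs <- stats::quantile(log(pos), c(0.25, 0.5, 0.75))
  kd_starts <- unique(pmax(c(kd_half, exp(qs)), min(pos) / 10))
  h_starts <- if (is.null(constrain_hill)) c(0.5, 1, 2) else NA
  if (amp0 <= 0) amp0 <- max(abs(resp), 1)

  best <- NULL
  for (kd0 in kd_starts) {
    for (h0 in h_starts) {
      fit <- tryCatch({
        if (is.null(constrain_hill)) {
          minpack.lm::nlsLM(
            resp ~ baseline + amplitude * conc^h / (Kd^h + conc^h),
            start = list(Kd = kd0, h = h0, amplitude = amp0,
                         baseline = base0),
            lower = c(Kd = min(pos) / 1e4, h = 0.05, amplitude = -Inf,
                      baseline = -Inf),
            upper = c(Kd = max(pos) * 1e4, h = 20, amplitude = Inf,
                      baseline = Inf),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          h_fix <- constrain_hill
          minpack.lm::nlsLM(
            resp ~ baseline + amplitude * conc^h_fix / (Kd^h_fix + conc^h_fix),
            start = list(Kd = kd0, amplitude = amp0, baseline = base0),
            lower = c(Kd = min(pos) / 1e4, amplitude = -Inf,
                      baseline = -Inf),
            upper = c(Kd = max(pos) * 1e4, amplitude = Inf, baseline = Inf),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(fit)
        best <- list(Kd = unname(cf[["Kd"]]),
                     hill = if (is.null(constrain_hill)) unname(cf[["h"]])
                            else constrain_hill,
                     amplitude = unname(cf[["amplitude"]]),
                     baseline = unname(cf[["baseline"]]),
                     rss = rss, converged = TRUE)
      }
    }
  }
  if (is.null(best)) {
    best <- list(Kd = kd_half, hill = constrain_hill %||% 1,
                 amplitude = amp0, baseline = base0,
                 rss = sum((resp - mean(resp))^2), converged = FALSE)
  }
  # flat curves: amplitude indistinguishable from noise -> Kd unidentifiable
  spread <- stats::sd(resp)
  if (!is.finite(spread) || spread == 0 ||
      abs(best$amplitude) < 1e-6 * max(abs(resp), 1)) {
    best$converged <- FALSE
  }
  structure(best, class = "BindingFit")
}

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf(
    "BindingFit: Kd = %.4g, hill = %.3g, amplitude = %.4g, baseline = %.4g\n  rss = %.4g, converged = %s\n",
    x$Kd, x$hill, x$amplitude, x$baseline, x$rss, x$converged))
  invisible(x)
}

#' Fit a one-site fluorescence-polarization binding curve
#'
#' One-site fit with the Hill coefficient fixed at 1; `baseline` is the
#' free-probe polarization and `amplitude` the bound-minus-free difference.
#' The simple hyperbolic form assumes the titrated protein is in excess of
#' the probe; when the fitted Kd approaches the probe concentration,
#' ligand depletion biases it upward — the quadratic `depletion = TRUE`
#' variant (requires `probe_conc`) accounts for that, but the hyperbolic
#' form is the default.
#'
#' @param curve A [titration_curve()] of polarization responses.
#' @param depletion Use the ligand-depletion (quadratic) binding form.
#' @param probe_conc Probe concentration (same units as the titration);
#'   required when `depletion = TRUE`.
#' @return A `BindingFit`.
#' @export
fit_fp_one_site <- function(curve, depletion = FALSE, probe_conc = NULL) {
  if (!depletion) return(fit_one_site_hill(curve, constrain_hill = 1))
  if (is.null(probe_conc) || probe_conc <= 0) {
    stop("depletion fit requires probe_conc > 0")
  }
  conc <- curve$concentration; resp <- curve$response
  if (length(conc) < 5L) stop("need at least 5 titration points for fitting")
  P <- probe_conc
  frac_bound <- function(c_tot, Kd) {
    s <- c_tot + P + Kd
    (s - sqrt(pmax(s^2 - 4 * c_tot * P, 0))) / (2 * P)
  }
  base0 <- min(resp); amp0 <- max(resp) - min(resp)
  pos <- conc[conc > 0]
  kd_starts <- unique(c(stats::median(pos), min(pos), max(pos) / 10))
  best <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ baseline + amplitude * frac_bound(conc, Kd),
        start = list(Kd = kd0, amplitude = amp0, baseline = base0),
        lower = c(Kd = 1e-12, amplitude = -Inf, baseline = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(Kd = unname(cf[["Kd"]]), hill = 1,
                   amplitude = unname(cf[["amplitude"]]),
                   baseline = unname(cf[["baseline"]]),
                   rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) {
    best <- list(Kd = stats::median(pos), hill = 1, amplitude = amp0,
                 baseline = base0, rss = sum((resp - mean(resp))^2),
                 converged = FALSE)
  }
  structure(best, class = "BindingFit")
}

#' Calibrate mass-photometry contrast against protein standards
#'
#' Least-squares line mapping interferometric contrast to molecular mass.
#' The conventional standard mixture spans 73-800 kDa (an IgG fragment, IgG,
#' apoferritin, GroEL).
#'
#' @param contrasts Measured contrasts of the standards.
#' @param standard_masses Known standard masses in kDa (default
#'   `c(73, 149, 479, 800)`).
#' @return List with `slope`, `intercept`, `r_squared` and
#'   `predict(contrast)`.
#' @export
mp_calibrate <- function(contrasts, standard_masses = c(73, 149, 479, 800)) {
  if (length(contrasts) != length(standard_masses)) stop("length mismatch")
  if (length(contrasts) < 2L) stop("need at least 2 standards")
  if (stats::sd(contrasts) == 0) stop("degenerate contrasts")
  fit <- stats::lm(standard_masses ~ contrasts)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (length(contrasts) > 2L) {
    suppressWarnings(summary(fit)$r.squared)
  } else 1
  list(slope = slope, intercept = intercept, r_squared = r2,
       predict = function(contrast) intercept + slope * contrast)
}

#' Fit Gaussian mixture peaks to a mass-photometry histogram
#'
#' Expectation-maximisation fit of a `k`-component univariate Gaussian
#' mixture with a shared standard deviation (via [mclust::Mclust()] model
#' `"E"`). `k` is chosen by the caller.
#'
#' @param masses Event masses in kDa.
#' @param k Number of components (>= 1); requires at least `10 * k` events.
#' @param seed RNG seed (the EM initialisation is deterministic, but the
#'   seed is fixed for reproducibility of any stochastic backend).
#' @return A `MassPeakSet` with ascending `means` (kDa), matching `weights`
#'   and shared `sigma` (kDa).
#' @export
fit_mass_peaks <- function(masses, k, seed = 1L) {
  stopifnot(k >= 1L)
  if (length(masses) < 10L * k) stop("need at least 10*k events")
  set.seed(as.integer(seed))
  fit <- mclust::Mclust(masses, G = k, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  structure(list(means = unname(fit$parameters$mean[ord]),
                 weights = unname(fit$parameters$pro[ord]),
                 sigma = sqrt(unname(fit$parameters$variance$sigmasq[1L])),
                 loglik = fit$loglik),
            class = "MassPeakSet")
}

#' @export
print.MassPeakSet <- function(x, ...) {
  cat("MassPeakSet:\n")
  for (i in seq_along(x$means)) {
    cat(sprintf("  %.1f kDa (weight %.3f)\n", x$means[i], x$weights[i]))
  }
  cat(sprintf("  shared sigma %.2f kDa\n", x$sigma))
  invisible(x)
}

#' Stoichiometry model for chaperone-clamp assemblies
#'
#' @param M_caf1 Mass of one CAF-1 heterotrimer in kDa (default 190, the
#'   measured free-complex peak).
#' @param M_pcna3 Mass of one PCNA homotrimer in kDa (default 90).
#' @param max_caf1,max_pcna3 Largest copy numbers considered.
#' @return A `CompositionModel`.
#' @export
composition_model <- function(M_caf1 = 190, M_pcna3 = 90, max_caf1 = 3L,
                              max_pcna3 = 1L) {
  stopifnot(M_caf1 > 0, M_pcna3 > 0, max_caf1 >= 0, max_pcna3 >= 0)
  structure(list(M_caf1 = M_caf1, M_pcna3 = M_pcna3,
                 max_caf1 = as.integer(max_caf1),
                 max_pcna3 = as.integer(max_pcna3)),
            class = "CompositionModel")
}

#' Assign a mass peak to an n x CAF-1 + m x PCNA-trimer composition
#'
#' Exhaustive search over copy numbers `0 <= a <= max_caf1`,
#' `0 <= b <= max_pcna3`, `(a, b) != (0, 0)`, minimising
#' `|peak_mass - a * M_caf1 - b * M_pcna3|`. Ties go to the smaller total
#' copy number `a + b`, then to the smaller chaperone count `a` (both
#' orderings are rare knife-edge cases exactly between two compositions).
#' Peaks farther than `tolerance` from every
#' composition are unassigned — instrument-fitted masses of large
#' assemblies can deviate tens of kDa from naive subunit sums, hence the
#' generous default.
#'
#' @param peak_mass Peak mass in kDa.
#' @param model A [composition_model()].
#' @param tolerance Maximum allowed residual in kDa (default 50).
#' @return List with `n_caf1`, `n_pcna3`, `residual_kDa`, `assigned`; the
#'   copy numbers are `NA` when unassigned.
#' @export
assign_composition <- function(peak_mass, model = composition_model(),
                               tolerance = 50) {
  stopifnot(inherits(model, "CompositionModel"), peak_mass > 0)
  grid <- expand.grid(a = 0:model$max_caf1, b = 0:model$max_pcna3)
  grid <- grid[grid$a + grid$b > 0L, , drop = FALSE]
  grid$mass <- grid$a * model$M_caf1 + grid$b * model$M_pcna3
  grid$resid <- abs(peak_mass - grid$mass)
  grid <- grid[order(grid$resid, grid$a + grid$b, grid$a), , drop = FALSE]
  top <- grid[1L, ]
  if (top$resid > tolerance) {
    return(list(n_caf1 = NA_integer_, n_pcna3 = NA_integer_,
                residual_kDa = top$resid, assigned = FALSE))
  }
  list(n_caf1 = as.integer(top$a), n_pcna3 = as.integer(top$b),
       residual_kDa = top$resid, assigned = TRUE)
}
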