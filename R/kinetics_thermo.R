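# Titration / kinetics fitting and the thermodynamic bookkeeping around
# them: depletion-aware 1:1 binding isotherms (tryptophan-fluorescence
# quenching titrations), Michaelis-Menten glutamylation kinetics, catalytic
# efficiency, fold changes, binding free-energy differences, and
# PAR/MMTS-based zinc:protein stoichiometry.

## gas constant, kcal / (mol K); 1 cal = 4.184 J
R_KCAL <- 1.987e-3

#' Bound fraction under exact 1:1 binding with ligand depletion
#'
#' The quadratic solution of the 1:1 equilibrium, valid at enzyme
#' concentrations comparable to Kd (no excess-ligand approximation):
#' `f = ((E + L + Kd) - sqrt((E + L + Kd)^2 - 4 E L)) / (2 E)`.
#'
#' @param L Total ligand concentration(s), molar.
#' @param E Total enzyme concentration, molar.
#' @param kd Dissociation constant, molar.
#' @return Fraction of enzyme bound, in \[0, 1\].
#' @export
bound_fraction <- function(L, E, kd) {
  s <- E + L + kd
  disc <- pmax(s^2 - 4 * E * L, 0)
  (s - sqrt(disc)) / (2 * E)
}

check_series <- function(xs, ys, what) {
  if (length(xs) != length(ys) || length(xs) < 4L)
    stop(what, " series needs equal-length vectors with at least 4 points")
  if (any(!is.finite(xs)) || any(!is.finite(ys)))
    stop("non-finite values in ", what, " series")
  if (any(xs < 0) || any(diff(xs) <= 0))
    stop(what, " concentrations must be non-negative and strictly increasing")
}

#' Fit a 1:1 binding isotherm to a titration series
#'
#' Nonlinear least-squares fit of
#' `signal = baseline + amplitude * f(L; E, Kd)` where `f` is the bound
#' fraction. The default model is the exact depletion-aware quadratic
#' ([bound_fraction()]); `model = "hyperbolic"` fits the Langmuir limit
#' `f = L / (Kd + L)`, appropriate when ligand is in large excess over
#' enzyme. Starting values come from a coarse logarithmic grid over Kd
#' (baseline and amplitude are profiled linearly at each grid point), and
#' the final fit is bounded Levenberg-Marquardt with `Kd >= 0`; the whole
#' procedure is deterministic.
#'
#' @param ligand_concs Total ligand concentrations, molar; non-negative,
#'   strictly increasing, length >= 4.
#' @param signal Measured signal (e.g. fluorescence, arbitrary units).
#' @param enzyme_conc Total enzyme concentration, molar (> 0).
#' @param model `"quadratic"` (default) or `"hyperbolic"`.
#' @return An object of class `c("binding_fit", "kinetic_fit")` with
#'   coefficients `kd`, `amplitude`, `baseline`, asymptotic standard
#'   errors, and the underlying `nls` fit. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`.
#' @examples
#' L <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6) * 1e-6
#' y <- 1 - 0.6 * bound_fraction(L, 0.5e-6, 62.5e-9)
#' fit <- fit_binding(L, y, enzyme_conc = 0.5e-6)
#' coef(fit)["kd"]
#' @export
fit_binding <- function(ligand_concs, signal, enzyme_conc,
                        model = c("quadratic", "hyperbolic")) {
  model <- match.arg(model)
  check_series(ligand_concs, signal, "titration")
  if (!is.numeric(enzyme_conc) || enzyme_conc <= 0)
    stop("'enzyme_conc' must be positive")
  frac <- function(L, kd)
    if (model == "quadratic") bound_fraction(L, enzyme_conc, kd)
    else L / (kd + L)

  ## coarse log-grid start: profile baseline/amplitude linearly per Kd
  pos <- ligand_concs[ligand_concs > 0]
  grid <- 10^seq(log10(min(pos) / 100), log10(max(pos) * 100), length.out = 40)
  sse <- vapply(grid, function(kd) {
    f <- frac(ligand_concs, kd)
    co <- tryCatch(stats::lm.fit(cbind(1, f), signal)$residuals,
                   error = function(e) rep(Inf, length(signal)))
    sum(co^2)
  }, numeric(1))
  kd0 <- grid[which.min(sse)]
  f0 <- frac(ligand_concs, kd0)
  lin <- stats::coef(stats::lm(signal ~ f0))
  start <- list(baseline = unname(lin[1]), amplitude = unname(lin[2]), kd = kd0)

  df <- data.frame(L = ligand_concs, y = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + amplitude * frac(L, kd), data = df, start = start,
      lower = c(baseline = -Inf, amplitude = -Inf, kd = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      rn <- sqrt(min(sse))
      stop("binding fit did not converge (last grid residual norm ",
           format(rn, digits = 4), "): ", conditionMessage(e))
    })
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3), names(co)))
  structure(
    list(coefficients = c(kd = unname(co["kd"]),
                          amplitude = unname(co["amplitude"]),
                          baseline = unname(co["baseline"])),
         se = c(kd = unname(se["kd"]), amplitude = unname(se["amplitude"]),
                baseline = unname(se["baseline"])),
         model = model, enzyme_conc = enzyme_conc, fit = fit, data = df),
    class = c("binding_fit", "kinetic_fit"))
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least-squares fit of `v = kcat * E * S / (Km + S)` to initial
#' rates measured over a substrate series. Start values are taken from the
#' observed saturation level and half-saturation point and refined by
#' bounded Levenberg-Marquardt (`kcat, Km >= 0`); deterministic.
#'
#' @param substrate_concs Substrate concentrations, molar; non-negative,
#'   strictly increasing, length >= 4.
#' @param rates Initial rates, molar per second; non-negative.
#' @param enzyme_conc Total enzyme concentration, molar (> 0).
#' @return An object of class `c("mm_fit", "kinetic_fit")` with
#'   coefficients `kcat` (per second) and `km` (molar), standard errors,
#'   and the underlying `nls` fit.
#' @examples
#' S <- seq(50, 300, by = 50) * 1e-6
#' v <- 5.3 * 50e-9 * S / (65.4e-6 + S)
#' coef(fit_mm(S, v, enzyme_conc = 50e-9))
#' @export
fit_mm <- function(substrate_concs, rates, enzyme_conc) {
  check_series(substrate_concs, rates, "kinetics")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!is.numeric(enzyme_conc) || enzyme_conc <= 0)
    stop("'enzyme_conc' must be positive")
  vmax0 <- max(rates) * 1.2
  km0 <- substrate_concs[which.min(abs(rates - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(substrate_concs)
  df <- data.frame(S = substrate_concs, v = rates)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ kcat * enzyme_conc * S / (km + S), data = df,
      start = list(kcat = vmax0 / enzyme_conc, km = km0),
      lower = c(kcat = 0, km = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge: ", conditionMessage(e)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 2), names(co)))
  structure(
    list(coefficients = c(kcat = unname(co["kcat"]), km = unname(co["km"])),
         se = c(kcat = unname(se["kcat"]), km = unname(se["km"])),
         enzyme_conc = enzyme_conc, fit = fit, data = df),
    class = c("mm_fit", "kinetic_fit"))
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
fitted.kinetic_fit <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.kinetic_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  L <- if (is.null(newdata)) object$data$L else
    if (is.list(newdata)) newdata$L else newdata
  f <- if (object$model == "quadratic")
    bound_fraction(L, object$enzyme_conc, co["kd"]) else L / (co["kd"] + L)
  unname(co["baseline"] + co["amplitude"] * f)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  S <- if (is.null(newdata)) object$data$S else
    if (is.list(newdata)) newdata$S else newdata
  unname(co["kcat"] * object$enzyme_conc * S / (co["km"] + S))
}

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  kind <- if (inherits(x, "binding_fit"))
    paste0("1:1 binding fit (", x$model, " model)")
  else "Michaelis-Menten fit"
  cat(kind, "\n")
  est <- x$coefficients
  cat(paste0("  ", names(est), " = ", signif(est, digits),
             " +/- ", signif(x$se, digits), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              rss = sum(stats::residuals(object$fit)^2),
              n = nrow(object$data))
  if (inherits(object, "mm_fit"))
    out$efficiency <- efficiency(object$coefficients["kcat"],
                                 object$coefficients["km"])
  class(out) <- "summary.kinetic_fit"
  out
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(signif(x$coefficients, 4))
  cat("n =", x$n, " RSS =", format(x$rss, digits = 4), "\n")
  if (!is.null(x$efficiency))
    cat("kcat/Km =", format(unname(x$efficiency), digits = 3), "M^-1 s^-1\n")
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat Turnover number, per second.
#' @param km Michaelis constant, molar (> 0).
#' @return Efficiency in inverse molar per second.
#' @examples
#' efficiency(5.3, 65.4e-6)  # ~8.1e4
#' @export
efficiency <- function(kcat, km) {
  if (any(km <= 0)) stop("Km must be positive")
  if (any(kcat < 0)) stop("kcat must be non-negative")
  kcat / km
}

#' Fold change between a reference and a variant value
#'
#' @param reference,variant Positive numbers (e.g. wild-type and mutant
#'   catalytic efficiencies).
#' @param sig_figs Significant figures for rounding (default 2).
#' @param invert When `TRUE`, reports `variant / reference` instead of
#'   `reference / variant` (use for quantities that increase in the
#'   variant, such as Km).
#' @return The rounded ratio.
#' @examples
#' fold_change(8.1e4, 19.25)                 # efficiency loss
#' fold_change(65.4, 139.4, invert = TRUE)   # Km increase
#' @export
fold_change <- function(reference, variant, sig_figs = 2L, invert = FALSE) {
  if (any(reference <= 0) || any(variant <= 0))
    stop("fold change requires strictly positive values")
  r <- if (invert) variant / reference else reference / variant
  signif(r, sig_figs)
}

#' Binding free-energy difference between two dissociation constants
#'
#' `delta_g(kd_ref, kd_variant, T) = R T ln(kd_variant / kd_ref)` in
#' kcal/mol with R = 1.987e-3 kcal/(mol K). Positive values mean the
#' variant binds less favourably than the reference.
#'
#' @param kd_ref,kd_variant Dissociation constants, molar (> 0).
#' @param temperature Temperature in kelvin (default 298.15, i.e. 25 C).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' delta_g(62.5e-9, 499e-9)  # ~1.23 kcal/mol
#' @export
delta_g <- function(kd_ref, kd_variant, temperature = 298.15) {
  if (any(kd_ref <= 0) || any(kd_variant <= 0) || any(temperature <= 0))
    stop("dissociation constants and temperature must be positive")
  R_KCAL * temperature * log(kd_variant / kd_ref)
}

#' Zinc:protein stoichiometry from a PAR/MMTS assay
#'
#' Calibrates the zinc-bound PAR absorbance at 500 nm against standards of
#' known zinc concentration (ordinary least squares), inverse-predicts the
#' released zinc concentration from the background-subtracted sample
#' absorbance, and reports the molar zinc:protein ratio.
#'
#' @param standards Data frame (or two-column matrix) with columns
#'   `zn_conc` (molar) and `a500` (absorbance); at least two distinct
#'   concentrations.
#' @param sample_a500_background Sample absorbance at 500 nm before zinc
#'   release.
#' @param sample_a500_plateau Sample absorbance after complete release.
#' @param protein_conc Protein concentration, molar (> 0).
#' @return A list with `ratio` (zinc per protein, dimensionless),
#'   `zn_conc` (molar), `calibration` (intercept, slope) and
#'   `extrapolated` (logical; `TRUE`, with a warning, when the sample
#'   absorbance falls outside the standard range).
#' @examples
#' zinc_ratio(data.frame(zn_conc = c(0, 10e-6), a500 = c(0, 0.5)),
#'            sample_a500_background = 0, sample_a500_plateau = 0.465,
#'            protein_conc = 10e-6)$ratio
#' @export
zinc_ratio <- function(standards, sample_a500_background,
                       sample_a500_plateau, protein_conc) {
  standards <- as.data.frame(standards)
  if (is.null(standards$zn_conc) || is.null(standards$a500))
    stop("'standards' needs columns zn_conc and a500")
  if (nrow(standards) < 2L || length(unique(standards$zn_conc)) < 2L)
    stop("singular calibration: need at least two distinct zinc standards")
  if (any(standards$a500 < 0) || sample_a500_background < 0 ||
      sample_a500_plateau < 0)
    stop("absorbances must be non-negative")
  if (protein_conc <= 0) stop("'protein_conc' must be positive")
  cal <- stats::lm(a500 ~ zn_conc, data = standards)
  slope <- unname(stats::coef(cal)[2])
  if (!is.finite(slope) || slope == 0)
    stop("singular calibration: zero slope")
  delta <- sample_a500_plateau - sample_a500_background
  zn <- (delta - unname(stats::coef(cal)[1])) / slope
  extrapolated <- delta < min(standards$a500) || delta > max(standards$a500)
  if (extrapolated)
    warning("sample absorbance outside the standard range; extrapolating")
  list(ratio = zn / protein_conc, zn_conc = zn,
       calibration = c(intercept = unname(stats::coef(cal)[1]), slope = slope),
       extrapolated = extrapolated)
}
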