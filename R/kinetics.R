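# ACE inhibition kinetics: endpoint inhibition percentages, Michaelis-Menten
# fits (double-reciprocal OLS and direct nonlinear least squares),
# inhibition-mode classification with secondary-plot Ki, and
# four-parameter-logistic IC50 estimation.

#' ACE inhibition percentage from an endpoint absorbance assay
#'
#' Implements the FAPGG endpoint formula
#' `100 * ((a1 - a2) - (b1 - b2)) / (a1 - a2)`, where a1/a2 are the blank
#' absorbances before/after the reaction and b1/b2 the sample absorbances
#' (340 nm). A negative result (apparent activation) is returned as-is with
#' a warning.
#'
#' @param a1,a2 blank absorbance before/after; requires `a1 > a2`.
#' @param b1,b2 sample absorbance before/after.
#' @return Inhibition percentage (vectorised).
#' @examples
#' inhibition_percent(1.0, 0.4, 0.9, 0.6)  # 50
#' @export
inhibition_percent <- function(a1, a2, b1, b2) {
  if (any(c(a1, a2, b1, b2) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  if (any(a1 <= a2))
    stop("blank must react: a1 > a2 is required", call. = FALSE)
  out <- 100 * ((a1 - a2) - (b1 - b2)) / (a1 - a2)
  if (any(out < 0))
    warning("negative inhibition (apparent activation) returned as-is")
  out
}

#' Fit Michaelis-Menten kinetics to one substrate series
#'
#' Two routes are provided: `"lineweaver"` (the default) fits the
#' double-reciprocal Lineweaver-Burk line 1/v = (Km/Vmax)(1/S) + 1/Vmax by
#' unweighted OLS, with Vmax and Km read off the intercepts; `"nls"` fits
#' v = Vmax * S / (Km + S) by direct nonlinear least squares
#' ([minpack.lm::nlsLM]), the classical cross-check for reciprocal-plot
#' estimates.
#'
#' @param substrate substrate concentrations (> 0, e.g. mM FAPGG).
#' @param rate initial rates (> 0).
#' @param method `"lineweaver"` or `"nls"`.
#' @return An object of class `mm_fit`: `Vmax`, `Km`, `slope` (Km/Vmax),
#'   `y_intercept` (1/Vmax), `x_intercept` (-1/Km), `method`, `data`,
#'   `r_squared`.
#' @export
fit_mm <- function(substrate, rate, method = c("lineweaver", "nls")) {
  method <- match.arg(method)
  stopifnot(length(substrate) == length(rate))
  if (any(substrate <= 0) || any(rate <= 0))
    stop("substrate concentrations and rates must be strictly positive",
         call. = FALSE)
  if (length(unique(substrate)) < 3L)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  if (method == "lineweaver") {
    lf <- stats::lm(I(1 / rate) ~ I(1 / substrate))
    b0 <- unname(stats::coef(lf)[1]); b1 <- unname(stats::coef(lf)[2])
    vmax <- 1 / b0
    km <- b1 / b0
    iv <- 1 / rate
    r2 <- 1 - sum(stats::resid(lf)^2) / sum((iv - mean(iv))^2)
  } else {
    st <- list(Vmax = max(rate) * 1.2, Km = stats::median(substrate))
    nf <- minpack.lm::nlsLM(rate ~ Vmax * substrate / (Km + substrate),
                            start = st,
                            lower = c(1e-12, 1e-12),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
    cf <- stats::coef(nf)
    vmax <- unname(cf["Vmax"]); km <- unname(cf["Km"])
    r2 <- 1 - sum(stats::resid(nf)^2) / sum((rate - mean(rate))^2)
  }
  if (!is.finite(vmax) || !is.finite(km) || vmax <= 0 || km <= 0)
    stop("kinetic fit failed: non-positive Vmax or Km", call. = FALSE)
  structure(list(Vmax = vmax, Km = km, slope = km / vmax,
                 y_intercept = 1 / vmax, x_intercept = -1 / km,
                 method = method, r_squared = r2,
                 data = data.frame(substrate = substrate, rate = rate)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s): Vmax = %.4g, Km = %.4g (R^2 %.4f)\n",
              x$method, x$Vmax, x$Km, x$r_squared))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(Vmax = object$Vmax, Km = object$Km)
}

#' @export
predict.mm_fit <- function(object, substrate = object$data$substrate, ...) {
  object$Vmax * substrate / (object$Km + substrate)
}

#' Lineweaver-Burk plot of one or more kinetic fits
#'
#' @param x an `mm_fit` or a list of them (e.g. per inhibitor
#'   concentration).
#' @param labels optional legend labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mm_fit <- function(x, labels = NULL, ...) {
  fits <- if (inherits(x, "mm_fit")) list(x) else x
  inv_s <- unlist(lapply(fits, function(f) 1 / f$data$substrate))
  inv_v <- unlist(lapply(fits, function(f) 1 / f$data$rate))
  graphics::plot(inv_s, inv_v, xlab = "1/[S]", ylab = "1/v",
                 main = "Lineweaver-Burk plot", ...)
  for (i in seq_along(fits))
    graphics::abline(fits[[i]]$y_intercept, fits[[i]]$slope, col = i)
  if (!is.null(labels))
    graphics::legend("topleft", legend = labels,
                     col = seq_along(fits), lty = 1, bty = "n")
  invisible(x)
}

#' Classify the inhibition mode and estimate Ki
#'
#' Fits a kinetic model per inhibitor concentration and compares the
#' apparent Km and Vmax trajectories against the uninhibited fit. The shift
#' in each parameter is read from a linear regression of the per-series
#' estimates on inhibitor concentration, evaluated at the highest
#' concentration — pooling the whole trajectory rather than trusting the
#' single noisiest series. With relative tolerance `tol` (default 0.10):
#' Km rising with Vmax constant is competitive; Vmax falling with Km
#' constant is non-competitive; both moving (Km up, Vmax down) is mixed;
#' neither moving is "none". A falling apparent Km is inconsistent with
#' these models and yields mode "none" with a diagnostic. Ki comes from the
#' secondary plot: the reciprocal-line slopes are regressed on inhibitor
#' concentration and Ki is the negated X-intercept.
#'
#' @param data data frame with columns `inhibitor_conc`, `substrate_conc`,
#'   `rate`; must contain inhibitor concentration 0 and at least one
#'   positive level.
#' @param tol relative tolerance for "constant" vs "varying".
#' @param method per-series fitting route, see [fit_mm()].
#' @return An object of class `inhibition_verdict`: `mode`, `Ki`,
#'   `evidence` (per-concentration Km, Vmax, slope and relative shifts),
#'   `fits` (the per-concentration `mm_fit`s), `secondary` (the slope ~
#'   inhibitor regression coefficients), `diagnostic`.
#' @export
classify_inhibition <- function(data, tol = 0.10,
                                method = c("lineweaver", "nls")) {
  method <- match.arg(method)
  need <- c("inhibitor_conc", "substrate_conc", "rate")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  concs <- sort(unique(data$inhibitor_conc))
  if (length(concs) < 2L || concs[1] != 0)
    stop("need inhibitor concentration 0 plus at least one positive level",
         call. = FALSE)
  fits <- lapply(concs, function(ci) {
    d <- data[data$inhibitor_conc == ci, ]
    fit_mm(d$substrate_conc, d$rate, method)
  })
  names(fits) <- as.character(concs)
  km <- vapply(fits, `[[`, numeric(1), "Km")
  vmax <- vapply(fits, `[[`, numeric(1), "Vmax")
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  ev <- data.frame(inhibitor_conc = concs, Km = km, Vmax = vmax,
                   slope = slope,
                   km_shift = km / km[1] - 1,
                   vmax_shift = vmax / vmax[1] - 1)
  rownames(ev) <- NULL
  # trajectory-pooled shift at the strongest inhibition: regress the
  # per-series estimates on [I] and compare fitted endpoints
  traj_shift <- function(v) {
    l <- stats::lm(v ~ concs)
    f0 <- unname(stats::coef(l)[1])
    ftop <- unname(stats::coef(l)[1] + stats::coef(l)[2] * max(concs))
    ftop / f0 - 1
  }
  km_traj <- traj_shift(km)
  vmax_traj <- traj_shift(vmax)
  km_up <- km_traj > tol
  km_down <- km_traj < -tol
  vmax_down <- vmax_traj < -tol
  diagnostic <- NULL
  if (km_down) {
    mode <- "none"
    diagnostic <- "apparent Km decreases with inhibitor: inconsistent with competitive/non-competitive/mixed models"
  } else if (km_up && !vmax_down) {
    mode <- "competitive"
  } else if (vmax_down && !km_up) {
    mode <- "non-competitive"
  } else if (km_up && vmax_down) {
    mode <- "mixed"
  } else {
    mode <- "none"
    diagnostic <- "no Km or Vmax shift beyond tolerance"
  }
  # secondary plot: LB slopes vs [I]; X-intercept = -Ki
  sec <- stats::lm(slope ~ concs)
  a <- unname(stats::coef(sec)[1]); bslope <- unname(stats::coef(sec)[2])
  ki <- if (mode != "none" && is.finite(bslope) && bslope > 0) {
    a / bslope
  } else {
    NA_real_
  }
  structure(list(mode = mode, Ki = ki, evidence = ev, fits = fits,
                 trajectory = c(km_shift = km_traj,
                                vmax_shift = vmax_traj),
                 secondary = c(intercept = a, slope = bslope),
                 tol = tol, diagnostic = diagnostic),
            class = "inhibition_verdict")
}

#' @export
print.inhibition_verdict <- function(x, ...) {
  cat("Inhibition mode:", x$mode)
  if (!is.na(x$Ki)) cat(sprintf("  (Ki = %.4g)", x$Ki))
  cat("\n")
  if (!is.null(x$diagnostic)) cat("note:", x$diagnostic, "\n")
  print(x$evidence, digits = 4)
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits inhibition (%) against inhibitor concentration with the 4PL model
#' `y = bottom + (top - bottom) / (1 + (ic50 / conc)^hill)` by nonlinear
#' least squares ([minpack.lm::nlsLM] on log IC50 for stability). The IC50
#' is the concentration at the midpoint between the fitted bottom and top
#' asymptotes. Inhibition values outside (-20, 120) and an IC50 outside the
#' fitted concentration span are flagged with warnings.
#'
#' @param conc inhibitor concentrations (> 0; at least 5 distinct values).
#' @param inhibition observed inhibition percentages.
#' @return An object of class `ic50_fit` with `ic50`, `coefficients`
#'   (bottom, top, ic50, hill), `data`, `in_span`.
#' @export
fit_ic50 <- function(conc, inhibition) {
  stopifnot(length(conc) == length(inhibition))
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 5L)
    stop("need at least 5 distinct concentrations spanning the transition",
         call. = FALSE)
  if (any(inhibition < -20 | inhibition > 120))
    warning("inhibition values outside (-20, 120): check the assay")
  # pad the asymptote starts so the initial Jacobian is full rank even on
  # exact 4PL data whose extremes coincide with the observed range
  rng <- diff(range(inhibition))
  if (rng == 0) rng <- 1
  mid <- (min(inhibition) + max(inhibition)) / 2
  start <- list(bottom = min(inhibition) - 0.05 * rng,
                top = max(inhibition) + 0.05 * rng,
                lic50 = mean(log(c(conc[which.min(abs(inhibition - mid))],
                                   exp(mean(log(range(conc))))))),
                hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      inhibition ~ bottom + (top - bottom) /
        (1 + (exp(lic50) / conc)^hill),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  ic50 <- unname(exp(cf["lic50"]))
  in_span <- ic50 >= min(conc) && ic50 <= max(conc)
  if (!in_span)
    warning("fitted IC50 lies outside the measured concentration span")
  structure(list(ic50 = ic50,
                 coefficients = c(bottom = unname(cf["bottom"]),
                                  top = unname(cf["top"]),
                                  ic50 = ic50,
                                  hill = unname(cf["hill"])),
                 data = data.frame(conc = conc, inhibition = inhibition),
                 in_span = in_span, nls = fit),
            class = "ic50_fit")
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
print.ic50_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "4PL dose-response fit: IC50 = %.4g (bottom %.3g, top %.3g, hill %.3g)\n",
    cf["ic50"], cf["bottom"], cf["top"], cf["hill"]))
  if (!x$in_span) cat("warning: IC50 outside the measured span\n")
  invisible(x)
}

#' @export
predict.ic50_fit <- function(object, conc = object$data$conc, ...) {
  cf <- object$coefficients
  unname(cf["bottom"] + (cf["top"] - cf["bottom"]) /
           (1 + (cf["ic50"] / conc)^cf["hill"]))
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc, d$inhibition, log = "x",
                 xlab = "inhibitor concentration",
                 ylab = "ACE inhibition (%)",
                 main = sprintf("IC50 = %.3g", x$ic50), ...)
  grid <- exp(seq(log(min(d$conc)), log(max(d$conc)), length.out = 200))
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

# Average residue masses for the mg/mL -> uM helper (free amino acids).
AA_MASS <- c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
             E = 147.13, Q = 146.15, G = 75.07, H = 155.15, I = 131.17,
             L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
             S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19)

#' Average molecular mass of a peptide
#'
#' Sum of free amino-acid average masses minus one water per peptide bond.
#'
#' @param sequence peptide sequence (canonical one-letter codes).
#' @return Mass in g/mol.
#' @export
peptide_mass <- function(sequence) {
  seq <- toupper(sequence)
  validate_sequence(seq, sequence)
  res <- strsplit(seq, "")[[1]]
  sum(AA_MASS[res]) - (length(res) - 1) * 18.02
}

#' Convert a peptide concentration from mg/mL to micromolar
#'
#' @param mg_ml concentration in mg/mL.
#' @param sequence peptide sequence used for the molar mass.
#' @return Concentration in uM.
#' @export
mgml_to_uM <- function(mg_ml, sequence) {
  1e6 * mg_ml / peptide_mass(sequence)
}
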