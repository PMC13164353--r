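# Box-Behnken response-surface modelling of hydrolysis conditions:
# factor coding, quadratic OLS fit, full ANOVA decomposition with
# lack-of-fit split, and constrained optimum search over the coded cube.

#' Factor coding for the three-factor hydrolysis design
#'
#' Maps natural factor levels to the coded levels -1/0/+1 and back. Defaults
#' are the hydrolysis study settings: temperature 50/55/60 degrees C,
#' pH 8/8.5/9, time 2/3/4 h. Intermediate values are mapped linearly.
#'
#' @param temperature,pH,time numeric length-3 vectors of strictly increasing
#'   natural levels for codes (-1, 0, +1).
#' @return A list of class `factor_coding`.
#' @export
bbd_coding <- function(temperature = c(50, 55, 60), pH = c(8, 8.5, 9),
                       time = c(2, 3, 4)) {
  levels <- list(temperature = temperature, pH = pH, time = time)
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) != 3L || any(diff(lv) <= 0))
      stop("factor '", nm, "': need 3 strictly increasing levels",
           call. = FALSE)
    # equispaced levels make code <-> natural a single linear map
    if (abs((lv[2] - lv[1]) - (lv[3] - lv[2])) > 1e-8 * diff(range(lv)))
      stop("factor '", nm, "': levels must be equispaced", call. = FALSE)
  }
  structure(list(levels = levels), class = "factor_coding")
}

#' Convert natural factor settings to coded units
#' @param x data frame with columns `temperature`, `pH`, `time` (natural
#'   units), or a length-3 numeric vector in that order.
#' @param coding a [bbd_coding] object.
#' @return Same shape as `x`, in coded units.
#' @export
code_factors <- function(x, coding = bbd_coding()) {
  map1 <- function(v, lv) (v - lv[2]) / (lv[2] - lv[1])
  factor_map(x, coding, map1)
}

#' Convert coded factor settings to natural units
#' @inheritParams code_factors
#' @export
decode_factors <- function(x, coding = bbd_coding()) {
  map1 <- function(v, lv) lv[2] + v * (lv[2] - lv[1])
  factor_map(x, coding, map1)
}

factor_map <- function(x, coding, map1) {
  nms <- names(coding$levels)
  if (is.numeric(x) && is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    out <- vapply(seq_along(nms),
                  function(i) map1(x[i], coding$levels[[i]]), numeric(1))
    names(out) <- nms
    return(out)
  }
  stopifnot(all(nms %in% names(x)))
  for (nm in nms) x[[nm]] <- map1(x[[nm]], coding$levels[[nm]])
  x
}

#' Read a hydrolysis experiment table
#'
#' @param path CSV file with header `temperature,pH,time,activity` (natural
#'   units; activity in percent).
#' @return A data frame.
#' @export
read_bbd_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "pH", "time", "activity")
  if (!all(need %in% names(df)))
    stop("design table needs columns temperature, pH, time, activity",
         call. = FALSE)
  if (any(!is.finite(df$activity)))
    stop("non-finite response in design table", call. = FALSE)
  df
}

#' Bundled 17-run hydrolysis optimisation experiment
#'
#' The published Box-Behnken experiment on proteinase K hydrolysis of royal
#' jelly proteins: 12 edge-midpoint runs plus 5 centre replicates, response
#' = ACE inhibitory activity (%) of the hydrolysate (triplicate means).
#'
#' @return A data frame with columns `temperature`, `pH`, `time`, `activity`.
#' @export
hydrolysis_design <- function() {
  read_bbd_design(system.file("extdata", "hydrolysis_design.csv",
                              package = "acepep", mustWork = TRUE))
}

bbd_model_matrix <- function(A, B, C) {
  cbind(`(Intercept)` = 1, A = A, B = B, C = C,
        AB = A * B, AC = A * C, BC = B * C,
        A2 = A^2, B2 = B^2, C2 = C^2)
}

#' Fit the coded quadratic response-surface model
#'
#' Ordinary least squares of the response on the full second-order model in
#' coded units: intercept, three linear terms, three two-way interactions and
#' three pure quadratic terms (10 parameters, 7 residual df on the 17-run
#' Box-Behnken design).
#'
#' @param design a design data frame (natural units) as returned by
#'   [hydrolysis_design()] or [read_bbd_design()].
#' @param coding a [bbd_coding] object.
#' @return An object of class `bbd_fit` with components `lm` (the underlying
#'   [stats::lm] fit), `coding`, `coded` (design in coded units) and
#'   `response`.
#' @examples
#' fit <- fit_bbd(hydrolysis_design())
#' coef(fit)
#' @export
fit_bbd <- function(design, coding = bbd_coding()) {
  stopifnot(is.data.frame(design))
  need <- c("temperature", "pH", "time", "activity")
  if (!all(need %in% names(design)))
    stop("design needs columns temperature, pH, time, activity",
         call. = FALSE)
  if (any(!is.finite(design$activity)))
    stop("non-finite response", call. = FALSE)
  cd <- code_factors(design[, c("temperature", "pH", "time")], coding)
  d <- data.frame(A = cd$temperature, B = cd$pH, C = cd$time,
                  y = design$activity)
  X <- bbd_model_matrix(d$A, d$B, d$C)
  if (qr(X)$rank < ncol(X))
    stop("design is rank-deficient for the quadratic model ",
         "(duplicated or missing design points)", call. = FALSE)
  fit <- stats::lm(y ~ A + B + C + I(A * B) + I(A * C) + I(B * C) +
                     I(A^2) + I(B^2) + I(C^2), data = d)
  cf <- stats::coef(fit)
  names(cf) <- colnames(X)
  structure(list(lm = fit, coding = coding, coded = d,
                 coefficients = cf, response = design$activity),
            class = "bbd_fit")
}

#' @export
coef.bbd_fit <- function(object, ...) object$coefficients

#' @export
fitted.bbd_fit <- function(object, ...) unname(stats::fitted(object$lm))

#' @export
residuals.bbd_fit <- function(object, ...) unname(stats::resid(object$lm))

#' Predict the response surface
#'
#' @param object a `bbd_fit`.
#' @param newdata data frame with columns `temperature`, `pH`, `time`; by
#'   default in natural units (`units = "natural"`), or already coded.
#' @param units `"natural"` or `"coded"`.
#' @param ... unused.
#' @return Numeric vector of predicted responses (%).
#' @export
predict.bbd_fit <- function(object, newdata = NULL,
                            units = c("natural", "coded"), ...) {
  if (is.null(newdata)) return(fitted(object))
  units <- match.arg(units)
  nms <- c("temperature", "pH", "time")
  stopifnot(all(nms %in% names(newdata)))
  cd <- if (units == "natural") {
    code_factors(newdata[, nms], object$coding)
  } else {
    newdata[, nms]
  }
  X <- bbd_model_matrix(cd$temperature, cd$pH, cd$time)
  unname(drop(X %*% object$coefficients))
}

predict_coded <- function(object, m) {
  # m: matrix with columns A,B,C in coded units
  X <- bbd_model_matrix(m[, 1], m[, 2], m[, 3])
  drop(X %*% object$coefficients)
}

#' @export
print.bbd_fit <- function(x, digits = 4, ...) {
  cat("Quadratic response-surface fit (coded units)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R-squared: %.4f on %d runs\n",
              summary(x$lm)$r.squared, nrow(x$coded)))
  invisible(x)
}

#' @export
summary.bbd_fit <- function(object, ...) {
  out <- list(fit = object, anova = anova(object),
              optimum = find_optimum(object))
  class(out) <- "summary.bbd_fit"
  out
}

#' @export
print.summary.bbd_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$anova)
  cat("\nConstrained optimum (coded cube):\n")
  op <- x$optimum
  cat(sprintf("  temperature %.2f, pH %.2f, time %.2f -> predicted %.2f%%\n",
              op$natural["temperature"], op$natural["pH"],
              op$natural["time"], op$predicted))
  invisible(x)
}

#' ANOVA decomposition of a response-surface fit
#'
#' Partial (marginal) sums of squares per model term — identical to
#' sequential sums of squares on the orthogonal Box-Behnken design — with
#' the residual split into lack of fit and pure error from replicate design
#' points. Term F tests use the residual mean square; the lack-of-fit test
#' uses the pure-error mean square. Diagnostics: R-squared, adjusted and
#' predicted R-squared, PRESS (leave-one-out identity), model standard
#' deviation, coefficient of variation and adequate precision
#' (signal-to-noise ratio (max fitted - min fitted) / sqrt(p * MS_resid / n)).
#'
#' @param object a `bbd_fit`.
#' @param ... unused.
#' @return A data frame of class `bbd_anova` with columns `source`, `ss`,
#'   `df`, `ms`, `f`, `p` and diagnostics in attributes
#'   (`attr(x, "diagnostics")`).
#' @export
anova.bbd_fit <- function(object, ...) {
  fit <- object$lm
  y <- object$coded$y
  n <- length(y)
  p <- length(object$coefficients)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::resid(fit)^2)
  ss_mod <- ss_tot - ss_res
  df_res <- n - p
  # marginal (type III) SS; for numeric predictors drop1 gives exactly this
  # drop1's AIC computation complains on an exact (zero-residual) fit;
  # only the marginal SS column is used here
  dr <- withCallingHandlers(
    stats::drop1(fit, scope = stats::formula(fit)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  term_ss <- dr$`Sum of Sq`[-1]
  term_names <- c("A (temperature)", "B (pH)", "C (time)",
                  "AB", "AC", "BC", "A^2", "B^2", "C^2")
  # replicate groups for pure error
  key <- interaction(object$coded$A, object$coded$B, object$coded$C,
                     drop = TRUE)
  reps <- table(key)
  has_reps <- any(reps > 1)
  if (has_reps) {
    ss_pe <- sum(tapply(y, key, function(v) sum((v - mean(v))^2)))
    df_pe <- sum(reps - 1)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
  } else {
    ss_pe <- df_pe <- ss_lof <- df_lof <- NA_real_
    warning("no replicated design points: lack-of-fit split unavailable")
  }
  ms_res <- ss_res / df_res
  rows <- list(
    c("Model", ss_mod, p - 1, ss_mod / (p - 1),
      (ss_mod / (p - 1)) / ms_res),
    mapply(function(nm, ss) c(nm, ss, 1, ss, ss / ms_res),
           term_names, term_ss, SIMPLIFY = FALSE),
    c("Residual", ss_res, df_res, ms_res, NA),
    if (has_reps) c("Lack of fit", ss_lof, df_lof, ss_lof / df_lof,
                    if (df_pe > 0 && ss_pe > 0)
                      (ss_lof / df_lof) / (ss_pe / df_pe) else NA),
    if (has_reps) c("Pure error", ss_pe, df_pe,
                    if (df_pe > 0) ss_pe / df_pe else NA, NA),
    c("Cor total", ss_tot, n - 1, NA, NA))
  rows <- c(rows[1], rows[[2]], rows[3:length(rows)])
  rows <- Filter(Negate(is.null), rows)
  tab <- data.frame(
    source = vapply(rows, `[[`, "", 1),
    ss = as.numeric(vapply(rows, `[[`, "", 2)),
    df = as.numeric(vapply(rows, `[[`, "", 3)),
    ms = as.numeric(vapply(rows, `[[`, "", 4)),
    f = as.numeric(vapply(rows, `[[`, "", 5)),
    stringsAsFactors = FALSE)
  # p-values: terms & model vs residual df; lack of fit vs pure-error df
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    src <- tab$source[i]
    if (is.na(tab$f[i])) next
    if (src == "Lack of fit") {
      tab$p[i] <- stats::pf(tab$f[i], tab$df[i], df_pe, lower.tail = FALSE)
    } else {
      tab$p[i] <- stats::pf(tab$f[i], tab$df[i], df_res, lower.tail = FALSE)
    }
  }
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  press <- sum((stats::resid(fit) / (1 - h))^2)
  diagnostics <- c(
    r_squared = 1 - ss_res / ss_tot,
    adj_r_squared = 1 - (ss_res / df_res) / (ss_tot / (n - 1)),
    pred_r_squared = 1 - press / ss_tot,
    press = press,
    std_dev = sqrt(ms_res),
    mean = mean(y),
    cv_percent = 100 * sqrt(ms_res) / mean(y),
    adeq_precision = (max(stats::fitted(fit)) - min(stats::fitted(fit))) /
      sqrt(p * ms_res / n))
  structure(tab, class = c("bbd_anova", "data.frame"),
            diagnostics = diagnostics)
}

#' @export
print.bbd_anova <- function(x, digits = 4, ...) {
  cat("ANOVA for the quadratic response-surface model\n")
  tab <- x
  tab$ss <- signif(tab$ss, digits + 1)
  tab$ms <- signif(tab$ms, digits + 1)
  tab$f <- signif(tab$f, digits)
  tab$p <- signif(tab$p, digits - 1)
  print.data.frame(tab, row.names = FALSE, na.print = "")
  d <- attr(x, "diagnostics")
  cat(sprintf(paste0("R-sq %.4f | adj %.4f | pred %.4f | PRESS %.2f | ",
                     "sd %.3f | Adeq Precision %.2f\n"),
              d["r_squared"], d["adj_r_squared"], d["pred_r_squared"],
              d["press"], d["std_dev"], d["adeq_precision"]))
  invisible(x)
}

#' Locate the constrained optimum of the fitted surface
#'
#' Maximises the fitted quadratic over the coded cube [-1, 1]^3. If the
#' stationary point of the quadratic is an interior maximum (negative
#' definite Hessian) it is returned directly; otherwise a multi-start
#' bound-constrained quasi-Newton search over the cube locates the boundary
#' optimum (with a warning for a saddle with no interior maximum).
#'
#' @param fit a `bbd_fit`.
#' @param coding optional [bbd_coding] used to decode (defaults to the
#'   coding stored in the fit).
#' @return A list with `coded` (length-3 vector), `natural` (named vector:
#'   temperature, pH, time), `predicted` (%), and `interior` (logical).
#' @examples
#' find_optimum(fit_bbd(hydrolysis_design()))
#' @export
find_optimum <- function(fit, coding = fit$coding) {
  stopifnot(inherits(fit, "bbd_fit"))
  b <- fit$coefficients
  g <- b[c("A", "B", "C")]
  H <- matrix(c(2 * b["A2"], b["AB"], b["AC"],
                b["AB"], 2 * b["B2"], b["BC"],
                b["AC"], b["BC"], 2 * b["C2"]), 3, 3)
  interior <- FALSE
  xopt <- NULL
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev < 0)) {
    xs <- drop(solve(H, -g))
    if (all(abs(xs) <= 1)) {
      interior <- TRUE
      xopt <- xs
    }
  }
  if (is.null(xopt)) {
    if (any(ev > 0) && any(ev < 0))
      warning("fitted surface is a saddle: returning boundary optimum")
    obj <- function(x) -predict_coded(fit, matrix(x, 1))
    starts <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                        lower = -1, upper = 1)
      if (is.null(best) || o$value < best$value) best <- o
    }
    xopt <- best$par
  }
  names(xopt) <- c("A", "B", "C")
  nat <- decode_factors(unname(xopt), coding)
  list(coded = xopt,
       natural = nat,
       predicted = unname(predict_coded(fit, matrix(xopt, 1))),
       interior = interior)
}

#' Contour plot of the fitted surface
#'
#' Draws filled contours of the fitted response over two factors with the
#' third held at its value in `at` (default: the located optimum).
#'
#' @param x a `bbd_fit`.
#' @param which character length-2, the factors on the axes (subset of
#'   `c("temperature", "pH", "time")`).
#' @param at optional named coded triple for the slice point.
#' @param n grid resolution per axis.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.bbd_fit <- function(x, which = c("temperature", "pH"), at = NULL,
                         n = 60, ...) {
  nms <- c("temperature", "pH", "time")
  which <- match.arg(which, nms, several.ok = TRUE)[1:2]
  if (is.null(at)) at <- find_optimum(x)$coded
  idx <- match(which, nms)
  grid <- seq(-1, 1, length.out = n)
  z <- outer(grid, grid, function(u, v) {
    m <- matrix(rep(at, each = length(u)), ncol = 3)
    m[, idx[1]] <- u
    m[, idx[2]] <- v
    predict_coded(x, m)
  })
  lv <- x$coding$levels
  ax <- function(i) lv[[nms[i]]][2] + grid * (lv[[nms[i]]][2] -
                                                lv[[nms[i]]][1])
  graphics::filled.contour(ax(idx[1]), ax(idx[2]), z,
                           xlab = which[1], ylab = which[2],
                           main = "Fitted ACE inhibitory activity (%)", ...)
  invisible(x)
}
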