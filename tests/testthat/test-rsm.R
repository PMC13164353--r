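test_that("factor coding is an inverse bijection at the design levels", {
  coding <- bbd_coding()
  nat <- data.frame(temperature = c(50, 55, 60), pH = c(8, 8.5, 9),
                    time = c(2, 3, 4))
  coded <- code_factors(nat, coding)
  expect_equal(coded$temperature, c(-1, 0, 1))
  expect_equal(coded$pH, c(-1, 0, 1))
  expect_equal(coded$time, c(-1, 0, 1))
  expect_equal(decode_factors(coded, coding), nat)
  # linear interpolation between levels
  expect_equal(unname(code_factors(c(56.03, 8.70, 3.09), coding)),
               c(0.206, 0.4, 0.09), tolerance = 1e-9)
  expect_error(bbd_coding(temperature = c(50, 60, 55)), "increasing")
})

test_that("noiseless quadratic surfaces are recovered exactly", {
  beta <- c(`(Intercept)` = 60, A = 2, B = -1.5, C = 1, AB = 0.8,
            AC = -0.3, BC = 0.2, A2 = -4, B2 = -2, C2 = -6)
  sim <- gen_bbd(beta, sigma = 0, seed = 3)
  fit <- fit_bbd(sim$design)
  expect_equal(coef(fit), beta, tolerance = 1e-8)
  an <- anova(fit)
  expect_equal(an$ss[an$source == "Residual"], 0, tolerance = 1e-12)
  expect_equal(an$ss[an$source == "Lack of fit"], 0, tolerance = 1e-12)

  # constant response: only the intercept survives
  sim$design$activity <- 55
  fitc <- fit_bbd(sim$design)
  expect_equal(unname(coef(fitc)[1]), 55)
  expect_equal(unname(coef(fitc)[-1]), rep(0, 9), tolerance = 1e-10)
  expect_equal(anova(fitc)$ss[1], 0, tolerance = 1e-12)
})

test_that("a degenerate design triggers a singularity error", {
  d <- hydrolysis_design()
  d[1:12, c("temperature", "pH", "time")] <- d[rep(13, 12),
                                               c("temperature", "pH", "time")]
  expect_error(fit_bbd(d), "rank-deficient")
})

test_that("ANOVA identities hold and match the orthogonality oracle", {
  set.seed(21)
  for (i in 1:10) {
    beta <- c(rnorm(1, 60, 5), rnorm(6, 0, 2), rnorm(3, -4, 1))
    names(beta) <- c("(Intercept)", "A", "B", "C", "AB", "AC", "BC",
                     "A2", "B2", "C2")
    sim <- gen_bbd(beta, sigma = 0.9, seed = 100 + i)
    fit <- fit_bbd(sim$design)
    an <- anova(fit)
    ss <- function(s) an$ss[an$source == s]
    df_ <- function(s) an$df[an$source == s]
    expect_equal(ss("Model") + ss("Residual"), ss("Cor total"),
                 tolerance = 1e-6 * ss("Cor total"))
    expect_equal(ss("Lack of fit") + ss("Pure error"), ss("Residual"),
                 tolerance = 1e-8)
    expect_equal(df_("Model"), 9)
    expect_equal(df_("Residual"), 7)
    expect_equal(df_("Lack of fit"), 3)
    expect_equal(df_("Pure error"), 4)
    expect_equal(df_("Cor total"), 16)
    # partial SS == sequential SS == 8 * beta_hat^2 for main effects on a BBD
    b <- coef(fit)
    for (term in c("A (temperature)", "B (pH)", "C (time)")) {
      bname <- substr(term, 1, 1)
      expect_equal(ss(term), 8 * b[[bname]]^2, tolerance = 1e-8)
    }
    # fitted + residual = observed
    expect_equal(fitted(fit) + residuals(fit), sim$design$activity)
    d <- attr(an, "diagnostics")
    expect_equal(unname(d["r_squared"]),
                 1 - ss("Residual") / ss("Cor total"))
  }
})

test_that("F-statistic p-values match the F distribution", {
  fit <- fit_bbd(hydrolysis_design())
  an <- anova(fit)
  i <- which(an$source == "Model")
  expect_equal(an$p[i], pf(an$f[i], 9, 7, lower.tail = FALSE))
  j <- which(an$source == "Lack of fit")
  expect_equal(an$p[j], pf(an$f[j], 3, 4, lower.tail = FALSE))
})

test_that("optimum search agrees with the dense-grid oracle", {
  # symmetric concave separable surface peaks at the centre
  beta0 <- c(`(Intercept)` = 10, A = 0, B = 0, C = 0, AB = 0, AC = 0,
             BC = 0, A2 = -1, B2 = -1, C2 = -1)
  sim <- gen_bbd(beta0, sigma = 0, seed = 5)
  opt0 <- find_optimum(fit_bbd(sim$design))
  expect_equal(unname(opt0$coded), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(opt0$predicted, 10)
  expect_equal(unname(opt0$natural), c(55, 8.5, 3))

  # a surface maximised at a vertex (convex in A)
  betaV <- c(`(Intercept)` = 10, A = 3, B = 2, C = -2, AB = 0, AC = 0,
             BC = 0, A2 = 2, B2 = -0.5, C2 = -0.5)
  simV <- gen_bbd(betaV, sigma = 0, seed = 6)
  fitV <- fit_bbd(simV$design)
  optV <- suppressWarnings(find_optimum(fitV))
  oV <- oracle_grid_optimum(betaV)
  expect_lt(max(abs(unname(optV$coded) - oV$coded)), 0.01)

  # random quadratics
  set.seed(33)
  for (i in 1:12) {
    beta <- c(rnorm(1, 50, 5), rnorm(6, 0, 1.5), rnorm(3, -2, 2))
    names(beta) <- names(beta0)
    sim <- gen_bbd(beta, sigma = 0, seed = 200 + i)
    opt <- suppressWarnings(find_optimum(fit_bbd(sim$design)))
    o <- oracle_grid_optimum(beta)
    expect_equal(opt$predicted, o$value, tolerance = 1e-4)
    expect_lt(max(abs(unname(opt$coded) - o$coded)), 0.01)
  }
})

test_that("the hydrolysis experiment reproduces the published fit", {
  fit <- fit_bbd(hydrolysis_design())
  an <- anova(fit)
  d <- attr(an, "diagnostics")
  expect_equal(unname(d["r_squared"]), 0.9868, tolerance = 0.005 / 0.9868)
  expect_equal(an$ss[an$source == "A (temperature)"], 23.81,
               tolerance = 0.05)
  expect_equal(an$f[an$source == "Model"], 58.08, tolerance = 0.05)
  opt <- find_optimum(fit)
  expect_true(opt$interior)
  expect_equal(unname(opt$natural["pH"]), 8.70, tolerance = 0.05 / 8.70)
  expect_equal(opt$predicted, 66.31, tolerance = 0.5 / 66.31)
  # lack of fit not significant, as reported
  expect_gt(an$p[an$source == "Lack of fit"], 0.05)
})
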