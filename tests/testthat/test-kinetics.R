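test_that("endpoint inhibition formula and its edge cases", {
  expect_equal(inhibition_percent(1.0, 0.4, 0.9, 0.6), 50)
  expect_equal(inhibition_percent(1.0, 0.4, 1.0, 0.4), 0)   # no inhibition
  expect_equal(inhibition_percent(1.0, 0.4, 0.7, 0.7), 100) # complete
  # affine invariance under common rescaling of all four absorbances
  expect_equal(inhibition_percent(2.0, 0.8, 1.8, 1.2),
               inhibition_percent(1.0, 0.4, 0.9, 0.6))
  expect_error(inhibition_percent(0.4, 0.4, 0.3, 0.2), "a1 > a2")
  expect_error(inhibition_percent(1, -0.1, 0.5, 0.2), "non-negative")
  expect_warning(inhibition_percent(1.0, 0.4, 0.9, 0.2), "negative")
})

test_that("noiseless Michaelis-Menten data is recovered exactly by both routes", {
  S <- c(0.25, 0.5, 1, 2)
  v <- 1.0 * S / (0.5 + S)
  for (m in c("lineweaver", "nls")) {
    fit <- fit_mm(S, v, method = m)
    expect_equal(unname(coef(fit)), c(1.0, 0.5), tolerance = 1e-8)
  }
  lb <- fit_mm(S, v)
  expect_equal(lb$y_intercept, 1, tolerance = 1e-10)
  expect_equal(lb$x_intercept, -2, tolerance = 1e-10)
  # at [I] = Ki the apparent Km doubles, Vmax is unchanged
  v_i <- 1.0 * S / (0.5 * 2 + S)
  fi <- fit_mm(S, v_i)
  expect_equal(unname(coef(fi)), c(1.0, 1.0), tolerance = 1e-8)
  expect_error(fit_mm(c(1, 2), c(0.5, 0.6)), "3 distinct")
  expect_error(fit_mm(S, -v), "positive")
})

test_that("reciprocal-OLS and direct NLS agree on lightly noisy data", {
  set.seed(17)
  S <- rep(0.5 * exp(seq(log(0.2), log(5), length.out = 8)), 1)
  for (i in 1:20) {
    v <- (1.0 * S / (0.5 + S)) * (1 + rnorm(length(S), 0, 0.02))
    f1 <- fit_mm(S, v, "lineweaver")
    f2 <- fit_mm(S, v, "nls")
    expect_equal(coef(f1), coef(f2), tolerance = 0.1)
  }
})

test_that("direct NLS beats reciprocal OLS under multiplicative noise", {
  set.seed(23)
  S <- 0.5 * exp(seq(log(0.2), log(5), length.out = 6))
  err <- function(fit) sum((coef(fit) - c(Vmax = 1, Km = 0.5))^2)
  rmse <- vapply(1:200, function(i) {
    v <- (1.0 * S / (0.5 + S)) * (1 + rnorm(length(S), 0, 0.08))
    c(err(fit_mm(S, v, "lineweaver")), err(fit_mm(S, v, "nls")))
  }, numeric(2))
  expect_lt(mean(rmse[2, ]), mean(rmse[1, ]))
})

test_that("generator round-trips classify all three inhibition modes", {
  for (mode in c("competitive", "non-competitive", "mixed")) {
    sim <- gen_kinetics(mode, cv = 0, seed = 2)
    verdict <- classify_inhibition(sim$data)
    expect_equal(verdict$mode, mode)
    expect_equal(verdict$Ki, 10, tolerance = 0.02)
  }
  # competitive evidence: Km rises, Vmax flat
  sim <- gen_kinetics("competitive", cv = 0, seed = 2)
  v <- classify_inhibition(sim$data)
  expect_true(all(diff(v$evidence$Km) > 0))
  expect_equal(v$evidence$Vmax, rep(1, nrow(v$evidence)), tolerance = 1e-6)
  # degenerate input: zero-inhibitor only
  d0 <- sim$data[sim$data$inhibitor_conc == 0, ]
  expect_error(classify_inhibition(d0), "at least one positive")
  # falling Km is flagged as inconsistent
  bad <- sim$data
  bad$rate[bad$inhibitor_conc > 0] <-
    with(bad[bad$inhibitor_conc > 0, ],
         1.0 * substrate_conc / (0.2 + substrate_conc))
  vb <- classify_inhibition(bad)
  expect_equal(vb$mode, "none")
  expect_match(vb$diagnostic, "Km decreases")
})

test_that("Ki is recovered within 10% at 2% noise", {
  set.seed(29)
  rel_err <- vapply(1:40, function(i) {
    sim <- gen_kinetics("competitive", Ki = 10,
                        inhibitor_concs = c(0, 5, 10, 20), replicates = 1,
                        cv = 0.02, seed = 1000 + i)
    abs(classify_inhibition(sim$data)$Ki - 10) / 10
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("4PL fits recover the dose-response generator", {
  sim <- gen_dose_response(ic50 = 16.9, hill = 1, sigma = 0, seed = 4)
  fit <- fit_ic50(sim$data$conc, sim$data$inhibition)
  expect_equal(fit$ic50, 16.9, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[c("bottom", "top", "hill")]),
               c(0, 100, 1), tolerance = 1e-5)
  # symmetry: reflecting the design around IC50 on the log axis leaves
  # the estimate unchanged
  concs <- 16.9 * 2^c(-3, -2, -1, 0, 1, 2, 3)
  y <- 100 / (1 + 16.9 / concs)
  f1 <- fit_ic50(concs, y)
  f2 <- fit_ic50(rev(16.9^2 / concs), rev(100 / (1 + 16.9 / (16.9^2 / concs))))
  expect_equal(f1$ic50, f2$ic50, tolerance = 1e-6)
  expect_error(fit_ic50(c(1, 2, 4, 8), c(10, 30, 60, 90)), "at least 5")
  expect_warning(fit_ic50(sim$data$conc, sim$data$inhibition + 30),
                 "outside")
})

test_that("peptide mass conversion matches a hand calculation", {
  # IDFDF: I 131.17 + D 133.10 + F 165.19 + D 133.10 + F 165.19 - 4*18.02
  expect_equal(peptide_mass("IDFDF"),
               131.17 + 133.10 + 165.19 + 133.10 + 165.19 - 4 * 18.02,
               tolerance = 1e-12)
  # 1 mg/mL of a ~655.67 g/mol peptide is ~1525 uM
  expect_equal(mgml_to_uM(1, "IDFDF"), 1e6 / peptide_mass("IDFDF"))
  expect_error(peptide_mass("IDXDF"), "illegal")
})
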