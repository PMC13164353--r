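test_that("generators are pure functions of (spec, seed)", {
  expect_identical(gen_proteome(seed = 42), gen_proteome(seed = 42))
  expect_identical(gen_bbd(seed = 42), gen_bbd(seed = 42))
  expect_identical(gen_kinetics("mixed", seed = 42),
                   gen_kinetics("mixed", seed = 42))
  expect_identical(gen_candidates(seed = 42), gen_candidates(seed = 42))
  expect_identical(gen_dose_response(seed = 42),
                   gen_dose_response(seed = 42))
  # different seeds give different draws
  expect_false(identical(gen_candidates(seed = 1)$candidates$abundance,
                         gen_candidates(seed = 2)$candidates$abundance))
  # labelled sub-streams: generators do not perturb each other
  a <- gen_candidates(seed = 7)
  invisible(gen_proteome(seed = 7))
  b <- gen_candidates(seed = 7)
  expect_identical(a, b)
})

test_that("planted motifs bound the occurrence frequency from below", {
  sim <- gen_proteome(n_proteins = 6, planting_rate = 2, seed = 5)
  for (pid in sim$records$id) {
    k <- sum(sim$truth$protein_id == pid)
    n <- nchar(sim$records$sequence[sim$records$id == pid])
    a <- occurrence_frequency(
      sim$records[sim$records$id == pid, , drop = FALSE],
      "ACE inhibitor", sim$ref)
    expect_gte(a, k / n)
  }
  # every truth row is a real match at the recorded position
  for (i in seq_len(nrow(sim$truth))) {
    seq <- sim$records$sequence[sim$records$id == sim$truth$protein_id[i]]
    s <- sim$truth$position[i]
    m <- sim$truth$motif[i]
    expect_equal(substr(seq, s, s + nchar(m) - 1), m)
  }
  # a motif using a residue outside the generator support never occurs:
  # the generator draws from all 20 residues, so instead check the exact-0
  # contract with an unplanted, absent motif on a tiny crafted reference
  expect_equal(occurrence_frequency("GGGG", "x", bioactive_ref("x", "WW")), 0)
  expect_error(gen_proteome(length_range = c(3, 5), motifs = "ACDEFGH"),
               "longer")
})

test_that("the synthetic response-surface experiment matches its spec", {
  sim <- gen_bbd(sigma = 0, seed = 8)
  expect_equal(nrow(sim$design), 17L)
  coded <- code_factors(sim$design[, c("temperature", "pH", "time")])
  m <- as.matrix(coded)
  # 12 edge midpoints (two factors at +/-1, one at 0) and 5 centres
  n_nonzero <- rowSums(m != 0)
  expect_equal(sum(n_nonzero == 2), 12L)
  expect_equal(sum(n_nonzero == 0), 5L)
  expect_true(all(m %in% c(-1, 0, 1)))
  # noiseless responses interpolate the generator truth
  expect_equal(coef(fit_bbd(sim$design)), sim$beta, tolerance = 1e-8)
  # centre replicates scatter like sigma
  set.seed(1)
  sds <- vapply(1:150, function(i) {
    s <- gen_bbd(sigma = 0.9, seed = i)
    sd(s$design$activity[13:17])
  }, numeric(1))
  # E[sd of 5 draws] = c4(5) * sigma ~= 0.94 * 0.9 = 0.846
  expect_equal(mean(sds), 0.94 * 0.9, tolerance = 0.1)
})

test_that("candidate generator truth ranking is the analytic score card", {
  sim <- gen_candidates(n = 25, seed = 3)
  card <- candidate_scores(sim$candidates)
  expect_equal(card$sequence, sim$truth$sequence)
  expect_equal(card$total, sim$truth$total)
  one <- gen_candidates(n = 1, seed = 3)
  expect_equal(one$truth$total, 100)
  expect_equal(one$truth$score_A, 100)
})

test_that("noiseless kinetic data reproduces the generator parameters", {
  for (mode in c("competitive", "non-competitive", "mixed")) {
    sim <- gen_kinetics(mode, Vmax = 2, Km = 0.8, Ki = 15, cv = 0, seed = 6)
    base <- sim$data[sim$data$inhibitor_conc == 0, ]
    fit <- fit_mm(base$substrate_conc, base$rate)
    expect_equal(unname(coef(fit)), c(2, 0.8), tolerance = 1e-8)
  }
  sim <- gen_dose_response(ic50 = 42.5, hill = 1.3, sigma = 0, seed = 6)
  expect_equal(fit_ic50(sim$data$conc, sim$data$inhibition)$ic50, 42.5,
               tolerance = 1e-6)
})

test_that("simulate_inputs writes a complete, reloadable input set", {
  out <- tempfile("siminputs")
  simulate_inputs(out, seed = 11)
  expect_true(all(file.exists(file.path(out,
    c("proteome.fasta", "reference.tsv", "design.csv", "candidates.csv",
      "kinetics.csv", "dose_response.csv", "truth.json")))))
  prot <- read_fasta(file.path(out, "proteome.fasta"))
  expect_equal(nrow(prot), 9L)
  ref <- read_bioactive_ref(file.path(out, "reference.tsv"))
  expect_gt(nrow(ref), 0)
  design <- read_bbd_design(file.path(out, "design.csv"))
  expect_equal(nrow(design), 17L)
  cand <- read_candidates(file.path(out, "candidates.csv"))
  expect_equal(nrow(cand), 57L)
})
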