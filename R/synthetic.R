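# Synthetic-data generators: every pipeline input with known ground truth,
# reproducible from (spec, seed). Each generator draws from its own stream
# derived from the master seed by a stable labelled sub-seed, so adding a
# generator never perturbs the others.

sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103 + h * 12289) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, label))
  force(expr)
}

# Background residue frequencies (rough vertebrate/insect proteome averages).
AA_FREQ <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.018,
             E = 0.062, Q = 0.041, G = 0.071, H = 0.022, I = 0.055,
             L = 0.092, K = 0.058, M = 0.023, F = 0.040, P = 0.051,
             S = 0.071, T = 0.057, V = 0.065, W = 0.013, Y = 0.032)

#' Generate a synthetic proteome with planted bioactive motifs
#'
#' Emulates a small protein family (defaults sized like the nine major royal
#' jelly proteins, 300-600 residues) by drawing residues from background
#' proteome frequencies and planting known bioactive motifs at random
#' non-overlapping positions. The planted-truth table allows every
#' downstream occurrence statistic to be checked against ground truth.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer length-2, residue-count range.
#' @param motifs character vector of motifs to plant (default: five
#'   ACE-inhibitory dipeptides from the bundled demo reference).
#' @param activity activity label attached to the motifs.
#' @param planting_rate expected planted motifs per 100 residues.
#' @param seed master seed.
#' @return A list: `records` ([protein_records]), `ref` ([bioactive_ref]),
#'   `truth` (data frame protein_id, motif, position).
#' @export
gen_proteome <- function(n_proteins = 9, length_range = c(300, 600),
                         motifs = c("IY", "VY", "KF", "VW", "AP"),
                         activity = "ACE inhibitor",
                         planting_rate = 1, seed = 1) {
  stopifnot(n_proteins >= 1, length_range[1] >= 2,
            length_range[2] >= length_range[1], planting_rate >= 0)
  motifs <- toupper(motifs)
  if (any(nchar(motifs) < 2))
    stop("motifs must be at least 2 residues", call. = FALSE)
  if (max(nchar(motifs)) > length_range[1])
    stop("motif longer than the shortest allowed protein", call. = FALSE)
  with_stream(seed, "proteome", {
    truth <- list()
    seqs <- character(n_proteins)
    ids <- sprintf("SYN%03d", seq_len(n_proteins))
    for (i in seq_len(n_proteins)) {
      n <- sample(seq(length_range[1], length_range[2]), 1)
      res <- sample(names(AA_FREQ), n, replace = TRUE, prob = AA_FREQ)
      k <- stats::rpois(1, planting_rate * n / 100)
      placed <- integer(0)
      plist <- list()
      for (j in seq_len(k)) {
        m <- sample(motifs, 1)
        lm_ <- nchar(m)
        # rejection-sample a start that does not overlap earlier plants
        for (try in 1:50) {
          s <- sample.int(n - lm_ + 1, 1)
          span <- s:(s + lm_ - 1)
          if (!any(span %in% placed)) {
            res[span] <- strsplit(m, "")[[1]]
            placed <- c(placed, span)
            plist[[length(plist) + 1]] <-
              data.frame(protein_id = ids[i], motif = m, position = s,
                         stringsAsFactors = FALSE)
            break
          }
        }
      }
      seqs[i] <- paste(res, collapse = "")
      truth[[i]] <- if (length(plist)) do.call(rbind, plist) else NULL
    }
    truth <- do.call(rbind, Filter(Negate(is.null), truth))
    if (is.null(truth))
      truth <- data.frame(protein_id = character(0), motif = character(0),
                          position = integer(0))
    list(records = protein_records(ids, seqs),
         ref = bioactive_ref(rep(activity, length(motifs)), motifs),
         truth = truth)
  })
}

#' Generate a synthetic Box-Behnken experiment
#'
#' Builds the 17-run three-factor Box-Behnken design (12 edge midpoints + 5
#' centre replicates) and simulates the response from a known coded
#' quadratic surface plus Gaussian noise. The default coefficient vector is
#' the fit to the bundled hydrolysis experiment, and the default noise is
#' sigma = 0.9 (the hydrolysis model's residual standard deviation), so the
#' generator emulates the study conditions.
#'
#' @param beta named numeric length-10 coefficient vector in coded units
#'   (`(Intercept)`, A, B, C, AB, AC, BC, A2, B2, C2).
#' @param sigma response noise standard deviation (percentage points).
#' @param coding a [bbd_coding] for decoding to natural units.
#' @param seed master seed.
#' @return A list: `design` (data frame temperature, pH, time, activity),
#'   `beta` (the generator truth), `sigma`.
#' @export
gen_bbd <- function(beta = NULL, sigma = 0.9, coding = bbd_coding(),
                    seed = 1) {
  if (is.null(beta)) beta <- coef(fit_bbd(hydrolysis_design(), coding))
  if (length(beta) != 10L)
    stop("beta must have 10 terms (coded quadratic model)", call. = FALSE)
  stopifnot(sigma >= 0)
  coded <- rbind(
    expand_pairs(1, 2), expand_pairs(1, 3), expand_pairs(2, 3),
    matrix(0, 5, 3))
  colnames(coded) <- c("A", "B", "C")
  X <- bbd_model_matrix(coded[, 1], coded[, 2], coded[, 3])
  mu <- drop(X %*% beta)
  y <- with_stream(seed, "bbd", mu + stats::rnorm(length(mu), 0, sigma))
  nat <- decode_factors(data.frame(temperature = coded[, 1],
                                   pH = coded[, 2], time = coded[, 3]),
                        coding)
  list(design = data.frame(nat, activity = y), beta = beta, sigma = sigma)
}

expand_pairs <- function(i, j) {
  out <- matrix(0, 4, 3)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  out[, i] <- pm[, 1]
  out[, j] <- pm[, 2]
  out
}

#' Generate synthetic inhibition-kinetics data
#'
#' Simulates initial rates over a substrate grid at several inhibitor
#' concentrations under a chosen inhibition model, with multiplicative
#' Gaussian noise: competitive (apparent Km scaled by 1 + I/Ki),
#' non-competitive (Vmax scaled by 1/(1 + I/Ki)) or mixed (both, the Vmax
#' effect through alpha * Ki).
#'
#' @param mode `"competitive"`, `"non-competitive"` or `"mixed"`.
#' @param Vmax,Km uninhibited kinetic parameters (rate units / substrate
#'   units, substrate in mM).
#' @param Ki inhibition constant (uM).
#' @param alpha mixed-mode factor (> 1; Vmax effect via alpha * Ki).
#' @param inhibitor_concs inhibitor levels (uM), must include 0.
#' @param substrate_concs substrate grid; default a 6-point geometric series
#'   spanning 0.2-5 x Km.
#' @param replicates technical replicates per (substrate, inhibitor) point
#'   (default 3, mirroring the triplicate assay design of the wet-lab
#'   protocol the generator stands in for).
#' @param cv relative (multiplicative) noise on rates, e.g. 0.02.
#' @param seed master seed.
#' @return A list: `data` (data frame inhibitor_conc, substrate_conc, rate),
#'   `truth` (the generator parameters).
#' @export
gen_kinetics <- function(mode = c("competitive", "non-competitive", "mixed"),
                         Vmax = 1, Km = 0.5, Ki = 10, alpha = 3,
                         inhibitor_concs = c(0, 5, 10),
                         substrate_concs = NULL, replicates = 3,
                         cv = 0.02, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(Vmax > 0, Km > 0, Ki > 0, alpha > 0, cv >= 0,
            replicates >= 1, 0 %in% inhibitor_concs)
  if (is.null(substrate_concs))
    substrate_concs <- Km * exp(seq(log(0.2), log(5), length.out = 6))
  grid <- expand.grid(substrate_conc = rep(substrate_concs, replicates),
                      inhibitor_conc = inhibitor_concs)
  v <- rate_model(mode, grid$substrate_conc, grid$inhibitor_conc,
                  Vmax, Km, Ki, alpha)
  rate <- with_stream(seed, paste0("kinetics-", mode),
                      v * (1 + stats::rnorm(length(v), 0, cv)))
  if (any(rate <= 0)) rate[rate <= 0] <- 1e-6 * Vmax
  list(data = data.frame(inhibitor_conc = grid$inhibitor_conc,
                         substrate_conc = grid$substrate_conc,
                         rate = rate),
       truth = list(mode = mode, Vmax = Vmax, Km = Km, Ki = Ki,
                    alpha = alpha, cv = cv, replicates = replicates))
}

rate_model <- function(mode, S, I, Vmax, Km, Ki, alpha) {
  switch(mode,
    "competitive" = Vmax * S / (Km * (1 + I / Ki) + S),
    "non-competitive" = (Vmax / (1 + I / Ki)) * S / (Km + S),
    "mixed" = Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))))
}

#' Generate a synthetic candidate-peptide table
#'
#' Emulates a de novo identification list: log-normal MS abundances (scale
#' ~1.5e10), uniform confidence scores and uniform negative binding
#' energies spanning the observed royal-jelly range. The truth ranking is
#' the score card computed from the generated channels.
#'
#' @param n number of candidates (default 57, the identified-peptide count
#'   the screen emulates).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters.
#' @param confidence_range,energy_range uniform ranges (energies negative,
#'   kcal/mol).
#' @param seed master seed.
#' @return A list: `candidates` (data frame), `truth` (the analytic
#'   `score_card`).
#' @export
gen_candidates <- function(n = 57, abundance_meanlog = log(1.5e10),
                           abundance_sdlog = 0.5,
                           confidence_range = c(380, 425),
                           energy_range = c(-9.5, -6.8), seed = 1) {
  stopifnot(n >= 1, energy_range[1] < 0, energy_range[2] < 0)
  with_stream(seed, "candidates", {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(names(AA_FREQ), sample(4:8, 1), replace = TRUE,
                   prob = AA_FREQ), collapse = "")
    }, character(1))
    # regenerate any duplicated sequence labels deterministically
    while (anyDuplicated(seqs)) {
      i <- which(duplicated(seqs))[1]
      seqs[i] <- paste(sample(names(AA_FREQ), 8, replace = TRUE), collapse = "")
    }
    cand <- data.frame(
      sequence = seqs,
      abundance = stats::rlnorm(n, abundance_meanlog, abundance_sdlog),
      confidence = stats::runif(n, confidence_range[1], confidence_range[2]),
      binding_energy = stats::runif(n, min(energy_range), max(energy_range)),
      stringsAsFactors = FALSE)
    list(candidates = cand, truth = candidate_scores(cand))
  })
}

#' Generate a synthetic dose-response series
#'
#' Four-parameter-logistic inhibition data with additive Gaussian noise on
#' the percentage scale. Default IC50 is 16.9 uM (the most potent
#' royal-jelly peptide) with a unit Hill slope; concentrations default to
#' an 8-point log-spaced series spanning ~0.06-17 x IC50.
#'
#' @param ic50 true IC50 (uM).
#' @param hill Hill slope.
#' @param bottom,top asymptotes (%).
#' @param concs concentration grid (uM).
#' @param sigma additive noise SD (percentage points).
#' @param seed master seed.
#' @return A list: `data` (data frame conc, inhibition), `truth`.
#' @export
gen_dose_response <- function(ic50 = 16.9, hill = 1, bottom = 0, top = 100,
                              concs = NULL, sigma = 2, seed = 1) {
  stopifnot(ic50 > 0, sigma >= 0)
  if (is.null(concs))
    concs <- ic50 * 2^seq(-4, 4, length.out = 8)
  mu <- bottom + (top - bottom) / (1 + (ic50 / concs)^hill)
  y <- with_stream(seed, "dose-response",
                   mu + stats::rnorm(length(mu), 0, sigma))
  list(data = data.frame(conc = concs, inhibition = y),
       truth = list(ic50 = ic50, hill = hill, bottom = bottom, top = top,
                    sigma = sigma))
}
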