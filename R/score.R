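# Composite candidate-peptide scoring: per-channel subscores from MS
# abundance, de novo confidence and docking binding energy, weighted total
# score, deterministic ranking and top-k selection.

#' Normalise a positive channel to a 0-100 subscore
#'
#' The default convention scales each value to 100 times its ratio to the
#' channel maximum, so the best candidate per channel scores exactly 100.
#' This is the convention that reproduces the published royal-jelly scoring
#' table; classic min-max scaling (`method = "min_max"`, worst value 0) is
#' available as an alternative. Binding energies must be supplied as the
#' (positive) magnitudes |energy|.
#'
#' @param values numeric vector of strictly positive channel values.
#' @param method `"ratio_max"` (default) or `"min_max"`.
#' @return Numeric vector of subscores in [0, 100].
#' @examples
#' subscore(c(8.4, 9.5))   # 88.42, 100
#' @export
subscore <- function(values, method = c("ratio_max", "min_max")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty value vector", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("subscore channel values must be finite and strictly positive",
         call. = FALSE)
  if (method == "ratio_max") {
    100 * values / max(values)
  } else {
    rng <- range(values)
    if (diff(rng) == 0) rep(100, length(values))
    else 100 * (values - rng[1]) / diff(rng)
  }
}

#' Read a candidate-peptide table
#'
#' @param path CSV with header `sequence,abundance,confidence,binding_energy`
#'   (additional columns are carried through).
#' @return A data frame.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("candidate file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "abundance", "confidence", "binding_energy")
  if (!all(need %in% names(df)))
    stop("candidate table needs columns sequence, abundance, confidence, ",
         "binding_energy", call. = FALSE)
  df
}

#' Bundled seven-candidate demonstration table
#'
#' The seven top-scoring candidate peptides reported for the royal-jelly
#' hydrolysate fraction C4-1, with their published MS abundances, de novo
#' confidence values, ACE docking binding energies (kcal/mol), published
#' subscores/totals and measured ACE inhibition at 1 mg/mL.
#'
#' @return A data frame.
#' @export
rj_candidates <- function() {
  read_candidates(system.file("extdata", "rj_candidates.csv",
                              package = "acepep", mustWork = TRUE))
}

validate_candidates <- function(candidates) {
  need <- c("sequence", "abundance", "confidence", "binding_energy")
  if (!all(need %in% names(candidates)))
    stop("candidate table needs columns sequence, abundance, confidence, ",
         "binding_energy", call. = FALSE)
  if (nrow(candidates) == 0L) stop("no candidates", call. = FALSE)
  if (any(!is.finite(candidates$abundance)) ||
      any(candidates$abundance <= 0))
    stop("abundances must be strictly positive", call. = FALSE)
  if (any(!is.finite(candidates$confidence)) ||
      any(candidates$confidence <= 0))
    stop("confidence scores must be strictly positive", call. = FALSE)
  if (any(!is.finite(candidates$binding_energy)) ||
      any(candidates$binding_energy >= 0))
    stop("binding energies must be strictly negative (kcal/mol)",
         call. = FALSE)
  invisible(candidates)
}

#' Score and rank candidate peptides
#'
#' Computes subscores A (abundance), B (de novo confidence) and
#' C (|binding energy|) with [subscore()], the weighted total
#' `w_A * A + w_B * B + w_C * C`, and ranks candidates by descending total
#' (ties broken by descending abundance, then sequence).
#'
#' @param candidates data frame with columns `sequence`, `abundance`,
#'   `confidence`, `binding_energy`.
#' @param weights numeric length-3 (A, B, C), non-negative, summing to 1
#'   within 1e-9. Default `c(0.40, 0.30, 0.30)`.
#' @param method subscore convention, see [subscore()].
#' @return A data frame of class `score_card`: input columns plus `score_A`,
#'   `score_B`, `score_C`, `total` and `rank`, ordered by rank.
#' @examples
#' candidate_scores(rj_candidates())
#' @export
candidate_scores <- function(candidates, weights = c(0.40, 0.30, 0.30),
                             method = c("ratio_max", "min_max")) {
  method <- match.arg(method)
  validate_candidates(candidates)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  out <- candidates
  out$score_A <- subscore(candidates$abundance, method)
  out$score_B <- subscore(candidates$confidence, method)
  out$score_C <- subscore(abs(candidates$binding_energy), method)
  out$total <- weights[1] * out$score_A + weights[2] * out$score_B +
    weights[3] * out$score_C
  ord <- order(-out$total, -out$abundance, out$sequence)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("score_card", "data.frame"),
            weights = weights, method = method)
}

#' Select the top-k candidates from a score card
#'
#' @param card a `score_card` from [candidate_scores()].
#' @param k number of candidates to keep (1 <= k <= nrow(card)).
#' @return The k highest-ranked rows, in rank order.
#' @export
select_top <- function(card, k) {
  stopifnot(inherits(card, "score_card"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  if (k > nrow(card))
    stop("k = ", k, " exceeds the number of candidates (", nrow(card), ")",
         call. = FALSE)
  card[seq_len(k), , drop = FALSE]
}

#' @export
print.score_card <- function(x, digits = 2, ...) {
  w <- attr(x, "weights")
  cat(sprintf("Candidate score card (weights A/B/C = %.2f/%.2f/%.2f, %s)\n",
              w[1], w[2], w[3], attr(x, "method")))
  cols <- c("rank", "sequence", "score_A", "score_B", "score_C", "total")
  tab <- as.data.frame(x)[, cols]
  tab[3:6] <- lapply(tab[3:6], round, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
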