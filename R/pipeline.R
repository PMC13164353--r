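# Pipeline orchestration: one validated configuration drives the enabled
# stages (index -> digest -> rsm -> score -> kinetics -> ic50) and a
# consolidated machine-readable report is written to the output directory.

PIPELINE_STAGES <- c("index", "digest", "rsm", "score", "kinetics", "ic50")

CONFIG_KEYS <- c("stages", "seed", "outdir", "fasta", "reference", "rules",
                 "design", "candidates", "kinetics", "dose_response",
                 "weights", "top_k", "tolerance", "count")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with the
#' stage list, input paths and stage parameters. Unknown keys are rejected;
#' referenced input files must exist.
#'
#' @param config a named list or the path to a YAML file.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config must enable at least one stage", call. = FALSE)
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) config$outdir <- "."
  if (is.null(config$weights)) config$weights <- c(0.40, 0.30, 0.30)
  if (is.null(config$top_k)) config$top_k <- 7L
  if (is.null(config$tolerance)) config$tolerance <- 0.10
  if (is.null(config$count)) config$count <- "all"
  for (key in c("fasta", "reference", "rules", "design", "candidates",
                "kinetics", "dose_response")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config key '", key, "': file not found: ", p, call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

stage_inputs <- list(
  index = c("fasta", "reference"),
  digest = c("fasta", "reference"),
  rsm = "design",
  score = "candidates",
  kinetics = "kinetics",
  ic50 = "dose_response")

#' Run the discovery pipeline
#'
#' Executes the enabled stages in canonical order and writes per-stage
#' tables plus a consolidated JSON report (with input hashes, seed and
#' package version for provenance) under `config$outdir`. A stage failure
#' aborts with a stage-named error; outputs of completed stages are
#' retained.
#'
#' @param config a [pipeline_config] (or list / YAML path accepted by it).
#' @return The report, invisibly (a nested list).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(config$seed))
  hashes <- list()
  for (key in unique(unlist(stage_inputs[config$stages]))) {
    if (!is.null(config[[key]]))
      hashes[[key]] <- unname(tools::md5sum(config[[key]]))
  }
  report <- list(
    provenance = list(
      package = "acepep",
      version = as.character(utils::packageVersion("acepep")),
      seed = as.integer(config$seed),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_md5 = hashes),
    stages = list())
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% config$stages]
  for (stage in stages) {
    message("[acepep] stage: ", stage)
    res <- tryCatch(
      run_stage(stage, config),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    report$stages[[stage]] <- res
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

run_stage <- function(stage, config) {
  out <- config$outdir
  switch(stage,
    index = {
      prot <- read_fasta(config$fasta)
      ref <- if (is.null(config$reference)) ace_reference() else
        read_bioactive_ref(config$reference)
      prof <- occurrence_profile(prot, ref, config$count)
      sa <- sigma_A(prot, ref, config$count)
      utils::write.table(prof, file.path(out, "occurrence_profile.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(sa, file.path(out, "sigma_A.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(n_proteins = nrow(prot), sigma_A = as.list(
        stats::setNames(sa$sigma_A, sa$protein_id)))
    },
    digest = {
      prot <- read_fasta(config$fasta)
      ref <- if (is.null(config$reference)) ace_reference() else
        read_bioactive_ref(config$reference)
      rules <- if (is.null(config$rules)) protease_rules() else
        read_protease_rules(config$rules)
      panel <- enzyme_panel(prot, rules, ref)
      utils::write.table(panel$per_pair,
                         file.path(out, "digest_per_pair.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(panel$per_enzyme,
                         file.path(out, "digest_per_enzyme.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(per_enzyme = panel$per_enzyme)
    },
    rsm = {
      design <- read_bbd_design(config$design)
      fit <- fit_bbd(design)
      an <- anova(fit)
      opt <- find_optimum(fit)
      utils::write.csv(as.data.frame(an),
                       file.path(out, "rsm_anova.csv"), row.names = FALSE)
      list(coefficients = as.list(coef(fit)),
           diagnostics = as.list(attr(an, "diagnostics")),
           optimum = list(natural = as.list(opt$natural),
                          predicted = opt$predicted))
    },
    score = {
      cand <- read_candidates(config$candidates)
      card <- candidate_scores(cand, config$weights)
      top <- select_top(card, min(config$top_k, nrow(card)))
      utils::write.csv(as.data.frame(card),
                       file.path(out, "score_card.csv"), row.names = FALSE)
      list(n_candidates = nrow(card),
           top = lapply(seq_len(nrow(top)), function(i)
             list(sequence = top$sequence[i], total = top$total[i])))
    },
    kinetics = {
      kin <- utils::read.csv(config$kinetics, stringsAsFactors = FALSE)
      verdict <- classify_inhibition(kin, tol = config$tolerance)
      utils::write.csv(verdict$evidence,
                       file.path(out, "kinetics_evidence.csv"),
                       row.names = FALSE)
      list(mode = verdict$mode,
           Ki = if (is.na(verdict$Ki)) NULL else verdict$Ki)
    },
    ic50 = {
      dr <- utils::read.csv(config$dose_response, stringsAsFactors = FALSE)
      fit <- fit_ic50(dr$conc, dr$inhibition)
      list(ic50 = fit$ic50, coefficients = as.list(coef(fit)))
    })
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Convenience wrapper over the generators: writes a FASTA proteome,
#' bioactive reference TSV, hydrolysis design CSV, candidate CSV, kinetics
#' CSV, dose-response CSV and a ground-truth JSON, all reproducible from
#' the seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @return The output directory, invisibly.
#' @export
simulate_inputs <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prot <- gen_proteome(seed = seed)
  writeLines(
    as.vector(rbind(paste0(">", prot$records$id), prot$records$sequence)),
    file.path(outdir, "proteome.fasta"))
  ref <- prot$ref
  names(ref) <- c("activity", "sequence")
  utils::write.table(ref, file.path(outdir, "reference.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bbd <- gen_bbd(seed = seed)
  utils::write.csv(bbd$design, file.path(outdir, "design.csv"),
                   row.names = FALSE)
  cand <- gen_candidates(seed = seed)
  utils::write.csv(cand$candidates, file.path(outdir, "candidates.csv"),
                   row.names = FALSE)
  kin <- gen_kinetics(seed = seed)
  utils::write.csv(kin$data, file.path(outdir, "kinetics.csv"),
                   row.names = FALSE)
  dr <- gen_dose_response(seed = seed)
  utils::write.csv(dr$data, file.path(outdir, "dose_response.csv"),
                   row.names = FALSE)
  truth <- list(proteome = prot$truth, bbd_beta = as.list(bbd$beta),
                kinetics = kin$truth, dose_response = dr$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
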