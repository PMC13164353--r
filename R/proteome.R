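# Proteome knowledge base: protein records, bioactive-peptide reference
# tables, and BIOPEP-style occurrence-frequency statistics.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a set of protein records
#'
#' A protein record holds an accession, an optional free-text description and
#' an amino-acid sequence over the 20 canonical one-letter codes. Ambiguity
#' codes (B, J, O, U, X, Z) are rejected: downstream occurrence and digestion
#' metrics are defined on exact residues only.
#'
#' @param id character vector of accession identifiers.
#' @param sequence character vector of amino-acid sequences (upper-cased on
#'   input).
#' @param description optional character vector of free-text descriptions.
#' @return A data frame of class `protein_records` with columns `id`,
#'   `description` and `sequence`.
#' @examples
#' protein_records("p1", "ACDEFGHIK")
#' @export
protein_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have the same length", call. = FALSE)
  description <- rep_len(as.character(description), length(id))
  for (i in seq_along(id)) validate_sequence(sequence[i], id[i])
  structure(
    data.frame(id = id, description = description, sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("protein_records", "data.frame"))
}

validate_sequence <- function(seq, id) {
  if (!nzchar(seq))
    stop("record '", id, "': empty sequence", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop("record '", id, "': illegal residue code(s) ",
         paste(bad, collapse = ", "),
         " (only the 20 canonical one-letter codes are allowed)",
         call. = FALSE)
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and validates every record against
#' the canonical 20-residue alphabet. Line-wrapped sequences are concatenated
#' and upper-cased; the first whitespace-delimited token of each header is the
#' accession, the remainder the description.
#'
#' @param path path to a FASTA file.
#' @return A [protein_records] data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA file '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (length(aa) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_records(ids, as.character(aa), desc)
}

#' Construct a bioactive-peptide reference table
#'
#' The reference maps activity labels (e.g. "ACE inhibitor") to short peptide
#' fragments known to carry that activity, in the manner of the BIOPEP-UWM
#' bioactive-peptide database. Entries are deduplicated on (activity,
#' fragment); activity labels are trimmed and matched case-insensitively.
#'
#' @param activity character vector of activity labels.
#' @param fragment character vector of peptide fragments (length >= 2).
#' @return A data frame of class `bioactive_ref` with columns `activity` and
#'   `fragment`.
#' @export
bioactive_ref <- function(activity, fragment) {
  activity <- tolower(trimws(as.character(activity)))
  fragment <- toupper(trimws(as.character(fragment)))
  if (length(activity) != length(fragment))
    stop("`activity` and `fragment` must have the same length", call. = FALSE)
  if (any(!nzchar(activity)))
    stop("empty activity label in reference", call. = FALSE)
  if (any(nchar(fragment) < 2L))
    stop("reference fragments must be at least 2 residues long",
         call. = FALSE)
  for (f in unique(fragment)) validate_sequence(f, paste0("fragment ", f))
  df <- unique(data.frame(activity = activity, fragment = fragment,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("bioactive_ref", "data.frame"))
}

#' Read a bioactive reference from tab-separated text
#'
#' Expects a header line `activity<TAB>sequence`.
#'
#' @param path path to the TSV file.
#' @return A [bioactive_ref] data frame.
#' @export
read_bioactive_ref <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("activity", "sequence")
  if (!all(need %in% names(df)))
    stop("reference table must have columns 'activity' and 'sequence'",
         call. = FALSE)
  bioactive_ref(df$activity, df$sequence)
}

#' Bundled demonstration ACE-inhibitor reference
#'
#' A small curated stand-in set of di- and tripeptides with reported ACE
#' inhibitory activity, shipped for examples and tests. It is *not* the
#' BIOPEP-UWM database and occurrence frequencies computed against it are not
#' comparable to BIOPEP output.
#'
#' @return A [bioactive_ref] data frame.
#' @export
ace_reference <- function() {
  read_bioactive_ref(system.file("extdata", "ace_reference_demo.tsv",
                                 package = "acepep", mustWork = TRUE))
}

# Overlapping start positions of `fragment` in `seq` (1-based).
match_starts <- function(fragment, seq) {
  pat <- paste0("(?=", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", fragment),
                ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Frequency of occurrence of bioactive fragments in a protein
#'
#' Computes the BIOPEP-style parameter A = a / N, where a counts matches of
#' reference fragments of one activity in the protein sequence and N is the
#' protein length. By default every (fragment, start-position) pair is
#' counted, overlapping matches included; `count = "distinct"` counts each
#' distinct fragment at most once per protein.
#'
#' @param protein a single-row [protein_records] entry, or a plain sequence
#'   string.
#' @param activity an activity label present in `ref` (an absent label gives
#'   A = 0).
#' @param ref a [bioactive_ref] table.
#' @param count counting convention, `"all"` (default) or `"distinct"`.
#' @return A single non-negative number.
#' @examples
#' ref <- bioactive_ref(c("ACE-inh", "ACE-inh"), c("GF", "FG"))
#' occurrence_frequency("GFGF", "ACE-inh", ref)  # 3/4
#' @export
occurrence_frequency <- function(protein, activity, ref,
                                 count = c("all", "distinct")) {
  count <- match.arg(count)
  seq <- as_sequence(protein)
  stopifnot(inherits(ref, "bioactive_ref"))
  activity <- tolower(trimws(activity))
  frags <- ref$fragment[ref$activity == activity]
  if (length(frags) == 0L) return(0)
  n <- nchar(seq)
  hits <- vapply(unique(frags), function(f) length(match_starts(f, seq)),
                 integer(1))
  a <- if (count == "all") sum(hits) else sum(hits > 0L)
  a / n
}

as_sequence <- function(protein) {
  if (inherits(protein, "protein_records")) {
    if (nrow(protein) != 1L)
      stop("expected a single protein record", call. = FALSE)
    protein$sequence
  } else {
    seq <- toupper(as.character(protein))
    validate_sequence(seq, "<input>")
    seq
  }
}

#' Per-activity occurrence profile and aggregate frequency
#'
#' For each protein, computes A for every distinct activity in the reference
#' and the aggregate occurrence frequency (the sum of the per-activity A
#' values over all activity categories).
#'
#' @param proteins a [protein_records] data frame.
#' @param ref a [bioactive_ref] table.
#' @inheritParams occurrence_frequency
#' @return A data frame of class `occurrence_profile` with columns
#'   `protein_id`, `activity` and `A`; rows with `activity == "<sigma_A>"` do
#'   not occur — use [sigma_A()] for the aggregate.
#' @export
occurrence_profile <- function(proteins, ref, count = c("all", "distinct")) {
  count <- match.arg(count)
  stopifnot(inherits(proteins, "protein_records"),
            inherits(ref, "bioactive_ref"))
  acts <- unique(ref$activity)
  rows <- expand.grid(protein_id = proteins$id, activity = acts,
                      stringsAsFactors = FALSE)
  if (nrow(rows)) {
    rows$A <- mapply(function(pid, act) {
      occurrence_frequency(proteins$sequence[match(pid, proteins$id)],
                           act, ref, count)
    }, rows$protein_id, rows$activity, USE.NAMES = FALSE)
    rows <- rows[order(match(rows$protein_id, proteins$id), rows$activity), ]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(protein_id = character(0), activity = character(0),
                       A = numeric(0))
  }
  structure(rows, class = c("occurrence_profile", "data.frame"))
}

#' Aggregate occurrence frequency per protein
#'
#' @inheritParams occurrence_profile
#' @return A data frame with columns `protein_id` and `sigma_A` (one row per
#'   protein; 0 for an empty reference).
#' @export
sigma_A <- function(proteins, ref, count = c("all", "distinct")) {
  prof <- occurrence_profile(proteins, ref, match.arg(count))
  s <- rep(0, nrow(proteins))
  names(s) <- proteins$id
  if (nrow(prof)) {
    sums <- tapply(prof$A, prof$protein_id, sum)
    s[names(sums)] <- as.numeric(sums)
  }
  data.frame(protein_id = proteins$id, sigma_A = unname(s),
             stringsAsFactors = FALSE)
}
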