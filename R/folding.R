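#' Folding configuration
#'
#' Controls how [fold_hairpins()] predicts one secondary structure per
#' sequence.
#'
#' The built-in engine is a maximum base-pairing dynamic program
#' (Nussinov-style) with a deterministic traceback: it maximizes the number
#' of admissible, non-crossing base pairs subject to a minimum hairpin-loop
#' size, and reports the pair count as the score. The external engine shells
#' out to any RNAfold-compatible folder (FASTA on standard input,
#' sequence line plus `"structure (energy)"` on standard output) and reports
#' the minimum free energy as the score. Descriptor extraction and
#' classification are agnostic to which engine produced the structure.
#'
#' @param min_loop Minimum number of unpaired bases enclosed by any pair.
#'   Default 3, the physical hairpin-loop minimum enforced by thermodynamic
#'   folders.
#' @param allowed_pairs Character vector of admissible ordered pairs; the
#'   default is Watson-Crick plus wobble: `AU, UA, GC, CG, GU, UG`. Must be
#'   symmetric (if `XY` is allowed, so is `YX`).
#' @param engine `"builtin"` (default) or `"external"`.
#' @param external_command Command line for the external folder (e.g.
#'   `"RNAfold --noPS"`); used only when `engine = "external"`.
#' @return A `folding_config` list.
#' @export
folding_config <- function(min_loop = 3L,
                           allowed_pairs = c("AU", "UA", "GC", "CG", "GU", "UG"),
                           engine = c("builtin", "external"),
                           external_command = "RNAfold --noPS") {
  engine <- match.arg(engine)
  min_loop <- as.integer(min_loop)
  if (is.na(min_loop) || min_loop < 0) {
    stop_input("min_loop must be a non-negative integer")
  }
  allowed_pairs <- toupper(allowed_pairs)
  if (length(allowed_pairs) == 0 ||
      any(nchar(allowed_pairs) != 2) ||
      any(!strsplit(paste(allowed_pairs, collapse = ""), "")[[1]] %in% c("A", "C", "G", "U"))) {
    stop_input("allowed_pairs must be non-empty two-letter combinations of A, C, G, U")
  }
  flipped <- paste0(substr(allowed_pairs, 2, 2), substr(allowed_pairs, 1, 1))
  if (!setequal(allowed_pairs, flipped)) {
    stop_input("allowed_pairs must be symmetric: if XY is allowed then YX must be")
  }
  structure(
    list(
      min_loop = min_loop, allowed_pairs = allowed_pairs,
      engine = engine, external_command = external_command
    ),
    class = "folding_config"
  )
}

pairable_matrix <- function(config) {
  bases <- c("A", "C", "G", "U")
  m <- matrix(FALSE, 4, 4, dimnames = list(bases, bases))
  for (p in config$allowed_pairs) {
    m[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  }
  m
}

#' Predict secondary structures for hairpin candidates
#'
#' Folds each sequence into a single dot-bracket structure. With the default
#' built-in engine the structure maximizes the number of admissible
#' non-crossing pairs (score = pair count, `score_kind = "pair_count"`);
#' with the external engine the structure and free energy come from an
#' RNAfold-compatible folder (`score_kind = "energy"`). Sequences too short
#' to close any loop fold to the all-unpaired structure. Per-record failures
#' are collected and reported together with their ids rather than aborting
#' at the first one.
#'
#' @param records A tibble with columns `id` and `sequence` (see
#'   [read_fasta()]).
#' @param config A [folding_config()].
#' @return `records` with added columns `structure`, `score`, `score_kind`.
#' @examples
#' recs <- tibble::tibble(id = "s1", description = "", sequence = "GGGAAACCC")
#' fold_hairpins(recs)
#' @export
fold_hairpins <- function(records, config = folding_config()) {
  check_record_columns(records)
  if (!inherits(config, "folding_config")) {
    stop_input("config must be a folding_config()")
  }
  if (nrow(records) == 0) {
    records$structure <- character(0)
    records$score <- numeric(0)
    records$score_kind <- character(0)
    return(records)
  }
  if (config$engine == "external") {
    return(fold_external(records, config))
  }
  pm <- pairable_matrix(config)
  structures <- character(nrow(records))
  scores <- numeric(nrow(records))
  failures <- character(0)
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(
      {
        b <- match(strsplit(records$sequence[i], "")[[1]], c("A", "C", "G", "U")) - 1L
        if (anyNA(b)) stop_input("sequence contains non-ACGU characters")
        nussinov_fold(b, config$min_loop, pm)
      },
      hairpin3d_error = function(e) e
    )
    if (inherits(res, "condition")) {
      failures <- c(failures, paste0(records$id[i], ": ", conditionMessage(res)))
    } else {
      structures[i] <- res$structure
      scores[i] <- res$pairs
    }
  }
  if (length(failures) > 0) {
    stop_input(paste0(
      "folding failed for ", length(failures), " record(s):\n  ",
      paste(failures, collapse = "\n  ")
    ))
  }
  records$structure <- structures
  records$score <- scores
  records$score_kind <- "pair_count"
  records
}

# External RNAfold-compatible engine: FASTA in on stdin, per record a header
# echo, the sequence, and "structure (energy)".
fold_external <- function(records, config) {
  cmd <- strsplit(config$external_command, "\\s+")[[1]]
  if (Sys.which(cmd[1]) == "") {
    stop_external(paste0("external folder not found on PATH: ", cmd[1]))
  }
  fasta_in <- tempfile(fileext = ".fa")
  on.exit(unlink(fasta_in), add = TRUE)
  write_fasta(records, fasta_in)
  out <- tryCatch(
    withr::with_dir(tempdir(), system2(cmd[1], cmd[-1], stdin = fasta_in, stdout = TRUE, stderr = FALSE)),
    error = function(e) stop_external(paste0("external folder failed: ", conditionMessage(e)))
  )
  vf <- tempfile(fileext = ".vienna")
  on.exit(unlink(vf), add = TRUE)
  writeLines(out, vf)
  parsed <- tryCatch(read_vienna(vf), hairpin3d_error = function(e) {
    stop_external(paste0("unparsable external folder output: ", conditionMessage(e)))
  })
  if (nrow(parsed) != nrow(records) || !identical(parsed$id, records$id)) {
    stop_external("external folder output does not match the input records")
  }
  records$structure <- parsed$structure
  records$score <- parsed$score
  records$score_kind <- parsed$score_kind
  records
}
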