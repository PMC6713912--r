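#' Read secondary structures in Vienna dot-bracket format
#'
#' Parses the RNAfold-style triplet format: a `>` header line, the sequence
#' line, then the dot-bracket structure line, optionally suffixed with a
#' parenthesized folding score, e.g. `"((((...)))) (-7.20)"`. When a score is
#' present it is parsed and tagged `score_kind = "energy"`; otherwise the
#' score is `NA` and `score_kind = "unspecified"`. Each structure is
#' validated: same length as the sequence and balanced brackets (matched
#' round brackets cannot cross, so balance implies a pseudoknot-free
#' structure).
#'
#' @param path Path to a Vienna dot-bracket file.
#' @param alphabet Alphabet policy passed to sequence normalization.
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `structure`, `score`, `score_kind`.
#' @export
read_vienna <- function(path, alphabet = c("coerce", "strict")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop_input(paste0("Vienna file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_input(paste0("Vienna file is empty: ", path))
  }
  if (length(lines) %% 3 != 0 || !all(startsWith(lines[seq(1, length(lines), by = 3)], ">"))) {
    stop_input("malformed Vienna file: expected repeating header/sequence/structure triplets")
  }
  n <- length(lines) %/% 3
  out <- vector("list", n)
  for (k in seq_len(n)) {
    header <- sub("^>", "", lines[3 * k - 2])
    id <- sub("\\s.*$", "", header)
    desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
    seq <- trimws(lines[3 * k - 1])
    struct_line <- trimws(lines[3 * k])
    score <- NA_real_
    score_kind <- "unspecified"
    m <- regexpr("\\s*\\(\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\)$", struct_line)
    if (m > 0) {
      suffix <- substr(struct_line, m, nchar(struct_line))
      score <- as.numeric(gsub("[()\\s]", "", gsub("\\s", "", suffix)))
      score_kind <- "energy"
      struct_line <- trimws(substr(struct_line, 1, m - 1))
    } else if (grepl("\\)$", struct_line) && grepl("\\([^.()]*\\)$", struct_line)) {
      stop_input(paste0("record '", id, "': malformed score suffix in '", struct_line, "'"))
    }
    out[[k]] <- tibble(
      id = id, description = desc, sequence = seq,
      structure = struct_line, score = score, score_kind = score_kind
    )
  }
  res <- dplyr::bind_rows(out)
  res <- normalize_records(res, alphabet)
  for (k in seq_len(nrow(res))) {
    validate_structure(res$structure[k], res$sequence[k], res$id[k])
  }
  res
}

#' Write folded records to a Vienna dot-bracket file
#'
#' Emits the same header/sequence/structure triplet format read by
#' [read_vienna()]. Scores of kind `"energy"` are written with two decimals
#' in the RNAfold style; pair-count scores from the built-in folder are
#' written as integers; unspecified scores are omitted.
#'
#' @param folded A tibble as produced by [fold_hairpins()] or [read_vienna()].
#' @param path Output path.
#' @return `folded`, invisibly.
#' @export
write_vienna <- function(folded, path) {
  check_folded_columns(folded)
  lines <- character(0)
  for (k in seq_len(nrow(folded))) {
    header <- folded$id[k]
    if ("description" %in% names(folded) && nzchar(folded$description[k] %||% "")) {
      header <- paste(header, folded$description[k])
    }
    struct <- folded$structure[k]
    kind <- if ("score_kind" %in% names(folded)) folded$score_kind[k] else "unspecified"
    if (!is.na(folded$score[k]) && kind == "energy") {
      struct <- sprintf("%s (%.2f)", struct, folded$score[k])
    } else if (!is.na(folded$score[k]) && kind == "pair_count") {
      struct <- sprintf("%s (%d)", struct, as.integer(folded$score[k]))
    }
    lines <- c(lines, paste0(">", header), folded$sequence[k], struct)
  }
  writeLines(lines, path)
  invisible(folded)
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

# A dot-bracket string over {., (, )} is valid iff brackets balance; with a
# single bracket type, matched pairs can never cross.
validate_structure <- function(structure, sequence, id = "?") {
  if (nchar(structure) != nchar(sequence)) {
    stop_input(paste0(
      "record '", id, "': structure length ", nchar(structure),
      " does not match sequence length ", nchar(sequence)
    ))
  }
  chars <- strsplit(structure, "")[[1]]
  if (any(!chars %in% c(".", "(", ")"))) {
    stop_input(paste0("record '", id, "': structure contains characters outside '.', '(', ')'"))
  }
  depth <- cumsum(ifelse(chars == "(", 1L, ifelse(chars == ")", -1L, 0L)))
  if (any(depth < 0) || (length(depth) > 0 && depth[length(depth)] != 0)) {
    stop_input(paste0("record '", id, "': unbalanced brackets in structure"))
  }
  invisible(structure)
}

check_folded_columns <- function(folded) {
  need <- c("id", "sequence", "structure", "score")
  if (!is.data.frame(folded) || !all(need %in% names(folded))) {
    stop_schema("expected a folded tibble with columns id, sequence, structure, score")
  }
  invisible(folded)
}
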