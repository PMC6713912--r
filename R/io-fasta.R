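#' Read hairpin candidate sequences from a FASTA file
#'
#' Reads a (possibly multi-record, multi-line) FASTA file into a tibble of
#' sequence records. Sequences are normalized to the RNA alphabet: under the
#' default `"coerce"` policy, `T` is mapped to `U` and lowercase letters are
#' folded to uppercase, so DNA-alphabet inputs (miRBase-style) are accepted
#' silently. Under `"strict"`, any character outside `A,C,G,U,T` (either
#' case) is an error naming the offending record and position. Ambiguity
#' codes (`N`, `R`, `Y`, ...) are rejected under both policies: the
#' structural descriptor is undefined for unknown bases.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Alphabet policy, `"coerce"` (default) or `"strict"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty)
#'   and `sequence` (uppercase RNA).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a hairpin", "GGGAAACCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, alphabet = c("coerce", "strict")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop_input(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop_input(paste0("FASTA file is empty (no records): ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(as.character(set))
  records <- tibble(id = ids, description = desc, sequence = seqs)
  normalize_records(records, alphabet)
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `records`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_record_columns(records)
  headers <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(records)
}

# Shared normalization/validation used by read_fasta and the simulator.
normalize_records <- function(records, alphabet = "coerce") {
  if (any(records$sequence == "" | is.na(records$sequence))) {
    bad <- records$id[records$sequence == "" | is.na(records$sequence)][1]
    stop_input(paste0("record '", bad, "' has an empty sequence"))
  }
  if (any(grepl("\\s", records$id)) || any(records$id == "")) {
    stop_input("record ids must be non-empty and contain no whitespace")
  }
  if (identical(alphabet, "strict")) {
    for (i in seq_len(nrow(records))) {
      hit <- regexpr("[^ACGUTacgut]", records$sequence[i])
      if (hit > 0) {
        stop_input(paste0(
          "record '", records$id[i], "' has illegal character '",
          substr(records$sequence[i], hit, hit), "' at position ", hit
        ))
      }
    }
  }
  seqs <- chartr("acgut", "ACGUT", records$sequence)
  seqs <- chartr("T", "U", seqs)
  # ambiguity codes and anything else non-ACGU are rejected in both policies
  for (i in seq_along(seqs)) {
    hit <- regexpr("[^ACGU]", seqs[i])
    if (hit > 0) {
      stop_input(paste0(
        "record '", records$id[i], "' has unsupported character '",
        substr(seqs[i], hit, hit), "' at position ", hit,
        " (ambiguity codes are not supported)"
      ))
    }
  }
  records$sequence <- seqs
  records
}

check_record_columns <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    stop_schema("expected a data frame with columns 'id' and 'sequence'")
  }
  invisible(records)
}
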