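# Case convention for the characteristic sequence: dots (nonbonding) keep
# the uppercase base, brackets (bonding) switch it to lowercase. The
# opposite reading is one switch away.
UPPERCASE_IS_UNPAIRED <- TRUE

#' Encode folded sequences as characteristic sequences
#'
#' A characteristic sequence carries base identity and pairing state in one
#' string: position `i` keeps its uppercase base when `structure[i] == "."`
#' (nonbonded) and switches to lowercase when it sits in a base pair
#' (`"("` or `")"`). The dot-bracket state string is kept alongside, so the
#' distinction between the two bracket directions is not lost.
#'
#' @param folded A tibble with columns `sequence` and `structure` (see
#'   [fold_hairpins()], [read_vienna()]).
#' @return `folded` with an added `characteristic` column.
#' @examples
#' x <- tibble::tibble(id = "s1", sequence = "GGGAAACCC", structure = "(((...)))")
#' encode_structure(x)$characteristic
#' @export
encode_structure <- function(folded) {
  if (!is.data.frame(folded) || !all(c("sequence", "structure") %in% names(folded))) {
    stop_schema("expected a tibble with columns 'sequence' and 'structure'")
  }
  n <- nrow(folded)
  out <- character(n)
  for (i in seq_len(n)) {
    validate_structure(folded$structure[i], folded$sequence[i],
                       if ("id" %in% names(folded)) folded$id[i] else "?")
    out[i] <- encode_one(folded$sequence[i], folded$structure[i])
  }
  folded$characteristic <- out
  folded
}

encode_one <- function(sequence, structure) {
  seq_chars <- strsplit(sequence, "")[[1]]
  paired <- strsplit(structure, "")[[1]] != "."
  if (!UPPERCASE_IS_UNPAIRED) paired <- !paired
  seq_chars[paired] <- tolower(seq_chars[paired])
  paste(seq_chars, collapse = "")
}

#' Decode characteristic sequences back to sequence and structure
#'
#' Inverse of [encode_structure()]: recovers the uppercase RNA sequence and
#' checks that letter case is consistent with the retained dot-bracket
#' states (uppercase with `.`, lowercase with `(` or `)`).
#'
#' @param encoded A tibble with columns `characteristic` and `structure`.
#' @return `encoded` with the `sequence` column recomputed from the
#'   characteristic letters.
#' @export
decode_structure <- function(encoded) {
  if (!is.data.frame(encoded) || !all(c("characteristic", "structure") %in% names(encoded))) {
    stop_schema("expected a tibble with columns 'characteristic' and 'structure'")
  }
  n <- nrow(encoded)
  seqs <- character(n)
  for (i in seq_len(n)) {
    cs <- strsplit(encoded$characteristic[i], "")[[1]]
    st <- strsplit(encoded$structure[i], "")[[1]]
    id <- if ("id" %in% names(encoded)) encoded$id[i] else "?"
    if (length(cs) != length(st)) {
      stop_input(paste0("record '", id, "': characteristic/structure length mismatch"))
    }
    if (any(!cs %in% c("A", "C", "G", "U", "a", "c", "g", "u"))) {
      stop_input(paste0("record '", id, "': characteristic letters outside {A,C,G,U,a,c,g,u}"))
    }
    is_lower <- cs %in% c("a", "c", "g", "u")
    expect_lower <- (st != ".") == UPPERCASE_IS_UNPAIRED
    if (any(is_lower != expect_lower)) {
      pos <- which(is_lower != expect_lower)[1]
      stop_input(paste0(
        "record '", id, "': case/state inconsistency at position ", pos,
        " ('", cs[pos], "' with state '", st[pos], "')"
      ))
    }
    seqs[i] <- toupper(encoded$characteristic[i])
  }
  encoded$sequence <- seqs
  encoded
}
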