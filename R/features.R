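#' The base-to-corner vector map
#'
#' Each RNA base is placed on a corner of the cube `{-1, +1}^3` by the three
#' chemical dichotomies of the bases: the x axis separates purines (`A`, `G`;
#' +1) from pyrimidines (`C`, `U`; -1), the y axis amino bases (`A`, `C`; +1)
#' from keto bases (`G`, `U`; -1), and the z axis strong hydrogen-bonders
#' (`G`, `C`; +1) from weak ones (`A`, `U`; -1). Lowercase (bonded) letters
#' take the negated vector of their uppercase form, so pairing flips a base
#' to the opposite corner. The eight letter vectors are distinct corners and
#' the four uppercase vectors sum to zero.
#'
#' @return A tibble with columns `letter`, `x`, `y`, `z` for the eight
#'   letters `A,C,G,U,a,c,g,u`.
#' @export
base_vectors <- function() {
  upper <- tibble(
    letter = c("A", "C", "G", "U"),
    x = c(1, -1, 1, -1),   # purine / pyrimidine
    y = c(1, 1, -1, -1),   # amino / keto
    z = c(-1, 1, 1, -1)    # weak / strong H-bond
  )
  lower <- upper
  lower$letter <- tolower(upper$letter)
  lower$x <- -upper$x
  lower$y <- -upper$y
  lower$z <- -upper$z
  dplyr::bind_rows(upper, lower)
}

#' Build the 3D curve of a characteristic sequence
#'
#' The curve starts at the origin and takes one step per letter, adding that
#' letter's corner vector from [base_vectors()]. Every step therefore has
#' per-axis increments in `{-1, +1}`, and the endpoint equals the sum of all
#' letter vectors.
#'
#' @param characteristic A single characteristic sequence (string over
#'   `A,C,G,U,a,c,g,u`).
#' @return A tibble with columns `position`, `letter`, `x`, `y`, `z` giving
#'   the curve points `P_1 .. P_n`.
#' @examples
#' hairpin_curve("gggAAAccc")
#' @export
hairpin_curve <- function(characteristic) {
  if (!is.character(characteristic) || length(characteristic) != 1) {
    stop_input("characteristic must be a single string")
  }
  letters_ <- strsplit(characteristic, "")[[1]]
  bv <- base_vectors()
  idx <- match(letters_, bv$letter)
  if (anyNA(idx)) {
    stop_input("characteristic contains letters outside {A,C,G,U,a,c,g,u}")
  }
  tibble(
    position = seq_along(letters_),
    letter = letters_,
    x = cumsum(bv$x[idx]),
    y = cumsum(bv$y[idx]),
    z = cumsum(bv$z[idx])
  )
}

#' Extract the 36-dimensional structural descriptor
#'
#' Curve points are grouped into 12 classes by base identity (`A,C,G,U`) and
#' dot-bracket state (`.`, `(`, `)`). For a class with `n_k` occurrences in
#' a sequence of length `n`, its three features are the geometric center of
#' its curve points divided by `n`:
#' `(1 / (n * n_k)) * sum of P_i over the class positions`. Absent classes
#' contribute exactly `(0, 0, 0)`. Since every curve coordinate is bounded
#' by the position index, all 36 features lie in `[-1, +1]`. Length
#' normalization makes descriptors comparable across hairpins of different
#' lengths (corpora mix roughly 50-180 nt).
#'
#' @param characteristic A single characteristic sequence.
#' @param structure The matching dot-bracket state string.
#' @return A named numeric vector of length 36, ordered as
#'   [feature_names()].
#' @export
extract_features <- function(characteristic, structure) {
  curve <- hairpin_curve(characteristic)
  states <- strsplit(structure, "")[[1]]
  if (length(states) != nrow(curve)) {
    stop_input("structure length does not match the characteristic sequence")
  }
  n <- nrow(curve)
  bases <- toupper(curve$letter)
  state_names <- c("." = "unpaired", "(" = "open", ")" = "close")
  out <- stats::setNames(numeric(36), feature_names())
  for (b in c("A", "C", "G", "U")) {
    for (s in c(".", "(", ")")) {
      sel <- bases == b & states == s
      if (any(sel)) {
        prefix <- paste(b, state_names[[s]], sep = "_")
        out[paste(prefix, c("x", "y", "z"), sep = "_")] <- c(
          mean(curve$x[sel]), mean(curve$y[sel]), mean(curve$z[sel])
        ) / n
      }
    }
  }
  out
}

#' Featurize hairpin candidates end to end
#'
#' Runs the full descriptor pipeline per record: fold (unless a `structure`
#' column is already present), case-encode, build the 3D curve, and extract
#' the 36 features. Rows keep the input order; identical sequences produce
#' identical rows.
#'
#' @param records A tibble with `id` and `sequence` columns; if it already
#'   has a `structure` column (e.g. from [read_vienna()]), folding is
#'   skipped.
#' @param config A [folding_config()] used when folding is needed.
#' @param label Optional class tag attached to every row
#'   (`"positive"`, `"negative"`, or `"unlabeled"`).
#' @return A feature tibble: `id`, `label`, then the 36 descriptor columns.
#' @examples
#' recs <- tibble::tibble(id = "s1", sequence = "GGGAAACCC")
#' featurize_hairpins(recs)
#' @export
featurize_hairpins <- function(records, config = folding_config(), label = "unlabeled") {
  check_record_columns(records)
  if (!label %in% c("positive", "negative", "unlabeled")) {
    stop_input("label must be one of 'positive', 'negative', 'unlabeled'")
  }
  if (nrow(records) == 0) {
    empty <- tibble(id = character(0), label = character(0))
    for (nm in feature_names()) empty[[nm]] <- numeric(0)
    return(empty)
  }
  folded <- if ("structure" %in% names(records)) records else fold_hairpins(records, config)
  encoded <- encode_structure(folded)
  failures <- character(0)
  rows <- vector("list", nrow(encoded))
  for (i in seq_len(nrow(encoded))) {
    rows[[i]] <- tryCatch(
      extract_features(encoded$characteristic[i], encoded$structure[i]),
      hairpin3d_error = function(e) {
        failures <<- c(failures, paste0(encoded$id[i], ": ", conditionMessage(e)))
        NULL
      }
    )
  }
  if (length(failures) > 0) {
    stop_input(paste0(
      "featurization failed for ", length(failures), " record(s):\n  ",
      paste(failures, collapse = "\n  ")
    ))
  }
  mat <- do.call(rbind, rows)
  out <- tibble(id = encoded$id, label = label)
  dplyr::bind_cols(out, as_tibble(mat))
}

#' Plot the 3D curve of a hairpin as axis projections
#'
#' Shows the cumulative purine/pyrimidine (x), amino/keto (y) and
#' strong/weak hydrogen-bond (z) coordinates along the sequence, one panel
#' per axis.
#'
#' @param characteristic A characteristic sequence (see
#'   [encode_structure()]).
#' @return A ggplot object.
#' @export
plot_curve <- function(characteristic) {
  curve <- hairpin_curve(characteristic)
  long <- tidyr::pivot_longer(curve, c("x", "y", "z"),
                              names_to = "axis", values_to = "coordinate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$coordinate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          x = "x: purine (+) / pyrimidine (-)",
                          y = "y: amino (+) / keto (-)",
                          z = "z: strong (+) / weak (-) H-bond"
                        ))) +
    ggplot2::labs(x = "sequence position", y = "cumulative coordinate") +
    ggplot2::theme_minimal()
}
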