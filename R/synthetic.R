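#' Synthetic corpus configuration
#'
#' Parameters of the generator that emulates a miRNA-precursor learning
#' corpus: stem-loop positives with imperfect stems, and composition-matched
#' pseudohairpin decoys as negatives.
#'
#' @param n_pos,n_neg Number of positive / negative records.
#' @param seed Integer seed; the corpus is fully determined by it.
#' @param stem_len_range Stem length interval in base pairs (default 18-30).
#' @param loop_len_range Terminal loop length interval in nt (default 4-12).
#' @param mismatch_rate Probability that a 3'-arm base breaks its
#'   complement (default 0.10).
#' @param bulge_rate Probability of a single-base bulge insertion per stem
#'   position (default 0.05).
#' @param gc_content Target GC fraction of drawn bases, both classes
#'   (default 0.5).
#' @param neg_mode `"dinucleotide_shuffle"` (default): negatives are
#'   hairpins passed through a dinucleotide-preserving shuffle, destroying
#'   the stem while keeping mono- and dinucleotide composition;
#'   `"random_matched"`: i.i.d. bases at the target GC with lengths drawn
#'   from the positive length distribution.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pos = 200L, n_neg = 200L, seed = 1L,
                         stem_len_range = c(18L, 30L),
                         loop_len_range = c(4L, 12L),
                         mismatch_rate = 0.10, bulge_rate = 0.05,
                         gc_content = 0.5,
                         neg_mode = c("dinucleotide_shuffle", "random_matched")) {
  neg_mode <- match.arg(neg_mode)
  if (mismatch_rate < 0 || mismatch_rate >= 1) stop_input("mismatch_rate must be in [0, 1)")
  if (bulge_rate < 0 || bulge_rate >= 1) stop_input("bulge_rate must be in [0, 1)")
  if (gc_content <= 0 || gc_content >= 1) stop_input("gc_content must be in (0, 1)")
  if (stem_len_range[1] > stem_len_range[2] || loop_len_range[1] > loop_len_range[2]) {
    stop_input("length ranges must be non-empty")
  }
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg), seed = as.integer(seed),
      stem_len_range = as.integer(stem_len_range),
      loop_len_range = as.integer(loop_len_range),
      mismatch_rate = mismatch_rate, bulge_rate = bulge_rate,
      gc_content = gc_content, neg_mode = neg_mode
    ),
    class = "synth_config"
  )
}

draw_bases <- function(n, gc) {
  strong <- stats::runif(n) < gc
  out <- character(n)
  out[strong] <- sample(c("G", "C"), sum(strong), replace = TRUE)
  out[!strong] <- sample(c("A", "U"), sum(!strong), replace = TRUE)
  out
}

complement_base <- c(A = "U", U = "A", G = "C", C = "G")

# uniform integer from a closed range; safe for degenerate one-value ranges
sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1) - 1L
}

#' Draw one miRNA-like stem-loop sequence
#'
#' Builds `stem + loop + reverse-complement(stem)`, with each 3'-arm base
#' independently replaced by a random non-complementary base with
#' probability `mismatch_rate`, and single-base bulges inserted into the
#' 3' arm with probability `bulge_rate` per stem position. Uses the current
#' RNG state: `set.seed()` before the call for reproducibility.
#'
#' @param config A [synth_config()].
#' @return A single RNA sequence string.
#' @export
simulate_hairpin <- function(config = synth_config()) {
  s <- sample_range(config$stem_len_range)
  l <- sample_range(config$loop_len_range)
  stem5 <- draw_bases(s, config$gc_content)
  loop <- draw_bases(l, config$gc_content)
  stem3 <- unname(complement_base[rev(stem5)])
  mism <- stats::runif(s) < config$mismatch_rate
  for (i in which(mism)) {
    stem3[i] <- sample(setdiff(c("A", "C", "G", "U"), stem3[i]), 1)
  }
  arm3 <- character(0)
  for (i in seq_len(s)) {
    arm3 <- c(arm3, stem3[i])
    if (stats::runif(1) < config$bulge_rate) {
      arm3 <- c(arm3, draw_bases(1, config$gc_content))
    }
  }
  paste(c(stem5, loop, arm3), collapse = "")
}

#' Draw one pseudohairpin decoy sequence
#'
#' In `"dinucleotide_shuffle"` mode, draws a hairpin via
#' [simulate_hairpin()] and applies an exact dinucleotide-preserving shuffle
#' (random Eulerian walk on the dinucleotide multigraph, Altschul-Erickson
#' style): the stem is destroyed but mono- and dinucleotide composition is
#' preserved, giving composition-realistic decoys. In `"random_matched"`
#' mode, draws i.i.d. bases at the target GC with a length from the positive
#' length distribution. Uses the current RNG state.
#'
#' @param config A [synth_config()].
#' @return A single RNA sequence string.
#' @export
simulate_pseudohairpin <- function(config = synth_config()) {
  if (config$neg_mode == "dinucleotide_shuffle") {
    dinucleotide_shuffle(simulate_hairpin(config))
  } else {
    s <- sample_range(config$stem_len_range)
    l <- sample_range(config$loop_len_range)
    paste(draw_bases(2 * s + l, config$gc_content), collapse = "")
  }
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Returns a uniform-random sequence with exactly the same first letter,
#' last letter, and dinucleotide counts as the input, computed as a random
#' Eulerian path on the dinucleotide multigraph: for every letter except the
#' terminal one, a "last exit" edge is drawn repeatedly until the last-exit
#' edges all lead to the terminal letter, the remaining edges are permuted,
#' and the path is walked from the first letter.
#'
#' @param sequence A single sequence string.
#' @return A shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  from <- s[-n]
  to <- s[-1]
  vertices <- unique(s)
  final <- s[n]
  adj <- split(to, factor(from, levels = vertices))
  needs_exit <- vertices[vertices != final &
                           vapply(adj[vertices], length, integer(1)) > 0]
  # draw last-exit edges until each vertex with out-edges reaches `final`
  repeat {
    last_exit <- vapply(needs_exit, function(v) {
      es <- adj[[v]]
      es[sample.int(length(es), 1)]
    }, character(1))
    ok <- all(vapply(needs_exit, function(v) {
      for (step in seq_along(vertices)) {
        v <- last_exit[[v]]
        if (identical(v, final)) return(TRUE)
        if (!v %in% needs_exit) return(FALSE)
      }
      FALSE
    }, logical(1)))
    if (ok) break
  }
  ordered <- adj
  for (v in vertices) {
    es <- adj[[v]]
    if (length(es) == 0) next
    if (v %in% needs_exit) {
      drop_idx <- match(last_exit[[v]], es)
      rest <- es[-drop_idx]
      ordered[[v]] <- c(if (length(rest)) sample(rest, length(rest)), last_exit[[v]])
    } else {
      ordered[[v]] <- sample(es, length(es))
    }
  }
  ptr <- stats::setNames(rep(1L, length(vertices)), vertices)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Generate a labeled synthetic corpus
#'
#' Draws `n_pos` miRNA-like hairpins and `n_neg` pseudohairpin decoys under
#' a single seed, with ids `syn_pos_0001`, ..., `syn_neg_0001`, ... . The
#' corpus is fully determined by the configuration: two runs with the same
#' seed are identical.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, `positives.fa` and
#'   `negatives.fa` are written there.
#' @return A list with tibbles `pos` and `neg` (columns `id`,
#'   `description`, `sequence`).
#' @examples
#' corpus <- simulate_corpus(synth_config(n_pos = 3, n_neg = 3, seed = 42))
#' corpus$pos
#' @export
simulate_corpus <- function(config = synth_config(), dir = NULL) {
  if (!inherits(config, "synth_config")) stop_input("config must be a synth_config()")
  build <- function() {
    pos <- vapply(seq_len(config$n_pos), function(i) simulate_hairpin(config), character(1))
    neg <- vapply(seq_len(config$n_neg), function(i) simulate_pseudohairpin(config), character(1))
    list(
      pos = tibble(
        id = sprintf("syn_pos_%04d", seq_len(config$n_pos)),
        description = "synthetic miRNA-like hairpin",
        sequence = pos
      ),
      neg = tibble(
        id = sprintf("syn_neg_%04d", seq_len(config$n_neg)),
        description = paste0("synthetic pseudohairpin (", config$neg_mode, ")"),
        sequence = neg
      )
    )
  }
  corpus <- withr::with_seed(config$seed, build())
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (config$n_pos > 0) write_fasta(corpus$pos, file.path(dir, "positives.fa"))
    else file.create(file.path(dir, "positives.fa"))
    if (config$n_neg > 0) write_fasta(corpus$neg, file.path(dir, "negatives.fa"))
    else file.create(file.path(dir, "negatives.fa"))
  }
  corpus
}
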