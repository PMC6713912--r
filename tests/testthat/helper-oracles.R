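# Independent oracles, deliberately naive: no code shared with the package.

# Exhaustive maximum-pairing oracle: enumerates every legal non-crossing
# pairing of the interval (no memoization, no DP) and returns the maximum
# pair count. Feasible for sequences up to ~12 nt.
brute_force_max_pairs <- function(sequence, min_loop = 3,
                                  allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  s <- strsplit(sequence, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i, j - 1) # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (paste0(s[k], s[j]) %in% allowed) {
        inner <- if (k + 1 <= j - 1) rec(k + 1, j - 1) else 0L
        outer <- if (k > i) rec(i, k - 1) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  if (length(s) < 2) 0L else rec(1L, length(s))
}

# Naive per-position recomputation of the 36-feature descriptor: explicit
# loops, base vectors written out locally.
naive_descriptor <- function(characteristic, structure) {
  vmap <- list(
    A = c(1, 1, -1), C = c(-1, 1, 1), G = c(1, -1, 1), U = c(-1, -1, -1),
    a = c(-1, -1, 1), c = c(1, -1, -1), g = c(-1, 1, -1), u = c(1, 1, 1)
  )
  cs <- strsplit(characteristic, "")[[1]]
  st <- strsplit(structure, "")[[1]]
  n <- length(cs)
  p <- c(0, 0, 0)
  sums <- list()
  counts <- list()
  for (i in seq_len(n)) {
    p <- p + vmap[[cs[i]]]
    key <- paste0(toupper(cs[i]), st[i])
    if (is.null(sums[[key]])) {
      sums[[key]] <- c(0, 0, 0)
      counts[[key]] <- 0
    }
    sums[[key]] <- sums[[key]] + p
    counts[[key]] <- counts[[key]] + 1
  }
  out <- numeric(0)
  for (b in c("A", "C", "G", "U")) {
    for (s2 in c(".", "(", ")")) {
      key <- paste0(b, s2)
      if (is.null(sums[[key]])) {
        out <- c(out, 0, 0, 0)
      } else {
        out <- c(out, sums[[key]] / (n * counts[[key]]))
      }
    }
  }
  out
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Pull (i, j) pair indices out of a dot-bracket string.
bracket_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1]] <- c(j, i)
    }
  }
  pairs
}

# A small folded corpus shared by several tests.
folded_synthetic <- function(n, seed = 101, ...) {
  cfg <- synth_config(n_pos = n, n_neg = 0, seed = seed, ...)
  fold_hairpins(simulate_corpus(cfg)$pos)
}

# Two well-separated 36-D Gaussian clouds: +1/-1 on the first six features,
# sd 0.1, n per class.
gaussian_cloud_table <- function(n_per_class = 50, seed = 400, sd = 0.1) {
  withr::with_seed(seed, {
    make <- function(center, label, offset) {
      m <- matrix(stats::rnorm(n_per_class * 36, sd = sd), n_per_class, 36)
      m[, 1:6] <- m[, 1:6] + center
      colnames(m) <- feature_names()
      dplyr::bind_cols(
        tibble::tibble(
          id = sprintf("%s_%03d", label, seq_len(n_per_class) + offset),
          label = label
        ),
        tibble::as_tibble(m)
      )
    }
    dplyr::bind_rows(make(1, "positive", 0), make(-1, "negative", 0))
  })
}
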