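test_that("read_fasta parses, normalizes, and round-trips records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGU"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, "s1")
  expect_equal(recs$description, "")
  expect_equal(recs$sequence, "ACGU")

  # multiline sequence, DNA alphabet, lowercase -> coerced
  writeLines(c(">s1 desc", "acg", "t"), fa)
  recs <- read_fasta(fa, alphabet = "coerce")
  expect_equal(recs$sequence, "ACGU")
  expect_equal(recs$description, "desc")

  # round trip preserves id, description, normalized sequence
  out <- withr::local_tempfile(fileext = ".fa")
  orig <- tibble::tibble(
    id = c("a1", "b2"), description = c("first record", ""),
    sequence = c("ACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUA", "GGCC")
  )
  write_fasta(orig, out, width = 20)
  expect_equal(as.data.frame(read_fasta(out)), as.data.frame(orig))
})

test_that("read_fasta rejects bad inputs with informative errors", {
  expect_error(read_fasta(file.path(tempdir(), "no_such.fa")),
               class = "hairpin3d_input_error")

  fa <- withr::local_tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(read_fasta(fa), "empty", class = "hairpin3d_input_error")

  writeLines(c(">s1", "ACGX"), fa)
  err <- expect_error(read_fasta(fa, alphabet = "strict"),
                      class = "hairpin3d_input_error")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "4")

  # ambiguity codes rejected under both policies
  writeLines(c(">amb", "ACGN"), fa)
  expect_error(read_fasta(fa, alphabet = "coerce"), "ambiguity",
               class = "hairpin3d_input_error")
  expect_error(read_fasta(fa, alphabet = "strict"), class = "hairpin3d_input_error")
})

test_that("read_vienna parses structures and optional energies", {
  vf <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c(">s1", "GGGAAACCC", "(((...)))"), vf)
  rec <- read_vienna(vf)
  expect_equal(rec$structure, "(((...)))")
  expect_equal(rec$score_kind, "unspecified")
  expect_true(is.na(rec$score))

  writeLines(c(">s1", "GGGAAACCC", "(((...))) (-1.10)"), vf)
  rec <- read_vienna(vf)
  expect_equal(rec$score, -1.10)
  expect_equal(rec$score_kind, "energy")

  # RNAfold prints a space before negative energies
  writeLines(c(">s1", "GGGAAACCC", "(((...))) ( -7.20)"), vf)
  expect_equal(read_vienna(vf)$score, -7.20)
})

test_that("read_vienna rejects malformed structures", {
  vf <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c(">s1", "GGGAAACCC", "((.))"), vf)
  expect_error(read_vienna(vf), "length", class = "hairpin3d_input_error")

  writeLines(c(">s1", "GGGAAACCC", "(((...))."), vf)
  expect_error(read_vienna(vf), "unbalanced", class = "hairpin3d_input_error")

  writeLines(c(">s1", "GGGAAACCC"), vf)
  expect_error(read_vienna(vf), "triplet", class = "hairpin3d_input_error")
})

test_that("read_vienna accepts everything fold_hairpins writes", {
  folded <- folded_synthetic(8)
  vf <- withr::local_tempfile(fileext = ".vienna")
  write_vienna(folded, vf)
  back <- read_vienna(vf)
  expect_equal(back$id, folded$id)
  expect_equal(back$sequence, folded$sequence)
  expect_equal(back$structure, folded$structure)
})

test_that("feature tables round-trip losslessly through TSV", {
  feats <- featurize_hairpins(folded_synthetic(3), label = "positive")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(feats, path)

  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_length(header, 38) # id + label + 36 descriptor names
  expect_equal(header, c("id", "label", feature_names()))

  back <- read_feature_table(path)
  expect_equal(back$id, feats$id)
  expect_equal(back$label, feats$label)
  expect_equal(
    as.matrix(back[, feature_names()]),
    as.matrix(feats[, feature_names()]),
    tolerance = 1e-12
  )
})

test_that("read_feature_table rejects schema violations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  feats <- featurize_hairpins(folded_synthetic(2), label = "negative")
  write_feature_table(feats, path)

  lines <- readLines(path)
  writeLines(sub("\tA_unpaired_x", "", lines), path) # drop a column
  expect_error(read_feature_table(path), class = "hairpin3d_schema_error")

  write_feature_table(feats, path)
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path) # duplicate an id
  expect_error(read_feature_table(path), "duplicated",
               class = "hairpin3d_schema_error")
})

test_that("models survive save/load with identical predictions", {
  tab <- gaussian_cloud_table(20)
  model <- train_classifier(tab, "random_forest", seed = 11)
  path <- withr::local_tempfile(fileext = ".model")
  save_model(model, path)
  restored <- load_model(path)
  expect_equal(restored$kind, "random_forest")
  newdata <- gaussian_cloud_table(10, seed = 500)
  expect_equal(predict(restored, newdata), predict(model, newdata))
})

test_that("load_model fails loudly on version mismatch and corrupt files", {
  path <- withr::local_tempfile(fileext = ".model")
  saveRDS(list(format_version = "hairpin3d-model-999", kind = "random_forest"), path)
  expect_error(load_model(path), "version", class = "hairpin3d_input_error")

  writeLines("not a model", path)
  expect_error(load_model(path), class = "hairpin3d_input_error")
})
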