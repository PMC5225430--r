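# Feature schema, contact order, MSA column features, derived transforms,
# external-score ingestion, Z-scoring.

test_that("schema has 25 features, 6 local, and the 5-feature view", {
  sch <- feature_schema()
  expect_identical(nrow(sch), 25L)
  expect_identical(sum(sch$local), 6L)
  expect_setequal(sch$name[sch$local],
                  c("verify3d_local", "mutation_score", "gap_ratio",
                    "conservation", "spad_local", "log_lspad_ratio"))
  sub <- feature_subset5()
  expect_length(sub, 5)
  expect_true(all(sub %in% sch$name))
})

test_that("contact order: extended chain has none, hairpin averages correctly", {
  ext <- structure_model(1:8, rep("ALA", 8), cbind((0:7) * 3.8, 0, 0))
  expect_warning(co <- compute_contact_order(ext, contact_cutoff = 6.0),
                 "no contacts")
  expect_identical(co, list(co = 0, relative_co = 0))

  # hairpin with exactly the contacts (1,6) and (2,5):
  # residues 1,2,3 out at y=0; 4,5,6 back at y=3; 6 A cutoff, sep >= 2
  xy <- rbind(c(0, 0), c(8, 0), c(16, 0), c(16, 3), c(8, 3), c(0, 3))
  hp <- structure_model(1:6, rep("ALA", 6), cbind(xy, 0))
  co <- compute_contact_order(hp, contact_cutoff = 6.0)
  expect_equal(co$co, (5 + 3) / 2)
  expect_equal(co$relative_co, 4 / 6)
})

test_that("relative contact order never exceeds 1", {
  set.seed(12)
  for (trial in 1:20) {
    sm <- generate_toy_structure(sample(5:15, 1),
                                 seed = trial)
    co <- suppressWarnings(compute_contact_order(sm))
    expect_lte(co$relative_co, 1)
  }
})

test_that("MSA column features follow the stated definitions", {
  msa <- rbind(c("A", "A", "A"),
               c("A", "-", "A"),
               c("A", "-", "S"),
               c("A", "-", "S"))
  f <- compute_msa_features(msa, target_row = 1)
  expect_identical(f$column, c(1L, 2L, 3L))
  # column 1: all A over 4 sequences
  expect_equal(f$conservation[1], 1.0)
  expect_equal(f$gap_ratio[1], 0.0)
  expect_equal(f$mutation_score[1], blosum45("A", "A"))
  # column 2: A,-,-,- -> gap ratio 3/4
  expect_equal(f$gap_ratio[2], 0.75)
  # column 3: A,A,S,S -> pairs AA, AS, AS, AS, AS, SS
  expect_equal(f$mutation_score[3],
               mean(c(blosum45("A", "A"), rep(blosum45("A", "S"), 4),
                      blosum45("S", "S"))))
  expect_equal(f$conservation[3], 2 / 4)
  expect_error(compute_msa_features(list(c("A", "A"), c("A"))), "ragged")
})

test_that("three-sequence column matches direct BLOSUM45 lookups", {
  msa <- rbind("A", "A", "S")
  f <- compute_msa_features(msa, 1)
  expect_equal(f$mutation_score,
               mean(c(blosum45("A", "A"), blosum45("A", "S"),
                      blosum45("A", "S"))))
  # BLOSUM45 spot values from the published matrix
  expect_identical(blosum45("A", "A"), 5L)
  expect_identical(blosum45("W", "W"), 15L)
  expect_identical(blosum45("A", "S"), 1L)
  expect_identical(blosum45("R", "K"), 3L)
  expect_identical(blosum45("C", "W"), -5L)
})

test_that("target-gap columns are skipped in the residue mapping", {
  msa <- rbind(c("A", "-", "C"),
               c("A", "G", "C"))
  f <- compute_msa_features(msa, 1)
  expect_identical(f$column, c(1L, 3L))
})

test_that("derived transforms: arithmetic and the log floor", {
  sch <- feature_schema()
  v <- matrix(NA_real_, 2, 25, dimnames = list(NULL, sch$name))
  v[, "verify3d"] <- 50; v[, "model_length"] <- 100
  v[, "spad"] <- 1; v[, "spad_local"] <- 1
  out <- derived_transforms(v)
  expect_equal(unname(out[1, "verify3d_L2"]), 0.005)
  expect_equal(unname(out[1, "log_verify3d_L2"]), log(0.005))
  expect_equal(unname(out[1, "log_spad"]), log(1))
  expect_equal(unname(out[1, "log_lspad_ratio"]), log(0.5))

  v[, "verify3d"] <- 0
  expect_warning(out2 <- derived_transforms(v), "clamped")
  expect_equal(unname(out2[1, "log_verify3d_L2"]), log(1e-6))
})

test_that("external score ingestion: broadcast, imputation, errors", {
  sm <- generate_toy_structure(10, seed = 44)
  sch <- feature_schema()
  path <- withr::local_tempfile(fileext = ".tsv")

  # complete per-residue local columns + one MODEL row for a global score
  vals <- matrix(rnorm(10 * 25), 10, 25, dimnames = list(NULL, sch$name))
  write_feature_tsv(vals, sm$residue_index,
                    local = sch$name[sch$local], path)
  got <- ingest_external_scores(path, sm)
  expect_identical(dim(got), c(10L, 25L))
  # per-model value broadcast: identical across residues
  expect_true(all(got[, "dope"] == got[1, "dope"]))
  expect_equal(got[1, "dope"], vals[1, "dope"])
  # local column preserved per residue
  expect_equal(got[, "gap_ratio"], vals[, "gap_ratio"],
               ignore_attr = TRUE)
  expect_length(attr(got, "imputed"), 0)

  # missing column -> NA + imputation flag
  sub <- vals[, setdiff(sch$name, "spad_local")]
  write_feature_tsv(sub, sm$residue_index,
                    local = intersect(colnames(sub), sch$name[sch$local]),
                    path)
  got2 <- ingest_external_scores(path, sm)
  expect_true(all(is.na(got2[, "spad_local"])))
  expect_identical(attr(got2, "imputed"), "spad_local")

  # unknown column -> schema error; wrong residue count -> format error
  writeLines(c("residue_index\tnot_a_feature", "1\t0.5"), path)
  expect_error(ingest_external_scores(path, sm), "schema error")
  writeLines(c("residue_index\tdope", "1\t0.5", "2\t0.5"), path)
  expect_error(ingest_external_scores(path, sm), "format error")
})

test_that("Z-scoring uses population std and handles degenerate columns", {
  train <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zscore_fit_transform(train), "zero-variance")
  expect_equal(z$train[, "a"], (c(1, 2, 3) - 2) / sqrt(2 / 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(z$train[1, "a"]), -1.22474487, tolerance = 1e-8)
  expect_true(all(z$train[, "b"] == 0))
  # a test value equal to the training mean maps to 0
  test <- cbind(a = 2, b = 7)
  expect_equal(unname(zscore_transform(z$fit, test)[1, "a"]), 0)
})

test_that("Z-scoring is idempotent on the training table", {
  set.seed(3)
  train <- matrix(rnorm(200), 40, 5)
  z1 <- suppressWarnings(zscore_fit_transform(train))
  z2 <- suppressWarnings(zscore_fit_transform(z1$train))
  expect_lt(max(abs(z2$fit$center)), 1e-9)
  expect_lt(max(abs(z2$fit$scale - 1)), 1e-9)
  expect_equal(z2$train, z1$train, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ingest -> transform -> normalise is order-stable", {
  sm <- generate_toy_structure(12, seed = 10)
  sch <- feature_schema()
  set.seed(4)
  vals <- matrix(rnorm(12 * 25), 12, 25, dimnames = list(NULL, sch$name))
  vals[, !sch$local] <- rep(vals[1, !sch$local], each = 12)
  vals[, "verify3d"] <- abs(vals[, "verify3d"])
  vals[, "spad"] <- abs(vals[, "spad"])
  vals[, "spad_local"] <- abs(vals[, "spad_local"])
  vals[, "model_length"] <- 12
  t1 <- derived_transforms(vals)
  perm <- sample(12)
  t2 <- derived_transforms(vals[perm, ])
  expect_equal(t2[order(perm), ], t1, ignore_attr = TRUE)
  fit <- suppressWarnings(zscore_fit(t1))
  expect_equal(zscore_transform(fit, t2)[order(perm), ],
               zscore_transform(fit, t1), ignore_attr = TRUE)
})

test_that("assemble_features fills computed features and flags the rest", {
  sm <- generate_toy_structure(8, "HHHHHHHH", seed = 2)
  msa <- rbind(rep("A", 8), rep("A", 8), c(rep("A", 4), rep("S", 4)))
  f <- assemble_features(sm, msa = msa)
  expect_identical(dim(f), c(8L, 25L))
  expect_equal(unname(f[1, "model_length"]), 8)
  expect_true(all(f[, "conservation"] %in% c(1, 2 / 3)))
  expect_true("dope" %in% attr(f, "imputed"))
  expect_false("mutation_score" %in% attr(f, "imputed"))
})
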