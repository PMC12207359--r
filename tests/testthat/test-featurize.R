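# Reaction featurization: fingerprints, one-hot blocks, condition
# scaling and label binarization.

obabel_popcount <- function(smiles, type) {
  out <- system2("obabel", c(paste0("-:", shQuote(smiles, type = "sh")),
                             "-ofpt", paste0("-xf", type)),
                 stdout = TRUE, stderr = FALSE)
  as.integer(sub(">\\s*(\\d+) bits set.*", "\\1",
                 grep("bits set", out, value = TRUE)[1]))
}

obabel_tanimoto <- function(s1, s2, type) {
  out <- system2("obabel", c(shQuote(paste0("-:", s1)),
                             shQuote(paste0("-:", s2)),
                             "-ofpt", paste0("-xf", type)),
                 stdout = TRUE, stderr = FALSE)
  as.numeric(sub(".*Tanimoto from first mol = ([0-9.eE+-]+).*", "\\1",
                 grep("Tanimoto", out, value = TRUE)[1]))
}

test_that("circular fingerprints are deterministic and spelling-invariant", {
  f1 <- morgan_fingerprint("CCO")
  f2 <- morgan_fingerprint("CCO")
  f3 <- morgan_fingerprint("OCC")   # same molecule, different atom order
  expect_identical(f1, f2)
  expect_identical(f1, f3)
  expect_length(f1, 512)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_error(morgan_fingerprint("C1CC"), "unparseable SMILES")
})

test_that("fingerprints agree with the command-line reference implementation", {
  mols <- c("C", "CCO", "C=Cc1ccccc1", "c1ccc(P(c2ccccc2)c2ccccc2)cc1")
  # popcounts of the unfolded fingerprint match the reference tool
  raw <- dkmeta:::ob_fingerprints(canonical_smiles(mols), "ECFP4")
  for (i in seq_along(mols)) {
    expect_equal(sum(raw[i, ]), obabel_popcount(mols[i], "ECFP4"),
                 info = mols[i])
  }
  # pairwise Tanimoto similarities reconstructed from our bit vectors
  # match the similarities the reference tool prints
  for (pair in list(c("CCO", "CCN"), c("CCO", "CCCO"),
                    c("C=Cc1ccccc1", "C=C(C)c1ccccc1"))) {
    a <- dkmeta:::ob_fingerprints(canonical_smiles(pair), "ECFP4")
    tan <- sum(a[1, ] & a[2, ]) / sum(a[1, ] | a[2, ])
    # the reference tool prints six significant digits
    expect_equal(tan, obabel_tanimoto(pair[1], pair[2], "ECFP4"),
                 tolerance = 1e-4, info = paste(pair, collapse = " vs "))
  }
})

test_that("MACCS keys have length 166 and are spelling-invariant", {
  f <- maccs_fingerprint("C=Cc1ccccc1")
  expect_length(f, 166)
  expect_true(all(f %in% c(0L, 1L)))
  expect_identical(maccs_fingerprint("OCC"), maccs_fingerprint("CCO"))
  # methane sets no (or nearly no) structural keys
  expect_lte(sum(maccs_fingerprint("C")), 3)
  expect_error(maccs_fingerprint("not-a-smiles"), "unparseable")
})

test_that("reaction encoding yields the 1544-dimensional layout", {
  rec <- generate_toy_reactions(6, seed = 5)
  X <- encode_reactions(rec)
  X2 <- encode_reactions(rec)
  expect_equal(dim(X), c(6L, 1544L))
  expect_identical(X, X2)                 # pure function of the records
  lay <- attr(X, "layout")
  # fingerprint block is binary; one-hot blocks sum to one
  fp_cols <- seq(lay$olefin_fp[1], lay$solvent_fp[2])
  expect_true(all(X[, fp_cols] %in% c(0, 1)))
  metal <- X[, seq(lay$metal_onehot[1], lay$metal_onehot[2])]
  addit <- X[, seq(lay$additive_onehot[1], lay$additive_onehot[2])]
  expect_equal(unname(rowSums(metal)), rep(1, 6))
  expect_equal(unname(rowSums(addit)), rep(1, 6))
})

test_that("additive flag flips exactly the two additive one-hot slots", {
  rec <- generate_toy_reactions(1, seed = 3)
  rec2 <- rec
  rec2$additive <- !rec$additive
  v1 <- encode_reaction(rec)
  v2 <- encode_reaction(rec2)
  lay <- attr(encode_reactions(rec), "layout")
  slots <- seq(lay$additive_onehot[1], lay$additive_onehot[2])
  expect_identical(which(v1 != v2), slots)
})

test_that("unknown metals and missing conditions are rejected", {
  rec <- generate_toy_reactions(2, seed = 11)
  rec$metal[2] <- "Pd"
  expect_error(encode_reactions(rec), "unknown metal.*Pd")
  rec2 <- generate_toy_reactions(2, seed = 11)
  rec2$pressure_bar[1] <- NA
  expect_error(encode_reactions(rec2), "missing pressure_bar")
  expect_silent(X <- encode_reactions(rec2, impute = list(pressure_bar = 1)))
  expect_equal(nrow(X), 2)
})

test_that("condition scaling standardizes only the three scalar slots", {
  rec <- generate_toy_reactions(20, seed = 2)
  sc <- fit_condition_scaler(rec)
  X <- encode_reactions(rec, scaler = sc)
  lay <- attr(X, "layout")
  cond <- X[, seq(lay$conditions[1], lay$conditions[2])]
  expect_equal(colMeans(cond), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(cond, 2, sd), rep(1, 3), tolerance = 1e-10)
  # fingerprints stay binary under scaling
  expect_true(all(X[, 1:1536] %in% c(0, 1)))
})

test_that("ee binarization thresholds strictly above the cutoff", {
  expect_identical(binarize_ee(85), 1L)
  expect_identical(binarize_ee(79), 0L)
  expect_identical(binarize_ee(80), 0L)   # boundary goes to the low class
  expect_identical(binarize_ee(c(90.1, 90), threshold = 90), c(1L, 0L))
  # monotone non-decreasing in ee
  ee <- seq(0, 100, by = 0.5)
  expect_true(all(diff(binarize_ee(ee)) >= 0))
  expect_error(binarize_ee(101), "\\[0, 100\\]")
  expect_error(binarize_ee(-1), "\\[0, 100\\]")
})
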