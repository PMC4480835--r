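# Feature providers, window encoding, delta features, matrix assembly and
# normalization.

test_that("biophysical scales follow the documented sign conventions", {
  expect_lt(biophysical_features("D")[["charge"]], 0)
  expect_lt(biophysical_features("E")[["charge"]], 0)
  expect_gt(biophysical_features("K")[["charge"]], 0)
  expect_gt(biophysical_features("R")[["charge"]], 0)
  expect_identical(biophysical_features("A")[["charge"]], 0)
  expect_lt(biophysical_features("G")[["volume"]], biophysical_features("W")[["volume"]])
  for (aa in AA_ALPHABET) expect_true(all(is.finite(biophysical_features(aa))))
  expect_error(biophysical_features("B"), "unknown")
})

test_that("delta features subtract native minus variant and are antisymmetric", {
  expect_identical(compute_delta(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(compute_delta(1:3, 1:2), "length")
  # I (4.5) vs S (-0.8) on the hydropathy scale
  expect_equal(compute_delta(aa_hydropathy("I"), aa_hydropathy("S")), 5.3)
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(compute_delta(a, b), -compute_delta(b, a))
  }
})

test_that("per-residue delta antisymmetry holds for the built-in linear scales", {
  reg <- default_registry()
  s <- strsplit("MKVLAT", "")[[1]]
  for (prov in c("biophys_delta", "aaindex_delta")) {
    f <- reg[[prov]]$fn
    for (i in 1:10) {
      set.seed(i)
      pair <- sample(AA_ALPHABET, 2)
      expect_equal(f(s, 1L, pair[1], pair[2]), -f(s, 1L, pair[2], pair[1]))
    }
  }
})

test_that("contact-potential features are symmetric-table-validated", {
  tbl <- contact_potential_matrix()
  expect_identical(tbl, t(tbl))
  v <- contact_potential_feature("A", "C", tbl)
  expect_length(v, 60L)
  expect_equal(unname(v[41:60]), unname(tbl["A", ] - tbl["C", ]))
  # delta flips sign under wt/var swap; wt = var gives zero delta
  v2 <- contact_potential_feature("C", "A", tbl)
  expect_equal(unname(v[41:60]), -unname(v2[41:60]))
  vd <- contact_potential_feature("A", "A", tbl)
  expect_true(all(vd[41:60] == 0))
  bad <- tbl; bad[1, 2] <- bad[1, 2] + 1
  expect_error(contact_potential_feature("A", "C", bad), "symmetric")
})

test_that("global features normalize composition and mark absent structure", {
  g <- global_features("AAAA")
  expect_equal(g[["comp.A"]], 1)
  expect_equal(sum(g[paste0("comp.", AA_ALPHABET)]), 1, tolerance = 1e-9)
  expect_true(all(is.na(g[c("ss.H", "ss.E", "ss.C", "acc.b", "acc.e")])))
  set.seed(2)
  for (i in 1:5) {
    s <- paste(sample(AA_ALPHABET, 50, replace = TRUE), collapse = "")
    expect_equal(sum(global_features(s)[1:20]), 1, tolerance = 1e-9)
  }
  withss <- global_features("MKVL",
                            structure_states = data.frame(ss = c("H", "H", "C", "E"),
                                                          acc = c("b", "e", "e", "b")))
  expect_equal(withss[["ss.H"]], 0.5)
  expect_equal(withss[["acc.b"]], 0.5)
})

test_that("window encoding pads out-of-sequence cells with indicators", {
  reg <- default_registry()
  prot <- "MKVLAT"
  w1 <- encode_window(prot, 3L, 1L, reg$biophys)
  expect_length(w1, 4L)  # 3 values + 1 indicator
  expect_equal(w1[1:3], unname(biophysical_features("V")))
  expect_identical(w1[4], 0)

  w5 <- encode_window(prot, 1L, 5L, reg$biophys)
  expect_length(w5, 5L * 3L + 5L)
  pad <- w5[16:20]
  expect_identical(pad, c(1, 1, 0, 0, 0))     # two cells before position 1
  expect_true(all(w5[1:6] == 0))              # padded cells zero-filled

  w21 <- encode_window("ACDEFGHIKL", 5L, 21L, reg$biophys)
  expect_length(w21, 21L * 3L + 21L)
  expect_true(all(is.finite(w21)))
  expect_error(encode_window(prot, 3L, 7L, reg$biophys), "window")
})

test_that("terminus proximity scales into (0, 1] and peaks centrally", {
  reg <- default_registry()
  s <- strsplit(paste(rep("A", 21), collapse = ""), "")[[1]]
  t1 <- reg$terminus$fn(s, 1L)
  t11 <- reg$terminus$fn(s, 11L)
  expect_lt(t1, t11)
  expect_equal(t11, 1)
  expect_gt(t1, 0)
})

test_that("layout is a pure function of the descriptor list", {
  reg <- default_registry()
  desc <- list(feature_descriptor("biophys", 1L), feature_descriptor("biophys_delta", 1L))
  lay <- vepnet:::feature_layout(desc, reg)
  # 3 values + 1 pad for the windowed block, 3 for the pairwise block
  expect_identical(nrow(lay), 7L)
  expect_identical(sum(lay$is_pad), 1L)
  lay2 <- vepnet:::feature_layout(desc, reg)
  expect_identical(lay, lay2)
  expect_error(vepnet:::feature_layout(list(feature_descriptor("composition", 5L)), reg),
               "window 1")
  expect_error(vepnet:::feature_layout(list(feature_descriptor("nope", 1L)), reg),
               "unresolved")
})

test_that("assembled matrices are deterministic with train-only normalization", {
  st <- small_study()
  reg <- default_registry()
  desc <- default_descriptors()
  fm1 <- assemble_feature_matrix(st$dataset, desc, reg, normalize = FALSE)
  fm2 <- assemble_feature_matrix(st$dataset, desc, reg, normalize = FALSE)
  expect_identical(fm1$x, fm2$x)

  fit_rows <- 1:300
  norm <- fit_normalization(fm1$x, rows = fit_rows, is_pad = fm1$layout$is_pad)
  xn <- apply_normalization(fm1$x, norm)
  non_pad <- !fm1$layout$is_pad
  expect_equal(unname(colMeans(xn[fit_rows, non_pad])),
               rep(0, sum(non_pad)), tolerance = 1e-10)
  sds <- apply(xn[fit_rows, non_pad], 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-10))

  # leakage: corrupting rows outside fit_rows leaves parameters unchanged
  xc <- fm1$x
  xc[400:600, ] <- xc[400:600, ] * 100 + 7
  norm2 <- fit_normalization(xc, rows = fit_rows, is_pad = fm1$layout$is_pad)
  expect_identical(norm, norm2)
})

test_that("missing external profile values exclude rows rather than impute", {
  prot <- tiny_proteins()
  profiles <- data.frame(protein_id = "p1", position = 1:6,
                         feature_name = "cons", value = runif(6))
  reg <- default_registry(profiles = profiles)
  variants <- data.frame(protein_id = c("p1", "p2"), position = c(1L, 2L),
                         wt = c("M", "K"), var = c("K", "A"),
                         label = c("effect", "neutral"))
  ds <- variant_dataset(prot, variants)
  desc <- list(feature_descriptor("profile.cons", 1L))
  expect_message(fm <- assemble_feature_matrix(ds, desc, reg), "excluding 1")
  expect_identical(nrow(fm$x), 1L)
  expect_identical(fm$variants$protein_id, "p1")
})
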