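test_that("cell-count scaling is plain unit arithmetic", {
  expect_equal(scale_cell_counts(10, 1e3), 1e4)
  expect_equal(scale_cell_counts(0, 1e3), 0)
  expect_equal(scale_cell_counts(24, 1e3), 2 * scale_cell_counts(12, 1e3))
  expect_error(scale_cell_counts(5, 0), "area")
})

test_that("assay generation is seeded and reproduces configured means at zero noise", {
  tab <- gen_assay_table(noise_cv = 0, replicates = 3)
  eff <- default_assay_effects()
  ag <- aggregate(value ~ surface + assay, tab, mean)
  m <- merge(ag, eff)
  expect_equal(m$value, m$mean, tolerance = 1e-12)
  expect_identical(gen_assay_table(seed = 5), gen_assay_table(seed = 5))
  expect_error(gen_assay_table(effects = data.frame(surface = "a",
                                                    assay = "x", mean = 1)),
               "reference")
})

test_that("normalization divides by the reference surface per assay", {
  tab <- gen_assay_table(noise_cv = 0)
  norm <- normalize_assays(tab)
  ref <- norm[norm$surface == "cholesterol_scl", ]
  expect_equal(ref$value_norm, rep(1, nrow(ref)))
  ## configured ratios recovered exactly at zero noise
  eff <- default_assay_effects()
  m <- merge(norm, eff)
  ref_eff <- eff[eff$surface == "cholesterol_scl", ]
  expected <- m$mean / ref_eff$mean[match(m$assay, ref_eff$assay)]
  expect_equal(m$value_norm, expected, tolerance = 1e-12)
  expect_error(normalize_assays(tab, reference_surface = "nope"), "missing")
})

test_that("the bioadhesion index is the mean of normalized components", {
  tab <- gen_assay_table(noise_cv = 0)
  idx <- bioadhesion_index(normalize_assays(tab))
  expect_equal(idx$index$index[idx$index$surface == "cholesterol_scl"], 1)
  ## hand-built component sets
  comp <- data.frame(surface = "s",
                     assay = c("ecoli_adhesion", "sepidermidis_adhesion",
                               "bsa_adsorption", "lysozyme_adsorption",
                               "fbs_adsorption"),
                     value_norm = c(1, 1, 1, 1, 6))
  expect_equal(bioadhesion_index(comp)$index$index, 2.0)
  comp$value_norm <- rep(0.7, 5)
  expect_equal(bioadhesion_index(comp)$index$index, 0.7)
  ## a surface lacking an assay that others have is a named error
  comp2 <- rbind(comp, transform(comp, surface = "s2"))
  expect_error(bioadhesion_index(comp2[-2, ]), "sepidermidis")
})

test_that("the index is invariant to per-assay rescaling and assay order", {
  tab <- gen_assay_table(seed = 77)
  idx1 <- bioadhesion_index(normalize_assays(tab))
  ## rescale each assay by an arbitrary factor before normalization
  tab2 <- tab
  for (a in unique(tab2$assay)) {
    f <- runif(1, 0.1, 10)
    tab2$value[tab2$assay == a] <- tab2$value[tab2$assay == a] * f
  }
  idx2 <- bioadhesion_index(normalize_assays(tab2))
  expect_equal(idx1$index, idx2$index, tolerance = 1e-12)
  ## permute rows
  tab3 <- tab[sample(nrow(tab)), ]
  idx3 <- bioadhesion_index(normalize_assays(tab3))
  m <- merge(idx1$index, idx3$index, by = "surface")
  expect_equal(m$index.x, m$index.y, tolerance = 1e-12)
  ## reference surface index is 1 regardless of the data
  expect_equal(idx2$index$index[idx2$index$surface == "cholesterol_scl"], 1)
})

test_that("the reference value uses the bare-substrate control of each assay class", {
  ## SiO2 for bacterial assays, gold for protein assays
  eff <- default_assay_effects()
  norm <- normalize_assays(gen_assay_table(effects = eff, noise_cv = 0))
  idx <- bioadhesion_index(norm)
  chol <- eff$mean[eff$surface == "cholesterol_scl"]
  expected <- mean(c(
    eff$mean[eff$surface == "SiO2" & grepl("adhesion", eff$assay)] /
      eff$mean[eff$surface == "cholesterol_scl" & grepl("adhesion", eff$assay)],
    eff$mean[eff$surface == "gold" & grepl("adsorption", eff$assay)] /
      eff$mean[eff$surface == "cholesterol_scl" & grepl("adsorption", eff$assay)]))
  expect_equal(idx$reference_value, expected, tolerance = 1e-12)
})
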