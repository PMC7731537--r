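test_that("zero heavy-isotope abundance yields an identity correction matrix", {
  iso <- isotope_table(overrides = list(
    C = c(1, 0), H = c(1, 0), N = c(1, 0), O = c(1, 0, 0),
    Si = c(1, 0, 0), S = c(1, 0, 0, 0, 0)))
  frag <- fragment_spec("toy", 3L, c(C = 5, H = 8, O = 2, Si = 1), 100)
  M <- build_correction_matrix(frag, iso, tracer_purity = 1)
  expect_equal(M[1:4, ], diag(4), ignore_attr = TRUE)
  expect_equal(M[5:6, ], matrix(0, 2, 4), ignore_attr = TRUE)
})

test_that("a single labeled carbon follows the one-atom binomial", {
  p <- 0.0107
  iso <- isotope_table(overrides = list(H = c(1, 0), O = c(1, 0, 0)))
  frag <- fragment_spec("one_carbon", 1L, c(C = 1, H = 1, O = 1), 50)
  M <- build_correction_matrix(frag, iso, tracer_purity = 1)
  expect_equal(M[, 1], c(1 - p, p, 0, 0), ignore_attr = TRUE)
  expect_equal(M[, 2], c(0, 1, 0, 0), ignore_attr = TRUE)
})

test_that("correction matrix columns match the brute-force isotope enumeration", {
  iso <- isotope_table()
  # small fragments (<= 12 atoms) where full enumeration is feasible
  frags <- list(
    fragment_spec("tiny", 2L, c(C = 3, H = 2, O = 1, Si = 1), 80),
    fragment_spec("mid", 3L, c(C = 5, H = 4, O = 2), 90),
    fragment_spec("sulfur", 2L, c(C = 3, H = 3, O = 2, S = 1), 85))
  for (frag in frags) {
    n <- frag$backbone_carbons
    M <- build_correction_matrix(frag, iso, tracer_purity = 0.99)
    for (j in 0:n) {
      comp <- frag$composition
      comp[["C"]] <- comp[["C"]] - j
      oracle <- brute_force_spectrum(comp, iso, n_labeled = j,
                                     purity = 0.99, max_offset = n + 2L)
      expect_equal(unname(M[, j + 1L]), oracle, tolerance = 1e-8)
    }
  }
})

test_that("correction round-trips any valid MID exactly at zero noise", {
  frag <- read_fragment_catalog()[["glutamate"]]
  M <- build_correction_matrix(frag, isotope_table())
  set.seed(3)
  for (rep in 1:20) {
    x <- random_mid(frag$backbone_carbons)
    raw <- as.numeric(M %*% x)
    expect_equal(as.numeric(correct_mid(raw, M)), x, tolerance = 1e-8)
  }
  # matrix column 0 corrects to a pure unlabeled pool
  corr <- correct_mid(M[, 1], M)
  expect_equal(as.numeric(corr), c(1, rep(0, frag$backbone_carbons)),
               tolerance = 1e-10)
})

test_that("correction is invariant to uniform intensity scaling", {
  frag <- read_fragment_catalog()[["malate"]]
  M <- build_correction_matrix(frag, isotope_table())
  set.seed(5)
  x <- random_mid(frag$backbone_carbons)
  raw <- as.numeric(M %*% x)
  expect_equal(as.numeric(correct_mid(raw * 2.7e6, M)),
               as.numeric(correct_mid(raw, M)), tolerance = 1e-12)
})

test_that("corrected MIDs stay accurate under additive SIM noise", {
  frag <- read_fragment_catalog()[["succinate"]]  # n = 4
  M <- build_correction_matrix(frag, isotope_table())
  tr <- tracer_spec("u13c5", enrichment = 0.06)
  x <- as.numeric(ideal_mid(tr, "succinate", 0.4))
  set.seed(17)
  errs <- replicate(200, {
    raw <- as.numeric(M %*% x) + rnorm(nrow(M), 0, 0.002)
    max(abs(as.numeric(correct_mid(pmax(raw, 0), M)) - x))
  })
  expect_lt(mean(errs), 0.005)  # within 0.5 percentage points per component
})

test_that("degenerate inputs are rejected with clear errors", {
  frag <- read_fragment_catalog()[["succinate"]]
  M <- build_correction_matrix(frag, isotope_table())
  expect_error(correct_mid(rep(0, 7), M), "all zero")
  expect_error(correct_mid(rep(0.1, 5), M), "does not match")
  iso_missing <- isotope_table()
  iso_missing$Si <- NULL
  expect_error(build_correction_matrix(frag, iso_missing), "missing from")
  expect_error(build_correction_matrix(frag, isotope_table(),
                                       tracer_purity = 0), "\\(0, 1\\]")
})

test_that("mole percent enrichment is the carbon-weighted labeling average", {
  expect_equal(mole_percent_enrichment(c(1, 0, 0, 0, 0)), 0)
  expect_equal(mole_percent_enrichment(c(0, 0, 0, 0, 1)), 1)
  # citrate with 2% at M4: 4 * 0.02 / 6
  expect_equal(mole_percent_enrichment(c(0.98, 0, 0, 0, 0.02, 0, 0)),
               0.02 * 4 / 6)
  expect_equal(fraction_labeled(c(0.98, 0, 0, 0, 0.02, 0, 0)), 0.02)
  # monotone in each labeled channel
  set.seed(9)
  base <- random_mid(4)
  for (i in 2:5) {
    up <- base
    up[i] <- up[i] + 0.05
    up[1] <- up[1] - 0.05
    expect_gt(mole_percent_enrichment(up), mole_percent_enrichment(base))
  }
  expect_error(mole_percent_enrichment(c(0.5, 0.2)), "sum to 1")
})

test_that("the packaged fragment catalog carries the monitored SIM channels", {
  cat <- read_fragment_catalog()
  expect_true(all(c("glutamate", "citrate", "fumarate", "malate",
                    "aspartate", "succinate", "alpha_ketoglutarate")
                  %in% names(cat)))
  expect_equal(cat$glutamate$m0_mz, 432.2)
  expect_equal(cat$citrate$m0_mz, 591.4)
  expect_gte(cat$malate$composition[["C"]], cat$malate$backbone_carbons)
})

test_that("tidy intensity tables correct per sample and metabolite", {
  frag <- read_fragment_catalog()["fumarate"]
  M <- build_correction_matrix(frag$fumarate, isotope_table())
  x <- c(0.9, 0, 0, 0, 0.1)
  tab <- data.frame(sample_id = "s1", metabolite = "fumarate",
                    channel = paste0("M", 0:6),
                    intensity = as.numeric(M %*% x) * 5e5)
  out <- correct_intensity_table(tab, frag)
  expect_equal(out$mpe$mpe, 0.1, tolerance = 1e-6)
  expect_equal(out$mids$fraction, x, tolerance = 1e-6)
  expect_error(correct_intensity_table(tab[-1, ], frag), "missing channel")
})
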