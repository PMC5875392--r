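test_that("shift_for_auc implements the closed-form calibration", {
  expect_equal(shift_for_auc(0.975), sqrt(2) * qnorm(0.975))
  expect_equal(shift_for_auc(0.975), 2.772, tolerance = 1e-3)
  expect_lt(shift_for_auc(0.5001), 0.001)        # symmetry limit
  expect_error(shift_for_auc(1.0), "strictly inside")
  expect_error(shift_for_auc(0.5), "strictly inside")
  expect_error(shift_for_auc(0.2), "strictly inside")
})

test_that("null features stay at AUC 0.5 within sampling bounds", {
  cohort <- make_cohort(300, 300, 20, n_informative = 0, seed = 1001)
  se_null <- sqrt((300 + 300 + 1) / (12 * 300 * 300)) # Mann-Whitney null SE
  for (i in 1:20) {
    auc <- roc_auc(cohort$matrix$values[i, ], cohort$labels$status,
                   compute_cutoff = FALSE)$auc
    expect_lt(abs(auc - 0.5), 3 * se_null)
  }
})

test_that("a planted marker lands near its target AUC", {
  cohort <- make_cohort(600, 1200, 5, n_informative = 1, target_auc = 0.97,
                        seed = 1002)
  auc <- roc_auc(cohort$matrix$values[1, ], cohort$labels$status,
                 compute_cutoff = FALSE)$auc
  expect_gte(auc, 0.955)
  expect_lte(auc, 0.985)
  expect_equal(cohort$manifest$target_auc[1], 0.97)
  expect_equal(cohort$manifest$delta[1], shift_for_auc(0.97))
  expect_true(all(cohort$manifest$delta[-1] == 0))
})

test_that("collinear blocks survive the lognormal margin transform", {
  spec <- synthetic_spec(600, 1200, 4,
                         collinear_blocks = list(c("miR-sim-0001",
                                                   "miR-sim-0002")),
                         block_r = 0.9, margin = "lognormal", seed = 1003)
  cohort <- generate_cohort(spec)
  v <- cohort$matrix$values
  expect_gt(spearman_rho(v[1, ], v[2, ]), 0.5)
  expect_lt(abs(spearman_rho(v[3, ], v[4, ])), 0.2)
  # lognormal margins fail the omnibus normality test decisively
  expect_lt(dagostino_pearson(v[3, ])$p_value, 1e-4)
})

test_that("rank statistics are invariant under monotone margin transforms", {
  cohort <- make_cohort(150, 150, 3, n_informative = 1, target_auc = 0.9,
                        seed = 1004)
  v <- cohort$matrix$values
  vt <- exp(v / 2) # strictly increasing transform of the observed values
  for (i in 1:3) {
    expect_equal(roc_auc(v[i, ], cohort$labels$status,
                         compute_cutoff = FALSE)$auc,
                 roc_auc(vt[i, ], cohort$labels$status,
                         compute_cutoff = FALSE)$auc)
  }
  expect_equal(spearman_rho(v[1, ], v[2, ]), spearman_rho(vt[1, ], vt[2, ]))
})

test_that("generation is bit-reproducible by seed and seed-sensitive", {
  spec <- synthetic_preset("desk", seed = 1005)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$manifest, b$manifest)
  c <- generate_cohort(synthetic_preset("desk", seed = 1006))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("fixture directories round trip through the package readers", {
  spec <- synthetic_spec(30, 40, 6,
                         planted_markers = data.frame(
                           feature_id = c("miR-sim-0001", "miR-sim-0002"),
                           target_auc = c(0.9, 0.8)),
                         collinear_blocks = list(c("miR-sim-0001",
                                                   "miR-sim-0003")),
                         seed = 1007)
  dir <- withr::local_tempdir()
  fx <- write_fixture(spec, dir)
  back <- read_expression_matrix(fx$paths[["matrix"]])
  expect_identical(back$values, fx$cohort$matrix$values)
  lab <- read_cohort_labels(fx$paths[["labels"]])
  expect_identical(lab$status, fx$cohort$labels$status)
  manifest <- jsonlite::read_json(fx$paths[["manifest"]],
                                  simplifyVector = TRUE)
  expect_true(isTRUE(manifest$synthetic))
  expect_setequal(manifest$planted_markers$feature_id,
                  c("miR-sim-0001", "miR-sim-0002"))
})

test_that("spec validation rejects inconsistent designs", {
  expect_error(synthetic_spec(10, 10, 5,
                              planted_markers = data.frame(
                                feature_id = "miR-sim-0009",
                                target_auc = 0.9)),
               "not in feature set")
  expect_error(synthetic_spec(10, 10, 5,
                              collinear_blocks = list(
                                c("miR-sim-0001", "miR-sim-0002"),
                                c("miR-sim-0002", "miR-sim-0003"))),
               "overlap")
  expect_error(synthetic_spec(10, 10, 5,
                              planted_markers = data.frame(
                                feature_id = "miR-sim-0001",
                                target_auc = 1.0)),
               "strictly inside")
  expect_error(synthetic_spec(10, 10, 6, cross_block_r = -0.6,
                              collinear_blocks = list(
                                c("miR-sim-0001", "miR-sim-0002"),
                                c("miR-sim-0003", "miR-sim-0004"),
                                c("miR-sim-0005", "miR-sim-0006"))),
               "cross_block_r")
})
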