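small_config <- function(...) {
  cfg <- default_config()
  cfg$n_subdivisions <- 1L
  modifyList(cfg, list(...))
}

test_that("zero-speed grid yields an all-zero curve", {
  lm <- generate_landmarks(variant_spec("bt_resistant", 6, seed = 3))
  cfg <- small_config(speeds = 0)
  curve <- run_variant(lm, cfg, reference_area_mm2 = 10)
  expect_equal(curve$max_deformation_mm, 0)
})

test_that("doubling the speed quadruples the deformation (linear path)", {
  lm <- generate_landmarks(variant_spec("bt_resistant", 6, seed = 3))
  cfg <- small_config(speeds = c(1.5, 3), reference_speed = 3)
  curve <- run_variant(lm, cfg, reference_area_mm2 = 10)
  expect_equal(curve$max_deformation_mm[2] / curve$max_deformation_mm[1], 4,
               tolerance = 1e-9)
})

test_that("default sweep curves rise monotonically to the top speed", {
  lm <- generate_landmarks(variant_spec("susceptible", 6, seed = 5))
  curve <- run_variant(lm, small_config(), reference_area_mm2 = 13.8)
  expect_equal(nrow(curve), 22L)
  expect_equal(curve$max_deformation_mm[1], 0)
  expect_true(all(diff(curve$max_deformation_mm) > 0))
  expect_equal(max(curve$max_deformation_mm),
               curve$max_deformation_mm[nrow(curve)])
  expect_equal(attr(curve, "reference_deformation_mm"),
               curve$max_deformation_mm[nrow(curve)])
})

test_that("share-of-sum percentages reproduce the reported arithmetic", {
  # the reported deformation triple and its printed percentages
  expect_equal(deformation_shares(c(0.0077, 0.0083, 0.0107)),
               c(29L, 31L, 40L))
  expect_equal(deformation_shares(c(1, 1, 1)), c(33L, 33L, 33L))
  expect_equal(deformation_shares(c(0, 2, 2)), c(0L, 50L, 50L))
  expect_true(all(is.na(deformation_shares(c(0, 0, 0)))))
  expect_error(deformation_shares(c(-1, 1)), "nonnegative")
})

test_that("variant comparison ranks, shares, and flags ties", {
  mk_curve <- function(variant, ref_def) {
    structure(data.frame(variant = variant, speed_mps = c(0, 4.2),
                         max_deformation_mm = c(0, ref_def)),
              class = c("deformation_curve", "data.frame"),
              reference_speed = 4.2, reference_deformation_mm = ref_def,
              meta = list())
  }
  cmp <- compare_variants(list(mk_curve("bt_resistant", 0.0077),
                               mk_curve("rotation_resistant", 0.0083),
                               mk_curve("susceptible", 0.0107)))
  expect_equal(cmp$variant[cmp$rank == 1], "susceptible")
  expect_equal(cmp$share_pct[order(cmp$variant)],
               c(29L, 31L, 40L)[order(c("bt_resistant",
                                        "rotation_resistant",
                                        "susceptible"))])
  expect_false(attr(cmp, "tie"))
  sums <- sum(cmp$share_pct)
  expect_true(abs(sums - 100) <= 1)

  tie <- compare_variants(list(mk_curve("a", 1), mk_curve("b", 1),
                               mk_curve("c", 1)))
  expect_true(attr(tie, "tie"))

  bad <- mk_curve("d", 1)
  bad$speed_mps <- c(0, 5)
  expect_error(compare_variants(list(mk_curve("a", 1), mk_curve("b", 1),
                                     bad)), "mismatched")
  expect_error(compare_variants(list(mk_curve("a", 1))), "three")
})

test_that("report writes curves, comparison, manifest and figure", {
  st <- run_study(seed = 2, config = small_config())
  out <- withr::local_tempdir()
  files <- report_sweep(st$comparison, st$curves, out, small_config(),
                        seed = 2)
  expect_true(all(file.exists(files)))
  curves <- read.csv(files["curves"])
  expect_equal(nrow(curves), 3 * 22)
  manifest <- jsonlite::read_json(files["manifest"])
  expect_equal(manifest$youngs_modulus, 1.5e8)
  expect_equal(manifest$poissons_ratio, 0.3)
  expect_equal(manifest$material_density, 1200)
  expect_equal(manifest$section_diameter, 4.5e-5)
  expect_equal(manifest$air_density, 1.225)
  expect_equal(manifest$scheme, "tributary_length")
  expect_equal(manifest$seed, 2)

  # re-running with the same config and seed is bit-identical
  st2 <- run_study(seed = 2, config = small_config())
  out2 <- withr::local_tempdir()
  files2 <- report_sweep(st2$comparison, st2$curves, out2, small_config(),
                         seed = 2)
  expect_identical(readLines(files["curves"]), readLines(files2["curves"]))
  expect_identical(readLines(files["comparison"]),
                   readLines(files2["comparison"]))
})

test_that("YAML config overrides merge over the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("section_diameter: 6.0e-5", "scheme: uniform_nodal",
               "material:", "  youngs_modulus: 2.0e+08"), path)
  cfg <- load_config(path)
  expect_equal(cfg$section_diameter, 6e-5)
  expect_equal(cfg$scheme, "uniform_nodal")
  expect_equal(cfg$material$youngs_modulus, 2e8)
  expect_equal(cfg$material$poissons_ratio, 0.3)  # default preserved
  expect_equal(cfg$reference_speed, 4.2)
})

test_that("aspect-ratio summary recovers the group means", {
  specs <- default_variant_specs(4)
  meas <- do.call(rbind, lapply(specs, generate_measurements))
  ar <- ar_summary(meas)
  expect_setequal(ar$variant, c("susceptible", "rotation_resistant",
                                "bt_resistant"))
  expect_equal(ar$mean_ar_rounded[ar$variant == "bt_resistant"], 7)
  expect_equal(ar$mean_ar_rounded[ar$variant == "susceptible"], 6)
  expect_equal(ar$mean_ar_rounded[ar$variant == "rotation_resistant"], 6)
})
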