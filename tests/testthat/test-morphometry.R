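test_that("TPS parsing handles single records, ids and validation", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=14",
               sprintf("%g %g", wing_template()[, 1], wing_template()[, 2]),
               "ID=s1"), path)
  got <- read_tps(path)
  expect_length(got, 1)
  expect_equal(got[[1]]$specimen_id, "s1")
  expect_equal(nrow(got[[1]]$coords), 14L)

  # LM count disagreeing with the expected landmark number is an error...
  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=13", sprintf("%g %g", 1:13, 1:13), "ID=s2"), bad)
  expect_error(read_tps(bad), "LM=13")
  # ... unless the count check is relaxed
  expect_length(read_tps(bad, n_landmarks = NULL), 1)

  empty <- withr::local_tempfile(fileext = ".tps")
  writeLines(character(0), empty)
  expect_error(read_tps(empty), "empty")
})

test_that("TPS write/read round trip is bit-exact for multi-specimen files", {
  specs <- variant_spec("bt_resistant", 5, seed = 3)
  lm <- generate_landmarks(specs)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(lm, path)
  back <- read_tps(path, variant = "bt_resistant")
  expect_length(back, 5)
  for (i in 1:5) {
    expect_identical(back[[i]]$coords, lm[[i]]$coords)
    expect_identical(back[[i]]$specimen_id, lm[[i]]$specimen_id)
  }
})

test_that("measurement CSV round trips with the documented header", {
  meas <- generate_measurements(variant_spec("susceptible", 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(meas, path)
  expect_identical(readLines(path, n = 1),
                   "specimen_id,variant,length_mm,width_mm,area_mm2")
  back <- read_measurements(path)
  expect_equal(back$area_mm2, meas$area_mm2)
})

test_that("GPA on identical configurations returns them with zero residual", {
  base <- landmark_set("a", "x", wing_template())
  gpa <- gpa_align(list(base, landmark_set("b", "x", wing_template())))
  expect_equal(gpa$mean$mean_procrustes_distance, 0, tolerance = 1e-14)
  expect_equal(gpa$mean$coords, normalize_shape(wing_template()),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GPA removes an arbitrary similarity transform exactly", {
  A <- wing_template()
  B <- similarity_transform(A, angle = 1.1, scale = 3.7, shift = c(5, -2))
  gpa <- gpa_align(list(landmark_set("a", "x", A),
                        landmark_set("b", "x", B)))
  expect_lt(sum((gpa$aligned[[1]]$coords - gpa$aligned[[2]]$coords)^2),
            1e-24)
})

test_that("GPA consensus is centered, unit-size, and similarity-invariant", {
  lm <- generate_landmarks(variant_spec("susceptible", 20, seed = 8))
  gpa <- gpa_align(lm)
  expect_lt(max(abs(colMeans(gpa$mean$coords))), 1e-12)
  expect_equal(centroid_size(gpa$mean$coords), 1, tolerance = 1e-12)

  # common similarity transform applied to every input leaves the consensus
  # unchanged up to rotation
  lm2 <- lapply(lm, function(s) {
    s$coords <- similarity_transform(s$coords, angle = 0.8, scale = 0.4,
                                     shift = c(3, 3))
    s
  })
  gpa2 <- gpa_align(lm2)
  expect_lt(procrustes_distance(gpa$mean$coords, gpa2$mean$coords), 1e-10)
})

test_that("GPA residual is monotone non-increasing over iterations", {
  lm <- generate_landmarks(variant_spec("rotation_resistant", 40,
                                        landmark_noise_sd = 0.05, seed = 21))
  gpa <- gpa_align(lm)
  expect_gte(length(gpa$ss_history), 2)
  expect_true(all(diff(gpa$ss_history) <= 1e-12))
  expect_true(gpa$converged)
})

test_that("GPA two-configuration rotation agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(31)
  A <- normalize_shape(wing_template())
  B <- normalize_shape(wing_template() + matrix(rnorm(28, sd = 0.02), 14, 2))
  R <- wingfem:::optimal_rotation(B, A)
  v <- vegan::procrustes(A, B, scale = FALSE)
  expect_equal(B %*% R, v$Yrot, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate and mismatched inputs are rejected", {
  good <- landmark_set("a", "x", wing_template())
  expect_error(gpa_align(list(good)), "at least 2")
  short <- landmark_set("c", "x", wing_template()[1:13, ])
  expect_error(gpa_align(list(good, short)), "mismatched")
  expect_error(landmark_set("d", "x", matrix(1, 14, 2)), "degenerate")
})

test_that("wireframe topology is validated", {
  ms <- structure(list(variant = "t", coords = normalize_shape(wing_template()),
                       n_specimens = 2L, mean_procrustes_distance = 0),
                  class = "mean_shape")
  # path graph over the 14 landmarks
  path_edges <- cbind(1:13, 2:14)
  wf <- build_wireframe(ms, path_edges, fixed_landmarks = 1L)
  expect_equal(nrow(wf$edges), 13L)

  # omitting landmark 14 disconnects the graph
  expect_error(build_wireframe(ms, cbind(1:12, 2:13), 1L), "connect")
  expect_error(build_wireframe(ms, rbind(path_edges, c(3, 3)), 1L), "self")
  expect_error(build_wireframe(ms, rbind(path_edges, c(2, 1)), 1L),
               "duplicate")
  expect_error(build_wireframe(ms, path_edges, integer(0)), "nonempty")
  expect_error(build_wireframe(ms, cbind(1:14, 2:15), 1L), "outside")

  # shipped template: 18 vein segments, base at landmarks 1-2
  wf0 <- build_wireframe(ms)
  expect_equal(nrow(wf0$edges), 18L)
  expect_equal(wf0$fixed_landmarks, c(1L, 2L))
})

test_that("aligned shapes export to a long table", {
  lm <- generate_landmarks(variant_spec("bt_resistant", 3, seed = 4))
  gpa <- gpa_align(lm)
  tab <- aligned_to_table(gpa$aligned)
  expect_equal(nrow(tab), 3 * 14)
  expect_named(tab, c("specimen_id", "variant", "landmark", "x", "y"))
})
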