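test_that("single-element cantilever matches Euler-Bernoulli closed forms", {
  model <- make_cantilever(1, L = 0.5,
                           mat = material(youngs_modulus = 2e9,
                                          poissons_ratio = 0.3, density = 1),
                           sec = cross_section(1e-3))
  E <- model$material$youngs_modulus
  G <- model$material$shear_modulus
  sec <- model$section
  L <- 0.5
  F <- 1e-3

  tip_z <- solve_linear(model, point_load(model, 2, 3, F))
  expect_equal(unname(tip_z$displacements[2, "uz"]), F * L^3 / (3 * E * sec$Iy),
               tolerance = 1e-13)
  tip_y <- solve_linear(model, point_load(model, 2, 2, F))
  expect_equal(unname(tip_y$displacements[2, "uy"]), F * L^3 / (3 * E * sec$Iz),
               tolerance = 1e-13)
  ax <- solve_linear(model, point_load(model, 2, 1, F))
  expect_equal(unname(ax$displacements[2, "ux"]), F * L / (E * sec$area),
               tolerance = 1e-13)
  tor <- solve_linear(model, point_load(model, 2, 4, 1e-4))
  expect_equal(unname(tor$rotations[2, "rx"]), 1e-4 * L / (G * sec$J),
               tolerance = 1e-13)
})

test_that("uniform-load cantilever with consistent nodal loads is exact", {
  model <- make_cantilever(1, L = 2)
  E <- model$material$youngs_modulus
  I <- model$section$Iy
  L <- 2
  w <- 0.07  # line load N/m, +z

  # discover the rotation sign convention from a point-load solve: the tip
  # slope of a tip-loaded cantilever is +FL^2/(2EI) in dw/dx terms
  probe <- solve_linear(model, point_load(model, 2, 3, 1e-3))
  s <- sign(probe$rotations[2, "ry"])

  # consistent (Hermite) nodal loads at the free end: wL/2, -wL^2/12 in
  # (w, dw/dx) coordinates
  loads <- matrix(0, 2, 6)
  loads[2, 3] <- w * L / 2
  loads[2, 5] <- s * (-w * L^2 / 12)
  def <- solve_linear(model, loads)
  expect_equal(unname(def$displacements[2, "uz"]), w * L^4 / (8 * E * I),
               tolerance = 1e-9)
})

test_that("zero load gives zero displacement and clamped DOFs stay zero", {
  model <- make_fixture_wing(2)
  def <- solve_linear(model, matrix(0, nrow(model$nodes), 6))
  expect_equal(max(abs(def$displacements)), 0)
  loaded <- solve_linear(model,
                         distribute_pressure(model, wind_load_case(4.2),
                                             1e-5, "tributary_length"))
  expect_equal(loaded$displacements[model$supports, ],
               matrix(0, length(model$supports), 3), ignore_attr = TRUE)
  expect_equal(loaded$rotations[model$supports, ],
               matrix(0, length(model$supports), 3), ignore_attr = TRUE)
})

test_that("two collinear elements condense to the single-element system", {
  m1 <- make_cantilever(1, L = 1)
  m2 <- make_cantilever(2, L = 1)
  K1 <- as.matrix(assemble_stiffness(m1))
  K2 <- as.matrix(assemble_stiffness(m2))
  # condense out the midnode (node 2 of m2): oracle is textbook static
  # condensation Kaa - Kab Kbb^-1 Kba over the end-node DOFs
  end <- c(1:6, 13:18)
  mid <- 7:12
  Kc <- K2[end, end] - K2[end, mid] %*% solve(K2[mid, mid]) %*% K2[mid, end]
  expect_equal(Kc, K1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("global stiffness is symmetric and SPD after constraints", {
  model <- make_fixture_wing(2)
  K <- assemble_stiffness(model)
  asym <- max(abs(K - Matrix::t(K))) / max(abs(K))
  expect_lt(asym, 1e-9)
  fac <- frame_factorization(model)
  ev <- eigen(as.matrix(fac$Kff), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("insufficient supports are reported as singular", {
  model <- make_cantilever(2)
  model$supports <- integer(0)
  loads <- point_load(model, 3, 3, 1)
  expect_error(suppressWarnings(solve_linear(model, loads)),
               "singular|constraints")
  expect_error(solve_linear(make_cantilever(1),
                            point_load(make_cantilever(1), 2, 3, NaN)),
               "non-finite")
})

test_that("response is linear in the load and work-energy consistent", {
  model <- make_fixture_wing(2)
  loads <- distribute_pressure(model, wind_load_case(2.5), 1.1e-5,
                               "tributary_length")
  base <- solve_linear(model, loads)
  for (alpha in c(0.5, 2, 10)) {
    scaled <- solve_linear(model, unclass(loads) * alpha)
    expect_equal(scaled$displacements, alpha * base$displacements,
                 tolerance = 1e-9)
  }
  # f^T u = u^T K u at the solution
  K <- assemble_stiffness(model)
  u <- as.vector(t(cbind(base$displacements, base$rotations)))
  f <- as.vector(t(unclass(loads)))
  expect_equal(sum(f * u), as.numeric(u %*% (K %*% u)),
               tolerance = 1e-9)
})

test_that("deformation grows from the clamped base to the distal tip", {
  model <- make_fixture_wing(2)
  loads <- distribute_pressure(model, wind_load_case(4.2), 1e-5,
                               "tributary_length")
  def <- solve_linear(model, loads)
  expect_equal(def$magnitude[model$supports], rep(0, 2))
  # the maximum sits at a node of maximal metric graph distance from the base
  g <- igraph::graph_from_edgelist(as.matrix(model$elements[, c("i", "j")]),
                                   directed = FALSE)
  igraph::E(g)$weight <- wingfem:::element_lengths(model)
  dist_base <- igraph::distances(g, v = model$supports)
  dmin <- apply(dist_base, 2, min)
  expect_equal(def$max_deformation_node, unname(which.max(dmin)))
  expect_equal(def$max_deformation, max(abs(def$displacements[, "uz"])))
})

test_that("convergence study: nodal point loads are exact at level 1", {
  builder <- function(lv) make_cantilever(lv, L = 1)
  loader <- function(model) point_load(model, nrow(model$nodes), 3, 1e-3)
  tab <- convergence_study(builder, loader, levels = c(1, 2, 4))
  expect_equal(tab$max_deformation,
               rep(tab$max_deformation[1], 3), tolerance = 1e-12)
  expect_true(all(tab$converged[-1]))
  expect_equal(tab$rel_change[2], 0, tolerance = 1e-12)
})

test_that("convergence study on the fixture wing settles under refinement", {
  loader <- function(model)
    distribute_pressure(model, wind_load_case(4.2), 1e-5, "tributary_length")
  tab <- convergence_study(make_fixture_wing, loader,
                           levels = c(1, 2, 4, 8))
  changes <- tab$rel_change[-1]
  expect_true(all(diff(changes) <= 0))
  expect_lt(changes[length(changes)], 0.01)
})

test_that("deformation fields export as CSV", {
  model <- make_cantilever(2)
  def <- solve_linear(model, point_load(model, 3, 3, 1e-3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_deformation(model, def, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$magnitude, def$magnitude)
})
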