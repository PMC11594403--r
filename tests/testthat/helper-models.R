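# Shared builders for structural test models. Units are deliberately benign
# (order-1 lengths and stiffnesses) except where a test targets the
# vein-scale fixture wing.

# Straight cantilever along +x: n_elements beams over length L, node 1 fixed.
make_cantilever <- function(n_elements = 1L, L = 1,
                            mat = material(youngs_modulus = 10,
                                           poissons_ratio = 0.3,
                                           density = 1),
                            sec = cross_section(0.1)) {
  xs <- seq(0, L, length.out = n_elements + 1L)
  structure(list(nodes = cbind(x = xs, y = 0, z = 0),
                 elements = data.frame(i = seq_len(n_elements),
                                       j = seq_len(n_elements) + 1L,
                                       edge = 1L),
                 material = mat, section = sec,
                 supports = 1L, n_subdivisions = 1L, n_landmarks = 2L),
            class = "frame_model")
}

# Point load/moment at one node of a frame model.
point_load <- function(model, node, dof, value) {
  loads <- matrix(0, nrow(model$nodes), 6)
  colnames(loads) <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")
  loads[node, dof] <- value
  loads
}

# Fixture wing frame: template wireframe at a given subdivision level,
# 8.4 mm scale, default vein material/section.
make_fixture_wing <- function(n_subdivisions = 2L, scale_mm = 8.4) {
  ms <- structure(list(variant = "fixture",
                       coords = normalize_shape(wing_template()),
                       n_specimens = 1L,
                       mean_procrustes_distance = 0),
                  class = "mean_shape")
  wf <- build_wireframe(ms)
  build_frame(wf, material(), cross_section(), scale_mm = scale_mm,
              n_subdivisions = n_subdivisions)
}

# Center and scale a configuration to unit centroid size.
normalize_shape <- function(coords) {
  co <- sweep(coords, 2, colMeans(coords))
  co / centroid_size(co)
}

# Full Procrustes distance between two configurations (centered, unit size,
# optimal rotation, no reflection).
procrustes_distance <- function(A, B) {
  A <- normalize_shape(A)
  B <- normalize_shape(B)
  R <- wingfem:::optimal_rotation(A, B)
  sqrt(sum((A %*% R - B)^2))
}

# Apply a similarity transform (rotation angle, scale, shift) to 2D coords.
similarity_transform <- function(coords, angle = 0, scale = 1,
                                 shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * coords %*% R, 2, shift, `+`)
}
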