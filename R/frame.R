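#' Isotropic elastic material for wing veins
#'
#' Defaults are the cuticle-like properties used throughout the analysis:
#' Young's modulus 150 MPa, Poisson's ratio 0.3, density 1200 kg/m^3.
#'
#' @param youngs_modulus Pa.
#' @param poissons_ratio dimensionless, in `[0, 0.5)`.
#' @param density kg/m^3 (kept for optional self-weight; wind-only loading
#'   does not use it).
#' @return an object of class `material` with derived shear modulus
#'   `G = E / (2 (1 + nu))`.
#' @export
material <- function(youngs_modulus = 150e6, poissons_ratio = 0.3,
                     density = 1200) {
  if (youngs_modulus <= 0) stop("youngs_modulus must be positive")
  if (poissons_ratio < 0 || poissons_ratio >= 0.5) {
    stop("poissons_ratio must be in [0, 0.5)")
  }
  if (density <= 0) stop("density must be positive")
  structure(list(youngs_modulus = youngs_modulus,
                 poissons_ratio = poissons_ratio,
                 density = density,
                 shear_modulus = youngs_modulus / (2 * (1 + poissons_ratio))),
            class = "material")
}

#' Solid circular beam cross-section
#'
#' The veins are idealized as solid circular beams; the default 45 micron
#' diameter is the vein thickness used for the wing models. Section constants
#' follow the solid circle: `A = pi d^2 / 4`, `I = pi d^4 / 64` (both bending
#' planes), `J = pi d^4 / 32`.
#'
#' @param diameter m.
#' @return an object of class `cross_section` with fields `area`, `Iy`, `Iz`,
#'   `J`.
#' @export
cross_section <- function(diameter = 45e-6) {
  if (diameter <= 0) stop("diameter must be positive")
  I <- pi * diameter^4 / 64
  structure(list(diameter = diameter,
                 shape = "solid_circular",
                 area = pi * diameter^2 / 4,
                 Iy = I, Iz = I,
                 J = pi * diameter^4 / 32),
            class = "cross_section")
}

#' Wing aspect ratio
#'
#' `AR = span^2 / area`, dimensionless. Under the default
#' `"single_wing_length"` convention the span is the measured length of the
#' dissected wing; `"full_span"` doubles it (both conventions are in use for
#' single-wing measurements; the default matches per-wing data).
#'
#' @param measurement one row (or a data frame) with `length_mm` and
#'   `area_mm2`; widths are validated as not exceeding lengths when present.
#' @param convention `"single_wing_length"` or `"full_span"`.
#' @return numeric vector of aspect ratios.
#' @export
aspect_ratio <- function(measurement,
                         convention = c("single_wing_length", "full_span")) {
  convention <- match.arg(convention)
  len <- measurement$length_mm
  area <- measurement$area_mm2
  if (any(len <= 0)) stop("wing length must be positive")
  if (any(area <= 0)) stop("wing area must be positive")
  if (!is.null(measurement$width_mm) &&
      any(measurement$width_mm > len + 1e-12)) {
    stop("wing width exceeds wing length")
  }
  span <- if (convention == "full_span") 2 * len else len
  span^2 / area
}

#' Build a 3D frame model from a vein wireframe
#'
#' Embeds the (dimensionless, unit-centroid-size) wireframe in the x-y plane
#' at `z = 0`, restores physical scale via `scale_mm` (normally the grand mean
#' centroid size of the raw specimens, in mm), converts to meters, and
#' subdivides every vein segment into `n_subdivisions` collinear beam
#' elements. Base landmarks become fixed supports clamping all six degrees of
#' freedom (no translation, no rotation).
#'
#' @param wireframe a [build_wireframe()] result.
#' @param material a [material()].
#' @param section a [cross_section()] shared by all elements.
#' @param scale_mm factor taking wireframe units to millimeters.
#' @param n_subdivisions beam elements per vein segment (>= 1).
#' @param edge_sections optional list of [cross_section()]s, one per
#'   wireframe edge, for tapered-vein experiments; overrides `section`
#'   edge by edge.
#' @return an object of class `frame_model`: `nodes` (n x 3, meters),
#'   `elements` (data frame `i`, `j`, `edge`), `material`, `section`,
#'   `supports` (node indices clamped in all 6 DOF), `n_subdivisions`.
#' @export
build_frame <- function(wireframe, material = wingfem::material(),
                        section = cross_section(), scale_mm = 1,
                        n_subdivisions = 1L, edge_sections = NULL) {
  stopifnot(inherits(wireframe, "vein_wireframe"))
  if (n_subdivisions < 1L) stop("n_subdivisions must be >= 1")
  n_subdivisions <- as.integer(n_subdivisions)
  if (scale_mm <= 0) stop("scale_mm must be positive")
  if (!is.null(edge_sections) &&
      length(edge_sections) != nrow(wireframe$edges)) {
    stop("edge_sections must have one cross_section per wireframe edge")
  }

  k <- nrow(wireframe$shape$coords)
  nodes <- cbind(wireframe$shape$coords * scale_mm * 1e-3, 0)
  colnames(nodes) <- c("x", "y", "z")

  elems <- list()
  for (e in seq_len(nrow(wireframe$edges))) {
    a <- wireframe$edges[e, 1]
    b <- wireframe$edges[e, 2]
    if (sum((nodes[a, ] - nodes[b, ])^2) == 0) {
      stop("zero-length edge after scaling: ", a, "-", b)
    }
    prev <- a
    for (s in seq_len(n_subdivisions)) {
      if (s < n_subdivisions) {
        t_frac <- s / n_subdivisions
        nodes <- rbind(nodes, nodes[a, ] + t_frac * (nodes[b, ] - nodes[a, ]))
        nxt <- nrow(nodes)
      } else {
        nxt <- b
      }
      elems[[length(elems) + 1L]] <- c(prev, nxt, e)
      prev <- nxt
    }
  }
  elements <- as.data.frame(do.call(rbind, elems))
  names(elements) <- c("i", "j", "edge")

  structure(list(nodes = nodes,
                 elements = elements,
                 material = material,
                 section = section,
                 edge_sections = edge_sections,
                 supports = wireframe$fixed_landmarks,
                 n_subdivisions = n_subdivisions,
                 n_landmarks = k),
            class = "frame_model")
}

#' @export
print.frame_model <- function(x, ...) {
  cat("<frame_model> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " beam elements, ", length(x$supports), " fixed node(s)\n", sep = "")
  invisible(x)
}

# Cross-section of element e (per-edge override or the shared default).
element_section <- function(model, e) {
  if (is.null(model$edge_sections)) return(model$section)
  model$edge_sections[[model$elements$edge[e]]]
}

# Element lengths (m).
element_lengths <- function(model) {
  d <- model$nodes[model$elements$j, , drop = FALSE] -
    model$nodes[model$elements$i, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Total skeleton length of a frame model
#'
#' Sum of element lengths (m); invariant under subdivision refinement.
#'
#' @param model a `frame_model`.
#' @return scalar length in meters.
#' @export
skeleton_length <- function(model) sum(element_lengths(model))

# Global DOF indices (6 per node) clamped by the supports.
fixed_dof_indices <- function(model) {
  as.vector(vapply(model$supports,
                   function(s) (s - 1L) * 6L + 1:6, integer(6)))
}

#' Serialize a frame model to plain-text files
#'
#' Writes `<prefix>_nodes.csv`, `<prefix>_elements.csv`,
#' `<prefix>_supports.csv`, and optionally a legacy-format VTK polyline file
#' of the (optionally deformed) skeleton with a point-data deformation scalar.
#'
#' @param model a `frame_model`.
#' @param prefix output path prefix.
#' @param vtk also write `<prefix>.vtk`.
#' @param deformation optional `deformation_field` used to displace the nodes
#'   and color the VTK output.
#' @return invisibly, the vector of files written.
#' @export
write_frame <- function(model, prefix, vtk = FALSE, deformation = NULL) {
  files <- character(0)
  nf <- paste0(prefix, "_nodes.csv")
  write.csv(data.frame(node = seq_len(nrow(model$nodes)), model$nodes),
            nf, row.names = FALSE)
  ef <- paste0(prefix, "_elements.csv")
  write.csv(model$elements, ef, row.names = FALSE)
  sf <- paste0(prefix, "_supports.csv")
  write.csv(data.frame(node = model$supports, fixed_dof = "all6"),
            sf, row.names = FALSE)
  files <- c(nf, ef, sf)
  if (vtk) {
    vf <- paste0(prefix, ".vtk")
    pts <- model$nodes
    scal <- rep(0, nrow(pts))
    if (!is.null(deformation)) {
      pts <- pts + deformation$displacements
      scal <- deformation$magnitude
    }
    con <- file(vf, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "wingfem vein skeleton", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(pts))), con)
    writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
    m <- nrow(model$elements)
    writeLines(sprintf("LINES %d %d", m, 3L * m), con)
    writeLines(sprintf("2 %d %d", model$elements$i - 1L,
                       model$elements$j - 1L), con)
    writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
                 "SCALARS deformation double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", scal), con)
    files <- c(files, vf)
  }
  invisible(files)
}
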