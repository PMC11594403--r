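#' Canonical 14-landmark hindwing vein template
#'
#' The package ships a synthetic hindwing template: 14 ordered landmarks in
#' dimensionless units (length axis along x, span roughly 1) joined by 18 vein
#' segments tracing three longitudinal veins (costal/radial, medial,
#' cubital/anal) that run from the wing base to the tip, plus three
#' crossveins. Landmarks 1 and 2 sit at the wing base (humeral and axillary
#' plates) and are the default fixed support. The topology is plausible for a
#' chrysomelid beetle hindwing but is not traced from any specimen; users with
#' digitized material replace it via TPS and edge-list files.
#'
#' @return `wing_template()`: a 14 x 2 matrix of landmark coordinates.
#' @export
wing_template <- function() {
  tps <- system.file("extdata", "hindwing_template.tps", package = "wingfem",
                     mustWork = TRUE)
  read_tps(tps)[[1]]$coords
}

#' @rdname wing_template
#' @return `wing_template_edges()`: an 18 x 2 integer matrix of 1-based
#'   landmark index pairs.
#' @export
wing_template_edges <- function() {
  path <- system.file("extdata", "hindwing_template_edges.csv",
                      package = "wingfem", mustWork = TRUE)
  as.matrix(read.csv(path))
}

#' @rdname wing_template
#' @return `wing_template_base()`: indices of the base (fixed-support)
#'   landmarks.
#' @export
wing_template_base <- function() c(1L, 2L)
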