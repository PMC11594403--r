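#' Dynamic pressure of wind
#'
#' `P = 1/2 rho v^2` — the pressure equivalent of steady wind of speed `v` in
#' air of density `rho`.
#'
#' @param wind_speed m/s, nonnegative.
#' @param air_density kg/m^3; default 1.225 (sea-level standard atmosphere).
#' @return pressure in Pa.
#' @export
wind_to_pressure <- function(wind_speed, air_density = 1.225) {
  if (any(wind_speed < 0)) stop("wind_speed must be nonnegative")
  if (air_density <= 0) stop("air_density must be positive")
  0.5 * air_density * wind_speed^2
}

#' A steady wind load case
#'
#' Bundles a wind speed with air density, the derived dynamic pressure
#' (always recomputed from speed and density, never stored independently) and
#' the load direction, by default the +z axis normal to the undeformed wing
#' plane.
#'
#' @param wind_speed m/s.
#' @param air_density kg/m^3.
#' @param direction 3-vector; normalized to unit length.
#' @return an object of class `wind_load_case`.
#' @export
wind_load_case <- function(wind_speed, air_density = 1.225,
                           direction = c(0, 0, 1)) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  structure(list(wind_speed = wind_speed,
                 air_density = air_density,
                 pressure = wind_to_pressure(wind_speed, air_density),
                 direction = direction / nrm),
            class = "wind_load_case")
}

#' Lump wind pressure onto the vein skeleton as nodal forces
#'
#' The wing membrane carries the dynamic pressure but the structural model is
#' a vein skeleton, so the total force `P x reference_area` (in the load
#' direction) is lumped onto the nodes. Under `"tributary_length"` each node
#' takes the share of total force proportional to its tributary length (half
#' of every adjacent element); supported nodes receive their share too — the
#' reactions absorb it. Under `"uniform_nodal"` the total is split equally
#' over free nodes only.
#'
#' @param model a `frame_model`.
#' @param case a [wind_load_case()].
#' @param reference_area loaded planform area, m^2 (normally the group's mean
#'   measured wing area).
#' @param scheme `"tributary_length"` or `"uniform_nodal"`.
#' @return an object of class `load_vector`: an n x 6 matrix (Fx, Fy, Fz, Mx,
#'   My, Mz per node, N and N m) with attribute `total_force`.
#' @export
distribute_pressure <- function(model, case, reference_area,
                                scheme = c("tributary_length",
                                           "uniform_nodal")) {
  stopifnot(inherits(model, "frame_model"), inherits(case, "wind_load_case"))
  scheme <- match.arg(scheme)
  if (reference_area <= 0) stop("reference_area must be positive")
  n <- nrow(model$nodes)
  if (n == 0L || nrow(model$elements) == 0L) stop("empty model")

  total <- case$pressure * reference_area
  weights <- numeric(n)
  if (scheme == "tributary_length") {
    len <- element_lengths(model)
    for (e in seq_along(len)) {
      weights[model$elements$i[e]] <- weights[model$elements$i[e]] + len[e] / 2
      weights[model$elements$j[e]] <- weights[model$elements$j[e]] + len[e] / 2
    }
  } else {
    free <- setdiff(seq_len(n), model$supports)
    weights[free] <- 1
  }
  weights <- weights / sum(weights)

  loads <- matrix(0, n, 6,
                  dimnames = list(NULL,
                                  c("Fx", "Fy", "Fz", "Mx", "My", "Mz")))
  loads[, 1:3] <- outer(weights * total, case$direction)
  structure(loads, class = "load_vector", total_force = total,
            scheme = scheme, reference_area = reference_area)
}

#' Parse a wind-speed sweep definition
#'
#' Accepts either a numeric vector of speeds or a `"min:max:n"` string (e.g.
#' `"0:4.2:22"` for 22 equally spaced speeds from 0 to 4.2 m/s).
#'
#' @param speeds numeric vector or sweep string.
#' @return numeric vector of speeds (m/s).
#' @export
parse_speed_grid <- function(speeds) {
  if (is.character(speeds)) {
    parts <- as.numeric(strsplit(speeds, ":")[[1]])
    if (length(parts) != 3 || any(is.na(parts)) || parts[3] < 2) {
      stop("sweep string must be 'min:max:n_points' with n_points >= 2")
    }
    speeds <- seq(parts[1], parts[2], length.out = as.integer(parts[3]))
  }
  if (any(speeds < 0)) stop("wind speeds must be nonnegative")
  sort(unique(speeds))
}
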