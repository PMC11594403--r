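#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one list: vein material
#' (Young's modulus 150 MPa, Poisson's ratio 0.3, density 1200 kg/m^3),
#' solid-circular section diameter (45 microns — the vein thickness), air
#' density (1.225 kg/m^3), load-lumping scheme, wind-speed grid (default: 22
#' points from 0 to the 4.2 m/s reference speed, twice the speed above which
#' rotation-resistant beetles were observed not to fly; an `extended` preset
#' covers 10-100 km/h), beam subdivision level, aspect-ratio convention and
#' solver choice.
#'
#' @return a named list; override entries via [load_config()] or
#'   `modifyList()`.
#' @export
default_config <- function() {
  list(
    material = list(youngs_modulus = 150e6, poissons_ratio = 0.3,
                    density = 1200),
    section_diameter = 45e-6,
    air_density = 1.225,
    scheme = "tributary_length",
    speeds = "0:4.2:22",
    reference_speed = 4.2,
    speed_presets = list(field = "0:4.2:22",
                         extended = "2.7778:27.7778:10"),
    n_subdivisions = 2L,
    ar_convention = "single_wing_length",
    solver = "linear",
    nonlinear = list(n_steps = 5L, tol = 1e-8),
    gpa = list(scale = TRUE, tol = 1e-10, max_iter = 100L)
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file; entries override [default_config()].
#' @return the merged configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

pipeline_log <- function(...) {
  if (isTRUE(getOption("wingfem.verbose", FALSE))) message(...)
}

#' Run the deformation pipeline for one variant group
#'
#' The full per-group chain: generalized Procrustes alignment of the
#' landmark configurations, wireframe construction, physical rescaling by
#' the grand mean centroid size, space-frame idealization, dynamic-pressure
#' loading at every speed of the grid, and a static solve per speed. The
#' linear path factorizes the stiffness once and reuses it across the sweep.
#'
#' @param landmarks list of [landmark_set()]s for one variant (raw
#'   digitized coordinates in mm, or a TPS path accepted by [read_tps()]).
#' @param config configuration list, see [default_config()].
#' @param measurements optional measurement data frame for this variant;
#'   its mean `area_mm2` becomes the loaded reference area.
#' @param reference_area_mm2 explicit loaded planform area (mm^2);
#'   overrides `measurements`.
#' @param edges,fixed_landmarks wireframe topology (default: shipped
#'   template).
#' @return a `deformation_curve`: data frame `variant`, `speed_mps`,
#'   `max_deformation_mm`, with attributes `reference_speed`,
#'   `reference_deformation_mm` and `meta` (stage parameters).
#' @export
run_variant <- function(landmarks, config = default_config(),
                        measurements = NULL, reference_area_mm2 = NULL,
                        edges = wing_template_edges(),
                        fixed_landmarks = wing_template_base()) {
  if (is.character(landmarks)) landmarks <- read_tps(landmarks)
  variant <- unique(vapply(landmarks, function(s) s$variant, character(1)))
  variant <- if (length(variant) == 1L) variant else "mixed"

  area_mm2 <- reference_area_mm2 %||%
    (if (!is.null(measurements)) mean(measurements$area_mm2) else NULL)
  if (is.null(area_mm2)) {
    stop("provide measurements or reference_area_mm2 for the loaded area")
  }

  pipeline_log("[", variant, "] GPA on ", length(landmarks), " specimens")
  gpa <- gpa_align(landmarks, scale = config$gpa$scale,
                   tol = config$gpa$tol, max_iter = config$gpa$max_iter)
  wf <- build_wireframe(gpa$mean, edges, fixed_landmarks)
  scale_mm <- gpa$mean_centroid_size
  pipeline_log("[", variant, "] wireframe: ", nrow(wf$edges),
               " segments, scale ", signif(scale_mm, 4), " mm")

  mat <- material(config$material$youngs_modulus,
                  config$material$poissons_ratio,
                  config$material$density)
  sec <- cross_section(config$section_diameter)
  model <- build_frame(wf, mat, sec, scale_mm = scale_mm,
                       n_subdivisions = config$n_subdivisions)
  pipeline_log("[", variant, "] frame: ", nrow(model$nodes), " nodes, ",
               nrow(model$elements), " elements")

  speeds <- parse_speed_grid(config$speeds)
  ref_speed <- config$reference_speed
  solve_speeds <- sort(unique(c(speeds, ref_speed)))
  area_m2 <- area_mm2 * 1e-6
  fac <- if (identical(config$solver, "linear")) frame_factorization(model)

  defs <- vapply(solve_speeds, function(v) {
    case <- wind_load_case(v, config$air_density)
    loads <- distribute_pressure(model, case, area_m2, config$scheme)
    def <- if (identical(config$solver, "nonlinear") && v > 0) {
      solve_nonlinear(model, loads, n_steps = config$nonlinear$n_steps,
                      tol = config$nonlinear$tol)
    } else {
      solve_linear(model, loads, factorization = fac)
    }
    def$max_deformation
  }, numeric(1))
  pipeline_log("[", variant, "] solved ", length(solve_speeds), " speeds (",
               config$solver, ")")

  on_grid <- solve_speeds %in% speeds
  curve <- data.frame(variant = variant,
                      speed_mps = solve_speeds[on_grid],
                      max_deformation_mm = defs[on_grid] * 1000)
  structure(curve,
            class = c("deformation_curve", "data.frame"),
            reference_speed = ref_speed,
            reference_deformation_mm =
              defs[match(ref_speed, solve_speeds)] * 1000,
            meta = list(variant = variant,
                        n_specimens = length(landmarks),
                        scale_mm = scale_mm,
                        reference_area_mm2 = area_mm2,
                        n_nodes = nrow(model$nodes),
                        n_elements = nrow(model$elements),
                        solver = config$solver,
                        scheme = config$scheme))
}

#' Integer percentage shares of a deformation triple
#'
#' Each value's share of the sum across the groups, rounded to the nearest
#' integer percent — the share-of-sum convention under which the reported
#' deformation triple maps onto its printed percentages.
#'
#' @param deformations numeric vector (any common unit).
#' @return integer percentages (sum 100 +/- rounding).
#' @export
deformation_shares <- function(deformations) {
  if (any(deformations < 0)) stop("deformations must be nonnegative")
  total <- sum(deformations)
  if (total == 0) return(rep(NA_integer_, length(deformations)))
  as.integer(round(100 * deformations / total))
}

#' Compare the three variant groups at the reference speed
#'
#' @param curves list of three `deformation_curve`s on a common speed grid.
#' @return a `variant_comparison`: data frame `variant`,
#'   `max_deformation_mm` (at the reference speed), `share_pct`, `rank`
#'   (1 = largest deformation), with attributes `reference_speed` and `tie`.
#' @export
compare_variants <- function(curves) {
  if (length(curves) != 3L) stop("expected exactly three variant curves")
  grids <- lapply(curves, function(c) c$speed_mps)
  if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1)))) {
    stop("variant curves are on mismatched speed grids")
  }
  ref_speeds <- vapply(curves, attr, numeric(1), "reference_speed")
  if (length(unique(ref_speeds)) != 1L) {
    stop("variant curves have different reference speeds")
  }
  d <- vapply(curves, attr, numeric(1), "reference_deformation_mm")
  variant <- vapply(curves, function(c) c$variant[1], character(1))
  shares <- deformation_shares(d)
  rank <- match(seq_along(d), order(d, decreasing = TRUE))
  out <- data.frame(variant = variant, max_deformation_mm = d,
                    share_pct = shares, rank = rank)
  structure(out[order(out$rank), ],
            class = c("variant_comparison", "data.frame"),
            reference_speed = ref_speeds[1],
            tie = anyDuplicated(d) > 0)
}

#' Write sweep results, comparison, manifest and figure
#'
#' @param comparison a `variant_comparison`.
#' @param curves the list of `deformation_curve`s behind it.
#' @param out_dir output directory (created if missing).
#' @param config the configuration used (recorded in the manifest together
#'   with package/R versions and a hash of the configuration).
#' @param seed the seed used for data generation, recorded in the manifest.
#' @return invisibly, the named vector of files written.
#' @export
report_sweep <- function(comparison, curves, out_dir,
                         config = default_config(), seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  curves_df <- do.call(rbind, lapply(curves, as.data.frame))
  curves_path <- file.path(out_dir, "deformation_curves.csv")
  write.csv(curves_df, curves_path, row.names = FALSE, quote = FALSE)

  comp_path <- file.path(out_dir, "variant_comparison.csv")
  write.csv(as.data.frame(comparison), comp_path, row.names = FALSE,
            quote = FALSE)

  cfg_yaml <- yaml::as.yaml(config)
  tmp <- tempfile(fileext = ".yaml")
  writeLines(cfg_yaml, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "wingfem",
    package_version = as.character(packageVersion("wingfem")),
    r_version = R.version.string,
    seed = seed,
    config_md5 = cfg_hash,
    air_density = config$air_density,
    youngs_modulus = config$material$youngs_modulus,
    poissons_ratio = config$material$poissons_ratio,
    material_density = config$material$density,
    section_diameter = config$section_diameter,
    scheme = config$scheme,
    reference_speed = config$reference_speed,
    config = config)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  fig_path <- file.path(out_dir, "deformation_vs_speed.pdf")
  p <- plot_deformation_curves(curves)
  ggplot2::ggsave(fig_path, p, width = 6, height = 4)

  invisible(c(curves = curves_path, comparison = comp_path,
              manifest = manifest_path, figure = fig_path))
}

#' Deformation-versus-speed figure
#'
#' @param curves list of `deformation_curve`s.
#' @return a ggplot object: max wing deformation (mm) against wind speed
#'   (m/s), one line per variant.
#' @export
plot_deformation_curves <- function(curves) {
  df <- do.call(rbind, lapply(curves, as.data.frame))
  ggplot2::ggplot(df, ggplot2::aes(x = speed_mps,
                                   y = max_deformation_mm,
                                   colour = variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "wind speed (m/s)", y = "max wing deformation (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Run the full three-variant study
#'
#' Generates the synthetic study groups from their default specifications,
#' runs the per-variant pipeline and the cross-variant comparison, and
#' summarizes wing geometry.
#'
#' @param seed top-level seed driving every random draw.
#' @param config configuration list.
#' @param specs variant specifications; default [default_variant_specs()].
#' @return list with `curves`, `comparison`, `measurements` (all groups
#'   pooled) and `aspect_ratio` (per-variant mean AR summary).
#' @export
run_study <- function(seed = 1L, config = default_config(),
                      specs = default_variant_specs(seed)) {
  landmarks <- lapply(specs, generate_landmarks)
  measurements <- lapply(specs, generate_measurements)
  curves <- Map(function(lm, ms) run_variant(lm, config, measurements = ms),
                landmarks, measurements)
  comparison <- compare_variants(unname(curves))
  meas_all <- do.call(rbind, c(measurements, make.row.names = FALSE))
  ar <- ar_summary(meas_all, convention = config$ar_convention)
  list(curves = curves, comparison = comparison,
       measurements = meas_all, aspect_ratio = ar)
}

#' Per-variant aspect-ratio summary
#'
#' @param measurements pooled measurement data frame.
#' @param convention passed to [aspect_ratio()].
#' @return data frame `variant`, `n`, `mean_ar`, `mean_ar_rounded`.
#' @export
ar_summary <- function(measurements,
                       convention = "single_wing_length") {
  ar <- aspect_ratio(measurements, convention)
  agg <- aggregate(ar, by = list(variant = measurements$variant), FUN = mean)
  data.frame(variant = agg$variant,
             n = as.vector(table(measurements$variant)[agg$variant]),
             mean_ar = agg$x,
             mean_ar_rounded = round(agg$x))
}
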