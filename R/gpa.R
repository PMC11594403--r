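#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the standard size measure of geometric morphometrics.
#'
#' @param coords a k x 2 numeric matrix.
#' @return a nonnegative scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
}

# Optimal rotation (no reflection unless allowed) taking X onto C,
# both centered. Returns the 2x2 rotation matrix R minimizing ||X R - C||.
optimal_rotation <- function(X, C, allow_reflection = FALSE) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Removes translation, size and orientation differences among configurations
#' and estimates their consensus (mean) shape. Each specimen is centered,
#' scaled to unit centroid size (full Procrustes superimposition, the default
#' of the standard morphometrics tools; set `scale = FALSE` for partial
#' Procrustes, which keeps original centroid sizes), and rotated to minimize
#' its summed squared distance from the iteratively re-estimated consensus.
#' Reflections are never admitted in the optimal rotation: wings are chiral,
#' and left wings must be reflected before alignment.
#'
#' @param specimens a list of [landmark_set()] objects with identical landmark
#'   counts (at least two specimens).
#' @param scale scale specimens to unit centroid size (full GPA).
#' @param tol convergence tolerance on the Procrustes distance between
#'   successive consensus estimates.
#' @param max_iter iteration cap.
#' @return a list with elements
#'   \describe{
#'     \item{aligned}{list of `landmark_set`s with dimensionless aligned
#'       coordinates,}
#'     \item{mean}{a `mean_shape`: consensus coordinates (centroid at the
#'       origin, unit centroid size), `variant`, `n_specimens` and
#'       `mean_procrustes_distance`,}
#'     \item{mean_centroid_size}{grand mean centroid size of the raw inputs
#'       (mm for digitized data) — the factor that restores physical scale,}
#'     \item{iterations, converged, ss_history}{iteration diagnostics;
#'       `ss_history` is the summed squared Procrustes residual after each
#'       rotation pass.}
#'   }
#' @export
gpa_align <- function(specimens, scale = TRUE, tol = 1e-10, max_iter = 100L) {
  if (length(specimens) < 2L) stop("GPA needs at least 2 specimens")
  k <- nrow(specimens[[1]]$coords)
  counts <- vapply(specimens, function(s) nrow(s$coords), integer(1))
  if (any(counts != k)) stop("specimens have mismatched landmark counts")

  sizes <- vapply(specimens, function(s) centroid_size(s$coords), numeric(1))
  if (any(sizes <= 0)) {
    stop("degenerate specimen (zero centroid size): ",
         specimens[[which(sizes <= 0)[1]]]$specimen_id)
  }

  X <- lapply(specimens, function(s) {
    co <- sweep(s$coords, 2, colMeans(s$coords))
    if (scale) co / centroid_size(co) else co
  })

  consensus <- X[[1]] / centroid_size(X[[1]])
  iter <- 0L
  converged <- FALSE
  ss_history <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    X <- lapply(X, function(co) co %*% optimal_rotation(co, consensus))
    ss_history[iter] <- sum(vapply(X, function(co) sum((co - consensus)^2),
                                   numeric(1)))
    new_consensus <- Reduce(`+`, X) / length(X)
    new_consensus <- sweep(new_consensus, 2, colMeans(new_consensus))
    new_consensus <- new_consensus / centroid_size(new_consensus)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  mpd <- mean(vapply(X, function(co) sqrt(sum((co - consensus)^2)),
                     numeric(1)))
  variants <- unique(vapply(specimens, function(s) s$variant, character(1)))
  variant <- if (length(variants) == 1L) variants else "mixed"

  aligned <- Map(function(s, co) {
    s$coords <- co
    dimnames(s$coords) <- list(NULL, c("x", "y"))
    s
  }, specimens, X)

  mean_shape <- structure(
    list(variant = variant,
         coords = consensus,
         n_specimens = length(specimens),
         mean_procrustes_distance = mpd),
    class = "mean_shape")

  list(aligned = aligned,
       mean = mean_shape,
       mean_centroid_size = mean(sizes),
       iterations = iter,
       converged = converged,
       ss_history = ss_history)
}

#' @export
print.mean_shape <- function(x, ...) {
  cat("<mean_shape> ", x$variant, ": ", nrow(x$coords),
      " landmarks from ", x$n_specimens, " specimens, mean Procrustes d = ",
      signif(x$mean_procrustes_distance, 4), "\n", sep = "")
  invisible(x)
}

#' Join a mean shape into a vein wireframe
#'
#' Attaches vein-segment connectivity and the base (fixed-support) landmarks
#' to a consensus shape, validating the topology: no self-edges, no duplicate
#' edges, every landmark reachable from every other.
#'
#' @param mean a `mean_shape` from [gpa_align()].
#' @param edges an m x 2 matrix of 1-based landmark index pairs; defaults to
#'   the shipped template connectivity.
#' @param fixed_landmarks nonempty integer vector of base landmark indices;
#'   defaults to the template's humeral/axillary base.
#' @return an object of class `vein_wireframe`.
#' @export
build_wireframe <- function(mean, edges = wing_template_edges(),
                            fixed_landmarks = wing_template_base()) {
  stopifnot(inherits(mean, "mean_shape"))
  k <- nrow(mean$coords)
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (any(edges < 1L | edges > k)) stop("edge index outside 1..", k)
  if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < k || !igraph::is_connected(g)) {
    stop("edge graph must connect all ", k, " landmarks")
  }
  fixed_landmarks <- as.integer(fixed_landmarks)
  if (length(fixed_landmarks) == 0L) stop("fixed_landmarks must be nonempty")
  if (any(fixed_landmarks < 1L | fixed_landmarks > k)) {
    stop("fixed landmark index outside 1..", k)
  }
  structure(list(shape = mean, edges = edges,
                 fixed_landmarks = sort(unique(fixed_landmarks))),
            class = "vein_wireframe")
}

#' @export
print.vein_wireframe <- function(x, ...) {
  cat("<vein_wireframe> ", nrow(x$shape$coords), " landmarks, ",
      nrow(x$edges), " vein segments, base at {",
      paste(x$fixed_landmarks, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Export aligned shapes as a long-format table
#'
#' @param aligned list of aligned [landmark_set()]s (from [gpa_align()]).
#' @return data frame with columns `specimen_id`, `variant`, `landmark`, `x`,
#'   `y`.
#' @export
aligned_to_table <- function(aligned) {
  do.call(rbind, lapply(aligned, function(s) {
    data.frame(specimen_id = s$specimen_id, variant = s$variant,
               landmark = seq_len(nrow(s$coords)),
               x = s$coords[, 1], y = s$coords[, 2])
  }))
}
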