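#' @title Space-frame finite element core
#' @description Internal machinery: 3D two-node Euler-Bernoulli frame
#'   elements (axial + biaxial bending + torsion, cubic Hermite transverse
#'   behavior), assembled into a sparse global stiffness operator with 6 DOF
#'   per node (ux, uy, uz, rx, ry, rz). Shear deformation is neglected: vein
#'   slenderness (segment lengths of hundreds of microns to millimeters
#'   against a 45 micron section) makes it irrelevant.
#' @name fem-core
#' @keywords internal
NULL

# Natural-DOF stiffness: d7 = (axial elongation, twist, theta_y_a, theta_y_b,
# theta_z_a, theta_z_b), all chord-relative. 7th row unused (kept 6x6).
natural_stiffness <- function(E, G, A, Iy, Iz, J, L) {
  k <- matrix(0, 6, 6)
  k[1, 1] <- E * A / L
  k[2, 2] <- G * J / L
  k[3:4, 3:4] <- (E * Iy / L) * matrix(c(4, 2, 2, 4), 2)
  k[5:6, 5:6] <- (E * Iz / L) * matrix(c(4, 2, 2, 4), 2)
  k
}

# B maps the 12 local nodal DOFs (ua, ra, ub, rb; components in the element
# frame) to the 6 natural deformations; evaluated on the undeformed chord of
# length L. Its null space is exactly the 6 rigid-body motions.
natural_B <- function(L) {
  B <- matrix(0, 6, 12)
  B[1, c(1, 7)] <- c(-1, 1)                      # elongation
  B[2, c(4, 10)] <- c(-1, 1)                     # twist
  B[3, c(3, 5, 9)] <- c(-1 / L, 1, 1 / L)        # theta_y at a
  B[4, c(3, 9, 11)] <- c(-1 / L, 1 / L, 1)       # theta_y at b
  B[5, c(2, 6, 8)] <- c(1 / L, 1, -1 / L)        # theta_z at a
  B[6, c(2, 8, 12)] <- c(1 / L, -1 / L, 1)       # theta_z at b
  B
}

# Orthonormal element triad. Rows: local x (along the element), local y,
# local z. Local z is global z projected orthogonal to the axis (the wing is
# initially planar, so local z stays the out-of-plane direction); for
# elements parallel to global z the fallback reference is global y.
element_triad <- function(p1, p2) {
  ex <- p2 - p1
  L <- sqrt(sum(ex^2))
  if (L == 0) stop("zero-length element")
  ex <- ex / L
  ezp <- c(0, 0, 1) - sum(c(0, 0, 1) * ex) * ex
  if (sqrt(sum(ezp^2)) < 1e-8) {
    ezp <- c(0, 1, 0) - sum(c(0, 1, 0) * ex) * ex
  }
  ez <- ezp / sqrt(sum(ezp^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])   # ez x ex
  rbind(ex, ey, ez, deparse.level = 0)
}

# 12x12 element stiffness in global coordinates.
element_stiffness_global <- function(p1, p2, mat, sec) {
  L <- sqrt(sum((p2 - p1)^2))
  B <- natural_B(L)
  k7 <- natural_stiffness(mat$youngs_modulus, mat$shear_modulus,
                          sec$area, sec$Iy, sec$Iz, sec$J, L)
  k_local <- t(B) %*% k7 %*% B
  lam <- element_triad(p1, p2)
  Tm <- matrix(0, 12, 12)
  for (b in 0:3) Tm[b * 3 + 1:3, b * 3 + 1:3] <- lam
  t(Tm) %*% k_local %*% Tm
}

#' Assemble the global stiffness operator of a frame model
#'
#' Builds the sparse symmetric stiffness matrix over all `6 n_nodes` degrees
#' of freedom. Boundary conditions are applied downstream by row/column
#' elimination of the clamped DOFs ([solve_linear()]), which keeps the
#' unconstrained operator available for rigid-body diagnostics.
#'
#' @param model a `frame_model`.
#' @return a `dsCMatrix` of size `6 n_nodes`.
#' @export
assemble_stiffness <- function(model) {
  stopifnot(inherits(model, "frame_model"))
  ne <- nrow(model$elements)
  ii <- jj <- xx <- vector("list", ne)
  for (e in seq_len(ne)) {
    a <- model$elements$i[e]
    b <- model$elements$j[e]
    ke <- element_stiffness_global(model$nodes[a, ], model$nodes[b, ],
                                   model$material,
                                   element_section(model, e))
    dofs <- c((a - 1L) * 6L + 1:6, (b - 1L) * 6L + 1:6)
    ii[[e]] <- rep(dofs, times = 12)
    jj[[e]] <- rep(dofs, each = 12)
    xx[[e]] <- as.vector(ke)
  }
  ndof <- 6L * nrow(model$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

new_deformation_field <- function(model, u) {
  n <- nrow(model$nodes)
  um <- matrix(u, n, 6, byrow = TRUE)
  displacements <- um[, 1:3, drop = FALSE]
  colnames(displacements) <- c("ux", "uy", "uz")
  rotations <- um[, 4:6, drop = FALSE]
  colnames(rotations) <- c("rx", "ry", "rz")
  magnitude <- sqrt(rowSums(displacements^2))
  structure(list(displacements = displacements,
                 rotations = rotations,
                 magnitude = magnitude,
                 max_deformation = max(abs(displacements[, 3])),
                 max_deformation_node = which.max(abs(displacements[, 3]))),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("<deformation_field> ", nrow(x$displacements), " nodes, max |uz| = ",
      signif(x$max_deformation, 5), " m (node ",
      x$max_deformation_node, ")\n", sep = "")
  invisible(x)
}

#' Linear static solution of a frame model
#'
#' Solves `K u = f` on the free degrees of freedom after eliminating the
#' clamped DOFs, using a sparse Cholesky factorization followed by one step
#' of iterative refinement (the 45-micron-section vein systems mix axial and
#' bending stiffnesses that differ by several orders of magnitude; the
#' refinement step keeps residuals at machine level).
#'
#' @param model a `frame_model`.
#' @param loads a `load_vector` (or n x 6 matrix of nodal forces/moments).
#' @param factorization optional cached factorization from
#'   [frame_factorization()]; reused across load cases in sweeps.
#' @return a `deformation_field`: per-node displacement (m) and rotation
#'   (rad) vectors, per-node displacement magnitude, `max_deformation` (the
#'   maximum absolute nodal z-displacement, m) and its node; reactions at
#'   supported DOF in attribute `reactions`.
#' @export
solve_linear <- function(model, loads, factorization = NULL) {
  stopifnot(inherits(model, "frame_model"))
  f <- as.vector(t(unclass(loads)))
  if (length(f) != 6L * nrow(model$nodes)) {
    stop("loads not conformable with model (need n_nodes x 6)")
  }
  if (any(!is.finite(f))) stop("non-finite loads")
  fac <- factorization %||% frame_factorization(model)
  u <- numeric(length(f))
  fr <- f[fac$free]
  uf <- Matrix::solve(fac$chol, fr)
  r <- fr - as.vector(fac$Kff %*% uf)
  uf <- as.vector(uf + Matrix::solve(fac$chol, r))
  u[fac$free] <- uf
  out <- new_deformation_field(model, u)
  reactions <- as.vector(fac$K %*% u - f)[fac$fixed]
  attr(out, "reactions") <- reactions
  out
}

#' Factorize the constrained stiffness of a frame model
#'
#' @param model a `frame_model`.
#' @return a list with the full operator `K`, free/fixed DOF indices, the
#'   reduced block `Kff` and its sparse Cholesky factorization — pass to
#'   [solve_linear()] to amortize factorization across a speed sweep.
#' @export
frame_factorization <- function(model) {
  K <- assemble_stiffness(model)
  fixed <- fixed_dof_indices(model)
  free <- setdiff(seq_len(nrow(K)), fixed)
  Kff <- K[free, free, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                 error = function(e) {
                   stop("stiffness is singular after applying supports ",
                        "(insufficient constraints): ", conditionMessage(e))
                 })
  list(K = K, Kff = Kff, chol = ch, free = free, fixed = fixed)
}

#' Mesh-refinement convergence study
#'
#' Re-solves the same physical problem at increasing beam-subdivision levels
#' and reports the maximum deformation per level with its relative change —
#' the discretization-verification step of the modeling workflow: the model
#' counts as converged when further refinement no longer changes the result
#' by more than `threshold`.
#'
#' @param builder function(level) returning a `frame_model` at that
#'   subdivision level.
#' @param loader function(model) returning the `load_vector` for that model.
#' @param levels integer vector of subdivision levels (>= 2 values).
#' @param threshold relative-change threshold declaring convergence
#'   (default 1%).
#' @return data frame with `level`, `n_nodes`, `n_elements`,
#'   `max_deformation` (m), `rel_change`, `converged`.
#' @export
convergence_study <- function(builder, loader, levels = c(1, 2, 4, 8),
                              threshold = 0.01) {
  if (length(levels) < 2L) stop("need at least 2 subdivision levels")
  rows <- lapply(levels, function(lv) {
    model <- builder(lv)
    def <- solve_linear(model, loader(model))
    data.frame(level = lv, n_nodes = nrow(model$nodes),
               n_elements = nrow(model$elements),
               max_deformation = def$max_deformation)
  })
  out <- do.call(rbind, rows)
  prev <- out$max_deformation[-nrow(out)]
  change <- abs(diff(out$max_deformation)) /
    ifelse(prev == 0, 1, abs(prev))
  out$rel_change <- c(NA, change)
  out$converged <- c(FALSE, change < threshold)
  out
}

#' Export a deformation field as CSV
#'
#' @param model the `frame_model` the field belongs to.
#' @param deformation a `deformation_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_deformation <- function(model, deformation, path) {
  df <- data.frame(node = seq_len(nrow(model$nodes)), model$nodes,
                   deformation$displacements,
                   magnitude = deformation$magnitude)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
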