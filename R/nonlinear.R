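#' @title Geometrically nonlinear frame solution
#' @description Corotational treatment: each element's rigid motion is
#'   removed by a chord-following frame (minimal rotation of the initial
#'   axis onto the current axis) and nodal rotations are tracked as rotation
#'   matrices updated multiplicatively, so the natural deformations (axial
#'   stretch, twist, chord-relative end rotations) stay small while global
#'   rotations may be moderate. Equilibrium is found by Newton-Raphson with
#'   incremental load stepping; the tangent uses the material stiffness plus
#'   a string-type geometric (stress-stiffening) term, which affects only
#'   the iteration path, not the converged equilibrium.
#' @name nonlinear-core
#' @keywords internal
NULL

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Rodrigues' rotation: exp of the skew of v.
expm_so3 <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3) + skew3(v))
  S <- skew3(v / th)
  diag(3) + sin(th) * S + (1 - cos(th)) * (S %*% S)
}

# Rotation vector of R (inverse of expm_so3), stable near identity.
log_so3 <- function(R) {
  c_th <- (sum(diag(R)) - 1) / 2
  c_th <- min(1, max(-1, c_th))
  th <- acos(c_th)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  if (th < 1e-8) return(v)
  v * th / sin(th)
}

# Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ab <- sum(a * b)
  if (c_ab < -1 + 1e-12) stop("element reversed direction during iteration")
  S <- skew3(v)
  diag(3) + S + (S %*% S) / (1 + c_ab)
}

# String-type geometric stiffness (transverse translational coupling with
# the axial force); enters the tangent only.
geometric_stiffness_local <- function(N, L) {
  kg <- matrix(0, 12, 12)
  for (d in 2:3) {
    idx <- c(d, d + 6L)
    kg[idx, idx] <- kg[idx, idx] + (N / L) * matrix(c(1, -1, -1, 1), 2)
  }
  kg
}

# Internal force vector and tangent triplets for the current state.
corotational_state <- function(model, u_trans, Rlist, tangent = TRUE) {
  n <- nrow(model$nodes)
  f_int <- numeric(6L * n)
  ii <- jj <- xx <- if (tangent) vector("list", nrow(model$elements))
  mat <- model$material
  for (e in seq_len(nrow(model$elements))) {
    sec <- element_section(model, e)
    a <- model$elements$i[e]
    b <- model$elements$j[e]
    p1 <- model$nodes[a, ]
    p2 <- model$nodes[b, ]
    l0 <- sqrt(sum((p2 - p1)^2))
    E0 <- t(element_triad(p1, p2))
    q1 <- p1 + u_trans[a, ]
    q2 <- p2 + u_trans[b, ]
    axis <- q2 - q1
    ln <- sqrt(sum(axis^2))
    if (ln == 0) stop("element collapsed to zero length")
    axis <- axis / ln
    # cancellation-free elongation: ln - l0 = (ln^2 - l0^2) / (ln + l0)
    dvec <- u_trans[b, ] - u_trans[a, ]
    elong <- (2 * sum((p2 - p1) * dvec) + sum(dvec^2)) / (ln + l0)
    Er <- rotation_between(E0[, 1], axis) %*% E0
    th_a <- log_so3(t(Er) %*% Rlist[[a]] %*% E0)
    th_b <- log_so3(t(Er) %*% Rlist[[b]] %*% E0)
    d6 <- c(elong,
            th_b[1] - th_a[1],
            th_a[2], th_b[2],
            th_a[3], th_b[3])
    k7 <- natural_stiffness(mat$youngs_modulus, mat$shear_modulus,
                            sec$area, sec$Iy, sec$Iz, sec$J, l0)
    f6 <- k7 %*% d6
    Bn <- natural_B(ln)
    f12 <- as.vector(t(Bn) %*% f6)
    Tm <- matrix(0, 12, 12)
    for (blk in 0:3) Tm[blk * 3 + 1:3, blk * 3 + 1:3] <- t(Er)
    f12g <- as.vector(t(Tm) %*% f12)
    dofs <- c((a - 1L) * 6L + 1:6, (b - 1L) * 6L + 1:6)
    f_int[dofs] <- f_int[dofs] + f12g
    if (tangent) {
      N_ax <- f6[1]
      ke <- t(Bn) %*% k7 %*% Bn + geometric_stiffness_local(N_ax, ln)
      keg <- t(Tm) %*% ke %*% Tm
      ii[[e]] <- rep(dofs, times = 12)
      jj[[e]] <- rep(dofs, each = 12)
      xx[[e]] <- as.vector(keg)
    }
  }
  out <- list(f_int = f_int)
  if (tangent) {
    ndof <- 6L * n
    K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(ndof, ndof))
    out$K_t <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  }
  out
}

#' Geometrically nonlinear static solution
#'
#' Incremental-iterative solution of the frame under the given loads: the
#' load is applied in `n_steps` equal increments and each increment is
#' equilibrated by Newton-Raphson on the corotational internal force, so
#' stress stiffening and follower-free finite rotation effects are captured.
#' Converged when the free-DOF residual norm drops below `tol` times the
#' applied-load norm. As the load tends to zero the solution tends to the
#' linear one.
#'
#' @param model a `frame_model`.
#' @param loads a `load_vector` (or n x 6 matrix).
#' @param n_steps number of load increments (>= 1).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap per increment.
#' @return a `deformation_field` (displacements m, rotations rad) with
#'   attributes `iterations` (total Newton iterations) and `residual` (final
#'   relative residual).
#' @export
solve_nonlinear <- function(model, loads, n_steps = 5L, tol = 1e-8,
                            max_iter = 50L) {
  stopifnot(inherits(model, "frame_model"))
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  f_ext <- as.vector(t(unclass(loads)))
  if (any(!is.finite(f_ext))) stop("non-finite loads")
  n <- nrow(model$nodes)
  fixed <- fixed_dof_indices(model)
  free <- setdiff(seq_len(6L * n), fixed)
  u_trans <- matrix(0, n, 3)
  Rlist <- rep(list(diag(3)), n)
  f_norm <- sqrt(sum(f_ext[free]^2))
  total_iter <- 0L
  rel_res <- 0

  for (s in seq_len(n_steps)) {
    lambda <- s / n_steps
    ref <- max(lambda * f_norm, .Machine$double.xmin)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      st <- corotational_state(model, u_trans, Rlist, tangent = TRUE)
      r <- lambda * f_ext - st$f_int
      rel_res <- sqrt(sum(r[free]^2)) / ref
      if (rel_res < tol) {
        converged <- TRUE
        break
      }
      total_iter <- total_iter + 1L
      Ktff <- st$K_t[free, free, drop = FALSE]
      du <- numeric(6L * n)
      du[free] <- as.vector(Matrix::solve(Ktff, r[free]))
      dm <- matrix(du, n, 6, byrow = TRUE)
      u_trans <- u_trans + dm[, 1:3, drop = FALSE]
      for (i in seq_len(n)) {
        if (any(dm[i, 4:6] != 0)) {
          Rlist[[i]] <- expm_so3(dm[i, 4:6]) %*% Rlist[[i]]
        }
      }
    }
    if (!converged) {
      stop(sprintf(paste0("nonlinear solve did not converge at load step ",
                          "%d/%d (relative residual %.3e after %d ",
                          "iterations)"), s, n_steps, rel_res, max_iter))
    }
  }

  u <- numeric(6L * n)
  um <- cbind(u_trans, t(vapply(Rlist, log_so3, numeric(3))))
  u <- as.vector(t(um))
  out <- new_deformation_field(model, u)
  attr(out, "iterations") <- total_iter
  attr(out, "residual") <- rel_res
  out
}
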