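# Finite-element operators on the structured grid.
#
# Bilinear quadrilateral (Q1) elements on the uniform nx x ny point grid;
# homogeneous Neumann boundary conditions are natural (nothing to impose).
# The mass matrix is lumped (row sums), which together with nodal evaluation
# of the ionic terms makes the ODE part a per-node collocation.

#' Assemble lumped mass and stiffness operators
#'
#' The stiffness matrix discretizes `-div(sigma(x) D grad(u))` with the
#' anisotropic tensor of [conductivity_model()]; element matrices are computed
#' with 2x2 Gauss quadrature (exact for Q1 gradients) and a per-element
#' constant tensor taken as the average of the nodal modulation/fiber fields
#' over the 4 corners.
#'
#' @param grid a `grid2d`
#' @param cond a `conductivity_model`
#' @return list with `mass` (length-N positive diagonal vector, sums to the
#'   domain area) and `stiffness` (N x N sparse `dgCMatrix`, symmetric, with
#'   the constant vector in its null space)
#' @export
assemble_operators <- function(grid, cond) {
  et <- element_tensor(grid, cond)
  hx <- grid$hx; hy <- grid$hy

  # Q1 shape-function gradients at the 2x2 Gauss points of the unit square.
  gp <- (1 + c(-1, 1) / sqrt(3)) / 2
  Cxx <- matrix(0, 4, 4); Cxy <- matrix(0, 4, 4); Cyy <- matrix(0, 4, 4)
  for (xi in gp) for (eta in gp) {
    dphi_dx <- c(-(1 - eta), (1 - eta), -eta, eta) / hx
    dphi_dy <- c(-(1 - xi), -xi, (1 - xi), xi) / hy
    wq <- 0.25 * hx * hy
    Cxx <- Cxx + wq * tcrossprod(dphi_dx)
    Cyy <- Cyy + wq * tcrossprod(dphi_dy)
    Cxy <- Cxy + wq * (outer(dphi_dx, dphi_dy) + outer(dphi_dy, dphi_dx))
  }

  corners <- et$corners
  nE <- nrow(corners)
  rows <- integer(16L * nE); cols <- integer(16L * nE); vals <- numeric(16L * nE)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * nE + seq_len(nE)
    rows[idx] <- corners[, a]
    cols[idx] <- corners[, b]
    vals[idx] <- Cxx[a, b] * et$dxx + Cxy[a, b] * et$dxy + Cyy[a, b] * et$dyy
    k <- k + 1L
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(grid$N, grid$N))
  A <- Matrix::drop0(Matrix::forceSymmetric((A + Matrix::t(A)) / 2))

  mass <- numeric(grid$N)
  cell <- hx * hy / 4
  for (a in 1:4) {
    tab <- tabulate(corners[, a], nbins = grid$N)
    mass <- mass + cell * tab
  }
  list(mass = mass, stiffness = A)
}
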