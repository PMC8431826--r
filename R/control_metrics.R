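#' Simulate the noise-free linear discrete-time dynamics
#'
#' Iterates `x(t+1) = A x(t) + B u(t)` from `x0` for as many steps as there
#' are input vectors.
#'
#' @param system a [control_system()].
#' @param x0 initial N-vector state.
#' @param inputs T x m matrix of control inputs (row t is `u(t-1)`), or a
#'   vector when m = 1.
#' @return An object of class `"trajectory"`: list with `states`
#'   ((T+1) x N matrix, row 1 = `x0`) and `inputs`.
#' @export
#' @examples
#' sys <- control_system(matrix(c(0, 1, 1, 0), 2), 1)
#' tr <- evolve_state(sys, c(1, 0), matrix(0, 2, 1))
#' tr$states    # swap dynamics: (1,0) -> (0,1) -> (1,0)
evolve_state <- function(system, x0, inputs) {
  stopifnot(inherits(system, "control_system"))
  n <- nrow(system$A)
  m <- ncol(system$B)
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("`x0` has wrong dimension", call. = FALSE)
  if (is.null(dim(inputs))) {
    if (m != 1L) stop("`inputs` must be a T x m matrix", call. = FALSE)
    inputs <- matrix(as.numeric(inputs), ncol = 1L)
  }
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != m) {
    stop(sprintf("`inputs` has %d columns but the control set has %d nodes",
                 ncol(inputs), m), call. = FALSE)
  }
  T_ <- nrow(inputs)
  states <- matrix(NA_real_, T_ + 1L, n)
  states[1L, ] <- x0
  for (t in seq_len(T_)) {
    states[t + 1L, ] <- as.numeric(system$A %*% states[t, ] +
                                     system$B %*% inputs[t, ])
  }
  structure(list(states = states, inputs = inputs), class = "trajectory")
}

#' Finite-horizon controllability Gramian
#'
#' Computes `W = sum_{t=0}^{h-1} A^t B B' (A')^t`, a symmetric positive
#' semidefinite matrix whose rank certifies which directions of state space
#' are reachable from the control set within `horizon` steps.
#'
#' @param system a [control_system()].
#' @param horizon number of steps (default N, the Cayley-Hamilton
#'   saturation point beyond which the rank cannot grow).
#' @return N x N symmetric positive semidefinite matrix.
#' @export
controllability_gramian <- function(system, horizon = nrow(system$A)) {
  stopifnot(inherits(system, "control_system"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("`horizon` must be >= 1", call. = FALSE)
  M <- system$B
  W <- matrix(0, nrow(system$A), nrow(system$A))
  for (t in seq_len(horizon)) {
    W <- W + M %*% t(M)
    if (t < horizon) M <- system$A %*% M
  }
  (W + t(W)) / 2
}

#' Numerical controllability verdict
#'
#' The system is controllable iff the horizon-N Gramian has full numerical
#' rank.  Rank is the number of singular values above `tol`, which defaults
#' to `N * .Machine$double.eps * max(singular value)` (the usual matrix
#' rank convention).  For a symmetric system matrix with distinct
#' eigenvalues and a single control node k, the verdict coincides with the
#' PBH eigenvector test: controllable iff no eigenvector has a zero k-th
#' component.
#'
#' @param system a [control_system()].
#' @param tol positive rank tolerance; `NULL` for the default.
#' @return List with `controllable` (logical), `rank`, `n`, `tol`,
#'   `smallest_retained` (smallest singular value counted toward the rank)
#'   and `singular_values`.
#' @export
is_controllable <- function(system, tol = NULL) {
  stopifnot(inherits(system, "control_system"))
  n <- nrow(system$A)
  W <- controllability_gramian(system, horizon = n)
  sv <- svd(W, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- n * .Machine$double.eps * max(sv)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  rank <- sum(sv > tol)
  list(controllable = rank == n,
       rank = rank,
       n = n,
       tol = tol,
       smallest_retained = if (rank > 0) min(sv[sv > tol]) else NA_real_,
       singular_values = sv)
}

#' Per-node modal controllability
#'
#' From the eigendecomposition `A = V diag(lambda) V'` of the symmetric
#' stabilized system matrix, the modal controllability of node i is
#' \deqn{\phi_i = \sum_{j=1}^{N} (1 - \lambda_j^2) v_{ij}^2,}
#' a scaled summary of how well node i can control all N eigenmodes.
#' Nodes with high values can push the system toward hard-to-reach
#' (high-energy) activity configurations.  The value is invariant to
#' eigenvector sign flips and to the ordering of the eigenpairs; eigenpairs
#' are returned sorted by descending eigenvalue.
#'
#' Note that under mean-edge-weight stabilization the spectral radius may
#' exceed 1, making some factors `1 - lambda_j^2` negative; use
#' `stabilize(x, "spectral")` upstream if all factors are required to be
#' nonnegative.
#'
#' @param A symmetric N x N numeric matrix (typically the output of
#'   [stabilize()]).
#' @return An object of class `"modal_result"`: list with `eigenvalues`
#'   (descending), `eigenvectors` (orthonormal columns), `phi` (per-node
#'   values).
#' @export
#' @examples
#' modal_controllability(matrix(c(0, 0.5, 0.5, 0), 2))$phi   # (0.75, 0.75)
modal_controllability <- function(A) {
  if (!is_square_numeric(A)) stop("`A` must be square numeric", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8) {
    stop("`A` must be symmetric for modal controllability", call. = FALSE)
  }
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  phi <- as.numeric((e$vectors^2) %*% (1 - e$values^2))
  structure(list(eigenvalues = e$values, eigenvectors = e$vectors, phi = phi),
            class = "modal_result")
}

#' @export
print.modal_result <- function(x, ...) {
  cat(sprintf("<modal_result> %d modes | lambda in [%.4g, %.4g] | phi in [%.4g, %.4g]\n",
              length(x$eigenvalues), min(x$eigenvalues), max(x$eigenvalues),
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Per-node network metrics table
#'
#' Convenience summary pairing each region's weighted degree (strength on
#' the raw weights) with its modal controllability on the stabilized
#' matrix.
#'
#' @param conn a [connectome()].
#' @param mode stabilization mode passed to [stabilize()].
#' @return data.frame with columns `label`, `weighted_degree`, `phi`.
#' @export
node_metrics <- function(conn, mode = "mean-edge") {
  stopifnot(inherits(conn, "connectome"))
  phi <- modal_controllability(stabilize(conn, mode))$phi
  data.frame(label = conn$labels,
             weighted_degree = rowSums(conn$weights),
             phi = phi,
             stringsAsFactors = FALSE)
}

#' Write the per-node metrics table as headered TSV
#'
#' @param metrics output of [node_metrics()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_node_metrics <- function(metrics, path) {
  write_tsv_full(metrics, path)
}
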