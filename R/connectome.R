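#' Construct a connectome object
#'
#' A connectome holds a weighted, symmetric, zero-diagonal region-by-region
#' adjacency matrix (streamline density; unitless after volume
#' normalization), ordered region labels, optional region volumes, and the
#' index of the analysis target node (the stimulated-region analog).
#'
#' Weights must be finite and nonnegative.  Small numerical asymmetry (up
#' to `sym_tol`, default 1e-9) is removed by averaging `A` with its
#' transpose; larger asymmetry is an error.  Diagonal entries must be zero
#' to within 1e-12 and are stored as exact zeros.
#'
#' @param weights N x N numeric matrix of nonnegative edge weights.
#' @param labels character vector of N region identifiers; defaults to
#'   `"R001"..."RNNN"`.
#' @param volumes optional numeric vector of N strictly positive region
#'   volumes.
#' @param target target region, given as a label or a 1-based index
#'   (default 1).
#' @param sym_tol maximum tolerated asymmetry before erroring.
#' @return An object of class `"connectome"`: a list with elements
#'   `weights`, `labels`, `volumes`, `target_index`.
#' @seealso [load_connectome()], [stabilize()], [generate_connectome()]
#' @export
#' @examples
#' A <- matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3, 3)
#' conn <- connectome(A, labels = c("a", "b", "c"), target = "b")
#' conn$target_index
connectome <- function(weights, labels = NULL, volumes = NULL, target = 1L,
                       sym_tol = 1e-9) {
  if (!is_square_numeric(weights)) {
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (n < 2L) stop("a connectome needs at least 2 regions", call. = FALSE)
  if (any(!is.finite(weights))) {
    stop("`weights` contains non-finite entries", call. = FALSE)
  }
  if (any(weights < 0)) stop("`weights` contains negative entries", call. = FALSE)
  if (any(abs(diag(weights)) > 1e-12)) {
    stop("`weights` has nonzero diagonal entries beyond tolerance 1e-12",
         call. = FALSE)
  }
  weights <- check_symmetric(weights, sym_tol, "adjacency")
  diag(weights) <- 0
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` length does not match matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("region labels must be unique", call. = FALSE)
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != n) {
      stop("`volumes` length does not match matrix dimension", call. = FALSE)
    }
    if (any(!is.finite(volumes)) || any(volumes <= 0)) {
      stop("`volumes` must be strictly positive and finite", call. = FALSE)
    }
  }
  if (is.character(target)) {
    target_index <- match(target, labels)
    if (is.na(target_index)) {
      stop(sprintf("target label '%s' not found among region labels", target),
           call. = FALSE)
    }
  } else {
    target_index <- as.integer(target)
    if (is.na(target_index) || target_index < 1L || target_index > n) {
      stop("`target` index out of range", call. = FALSE)
    }
  }
  dimnames(weights) <- NULL
  structure(list(weights = weights, labels = labels, volumes = volumes,
                 target_index = target_index),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$labels)
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectome> %d regions, %d edges, target '%s'\n",
              n, sum(ut > 0), x$labels[x$target_index]))
  cat(sprintf("  density %.3f | mean nonzero weight %.4g | volumes: %s\n",
              mean(ut > 0), if (any(ut > 0)) mean(ut[ut > 0]) else NA,
              if (is.null(x$volumes)) "absent" else "present"))
  invisible(x)
}

# sniff the delimiter of a numeric grid file: tab if the first line has
# tabs, otherwise comma.
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a connectome from delimited text files
#'
#' Reads an N x N numeric adjacency grid (comma- or tab-delimited, no
#' header), one region label per line, and optionally one positive region
#' volume per line, and returns a validated [connectome()].  Asymmetry up
#' to 1e-9 (numeric noise) is symmetrized by averaging; anything larger is
#' an error, as is any nonzero diagonal, negative weight, or dimension
#' mismatch between the grid and the label file.
#'
#' @param adjacency_path path to the delimited N x N grid.
#' @param labels_path path to the label file (N lines).
#' @param volumes_path optional path to a volumes file (N lines).
#' @param target_label label of the analysis target node; defaults to the
#'   first label.
#' @return A `"connectome"` object.
#' @seealso [write_connectome()]
#' @export
load_connectome <- function(adjacency_path, labels_path, volumes_path = NULL,
                            target_label = NULL) {
  sep <- detect_sep(adjacency_path)
  grid <- utils::read.table(adjacency_path, sep = sep, header = FALSE,
                            colClasses = "numeric")
  A <- as.matrix(grid)
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) {
    stop(sprintf("adjacency grid is %d x %d: dimension mismatch (square matrix required)",
                 nrow(A), ncol(A)), call. = FALSE)
  }
  labels <- readLines(labels_path)
  labels <- labels[nzchar(labels)]
  if (length(labels) != nrow(A)) {
    stop(sprintf("label file has %d entries but adjacency is %d x %d: dimension mismatch",
                 length(labels), nrow(A), ncol(A)), call. = FALSE)
  }
  volumes <- NULL
  if (!is.null(volumes_path)) {
    volumes <- as.numeric(readLines(volumes_path))
    volumes <- volumes[!is.na(volumes)]
  }
  target <- if (is.null(target_label)) 1L else target_label
  connectome(A, labels = labels, volumes = volumes, target = target)
}

#' Write a connectome to delimited text files
#'
#' The adjacency grid is written at full precision (17 significant digits),
#' so `load_connectome(write_connectome(conn, ...))` round-trips
#' bit-identically.
#'
#' @param conn a `"connectome"` object.
#' @param adjacency_path output path for the grid.
#' @param labels_path optional output path for labels (one per line).
#' @param volumes_path optional output path for volumes.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @return Invisibly, `adjacency_path`.
#' @export
write_connectome <- function(conn, adjacency_path, labels_path = NULL,
                             volumes_path = NULL, sep = "\t") {
  stopifnot(inherits(conn, "connectome"))
  lines <- apply(conn$weights, 1L, function(r) paste(format_full(r), collapse = sep))
  writeLines(lines, adjacency_path)
  if (!is.null(labels_path)) writeLines(conn$labels, labels_path)
  if (!is.null(volumes_path) && !is.null(conn$volumes)) {
    writeLines(format_full(conn$volumes), volumes_path)
  }
  invisible(adjacency_path)
}

#' Volume-normalize a streamline count matrix
#'
#' Divides each pairwise streamline count by the sum of the two region
#' volumes: `out[i, j] = counts[i, j] / (volumes[i] + volumes[j])`.  The
#' diagonal stays zero and symmetry of `counts` is preserved.  Doubling all
#' volumes halves all weights (scale equivariance).
#'
#' @param counts N x N nonnegative matrix of streamline counts.
#' @param volumes numeric vector of N strictly positive region volumes.
#' @return N x N matrix of volume-normalized densities.
#' @export
#' @examples
#' normalize_by_volume(matrix(c(0, 10, 10, 0), 2), c(2, 3))
normalize_by_volume <- function(counts, volumes) {
  if (!is_square_numeric(counts)) {
    stop("`counts` must be a square numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and nonnegative", call. = FALSE)
  }
  volumes <- as.numeric(volumes)
  if (length(volumes) != nrow(counts)) {
    stop("`volumes` length does not match `counts` dimension", call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("`volumes` must be strictly positive (zero or negative volume)",
         call. = FALSE)
  }
  out <- counts / outer(volumes, volumes, "+")
  diag(out) <- 0
  out
}

#' Stabilize a system matrix for the linear dynamics model
#'
#' The discrete-time model `x(t+1) = A x(t) + B u(t)` is defined on a
#' rescaled adjacency matrix.  The primary mode divides every entry by the
#' mean edge weight, computed over the *nonzero* off-diagonal entries with
#' each undirected edge counted once, so the rescaled network has mean
#' nonzero edge weight exactly 1.  The alternative `"spectral"` mode
#' divides by `1 + max |eigenvalue|`, which guarantees spectral radius
#' strictly below 1 and keeps every modal factor `1 - lambda_j^2`
#' nonnegative.
#'
#' @param x a `"connectome"` or a symmetric zero-diagonal numeric matrix.
#' @param mode `"mean-edge"` (default) or `"spectral"`.
#' @return The stabilized N x N matrix.
#' @seealso [modal_controllability()], [control_system()]
#' @export
#' @examples
#' A <- matrix(c(0, 2, 2, 0), 2)
#' stabilize(A)                  # edges rescaled to mean 1
stabilize <- function(x, mode = c("mean-edge", "spectral")) {
  mode <- match.arg(mode)
  A <- if (inherits(x, "connectome")) x$weights else x
  if (!is_square_numeric(A)) stop("`x` must be square numeric", call. = FALSE)
  A <- check_symmetric(A, 1e-9, "adjacency")
  ut <- A[upper.tri(A)]
  nz <- ut[ut != 0]
  if (length(nz) == 0L) {
    stop("all-zero network: nothing to stabilize", call. = FALSE)
  }
  if (mode == "mean-edge") {
    A / mean(nz)
  } else {
    lam <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    A / (1 + lam)
  }
}

#' Build the control input matrix for a set of control nodes
#'
#' Column i of the returned N x m matrix is the canonical basis vector of
#' the i-th control node, in the order given.
#'
#' @param control_set integer vector of distinct 1-based node indices.
#' @param n number of nodes.
#' @return N x m numeric matrix.
#' @export
#' @examples
#' build_input_matrix(c(3, 1), 3)   # columns e_3, e_1
build_input_matrix <- function(control_set, n) {
  control_set <- as.integer(control_set)
  n <- as.integer(n)
  if (length(control_set) < 1L) stop("empty control set", call. = FALSE)
  if (anyDuplicated(control_set)) {
    stop("duplicate index in control set", call. = FALSE)
  }
  if (any(is.na(control_set)) || any(control_set < 1L) || any(control_set > n)) {
    stop("control-set index out of range", call. = FALSE)
  }
  B <- matrix(0, n, length(control_set))
  B[cbind(control_set, seq_along(control_set))] <- 1
  B
}

#' Assemble a linear control system
#'
#' Bundles a stabilized symmetric system matrix with a control set and its
#' input map `B = [e_k1 ... e_km]` for use with [evolve_state()],
#' [controllability_gramian()] and [is_controllable()].
#'
#' @param A stabilized N x N symmetric zero-diagonal matrix.
#' @param control_set integer vector of distinct 1-based control node
#'   indices.
#' @return An object of class `"control_system"` with elements `A`,
#'   `control_set`, `B`.
#' @export
control_system <- function(A, control_set) {
  if (!is_square_numeric(A)) stop("`A` must be square numeric", call. = FALSE)
  A <- check_symmetric(A, 1e-9, "system matrix")
  if (any(abs(diag(A)) > 1e-12)) {
    stop("system matrix must have zero diagonal", call. = FALSE)
  }
  B <- build_input_matrix(control_set, nrow(A))
  structure(list(A = A, control_set = as.integer(control_set), B = B),
            class = "control_system")
}

#' @export
print.control_system <- function(x, ...) {
  cat(sprintf("<control_system> %d nodes, control set {%s}\n",
              nrow(x$A), paste(x$control_set, collapse = ", ")))
  invisible(x)
}
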