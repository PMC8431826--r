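# Community structure, partition similarity, consensus, and boundary
# controllability ranking.

as_assignment <- function(p) {
  if (inherits(p, "partition")) p$assignment else as.integer(as.factor(p))
}

# relabel a membership vector so module ids are contiguous integers in
# order of first appearance -- makes partitions from different runs
# directly comparable with identical().
canonicalize_assignment <- function(m) {
  m <- as.integer(m)
  as.integer(match(m, unique(m)))
}

new_partition <- function(assignment, gamma, quality, seed) {
  structure(list(assignment = canonicalize_assignment(assignment),
                 gamma = gamma, quality = quality, seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, %d modules, gamma = %s, Q = %s\n",
              length(x$assignment), max(x$assignment),
              format(x$gamma), format(x$quality)))
  invisible(x)
}

#' Modularity quality of a partition
#'
#' Newman-Girvan modularity with a resolution parameter:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left( a_{ij} -
#'   \gamma \frac{k_i k_j}{2m} \right) \delta(m_i, m_j),}
#' where `m` is the total edge weight and `k` the node strengths.  The sum
#' runs over all ordered node pairs including `i = j` (the diagonal of the
#' adjacency is zero, but the null term still counts), matching the
#' convention of `igraph::modularity()`.
#'
#' @param adjacency symmetric nonnegative N x N matrix.
#' @param assignment module membership vector (any labels; a
#'   `"partition"` is also accepted).
#' @param gamma resolution parameter (default 1).
#' @return Scalar Q.
#' @export
modularity_q <- function(adjacency, assignment, gamma = 1) {
  A <- if (inherits(adjacency, "connectome")) adjacency$weights else adjacency
  if (!is_square_numeric(A)) stop("`adjacency` must be square numeric", call. = FALSE)
  asg <- as_assignment(assignment)
  if (length(asg) != nrow(A) || anyNA(asg)) {
    stop("`assignment` must cover all nodes", call. = FALSE)
  }
  m2 <- sum(A)
  if (m2 <= 0) stop("zero total edge weight: modularity undefined", call. = FALSE)
  k <- rowSums(A)
  same <- outer(asg, asg, "==")
  (sum(A[same]) - gamma * sum((k %o% k)[same]) / m2) / m2
}

#' Locally greedy modularity maximization (Louvain)
#'
#' Runs the Louvain multilevel algorithm at resolution `gamma` on a
#' weighted undirected graph.  The optimization is stochastic (the node
#' sweep order is randomized); the result is fully determined by `seed`.
#' Networks with no edges yield the all-singleton partition with quality
#' `NA`.
#'
#' @param adjacency symmetric nonnegative N x N matrix (or a
#'   `"connectome"`).
#' @param gamma resolution parameter.
#' @param seed integer RNG seed for this optimization.
#' @return A `"partition"`: list with `assignment` (contiguous module ids
#'   in order of first appearance), `gamma`, `quality` (Q at `gamma`,
#'   recomputable via [modularity_q()]), `seed`.
#' @export
louvain_partition <- function(adjacency, gamma = 1, seed = 1L) {
  A <- if (inherits(adjacency, "connectome")) adjacency$weights else adjacency
  if (!is_square_numeric(A)) stop("`adjacency` must be square numeric", call. = FALSE)
  A <- check_symmetric(A, 1e-9, "adjacency")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) {
    return(new_partition(seq_len(nrow(A)), gamma, NA_real_, seed))
  }
  mem <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
  })
  asg <- canonicalize_assignment(as.integer(mem))
  new_partition(asg, gamma, modularity_q(A, asg, gamma), seed)
}

#' z-Rand similarity between two partitions
#'
#' Standardizes the pair-counting Rand statistic `w` (the number of node
#' pairs placed together in both partitions) against its mean and variance
#' under the hypergeometric null model in which both partitions keep their
#' module sizes but node labels are randomly permuted.  Large positive
#' values mean the partitions agree far beyond chance; independently
#' shuffled labels give values fluctuating around 0.  Symmetric in its
#' arguments.
#'
#' When the null variance is degenerate (for example comparing two
#' all-singleton partitions), the score is defined as 0 with a warning.
#'
#' @param p1,p2 membership vectors over the same nodes, or `"partition"`
#'   objects.
#' @return Scalar z-score.
#' @export
zrand <- function(p1, p2) {
  l1 <- as_assignment(p1)
  l2 <- as_assignment(p2)
  n <- length(l1)
  if (length(l2) != n) stop("partitions cover different node sets", call. = FALSE)
  if (n < 4L) stop("z-Rand needs at least 4 nodes", call. = FALSE)
  M <- n * (n - 1) / 2
  ct <- table(l1, l2)
  a <- rowSums(ct)
  b <- colSums(ct)
  M1 <- sum(a * (a - 1) / 2)
  M2 <- sum(b * (b - 1) / 2)
  w <- sum(ct * (ct - 1) / 2)
  Ew <- M1 * M2 / M
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(a^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(b^3)
  vw <- M / 16 -
    (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
      ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (!is.finite(vw) || vw <= 1e-12) {
    warning("degenerate null variance in z-Rand; returning 0")
    return(0)
  }
  (w - Ew) / sqrt(vw)
}

#' Association-matrix consensus partition
#'
#' Summarizes an ensemble of stochastic partitions of the same nodes by
#' the Lancichinetti-Fortunato procedure: build the co-assignment
#' (association) frequency matrix, zero out entries at or below the
#' co-assignment level expected from random label permutations (given the
#' observed module sizes), recluster the thresholded matrix with the same
#' Louvain procedure, and repeat until all reclustering runs return an
#' identical partition or `max_iter` iterations have passed.  On
#' non-convergence the most frequent partition of the final ensemble is
#' returned with a warning.
#'
#' @param partitions list of at least two `"partition"` objects (or
#'   membership vectors) over the same nodes.
#' @param seed integer seed driving the reclustering runs.
#' @param n_rerun number of Louvain runs per consensus iteration (capped
#'   at the ensemble size; default 20).
#' @param max_iter maximum consensus iterations (default 10).
#' @param gamma_recluster resolution used when reclustering the
#'   association matrix (default 1).
#' @return A `"partition"` (quality `NA`: the association matrix, not the
#'   original adjacency, was clustered; `gamma` is taken from the inputs
#'   when they agree).
#' @export
consensus_partition <- function(partitions, seed = 1L, n_rerun = 20L,
                                max_iter = 10L, gamma_recluster = 1) {
  if (length(partitions) < 2L) {
    stop("consensus needs at least 2 partitions", call. = FALSE)
  }
  asgs <- lapply(partitions, as_assignment)
  n <- length(asgs[[1L]])
  if (any(vapply(asgs, length, 1L) != n)) {
    stop("partitions cover different node sets", call. = FALSE)
  }
  gammas <- unlist(lapply(partitions, function(p) {
    if (inherits(p, "partition")) p$gamma else NA_real_
  }))
  gamma_in <- if (length(unique(gammas[!is.na(gammas)])) == 1L) {
    unique(gammas[!is.na(gammas)])
  } else {
    NA_real_
  }
  n_rerun <- max(2L, min(as.integer(n_rerun), length(partitions)))

  association <- function(asg_list) {
    D <- matrix(0, n, n)
    for (a in asg_list) D <- D + outer(a, a, "==")
    D / length(asg_list)
  }
  perm_expected <- function(asg_list) {
    mean(vapply(asg_list, function(a) {
      sz <- tabulate(a)
      sum(sz * (sz - 1)) / (n * (n - 1))
    }, 1))
  }

  current <- asgs
  for (iter in seq_len(as.integer(max_iter))) {
    D <- association(current)
    thr <- perm_expected(current)
    D[D <= thr] <- 0
    diag(D) <- 0
    runs <- lapply(seq_len(n_rerun), function(r) {
      louvain_partition(D, gamma = gamma_recluster,
                        seed = derive_seed(seed, iter * 1000L + r))$assignment
    })
    if (all(vapply(runs[-1L], identical, TRUE, y = runs[[1L]]))) {
      return(new_partition(runs[[1L]], gamma_in, NA_real_, seed))
    }
    current <- runs
  }
  warning("consensus did not converge; returning the modal partition")
  keys <- vapply(current, paste, "", collapse = ",")
  modal_key <- names(sort(table(keys), decreasing = TRUE))[1L]
  new_partition(current[[match(modal_key, keys)]], gamma_in, NA_real_, seed)
}

#' Resolution sweep with z-Rand-based selection and consensus
#'
#' For each resolution in `gamma_grid`, runs `n_opt` seeded Louvain
#' optimizations and scores their reproducibility by the mean pairwise
#' [zrand()].  The selected resolution `gamma*` maximizes the mean z-Rand
#' (ties broken toward the smallest, i.e. coarsest, resolution), and the
#' partitions obtained there are summarized into a consensus partition.
#'
#' @param x a `"connectome"` or adjacency matrix.
#' @param gamma_grid resolutions to scan (default 1.0 to 4.0 in steps of
#'   0.1).
#' @param n_opt optimizations per resolution (default 100; must be >= 2).
#' @param seed master seed; every optimization gets a sub-seed derived
#'   from it.
#' @param consensus_all if `TRUE` (default), build a consensus at every
#'   resolution so the sweep report can list module counts; if `FALSE`,
#'   only at `gamma*`.
#' @param n_rerun passed to [consensus_partition()].
#' @param method `"association"` (default; consensus by association-matrix
#'   reclustering) or `"best"` (pick the single partition with the highest
#'   mean z-Rand to the rest of its ensemble).
#' @return An object of class `"gamma_sweep"`: list with `gamma_grid`,
#'   `mean_zrand`, `partitions` (list of per-gamma ensembles),
#'   `selected_gamma`, `consensus` (a `"partition"` at `gamma*` whose
#'   `quality` is evaluated on the input adjacency), and `summary`
#'   (data.frame gamma / mean_zrand / n_modules).
#' @export
sweep_and_select <- function(x, gamma_grid = seq(1, 4, by = 0.1),
                             n_opt = 100L, seed = 1L,
                             consensus_all = TRUE, n_rerun = 20L,
                             method = c("association", "best")) {
  method <- match.arg(method)
  A <- if (inherits(x, "connectome")) x$weights else x
  if (length(gamma_grid) == 0L) stop("empty gamma grid", call. = FALSE)
  n_opt <- as.integer(n_opt)
  if (n_opt < 2L) stop("`n_opt` must be >= 2", call. = FALSE)
  gamma_grid <- sort(as.numeric(gamma_grid))

  ensembles <- vector("list", length(gamma_grid))
  mean_z <- numeric(length(gamma_grid))
  for (i in seq_along(gamma_grid)) {
    parts <- lapply(seq_len(n_opt), function(r) {
      louvain_partition(A, gamma = gamma_grid[i],
                        seed = derive_seed(seed, (i - 1L) * n_opt + r))
    })
    z <- 0
    npair <- 0L
    for (p in seq_len(n_opt - 1L)) {
      for (q in seq(p + 1L, n_opt)) {
        z <- z + zrand(parts[[p]], parts[[q]])
        npair <- npair + 1L
      }
    }
    ensembles[[i]] <- parts
    mean_z[i] <- z / npair
  }
  sel <- which.max(mean_z)   # ties resolve to the smallest gamma

  build_consensus <- function(i) {
    if (method == "association") {
      consensus_partition(ensembles[[i]], seed = derive_seed(seed, 900000L + i),
                          n_rerun = n_rerun)
    } else {
      scores <- vapply(seq_len(n_opt), function(p) {
        mean(vapply(setdiff(seq_len(n_opt), p), function(q) {
          zrand(ensembles[[i]][[p]], ensembles[[i]][[q]])
        }, 1))
      }, 1)
      ensembles[[i]][[which.max(scores)]]
    }
  }

  n_modules <- rep(NA_integer_, length(gamma_grid))
  consensus <- NULL
  for (i in seq_along(gamma_grid)) {
    if (consensus_all || i == sel) {
      cons_i <- build_consensus(i)
      n_modules[i] <- max(cons_i$assignment)
      if (i == sel) consensus <- cons_i
    }
  }
  if (sum(A) > 0) {
    consensus$quality <- modularity_q(A, consensus$assignment, gamma_grid[sel])
  }
  structure(list(gamma_grid = gamma_grid,
                 mean_zrand = mean_z,
                 partitions = ensembles,
                 selected_gamma = gamma_grid[sel],
                 consensus = consensus,
                 summary = data.frame(gamma = gamma_grid,
                                      mean_zrand = mean_z,
                                      n_modules = n_modules)),
            class = "gamma_sweep")
}

#' @export
print.gamma_sweep <- function(x, ...) {
  cat(sprintf("<gamma_sweep> %d resolutions, gamma* = %.2f (mean z-Rand %.2f), consensus: %d modules\n",
              length(x$gamma_grid), x$selected_gamma,
              x$mean_zrand[match(x$selected_gamma, x$gamma_grid)],
              max(x$consensus$assignment)))
  invisible(x)
}

#' Boundary controllability ranking
#'
#' Boundary controllers are regions positioned to couple or decouple
#' network modules.  Given a partition with at least two modules, each
#' node's boundary fraction is the share of its strength carried by
#' inter-module edges, `sum_{j: m_j != m_i} a_ij / sum_j a_ij` (0 for
#' isolated nodes).  Nodes with at least one inter-module edge are flagged
#' as boundary nodes and always outrank non-boundary nodes.  Rank 1 is the
#' strongest boundary controller; within the boundary set ranking is by
#' descending fraction, then descending number of distinct foreign
#' modules, then input order; non-boundary nodes follow, by descending
#' strength then input order.  The zero-centered rank is
#' `rank - (N + 1) / 2`.
#'
#' @param x a `"connectome"` or adjacency matrix.
#' @param partition a `"partition"` or membership vector covering all
#'   nodes, with >= 2 modules.
#' @return An object of class `"boundary_result"`: data.frame with columns
#'   `label`, `strength`, `boundary_fraction`, `n_foreign_modules`,
#'   `is_boundary`, `rank`, `centered_rank`.
#' @export
boundary_controllability <- function(x, partition) {
  A <- if (inherits(x, "connectome")) x$weights else x
  labels <- if (inherits(x, "connectome")) x$labels else sprintf("R%03d", seq_len(nrow(A)))
  if (!is_square_numeric(A)) stop("`x` must be square numeric", call. = FALSE)
  asg <- as_assignment(partition)
  n <- nrow(A)
  if (length(asg) != n || anyNA(asg)) {
    stop("partition must cover all nodes", call. = FALSE)
  }
  if (length(unique(asg)) < 2L) {
    stop("single-module partition: boundary controllability undefined",
         call. = FALSE)
  }
  strength <- rowSums(A)
  cross <- vapply(seq_len(n), function(i) sum(A[i, asg != asg[i]]), 1)
  frac <- ifelse(strength > 0, cross / strength, 0)
  is_boundary <- cross > 0
  n_foreign <- vapply(seq_len(n), function(i) {
    length(unique(asg[A[i, ] > 0 & asg != asg[i]]))
  }, 1L)

  idx_b <- which(is_boundary)
  idx_n <- which(!is_boundary)
  ord <- c(idx_b[order(-frac[idx_b], -n_foreign[idx_b], idx_b)],
           idx_n[order(-strength[idx_n], idx_n)])
  rank <- integer(n)
  rank[ord] <- seq_len(n)

  structure(data.frame(label = labels,
                       strength = strength,
                       boundary_fraction = frac,
                       n_foreign_modules = n_foreign,
                       is_boundary = is_boundary,
                       rank = rank,
                       centered_rank = rank - (n + 1) / 2,
                       stringsAsFactors = FALSE),
            class = c("boundary_result", "data.frame"))
}

#' Write a partition as two-column TSV (label, module)
#'
#' @param partition a `"partition"`.
#' @param labels node labels in partition order.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, labels, path) {
  write_tsv_full(data.frame(label = labels,
                            module = as_assignment(partition),
                            stringsAsFactors = FALSE), path)
}

#' Write the resolution-sweep report as TSV
#'
#' Columns: gamma, mean_zrand, n_modules (of the consensus at each
#' resolution, where computed).
#'
#' @param sweep a `"gamma_sweep"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sweep_report <- function(sweep, path) {
  write_tsv_full(sweep$summary, path)
}

#' Write the boundary-controllability report as TSV
#'
#' @param boundary a `"boundary_result"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_boundary_report <- function(boundary, path) {
  write_tsv_full(as.data.frame(boundary), path)
}
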