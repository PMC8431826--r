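# Programmatic fixtures shared across test files.

# adjacency of two k-cliques, optionally joined by one unit-weight bridge
# between the last node of clique 1 and the first node of clique 2
two_cliques <- function(k = 5, bridge = TRUE, w = 1) {
  n <- 2L * k
  A <- matrix(0, n, n)
  A[seq_len(k), seq_len(k)] <- w
  A[(k + 1):n, (k + 1):n] <- w
  diag(A) <- 0
  if (bridge) A[k, k + 1L] <- A[k + 1L, k] <- w
  A
}

planted_two_cliques <- function(k = 5) rep(1:2, each = k)

# barbell: two 3-cliques connected by a single bridge edge (nodes 3 and 4)
barbell <- function() two_cliques(k = 3, bridge = TRUE)

# random symmetric zero-diagonal matrix with entries in (-1, 1)
rand_sym <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n, -1, 1), n, n)
  A <- (M + t(M)) / 2
  diag(A) <- 0
  A
}

# ring of k cliques: strong within-module connectivity, elevated coupling
# between ring-adjacent modules (so resolution 1 merges ambiguously),
# sparse elsewhere.  Community structure is stably recoverable only near
# one resolution.
ring_of_cliques <- function(seed, n_per = 12L, k = 4L,
                            p_in = 0.95, p_ring = 0.5, p_far = 0.02) {
  set.seed(seed)
  n <- n_per * k
  mods <- rep(seq_len(k), each = n_per)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- abs(mods[i] - mods[j])
      adjacent <- d == 1L || d == k - 1L
      p <- if (mods[i] == mods[j]) p_in else if (adjacent) p_ring else p_far
      if (runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
  }
  list(A = A, modules = mods)
}

# coefficient list with every generator effect zeroed except those given
zero_coefs <- function(...) {
  base <- list(
    intercept = 0, task = 0, session = 0, session_task = 0,
    stimulation = 0, stimulation_session = 0, stimulation_session_task = 0,
    entropy = 0, association = 0, boundary = 0, stimulation_boundary = 0,
    session_boundary = 0, stimulation_session_boundary = 0,
    boundary_entropy = 0, modal = 0, modal_entropy = 0,
    boundary_association = 0, modal_association = 0,
    task_entropy = 0, task_association = 0, trial_order = 0,
    trial_entropy = 0)
  override <- list(...)
  base[names(override)] <- override
  base
}

# small hand-built trial table
manual_trials <- function(rt, is_error = rep(FALSE, length(rt)),
                          task = "sentence_completion",
                          group = "sham", session = "pre") {
  n <- length(rt)
  data.frame(subject = rep("S001", n), group = group, session = session,
             task = task, trial_order = seq_len(n),
             entropy = seq(0.1, 0.9, length.out = n),
             association = seq(0.9, 0.1, length.out = n),
             rt_ms = rt, is_error = is_error,
             stringsAsFactors = FALSE)
}
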