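# Independent oracles used to check package computations.  These are
# deliberately written as naive loops / enumerations so they share no code
# path with the implementation they test.

# modal controllability by explicit double loop over nodes and modes
oracle_phi <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  n <- nrow(A)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      s <- s + (1 - e$values[j]^2) * e$vectors[i, j]^2
    }
    phi[i] <- s
  }
  phi
}

# modularity by brute-force double loop over ordered node pairs
oracle_modularity <- function(A, asg, gamma = 1) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (asg[i] == asg[j]) {
        q <- q + A[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# pair-counting w: number of node pairs co-clustered in both partitions
oracle_pair_w <- function(l1, l2) {
  n <- length(l1)
  w <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (l1[i] == l1[j] && l2[i] == l2[j]) w <- w + 1L
    }
  }
  w
}

# all permutations of 1..n (n! rows) by simple recursion
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# all set partitions of n elements as restricted-growth membership vectors
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(vec) {
    if (length(vec) == n) {
      out[[length(out) + 1L]] <<- vec
      return(invisible())
    }
    for (b in seq_len(max(vec) + 1L)) grow(c(vec, b))
  }
  grow(1L)
  out
}

# PBH test for a symmetric matrix with distinct eigenvalues and a single
# control node k: controllable iff no eigenvector is orthogonal to e_k
oracle_pbh_single <- function(A, k, tol = 1e-8) {
  V <- eigen(A, symmetric = TRUE)$vectors
  all(abs(V[k, ]) > tol)
}

# sample skewness g1
oracle_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
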