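test_that("modularity matches closed forms and the double-loop oracle", {
  # all-in-one partition at gamma 1 scores exactly 0 on any graph
  for (seed in 1:3) {
    A <- abs(rand_sym(8, seed = 100 + seed))
    diag(A) <- 0
    expect_equal(modularity_q(A, rep(1, 8), gamma = 1), 0, tolerance = 1e-12)
  }

  # two disconnected equal-weight cliques, split correctly: Q = 1/2
  A2 <- two_cliques(k = 4, bridge = FALSE)
  expect_equal(modularity_q(A2, planted_two_cliques(4), gamma = 1), 0.5,
               tolerance = 1e-12)

  # random weighted graph, random partition, several resolutions
  for (seed in 1:3) {
    A <- abs(rand_sym(9, seed = 110 + seed))
    diag(A) <- 0
    set.seed(seed)
    asg <- sample(3, 9, replace = TRUE)
    for (gam in c(0.5, 1, 2.5)) {
      expect_equal(modularity_q(A, asg, gam), oracle_modularity(A, asg, gam),
                   tolerance = 1e-12)
    }
    # cross-check against igraph's resolution-scaled modularity
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(A, asg, 1.7),
                 igraph::modularity(g, asg, weights = igraph::E(g)$weight,
                                    resolution = 1.7),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(matrix(0, 4, 4), rep(1, 4)), "zero total")
})

test_that("Louvain recovers planted cliques, respects resolution, and is seeded", {
  A <- two_cliques(k = 5, bridge = TRUE)
  p <- louvain_partition(A, gamma = 1, seed = 3)
  expect_equal(ari(p$assignment, planted_two_cliques(5)), 1)
  expect_equal(p$quality, modularity_q(A, p$assignment, 1), tolerance = 1e-10)

  # complete uniform graph: single module at gamma 1, finer at gamma 4
  K <- matrix(1, 8, 8)
  diag(K) <- 0
  p1 <- louvain_partition(K, gamma = 1, seed = 5)
  expect_equal(max(p1$assignment), 1L)
  p4 <- louvain_partition(K, gamma = 4, seed = 5)
  expect_gte(max(p4$assignment), max(p1$assignment))

  # determinism given seed
  conn <- generate_connectome(connectome_gen_config(n_nodes = 40,
                                                    n_modules = 4, seed = 8))
  expect_identical(louvain_partition(conn, 1.5, seed = 42)$assignment,
                   louvain_partition(conn, 1.5, seed = 42)$assignment)

  # never below the all-in-one partition's quality at the same gamma
  for (seed in 1:5) {
    c2 <- generate_connectome(connectome_gen_config(n_nodes = 30,
                                                    n_modules = 3,
                                                    seed = seed))
    for (gam in c(1, 2, 4)) {
      p <- louvain_partition(c2, gam, seed = seed)
      expect_gte(p$quality, modularity_q(c2$weights, rep(1, 30), gam) - 1e-12)
    }
  }
})

test_that("z-Rand null moments match exhaustive permutation enumeration", {
  cases <- list(list(c(1, 1, 1, 2, 2, 3), c(1, 1, 2, 2, 3, 3)),
                list(c(1, 1, 2, 2, 2, 2, 3), c(1, 2, 1, 2, 3, 3, 3)),
                list(c(1, 1, 1, 1, 2, 2), c(1, 2, 1, 2, 1, 2)))
  for (case in cases) {
    l1 <- case[[1]]
    l2 <- case[[2]]
    n <- length(l1)
    perms <- oracle_perms(n)
    ws <- apply(perms, 1L, function(p) oracle_pair_w(l1, l2[p]))
    mu <- mean(ws)
    sg <- sqrt(mean(ws^2) - mean(ws)^2)
    z_perm <- (oracle_pair_w(l1, l2) - mu) / sg
    expect_equal(zrand(l1, l2), z_perm, tolerance = 1e-10)
  }
})

test_that("z-Rand is symmetric, positive on identity, and 0 when degenerate", {
  set.seed(120)
  for (rep in 1:5) {
    a <- sample(3, 10, replace = TRUE)
    b <- sample(4, 10, replace = TRUE)
    expect_equal(zrand(a, b), zrand(b, a), tolerance = 1e-12)
  }
  p <- c(1, 1, 1, 2, 2, 3, 3, 3)
  expect_gt(zrand(p, p), 0)
  expect_warning(z0 <- zrand(1:6, 1:6), "degenerate")
  expect_equal(z0, 0)
})

test_that("the resolution sweep selects by mean z-Rand with coarse tie-break", {
  # deterministic two-clique graph: identical partitions at every
  # resolution, so the tie-break picks the smallest gamma
  A <- two_cliques(k = 4, bridge = FALSE)
  sw <- sweep_and_select(A, gamma_grid = c(1, 1.5), n_opt = 3, seed = 7,
                         consensus_all = FALSE)
  expect_equal(sw$selected_gamma, 1)
  expect_equal(sw$mean_zrand[1], sw$mean_zrand[2], tolerance = 1e-12)

  # singleton grid
  sw2 <- sweep_and_select(A, gamma_grid = 2.0, n_opt = 3, seed = 7,
                          consensus_all = FALSE)
  expect_equal(sw2$selected_gamma, 2.0)
  expect_error(sweep_and_select(A, gamma_grid = numeric(0), n_opt = 3),
               "empty")
  expect_error(sweep_and_select(A, gamma_grid = 1, n_opt = 1), "n_opt")
})

test_that("the sweep finds structure detectable only near one resolution", {
  hits <- 0L
  for (seed in 1:3) {
    rg <- ring_of_cliques(seed)
    sw <- sweep_and_select(rg$A, gamma_grid = seq(1, 2.5, 0.5), n_opt = 12,
                           seed = seed, consensus_all = FALSE)
    if (sw$selected_gamma == 1.5 &&
        ari(sw$consensus$assignment, rg$modules) > 0.9) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)
})

test_that("consensus reproduces unanimity, majorities, and is seeded", {
  A <- two_cliques(k = 5, bridge = TRUE)
  parts <- lapply(1:6, function(s) louvain_partition(A, 1, seed = s))
  cons <- consensus_partition(parts, seed = 1)
  expect_identical(cons$assignment, parts[[1]]$assignment)

  # 9 identical + 1 random partition: majority wins
  majority <- rep(1:2, each = 5)
  set.seed(130)
  noise <- sample(4, 10, replace = TRUE)
  ens <- c(replicate(9, majority, simplify = FALSE), list(noise))
  cons2 <- consensus_partition(ens, seed = 2)
  expect_equal(ari(cons2$assignment, majority), 1)

  # deterministic given seed, even for a conflicted ensemble
  conflict <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 1, 2, 2), c(1, 2, 1, 2))
  c1 <- suppressWarnings(consensus_partition(conflict, seed = 9))
  c2 <- suppressWarnings(consensus_partition(conflict, seed = 9))
  expect_identical(c1$assignment, c2$assignment)
  expect_error(consensus_partition(parts[1]), "at least 2")
})

test_that("boundary ranking puts bridge nodes first and handles edge cases", {
  A <- barbell()
  part <- rep(1:2, each = 3)
  bd <- boundary_controllability(A, part)
  expect_setequal(bd$rank[c(3, 4)], c(1L, 2L))
  expect_true(all(bd$boundary_fraction >= 0 & bd$boundary_fraction <= 1))
  expect_setequal(bd$rank, 1:6)
  expect_equal(bd$centered_rank, bd$rank - 3.5)
  # boundary nodes outrank every non-boundary node
  expect_lt(max(bd$rank[bd$is_boundary]), min(bd$rank[!bd$is_boundary]))

  # two disconnected cliques with a two-module partition: no boundary
  # nodes, no error
  D <- two_cliques(k = 4, bridge = FALSE)
  bd2 <- boundary_controllability(D, planted_two_cliques(4))
  expect_true(all(!bd2$is_boundary))
  expect_true(all(bd2$boundary_fraction == 0))

  # node whose entire strength crosses modules gets fraction 1 and rank 1
  S <- matrix(0, 4, 4)
  S[1, 3] <- S[3, 1] <- 1
  S[1, 4] <- S[4, 1] <- 1
  S[3, 4] <- S[4, 3] <- 1
  S[2, 3] <- S[3, 2] <- 0.1
  bd3 <- boundary_controllability(S, c(1, 1, 2, 2))
  expect_equal(bd3$boundary_fraction[1], 1)
  expect_equal(bd3$rank[1], 1L)

  expect_error(boundary_controllability(A, rep(1, 6)), "single-module")
})

test_that("boundary fractions are equivariant under node relabeling", {
  conn <- generate_connectome(connectome_gen_config(n_nodes = 30,
                                                    n_modules = 3, seed = 17))
  part <- attr(conn, "planted_modules")
  bd <- boundary_controllability(conn$weights, part)
  set.seed(18)
  p <- sample(30)
  bd_p <- boundary_controllability(conn$weights[p, p], part[p])
  expect_equal(bd_p$boundary_fraction, bd$boundary_fraction[p],
               tolerance = 1e-12)
  expect_equal(bd_p$is_boundary, bd$is_boundary[p])
})

test_that("partition, sweep and boundary reports round-trip through TSV", {
  conn <- generate_connectome(connectome_gen_config(n_nodes = 24,
                                                    n_modules = 3, seed = 23))
  sw <- sweep_and_select(conn, gamma_grid = c(1, 2), n_opt = 4, seed = 5,
                         consensus_all = TRUE)
  dir <- withr::local_tempdir()
  write_partition(sw$consensus, conn$labels, file.path(dir, "part.tsv"))
  write_sweep_report(sw, file.path(dir, "sweep.tsv"))
  write_boundary_report(boundary_controllability(conn, sw$consensus),
                        file.path(dir, "bd.tsv"))
  part <- read.delim(file.path(dir, "part.tsv"))
  expect_equal(part$module, sw$consensus$assignment)
  swr <- read.delim(file.path(dir, "sweep.tsv"))
  expect_equal(swr$mean_zrand, sw$mean_zrand, tolerance = 1e-15)
  expect_equal(nrow(read.delim(file.path(dir, "bd.tsv"))), 24)
})
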