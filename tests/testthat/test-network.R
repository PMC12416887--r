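# Correlation networks, path enumeration vs exhaustive oracles, community
# recovery, current-flow betweenness vs dense linear-solve oracle.

test_that("correlation matrix behaves at its limits", {
  set.seed(61)
  nf <- 5000
  # two independent isotropic nodes plus one duplicated node
  base <- array(rnorm(2 * 3 * nf), c(2, 3, nf))
  coords <- array(0, c(3, 3, nf))
  coords[1:2, , ] <- base
  coords[3, , ] <- base[1, , ]  # exact duplicate of node 1
  atoms <- tibble::tibble(atom_id = 1:3, name = "CA", resid = 1:3,
                          resname = "GLY", chain = "A", element = "C")
  top <- new_topology(atoms)
  traj <- new_trajectory(coords, c(50, 50, 50))
  C <- covariance_matrix(traj, top, superpose = FALSE)
  expect_equal(C[1, 3], 1)             # duplicated node: C = 1
  expect_lt(abs(C[1, 2]), 0.1)         # independence limit
  expect_true(all(abs(C) <= 1 + 1e-12))
})

test_that("elastic-network correlations recover the analytic ground truth", {
  spec <- two_block_network(n_per_block = 5, seed = 19)
  out <- sample_elastic_network(spec, n_frames_sim = 1e4)
  C <- covariance_matrix(out$trajectory, out$topology, superpose = FALSE)
  rel <- norm(C - out$correlation, "F") / norm(out$correlation, "F")
  expect_lt(rel, 0.05)
})

test_that("graph weights follow w = -log|C| and drop zero edges", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 1
  C[2, 3] <- C[3, 2] <- exp(-1)
  dimnames(C) <- list(c("a", "b", "c"), c("a", "b", "c"))
  adj <- matrix(TRUE, 3, 3, dimnames = dimnames(C))
  rg <- build_graph(adj, C)
  e_ab <- rg$edges$w[rg$edges$from == "a" & rg$edges$to == "b"]
  e_bc <- rg$edges$w[(rg$edges$from == "b" & rg$edges$to == "c") |
                       (rg$edges$from == "c" & rg$edges$to == "b")]
  expect_equal(e_ab, 0)    # |C| = 1 -> w = 0
  expect_equal(e_bc, 1)    # |C| = 1/e -> w = 1
  # C = 0 edge dropped (a-c)
  expect_equal(nrow(rg$edges), 2)
  # unnormalised input rejected
  C2 <- C; C2[1, 2] <- C2[2, 1] <- 1.4
  expect_error(build_graph(adj, C2), "not normalised")
  # edge set equals contact-map truth exactly
  expect_setequal(paste(rg$edges$from, rg$edges$to),
                  c("a b", "b c"))
})

test_that("optimal path picks the lighter two-hop route", {
  W <- matrix(Inf, 3, 3); diag(W) <- 0
  W[1, 3] <- W[3, 1] <- 1.0
  W[1, 2] <- W[2, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.4
  rg <- graph_from_W(W)
  op <- optimal_path(rg, "01", "03")
  expect_equal(op$length, 0.8)
  expect_equal(op$path[[1]], c("01", "02", "03"))
  # suboptimal enumeration keeps the direct edge (1.0 <= 1.2)
  ps <- suboptimal_paths(rg, "01", "03")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$length, c(0.8, 1.0))
  # a second-best path beyond 1.5x optimal is excluded
  W2 <- W; W2[1, 3] <- W2[3, 1] <- 1.3
  ps2 <- suboptimal_paths(graph_from_W(W2), "01", "03")
  expect_equal(nrow(ps2), 1)
  # single-edge graph
  W1 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  op1 <- optimal_path(graph_from_W(W1), "01", "02")
  expect_equal(op1$length, 0.7)
  # disconnected pair errors
  W3 <- matrix(Inf, 4, 4); diag(W3) <- 0
  W3[1, 2] <- W3[2, 1] <- 1; W3[3, 4] <- W3[4, 3] <- 1
  rg3 <- structure(list(), class = "residue_graph")
  C3 <- exp(-W3); C3[!is.finite(W3)] <- 0; diag(C3) <- 1
  labs <- sprintf("%02d", 1:4); dimnames(C3) <- list(labs, labs)
  adj3 <- is.finite(W3) & W3 > 0; dimnames(adj3) <- dimnames(C3)
  expect_error(optimal_path(build_graph(adj3, C3), "01", "03"),
               "disconnected")
})

test_that("path sets equal exhaustive enumeration on 100 random graphs", {
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(5:8, 1)
    W <- random_graph_W(n)
    rg <- graph_from_W(W)
    st <- sample(n, 2)
    s <- sprintf("%02d", st[1]); t <- sprintf("%02d", st[2])
    all_paths <- enumerate_paths_oracle(W, st[1], st[2])
    lens <- vapply(all_paths, `[[`, numeric(1), "length")
    op <- optimal_path(rg, s, t)
    expect_equal(op$length, min(lens), tolerance = 1e-12)
    ps <- suboptimal_paths(rg, s, t)
    keep <- lens <= 1.5 * min(lens) + 1e-12
    # identical path sets (as unordered sets of node sequences)
    oracle_set <- sort(vapply(all_paths[keep], function(p) {
      paste(sprintf("%02d", p$path), collapse = "-")
    }, character(1)))
    got_set <- sort(vapply(ps$path, paste, character(1), collapse = "-"))
    expect_identical(got_set, oracle_set)
    # every returned path satisfies the 1.5x bound; lengths nondecreasing
    expect_true(all(ps$length <= 1.5 * op$length + 1e-9))
    expect_true(!is.unsorted(ps$length))
  }
})

test_that("communities split cliques and respect components", {
  # two 4-cliques joined by one weak edge
  n <- 8
  C <- diag(n)
  for (i in 1:3) for (j in (i + 1):4) C[i, j] <- C[j, i] <- 0.9
  for (i in 5:7) for (j in (i + 1):8) C[i, j] <- C[j, i] <- 0.9
  C[4, 5] <- C[5, 4] <- 0.1
  labs <- sprintf("%02d", 1:n); dimnames(C) <- list(labs, labs)
  adj <- abs(C) > 0 & !diag(n); dimnames(adj) <- dimnames(C)
  rg <- build_graph(adj, C)
  comm <- detect_communities(rg)
  expect_equal(comm$n_communities, 2)
  expect_equal(length(unique(comm$membership[1:4])), 1)
  expect_equal(length(unique(comm$membership[5:8])), 1)
  expect_gt(comm$modularity, 0.3)
  # a single clique stays whole
  C1 <- matrix(0.8, 4, 4); diag(C1) <- 1
  labs1 <- sprintf("%02d", 1:4); dimnames(C1) <- list(labs1, labs1)
  adj1 <- !diag(4) > 0; dimnames(adj1) <- dimnames(C1)
  comm1 <- detect_communities(build_graph(adj1, C1))
  expect_equal(comm1$n_communities, 1)
  # disconnected components are never merged
  C2 <- diag(6)
  C2[1, 2] <- C2[2, 1] <- C2[2, 3] <- C2[3, 2] <- 0.9
  C2[4, 5] <- C2[5, 4] <- C2[5, 6] <- C2[6, 5] <- 0.9
  labs2 <- sprintf("%02d", 1:6); dimnames(C2) <- list(labs2, labs2)
  adj2 <- abs(C2) > 0 & !diag(6); dimnames(adj2) <- dimnames(C2)
  comm2 <- detect_communities(build_graph(adj2, C2))
  m <- comm2$membership
  expect_true(all(m[1:3] != m[4:6]))
})

test_that("planted two-block partition is recovered with ARI = 1", {
  spec <- two_block_network(n_per_block = 6, k_intra = 10, k_inter = 0.5,
                            seed = 23)
  out <- sample_elastic_network(spec, n_frames_sim = 5000)
  C <- covariance_matrix(out$trajectory, out$topology, superpose = FALSE)
  adj <- matrix(FALSE, nrow(C), ncol(C), dimnames = dimnames(C))
  adj[cbind(spec$springs$i, spec$springs$j)] <- TRUE
  adj <- adj | t(adj)
  comm <- detect_communities(build_graph(adj, C))
  ari <- mclust::adjustedRandIndex(comm$membership, out$partition)
  expect_equal(ari, 1.0)
})

test_that("information flow matches hand cases and the dense oracle", {
  # path graph A-B-C: all current traverses B
  A <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                       c("A", "B", "C")))
  A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  fl <- information_flow(A, "A", "C")
  expect_equal(fl$flow[fl$node == "B"], 1)
  expect_equal(fl$flow[fl$node %in% c("A", "C")], c(1, 1))
  # two equal parallel branches: each branch node carries half
  A2 <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  A2[1, 2] <- A2[2, 1] <- 1; A2[2, 3] <- A2[3, 2] <- 1
  A2[1, 4] <- A2[4, 1] <- 1; A2[4, 3] <- A2[3, 4] <- 1
  fl2 <- information_flow(A2, "A", "C")
  expect_equal(fl2$flow[fl2$node == "B"], 0.5)
  expect_equal(fl2$flow[fl2$node == "D"], 0.5)
  # Kirchhoff balance at interior nodes and flow-scale invariance
  set.seed(55)
  for (trial in 1:20) {
    n <- 10
    A3 <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) A3[i, j] <- A3[j, i] <- runif(1, 0.1, 2)
    }
    g <- igraph::graph_from_adjacency_matrix(A3 > 0, mode = "undirected")
    if (igraph::components(g)$no != 1) next
    fl3 <- information_flow(A3, 1, n)
    # independent oracle: full pseudo-inverse potentials
    L <- diag(rowSums(A3)) - A3
    b <- rep(0, n); b[1] <- 1; b[n] <- -1
    P <- as.vector(MASS::ginv(L) %*% b)
    P <- P - P[n]
    fo <- 0.5 * rowSums(abs(outer(P, P, "-")) * A3)
    fo[c(1, n)] <- 1
    expect_equal(fl3$flow, fo, tolerance = 1e-8)
    # interior node current balance
    cur <- (outer(P, P, "-")) * A3
    net <- rowSums(cur)
    expect_equal(net[2:(n - 1)], rep(0, n - 2), tolerance = 1e-9)
    # uniform conductance scaling leaves flows unchanged
    fl3b <- information_flow(A3 * 7.3, 1, n)
    expect_equal(fl3b$flow, fl3$flow, tolerance = 1e-9)
  }
  # disconnected source/sink errors
  A4 <- matrix(0, 4, 4)
  A4[1, 2] <- A4[2, 1] <- 1; A4[3, 4] <- A4[4, 3] <- 1
  expect_error(information_flow(A4, 1, 4), "different components")
})

test_that("flow report ranks and highlights with a strict threshold", {
  fl <- structure(
    tibble::tibble(node = c("s", "a", "b", "c", "t"),
                   flow = c(1, 0.021, 0.02, 0.5, 1),
                   potential = 0),
    class = c("flow_profile", "tbl_df", "tbl", "data.frame"),
    source = "s", sink = "t")
  rep <- flow_profile_report(fl)
  expect_equal(rep$node, c("c", "a", "b"))
  expect_equal(rep$highlight, c(TRUE, TRUE, FALSE))  # 0.02 is not > 0.02
})
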