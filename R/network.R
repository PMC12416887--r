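# Residue-level coupling networks: Pearson-normalised covariance of C-alpha
# fluctuations, contact-gated graphs weighted w = -log|C|, optimal and
# suboptimal coupling pathways, divisive community detection, and
# current-flow information betweenness on mutual-information conductances.

#' Normalised covariance (correlation) of C-alpha fluctuations
#'
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>) over frames, after
#' optional least-squares superposition of every frame onto a reference to
#' remove rigid-body motion. |C_ij| <= 1 by construction.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param selection Node atoms (typically `"name CA"`); one atom per node.
#' @param superpose Superpose frames onto `reference_frame` first.
#' @param reference_frame Frame used as the fit reference.
#' @return `[n, n]` correlation matrix with node residue numbers as
#'   dimnames.
#' @export
covariance_matrix <- function(trajectory, topology, selection = "name CA",
                              superpose = TRUE, reference_frame = 1) {
  idx <- resolve_indices(topology, selection)
  nf <- n_frames(trajectory)
  n <- length(idx)
  X <- array(0, c(n, 3, nf))
  ref <- as.vector(t(frame_coords(trajectory, reference_frame)[idx, ,
                                                               drop = FALSE]))
  for (f in seq_len(nf)) {
    xyz <- trajectory$coords[idx, , f, drop = FALSE][, , 1]
    if (superpose) {
      mob <- as.vector(t(xyz))
      fitted <- bio3d::fit.xyz(ref, mob, fixed.inds = seq_along(ref),
                               mobile.inds = seq_along(mob))
      xyz <- matrix(fitted, ncol = 3, byrow = TRUE)
    }
    X[, , f] <- xyz
  }
  mu <- apply(X, c(1, 2), mean)
  num <- matrix(0, n, n)
  for (d in 1:3) {
    D <- X[, d, ] - mu[, d]
    if (n == 1) D <- matrix(D, nrow = 1)
    num <- num + tcrossprod(D) / nf
  }
  v <- diag(num)
  if (any(v <= 0)) {
    bad <- topology$atoms$resid[idx[v <= 0]]
    abort(paste0("zero-variance node(s): residue ",
                 paste(bad, collapse = ", ")))
  }
  C <- num / sqrt(tcrossprod(v))
  lab <- paste0(topology$atoms$resid[idx], ".", topology$atoms$chain[idx])
  dimnames(C) <- list(lab, lab)
  C
}

#' Build the coupling-weighted residue graph
#'
#' Contact edges (5 A / 75% occupancy rule) are weighted
#' w_ij = -log|C_ij|; edges with C = 0 are dropped (infinite weight).
#' Inputs with |C| > 1 are an error — they signal an unnormalised
#' covariance.
#'
#' @param contacts Either a logical adjacency matrix matching `C`, or a
#'   [residue_contact_map()] tibble (its `contact` rows define edges; node
#'   labels must match `rownames(C)` as `resid.chain`).
#' @param C Correlation matrix from [covariance_matrix()].
#' @return Object of class `residue_graph`: list with the igraph `graph`
#'   and the edge tibble `edges` (`from, to, C, w`).
#' @export
build_graph <- function(contacts, C) {
  if (max(abs(C)) > 1 + 1e-9) {
    abort("|C| > 1: input covariance is not normalised")
  }
  n <- nrow(C)
  labs <- rownames(C) %||% as.character(seq_len(n))
  if (is.matrix(contacts)) {
    adj <- contacts
  } else {
    adj <- matrix(FALSE, n, n, dimnames = list(labs, labs))
    hits <- contacts[contacts$contact, ]
    a <- paste0(hits$resid_a, ".", hits$chain_a)
    b <- paste0(hits$resid_b, ".", hits$chain_b)
    keep <- a %in% labs & b %in% labs
    adj[cbind(a[keep], b[keep])] <- TRUE
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  cvals <- C[pairs]
  nz <- abs(cvals) > 0
  pairs <- pairs[nz, , drop = FALSE]
  cvals <- cvals[nz]
  edges <- tibble(
    from = labs[pairs[, 1]], to = labs[pairs[, 2]],
    C = cvals, w = -log(abs(cvals))
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = labs))
  structure(list(graph = g, edges = edges, labels = labs),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph> ", length(x$labels), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

graph_weight_matrix <- function(rg) {
  n <- length(rg$labels)
  W <- matrix(Inf, n, n, dimnames = list(rg$labels, rg$labels))
  diag(W) <- 0
  i <- match(rg$edges$from, rg$labels)
  j <- match(rg$edges$to, rg$labels)
  W[cbind(i, j)] <- rg$edges$w
  W[cbind(j, i)] <- rg$edges$w
  W
}

#' Optimal coupling pathway (Floyd-Warshall)
#'
#' Minimum-total-weight path between two nodes with deterministic
#' reconstruction (strict-improvement updates in fixed node order).
#'
#' @param rg A [build_graph()] residue graph.
#' @param source,sink Node labels (as in `rownames(C)`).
#' @return Tibble of class `path_set` row: `path` (list of node labels),
#'   `length`, `optimal = TRUE`.
#' @export
optimal_path <- function(rg, source, sink) {
  W <- graph_weight_matrix(rg)
  n <- nrow(W)
  nxt <- matrix(NA_integer_, n, n)
  nxt[is.finite(W) & W > 0] <- col(W)[is.finite(W) & W > 0]
  D <- W
  for (k in seq_len(n)) {
    through <- outer(D[, k], D[k, ], "+")
    better <- through < D
    if (any(better)) {
      D[better] <- through[better]
      nxt[better] <- matrix(nxt[, k], n, n)[better]
    }
  }
  si <- match(source, rg$labels); ti <- match(sink, rg$labels)
  if (is.na(si) || is.na(ti)) abort("source/sink not in graph")
  if (!is.finite(D[si, ti])) {
    abort(paste0("no path between ", source, " and ", sink,
                 " (disconnected)"))
  }
  path <- si
  while (path[length(path)] != ti) {
    path <- c(path, nxt[path[length(path)], ti])
  }
  out <- tibble(path = list(rg$labels[path]), length = D[si, ti],
                optimal = TRUE)
  structure(out, class = c("path_set", class(out)),
            source = source, sink = sink, cutoff_ratio = NA_real_)
}

#' Optimal plus suboptimal coupling pathways
#'
#' All simple paths whose total weight is within `(1 + cutoff_ratio)` times
#' the optimal length (default 1.5x), enumerated by depth-first search with
#' pruning at the bound, capped at `max_paths` (a `truncated` attribute
#' flags the cap). Paths are listed in nondecreasing length with
#' lexicographic tie-break.
#'
#' @param rg A residue graph.
#' @param source,sink Node labels.
#' @param cutoff_ratio Allowed fractional excess over the optimal length
#'   (default 0.5).
#' @param max_paths Enumeration guard (default 1000).
#' @return `path_set` tibble: `path` (list-column), `length`, `optimal`.
#' @export
suboptimal_paths <- function(rg, source, sink, cutoff_ratio = 0.5,
                             max_paths = 1000) {
  opt <- optimal_path(rg, source, sink)
  bound <- (1 + cutoff_ratio) * opt$length + 1e-12
  W <- graph_weight_matrix(rg)
  n <- nrow(W)
  si <- match(source, rg$labels); ti <- match(sink, rg$labels)
  nbrs <- lapply(seq_len(n), function(i) which(is.finite(W[i, ]) & W[i, ] > 0))
  found <- list()
  truncated <- FALSE
  visit <- function(path, len) {
    if (truncated) return()
    u <- path[length(path)]
    if (u == ti) {
      found[[length(found) + 1]] <<- list(path = path, length = len)
      if (length(found) >= max_paths) truncated <<- TRUE
      return()
    }
    for (v in nbrs[[u]]) {
      if (v %in% path) next
      nl <- len + W[u, v]
      if (nl > bound) next
      visit(c(path, v), nl)
    }
  }
  visit(si, 0)
  lens <- vapply(found, `[[`, numeric(1), "length")
  ord <- order(lens, vapply(found, function(p) {
    paste(sprintf("%04d", p$path), collapse = "")
  }, character(1)))
  out <- tibble(
    path = lapply(found[ord], function(p) rg$labels[p$path]),
    length = lens[ord]
  )
  out$optimal <- seq_len(nrow(out)) == 1
  structure(out, class = c("path_set", class(out)),
            source = source, sink = sink, cutoff_ratio = cutoff_ratio,
            truncated = truncated)
}

#' Dynamic community detection
#'
#' Divisive (Girvan-Newman) clustering: edges are removed in order of
#' highest edge betweenness computed with the coupling weights w as
#' distances, and the partition kept is the one maximising modularity with
#' edge affinity |C| as strength. Ties break on the lowest edge index, so
#' the result is deterministic. Disconnected components are never merged.
#'
#' @param rg A residue graph.
#' @return List: `membership` (named integer vector), `modularity`,
#'   `n_communities`.
#' @export
detect_communities <- function(rg) {
  if (!nrow(rg$edges)) abort("graph has no edges")
  g <- rg$graph
  strength_w <- abs(igraph::E(g)$C)
  best_mod <- -Inf
  best_mem <- igraph::components(g)$membership
  work <- g
  repeat {
    mem <- igraph::components(work)$membership
    mod <- igraph::modularity(g, mem[igraph::V(g)$name],
                              weights = strength_w)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
    if (igraph::ecount(work) == 0) break
    eb <- igraph::edge_betweenness(work, weights = igraph::E(work)$w)
    drop <- which(eb == max(eb))[1]
    work <- igraph::delete_edges(work, drop)
  }
  membership <- best_mem[rg$labels]
  names(membership) <- rg$labels
  list(membership = membership, modularity = best_mod,
       n_communities = length(unique(membership)))
}

#' Current-flow information betweenness
#'
#' Treats A_ij = |C_ij| * M_ij as conductances, injects one unit of current
#' at the source and drains it at the sink: potentials solve the reduced
#' Laplacian system (sink grounded), and the flow through node i is
#' f_i = 1/2 sum_j |P_i - P_j| A_ij, with f_source = f_sink = 1 by the
#' unit-supply convention.
#'
#' @param A Symmetric nonnegative conductance matrix (dimnames = node
#'   labels).
#' @param source,sink Node labels or indices.
#' @return Object of class `flow_profile`: tibble `node, flow, potential`,
#'   with source/sink attributes.
#' @export
information_flow <- function(A, source, sink) {
  A <- as.matrix(A)
  if (any(A < -1e-12)) abort("conductances must be nonnegative")
  diag(A) <- 0
  n <- nrow(A)
  labs <- rownames(A) %||% as.character(seq_len(n))
  si <- if (is.character(source)) match(source, labs) else as.integer(source)
  ti <- if (is.character(sink)) match(sink, labs) else as.integer(sink)
  if (is.na(si) || is.na(ti) || si == ti) abort("invalid source/sink")
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  if (comp[si] != comp[ti]) {
    abort("source and sink lie in different components")
  }
  L <- diag(rowSums(A)) - A
  keep <- setdiff(which(comp == comp[si]), ti)
  b <- rep(0, length(keep))
  b[match(si, keep)] <- 1
  Lred <- L[keep, keep, drop = FALSE]
  P <- rep(0, n)
  sol <- tryCatch(solve(Lred, b), error = function(e) {
    abort("reduced Laplacian is singular (disconnected conductance graph)")
  })
  P[keep] <- sol
  flow <- unname(0.5 * rowSums(abs(outer(P, P, "-")) * A))
  flow[c(si, ti)] <- 1
  out <- tibble(node = labs, flow = flow, potential = unname(P))
  structure(out, class = c("flow_profile", class(out)),
            source = labs[si], sink = labs[ti])
}

#' Build the mutual-information conductance matrix
#'
#' A_ij = |C_ij| * M_ij on contact edges (zero elsewhere).
#'
#' @param C Correlation matrix.
#' @param M Mutual-information matrix (same ordering).
#' @param adjacency Logical contact matrix (default: all off-diagonal).
#' @return Conductance matrix.
#' @export
conductance_matrix <- function(C, M, adjacency = NULL) {
  A <- abs(C) * M
  if (!is.null(adjacency)) A[!adjacency] <- 0
  diag(A) <- 0
  A[A < 0] <- 0
  A
}

#' Rank nodes by information flow
#'
#' @param flow A [information_flow()] profile.
#' @param highlight_threshold Nodes with flow strictly above this are
#'   highlighted (default 0.02).
#' @param drop_endpoints Exclude source/sink rows from the ranking.
#' @return Tibble `node, flow, highlight`, sorted by flow descending.
#' @export
flow_profile_report <- function(flow, highlight_threshold = 0.02,
                                drop_endpoints = TRUE) {
  out <- as_tibble(flow)[, c("node", "flow")]
  if (drop_endpoints) {
    out <- out[!out$node %in% c(attr(flow, "source"), attr(flow, "sink")), ]
  }
  out <- out[order(-out$flow, out$node), ]
  out$highlight <- out$flow > highlight_threshold
  out
}
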