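# Programmatic fixtures shared across the suite. Everything is built in
# code; nothing is read from disk except files the tests write themselves.

# Minimal 4-chain channel-like topology: S4 (205-225) and S6 (307-325)
# C-alpha traces per chain, plus charged-group atoms for R207/R210/R213
# (CZ) and E219 (CD). Chains sit at the corners of a square; helices are
# vertical so tilt and displacement fixtures are easy to script.
make_channel_fixture <- function() {
  chains <- c("A", "B", "C", "D")
  offs <- list(A = c(15, 15), B = c(-15, 15), C = c(-15, -15),
               D = c(15, -15))
  rows <- list()
  xyz <- list()
  aid <- 0
  for (ch in chains) {
    o <- offs[[ch]]
    for (res in 205:225) {
      aid <- aid + 1
      resname <- if (res %in% c(207, 210, 213)) "ARG" else
        if (res == 219) "GLU" else "ALA"
      rows[[aid]] <- data.frame(atom_id = aid, name = "CA", resid = res,
                                resname = resname, chain = ch,
                                element = "C")
      xyz[[aid]] <- c(o[1], o[2], (res - 215) * 1.5)
      if (resname %in% c("ARG", "GLU")) {
        aid <- aid + 1
        nm <- if (resname == "ARG") "CZ" else "CD"
        rows[[aid]] <- data.frame(atom_id = aid, name = nm, resid = res,
                                  resname = resname, chain = ch,
                                  element = "C")
        xyz[[aid]] <- c(o[1] + 2, o[2], (res - 215) * 1.5)
      }
    }
    for (res in 307:325) {
      aid <- aid + 1
      rows[[aid]] <- data.frame(atom_id = aid, name = "CA", resid = res,
                                resname = "LEU", chain = ch,
                                element = "C")
      xyz[[aid]] <- c(o[1] / 3, o[2] / 3, (res - 316) * 1.5)
    }
  }
  atoms <- do.call(rbind, rows)
  coords <- do.call(rbind, xyz)
  list(topology = new_topology(atoms),
       trajectory = new_trajectory(coords, c(80, 80, 80)))
}

# ideal straight helix of n CA atoms: rise 1.5 A/residue, radius 2.3 A,
# 100 degrees per residue, tilted by `tilt_deg` about the y axis
make_helix_coords <- function(n = 12, tilt_deg = 0) {
  t <- seq_len(n)
  xyz <- cbind(2.3 * cos(t * 100 * pi / 180),
               2.3 * sin(t * 100 * pi / 180),
               1.5 * t)
  th <- tilt_deg * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  xyz %*% t(R)
}

# topology of n identical beads with charges/radii assigned
make_bead_topology <- function(n, charge = 0, radius = 1.5,
                               resname = "BEA", name = "C") {
  new_topology(tibble::tibble(
    atom_id = seq_len(n), name = name, resid = seq_len(n),
    resname = resname, chain = "A", element = "C",
    charge = rep_len(charge, n), radius = rep_len(radius, n)
  ))
}

# independent quaternion-based superposition + RMSD oracle (Horn's method),
# used to cross-check the Kabsch-based implementation
quaternion_rmsd <- function(ref, mob) {
  rc <- colMeans(ref); mc <- colMeans(mob)
  A <- sweep(ref, 2, rc); B <- sweep(mob, 2, mc)
  M <- t(B) %*% A
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- B %*% t(R)
  sqrt(mean(rowSums((fitted - A)^2)))
}

# exhaustive simple-path enumeration oracle for small graphs
enumerate_paths_oracle <- function(W, s, t) {
  n <- nrow(W)
  res <- list()
  visit <- function(path, len) {
    u <- path[length(path)]
    if (u == t) {
      res[[length(res) + 1]] <<- list(path = path, length = len)
      return()
    }
    for (v in seq_len(n)) {
      if (is.finite(W[u, v]) && W[u, v] > 0 && !(v %in% path)) {
        visit(c(path, v), len + W[u, v])
      }
    }
  }
  visit(s, 0)
  res
}

# random connected weighted graph on n nodes (weight matrix, Inf = no edge)
random_graph_W <- function(n, p = 0.45) {
  repeat {
    W <- matrix(Inf, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        W[i, j] <- W[j, i] <- stats::runif(1, 0.2, 2)
      }
    }
    diag(W) <- 0
    g <- igraph::graph_from_adjacency_matrix(is.finite(W) & W > 0,
                                             mode = "undirected")
    if (igraph::components(g)$no == 1) return(W)
  }
}

# wrap a weight matrix as a residue_graph (labels 01..n for lexicographic
# determinism)
graph_from_W <- function(W) {
  n <- nrow(W)
  labs <- sprintf("%02d", seq_len(n))
  C <- exp(-W)            # so that -log|C| recovers W
  C[!is.finite(W)] <- 0
  diag(C) <- 1
  dimnames(C) <- list(labs, labs)
  adj <- is.finite(W) & W > 0
  dimnames(adj) <- dimnames(C)
  build_graph(adj, C)
}
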