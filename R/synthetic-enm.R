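# Elastic-network trajectory generator: i.i.d. Gaussian frames with the
# exact covariance implied by a spring Hessian at temperature T. Serves as
# ground truth for correlation, community and information-flow analyses.

#' Specify a synthetic elastic network
#'
#' Defines an anisotropic elastic network of C-alpha beads: equilibrium
#' coordinates, harmonic springs, temperature, and (optionally) a planted
#' community partition used later to score community recovery.
#'
#' @param equilibrium_coordinates `[n, 3]` matrix of bead positions (A).
#' @param springs Data frame with columns `i`, `j`, `k` (spring constant,
#'   kcal mol^-1 A^-2).
#' @param temperature Kelvin.
#' @param planted_partition Optional integer vector of community labels,
#'   length n.
#' @param seed RNG seed (mandatory: generators are reproducible by
#'   construction).
#' @return Object of class `elastic_network_spec`.
#' @export
elastic_network_spec <- function(equilibrium_coordinates, springs,
                                 temperature = 300, planted_partition = NULL,
                                 seed) {
  xyz <- as.matrix(equilibrium_coordinates)
  stopifnot(ncol(xyz) == 3)
  n <- nrow(xyz)
  springs <- as_tibble(springs)
  stopifnot(all(c("i", "j", "k") %in% names(springs)))
  if (any(springs$i == springs$j)) abort("self-springs are not allowed")
  if (any(springs$k <= 0)) abort("spring constants must be positive")
  g <- igraph::graph_from_edgelist(cbind(springs$i, springs$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1) {
    abort("spring graph is disconnected")
  }
  if (!is.null(planted_partition) && length(planted_partition) != n) {
    abort("planted_partition length must equal the number of residues")
  }
  if (missing(seed)) abort("seed is a mandatory field")
  structure(list(n_residues = n, xyz = xyz, springs = springs,
                 temperature = temperature,
                 planted_partition = planted_partition, seed = seed),
            class = "elastic_network_spec")
}

enm_hessian <- function(spec) {
  n <- spec$n_residues
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(spec$springs))) {
    i <- spec$springs$i[r]; j <- spec$springs$j[r]; k <- spec$springs$k[r]
    d <- spec$xyz[j, ] - spec$xyz[i, ]
    e <- d / sqrt(sum(d^2))
    K <- k * tcrossprod(e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  H
}

# residue-residue correlation implied by a 3n x 3n covariance
residue_correlation_from_cov <- function(sigma, n) {
  tr_block <- function(i, j) {
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    sum(diag(sigma[ii, jj, drop = FALSE]))
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    C[i, j] <- C[j, i] <- tr_block(i, j)
  }
  d <- sqrt(diag(C))
  C / tcrossprod(d)
}

#' Sample an elastic-network trajectory
#'
#' Frames are i.i.d. draws from the multivariate Gaussian with covariance
#' `kB*T * H^+`, where `H` is the spring Hessian and `H^+` its
#' pseudo-inverse with rigid-body (near-zero) modes removed. The exact
#' covariance and residue-residue correlation used are returned alongside,
#' so downstream estimators can be scored against ground truth.
#'
#' @param spec An [elastic_network_spec()].
#' @param n_frames_sim Number of frames to draw.
#' @param time_step ns per frame (presentation only; frames are i.i.d.).
#' @return List: `trajectory`, `topology` (C-alpha beads), `covariance`
#'   (3n x 3n, A^2), `correlation` (n x n), `partition` (planted labels or
#'   NULL).
#' @export
sample_elastic_network <- function(spec, n_frames_sim = 1000, time_step = 1) {
  n <- spec$n_residues
  H <- enm_hessian(spec)
  eg <- eigen(H, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  keep <- eg$values > tol
  # a generic 3-D network sheds exactly its 6 rigid-body modes here;
  # degenerate fixtures (e.g. a dimer) shed more, which the tolerance handles
  kBT <- kB_KCAL * spec$temperature
  sigma <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) * (kBT / eg$values[keep]))
  set.seed(spec$seed)
  amp <- sqrt(kBT / eg$values[keep])
  nm <- sum(keep)
  coords <- array(0, c(n, 3, n_frames_sim))
  mu <- as.vector(t(spec$xyz))
  V <- eg$vectors[, keep, drop = FALSE]
  z <- matrix(rnorm(nm * n_frames_sim), nm, n_frames_sim) * amp
  X <- V %*% z + mu
  for (f in seq_len(n_frames_sim)) {
    coords[, , f] <- matrix(X[, f], ncol = 3, byrow = TRUE)
  }
  if (spec$temperature == 0) {
    for (f in seq_len(n_frames_sim)) coords[, , f] <- spec$xyz
  }
  box <- apply(spec$xyz, 2, function(v) diff(range(v))) + 30
  atoms <- tibble(
    atom_id = seq_len(n), name = "CA", resid = seq_len(n),
    resname = "GLY", chain = "A", element = "C"
  )
  list(
    trajectory = new_trajectory(coords, box, time_step = time_step),
    topology = new_topology(atoms),
    covariance = sigma,
    correlation = residue_correlation_from_cov(sigma, n),
    partition = spec$planted_partition
  )
}

#' Build a two-block planted-community elastic network
#'
#' Two spatially separated blocks of beads with strong intra-block springs
#' and a few weak inter-block springs: community structure is known by
#' construction (labels 1 and 2).
#'
#' @param n_per_block Beads per block.
#' @param k_intra,k_inter Spring constants (kcal mol^-1 A^-2); contrast
#'   `k_intra >> k_inter` makes the partition recoverable.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return An [elastic_network_spec()] with `planted_partition` set.
#' @export
two_block_network <- function(n_per_block = 8, k_intra = 10, k_inter = 0.5,
                              temperature = 300, seed) {
  set.seed(seed)
  n <- 2 * n_per_block
  xyz <- rbind(
    matrix(rnorm(3 * n_per_block, sd = 3), ncol = 3),
    matrix(rnorm(3 * n_per_block, sd = 3), ncol = 3) +
      matrix(c(20, 0, 0), n_per_block, 3, byrow = TRUE)
  )
  intra <- function(off) {
    pr <- t(utils::combn(n_per_block, 2)) + off
    tibble(i = pr[, 1], j = pr[, 2], k = k_intra)
  }
  bridge <- tibble(i = c(1, 2), j = c(n_per_block + 1, n_per_block + 2),
                   k = k_inter)
  elastic_network_spec(
    xyz, dplyr::bind_rows(intra(0), intra(n_per_block), bridge),
    temperature = temperature,
    planted_partition = rep(1:2, each = n_per_block), seed = seed
  )
}
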