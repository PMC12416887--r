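# Gaussian-mixture entropy and mutual information between residue nodes.
# The per-node coordinate x is the scalar distance of the node to its mean
# (equilibrium) position; densities are estimated with Gaussian mixtures
# selected by BIC over 1-5 components (deterministic model-based
# initialisation on a fixed subset, so no RNG enters the estimate).

gmm_fit_density <- function(x, max_components = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 100) abort("need at least 100 samples for a GMM density")
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-10)) abort("degenerate (zero-variance) samples")
  init <- if (n > 2000) list(subset = round(seq(1, n, length.out = 1000)))
    else NULL
  fit <- mclust::densityMclust(
    if (ncol(x) == 1) x[, 1] else x,
    G = 1:max_components, plot = FALSE, verbose = FALSE,
    initialization = init
  )
  fit
}

#' Gaussian-mixture differential entropy of samples
#'
#' Fits a GMM (components chosen by BIC over 1-5) and returns the sample
#' mean of -ln rho_hat(x), in nats. Works for 1-D (node entropy) and 2-D
#' (joint entropy) samples.
#'
#' @param x Numeric vector or 2-column matrix of samples (>= 100).
#' @param max_components BIC search range upper bound.
#' @return Entropy in nats.
#' @export
gmm_entropy <- function(x, max_components = 5) {
  fit <- gmm_fit_density(x, max_components)
  d <- pmax(fit$density, 1e-300)
  mean(-log(d))
}

node_distance_series <- function(trajectory, topology, selection) {
  idx <- resolve_indices(topology, selection, "node selection")
  nf <- n_frames(trajectory)
  vapply(idx, function(i) {
    xyz <- t(trajectory$coords[i, , ])
    mu <- colMeans(xyz)
    sqrt(rowSums(sweep(xyz, 2, mu)^2))
  }, numeric(nf))
}

#' Node fluctuation entropy
#'
#' H_i = mean of -ln rho_i(x) with x the per-frame distance of the node
#' atom to its mean position and rho the BIC-selected GMM density.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param node Selection resolving to one atom (e.g. `"resid 213 and name
#'   CA and chain A"`).
#' @return Entropy in nats.
#' @export
node_entropy <- function(trajectory, topology, node) {
  x <- node_distance_series(trajectory, topology, node)
  if (ncol(x) != 1) abort("node selection must resolve to a single atom")
  gmm_entropy(x[, 1])
}

#' Pairwise mutual information between two nodes
#'
#' M_ij = H_i + H_j - H_ij with the joint entropy from a 2-D GMM on the
#' pair of distance-to-mean coordinates. Slightly negative estimates are
#' clipped to zero with a warning; identical nodes short-circuit to
#' M = H_i (degenerate joint density).
#'
#' @param trajectory,topology Trajectory and topology.
#' @param node_i,node_j Single-atom selections.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(trajectory, topology, node_i, node_j) {
  xi <- node_distance_series(trajectory, topology, node_i)[, 1]
  xj <- node_distance_series(trajectory, topology, node_j)[, 1]
  mutual_information_samples(xi, xj)
}

#' @rdname mutual_information
#' @param xi,xj Precomputed scalar coordinate series.
#' @export
mutual_information_samples <- function(xi, xj) {
  if (sd(xi - xj) < 1e-10 || abs(stats::cor(xi, xj)) > 1 - 1e-12) {
    # duplicated node: H_ij = H_i, so M = H_i
    return(gmm_entropy(xi))
  }
  m <- gmm_entropy(xi) + gmm_entropy(xj) - gmm_entropy(cbind(xi, xj))
  if (m < 0) {
    if (m < -0.2) {
      warn(paste0("mutual information estimate ", signif(m, 3),
                  " clipped to 0"))
    }
    m <- 0
  }
  m
}

#' Mutual-information matrix over nodes
#'
#' @param trajectory,topology Trajectory and topology.
#' @param selection Node atoms (one per node).
#' @return Symmetric matrix of M_ij (nats); diagonal holds H_i.
#' @export
mutual_information_matrix <- function(trajectory, topology,
                                      selection = "name CA") {
  X <- node_distance_series(trajectory, topology, selection)
  n <- ncol(X)
  idx <- resolve_indices(topology, selection)
  labs <- paste0(topology$atoms$resid[idx], ".",
                 topology$atoms$chain[idx])
  M <- matrix(0, n, n, dimnames = list(labs, labs))
  H <- vapply(seq_len(n), function(i) gmm_entropy(X[, i]), numeric(1))
  diag(M) <- H
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hij <- gmm_entropy(cbind(X[, i], X[, j]))
    M[i, j] <- M[j, i] <- max(0, H[i] + H[j] - hij)
  }
  M
}
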