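# Residue-residue contacts: minimal heavy-atom distance <= 5 A in at least
# 75% of frames (occupancy rule used to define network edges).

#' Residue contact map with occupancies
#'
#' For every residue pair across two selections, computes the fraction of
#' frames in which the minimal heavy-atom distance is within `cutoff`
#' (occupancy), and flags a contact when occupancy >= `occupancy`.
#' Hydrogens are excluded; self-pairs are skipped.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param selection_a,selection_b Selections (object/expression/indices)
#'   defining the two residue groups.
#' @param cutoff Distance cutoff, A (default 5).
#' @param occupancy Occupancy threshold (default 0.75).
#' @return Tibble `resid_a, chain_a, resid_b, chain_b, occupancy, contact`.
#' @export
residue_contact_map <- function(trajectory, topology, selection_a,
                                selection_b = selection_a, cutoff = 5,
                                occupancy = 0.75) {
  at <- topology$atoms
  heavy <- !is_hydrogen(at$element, at$name)
  ia <- intersect(resolve_indices(topology, selection_a, "selection_a"),
                  which(heavy))
  ib <- intersect(resolve_indices(topology, selection_b, "selection_b"),
                  which(heavy))
  if (!length(ia) || !length(ib)) abort("empty heavy-atom selection")
  key_a <- paste(at$resid[ia], at$chain[ia])
  key_b <- paste(at$resid[ib], at$chain[ib])
  ra <- unique(key_a); rb <- unique(key_b)
  ga <- match(key_a, ra); gb <- match(key_b, rb)
  nf <- n_frames(trajectory)
  hits <- matrix(0, length(ra), length(rb))
  for (f in seq_len(nf)) {
    xa <- trajectory$coords[ia, , f, drop = FALSE][, , 1]
    xb <- trajectory$coords[ib, , f, drop = FALSE][, , 1]
    if (length(ia) == 1) xa <- matrix(xa, nrow = 1)
    if (length(ib) == 1) xb <- matrix(xb, nrow = 1)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    within <- d2 <= cutoff^2 + 1e-12
    # min over atoms of each residue pair == any atom pair within cutoff
    mm <- matrix(FALSE, length(ra), length(rb))
    w <- which(within, arr.ind = TRUE)
    if (nrow(w)) {
      mm[cbind(ga[w[, 1]], gb[w[, 2]])] <- TRUE
    }
    hits <- hits + mm
  }
  occ <- hits / nf
  pa <- do.call(rbind, strsplit(ra, " "))
  pb <- do.call(rbind, strsplit(rb, " "))
  grid <- expand.grid(a = seq_along(ra), b = seq_along(rb))
  out <- tibble(
    resid_a = as.integer(pa[grid$a, 1]), chain_a = pa[grid$a, 2],
    resid_b = as.integer(pb[grid$b, 1]), chain_b = pb[grid$b, 2],
    occupancy = occ[cbind(grid$a, grid$b)]
  )
  out <- out[!(out$resid_a == out$resid_b & out$chain_a == out$chain_b), ]
  out$contact <- out$occupancy >= occupancy
  out
}
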