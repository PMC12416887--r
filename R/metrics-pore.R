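# Pore geometry and hydration: HOLE-style maximum-inscribed-sphere radius
# profiles along the channel axis, and the pore-water counter bounded by the
# L312 ring below and the P320 centre-of-mass plane above.

slice_radius <- function(center_xy, z, xyz, radii, cap) {
  d <- sqrt((xyz[, 1] - center_xy[1])^2 + (xyz[, 2] - center_xy[2])^2 +
              (xyz[, 3] - z)^2) - radii
  min(c(d, cap))
}

#' Pore radius profile
#'
#' For each z slice, finds the largest sphere centred on the slice that
#' touches no atom: radius(c) = min over atoms of (distance to atom centre
#' minus its van der Waals radius), maximised over candidate centres. The
#' centre search scans a coarse xy grid (0.25 A) around `axis_hint` and then
#' refines locally (Nelder-Mead); the result is deterministic. Slices with
#' no atoms nearby report the bulk sentinel `cap`.
#'
#' @param trajectory,topology Trajectory (frame `frame` used) and topology
#'   with vdW radii assigned.
#' @param frame Frame index.
#' @param axis_hint Length-2 xy of the approximate pore axis (default from
#'   the geometric centre of all atoms).
#' @param z_range `c(z_min, z_max)` of the profile.
#' @param dz Slice spacing, A (default 0.5).
#' @param search_radius Lateral half-width of the centre search, A.
#' @param cap Bulk sentinel radius, A.
#' @return Object of class `pore_profile`: tibble `z, radius, x, y`
#'   (refined centre per slice).
#' @export
pore_radius_profile <- function(trajectory, topology, frame = 1,
                                axis_hint = NULL, z_range = NULL, dz = 0.5,
                                search_radius = 4, cap = 15) {
  at <- topology$atoms
  if (anyNA(at$radius)) abort("vdW radii must be assigned (assign_parameters)")
  xyz <- frame_coords(trajectory, frame)
  heavy <- !is_hydrogen(at$element, at$name)
  xyz <- xyz[heavy, , drop = FALSE]
  radii <- at$radius[heavy]
  if (is.null(axis_hint)) axis_hint <- colMeans(xyz[, 1:2, drop = FALSE])
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  zs <- seq(z_range[1], z_range[2], by = dz)
  grid_step <- 0.25
  gx <- seq(-search_radius, search_radius, by = grid_step)
  cand <- as.matrix(expand.grid(x = gx + axis_hint[1],
                                y = gx + axis_hint[2]))
  rows <- purrr::map_dfr(zs, function(z) {
    near <- abs(xyz[, 3] - z) <= cap + max(radii)
    if (!any(near)) {
      return(tibble(z = z, radius = cap,
                    x = axis_hint[1], y = axis_hint[2]))
    }
    sub <- xyz[near, , drop = FALSE]
    sr <- radii[near]
    vals <- vapply(seq_len(nrow(cand)), function(k) {
      slice_radius(cand[k, ], z, sub, sr, cap)
    }, numeric(1))
    # refine from several coarse starts: the radius field is a min of
    # cones, so a single local search can sit on the wrong ridge
    starts <- head(order(vals, decreasing = TRUE), 8)
    r <- vals[starts[1]]
    ctr <- cand[starts[1], ]
    for (s in starts) {
      ref <- optim(cand[s, ], function(p) {
        # keep the centre search inside the stated box around the axis
        if (any(abs(p - axis_hint) > search_radius)) return(Inf)
        -slice_radius(p, z, sub, sr, cap)
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-8, maxit = 200))
      if (-ref$value > r) {
        r <- -ref$value
        ctr <- ref$par
      }
    }
    tibble(z = z, radius = max(0, min(r, cap)), x = ctr[1], y = ctr[2])
  })
  structure(rows, class = c("pore_profile", class(rows)), cap = cap)
}

#' Count pore waters per frame
#'
#' Pore waters occupy the inner cavity below the selectivity filter: z
#' between the centre of mass of the lower boundary residue ring (default
#' L312) and the plane through the centre of mass of the upper boundary
#' ring (default P320), and within `lateral_radius` of the pore axis. The
#' water O position is used.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param water_selection Selection of water bead/O atoms.
#' @param lower_residue,upper_residue Boundary residue numbers (all chains
#'   must contain them).
#' @param lateral_radius Lateral bound, A (default 10): the published
#'   definition is z-based and needs a lateral cut to exclude bulk waters.
#' @return Tibble `time_ns, value` (counts).
#' @export
count_pore_waters <- function(trajectory, topology, water_selection,
                              lower_residue = 312, upper_residue = 320,
                              lateral_radius = 10) {
  at <- topology$atoms
  wi <- resolve_indices(topology, water_selection, "water selection")
  lo_idx <- which(at$resid == lower_residue)
  hi_idx <- which(at$resid == upper_residue)
  if (!length(lo_idx) || !length(hi_idx)) {
    abort(paste0("boundary residues ", lower_residue, "/", upper_residue,
                 " not found in topology"))
  }
  m_lo <- element_mass(at$element[lo_idx])
  m_hi <- element_mass(at$element[hi_idx])
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    xyz <- trajectory$coords[, , f]
    z_lo <- sum(xyz[lo_idx, 3] * m_lo) / sum(m_lo)
    z_hi <- sum(xyz[hi_idx, 3] * m_hi) / sum(m_hi)
    axis_xy <- colMeans(xyz[c(lo_idx, hi_idx), 1:2, drop = FALSE])
    w <- xyz[wi, , drop = FALSE]
    inside <- w[, 3] >= min(z_lo, z_hi) & w[, 3] <= max(z_lo, z_hi) &
      (w[, 1] - axis_xy[1])^2 + (w[, 2] - axis_xy[2])^2 <= lateral_radius^2
    sum(inside)
  }, numeric(1))
  tibble(time_ns = frame_times(trajectory), value = vals)
}

#' Count in-cylinder beads against fixed planes
#'
#' Low-level counter used when boundary planes are known directly (e.g. for
#' scripted systems): beads with z in `[z_lo, z_hi]` and within
#' `lateral_radius` of the axis.
#'
#' @param trajectory A trajectory.
#' @param indices Atom indices to count.
#' @param z_lo,z_hi Plane heights, A.
#' @param lateral_radius Lateral bound, A.
#' @param axis_xy Pore axis xy (default c(0, 0)).
#' @return Tibble `time_ns, value`.
#' @export
count_in_region <- function(trajectory, indices, z_lo, z_hi,
                            lateral_radius = 10, axis_xy = c(0, 0)) {
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    w <- trajectory$coords[indices, , f, drop = FALSE][, , 1]
    if (length(indices) == 1) w <- matrix(w, nrow = 1)
    sum(w[, 3] >= z_lo & w[, 3] <= z_hi &
          (w[, 1] - axis_xy[1])^2 + (w[, 2] - axis_xy[2])^2 <=
          lateral_radius^2)
  }, numeric(1))
  tibble(time_ns = frame_times(trajectory), value = vals)
}
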