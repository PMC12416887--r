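# Per-frame conformational observables: charged-group z-displacement, helix
# centre-of-mass displacement, helix tilt, backbone RMSD, membrane thickness,
# and lateral free-energy surfaces. All return tidy tibbles keyed by
# time_ns/chain so results chain with dplyr verbs.

#' Centred running average of a value column
#'
#' @param x Numeric vector.
#' @param window Window size in frames (centred); `1` returns `x`.
#' @return Numeric vector of the same length.
#' @export
running_average <- function(x, window = 50) {
  if (window < 1) abort("averaging window must be >= 1")
  if (window == 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

helix_residues <- function(topology, helix) {
  if (!helix %in% names(topology$helices)) {
    abort(paste0("helix '", helix, "' is not defined in the topology"))
  }
  rg <- topology$helices[[helix]]
  seq(rg[1], rg[2])
}

#' z-displacement of residue charged groups
#'
#' Tracks the representative charged-group atom of each residue (Arg:
#' guanidinium CZ; Asp/Glu: side-chain carboxyl carbon) relative to a
#' reference frame, per chain, plus the across-chain mean (rows with
#' `chain == "mean"`) since equivalent subunits share residue numbers.
#'
#' @param trajectory,topology Trajectory and its topology.
#' @param residues Integer residue numbers (Arg/Asp/Glu/Lys).
#' @param reference_frame Frame index used as zero (default 1).
#' @return Tibble `time_ns, residue, chain, value` (value in A).
#' @export
charged_group_z_displacement <- function(trajectory, topology, residues,
                                         reference_frame = 1) {
  at <- topology$atoms
  tms <- frame_times(trajectory)
  out <- purrr::map_dfr(residues, function(res) {
    rows <- which(at$resid == res)
    if (!length(rows)) abort(paste0("residue ", res, " not in topology"))
    rep_atom <- charged_group_atom(at$resname[rows[1]])
    if (is.na(rep_atom)) {
      abort(paste0("residue ", res, " (", at$resname[rows[1]],
                   ") has no charged-group convention"))
    }
    sel <- rows[at$name[rows] == rep_atom]
    if (!length(sel)) {
      abort(paste0("representative atom ", rep_atom,
                   " missing for residue ", res))
    }
    z <- trajectory$coords[sel, 3, , drop = FALSE]  # [chains, 1, frames]
    z0 <- z[, 1, reference_frame]
    dz <- sweep(z[, 1, , drop = TRUE], 1, z0)
    if (length(sel) == 1) dz <- matrix(dz, nrow = 1)
    chains <- at$chain[sel]
    per_chain <- purrr::map_dfr(seq_along(sel), function(k) {
      tibble(time_ns = tms, residue = res, chain = chains[k],
             value = dz[k, ])
    })
    mean_rows <- tibble(time_ns = tms, residue = res, chain = "mean",
                        value = colMeans(dz))
    dplyr::bind_rows(per_chain, mean_rows)
  })
  out
}

com_xyz <- function(xyz, masses) {
  colSums(xyz * masses) / sum(masses)
}

#' Helix centre-of-mass displacement
#'
#' Displacement of the centre of mass of a helix relative to a reference
#' frame: along z, or in the membrane plane (`axis = "xy"`, where `value`
#' is the lateral displacement magnitude and `x`, `y` give the components).
#'
#' @param trajectory,topology Trajectory and topology.
#' @param helix Helix name defined in the topology (e.g. `"S4"`).
#' @param reference_frame Zero-point frame (default 1).
#' @param axis `"z"` or `"xy"`.
#' @param mass_weighted Mass-weighted (default) or geometric COM.
#' @return Tibble `time_ns, chain, value` (+ `x`, `y` for `axis = "xy"`).
#' @export
helix_com_displacement <- function(trajectory, topology, helix,
                                   reference_frame = 1,
                                   axis = c("z", "xy"),
                                   mass_weighted = TRUE) {
  axis <- match.arg(axis)
  at <- topology$atoms
  resids <- helix_residues(topology, helix)
  idx <- which(at$resid %in% resids)
  if (!length(idx)) abort(paste0("helix ", helix, " selects no atoms"))
  tms <- frame_times(trajectory)
  purrr::map_dfr(unique(at$chain[idx]), function(ch) {
    sel <- idx[at$chain[idx] == ch]
    m <- if (mass_weighted) element_mass(at$element[sel]) else
      rep(1, length(sel))
    coms <- t(vapply(seq_len(n_frames(trajectory)), function(f) {
      com_xyz(trajectory$coords[sel, , f, drop = FALSE][, , 1], m)
    }, numeric(3)))
    ref <- coms[reference_frame, ]
    d <- sweep(coms, 2, ref)
    if (axis == "z") {
      tibble(time_ns = tms, chain = ch, value = d[, 3])
    } else {
      tibble(time_ns = tms, chain = ch,
             value = sqrt(d[, 1]^2 + d[, 2]^2), x = d[, 1], y = d[, 2])
    }
  })
}

principal_axis_tilt <- function(xyz) {
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  nc <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(axis * nc) < 0) axis <- -axis
  # fold to [0, 90]: angle between the axis line and the membrane normal
  acos(min(1, abs(axis[3]) / sqrt(sum(axis^2)))) * 180 / pi
}

#' Helix tilt angle
#'
#' Angle between the helix principal axis (first principal component of the
#' C-alpha coordinates, oriented N to C) and the membrane normal (+z),
#' folded into 0-90 degrees. At least four C-alpha atoms are required.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param helix Helix name.
#' @param residue_subset Optional residue numbers restricting the segment
#'   (e.g. 313-324 for the lower half of S6).
#' @return Tibble `time_ns, chain, value` (degrees).
#' @export
helix_tilt_angle <- function(trajectory, topology, helix,
                             residue_subset = NULL) {
  at <- topology$atoms
  resids <- helix_residues(topology, helix)
  if (!is.null(residue_subset)) resids <- intersect(resids, residue_subset)
  idx <- which(at$resid %in% resids & at$name == "CA")
  tms <- frame_times(trajectory)
  purrr::map_dfr(unique(at$chain[idx]), function(ch) {
    sel <- idx[at$chain[idx] == ch]
    sel <- sel[order(at$resid[sel])]
    if (length(sel) < 4) {
      abort(paste0("tilt needs >= 4 C-alpha atoms; got ", length(sel),
                   " in chain ", ch))
    }
    ang <- vapply(seq_len(n_frames(trajectory)), function(f) {
      principal_axis_tilt(trajectory$coords[sel, , f, drop = FALSE][, , 1])
    }, numeric(1))
    tibble(time_ns = tms, chain = ch, value = ang)
  })
}

#' Backbone RMSD to a reference
#'
#' Root-mean-square deviation of selected atoms to reference coordinates,
#' optionally after least-squares superposition (optimal rigid-body fit).
#'
#' @param trajectory,topology Trajectory and topology.
#' @param selection Selection (object, expression string, or indices).
#' @param reference_coordinates `[n_sel, 3]` matrix matching the selection
#'   1:1.
#' @param superpose Remove rigid-body motion first (default TRUE).
#' @return Tibble `time_ns, value` (A).
#' @export
backbone_rmsd <- function(trajectory, topology, selection,
                          reference_coordinates, superpose = TRUE) {
  idx <- resolve_indices(topology, selection)
  ref <- as.matrix(reference_coordinates)
  if (nrow(ref) != length(idx)) {
    abort(paste0("selection has ", length(idx), " atoms but reference has ",
                 nrow(ref), " rows"))
  }
  ref_xyz <- as.vector(t(ref))
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    mob <- as.vector(t(trajectory$coords[idx, , f, drop = FALSE][, , 1]))
    if (superpose) {
      mob <- bio3d::fit.xyz(ref_xyz, mob,
                            fixed.inds = seq_along(ref_xyz),
                            mobile.inds = seq_along(mob))
    }
    sqrt(sum((mob - ref_xyz)^2) / length(idx))
  }, numeric(1))
  tibble(time_ns = frame_times(trajectory), value = vals)
}

#' Membrane thickness from headgroup positions
#'
#' Per frame, headgroup atoms are split into leaflets about their mean z and
#' the thickness is the difference of leaflet mean heights. Invariant under
#' rigid translation of the whole system.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param headgroup_selection Selection of headgroup atoms.
#' @return Tibble `time_ns, value` (A).
#' @export
membrane_thickness <- function(trajectory, topology, headgroup_selection) {
  idx <- resolve_indices(topology, headgroup_selection,
                         "headgroup selection")
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    z <- trajectory$coords[idx, 3, f]
    mid <- mean(z)
    up <- z[z > mid]; dn <- z[z <= mid]
    if (!length(up) || !length(dn)) {
      abort("headgroup selection covers only one leaflet")
    }
    abs(mean(up) - mean(dn))
  }, numeric(1))
  tibble(time_ns = frame_times(trajectory), value = vals)
}

#' 2-D free-energy surface from lateral samples
#'
#' Bins samples on a regular 2-D grid and converts the occupancy P(x, y) to
#' a free energy F = -RT ln P, shifted so the minimum is zero. Empty bins
#' carry +Inf.
#'
#' @param samples_xy Data frame or matrix with two columns (x, y; A).
#' @param temperature Kelvin (default 300).
#' @param bin_width Bin width (A).
#' @return Object of class `fes2d`: tibble `x, y, free_energy` (bin
#'   centres, kcal/mol) with edge vectors in attributes.
#' @export
free_energy_surface_2d <- function(samples_xy, temperature = 300,
                                   bin_width = 0.5) {
  if (bin_width <= 0) abort("bin_width must be positive")
  xy <- as.matrix(samples_xy)[, 1:2, drop = FALSE]
  if (!nrow(xy)) abort("at least one sample is required")
  ex <- seq(floor(min(xy[, 1]) / bin_width) * bin_width,
            max(xy[, 1]) + bin_width, by = bin_width)
  ey <- seq(floor(min(xy[, 2]) / bin_width) * bin_width,
            max(xy[, 2]) + bin_width, by = bin_width)
  ix <- findInterval(xy[, 1], ex, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2], ey, rightmost.closed = TRUE)
  counts <- matrix(0, length(ex) - 1, length(ey) - 1)
  for (k in seq_len(nrow(xy))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  P <- counts / sum(counts)
  FE <- -R_KCAL * temperature * log(P)
  FE <- FE - min(FE[is.finite(FE)])
  centers_x <- ex[-length(ex)] + bin_width / 2
  centers_y <- ey[-length(ey)] + bin_width / 2
  out <- tibble(
    x = rep(centers_x, each = length(centers_y)),
    y = rep(centers_y, times = length(centers_x)),
    free_energy = as.vector(t(FE))
  )
  structure(out, class = c("fes2d", class(out)),
            x_edges = ex, y_edges = ey, temperature = temperature)
}
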