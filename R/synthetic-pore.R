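# Scripted pore trajectories: water beads placed inside a cylindrical pore
# region and ions following prescribed z(t) paths, with crossing counts and
# per-frame water occupancy known by construction.

#' Specify a scripted pore trajectory
#'
#' @param frames Number of frames.
#' @param box Length-3 box (A), z centred on 0.
#' @param pore_span `c(z_lo, z_hi)` of the pore region (A).
#' @param pore_radius Lateral pore radius (A) for water placement.
#' @param water_counts Integer vector (length `frames`, recycled if scalar):
#'   scripted number of in-pore water beads per frame.
#' @param bulk_waters Waters placed outside the pore region per frame (noise
#'   for the counter to reject).
#' @param ion_paths List of numeric vectors, one z(t) (length `frames`) per
#'   ion. Crossing counts are declared via [make_crossing_path()] or counted
#'   analytically at build time from the scripted path.
#' @param wrap Logical: wrap ion z into the box (paths leaving the box
#'   without `wrap = TRUE` are an error).
#' @param seed RNG seed for lateral placements.
#' @return Object of class `pore_script_spec`.
#' @export
pore_script_spec <- function(frames, box = c(40, 40, 60),
                             pore_span = c(-12, 12), pore_radius = 5,
                             water_counts = 0, bulk_waters = 0,
                             ion_paths = list(), wrap = FALSE, seed) {
  if (missing(seed)) abort("seed is a mandatory field")
  stopifnot(pore_span[1] < pore_span[2])
  water_counts <- rep_len(as.integer(water_counts), frames)
  for (p in ion_paths) {
    if (length(p) != frames) abort("every ion path must have one z per frame")
    if (!wrap && any(abs(p) > box[3] / 2)) {
      abort("ion path leaves the box; use wrap = TRUE for periodic imaging")
    }
  }
  structure(list(frames = frames, box = box, pore_span = pore_span,
                 pore_radius = pore_radius, water_counts = water_counts,
                 bulk_waters = bulk_waters, ion_paths = ion_paths,
                 wrap = wrap, seed = seed),
            class = "pore_script_spec")
}

# double-crossing count on an exact (unwrapped) scripted path: a path that
# advances several box lengths crosses one periodic image of the plane pair
# per box length, so crossings are summed over all relevant images
script_crossings <- function(z, lo, hi, box_z = Inf) {
  ks <- if (is.finite(box_z)) {
    seq(floor((min(z) - hi) / box_z), ceiling((max(z) - lo) / box_z))
  } else 0
  up <- 0L; down <- 0L
  for (k in ks) {
    shift <- if (k == 0) 0 else k * box_z
    l <- lo + shift; h <- hi + shift
    state <- if (z[1] < l) "below" else if (z[1] > h) "above" else "mid"
    for (t in seq_along(z)[-1]) {
      if (z[t] < l) {
        if (state == "above") down <- down + 1L
        state <- "below"
      } else if (z[t] > h) {
        if (state == "below") up <- up + 1L
        state <- "above"
      }
    }
  }
  c(up = up, down = down)
}

#' Build a monotone multi-crossing ion path
#'
#' A path that crosses the pore region bottom-to-top `n_crossings` times
#' (advancing one box length per crossing, to be wrapped periodically), so
#' the ground-truth crossing count is exact by construction.
#'
#' @param n_crossings Number of full upward crossings.
#' @param frames Path length in frames.
#' @param box_z Box z length (A).
#' @return Numeric z(t), unwrapped (use `wrap = TRUE` in the spec).
#' @export
make_crossing_path <- function(n_crossings, frames, box_z = 60) {
  seq(-box_z / 2 + 1, -box_z / 2 + 1 + n_crossings * box_z,
      length.out = frames)
}

#' Generate the scripted pore trajectory
#'
#' Waters are single beads (an O position suffices for the counter); in-pore
#' waters are placed uniformly inside the cylinder of `pore_radius` over
#' `pore_span`, bulk waters outside it. Ions follow their scripted z exactly
#' at x = y = 0.
#'
#' @param spec A [pore_script_spec()].
#' @param time_step ns per frame.
#' @return List: `trajectory`, `topology`, `ground_truth` (list with
#'   `crossings_up`, `crossings_down`, per-ion tibble `by_ion`, and
#'   `pore_waters` per frame).
#' @export
script_pore_trajectory <- function(spec, time_step = 1) {
  set.seed(spec$seed)
  n_ion <- length(spec$ion_paths)
  max_w <- max(spec$water_counts) + spec$bulk_waters
  n_at <- n_ion + max_w
  coords <- array(0, c(max(n_at, 1), 3, spec$frames))
  lo <- spec$pore_span[1]; hi <- spec$pore_span[2]
  half_z <- spec$box[3] / 2
  for (f in seq_len(spec$frames)) {
    row <- 0
    for (i in seq_len(n_ion)) {
      z <- spec$ion_paths[[i]][f]
      if (spec$wrap) z <- z - spec$box[3] * round(z / spec$box[3])
      coords[i, , f] <- c(0, 0, z)
      row <- i
    }
    nw <- spec$water_counts[f]
    if (nw > 0) {
      r <- spec$pore_radius * sqrt(stats::runif(nw)) * 0.98
      th <- stats::runif(nw, 0, 2 * pi)
      zz <- stats::runif(nw, lo + 0.1, hi - 0.1)
      coords[row + seq_len(nw), , f] <- cbind(r * cos(th), r * sin(th), zz)
      row <- row + nw
    }
    extra <- max_w - nw
    if (extra > 0) {
      # parked well above the pore region (bulk phase)
      coords[row + seq_len(extra), , f] <-
        cbind(stats::runif(extra, -spec$box[1] / 4, spec$box[1] / 4),
              stats::runif(extra, -spec$box[2] / 4, spec$box[2] / 4),
              stats::runif(extra, hi + 5, half_z - 1))
    }
  }
  atoms <- tibble(
    atom_id = seq_len(max(n_at, 1)),
    name = c(rep("K", n_ion), rep("O", max_w))[seq_len(max(n_at, 1))],
    resid = seq_len(max(n_at, 1)),
    resname = c(rep("POT", n_ion), rep("HOH", max_w))[seq_len(max(n_at, 1))],
    chain = "A",
    element = c(rep("K", n_ion), rep("O", max_w))[seq_len(max(n_at, 1))]
  )
  by_ion <- purrr::map_dfr(seq_len(n_ion), function(i) {
    cr <- script_crossings(spec$ion_paths[[i]], lo, hi,
                           box_z = if (spec$wrap) spec$box[3] else Inf)
    tibble(ion = i, up = cr["up"], down = cr["down"])
  })
  gt <- list(
    crossings_up = if (n_ion) sum(by_ion$up) else 0L,
    crossings_down = if (n_ion) sum(by_ion$down) else 0L,
    by_ion = by_ion,
    pore_waters = spec$water_counts
  )
  list(trajectory = new_trajectory(coords, spec$box, time_step = time_step),
       topology = new_topology(atoms), ground_truth = gt)
}
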