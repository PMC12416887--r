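# Time-averaged electrostatic potential maps: each atom's charge is smeared
# as a spherical Gaussian (inverse width beta, default 0.25 1/A), the
# periodic Poisson equation del^2 phi = -4 pi rho is solved spectrally
# (tinfoil boundary, uniform-background neutralisation, zero-mean gauge),
# and the external transmembrane potential is added as a linear ramp.
# Internal units are Gaussian (e, A); stored potentials are mV.

#' Define a potential grid geometry
#'
#' @param box Length-3 box (A); the grid is periodic and cell-aligned.
#' @param spacing Target grid spacing, A (default 1; actual spacing is
#'   box/dims after rounding to an even node count).
#' @param origin Grid origin (default -box/2, so the box is centred on 0).
#' @return Object of class `grid_spec` with fields `origin`, `spacing`
#'   (per-axis), `dims`, `box`.
#' @export
grid_spec <- function(box, spacing = 1, origin = -box / 2) {
  dims <- pmax(4L, as.integer(round(box / spacing)))
  dims <- dims + dims %% 2L  # even counts keep the FFT frequencies simple
  structure(list(origin = origin, spacing = box / dims, dims = dims,
                 box = box), class = "grid_spec")
}

grid_axes <- function(gs) {
  lapply(1:3, function(d) gs$origin[d] + (0:(gs$dims[d] - 1)) * gs$spacing[d])
}

#' Spread point charges as Gaussians onto a grid
#'
#' Accumulates rho(r) = sum_i q_i (beta/sqrt(pi))^3 exp(-beta^2 |r - r_i|^2)
#' with periodic wrapping (atoms outside the box are wrapped in, never an
#' error). The grid integral of the density equals the total charge to
#' quadrature accuracy.
#'
#' @param coords `[n, 3]` charge positions (A), or a trajectory frame.
#' @param charges Charges, e (or a topology whose atoms carry charges).
#' @param gs A [grid_spec()].
#' @param beta Gaussian inverse width, 1/A (default 0.25).
#' @return Object of class `charge_grid`: 3-D array (e/A^3) with the spec
#'   attached.
#' @export
spread_charges <- function(coords, charges, gs, beta = 0.25) {
  if (inherits(charges, "topology")) charges <- charges$atoms$charge
  if (anyNA(charges)) abort("charges must be assigned for all atoms")
  x <- as.matrix(coords)
  rho <- array(0, gs$dims)
  axes <- grid_axes(gs)
  cut <- sqrt(26) / beta  # exp(-26) ~ 5e-12 tail truncation
  pref <- (beta / sqrt(pi))^3
  for (i in seq_len(nrow(x))) {
    if (charges[i] == 0) next
    # the Gaussian is separable, so summing each axis factor over its
    # periodic images yields the full 3-D image sum exactly
    gfac <- lapply(1:3, function(d) {
      dd <- axes[[d]] - x[i, d]
      dd <- dd - gs$box[d] * round(dd / gs$box[d])
      kmax <- ceiling(cut / gs$box[d])
      g <- 0
      for (s in -kmax:kmax) g <- g + exp(-beta^2 * (dd + s * gs$box[d])^2)
      g
    })
    rho <- rho + (charges[i] * pref) *
      outer(outer(gfac[[1]], gfac[[2]]), gfac[[3]])
  }
  structure(rho, class = "charge_grid", grid_spec = gs, beta = beta)
}

#' Solve the periodic Poisson equation spectrally
#'
#' del^2 phi = -4 pi rho on the periodic grid: phi_k = 4 pi rho_k / k^2 with
#' the k = 0 mode set to zero (uniform-background neutralisation of
#' non-neutral cells and zero-mean potential gauge). Output in mV.
#'
#' @param rho A [spread_charges()] density grid.
#' @return Object of class `potential_grid`: 3-D array (mV) with grid spec,
#'   `beta` and `frames_averaged` attributes.
#' @export
solve_poisson_periodic <- function(rho) {
  gs <- attr(rho, "grid_spec")
  n <- gs$dims
  kax <- lapply(1:3, function(d) {
    m <- 0:(n[d] - 1)
    m[m > n[d] / 2] <- m[m > n[d] / 2] - n[d]
    2 * pi * m / gs$box[d]
  })
  K2 <- outer(outer(kax[[1]]^2, kax[[2]]^2, "+"), kax[[3]]^2, "+")
  rh <- fft(unclass(rho))
  ph <- 4 * pi * rh / K2
  ph[1, 1, 1] <- 0
  phi <- Re(fft(ph, inverse = TRUE)) / prod(n)
  phi <- phi * POT_E_PER_A_MV
  structure(phi, class = "potential_grid", grid_spec = gs,
            beta = attr(rho, "beta"), frames_averaged = 1L)
}

#' Add the external transmembrane potential ramp
#'
#' Adds the linear ramp of the constant-field convention: zero below the
#' membrane span, `voltage` above it, linear within. With `membrane_span`
#' equal to the full box z extent this is the E = V/L_z field applied
#' across the whole cell.
#'
#' @param grid A `potential_grid`.
#' @param voltage Applied voltage, mV (can be negative; adding then adding
#'   the negated ramp restores the original grid exactly).
#' @param membrane_span `c(z_lo, z_hi)` (default the full box z extent).
#' @return The grid with the ramp added.
#' @export
add_external_potential <- function(grid, voltage, membrane_span = NULL) {
  gs <- attr(grid, "grid_spec")
  if (is.null(membrane_span)) {
    membrane_span <- c(gs$origin[3], gs$origin[3] + gs$box[3])
  }
  zax <- grid_axes(gs)[[3]]
  ramp <- voltage * electrical_distance(zax, membrane_span)
  out <- unclass(grid) + rep(ramp, each = gs$dims[1] * gs$dims[2])
  attributes(out) <- attributes(grid)
  out
}

#' Time-averaged potential map over a trajectory window
#'
#' Arithmetic mean of per-frame potential maps (spread + Poisson solve per
#' frame); the number of frames averaged is recorded.
#'
#' @param trajectory,topology Trajectory and topology (charges assigned).
#' @param window Frame indices to average (default all).
#' @param gs A [grid_spec()]; defaults to the first-frame box at 1 A.
#' @param beta Gaussian inverse width, 1/A.
#' @return A `potential_grid`.
#' @export
time_average_maps <- function(trajectory, topology, window = NULL,
                              gs = NULL, beta = 0.25) {
  if (is.null(window)) window <- seq_len(n_frames(trajectory))
  if (!length(window)) abort("empty averaging window")
  if (any(window < 1 | window > n_frames(trajectory))) {
    abort("window lies outside the trajectory")
  }
  if (is.null(gs)) gs <- grid_spec(trajectory$box[window[1], ])
  acc <- NULL
  for (f in window) {
    phi <- solve_poisson_periodic(
      spread_charges(frame_coords(trajectory, f), topology, gs, beta))
    acc <- if (is.null(acc)) unclass(phi) else acc + unclass(phi)
  }
  out <- acc / length(window)
  structure(out, class = "potential_grid", grid_spec = gs, beta = beta,
            frames_averaged = length(window))
}

wrap_frac_index <- function(x, origin, spacing, n, box) {
  u <- (x - origin) / spacing
  u - (n) * floor(u / n)
}

#' Probe a potential grid at points
#'
#' Trilinear interpolation with periodic wrapping; probing exactly at a
#' grid node returns the stored value.
#'
#' @param grid A `potential_grid` (or `charge_grid`).
#' @param points `[m, 3]` matrix or length-3 vector (A).
#' @return Tibble `x, y, z, value`.
#' @export
probe_grid <- function(grid, points) {
  gs <- attr(grid, "grid_spec")
  p <- matrix(as.numeric(points), ncol = 3)
  vals <- vapply(seq_len(nrow(p)), function(k) {
    u <- vapply(1:3, function(d) {
      wrap_frac_index(p[k, d], gs$origin[d], gs$spacing[d], gs$dims[d],
                      gs$box[d])
    }, numeric(1))
    i0 <- floor(u)
    fr <- u - i0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- (c(i0[1] + dx, i0[2] + dy, i0[3] + dz)) %% gs$dims + 1
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      val <- val + w * grid[ii[1], ii[2], ii[3]]
    }
    val
  }, numeric(1))
  tibble(x = p[, 1], y = p[, 2], z = p[, 3], value = vals)
}

#' Extract a 2-D slice of a potential grid
#'
#' Samples the grid on a plane defined by a point and a normal, on a
#' regular (u, v) raster in the plane.
#'
#' @param grid A `potential_grid`.
#' @param point Length-3 point on the plane (A).
#' @param normal Length-3 plane normal (non-degenerate).
#' @param extent Half-width of the raster, A.
#' @param spacing Raster spacing, A.
#' @return Tibble `u, v, x, y, z, value`.
#' @export
probe_plane <- function(grid, point, normal, extent = 20, spacing = 1) {
  nrm <- normal / sqrt(sum(normal^2))
  if (!is.finite(sum(nrm))) abort("degenerate plane normal")
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  uv <- expand.grid(u = seq(-extent, extent, by = spacing),
                    v = seq(-extent, extent, by = spacing))
  pts <- cbind(point[1] + uv$u * e1[1] + uv$v * e2[1],
               point[2] + uv$u * e1[2] + uv$v * e2[2],
               point[3] + uv$u * e1[3] + uv$v * e2[3])
  out <- probe_grid(grid, pts)
  dplyr::bind_cols(tibble(u = uv$u, v = uv$v), out)
}

#' Write / read a scalar grid in OpenDX format
#'
#' Standard OpenDX regular-grid scalar format (gridpositions /
#' gridconnections / array, data in z-fastest order), as used for
#' molecular potential maps.
#'
#' @param grid A `potential_grid` or `charge_grid`.
#' @param path Output path.
#' @return `path` invisibly (write); a `potential_grid` (read).
#' @export
write_dx <- function(grid, path) {
  gs <- attr(grid, "grid_spec")
  n <- gs$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", gs$origin[1], gs$origin[2], gs$origin[3]),
    sprintf("delta %.6f 0 0", gs$spacing[1]),
    sprintf("delta 0 %.6f 0", gs$spacing[2]),
    sprintf("delta 0 0 %.6f", gs$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d",
                   " data follows"), prod(n))
  ), con)
  v <- as.vector(aperm(unclass(grid), c(3, 2, 1)))  # z fastest
  full <- length(v) %/% 3
  if (full > 0) {
    m <- matrix(v[seq_len(3 * full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10e %.10e %.10e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(v) %% 3 > 0) {
    rem <- v[(3 * full + 1):length(v)]
    writeLines(paste(sprintf("%.10e", rem), collapse = " "), con)
  }
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field"), con)
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  n <- as.integer(tail(strsplit(cl, "\\s+")[[1]], 3))
  org <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dd <- t(vapply(deltas, function(s) {
    as.numeric(strsplit(trimws(sub("delta", "", s)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- diag(dd)
  i0 <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > i0] - 1, length(lines))
  v <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):iend]), "\\s+")))
  v <- v[seq_len(prod(n))]
  arr <- aperm(array(v, c(n[3], n[2], n[1])), c(3, 2, 1))
  gs <- structure(list(origin = org, spacing = spacing, dims = n,
                       box = spacing * n), class = "grid_spec")
  structure(arr, class = "potential_grid", grid_spec = gs,
            beta = NA_real_, frames_averaged = NA_integer_)
}
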