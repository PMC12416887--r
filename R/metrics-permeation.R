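# Ion permeation: two-plane double-crossing event counter on unwrapped z
# coordinates, and the single-channel conductance estimate g = N q / (T V).

#' Unwrap a periodic z series
#'
#' Removes box-length jumps so crossings through the periodic boundary
#' appear as monotone passes.
#'
#' @param z Wrapped z series, A.
#' @param box_z Box length along z (scalar or per-frame), A.
#' @return Unwrapped z series.
#' @export
unwrap_z <- function(z, box_z) {
  box_z <- rep_len(box_z, length(z))
  dz <- diff(z)
  jumps <- -box_z[-1] * round(dz / box_z[-1])
  z + c(0, cumsum(jumps))
}

#' Count ion permeation events
#'
#' One event per ion excursion that enters below `plane_lower` and exits
#' above `plane_upper` (or the reverse) without returning past its entry
#' plane in between — the double-crossing criterion, which is immune to
#' recrossings between the planes. Coordinates are unwrapped along z first,
#' so periodic recycling of ions is counted correctly.
#'
#' @param trajectory A trajectory.
#' @param ion_selection Atom indices (or selection) of the permeant ions;
#'   pass the topology via `topology` when using an expression.
#' @param plane_lower,plane_upper Plane heights, A (`plane_lower <
#'   plane_upper`, both inside the box).
#' @param direction Count `"up"`, `"down"` or `"both"` crossings.
#' @param topology Optional topology for expression selections.
#' @return List: `events` (tibble `ion, frame, direction`) and `count`.
#' @export
count_permeation_events <- function(trajectory, ion_selection,
                                    plane_lower, plane_upper,
                                    direction = c("both", "up", "down"),
                                    topology = NULL) {
  direction <- match.arg(direction)
  if (plane_lower >= plane_upper) {
    abort("plane_lower must be below plane_upper")
  }
  half <- max(trajectory$box[, 3]) / 2
  if (plane_lower < -half || plane_upper > half) {
    abort("planes lie outside the box")
  }
  idx <- if (is.null(topology)) {
    as.integer(ion_selection)
  } else {
    resolve_indices(topology, ion_selection, "ion selection")
  }
  box_z <- trajectory$box[, 3]
  compartment <- function(z) {
    ifelse(z < plane_lower, "below", ifelse(z > plane_upper, "above", "mid"))
  }
  events <- purrr::map_dfr(seq_along(idx), function(k) {
    z <- trajectory$coords[idx[k], 3, ]
    comp <- compartment(z)
    # a frame-to-frame jump larger than half the box is periodic recycling,
    # not passage through the pore region
    wrapjump <- c(FALSE, abs(diff(z)) > box_z[-1] / 2)
    state <- comp[1]
    if (state == "mid") state <- NA_character_
    out <- list()
    for (t in seq_along(z)[-1]) {
      cc <- comp[t]
      if (cc == "mid") next
      direct_wrap <- comp[t - 1] != "mid" && wrapjump[t]
      if (!is.na(state) && cc != state && !direct_wrap) {
        out[[length(out) + 1]] <- tibble(
          ion = idx[k], frame = t,
          direction = if (cc == "above") "up" else "down"
        )
      }
      state <- cc
    }
    dplyr::bind_rows(out)
  })
  if (direction != "both" && nrow(events)) {
    events <- events[events$direction == direction, ]
  }
  list(events = events, count = nrow(events))
}

#' Single-channel conductance estimate
#'
#' g = (N q) / (T V): `N` permeation events of charge `charge_per_ion`
#' over `duration` under `voltage`.
#'
#' @param event_count Number of permeation events.
#' @param duration ns.
#' @param voltage mV (non-zero).
#' @param charge_per_ion e (default +1, K+).
#' @return Conductance in pS.
#' @export
estimate_conductance <- function(event_count, duration, voltage,
                                 charge_per_ion = 1) {
  if (duration <= 0) abort("duration must be positive")
  if (voltage == 0) abort("voltage must be non-zero")
  event_count * charge_per_ion * COND_PS_FACTOR / (duration * voltage)
}
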