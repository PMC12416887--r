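# Membrane-slab charge system with an analytically known transmembrane
# potential: under the constant-field convention the fraction of the applied
# voltage felt at height z (the electrical distance) is 0 below the membrane,
# 1 above it, and linear within. Every coupling factor and gating-charge
# contribution is therefore exact, enabling machine-precision recovery tests.

#' Specify a synthetic membrane-slab charge system
#'
#' Point charges in a box with a membrane spanning `[z_lo, z_hi]` under an
#' applied voltage. Charges are `fixed` or `two-state` (distinct resting and
#' activated positions).
#'
#' @param membrane_span Length-2 numeric, `c(z_lo, z_hi)` (A).
#' @param applied_voltage mV.
#' @param charges Data frame with columns `label`, `q` (e), `x`, `y`,
#'   `z_resting`, `z_activated` (A; equal for fixed charges).
#' @param box Length-3 box (A); z extent must contain all charges.
#' @return Object of class `slab_system_spec`.
#' @export
slab_system_spec <- function(membrane_span, applied_voltage, charges, box) {
  stopifnot(length(membrane_span) == 2, length(box) == 3)
  if (membrane_span[1] >= membrane_span[2]) {
    abort("membrane_span must satisfy z_lo < z_hi")
  }
  ch <- as_tibble(charges)
  need <- c("label", "q", "x", "y", "z_resting", "z_activated")
  stopifnot(all(need %in% names(ch)))
  half <- box / 2
  for (col in c("z_resting", "z_activated")) {
    if (any(abs(ch[[col]]) > half[3]) ||
        any(abs(ch$x) > half[1]) || any(abs(ch$y) > half[2])) {
      abort("charge position outside the box")
    }
  }
  structure(list(membrane_span = membrane_span,
                 applied_voltage = applied_voltage,
                 charges = ch, box = box),
            class = "slab_system_spec")
}

#' Fraction of the applied potential at height z (electrical distance)
#'
#' For the linear transmembrane potential of the constant-field convention:
#' 0 below the membrane, 1 above, `(z - z_lo)/(z_hi - z_lo)` within.
#'
#' @param z Height(s), A.
#' @param membrane_span `c(z_lo, z_hi)`, A.
#' @return Numeric in `[0, 1]`.
#' @export
electrical_distance <- function(z, membrane_span) {
  pmin(1, pmax(0, (z - membrane_span[1]) /
                 (membrane_span[2] - membrane_span[1])))
}

#' Build the slab system: topology, state trajectories, analytic couplings
#'
#' @param spec A [slab_system_spec()].
#' @return List: `topology` (one pseudo-atom per charge, charges assigned),
#'   `resting`, `activated` (single-frame trajectories), and `couplings`, a
#'   tibble with the analytic electrical distance of every charge in both
#'   states plus its exact gating-charge contribution `q * (f_activated -
#'   f_resting)` (e).
#' @export
build_slab_system <- function(spec) {
  ch <- spec$charges
  n <- nrow(ch)
  atoms <- tibble(
    atom_id = seq_len(n), name = "Q", resid = seq_len(n),
    resname = "ION", chain = "A", element = "K",
    charge = ch$q, radius = 2.0
  )
  topo <- new_topology(atoms)
  mk <- function(zcol) {
    new_trajectory(cbind(ch$x, ch$y, ch[[zcol]]), spec$box)
  }
  f_r <- electrical_distance(ch$z_resting, spec$membrane_span)
  f_a <- electrical_distance(ch$z_activated, spec$membrane_span)
  couplings <- tibble(
    label = ch$label, q = ch$q,
    f_resting = f_r, f_activated = f_a,
    contribution = ch$q * (f_a - f_r)
  )
  list(topology = topo, resting = mk("z_resting"),
       activated = mk("z_activated"), couplings = couplings)
}
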