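# Gating-charge thermodynamics. The total gating charge is
#   dQ = sum_i q_i * df_i,
# where df_i is the change, between conformational states, of the coupling
# factor f (the electrical distance: the fraction of the transmembrane
# potential felt by charge i). f is obtained from charging free energies at
# two voltages by thermodynamic integration:
#   f_s(i) = [dG_s(V2, q_i) - dG_s(V1, q_i)] / (q_i (V2 - V1)).
# Sign convention: f rises from the intracellular (f = 0) to the
# extracellular (f = 1) side, so outward movement of a positive charge
# during activation gives a positive contribution (per-residue anchors such
# as R210 = +0.25 e then carry their conventional signs).

default_lambda_grid <- function() seq(0, 1, by = 0.1)

#' Assemble a thermodynamic-integration curve
#'
#' @param lambda Coupling-parameter grid (default 0, 0.1, ..., 1).
#' @param mean_force Mean force <dH/dlambda> per window, kcal/mol.
#' @param stderr Standard error per window, kcal/mol (default 0).
#' @param residue,state,voltage Metadata: residue identifier, state label
#'   (`"closed"`/`"open"` or similar), voltage in mV.
#' @return Tibble of class `ti_curve`.
#' @export
ti_curve <- function(lambda = default_lambda_grid(), mean_force,
                     stderr = 0, residue = NA, state = NA, voltage = NA) {
  if (is.unsorted(lambda, strictly = TRUE)) {
    abort("lambda grid must be strictly increasing")
  }
  if (length(mean_force) != length(lambda)) {
    abort("mean_force must match the lambda grid length")
  }
  if (any(!is.finite(mean_force))) abort("mean forces must be finite")
  out <- tibble(residue = residue, state = state, voltage = voltage,
                lambda = lambda, mean_force = mean_force,
                stderr = rep_len(stderr, length(lambda)))
  structure(out, class = c("ti_curve", class(out)))
}

#' Integrate a TI curve into a charging free energy
#'
#' Trapezoidal quadrature of the mean force over lambda (exact for the
#' linear response expected when charging in a near-linear dielectric);
#' the error is the root-sum-square of trapezoid-weighted window errors.
#' The grid must span [0, 1].
#'
#' @param curve A [ti_curve()].
#' @return Tibble `residue, state, voltage, delta_G, error` (kcal/mol).
#' @export
integrate_ti <- function(curve) {
  lam <- curve$lambda
  if (abs(lam[1]) > 1e-12 || abs(lam[length(lam)] - 1) > 1e-12) {
    abort("lambda grid must span [0, 1]")
  }
  n <- length(lam)
  h <- diff(lam)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-length(h)] + h[-1]) / 2
  tibble(
    residue = curve$residue[1], state = curve$state[1],
    voltage = curve$voltage[1],
    delta_G = sum(w * curve$mean_force),
    error = sqrt(sum((w * curve$stderr)^2))
  )
}

#' Voltage coupling factor from two charging free energies
#'
#' f = [dG(V2) - dG(V1)] / (q (V2 - V1)), with the e.mV-to-kcal/mol
#' conversion handled internally. Values far outside [0, 1] (beyond
#' [-0.2, 1.2]) are flagged with a warning, as they signal noisy inputs.
#'
#' @param dG_V2,dG_V1 Rows from [integrate_ti()] for the same residue and
#'   state at two voltages.
#' @param q Residue charge, e (non-zero).
#' @return Tibble `residue, state, f, error`.
#' @export
coupling_factor <- function(dG_V2, dG_V1, q) {
  if (q == 0) abort("q must be non-zero")
  if (isTRUE(dG_V2$voltage == dG_V1$voltage)) {
    abort("the two free energies must come from different voltages")
  }
  if (!identical(dG_V2$residue, dG_V1$residue) ||
      !identical(dG_V2$state, dG_V1$state)) {
    abort("residue/state mismatch between the two free energies")
  }
  dv <- (dG_V2$voltage - dG_V1$voltage) * E_MV_TO_KCAL
  f <- (dG_V2$delta_G - dG_V1$delta_G) / (q * dv)
  err <- sqrt(dG_V2$error^2 + dG_V1$error^2) / abs(q * dv)
  if (is.finite(f) && (f < -0.2 || f > 1.2)) {
    warn(paste0("coupling factor ", signif(f, 3), " for residue ",
                dG_V2$residue, " lies outside [-0.2, 1.2]"))
  }
  tibble(residue = dG_V2$residue, state = dG_V2$state, f = f, error = err)
}

#' Per-residue and total gating charge
#'
#' Combines per-residue coupling factors of the closed and open states with
#' the residue charges: contribution_i = q_i (f_open - f_closed), so an
#' outward (extracellular-ward) movement of a positive charge contributes
#' positively. Errors are propagated in quadrature.
#'
#' @param f_closed,f_open Tibbles `residue, f` (optional `error`) for the
#'   two states; residue sets must match.
#' @param charges Tibble `residue, q` (e).
#' @return Tibble of class `gating_charge_table` with columns `residue, q,
#'   f_closed, f_open, contribution, error`; attributes `total` and
#'   `total_error`.
#' @export
total_gating_charge <- function(f_closed, f_open, charges) {
  fc <- as_tibble(f_closed); fo <- as_tibble(f_open)
  ch <- as_tibble(charges)
  if (!setequal(fc$residue, fo$residue) ||
      !setequal(fc$residue, ch$residue)) {
    only <- c(setdiff(fc$residue, fo$residue),
              setdiff(fo$residue, fc$residue),
              setdiff(ch$residue, fc$residue))
    abort(paste0("residue sets do not match across states/charges: ",
                 paste(unique(only), collapse = ", ")))
  }
  if (!"error" %in% names(fc)) fc$error <- 0
  if (!"error" %in% names(fo)) fo$error <- 0
  ord <- ch$residue
  fc <- fc[match(ord, fc$residue), ]
  fo <- fo[match(ord, fo$residue), ]
  out <- tibble(
    residue = ord, q = ch$q,
    f_closed = fc$f, f_open = fo$f,
    contribution = ch$q * (fo$f - fc$f),
    error = abs(ch$q) * sqrt(fc$error^2 + fo$error^2)
  )
  structure(out, class = c("gating_charge_table", class(out)),
            total = sum(out$contribution),
            total_error = sqrt(sum(out$error^2)))
}

#' @export
print.gating_charge_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("# total gating charge: %.3f +/- %.3f e\n",
              attr(x, "total"), attr(x, "total_error")))
  invisible(x)
}

#' Fraction of the total gating charge carried by selected residues
#'
#' @param table A [total_gating_charge()] table, or any tibble with
#'   `residue` and `contribution` columns (total taken as the column sum
#'   unless a `total` attribute is present).
#' @param residues Residues to sum (must be rows of the table).
#' @param total Optional explicit total (e) overriding the table's.
#' @return Percentage (100 x selected / total).
#' @export
fraction_of_total <- function(table, residues, total = NULL) {
  if (!all(residues %in% table$residue)) {
    abort("residues must all be present in the table")
  }
  tot <- total %||% attr(table, "total") %||% sum(table$contribution)
  if (tot == 0) abort("total gating charge is zero")
  100 * sum(table$contribution[table$residue %in% residues]) / tot
}

#' Mean force and block-averaged error from window samples
#'
#' Window mean of dH/dlambda samples with the standard error estimated by
#' block averaging (default 5 blocks): the spread of block means over
#' sqrt(n_blocks).
#'
#' @param samples Numeric vector of per-window samples (>= 2).
#' @param blocks Number of blocks (default 5).
#' @return List `mean`, `stderr`.
#' @export
block_mean_force <- function(samples, blocks = 5) {
  n <- length(samples)
  if (n < 2) abort("need at least 2 samples per window")
  if (sd(samples) == 0) return(list(mean = samples[1], stderr = 0))
  blocks <- min(blocks, n)
  grp <- cut(seq_len(n), blocks, labels = FALSE)
  bm <- tapply(samples, grp, mean)
  list(mean = mean(samples), stderr = sd(bm) / sqrt(blocks))
}

#' Build TI curves per window from a sample table
#'
#' @param samples Tibble `residue, state, voltage_mV, lambda, sample` of
#'   per-window energy-derivative samples.
#' @param blocks Blocks for the error estimate.
#' @return A [ti_curve()] per residue/state/voltage, row-bound.
#' @export
mean_force_from_samples <- function(samples, blocks = 5) {
  samples <- as_tibble(samples)
  grp <- dplyr::group_by(samples, .data$residue, .data$state,
                         .data$voltage_mV, .data$lambda)
  win <- dplyr::summarise(
    grp,
    mean_force = block_mean_force(.data$sample, blocks)$mean,
    stderr = block_mean_force(.data$sample, blocks)$stderr,
    .groups = "drop"
  )
  out <- purrr::map_dfr(
    split(win, list(win$residue, win$state, win$voltage_mV), drop = TRUE),
    function(d) {
      d <- d[order(d$lambda), ]
      ti_curve(d$lambda, d$mean_force, d$stderr, residue = d$residue[1],
               state = d$state[1], voltage = d$voltage_mV[1])
    })
  out
}

#' Read/write the TI mean-force CSV interchange table
#'
#' Columns: `residue,state,voltage_mV,lambda,mean_force_kcal_mol,stderr`.
#'
#' @param path CSV path.
#' @return Tibble (read) or `path` invisibly (write).
#' @export
read_ti_table <- function(path) {
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("residue", "state", "voltage_mV", "lambda",
            "mean_force_kcal_mol", "stderr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("TI table missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab
}

#' @rdname read_ti_table
#' @param curves Row-bound [ti_curve()] tibble.
#' @export
write_ti_table <- function(curves, path) {
  out <- tibble(residue = curves$residue, state = curves$state,
                voltage_mV = curves$voltage,
                lambda = curves$lambda,
                mean_force_kcal_mol = curves$mean_force,
                stderr = curves$stderr)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Published per-residue gating-charge contributions for BK Core-MT
#'
#' Loads the packaged reference table of per-residue contributions to the
#' gating charge per VSD (e), used by the aggregation examples: the key S4
#' arginines R210 and R213 dominate the stated per-VSD total of ~0.45 e.
#'
#' @return Tibble `residue, helix, contribution_e, error_e`.
#' @export
bk_gating_contributions <- function() {
  path <- system.file("extdata", "bk_vsd_gating_contributions.csv",
                      package = "voltgate")
  as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

# ---- analytic TI engine on the slab system -------------------------------

#' TI curves from the analytic slab Hamiltonian
#'
#' For the membrane-slab system the charging Hamiltonian is
#' H(lambda) = lambda q V f(z), so the mean force is constant in lambda and
#' the whole TI-to-coupling-factor chain can be exercised against exact
#' ground truth.
#'
#' @param slab Output of [build_slab_system()].
#' @param spec The matching [slab_system_spec()].
#' @param state `"resting"` or `"activated"`.
#' @param voltage Applied voltage, mV.
#' @param lambda Lambda grid.
#' @return Row-bound [ti_curve()]s, one per charge.
#' @export
slab_ti_curves <- function(slab, spec, state = c("resting", "activated"),
                           voltage, lambda = default_lambda_grid()) {
  state <- match.arg(state)
  ch <- spec$charges
  z <- if (state == "resting") ch$z_resting else ch$z_activated
  f <- electrical_distance(z, spec$membrane_span)
  purrr::map_dfr(seq_len(nrow(ch)), function(i) {
    mf <- rep(ch$q[i] * voltage * f[i] * E_MV_TO_KCAL, length(lambda))
    ti_curve(lambda, mf, 0, residue = ch$label[i], state = state,
             voltage = voltage)
  })
}

#' End-to-end slab gating charge via TI
#'
#' Runs the full chain — analytic TI curves at two voltages in both states,
#' trapezoidal integration, coupling factors, gating-charge table — on a
#' slab system. The result must equal the capacitor ground truth
#' sum(q dz / L) to machine precision.
#'
#' @param spec A [slab_system_spec()].
#' @param V1,V2 The two voltages (mV) used for the coupling factors.
#' @return A `gating_charge_table`.
#' @export
slab_gating_charge <- function(spec, V1 = 0, V2 = spec$applied_voltage) {
  slab <- build_slab_system(spec)
  one_state <- function(state) {
    purrr::map_dfr(unique(spec$charges$label), function(lb) {
      cv2 <- slab_ti_curves(slab, spec, state, V2)
      cv1 <- slab_ti_curves(slab, spec, state, V1)
      g2 <- integrate_ti(cv2[cv2$residue == lb, ])
      g1 <- integrate_ti(cv1[cv1$residue == lb, ])
      coupling_factor(g2, g1, spec$charges$q[spec$charges$label == lb])
    })
  }
  f_rest <- one_state("resting")
  f_act <- one_state("activated")
  total_gating_charge(
    f_closed = f_rest, f_open = f_act,
    charges = tibble(residue = spec$charges$label, q = spec$charges$q)
  )
}
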