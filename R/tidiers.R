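# broom-style tidiers for the package's result objects.

#' Tidy a gating-charge table
#'
#' @param x A [total_gating_charge()] result.
#' @param ... Unused.
#' @return Tibble with one row per residue.
#' @method tidy gating_charge_table
#' @export
tidy.gating_charge_table <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a gating-charge table
#'
#' @param x A [total_gating_charge()] result.
#' @param ... Unused.
#' @return Tibble `total, total_error, n_residues`.
#' @method glance gating_charge_table
#' @export
glance.gating_charge_table <- function(x, ...) {
  tibble(total = attr(x, "total"), total_error = attr(x, "total_error"),
         n_residues = nrow(x))
}

#' Tidy a path set
#'
#' @param x A [suboptimal_paths()] / [optimal_path()] result.
#' @param ... Unused.
#' @return Tibble `rank, length, optimal, n_nodes, path` (path collapsed
#'   to a string).
#' @method tidy path_set
#' @export
tidy.path_set <- function(x, ...) {
  tibble(
    rank = seq_len(nrow(x)),
    length = x$length,
    optimal = x$optimal,
    n_nodes = vapply(x$path, length, integer(1)),
    path = vapply(x$path, paste, character(1), collapse = " -> ")
  )
}

#' One-row summary of a path set
#'
#' @param x A `path_set`.
#' @param ... Unused.
#' @return Tibble `source, sink, optimal_length, n_paths, truncated`.
#' @method glance path_set
#' @export
glance.path_set <- function(x, ...) {
  tibble(
    source = attr(x, "source"), sink = attr(x, "sink"),
    optimal_length = min(x$length), n_paths = nrow(x),
    truncated = isTRUE(attr(x, "truncated"))
  )
}

#' Tidy a flow profile
#'
#' @param x An [information_flow()] result.
#' @param ... Unused.
#' @return The node/flow/potential tibble with endpoint flags.
#' @method tidy flow_profile
#' @export
tidy.flow_profile <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$role <- ifelse(out$node == attr(x, "source"), "source",
                     ifelse(out$node == attr(x, "sink"), "sink", "interior"))
  out
}
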