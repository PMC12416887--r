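# Reproducible pipeline front end: validated run configuration, step
# dispatch over the analysis modules, and a JSON manifest so every run can
# be reconstructed from its outputs.

#' Default run configuration
#'
#' All defaults equal the method's standard parameter values: 5 A contact
#' cutoff, 75% occupancy, beta = 0.25 1/A, 1 A grid spacing, lambda step
#' 0.1, 50% suboptimal-path cutoff, 0.02 flow highlight, T = 300 K.
#'
#' @param seed RNG seed.
#' @param out_dir Output directory.
#' @return Named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1, out_dir = "voltgate-results") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    contact_cutoff_A = 5,
    contact_occupancy = 0.75,
    beta_invA = 0.25,
    grid_spacing_A = 1,
    lambda_step = 0.1,
    path_cutoff_ratio = 0.5,
    flow_highlight = 0.02,
    temperature_K = 300,
    voltage_mV = 750,
    membrane_span_A = c(-20, 20),
    enm_frames = 2000,
    pore_frames = 200
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config Named list (e.g. parsed from YAML); missing fields take
#'   defaults, unknown fields are an error naming the field.
#' @return A complete `run_config`.
#' @export
validate_run_config <- function(config) {
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  num_fields <- setdiff(names(base), "out_dir")
  for (nm in num_fields) {
    if (!is.numeric(base[[nm]])) {
      abort(paste0("config field '", nm, "' must be numeric"))
    }
  }
  if (base$contact_occupancy < 0 || base$contact_occupancy > 1) {
    abort("config field 'contact_occupancy' must lie in [0, 1]")
  }
  base
}

#' Read a YAML run configuration
#'
#' @param path YAML file; fields as in [default_run_config()].
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  validate_run_config(yaml::read_yaml(path))
}

write_manifest <- function(out_dir, step, config, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("voltgate")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[setdiff(names(config), c("seed", "out_dir"))],
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, paste0("manifest-", step, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

pipeline_systems <- function(config) {
  span <- config$membrane_span_A
  charges <- tibble(
    label = c("R210", "R213", "E219"),
    q = c(1, 1, -1),
    x = c(5, -5, 0), y = c(0, 5, -5),
    z_resting = c(-8, -10, 4),
    z_activated = c(0, 0, 7)
  )
  slab <- slab_system_spec(span, config$voltage_mV, charges,
                           box = c(60, 60, 80))
  enm <- two_block_network(n_per_block = 6, temperature =
                             config$temperature_K, seed = config$seed)
  pore <- pore_script_spec(
    frames = config$pore_frames, water_counts = 30, bulk_waters = 10,
    ion_paths = list(make_crossing_path(5, config$pore_frames)),
    wrap = TRUE, seed = config$seed + 1
  )
  list(slab = slab, enm = enm, pore = pore)
}

run_step_synth <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  enm <- sample_elastic_network(sys$enm, n_frames_sim = config$enm_frames)
  write_structure(enm$trajectory, enm$topology,
                  file.path(od, "enm-trajectory.pdb"))
  pore <- script_pore_trajectory(sys$pore)
  write_structure(pore$trajectory, pore$topology,
                  file.path(od, "pore-trajectory.pdb"))
  slab <- build_slab_system(sys$slab)
  write_structure(slab$resting, slab$topology,
                  file.path(od, "slab-resting.pdb"))
  write_structure(slab$activated, slab$topology,
                  file.path(od, "slab-activated.pdb"))
  gt <- list(
    slab_couplings = sys$slab$charges,
    pore_crossings_up = pore$ground_truth$crossings_up,
    pore_waters = pore$ground_truth$pore_waters,
    enm_partition = sys$enm$planted_partition
  )
  jsonlite::write_json(gt, file.path(od, "ground-truth.json"),
                       auto_unbox = TRUE, digits = NA)
  c("enm-trajectory.pdb", "pore-trajectory.pdb", "slab-resting.pdb",
    "slab-activated.pdb", "ground-truth.json")
}

run_step_metrics <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  pore <- script_pore_trajectory(sys$pore)
  wi <- which(pore$topology$atoms$resname == "HOH")
  waters <- count_in_region(pore$trajectory, wi,
                            sys$pore$pore_span[1], sys$pore$pore_span[2],
                            lateral_radius = sys$pore$pore_radius + 1)
  write.csv(waters, file.path(od, "pore-waters.csv"), row.names = FALSE)
  ions <- which(pore$topology$atoms$resname == "POT")
  ev <- count_permeation_events(pore$trajectory, ions,
                                sys$pore$pore_span[1],
                                sys$pore$pore_span[2], direction = "up")
  dur <- config$pore_frames * pore$trajectory$time_step
  cond <- tibble(
    events = ev$count, duration_ns = dur,
    voltage_mV = config$voltage_mV,
    conductance_pS = estimate_conductance(ev$count, dur, config$voltage_mV)
  )
  write.csv(cond, file.path(od, "conductance.csv"), row.names = FALSE)
  c("pore-waters.csv", "conductance.csv")
}

run_step_gating <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  tab <- slab_gating_charge(sys$slab, V1 = 0, V2 = config$voltage_mV)
  write.csv(tidy(tab), file.path(od, "gating-charge.csv"),
            row.names = FALSE)
  write.csv(glance(tab), file.path(od, "gating-charge-total.csv"),
            row.names = FALSE)
  c("gating-charge.csv", "gating-charge-total.csv")
}

run_step_fieldmap <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  slab <- build_slab_system(sys$slab)
  gs <- grid_spec(sys$slab$box, spacing = config$grid_spacing_A)
  phi <- solve_poisson_periodic(spread_charges(
    frame_coords(slab$resting, 1), slab$topology, gs,
    beta = config$beta_invA))
  phi <- add_external_potential(phi, config$voltage_mV,
                                config$membrane_span_A)
  write_dx(phi, file.path(od, "potential-resting.dx"))
  "potential-resting.dx"
}

run_step_network <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  enm <- sample_elastic_network(sys$enm, n_frames_sim = config$enm_frames)
  C <- covariance_matrix(enm$trajectory, enm$topology, superpose = FALSE)
  adj <- matrix(FALSE, nrow(C), ncol(C), dimnames = dimnames(C))
  adj[cbind(sys$enm$springs$i, sys$enm$springs$j)] <- TRUE
  adj <- adj | t(adj)
  rg <- build_graph(adj, C)
  write.csv(rg$edges, file.path(od, "network-edges.csv"),
            row.names = FALSE)
  comm <- detect_communities(rg)
  write.csv(tibble(node = names(comm$membership),
                   community = comm$membership),
            file.path(od, "communities.csv"), row.names = FALSE)
  ps <- suboptimal_paths(rg, rg$labels[1],
                         rg$labels[length(rg$labels)],
                         cutoff_ratio = config$path_cutoff_ratio)
  write.csv(tidy(ps), file.path(od, "paths.csv"), row.names = FALSE)
  c("network-edges.csv", "communities.csv", "paths.csv")
}

run_step_flow <- function(config) {
  sys <- pipeline_systems(config)
  od <- config$out_dir
  enm <- sample_elastic_network(sys$enm,
                               n_frames_sim = min(config$enm_frames, 1000))
  C <- covariance_matrix(enm$trajectory, enm$topology, superpose = FALSE)
  n <- nrow(C)
  # MI on every contact pair is the expensive part; restrict to springs
  adj <- matrix(FALSE, n, n, dimnames = dimnames(C))
  adj[cbind(sys$enm$springs$i, sys$enm$springs$j)] <- TRUE
  adj <- adj | t(adj)
  X <- node_distance_series(enm$trajectory, enm$topology, "name CA")
  M <- matrix(0, n, n, dimnames = dimnames(C))
  H <- vapply(seq_len(n), function(i) gmm_entropy(X[, i]), numeric(1))
  pr <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    M[i, j] <- M[j, i] <- max(0, H[i] + H[j] -
                                gmm_entropy(cbind(X[, i], X[, j])))
  }
  A <- conductance_matrix(C, M, adj)
  fl <- information_flow(A, rownames(C)[1], rownames(C)[n])
  write.csv(flow_profile_report(fl, config$flow_highlight),
            file.path(od, "information-flow.csv"), row.names = FALSE)
  "information-flow.csv"
}

#' Run a pipeline step
#'
#' Dispatches one of the analysis steps (`synth`, `metrics`,
#' `gating-charge`, `fieldmap`, `network`, `flow`, or `all`) on the
#' packaged synthetic systems, writes its result files into
#' `config$out_dir`, and records a JSON manifest (parameters, seed,
#' checksums). Runs are idempotent given an identical configuration.
#'
#' @param step Step name.
#' @param config A validated [default_run_config()]-style list.
#' @return Tibble `step, manifest, n_outputs`, invisibly.
#' @export
run_pipeline <- function(step = c("all", "synth", "metrics",
                                  "gating-charge", "fieldmap", "network",
                                  "flow"),
                         config = default_run_config()) {
  step <- match.arg(step)
  config <- validate_run_config(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (step == "all") {
    c("synth", "metrics", "gating-charge", "fieldmap", "network", "flow")
  } else step
  runners <- list(
    synth = run_step_synth, metrics = run_step_metrics,
    `gating-charge` = run_step_gating, fieldmap = run_step_fieldmap,
    network = run_step_network, flow = run_step_flow
  )
  res <- purrr::map_dfr(steps, function(s) {
    files <- file.path(config$out_dir, runners[[s]](config))
    mf <- write_manifest(config$out_dir, s, config, files)
    tibble(step = s, manifest = mf, n_outputs = length(files))
  })
  invisible(res)
}
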