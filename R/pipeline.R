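#' System record for the per-system analysis pipeline
#'
#' Describes one dimer system: its label, optional experimental melting
#' temperature, the per-run input files (multi-model PDB trajectory, HILLS,
#' COLVAR), the chain mapping and the CV interval of the bound minimum.
#'
#' @param system_id label (e.g. a PDB code)
#' @param runs list of runs, each `list(trajectory=, hills=, colvar=)`
#' @param bound_region CV interval `c(lo, hi)` (nm) containing the bound
#'   minimum
#' @param tm_celsius experimental melting temperature, degrees C (NA if
#'   unavailable; such systems are excluded from the correlation but kept
#'   in the depth table)
#' @param chain_a,chain_b chain identifiers in the trajectory files
#' @param frame_spacing ns per trajectory frame
#' @param reference_trajectory optional path to an unbiased bound-state
#'   trajectory (the analogue of a conventional-MD run); when present the
#'   sigmoid memberships are fitted on its full descriptor series, otherwise
#'   on the pooled first fraction of the biased runs
#' @return object of class `system_record`
#' @export
system_record <- function(system_id, runs, bound_region, tm_celsius = NA,
                          chain_a = "A", chain_b = "B", frame_spacing = 1,
                          reference_trajectory = NULL) {
  stopifnot(length(runs) >= 1)
  structure(list(system_id = system_id, runs = runs,
                 bound_region = bound_region, tm_celsius = tm_celsius,
                 chain_a = chain_a, chain_b = chain_b,
                 frame_spacing = frame_spacing,
                 reference_trajectory = reference_trajectory),
            class = "system_record")
}

#' Pipeline configuration
#'
#' All stage thresholds in one place, with the defaults of the individual
#' modules.
#'
#' @param native_cutoff native-contact heavy-atom cutoff, Angstrom
#' @param probe_radius SASA probe, Angstrom
#' @param sasa_points SASA sphere points per atom
#' @param reference_fraction fraction of each run's first frames pooled as
#'   the bound reference window for the sigmoid fits
#' @param th_dissociation,th_unbound state thresholds
#' @param dwell_fraction fraction of a run's frames a state curve must stay
#'   below threshold to count as a transition (biased runs broaden the
#'   bound basin before the actual escape, so brief excursions are ignored)
#' @param min_occurrence occurrence filter for reported contacts
#' @param temperature K
#' @param criteria a [contact_criteria()] list
#' @export
pipeline_config <- function(native_cutoff = 4.5, probe_radius = 1.4,
                            sasa_points = 240, reference_fraction = 0.25,
                            th_dissociation = 0.5, th_unbound = 0.05,
                            dwell_fraction = 0.05, min_occurrence = 0.2,
                            temperature = 300,
                            criteria = contact_criteria()) {
  as.list(environment())
}

#' Run the full analysis chain on one system
#'
#' descriptors -> sigmoid fits (pooled bound reference windows) -> state
#' classification per run -> free-energy reconstruction truncated at each
#' run's dissociation -> combined depth with leave-one-out bounds ->
#' contact occurrence in the bound and encounter windows -> interdomain
#' orientation variability per window.
#'
#' @param record a [system_record()]
#' @param config a [pipeline_config()]
#' @return manifest entry: list with per-run transition reports, a
#'   `depth_estimate`, occurrence tables and orientation summaries
#' @export
run_system <- function(record, config = pipeline_config()) {
  nr <- length(record$runs)
  # the native structure: the unbiased reference when available, else the
  # first frame of the first run
  ref_traj <- if (!is.null(record$reference_trajectory))
    load_trajectory(record$reference_trajectory, chain_a = record$chain_a,
                    chain_b = record$chain_b,
                    frame_spacing = record$frame_spacing) else NULL
  trajs <- vector("list", nr); descs <- vector("list", nr)
  native <- if (!is.null(ref_traj))
    define_native_contacts(ref_traj, 1, config$native_cutoff) else NULL
  for (i in seq_len(nr)) {
    trajs[[i]] <- load_trajectory(record$runs[[i]]$trajectory,
                                  chain_a = record$chain_a,
                                  chain_b = record$chain_b,
                                  frame_spacing = record$frame_spacing)
    if (is.null(native))
      native <- define_native_contacts(trajs[[i]], 1, config$native_cutoff)
    descs[[i]] <- descriptor_timeseries(trajs[[i]], native,
                                        config$probe_radius,
                                        config$sasa_points)
  }
  # bound reference window for the sigmoid fits
  ref_vals <- if (!is.null(ref_traj)) {
    ref_desc <- descriptor_timeseries(ref_traj, native,
                                      config$probe_radius,
                                      config$sasa_points)
    function(name) ref_desc[[name]]$value
  } else {
    function(name) unlist(lapply(descs, function(d) {
      v <- d[[name]]$value
      head(v, max(3, ceiling(config$reference_fraction * length(v))))
    }))
  }
  fits <- list(
    com_distance = fit_half_bell(ref_vals("com_distance"), "right"),
    q_native = fit_half_bell(ref_vals("q_native"), "left"))

  run_reports <- vector("list", nr)
  fes_runs <- vector("list", nr)
  occ_bound <- list(); occ_enc <- list()
  orient_sds <- list()
  for (i in seq_len(nr)) {
    cls <- classify_states(descs[[i]], fits, config$th_dissociation,
                           config$th_unbound,
                           min_dwell = max(10, ceiling(config$dwell_fraction *
                                                         nrow(descs[[i]]$com_distance))))
    nf <- n_frames(trajs[[i]])
    cv <- read_colvar(record$runs[[i]]$colvar)
    hills <- read_hills(record$runs[[i]]$hills)
    # trajectory frames and CV samples span the same time; map by proportion
    until_cv <- if (is.na(cls$t_dissociation)) NA else
      max(1, floor(nrow(cv) * cls$t_dissociation / nf))
    fes_runs[[i]] <- list(cv = cv, hills = hills, until_frame = until_cv)
    run_reports[[i]] <- list(
      t_dissociation = cls$t_dissociation, t_unbound = cls$t_unbound,
      n_frames = nf,
      no_dissociation = is.na(cls$t_dissociation))

    win_b <- which(cls$labels == "bound")
    win_e <- which(cls$labels == "encounter")
    contact_tabs <- lapply(seq_len(nf), function(f)
      detect_contacts(trajs[[i]], f, config$criteria))
    occ_from <- function(win) {
      if (!length(win)) return(NULL)
      tb <- do.call(rbind, contact_tabs[win])
      list(tab = tb, n = length(win))
    }
    occ_bound[[i]] <- occ_from(win_b)
    occ_enc[[i]] <- occ_from(win_e)

    def <- define_reference_frames(trajs[[i]], 1)
    om <- orientation_timeseries(trajs[[i]], def)
    for (w in c("bound", "encounter")) {
      sel <- cls$labels == w
      if (sum(sel) >= 2) {
        vs <- variability_summary(om[sel, -1, drop = FALSE],
                                  rep(w, sum(sel)))
        orient_sds[[length(orient_sds) + 1]] <- cbind(run = i, vs)
      }
    }
  }

  depth <- if (nr >= 3) {
    loo_depth(fes_runs, record$bound_region, config$temperature)
  } else {
    grid <- default_grid(unlist(lapply(fes_runs, function(r) r$cv$cv)))
    dens <- lapply(fes_runs, function(r)
      reweighted_histogram(r$cv, r$hills, NULL, grid,
                           until_frame = r$until_frame %||% NA,
                           temperature = config$temperature))
    prof <- combine_runs(dens, NULL, grid, config$temperature)
    structure(list(mean_depth = minimum_depth(prof, record$bound_region),
                   loo_min = NA, loo_max = NA, n_runs = nr, profile = prof),
              class = "depth_estimate")
  }

  # concatenated occurrence over all runs, per window
  concat_occ <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) return(NULL)
    tb <- do.call(rbind, lapply(lst, `[[`, "tab"))
    ntot <- sum(vapply(lst, `[[`, numeric(1), "n"))
    if (is.null(tb) || !nrow(tb)) return(NULL)
    key <- paste(tb$type, tb$resno_a, tb$resno_b, sep = "|")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\\|"))
    out <- data.frame(type = parts[, 1], resno_a = as.integer(parts[, 2]),
                      resno_b = as.integer(parts[, 3]),
                      occurrence = as.numeric(cnt) / ntot)
    attr(out, "n_frames") <- ntot
    class(out) <- c("occurrence_matrix", "data.frame")
    out[order(-out$occurrence), ]
  }
  orient_summary <- if (length(orient_sds)) {
    all_sd <- do.call(rbind, orient_sds)
    agg <- aggregate(all_sd[, grep("^sd_", names(all_sd))],
                     by = list(window = all_sd$window), FUN = mean)
    agg
  } else NULL

  list(system_id = record$system_id, tm_celsius = record$tm_celsius,
       fits = fits, runs = run_reports, depth = depth,
       occurrence_bound = concat_occ(occ_bound),
       occurrence_encounter = concat_occ(occ_enc),
       orientation = orient_summary)
}

#' Run a panel of systems and correlate depths with melting temperatures
#'
#' Executes [run_system()] for each record (a failing system is recorded
#' and the rest proceed), then correlates the per-system bound-minimum
#' depths with the available melting temperatures (Pearson and Spearman);
#' systems without a Tm stay in the depth table but are excluded from the
#' correlation.
#'
#' @param records list of [system_record()]s
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for the manifest JSON
#' @return list (systems, depth_table, correlation, failed)
#' @export
run_panel <- function(records, config = pipeline_config(), out_dir = NULL) {
  systems <- list(); failed <- list()
  for (rec in records) {
    res <- tryCatch(run_system(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      failed[[rec$system_id]] <- conditionMessage(res)
    } else {
      systems[[rec$system_id]] <- res
    }
  }
  depth_table <- do.call(rbind, lapply(systems, function(s)
    data.frame(system_id = s$system_id, tm_celsius = s$tm_celsius,
               depth = s$depth$mean_depth, loo_min = s$depth$loo_min,
               loo_max = s$depth$loo_max)))
  rownames(depth_table) <- NULL
  correlation <- NULL
  if (!is.null(depth_table) && sum(!is.na(depth_table$tm_celsius)) >= 3) {
    correlation <- correlate_depth_tm(depth_table$depth,
                                      depth_table$tm_celsius,
                                      depth_table$system_id)
  } else {
    warning("fewer than 3 systems with melting temperatures; ",
            "correlation skipped")
  }
  out <- list(systems = systems, depth_table = depth_table,
              correlation = correlation, failed = failed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
      depth_table = depth_table,
      correlation = correlation,
      failed = failed,
      transitions = lapply(systems, `[[`, "runs"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Read a panel configuration file
#'
#' A YAML (or JSON) file listing the systems of a panel; each entry gives
#' `system_id`, `bound_region`, optional `tm_celsius`, optional
#' `reference_trajectory`, chain identifiers and a list of `runs` with
#' `trajectory` / `hills` / `colvar` paths. Relative paths are resolved
#' against the configuration file's directory.
#'
#' @param path configuration file
#' @return list of [system_record()]s
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  lapply(cfg$systems, function(s) {
    runs <- lapply(s$runs, function(r)
      list(trajectory = resolve(r$trajectory), hills = resolve(r$hills),
           colvar = resolve(r$colvar)))
    system_record(
      system_id = s$system_id, runs = runs,
      bound_region = as.numeric(unlist(s$bound_region)),
      tm_celsius = s$tm_celsius %||% NA,
      chain_a = s$chain_a %||% "A", chain_b = s$chain_b %||% "B",
      frame_spacing = s$frame_spacing %||% 1,
      reference_trajectory = resolve(s$reference_trajectory))
  })
}

#' Write a synthetic system's input files
#'
#' Generates a complete per-system input set for [run_system()]: for each
#' run a 1-D Langevin metadynamics simulation on a Gaussian-well potential
#' of the requested depth produces HILLS and COLVAR files, and the CV
#' series (downsampled) drives a toy-dimer trajectory written as a
#' multi-model PDB. The realized bound-well depth equals `well_depth` (the
#' plateau of the Gaussian well).
#'
#' @param system_id label
#' @param well_depth bound-minimum depth, kJ/mol
#' @param out_dir directory for the generated files
#' @param tm_celsius melting temperature to attach (NA allowed)
#' @param n_runs metadynamics repetitions
#' @param n_steps Langevin steps per run
#' @param seed integer seed (runs use seed, seed+1, ...)
#' @param residues_per_chain,n_interface_pairs toy-dimer size
#' @param hill_height,hill_width,deposit_stride metadynamics schedule
#' @param traj_frames frames kept in the written trajectory
#' @param noise_sigma per-atom jitter of the written frames, Angstrom
#' @return a [system_record()]
#' @export
synthesize_system <- function(system_id, well_depth, out_dir,
                              tm_celsius = NA, n_runs = 3, n_steps = 4e5,
                              seed = 1, residues_per_chain = 20,
                              n_interface_pairs = 8, hill_height = 0.5,
                              hill_width = 0.05, deposit_stride = 2000,
                              traj_frames = 300, noise_sigma = 1.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dimer <- build_toy_dimer(residues_per_chain, n_interface_pairs, seed)
  d0 <- com_distance(dimer$traj, 1)
  s0 <- d0 / 10
  dom <- c(s0 - 0.2, s0 + 1.0)
  alpha <- 50
  sg <- seq(dom[1], dom[2], length.out = 1201)
  pot <- tabulated_potential(sg, well_depth * (1 - exp(-alpha * (sg - s0)^2)),
                             domain = dom)

  # unbiased bound-state reference run (the cMD analogue); its domain is
  # restricted to the bound basin so it characterizes the bound state even
  # for shallow wells
  dom0 <- c(s0 - 0.2, s0 + 0.3)
  sg0 <- seq(dom0[1], dom0[2], length.out = 601)
  pot0 <- tabulated_potential(sg0,
                              well_depth * (1 - exp(-alpha * (sg0 - s0)^2)),
                              domain = dom0)
  lv0 <- langevin_params(n_steps = max(2e4, n_steps / 10), mass = 4,
                         seed = seed + 99)
  ref <- simulate_langevin_metadynamics(pot0, lv0, hill_height = 0,
                                        cv_stride = 100, x0 = s0)
  ref_traj <- trajectory_from_cv(dimer, ref$cv$cv, frame_spacing = 1,
                                 noise_sigma = noise_sigma, seed = seed + 3)
  ref_path <- file.path(out_dir, sprintf("%s_reference.pdb", system_id))
  write_trajectory(ref_traj, ref_path)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    lv <- langevin_params(n_steps = n_steps, mass = 4,
                          seed = seed + 1000 * r)
    sim <- simulate_langevin_metadynamics(pot, lv, hill_height, hill_width,
                                          deposit_stride, cv_stride = 100,
                                          x0 = s0)
    stride <- max(1, floor(nrow(sim$cv) / traj_frames))
    idx <- seq(1, nrow(sim$cv), by = stride)
    traj <- trajectory_from_cv(dimer, sim$cv$cv[idx],
                               frame_spacing = 1,
                               noise_sigma = noise_sigma,
                               seed = seed + 7 * r)
    paths <- list(
      trajectory = file.path(out_dir, sprintf("%s_run%d.pdb", system_id, r)),
      hills = file.path(out_dir, sprintf("%s_run%d.hills", system_id, r)),
      colvar = file.path(out_dir, sprintf("%s_run%d.colvar", system_id, r)))
    write_trajectory(traj, paths$trajectory)
    write_hills(sim$hills, paths$hills)
    write_colvar(sim$cv, paths$colvar)
    runs[[r]] <- paths
  }
  system_record(system_id, runs,
                bound_region = c(s0 - 0.1, s0 + 0.1),
                tm_celsius = tm_celsius,
                reference_trajectory = ref_path)
}
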