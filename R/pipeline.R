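# Pipeline runner: executes the analysis stages in dependency order on a
# replica set (loaded from files or generated from a scenario spec) and
# validates detector output against a planted event log.

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stage order: load -> binding event -> phosphorus plane -> depth / tilt /
#' density -> interactions (with replica consensus) -> lipids -> gate.  A
#' stage requiring an earlier disabled stage raises an ordering error naming
#' the missing stage.  The result is a pure function of (inputs, config,
#' seed).
#'
#' @param config an [run_config()]; exactly one of `config$scenario`
#'   (synthetic generation) or `config$input` (file paths) must be set.
#' @param verbose emit one structured log line per stage.
#' @return class `mi_report`: stage outputs, the config, its hash, and a
#'   machine-readable `summary` list.  When `config$output_dir` is set all
#'   tabular outputs are written as CSV (stamped with the config hash) plus
#'   a `summary.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  .assert(inherits(config, "mi_run_config"), "mi_config_error",
          "config must come from run_config()")
  th <- config$thresholds
  scenario_log <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    events <- lapply(sc$events, function(e)
      scenario_event(e$kind, e$start, e$end))
    sc$events <- NULL
    spec <- do.call(scenario_spec, c(sc, list(events = events,
                                              seed = config$seed)))
    scn <- build_scenario(spec)
    reps <- scn$replicas
    scenario_log <- scn$log
    .log_stage(verbose, "load", "scenario: %d replicas, %d atoms, %d frames",
               length(reps$replicas), n_atoms(reps$replicas[[1]]),
               n_frames(reps$replicas[[1]]))
  } else {
    .assert(!is.null(config$input), "mi_config_error",
            "config needs either a scenario or input paths")
    inp <- config$input
    traj <- load_trajectory(inp$topology, inp$trajectory, psf_path = inp$psf,
                            frame_interval = if (is.null(inp$frame_interval))
                              1 else inp$frame_interval)
    reps <- replica_set("input", list(traj))
    .log_stage(verbose, "load", "%s: %d atoms, %d frames", inp$topology,
               n_atoms(traj), n_frames(traj))
  }
  traj <- reps$replicas[[1]]
  nf <- n_frames(traj)
  report <- list(config = config, config_hash = config_hash(config),
                 scenario_log = scenario_log, replicas = reps,
                 n_replicas = length(reps$replicas))
  st <- config$stages

  prot_ids <- select_atoms(traj, "protein")
  lip_ids <- select_atoms(traj, "lipid")

  bound_window <- frame_window(0, nf - 1L)
  if (st$binding) {
    report$binding_frame <- vapply(reps$replicas, function(tr)
      detect_binding_event(tr, prot_ids, lip_ids,
                           cutoff = th$binding_cutoff,
                           dwell = th$binding_dwell), integer(1))
    bf <- report$binding_frame[1]
    if (!is.na(bf)) bound_window <- frame_window(bf, nf - 1L)
    .log_stage(verbose, "binding", "cutoff=%g A dwell=%g ns -> frame %s",
               th$binding_cutoff, th$binding_dwell, bf)
  }
  report$bound_window <- bound_window

  if (st$membrane) {
    .assert(st$binding, "mi_ordering_error",
            "membrane stage requires the binding stage")
    ref <- proximal_bilayer_reference(traj, prot_ids, bound_window)
    report$bilayer_ref <- ref
    report$depth <- depth_of_insertion(traj, ref, bound_window)
    rtilt <- config$residues$tilt
    ca <- function(r) {
      ids <- select_atoms(traj, sprintf("protein and resid %d and name CA", r))
      .assert(length(ids) == 1, "mi_topology_error",
              "tilt residue %d has no unique CA", r)
      ids
    }
    report$tilt <- tilt_series(traj, ca(rtilt[1]), ca(rtilt[2]), bound_window)
    dw_frames <- min(nf, max(1L, ceiling(th$density_window /
                                           traj$frame_interval)))
    dwin <- frame_window(nf - dw_frames, nf - 1L)
    report$density <- density_profile(
      traj, list(protein = prot_ids, lipid = lip_ids,
                 phosphorus = select_atoms(traj, "flag:phosphorus")),
      window = dwin, bin = 1)
    .log_stage(verbose, "membrane",
               "plane z=%.2f A, tilt %.1f +/- %.1f deg, density over [%d,%d]",
               ref$mean_z, report$tilt$mean, report$tilt$sd,
               dwin$start, dwin$end)
  }

  if (st$interactions) {
    per_rep <- lapply(reps$replicas, function(tr) {
      list(hydrophobic = detect_hydrophobic(tr,
             cutoff = th$hydrophobic_cutoff,
             min_consecutive = th$min_consecutive),
           hbond = detect_hbonds(tr, d_ha = th$hbond_distance,
             angle_min = th$hbond_angle,
             min_consecutive = th$min_consecutive),
           cation_pi = detect_cation_pi(tr, cutoff = th$cation_pi_cutoff,
             min_consecutive = th$min_consecutive))
    })
    report$events <- per_rep
    invs <- lapply(per_rep, function(ev)
      interaction_inventory(rbind(ev$hydrophobic, ev$hbond, ev$cation_pi),
                            nf, traj$frame_interval, bound_window))
    report$inventories <- invs
    report$consensus <- replica_consensus(invs)
    report$contact_series <- windowed_contact_series(
      per_rep[[1]]$hydrophobic, nf, traj$frame_interval,
      window_width = min(th$contact_window, nf * traj$frame_interval))
    .log_stage(verbose, "interactions",
               "%d hydrophobic, %d hbond, %d cation-pi events (replica 1); %d consensus pairs",
               nrow(per_rep[[1]]$hydrophobic), nrow(per_rep[[1]]$hbond),
               nrow(per_rep[[1]]$cation_pi), nrow(report$consensus))
  }

  if (st$lipids) {
    .assert(st$membrane, "mi_ordering_error",
            "lipids stage requires the membrane stage (phosphorus plane)")
    ref <- report$bilayer_ref
    upper_lip <- sort(unique(traj$atoms$resid[.ai(ref$leaflet_ids)]))
    report$lipid_table <- lipid_conformation_table(
      traj, ref, lipids = upper_lip, leaflet = "upper",
      window = bound_window)
    deviant <- report$lipid_table$lipid[
      report$lipid_table$classification != "bilayer"]
    fp <- config$residues$gate_footprint
    fp_ids <- select_atoms(traj, paste("protein and resid",
                                       paste(fp, collapse = " ")))
    opp <- setdiff(c(ref$leaflets$upper, ref$leaflets$lower), ref$leaflet_ids)
    opp_ref <- fit_phosphorus_plane(traj, opp, bound_window)
    opp_lip <- sort(unique(traj$atoms$resid[.ai(opp)]))
    opp_table <- lipid_conformation_table(traj, opp_ref, lipids = opp_lip,
                                          leaflet = "lower",
                                          window = bound_window)
    report$opposite_lipid_table <- opp_table
    report$under_gate <- count_lipids_under_gate(
      traj, fp_ids, deviant, ref$leaflet_ids,
      radius = th$footprint_radius, window = bound_window)
    report$opposite_deviant_count <- sum(opp_table$classification != "bilayer")
    .log_stage(verbose, "lipids",
               "%d deviant lipids; mean %.2f under the gate; %d deviant in opposite leaflet",
               length(deviant), report$under_gate$mean_count,
               report$opposite_deviant_count)
  }

  if (st$gate) {
    gs <- gate_distances(traj, config$residues$gate_pair1,
                         config$residues$gate_pair2)
    seg <- segment_states(gs$d1, open_threshold = th$gate_open_threshold,
                          min_dwell = th$gate_min_dwell,
                          frame_interval = traj$frame_interval)
    report$gate <- list(series = gs, segments = seg,
                        density = if (nf >= 50)
                          estimate_state_density(gs$d1,
                            coordinate = "gate distance d1") else NULL)
    .log_stage(verbose, "gate",
               "open fraction %.3f at threshold %.2f A",
               seg$open_fraction, seg$threshold)
  }

  report$summary <- .report_summary(report)
  class(report) <- "mi_report"
  if (!is.null(config$output_dir)) .write_report(report, config$output_dir)
  report
}

.report_summary <- function(report) {
  s <- list(config_hash = report$config_hash,
            n_replicas = report$n_replicas)
  if (!is.null(report$binding_frame))
    s$binding_frame = as.integer(report$binding_frame)
  if (!is.null(report$tilt))
    s$tilt <- list(mean = report$tilt$mean, sd = report$tilt$sd)
  if (!is.null(report$events)) {
    ev1 <- report$events[[1]]
    s$n_events <- list(hydrophobic = nrow(ev1$hydrophobic),
                       hbond = nrow(ev1$hbond),
                       cation_pi = nrow(ev1$cation_pi))
    s$n_consensus <- nrow(report$consensus)
  }
  if (!is.null(report$lipid_table))
    s$lipids <- list(
      n_deviant = sum(report$lipid_table$classification != "bilayer"),
      mean_under_gate = report$under_gate$mean_count,
      opposite_deviant = report$opposite_deviant_count)
  if (!is.null(report$gate))
    s$gate <- list(open_fraction = report$gate$segments$open_fraction,
                   threshold = report$gate$segments$threshold)
  s
}

.write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$config_hash
  if (!is.null(report$depth))
    .write_csv_stamped(report$depth, file.path(dir, "depth.csv"), h)
  if (!is.null(report$density))
    .write_csv_stamped(report$density, file.path(dir, "density.csv"), h)
  if (!is.null(report$events))
    for (k in names(report$events[[1]])) {
      ev <- do.call(rbind, lapply(seq_along(report$events), function(r)
        cbind(replica = r, report$events[[r]][[k]])))
      .write_csv_stamped(ev, file.path(dir, paste0("events_", k, ".csv")), h)
    }
  if (!is.null(report$consensus))
    .write_csv_stamped(report$consensus, file.path(dir, "consensus.csv"), h)
  if (!is.null(report$contact_series))
    .write_csv_stamped(report$contact_series,
                       file.path(dir, "contact_series.csv"), h)
  if (!is.null(report$lipid_table))
    .write_csv_stamped(report$lipid_table, file.path(dir, "lipids.csv"), h)
  if (!is.null(report$gate)) {
    .write_csv_stamped(as.data.frame(report$gate$series),
                       file.path(dir, "gate_series.csv"), h)
    .write_csv_stamped(report$gate$segments$intervals,
                       file.path(dir, "gate_segments.csv"), h)
    if (!is.null(report$gate$density))
      .write_csv_stamped(as.data.frame(report$gate$density),
                         file.path(dir, "gate_density.csv"), h)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.mi_report <- function(x, ...) {
  cat("<mi_report>\n")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

# merged residue-level presence runs for one lipid partner
.lipid_contact_runs <- function(events, lipid_key, n_frames) {
  ev <- events[events$key1 == lipid_key | events$key2 == lipid_key, ,
               drop = FALSE]
  if (!nrow(ev)) return(.true_runs(logical(n_frames)))
  m <- logical(n_frames)
  for (r in seq_len(nrow(ev))) m[.fi(ev$start[r]:ev$end[r])] <- TRUE
  .true_runs(m)
}

#' Validate a pipeline report against a planted event log
#'
#' Compares every planted event with the corresponding detection in the
#' report and returns one row per discrepancy beyond `tol_frames`: planted
#' vs detected windows, frame offsets, misses, and false positives (lipid
#' partners detected for a planted kind but never planted in any event).
#' Perfect recovery yields an empty table.
#'
#' @param report an `mi_report` produced from the log's scenario.
#' @param log ground-truth event table from [build_scenario()].
#' @param tol_frames allowed absolute frame offset (0 for noise-free
#'   scenarios, 1 at 0.2 A positional noise).
#' @return data.frame of discrepancies (0 rows when all planted events are
#'   recovered within tolerance).
#' @export
validate_against_eventlog <- function(report, log, tol_frames = 0) {
  .assert(inherits(report, "mi_report"), "mi_config_error",
          "report must come from run_pipeline()")
  if (!is.null(report$scenario_log) && !is.null(attr(log, "scenario_id")))
    .assert(identical(attr(report$scenario_log, "scenario_id"),
                      attr(log, "scenario_id")),
            "mi_scenario_error", "report and log come from different scenarios")
  traj <- report$replicas$replicas[[1]]
  th <- report$config$thresholds
  nf <- n_frames(traj)
  disc <- list()
  note <- function(kind, lipid, es, ee, ds, de, status)
    disc[[length(disc) + 1]] <<- data.frame(
      event_kind = kind, lipid = lipid, expected_start = es,
      expected_end = ee, detected_start = ds, detected_end = de,
      status = status, stringsAsFactors = FALSE)
  ok <- function(a, b) !is.na(a) && !is.na(b) && abs(a - b) <= tol_frames
  lipkey <- function(l) sprintf("MEMB:TOYL%d", l)
  ev1 <- report$events[[1]]

  # bridge gaps of <= tol_frames between runs: a dropout shorter than the
  # stated frame tolerance does not count as a separate event
  merge_runs <- function(runs) {
    if (nrow(runs) <= 1 || tol_frames <= 0) return(runs)
    runs <- runs[order(runs$start), , drop = FALSE]
    out <- runs[1, ]
    for (r in seq_len(nrow(runs))[-1]) {
      if (runs$start[r] - out$end[nrow(out)] - 1L <= tol_frames)
        out$end[nrow(out)] <- runs$end[r]
      else out <- rbind(out, runs[r, ])
    }
    out
  }

  check_window <- function(kind, lipid, w_start, w_end, runs) {
    runs <- merge_runs(runs)
    if (!nrow(runs)) { note(kind, lipid, w_start, w_end, NA, NA, "miss"); return() }
    best <- which.min(abs(runs$start - w_start) + abs(runs$end - w_end))
    if (!ok(runs$start[best], w_start) || !ok(runs$end[best], w_end))
      note(kind, lipid, w_start, w_end, runs$start[best], runs$end[best],
           "offset")
    if (nrow(runs) > 1)
      note(kind, lipid, w_start, w_end, NA, NA, "split")
  }

  for (r in seq_len(nrow(log))) {
    kind <- log$event_kind[r]
    ws <- log$start_frame[r]; we <- log$end_frame[r]
    lip <- log$lipid[r]
    if (kind == "binding") {
      bf <- report$binding_frame[1]
      if (is.na(bf)) note(kind, NA, ws, we, NA, NA, "miss")
      else if (!ok(bf, ws)) note(kind, NA, ws, we, bf, NA, "offset")
    } else if (kind == "gate_open") {
      iv <- report$gate$segments$intervals
      open <- iv[iv$state == "open", , drop = FALSE]
      check_window(kind, NA, ws, we, data.frame(start = open$start,
                                                end = open$end))
    } else if (kind == "hbond_on") {
      runs <- .lipid_contact_runs(ev1$hbond, lipkey(lip), nf)
      check_window(kind, lip, ws, we, runs)
    } else if (kind == "hbond_off") {
      runs <- merge_runs(.lipid_contact_runs(ev1$hbond, lipkey(lip), nf))
      if (!nrow(runs)) note(kind, lip, ws, we, NA, NA, "miss")
      else {
        best <- which.min(abs(runs$end - (ws - 1L)))
        if (!ok(runs$end[best], ws - 1L))
          note(kind, lip, ws, we, NA, runs$end[best], "offset")
      }
    } else if (kind == "contact_on") {
      runs <- .lipid_contact_runs(ev1$hydrophobic, lipkey(lip), nf)
      check_window(kind, lip, ws, we, runs)
    } else if (kind == "contact_off") {
      runs <- merge_runs(.lipid_contact_runs(ev1$hydrophobic, lipkey(lip), nf))
      if (!nrow(runs)) note(kind, lip, ws, we, NA, NA, "miss")
      else {
        best <- which.min(abs(runs$end - (ws - 1L)))
        if (!ok(runs$end[best], ws - 1L))
          note(kind, lip, ws, we, NA, runs$end[best], "offset")
      }
    } else if (kind == "snorkel") {
      lt <- report$lipid_table
      hit <- lt$lipid == lip
      if (!any(hit) || lt$classification[hit] == "bilayer") {
        note(kind, lip, ws, we, NA, NA, "miss")
      } else {
        hts <- terminal_height_series(traj, lip, report$bilayer_ref, "sn2")
        runs <- .true_runs(hts > th$snorkel_offset)
        check_window(kind, lip, ws, we, runs)
      }
    } else if (kind == "tail_insertion") {
      lt <- report$lipid_table
      hit <- lt$lipid == lip
      if (!any(hit) || lt$classification[hit] != "inserted") {
        note(kind, lip, ws, we, NA, NA, "miss")
      } else {
        tilt <- tail_tilt_series(traj, lip, "sn2")
        runs <- .true_runs(tilt <= th$inserted_max)
        check_window(kind, lip, ws, we, runs)
      }
    }
  }

  # false positives: planted-kind detections on lipids never planted
  planted_lip <- unique(log$lipid[!is.na(log$lipid)])
  for (kind in intersect(c("hbond", "hydrophobic"),
                         c(if (any(log$event_kind %in%
                                   c("hbond_on", "hbond_off"))) "hbond",
                           if (any(log$event_kind %in%
                                   c("contact_on", "contact_off")))
                             "hydrophobic"))) {
    ev <- ev1[[kind]]
    if (!nrow(ev)) next
    lipids_seen <- unique(c(ev$key1, ev$key2))
    lipids_seen <- lipids_seen[grepl("^MEMB:", lipids_seen)]
    extra <- setdiff(lipids_seen, vapply(planted_lip, lipkey, ""))
    for (x in extra)
      note(paste0(kind, "_detection"), NA, NA, NA, NA, NA,
           sprintf("false_positive:%s", x))
  }

  if (!length(disc))
    return(data.frame(event_kind = character(0), lipid = integer(0),
                      expected_start = integer(0), expected_end = integer(0),
                      detected_start = integer(0), detected_end = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, disc)
}
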