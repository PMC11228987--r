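# Per-lipid conformational classification: tail tilt, snorkeling, cavity
# insertion, and counting perturbed lipids under the protein footprint.

# designated C2 and terminal carbon rows for one lipid tail
.tail_rows <- function(atoms, lipid, tail = c("sn2", "sn1")) {
  tail <- match.arg(tail)
  in_lip <- atoms$segid != "PROT" & atoms$resid == lipid &
    !(atoms$resname %in% .AMINO_ACIDS)
  c2 <- which(in_lip & atoms$c2_carbon)
  pre <- if (tail == "sn2") "C2" else "C3"
  term <- which(in_lip & atoms$tail_terminal_carbon &
                  substr(atoms$name, 1, 2) == pre)
  .assert(length(c2) == 1 && length(term) == 1, "mi_topology_error",
          "lipid %d lacks a designated C2 or terminal carbon for %s",
          lipid, tail)
  c(c2 = c2, term = term)
}

#' Lipid tail tilt-angle series
#'
#' Per-frame angle between the C2 to terminal-carbon vector (C218 for sn-2,
#' C316 for sn-1 in CHARMM naming) and +z, reported unfolded on
#' \[0, 180\] degrees: values above 150 degrees mean the tail points down
#' into the bilayer (upper leaflet), values of 45 degrees and below are
#' characteristic of insertion into the protein cavity.
#'
#' @param traj an `mi_trajectory`.
#' @param lipid lipid residue id.
#' @param tail `"sn2"` or `"sn1"`.
#' @return numeric vector of per-frame angles, degrees.
#' @export
tail_tilt_series <- function(traj, lipid, tail = c("sn2", "sn1")) {
  rows <- .tail_rows(traj$atoms, lipid, tail)
  v <- traj$coords[rows["term"], , ] - traj$coords[rows["c2"], , ]
  v <- matrix(v, nrow = 3)
  acos(pmin(1, pmax(-1, v[3, ] / sqrt(colSums(v^2))))) * 180 / pi
}

#' Terminal-carbon height series relative to the phosphorus plane
#'
#' @param traj an `mi_trajectory`.
#' @param lipid lipid residue id.
#' @param ref `mi_bilayer_ref` of the relevant leaflet.
#' @param tail `"sn2"` or `"sn1"`.
#' @param plane `"window"` (averaged plane) or `"frame"`.
#' @return per-frame signed z of the terminal carbon minus the plane, A.
#' @export
terminal_height_series <- function(traj, lipid, ref, tail = c("sn2", "sn1"),
                                   plane = c("window", "frame")) {
  plane <- match.arg(plane)
  rows <- .tail_rows(traj$atoms, lipid, tail)
  z <- traj$coords[rows["term"], 3, ]
  z - if (plane == "window") ref$mean_z else ref$plane_z
}

#' Classify a lipid tail as snorkeling
#'
#' A tail snorkels when its terminal carbon sits higher than 5 A below the
#' averaged phosphorus plane (height > z_offset with z_offset = -5 A) for
#' strictly more than `threshold_fraction` of the analysis window.  For
#' lower-leaflet lipids the criterion mirrors in sign automatically (heights
#' are measured toward the midplane).
#'
#' @param heights per-frame terminal-carbon heights relative to the plane
#'   from [terminal_height_series()] (upper leaflet: positive = toward the
#'   head groups; pass `-heights` for the lower leaflet, or use
#'   `leaflet = "lower"`).
#' @param threshold_fraction strict fraction-of-frames threshold (default
#'   0.01, i.e. more than 1 percent).
#' @param z_offset criterion height, A (default -5).
#' @param leaflet `"upper"` or `"lower"`; `"lower"` negates the heights so
#'   the same criterion applies.
#' @return list: `snorkeling` (logical), `snorkel_fraction`, `frames`
#'   (logical per-frame criterion).
#' @export
classify_snorkeling <- function(heights, threshold_fraction = 0.01,
                                z_offset = -5, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  if (leaflet == "lower") heights <- -heights
  hit <- heights > z_offset
  frac <- mean(hit)
  list(snorkeling = frac > threshold_fraction, snorkel_fraction = frac,
       frames = hit)
}

#' Classify tail insertion states from a tilt series
#'
#' Labels each frame `inserted` (tilt <= 45 degrees), `bilayer`
#' (>= 150 degrees) or `intermediate`, and reports the longest inserted
#' dwell (a run of k frames lasts k * frame_interval ns), the quantity that
#' distinguishes short from long cavity visits.
#'
#' @param tilt per-frame tilt series, degrees (unfolded 0-180).
#' @param frame_interval ns per frame.
#' @param inserted_max,bilayer_min thresholds, degrees.
#' @return list: `states` (character per frame), `longest_inserted_dwell`
#'   (ns), `inserted_fraction`.
#' @export
classify_insertion <- function(tilt, frame_interval = 1, inserted_max = 45,
                               bilayer_min = 150) {
  states <- ifelse(tilt <= inserted_max, "inserted",
                   ifelse(tilt >= bilayer_min, "bilayer", "intermediate"))
  runs <- .true_runs(states == "inserted")
  list(states = states,
       longest_inserted_dwell = if (nrow(runs)) max(runs$length) *
         frame_interval else 0,
       inserted_fraction = mean(states == "inserted"))
}

#' Full per-lipid conformation table
#'
#' Tail tilt summary, snorkel fraction and a three-way classification
#' (`bilayer`, `snorkeling`, `inserted`) for every lipid of a leaflet.
#' A lipid is `inserted` when any frame of its tail is at or below the
#' inserted-tilt threshold, else `snorkeling` when the snorkel criterion
#' holds, else `bilayer`.
#'
#' @param traj an `mi_trajectory`.
#' @param ref `mi_bilayer_ref` of the leaflet under study.
#' @param lipids lipid residue ids (default: lipids whose phosphorus is in
#'   `ref$leaflet_ids`).
#' @param leaflet `"upper"` or `"lower"`.
#' @param tail `"sn2"` or `"sn1"`.
#' @param window optional `mi_window` restricting the analysis frames.
#' @return data.frame: lipid, tail, tilt mean, snorkel_fraction,
#'   longest inserted dwell (ns), classification.
#' @export
lipid_conformation_table <- function(traj, ref, lipids = NULL,
                                     leaflet = "upper",
                                     tail = "sn2", window = NULL) {
  at <- traj$atoms
  if (is.null(lipids))
    lipids <- sort(unique(at$resid[.ai(ref$leaflet_ids)]))
  fr <- if (is.null(window)) seq_len(n_frames(traj)) else
    .fi(.window_frames(window, traj))
  rows <- lapply(lipids, function(l) {
    tilt <- tail_tilt_series(traj, l, tail)[fr]
    hts <- terminal_height_series(traj, l, ref, tail)[fr]
    snork <- classify_snorkeling(hts, leaflet = leaflet)
    if (leaflet == "lower") tilt <- 180 - tilt
    ins <- classify_insertion(tilt, traj$frame_interval)
    cls <- if (ins$inserted_fraction > 0) "inserted" else
      if (snork$snorkeling) "snorkeling" else "bilayer"
    data.frame(lipid = l, tail = tail, tilt_mean = mean(tilt),
               snorkel_fraction = snork$snorkel_fraction,
               longest_inserted_dwell = ins$longest_inserted_dwell,
               classification = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count perturbed lipids under the protein footprint
#'
#' Per frame, the number of lipids whose phosphorus lies within `radius`
#' (in-plane, minimum image) of the footprint centroid AND that satisfy the
#' deviant predicate (snorkeling or cavity-inserted over the window).  Run
#' on the opposite leaflet with the same predicate it yields the baseline
#' count away from the protein.
#'
#' @param traj an `mi_trajectory`.
#' @param footprint_ids 0-based protein atom ids defining the footprint
#'   (e.g. the gate residues); their per-frame xy centroid is the origin.
#' @param deviant_lipids lipid residue ids satisfying the deviant predicate
#'   (e.g. from [lipid_conformation_table()] classifications).
#' @param leaflet_p_ids phosphorus atom ids of the leaflet to count over.
#' @param radius footprint radius, A (default 15).
#' @param window `mi_window`; defaults to all frames.
#' @return list: `counts` (per-frame), `mean_count`.
#' @export
count_lipids_under_gate <- function(traj, footprint_ids, deviant_lipids,
                                    leaflet_p_ids, radius = 15,
                                    window = NULL) {
  .assert(length(footprint_ids) > 0, "mi_format_error", "empty footprint")
  if (is.null(window)) window <- frame_window(0, n_frames(traj) - 1L)
  fr <- .window_frames(window, traj)
  at <- traj$atoms
  prow <- .ai(leaflet_p_ids)
  plip <- at$resid[prow]
  frow <- .ai(footprint_ids)
  counts <- vapply(.fi(fr), function(f) {
    cen <- colMeans(.fm(traj$coords, frow, f))[1:2]
    d <- .fm(traj$coords, prow, f)
    dx <- d[, 1] - cen[1]; dy <- d[, 2] - cen[2]
    dx <- dx - traj$box[f, 1] * round(dx / traj$box[f, 1])
    dy <- dy - traj$box[f, 2] * round(dy / traj$box[f, 2])
    under <- sqrt(dx^2 + dy^2) <= radius
    sum(under & plip %in% deviant_lipids)
  }, numeric(1))
  list(counts = counts, mean_count = mean(counts))
}
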