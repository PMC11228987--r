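# Gate-opening quantification: the two diagnostic residue-pair distances,
# kernel density estimation of the state populations, and open/closed
# segmentation.

#' Gate-opening distance series
#'
#' Per-frame distances for the two diagnostic residue pairs flanking the
#' cavity entrance (omega-4 PRO564 to omega-1 TRP473, and omega-4 TRP562 to
#' omega-1 SER476 in the reference system).  Atom choice per pair:
#' `closest` (closest heavy atom, default - robust to side-chain flips of
#' the gate tryptophans), `ca` (alpha carbons) or `named` (explicit atom
#' names via `atoms_1`/`atoms_2`).
#'
#' @param traj an `mi_trajectory`.
#' @param pair1,pair2 length-2 integer vectors of residue ids, e.g.
#'   `c(564, 473)`.
#' @param mode `"closest"`, `"ca"` or `"named"`.
#' @param atoms_1,atoms_2 atom names (length 2, one per residue) for
#'   `mode = "named"`.
#' @return class `mi_gate_series`: data.frame with `frame`, `time`, `d1`,
#'   `d2`; the mode is recorded as an attribute.
#' @export
gate_distances <- function(traj, pair1 = c(564, 473), pair2 = c(562, 476),
                           mode = c("closest", "ca", "named"),
                           atoms_1 = NULL, atoms_2 = NULL) {
  mode <- match.arg(mode)
  at <- traj$atoms
  res_ids <- function(r, names_wanted = NULL) {
    rows <- which(at$resid == r & at$resname %in% .AMINO_ACIDS)
    .assert(length(rows) > 0, "mi_topology_error", "residue %d not found", r)
    if (!is.null(names_wanted)) {
      rows <- rows[at$name[rows] %in% names_wanted]
      .assert(length(rows) > 0, "mi_topology_error",
              "residue %d has no atom named %s", r,
              paste(names_wanted, collapse = "/"))
    }
    at$atom_id[rows]
  }
  dist_series <- function(pair, names2) {
    if (mode == "ca") {
      a <- res_ids(pair[1], "CA"); b <- res_ids(pair[2], "CA")
    } else if (mode == "named") {
      .assert(!is.null(names2), "mi_config_error",
              "mode 'named' requires atom names")
      a <- res_ids(pair[1], names2[1]); b <- res_ids(pair[2], names2[2])
    } else {
      a <- .heavy_ids(traj, res_ids(pair[1]))
      b <- .heavy_ids(traj, res_ids(pair[2]))
    }
    min_distance_series(traj, a, b, heavy_only = FALSE)
  }
  out <- data.frame(frame = seq_len(n_frames(traj)) - 1L, time = traj$times,
                    d1 = dist_series(pair1, atoms_1),
                    d2 = dist_series(pair2, atoms_2))
  attr(out, "mode") <- mode
  attr(out, "pairs") <- list(pair1 = pair1, pair2 = pair2)
  class(out) <- c("mi_gate_series", "data.frame")
  out
}

#' Kernel density estimate of a state coordinate
#'
#' Gaussian-kernel density of a distance series (an inter-residue gate
#' distance or a residue-to-bilayer distance; the output records which),
#' evaluated on a regular grid and normalised so the trapezoidal integral
#' is 1.  Bandwidth follows Scott's rule by default.
#'
#' @param x numeric samples (at least 50; fewer frames are too few for a
#'   meaningful state density).
#' @param bw bandwidth (angstrom) or `NULL` for Scott's rule.
#' @param n_grid grid size.
#' @param coordinate label recorded with the output.
#' @return class `mi_state_density`: data.frame `x`, `density`; attributes
#'   `bw`, `coordinate`, `modes` (grid local maxima, decreasing density).
#' @export
estimate_state_density <- function(x, bw = NULL, n_grid = 512,
                                   coordinate = "distance") {
  x <- x[is.finite(x)]
  .assert(length(x) >= 50, "mi_config_error",
          "need at least 50 samples for a state density (got %d); analyse more frames",
          length(x))
  if (is.null(bw)) bw <- bw.nrd(x)   # Scott's rule
  # degenerate (near-constant) samples: fall back to a small fixed bandwidth
  if (!is.finite(bw) || bw <= 0) bw <- max(0.01, 1e-3 * max(abs(x), 1))
  d <- density(x, bw = bw, n = n_grid, cut = 3)
  dx <- diff(d$x[1:2])
  area <- sum((d$y[-1] + d$y[-length(d$y)]) / 2) * dx
  y <- d$y / area
  # local maxima on the grid
  up <- c(FALSE, diff(y) > 0); dn <- c(diff(y) < 0, FALSE)
  peaks <- which(up & dn)
  modes <- d$x[peaks][order(y[peaks], decreasing = TRUE)]
  out <- data.frame(x = d$x, density = y)
  attr(out, "bw") <- bw
  attr(out, "coordinate") <- coordinate
  attr(out, "modes") <- modes
  class(out) <- c("mi_state_density", "data.frame")
  out
}

#' Segment a gate-distance series into closed/open states
#'
#' Frames at or below the threshold are closed, above it open; intervals
#' shorter than `min_dwell` (a run of k frames lasts k * frame_interval ns)
#' are merged into their neighbours, shortest first, so the result tiles
#' the trajectory with alternating states.  When no threshold is given it
#' defaults to the density minimum between the two largest KDE modes of the
#' series (falling back to the series midrange for unimodal data).
#'
#' @param x distance series, angstrom.
#' @param open_threshold angstrom, or `NULL` to derive from the KDE.
#' @param min_dwell ns.
#' @param frame_interval ns per frame.
#' @return list: `intervals` (data.frame state/start/end, 0-based
#'   inclusive, tiling all frames), `open_fraction`, `threshold`.
#' @export
segment_states <- function(x, open_threshold = NULL, min_dwell = 0,
                           frame_interval = 1) {
  n <- length(x)
  if (is.null(open_threshold)) {
    if (n >= 50) {
      den <- estimate_state_density(x)
      modes <- attr(den, "modes")
      if (length(modes) >= 2) {
        lo <- min(modes[1:2]); hi <- max(modes[1:2])
        between <- den$x > lo & den$x < hi
        open_threshold <- den$x[between][which.min(den$density[between])]
      }
    }
    if (is.null(open_threshold)) open_threshold <- mean(range(x))
  }
  .assert(open_threshold > 0, "mi_config_error", "threshold must be positive")
  open <- x > open_threshold
  min_frames <- if (min_dwell <= 0) 0L else
    ceiling(min_dwell / frame_interval - 1e-9)
  repeat {
    r <- rle(open)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_frames)
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    # flip the shortest short interval into its neighbours' state
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    open[starts[k]:ends[k]] <- !r$values[k]
  }
  r <- rle(open)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  intervals <- data.frame(state = ifelse(r$values, "open", "closed"),
                          start = starts - 1L, end = ends - 1L,
                          stringsAsFactors = FALSE)
  list(intervals = intervals, open_fraction = mean(open),
       threshold = open_threshold)
}
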