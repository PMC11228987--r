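# Internal helpers shared across modules.

# 0-based atom ids / frame indices -> 1-based R indices
.ai <- function(ids) as.integer(ids) + 1L
.fi <- function(frames) as.integer(frames) + 1L

# rows of one frame as an n x 3 matrix (robust to length-1 row sets)
.fm <- function(coords, rows, f) matrix(coords[rows, , f], ncol = 3)

.stop_mi <- function(class, msg, ...) {
  stop(structure(class = c(class, "mi_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @noRd
.assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) .stop_mi(class, msg, ...)
  invisible(TRUE)
}

# Maximal runs of TRUE in a logical vector, as 0-based inclusive windows.
# Returns a data.frame(start, end, length) with one row per run.
.true_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L,
             length = r$lengths[keep])
}

# Approximate atomic numbers for electron-weighted densities.
.ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, K = 19,
                    NA. = 11, CL = 17, MG = 12, CA. = 20, F = 9, FE = 26)

.element_z <- function(element) {
  z <- .ATOMIC_NUMBER[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements treated as carbon-like
  unname(z)
}

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06, K = 39.098)

.element_mass <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Guess the element from a PDB/CHARMM atom name (leading letters, first match
# against two-letter then one-letter symbols).
.guess_element <- function(name) {
  lead <- toupper(sub("^[0-9]*", "", name))
  one <- substr(lead, 1, 1)
  one[one == ""] <- "C"
  one
}
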