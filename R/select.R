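# Atom selection mini-language.
#
# Grammar (whitespace-tokenised, case-sensitive values):
#   expr    := and ("or" and)*
#   and     := unary ("and" unary)*
#   unary   := "not" unary | "(" expr ")" | term
#   term    := "flag:IDENT"
#            | "name" v+ | "resname" v+ | "segid" v+ | "element" v+
#            | "resid" v+          (values may be single ids or lo:hi ranges)
#            | "all" | "protein" | "lipid" | "heavy"
# Examples: "resname TRP and name CA", "flag:phosphorus",
#           "segid PROT and resid 470:480".

#' Select atoms by expression
#'
#' Evaluates a selection expression against a trajectory topology and
#' returns a deterministic, sorted list of 0-based atom ids (possibly
#' empty).  See the grammar in the package source; keywords `and`, `or`,
#' `not` and parentheses combine terms such as `name CA`, `resname TRP`,
#' `resid 470:480`, `segid MEMB`, `element P`, `flag:phosphorus`,
#' `protein`, `lipid`, `heavy`, `all`.
#'
#' @param traj an `mi_trajectory` (or bare atom table).
#' @param expression selection string.
#' @return sorted integer vector of 0-based atom ids.
#' @export
select_atoms <- function(traj, expression) {
  at <- if (inherits(traj, "mi_trajectory")) traj$atoms else traj
  toks <- .tokenize(expression)
  st <- new.env()
  st$toks <- toks; st$pos <- 1L; st$expr <- expression
  mask <- .parse_or(st, at)
  if (st$pos <= length(st$toks$word))
    .parse_err(st, "unexpected trailing token '%s'", st$toks$word[st$pos])
  sort(at$atom_id[mask])
}

.tokenize <- function(expression) {
  .assert(is.character(expression) && length(expression) == 1 &&
            nzchar(trimws(expression)), "mi_parse_error", "empty selection")
  spaced <- gsub("([()])", " \\1 ", expression)
  # keep character offsets approximate via token order
  m <- gregexpr("[^ \t]+", spaced)[[1]]
  word <- regmatches(spaced, gregexpr("[^ \t]+", spaced))[[1]]
  list(word = word, at = as.integer(m))
}

.parse_err <- function(st, msg, ...) {
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else
    nchar(st$expr) + 1L
  .stop_mi("mi_parse_error",
           paste0("selection parse error at position %d: ", msg),
           pos, ...)
}

.peek <- function(st) if (st$pos <= length(st$toks$word)) st$toks$word[st$pos] else NA
.take <- function(st) { w <- .peek(st); st$pos <- st$pos + 1L; w }

.parse_or <- function(st, at) {
  m <- .parse_and(st, at)
  while (identical(.peek(st), "or")) { .take(st); m <- m | .parse_and(st, at) }
  m
}

.parse_and <- function(st, at) {
  m <- .parse_unary(st, at)
  while (identical(.peek(st), "and")) { .take(st); m <- m & .parse_unary(st, at) }
  m
}

.parse_unary <- function(st, at) {
  w <- .peek(st)
  if (is.na(w)) .parse_err(st, "expected a term")
  if (w == "not") { .take(st); return(!.parse_unary(st, at)) }
  if (w == "(") {
    .take(st)
    m <- .parse_or(st, at)
    if (!identical(.peek(st), ")")) .parse_err(st, "expected ')'")
    .take(st)
    return(m)
  }
  .parse_term(st, at)
}

.KEYWORDS <- c("and", "or", "not", "(", ")")

.parse_values <- function(st) {
  vals <- character(0)
  while (!is.na(.peek(st)) && !(.peek(st) %in% .KEYWORDS) &&
         !(.peek(st) %in% c("name", "resname", "segid", "element", "resid")))
    vals <- c(vals, .take(st))
  if (!length(vals)) .parse_err(st, "expected at least one value")
  vals
}

.parse_term <- function(st, at) {
  w <- .take(st)
  if (grepl("^flag:", w)) {
    fl <- sub("^flag:", "", w)
    if (!fl %in% .FLAG_COLS) {
      st$pos <- st$pos - 1L
      .parse_err(st, "unknown flag '%s'", fl)
    }
    return(at[[fl]])
  }
  switch(w,
    all = rep(TRUE, nrow(at)),
    protein = at$resname %in% .AMINO_ACIDS,
    lipid = at$resname %in% .LIPID_RESNAMES,
    heavy = at$element != "H",
    name = at$name %in% .parse_values(st),
    resname = at$resname %in% .parse_values(st),
    segid = at$segid %in% .parse_values(st),
    element = at$element %in% .parse_values(st),
    resid = {
      vals <- .parse_values(st)
      keep <- rep(FALSE, nrow(at))
      for (v in vals) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          lohi <- as.integer(strsplit(v, ":")[[1]])
          keep <- keep | (at$resid >= lohi[1] & at$resid <= lohi[2])
        } else if (grepl("^-?[0-9]+$", v)) {
          keep <- keep | at$resid == as.integer(v)
        } else {
          st$pos <- st$pos - 1L
          .parse_err(st, "bad resid value '%s'", v)
        }
      }
      keep
    },
    { st$pos <- st$pos - 1L; .parse_err(st, "unknown term '%s'", w) })
}
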