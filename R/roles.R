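# Atom role assignment: maps naming conventions (CHARMM-style) to the role
# flags the detectors consume.  Fully overridable via a YAML/CSV config so
# that non-default force-field naming or a curated hydrophobic-candidate
# table can be supplied.

.AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE",
                  "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.LIPID_RESNAMES <- c("POPC", "POPE", "POPS", "POPI", "DOPC", "DPPC", "PSM",
                     "CHL1", "CER1", "CER", "SAPI", "PLPI", "TOYL")

#' Assign atom role flags from naming conventions
#'
#' Derives every role flag from atom/residue names and bonds:
#' * `phosphorus` — element P;
#' * `choline_nitrogen` — lipid N named `N`;
#' * `c2_carbon` — lipid glycerol `C2`;
#' * `tail_terminal_carbon` — highest-numbered carbon of each acyl tail
#'   (`C2nn` = sn-2, `C3nn` = sn-1, e.g. C218/C316), overridable;
#' * `alpha_carbon`/`beta_carbon`/`backbone` — protein CA/CB and N,CA,C,O;
#' * `aromatic_ring_member` — six-membered rings of TRP (CD2,CE2,CE3,CZ2,
#'   CZ3,CH2) and PHE/TYR (CG,CD1,CD2,CE1,CE2,CZ);
#' * `hbond_hydrogen` — H bonded to N/O/S; `hbond_donor_heavy` — that heavy
#'   atom; `hbond_acceptor` — any O, plus N carrying no hydrogen;
#' * `hydrophobic_candidate` — carbons bonded to no N/O/S/P atom, plus S of
#'   Cys/Met (a standard apolarity proxy; supply a curated table through
#'   `config` when one is available).
#'
#' @param traj an `mi_trajectory` (bonds must be populated).
#' @param config optional override table (data.frame or path for
#'   [load_role_config()]) with columns `flag`, `name`, optional `resname`,
#'   `value`; rows are applied after the defaults, matching atom name and
#'   residue name exactly.
#' @return the atom table with updated flag columns.
#' @export
assign_roles <- function(traj, config = NULL) {
  at <- traj$atoms
  n <- nrow(at)
  elem <- at$element
  is_prot <- at$resname %in% .AMINO_ACIDS
  is_lip <- at$resname %in% .LIPID_RESNAMES |
    (!is_prot & grepl("^(MEMB|LIP)", at$segid))

  at$phosphorus <- elem == "P"
  at$choline_nitrogen <- is_lip & elem == "N" & at$name == "N"
  at$c2_carbon <- is_lip & at$name == "C2"
  at$alpha_carbon <- is_prot & at$name == "CA"
  at$beta_carbon <- is_prot & at$name == "CB"
  at$backbone <- is_prot & at$name %in% c("N", "CA", "C", "O")

  ring6 <- list(TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  at$aromatic_ring_member <- mapply(function(rn, nm)
    rn %in% names(ring6) && nm %in% ring6[[rn]], at$resname, at$name)

  # terminal tail carbon: highest-numbered C2nn / C3nn per lipid residue
  at$tail_terminal_carbon <- FALSE
  tailc <- is_lip & grepl("^C[23][0-9]+$", at$name)
  if (any(tailc)) {
    idx <- which(tailc)
    tail_id <- substr(at$name[idx], 2, 2)
    cnum <- as.integer(substring(at$name[idx], 3))
    key <- paste(at$segid[idx], at$resid[idx], tail_id)
    top <- tapply(seq_along(idx), key, function(i) idx[i][which.max(cnum[i])])
    at$tail_terminal_carbon[unlist(top)] <- TRUE
  }

  # bond-derived roles
  adj <- .adjacency(traj$bonds, n)
  has_h <- logical(n); bonded_polar <- logical(n)
  h_rows <- which(elem == "H")
  donor_of_h <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    nbe <- elem[nb]
    if (elem[i] %in% c("N", "O", "S") && any(nbe == "H")) has_h[i] <- TRUE
    if (elem[i] == "C" && any(nbe %in% c("N", "O", "S", "P")))
      bonded_polar[i] <- TRUE
    if (elem[i] == "H") {
      heavy <- nb[nbe %in% c("N", "O", "S")]
      if (length(heavy)) donor_of_h[i] <- heavy[1]
    }
  }
  at$hbond_donor_heavy <- has_h
  at$hbond_hydrogen <- !is.na(donor_of_h)
  at$hbond_acceptor <- elem == "O" | (elem == "N" & !has_h & !at$choline_nitrogen)
  at$hydrophobic_candidate <- (elem == "C" & !bonded_polar) |
    (elem == "S" & at$resname %in% c("CYS", "MET"))

  if (!is.null(config)) {
    if (is.character(config)) config <- load_role_config(config)
    .assert(all(c("flag", "name", "value") %in% names(config)),
            "mi_config_error", "role config needs columns flag, name, value")
    .assert(all(config$flag %in% .FLAG_COLS), "mi_config_error",
            "unknown role flag in config: %s",
            paste(setdiff(config$flag, .FLAG_COLS), collapse = ", "))
    for (r in seq_len(nrow(config))) {
      hit <- at$name == config$name[r]
      if (!is.null(config$resname) && !is.na(config$resname[r]) &&
          nzchar(config$resname[r]))
        hit <- hit & at$resname == config$resname[r]
      at[[config$flag[r]]][hit] <- as.logical(config$value[r])
    }
  }
  at
}

.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    b <- bonds + 1L
    for (k in seq_len(nrow(b))) {
      adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
      adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
    }
  }
  adj
}

#' Load a role-assignment override table
#'
#' Accepts CSV (columns `flag,name,resname,value`) or YAML (a list of
#' records with those fields).
#'
#' @param path config file.
#' @return data.frame of overrides for [assign_roles()].
#' @export
load_role_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    do.call(rbind, lapply(recs, function(r)
      data.frame(flag = r$flag, name = r$name,
                 resname = if (is.null(r$resname)) NA_character_ else r$resname,
                 value = isTRUE(r$value), stringsAsFactors = FALSE)))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}
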