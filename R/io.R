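#' Read a structure file
#'
#' Parses a PDB or GRO file into an [annotated_complex()].  PDB coordinates
#' (Angstrom by format convention) are converted to nm on load; GRO files
#' are nm natively.  Water and ion chains are recognised by canonical
#' residue names; remaining chains default to receptor (first) and partner,
#' overridable through `chain_roles`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param chain_roles optional named character vector chain -> role.
#' @return an [annotated_complex()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           chain_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (format == "pdb") {
    parsed <- parse_pdb(readLines(path), path, first_model_only = TRUE)
    annotated_complex(parsed$atoms, chain_roles = chain_roles)
  } else {
    annotated_complex(parse_gro(readLines(path), path), chain_roles = chain_roles)
  }
}

# fixed-column PDB ATOM/HETATM parser; returns atoms tibble (nm) plus the
# per-model coordinate list and box when requested
parse_pdb <- function(lines, path, first_model_only = TRUE) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  box <- NULL
  cryst <- lines[startsWith(lines, "CRYST1")]
  if (length(cryst)) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33))) * 0.1
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  atom_lines_of <- function(idx) {
    ln <- lines[idx]
    short <- nchar(ln) < 54
    if (any(short)) {
      abort(paste0("truncated ATOM record in ", path, " at line ",
                   idx[which(short)[1]]))
    }
    tibble::tibble(
      serial = as.integer(substr(ln, 7, 11)),
      name = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      resname = trimws(substr(ln, 18, 21)),
      chain = substr(ln, 22, 22),
      resnum = as.integer(substr(ln, 23, 26)),
      icode = trimws(substr(ln, 27, 27)),
      x = as.numeric(substr(ln, 31, 38)) * 0.1,
      y = as.numeric(substr(ln, 39, 46)) * 0.1,
      z = as.numeric(substr(ln, 47, 54)) * 0.1,
      element = trimws(substr(paste0(ln, "  "), 77, 78))
    )
  }
  finish <- function(at, idx) {
    if (anyNA(at$serial) || anyNA(at$x) || anyNA(at$y) || anyNA(at$z)) {
      bad <- which(is.na(at$serial) | is.na(at$x) | is.na(at$y) | is.na(at$z))[1]
      abort(paste0("unparsable ATOM record in ", path, " at line ", idx[bad]))
    }
    at <- at[at$altloc %in% c(" ", "", "A"), ]
    at$element[at$element == ""] <- guess_element(at$name[at$element == ""],
                                                  at$resname[at$element == ""])
    at[, c("serial", "name", "element", "chain", "resnum", "icode",
           "resname", "x", "y", "z")]
  }

  if (length(model_starts) == 0 || first_model_only) {
    idx <- which(is_atom)
    if (length(model_starts) > 0) {
      # restrict to the first model
      stop1 <- which(startsWith(lines, "ENDMDL"))
      stop1 <- if (length(stop1)) stop1[1] else length(lines)
      idx <- idx[idx > model_starts[1] & idx < stop1]
    }
    if (length(idx) == 0) abort(paste0("no ATOM records in ", path))
    return(list(atoms = finish(atom_lines_of(idx), idx), box = box,
                models = NULL, times = NULL))
  }

  # multi-model: one coordinate set per MODEL
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(model_starts)) {
    abort(paste0("unbalanced MODEL/ENDMDL records in ", path))
  }
  atoms <- NULL
  models <- vector("list", length(model_starts))
  times <- rep(NA_real_, length(model_starts))
  for (m in seq_along(model_starts)) {
    idx <- which(is_atom)
    idx <- idx[idx > model_starts[m] & idx < ends[m]]
    at <- finish(atom_lines_of(idx), idx)
    if (m == 1) atoms <- at
    tl <- lines[model_starts[m]:ends[m]]
    tl <- tl[startsWith(tl, "REMARK  TIME")]
    if (length(tl)) times[m] <- as.numeric(trimws(substr(tl[1], 13, nchar(tl[1]))))
    models[[m]] <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  }
  if (length(unique(lengths(models))) != 1) {
    abort(paste0("models differ in atom count in ", path))
  }
  list(atoms = atoms, box = box, models = models,
       times = if (all(is.na(times))) NULL else times)
}

guess_element <- function(name, resname) {
  el <- toupper(substr(gsub("^[0-9]", "", name), 1, 1))
  ion <- toupper(resname) %in% .ion_resnames
  el[ion] <- toupper(resname[ion])
  el[el == "SOD"] <- "NA"; el[el == "CLA"] <- "CL"; el[el == "POT"] <- "K"
  el[el == "CAL"] <- "CA"
  el
}

parse_gro <- function(lines, path) {
  if (length(lines) < 3) abort(paste0("truncated GRO file: ", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(paste0("unparsable atom count in ", path, " at line 2"))
  if (length(lines) < 2 + n) {
    abort(paste0("GRO file ", path, " declares ", n, " atoms but has fewer lines"))
  }
  ln <- lines[3:(2 + n)]
  short <- nchar(ln) < 44
  if (any(short)) {
    abort(paste0("truncated atom record in ", path, " at line ",
                 2 + which(short)[1]))
  }
  name <- trimws(substr(ln, 11, 15))
  resname <- trimws(substr(ln, 6, 10))
  tibble::tibble(
    serial = as.integer(substr(ln, 16, 20)),
    name = name,
    element = guess_element(name, resname),
    chain = "A",
    resnum = as.integer(substr(ln, 1, 5)),
    icode = "",
    resname = resname,
    x = as.numeric(substr(ln, 21, 28)),
    y = as.numeric(substr(ln, 29, 36)),
    z = as.numeric(substr(ln, 37, 44))
  )
}

#' Write a structure as PDB
#'
#' @param complex an [annotated_complex()].
#' @param path output path; coordinates written in Angstrom per PDB format.
#' @param box optional length-3 box (nm) written as CRYST1.
#' @return `path`, invisibly.
#' @export
write_structure <- function(complex, path, box = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box)) writeLines(cryst1_line(box), con)
  writeLines(pdb_atom_lines(complex$atoms), con)
  writeLines("END", con)
  invisible(path)
}

cryst1_line <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90)
}

pdb_atom_lines <- function(atoms, xyz = NULL) {
  if (is.null(xyz)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
  }
  name4 <- ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000, substr(name4, 1, 4),
          substr(atoms$resname, 1, 3),
          atoms$chain, atoms$resnum %% 10000,
          ifelse(atoms$icode == "", " ", atoms$icode),
          xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10, 1, 0, atoms$element)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param complex an [annotated_complex()] (topology).
#' @param ensemble a [trajectory_ensemble()]; one file per replica when
#'   `ensemble` has several replicas and `path` contains `%s`.
#' @param path output path (single replica) or template with `%s`.
#' @return character vector of files written, invisibly.
#' @export
write_trajectory_pdb <- function(complex, ensemble, path) {
  files <- character(0)
  multi <- length(ensemble$replicas) > 1
  for (r in ensemble$replicas) {
    p <- if (multi) sprintf(path, r$id) else path
    con <- file(p, "w")
    if (!is.null(r$box)) writeLines(cryst1_line(r$box[1, ]), con)
    for (f in seq_len(nrow(r$xyz))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf("REMARK  TIME %.6f", r$time[f]), con)
      xyz <- matrix(r$xyz[f, ], ncol = 3, byrow = TRUE)
      writeLines(pdb_atom_lines(complex$atoms, xyz), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    close(con)
    files <- c(files, p)
  }
  invisible(files)
}

#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB or a DCD file as one replica against a known
#' topology.  PDB/DCD coordinates (Angstrom) are converted to nm.
#'
#' @param path trajectory file.
#' @param topology the [annotated_complex()] the frames belong to.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @param dt frame spacing in ns used when the file carries no times.
#' @param replica_id id stored on the replica.
#' @return a single-replica [trajectory_ensemble()].
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "dcd"),
                            dt = 1, replica_id = "rep1") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  n_top <- nrow(topology$atoms)
  if (format == "pdb") {
    parsed <- parse_pdb(readLines(path), path, first_model_only = FALSE)
    models <- parsed$models
    if (is.null(models)) {
      models <- list(as.vector(t(as.matrix(parsed$atoms[, c("x", "y", "z")]))))
    }
    if (length(models) == 0) abort(paste0("zero frames in ", path))
    xyz <- do.call(rbind, models)
    times <- parsed$times %||% (seq_len(nrow(xyz)) - 1) * dt
    box <- if (!is.null(parsed$box)) {
      matrix(parsed$box, nrow(xyz), 3, byrow = TRUE)
    }
  } else {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      abort("DCD reading requires the bio3d package")
    }
    xyz <- bio3d::read.dcd(path, verbose = FALSE) * 0.1
    times <- (seq_len(nrow(xyz)) - 1) * dt
    box <- NULL
  }
  if (ncol(xyz) != 3 * n_top) {
    abort(paste0("trajectory atom count (", ncol(xyz) / 3,
                 ") does not match topology (", n_top, ")"))
  }
  trajectory_ensemble(list(list(id = replica_id, xyz = xyz, box = box,
                                time = times)))
}
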