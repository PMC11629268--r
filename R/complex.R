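#' Annotated molecular complex
#'
#' The central structure container: a flat atom table, a residue table with
#' generic-numbering (Ballesteros-Weinstein for receptors, CGN-style for G
#' alpha, strand-loop names for arrestin) and substructure annotations, and
#' a chain-role map distinguishing receptor, partner, membrane, water and
#' ion chains.  Coordinates are always stored in nm.
#'
#' @param atoms tibble with columns serial, name, element, chain, resnum,
#'   icode, resname, x, y, z (nm).
#' @param chain_roles named character vector chain -> role; roles are
#'   `receptor`, `partner`, `membrane`, `water`, `ion`.  Missing chains are
#'   defaulted: solvent/ion chains by residue name, the first remaining
#'   chain `receptor`, the rest `partner`.
#' @param disulfides optional list of residue-key pairs.
#' @return an object of class `annotated_complex` with elements `atoms`
#'   (tibble, including derived columns `is_backbone`, `is_sidechain_heavy`,
#'   `vdw_radius`, `mass`, `residue_index`), `residues` (tibble with
#'   `generic_number`, `substructure`, `chain_role`), `chain_roles`,
#'   `disulfides`.
#' @export
annotated_complex <- function(atoms, chain_roles = NULL, disulfides = list()) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("serial", "name", "element", "chain", "resnum", "icode",
           "resname", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(atoms$serial)) {
    abort(paste0("duplicate atom serial(s): ",
                 paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", ")))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite atom coordinates")
  }

  atoms$element <- toupper(atoms$element)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$chain <- as.character(atoms$chain)
  atoms$icode <- as.character(atoms$icode)
  atoms$is_backbone <- atoms$name %in% .backbone_names &
    !atoms$resname %in% c(.water_resnames, .ion_resnames)
  atoms$is_sidechain_heavy <- !atoms$is_backbone & atoms$element != "H" &
    !atoms$resname %in% c(.water_resnames, .ion_resnames)
  atoms$vdw_radius <- element_radius(atoms$element)
  atoms$mass <- element_mass(atoms$element)

  res_key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
  ures <- !duplicated(res_key)
  residues <- tibble::tibble(
    chain = atoms$chain[ures],
    resnum = atoms$resnum[ures],
    icode = atoms$icode[ures],
    resname = atoms$resname[ures],
    generic_number = NA_character_,
    substructure = NA_character_
  )
  atoms$residue_index <- match(res_key, res_key[ures])

  # default chain roles from residue naming
  roles <- character(0)
  for (ch in unique(residues$chain)) {
    rn <- residues$resname[residues$chain == ch]
    roles[ch] <- if (all(rn %in% .water_resnames)) "water"
      else if (all(rn %in% .ion_resnames)) "ion"
      else NA_character_
  }
  prot <- names(roles)[is.na(roles)]
  if (length(prot)) {
    roles[prot[1]] <- "receptor"
    if (length(prot) > 1) roles[prot[-1]] <- "partner"
  }
  if (!is.null(chain_roles)) {
    bad <- setdiff(names(chain_roles), names(roles))
    if (length(bad)) abort(paste0("chain_roles names unknown chains: ",
                                  paste(bad, collapse = ", ")))
    roles[names(chain_roles)] <- unname(chain_roles)
  }
  residues$chain_role <- unname(roles[residues$chain])

  structure(
    list(atoms = atoms, residues = residues, chain_roles = roles,
         disulfides = disulfides),
    class = "annotated_complex"
  )
}

#' @export
print.annotated_complex <- function(x, ...) {
  cat("<annotated_complex> ", nrow(x$atoms), " atoms, ",
      nrow(x$residues), " residues\n", sep = "")
  rl <- table(x$residues$chain_role)
  cat("  chains:", paste(sprintf("%s(%s)", names(x$chain_roles), x$chain_roles),
                         collapse = " "), "\n")
  cat("  residues by role:", paste(sprintf("%s=%d", names(rl), rl), collapse = " "), "\n")
  n_gn <- sum(!is.na(x$residues$generic_number))
  cat("  generic numbers assigned:", n_gn, "\n")
  invisible(x)
}

#' Resolve a residue selector
#'
#' Looks a residue up either by generic number (e.g. `"3.50"`, `"H5.23"`)
#' or by residue key `list(chain=, resnum=, icode=)` / `"A/141"` string.
#'
#' @param complex an [annotated_complex()].
#' @param selector generic-number string, `"chain/resnum"` string, or a list
#'   with `chain`, `resnum` and optional `icode`.
#' @return one-row tibble (the residue record) with its `residue_index`.
#' @export
resolve <- function(complex, selector) {
  res <- complex$residues
  res$residue_index <- seq_len(nrow(res))
  if (is.list(selector) && !is.null(selector$chain)) {
    icode <- selector$icode %||% ""
    hit <- which(res$chain == selector$chain & res$resnum == selector$resnum &
                   res$icode == icode)
  } else if (is.character(selector) && grepl("/", selector, fixed = TRUE)) {
    parts <- strsplit(selector, "/", fixed = TRUE)[[1]]
    hit <- which(res$chain == parts[1] & res$resnum == as.integer(parts[2]))
  } else if (is.character(selector)) {
    hit <- which(!is.na(res$generic_number) & res$generic_number == selector)
  } else {
    abort("malformed residue selector")
  }
  if (length(hit) == 0) {
    abort(paste0("no residue matches selector '", format_selector(selector), "'"))
  }
  if (length(hit) > 1) {
    abort(paste0("selector '", format_selector(selector), "' is ambiguous"))
  }
  res[hit, , drop = FALSE]
}

format_selector <- function(selector) {
  if (is.list(selector)) paste(selector$chain, selector$resnum, sep = "/")
  else as.character(selector)
}

#' @keywords internal
residue_atom_idx <- function(complex, residue_index, names = NULL,
                             heavy_only = FALSE, sidechain = FALSE) {
  a <- complex$atoms
  idx <- which(a$residue_index == residue_index)
  if (!is.null(names)) idx <- idx[a$name[idx] %in% names]
  if (heavy_only) idx <- idx[a$element[idx] != "H"]
  if (sidechain) idx <- idx[a$is_sidechain_heavy[idx]]
  idx
}

# side-chain heavy atoms with glycine fallback to CA
#' @keywords internal
sidechain_idx_or_ca <- function(complex, residue_index) {
  idx <- residue_atom_idx(complex, residue_index, sidechain = TRUE)
  if (length(idx) == 0) {
    idx <- residue_atom_idx(complex, residue_index, names = "CA")
  }
  if (length(idx) == 0) {
    abort("residue has neither side-chain heavy atoms nor CA")
  }
  idx
}

#' @keywords internal
chains_with_role <- function(complex, role) {
  names(complex$chain_roles)[complex$chain_roles %in% role]
}

#' @keywords internal
atoms_in_chains <- function(complex, chains) {
  which(complex$atoms$chain %in% chains)
}

#' Attach residue annotations from a table
#'
#' Reads a TSV with columns `chain`, `resnum`, `icode`, `generic_number`,
#' `substructure` and attaches generic numbers and substructure labels to
#' the matching residues of the complex.
#'
#' @param path TSV file path (header required).
#' @param complex an [annotated_complex()].
#' @return the complex with annotations attached.
#' @export
read_annotation_table <- function(path, complex) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chain = readr::col_character(), resnum = readr::col_integer(),
    icode = readr::col_character(), generic_number = readr::col_character(),
    substructure = readr::col_character()
  ), progress = FALSE)
  apply_annotations(complex, tab)
}

#' @rdname read_annotation_table
#' @param table a data frame with the same columns as the TSV.
#' @export
apply_annotations <- function(complex, table) {
  tab <- tibble::as_tibble(table)
  if (nrow(tab) == 0) return(complex)
  tab$icode[is.na(tab$icode)] <- ""
  res <- complex$residues
  key <- paste(res$chain, res$resnum, res$icode, sep = "|")
  tkey <- paste(tab$chain, tab$resnum, tab$icode, sep = "|")
  hit <- match(tkey, key)
  if (anyNA(hit)) {
    abort(paste0("annotation rows reference nonexistent residues: ",
                 paste(tkey[is.na(hit)], collapse = ", ")))
  }
  dup <- tab %>%
    dplyr::filter(!is.na(.data$generic_number)) %>%
    dplyr::count(.data$chain, .data$generic_number) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate generic_number within a chain: ",
                 paste(paste0(dup$chain, ":", dup$generic_number), collapse = ", ")))
  }
  res$generic_number[hit] <- tab$generic_number
  res$substructure[hit] <- tab$substructure
  complex$residues <- res
  complex
}

#' Annotation table of a complex
#'
#' @param complex an [annotated_complex()].
#' @return tibble with columns chain, resnum, icode, generic_number,
#'   substructure (annotated residues only).
#' @export
annotation_table <- function(complex) {
  complex$residues %>%
    dplyr::filter(!is.na(.data$generic_number) | !is.na(.data$substructure)) %>%
    dplyr::select("chain", "resnum", "icode", "generic_number", "substructure")
}
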