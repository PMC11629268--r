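#' SASA parameters
#'
#' Parameters of the Shrake-Rupley solvent-accessible surface area
#' calculation: probe radius (water, 0.14 nm by convention), number of
#' deterministic golden-spiral test points per atom, and an optional
#' element radius override table.
#'
#' @param probe probe radius, nm (default 0.14).
#' @param n_points sphere points per atom (default 960; >= 32).
#' @param radii optional named numeric vector element -> radius (nm)
#'   overriding the bundled Bondi-style table.
#' @return a `sasa_params` list.
#' @export
sasa_params <- function(probe = 0.14, n_points = 960, radii = NULL) {
  if (probe < 0) abort("probe radius must be >= 0")
  if (n_points < 32) abort("n_points must be >= 32")
  structure(list(probe = probe, n_points = as.integer(n_points),
                 radii = radii), class = "sasa_params")
}

#' @keywords internal
atom_radii_for <- function(complex, idx, params) {
  if (is.null(params$radii)) return(complex$atoms$vdw_radius[idx])
  el <- toupper(complex$atoms$element[idx])
  r <- params$radii[el]
  if (anyNA(r)) {
    abort(paste0("no radius for element(s): ",
                 paste(unique(el[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Per-residue SASA of an atom subset
#'
#' Shrake-Rupley SASA of the atoms of the given chains, computed with the
#' other atoms of the complex entirely absent (they neither occlude nor
#' contribute); summed per residue, nm^2.
#'
#' @param complex an [annotated_complex()].
#' @param coords n_atoms-by-3 coordinate matrix (nm); defaults to the
#'   structure's own coordinates.
#' @param chains chain subset to include.
#' @param params a [sasa_params()].
#' @return tibble: chain, resnum, resname, sasa (nm^2).
#' @export
sasa_per_residue <- function(complex, coords = NULL, chains, params = sasa_params()) {
  idx <- atoms_in_chains(complex, chains)
  if (length(idx) == 0) abort("empty chain subset for SASA")
  if (is.null(coords)) coords <- as.matrix(complex$atoms[, c("x", "y", "z")])
  per_atom <- .sasa_shrake_rupley(coords[idx, , drop = FALSE],
                                  atom_radii_for(complex, idx, params),
                                  params$probe, params$n_points)
  tibble::tibble(
    residue_index = complex$atoms$residue_index[idx],
    sasa = per_atom
  ) %>%
    dplyr::group_by(.data$residue_index) %>%
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop") %>%
    dplyr::mutate(
      chain = complex$residues$chain[.data$residue_index],
      resnum = complex$residues$resnum[.data$residue_index],
      resname = complex$residues$resname[.data$residue_index]
    ) %>%
    dplyr::select("chain", "resnum", "resname", "sasa")
}

#' Per-atom SASA of an arbitrary coordinate/radius set
#'
#' Low-level access to the Shrake-Rupley kernel, mainly for analytic
#' checks and oracles.
#'
#' @param coords n-by-3 matrix, nm.
#' @param radii atom radii, nm.
#' @param params a [sasa_params()].
#' @return numeric vector of per-atom areas, nm^2.
#' @export
sasa_atoms <- function(coords, radii, params = sasa_params()) {
  .sasa_shrake_rupley(as.matrix(coords), radii, params$probe, params$n_points)
}
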