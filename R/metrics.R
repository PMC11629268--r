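#' Calpha-Calpha distance series
#'
#' Per-frame Euclidean distance (minimum-image when box vectors are
#' present) between the Calpha atoms of two residues, nm.  This is the
#' standard TM3-TM6 (3.50/6.34) and TM3-TM7 (3.50/7.53) activation
#' read-out.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param complex the matching [annotated_complex()].
#' @param res_a,res_b residue selectors as in [resolve()] (generic numbers
#'   such as "3.50" or "chain/resnum").
#' @return a [metric_series()], unit "nm".
#' @export
ca_distance <- function(ensemble, complex, res_a, res_b) {
  ia <- resolve(complex, res_a)$residue_index
  ib <- resolve(complex, res_b)$residue_index
  ca <- function(ri) {
    i <- residue_atom_idx(complex, ri, names = "CA")
    if (length(i) != 1) abort("residue lacks a CA atom")
    i
  }
  ia <- ca(ia); ib <- ca(ib)
  out <- purrr::map(ensemble$replicas, function(rep) {
    pair_distance(atom_series(rep, ia), atom_series(rep, ib),
                  box = if (!is.null(rep$box)) rep$box[1, ])
  })
  series_from_replicas(
    ensemble, out,
    paste0("ca_distance_", format_selector(res_a), "_", format_selector(res_b)),
    "nm")
}

# per-frame side-chain COM of one residue over one replica
sc_com_series <- function(rep, complex, residue_index) {
  idx <- sidechain_idx_or_ca(complex, residue_index)
  com_series(rep, idx, complex$atoms$mass)
}

#' Side-chain centre-of-mass distance series
#'
#' Per-frame distance between the mass-weighted centres of mass of the
#' side-chain heavy atoms of two residues (glycine falls back to Calpha),
#' nm.  Used for the TM3-TM7 packing (3.43/7.53) and transmission-switch
#' (3.40/6.48, 5.51/6.44) read-outs.
#'
#' @inheritParams ca_distance
#' @return a [metric_series()], unit "nm".
#' @export
sidechain_com_distance <- function(ensemble, complex, res_a, res_b) {
  ia <- resolve(complex, res_a)$residue_index
  ib <- resolve(complex, res_b)$residue_index
  out <- purrr::map(ensemble$replicas, function(rep) {
    ca_ <- sc_com_series(rep, complex, ia)
    cb_ <- sc_com_series(rep, complex, ib)
    pair_distance(ca_, cb_, box = if (!is.null(rep$box)) rep$box[1, ])
  })
  series_from_replicas(
    ensemble, out,
    paste0("sc_com_distance_", format_selector(res_a), "_", format_selector(res_b)),
    "nm")
}

#' Motif backbone RMSD to a reference structure
#'
#' Superposes each frame onto an annotated reference structure over a fit
#' selection (typically receptor transmembrane Calpha atoms), then reports
#' the RMSD over the motif backbone atoms (N, CA, C, O) without
#' re-fitting, nm.  The canonical use is the NPxxY motif (7.49-7.53)
#' against an inactive-state reference.
#'
#' @inheritParams ca_distance
#' @param motif character vector of residue selectors forming the motif.
#' @param reference an [annotated_complex()] carrying the same annotations
#'   (the inactive reference).
#' @param fit_selectors residue selectors for the fit; their CA atoms are
#'   used.  Defaults to all receptor residues with generic numbers.
#' @return a [metric_series()], unit "nm".
#' @export
motif_rmsd <- function(ensemble, complex, motif, reference,
                       fit_selectors = NULL) {
  backbone <- c("N", "CA", "C", "O")
  map_atoms <- function(cx, selectors, names) {
    unlist(purrr::map(selectors, function(s) {
      ri <- resolve(cx, s)$residue_index
      idx <- residue_atom_idx(cx, ri, names = names)
      if (length(idx) != length(names)) {
        abort(paste0("motif residue ", format_selector(s),
                     " lacks backbone atoms in one structure"))
      }
      idx[match(names, cx$atoms$name[idx])]
    }))
  }
  fit_selectors <- fit_selectors %||% {
    r <- complex$residues
    r$generic_number[!is.na(r$generic_number) & r$chain_role == "receptor"]
  }
  fit_mob <- unlist(purrr::map(fit_selectors, function(s) {
    residue_atom_idx(complex, resolve(complex, s)$residue_index, names = "CA")
  }))
  fit_ref <- unlist(purrr::map(fit_selectors, function(s) {
    residue_atom_idx(reference, resolve(reference, s)$residue_index, names = "CA")
  }))
  motif_mob <- map_atoms(complex, motif, backbone)
  motif_ref <- map_atoms(reference, motif, backbone)
  ref_xyz <- as.matrix(reference$atoms[, c("x", "y", "z")])
  ref_fit <- ref_xyz[fit_ref, , drop = FALSE]
  ref_motif <- ref_xyz[motif_ref, , drop = FALSE]
  out <- purrr::map(ensemble$replicas, function(rep) {
    vapply(seq_len(nrow(rep$xyz)), function(f) {
      Xs <- kabsch_fit(frame_coords_of(rep, f), ref_fit, fit_mob)
      sqrt(mean(rowSums((Xs[motif_mob, , drop = FALSE] - ref_motif)^2)))
    }, numeric(1))
  })
  series_from_replicas(ensemble, out, "motif_rmsd", "nm")
}

#' Triangle area from three side-chain centres of mass
#'
#' Per frame, the three pairwise side-chain COM distances are combined by
#' Heron's formula into a triangle area, nm^2.  This is the sodium-pocket
#' (2.50/3.39/7.49) and hydrophobic-lock (3.43/6.40/6.41) read-out.
#' Degenerate (collinear beyond tolerance) frames yield area 0.
#'
#' @inheritParams ca_distance
#' @param res_c third residue selector.
#' @return a [metric_series()], unit "nm^2".
#' @export
triangle_area <- function(ensemble, complex, res_a, res_b, res_c) {
  idx <- purrr::map_int(list(res_a, res_b, res_c),
                        ~ resolve(complex, .x)$residue_index)
  if (length(unique(idx)) != 3) abort("triangle requires three distinct residues")
  out <- purrr::map(ensemble$replicas, function(rep) {
    p <- purrr::map(idx, ~ sc_com_series(rep, complex, .x))
    d1 <- pair_distance(p[[1]], p[[2]])
    d2 <- pair_distance(p[[2]], p[[3]])
    d3 <- pair_distance(p[[1]], p[[3]])
    heron_area(d1, d2, d3)
  })
  series_from_replicas(ensemble, out, "triangle_area", "nm^2")
}

#' Heron's formula (degenerate-safe)
#' @param a,b,c side lengths.
#' @return triangle areas; 0 where the triangle inequality is violated
#'   within numerical tolerance.
#' @export
heron_area <- function(a, b, c) {
  s <- (a + b + c) / 2
  arg <- s * (s - a) * (s - b) * (s - c)
  sqrt(pmax(arg, 0))
}

#' Distance to the closest ion
#'
#' Per frame, the minimum over all ions of the named type of the distance
#' between the residue's Calpha and the ion (minimum image), nm.
#'
#' @inheritParams ca_distance
#' @param res residue selector (e.g. "2.50").
#' @param ion ion residue name (default "NA", sodium).
#' @return a [metric_series()], unit "nm".
#' @export
closest_ion_distance <- function(ensemble, complex, res, ion = "NA") {
  ri <- resolve(complex, res)$residue_index
  ica <- residue_atom_idx(complex, ri, names = "CA")
  if (length(ica) != 1) abort("residue lacks a CA atom")
  ions <- which(complex$atoms$resname == toupper(ion) &
                  complex$residues$chain_role[complex$atoms$residue_index] == "ion")
  if (length(ions) == 0) abort(paste0("no ions of type ", ion, " in complex"))
  out <- purrr::map(ensemble$replicas, function(rep) {
    box <- if (!is.null(rep$box)) rep$box[1, ]
    ca <- atom_series(rep, ica)
    d <- matrix(Inf, nrow(rep$xyz), length(ions))
    for (j in seq_along(ions)) {
      d[, j] <- pair_distance(ca, atom_series(rep, ions[j]), box = box)
    }
    apply(d, 1, min)
  })
  series_from_replicas(ensemble, out, paste0("closest_", ion, "_distance"), "nm")
}

#' Water count within a shell of a residue
#'
#' Per frame, the number of water molecules whose oxygen lies within
#' `radius` of any heavy atom of the residue (minimum image).  The
#' most inclusive reading ("any heavy atom") is the default; `ref = "ca"`
#' or `"com"` switch the reference point.
#'
#' @inheritParams ca_distance
#' @param res residue selector.
#' @param radius shell radius in Angstrom (the conventional unit for this
#'   cutoff; default 8 A = 0.8 nm).
#' @param ref `"heavy"` (default), `"ca"` or `"com"`.
#' @return a [metric_series()], unit "count".
#' @export
water_count <- function(ensemble, complex, res, radius = 8, ref = "heavy") {
  if (radius <= 0) abort("radius must be positive")
  r_nm <- radius / 10
  ri <- resolve(complex, res)$residue_index
  wat_o <- which(complex$atoms$resname %in% .water_resnames &
                   complex$atoms$element == "O")
  if (length(wat_o) == 0) {
    warning("no water molecules in complex; returning zero counts")
    out <- purrr::map(ensemble$replicas, ~ rep(0, nrow(.x$xyz)))
    return(series_from_replicas(ensemble, out, "water_count", "count"))
  }
  ref_idx <- switch(ref,
    heavy = residue_atom_idx(complex, ri, heavy_only = TRUE),
    ca = residue_atom_idx(complex, ri, names = "CA"),
    com = sidechain_idx_or_ca(complex, ri),
    abort("ref must be 'heavy', 'ca' or 'com'"))
  out <- purrr::map(ensemble$replicas, function(rep) {
    box <- if (!is.null(rep$box)) rep$box[1, ]
    n <- nrow(rep$xyz)
    within <- matrix(FALSE, n, length(wat_o))
    if (ref == "com") {
      refs <- com_series(rep, ref_idx, complex$atoms$mass)
      for (j in seq_along(wat_o)) {
        within[, j] <- pair_distance(refs, atom_series(rep, wat_o[j]),
                                     box = box) <= r_nm
      }
    } else {
      for (j in seq_along(wat_o)) {
        dmin <- rep(Inf, n)
        wa <- atom_series(rep, wat_o[j])
        for (i in ref_idx) {
          dmin <- pmin(dmin, pair_distance(atom_series(rep, i), wa, box = box))
        }
        within[, j] <- dmin <= r_nm
      }
    }
    rowSums(within)
  })
  series_from_replicas(ensemble, out, "water_count", "count")
}

#' The standard activation metric set
#'
#' Convenience wrapper computing the eight class-A activation read-outs in
#' one call using Ballesteros-Weinstein selectors: TM3-TM6 Calpha distance
#' (3.50/6.34), TM3-TM7 Calpha distance (3.50/7.53), TM3-TM7 side-chain
#' packing (3.43/7.53), transmission switch (3.40/6.48 and 5.51/6.44),
#' sodium-pocket area (2.50/3.39/7.49), hydrophobic-lock area
#' (3.43/6.40/6.41), closest sodium ion to 2.50, and water count within
#' 8 A of 2.50.  Metrics whose selectors or particles are absent are
#' skipped with a message.  NPxxY motif RMSD requires a reference and is
#' computed only when `inactive_reference` is supplied.
#'
#' @inheritParams ca_distance
#' @param inactive_reference optional annotated inactive-state structure
#'   for the NPxxY backbone RMSD.
#' @return named list of [metric_series()].
#' @export
activation_metrics <- function(ensemble, complex, inactive_reference = NULL) {
  out <- list()
  try_metric <- function(name, fn) {
    v <- tryCatch(fn(), error = function(e) {
      message("skipping ", name, ": ", conditionMessage(e)); NULL
    })
    if (!is.null(v)) out[[name]] <<- v
  }
  try_metric("tm3_tm6_ca", function() ca_distance(ensemble, complex, "3.50", "6.34"))
  try_metric("tm3_tm7_ca", function() ca_distance(ensemble, complex, "3.50", "7.53"))
  try_metric("tm3_tm7_sc", function() sidechain_com_distance(ensemble, complex, "3.43", "7.53"))
  try_metric("switch_3.40_6.48", function() sidechain_com_distance(ensemble, complex, "3.40", "6.48"))
  try_metric("switch_5.51_6.44", function() sidechain_com_distance(ensemble, complex, "5.51", "6.44"))
  try_metric("na_pocket_area", function() triangle_area(ensemble, complex, "2.50", "3.39", "7.49"))
  try_metric("hydrophobic_lock_area", function() triangle_area(ensemble, complex, "3.43", "6.40", "6.41"))
  try_metric("closest_na", function() closest_ion_distance(ensemble, complex, "2.50", "NA"))
  try_metric("water_count_2.50", function() water_count(ensemble, complex, "2.50", radius = 8))
  if (!is.null(inactive_reference)) {
    try_metric("npxxy_rmsd", function() {
      motif_rmsd(ensemble, complex, c("7.49", "7.50", "7.51", "7.52", "7.53"),
                 inactive_reference)
    })
  }
  out
}
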