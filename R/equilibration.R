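#' Receptor helicity over time
#'
#' Per frame, the fraction of receptor residues whose backbone dihedrals
#' fall inside the alpha-helical window (phi in \[-100, -30\] deg, psi in
#' \[-67, -7\] deg by default).  A dihedral-window definition is used rather
#' than hydrogen-bond pattern assignment: it is dependency-free and fully
#' adequate as a stationarity diagnostic.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param complex the matching [annotated_complex()].
#' @param chains chains to score; default all receptor chains.
#' @param phi_window,psi_window helical windows in degrees.
#' @return a [metric_series()], unit "fraction".
#' @export
helicity <- function(ensemble, complex, chains = NULL,
                     phi_window = c(-100, -30), psi_window = c(-67, -7)) {
  chains <- chains %||% chains_with_role(complex, "receptor")
  res <- complex$residues
  out <- purrr::map(ensemble$replicas, function(rep) {
    n <- nrow(rep$xyz)
    in_window <- matrix(0, n, 0)
    for (ch in chains) {
      cr <- which(res$chain == ch)
      if (length(cr) < 3) abort("chain too short for backbone dihedrals")
      ca_idx <- function(ri, nm) {
        i <- which(complex$atoms$residue_index == ri & complex$atoms$name == nm)
        if (length(i) != 1) NA_integer_ else i
      }
      for (p in 2:(length(cr) - 1)) {
        ri <- cr[p]
        i_cprev <- ca_idx(cr[p - 1], "C")
        i_n <- ca_idx(ri, "N"); i_ca <- ca_idx(ri, "CA"); i_c <- ca_idx(ri, "C")
        i_nnext <- ca_idx(cr[p + 1], "N")
        if (anyNA(c(i_cprev, i_n, i_ca, i_c, i_nnext))) next
        phi <- dihedral_angle(atom_series(rep, i_cprev), atom_series(rep, i_n),
                              atom_series(rep, i_ca), atom_series(rep, i_c))
        psi <- dihedral_angle(atom_series(rep, i_n), atom_series(rep, i_ca),
                              atom_series(rep, i_c), atom_series(rep, i_nnext))
        ok <- phi >= phi_window[1] & phi <= phi_window[2] &
          psi >= psi_window[1] & psi <= psi_window[2]
        in_window <- cbind(in_window, as.numeric(ok))
      }
    }
    if (ncol(in_window) == 0) abort("no scorable residues for helicity")
    rowMeans(in_window)
  })
  series_from_replicas(ensemble, out, "helicity", "fraction")
}

#' Receptor-membrane z offset
#'
#' Per frame, the absolute z-component of the distance between the
#' mass-weighted centres of mass of the receptor and of the membrane (or
#' membrane stand-in particle set), in nm.
#'
#' @inheritParams helicity
#' @param membrane_chains chains of the membrane selection; default all
#'   chains with role `membrane`.
#' @return a [metric_series()], unit "nm".
#' @export
membrane_offset <- function(ensemble, complex, chains = NULL,
                            membrane_chains = NULL) {
  chains <- chains %||% chains_with_role(complex, "receptor")
  membrane_chains <- membrane_chains %||% chains_with_role(complex, "membrane")
  ri <- atoms_in_chains(complex, chains)
  mi <- atoms_in_chains(complex, membrane_chains)
  if (length(ri) == 0 || length(mi) == 0) {
    abort("empty receptor or membrane selection")
  }
  m <- complex$atoms$mass
  out <- purrr::map(ensemble$replicas, function(rep) {
    abs(com_series(rep, ri, m)[, 3] - com_series(rep, mi, m)[, 3])
  })
  series_from_replicas(ensemble, out, "membrane_offset_z", "nm")
}

#' Simulation box xy area
#'
#' Per frame, the product of the x and y box vectors, nm^2.
#'
#' @param ensemble a [trajectory_ensemble()] with box information.
#' @return a [metric_series()], unit "nm^2".
#' @export
box_area <- function(ensemble) {
  out <- purrr::map(ensemble$replicas, function(rep) {
    if (is.null(rep$box)) abort("trajectory carries no box vectors")
    rep$box[, 1] * rep$box[, 2]
  })
  series_from_replicas(ensemble, out, "box_area", "nm^2")
}

# indices of CA atoms of the given chains
#' @keywords internal
ca_selection <- function(complex, chains) {
  which(complex$atoms$chain %in% chains & complex$atoms$name == "CA")
}

#' RMSD time series after least-squares superposition
#'
#' Per frame, each structure is superposed (Kabsch) onto the reference over
#' `fit_idx`, then the RMSD over `sel_idx` is computed, in nm.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param complex the matching [annotated_complex()].
#' @param sel_idx atom indices the RMSD is computed over (e.g. CA atoms).
#' @param reference reference coordinates: `"first"` (initial frame of each
#'   replica) or an n_atoms-by-3 matrix.
#' @param fit_idx atom indices used for the superposition; defaults to
#'   `sel_idx`.
#' @return a [metric_series()], unit "nm".
#' @export
rmsd_series <- function(ensemble, complex, sel_idx, reference = "first",
                        fit_idx = NULL) {
  fit_idx <- fit_idx %||% sel_idx
  if (length(sel_idx) < 1 || length(fit_idx) < 3) {
    abort("selection must have >= 1 atom and fit selection >= 3 atoms")
  }
  out <- purrr::map(ensemble$replicas, function(rep) {
    ref <- if (is.matrix(reference)) reference else frame_coords_of(rep, 1)
    ref_fit <- ref[fit_idx, , drop = FALSE]
    check_fit_conditioning(ref_fit)
    vapply(seq_len(nrow(rep$xyz)), function(f) {
      Xf <- frame_coords_of(rep, f)
      Xs <- kabsch_fit(Xf, ref_fit, fit_idx)
      sqrt(mean(rowSums((Xs[sel_idx, , drop = FALSE] -
                           ref[sel_idx, , drop = FALSE])^2)))
    }, numeric(1))
  })
  series_from_replicas(ensemble, out, "rmsd", "nm")
}

frame_coords_of <- function(rep, f) {
  matrix(rep$xyz[f, ], ncol = 3, byrow = TRUE)
}

check_fit_conditioning <- function(ref_fit) {
  sv <- svd(sweep(ref_fit, 2, colMeans(ref_fit)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
    abort("fit selection is degenerate (collinear); superposition ill-conditioned")
  }
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed to the first frame, the mean structure is formed,
#' frames are re-fitted to it, and the RMSF per selected atom is
#' sqrt(mean |r - <r>|^2), nm.  Values are averaged over replicas.
#'
#' @inheritParams rmsd_series
#' @param sel_idx atom indices to report (typically CA atoms).
#' @return tibble with columns chain, resnum, resname, atom, rmsf.
#' @export
rmsf <- function(ensemble, complex, sel_idx) {
  if (sum(n_frames(ensemble)) < 2) abort("RMSF requires at least 2 frames")
  per_rep <- purrr::map(ensemble$replicas, function(rep) {
    n <- nrow(rep$xyz)
    ref <- frame_coords_of(rep, 1)[sel_idx, , drop = FALSE]
    fitted <- array(0, c(n, length(sel_idx), 3))
    for (f in seq_len(n)) {
      Xs <- kabsch_fit(frame_coords_of(rep, f), ref, sel_idx)
      fitted[f, , ] <- Xs[sel_idx, ]
    }
    mean_str <- apply(fitted, c(2, 3), mean)
    for (f in seq_len(n)) {
      Xs <- kabsch_fit(matrix(fitted[f, , ], ncol = 3), mean_str,
                       seq_along(sel_idx))
      fitted[f, , ] <- Xs
    }
    mean_str <- apply(fitted, c(2, 3), mean)
    dev2 <- 0
    for (f in seq_len(n)) {
      dev2 <- dev2 + rowSums((matrix(fitted[f, , ], ncol = 3) - mean_str)^2)
    }
    sqrt(dev2 / n)
  })
  vals <- rowMeans(do.call(cbind, per_rep))
  a <- complex$atoms[sel_idx, ]
  tibble::tibble(chain = a$chain, resnum = a$resnum, resname = a$resname,
                 atom = a$name, rmsf = vals)
}

#' Detect the equilibrated part of a run
#'
#' Applies a windowed stationarity rule to a set of metric series: the
#' discard time is the earliest frame time t such that, for every metric,
#' the mean of each subsequent window of width `window` ns lies within
#' `k` standard deviations (of the final half of that metric) of the
#' final-half mean.  If no such time exists the full length is flagged.
#' A fixed cut can be imposed with `discard`, reproducing the common
#' fixed-window workflow.
#'
#' @param metrics list of [metric_series()] sharing a time grid.
#' @param window window width, ns (default 50).
#' @param k tolerance in final-half standard deviations (default 2).
#' @param discard optional fixed discard time in ns overriding the rule.
#' @return a list of class `equilibration_report`: `discard_time` (named
#'   per replica, ns), `flags` tibble (per metric and replica: stationary
#'   from detected time), `window`, `k`.
#' @export
detect_equilibration <- function(metrics, window = 50, k = 2, discard = NULL) {
  if (length(metrics) == 0) abort("no metric series supplied")
  reps <- unique(unlist(purrr::map(metrics, ~ unique(.x$replica))))
  if (!is.null(discard)) {
    dt_rep <- setNames(rep(discard, length(reps)), reps)
    flags <- tidyr::expand_grid(replica = reps,
                                metric = vapply(metrics, attr, "",
                                                which = "metric_name"))
    flags$converged <- TRUE
    return(structure(list(discard_time = dt_rep, flags = flags,
                          window = window, k = k, fixed = TRUE),
                     class = "equilibration_report"))
  }
  per_rep <- purrr::map(setNames(reps, reps), function(r) {
    cuts <- purrr::map_dbl(metrics, function(ms) {
      d <- ms[ms$replica == r, ]
      stationary_onset(d$time, d$value, window, k)
    })
    names(cuts) <- vapply(metrics, attr, "", which = "metric_name")
    cuts
  })
  dt_rep <- vapply(per_rep, max, numeric(1))
  flags <- dplyr::bind_rows(purrr::imap(per_rep, function(cuts, r) {
    tibble::tibble(replica = r, metric = names(cuts), onset = cuts,
                   converged = is.finite(cuts))
  }))
  warn_flag <- !all(flags$converged)
  end_time <- max(unlist(purrr::map(metrics, ~ max(.x$time))))
  dt_rep[!is.finite(dt_rep)] <- end_time
  structure(list(discard_time = dt_rep, flags = flags, window = window,
                 k = k, fixed = FALSE, warning = warn_flag),
            class = "equilibration_report")
}

# earliest time from which every subsequent window mean is within k sigma
# of the final-half mean; Inf if never
stationary_onset <- function(time, value, window, k) {
  n <- length(time)
  half <- value[time >= (time[1] + (time[n] - time[1]) / 2)]
  mu <- mean(half)
  # noise scale from first differences: robust against residual slow trend,
  # so a drifting final half does not inflate the acceptance band
  sigma <- stats::sd(diff(half)) / sqrt(2)
  if (!is.finite(sigma) || sigma < 1e-12) sigma <- 1e-12
  # window means on a rolling grid anchored at each candidate start; a
  # candidate must leave at least one full window of tail to assess
  for (s in which(time <= time[n] - window)) {
    t0 <- time[s]
    ok <- TRUE
    w_start <- t0
    while (w_start < time[n] - 1e-9) {
      in_w <- time >= w_start & time < w_start + window
      if (any(in_w)) {
        if (abs(mean(value[in_w]) - mu) > k * sigma) { ok <- FALSE; break }
      }
      w_start <- w_start + window
    }
    if (ok) return(t0)
  }
  Inf
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat("<equilibration_report> window =", x$window, "ns, k =", x$k, "\n")
  for (r in names(x$discard_time)) {
    cat(sprintf("  %s: discard first %.1f ns\n", r, x$discard_time[r]))
  }
  if (isTRUE(x$warning)) cat("  warning: some metrics never stationary\n")
  invisible(x)
}
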