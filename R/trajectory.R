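#' Trajectory ensemble container
#'
#' Holds one or more replicas of a trajectory for a fixed topology.  Each
#' replica stores frame coordinates as an `n_frames x (3 * n_atoms)` matrix
#' in bio3d-style flat layout (x1, y1, z1, x2, ...), orthorhombic box
#' vectors (nm) and frame times (ns).
#'
#' @param replicas list of replicas; each replica is a list with elements
#'   `id`, `xyz` (frames-by-3n matrix, nm), `box` (frames-by-3 matrix, nm,
#'   or NULL for non-periodic), `time` (ns, strictly increasing).
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(replicas) {
  if (length(replicas) == 0) abort("trajectory has zero replicas")
  n3 <- unique(vapply(replicas, function(r) ncol(r$xyz), integer(1)))
  if (length(n3) != 1) abort("replicas disagree on atom count")
  for (r in replicas) {
    if (nrow(r$xyz) == 0) abort("replica has zero frames")
    if (length(r$time) != nrow(r$xyz)) abort("times and frames differ in length")
    if (any(diff(r$time) <= 0)) abort("frame times must be strictly increasing")
    if (!is.null(r$box)) {
      if (any(!is.finite(r$box)) || any(r$box <= 0)) {
        abort("box components must be positive")
      }
    }
  }
  structure(list(replicas = replicas, n_atoms = n3 / 3L),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) nrow(r$xyz), integer(1))
  cat("<trajectory_ensemble> ", length(x$replicas), " replica(s), ",
      x$n_atoms, " atoms\n", sep = "")
  for (i in seq_along(x$replicas)) {
    r <- x$replicas[[i]]
    cat(sprintf("  %s: %d frames, t = %.3f..%.3f ns\n",
                r$id, nf[i], min(r$time), max(r$time)))
  }
  invisible(x)
}

#' @keywords internal
n_frames <- function(ensemble) {
  vapply(ensemble$replicas, function(r) nrow(r$xyz), integer(1))
}

#' Extract one frame as an n-by-3 coordinate matrix
#' @param ensemble a [trajectory_ensemble()].
#' @param replica replica index.
#' @param frame frame index.
#' @return n_atoms-by-3 matrix, nm.
#' @export
frame_coords <- function(ensemble, replica, frame) {
  matrix(ensemble$replicas[[replica]]$xyz[frame, ], ncol = 3, byrow = TRUE)
}

# coordinates of one atom across frames of one replica: n_frames x 3
#' @keywords internal
atom_series <- function(rep, atom_idx) {
  rep$xyz[, (3 * (atom_idx - 1) + 1):(3 * atom_idx), drop = FALSE]
}

# per-frame COM of a fixed atom selection, n_frames x 3
#' @keywords internal
com_series <- function(rep, idx, masses) {
  m <- masses[idx]
  out <- matrix(0, nrow(rep$xyz), 3)
  for (k in seq_along(idx)) {
    out <- out + m[k] * atom_series(rep, idx[k])
  }
  out / sum(m)
}

#' Discard the start of each replica
#'
#' Drops all frames with time < `discard` (ns).  `discard` may be a single
#' value applied to every replica or a vector with one entry per replica.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param discard time in ns; frames strictly before it are removed.
#' @return the truncated ensemble.
#' @export
discard_initial <- function(ensemble, discard) {
  discard <- rep_len(discard, length(ensemble$replicas))
  reps <- purrr::map2(ensemble$replicas, discard, function(r, d) {
    keep <- r$time >= d
    if (!any(keep)) abort("discard window removes every frame of a replica")
    r$xyz <- r$xyz[keep, , drop = FALSE]
    if (!is.null(r$box)) r$box <- r$box[keep, , drop = FALSE]
    r$time <- r$time[keep]
    r
  })
  trajectory_ensemble(reps)
}

#' Combine single-replica ensembles
#' @param ... trajectory_ensemble objects.
#' @return one ensemble with all replicas.
#' @export
bind_replicas <- function(...) {
  ens <- list(...)
  reps <- purrr::flatten(purrr::map(ens, "replicas"))
  ids <- vapply(reps, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    for (i in seq_along(reps)) reps[[i]]$id <- paste0("rep", i)
  }
  trajectory_ensemble(reps)
}
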