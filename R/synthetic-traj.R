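#' @keywords internal
rvonmises <- function(n, mu_deg, kappa) {
  # Best & Fisher (1979) rejection sampler; kappa = 0 falls back to uniform
  if (kappa < 1e-8) return(runif(n, -180, 180))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      th <- sign(u3 - 0.5) * acos(f)
      out[i] <- th + mu
      i <- i + 1
    }
  }
  wrap_angle(out * 180 / pi)
}

#' @keywords internal
sample_torsion_mixture <- function(n, modes) {
  w <- vapply(modes, function(m) m[3], numeric(1))
  comp <- sample.int(length(modes), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_along(modes)) {
    nk <- sum(comp == k)
    if (nk > 0) out[comp == k] <- rvonmises(nk, modes[[k]][1], modes[[k]][2])
  }
  out
}

# parent map of a residue type's side-chain template (atom -> parent atom)
sc_parent_map <- function(resname) {
  tmpl <- sidechain_template(resname)
  if (is.null(tmpl)) return(character(0))
  setNames(vapply(tmpl, function(r) r$c, character(1)),
           vapply(tmpl, function(r) r$atom, character(1)))
}

# side-chain atom names downstream of `through` (exclusive) in the template
sc_downstream <- function(resname, through) {
  pm <- sc_parent_map(resname)
  hits <- character(0)
  for (atom in names(pm)) {
    a <- atom
    found <- FALSE
    repeat {
      p <- if (a %in% names(pm)) pm[[a]] else NULL
      if (is.null(p)) break
      if (p == through) { found <- TRUE; break }
      a <- p
    }
    if (found) hits <- c(hits, atom)
  }
  hits
}

# set a named torsion of one residue to `value` (deg) in coordinate set X
#' @keywords internal
set_torsion <- function(X, complex, residue_index, angle, value) {
  res <- complex$residues[residue_index, ]
  a <- complex$atoms
  own <- function(name) {
    i <- which(a$residue_index == residue_index & a$name == name)
    if (length(i) != 1) abort(paste0("atom ", name, " not found for torsion"))
    i
  }
  if (grepl("^chi[0-9]$", angle)) {
    k <- as.integer(substr(angle, 4, 4))
    defs <- chi_definitions(res$resname)
    if (is.null(defs) || length(defs) < k) {
      abort(paste0(res$resname, " has no ", angle))
    }
    q <- defs[[k]]
    idx <- vapply(q, own, integer(1))
    moving_names <- unique(c(q[4], sc_downstream(res$resname, q[3])))
    moving <- which(a$residue_index == residue_index & a$name %in% moving_names)
  } else if (angle %in% c("phi", "psi")) {
    chain_res <- which(complex$residues$chain == res$chain)
    pos_in_chain <- match(residue_index, chain_res)
    if (angle == "phi") {
      if (pos_in_chain == 1) abort("first residue has no phi")
      prev <- chain_res[pos_in_chain - 1]
      idx <- c(which(a$residue_index == prev & a$name == "C"),
               own("N"), own("CA"), own("C"))
      moving <- which((a$residue_index == residue_index & a$name %in% c("C", "O")) |
                        (a$chain == res$chain & a$residue_index > residue_index))
    } else {
      if (pos_in_chain == length(chain_res)) abort("last residue has no psi")
      nxt <- chain_res[pos_in_chain + 1]
      idx <- c(own("N"), own("CA"), own("C"),
               which(a$residue_index == nxt & a$name == "N"))
      moving <- which((a$residue_index == residue_index & a$name == "O") |
                        (a$chain == res$chain & a$residue_index > residue_index))
    }
  } else {
    abort(paste0("unsupported torsion name: ", angle))
  }
  cur <- dihedral_angle(X[idx[1], ], X[idx[2], ], X[idx[3], ], X[idx[4], ])
  delta <- wrap_angle(value - cur)
  if (length(moving) > 0 && abs(delta) > 1e-12) {
    X[moving, ] <- rotate_about_axis(X[moving, , drop = FALSE], X[idx[3], ],
                                     X[idx[3], ] - X[idx[2], ], delta)
  }
  X
}

# measurement point of a residue for distance targets
target_point <- function(X, complex, residue_index, kind) {
  if (kind == "ca") {
    i <- residue_atom_idx(complex, residue_index, names = "CA")
    if (length(i) == 0) i <- residue_atom_idx(complex, residue_index)[1]
    X[i[1], ]
  } else if (kind == "com") {
    i <- sidechain_idx_or_ca(complex, residue_index)
    mass_com(X[i, , drop = FALSE], complex$atoms$mass[i])
  } else {
    X[residue_atom_idx(complex, residue_index)[1], ]
  }
}

#' Generate a synthetic trajectory ensemble
#'
#' Realises the statistical targets of a [synthetic_spec()] on the toy
#' complex: Gaussian distance series by rigid displacement of the second
#' residue along the pair axis, von Mises mixture draws applied to named
#' torsions, scripted burial of interface residues by a dedicated blocker
#' group, scripted contact geometry strictly inside/outside each category's
#' criterion, and an optional exponentially relaxing drift segment
#' prepended to each replica.  The realisation (masks, draws, frame times)
#' is recorded in the `ground_truth` attribute of the returned ensemble.
#'
#' @param complex the [generate_toy_complex()] output for the same spec.
#' @param spec the [synthetic_spec()].
#' @return a [trajectory_ensemble()] with attribute `ground_truth`.
#' @export
generate_trajectory <- function(complex, spec) {
  check_spec_conflicts(complex, spec)
  X0 <- as.matrix(complex$atoms[, c("x", "y", "z")])
  n_stat <- spec$n_frames
  n_drift <- if (!is.null(spec$drift)) {
    round((spec$drift$duration %||% (4 * spec$drift$tau)) / spec$dt)
  } else 0L
  n_total <- n_stat + n_drift
  receptor_atoms <- atoms_in_chains(complex, chains_with_role(complex, "receptor"))

  # blocker residue indices in schedule order
  blk_res <- which(complex$residues$resname == "BLK")
  if (length(spec$burial_schedule) > length(blk_res)) {
    abort("complex has fewer blocker residues than burial schedule entries")
  }

  replicas <- vector("list", spec$n_replicas)
  truth <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    set.seed(spec$seed + 1000L * (r - 1L))
    dist_draws <- purrr::map(spec$distance_targets, function(d) {
      rnorm(n_total, d$mean, d$sd)
    })
    tor_draws <- purrr::map(spec$torsion_targets, function(tt) {
      sample_torsion_mixture(n_total, tt$modes)
    })
    stat_frames <- n_drift + seq_len(n_stat)
    # the first stationary frame is kept exposed so a scheduled residue is
    # an additional-interface candidate, not an original member
    burial_masks <- purrr::map(spec$burial_schedule, function(b) {
      k <- round(b$fraction * n_stat)
      pool <- stat_frames[-1]
      if (k > length(pool)) sort(c(stat_frames[1], sample(pool, k - 1)))
      else sort(sample(pool, k))
    })
    contact_masks <- purrr::map(spec$contact_schedule, function(cs) {
      k <- round(cs$occupancy / 100 * n_stat)
      sort(sample(stat_frames, k))
    })

    prot_atoms <- atoms_in_chains(
      complex, chains_with_role(complex, c("receptor", "partner")))

    xyz <- matrix(NA_real_, n_total, 3 * nrow(X0))
    for (f in seq_len(n_total)) {
      X <- X0
      if (spec$jitter > 0) {
        X[prot_atoms, ] <- X[prot_atoms, ] +
          matrix(rnorm(3 * length(prot_atoms), 0, spec$jitter),
                 ncol = 3)
      }
      for (j in seq_along(spec$torsion_targets)) {
        tt <- spec$torsion_targets[[j]]
        ri <- resolve(complex, tt$residue)$residue_index
        X <- set_torsion(X, complex, ri, tt$angle, tor_draws[[j]][f])
      }
      for (j in seq_along(spec$distance_targets)) {
        d <- spec$distance_targets[[j]]
        kind <- d$kind %||% "ca"
        ra <- resolve(complex, d$a)$residue_index
        rb <- resolve(complex, d$b)$residue_index
        pa <- target_point(X, complex, ra, kind)
        pb <- target_point(X, complex, rb, kind)
        u <- unitv(pb - pa)
        shift <- (pa + dist_draws[[j]][f] * u) - pb
        ib <- residue_atom_idx(complex, rb)
        X[ib, ] <- sweep(X[ib, , drop = FALSE], 2, shift, "+")
      }
      for (j in seq_along(spec$burial_schedule)) {
        if (f %in% burial_masks[[j]]) {
          b <- spec$burial_schedule[[j]]
          ri <- resolve(complex, b$residue)$residue_index
          hi <- residue_atom_idx(complex, ri, heavy_only = TRUE)
          rc <- colMeans(X[hi, , drop = FALSE])
          out_dir <- rc - colMeans(X[receptor_atoms, , drop = FALSE])
          out_dir <- if (vnorm(out_dir) < 1e-9) c(1, 0, 0) else unitv(out_dir)
          bi <- residue_atom_idx(complex, blk_res[j])
          X[bi, ] <- sweep(fibonacci_sphere(length(bi), 0.2), 2,
                           rc + 0.35 * out_dir, "+")
        }
      }
      for (j in seq_along(spec$contact_schedule)) {
        cs <- spec$contact_schedule[[j]]
        X <- place_contact(X, complex, cs, on = f %in% contact_masks[[j]])
      }
      if (n_drift > 0 && f <= n_drift) {
        t_d <- (f - 1) * spec$dt
        off <- spec$drift$amplitude * exp(-t_d / spec$drift$tau)
        X[receptor_atoms, 3] <- X[receptor_atoms, 3] + off
      }
      xyz[f, ] <- as.vector(t(X))
    }
    times <- (seq_len(n_total) - 1) * spec$dt
    replicas[[r]] <- list(id = paste0("rep", r), xyz = xyz,
                          box = matrix(spec$box, n_total, 3, byrow = TRUE),
                          time = times)
    truth[[r]] <- list(
      replica = paste0("rep", r),
      n_drift = n_drift,
      time = times,
      distance_draws = dist_draws,
      torsion_draws = tor_draws,
      burial_frames = burial_masks,
      contact_frames = contact_masks
    )
  }
  ens <- trajectory_ensemble(replicas)
  attr(ens, "ground_truth") <- list(spec_seed = spec$seed, dt = spec$dt,
                                    n_frames = n_stat, n_drift = n_drift,
                                    replicas = truth)
  ens
}

check_spec_conflicts <- function(complex, spec) {
  moved <- c(
    vapply(spec$distance_targets, function(d) format_selector(d$b), character(1)),
    vapply(spec$contact_schedule, function(cs) format_selector(cs$b), character(1))
  )
  dup <- moved[duplicated(moved)]
  if (length(dup)) {
    abort(paste0("mutually inconsistent targets move the same residue: ",
                 paste(unique(dup), collapse = ", ")))
  }
}

# construct on/off contact geometry by moving residue b rigidly
place_contact <- function(X, complex, cs, on) {
  ra <- resolve(complex, cs$a)$residue_index
  rb <- resolve(complex, cs$b)$residue_index
  resa <- complex$residues$resname[ra]
  resb <- complex$residues$resname[rb]
  chem_a <- residue_chemistry(resa)
  chem_b <- residue_chemistry(resb)
  named_idx <- function(ri, nm) {
    i <- residue_atom_idx(complex, ri, names = nm)
    if (length(i) == 0) abort(paste0("contact schedule: no atoms ",
                                     paste(nm, collapse = "/"), " in residue"))
    i[1]
  }
  ib_all <- residue_atom_idx(complex, rb)
  translate_b <- function(shift) {
    X[ib_all, ] <<- sweep(X[ib_all, , drop = FALSE], 2, shift, "+")
  }
  cat <- cs$category
  off_d <- 1.5
  if (cat %in% c("ionic", "salt_bridge")) {
    if (length(chem_a$neg) && length(chem_b$pos)) {
      ia <- named_idx(ra, chem_a$neg); ib <- named_idx(rb, chem_b$pos)
    } else if (length(chem_a$pos) && length(chem_b$neg)) {
      ia <- named_idx(ra, chem_a$pos); ib <- named_idx(rb, chem_b$neg)
    } else abort("ionic schedule requires oppositely charged residues")
    d <- if (on) 0.30 else off_d
    u <- unitv(X[ib, ] - X[ia, ])
    translate_b((X[ia, ] + d * u) - X[ib, ])
  } else if (cat == "hbond") {
    don <- if (length(chem_a$donors)) chem_a$donors else "N"
    acc <- if (length(chem_b$acceptors)) chem_b$acceptors else "O"
    ia <- named_idx(ra, don); ib <- named_idx(rb, acc)
    d <- if (on) 0.30 else off_d
    u <- unitv(X[ib, ] - X[ia, ])
    translate_b((X[ia, ] + d * u) - X[ib, ])
  } else if (cat == "hydrophobic") {
    ia <- named_idx(ra, chem_a$hydrophobic); ib <- named_idx(rb, chem_b$hydrophobic)
    d <- if (on) 0.40 else off_d
    u <- unitv(X[ib, ] - X[ia, ])
    translate_b((X[ia, ] + d * u) - X[ib, ])
  } else if (cat == "vdw") {
    ha <- residue_atom_idx(complex, ra, heavy_only = TRUE)
    hb <- residue_atom_idx(complex, rb, heavy_only = TRUE)
    ia <- ha[1]; ib <- hb[1]
    d_on <- complex$atoms$vdw_radius[ia] + complex$atoms$vdw_radius[ib] + 0.02
    d <- if (on) d_on else off_d
    u <- unitv(X[ib, ] - X[ia, ])
    translate_b((X[ia, ] + d * u) - X[ib, ])
  } else if (cat == "pi_cation") {
    if (length(chem_a$ring)) {
      ring_i <- residue_atom_idx(complex, ra, names = chem_a$ring)
      icat <- named_idx(rb, chem_b$pos)
      g <- ring_geometry(X[ring_i, , drop = FALSE])
      d <- if (on) 0.45 else off_d
      translate_b((g$centroid + d * g$normal) - X[icat, ])
    } else {
      ring_i <- residue_atom_idx(complex, rb, names = chem_b$ring)
      icat <- named_idx(ra, chem_a$pos)
      g <- ring_geometry(X[ring_i, , drop = FALSE])
      d <- if (on) 0.45 else off_d
      # move b so its ring centroid sits on the cation axis
      translate_b((X[icat, ] + d * g$normal) - g$centroid)
    }
  } else if (cat %in% c("pi_stack", "t_stack")) {
    ring_a <- residue_atom_idx(complex, ra, names = chem_a$ring)
    ring_b <- residue_atom_idx(complex, rb, names = chem_b$ring)
    ga <- ring_geometry(X[ring_a, , drop = FALSE])
    gb <- ring_geometry(X[ring_b, , drop = FALSE])
    target_n <- if (cat == "pi_stack") ga$normal else orth_complement(ga$normal)
    # rotate b about its ring centroid so its normal matches target
    cr <- vcross(gb$normal, target_n)
    s <- vnorm(cr)
    cth <- sum(gb$normal * target_n)
    if (s > 1e-9) {
      ang <- atan2(s, cth) * 180 / pi
      X[ib_all, ] <- rotate_about_axis(X[ib_all, , drop = FALSE], gb$centroid,
                                       cr, ang)
    }
    gb <- ring_geometry(X[ring_b, , drop = FALSE])
    d <- if (on) { if (cat == "pi_stack") 0.45 else 0.55 } else off_d
    translate_b((ga$centroid + d * ga$normal) - gb$centroid)
  } else {
    abort(paste0("unknown contact category: ", cat))
  }
  X
}

orth_complement <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(vcross(v, u))
}

#' Write a synthetic fixture to disk
#'
#' Emits the toy complex as PDB, each replica as a multi-model PDB, the
#' annotation TSV and the realised ground truth as JSON.
#'
#' @param complex an [annotated_complex()].
#' @param ensemble a [trajectory_ensemble()] (typically from
#'   [generate_trajectory()]).
#' @param dir output directory (created if missing).
#' @return named list of file paths written, invisibly.
#' @export
write_fixture <- function(complex, ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  box <- ensemble$replicas[[1]]$box
  files <- list(
    structure = file.path(dir, "complex.pdb"),
    annotation = file.path(dir, "annotation.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_structure(complex, files$structure,
                  box = if (!is.null(box)) box[1, ])
  traj_files <- character(0)
  for (r in ensemble$replicas) {
    p <- file.path(dir, paste0("traj_", r$id, ".pdb"))
    write_trajectory_pdb(complex, trajectory_ensemble(list(r)), p)
    traj_files <- c(traj_files, p)
  }
  files$trajectories <- traj_files
  readr::write_tsv(annotation_table(complex), files$annotation, progress = FALSE)
  gt <- attr(ensemble, "ground_truth") %||% list()
  jsonlite::write_json(gt, files$ground_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}
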