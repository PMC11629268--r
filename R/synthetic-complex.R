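#' Specification of a synthetic toy system
#'
#' Describes a fully deterministic toy receptor-partner complex and the
#' statistical structure of the trajectory to generate for it: Gaussian
#' inter-residue distance series, wrapped-mixture torsion distributions,
#' scripted interface burial schedules, scripted contact on/off schedules
#' with target occupancies, explicit solvent shells and an optional
#' non-equilibrated drift segment.  All realised quantities are recorded as
#' ground truth at generation time.
#'
#' @param seed integer RNG seed; the whole realisation is a deterministic
#'   function of the spec including this seed.
#' @param n_frames number of stationary frames per replica.
#' @param n_replicas number of replicas (replica r uses seed + 1000 * (r-1)).
#' @param dt frame spacing, ns.
#' @param box orthorhombic box vector, nm.
#' @param helix_layout list of chain layouts; each a list with `chain`,
#'   `role` ("receptor"/"partner"), `sequence` (three-letter codes),
#'   `first_resnum`, `origin` (nm), `axis`, optional `phi`, `psi` (deg,
#'   defaults -57/-47), optional `generic_numbers` and `substructure`
#'   character vectors (one entry per residue).
#' @param distance_targets list of `list(a=, b=, mean=, sd=, kind=)` with
#'   selectors as in [resolve()]; `kind` is `"ca"` (default), `"com"`
#'   (side-chain centre of mass) or `"atom"` (first atom of each residue,
#'   used for ion approaches).  Residue `b` is displaced.
#' @param torsion_targets list of `list(residue=, angle=, modes=)` where
#'   `modes` is a list of `c(mode_deg, kappa, weight)` von Mises components
#'   (weights summing to 1).
#' @param burial_schedule list of `list(residue=, fraction=)`; each entry
#'   gets a dedicated blocker pseudo-residue on the partner chain that
#'   covers the residue in exactly `round(fraction * n_frames)` frames.
#' @param contact_schedule list of `list(a=, b=, category=, occupancy=)`
#'   with occupancy in percent; `b` (partner side) is moved into/out of the
#'   category's geometric criterion.
#' @param solvent list of shells `list(n_waters=, n_na=, center=, radius=)`.
#' @param membrane optional `list(n_particles=, z_center=, half_extent=)`
#'   slab of phosphorus-like particles (chain "M", role membrane).
#' @param drift optional `list(tau=, amplitude=, duration=)` (ns, nm, ns):
#'   a prepended segment in which the receptor is displaced by
#'   `amplitude * exp(-t/tau)` along +z, emulating initial relaxation.
#' @param jitter standard deviation (nm) of isotropic Gaussian positional
#'   noise added independently per protein atom, axis and frame before any
#'   scheduled modification (scheduled quantities stay exact).  Default 0.
#' @return a `synthetic_spec` object (validated list).
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 100L, n_replicas = 1L,
                           dt = 1, box = c(30, 30, 30),
                           helix_layout = list(),
                           distance_targets = list(),
                           torsion_targets = list(),
                           burial_schedule = list(),
                           contact_schedule = list(),
                           solvent = list(), membrane = NULL, drift = NULL,
                           jitter = 0) {
  spec <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
               n_replicas = as.integer(n_replicas), dt = dt, box = box,
               helix_layout = helix_layout,
               distance_targets = distance_targets,
               torsion_targets = torsion_targets,
               burial_schedule = burial_schedule,
               contact_schedule = contact_schedule,
               solvent = solvent, membrane = membrane, drift = drift,
               jitter = jitter)
  if (jitter < 0) abort("jitter must be >= 0")
  for (d in distance_targets) {
    if (is.null(d$sd) || d$sd <= 0) abort("distance target SD must be > 0")
  }
  for (b in burial_schedule) {
    if (b$fraction < 0 || b$fraction > 1) abort("burial fraction must be in [0,1]")
  }
  for (cs in contact_schedule) {
    if (cs$occupancy < 0 || cs$occupancy > 100) {
      abort("contact occupancy must be in [0,100] percent")
    }
  }
  for (tt in torsion_targets) {
    w <- sum(vapply(tt$modes, function(m) m[3], numeric(1)))
    if (abs(w - 1) > 1e-9) abort("torsion mode weights must sum to 1")
  }
  structure(spec, class = "synthetic_spec")
}

# build a linear peptide with fixed backbone dihedrals via internal
# coordinates; returns tibble(name, resname, resnum, x, y, z)
#' @keywords internal
build_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                          first_resnum = 1L,
                          chi_defaults = c(chi1 = -60, chi2 = 180, chi3 = 180,
                                           chi4 = 180, chi5 = 0)) {
  nres <- length(sequence)
  if (nres < 1) abort("empty sequence")
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  rows <- list()
  # per-residue named position store for side-chain references
  pos <- vector("list", nres)
  add <- function(i, name, p) {
    pos[[i]][[name]] <<- as.numeric(p)
    rows[[length(rows) + 1]] <<- list(name = name, resname = sequence[i],
                                      resnum = first_resnum + i - 1L,
                                      x = p[1], y = p[2], z = p[3])
  }
  ang <- function(d) d * pi / 180
  # seed backbone of residue 1
  add(1, "N", c(0, 0, 0))
  add(1, "CA", c(0.1458, 0, 0))
  u <- c(-cos(ang(111.2)), sin(ang(111.2)), 0)
  add(1, "C", pos[[1]]$CA + 0.1525 * u)
  for (i in seq_len(nres)) {
    if (i > 1) {
      n_new <- nerf_place(pos[[i - 1]]$N, pos[[i - 1]]$CA, pos[[i - 1]]$C,
                          0.1329, 116.2, psi[i - 1])
      add(i, "N", n_new)
      add(i, "CA", nerf_place(pos[[i - 1]]$CA, pos[[i - 1]]$C, pos[[i]]$N,
                              0.1458, 121.7, omega))
      add(i, "C", nerf_place(pos[[i - 1]]$C, pos[[i]]$N, pos[[i]]$CA,
                             0.1525, 111.2, phi[i]))
    }
    # carbonyl O: torsion psi + 180 about CA-C
    add(i, "O", nerf_place(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                           0.1229, 120.5, psi[i] + 180))
    tmpl <- sidechain_template(sequence[i])
    if (is.null(tmpl)) abort(paste0("no side-chain template for ", sequence[i]))
    for (row in tmpl) {
      tor <- resolve_torsion_value(row$tor, chi_defaults)
      add(i, row$atom, nerf_place(pos[[i]][[row$a]], pos[[i]][[row$b]],
                                  pos[[i]][[row$c]], row$r, row$ang, tor))
    }
  }
  dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
}

# torsion spec may be numeric or "chiK" / "chiK+d" / "chiK-d"
#' @keywords internal
resolve_torsion_value <- function(tor, chi_values) {
  if (is.numeric(tor)) return(tor)
  m <- regmatches(tor, regexec("^chi([0-9])([+-][0-9.]+)?$", tor))[[1]]
  if (length(m) == 0) abort(paste0("malformed torsion reference: ", tor))
  base <- chi_values[[paste0("chi", m[2])]]
  off <- if (m[3] == "") 0 else as.numeric(m[3])
  wrap_angle(base + off)
}

# rigid transform: rotate CA principal axis onto `axis`, centre at `origin`
align_chain <- function(coords, ca_rows, axis, origin) {
  X <- as.matrix(coords)
  ca <- X[ca_rows, , drop = FALSE]
  ctr <- colMeans(ca)
  Xc <- sweep(X, 2, ctr)
  if (nrow(ca) >= 3) {
    v <- svd(sweep(ca, 2, ctr))$v[, 1]
    # orient consistently: along increasing residue order
    if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v
    b <- unitv(axis)
    cr <- vcross(v, b)
    s <- vnorm(cr)
    cth <- sum(v * b)
    if (s > 1e-12) {
      k <- cr / s
      kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      th <- atan2(s, cth)
      R <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
      Xc <- Xc %*% t(R)
    } else if (cth < 0) {
      Xc <- -Xc
    }
  }
  sweep(Xc, 2, origin, "+")
}

#' @keywords internal
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a toy receptor-partner complex
#'
#' Builds the fully atomistic toy system described by a [synthetic_spec()]:
#' ideal helical chains with side chains from idealised internal
#' coordinates, blocker pseudo-residues for each burial schedule entry,
#' solvent shells, ions and an optional membrane slab.  Annotations
#' (generic numbers, substructures) from the layout are attached.
#'
#' @param spec a [synthetic_spec()].
#' @return an [annotated_complex()] centred in `spec$box / 2`.
#' @export
generate_toy_complex <- function(spec) {
  if (length(spec$helix_layout) == 0) abort("helix_layout is empty")
  serial <- 0L
  all_atoms <- list()
  roles <- character(0)
  ann <- list()
  centre <- spec$box / 2

  for (lay in spec$helix_layout) {
    pep <- build_peptide(lay$sequence, phi = lay$phi %||% -57,
                         psi = lay$psi %||% -47,
                         first_resnum = lay$first_resnum %||% 1L)
    ca_rows <- which(pep$name == "CA")
    xyz <- align_chain(pep[, c("x", "y", "z")], ca_rows,
                       lay$axis %||% c(0, 0, 1),
                       centre + (lay$origin %||% c(0, 0, 0)))
    pep$x <- xyz[, 1]; pep$y <- xyz[, 2]; pep$z <- xyz[, 3]
    pep$chain <- lay$chain
    pep$icode <- ""
    pep$element <- guess_element(pep$name, pep$resname)
    pep$serial <- serial + seq_len(nrow(pep))
    serial <- serial + nrow(pep)
    all_atoms[[length(all_atoms) + 1]] <- pep
    roles[lay$chain] <- lay$role %||% "receptor"
    nres <- length(lay$sequence)
    ann[[length(ann) + 1]] <- tibble::tibble(
      chain = lay$chain,
      resnum = (lay$first_resnum %||% 1L) + seq_len(nres) - 1L,
      icode = "",
      generic_number = lay$generic_numbers %||% rep(NA_character_, nres),
      substructure = rep_len(lay$substructure %||% NA_character_, nres)
    )
  }

  # steric check between protein chains
  prot <- dplyr::bind_rows(all_atoms)
  for (c1 in unique(prot$chain)) {
    for (c2 in unique(prot$chain)) {
      if (c1 >= c2) next
      X1 <- as.matrix(prot[prot$chain == c1, c("x", "y", "z")])
      X2 <- as.matrix(prot[prot$chain == c2, c("x", "y", "z")])
      dmin <- min_cross_dist(X1, X2)
      if (dmin < 0.2) {
        abort(sprintf("chains %s and %s overlap (min distance %.3f nm < 0.2 nm)",
                      c1, c2, dmin))
      }
    }
  }

  # blocker pseudo-residues: one per burial entry, parked far in +z
  if (length(spec$burial_schedule) > 0) {
    partner_chain <- names(roles)[roles == "partner"][1]
    if (is.na(partner_chain)) abort("burial schedule requires a partner chain")
    max_resnum <- max(prot$resnum[prot$chain == partner_chain])
    blocks <- list()
    for (k in seq_along(spec$burial_schedule)) {
      shell <- fibonacci_sphere(8, 0.2)
      park <- centre + c(2 * k, 0, spec$box[3] / 2 - 2)
      blocks[[k]] <- tibble::tibble(
        name = paste0("C", 1:8), resname = "BLK",
        resnum = max_resnum + k,
        x = shell[, 1] + park[1], y = shell[, 2] + park[2],
        z = shell[, 3] + park[3],
        chain = partner_chain, icode = "", element = "C",
        serial = serial + 1:8
      )
      serial <- serial + 8L
      ann[[length(ann) + 1]] <- tibble::tibble(
        chain = partner_chain, resnum = max_resnum + k, icode = "",
        generic_number = NA_character_, substructure = "decoy"
      )
    }
    all_atoms <- c(all_atoms, blocks)
  }

  # membrane slab: grid of P particles at z_center
  if (!is.null(spec$membrane)) {
    mem <- spec$membrane
    n <- mem$n_particles
    side <- ceiling(sqrt(n))
    g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n), ]
    he <- mem$half_extent %||% 3
    all_atoms[[length(all_atoms) + 1]] <- tibble::tibble(
      name = "P", resname = "MEM", resnum = seq_len(n),
      x = centre[1] + (g$ix - (side + 1) / 2) / side * 2 * he,
      y = centre[2] + (g$iy - (side + 1) / 2) / side * 2 * he,
      z = mem$z_center,
      chain = "M", icode = "", element = "P", serial = serial + seq_len(n)
    )
    serial <- serial + n
    roles["M"] <- "membrane"
  }

  atoms <- dplyr::bind_rows(all_atoms)
  cplx <- annotated_complex(atoms, chain_roles = roles)
  cplx <- apply_annotations(cplx, dplyr::bind_rows(ann))

  # solvent shells (deterministic placement around named residues)
  if (length(spec$solvent) > 0) {
    sol_atoms <- list()
    wat_res <- 0L
    ion_res <- 0L
    for (sh in spec$solvent) {
      ctr_res <- resolve(cplx, sh$center)
      idx <- residue_atom_idx(cplx, ctr_res$residue_index, heavy_only = TRUE)
      ctr0 <- colMeans(as.matrix(cplx$atoms[idx, c("x", "y", "z")]))
      nw <- sh$n_waters %||% 0L
      if (nw > 0) {
        o <- sweep(fibonacci_sphere(nw, sh$radius), 2, ctr0, "+")
        for (w in seq_len(nw)) {
          wat_res <- wat_res + 1L
          sol_atoms[[length(sol_atoms) + 1]] <- tibble::tibble(
            name = c("O", "H1", "H2"), resname = "HOH", resnum = wat_res,
            x = o[w, 1] + c(0, 0.0957, -0.024),
            y = o[w, 2] + c(0, 0, 0.0927),
            z = o[w, 3],
            chain = "W", icode = "", element = c("O", "H", "H"),
            serial = serial + 1:3
          )
          serial <- serial + 3L
        }
      }
      ni <- sh$n_na %||% 0L
      if (ni > 0) {
        p <- sweep(fibonacci_sphere(ni, sh$radius * 1.05), 2, ctr0, "+")
        for (w in seq_len(ni)) {
          ion_res <- ion_res + 1L
          sol_atoms[[length(sol_atoms) + 1]] <- tibble::tibble(
            name = "NA", resname = "NA", resnum = ion_res,
            x = p[w, 1], y = p[w, 2], z = p[w, 3],
            chain = "I", icode = "", element = "NA", serial = serial + 1L
          )
          serial <- serial + 1L
        }
      }
    }
    atoms <- dplyr::bind_rows(atoms, dplyr::bind_rows(sol_atoms))
    roles["W"] <- "water"; roles["I"] <- "ion"
    roles <- roles[!is.na(names(roles))]
    cplx2 <- annotated_complex(atoms, chain_roles = roles[names(roles) %in% atoms$chain])
    cplx2 <- apply_annotations(cplx2, dplyr::bind_rows(ann))
    cplx <- cplx2
  }
  cplx
}

#' @keywords internal
min_cross_dist <- function(X1, X2) {
  # chunked to bound memory
  dmin <- Inf
  step <- 2000
  for (s in seq(1, nrow(X1), by = step)) {
    e <- min(s + step - 1, nrow(X1))
    d2 <- outer(rowSums(X1[s:e, , drop = FALSE]^2), rowSums(X2^2), "+") -
      2 * X1[s:e, , drop = FALSE] %*% t(X2)
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  dmin
}
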