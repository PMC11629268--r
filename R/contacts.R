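#' Geometric contact criteria
#'
#' Distance/angle thresholds for the interaction categories: ionic
#' (charged-group N/O pair), salt bridge (ionic pair also satisfying
#' hydrogen-bond geometry), hydrogen bond (donor-acceptor heavy-atom
#' distance, with a donor-H-acceptor angle criterion when hydrogens are
#' present and a heavy-atom-only fallback when they are not), aromatic
#' (pi-cation, pi-stacking, T-stacking on ring centroids and normals),
#' hydrophobic (apolar carbon pairs) and van der Waals (radius sum plus a
#' pad; the residual category, suppressed for a residue pair whenever a
#' more specific category holds).  Defaults mirror widely used
#' interaction-fingerprint conventions; every threshold is configurable
#' and echoed into outputs.
#'
#' @param ionic_dist charged N/O pair cutoff, nm.
#' @param hbond_dist donor-acceptor heavy-atom cutoff, nm.
#' @param hbond_angle minimum donor-H-acceptor angle, degrees.
#' @param pi_cation_dist,pi_cation_angle cation-centroid cutoff (nm) and
#'   maximum off-axis angle (deg).
#' @param pi_stack_dist,pi_stack_angle centroid cutoff (nm) and maximum
#'   ring-normal angle (deg) for parallel stacking.
#' @param t_stack_dist,t_stack_angle centroid cutoff (nm) and normal angle
#'   window (deg, length 2) for T-stacking.
#' @param hydrophobic_dist apolar carbon pair cutoff, nm.
#' @param vdw_pad pad added to the radius sum, nm.
#' @return a `contact_criteria` list.
#' @export
contact_criteria <- function(ionic_dist = 0.40, hbond_dist = 0.35,
                             hbond_angle = 110, pi_cation_dist = 0.60,
                             pi_cation_angle = 60, pi_stack_dist = 0.70,
                             pi_stack_angle = 30, t_stack_dist = 0.70,
                             t_stack_angle = c(60, 90),
                             hydrophobic_dist = 0.45, vdw_pad = 0.05) {
  out <- as.list(environment())
  if (any(unlist(out) <= 0)) abort("all contact thresholds must be positive")
  structure(out, class = "contact_criteria")
}

# precompute atom-class indices for the two groups
contact_env <- function(complex, chains_a, chains_b) {
  a <- complex$atoms
  res <- complex$residues
  grp <- function(chains) {
    ridx <- which(res$chain %in% chains)
    pos <- integer(0); neg <- integer(0); don <- integer(0); acc <- integer(0)
    hyd <- integer(0); heavy <- integer(0)
    rings <- list()
    for (ri in ridx) {
      rn <- res$resname[ri]
      if (rn == "BLK") {
        heavy <- c(heavy, residue_atom_idx(complex, ri, heavy_only = TRUE))
        next
      }
      chem <- residue_chemistry(rn)
      pos <- c(pos, residue_atom_idx(complex, ri, names = chem$pos))
      neg <- c(neg, residue_atom_idx(complex, ri, names = chem$neg))
      don <- c(don, residue_atom_idx(complex, ri, names = c(chem$donors,
        if (rn != "PRO") "N")))
      acc <- c(acc, residue_atom_idx(complex, ri, names = c(chem$acceptors, "O")))
      hyd <- c(hyd, residue_atom_idx(complex, ri, names = chem$hydrophobic))
      heavy <- c(heavy, residue_atom_idx(complex, ri, heavy_only = TRUE))
      if (length(chem$ring)) {
        rg <- residue_atom_idx(complex, ri, names = chem$ring)
        if (length(rg) >= 5) rings[[length(rings) + 1]] <- list(ri = ri, idx = rg)
      }
    }
    list(res = ridx, pos = pos, neg = neg, don = don, acc = acc, hyd = hyd,
         heavy = heavy, rings = rings)
  }
  list(a = grp(chains_a), b = grp(chains_b))
}

# cross-distance matrix between two index sets in coordinate matrix X
cross_dist <- function(X, i, j) {
  if (length(i) == 0 || length(j) == 0) {
    return(matrix(numeric(0), length(i), length(j)))
  }
  A <- X[i, , drop = FALSE]; B <- X[j, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

pairs_below <- function(complex, X, i, j, cutoff) {
  d <- cross_dist(X, i, j)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (length(hits) == 0) return(NULL)
  tibble::tibble(ai = i[hits[, 1]], bj = j[hits[, 2]],
                 ra = complex$atoms$residue_index[i[hits[, 1]]],
                 rb = complex$atoms$residue_index[j[hits[, 2]]],
                 d = d[hits])
}

#' Detect contacts in a single frame
#'
#' All inter-group residue pairs satisfying any category criterion.  A
#' pair may carry several categories, except van der Waals, which is
#' suppressed when a more specific category holds for the same pair.
#'
#' @param complex an [annotated_complex()].
#' @param X n_atoms-by-3 coordinate matrix (nm).
#' @param chains_a,chains_b the two disjoint chain groups.
#' @param criteria a [contact_criteria()].
#' @param env precomputed atom classes (internal reuse across frames).
#' @return tibble: res_a, res_b (residue indices), category, subtype.
#' @export
detect_frame <- function(complex, X, chains_a, chains_b,
                         criteria = contact_criteria(), env = NULL) {
  if (length(intersect(chains_a, chains_b))) abort("contact groups overlap")
  env <- env %||% contact_env(complex, chains_a, chains_b)
  at <- complex$atoms
  out <- list()
  add <- function(ra, rb, category, subtype = NA_character_) {
    if (length(ra) == 0) return()
    out[[length(out) + 1]] <<- tibble::tibble(res_a = ra, res_b = rb,
                                              category = category,
                                              subtype = subtype)
  }

  # ionic + salt bridge
  ion <- dplyr::bind_rows(
    pairs_below(complex, X, env$a$neg, env$b$pos, criteria$ionic_dist),
    pairs_below(complex, X, env$a$pos, env$b$neg, criteria$ionic_dist)
  )
  if (nrow(ion %||% tibble::tibble())) {
    u <- dplyr::distinct(ion, .data$ra, .data$rb)
    add(u$ra, u$rb, "ionic")
    sb <- dplyr::distinct(ion[ion$d <= criteria$hbond_dist, ], .data$ra, .data$rb)
    add(sb$ra, sb$rb, "salt_bridge")
  }

  # hydrogen bonds (both directions), with H-angle check when H present
  hb_dir <- function(di, aj) {
    hb <- pairs_below(complex, X, di, aj, criteria$hbond_dist)
    if (is.null(hb) || nrow(hb) == 0) return(NULL)
    keep <- vapply(seq_len(nrow(hb)), function(r) {
      hbond_geometry_ok(complex, X, hb$ai[r], hb$bj[r], criteria$hbond_angle)
    }, logical(1))
    hb[keep, ]
  }
  hb <- dplyr::bind_rows(hb_dir(env$a$don, env$b$acc),
                         flip_ab(hb_dir(env$b$don, env$a$acc)))
  if (nrow(hb %||% tibble::tibble())) {
    hb$subtype <- hbond_subtype(at$is_backbone[hb$ai], at$is_backbone[hb$bj])
    u <- dplyr::distinct(hb, .data$ra, .data$rb, .data$subtype)
    add(u$ra, u$rb, "hbond", u$subtype)
  }

  # aromatic
  ring_geoms <- function(g) purrr::map(g$rings, function(rg) {
    c(rg, ring_geometry(X[rg$idx, , drop = FALSE]))
  })
  ra_g <- ring_geoms(env$a); rb_g <- ring_geoms(env$b)
  acute <- function(deg) pmin(deg, 180 - deg)
  for (g in ra_g) {
    # pi-cation: ring on side a, cation on side b
    for (ic in env$b$pos) {
      v <- X[ic, ] - g$centroid
      d <- vnorm(v)
      if (d <= criteria$pi_cation_dist) {
        ang <- acute(acos(pmin(1, abs(sum(unitv(v) * g$normal)))) * 180 / pi)
        off_axis <- acos(pmin(1, abs(sum(unitv(v) * g$normal)))) * 180 / pi
        if (off_axis <= criteria$pi_cation_angle) {
          add(g$ri, at$residue_index[ic], "pi_cation")
        }
      }
    }
    for (h in rb_g) {
      v <- h$centroid - g$centroid
      d <- vnorm(v)
      if (d > max(criteria$pi_stack_dist, criteria$t_stack_dist)) next
      nang <- acute(acos(pmin(1, abs(sum(g$normal * h$normal)))) * 180 / pi)
      if (d <= criteria$pi_stack_dist && nang <= criteria$pi_stack_angle) {
        add(g$ri, h$ri, "pi_stack")
      }
      if (d <= criteria$t_stack_dist && nang >= criteria$t_stack_angle[1] &&
          nang <= criteria$t_stack_angle[2]) {
        add(g$ri, h$ri, "t_stack")
      }
    }
  }
  for (h in rb_g) {
    # pi-cation with ring on side b
    for (ic in env$a$pos) {
      v <- X[ic, ] - h$centroid
      if (vnorm(v) <= criteria$pi_cation_dist) {
        off_axis <- acos(pmin(1, abs(sum(unitv(v) * h$normal)))) * 180 / pi
        if (off_axis <= criteria$pi_cation_angle) {
          add(at$residue_index[ic], h$ri, "pi_cation")
        }
      }
    }
  }

  # hydrophobic
  hyd <- pairs_below(complex, X, env$a$hyd, env$b$hyd, criteria$hydrophobic_dist)
  if (!is.null(hyd) && nrow(hyd)) {
    u <- dplyr::distinct(hyd, .data$ra, .data$rb)
    add(u$ra, u$rb, "hydrophobic")
  }

  # van der Waals: heavy pairs within r1 + r2 + pad
  dv <- cross_dist(X, env$a$heavy, env$b$heavy)
  if (length(dv)) {
    rsum <- outer(at$vdw_radius[env$a$heavy], at$vdw_radius[env$b$heavy], "+") +
      criteria$vdw_pad
    hits <- which(dv <= rsum, arr.ind = TRUE)
    if (length(hits)) {
      u <- dplyr::distinct(tibble::tibble(
        ra = at$residue_index[env$a$heavy[hits[, 1]]],
        rb = at$residue_index[env$b$heavy[hits[, 2]]]
      ), .data$ra, .data$rb)
      add(u$ra, u$rb, "vdw")
    }
  }

  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(res_a = integer(0), res_b = integer(0),
                          category = character(0), subtype = character(0)))
  }
  res <- dplyr::distinct(res, .data$res_a, .data$res_b, .data$category,
                         .data$subtype)
  # vdW is residual: drop it where a specific category exists for the pair
  specific <- res[res$category != "vdw", c("res_a", "res_b")]
  if (nrow(specific)) {
    res <- res[!(res$category == "vdw" &
                   paste(res$res_a, res$res_b) %in%
                   paste(specific$res_a, specific$res_b)), ]
  }
  res
}

flip_ab <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0) return(tab)
  tab[, c("ai", "bj", "ra", "rb")] <- tab[, c("bj", "ai", "rb", "ra")]
  tab
}

# donor-H-acceptor angle criterion; TRUE when no hydrogen rides the donor
hbond_geometry_ok <- function(complex, X, donor_i, acceptor_j, min_angle) {
  a <- complex$atoms
  hs <- which(a$residue_index == a$residue_index[donor_i] & a$element == "H")
  if (length(hs) == 0) return(TRUE)
  dh <- cross_dist(X, donor_i, hs)
  hs <- hs[dh[1, ] <= 0.125]
  if (length(hs) == 0) return(TRUE)
  for (h in hs) {
    v1 <- X[donor_i, ] - X[h, ]
    v2 <- X[acceptor_j, ] - X[h, ]
    ang <- acos(pmin(1, pmax(-1, sum(unitv(v1) * unitv(v2))))) * 180 / pi
    if (ang >= min_angle) return(TRUE)
  }
  FALSE
}

#' Contact occupancy over an ensemble
#'
#' Detects contacts in every retained frame of every replica, computes the
#' percentage of frames each (residue pair, category, subtype) is present
#' per replica, and averages occupancies across replicas (unweighted).
#'
#' @param ensemble a [trajectory_ensemble()] (post-discard).
#' @param complex the matching [annotated_complex()].
#' @param chains_a,chains_b disjoint chain groups; default receptor and
#'   partner chains.
#' @param criteria a [contact_criteria()].
#' @param stride analyse every `stride`-th frame.
#' @return a `contact_records` tibble: chain_a, resnum_a, resname_a, gn_a,
#'   chain_b, resnum_b, resname_b, gn_b, category, subtype, one
#'   `occ_<replica>` column per replica, and `occupancy` (the average, %).
#' @export
contact_occupancy <- function(ensemble, complex, chains_a = NULL,
                              chains_b = NULL,
                              criteria = contact_criteria(), stride = 1L) {
  chains_a <- chains_a %||% chains_with_role(complex, "receptor")
  chains_b <- chains_b %||% chains_with_role(complex, "partner")
  env <- contact_env(complex, chains_a, chains_b)
  per_rep <- purrr::map(ensemble$replicas, function(rep) {
    frames <- seq(1, nrow(rep$xyz), by = stride)
    counts <- purrr::map(frames, function(f) {
      detect_frame(complex, frame_coords_of(rep, f), chains_a, chains_b,
                   criteria, env = env)
    }) %>% dplyr::bind_rows()
    if (nrow(counts) == 0) {
      return(tibble::tibble(res_a = integer(0), res_b = integer(0),
                            category = character(0), subtype = character(0),
                            occ = numeric(0), replica = rep$id))
    }
    counts %>%
      dplyr::count(.data$res_a, .data$res_b, .data$category, .data$subtype) %>%
      dplyr::mutate(occ = 100 * .data$n / length(frames),
                    replica = rep$id) %>%
      dplyr::select(-"n")
  }) %>% dplyr::bind_rows()
  if (nrow(per_rep) == 0) {
    return(structure(tibble::tibble(), class = c("contact_records", "tbl_df",
                                                 "tbl", "data.frame")))
  }
  rep_ids <- vapply(ensemble$replicas, function(r) r$id, character(1))
  wide <- per_rep %>%
    tidyr::pivot_wider(names_from = "replica", values_from = "occ",
                       names_prefix = "occ_", values_fill = 0)
  occ_cols <- paste0("occ_", rep_ids)
  for (oc in setdiff(occ_cols, names(wide))) wide[[oc]] <- 0
  wide$occupancy <- rowMeans(wide[, occ_cols, drop = FALSE])
  res <- complex$residues
  decorate <- function(tab, col, suffix) {
    tab[[paste0("chain_", suffix)]] <- res$chain[tab[[col]]]
    tab[[paste0("resnum_", suffix)]] <- res$resnum[tab[[col]]]
    tab[[paste0("resname_", suffix)]] <- res$resname[tab[[col]]]
    tab[[paste0("gn_", suffix)]] <- res$generic_number[tab[[col]]]
    tab
  }
  wide <- decorate(wide, "res_a", "a")
  wide <- decorate(wide, "res_b", "b")
  out <- wide[, c("chain_a", "resnum_a", "resname_a", "gn_a",
                  "chain_b", "resnum_b", "resname_b", "gn_b",
                  "category", "subtype", occ_cols, "occupancy")]
  out <- dplyr::arrange(out, dplyr::desc(.data$occupancy))
  attr(out, "criteria") <- criteria
  class(out) <- c("contact_records", class(out))
  out
}

hbond_subtype <- function(bb_a, bb_b) {
  dplyr::case_when(bb_a & bb_b ~ "bb-bb",
                   !bb_a & !bb_b ~ "sc-sc",
                   TRUE ~ "bb-sc")
}

#' Filter contacts by average occupancy
#'
#' Keeps records whose replica-averaged occupancy is at least `threshold`
#' percent (the conventional reporting cut is 30%; strictly-less-than is
#' excluded, so the boundary value is kept).
#'
#' @param records a `contact_records` tibble.
#' @param threshold percent (default 30).
#' @return filtered records.
#' @export
filter_occupancy <- function(records, threshold = 30) {
  if (nrow(records) == 0) return(records)
  records[records$occupancy >= threshold, ]
}

#' Substructure-pair contact matrix
#'
#' Groups contacts at or above `min_occupancy` percent by the annotated
#' substructures of the two residues, listing the generic-number pair
#' labels in each cell.  Unannotated residues are binned as "unassigned".
#'
#' @param records a `contact_records` tibble.
#' @param complex the annotated complex.
#' @param min_occupancy percent threshold (default 50).
#' @return tibble: substructure_a, substructure_b, n_pairs, pairs (label).
#' @export
contact_matrix <- function(records, complex, min_occupancy = 50) {
  if (nrow(records) == 0) {
    return(tibble::tibble(substructure_a = character(0),
                          substructure_b = character(0),
                          n_pairs = integer(0), pairs = character(0)))
  }
  res <- complex$residues
  key <- paste(res$chain, res$resnum, sep = "|")
  sub <- setNames(res$substructure, key)
  keep <- records[records$occupancy >= min_occupancy, ]
  keep$substructure_a <- unname(sub[paste(keep$chain_a, keep$resnum_a, sep = "|")])
  keep$substructure_b <- unname(sub[paste(keep$chain_b, keep$resnum_b, sep = "|")])
  keep$substructure_a[is.na(keep$substructure_a)] <- "unassigned"
  keep$substructure_b[is.na(keep$substructure_b)] <- "unassigned"
  lab <- function(gn, ch, rn) ifelse(is.na(gn), paste0(ch, "/", rn), gn)
  keep$pair_label <- paste(lab(keep$gn_a, keep$chain_a, keep$resnum_a),
                           lab(keep$gn_b, keep$chain_b, keep$resnum_b),
                           sep = " - ")
  keep %>%
    dplyr::distinct(.data$substructure_a, .data$substructure_b,
                    .data$pair_label) %>%
    dplyr::group_by(.data$substructure_a, .data$substructure_b) %>%
    dplyr::summarise(n_pairs = dplyr::n(),
                     pairs = paste(sort(unique(.data$pair_label)),
                                   collapse = "; "),
                     .groups = "drop")
}
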