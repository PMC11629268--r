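# Independent brute-force oracles, deliberately written without reusing the
# package's production code paths.

# dense-sampling Shrake-Rupley in plain R (golden-spiral points)
r_sasa_oracle <- function(coords, radii, probe = 0.14, n_points = 10000) {
  n <- nrow(coords)
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sph <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  er <- radii + probe
  out <- numeric(n)
  for (a in seq_len(n)) {
    pts <- sweep(sph * er[a], 2, coords[a, ], "+")
    free <- rep(TRUE, n_points)
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- (pts[, 1] - coords[b, 1])^2 + (pts[, 2] - coords[b, 2])^2 +
        (pts[, 3] - coords[b, 3])^2
      free <- free & d2 >= er[b]^2
      if (!any(free)) break
    }
    out[a] <- 4 * pi * er[a]^2 * sum(free) / n_points
  }
  out
}

# literal reimplementation of the interface membership / presence rules
membership_oracle <- function(dsasa0, resname, sasa_max, min_dsasa = 0.05,
                              min_norm_pct = 10) {
  member <- logical(length(dsasa0))
  for (i in seq_along(dsasa0)) {
    in_interface <- dsasa0[i] > 0
    norm <- 100 * dsasa0[i] / sasa_max[[resname[i]]]
    exclude <- (dsasa0[i] < min_dsasa) && (norm < min_norm_pct)
    member[i] <- in_interface && !exclude
  }
  member
}

presence_oracle <- function(dsasa_frames, original, eps = 0, threshold = 50) {
  presence <- 100 * vapply(dsasa_frames, function(v) mean(v > eps), numeric(1))
  additional <- !original & presence > threshold
  list(presence = presence, additional = additional)
}

# nested-loop contact detection over residue pairs
contact_oracle <- function(complex, X, chains_a, chains_b,
                           criteria = contact_criteria()) {
  res <- complex$residues
  at <- complex$atoms
  ra_all <- which(res$chain %in% chains_a)
  rb_all <- which(res$chain %in% chains_b)
  get_idx <- function(ri, names) {
    which(at$residue_index == ri & at$name %in% names)
  }
  dist1 <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  min_dist <- function(ii, jj) {
    if (length(ii) == 0 || length(jj) == 0) return(Inf)
    m <- Inf
    for (i in ii) for (j in jj) m <- min(m, dist1(i, j))
    m
  }
  acute <- function(deg) min(deg, 180 - deg)
  rows <- list()
  add <- function(ra, rb, category, subtype = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(res_a = ra, res_b = rb,
                                            category = category,
                                            subtype = subtype)
  }
  for (ra in ra_all) {
    rna <- res$resname[ra]
    if (rna == "BLK") ca <- list(pos = character(0), neg = character(0),
                                 donors = character(0),
                                 acceptors = character(0),
                                 ring = character(0),
                                 hydrophobic = character(0))
    else ca <- gpcrtraj:::residue_chemistry(rna)
    for (rb in rb_all) {
      rnb <- res$resname[rb]
      if (rnb == "BLK") cb <- list(pos = character(0), neg = character(0),
                                   donors = character(0),
                                   acceptors = character(0),
                                   ring = character(0),
                                   hydrophobic = character(0))
      else cb <- gpcrtraj:::residue_chemistry(rnb)
      any_specific <- FALSE
      d_ion <- min(min_dist(get_idx(ra, ca$neg), get_idx(rb, cb$pos)),
                   min_dist(get_idx(ra, ca$pos), get_idx(rb, cb$neg)))
      if (d_ion <= criteria$ionic_dist) {
        add(ra, rb, "ionic"); any_specific <- TRUE
        if (d_ion <= criteria$hbond_dist) add(ra, rb, "salt_bridge")
      }
      don_a <- get_idx(ra, c(ca$donors, if (rna != "PRO") "N"))
      acc_a <- get_idx(ra, c(ca$acceptors, "O"))
      don_b <- get_idx(rb, c(cb$donors, if (rnb != "PRO") "N"))
      acc_b <- get_idx(rb, c(cb$acceptors, "O"))
      hb_subtypes <- character(0)
      for (i in don_a) for (j in acc_b) {
        if (dist1(i, j) <= criteria$hbond_dist) {
          st <- if (at$is_backbone[i] && at$is_backbone[j]) "bb-bb"
          else if (!at$is_backbone[i] && !at$is_backbone[j]) "sc-sc"
          else "bb-sc"
          hb_subtypes <- union(hb_subtypes, st)
        }
      }
      for (i in don_b) for (j in acc_a) {
        if (dist1(i, j) <= criteria$hbond_dist) {
          st <- if (at$is_backbone[i] && at$is_backbone[j]) "bb-bb"
          else if (!at$is_backbone[i] && !at$is_backbone[j]) "sc-sc"
          else "bb-sc"
          hb_subtypes <- union(hb_subtypes, st)
        }
      }
      for (st in hb_subtypes) { add(ra, rb, "hbond", st); any_specific <- TRUE }
      ring_a <- get_idx(ra, ca$ring); ring_b <- get_idx(rb, cb$ring)
      geom <- function(idx) {
        ctr <- colMeans(X[idx, , drop = FALSE])
        s <- svd(sweep(X[idx, , drop = FALSE], 2, ctr))
        list(c = ctr, n = s$v[, 3])
      }
      if (length(ring_a) >= 5) {
        ga <- geom(ring_a)
        for (j in get_idx(rb, cb$pos)) {
          v <- X[j, ] - ga$c
          if (sqrt(sum(v^2)) <= criteria$pi_cation_dist) {
            off <- acos(min(1, abs(sum(v / sqrt(sum(v^2)) * ga$n)))) * 180 / pi
            if (off <= criteria$pi_cation_angle) {
              add(ra, rb, "pi_cation"); any_specific <- TRUE
            }
          }
        }
        if (length(ring_b) >= 5) {
          gb <- geom(ring_b)
          d <- sqrt(sum((gb$c - ga$c)^2))
          nang <- acute(acos(min(1, abs(sum(ga$n * gb$n)))) * 180 / pi)
          if (d <= criteria$pi_stack_dist && nang <= criteria$pi_stack_angle) {
            add(ra, rb, "pi_stack"); any_specific <- TRUE
          }
          if (d <= criteria$t_stack_dist && nang >= criteria$t_stack_angle[1] &&
              nang <= criteria$t_stack_angle[2]) {
            add(ra, rb, "t_stack"); any_specific <- TRUE
          }
        }
      }
      if (length(ring_b) >= 5) {
        gb <- geom(ring_b)
        for (j in get_idx(ra, ca$pos)) {
          v <- X[j, ] - gb$c
          if (sqrt(sum(v^2)) <= criteria$pi_cation_dist) {
            off <- acos(min(1, abs(sum(v / sqrt(sum(v^2)) * gb$n)))) * 180 / pi
            if (off <= criteria$pi_cation_angle) {
              add(ra, rb, "pi_cation"); any_specific <- TRUE
            }
          }
        }
      }
      if (min_dist(get_idx(ra, ca$hydrophobic),
                   get_idx(rb, cb$hydrophobic)) <= criteria$hydrophobic_dist) {
        add(ra, rb, "hydrophobic"); any_specific <- TRUE
      }
      ha <- which(at$residue_index == ra & at$element != "H")
      hb_ <- which(at$residue_index == rb & at$element != "H")
      vdw_hit <- FALSE
      for (i in ha) {
        for (j in hb_) {
          if (dist1(i, j) <= at$vdw_radius[i] + at$vdw_radius[j] +
              criteria$vdw_pad) { vdw_hit <- TRUE; break }
        }
        if (vdw_hit) break
      }
      if (vdw_hit && !any_specific) add(ra, rb, "vdw")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- data.frame(res_a = integer(0), res_b = integer(0),
                      category = character(0), subtype = character(0))
  }
  unique(out)
}

contact_set_string <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  sort(paste(tab$res_a, tab$res_b, tab$category,
             ifelse(is.na(tab$subtype), "-", tab$subtype)))
}
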