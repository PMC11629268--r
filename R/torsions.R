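#' Extract backbone and side-chain torsions
#'
#' Computes phi, psi and chi1..chi5 (where defined by the residue type and
#' present atoms) for every selected residue and every frame, pooling all
#' replicas.  First residues of a chain lack phi, last residues lack psi;
#' features with missing atoms are omitted silently (a message lists them
#' with `verbose = TRUE`).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param complex the matching [annotated_complex()].
#' @param chains chains to process; default receptor chains.
#' @param verbose message omitted features.
#' @return tibble with columns replica, frame, time, chain, resnum,
#'   resname, generic_number, angle, angle_class ("backbone"/"sidechain"),
#'   value (degrees in \[-180, 180)).
#' @export
extract_torsions <- function(ensemble, complex, chains = NULL,
                             verbose = FALSE) {
  chains <- chains %||% chains_with_role(complex, "receptor")
  res <- complex$residues
  a <- complex$atoms
  idx_of <- function(ri, nm) {
    i <- which(a$residue_index == ri & a$name == nm)
    if (length(i) == 1) i else NA_integer_
  }
  feats <- list()
  omitted <- character(0)
  for (ch in chains) {
    cr <- which(res$chain == ch & !res$resname %in% c("BLK"))
    for (p in seq_along(cr)) {
      ri <- cr[p]
      quads <- list()
      if (p > 1) {
        quads$phi <- c(idx_of(cr[p - 1], "C"), idx_of(ri, "N"),
                       idx_of(ri, "CA"), idx_of(ri, "C"))
      }
      if (p < length(cr)) {
        quads$psi <- c(idx_of(ri, "N"), idx_of(ri, "CA"),
                       idx_of(ri, "C"), idx_of(cr[p + 1], "N"))
      }
      defs <- chi_definitions(res$resname[ri])
      for (k in seq_along(defs)) {
        quads[[paste0("chi", k)]] <- vapply(defs[[k]], idx_of, integer(1),
                                            ri = ri)
      }
      for (nm in names(quads)) {
        q <- quads[[nm]]
        if (anyNA(q)) {
          omitted <- c(omitted, paste0(ch, "/", res$resnum[ri], ":", nm))
          next
        }
        feats[[length(feats) + 1]] <- list(ri = ri, angle = nm, quad = q)
      }
    }
  }
  if (verbose && length(omitted)) {
    message("omitted torsions (missing atoms): ", paste(omitted, collapse = ", "))
  }
  rows <- purrr::map(ensemble$replicas, function(rep) {
    n <- nrow(rep$xyz)
    purrr::map(feats, function(ft) {
      v <- dihedral_angle(atom_series(rep, ft$quad[1]), atom_series(rep, ft$quad[2]),
                          atom_series(rep, ft$quad[3]), atom_series(rep, ft$quad[4]))
      tibble::tibble(
        replica = rep$id, frame = seq_len(n), time = rep$time,
        chain = res$chain[ft$ri], resnum = res$resnum[ft$ri],
        resname = res$resname[ft$ri],
        generic_number = res$generic_number[ft$ri],
        angle = ft$angle,
        angle_class = ifelse(ft$angle %in% c("phi", "psi"),
                             "backbone", "sidechain"),
        value = v
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  rows
}

#' Circular histogram of a torsion sample
#'
#' Equal-width bins over \[-180, 180), normalised to sum 1.
#'
#' @param values angles in degrees.
#' @param n_bins number of bins (>= 2; default 36, i.e. 10-degree bins).
#' @return probability vector of length `n_bins`.
#' @export
torsion_histogram <- function(values, n_bins = 36) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (length(values) == 0) abort("empty torsion sample")
  v <- wrap_angle(values)
  bin <- pmin(floor((v + 180) / (360 / n_bins)) + 1, n_bins)
  p <- tabulate(bin, nbins = n_bins)
  p / sum(p)
}

#' Jensen-Shannon distance between two probability vectors
#'
#' sqrt(JS divergence) with base-2 logarithms, so values lie in \[0, 1\];
#' 0 log 0 terms are taken as 0 and no pseudocounts are added.
#'
#' @param p,q probability vectors of equal length, each summing to 1
#'   (within 1e-9).
#' @return scalar in \[0, 1\].
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q)) abort("probability vectors differ in length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("probability vectors must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d2 <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, d2)))
}

#' Compare two ensembles residue-by-residue via JSD
#'
#' For every torsion feature shared by both ensembles (same residue and
#' angle), pools all replicas per ensemble, forms circular histograms and
#' computes the Jensen-Shannon distance.  Only features present in both
#' ensembles are compared.
#'
#' @param torsions_a,torsions_b torsion tables from [extract_torsions()]
#'   (post-discard).
#' @param n_bins histogram bins (default 36).
#' @param label comparison label (e.g. "Gq vs Gi").
#' @return a `jsd_map` tibble: chain, resnum, resname, generic_number,
#'   angle, angle_class, jsd.
#' @export
compare_ensembles <- function(torsions_a, torsions_b, n_bins = 36,
                              label = "A vs B") {
  key_cols <- c("chain", "resnum", "resname", "generic_number", "angle",
                "angle_class")
  agg <- function(tt) {
    tt %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) %>%
      dplyr::summarise(values = list(.data$value), .groups = "drop")
  }
  a <- agg(torsions_a)
  b <- agg(torsions_b)
  shared <- dplyr::inner_join(a, b, by = key_cols, suffix = c("_a", "_b"))
  if (nrow(shared) == 0) abort("ensembles share no torsion features")
  shared$jsd <- purrr::map2_dbl(shared$values_a, shared$values_b, function(x, y) {
    jensen_shannon_distance(torsion_histogram(x, n_bins),
                            torsion_histogram(y, n_bins))
  })
  out <- shared %>% dplyr::select(-"values_a", -"values_b")
  attr(out, "comparison") <- label
  attr(out, "n_bins") <- n_bins
  class(out) <- c("jsd_map", class(out))
  out
}

#' Per-residue JSD summary
#'
#' The per-residue reporting scalar: the maximum JSD over that residue's
#' angles, separately for backbone and side-chain torsions.
#'
#' @param map a `jsd_map` from [compare_ensembles()].
#' @return tibble: chain, resnum, resname, generic_number, backbone_max,
#'   sidechain_max.
#' @export
jsd_residue_summary <- function(map) {
  tibble::as_tibble(map) %>%
    dplyr::group_by(.data$chain, .data$resnum, .data$resname,
                    .data$generic_number) %>%
    dplyr::summarise(
      backbone_max = max(c(-Inf, .data$jsd[.data$angle_class == "backbone"])),
      sidechain_max = max(c(-Inf, .data$jsd[.data$angle_class == "sidechain"])),
      .groups = "drop"
    ) %>%
    dplyr::mutate(backbone_max = ifelse(is.finite(.data$backbone_max),
                                        .data$backbone_max, NA_real_),
                  sidechain_max = ifelse(is.finite(.data$sidechain_max),
                                         .data$sidechain_max, NA_real_))
}

#' Residues with high side-chain JSD
#'
#' Residues whose side-chain maximum JSD exceeds the display threshold,
#' sorted by value descending.  The conventional display threshold is 0.6.
#'
#' @param map a `jsd_map`.
#' @param threshold JSD threshold (default 0.6); strictly greater kept.
#' @return tibble of residues sorted by `sidechain_max` descending.
#' @export
select_high_jsd <- function(map, threshold = 0.6) {
  jsd_residue_summary(map) %>%
    dplyr::filter(!is.na(.data$sidechain_max),
                  .data$sidechain_max > threshold) %>%
    dplyr::arrange(dplyr::desc(.data$sidechain_max))
}

#' Plot a JSD map
#'
#' Per-residue backbone and side-chain maximum JSD along the sequence,
#' with the display threshold drawn.
#'
#' @param object a `jsd_map`.
#' @param threshold display threshold line (default 0.6).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.jsd_map <- function(object, threshold = 0.6, ...) {
  s <- jsd_residue_summary(object) %>%
    tidyr::pivot_longer(c("backbone_max", "sidechain_max"),
                        names_to = "class", values_to = "jsd")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$resnum, y = .data$jsd,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "max JSD",
                  title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}
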