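#' Per-residue delta-SASA over a trajectory
#'
#' For every frame, the SASA of each receptor (partner) residue is
#' computed twice: with only its own group present (monomer) and with both
#' groups present (complex); the difference is the per-residue buried
#' area.  Solvent, ions and membrane never occlude: the calculation always
#' runs on the receptor/partner chains alone.
#'
#' @param ensemble a [trajectory_ensemble()] (post-discard).
#' @param complex the matching [annotated_complex()].
#' @param receptor_chains,partner_chains disjoint chain sets; default from
#'   chain roles.
#' @param params a [sasa_params()].
#' @param stride analyse every `stride`-th frame (default 1).
#' @return tibble: replica, frame, time, side ("receptor"/"partner"),
#'   chain, resnum, resname, sasa_mon, sasa_complex, dsasa (nm^2).
#' @export
delta_sasa <- function(ensemble, complex, receptor_chains = NULL,
                       partner_chains = NULL, params = sasa_params(),
                       stride = 1L) {
  receptor_chains <- receptor_chains %||% chains_with_role(complex, "receptor")
  partner_chains <- partner_chains %||% chains_with_role(complex, "partner")
  if (length(intersect(receptor_chains, partner_chains))) {
    abort("receptor and partner chain sets overlap")
  }
  both <- c(receptor_chains, partner_chains)
  side_of <- function(tab) {
    tab$side <- ifelse(tab$chain %in% receptor_chains, "receptor", "partner")
    tab
  }
  rows <- purrr::map(ensemble$replicas, function(rep) {
    frames <- seq(1, nrow(rep$xyz), by = stride)
    purrr::map(frames, function(f) {
      X <- frame_coords_of(rep, f)
      mon <- dplyr::bind_rows(
        sasa_per_residue(complex, X, receptor_chains, params),
        sasa_per_residue(complex, X, partner_chains, params)
      )
      cpx <- sasa_per_residue(complex, X, both, params)
      out <- dplyr::left_join(
        dplyr::rename(mon, sasa_mon = "sasa"),
        dplyr::rename(cpx, sasa_complex = "sasa"),
        by = c("chain", "resnum", "resname")
      )
      out$dsasa <- out$sasa_mon - out$sasa_complex
      out$replica <- rep$id
      out$frame <- f
      out$time <- rep$time[f]
      side_of(out)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  rows[, c("replica", "frame", "time", "side", "chain", "resnum", "resname",
           "sasa_mon", "sasa_complex", "dsasa")]
}

#' Interface area series
#'
#' Per frame, the buried areas of the two sides are summed and averaged:
#' interface area = (sum of receptor delta-SASA + sum of partner
#' delta-SASA) / 2, nm^2.
#'
#' @param dsasa_table output of [delta_sasa()].
#' @return an `interface_area_series` tibble: replica, frame, time,
#'   dsasa_receptor, dsasa_partner, area.
#' @export
interface_area <- function(dsasa_table) {
  out <- dsasa_table %>%
    dplyr::group_by(.data$replica, .data$frame, .data$time) %>%
    dplyr::summarise(
      dsasa_receptor = sum(.data$dsasa[.data$side == "receptor"]),
      dsasa_partner = sum(.data$dsasa[.data$side == "partner"]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(area = (.data$dsasa_receptor + .data$dsasa_partner) / 2)
  class(out) <- c("interface_area_series", class(out))
  out
}

#' @rdname interface_area
#' @param x an `interface_area_series`.
#' @param ... unused.
#' @export
glance.interface_area_series <- function(x, ...) {
  per_rep <- tibble::as_tibble(x) %>%
    dplyr::group_by(.data$replica) %>%
    dplyr::summarise(rep_mean = mean(.data$area), .groups = "drop")
  tibble::tibble(mean_area = mean(per_rep$rep_mean),
                 sem_area = sem(per_rep$rep_mean),
                 n_replicas = nrow(per_rep), n_frames = nrow(x))
}

#' @rdname interface_area
#' @param object an `interface_area_series`.
#' @export
autoplot.interface_area_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$area,
                               colour = .data$replica)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = expression("interface area (nm"^2*")")) +
    ggplot2::theme_minimal()
}

#' Original interface membership
#'
#' Classifies residues into the original interface from the first retained
#' frame: a residue is a member iff its delta-SASA is greater than 0 and it
#' is NOT excluded by the noise filter.  The filter excludes a residue only
#' when BOTH conditions hold (conjunction): delta-SASA below `min_dsasa`
#' (default 0.05 nm^2) AND normalised delta-SASA (delta-SASA divided by the
#' residue type's maximal accessibility) below `min_norm` (default 10%).
#' A disjunction mode is available for sensitivity analysis.
#'
#' @param dsasa_table output of [delta_sasa()] (or any table with columns
#'   replica, time, chain, resnum, resname, dsasa).
#' @param sasa_max named vector residue type -> maximal SASA (nm^2).
#' @param replica replica whose first frame defines t0 (default: first).
#' @param min_dsasa,min_norm exclusion thresholds (nm^2, percent).
#' @param mode `"conjunction"` (default, the literal rule) or
#'   `"disjunction"`.
#' @return tibble: side, chain, resnum, resname, dsasa_t0, norm_t0 (%),
#'   original_member.
#' @export
original_interface <- function(dsasa_table, sasa_max = sasa_max_table(),
                               replica = NULL, min_dsasa = 0.05,
                               min_norm = 10, mode = c("conjunction",
                                                       "disjunction")) {
  mode <- match.arg(mode)
  replica <- replica %||% dsasa_table$replica[1]
  t0 <- dsasa_table %>% dplyr::filter(.data$replica == !!replica)
  t0 <- t0 %>% dplyr::filter(.data$time == min(.data$time))
  missing_types <- setdiff(unique(t0$resname), names(sasa_max))
  if (length(missing_types)) {
    abort(paste0("residue type(s) missing from SASA_max table: ",
                 paste(missing_types, collapse = ", ")))
  }
  t0 %>%
    dplyr::mutate(
      norm_t0 = 100 * .data$dsasa / unname(sasa_max[.data$resname]),
      excluded = if (mode == "conjunction") {
        .data$dsasa < min_dsasa & .data$norm_t0 < min_norm
      } else {
        .data$dsasa < min_dsasa | .data$norm_t0 < min_norm
      },
      original_member = .data$dsasa > 0 & !.data$excluded
    ) %>%
    dplyr::select("side", "chain", "resnum", "resname",
                  dsasa_t0 = "dsasa", "norm_t0", "original_member")
}

#' Interface presence and additional residues
#'
#' Presence is the percentage of retained frames (all replicas pooled) in
#' which a residue's delta-SASA exceeds `eps` (default 0, matching the
#' "higher than 0" rule; a noise floor can be set).  Residues not in the
#' original interface whose presence exceeds `threshold` (default 50%)
#' are flagged as additional interface members.
#'
#' @param dsasa_table output of [delta_sasa()].
#' @param membership output of [original_interface()].
#' @param eps per-frame presence criterion on delta-SASA (nm^2).
#' @param threshold additional-membership presence threshold, percent.
#' @return tibble: side, chain, resnum, resname, presence (%),
#'   original_member, additional_member.
#' @export
interface_presence <- function(dsasa_table, membership, eps = 0,
                               threshold = 50) {
  pres <- dsasa_table %>%
    dplyr::group_by(.data$side, .data$chain, .data$resnum, .data$resname) %>%
    dplyr::summarise(presence = 100 * mean(.data$dsasa > eps),
                     .groups = "drop")
  out <- dplyr::left_join(
    pres,
    membership[, c("chain", "resnum", "original_member")],
    by = c("chain", "resnum")
  )
  out$original_member[is.na(out$original_member)] <- FALSE
  out$additional_member <- !out$original_member & out$presence > threshold
  out
}

#' Per-substructure interface area
#'
#' Sums per-residue delta-SASA within annotated substructures (TM helices,
#' intracellular loops, H5, arrestin loops, ...), averaging over frames
#' within each replica and reporting mean and SEM across replicas.
#' Residues without a substructure annotation are grouped under
#' "unassigned" with a warning.
#'
#' @param dsasa_table output of [delta_sasa()].
#' @param complex the annotated complex (source of substructure labels).
#' @return tibble: side, substructure, mean_area, sem_area, n_replicas.
#' @export
aggregate_by_substructure <- function(dsasa_table, complex) {
  res <- complex$residues
  key <- paste(res$chain, res$resnum, sep = "|")
  sub <- setNames(res$substructure, key)
  tab <- dsasa_table
  tab$substructure <- unname(sub[paste(tab$chain, tab$resnum, sep = "|")])
  if (anyNA(tab$substructure)) {
    warning("residues without substructure annotation grouped as 'unassigned'")
    tab$substructure[is.na(tab$substructure)] <- "unassigned"
  }
  per_rep <- tab %>%
    dplyr::group_by(.data$replica, .data$frame, .data$side,
                    .data$substructure) %>%
    dplyr::summarise(frame_area = sum(.data$dsasa), .groups = "drop") %>%
    # substructures absent in a frame contribute 0
    tidyr::complete(tidyr::nesting(!!rlang::sym("replica"), !!rlang::sym("frame")),
                    .data$side, .data$substructure,
                    fill = list(frame_area = 0)) %>%
    dplyr::group_by(.data$replica, .data$side, .data$substructure) %>%
    dplyr::summarise(rep_area = mean(.data$frame_area), .groups = "drop")
  per_rep %>%
    dplyr::group_by(.data$side, .data$substructure) %>%
    dplyr::summarise(mean_area = mean(.data$rep_area),
                     sem_area = sem(.data$rep_area),
                     n_replicas = dplyr::n(), .groups = "drop")
}
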