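#' Run configuration
#'
#' Validates (and optionally loads from YAML) the configuration of a full
#' analysis run.  Every threshold of the protocol is configuration with
#' the conventional defaults, never hard-coded: presence 50%, occupancy
#' filter 30%, contact-matrix display 50%, JSD display 0.6, delta-SASA
#' exclusion 0.05 nm^2 and 10%, water shell 8 A.
#'
#' @param config list or YAML file path.  Fields: `systems` (list of
#'   `label`, `structure`, `trajectories`, optional `annotation`, optional
#'   `dt`), `comparisons` (list of label pairs), `discard` ("auto" or ns),
#'   `window`, `k`, `thresholds`, `sasa` (probe, n_points), `jsd_bins`,
#'   `stride`, `seed`, `out_dir`.
#' @return validated `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    discard = "auto", window = 50, k = 2, jsd_bins = 36, seed = 1L,
    stride = 1L,
    thresholds = list(presence = 50, occupancy = 30, occupancy_display = 50,
                      jsd_display = 0.6, min_dsasa = 0.05, min_norm = 10,
                      water_radius = 8),
    sasa = list(probe = 0.14, n_points = 960),
    comparisons = list(),
    out_dir = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$thresholds)) {
    if (is.null(config$thresholds[[nm]])) {
      config$thresholds[[nm]] <- defaults$thresholds[[nm]]
    }
  }
  if (length(config$systems) == 0) abort("config declares no systems")
  labels <- vapply(config$systems, function(s) s$label, character(1))
  if (anyDuplicated(labels)) abort("system labels must be unique")
  for (cmp in config$comparisons) {
    bad <- setdiff(unlist(cmp), labels)
    if (length(bad)) {
      abort(paste0("comparison references undefined system label(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(config, class = "run_config")
}

load_system <- function(sys) {
  if (is.list(sys$chain_roles)) sys$chain_roles <- unlist(sys$chain_roles)
  cplx <- if (inherits(sys$structure, "annotated_complex")) sys$structure
    else read_structure(sys$structure, chain_roles = sys$chain_roles)
  if (!is.null(sys$annotation)) {
    cplx <- read_annotation_table(sys$annotation, cplx)
  }
  ens <- if (inherits(sys$trajectories, "trajectory_ensemble")) {
    sys$trajectories
  } else {
    reps <- purrr::imap(sys$trajectories, function(p, i) {
      read_trajectory(p, cplx, dt = sys$dt %||% 1,
                      replica_id = paste0("rep", i))$replicas[[1]]
    })
    trajectory_ensemble(reps)
  }
  list(complex = cplx, ensemble = ens)
}

#' Run the full analysis pipeline
#'
#' For every configured system: equilibration diagnostics and discard
#' detection, activation metrics, torsion extraction, delta-SASA interface
#' protocol and contact occupancies; then the configured pairwise JSD
#' comparisons, cross-system summary tables and a manifest recording every
#' parameter.  With `out_dir` set, per-system CSVs, comparison CSVs,
#' summary CSVs and a `manifest.json` are written; outputs are a pure
#' function of config plus inputs, so reruns are bit-identical.
#'
#' @param config a [run_config()] (or list/path coerced through it).
#' @return a `report_bundle` list: `systems` (per label: equilibration
#'   report, metrics, torsions, interface tables, contacts), `comparisons`
#'   (per pair: jsd_map), `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  set.seed(config$seed)
  th <- config$thresholds
  sp <- sasa_params(probe = config$sasa$probe, n_points = config$sasa$n_points)
  crit <- do.call(contact_criteria, config$contacts %||% list())

  systems <- list()
  for (sys in config$systems) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(paste0("stage '", what, "' failed for system '", sys$label,
                     "': ", conditionMessage(e)))
      })
    }
    loaded <- stage("load", load_system(sys))
    cplx <- loaded$complex
    ens <- loaded$ensemble

    eq_metrics <- stage("equilibration", {
      ms <- list(helicity = helicity(ens, cplx))
      if (!is.null(ens$replicas[[1]]$box)) ms$box_area <- box_area(ens)
      rc <- ca_selection(cplx, chains_with_role(cplx, "receptor"))
      pc <- ca_selection(cplx, chains_with_role(cplx, "partner"))
      if (length(rc) >= 3) ms$rmsd_receptor <- rmsd_series(ens, cplx, rc)
      if (length(pc) >= 3) ms$rmsd_partner <- rmsd_series(ens, cplx, pc)
      if (length(chains_with_role(cplx, "membrane"))) {
        ms$membrane_offset <- membrane_offset(ens, cplx)
      }
      ms
    })
    report <- stage("discard", {
      if (identical(config$discard, "auto")) {
        detect_equilibration(eq_metrics, window = config$window, k = config$k)
      } else {
        detect_equilibration(eq_metrics, window = config$window, k = config$k,
                             discard = config$discard)
      }
    })
    kept <- stage("discard", discard_initial(ens, report$discard_time))

    metrics <- stage("activation_metrics", activation_metrics(kept, cplx))
    torsions <- stage("torsions", extract_torsions(kept, cplx))
    dsasa <- stage("interface", delta_sasa(kept, cplx, params = sp,
                                           stride = config$stride))
    iface <- stage("interface", interface_area(dsasa))
    membership <- stage("interface",
                        original_interface(dsasa, min_dsasa = th$min_dsasa,
                                           min_norm = th$min_norm))
    presence <- stage("interface",
                      interface_presence(dsasa, membership,
                                         threshold = th$presence))
    by_sub <- stage("interface", aggregate_by_substructure(dsasa, cplx))
    contacts <- stage("contacts",
                      contact_occupancy(kept, cplx, criteria = crit,
                                        stride = config$stride))
    kept_contacts <- filter_occupancy(contacts, th$occupancy)
    cmatrix <- stage("contacts",
                     contact_matrix(kept_contacts, cplx,
                                    min_occupancy = th$occupancy_display))

    systems[[sys$label]] <- list(
      complex = cplx, equilibration = report, eq_metrics = eq_metrics,
      metrics = metrics, torsions = torsions, dsasa = dsasa,
      interface = iface, membership = membership, presence = presence,
      by_substructure = by_sub, contacts = contacts,
      contacts_filtered = kept_contacts, contact_matrix = cmatrix,
      n_frames_total = sum(n_frames(ens)),
      n_frames_retained = sum(n_frames(kept))
    )
  }

  comparisons <- list()
  for (cmp in config$comparisons) {
    lab <- paste(cmp[[1]], "vs", cmp[[2]])
    comparisons[[lab]] <- compare_ensembles(
      systems[[cmp[[1]]]]$torsions, systems[[cmp[[2]]]]$torsions,
      n_bins = config$jsd_bins, label = lab
    )
  }

  bundle <- structure(list(systems = systems, comparisons = comparisons,
                           config = config),
                      class = "report_bundle")
  bundle$summary <- summarize_bundle(bundle)
  bundle$manifest <- bundle_manifest(bundle)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Cross-system summary tables
#'
#' One table per quantity with systems as rows and mean +/- SEM across
#' replicas as cells: interface area, per-substructure areas, and the
#' activation-metric means.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @return list of tibbles: `interface_area`, `substructure_area`,
#'   `metrics`.
#' @export
summarize_bundle <- function(bundle) {
  iface <- purrr::imap(bundle$systems, function(s, lab) {
    g <- glance(s$interface)
    tibble::tibble(system = lab, mean_area = g$mean_area, sem_area = g$sem_area,
                   n_replicas = g$n_replicas)
  }) %>% dplyr::bind_rows()
  subs <- purrr::imap(bundle$systems, function(s, lab) {
    dplyr::mutate(s$by_substructure, system = lab, .before = 1)
  }) %>% dplyr::bind_rows()
  mets <- purrr::imap(bundle$systems, function(s, lab) {
    purrr::imap(s$metrics, function(ms, nm) {
      g <- glance(ms)
      tibble::tibble(system = lab, metric = nm, units = g$units,
                     mean = g$mean, sem = g$sem)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  list(interface_area = iface, substructure_area = subs, metrics = mets)
}

bundle_manifest <- function(bundle) {
  cfg <- bundle$config
  list(
    package_version = as.character(utils::packageVersion("gpcrtraj")),
    seed = cfg$seed,
    thresholds = cfg$thresholds,
    sasa = cfg$sasa,
    discard = cfg$discard, window = cfg$window, k = cfg$k,
    jsd_bins = cfg$jsd_bins, stride = cfg$stride,
    systems = purrr::imap(bundle$systems, function(s, lab) {
      list(label = lab,
           discard_time = as.list(s$equilibration$discard_time),
           n_frames_total = s$n_frames_total,
           n_frames_retained = s$n_frames_retained)
    }),
    comparisons = names(bundle$comparisons)
  )
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(bundle$systems)) {
    s <- bundle$systems[[lab]]
    d <- file.path(out_dir, lab)
    dir.create(d, showWarnings = FALSE)
    mt <- purrr::imap(s$metrics, ~ tidy(.x)) %>% dplyr::bind_rows()
    readr::write_csv(mt, file.path(d, "metrics.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(s$interface),
                     file.path(d, "interface_area.csv"), progress = FALSE)
    readr::write_csv(s$presence, file.path(d, "interface_residues.csv"),
                     progress = FALSE)
    readr::write_csv(s$by_substructure,
                     file.path(d, "interface_substructure.csv"),
                     progress = FALSE)
    if (nrow(s$contacts)) {
      readr::write_csv(s$contacts, file.path(d, "contacts.csv"),
                       progress = FALSE)
    }
    readr::write_csv(s$contact_matrix, file.path(d, "contact_matrix.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(discard_time = as.list(s$equilibration$discard_time)),
      file.path(d, "equilibration.json"), auto_unbox = TRUE, digits = NA)
  }
  for (lab in names(bundle$comparisons)) {
    f <- file.path(out_dir, paste0("jsd_", gsub("[^A-Za-z0-9]+", "_", lab),
                                   ".csv"))
    readr::write_csv(tibble::as_tibble(bundle$comparisons[[lab]]), f,
                     progress = FALSE)
  }
  readr::write_csv(bundle$summary$interface_area,
                   file.path(out_dir, "summary_interface_area.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$summary$metrics,
                   file.path(out_dir, "summary_metrics.csv"), progress = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
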