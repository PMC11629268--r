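#' Bundled two-system synthetic study
#'
#' Builds the package's reference pair of toy systems: a receptor helix
#' annotated with the Ballesteros-Weinstein positions used by the
#' activation metrics (2.50, 3.39/3.40/3.43/3.50, 5.51, 6.34-6.48,
#' 7.49-7.53) coupled to a partner helix annotated as the G alpha C-terminal
#' helix (H5).  The two systems differ the way two coupling partners
#' would: a different TM3-TM6 distance distribution, a shifted chi1
#' rotamer at 3.50, and different scripted interface/contact schedules.
#' Fixtures (PDB, multi-model PDB per replica, annotation TSV, ground
#' truth JSON) are written to `dir` and a ready [run_config()] is
#' returned.
#'
#' @param dir output directory for the fixtures.
#' @param seed integer seed controlling both systems.
#' @param n_frames stationary frames per replica (default 60).
#' @param n_replicas replicas per system (default 2).
#' @return a [run_config()] whose systems point at the written fixtures.
#' @export
demo_two_system_config <- function(dir, seed = 1L, n_frames = 60L,
                                   n_replicas = 2L) {
  receptor <- list(
    chain = "A", role = "receptor",
    sequence = c("ALA", "ASP", "LEU", "THR", "VAL", "ILE", "ARG", "LEU",
                 "VAL", "ALA", "PHE", "VAL", "LEU", "VAL", "VAL", "PHE",
                 "TRP", "LEU", "ASN", "PRO", "ILE", "PHE", "TYR", "LYS"),
    generic_numbers = c(NA, "2.50", NA, "3.39", "3.40", "3.43", "3.50", NA,
                        "5.51", NA, NA, "6.34", NA, "6.40", "6.41", "6.44",
                        "6.48", NA, "7.49", "7.50", "7.51", "7.52", "7.53",
                        "8.50"),
    substructure = c(rep("TM2", 3), rep("TM3", 5), rep("TM5", 2),
                     rep("TM6", 7), rep("TM7", 6), "H8"),
    origin = c(0, 0, 0), axis = c(0, 0, 1)
  )
  partner <- list(
    chain = "B", role = "partner",
    sequence = c("ARG", "ASP", "LEU", "PHE", "GLU", "LYS", "SER", "ALA",
                 "LEU", "TYR", "ASN", "GLU"),
    generic_numbers = c("H5.13", NA, "H5.16", NA, "H5.19", "H5.21", "H5.23",
                        NA, "H5.24", NA, "H5.25", "H5.26"),
    substructure = rep("H5", 12),
    origin = c(2.3, 0, 0), axis = c(0, 0, 1)
  )
  base <- list(
    helix_layout = list(receptor, partner),
    n_frames = as.integer(n_frames), n_replicas = as.integer(n_replicas),
    dt = 1, jitter = 0.01,
    membrane = list(n_particles = 36, z_center = 3, half_extent = 3),
    solvent = list(
      list(n_waters = 15, n_na = 0, center = "2.50", radius = 0.6),
      list(n_waters = 10, n_na = 3, center = "2.50", radius = 1.8)
    ),
    drift = list(tau = 10, amplitude = 0.4, duration = 40),
    burial = list(residue = "A/13", fraction = NA)
  )
  make_spec <- function(seed, tm36_mean, chi1_mode, burial_frac, contacts) {
    synthetic_spec(
      seed = seed, n_frames = base$n_frames, n_replicas = base$n_replicas,
      dt = base$dt, jitter = base$jitter,
      helix_layout = base$helix_layout,
      distance_targets = list(
        list(a = "3.50", b = "6.34", mean = tm36_mean, sd = 0.05, kind = "ca")
      ),
      torsion_targets = list(
        list(residue = "3.50", angle = "chi1",
             modes = list(c(chi1_mode, 100, 1)))
      ),
      burial_schedule = list(list(residue = "A/13", fraction = burial_frac)),
      contact_schedule = contacts,
      solvent = base$solvent, membrane = base$membrane, drift = base$drift
    )
  }
  specs <- list(
    Gq = make_spec(seed, 1.30, -60, 0.60, list(
      list(a = "3.50", b = "B/2", category = "ionic", occupancy = 80),
      list(a = "6.48", b = "B/9", category = "hydrophobic", occupancy = 60)
    )),
    Gi = make_spec(seed + 500L, 1.15, 180, 0.40, list(
      list(a = "3.50", b = "B/2", category = "ionic", occupancy = 55),
      list(a = "7.49", b = "B/11", category = "hbond", occupancy = 35)
    ))
  )
  systems <- purrr::imap(specs, function(sp, lab) {
    cx <- generate_toy_complex(sp)
    ens <- generate_trajectory(cx, sp)
    files <- write_fixture(cx, ens, file.path(dir, lab))
    list(label = lab, structure = files$structure,
         trajectories = files$trajectories, annotation = files$annotation,
         dt = sp$dt,
         chain_roles = c(A = "receptor", B = "partner", M = "membrane",
                         W = "water", I = "ion"))
  })
  run_config(list(
    systems = unname(systems),
    comparisons = list(c("Gq", "Gi")),
    discard = "auto", window = 20, k = 2,
    sasa = list(probe = 0.14, n_points = 240),
    stride = 2L, seed = as.integer(seed),
    out_dir = file.path(dir, "results")
  ))
}
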