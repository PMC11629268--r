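test_that("helicity scores ideal helices and extended chains", {
  lay_helix <- two_helix_layout()
  spec <- synthetic_spec(seed = 1, n_frames = 4, helix_layout = lay_helix)
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  h <- helicity(ens, cx)
  expect_true(all(h$value == 1))

  lay_ext <- list(list(chain = "A", role = "receptor",
                       sequence = rep("ALA", 10), phi = 180, psi = 180,
                       origin = c(0, 0, 0), axis = c(0, 0, 1)))
  spec_e <- synthetic_spec(seed = 1, n_frames = 2, helix_layout = lay_ext)
  cx_e <- generate_toy_complex(spec_e)
  ens_e <- generate_trajectory(cx_e, spec_e)
  expect_true(all(helicity(ens_e, cx_e)$value == 0))
})

test_that("membrane offset is the COM z gap and is translation invariant", {
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C",
                                x = 0, y = 0, z = 2)),
    list(chain = "M", resnum = 1, resname = "MEM",
         atoms = tibble::tibble(name = c("P", "P2"), element = "P",
                                x = c(0, 1), y = 0, z = 0))
  ), chain_roles = c(A = "receptor", M = "membrane"))
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  ens <- manual_ensemble(cx, frames = list(X, X + 5))
  mo <- membrane_offset(ens, cx)
  expect_equal(mo$value, c(2, 2))
  expect_error(membrane_offset(ens, cx, membrane_chains = character(0)),
               "empty")
})

test_that("box area multiplies x and y and flags missing boxes", {
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C",
                                x = 0, y = 0, z = 0))))
  ens <- manual_ensemble(cx, box = c(10, 12, 8))
  expect_equal(box_area(ens)$value, 120)
  ens2 <- manual_ensemble(cx)
  expect_error(box_area(ens2), "box")
})

test_that("rmsd series is superposition invariant with a closed-form case", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  atoms <- tibble::tibble(
    serial = 1:10, name = "CA", element = "C", chain = "A", resnum = 1:10,
    icode = "", resname = "ALA", x = X[, 1], y = X[, 2], z = X[, 3])
  cx <- annotated_complex(atoms)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Xd <- X; Xd[10, ] <- Xd[10, ] + c(0.1, 0, 0)
  ens <- manual_ensemble(cx, frames = list(X, X %*% R, Xd))
  r_all <- rmsd_series(ens, cx, sel_idx = 1:10, fit_idx = 1:9)
  expect_equal(r_all$value[1], 0)
  expect_lt(r_all$value[2], 1e-10)
  expect_equal(r_all$value[3], sqrt(0.1^2 / 10), tolerance = 1e-8)

  # collinear fit selection is rejected
  Xc <- cbind(1:10 / 10, 0, 0)
  ensc <- manual_ensemble(cx, frames = list(Xc, Xc))
  expect_error(rmsd_series(ensc, cx, sel_idx = 1:10), "degenerate")
})

test_that("rmsf recovers isotropic jitter and vanishes for rigid motion", {
  lay <- two_helix_layout()
  spec0 <- synthetic_spec(seed = 5, n_frames = 4, helix_layout = lay)
  cx <- generate_toy_complex(spec0)
  ens0 <- generate_trajectory(cx, spec0)
  sel <- which(cx$atoms$name == "CA" & cx$atoms$chain == "A")
  expect_true(all(rmsf(ens0, cx, sel)$rmsf == 0))

  spec_j <- synthetic_spec(seed = 5, n_frames = 150, helix_layout = lay,
                           jitter = 0.05)
  ens_j <- generate_trajectory(cx, spec_j)
  rf <- rmsf(ens_j, cx, sel)
  expect_equal(mean(rf$rmsf), 0.05 * sqrt(3), tolerance = 0.12)

  # rigid-body translation only: zero after fitting
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  ens_t <- manual_ensemble(cx, frames = list(X, X + 1, X + 2))
  expect_lt(max(rmsf(ens_t, cx, sel)$rmsf), 1e-10)

  ens_1 <- manual_ensemble(cx, frames = list(X))
  expect_error(rmsf(ens_1, cx, sel), "2 frames")
})

test_that("stationarity detection finds onset, handles ramps, stays monotone", {
  mk <- function(v, t = seq_along(v) - 1) {
    metric_series(tibble::tibble(replica = "rep1", time = t, value = v),
                  "m", "nm")
  }
  set.seed(2)
  noise <- rnorm(400, 0, 0.05)
  flat <- mk(noise)
  rep0 <- detect_equilibration(list(flat), window = 50, k = 2)
  expect_equal(unname(rep0$discard_time), 0)

  ramp <- mk(seq(0, 10, length.out = 400) + noise)
  repr <- detect_equilibration(list(ramp), window = 50, k = 2)
  expect_equal(unname(repr$discard_time), 399)
  expect_true(repr$warning)

  drift <- mk(2 * exp(-(0:399) / 50) + noise)
  repd <- detect_equilibration(list(drift), window = 50, k = 2)
  d1 <- unname(repd$discard_time)
  expect_gte(d1, 50)
  expect_lte(d1, 300)
  # appending stationary tail never pushes the discard time later by more
  # than the grid effect of re-estimating the reference mean (10% window)
  longer <- mk(c(2 * exp(-(0:399) / 50) + noise,
                 rnorm(200, 0, 0.05)))
  d2 <- unname(detect_equilibration(list(longer), window = 50,
                                    k = 2)$discard_time)
  expect_lte(d2, d1 + 5)

  # fixed override reproduces the fixed-cut workflow
  fixed <- detect_equilibration(list(drift), discard = 200)
  expect_equal(unname(fixed$discard_time), 200)
})
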