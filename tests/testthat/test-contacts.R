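test_that("constructed geometries classify into the right categories", {
  # Asp carboxylate 0.35 nm from Arg guanidinium: ionic + salt bridge
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ASP",
         atoms = tibble::tibble(name = c("CA", "CB", "CG", "OD1", "OD2"),
                                element = c("C", "C", "C", "O", "O"),
                                x = c(-0.4, -0.25, -0.12, 0, -0.1),
                                y = c(0, 0, 0, 0, 0.1), z = 0)),
    list(chain = "B", resnum = 1, resname = "ARG",
         atoms = tibble::tibble(name = c("CA", "NE", "NH1"),
                                element = c("C", "N", "N"),
                                x = c(0.8, 0.5, 0.35), y = 0, z = 0))))
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  det <- detect_frame(cx, X, "A", "B")
  expect_true(all(c("ionic", "salt_bridge") %in% det$category))
  # vdW suppressed for the same pair
  expect_false("vdw" %in% det$category)

  # backbone-backbone hydrogen bond at 0.33 nm
  cx_hb <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = c("N", "CA", "C", "O"),
                                element = c("N", "C", "C", "O"),
                                x = c(-0.5, -0.35, -0.15, 0), y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = c("N", "CA", "C", "O"),
                                element = c("N", "C", "C", "O"),
                                x = c(0.33, 0.5, 0.7, 0.85), y = 0, z = 0))))
  det_hb <- detect_frame(cx_hb, as.matrix(cx_hb$atoms[, c("x", "y", "z")]),
                         "A", "B")
  hb <- det_hb[det_hb$category == "hbond", ]
  expect_true(nrow(hb) >= 1 && all(hb$subtype == "bb-bb"))
})

test_that("aromatic geometries split into pi, T and cation classes", {
  hexagon <- function(ctr, normal_axis = "z", r = 0.139) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    if (normal_axis == "z") {
      cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3])
    } else {
      cbind(ctr[1], ctr[2] + r * cos(th), ctr[3] + r * sin(th))
    }
  }
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  mk_phe <- function(chain, ctr, axis = "z") {
    h <- hexagon(ctr, axis)
    list(chain = chain, resnum = 1, resname = "PHE",
         atoms = tibble::tibble(name = c("CA", ring_names), element = "C",
                                x = c(ctr[1] + 1, h[, 1]),
                                y = c(ctr[2], h[, 2]),
                                z = c(ctr[3] - 0.2, h[, 3])))
  }
  # stacked parallel rings, centroids 0.45 nm apart
  cx_p <- build_manual_complex(list(mk_phe("A", c(0, 0, 0)),
                                    mk_phe("B", c(0, 0, 0.45))))
  det_p <- detect_frame(cx_p, as.matrix(cx_p$atoms[, c("x", "y", "z")]),
                        "A", "B")
  expect_true("pi_stack" %in% det_p$category)
  expect_false("t_stack" %in% det_p$category)

  # perpendicular rings at 0.55 nm
  cx_t <- build_manual_complex(list(mk_phe("A", c(0, 0, 0)),
                                    mk_phe("B", c(0, 0, 0.55), axis = "x")))
  det_t <- detect_frame(cx_t, as.matrix(cx_t$atoms[, c("x", "y", "z")]),
                        "A", "B")
  expect_true("t_stack" %in% det_t$category)
  expect_false("pi_stack" %in% det_t$category)

  # lysine ammonium on the ring axis at 0.4 nm
  cx_c <- build_manual_complex(list(
    mk_phe("A", c(0, 0, 0)),
    list(chain = "B", resnum = 1, resname = "LYS",
         atoms = tibble::tibble(name = c("CA", "NZ"), element = c("C", "N"),
                                x = 0, y = c(0.9, 0), z = c(0.6, 0.40)))))
  det_c <- detect_frame(cx_c, as.matrix(cx_c$atoms[, c("x", "y", "z")]),
                        "A", "B")
  expect_true("pi_cation" %in% det_c$category)
})

test_that("detection equals the all-pairs oracle on jittered helix dimers", {
  spec <- synthetic_spec(seed = 17, n_frames = 3, jitter = 0.05,
                         helix_layout = two_helix_layout(8, 6, gap = 1.25))
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  for (f in 1:3) {
    X <- frame_coords(ens, 1, f)
    mine <- detect_frame(cx, X, "A", "B")
    oracle <- contact_oracle(cx, X, "A", "B")
    expect_identical(contact_set_string(mine), contact_set_string(oracle))
  }
})

test_that("occupancies average over replicas and scheduled contacts recover", {
  spec <- synthetic_spec(
    seed = 21, n_frames = 100, n_replicas = 1,
    helix_layout = two_helix_layout(8, 6, gap = 2.5),
    contact_schedule = list(
      list(a = "A/4", b = "B/2", category = "ionic", occupancy = 45)))
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  occ <- contact_occupancy(ens, cx)
  ionic <- occ[occ$category == "ionic" & occ$resnum_a == 4, ]
  expect_equal(ionic$occupancy, 45)

  # replica averaging is the unweighted mean: 100 / 0 / 50 -> 50
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  ri <- resolve(cx, "A/4")$residue_index
  rb <- resolve(cx, "B/2")$residue_index
  on_X <- gpcrtraj:::place_contact(X, cx, list(a = "A/4", b = "B/2",
                                               category = "ionic"), on = TRUE)
  off_X <- gpcrtraj:::place_contact(X, cx, list(a = "A/4", b = "B/2",
                                                category = "ionic"), on = FALSE)
  mk_rep <- function(id, frames) {
    list(id = id, xyz = do.call(rbind, lapply(frames, function(m) as.vector(t(m)))),
         box = NULL, time = seq_along(frames) - 1)
  }
  ens3 <- trajectory_ensemble(list(
    mk_rep("r1", list(on_X, on_X)),
    mk_rep("r2", list(off_X, off_X)),
    mk_rep("r3", list(on_X, off_X))))
  occ3 <- contact_occupancy(ens3, cx)
  ionic3 <- occ3[occ3$category == "ionic", ]
  expect_equal(sort(unlist(ionic3[1, c("occ_r1", "occ_r2", "occ_r3")])),
               c(occ_r2 = 0, occ_r3 = 50, occ_r1 = 100))
  expect_equal(ionic3$occupancy[1], 50)
})

test_that("the occupancy filter keeps the boundary and is idempotent", {
  rec <- tibble::tibble(occupancy = c(29.9, 30, 45, 12))
  kept <- filter_occupancy(rec, 30)
  expect_equal(kept$occupancy, c(30, 45))
  expect_identical(filter_occupancy(kept, 30), kept)
  # raising the threshold never adds records
  expect_true(nrow(filter_occupancy(rec, 50)) <= nrow(kept))
  expect_equal(nrow(filter_occupancy(rec[0, ], 30)), 0)
})

test_that("the contact matrix groups pairs by substructure", {
  spec <- synthetic_spec(
    seed = 23, n_frames = 50,
    helix_layout = two_helix_layout(8, 6, gap = 2.5),
    contact_schedule = list(
      list(a = "A/4", b = "B/2", category = "ionic", occupancy = 80)))
  cx <- generate_toy_complex(spec)
  cx <- apply_annotations(cx, tibble::tibble(
    chain = c(rep("A", 8), rep("B", 6)), resnum = c(1:8, 1:6), icode = "",
    generic_number = NA_character_,
    substructure = c(rep("TM3", 8), rep("H5", 6))))
  ens <- generate_trajectory(cx, spec)
  occ <- contact_occupancy(ens, cx)
  cm <- contact_matrix(occ, cx, min_occupancy = 50)
  expect_true(nrow(cm) >= 1)
  expect_true(all(cm$substructure_a == "TM3" & cm$substructure_b == "H5"))
  # an impossible threshold empties the matrix
  expect_equal(nrow(contact_matrix(occ, cx, min_occupancy = 100.01)), 0)
})
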