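test_that("CA distances honour geometry and the minimum image", {
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C", x = 0, y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C", x = 1.2, y = 0, z = 0))))
  ens <- manual_ensemble(cx)
  expect_equal(ca_distance(ens, cx, "A/1", "B/1")$value, 1.2)

  # pair straddling a 10 nm periodic box
  cx2 <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C", x = 0.1, y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CA", element = "C", x = 9.9, y = 0, z = 0))))
  ens2 <- manual_ensemble(cx2, box = c(10, 10, 10))
  expect_equal(ca_distance(ens2, cx2, "A/1", "B/1")$value, 0.2)

  cx3 <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CB", element = "C", x = 0, y = 0, z = 0))))
  expect_error(ca_distance(manual_ensemble(cx3), cx3, "A/1", "A/1"), "CA")
})

test_that("side-chain COM distances use masses and the glycine fallback", {
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "CYS",
         atoms = tibble::tibble(name = c("CA", "CB", "CG"),
                                element = "C",
                                x = c(-1, 0, 0.2), y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "SER",
         atoms = tibble::tibble(name = c("CA", "CB"), element = "C",
                                x = c(2, 0.6), y = 0, z = 0))))
  ens <- manual_ensemble(cx)
  # equal-mass two-atom side chain at 0 and 0.2 -> COM 0.1; point at 0.6
  expect_equal(sidechain_com_distance(ens, cx, "A/1", "B/1")$value, 0.5)

  cx_gly <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "GLY",
         atoms = tibble::tibble(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                                x = c(-0.1, 0, 0.1, 0.2), y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = c("CA", "CB"), element = "C",
                                x = c(1, 0.7), y = 0, z = 0))))
  ens_g <- manual_ensemble(cx_gly)
  expect_equal(sidechain_com_distance(ens_g, cx_gly, "A/1", "B/1")$value, 0.7)
})

test_that("triangle areas match closed forms and the cross-product oracle", {
  mk_point_res <- function(chain, p) {
    list(chain = chain, resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CB", element = "C",
                                x = p[1], y = p[2], z = p[3]))
  }
  s <- 0.5
  pts <- list(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  cx <- build_manual_complex(purrr::map2(c("A", "B", "C"), pts, mk_point_res))
  ens <- manual_ensemble(cx)
  a <- triangle_area(ens, cx, "A/1", "B/1", "C/1")$value
  expect_equal(a, sqrt(3) / 4 * s^2, tolerance = 1e-9)
  # independent cross-product oracle
  ab <- pts[[2]] - pts[[1]]; ac <- pts[[3]] - pts[[1]]
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  expect_equal(a, 0.5 * sqrt(sum(cr^2)), tolerance = 1e-12)

  # right triangle legs 0.3 / 0.4
  pts_r <- list(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.4, 0))
  cx_r <- build_manual_complex(purrr::map2(c("A", "B", "C"), pts_r, mk_point_res))
  expect_equal(triangle_area(manual_ensemble(cx_r), cx_r,
                             "A/1", "B/1", "C/1")$value, 0.06,
               tolerance = 1e-9)

  # collinear -> 0 with no NaN
  pts_c <- list(c(0, 0, 0), c(0.3, 0, 0), c(0.7, 0, 0))
  cx_c <- build_manual_complex(purrr::map2(c("A", "B", "C"), pts_c, mk_point_res))
  expect_equal(triangle_area(manual_ensemble(cx_c), cx_c,
                             "A/1", "B/1", "C/1")$value, 0)
})

test_that("motif RMSD vanishes for self and rotations, tracks displacement", {
  lay <- two_helix_layout()
  spec <- synthetic_spec(seed = 2, n_frames = 1, helix_layout = lay)
  cx <- generate_toy_complex(spec)
  ann <- tibble::tibble(chain = "A", resnum = 5:9, icode = "",
                        generic_number = paste0("7.", 49:53),
                        substructure = "TM7")
  cx <- apply_annotations(cx, ann)
  fitsel <- paste0("A/", c(1:4, 10:15))
  motif <- paste0("7.", 49:53)
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  motif_atoms <- which(cx$atoms$chain == "A" & cx$atoms$resnum %in% 5:9 &
                         cx$atoms$name %in% c("N", "CA", "C", "O"))
  Xd <- X
  Xd[cx$atoms$resnum %in% 5:9 & cx$atoms$chain == "A", 1] <-
    Xd[cx$atoms$resnum %in% 5:9 & cx$atoms$chain == "A", 1] + 0.3
  ens <- manual_ensemble(cx, frames = list(X, X %*% R, Xd))
  m <- motif_rmsd(ens, cx, motif, reference = cx, fit_selectors = fitsel)
  expect_equal(m$value[1], 0, tolerance = 1e-10)
  expect_equal(m$value[2], 0, tolerance = 1e-10)
  expect_equal(m$value[3], 0.3, tolerance = 1e-9)

  expect_error(motif_rmsd(ens, cx, c(motif, "9.99"), reference = cx,
                          fit_selectors = fitsel), "9.99")
})

test_that("closest-ion distances take the minimum over ions and images", {
  cx <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ASP",
         atoms = tibble::tibble(name = "CA", element = "C", x = 0, y = 0, z = 0)),
    list(chain = "I", resnum = 1, resname = "NA",
         atoms = tibble::tibble(name = "NA", element = "NA", x = 3.1, y = 0, z = 0)),
    list(chain = "I", resnum = 2, resname = "NA",
         atoms = tibble::tibble(name = "NA", element = "NA", x = 0, y = 0.9, z = 0))))
  ens <- manual_ensemble(cx)
  expect_equal(closest_ion_distance(ens, cx, "A/1", "NA")$value, 0.9)

  # single ion across the periodic boundary
  cx2 <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ASP",
         atoms = tibble::tibble(name = "CA", element = "C", x = 0.2, y = 0, z = 0)),
    list(chain = "I", resnum = 1, resname = "NA",
         atoms = tibble::tibble(name = "NA", element = "NA", x = 9.8, y = 0, z = 0))))
  ens2 <- manual_ensemble(cx2, box = c(10, 10, 10))
  expect_equal(closest_ion_distance(ens2, cx2, "A/1", "NA")$value, 0.4)

  expect_error(closest_ion_distance(ens, cx, "A/1", "CL"), "no ions")
})

test_that("water counts use the nearest-heavy-atom shell", {
  lay <- list(list(chain = "A", role = "receptor",
                   sequence = rep("ALA", 6), origin = c(0, 0, 0),
                   axis = c(0, 0, 1)))
  spec <- synthetic_spec(
    seed = 6, n_frames = 2, helix_layout = lay,
    solvent = list(list(n_waters = 5, n_na = 0, center = "A/3", radius = 0.5),
                   list(n_waters = 7, n_na = 0, center = "A/3", radius = 2.2)))
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  expect_true(all(water_count(ens, cx, "A/3", radius = 8)$value == 5))
  # all waters beyond the shell
  spec0 <- synthetic_spec(
    seed = 6, n_frames = 2, helix_layout = lay,
    solvent = list(list(n_waters = 6, n_na = 0, center = "A/3", radius = 2.5)))
  cx0 <- generate_toy_complex(spec0)
  ens0 <- generate_trajectory(cx0, spec0)
  expect_true(all(water_count(ens0, cx0, "A/3", radius = 8)$value == 0))
  # no waters at all: zero series with a warning
  spec_n <- synthetic_spec(seed = 6, n_frames = 2, helix_layout = lay)
  cx_n <- generate_toy_complex(spec_n)
  ens_n <- generate_trajectory(cx_n, spec_n)
  expect_warning(wc <- water_count(ens_n, cx_n, "A/3"), "no water")
  expect_true(all(wc$value == 0))
})

test_that("distance metrics are invariant to global rotation and translation", {
  lay <- two_helix_layout()
  spec <- synthetic_spec(seed = 3, n_frames = 1, helix_layout = lay)
  cx <- generate_toy_complex(spec)
  X <- as.matrix(cx$atoms[, c("x", "y", "z")])
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  ens <- manual_ensemble(cx, frames = list(X, sweep(X %*% R, 2, c(1, 2, 3), "+")))
  for (f in list(function(e) ca_distance(e, cx, "A/3", "B/4"),
                 function(e) sidechain_com_distance(e, cx, "A/2", "B/4"),
                 function(e) triangle_area(e, cx, "A/2", "A/5", "B/4"))) {
    v <- f(ens)$value
    expect_equal(v[1], v[2], tolerance = 1e-9)
  }
})
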