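test_that("torsion histograms are normalised circular bins", {
  expect_equal(torsion_histogram(rep(10, 50), n_bins = 36),
               c(rep(0, 19), 1, rep(0, 16)))
  set.seed(1)
  h <- torsion_histogram(runif(20000, -180, 180), n_bins = 10)
  expect_equal(sum(h), 1)
  expect_true(all(abs(h - 0.1) < 0.02))
  expect_error(torsion_histogram(1, n_bins = 1), "n_bins")
  # wrap: 180 maps into the first bin with -180
  expect_equal(torsion_histogram(c(-180, 180), n_bins = 36)[1], 1)
})

test_that("Jensen-Shannon distance matches direct summation and its bounds", {
  p <- c(1, 0); q <- c(0.5, 0.5)
  # independent brute-force evaluation of the defining formula
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  expected <- sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
  expect_equal(jensen_shannon_distance(p, q), expected, tolerance = 1e-12)
  expect_equal(expected, 0.558, tolerance = 1e-3)

  expect_equal(jensen_shannon_distance(q, q), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)
  expect_error(jensen_shannon_distance(c(1, 0), c(1, 0, 0)), "length")
  expect_error(jensen_shannon_distance(c(0.7, 0.7), q), "sum")

  set.seed(42)
  for (i in 1:200) {
    a <- runif(12); a <- a / sum(a)
    b <- runif(12); b <- b / sum(b)
    c_ <- runif(12); c_ <- c_ / sum(c_)
    dab <- jensen_shannon_distance(a, b)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, jensen_shannon_distance(b, a), tolerance = 1e-12)
    # metric property on sampled triples
    expect_lte(dab, jensen_shannon_distance(a, c_) +
                 jensen_shannon_distance(c_, b) + 1e-12)
  }
})

test_that("torsion extraction reads the built geometry back", {
  lay <- list(
    list(chain = "A", role = "receptor",
         sequence = c("ALA", "ALA", "LEU", "ALA", "ALA"),
         origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(chain = "B", role = "partner", sequence = rep("LYS", 5),
         origin = c(2.5, 0, 0), axis = c(0, 0, 1)))
  spec <- synthetic_spec(seed = 8, n_frames = 3, helix_layout = lay)
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  tor <- extract_torsions(ens, cx)
  expect_true(all(abs(tor$value[tor$angle == "phi"] + 57) < 1e-6))
  expect_true(all(abs(tor$value[tor$angle == "psi"] + 47) < 1e-6))
  # alanine emits no chi angles; terminal residues lack phi/psi
  expect_false(any(tor$angle == "chi1" & tor$resname == "ALA"))
  expect_false(any(tor$resnum == 1 & tor$angle == "phi" & tor$chain == "A"))
  expect_false(any(tor$resnum == 5 & tor$angle == "psi" & tor$chain == "A"))
})

test_that("extraction agrees with the bio3d torsion oracle", {
  lay <- two_helix_layout(n_receptor = 6, n_partner = 4)
  spec <- synthetic_spec(seed = 12, n_frames = 1, helix_layout = lay,
                         jitter = 0.03)
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  tor <- extract_torsions(ens, cx)
  X <- frame_coords(ens, 1, 1)
  # bio3d torsion.xyz on an explicit quadruple
  ri <- resolve(cx, "A/3")$residue_index
  q <- purrr::map_int(c("N", "CA", "CB", "CG"), function(nm) {
    which(cx$atoms$residue_index == ri & cx$atoms$name == nm)
  })
  oracle <- bio3d::torsion.xyz(as.vector(t(X[q, ])), atm.inc = 4)
  mine <- tor$value[tor$resnum == 3 & tor$chain == "A" & tor$angle == "chi1" &
                      tor$frame == 1]
  expect_equal(gpcrtraj:::wrap_angle(mine - oracle), 0, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("bimodal chi targets appear as bimodal empirical distributions", {
  lay <- two_helix_layout()
  spec <- synthetic_spec(
    seed = 10, n_frames = 600, helix_layout = lay,
    torsion_targets = list(list(residue = "A/3", angle = "chi1",
                                modes = list(c(-60, 50, 0.5),
                                             c(180, 50, 0.5)))))
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  tor <- extract_torsions(ens, cx)
  v <- tor$value[tor$resnum == 3 & tor$angle == "chi1"]
  near <- function(x, mu) mean(abs(gpcrtraj:::wrap_angle(x - mu)) < 30)
  expect_gt(near(v, -60), 0.35)
  expect_gt(near(v, 180), 0.35)
  expect_lt(near(v, 60), 0.05)
})

test_that("ensemble comparison is symmetric, null on self, sharp on contrast", {
  lay <- two_helix_layout(n_receptor = 8, n_partner = 4)
  mk <- function(seed, mode) {
    spec <- synthetic_spec(
      seed = seed, n_frames = 500, helix_layout = lay,
      torsion_targets = list(
        list(residue = "A/3", angle = "chi1", modes = list(c(mode, 400, 1))),
        list(residue = "A/8", angle = "chi1", modes = list(c(-60, 30, 1)))))
    cx <- generate_toy_complex(spec)
    list(cx = cx, tor = extract_torsions(generate_trajectory(cx, spec), cx))
  }
  a <- mk(31, -60)
  b <- mk(32, 60)
  self <- compare_ensembles(a$tor, a$tor)
  expect_true(all(self$jsd == 0))

  m1 <- compare_ensembles(a$tor, b$tor)
  m2 <- compare_ensembles(b$tor, a$tor)
  expect_equal(m1$jsd, m2$jsd)
  expect_gt(m1$jsd[m1$resnum == 3 & m1$angle == "chi1"], 0.9)
  expect_true(all(m1$jsd[!(m1$resnum == 3 & m1$angle == "chi1")] < 0.2))
  top <- select_high_jsd(m1, threshold = 0.6)
  expect_equal(top$resnum, 3)

  # coarsening nested bins can never increase the distance
  j36 <- m1$jsd
  j18 <- compare_ensembles(a$tor, b$tor, n_bins = 18)$jsd
  expect_true(all(j18 <= j36 + 1e-9))

  expect_error(compare_ensembles(a$tor[0, ], b$tor), "share")
})
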