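test_that("delta-SASA vanishes without occlusion and reaches the engulfed bound", {
  spec_far <- synthetic_spec(seed = 2, n_frames = 2,
                             helix_layout = two_helix_layout(8, 5, gap = 10))
  cx <- generate_toy_complex(spec_far)
  ens <- generate_trajectory(cx, spec_far)
  ds <- delta_sasa(ens, cx, params = sasa_params(n_points = 240))
  expect_true(all(ds$dsasa == 0))

  # a single atom fully caged by partner atoms loses its whole monomer SASA
  shell <- gpcrtraj:::fibonacci_sphere(40, 0.33)
  cage <- build_manual_complex(list(
    list(chain = "A", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = "CB", element = "C", x = 0, y = 0, z = 0)),
    list(chain = "B", resnum = 1, resname = "ALA",
         atoms = tibble::tibble(name = paste0("C", seq_len(40)), element = "C",
                                x = shell[, 1], y = shell[, 2], z = shell[, 3]))))
  ens_c <- manual_ensemble(cage)
  ds_c <- delta_sasa(ens_c, cage, receptor_chains = "A", partner_chains = "B",
                     params = sasa_params(n_points = 960))
  a_row <- ds_c[ds_c$chain == "A", ]
  expect_equal(a_row$sasa_complex, 0, tolerance = 1e-9)
  expect_equal(a_row$dsasa, a_row$sasa_mon)

  expect_error(delta_sasa(ens_c, cage, receptor_chains = "A",
                          partner_chains = c("A", "B")), "overlap")
})

test_that("occlusion only reduces exposure (dsasa >= 0 up to sampling noise)", {
  spec <- synthetic_spec(seed = 5, n_frames = 3, jitter = 0.02,
                         helix_layout = two_helix_layout(10, 8, gap = 1.2))
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  ds <- delta_sasa(ens, cx, params = sasa_params(n_points = 480))
  expect_true(all(ds$dsasa >= -0.01))
  expect_true(any(ds$dsasa > 0))
})

test_that("interface area is the exact mean of the two sides", {
  tab <- tibble::tibble(
    replica = "rep1", frame = 1L, time = 0,
    side = c("receptor", "receptor", "partner"),
    chain = c("A", "A", "B"), resnum = c(1L, 2L, 1L),
    resname = "ALA", sasa_mon = 20, sasa_complex = 0,
    dsasa = c(10, 6, 14))
  ia <- interface_area(tab)
  expect_equal(ia$area, (16 + 14) / 2)
  # zero-contact frame
  tab0 <- dplyr::mutate(tab, dsasa = 0)
  expect_equal(interface_area(tab0)$area, 0)
})

test_that("membership rules follow the literal conjunction", {
  mk_row <- function(dsasa, resname = "ALA") {
    tibble::tibble(replica = "rep1", frame = 1L, time = 0, side = "receptor",
                   chain = "A", resnum = seq_along(dsasa), resname = resname,
                   sasa_mon = 1, sasa_complex = 1 - dsasa, dsasa = dsasa)
  }
  # ALA SASA_max = 1.29 nm^2
  tab <- mk_row(c(0.20, 0.03, 0.16, 0))
  tab$resname[3] <- "GLY"  # 0.03/1.04 = 2.9 % ; 0.16/1.04 = 15.4 %
  tab$dsasa[3] <- 0.03
  m <- original_interface(tab)
  # 0.20 -> member; 0.03 ALA (2.3 %) -> both filters met -> excluded;
  # 0.03 GLY normalised 2.9 % -> excluded; 0 -> not in interface
  expect_equal(m$original_member, c(TRUE, FALSE, FALSE, FALSE))

  # only one exclusion condition met: small area but high normalised value
  tab2 <- mk_row(0.03, resname = "GLY")
  tab2$dsasa <- 0.03
  sm <- c(GLY = 0.2)  # normalised 15 % > 10 %
  m2 <- original_interface(tab2, sasa_max = sm)
  expect_true(m2$original_member)
  # disjunction mode excludes it
  m3 <- original_interface(tab2, sasa_max = sm, mode = "disjunction")
  expect_false(m3$original_member)

  expect_error(original_interface(mk_row(0.2, resname = "XXX")), "SASA_max")
})

test_that("membership and presence equal a brute-force oracle on random tables", {
  set.seed(99)
  sm <- sasa_max_table()
  types <- setdiff(names(sm), "BLK")
  for (case in 1:200) {
    n <- sample(3:12, 1)
    resname <- sample(types, n, replace = TRUE)
    d0 <- round(runif(n, -0.02, 0.30), 3)
    tab <- tibble::tibble(replica = "rep1", frame = 1L, time = 0,
                          side = "receptor", chain = "A", resnum = seq_len(n),
                          resname = resname, sasa_mon = 1,
                          sasa_complex = 1 - d0, dsasa = d0)
    m <- original_interface(tab)
    expect_identical(m$original_member, membership_oracle(d0, resname, sm))

    # presence over random frame series
    nf <- 20
    frames <- purrr::map(seq_len(n), ~ round(runif(nf, -0.05, 0.3), 3))
    long <- purrr::imap(frames, function(v, i) {
      tibble::tibble(replica = "rep1", frame = seq_len(nf),
                     time = seq_len(nf) - 1, side = "receptor", chain = "A",
                     resnum = i, resname = resname[i], sasa_mon = 1,
                     sasa_complex = 1 - v, dsasa = v)
    }) %>% dplyr::bind_rows()
    pres <- interface_presence(long, m)
    pres <- pres[order(pres$resnum), ]
    oracle <- presence_oracle(frames, m$original_member[order(m$resnum)])
    expect_equal(pres$presence, oracle$presence)
    expect_identical(pres$additional_member, oracle$additional)
  }
})

test_that("substructure aggregation conserves the side totals", {
  spec <- synthetic_spec(seed = 5, n_frames = 4,
                         helix_layout = two_helix_layout(10, 8, gap = 1.2))
  cx <- generate_toy_complex(spec)
  cx <- apply_annotations(cx, tibble::tibble(
    chain = c(rep("A", 10), rep("B", 8)),
    resnum = c(1:10, 1:8), icode = "",
    generic_number = NA_character_,
    substructure = c(rep("TM6", 5), rep("ICL2", 5), rep("H5", 8))))
  ens <- generate_trajectory(cx, spec)
  ds <- delta_sasa(ens, cx, params = sasa_params(n_points = 240))
  agg <- aggregate_by_substructure(ds, cx)
  side_tot <- interface_area(ds) %>%
    dplyr::group_by(.data$replica) %>%
    dplyr::summarise(r = mean(.data$dsasa_receptor), .groups = "drop")
  agg_tot <- sum(agg$mean_area[agg$side == "receptor"])
  expect_equal(agg_tot, mean(side_tot$r), tolerance = 1e-9)
})
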