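test_that("read_pdb copies printed fields of a minimal single-model file", {
  f <- write_pdb_text(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"))
  fr <- read_pdb(f)
  expect_s3_class(fr, "structure_frame")
  expect_equal(n_atoms(fr), 2L)
  expect_equal(fr$coords[1, ], c(11.104, 6.134, -6.504))
  expect_equal(fr$coords[2, ], c(11.639, 6.071, -5.147))
  expect_equal(fr$atoms$atom_name, c("N", "CA"))
  expect_equal(fr$atoms$element, c("N", "C"))
})

test_that("multi-MODEL files become trajectories with one frame per model", {
  mk <- function(m, x) c(
    sprintf("MODEL     %4d", m),
    sprintf("ATOM      1  CA  ALA A   1      %7.3f   0.000   0.000  1.00  0.00           C", x),
    sprintf("ATOM      2  CA  ALA A   2      %7.3f   3.800   0.000  1.00  0.00           C", x),
    sprintf("ATOM      3  CA  ALA A   3      %7.3f   7.600   0.000  1.00  0.00           C", x),
    "ENDMDL")
  f <- write_pdb_text(c(mk(1, 1.0), mk(2, 2.0), "END"))
  tr <- read_pdb(f, model_policy = "all", timestep = 0.5)
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$times, c(0, 0.5))
  expect_equal(tr$frames[2, 1, 1], 2.0)
  fr <- read_pdb(f, model_policy = "first")
  expect_s3_class(fr, "structure_frame")
})

test_that("altloc resolution keeps the highest-occupancy copy, ties to lexicographic", {
  f <- write_pdb_text(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BGLY A   2       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA AGLY A   2       4.000   0.000   0.000  0.50  0.00           C",
    "END"))
  fr <- read_pdb(f)
  expect_equal(n_atoms(fr), 2L)
  # occupancy 0.6 copy wins for residue 1 (brute-force max-occupancy scan)
  expect_equal(fr$coords[1, 1], 1.0)
  expect_equal(fr$atoms$occupancy[1], 0.6)
  # tie at residue 2 broken by altloc identifier: A
  expect_equal(fr$atoms$altloc[2], "A")
  expect_equal(fr$coords[2, 1], 4.0)
})

test_that("structures without altlocs pass through altloc resolution unchanged", {
  fr <- toy_ca_chain(8)
  f <- tempfile(fileext = ".pdb")
  write_pdb(fr, f)
  fr2 <- read_pdb(f)
  expect_equal(n_atoms(fr2), 8L)
  expect_equal(fr2$coords, round(fr$coords, 3), tolerance = 1e-9)
})

test_that("HETATM records are retained, flagged, and excluded from Calpha selections", {
  f <- write_pdb_text(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    3 ZN    ZN A  90       1.000   2.000   3.000  1.00  0.00          ZN",
    "HETATM    4 CA    CA A  91       5.000   5.000   5.000  1.00  0.00          CA",
    "END"))
  fr <- read_pdb(f)
  expect_equal(n_atoms(fr), 4L)
  expect_equal(sum(fr$atoms$is_hetatm), 2L)
  # the calcium ion named CA must never enter a Calpha selection
  idx <- suppressWarnings(select_ca(fr, list(c(1, 100)), "A"))
  expect_equal(length(idx), 2L)
  expect_true(all(fr$atoms$element[idx] == "C"))
})

test_that("empty or unparseable input raises typed errors", {
  f <- write_pdb_text(c("REMARK nothing here", "END"))
  expect_error(read_pdb(f), class = "hingescope_error")
  expect_error(read_pdb(tempfile()), class = "hingescope_io_error")
})

test_that("select_ca resolves ranges, orders by residue, reports missing residues", {
  fr <- toy_ca_chain(10)
  expect_equal(length(select_ca(fr, list(c(3, 5)), "A")), 3L)
  expect_equal(length(select_ca(fr, list(c(3, 5), c(8, 8)), "A")), 4L)
  # range-order invariance
  expect_equal(select_ca(fr, list(c(8, 8), c(3, 5)), "A"),
               select_ca(fr, list(c(3, 5), c(8, 8)), "A"),
               ignore_attr = TRUE)
  # residue 4 absent: proceed with the present subset and report (set difference)
  fr_gap <- toy_ca_chain(10, drop_residues = 4)
  expect_warning(idx <- select_ca(fr_gap, list(c(3, 5)), "A"),
                 class = "hingescope_missing_residues")
  expect_equal(length(idx), 2L)
  expect_equal(attr(idx, "missing_residues"), 4L)
  # wrong chain: empty-selection error
  expect_error(select_ca(fr, list(c(3, 5)), "B"),
               class = "hingescope_empty_selection")
})

test_that("PDB write-read round trip preserves atoms and coordinates to 3 decimals", {
  set.seed(42)
  toy <- build_toy_enzyme(synthetic_hinge_params(n_res_domain1 = 20,
                                                 n_res_domain2 = 20))
  fr <- toy$frame
  fr$coords <- fr$coords + matrix(rnorm(length(fr$coords), sd = 0.2),
                                  ncol = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(fr, f)
  fr2 <- read_pdb(f)
  expect_equal(n_atoms(fr2), n_atoms(fr))
  expect_equal(fr2$atoms$atom_name, fr$atoms$atom_name)
  expect_equal(fr2$atoms$residue_number, fr$atoms$residue_number)
  expect_equal(fr2$coords, round(fr$coords, 3), tolerance = 1e-9)
})

test_that("time-series CSV writes header plus one row per frame and round-trips", {
  d <- data.frame(time_ns = c(0, 0.1, 0.2), distance_A = c(12.1, 13.2, 14.3))
  f <- tempfile(fileext = ".csv")
  write_timeseries(d, f)
  expect_equal(length(readLines(f)), 4L)
  # degenerate input: empty series -> header-only CSV
  write_timeseries(d[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  # 100-frame round trip, 6 significant digits
  set.seed(3)
  big <- data.frame(time_ns = seq(0, 9.9, by = 0.1),
                    distance_A = runif(100, 10, 25),
                    angle_deg = runif(100, 0, 30))
  write_timeseries(big, f)
  back <- read_timeseries(f)
  expect_equal(back$distance_A, big$distance_A, tolerance = 1e-6)
  expect_equal(back$angle_deg, big$angle_deg, tolerance = 1e-6)
})

test_that("region sets validate non-overlap and lip-in-subdomain containment", {
  expect_error(region_set("A", lip1 = list(c(5, 3)), lip2 = list(c(20, 25)),
                          subdomain1 = list(c(1, 10)),
                          subdomain2 = list(c(11, 30))),
               class = "hingescope_invalid_region")
  expect_error(region_set("A", lip1 = list(c(1, 5), c(4, 8)),
                          lip2 = list(c(20, 25)),
                          subdomain1 = list(c(1, 10)),
                          subdomain2 = list(c(11, 30))),
               class = "hingescope_invalid_region")
  expect_error(region_set("A", lip1 = list(c(1, 12)), lip2 = list(c(20, 25)),
                          subdomain1 = list(c(1, 10)),
                          subdomain2 = list(c(11, 30))),
               class = "hingescope_invalid_region")
  ok <- region_set("A", lip1 = list(c(2, 4)), lip2 = list(c(20, 25)),
                   subdomain1 = list(c(1, 10)), subdomain2 = list(c(11, 30)))
  expect_s3_class(ok, "region_set")
})

test_that("shipped region presets load and honour the published residue sets", {
  sace <- region_preset("sace_cdomain")
  expect_equal(sace$lip1[[1]], c(73L, 100L))
  expect_equal(sace$lip2[[3]], c(284L, 293L))
  expect_equal(sace$subdomain1[[1]], c(40L, 122L))
  ace2 <- region_preset("ace2")
  expect_equal(ace2$lip1[[1]], c(54L, 81L))
  expect_equal(ace2$lip2[[1]], c(109L, 131L))
  expect_error(region_preset("nonexistent"), class = "hingescope_unknown_preset")
  # round trip through YAML
  f <- tempfile(fileext = ".yaml")
  write_region_set(sace, f)
  again <- region_preset(f)
  expect_equal(again$lip1, sace$lip1)
  expect_equal(again$subdomain2, sace$subdomain2)
})
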