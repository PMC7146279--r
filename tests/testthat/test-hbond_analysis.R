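# Hand-built frame from explicit element/coordinate pairs.
mk_frame <- function(elements, coords, chains = "A") {
  n <- length(elements)
  atoms <- data.frame(serial = seq_len(n), atom_name = elements,
                      element = elements, residue_name = "UNK",
                      residue_number = seq_len(n), insertion_code = "",
                      chain_id = rep(chains, length.out = n), altloc = "",
                      occupancy = 1, is_hetatm = FALSE,
                      stringsAsFactors = FALSE)
  structure_frame(atoms, coords)
}

test_that("find_donors_acceptors applies polar-atom chemistry with proximal hydrogens", {
  # backbone amide N with its H, plus a carbonyl O
  fr <- mk_frame(c("N", "H", "O"),
                 rbind(c(0, 0, 0), c(1.0, 0, 0), c(4, 4, 4)))
  da <- find_donors_acceptors(fr, 1:3)
  expect_equal(nrow(da$donors), 1L)
  expect_equal(da$donors$donor, 1L)
  expect_equal(da$donors$hydrogen, 2L)
  expect_equal(sort(da$acceptors), c(1L, 3L))
  # carbon-only selection: nothing
  fr2 <- mk_frame(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  da2 <- find_donors_acceptors(fr2, 1:2)
  expect_equal(nrow(da2$donors), 0L)
  expect_equal(length(da2$acceptors), 0L)
  # lysine-like NZ with 3 hydrogens: 3 donor pairs sharing one donor
  fr3 <- mk_frame(c("N", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  da3 <- find_donors_acceptors(fr3, 1:4)
  expect_equal(nrow(da3$donors), 3L)
  expect_equal(unique(da3$donors$donor), 1L)
  # hydrogens beyond 1.25 A are not covalent
  fr4 <- mk_frame(c("N", "H"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_equal(nrow(find_donors_acceptors(fr4, 1:2)$donors), 0L)
  expect_error(find_donors_acceptors(fr, integer(0)),
               class = "hingescope_empty_selection")
})

test_that("detect_hbonds applies inclusive distance and angle criteria", {
  # D at origin, H at (1,0,0), A at (3.2,0,0): distance 3.2, angle 0 -> bond
  fr <- mk_frame(c("N", "H", "O"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(3.2, 0, 0)),
                 chains = c("L", "L", "P"))
  hb <- detect_hbonds(fr, 1:2, 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$da_distance_A, 3.2, tolerance = 1e-9)
  expect_equal(hb$hda_angle_deg, 0, tolerance = 1e-9)
  # acceptor at 3.4 A: distance criterion fails
  fr2 <- mk_frame(c("N", "H", "O"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(3.4, 0, 0)))
  expect_equal(nrow(detect_hbonds(fr2, 1:2, 3L)), 0L)
  # exact boundary 3.3 A is inclusive
  fr3 <- mk_frame(c("N", "H", "O"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(3.3, 0, 0)))
  expect_equal(nrow(detect_hbonds(fr3, 1:2, 3L)), 1L)
  # overlapping selections are rejected
  expect_error(detect_hbonds(fr, 1:2, 2:3),
               class = "hingescope_selection_overlap")
  # no hydrogens: explicit condition unless heavy-atom mode is enabled
  fr4 <- mk_frame(c("N", "O"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_error(detect_hbonds(fr4, 1L, 2L),
               class = "hingescope_no_hydrogens")
  hv <- detect_hbonds(fr4, 1L, 2L, heavy_atom_mode = TRUE)
  expect_equal(nrow(hv), 1L)
  expect_true(attr(hv, "heavy_atom_mode"))
  expect_true(is.na(hv$hydrogen))
})

test_that("detect_hbonds agrees exactly with the brute-force all-pairs oracle", {
  crit <- hbond_criteria()
  for (seed in 1:20) {
    fr <- random_polar_frame(60, seed = seed)
    selA <- 1:30; selB <- 31:60
    got <- detect_hbonds(fr, selA, selB, crit)
    want <- oracle_hbonds(fr, selA, selB, crit)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0)
      expect_equal(unname(as.matrix(got[, c("donor", "hydrogen", "acceptor")])),
                   unname(want))
  }
})

test_that("bond sets are symmetric in the selections and monotone in the criteria", {
  set.seed(81)
  fr <- random_polar_frame(80, seed = 5)
  selA <- 1:40; selB <- 41:80
  base <- detect_hbonds(fr, selA, selB)
  swapped <- detect_hbonds(fr, selB, selA)
  expect_equal(base, swapped, ignore_attr = TRUE)
  # rigid-motion invariance of the bond set
  R <- random_rotation()
  fr2 <- fr
  fr2$coords <- fr$coords %*% t(R) + matrix(c(7, -3, 11), 80, 3, byrow = TRUE)
  moved <- detect_hbonds(fr2, selA, selB)
  expect_equal(moved[, 1:3], base[, 1:3])
  # tightening either criterion never adds bonds
  for (d in c(3.3, 3.0, 2.8)) for (a in c(30, 20, 10)) {
    sub <- detect_hbonds(fr, selA, selB, hbond_criteria(d, a))
    expect_lte(nrow(sub), nrow(base))
    key <- function(x) paste(x$donor, x$hydrogen, x$acceptor)
    expect_true(all(key(sub) %in% key(base)))
  }
})

test_that("hbond_count_series reports per-frame counts with population mean/sd", {
  fx <- generate_hbond_fixture(2, 0, seed = 3)
  n <- n_atoms(fx$frame)
  frames <- array(0, dim = c(3, n, 3))
  for (m in 1:3) frames[m, , ] <- fx$frame$coords
  tr <- trajectory(fx$frame$atoms, frames, timestep = 0.1)
  hs <- hbond_count_series(tr, fx$selectionA, fx$selectionB)
  expect_equal(hs$counts, c(2L, 2L, 2L))
  expect_equal(hs$mean, 2)
  expect_equal(hs$sd, 0)

  # frames alternating 1 and 3 bonds: mean 2, population sd 1
  fx3 <- generate_hbond_fixture(3, 0, seed = 4)
  n3 <- n_atoms(fx3$frame)
  co_3 <- fx3$frame$coords
  co_1 <- co_3
  drop2 <- fx3$ground_truth$acceptor[1:2]
  co_1[drop2, 3] <- co_1[drop2, 3] + 50  # push two acceptors out of range
  frames <- array(0, dim = c(4, n3, 3))
  frames[1, , ] <- co_1; frames[2, , ] <- co_3
  frames[3, , ] <- co_1; frames[4, , ] <- co_3
  tr4 <- trajectory(fx3$frame$atoms, frames, timestep = 0.1)
  hs4 <- hbond_count_series(tr4, fx3$selectionA, fx3$selectionB)
  expect_equal(hs4$counts, c(1L, 3L, 1L, 3L))
  expect_equal(hs4$mean, 2)
  expect_equal(hs4$sd, 1)  # denominator T (population convention)
})

test_that("planted fixtures are recovered exactly: true bonds found, decoys rejected", {
  expect_equal(nrow(detect_hbonds(generate_hbond_fixture(3, 0, seed = 1)$frame,
                                  generate_hbond_fixture(3, 0, seed = 1)$selectionA,
                                  generate_hbond_fixture(3, 0, seed = 1)$selectionB)),
               3L)
  fx0 <- generate_hbond_fixture(0, 5, seed = 2)
  expect_equal(nrow(detect_hbonds(fx0$frame, fx0$selectionA, fx0$selectionB)),
               0L)
  for (seed in 1:10) {
    fx <- generate_hbond_fixture(4, 4, seed = seed)
    hb <- detect_hbonds(fx$frame, fx$selectionA, fx$selectionB)
    expect_equal(nrow(hb), 4L)
    truth <- fx$ground_truth[fx$ground_truth$kind == "true", ]
    expect_equal(hb$donor, truth$donor)
    expect_equal(hb$acceptor, truth$acceptor)
  }
})
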