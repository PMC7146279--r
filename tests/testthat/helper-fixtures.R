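# Shared fixtures and independent oracles for the test suite.

# Chain of n residues, one Calpha each, on an idealised alpha-helical path
# (non-collinear, ~100 degrees turn and 1.5 A rise per residue).
toy_ca_chain <- function(n = 10, chain = "A", drop_residues = integer(0)) {
  res <- setdiff(seq_len(n), drop_residues)
  atoms <- data.frame(serial = seq_along(res), atom_name = "CA",
                      element = "C", residue_name = "ALA",
                      residue_number = res, insertion_code = "",
                      chain_id = chain, altloc = "", occupancy = 1,
                      is_hetatm = FALSE, stringsAsFactors = FALSE)
  ang <- res * 100 * pi / 180
  structure_frame(atoms, cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * res))
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Uniform random rotation built from a random axis and angle (Rodrigues).
random_rotation <- function() {
  ax <- rnorm(3)
  rotation_about_axis(ax, runif(1, 0, 180))
}

# Random frame of polar/apolar atoms in a box, for H-bond oracle tests.
random_polar_frame <- function(n = 60, box = 12, p_h = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  el <- sample(c("N", "O", "H", "C"), n, replace = TRUE,
               prob = c(0.2, 0.2, p_h, 1 - 0.4 - p_h))
  atoms <- data.frame(serial = seq_len(n), atom_name = el, element = el,
                      residue_name = "UNK", residue_number = seq_len(n),
                      insertion_code = "", chain_id = "A", altloc = "",
                      occupancy = 1, is_hetatm = FALSE,
                      stringsAsFactors = FALSE)
  structure_frame(atoms, matrix(runif(3 * n, 0, box), n, 3))
}

# Brute-force all-pairs hydrogen-bond oracle: explicit loops, same geometric
# definitions, written independently of detect_hbonds.
oracle_hbonds <- function(frame, selA, selB, criteria) {
  el <- frame$atoms$element
  xyz <- frame$coords
  hits <- list()
  for (dir in 1:2) {
    sd_ <- if (dir == 1) selA else selB
    sa_ <- if (dir == 1) selB else selA
    for (d in sd_) {
      if (!el[d] %in% c("N", "O")) next
      for (h in seq_len(nrow(xyz))) {
        if (el[h] != "H") next
        if (sqrt(sum((xyz[h, ] - xyz[d, ])^2)) > 1.25) next
        for (a in sa_) {
          if (!el[a] %in% c("N", "O") || a == d) next
          v_da <- xyz[a, ] - xyz[d, ]
          dist <- sqrt(sum(v_da^2))
          if (dist > criteria$max_da_distance) next
          v_dh <- xyz[h, ] - xyz[d, ]
          ang <- acos(min(1, max(-1, sum(v_dh * v_da) /
                                   (sqrt(sum(v_dh^2)) * dist)))) * 180 / pi
          if (ang > criteria$max_hda_angle) next
          hits[[length(hits) + 1L]] <- c(d, h, a)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))))
  m <- unique(do.call(rbind, hits))
  colnames(m) <- c("donor", "hydrogen", "acceptor")
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Two-pointer conversion-count oracle: scan endpoint states only.
oracle_conversions <- function(states) {
  last <- NA_character_
  n <- 0L
  for (s in states) {
    if (s == "semi_open") next
    if (!is.na(last) && s != last) n <- n + 1L
    last <- s
  }
  n
}
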