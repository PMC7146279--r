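#' Geometric hydrogen-bond criteria
#'
#' A donor-hydrogen...acceptor triple counts as a hydrogen bond when the
#' donor-acceptor distance is at most `max_da_distance` and the
#' hydrogen-donor-acceptor angle — measured at the donor, between the D->H
#' and D->A vectors, so small values mean a near-linear D-H...A geometry —
#' is at most `max_hda_angle`. Both criteria are inclusive. Defaults are the
#' standard 3.3 Angstrom / 30 degree cutoffs.
#'
#' @param max_da_distance donor-acceptor distance cutoff, Angstrom.
#' @param max_hda_angle proton-donor-acceptor angle cutoff, degrees.
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.3, max_hda_angle = 30) {
  if (max_da_distance <= 0 || max_hda_angle <= 0)
    hs_stop("invalid_criteria", "criteria must be strictly positive")
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criteria")
}

# Covalent D-H assignment by proximity: an N/O with a hydrogen within this
# many Angstrom is a donor through that hydrogen (PDB inputs may lack CONECT).
.hs_covalent_h_cutoff <- 1.25

#' Enumerate hydrogen-bond donors and acceptors in a selection
#'
#' Donors are N or O atoms with at least one covalently proximal hydrogen
#' (H within 1.25 Angstrom anywhere in the frame); each (donor, hydrogen)
#' pair is listed separately, so e.g. a lysine NZ with three hydrogens
#' yields three donor pairs. Acceptors are all N and O atoms in the
#' selection.
#'
#' @param frame a [structure_frame()].
#' @param selection atom indices.
#' @return list with `donors` (data.frame: `donor`, `hydrogen` atom indices)
#'   and `acceptors` (integer indices).
#' @export
find_donors_acceptors <- function(frame, selection) {
  stopifnot(inherits(frame, "structure_frame"))
  if (length(selection) == 0L)
    hs_stop("empty_selection", "empty selection")
  el <- frame$atoms$element
  polar <- selection[el[selection] %in% c("N", "O")]
  h_all <- which(el == "H")
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(polar) > 0L && length(h_all) > 0L) {
    hx <- frame$coords[h_all, , drop = FALSE]
    pairs <- lapply(polar, function(d) {
      dd <- sweep(hx, 2, frame$coords[d, ])
      near <- h_all[rowSums(dd^2) <= .hs_covalent_h_cutoff^2]
      if (length(near) == 0L) return(NULL)
      data.frame(donor = d, hydrogen = near)
    })
    pairs <- pairs[!vapply(pairs, is.null, logical(1))]
    if (length(pairs) > 0L) donors <- do.call(rbind, pairs)
  }
  list(donors = donors, acceptors = polar)
}

#' Detect hydrogen bonds between two selections of one conformation
#'
#' Reports every (donor-in-A, acceptor-in-B) and (donor-in-B,
#' acceptor-in-A) triple satisfying the geometric criteria, one record per
#' unique (donor, hydrogen, acceptor) triple. Structures lacking hydrogens
#' raise a `no_hydrogens` error unless `heavy_atom_mode = TRUE`, which
#' applies the distance criterion only and marks the output accordingly —
#' crystal structures carry no protons, and silent misuse must be
#' impossible.
#'
#' @param frame a [structure_frame()].
#' @param selectionA,selectionB disjoint atom index vectors.
#' @param criteria an [hbond_criteria()].
#' @param heavy_atom_mode apply the distance criterion only (no hydrogens
#'   required); the result carries attribute `heavy_atom_mode = TRUE` and
#'   `hydrogen` is `NA`.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `da_distance_A`, `hda_angle_deg`.
#' @export
detect_hbonds <- function(frame, selectionA, selectionB,
                          criteria = hbond_criteria(),
                          heavy_atom_mode = FALSE) {
  stopifnot(inherits(frame, "structure_frame"))
  if (length(intersect(selectionA, selectionB)) > 0L)
    hs_stop("selection_overlap", "selections A and B overlap")
  if (!heavy_atom_mode && !any(frame$atoms$element == "H"))
    hs_stop("no_hydrogens",
            "structure carries no hydrogens; add protons or enable heavy_atom_mode")

  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), da_distance_A = numeric(0),
                      hda_angle_deg = numeric(0))
  one_direction <- function(sd, sa) {
    da <- find_donors_acceptors(frame, sd)
    ac <- find_donors_acceptors(frame, sa)$acceptors
    if (heavy_atom_mode) {
      dn <- unique(sd[frame$atoms$element[sd] %in% c("N", "O")])
      if (length(dn) == 0L || length(ac) == 0L) return(empty)
      grid <- expand.grid(donor = dn, acceptor = ac)
      grid$hydrogen <- NA_integer_
    } else {
      if (nrow(da$donors) == 0L || length(ac) == 0L) return(empty)
      grid <- merge(da$donors, data.frame(acceptor = ac))
    }
    d <- frame$coords[grid$donor, , drop = FALSE]
    a <- frame$coords[grid$acceptor, , drop = FALSE]
    v_da <- a - d
    dist <- sqrt(rowSums(v_da^2))
    keep <- dist <= criteria$max_da_distance & grid$donor != grid$acceptor
    if (!heavy_atom_mode) {
      h <- frame$coords[grid$hydrogen, , drop = FALSE]
      v_dh <- h - d
      cosang <- rowSums(v_dh * v_da) /
        (sqrt(rowSums(v_dh^2)) * pmax(dist, 1e-12))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      keep <- keep & ang <= criteria$max_hda_angle
    } else ang <- rep(NA_real_, nrow(grid))
    out <- data.frame(donor = grid$donor[keep],
                      hydrogen = grid$hydrogen[keep],
                      acceptor = grid$acceptor[keep],
                      da_distance_A = dist[keep],
                      hda_angle_deg = ang[keep])
    out
  }
  res <- rbind(one_direction(selectionA, selectionB),
               one_direction(selectionB, selectionA))
  res <- unique(res)
  if (heavy_atom_mode && nrow(res) > 0L) {
    # without hydrogens donor/acceptor roles are indistinguishable: report
    # each heavy-atom pair once
    res <- res[!duplicated(paste(pmin(res$donor, res$acceptor),
                                 pmax(res$donor, res$acceptor))), ,
               drop = FALSE]
  }
  res <- res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "heavy_atom_mode") <- heavy_atom_mode
  res
}

#' Per-frame hydrogen-bond counts over a trajectory
#'
#' Counts the detected bonds in every frame and summarises as mean and
#' standard deviation over frames. The sd uses the population convention
#' (denominator T, not T-1); both are recomputable from `counts`.
#'
#' @inheritParams detect_hbonds
#' @param traj a [trajectory()].
#' @return an `hbond_series`: list with `counts` (integer per frame),
#'   `times`, `mean`, `sd`.
#' @export
hbond_count_series <- function(traj, selectionA, selectionB,
                               criteria = hbond_criteria(),
                               heavy_atom_mode = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  nt <- n_frames(traj)
  counts <- vapply(seq_len(nt), function(m) {
    nrow(detect_hbonds(get_frame(traj, m), selectionA, selectionB,
                       criteria, heavy_atom_mode))
  }, numeric(1))
  structure(list(counts = as.integer(counts), times = traj$times,
                 mean = mean(counts),
                 sd = sqrt(mean((counts - mean(counts))^2)),
                 heavy_atom_mode = heavy_atom_mode),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("<hbond_series> %d frames, %.2f +/- %.2f bonds%s\n",
              length(x$counts), x$mean, x$sd,
              if (isTRUE(x$heavy_atom_mode)) " [heavy-atom mode]" else ""))
  invisible(x)
}
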