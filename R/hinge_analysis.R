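#' Conformational-state thresholds on the lip-center distance
#'
#' The mouth of the enzyme is called closed when the distance between the
#' two lip Calpha centers is shorter than `closed_max`, open when it is
#' longer than `open_min`, and semi-open in between. The defaults (15 and
#' 20 Angstrom) are the published ACE definitions.
#'
#' @param closed_max upper bound of the closed state, Angstrom.
#' @param open_min lower bound of the open state, Angstrom.
#' @return a `state_thresholds` list.
#' @export
state_thresholds <- function(closed_max = 15, open_min = 20) {
  if (!(closed_max > 0 && open_min > closed_max))
    hs_stop("invalid_thresholds", "need 0 < closed_max < open_min")
  structure(list(closed_max = closed_max, open_min = open_min),
            class = "state_thresholds")
}

#' The three conformational states
#' @return character vector `c("closed", "semi_open", "open")` in order of
#'   increasing lip distance.
#' @export
conformational_states <- function() c("closed", "semi_open", "open")

#' Lip-center distance of one conformation
#'
#' Euclidean distance between the centers of geometry of the lip I and
#' lip II Calpha atoms — the mouth-opening coordinate of the hinge-bending
#' motion.
#'
#' @param frame a [structure_frame()].
#' @param regions a [region_set()].
#' @return distance in Angstrom.
#' @export
lip_distance <- function(frame, regions) {
  stopifnot(inherits(frame, "structure_frame"), inherits(regions, "region_set"))
  i1 <- select_ca(frame, regions$lip1, regions$chain_id)
  i2 <- select_ca(frame, regions$lip2, regions$chain_id)
  c1 <- center_of_geometry(frame$coords[i1, , drop = FALSE])
  c2 <- center_of_geometry(frame$coords[i2, , drop = FALSE])
  sqrt(sum((c1 - c2)^2))
}

#' Classify a lip distance into closed / semi-open / open
#'
#' Open and closed are defined by strict inequalities (distance strictly
#' above `open_min`, strictly below `closed_max`); distances exactly at a
#' threshold fall to semi-open.
#'
#' @param distance lip-center distance(s), Angstrom (vectorised).
#' @param thresholds a [state_thresholds()].
#' @return character vector of states.
#' @export
classify_state <- function(distance, thresholds = state_thresholds()) {
  if (any(distance < 0) || any(!is.finite(distance)))
    hs_stop("domain_error", "distances must be finite and non-negative")
  ifelse(distance < thresholds$closed_max, "closed",
         ifelse(distance > thresholds$open_min, "open", "semi_open"))
}

#' Hinge-bending angle between two conformations
#'
#' Measures the rigid rotation of subdomain I relative to subdomain II:
#' (1) the frame is superposed onto the reference by [kabsch()] on the
#' Calpha atoms of subdomain II common to both structures (the fixed
#' anchor); (2) the aligned frame's subdomain I Calpha set is Kabsch-fitted
#' onto the reference subdomain I; (3) the [rotation_angle()] of that
#' second fit is returned. When the structures share only a subset of the
#' region residues (crystal gaps), the intersection is used for both fits.
#'
#' @param frame,reference [structure_frame()] objects. For structure-pair
#'   comparisons the closed structure is conventionally the reference.
#' @param regions a [region_set()].
#' @return hinge-bending angle in degrees, `[0, 180]`.
#' @export
hinge_angle <- function(frame, reference, regions) {
  stopifnot(inherits(frame, "structure_frame"),
            inherits(reference, "structure_frame"),
            inherits(regions, "region_set"))
  sel <- hinge_selections(frame$atoms, reference$atoms, regions)
  hinge_angle_core(frame$coords, reference$coords, sel)
}

# Resolve the subdomain Calpha selections common to two topologies once;
# returns paired index vectors for both fits.
hinge_selections <- function(atoms_f, atoms_r, regions) {
  pick_common <- function(region) {
    i_f <- suppressWarnings(select_ca(atoms_f, region, regions$chain_id))
    i_r <- suppressWarnings(select_ca(atoms_r, region, regions$chain_id))
    key_f <- paste(atoms_f$residue_number[i_f], atoms_f$insertion_code[i_f])
    key_r <- paste(atoms_r$residue_number[i_r], atoms_r$insertion_code[i_r])
    common <- intersect(key_f, key_r)
    if (length(common) < 3L)
      hs_stop("underdetermined",
              "fewer than 3 common residues between frame and reference in region")
    list(f = i_f[match(common, key_f)], r = i_r[match(common, key_r)])
  }
  list(s2 = pick_common(regions$subdomain2),
       s1 = pick_common(regions$subdomain1))
}

# Two-stage superposition on pre-resolved selections.
hinge_angle_core <- function(coords_f, coords_r, sel) {
  tf2 <- kabsch(coords_f[sel$s2$f, , drop = FALSE],
                coords_r[sel$s2$r, , drop = FALSE])
  aligned_s1 <- apply_transform(coords_f[sel$s1$f, , drop = FALSE], tf2)
  tf1 <- kabsch(aligned_s1, coords_r[sel$s1$r, , drop = FALSE])
  rotation_angle(tf1$rotation)
}

#' Count conversions between the closed and open states
#'
#' A conversion is counted each time the sequence reaches `open` after most
#' recently having been `closed`, or reaches `closed` after most recently
#' having been `open`. Semi-open frames are transparent: they neither count
#' nor reset the most recent endpoint, so a closed -> semi-open -> closed
#' excursion is not a conversion but closed -> semi-open -> open is.
#'
#' @param states character vector over `c("closed","semi_open","open")`.
#' @return integer conversion count.
#' @export
count_conversions <- function(states) {
  if (length(states) == 0L)
    hs_stop("invalid_input", "empty state sequence")
  bad <- setdiff(unique(states), conformational_states())
  if (length(bad) > 0L)
    hs_stop("invalid_input", "unknown states: %s", paste(bad, collapse = ","))
  endpoints <- states[states != "semi_open"]
  if (length(endpoints) < 2L) return(0L)
  sum(endpoints[-1] != endpoints[-length(endpoints)])
}

#' Full hinge analysis of a trajectory
#'
#' Computes, per frame: the lip-center distance, its conformational state,
#' and the hinge-bending angle against a reference conformation; then the
#' state occupancies and the number of closed <-> open conversions.
#'
#' @param traj a [trajectory()] whose topology contains the region residues.
#' @param regions a [region_set()].
#' @param thresholds a [state_thresholds()].
#' @param reference a [structure_frame()] for the hinge angle, or a frame
#'   index into `traj` (default 1: the first production frame).
#' @param angles compute per-frame hinge angles (set `FALSE` to skip the
#'   superpositions when only distances/states are needed).
#' @return a `hinge_result`: list with `table` (data.frame: `time_ns`,
#'   `distance_A`, `state`, `angle_deg`), `occupancy` (named fractions
#'   summing to 1), `n_conversions`, `thresholds`.
#' @export
analyze_trajectory <- function(traj, regions, thresholds = state_thresholds(),
                               reference = 1L, angles = TRUE) {
  stopifnot(inherits(traj, "trajectory"), inherits(regions, "region_set"))
  ref_frame <- if (inherits(reference, "structure_frame")) reference
               else get_frame(traj, as.integer(reference))
  i1 <- select_ca(traj, regions$lip1, regions$chain_id)
  i2 <- select_ca(traj, regions$lip2, regions$chain_id)
  nt <- n_frames(traj)
  dist <- vapply(seq_len(nt), function(m) {
    fr <- traj$frames[m, , , drop = TRUE]
    c1 <- colMeans(fr[i1, , drop = FALSE])
    c2 <- colMeans(fr[i2, , drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }, numeric(1))
  state <- classify_state(dist, thresholds)
  ang <- if (isTRUE(angles)) {
    sel <- hinge_selections(traj$topology, ref_frame$atoms, regions)
    vapply(seq_len(nt), function(m)
      hinge_angle_core(traj$frames[m, , , drop = TRUE], ref_frame$coords, sel),
      numeric(1))
  } else rep(NA_real_, nt)
  occ <- vapply(conformational_states(),
                function(s) mean(state == s), numeric(1))
  out <- list(
    table = data.frame(time_ns = traj$times, distance_A = dist,
                       state = state, angle_deg = ang),
    occupancy = occ,
    n_conversions = count_conversions(state),
    thresholds = thresholds)
  class(out) <- "hinge_result"
  out
}

#' @export
print.hinge_result <- function(x, ...) {
  cat(sprintf(
    "<hinge_result> %d frames | distance %.2f-%.2f A | occupancy closed %.3f / semi %.3f / open %.3f | %d conversions\n",
    nrow(x$table), min(x$table$distance_A), max(x$table$distance_A),
    x$occupancy[["closed"]], x$occupancy[["semi_open"]],
    x$occupancy[["open"]], x$n_conversions))
  invisible(x)
}
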