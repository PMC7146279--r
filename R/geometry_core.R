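#' Center of geometry of a point set
#'
#' Unweighted arithmetic mean of the coordinate rows — the "center" operator
#' behind the lip-center distance.
#'
#' @param coords numeric M x 3 matrix, Angstrom.
#' @return numeric length-3 vector.
#' @export
center_of_geometry <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L)
    hs_stop("empty_selection", "center_of_geometry of an empty point set")
  colMeans(coords)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rigid motion (rotation + translation, no reflection)
#' minimising the root-mean-square deviation of `mobile` onto `reference`,
#' via singular-value decomposition of the cross-covariance with a sign
#' correction on the smallest singular vector to enforce determinant +1.
#' Point sets are paired index-for-index; fits are unweighted.
#'
#' @param mobile,reference numeric M x 3 matrices (M >= 3), paired rows.
#' @return a `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), and `rmsd` (fitted RMSD, Angstrom). The
#'   transform maps mobile points x to `rotation %*% x + translation`.
#' @examples
#' set.seed(1)
#' ref <- matrix(rnorm(30), ncol = 3)
#' tf <- kabsch(ref, ref)
#' tf$rmsd  # 0
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    hs_stop("pairing_error", "point sets differ in size (%d vs %d)",
            nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3L)
    hs_stop("underdetermined", "rigid superposition needs at least 3 points")
  pc <- colMeans(mobile); qc <- colMeans(reference)
  P <- sweep(mobile, 2, pc); Q <- sweep(reference, 2, qc)
  H <- crossprod(P, Q)                      # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    hs_warn("degenerate_points", "near-collinear point set; rotation poorly determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(qc - R %*% pc)
  fitted <- P %*% t(R) - Q
  out <- list(rotation = R, translation = tr,
              rmsd = sqrt(mean(rowSums(fitted^2))))
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg, |t| = %.3f A, fitted RMSD %.4g A\n",
              rotation_angle(x$rotation), sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords numeric N x 3 matrix.
#' @param transform a `rigid_transform` from [kabsch()] (or a list with
#'   `rotation` and `translation`).
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

#' Root-mean-square deviation between paired point sets (no fitting)
#' @param coordsA,coordsB numeric M x 3 matrices, paired rows.
#' @return RMSD in Angstrom.
#' @export
paired_rmsd <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB))
    hs_stop("pairing_error", "point sets differ in size (%d vs %d)",
            nrow(coordsA), nrow(coordsB))
  if (nrow(coordsA) == 0L) hs_stop("empty_selection", "empty point sets")
  sqrt(mean(rowSums((coordsA - coordsB)^2)))
}

#' Rotation angle of a 3 x 3 rotation matrix
#'
#' The scalar magnitude of a rotation: `acos((trace - 1) / 2)` with the
#' argument clamped to `[-1, 1]`, in degrees in `[0, 180]`. This is the
#' quantity reported as the hinge-bending angle.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1
#'   (validated to 1e-6).
#' @return angle in degrees.
#' @export
rotation_angle <- function(rotation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    hs_stop("invalid_rotation", "input is not a proper rotation matrix (tol 1e-6)")
  arg <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#' @param axis length-3 vector (normalised internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Per-frame Calpha RMSD against a reference conformation
#'
#' Each frame is superposed onto the reference by [kabsch()] on
#' `fit_selection`, then the RMSD over `analysis_selection` is computed
#' without further fitting. With both selections equal to all Calpha atoms
#' this reproduces the conventional "Calpha RMSD vs the initial structure"
#' trajectory statistic.
#'
#' @param traj a [trajectory()].
#' @param reference a [structure_frame()] or a frame index into `traj`
#'   (default 1, the first frame).
#' @param analysis_selection,fit_selection atom index vectors (e.g. from
#'   [select_ca()]); `fit_selection` defaults to `analysis_selection`.
#' @return data.frame with columns `time_ns`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, reference = 1L, analysis_selection,
                        fit_selection = analysis_selection) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(analysis_selection) == 0L || length(fit_selection) == 0L)
    hs_stop("empty_selection", "empty atom selection")
  ref_coords <- if (inherits(reference, "structure_frame")) reference$coords
                else traj$frames[as.integer(reference), , , drop = TRUE]
  nt <- n_frames(traj)
  vals <- vapply(seq_len(nt), function(m) {
    fr <- traj$frames[m, , , drop = TRUE]
    tf <- kabsch(fr[fit_selection, , drop = FALSE],
                 ref_coords[fit_selection, , drop = FALSE])
    paired_rmsd(apply_transform(fr[analysis_selection, , drop = FALSE], tf),
                ref_coords[analysis_selection, , drop = FALSE])
  }, numeric(1))
  data.frame(time_ns = traj$times, rmsd_A = vals)
}

#' Per-residue Calpha root-mean-square fluctuation
#'
#' Two-pass mean-structure convention: every frame is first aligned (on
#' `alignment_selection`) to the first frame, the time-average structure is
#' computed, then every frame is re-aligned to that mean and
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` is taken over the atoms of
#' `analysis_selection`. Fits are unweighted.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param analysis_selection atom indices whose fluctuation is reported
#'   (typically one Calpha per residue).
#' @param alignment_selection atom indices used for the rigid alignment;
#'   defaults to `analysis_selection`.
#' @return a `fluctuation_profile`: data.frame with columns
#'   `residue_number`, `rmsf_A`.
#' @export
rmsf_profile <- function(traj, analysis_selection,
                         alignment_selection = analysis_selection) {
  stopifnot(inherits(traj, "trajectory"))
  nt <- n_frames(traj)
  if (nt < 2L)
    hs_stop("insufficient_frames", "RMSF needs at least 2 frames, got %d", nt)
  if (length(analysis_selection) == 0L || length(alignment_selection) == 0L)
    hs_stop("empty_selection", "empty atom selection")
  sel <- analysis_selection; ali <- alignment_selection
  align_to <- function(ref_ali_coords) {
    # returns T x |sel| x 3 array of aligned analysis coordinates
    out <- array(0, dim = c(nt, length(sel), 3L))
    for (m in seq_len(nt)) {
      fr <- traj$frames[m, , , drop = TRUE]
      tf <- kabsch(fr[ali, , drop = FALSE], ref_ali_coords)
      out[m, , ] <- apply_transform(fr[sel, , drop = FALSE], tf)
    }
    out
  }
  # pass 1: align to frame 1, form the mean structure over the union of
  # selections actually needed (analysis + alignment atoms)
  both <- sort(unique(c(sel, ali)))
  ref1 <- traj$frames[1, , , drop = TRUE][ali, , drop = FALSE]
  mean_both <- matrix(0, length(both), 3L)
  for (m in seq_len(nt)) {
    fr <- traj$frames[m, , , drop = TRUE]
    tf <- kabsch(fr[ali, , drop = FALSE], ref1)
    mean_both <- mean_both + apply_transform(fr[both, , drop = FALSE], tf)
  }
  mean_both <- mean_both / nt
  # pass 2: re-align every frame to the mean on the alignment atoms
  aligned <- align_to(mean_both[match(ali, both), , drop = FALSE])
  mean_sel <- apply(aligned, c(2, 3), mean)
  disp2 <- (aligned - aperm(array(mean_sel, c(length(sel), 3L, nt)),
                            c(3, 1, 2)))^2
  rmsf <- sqrt(vapply(seq_along(sel), function(i) 3 * mean(disp2[, i, ]),
                      numeric(1)))
  res <- traj$topology$residue_number[sel]
  out <- data.frame(residue_number = res, rmsf_A = rmsf)
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}
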