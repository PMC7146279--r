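#' Parameters for the synthetic two-domain hinge system
#'
#' Describes a Calpha-only toy enzyme made of two compact rigid domains
#' facing each other across a cleft, with domain I rotating about a hinge
#' axis relative to a fixed domain II following a prescribed angle
#' schedule, plus additive Gaussian coordinate noise. The geometry is sized
#' so that the mouth is closed (lip distance < 15 Angstrom) at 0 degrees
#' and opens past 20 Angstrom at a computable angle `theta_open` reported
#' by [build_toy_enzyme()].
#'
#' @param n_res_domain1,n_res_domain2 residue counts per domain (>= 10).
#' @param lip_fraction fraction of each domain's residues designated as the
#'   lip (the patch facing the other domain), in (0, 1].
#' @param hinge_axis length-3 axis vector (normalised internally; must be
#'   non-zero). With the default geometry, positive schedule angles about
#'   the default axis open the mouth.
#' @param hinge_point point the hinge axis passes through, Angstrom.
#' @param angle_schedule one of
#'   `list(type = "constant", theta = <deg>)`,
#'   `list(type = "sinusoid", amplitude = <deg>, period = <ns>)` (the angle
#'   sweeps 0 -> amplitude -> 0 each period), or
#'   `list(type = "random_walk", step_sd = <deg>, bounds = c(lo, hi))`
#'   (reflecting bounds, default `c(0, 1.5 * theta_open)`).
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom, applied
#'   after rotation to all atoms of both domains.
#' @param n_frames number of frames (>= 1).
#' @param timestep frame spacing, ns.
#' @param seed integer seed; all stochastic paths flow from it.
#' @return a `synthetic_hinge_params` list.
#' @export
synthetic_hinge_params <- function(n_res_domain1 = 100, n_res_domain2 = 100,
                                   lip_fraction = 0.2,
                                   hinge_axis = c(0, -1, 0),
                                   hinge_point = c(0, 0, 0),
                                   angle_schedule = list(type = "constant",
                                                         theta = 0),
                                   noise_sd = 0, n_frames = 1,
                                   timestep = 0.1, seed = 1L) {
  if (n_res_domain1 < 10L || n_res_domain2 < 10L)
    hs_stop("parameterization", "each domain needs at least 10 residues")
  if (!(lip_fraction > 0 && lip_fraction <= 1))
    hs_stop("parameterization", "lip_fraction must be in (0, 1]")
  nrm <- sqrt(sum(hinge_axis^2))
  if (nrm < 1e-12) hs_stop("parameterization", "hinge_axis must be non-zero")
  if (noise_sd < 0) hs_stop("parameterization", "noise_sd must be >= 0")
  if (n_frames < 1L) hs_stop("parameterization", "n_frames must be >= 1")
  if (timestep <= 0) hs_stop("parameterization", "timestep must be positive")
  if (is.null(angle_schedule$type) ||
      !angle_schedule$type %in% c("constant", "sinusoid", "random_walk"))
    hs_stop("parameterization", "unknown angle_schedule type")
  structure(list(n_res_domain1 = as.integer(n_res_domain1),
                 n_res_domain2 = as.integer(n_res_domain2),
                 lip_fraction = lip_fraction,
                 hinge_axis = hinge_axis / nrm,
                 hinge_point = as.numeric(hinge_point),
                 angle_schedule = angle_schedule,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 timestep = timestep, seed = as.integer(seed)),
            class = "synthetic_hinge_params")
}

# Compact Calpha lattice: n points on a near-cubic grid, 3.8 A spacing,
# centred at the origin, ordered z-layer by z-layer.
ca_lattice <- function(n, spacing = 3.8) {
  nz <- max(1L, floor(n^(1 / 3)))
  ny <- max(1L, floor(sqrt(n / nz)))
  nx <- ceiling(n / (nz * ny))
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  g <- g[order(g$z, g$y, g$x), ][seq_len(n), ]
  xyz <- as.matrix(g) * spacing
  sweep(xyz, 2, colMeans(xyz))
}

# Internal mouth geometry constants: the mouth centre sits mouth_reach
# Angstrom from the hinge point along +x, and the two inner faces are
# mouth_gap apart at 0 degrees, giving a closed-state lip distance and a
# theta_open in the 10-25 degree range typical of enzyme hinge motions.
.hs_mouth_reach <- 25
.hs_mouth_gap <- 12

#' Build the synthetic two-domain toy enzyme
#'
#' Constructs the Calpha-only structure at hinge angle 0 (closed), selects
#' the lips as the mutually closest `lip_fraction` of each domain's
#' residues, and reports the opening angle `theta_open` at which the
#' lip-center distance reaches 20 Angstrom (computed in closed form from
#' the Rodrigues rotation of the lip-I center about the hinge axis).
#'
#' @param params a [synthetic_hinge_params()].
#' @param open_min mouth-open threshold defining `theta_open`, Angstrom.
#' @return list with `frame` ([structure_frame()]), `regions`
#'   ([region_set()]; domain I is subdomain 1, residues `1..n1`),
#'   `domain1_atoms` (indices of the mobile domain), `theta_open` (deg),
#'   `lip_distance_closed` (Angstrom), `hinge_axis`, `hinge_point`, and
#'   `lip_distance_at` (function of theta in degrees, closed form).
#' @export
build_toy_enzyme <- function(params = synthetic_hinge_params(),
                             open_min = 20) {
  stopifnot(inherits(params, "synthetic_hinge_params"))
  n1 <- params$n_res_domain1; n2 <- params$n_res_domain2
  lat1 <- ca_lattice(n1); lat2 <- ca_lattice(n2)
  # domain I above the cleft (+z), domain II below; inner faces mouth_gap apart
  shift1 <- c(.hs_mouth_reach, 0, .hs_mouth_gap / 2 - min(lat1[, 3]))
  shift2 <- c(.hs_mouth_reach, 0, -.hs_mouth_gap / 2 - max(lat2[, 3]))
  d1 <- sweep(lat1, 2, -shift1)
  d2 <- sweep(lat2, 2, -shift2)
  coords <- rbind(d1, d2)
  n <- n1 + n2
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA", element = "C",
                      residue_name = "ALA", residue_number = seq_len(n),
                      insertion_code = "", chain_id = "A", altloc = "",
                      occupancy = 1, is_hetatm = FALSE,
                      stringsAsFactors = FALSE)
  frame <- structure_frame(atoms, coords)

  k1 <- max(1L, round(params$lip_fraction * n1))
  k2 <- max(1L, round(params$lip_fraction * n2))
  cen1 <- colMeans(d1); cen2 <- colMeans(d2)
  lip1_res <- order(rowSums(sweep(d1, 2, cen2)^2))[seq_len(k1)]
  lip2_res <- n1 + order(rowSums(sweep(d2, 2, cen1)^2))[seq_len(k2)]
  regions <- region_set("A",
                        lip1 = residues_to_ranges(lip1_res),
                        lip2 = residues_to_ranges(lip2_res),
                        subdomain1 = list(c(1L, n1)),
                        subdomain2 = list(c(n1 + 1L, n)))

  # closed-form lip-center distance as a function of the hinge angle:
  # rotating all domain-I atoms rotates their lip center exactly, so
  # d(theta)^2 = |w0|^2 + |v_perp|^2 + 2 cos(theta) w0.v_perp
  #            + 2 sin(theta) w0.(a x v),  v = c1 - hinge_point
  a <- params$hinge_axis; p <- params$hinge_point
  c1 <- colMeans(coords[lip1_res, , drop = FALSE])
  c2 <- colMeans(coords[lip2_res, , drop = FALSE])
  v <- c1 - p
  v_par <- sum(a * v) * a
  v_perp <- v - v_par
  axv <- c(a[2] * v[3] - a[3] * v[2], a[3] * v[1] - a[1] * v[3],
           a[1] * v[2] - a[2] * v[1])
  w0 <- p + v_par - c2
  dist_at <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sqrt(sum(w0^2) + sum(v_perp^2) +
           2 * cos(th) * sum(w0 * v_perp) + 2 * sin(th) * sum(w0 * axv))
  }
  d_closed <- dist_at(0)
  grid <- seq(0, 90, by = 0.5)
  dvals <- vapply(grid, dist_at, numeric(1))
  if (max(dvals) < open_min)
    hs_stop("parameterization",
            "infeasible geometry: lip distance cannot reach %.1f A for any theta <= 90 deg",
            open_min)
  i_cross <- which(dvals >= open_min)[1]
  theta_open <- if (i_cross == 1L) 0 else
    stats::uniroot(function(t) dist_at(t) - open_min,
                   lower = grid[i_cross - 1L], upper = grid[i_cross],
                   tol = 1e-12)$root
  list(frame = frame, regions = regions,
       domain1_atoms = seq_len(n1),
       theta_open = theta_open, lip_distance_closed = d_closed,
       hinge_axis = a, hinge_point = p, lip_distance_at = dist_at)
}

# Collapse a set of residue numbers into inclusive [start, end] runs.
residues_to_ranges <- function(res) {
  res <- sort(unique(as.integer(res)))
  breaks <- c(0L, which(diff(res) > 1L), length(res))
  lapply(seq_len(length(breaks) - 1L), function(i)
    c(res[breaks[i] + 1L], res[breaks[i + 1L]]))
}

#' Generate a synthetic hinge-bending trajectory with ground truth
#'
#' Frame t is the toy enzyme with domain I rotated by theta(t) about the
#' hinge axis through the hinge point, plus i.i.d. Gaussian coordinate
#' noise applied to all atoms of both domains (so alignment-based analyses
#' are stressed realistically). The ground truth records the programmed
#' angle, the noise-free lip distance (closed form), and the ideal state
#' under the supplied thresholds. Bit-reproducible from `params$seed`.
#'
#' @param params a [synthetic_hinge_params()].
#' @param thresholds [state_thresholds()] used for the ideal state labels.
#' @return list with `trajectory` ([trajectory()]), `ground_truth`
#'   (data.frame: `frame`, `time_ns`, `theta_deg`, `lip_distance_ideal_A`,
#'   `state_ideal`), and `toy` (the [build_toy_enzyme()] output).
#' @export
generate_hinge_trajectory <- function(params = synthetic_hinge_params(),
                                      thresholds = state_thresholds()) {
  stopifnot(inherits(params, "synthetic_hinge_params"))
  toy <- build_toy_enzyme(params, open_min = thresholds$open_min)
  nt <- params$n_frames
  times <- (seq_len(nt) - 1) * params$timestep
  set.seed(params$seed)
  theta <- schedule_angles(params$angle_schedule, times, toy$theta_open)
  base <- toy$frame$coords
  idx1 <- toy$domain1_atoms
  n <- nrow(base)
  frames <- array(0, dim = c(nt, n, 3L))
  p <- toy$hinge_point
  for (m in seq_len(nt)) {
    co <- base
    R <- rotation_about_axis(toy$hinge_axis, theta[m])
    co[idx1, ] <- sweep(sweep(base[idx1, , drop = FALSE], 2, p) %*% t(R), 2, -p)
    if (params$noise_sd > 0)
      co <- co + matrix(rnorm(3L * n, sd = params$noise_sd), n, 3L)
    frames[m, , ] <- co
  }
  traj <- trajectory(toy$frame$atoms, frames, times = times)
  d_ideal <- vapply(theta, toy$lip_distance_at, numeric(1))
  gt <- data.frame(frame = seq_len(nt), time_ns = times, theta_deg = theta,
                   lip_distance_ideal_A = d_ideal,
                   state_ideal = classify_state(d_ideal, thresholds))
  list(trajectory = traj, ground_truth = gt, toy = toy)
}

# Evaluate the angle schedule at the frame times (degrees per frame).
schedule_angles <- function(schedule, times, theta_open) {
  nt <- length(times)
  switch(schedule$type,
    constant = rep(schedule$theta, nt),
    sinusoid = {
      if (is.null(schedule$amplitude) || is.null(schedule$period))
        hs_stop("parameterization", "sinusoid schedule needs amplitude and period")
      schedule$amplitude / 2 * (1 - cos(2 * pi * times / schedule$period))
    },
    random_walk = {
      if (is.null(schedule$step_sd))
        hs_stop("parameterization", "random_walk schedule needs step_sd")
      bounds <- if (is.null(schedule$bounds)) c(0, 1.5 * theta_open)
                else schedule$bounds
      th <- numeric(nt)
      cur <- if (is.null(schedule$start)) bounds[1] else schedule$start
      for (i in seq_len(nt)) {
        cur <- reflect_into(cur + rnorm(1, sd = schedule$step_sd), bounds)
        th[i] <- cur
      }
      th
    })
}

reflect_into <- function(x, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate a hydrogen-bond test fixture with planted true bonds and decoys
#'
#' Builds a frame of isolated donor-hydrogen-acceptor triples on a sparse
#' grid (20 Angstrom pitch, so triples cannot interact): `n_true` triples
#' satisfy both geometric criteria with margin (>= 0.05 Angstrom on the
#' distance, >= 2 degrees on the angle) and `n_decoys` violate exactly one
#' criterion by at least the same margin, alternating which criterion.
#' Donors and hydrogens form selection A, acceptors selection B, so every
#' planted bond crosses the selections.
#'
#' @param n_true,n_decoys triple counts (>= 0).
#' @param criteria an [hbond_criteria()].
#' @param seed integer seed.
#' @return list with `frame`, `selectionA`, `selectionB`, and
#'   `ground_truth` (data.frame: `donor`, `hydrogen`, `acceptor`, `kind`
#'   in `true` / `decoy_distance` / `decoy_angle`).
#' @export
generate_hbond_fixture <- function(n_true, n_decoys,
                                   criteria = hbond_criteria(), seed = 1L) {
  if (n_true < 0 || n_decoys < 0)
    hs_stop("parameterization", "counts must be >= 0")
  set.seed(seed)
  ntot <- n_true + n_decoys
  kinds <- c(rep("true", n_true),
             rep(c("decoy_distance", "decoy_angle"), length.out = n_decoys))
  side <- ceiling(sqrt(max(ntot, 1L)))
  serial <- 0L
  rows <- list(); coords <- list(); gt <- list()
  selA <- integer(0); selB <- integer(0)
  rand_unit <- function() {
    v <- rnorm(3); v / sqrt(sum(v^2))
  }
  for (i in seq_len(ntot)) {
    b <- c(20 * ((i - 1) %% side), 20 * ((i - 1) %/% side), 0)
    u <- rand_unit()
    # unit vector orthogonal to u
    nperp <- rand_unit()
    nperp <- nperp - sum(nperp * u) * u
    nperp <- nperp / sqrt(sum(nperp^2))
    kind <- kinds[i]
    phi <- if (kind == "decoy_angle")
      runif(1, criteria$max_hda_angle + 2, min(criteria$max_hda_angle + 45, 170))
    else runif(1, 0, criteria$max_hda_angle - 2)
    r <- if (kind == "decoy_distance")
      runif(1, criteria$max_da_distance + 0.05, criteria$max_da_distance + 1.5)
    else runif(1, 2.6, criteria$max_da_distance - 0.05)
    w <- cos(phi * pi / 180) * u + sin(phi * pi / 180) * nperp
    xyz_d <- b
    xyz_h <- b + 1.0 * u
    xyz_a <- b + r * w
    idx <- serial + 1:3
    rows[[i]] <- data.frame(
      serial = idx, atom_name = c("N", "H", "O"),
      element = c("N", "H", "O"), residue_name = c("DON", "DON", "ACC"),
      residue_number = c(i, i, 1000L + i), insertion_code = "",
      chain_id = c("L", "L", "P"), altloc = "", occupancy = 1,
      is_hetatm = FALSE, stringsAsFactors = FALSE)
    coords[[i]] <- rbind(xyz_d, xyz_h, xyz_a)
    selA <- c(selA, idx[1:2]); selB <- c(selB, idx[3])
    gt[[i]] <- data.frame(donor = idx[1], hydrogen = idx[2],
                          acceptor = idx[3], kind = kind,
                          stringsAsFactors = FALSE)
    serial <- serial + 3L
  }
  if (ntot == 0L) {
    frame <- structure_frame(
      data.frame(serial = 1L, atom_name = "C", element = "C",
                 residue_name = "DUM", residue_number = 1L, chain_id = "X",
                 occupancy = 1), matrix(0, 1, 3))
    return(list(frame = frame, selectionA = integer(0),
                selectionB = integer(0),
                ground_truth = data.frame(donor = integer(0),
                                          hydrogen = integer(0),
                                          acceptor = integer(0),
                                          kind = character(0))))
  }
  frame <- structure_frame(do.call(rbind, rows), do.call(rbind, coords))
  list(frame = frame, selectionA = selA, selectionB = selB,
       ground_truth = do.call(rbind, gt))
}
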