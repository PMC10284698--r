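#' Rotor simulator configuration
#'
#' Coarse-grained lattice-rotor stand-in for an atomistic sterol multilayer:
#' each molecule is a unit orientation axis plus a head-height degree of
#' freedom on a fixed 2D lattice; only the water-facing interfacial layer is
#' mobile. The energy (in kT units) is
#' `E = -J sum_<ij> u_i.u_j - h sum_i u_iz + 1/2 z_stiffness sum_i dz_i^2`,
#' and Metropolis proposals that carry an axis across the equator pay an
#' extra `flip_barrier` (applied symmetrically, so the stationary
#' distribution is untouched; it only slows axis inversion, mimicking the
#' analogue-dependent reorientation kinetics).
#'
#' @param box_xy lateral box (nm), default 7.1554 x 7.1554.
#' @param n_layers number of stacked layers (default 4, two double layers).
#' @param per_layer molecules per layer (default 128).
#' @param lattice_spacing optional lattice spacing (nm); when supplied it is
#'   checked against the box, otherwise spacing is derived from the box.
#' @param coupling_J nearest-neighbor alignment energy (kT).
#' @param polarity_field_h interfacial polarity field favoring head-to-water
#'   orientation (kT).
#' @param flip_barrier extra barrier for equator-crossing proposals (kT);
#'   low for cholesterol-like, high for stigmasterol-like behavior.
#' @param z_stiffness harmonic restraint on head-height excursions
#'   (kT nm^-2).
#' @param reverted_fraction fraction of interfacial molecules initialized
#'   head-down, in `[0, 1]`.
#' @param sweeps,burn_in,sample_stride Monte Carlo schedule (one sweep = one
#'   proposal per mobile molecule); frames are recorded every
#'   `sample_stride` sweeps after `burn_in`.
#' @param ang_step,z_step proposal scales (rad, nm).
#' @param molecule_length rigid molecule length (nm) used for layer
#'   stacking and head positions.
#' @param type molecule type label.
#' @param seed RNG seed.
#' @return a `rotor_config` list.
#' @export
rotor_config <- function(box_xy = c(7.1554, 7.1554), n_layers = 4L,
                         per_layer = 128L, lattice_spacing = NULL,
                         coupling_J = 0.5, polarity_field_h = 0.1,
                         flip_barrier = 0, z_stiffness = 20,
                         reverted_fraction = 0, sweeps = 20000L,
                         burn_in = 2000L, sample_stride = 50L,
                         ang_step = 0.4, z_step = 0.08,
                         molecule_length = 1.7, type = "cholesterol",
                         seed = 1L) {
  if (reverted_fraction < 0 || reverted_fraction > 1)
    stop_se("'reverted_fraction' must be in [0,1]")
  if (flip_barrier < 0) stop_se("'flip_barrier' must be >= 0")
  if (z_stiffness <= 0) stop_se("'z_stiffness' must be > 0")
  if (per_layer < 2 || n_layers < 1) stop_se("invalid layer geometry")
  structure(list(box_xy = box_xy, n_layers = as.integer(n_layers),
                 per_layer = as.integer(per_layer),
                 lattice_spacing = lattice_spacing, coupling_J = coupling_J,
                 polarity_field_h = polarity_field_h,
                 flip_barrier = flip_barrier, z_stiffness = z_stiffness,
                 reverted_fraction = reverted_fraction,
                 sweeps = as.integer(sweeps), burn_in = as.integer(burn_in),
                 sample_stride = as.integer(sample_stride),
                 ang_step = ang_step, z_step = z_step,
                 molecule_length = molecule_length, type = type,
                 seed = as.integer(seed)),
            class = "rotor_config")
}

#' Preset rotor configurations for sterol analogues
#'
#' `"cholesterol"`: no extra flip barrier and a soft head-height restraint
#' (mobile, rough, spontaneously re-orienting interface).
#' `"stigmasterol"`: a high flip barrier and a stiff restraint (no
#' back-reorientation on the simulated timescale, smoother interface).
#' These constants were calibrated once against the qualitative interfacial
#' regime the two analogues show and then frozen.
#'
#' @param analogue `"cholesterol"` or `"stigmasterol"`.
#' @param ... overrides passed to [rotor_config()].
#' @return a `rotor_config`.
#' @export
rotor_preset <- function(analogue = c("cholesterol", "stigmasterol"), ...) {
  analogue <- match.arg(analogue)
  defaults <- switch(analogue,
    cholesterol = list(flip_barrier = 0, z_stiffness = 20,
                       type = "cholesterol"),
    stigmasterol = list(flip_barrier = 15, z_stiffness = 80,
                        type = "stigmasterol"))
  do.call(rotor_config, utils::modifyList(defaults, list(...)))
}

## factor per_layer into the most nearly square nx x ny grid (nx along x)
.lattice_dims <- function(per_layer, max_aspect = 2) {
  divs <- which(per_layer %% seq_len(per_layer) == 0)
  best <- NULL; best_aspect <- Inf
  for (ny in divs) {
    nx <- per_layer / ny
    aspect <- max(nx, ny) / min(nx, ny)
    if (aspect < best_aspect) { best <- c(nx, ny); best_aspect <- aspect }
  }
  if (best_aspect > max_aspect)
    stop_se("per_layer = ", per_layer, " is not expressible on a near-square ",
            "lattice (best aspect ratio ", format(best_aspect), ")")
  as.integer(best)
}

new_layer_trajectory <- function(molecules, axis, head_z, time, box, config,
                                 interface = NULL, mc_log = NULL) {
  nrm <- sqrt(axis[, , 1]^2 + axis[, , 2]^2 + axis[, , 3]^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop_se("axis vectors must be unit norm (max deviation ",
            format(max(abs(nrm - 1))), ")")
  structure(list(molecules = molecules, axis = axis, head_z = head_z,
                 time = time, box = box, config = config,
                 interface = interface, mc_log = mc_log),
            class = "layer_trajectory")
}

#' @export
print.layer_trajectory <- function(x, ...) {
  cat(sprintf("layer_trajectory: %d molecules x %d frames, box %.3f x %.3f x %.1f nm\n",
              nrow(x$molecules), dim(x$axis)[1], x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build a sterol multilayer start configuration
#'
#' Places `per_layer` molecules per layer on a near-square lattice inside
#' the lateral box and stacks `n_layers` layers along z as two double
#' layers: heads down at the substrate, head-to-head at the inner
#' double-layer interface, and heads up toward water at the top. A
#' `reverted_fraction` of interfacial (topmost-layer) molecules is
#' initialized head-down (rounded to the nearest molecule, e.g. 10% of 128
#' gives 13).
#'
#' @param config a [rotor_config()].
#' @return a single-frame `layer_trajectory`.
#' @export
build_multilayer <- function(config) {
  stopifnot(inherits(config, "rotor_config"))
  dims <- .lattice_dims(config$per_layer)
  nx <- dims[1]; ny <- dims[2]
  ax_sp <- config$box_xy[1] / nx
  ay_sp <- config$box_xy[2] / ny
  if (!is.null(config$lattice_spacing) &&
      (nx * config$lattice_spacing > config$box_xy[1] + 1e-9 ||
       ny * config$lattice_spacing > config$box_xy[2] + 1e-9))
    stop_se("lattice does not fit the box at the requested spacing")
  L <- config$molecule_length
  xy <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  n_tot <- config$n_layers * config$per_layer
  mol <- data.frame(
    molecule_id = seq_len(n_tot),
    layer = rep(seq_len(config$n_layers), each = config$per_layer),
    x = rep((xy$ix - 0.5) * ax_sp, config$n_layers),
    y = rep((xy$iy - 0.5) * ay_sp, config$n_layers),
    type = config$type, stringsAsFactors = FALSE)
  ## head direction per layer: down, up, down, up ... so that tails meet
  ## inside each double layer and heads meet between double layers
  head_dir <- rep(c(-1, 1), length.out = config$n_layers)[mol$layer]
  axis <- array(0, c(1, n_tot, 3))
  axis[1, , 3] <- head_dir
  z_center <- (mol$layer - 0.5) * L
  head_z <- matrix(z_center + head_dir * L / 2, 1)

  interface <- mol$molecule_id[mol$layer == config$n_layers]
  n_rev <- round(config$reverted_fraction * length(interface))
  if (n_rev > 0) {
    rev_ids <- with_seed(config$seed,
                         sample(interface, n_rev))
    axis[1, rev_ids, 3] <- -axis[1, rev_ids, 3]
    head_z[1, rev_ids] <- z_center[rev_ids] - head_dir[rev_ids] * L / 2
  }
  new_layer_trajectory(mol, axis, head_z, time = 0,
                       box = c(config$box_xy, 50), config = config,
                       interface = interface)
}

#' Metropolis dynamics of the interfacial rotor layer
#'
#' Runs single-axis Metropolis Monte Carlo on the topmost (water-facing)
#' layer of a multilayer start configuration: symmetric small-angle axis
#' rotations, axis inversions and head-height displacements, with
#' equator-crossing proposals paying the configured `flip_barrier`. Lower
#' layers are frozen (the substrate restraint). Frames are recorded every
#' `sample_stride` sweeps after `burn_in`; a subsample of proposal
#' energies, acceptance probabilities and decisions is logged for
#' detailed-balance checks.
#'
#' @param start single-frame trajectory from [build_multilayer()].
#' @param config a [rotor_config()] matching `start`'s geometry (defaults
#'   to the configuration stored in `start`).
#' @return a `layer_trajectory` with the recorded frames; acceptance
#'   statistics and the proposal log are in `$mc_log`.
#' @export
rotor_mc_simulate <- function(start, config = start$config) {
  stopifnot(inherits(start, "layer_trajectory"))
  if (dim(start$axis)[1] != 1) stop_se("'start' must have exactly one frame")
  if (config$sweeps < 1) stop_se("'sweeps' must be >= 1")
  if (config$sweeps <= config$burn_in + config$sample_stride)
    stop_se("sweeps too small for the requested burn_in and stride")
  if (nrow(start$molecules) != config$n_layers * config$per_layer)
    stop_se("'start' geometry does not match 'config'")
  iface <- start$interface
  if (is.null(iface) || !length(iface)) stop_se("no interfacial molecules")
  dims <- .lattice_dims(config$per_layer)
  n_int <- length(iface)
  ## lattice neighbor table (periodic, 4-neighbor) in the interface ordering
  idx <- matrix(seq_len(n_int), nrow = dims[1], ncol = dims[2])
  nbr <- matrix(0L, n_int, 4)
  for (iy in seq_len(dims[2])) for (ix in seq_len(dims[1])) {
    i <- idx[ix, iy]
    nbr[i, ] <- c(idx[if (ix == 1) dims[1] else ix - 1, iy],
                  idx[if (ix == dims[1]) 1 else ix + 1, iy],
                  idx[ix, if (iy == 1) dims[2] else iy - 1],
                  idx[ix, if (iy == dims[2]) 1 else iy + 1]) - 1L
  }
  u0 <- matrix(start$axis[1, iface, ], n_int, 3)
  base_z <- start$head_z[1, iface]
  res <- with_seed(config$seed,
    rotor_mc_kernel(u0, nbr, config$coupling_J, config$polarity_field_h,
                    config$flip_barrier, config$z_stiffness,
                    config$ang_step, config$z_step, config$sweeps,
                    config$burn_in, config$sample_stride))
  ## with no burn-in the run is a relaxation experiment (e.g. steered
  ## reverted starts): keep the constructed state as the first frame
  keep_start <- config$burn_in == 0
  res_axis <- res$axis; res_dz <- res$dz
  if (keep_start) {
    n0 <- dim(res$axis)[2]
    res_axis <- array(NA_real_, c(dim(res$axis)[1] + 1, n0, 3))
    res_axis[1, , ] <- matrix(start$axis[1, iface, ], n0, 3)
    res_axis[-1, , ] <- res$axis
    res_dz <- rbind(0, res$dz)
  }
  n_frames <- dim(res_axis)[1]
  n_tot <- nrow(start$molecules)
  axis <- array(rep(start$axis[1, , ], each = n_frames),
                c(n_frames, n_tot, 3))
  head_z <- matrix(rep(start$head_z[1, ], each = n_frames), n_frames, n_tot)
  axis[, iface, ] <- res_axis
  head_z[, iface] <- sweep(res_dz, 2, base_z, `+`)
  log_df <- as.data.frame(res$log)
  names(log_df) <- c("move_type", "delta_e", "accept_prob", "u_rand",
                     "accepted", "crossed")
  times <- config$burn_in + seq_len(dim(res$axis)[1]) * config$sample_stride
  if (keep_start) times <- c(0, times)
  new_layer_trajectory(start$molecules, axis, head_z,
                       time = times,
                       box = start$box, config = config, interface = iface,
                       mc_log = list(log = log_df,
                                     acceptance = res$acceptance))
}

#' Total rotor energy of the interfacial layer (kT)
#'
#' Reference implementation of the rotor Hamiltonian used by the Metropolis
#' kernel, for a single frame.
#'
#' @param traj a `layer_trajectory`.
#' @param frame frame index.
#' @return energy in kT.
#' @export
rotor_energy <- function(traj, frame = 1) {
  config <- if (inherits(traj$config, "rotor_config")) traj$config
  else do.call(rotor_config, traj$config)
  iface <- traj$interface
  dims <- .lattice_dims(config$per_layer)
  u <- matrix(traj$axis[frame, iface, ], length(iface), 3)
  idx <- matrix(seq_along(iface), dims[1], dims[2])
  e <- 0
  for (iy in seq_len(dims[2])) for (ix in seq_len(dims[1])) {
    i <- idx[ix, iy]
    jr <- idx[if (ix == dims[1]) 1 else ix + 1, iy]
    ju <- idx[ix, if (iy == dims[2]) 1 else iy + 1]
    e <- e - config$coupling_J * sum(u[i, ] * (u[jr, ] + u[ju, ]))
  }
  base <- build_multilayer(config)
  dz <- traj$head_z[frame, iface] - base$head_z[1, iface]
  e - config$polarity_field_h * sum(u[, 3]) +
    0.5 * config$z_stiffness * sum(dz^2)
}
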