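# Independent oracles and fixture builders used across the suite.

## RK4 integration of dsigma/dt = -k sigma^n, independent of the closed form
rk4_sigma <- function(times, k, sigma0, order) {
  f <- function(t, y, parms) list(-parms$k * y^parms$n)
  out <- deSolve::ode(y = sigma0, times = times, func = f,
                      parms = list(k = k, n = order), method = "rk4",
                      hini = min(diff(times), 0.01) / 10)
  unname(out[, 2])
}

## brute-force orientational correlation: explicit double loop over pairs
## and frames with minimum-image lateral distances
brute_force_cr <- function(traj, selection, bin_width, max_distance) {
  idx <- match(selection, traj$molecules$molecule_id)
  n <- length(idx)
  n_bins <- ceiling(max_distance / bin_width)
  n_frames <- dim(traj$axis)[1]
  sums <- rep(0, n_bins); cnt_pairs <- rep(0L, n_bins)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    dx <- traj$molecules$x[idx[a]] - traj$molecules$x[idx[b]]
    dy <- traj$molecules$y[idx[a]] - traj$molecules$y[idx[b]]
    dx <- dx - traj$box[1] * round(dx / traj$box[1])
    dy <- dy - traj$box[2] * round(dy / traj$box[2])
    d <- sqrt(dx^2 + dy^2)
    if (d > max_distance) next
    bin <- min(floor(d / bin_width) + 1, n_bins)
    cnt_pairs[bin] <- cnt_pairs[bin] + 1L
    for (f in seq_len(n_frames))
      sums[bin] <- sums[bin] + sum(traj$axis[f, idx[a], ] * traj$axis[f, idx[b], ])
  }
  vals <- ifelse(cnt_pairs > 0, sums / (cnt_pairs * n_frames), NA_real_)
  list(c_r = vals, n_pairs = cnt_pairs)
}

## modified Bessel function of the first kind by direct series summation
bessel_series <- function(x, nu, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)))
}

## hand-built toy trajectory: molecules on given xy positions with given
## per-frame axes (list of n x 3 matrices) and head-z matrix
make_toy_traj <- function(x, y, axes, head_z = NULL, box = c(10, 10, 50),
                          layer = NULL) {
  n <- length(x)
  n_frames <- length(axes)
  ax <- array(NA_real_, c(n_frames, n, 3))
  for (f in seq_len(n_frames)) ax[f, , ] <- axes[[f]]
  if (is.null(head_z)) head_z <- matrix(0, n_frames, n)
  sterolentropy:::new_layer_trajectory(
    molecules = data.frame(molecule_id = seq_len(n),
                           layer = layer %||% rep(1L, n),
                           x = x, y = y, type = "toy",
                           stringsAsFactors = FALSE),
    axis = ax, head_z = head_z, time = seq_len(n_frames),
    box = box, config = list(toy = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## axes from tilt angles (degrees) in the xz plane
axes_from_tilt <- function(deg) {
  th <- deg * pi / 180
  cbind(sin(th), 0, cos(th))
}
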