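#' Select the interfacial molecule set of a trajectory
#'
#' Molecules of the topmost layer index, or — for imported trajectories
#' without meaningful layer labels — molecules whose head z in the reference
#' frame exceeds `max(head z) - cutoff`. The selection is frozen at the
#' reference frame and reused for all frames.
#'
#' @param traj a `layer_trajectory`.
#' @param cutoff optional z cutoff (nm) below the maximal head height; when
#'   given, z-based selection is used instead of layer labels.
#' @param reference_frame frame used to freeze the selection.
#' @return integer vector of molecule ids.
#' @export
select_interface <- function(traj, cutoff = NULL, reference_frame = 1) {
  sel <- if (is.null(cutoff)) {
    traj$molecules$molecule_id[traj$molecules$layer ==
                                 max(traj$molecules$layer)]
  } else {
    z <- traj$head_z[reference_frame, ]
    traj$molecules$molecule_id[z >= max(z) - cutoff]
  }
  if (!length(sel)) stop_se("interface selection is empty")
  sel
}

#' Tilt angles of molecular axes against the interface normal
#'
#' `angle = arccos(u . z)` in degrees, in `[0, 180]`: 0 is head-up
#' (hydroxyl toward water), 180 is fully reverted. For atomistic imports
#' the axis is the tail-to-head ring vector (C17 to C3 direction), built by
#' [traj_from_gro()].
#'
#' @param traj a `layer_trajectory`.
#' @param selection molecule ids (default: interfacial set).
#' @return matrix frames x molecules of angles (degrees), with molecule ids
#'   as column names.
#' @export
tilt_angles <- function(traj, selection = select_interface(traj)) {
  uz <- traj$axis[, selection, 3, drop = FALSE]
  ang <- acos(pmin(1, pmax(-1, uz))) * 180 / pi
  out <- matrix(ang, dim(traj$axis)[1], length(selection))
  colnames(out) <- selection
  out
}

## signed minimum-image lateral distances between selected molecules
.pair_table <- function(traj, selection) {
  i <- match(selection, traj$molecules$molecule_id)
  x <- traj$molecules$x[i]; y <- traj$molecules$y[i]
  n <- length(i)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[pairs[, 1]] - x[pairs[, 2]]
  dy <- y[pairs[, 1]] - y[pairs[, 2]]
  bx <- traj$box[1]; by <- traj$box[2]
  dx <- dx - bx * round(dx / bx)
  dy <- dy - by * round(dy / by)
  data.frame(i = pairs[, 1], j = pairs[, 2], d = sqrt(dx^2 + dy^2))
}

#' Lateral orientational correlation function
#'
#' `C_r(d)`: mean over frames and over molecule pairs at minimum-image
#' lateral distance in bin `d` of the axis correlation — the plain dot
#' product `u_i . u_j` by default, or the second-Legendre form
#' `(3 (u_i.u_j)^2 - 1)/2`. Dispersion is the s.d. of per-time-window means
#' (the curve replotted over `windows` consecutive frame blocks). Empty
#' bins are kept with `n_pairs = 0` and `NA` value, never silently zero.
#'
#' @param traj a `layer_trajectory`.
#' @param selection molecule ids (default: interfacial set).
#' @param bin_width lateral distance bin width (nm).
#' @param max_distance largest pair distance analyzed (nm).
#' @param windows number of time windows for the dispersion estimate.
#' @param method `"dot"` (default) or `"p2"`.
#' @return a `correlation_curve` data frame: `bin_center, c_r, sd, n_pairs`.
#' @export
orientation_correlation <- function(traj, selection = select_interface(traj),
                                    bin_width = 0.1, max_distance = 3,
                                    windows = 10, method = c("dot", "p2")) {
  method <- match.arg(method)
  if (length(selection) < 2) stop_se("need at least 2 selected molecules")
  pt <- .pair_table(traj, selection)
  keep <- pt$d <= max_distance
  pt <- pt[keep, ]
  bin <- pmin(floor(pt$d / bin_width) + 1L, ceiling(max_distance / bin_width))
  n_bins <- ceiling(max_distance / bin_width)
  n_frames <- dim(traj$axis)[1]
  u <- traj$axis[, selection, , drop = FALSE]
  ## dot products for all pairs x frames: frames x pairs
  dots <- u[, pt$i, 1, drop = FALSE] * u[, pt$j, 1, drop = FALSE] +
    u[, pt$i, 2, drop = FALSE] * u[, pt$j, 2, drop = FALSE] +
    u[, pt$i, 3, drop = FALSE] * u[, pt$j, 3, drop = FALSE]
  dots <- matrix(dots, n_frames, nrow(pt))
  if (method == "p2") dots <- (3 * dots^2 - 1) / 2
  win <- if (n_frames >= windows)
    cut(seq_len(n_frames), windows, labels = FALSE) else rep(1L, n_frames)
  binf <- factor(bin, levels = seq_len(n_bins))
  cnt <- as.integer(table(binf))
  value <- rep(NA_real_, n_bins); disp <- rep(NA_real_, n_bins)
  per_win <- matrix(0, n_bins, n_frames)  # per-bin sums over pairs, by frame
  rs <- rowsum(t(dots), bin)
  per_win[as.integer(rownames(rs)), ] <- rs
  for (b in seq_len(n_bins)) {
    if (cnt[b] == 0) next
    frame_means <- per_win[b, ] / cnt[b]
    value[b] <- mean(frame_means)
    wm <- tapply(frame_means, win, mean)
    disp[b] <- if (length(wm) > 1) stats::sd(wm) else NA_real_
  }
  structure(data.frame(bin_center = (seq_len(n_bins) - 0.5) * bin_width,
                       c_r = value, sd = disp, n_pairs = cnt),
            class = c("correlation_curve", "data.frame"),
            method = method)
}

#' Correlation decay distance
#'
#' Smallest distance at which `C_r` falls below a threshold fraction
#' (default 1/e) of its value in the first populated bin, with linear
#' interpolation between the straddling bins. When the curve never drops
#' below the threshold within the analyzed range, `Inf` is returned with
#' attribute `censored = TRUE` (read "> max distance").
#'
#' @param curve a `correlation_curve`.
#' @param threshold_frac threshold as a fraction of the first populated
#'   bin's value (default `exp(-1)`).
#' @return decay distance (nm), or `Inf` (censored).
#' @export
decay_distance <- function(curve, threshold_frac = exp(-1)) {
  pop <- which(curve$n_pairs > 0 & !is.na(curve$c_r))
  if (!length(pop)) stop_se("no populated bins")
  thr <- curve$c_r[pop[1]] * threshold_frac
  x <- curve$bin_center[pop]; v <- curve$c_r[pop]
  below <- which(v < thr)
  if (!length(below)) return(structure(Inf, censored = TRUE,
                                       max_distance = max(x)))
  b <- below[1]
  if (b == 1) return(structure(x[1], censored = FALSE))
  x0 <- x[b - 1]; x1 <- x[b]; v0 <- v[b - 1]; v1 <- v[b]
  structure(x0 + (v0 - thr) / (v0 - v1) * (x1 - x0), censored = FALSE)
}

#' Interfacial head-height RMSD over time
#'
#' Per frame, the root-mean-square deviation over the selected molecules of
#' the head z relative to the reference frame (or to the per-molecule time
#' mean). With several trajectories, the mean curve and the s.e.m. across
#' trajectories are returned.
#'
#' @param trajs a `layer_trajectory` or list of them (matching selections).
#' @param selection molecule ids.
#' @param reference `"first"` (default) or `"mean"`.
#' @param stride analyze every `stride`-th frame.
#' @return data frame `time, rmsd, sem` (sem `NA` for a single trajectory).
#' @export
interface_z_rmsd <- function(trajs, selection = NULL,
                             reference = c("first", "mean"), stride = 1) {
  reference <- match.arg(reference)
  if (inherits(trajs, "layer_trajectory")) trajs <- list(trajs)
  if (is.null(selection)) selection <- select_interface(trajs[[1]])
  curves <- lapply(trajs, function(tr) {
    if (!all(selection %in% tr$molecules$molecule_id))
      stop_se("selection does not match trajectory molecules")
    z <- tr$head_z[, selection, drop = FALSE]
    if (nrow(z) < 2) stop_se("need at least 2 frames")
    idx <- seq(1, nrow(z), by = stride)
    z <- z[idx, , drop = FALSE]
    ref <- if (reference == "first") z[1, ] else colMeans(z)
    dev <- sweep(z, 2, ref)
    data.frame(time = tr$time[idx], rmsd = sqrt(rowMeans(dev^2)))
  })
  rmsd <- sapply(curves, `[[`, "rmsd")
  rmsd <- matrix(rmsd, ncol = length(curves))
  data.frame(time = curves[[1]]$time,
             rmsd = rowMeans(rmsd),
             sem = if (ncol(rmsd) > 1)
               apply(rmsd, 1, stats::sd) / sqrt(ncol(rmsd)) else NA_real_)
}

#' Detect orientational flip events with hysteresis
#'
#' A molecule is "reverted" once its tilt exceeds `reverted_threshold` and
#' "aligned" once it drops below `aligned_threshold`; the band between the
#' two is hysteresis, so angular noise around the equator never counts as
#' an event. A down-to-up event is recorded at the first frame an axis last
#' seen reverted crosses below the aligned threshold (and vice versa). The
#' recovered fraction is the share of initially reverted molecules with a
#' down-to-up event within the frame budget.
#'
#' @param traj a `layer_trajectory`.
#' @param selection molecule ids.
#' @param aligned_threshold,reverted_threshold hysteresis thresholds
#'   (degrees), aligned < reverted.
#' @param budget_frames frame budget for the recovered fraction (default:
#'   all frames).
#' @return a `flip_events` list: `events` (data frame `molecule_id, frame,
#'   direction`), `recovered_fraction`, `n_initially_reverted`,
#'   `mean_first_passage_frames`.
#' @export
detect_flips <- function(traj, selection = select_interface(traj),
                         aligned_threshold = 60, reverted_threshold = 120,
                         budget_frames = NULL) {
  if (aligned_threshold >= reverted_threshold)
    stop_se("'aligned_threshold' must be below 'reverted_threshold'")
  ang <- tilt_angles(traj, selection)
  n_frames <- nrow(ang)
  budget <- budget_frames %||% n_frames
  events <- list(); fp <- numeric(0)
  init_rev <- ang[1, ] >= reverted_threshold
  recovered <- logical(ncol(ang))
  for (m in seq_len(ncol(ang))) {
    state <- if (ang[1, m] >= reverted_threshold) "down"
    else if (ang[1, m] <= aligned_threshold) "up" else "band"
    for (f in seq_len(n_frames)[-1]) {
      a <- ang[f, m]
      new_state <- if (a >= reverted_threshold) "down"
      else if (a <= aligned_threshold) "up" else state
      if (new_state != state && new_state != "band" && state != "band") {
        dir <- if (new_state == "up") "down_to_up" else "up_to_down"
        events[[length(events) + 1]] <-
          data.frame(molecule_id = selection[m], frame = f, direction = dir,
                     stringsAsFactors = FALSE)
        if (init_rev[m] && dir == "down_to_up" && !recovered[m] &&
            f <= budget) {
          recovered[m] <- TRUE
          fp <- c(fp, f)
        }
      }
      state <- new_state
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
  else data.frame(molecule_id = integer(0), frame = integer(0),
                  direction = character(0), stringsAsFactors = FALSE)
  structure(list(events = ev,
                 recovered_fraction = if (any(init_rev))
                   mean(recovered[init_rev]) else NA_real_,
                 n_initially_reverted = sum(init_rev),
                 mean_first_passage_frames = if (length(fp)) mean(fp)
                 else NA_real_),
            class = "flip_events")
}

#' @export
print.flip_events <- function(x, ...) {
  cat(sprintf("flip events: %d events, %d initially reverted, recovered fraction %s\n",
              nrow(x$events), x$n_initially_reverted,
              format(x$recovered_fraction, digits = 3)))
  invisible(x)
}
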