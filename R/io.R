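#' Write a pipeline CSV with a commented metadata header
#'
#' All tabular artifacts of the pipeline are RFC-4180 CSV preceded by `#`
#' comment lines of `key: value` metadata (generator name, package version,
#' seed, parameters), so every file records how to reproduce it.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named list of scalar metadata; written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(df, path, meta = list()) {
  stopifnot(is.data.frame(df))
  meta <- c(list(package = "sterolentropy",
                 version = as.character(utils::packageVersion("sterolentropy"))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15),
                                            collapse = ",")), con)
  ## serialize doubles at 17 significant digits so reading back is lossless
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV written by [write_pipeline_csv()]
#'
#' @param path file path.
#' @return data frame; header metadata is attached as attribute `"meta"`
#'   (a named list of character values).
#' @export
read_pipeline_csv <- function(path) {
  if (!file.exists(path)) stop_se("input file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Serialize a layer trajectory to a tabular file plus JSON sidecar
#'
#' One long-format CSV row per molecule per frame
#' (`frame, molecule_id, layer, x, y, z_head, axis_x, axis_y, axis_z, type`)
#' and a `<path>.json` sidecar holding the box and rotor configuration.
#'
#' @param traj a `layer_trajectory` (see [build_multilayer()]).
#' @param path output CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "layer_trajectory"))
  n_frames <- dim(traj$axis)[1]
  nm <- nrow(traj$molecules)
  df <- data.frame(
    frame = rep(seq_len(n_frames), each = nm),
    molecule_id = rep(traj$molecules$molecule_id, n_frames),
    layer = rep(traj$molecules$layer, n_frames),
    x = rep(traj$molecules$x, n_frames),
    y = rep(traj$molecules$y, n_frames),
    z_head = as.vector(t(traj$head_z)),
    axis_x = as.vector(t(traj$axis[, , 1])),
    axis_y = as.vector(t(traj$axis[, , 2])),
    axis_z = as.vector(t(traj$axis[, , 3])),
    type = rep(traj$molecules$type, n_frames))
  write_pipeline_csv(df, path, meta = list(generator = "layer_trajectory",
                                           n_frames = n_frames,
                                           n_molecules = nm))
  side <- list(box = traj$box, time = traj$time,
               config = traj$config[!vapply(traj$config, is.null, TRUE)])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path CSV path (sidecar `<path>.json` must be present).
#' @return a `layer_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read_pipeline_csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- sort(unique(df$frame))
  one <- df[df$frame == frames[1], ]
  nm <- nrow(one)
  ax <- array(NA_real_, c(length(frames), nm, 3))
  hz <- matrix(NA_real_, length(frames), nm)
  for (i in seq_along(frames)) {
    fr <- df[df$frame == frames[i], ]
    fr <- fr[order(fr$molecule_id), ]
    ax[i, , 1] <- fr$axis_x; ax[i, , 2] <- fr$axis_y; ax[i, , 3] <- fr$axis_z
    hz[i, ] <- fr$z_head
  }
  one <- one[order(one$molecule_id), ]
  new_layer_trajectory(
    molecules = data.frame(molecule_id = one$molecule_id, layer = one$layer,
                           x = one$x, y = one$y, type = one$type,
                           stringsAsFactors = FALSE),
    axis = ax, head_z = hz,
    time = as.numeric(side$time),
    box = as.numeric(side$box),
    config = side$config)
}

#' Read a GRO-style coordinate file (single frame)
#'
#' Minimal fixed-width reader for Gromacs `.gro` coordinate frames
#' (residue id/name, atom name/number, x, y, z in nm). Velocities, if
#' present, are ignored.
#'
#' @param path file path.
#' @return list with `title`, `atoms` (data frame: `resid, resname, atom,
#'   atomnum, x, y, z`) and `box` (length-3 numeric, nm).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop_se("input file not found: ", path)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  atoms <- data.frame(
    resid = as.integer(substr(at, 1, 5)),
    resname = trimws(substr(at, 6, 10)),
    atom = trimws(substr(at, 11, 15)),
    atomnum = as.integer(substr(at, 16, 20)),
    x = as.numeric(substr(at, 21, 28)),
    y = as.numeric(substr(at, 29, 36)),
    z = as.numeric(substr(at, 37, 44)),
    stringsAsFactors = FALSE)
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(title = lines[1], atoms = atoms, box = box)
}

#' Write a GRO-style coordinate file (single frame)
#' @param atoms data frame as returned in `read_gro()$atoms`.
#' @param box length-3 numeric box (nm).
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, box, path, title = "sterolentropy frame") {
  lines <- c(title, format(nrow(atoms)))
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  atoms$resid, atoms$resname, atoms$atom,
                  atoms$atomnum, atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, body, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])),
             path)
  invisible(path)
}

#' Build a single-frame trajectory from GRO coordinates
#'
#' For sterol residues the molecular axis is the normalized C3 to C17 vector
#' (ring carbon near the hydroxyl head to the tail-end ring carbon) and the
#' head z is taken from the O3 hydroxyl oxygen (falling back to C3).
#' Molecules missing either named atom are rejected by residue id.
#'
#' @param gro result of [read_gro()].
#' @param head_atom,axis_from,axis_to atom names used for head z and axis.
#' @return a single-frame `layer_trajectory` with `layer = 1` for all
#'   molecules (use z-cutoff interface selection downstream).
#' @export
traj_from_gro <- function(gro, head_atom = "O3", axis_from = "C3",
                          axis_to = "C17") {
  at <- gro$atoms
  ids <- sort(unique(at$resid))
  take <- function(name) {
    m <- at[at$atom == name, ]
    m[match(ids, m$resid), c("x", "y", "z")]
  }
  a <- take(axis_from); b <- take(axis_to); h <- take(head_atom)
  bad <- ids[is.na(a$x) | is.na(b$x)]
  if (length(bad))
    stop_se("molecules missing axis atoms ", axis_from, "/", axis_to, ": ",
            paste(bad, collapse = ", "))
  v <- as.matrix(b - a)
  ## axis points from tail carbon toward the head end so that +z means
  ## hydroxyl-up, matching the rotor convention
  v <- -v
  v <- v / sqrt(rowSums(v^2))
  hz <- ifelse(is.na(h$z), a$z, h$z)
  new_layer_trajectory(
    molecules = data.frame(molecule_id = seq_along(ids), layer = 1L,
                           x = a$x, y = a$y,
                           type = at$resname[match(ids, at$resid)],
                           stringsAsFactors = FALSE),
    axis = array(v, c(1, length(ids), 3)),
    head_z = matrix(hz, 1),
    time = 0, box = gro$box, config = list(source = "gro"))
}
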