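# Trajectory and observable I/O: XYZ and VTF bead trajectories, tidy CSV
# observable tables, run manifests, checkpoints.

#' Write a bead trajectory in XYZ format
#'
#' One block per frame: atom count, a comment line with the time stamp,
#' then `C x y z` rows at full precision.
#'
#' @param frames N x 3 x nframes array of bead positions.
#' @param path output file.
#' @param times optional frame time stamps.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, times = NULL) {
  N <- dim(frames)[1]
  nf <- dim(frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(N), con)
    writeLines(sprintf("frame %d t= %s", f,
                       if (is.null(times)) "NA" else format(times[f], digits = 17)),
               con)
    writeLines(sprintf("C %s %s %s",
                       format(frames[, 1, f], digits = 17),
                       format(frames[, 2, f], digits = 17),
                       format(frames[, 3, f], digits = 17)), con)
  }
  invisible(path)
}

#' Read an XYZ bead trajectory
#'
#' @param path file written by [write_xyz()].
#' @return list with `frames` (N x 3 x nframes) and `times`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1
  frames <- list()
  times <- numeric(0)
  N0 <- NULL
  while (i <= length(lines)) {
    N <- suppressWarnings(as.integer(lines[i]))
    if (is.na(N)) stop("malformed XYZ: expected atom count at line ", i)
    if (is.null(N0)) N0 <- N
    if (N != N0) stop("malformed XYZ: frame with wrong atom count at line ", i)
    if (i + 1 + N > length(lines)) stop("truncated XYZ frame at line ", i)
    tm <- suppressWarnings(as.numeric(sub(".*t= *", "", lines[i + 1])))
    times <- c(times, tm)
    block <- lines[(i + 2):(i + 1 + N)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) != 4)
    if (length(bad) > 0) stop("malformed XYZ atom row at line ", i + 1 + bad[1])
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + N
  }
  arr <- array(0, c(N0, 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  list(frames = arr, times = times)
}

#' Write a bead trajectory in VTF format
#'
#' Structure block declaring the beads and the `N - 1` backbone bonds,
#' followed by one `timestep` block of coordinates per frame.
#'
#' @param frames N x 3 x nframes array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtf <- function(frames, path) {
  N <- dim(frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("atom 0:%d radius 0.5 name C", N - 1), con)
  if (N > 1) {
    writeLines(sprintf("bond %d:%d", 0:(N - 2), 1:(N - 1)), con)
  }
  for (f in seq_len(dim(frames)[3])) {
    writeLines("timestep ordered", con)
    writeLines(sprintf("%s %s %s",
                       format(frames[, 1, f], digits = 17),
                       format(frames[, 2, f], digits = 17),
                       format(frames[, 3, f], digits = 17)), con)
  }
  invisible(path)
}

#' Read a VTF bead trajectory
#'
#' Minimal reader for files produced by [write_vtf()].
#'
#' @param path input file.
#' @return list with `frames`, `bonds` (2-column matrix, 0-based as
#'   written).
#' @export
read_vtf <- function(path) {
  lines <- readLines(path)
  atom_line <- grep("^atom ", lines, value = TRUE)[1]
  N <- as.integer(sub("^atom 0:([0-9]+).*", "\\1", atom_line)) + 1L
  bond_lines <- grep("^bond ", lines, value = TRUE)
  bonds <- do.call(rbind, lapply(bond_lines, function(l) {
    as.integer(strsplit(sub("^bond ", "", l), ":")[[1]])
  }))
  ts <- grep("^timestep", lines)
  frames <- array(0, c(N, 3, length(ts)))
  for (f in seq_along(ts)) {
    block <- lines[(ts[f] + 1):(ts[f] + N)]
    xyz <- t(vapply(strsplit(trimws(block), "[[:space:]]+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
    frames[, , f] <- xyz
  }
  list(frames = frames, bonds = bonds)
}

#' Write / read tidy observable tables
#'
#' Per-frame observables as plain CSV for downstream statistics.
#'
#' @param df data.frame (e.g. from [analyze_conformation()]).
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_observables <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  utils::read.csv(path)
}

#' Write a run manifest
#'
#' JSON manifest tying outputs to the configuration, seed and file
#' checksums, so any output file is reachable from exactly one manifest.
#'
#' @param run a `nemapoly_run`.
#' @param files named character vector of output files to inventory.
#' @param path manifest path.
#' @return `path`, invisibly.
#' @importFrom tools md5sum
#' @export
write_run_manifest <- function(run, files, path) {
  inv <- lapply(files, function(f) {
    list(path = f, bytes = file.info(f)$size,
         md5 = unname(tools::md5sum(f)))
  })
  manifest <- list(
    package = "nemapoly",
    version = as.character(utils::packageVersion("nemapoly")),
    seed = run$seed,
    config = unclass(run$config)[config_field_order()],
    frames = dim(run$frames)[3],
    files = inv)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Save / restore a run checkpoint
#'
#' The checkpoint contains the full phase-space state and RNG stream
#' states; resuming reproduces the uninterrupted trajectory exactly.
#'
#' @param run a `nemapoly_run`.
#' @param path checkpoint file.
#' @return `path` (save) / the state list (load).
#' @export
save_checkpoint <- function(run, path) {
  saveRDS(list(config = run$config, seed = run$seed, state = run$state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
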