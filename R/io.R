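## Readers and writers. Canonical on-disk units are pixels and frames (the
## units of tracking exports); conversion to mm / hr happens at read time
## through a unit context.

#' Unit context for tracking data
#'
#' @param mm_per_px spatial scale (mm per pixel).
#' @param hr_per_frame frame interval in hours; the default 0.25 hr is the
#'   15-minute imaging cadence of the plate time-lapse.
#' @return list of class `unit_context`.
#' @export
unit_context <- function(mm_per_px = 1, hr_per_frame = 0.25) {
  stopifnot(mm_per_px > 0, hr_per_frame > 0)
  structure(list(mm_per_px = mm_per_px, hr_per_frame = hr_per_frame),
            class = "unit_context")
}

#' Read tracked-aggregate trajectories from CSV
#'
#' Reads tracking exports (one row per detection) and converts them into
#' [trajectory()] objects in mm / hr. The column mapping absorbs arbitrary
#' source schemas; positions and areas are assumed to be in pixels and are
#' scaled by the unit context. If a `t` column is mapped it is used as the
#' time axis (already in hours); otherwise time is `frame * hr_per_frame`.
#'
#' @param path CSV file.
#' @param column_map named character vector mapping the roles `track_id`,
#'   `frame`, `x`, `y` (and optionally `area`, `t`, `merge_class`) to the
#'   file's column names.
#' @param units a [unit_context()].
#' @param min_points drop tracks with fewer points (default 2).
#' @return named list of [trajectory()] objects.
#' @export
read_tracks <- function(path,
                        column_map = c(track_id = "track_id", frame = "frame",
                                       x = "x", y = "y", area = "area"),
                        units = unit_context(), min_points = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE)
  need <- c("track_id", "frame", "x", "y")
  for (role in need) {
    if (!role %in% names(column_map))
      stop("column_map lacks required role '", role, "'")
    if (!column_map[[role]] %in% names(raw))
      stop("mapped column '", column_map[[role]], "' (role '", role,
           "') not present in ", path)
  }
  df <- data.frame(track_id = raw[[column_map[["track_id"]]]],
                   frame = raw[[column_map[["frame"]]]],
                   x = as.numeric(raw[[column_map[["x"]]]]),
                   y = as.numeric(raw[[column_map[["y"]]]]))
  df$area <- if ("area" %in% names(column_map) &&
                 column_map[["area"]] %in% names(raw))
    as.numeric(raw[[column_map[["area"]]]]) else NA_real_
  df$t <- if ("t" %in% names(column_map) && column_map[["t"]] %in% names(raw))
    as.numeric(raw[[column_map[["t"]]]]) else df$frame * units$hr_per_frame
  df$merge_class <- if ("merge_class" %in% names(column_map) &&
                        column_map[["merge_class"]] %in% names(raw))
    as.character(raw[[column_map[["merge_class"]]]]) else NA_character_
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup))
    stop("duplicated (track, frame) row(s) at file row(s): ",
         paste(which(dup), collapse = ", "))
  out <- list()
  for (id in unique(df$track_id)) {
    tr <- df[df$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (any(diff(tr$t) <= 0))
      stop("non-monotone times within track ", id)
    if (nrow(tr) < min_points) next
    out[[as.character(id)]] <- trajectory(
      tr$t, tr$x * units$mm_per_px, tr$y * units$mm_per_px,
      area = tr$area * units$mm_per_px^2,
      track_id = id, merge_class = tr$merge_class[1])
  }
  out
}

#' Write trajectories to CSV
#'
#' Inverse of [read_tracks()] with an identity unit context: columns
#' `track_id`, `frame`, `t`, `x`, `y`, `area`, `merge_class`, full `%.17g`
#' precision, so write-then-read round-trips values exactly.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path output CSV file.
#' @export
write_tracks <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    data.frame(track_id = attr(tr, "track_id"),
               frame = seq_len(nrow(tr)),
               t = fmt_full(tr$t), x = fmt_full(tr$x), y = fmt_full(tr$y),
               area = fmt_full(tr$area),
               merge_class = attr(tr, "merge_class"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_full <- function(v) {
  out <- sprintf("%.17g", as.numeric(v))
  out[is.na(v)] <- "NA"
  out
}

#' Write simulation snapshots as plain text
#'
#' Stores a run in a directory: `meta.txt` (parameters, seed, snapshot
#' times), one `agents_<k>.csv` per snapshot (`agent_id`, `x`, `y`,
#' `state`), and one `field_<k>.txt` (whitespace-separated concentration
#' matrix) per snapshot when fields were kept. All numbers use `%.17g`, so
#' [read_snapshots()] restores values exactly.
#'
#' @param sim a `spotdyn_sim` object.
#' @param dir output directory (created if needed).
#' @export
write_snapshots <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("%s = %.17g", names(unclass(sim$params)),
                    as.numeric(unlist(unclass(sim$params)))),
            sprintf("seed = %s", if (is.null(sim$seed)) "NA" else sim$seed),
            sprintf("n_snapshots = %d", length(sim$snapshots)),
            sprintf("times = %s",
                    paste(sprintf("%.17g", sim$times), collapse = ",")))
  writeLines(meta, file.path(dir, "meta.txt"))
  for (k in seq_along(sim$snapshots)) {
    s <- sim$snapshots[[k]]
    df <- data.frame(agent_id = seq_len(nrow(s$positions)),
                     x = fmt_full(s$positions[, 1]),
                     y = fmt_full(s$positions[, 2]),
                     state = s$state)
    write.csv(df, file.path(dir, sprintf("agents_%04d.csv", k)),
              row.names = FALSE, quote = FALSE)
    if (!is.null(s$field)) {
      con <- file(file.path(dir, sprintf("field_%04d.txt", k)), "w")
      writeLines(apply(s$field, 1, function(row)
        paste(sprintf("%.17g", row), collapse = " ")), con)
      close(con)
    }
  }
  invisible(dir)
}

#' Read simulation snapshots written by [write_snapshots()]
#'
#' @param dir snapshot directory.
#' @return a `spotdyn_sim`-like object (params, times, snapshots).
#' @export
read_snapshots <- function(dir) {
  meta_path <- file.path(dir, "meta.txt")
  if (!file.exists(meta_path)) stop("not a snapshot directory: ", dir)
  meta <- readLines(meta_path)
  pos <- regexpr(" = ", meta, fixed = TRUE)
  keys <- substr(meta, 1L, pos - 1L)
  vals <- substr(meta, pos + 3L, nchar(meta))
  nsnap <- as.integer(vals[keys == "n_snapshots"])
  times <- as.numeric(strsplit(vals[keys == "times"], ",")[[1]])
  pkeys <- setdiff(keys, c("seed", "n_snapshots", "times"))
  params <- do.call(sim_params,
                    as.list(setNames(as.numeric(vals[match(pkeys, keys)]),
                                     pkeys)))
  seed_val <- vals[keys == "seed"]
  snaps <- vector("list", nsnap)
  for (k in seq_len(nsnap)) {
    f <- file.path(dir, sprintf("agents_%04d.csv", k))
    if (!file.exists(f)) stop("corrupt snapshot directory at index ", k)
    df <- tryCatch(read.csv(f), error = function(e)
      stop("corrupt agent table at snapshot ", k, ": ", conditionMessage(e)))
    s <- list(time = times[k],
              positions = cbind(x = df$x, y = df$y),
              state = as.integer(df$state))
    ff <- file.path(dir, sprintf("field_%04d.txt", k))
    if (file.exists(ff)) {
      rows <- strsplit(readLines(ff), " ", fixed = TRUE)
      s$field <- do.call(rbind, lapply(rows, as.numeric))
    }
    snaps[[k]] <- s
  }
  out <- list(params = params,
              seed = if (seed_val == "NA") NULL else as.integer(seed_val),
              times = times, snapshots = snaps)
  class(out) <- "spotdyn_sim"
  out
}
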