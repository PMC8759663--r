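## Aggregate detection: neighborhood density maps, threshold segmentation,
## frame-to-frame track linking and merge-event classification.

#' Local agent-density map
#'
#' For each pixel of the grid, counts the agents whose position lies within
#' Euclidean distance `radius` of the pixel center (periodic metric by
#' default, matching the simulation domain). `radius = 0` gives raw
#' containing-pixel counts, which sum to the number of agents.
#'
#' @param positions n x 2 matrix of agent positions (px).
#' @param radius neighborhood radius, px (>= 0).
#' @param grid_size pixels per side.
#' @param periodic logical; use the periodic metric.
#' @return integer `grid_size` x `grid_size` matrix of counts.
#' @export
local_density_map <- function(positions, radius = 3, grid_size,
                              periodic = TRUE) {
  if (radius < 0) stop("radius must be >= 0")
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  cpp_density_map(positions[, 1], positions[, 2], radius,
                  as.integer(grid_size), periodic)
}

#' Segment aggregates from a density map
#'
#' Pixels whose neighborhood count strictly exceeds `count_threshold` are
#' foreground; foreground is labelled into 8-connected components (periodic
#' wrap by default) and components smaller than `min_area` pixels are
#' discarded. Each surviving component is reported with its pixel-count area
#' and the mean of its member pixel centers as centroid (computed with
#' periodic unwrapping so aggregates straddling the domain edge get a
#' sensible centroid).
#'
#' @param density integer count matrix from [local_density_map()].
#' @param count_threshold keep pixels with counts strictly greater than this.
#' @param min_area discard components with fewer pixels than this.
#' @param periodic logical; treat the map as periodic when labelling.
#' @return data.frame with columns `id`, `x`, `y` (centroid, px), `area`
#'   (pixel count).
#' @export
segment_aggregates <- function(density, count_threshold = 40, min_area = 10,
                               periodic = TRUE) {
  mask <- (density > count_threshold) * 1L
  storage.mode(mask) <- "integer"
  lab <- cpp_label_components(mask, eight = TRUE, periodic = periodic)
  ids <- sort(unique(lab[lab > 0L]))
  n <- nrow(density)
  out <- lapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    # pixel centers; unwrap around the first member for periodic components
    cx <- idx[, 1] - 0.5
    cy <- idx[, 2] - 0.5
    if (periodic) {
      cx <- cx[1] + wrap_diff(cx - cx[1], n)
      cy <- cy[1] + wrap_diff(cy - cy[1], n)
    }
    data.frame(x = mean(cx) %% n, y = mean(cy) %% n, area = nrow(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  data.frame(id = seq_len(nrow(out)), out, row.names = NULL)
}

#' Segment aggregates in every snapshot of a simulation
#'
#' Convenience wrapper applying [local_density_map()] and
#' [segment_aggregates()] to each snapshot.
#'
#' @param sim a `spotdyn_sim` object.
#' @param radius,count_threshold,min_area segmentation settings.
#' @return data.frame of detections with columns `frame` (snapshot index),
#'   `time`, `x`, `y`, `area`.
#' @export
detect_aggregates <- function(sim, radius = 3, count_threshold = 40,
                              min_area = 10) {
  res <- lapply(seq_along(sim$snapshots), function(f) {
    s <- sim$snapshots[[f]]
    dm <- local_density_map(s$positions, radius = radius,
                            grid_size = sim$params$grid_size)
    det <- segment_aggregates(dm, count_threshold = count_threshold,
                              min_area = min_area)
    if (nrow(det) == 0L) return(NULL)
    data.frame(frame = f, time = s$time, det[, c("x", "y", "area")])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), time = numeric(0), x = numeric(0),
                      y = numeric(0), area = integer(0))
  out
}

#' Link detections into tracks and record merge events
#'
#' Greedy nearest-neighbor linking between consecutive frames: every live
#' track claims its nearest detection within the gate; when several tracks
#' claim the same detection, the closest claimant keeps the track and the
#' others are terminated and recorded as merging into the survivor.
#' Unclaimed detections start new tracks. The default gate is 3 times the
#' mean frame-to-frame nearest-neighbor displacement measured on the data.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `area`
#'   (and optionally `time`).
#' @param max_link_distance linking gate in the same units as `x`/`y`;
#'   `NULL` for the data-driven default.
#' @return list with `tracks` (data.frame `track_id`, `frame`, `time`, `x`,
#'   `y`, `area`) and `merge_events` (data.frame `event_id`, `frame`,
#'   `survivor`, `participant`; participants include the survivor).
#' @export
link_tracks <- function(detections, max_link_distance = NULL) {
  det <- detections[order(detections$frame), , drop = FALSE]
  if (!"time" %in% names(det)) det$time <- det$frame
  frames <- sort(unique(det$frame))
  if (is.null(max_link_distance))
    max_link_distance <- 3 * mean_frame_displacement(det, frames)

  rows <- vector("list", length(frames))
  events <- list()
  cur <- det[det$frame == frames[1], , drop = FALSE]
  active <- data.frame(track_id = seq_len(nrow(cur)), x = cur$x, y = cur$y)
  next_id <- nrow(cur) + 1L
  rows[[1]] <- data.frame(track_id = active$track_id, frame = cur$frame,
                          time = cur$time, x = cur$x, y = cur$y,
                          area = cur$area)
  for (fi in seq_along(frames)[-1]) {
    cur <- det[det$frame == frames[fi], , drop = FALSE]
    nd <- nrow(cur)
    na <- nrow(active)
    link_to <- rep(NA_integer_, nd) # detection -> surviving track id
    new_active <- NULL
    if (na > 0L && nd > 0L) {
      dmat <- outer(active$x, cur$x, `-`)^2 + outer(active$y, cur$y, `-`)^2
      claim <- apply(dmat, 1L, which.min)
      claim_d <- sqrt(dmat[cbind(seq_len(na), claim)])
      claim[claim_d > max_link_distance] <- NA_integer_
      for (d in unique(claim[!is.na(claim)])) {
        claimants <- which(!is.na(claim) & claim == d)
        winner <- claimants[which.min(claim_d[claimants])]
        link_to[d] <- active$track_id[winner]
        losers <- setdiff(claimants, winner)
        if (length(losers) > 0L) {
          events[[length(events) + 1L]] <- data.frame(
            frame = frames[fi],
            survivor = active$track_id[winner],
            participant = c(active$track_id[winner], active$track_id[losers]))
        }
      }
    }
    # continue linked tracks, start new ones for unclaimed detections
    tid <- link_to
    if (any(is.na(tid))) {
      n_new <- sum(is.na(tid))
      tid[is.na(tid)] <- seq.int(next_id, length.out = n_new)
      next_id <- next_id + n_new
    }
    rows[[fi]] <- data.frame(track_id = tid, frame = cur$frame,
                             time = cur$time, x = cur$x, y = cur$y,
                             area = cur$area)
    active <- data.frame(track_id = tid, x = cur$x, y = cur$y)
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  if (length(events) > 0L) {
    merge_events <- do.call(rbind, Map(function(e, i) {
      data.frame(event_id = i, e)
    }, events, seq_along(events)))
  } else {
    merge_events <- data.frame(event_id = integer(0), frame = integer(0),
                               survivor = integer(0), participant = integer(0))
  }
  list(tracks = tracks, merge_events = merge_events,
       gate = max_link_distance)
}

# mean frame-to-frame nearest-neighbor displacement, used for the default gate
mean_frame_displacement <- function(det, frames) {
  d <- numeric(0)
  for (fi in seq_along(frames)[-1]) {
    a <- det[det$frame == frames[fi - 1L], , drop = FALSE]
    b <- det[det$frame == frames[fi], , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    dm <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
    d <- c(d, apply(dm, 1L, min))
  }
  if (length(d) == 0L || mean(d) == 0) 1 else mean(d)
}

#' Classify tracks by merging participation
#'
#' Counts, for every track, the distinct other tracks it shared a merge
#' event with (survivor chains count: a survivor that merges again
#' accumulates partners). Tracks with no partners are `non_merger`, with one
#' partner `two_spot_merger`, with two or more `three_spot_merger`.
#'
#' @param tracks,merge_events output of [link_tracks()].
#' @return list with `classes` (named character vector by track id),
#'   `fractions` (non_merger / two_spot_merger / three_spot_merger), and
#'   `count_reduction` (fractional reduction in aggregate number,
#'   `sum(participants - 1) / n_tracks`).
#' @export
classify_merging <- function(tracks, merge_events) {
  ids <- sort(unique(tracks$track_id))
  partners <- lapply(setNames(vector("list", length(ids)), ids), function(x) integer(0))
  if (nrow(merge_events) > 0L) {
    for (e in unique(merge_events$event_id)) {
      part <- merge_events$participant[merge_events$event_id == e]
      for (p in part) {
        key <- as.character(p)
        partners[[key]] <- union(partners[[key]], setdiff(part, p))
      }
    }
  }
  np <- vapply(as.character(ids), function(k) length(partners[[k]]), integer(1))
  classes <- ifelse(np == 0L, "non_merger",
                    ifelse(np == 1L, "two_spot_merger", "three_spot_merger"))
  names(classes) <- ids
  lost <- if (nrow(merge_events) > 0L) {
    sum(tapply(merge_events$participant, merge_events$event_id,
               function(p) length(p) - 1L))
  } else 0L
  fractions <- c(non_merger = mean(classes == "non_merger"),
                 two_spot_merger = mean(classes == "two_spot_merger"),
                 three_spot_merger = mean(classes == "three_spot_merger"))
  list(classes = classes, fractions = fractions,
       count_reduction = lost / length(ids))
}
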