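# Time linking of per-frame features: two-stage linear-assignment tracking
# (frame-to-frame linking, then gap closing) followed by minimum-lifetime
# pruning of short-lived, likely spurious features.

#' Solve a linear assignment problem
#'
#' Minimum-cost perfect assignment on a square cost matrix by the Hungarian
#' method with shortest augmenting paths (O(n^3)). Forbidden assignments are
#' encoded as large finite costs.
#'
#' @param cost numeric square matrix.
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer(0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1]: row matched to column j (0 = virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) out[p[j + 1]] <- j
  out
}

# Linking cost between a track's current tip (with its feature type) and a
# candidate feature: Euclidean distance between anchor points. Line/curve
# anchors use whichever end lies nearer the previous tip (orientation
# consistency); type mismatches are forbidden (Inf).
link_cost <- function(prev_type, prev_tip, feature) {
  type <- class(feature)[1]
  if (type != prev_type) return(list(cost = Inf, tip = NULL))
  if (type == "mt_spot") {
    return(list(cost = sqrt(sum((feature$center - prev_tip)^2)),
                tip = feature$center))
  }
  ends <- if (type == "mt_line") {
    list(feature$end, feature$start)
  } else {
    list(feature_tip(feature), feature$origin)
  }
  d <- vapply(ends, function(e) sqrt(sum((e - prev_tip)^2)), 0)
  k <- which.min(d)
  list(cost = d[k], tip = ends[[k]])
}

BIG_COST <- 1e9

#' Link per-frame features into tracks
#'
#' Two-stage linear-assignment tracker. Stage one links features frame to
#' frame by minimizing the total anchor-point distance (spot centers;
#' line/curve free-end tips), with births and deaths available at cost
#' `max_link_cost`, so no realized link ever costs more than
#' `max_link_cost`. Stage two closes gaps: a track that ends may be joined
#' to one that starts up to `max_gap` frames later if the tip distance is
#' within `max_link_cost`.
#'
#' @param per_frame_features list (one element per frame) of feature lists.
#' @param max_link_cost maximum link distance (micron); also the birth/death
#'   cost of the assignment problem.
#' @param max_gap maximum number of skipped frames bridged by gap closing.
#' @param frame_interval seconds between frames (for lifetimes).
#' @return list of `mt_track` objects: each has `id`, `frames` (1-based,
#'   strictly increasing), `features`, `tips`, `gap_frames`, and `lifetime`
#'   (`(last - first + 1) * frame_interval` seconds).
#' @export
link_features <- function(per_frame_features, max_link_cost = 1, max_gap = 1,
                          frame_interval = 1) {
  n_frames <- length(per_frame_features)
  stopifnot(n_frames >= 1)
  tracks <- list()   # open + closed tracklets
  active <- integer(0)  # indices into `tracks` that are open

  new_track <- function(frame, feature) {
    list(frames = frame, features = list(feature),
         tips = list(feature_tip(feature)),
         type = class(feature)[1])
  }

  for (f0 in seq_len(n_frames)) {
    feats <- per_frame_features[[f0]]
    if (f0 == 1) {
      for (ft in feats) {
        tracks[[length(tracks) + 1]] <- new_track(1L, ft)
        active <- c(active, length(tracks))
      }
      next
    }
    np <- length(active); nn <- length(feats)
    if (np == 0 && nn == 0) next
    # square LAP with birth/death blocks
    n <- np + nn
    C <- matrix(0, n, n)
    if (np > 0 && nn > 0) {
      for (a in seq_len(np)) {
        tr <- tracks[[active[a]]]
        tip <- tr$tips[[length(tr$tips)]]
        for (b in seq_len(nn)) {
          lc <- link_cost(tr$type, tip, feats[[b]])
          C[a, b] <- if (is.finite(lc$cost) && lc$cost <= max_link_cost) {
            lc$cost
          } else BIG_COST
        }
      }
    }
    if (np > 0) {
      C[seq_len(np), nn + seq_len(np)] <- BIG_COST
      for (a in seq_len(np)) C[a, nn + a] <- max_link_cost
    }
    if (nn > 0) {
      C[np + seq_len(nn), seq_len(nn)] <- BIG_COST
      for (b in seq_len(nn)) C[np + b, b] <- max_link_cost
    }
    asgn <- solve_lap(C)
    next_active <- integer(0)
    linked_feat <- logical(nn)
    for (a in seq_len(np)) {
      j <- asgn[a]
      if (j <= nn && C[a, j] < BIG_COST) {
        ti <- active[a]
        tr <- tracks[[ti]]
        lc <- link_cost(tr$type, tr$tips[[length(tr$tips)]], feats[[j]])
        tr$frames <- c(tr$frames, f0)
        tr$features <- c(tr$features, feats[j])
        tr$tips <- c(tr$tips, list(lc$tip))
        tracks[[ti]] <- tr
        next_active <- c(next_active, ti)
        linked_feat[j] <- TRUE
      }
    }
    for (b in which(!linked_feat)) {
      tracks[[length(tracks) + 1]] <- new_track(f0, feats[[b]])
      next_active <- c(next_active, length(tracks))
    }
    active <- next_active
  }

  # gap closing: join a tracklet end to a tracklet start within max_gap
  if (max_gap > 0 && length(tracks) > 1) {
    repeat {
      ends <- vapply(tracks, function(t) t$frames[length(t$frames)], 0)
      starts <- vapply(tracks, function(t) t$frames[1], 0)
      ne <- length(tracks)
      C <- matrix(BIG_COST, ne, ne)
      found <- FALSE
      for (a in seq_len(ne)) for (b in seq_len(ne)) {
        if (a == b) next
        gap <- starts[b] - ends[a] - 1
        if (gap < 1 || gap > max_gap) next
        ta <- tracks[[a]]; tb <- tracks[[b]]
        if (ta$type != tb$type) next
        d <- sqrt(sum((ta$tips[[length(ta$tips)]] - tb$tips[[1]])^2))
        if (d <= max_link_cost) { C[a, b] <- d; found <- TRUE }
      }
      if (!found) break
      # greedily merge the single best pair, then re-evaluate
      ij <- arrayInd(which.min(C), dim(C))
      a <- ij[1]; b <- ij[2]
      ta <- tracks[[a]]; tb <- tracks[[b]]
      ta$gap_frames <- c(ta$gap_frames,
        (ta$frames[length(ta$frames)] + 1):(tb$frames[1] - 1))
      ta$frames <- c(ta$frames, tb$frames)
      ta$features <- c(ta$features, tb$features)
      ta$tips <- c(ta$tips, tb$tips)
      tracks[[a]] <- ta
      tracks[[b]] <- NULL
    }
  }

  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    out[[i]] <- structure(list(
      id = i, frames = tr$frames, features = tr$features, tips = tr$tips,
      type = tr$type,
      gap_frames = if (is.null(tr$gap_frames)) integer(0) else tr$gap_frames,
      frame_interval = frame_interval,
      lifetime = (tr$frames[length(tr$frames)] - tr$frames[1] + 1) *
        frame_interval), class = "mt_track")
  }
  out
}

#' @export
print.mt_track <- function(x, ...) {
  cat(sprintf("<mt_track %d [%s]: frames %d-%d (%d observed), lifetime %gs>\n",
              x$id, x$type, x$frames[1], x$frames[length(x$frames)],
              length(x$frames), x$lifetime))
  invisible(x)
}

#' Remove short-lived tracks
#'
#' Keeps exactly the tracks with at least `min_frames` observed (linked)
#' frames; features seen for fewer frames are treated as spurious and
#' removed entirely. Idempotent.
#'
#' @param tracks list of `mt_track`.
#' @param min_frames minimum number of observed frames (>= 1).
#' @return filtered list of tracks.
#' @export
prune_short_tracks <- function(tracks, min_frames = 3) {
  stopifnot(min_frames >= 1)
  tracks[vapply(tracks, function(t) length(t$frames) >= min_frames, TRUE)]
}

#' Length time-series of a track
#'
#' @param track an `mt_track`.
#' @return data.frame with `time` (seconds) and `length` (micron) at the
#'   observed frames.
#' @export
length_series <- function(track) {
  data.frame(
    time = (track$frames - 1) * track$frame_interval,
    length = vapply(track$features, feature_length, 0))
}

#' Flatten tracks to a data frame
#'
#' One row per (track, frame) with tip position, feature type, length and
#' amplitude; the serialization format used for CSV export.
#'
#' @param tracks list of `mt_track`.
#' @return data.frame with columns track_id, frame, time_s, type, length_um,
#'   tip_x, tip_y, tip_z, amplitude.
#' @export
tracks_to_df <- function(tracks) {
  rows <- list()
  for (tr in tracks) {
    for (k in seq_along(tr$frames)) {
      tip <- tr$tips[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        track_id = tr$id, frame = tr$frames[k],
        time_s = (tr$frames[k] - 1) * tr$frame_interval,
        type = sub("^mt_", "", tr$type),
        length_um = feature_length(tr$features[[k]]),
        tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
        amplitude = tr$features[[k]]$amplitude)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      time_s = numeric(0), type = character(0),
                      length_um = numeric(0), tip_x = numeric(0),
                      tip_y = numeric(0), tip_z = numeric(0),
                      amplitude = numeric(0)))
  }
  do.call(rbind, rows)
}
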