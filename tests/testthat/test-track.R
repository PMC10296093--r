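# Time linking and minimum-lifetime pruning.

mk_spot_at <- function(x, y = 2, z = 1.75) {
  mt_spot(5, c(x, y, z), c(0.2, 0.2, 0.45))
}
mk_line_to <- function(tip, pole = c(2, 2, 1.75)) {
  mt_line(3, pole, tip, c(0.15, 0.15, 0.35))
}

# exhaustive minimum-cost matching with births/deaths at cost b
brute_force_cost <- function(D, b) {
  np <- nrow(D); nn <- ncol(D)
  best <- Inf
  # enumerate all partial injective mappings prev -> next
  choices <- c(0, seq_len(nn))
  grid <- do.call(expand.grid, rep(list(choices), np))
  for (r in seq_len(nrow(grid))) {
    m <- as.integer(grid[r, ])
    used <- m[m > 0]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_len(np),
                     function(i) m[i] == 0 || D[i, m[i]] <= b, TRUE))
    if (!ok) next
    cost <- sum(vapply(seq_len(np),
                       function(i) if (m[i] > 0) D[i, m[i]] else b, 0)) +
      b * (nn - length(used))
    best <- min(best, cost)
  }
  best
}

track_total_cost <- function(tracks, frame, b, feats_prev, feats_next) {
  # cost realized by the tracker between two frames, from its link set
  linked <- 0; nlink <- 0
  for (tr in tracks) {
    k <- which(tr$frames == frame)
    if (length(k) == 1 && any(tr$frames == frame + 1)) {
      a <- tr$tips[[k]]; bb <- tr$tips[[which(tr$frames == frame + 1)]]
      linked <- linked + sqrt(sum((a - bb)^2))
      nlink <- nlink + 1
    }
  }
  linked + b * (length(feats_prev) - nlink) + b * (length(feats_next) - nlink)
}

test_that("a stationary spot over 5 frames gives one 5-frame track", {
  frames <- replicate(5, list(mk_spot_at(2)), simplify = FALSE)
  tracks <- link_features(frames, max_link_cost = 1, frame_interval = 2)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, 1:5)
  expect_equal(tracks[[1]]$lifetime, 10)
})

test_that("linking is optimal versus brute force on small cases", {
  set.seed(21)
  for (rep in 1:15) {
    np <- sample(1:4, 1); nn <- sample(1:4, 1)
    prev <- lapply(runif(np, 1, 3), mk_spot_at)
    nxt <- lapply(runif(nn, 1, 3), mk_spot_at)
    D <- matrix(Inf, np, nn)
    for (i in seq_len(np)) for (j in seq_len(nn)) {
      D[i, j] <- sqrt(sum((prev[[i]]$center - nxt[[j]]$center)^2))
    }
    b <- 0.8
    tracks <- link_features(list(prev, nxt), max_link_cost = b, max_gap = 0)
    got <- track_total_cost(tracks, 1, b, prev, nxt)
    expect_equal(got, brute_force_cost(D, b), tolerance = 1e-9)
  }
})

test_that("far-apart swaps become births and deaths, not long links", {
  # two spots 3 um apart; in frame 2 they swap positions -> any link would
  # cost 3 um > max_link_cost, so the tracker must end two tracks and start
  # two new ones
  f1 <- list(mk_spot_at(1), mk_spot_at(4))
  f2 <- list(mk_spot_at(4), mk_spot_at(1))
  # links of cost 0 exist (same positions) -> tracker should use them
  tracks <- link_features(list(f1, f2), max_link_cost = 1, max_gap = 0)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, function(t) length(t$frames), 0L) == 2))
  # every realized link costs <= max_link_cost
  for (tr in tracks) {
    for (k in seq_len(length(tr$frames) - 1)) {
      d <- sqrt(sum((tr$tips[[k]] - tr$tips[[k + 1]])^2))
      expect_lte(d, 1)
    }
  }
})

test_that("gap closing bridges a single missing frame", {
  present <- mk_spot_at(2)
  frames <- list(list(present), list(), list(mk_spot_at(2.05)))
  tracks <- link_features(frames, max_link_cost = 1, max_gap = 1)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, c(1L, 3L))
  expect_equal(tracks[[1]]$gap_frames, 2L)
  # with max_gap = 0 the same input yields two tracks
  tracks0 <- link_features(frames, max_link_cost = 1, max_gap = 0)
  expect_length(tracks0, 2)
})

test_that("line tips link end-to-end with orientation consistency", {
  t1 <- mk_line_to(c(3.5, 2, 1.75))
  t2 <- mk_line_to(c(3.6, 2.1, 1.75))
  tracks <- link_features(list(list(t1), list(t2)), max_link_cost = 1)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$tips[[2]], c(3.6, 2.1, 1.75))
})

test_that("no feature appears in two tracks", {
  set.seed(33)
  frames <- lapply(1:4, function(f) lapply(runif(3, 1, 3), mk_spot_at))
  tracks <- link_features(frames, max_link_cost = 0.7)
  seen <- c()
  for (tr in tracks) {
    for (k in seq_along(tr$frames)) {
      key <- paste(tr$frames[k], paste(tr$features[[k]]$center, collapse = ","))
      expect_false(key %in% seen)
      seen <- c(seen, key)
    }
  }
})

test_that("prune_short_tracks keeps exactly the long-enough tracks and is idempotent", {
  frames <- list(
    list(mk_spot_at(1), mk_spot_at(3)),
    list(mk_spot_at(1.05)),
    list(mk_spot_at(1.1)))
  tracks <- link_features(frames, max_link_cost = 0.5)
  expect_length(prune_short_tracks(tracks, 1), length(tracks))  # identity
  p2 <- prune_short_tracks(tracks, 2)
  expect_length(p2, 1)   # the 1-frame feature at x=3 is removed
  expect_equal(prune_short_tracks(p2, 2), p2)  # idempotent
  p3 <- prune_short_tracks(tracks, 3)
  expect_length(p3, 1)
  counts <- vapply(tracks, function(t) length(t$frames), 0L)
  expect_equal(length(prune_short_tracks(tracks, 2)), sum(counts >= 2))
})

test_that("assignment solver matches brute force on random square problems", {
  set.seed(5)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (n in 2:4) {
    for (rep in 1:10) {
      C <- matrix(runif(n * n), n, n)
      a <- solve_lap(C)
      got <- sum(C[cbind(seq_len(n), a)])
      best <- min(vapply(perms(seq_len(n)),
                         function(p) sum(C[cbind(seq_len(n), p)]), 0))
      expect_equal(got, best, tolerance = 1e-12)
    }
  }
})

test_that("tracks flatten to the documented data frame layout", {
  frames <- replicate(3, list(mk_line_to(c(3.5, 2, 1.75))), simplify = FALSE)
  tracks <- link_features(frames, max_link_cost = 1, frame_interval = 5)
  df <- tracks_to_df(tracks)
  expect_equal(names(df), c("track_id", "frame", "time_s", "type",
                            "length_um", "tip_x", "tip_y", "tip_z",
                            "amplitude"))
  expect_equal(df$time_s, c(0, 5, 10))
  expect_equal(df$type, rep("line", 3))
  expect_equal(df$length_um, rep(feature_length(mk_line_to(c(3.5, 2, 1.75))), 3))
})
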