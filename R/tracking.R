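# Track assembly across frames, discontinuity heuristics (merge repair and
# division calling), the lineage-capture statistic, and evaluation against
# synthetic ground truth.

#' Detect nuclei in every frame of a movie
#'
#' Applies flat-field correction and threshold segmentation frame by frame.
#'
#' @param frames List of numeric matrices (a movie), e.g. `$frames` of a
#'   [make_movie()] result or [read_movie_tiff()] output.
#' @param threshold,min_area Passed to [segment_cells()].
#' @param correct Apply [correct_illumination()] before segmenting.
#' @return List of detection data frames, one per frame.
#' @export
detect_frames <- function(frames, threshold = "auto", min_area = 20L,
                          correct = TRUE) {
  lapply(frames, function(f) {
    img <- if (correct) correct_illumination(f)$corrected else f
    segment_cells(img, threshold = threshold, min_area = min_area)
  })
}

# internal track store helpers -------------------------------------------

new_track <- function(id, parent, frame, det_row) {
  list(id = id, parent = parent,
       frames = frame, x = det_row$x_px, y = det_row$y_px,
       intensity = det_row$intensity, area = det_row$area)
}

append_obs <- function(tr, frame, x, y, intensity, area) {
  tr$frames <- c(tr$frames, frame)
  tr$x <- c(tr$x, x); tr$y <- c(tr$y, y)
  tr$intensity <- c(tr$intensity, intensity)
  tr$area <- c(tr$area, area)
  tr
}

tracks_to_df <- function(tracks) {
  if (!length(tracks)) {
    return(data.frame(track_id = integer(), parent_id = integer(),
                      frame = integer(), x_px = numeric(), y_px = numeric(),
                      intensity = numeric(), area = numeric()))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$id, parent_id = tr$parent, frame = tr$frames,
               x_px = tr$x, y = tr$y, intensity = tr$intensity,
               area = tr$area)
  })) -> df
  names(df)[names(df) == "y"] <- "y_px"
  df
}

#' Assemble raw tracks by frame-to-frame optimal assignment
#'
#' Pure linking: every unmatched detection starts a new track and every
#' unmatched track ends. No merge repair or division calling is done here;
#' see [resolve_discontinuities()].
#'
#' @param detections List of per-frame detection data frames
#'   ([detect_frames()]).
#' @param params A [link_params()].
#' @return A list of track records (internal form accepted by
#'   [resolve_discontinuities()] and [tracks_to_df()]).
#' @export
link_tracks <- function(detections, params = link_params()) {
  tracks <- list()
  active <- integer(0)       # indices into tracks with a row at frame f-1
  next_id <- 1L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    if (f == 1L) {
      for (j in seq_len(nrow(det))) {
        tracks[[next_id]] <- new_track(next_id, NA_integer_, f, det[j, ])
        active <- c(active, next_id)
        next_id <- next_id + 1L
      }
      next
    }
    cur <- if (length(active)) {
      do.call(rbind, lapply(tracks[active], function(tr) {
        k <- length(tr$frames)
        data.frame(x_px = tr$x[k], y_px = tr$y[k],
                   intensity = tr$intensity[k], area = tr$area[k])
      }))
    } else {
      data.frame(x_px = numeric(), y_px = numeric(),
                 intensity = numeric(), area = numeric())
    }
    lk <- link_frames(cur, det, params)
    new_active <- integer(0)
    if (nrow(lk$matches)) {
      for (r in seq_len(nrow(lk$matches))) {
        ti <- active[lk$matches$i[r]]
        j <- lk$matches$j[r]
        tracks[[ti]] <- append_obs(tracks[[ti]], f, det$x_px[j],
                                   det$y_px[j], det$intensity[j],
                                   det$area[j])
        new_active <- c(new_active, ti)
      }
    }
    for (j in lk$births) {
      tracks[[next_id]] <- new_track(next_id, NA_integer_, f, det[j, ])
      new_active <- c(new_active, next_id)
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  tracks
}

track_at <- function(tr, f) {
  k <- match(f, tr$frames)
  if (is.na(k)) NULL
  else list(x = tr$x[k], y = tr$y[k], intensity = tr$intensity[k],
            area = tr$area[k], k = k)
}

#' Repair tracking discontinuities and call divisions
#'
#' Two heuristics exploit discontinuities in the raw tracks:
#'
#' 1. *Merge repair*: a track that ends while an adjacent (within the gate)
#'    continuing track roughly doubles in intensity (factor in
#'    `[1.6, 2.6]`) is taken to have merged into it. The merged
#'    observations are split two ways in proportion to the pre-merge
#'    intensities and both tracks continue; if the merged track later
#'    roughly halves while a new track appears within the gate, that new
#'    track is the re-separated partner and continues the repaired track
#'    (no division is recorded).
#' 2. *Division calling*: a remaining new track appearing within the gate
#'    of an existing track whose intensity roughly halves (ratio in
#'    `[1/2.6, 1/1.6]`) at that frame is recorded as a division; the
#'    existing track is split at that frame into two daughter tracks with
#'    parent links.
#'
#' @param tracks Track list from [link_tracks()].
#' @param params A [link_params()] (the same gate is used for adjacency).
#' @param double_range Intensity-ratio band `[lo, hi]` that counts as
#'   "roughly doubled" in merge repair.
#' @param half_range Intensity-ratio band that counts as "roughly halved"
#'   in division calling. Slightly wider than `1/double_range`: measured
#'   component intensities of daughters carry threshold-truncation and
#'   partition noise on top of the inherited-label split.
#' @return A list: `tracks` (data frame: `track_id`, `parent_id`, `frame`,
#'   `x_px`, `y_px`, `intensity`, `area`), `divisions` (data frame:
#'   `frame`, `parent`, `child1`, `child2`), `census` (data frame: `frame`,
#'   `n_tracked`).
#' @export
resolve_discontinuities <- function(tracks, params = link_params(),
                                    double_range = c(1.6, 2.6),
                                    half_range = c(1 / 2.8, 1 / 1.4)) {
  gate <- params$gate
  lo <- double_range[1]; hi <- double_range[2]
  n_frames <- if (length(tracks)) max(unlist(lapply(tracks, function(t)
    max(t$frames)))) else 0L
  dead <- rep(FALSE, length(tracks))   # tracks absorbed into another

  ends <- vapply(tracks, function(t) max(t$frames), 0)
  starts <- vapply(tracks, function(t) min(t$frames), 0)

  # --- merge repair -------------------------------------------------------
  consumed_birth <- rep(FALSE, length(tracks))
  for (a in order(ends)) {
    if (dead[a]) next
    f <- ends[a]
    if (f >= n_frames) next
    pa <- track_at(tracks[[a]], f)
    best <- NULL; best_d <- Inf
    for (b in seq_along(tracks)) {
      if (b == a || dead[b]) next
      ob0 <- track_at(tracks[[b]], f)
      ob1 <- track_at(tracks[[b]], f + 1L)
      if (is.null(ob0) || is.null(ob1) || ob0$intensity <= 0) next
      ratio <- ob1$intensity / ob0$intensity
      d <- sqrt((pa$x - ob1$x)^2 + (pa$y - ob1$y)^2)
      if (ratio >= lo && ratio <= hi && d <= gate && d < best_d) {
        best <- b; best_d <- d
      }
    }
    if (is.null(best)) next
    b <- best
    braw <- tracks[[b]]   # pre-partition snapshot: ratio tests need raw values
    ob0 <- track_at(braw, f)
    share <- pa$intensity / (pa$intensity + ob0$intensity)
    off_a <- c(pa$x - (pa$x + ob0$x) / 2, pa$y - (pa$y + ob0$y) / 2)
    g <- f + 1L
    repeat {
      ob <- track_at(braw, g)
      if (is.null(ob)) break
      # did the merged blob re-separate at g (B halves, a new track nearby)?
      if (g > f + 1L) {
        obp <- track_at(braw, g - 1L)
        cand <- which(!dead & starts == g & !consumed_birth &
                        seq_along(tracks) != a)
        hit <- NA_integer_; hd <- Inf
        for (cc in cand) {
          oc <- track_at(tracks[[cc]], g)
          d <- sqrt((oc$x - obp$x)^2 + (oc$y - obp$y)^2)
          ratio <- ob$intensity / obp$intensity
          if (d <= gate && ratio >= 1 / hi && ratio <= 1 / lo && d < hd) {
            hit <- cc; hd <- d
          }
        }
        if (!is.na(hit)) {
          # A continues as the re-separated track
          hh <- tracks[[hit]]
          for (k in seq_along(hh$frames)) {
            tracks[[a]] <- append_obs(tracks[[a]], hh$frames[k], hh$x[k],
                                      hh$y[k], hh$intensity[k], hh$area[k])
          }
          dead[hit] <- TRUE
          consumed_birth[hit] <- TRUE
          break
        }
      }
      # shadow observation for A inside the merged blob
      ia <- share * ob$intensity
      tracks[[a]] <- append_obs(tracks[[a]], g, ob$x + off_a[1],
                                ob$y + off_a[2], ia,
                                round(share * ob$area))
      k <- ob$k
      tracks[[b]]$intensity[k] <- (1 - share) * ob$intensity
      tracks[[b]]$area[k] <- ob$area - round(share * ob$area)
      g <- g + 1L
    }
    ends[a] <- max(tracks[[a]]$frames)
  }

  # --- division calling ---------------------------------------------------
  # Births are resolved frame by frame: all births of a frame are paired
  # with candidate parents evaluated on the *pre-split* track states, so
  # simultaneous divisions (synchronized cell cycles) are each attributed.
  divisions <- list()
  next_id <- max(c(0L, vapply(tracks, function(t) t$id, 0L))) + 1L
  starts <- vapply(tracks, function(t) min(t$frames), 0)
  birth_frames <- sort(unique(starts[starts > 1L & !dead & !consumed_birth]))
  for (f in birth_frames) {
    births <- which(starts == f & !dead & !consumed_birth)
    # candidate parents: alive across f-1 -> f with roughly halved intensity
    cand <- list()
    for (p in seq_along(tracks)) {
      if (dead[p] || starts[p] >= f) next
      op0 <- track_at(tracks[[p]], f - 1L)
      op1 <- track_at(tracks[[p]], f)
      if (is.null(op0) || is.null(op1) || op0$intensity <= 0) next
      ratio <- op1$intensity / op0$intensity
      if (ratio >= half_range[1] && ratio <= half_range[2]) {
        # anchor candidate at the parent's pre-division position: both
        # daughters are born within ~2 cell radii of it
        cand[[length(cand) + 1L]] <- list(p = p, x = op0$x, y = op0$y)
      }
    }
    if (!length(cand)) next
    taken <- rep(FALSE, length(cand))
    for (cix in births) {
      oc <- track_at(tracks[[cix]], f)
      best <- NULL; best_d <- Inf
      for (k in seq_along(cand)) {
        if (taken[k] || cand[[k]]$p == cix) next
        d <- sqrt((oc$x - cand[[k]]$x)^2 + (oc$y - cand[[k]]$y)^2)
        if (d <= gate && d < best_d) { best <- k; best_d <- d }
      }
      if (is.null(best)) next
      taken[best] <- TRUE
      p <- cand[[best]]$p
      # split the parent at f: observations >= f become daughter D
      kk <- which(tracks[[p]]$frames >= f)
      dtr <- list(id = next_id, parent = tracks[[p]]$id,
                  frames = tracks[[p]]$frames[kk], x = tracks[[p]]$x[kk],
                  y = tracks[[p]]$y[kk],
                  intensity = tracks[[p]]$intensity[kk],
                  area = tracks[[p]]$area[kk])
      next_id <- next_id + 1L
      for (fld in c("frames", "x", "y", "intensity", "area")) {
        tracks[[p]][[fld]] <- tracks[[p]][[fld]][-kk]
      }
      tracks[[length(tracks) + 1L]] <- dtr
      dead <- c(dead, FALSE); consumed_birth <- c(consumed_birth, FALSE)
      starts <- c(starts, f)
      tracks[[cix]]$parent <- tracks[[p]]$id
      divisions[[length(divisions) + 1L]] <-
        data.frame(frame = f, parent = tracks[[p]]$id, child1 = dtr$id,
                   child2 = tracks[[cix]]$id)
    }
  }

  tracks <- tracks[!dead & vapply(tracks, function(t) length(t$frames) > 0L,
                                  TRUE)]
  df <- tracks_to_df(tracks)
  df <- df[order(df$track_id, df$frame), ]
  rownames(df) <- NULL
  census <- as.data.frame(table(factor(df$frame, levels = seq_len(n_frames))),
                          stringsAsFactors = FALSE)
  names(census) <- c("frame", "n_tracked")
  census$frame <- as.integer(census$frame)
  list(tracks = df,
       divisions = if (length(divisions)) do.call(rbind, divisions)
                   else data.frame(frame = integer(), parent = integer(),
                                   child1 = integer(), child2 = integer()),
       census = census)
}

#' Segment, link and lineage-resolve a whole movie
#'
#' Convenience pipeline: [detect_frames()] then [link_tracks()] then
#' [resolve_discontinuities()].
#'
#' @param frames List of frame matrices.
#' @param threshold,min_area Segmentation settings ([segment_cells()]).
#' @param params Linking settings ([link_params()]).
#' @param correct Apply flat-field correction first.
#' @return As [resolve_discontinuities()], plus `detections`.
#' @export
track_movie <- function(frames, threshold = "auto", min_area = 20L,
                        params = link_params(), correct = TRUE) {
  det <- detect_frames(frames, threshold = threshold, min_area = min_area,
                       correct = correct)
  res <- resolve_discontinuities(link_tracks(det, params), params)
  res$detections <- det
  res
}

#' Lineage-capture fraction of a tracked movie
#'
#' Per frame, the captured fraction is the number of tracked cells divided
#' by the expected (ground-truth or model) cell count, capped at 1. The
#' movie's capture fraction is the minimum over frames, and is classified
#' against the usual thresholds.
#'
#' @param tracking A [resolve_discontinuities()] / [track_movie()] result
#'   (its `census` is used), or a census data frame
#'   (`frame`, `n_tracked`).
#' @param expected Expected cell count per frame: a numeric vector (one per
#'   frame) or a data frame with `frame` and `count` columns.
#' @param thresholds Classification thresholds.
#' @return A list: `per_frame` (fractions), `fraction` (minimum over
#'   frames), `passes` (named logical per threshold).
#' @export
lineage_capture_fraction <- function(tracking, expected,
                                     thresholds = c(0.5, 0.9)) {
  census <- if (is.data.frame(tracking)) tracking else tracking$census
  if (is.data.frame(expected)) {
    expected <- expected$count[match(census$frame, expected$frame)]
  }
  if (length(expected) != nrow(census)) {
    stop("lineage_capture_fraction(): expected counts must cover every frame",
         call. = FALSE)
  }
  if (any(expected <= 0)) {
    stop("lineage_capture_fraction(): expected count must be > 0",
         call. = FALSE)
  }
  per_frame <- pmin(census$n_tracked / expected, 1)
  frac <- min(per_frame)
  list(per_frame = per_frame, fraction = frac,
       passes = stats::setNames(frac >= thresholds,
                                paste0("ge_", thresholds)))
}

#' Evaluate tracking against synthetic ground truth
#'
#' Matches tracked observations to ground-truth cells frame by frame
#' (greedy nearest within `match_dist`), then scores: *link recovery*, the
#' fraction of ground-truth frame-to-frame cell links (both endpoints inside
#' the FOV) whose two observations lie on the same track; and *division
#' recall*, the fraction of ground-truth divisions with a called division
#' within one frame and `match_dist_div` pixels.
#'
#' @param tracking A [track_movie()] result.
#' @param movie The [make_movie()] ground truth (`truth` and `divisions`
#'   are used).
#' @param match_dist Max observation-to-truth distance in px.
#' @param match_dist_div Max parent-position distance for division matching.
#' @return A list with `link_recovery`, `n_links`, `n_links_recovered`,
#'   `division_recall`, `n_divisions`, `n_divisions_recovered`,
#'   `n_false_divisions`.
#' @export
evaluate_tracking <- function(tracking, movie, match_dist = 5,
                              match_dist_div = 15) {
  truth <- movie$truth
  trk <- tracking$tracks
  n_frames <- length(movie$frames)
  # (frame, cell_id) -> track_id
  assign_map <- new.env(hash = TRUE)
  for (f in seq_len(n_frames)) {
    tt <- truth[truth$frame == f & truth$in_fov, ]
    oo <- trk[trk$frame == f, ]
    if (!nrow(tt) || !nrow(oo)) next
    D <- sqrt(outer(tt$x_px, oo$x_px, "-")^2 +
                outer(tt$y_px, oo$y_px, "-")^2)
    D[D > match_dist] <- Inf
    while (any(is.finite(D))) {
      k <- arrayInd(which.min(D), dim(D))
      assign(sprintf("%d_%d", f, tt$cell_id[k[1]]),
             oo$track_id[k[2]], envir = assign_map)
      D[k[1], ] <- Inf; D[, k[2]] <- Inf
    }
  }
  get_tid <- function(f, cid) {
    key <- sprintf("%d_%d", f, cid)
    if (exists(key, envir = assign_map, inherits = FALSE))
      get(key, envir = assign_map) else NA_integer_
  }
  n_links <- 0L; n_rec <- 0L
  for (f in seq_len(n_frames - 1L)) {
    t0 <- truth[truth$frame == f & truth$in_fov, ]
    t1 <- truth[truth$frame == f + 1L & truth$in_fov, ]
    common <- intersect(t0$cell_id, t1$cell_id)
    for (cid in common) {
      n_links <- n_links + 1L
      a <- get_tid(f, cid); b <- get_tid(f + 1L, cid)
      if (!is.na(a) && !is.na(b) && a == b) n_rec <- n_rec + 1L
    }
  }
  # division matching: truth parent last position vs called parent track
  tdiv <- movie$divisions
  cdiv <- tracking$divisions
  used <- rep(FALSE, nrow(cdiv))
  n_drec <- 0L
  if (nrow(tdiv)) {
    for (r in seq_len(nrow(tdiv))) {
      fd <- tdiv$frame[r]
      pr <- truth[truth$frame == fd - 1L & truth$cell_id == tdiv$parent[r], ]
      if (!nrow(pr)) next
      hit <- FALSE
      for (s in seq_len(nrow(cdiv))) {
        if (used[s] || abs(cdiv$frame[s] - fd) > 1L) next
        pt <- trk[trk$track_id == cdiv$parent[s] &
                    trk$frame == cdiv$frame[s] - 1L, ]
        if (!nrow(pt)) next
        d <- sqrt((pt$x_px[1] - pr$x_px)^2 + (pt$y_px[1] - pr$y_px)^2)
        if (d <= match_dist_div) { used[s] <- TRUE; hit <- TRUE; break }
      }
      if (hit) n_drec <- n_drec + 1L
    }
  }
  list(link_recovery = if (n_links) n_rec / n_links else NA_real_,
       n_links = n_links, n_links_recovered = n_rec,
       division_recall = if (nrow(tdiv)) n_drec / nrow(tdiv) else NA_real_,
       n_divisions = nrow(tdiv), n_divisions_recovered = n_drec,
       n_false_divisions = sum(!used))
}

#' Write tracks to CSV
#'
#' @param tracking A [track_movie()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracking, path) {
  df <- tracking$tracks[, c("frame", "track_id", "parent_id", "x_px",
                            "y_px", "intensity", "area")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize the lineage forest to JSON
#'
#' @param tracking A [track_movie()] result.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
lineage_to_json <- function(tracking, path = NULL) {
  trk <- tracking$tracks
  ids <- unique(trk$track_id)
  forest <- lapply(ids, function(id) {
    rows <- trk[trk$track_id == id, ]
    list(track_id = id, parent_id = rows$parent_id[1],
         start_frame = min(rows$frame), end_frame = max(rows$frame),
         n_obs = nrow(rows))
  })
  js <- jsonlite::toJSON(forest, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
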