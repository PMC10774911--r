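# Frame-to-frame bubble tracking: constant-velocity Kalman prediction with
# globally optimal gated assignment per frame, plus the overlapping-trace
# correction that repairs tracks wrongly truncated when two PSFs merge for
# one frame.

#' Tracker configuration
#'
#' @param gate Association gate radius in um (default 150).
#' @param q_pos,q_vel Process noise standard deviations for position
#'   (um/frame^2 random walk on velocity) and velocity (default 5, 10).
#' @param r_meas Measurement noise standard deviation in um (default 15).
#' @param max_coast Frames a track may survive without a detection
#'   (default 2).
#' @param min_length Minimum number of samples for a track to be reported
#'   (default 3).
#' @param weight_gain Assignment-cost penalty in um per unit difference
#'   between a detection's weight (intensity mass) and the track's running
#'   weight (default 1500). Bubble intensity persists along a track, so
#'   this second parameter disambiguates neighbors when the per-frame
#'   displacement exceeds the bubble spacing (fast macrovessel flow);
#'   set 0 for purely positional association.
#' @param gate_locked Gate radius in um once a track has at least two
#'   samples and its velocity estimate has locked in (default `gate`).
#'   Fast-flow scenes use a wide birth gate with a tight locked gate:
#'   aliased birth associations then fail to extend and are dropped by
#'   `min_length`.
#' @return A `tracker_config` object.
#' @export
tracker_config <- function(gate = 150, q_pos = 5, q_vel = 10, r_meas = 15,
                           max_coast = 2L, min_length = 3L,
                           weight_gain = 1500, gate_locked = NULL) {
  stopifnot(gate > 0, weight_gain >= 0)
  if (is.null(gate_locked)) gate_locked <- gate
  structure(list(gate = gate, q_pos = q_pos, q_vel = q_vel, r_meas = r_meas,
                 max_coast = as.integer(max_coast),
                 min_length = as.integer(min_length),
                 weight_gain = weight_gain, gate_locked = gate_locked),
            class = "tracker_config")
}

# constant-velocity Kalman update for one track state
# state: x = (depth, lateral, v_depth, v_lateral); P 4x4
kalman_predict <- function(st, config) {
  F4 <- diag(4); F4[1, 3] <- 1; F4[2, 4] <- 1
  Q <- diag(c(config$q_pos^2, config$q_pos^2, config$q_vel^2,
              config$q_vel^2))
  list(x = as.numeric(F4 %*% st$x), P = F4 %*% st$P %*% t(F4) + Q)
}

kalman_correct <- function(st, z, config) {
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(config$r_meas^2, 2)
  S <- H %*% st$P %*% t(H) + R
  K <- st$P %*% t(H) %*% solve(S)
  x <- st$x + as.numeric(K %*% (z - st$x[1:2]))
  P <- (diag(4) - K %*% H) %*% st$P
  list(x = x, P = P)
}

#' Build tracks from per-frame detections
#'
#' Constant-velocity Kalman filtering with globally optimal (Hungarian)
#' gated assignment per frame. Unmatched detections open new tracks;
#' tracks coast up to `max_coast` frames and then terminate.
#'
#' @param detections Tibble with `frame`, `depth_um`, `lateral_um`.
#' @param config A [tracker_config()].
#' @return A tibble of class `ulm_tracks`: `track`, `frame`, `depth_um`,
#'   `lateral_um`, `interpolated` (logical), `status` (`active`,
#'   `terminated`, `corrected`).
#' @export
build_tracks <- function(detections, config = tracker_config()) {
  empty <- tibble::tibble(track = integer(), frame = integer(),
                          depth_um = numeric(), lateral_um = numeric(),
                          interpolated = logical(), status = character())
  class(empty) <- c("ulm_tracks", class(empty))
  if (nrow(detections) == 0) return(empty)
  wcol <- intersect(c("weight", "intensity"), names(detections))[1]
  frames <- sort(unique(detections$frame))
  active <- list()   # each: id, st, w, coast, samples (list of c(frame, d, l))
  done <- list()
  next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    wdet <- if (!is.na(wcol)) det[[wcol]] else NULL
    # predict all active tracks
    preds <- lapply(active, function(tr) kalman_predict(tr$st, config))
    if (length(active) && nrow(det)) {
      P <- do.call(rbind, lapply(preds, function(p) p$x[1:2]))
      D <- sqrt(outer(P[, 1], det$depth_um, `-`)^2 +
                  outer(P[, 2], det$lateral_um, `-`)^2)
      locked <- vapply(active, function(tr) length(tr$samples) >= 2L,
                       logical(1))
      # at birth the distance carries little information (any candidate in
      # the wide gate is kinematically possible), so weight similarity
      # dominates and distance only tie-breaks
      cost <- D * ifelse(locked, 1, 0.05)
      if (!is.null(wdet) && config$weight_gain > 0) {
        wtrk <- vapply(active, function(tr) tr$w, numeric(1))
        cost <- cost + config$weight_gain * abs(outer(wtrk, wdet, `-`))
      }
      gates <- ifelse(locked, config$gate_locked, config$gate)
      cost[D > gates] <- BIG_COST
      m <- assign_with_unmatch(cost, unmatch_row = gates,
                               unmatch_col = rep(config$gate, nrow(det)))
    } else {
      m <- tibble::tibble(row = integer(), col = integer())
    }
    new_active <- list()
    for (i in seq_along(active)) {
      tr <- active[[i]]
      hit <- m$col[m$row == i]
      if (length(hit)) {
        z <- c(det$depth_um[hit], det$lateral_um[hit])
        tr$st <- kalman_correct(preds[[i]], z, config)
        tr$coast <- 0L
        if (!is.null(wdet)) tr$w <- 0.7 * tr$w + 0.3 * wdet[hit]
        tr$samples[[length(tr$samples) + 1L]] <- c(f, z)
        new_active[[length(new_active) + 1L]] <- tr
      } else {
        tr$st <- preds[[i]]
        tr$coast <- tr$coast + 1L
        # a single-sample track has no velocity lock: if its bubble is not
        # re-detected immediately, the candidate was spurious
        if (tr$coast > config$max_coast || length(tr$samples) < 2L)
          done[[length(done) + 1L]] <- tr
        else new_active[[length(new_active) + 1L]] <- tr
      }
    }
    # unmatched detections start tracks
    for (j in setdiff(seq_len(nrow(det)), m$col)) {
      z <- c(det$depth_um[j], det$lateral_um[j])
      st <- list(x = c(z, 0, 0),
                 P = diag(c(config$r_meas^2, config$r_meas^2,
                            (config$gate / 2)^2, (config$gate / 2)^2)))
      new_active[[length(new_active) + 1L]] <-
        list(id = next_id, st = st,
             w = if (!is.null(wdet)) wdet[j] else 0,
             coast = 0L, samples = list(c(f, z)))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  done <- c(done, active)
  rows <- purrr::map_dfr(done, function(tr) {
    s <- do.call(rbind, tr$samples)
    tibble::tibble(track = tr$id, frame = as.integer(s[, 1]),
                   depth_um = s[, 2], lateral_um = s[, 3],
                   interpolated = FALSE, status = "active")
  })
  if (nrow(rows) == 0) return(empty)
  keep <- rows |>
    dplyr::count(.data$track) |>
    dplyr::filter(.data$n >= config$min_length) |>
    dplyr::pull(.data$track)
  out <- rows |>
    dplyr::filter(.data$track %in% keep) |>
    dplyr::arrange(.data$track, .data$frame)
  class(out) <- c("ulm_tracks", class(out))
  out
}

# constant-velocity extrapolation of a track to frame f from its samples
# strictly before f (needs >= 2 samples; else NULL)
cv_predict_at <- function(s, f) {
  s <- s[s$frame < f, , drop = FALSE]
  n <- nrow(s)
  if (n < 2) return(NULL)
  dt <- s$frame[n] - s$frame[n - 1]
  v <- c(s$depth_um[n] - s$depth_um[n - 1],
         s$lateral_um[n] - s$lateral_um[n - 1]) / dt
  c(s$depth_um[n], s$lateral_um[n]) + v * (f - s$frame[n])
}

#' Tag detections with the raw-frame amplitude at their centers
#'
#' Replaces (or adds) the `weight` column with the bilinearly interpolated
#' native-frame intensity at each detected center. Network likelihood maps
#' are intensity-blind by construction (training references peak at 1 for
#' every bubble), so this restores the per-bubble intensity cue that the
#' multi-parameter tracker uses to disambiguate neighbors.
#'
#' @param detections Detection tibble for one frame.
#' @param frame Native-resolution image the detections came from.
#' @param grid An [grid_spec()].
#' @return The detections with `weight` set to the frame amplitude.
#' @export
annotate_intensity <- function(detections, frame, grid = grid_spec()) {
  if (nrow(detections) == 0) return(detections)
  ri <- detections$depth_um / grid$native_pixel + 0.5
  ci <- detections$lateral_um / grid$native_pixel + 0.5
  detections$weight <- bilinear_at(frame, ri, ci)
  detections
}

#' Filter tracks by constant-velocity straightness
#'
#' Drops tracks whose RMS residual from a constant-velocity (linear in
#' time) fit exceeds `resid_max`. In straight-vessel scenes real bubbles
#' move at constant velocity to within localization noise, while chains of
#' mis-associated detections wander; the residual separates the two
#' regardless of speed.
#'
#' @param tracks `ulm_tracks` tibble.
#' @param resid_max Maximum RMS residual in um (default 30).
#' @return Filtered `ulm_tracks` tibble.
#' @export
filter_straight_tracks <- function(tracks, resid_max = 30) {
  if (nrow(tracks) == 0) return(tracks)
  keep <- tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::summarize(rms = {
      if (dplyr::n() < 3) 0 else {
        rd <- stats::lm.fit(cbind(1, .data$frame),
                            cbind(.data$depth_um, .data$lateral_um))$residuals
        sqrt(mean(rd^2) * 2)
      }
    }) |>
    dplyr::filter(.data$rms <= resid_max) |>
    dplyr::pull(.data$track)
  out <- tracks[tracks$track %in% keep, , drop = FALSE]
  class(out) <- class(tracks)
  out
}

#' Correct tracks truncated by overlapping traces
#'
#' An overlap event is a frame where one detection lies within the gate of
#' two or more tracks' predicted positions. Both tracks skip that frame;
#' each track that re-acquires a candidate at the following frame has the
#' skipped position filled by piecewise-cubic interpolation of each
#' coordinate against time (flagged `interpolated`); a track with no
#' candidate at the following frame is terminated before the event.
#'
#' @param tracks `ulm_tracks` tibble from [build_tracks()].
#' @param detections The original detection tibble.
#' @param config A [tracker_config()].
#' @return Corrected `ulm_tracks` tibble.
#' @export
correct_overlaps <- function(tracks, detections, config = tracker_config()) {
  if (nrow(tracks) == 0) return(tracks)
  ids <- unique(tracks$track)
  tl <- lapply(ids, function(id)
    tracks[tracks$track == id, , drop = FALSE])
  names(tl) <- as.character(ids)
  frames <- sort(unique(tracks$frame))
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    if (!nrow(det)) next
    # predicted positions of tracks that are alive around f
    preds <- list()
    for (id in names(tl)) {
      s <- tl[[id]]
      # include tracks that ended just before f: a merged trace at f looks
      # like a premature termination of the slower track
      if (f <= min(s$frame) || f > max(s$frame) + 1L + config$max_coast) next
      p <- cv_predict_at(s, f)
      if (!is.null(p)) preds[[id]] <- p
    }
    if (length(preds) < 2) next
    Pm <- do.call(rbind, preds)
    for (j in seq_len(nrow(det))) {
      dists <- sqrt((Pm[, 1] - det$depth_um[j])^2 +
                      (Pm[, 2] - det$lateral_um[j])^2)
      claim <- which(dists <= config$gate)
      if (length(claim) < 2) next
      # a genuine merged-trace event: the detection is the frame-f sample of
      # at least one claiming track, while another claimant has no sample of
      # its own at f (its trace merged into this detection)
      own <- vapply(claim, function(ci) {
        s <- tl[[rownames(Pm)[ci]]]
        r <- s[s$frame == f, , drop = FALSE]
        nrow(r) > 0 &&
          abs(r$depth_um[1] - det$depth_um[j]) < 1e-6 &&
          abs(r$lateral_um[1] - det$lateral_um[j]) < 1e-6
      }, logical(1))
      absent <- vapply(claim, function(ci) {
        !f %in% tl[[rownames(Pm)[ci]]]$frame
      }, logical(1))
      if (!any(own) || !any(absent)) next
      for (ci in claim[own | absent]) {
        id <- rownames(Pm)[ci]
        s <- tl[[id]]
        s <- s[s$frame != f, , drop = FALSE]  # skip the merged detection
        # re-acquire at f + 1: keep the track only if it has a sample there
        # (or a detection near its prediction at f + 1)
        has_next <- (f + 1) %in% s$frame
        if (!has_next) {
          p4 <- cv_predict_at(s, f + 1)
          dn <- detections[detections$frame == f + 1, , drop = FALSE]
          if (!is.null(p4) && nrow(dn)) {
            dd <- sqrt((dn$depth_um - p4[1])^2 + (dn$lateral_um - p4[2])^2)
            jn <- which.min(dd)
            if (dd[jn] <= config$gate) {
              s <- dplyr::bind_rows(s, tibble::tibble(
                track = s$track[1], frame = f + 1L,
                depth_um = dn$depth_um[jn], lateral_um = dn$lateral_um[jn],
                interpolated = FALSE, status = s$status[1]))
              s <- dplyr::arrange(s, .data$frame)
              has_next <- TRUE
            }
          }
        }
        if (has_next) {
          # fill frame f by per-coordinate piecewise-cubic interpolation
          if (nrow(s) >= 2 && f > min(s$frame) && f < max(s$frame)) {
            dep <- stats::spline(s$frame, s$depth_um, xout = f,
                                 method = "natural")$y
            lat <- stats::spline(s$frame, s$lateral_um, xout = f,
                                 method = "natural")$y
            s <- dplyr::bind_rows(s, tibble::tibble(
              track = s$track[1], frame = f, depth_um = dep,
              lateral_um = lat, interpolated = TRUE,
              status = "corrected"))
            s <- dplyr::arrange(s, .data$frame)
            s$status <- "corrected"
          }
        } else {
          # no candidate after the event: terminate before it
          s <- s[s$frame < f, , drop = FALSE]
          if (nrow(s)) s$status <- "terminated"
        }
        tl[[id]] <- s
      }
    }
  }
  out <- dplyr::bind_rows(tl)
  out <- out[!duplicated(out[, c("track", "frame")]), , drop = FALSE]
  out <- dplyr::arrange(out, .data$track, .data$frame)
  class(out) <- c("ulm_tracks", class(out))
  out
}

#' Per-sample track speeds
#'
#' Speeds from central differences of track positions times the frame
#' rate. Only differences over consecutive frames measure velocity (spans
#' bridging coasted gaps are discarded), and samples violating the
#' steady-flow consistency bound `accel_max` (change of the per-frame
#' velocity vector between adjacent steps, in um/frame) are discarded:
#' mis-associated chains produce erratic velocities while real bubbles in
#' straight vessels move at constant velocity to within localization
#' noise.
#'
#' @param tracks `ulm_tracks` tibble.
#' @param grid An [grid_spec()] (frame interval).
#' @param accel_max Maximum velocity change between adjacent steps in
#'   um/frame (default `Inf`; vessel studies use ~150).
#' @return Tibble with `track`, `frame`, `depth_um`, `lateral_um`,
#'   `speed_um_s`.
#' @export
track_speeds <- function(tracks, grid = grid_spec(), accel_max = Inf) {
  tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      speed_um_s = {
        n <- dplyr::n()
        if (n < 2) NA_real_ else {
          d <- .data$depth_um; l <- .data$lateral_um; fr <- .data$frame
          i_p <- pmax(seq_len(n) - 1L, 1L)
          i_n <- pmin(seq_len(n) + 1L, n)
          sp <- sqrt((d[i_n] - d[i_p])^2 + (l[i_n] - l[i_p])^2) /
            ((fr[i_n] - fr[i_p]) * grid$frame_interval)
          sp[(fr[i_n] - fr[i_p]) > (i_n - i_p)] <- NA_real_
          if (is.finite(accel_max) && n >= 3) {
            # per-step velocity vectors (um/frame) on consecutive frames
            vd <- diff(d) / diff(fr)
            vl <- diff(l) / diff(fr)
            dv <- sqrt(diff(vd)^2 + diff(vl)^2)   # at samples 2..n-1
            gap <- diff(fr) != 1L                 # per step, length n-1
            both_consec <- !gap[seq_len(n - 2)] & !gap[2:(n - 1)]
            bad_step <- dv > accel_max & both_consec
            bad <- c(FALSE, bad_step, FALSE)
            # a violating kink invalidates the sample at the kink and its
            # neighbors (their central differences straddle it)
            bad <- bad | c(bad[-1], FALSE) | c(FALSE, bad[-n])
            sp[bad] <- NA_real_
          }
          sp
        }
      }) |>
    dplyr::ungroup()
}
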