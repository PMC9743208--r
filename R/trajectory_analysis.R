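# Trajectory classification: per-frame (Z, d, phi) traces for recognition
# regions, separation of 3D and 1D diffusion by an axis-distance cutoff
# (R_c = 32 A), groove tracking vs hopping by comparison against the linear
# major-groove relation phi(Z) with a 1.5 bp tolerance, noise-smoothing
# rules (hops spanning < 1 bp are counted as groove tracking; groove
# tracking shorter than 0.5 ns is counted as hopping), flip detection for
# dimeric binders, and event statistics.

.R_CUTOFF <- 32 # A; frames with d > R_c are 3D diffusion

#' Groove calibration of a DNA model
#'
#' Returns the linear relation `phi_groove(Z) = slope * Z + phase0` that
#' locates the major-groove center along the duplex. For straight DNA the
#' calibration is fitted from the phosphate-bead geometry: the groove
#' azimuth per base pair is the bisector of the two backbone azimuths on
#' the major-groove side, and a least-squares line of the unwrapped
#' azimuth against Z gives slope and phase. The fit must agree with the
#' ideal relation `slope = 2 pi / (repeat x rise)` for generator DNA.
#'
#' @param dna a `dna_model` or a DNA `cg_topology`
#' @param repeat_bp,rise fallbacks used to report the helical repeat when
#'   fitting from a bare topology
#' @return list with `slope` (rad/A), `phase0` (rad at Z = 0),
#'   `repeat_bp`, `rise`
#' @export
calibrate_groove <- function(dna, repeat_bp = .HELICAL_REPEAT,
                             rise = .BP_RISE) {
  topo <- if (inherits(dna, "dna_model")) coarse_grain_dna(dna$atoms)
          else dna
  b <- topo$beads
  ph <- b[b$role == "phosphate", , drop = FALSE]
  if (nrow(ph) < 4) stop("too few phosphate beads to calibrate the groove")
  chains <- sort(unique(ph$chain_id))
  if (length(chains) != 2) stop("groove calibration needs a two-strand duplex")
  a <- ph[ph$chain_id == chains[1], , drop = FALSE]
  bb <- ph[ph$chain_id == chains[2], , drop = FALSE]
  # pair phosphates of the two strands by height
  jj <- vapply(a$z, function(z) which.min(abs(bb$z - z)), integer(1))
  ok <- abs(bb$z[jj] - a$z) < rise / 2
  a <- a[ok, , drop = FALSE]; b2 <- bb[jj[ok], , drop = FALSE]
  az_a <- atan2(a$x, a$y)
  az_b <- atan2(b2$x, b2$y)
  # bisector on the wider (major-groove) side: the negative mean direction
  mx <- sin(az_a) + sin(az_b)
  my <- cos(az_a) + cos(az_b)
  center <- atan2(-mx, -my)
  ordz <- order(a$z)
  z <- a$z[ordz]
  cu <- .unwrap_angle(center[ordz])
  fit <- lsfit(z, cu)
  slope <- fit$coefficients[2]
  phase0 <- .wrap_angle(fit$coefficients[1])
  list(slope = unname(slope), phase0 = unname(phase0),
       repeat_bp = unname(2 * pi / (slope * rise)), rise = rise)
}

# unwrap a wrapped angle series to a continuous one
.unwrap_angle <- function(a) {
  if (length(a) < 2) return(a)
  d <- .wrap_angle(diff(a))
  cumsum(c(a[1], d))
}

#' Compute the (Z, d, phi) helix trace of recognition regions
#'
#' For each recognition region (a set of bead indices) and each frame, the
#' region's center of mass is reduced to its projection `Z` on the DNA
#' axis (the Z axis), its distance `d` from the axis, and the rotational
#' angle `phi` between the COM's (x, y) vector and the reference vector
#' (0, 1), signed by the x component (`phi = atan2(x, y)`). A continuous
#' unwrapped copy of phi is retained for rotational MSD analysis. A frame
#' whose COM lies on the axis (d = 0) has undefined phi and is excluded
#' from the groove test.
#'
#' @param trajectory a `cg_trajectory`
#' @param recognition_bead_sets list of integer vectors of bead indices,
#'   one per recognition region
#' @param groove groove calibration (list with `slope`, `phase0`,
#'   `repeat_bp`, `rise`), e.g. from [calibrate_groove()] or a generated
#'   `dna_model`'s `$groove`
#' @param R_c 3D cutoff distance from the axis, Angstrom (default 32)
#' @return object of class `helix_trace`
#' @export
compute_helix_trace <- function(trajectory, recognition_bead_sets, groove,
                                R_c = .R_CUTOFF) {
  if (!length(recognition_bead_sets))
    stop("recognition_bead_sets must name at least one region")
  if (any(vapply(recognition_bead_sets, length, integer(1)) == 0))
    stop("empty recognition region bead set")
  nf <- trajectory$n_frames
  frame_us <- trajectory$frame_ns * 1e-3
  out <- vector("list", length(recognition_bead_sets))
  for (r in seq_along(recognition_bead_sets)) {
    sel <- recognition_bead_sets[[r]]
    com <- t(vapply(seq_len(nf), function(fr) {
      sub <- trajectory$frames[sel, , fr, drop = FALSE]
      colMeans(matrix(sub, ncol = 3))
    }, numeric(3)))
    d <- sqrt(com[, 1]^2 + com[, 2]^2)
    phi <- ifelse(d > 0, atan2(com[, 1], com[, 2]), NA_real_)
    out[[r]] <- data.frame(
      region = r, frame = seq_len(nf), time_us = (seq_len(nf) - 1) * frame_us,
      Z = com[, 3], d = d, phi = phi,
      phi_unwrapped = .unwrap_angle(ifelse(is.na(phi), 0, phi))
    )
  }
  structure(list(frames = do.call(rbind, out), groove = groove,
                 frame_ns = trajectory$frame_ns, R_c = R_c,
                 n_regions = length(recognition_bead_sets)),
            class = "helix_trace")
}

.trace_region <- function(trace, region) {
  fr <- trace$frames[trace$frames$region == region, , drop = FALSE]
  if (!nrow(fr)) stop("trace has no region ", region)
  fr[order(fr$frame), , drop = FALSE]
}

#' Classify each frame as 1D or 3D diffusion
#'
#' A frame is 3D iff the recognition region's distance from the DNA axis
#' exceeds `R_c` (closed threshold: `d = R_c` exactly is 1D).
#'
#' @param trace a `helix_trace`
#' @param region region id (default 1)
#' @return character vector, `"1D"` or `"3D"` per frame
#' @export
classify_1d_3d <- function(trace, region = 1) {
  fr <- .trace_region(trace, region)
  ifelse(fr$d > trace$R_c, "3D", "1D")
}

# deviation (in bp) of each frame's phi from the groove-center relation
.groove_deviation_bp <- function(fr, groove) {
  dev <- .wrap_angle(fr$phi - (groove$slope * fr$Z + groove$phase0))
  dev / (2 * pi / groove$repeat_bp)
}

# contiguous runs of a logical/label vector -> data.frame(start, end, value)
.runs <- function(v) {
  r <- rle(v)
  end <- cumsum(r$lengths)
  data.frame(start = c(1L, head(end, -1) + 1L), end = end,
             value = r$values, stringsAsFactors = FALSE)
}

#' Segment a helix trace into groove-tracking and hopping events
#'
#' Within 1D intervals of at least `min_1d_ns`, frames within
#' `groove_tol_bp` of the major-groove center are groove tracking and the
#' remaining 1D frames are hopping. Two smoothing rules then remove noise
#' events, iterated to a fixed point: hopping events spanning less than
#' `min_hop_span_bp` are counted as parts of groove tracking, and groove
#' tracking lasting less than `min_groove_ns` is counted as hopping.
#' A hop's span is Z at reattachment minus Z at detachment (the signed
#' value is stored; magnitudes are reported in the statistics).
#'
#' @param trace a `helix_trace` with groove calibration
#' @param region region id (default 1)
#' @param groove_tol_bp groove-tracking tolerance, bp (default 1.5)
#' @param min_1d_ns minimum 1D interval used for classification, ns
#'   (default 5, i.e. 100 MD steps at 50 ps/step; applied on the saved
#'   frame clock, so intervals shorter than one frame never qualify)
#' @param min_hop_span_bp hops below this span merge into groove (default 1)
#' @param min_groove_ns groove events below this duration become hops
#'   (default 0.5)
#' @return list with `events` (data frame: `region`, `type`, `start_frame`,
#'   `end_frame`, `start_us`, `end_us`, `duration_us`, `span_bp`),
#'   `labels` (per-frame `"3D"`/`"groove"`/`"hop"`), and `qualifying`
#'   (logical per frame: part of a used 1D interval)
#' @export
segment_events <- function(trace, region = 1, groove_tol_bp = 1.5,
                           min_1d_ns = 5, min_hop_span_bp = 1,
                           min_groove_ns = 0.5) {
  if (is.null(trace$groove)) stop("trace has no groove calibration")
  fr <- .trace_region(trace, region)
  nf <- nrow(fr)
  frame_us <- if (nf > 1) diff(fr$time_us[1:2]) else trace$frame_ns * 1e-3
  is3d <- fr$d > trace$R_c
  dev <- .groove_deviation_bp(fr, trace$groove)
  on_groove <- !is.na(dev) & abs(dev) <= groove_tol_bp & !is.na(fr$phi)
  labels <- ifelse(is3d, "3D", ifelse(on_groove, "groove", "hop"))

  # qualifying 1D intervals
  qual <- rep(FALSE, nf)
  runs1d <- .runs(!is3d)
  min_frames <- max(1, ceiling(min_1d_ns / (frame_us * 1e3)))
  for (rr in seq_len(nrow(runs1d))) {
    if (runs1d$value[rr] && (runs1d$end[rr] - runs1d$start[rr] + 1) >= min_frames)
      qual[runs1d$start[rr]:runs1d$end[rr]] <- TRUE
  }

  span_of <- function(s, e) {
    # reattachment minus detachment: reference the frame preceding the event
    z0 <- if (s > 1 && !is3d[s - 1]) fr$Z[s - 1] else fr$Z[s]
    (fr$Z[e] - z0) / trace$groove$rise
  }

  # smoothing within each qualifying interval, iterated to a fixed point
  for (rr in which(runs1d$value &
                   (runs1d$end - runs1d$start + 1) >= min_frames)) {
    idx <- runs1d$start[rr]:runs1d$end[rr]
    lab <- labels[idx]
    for (iter in 1:100) {
      before <- lab
      ev <- .runs(lab)
      # rule 1: hops spanning < min_hop_span_bp become groove tracking
      for (m in seq_len(nrow(ev))) {
        if (ev$value[m] == "hop") {
          s <- idx[ev$start[m]]; e <- idx[ev$end[m]]
          if (abs(span_of(s, e)) < min_hop_span_bp)
            lab[ev$start[m]:ev$end[m]] <- "groove"
        }
      }
      ev <- .runs(lab)
      # rule 2: groove tracking shorter than min_groove_ns becomes hopping
      for (m in seq_len(nrow(ev))) {
        if (ev$value[m] == "groove") {
          dur_ns <- (ev$end[m] - ev$start[m] + 1) * frame_us * 1e3
          if (dur_ns < min_groove_ns) lab[ev$start[m]:ev$end[m]] <- "hop"
        }
      }
      if (identical(lab, before)) break
    }
    labels[idx] <- lab
  }

  ev_out <- NULL
  for (rr in which(runs1d$value &
                   (runs1d$end - runs1d$start + 1) >= min_frames)) {
    idx <- runs1d$start[rr]:runs1d$end[rr]
    ev <- .runs(labels[idx])
    for (m in seq_len(nrow(ev))) {
      s <- idx[ev$start[m]]; e <- idx[ev$end[m]]
      ev_out <- rbind(ev_out, data.frame(
        region = region, type = ev$value[m], start_frame = s, end_frame = e,
        start_us = fr$time_us[s], end_us = fr$time_us[e] + frame_us,
        duration_us = (e - s + 1) * frame_us,
        span_bp = span_of(s, e), stringsAsFactors = FALSE))
    }
  }
  if (is.null(ev_out))
    ev_out <- data.frame(region = integer(), type = character(),
                         start_frame = integer(), end_frame = integer(),
                         start_us = numeric(), end_us = numeric(),
                         duration_us = numeric(), span_bp = numeric())
  list(events = ev_out, labels = labels, qualifying = qual)
}

#' Detect flips of a dimeric binder
#'
#' A flip is recorded when the Z-order of the two recognition-region COMs
#' inverts and the inverted order persists for at least `debounce_frames`
#' frames (shorter inversions are treated as noise).
#'
#' @param trace a two-region `helix_trace`
#' @param debounce_frames persistence requirement, frames (default 10)
#' @return numeric vector of flip times in microseconds (empty, with a
#'   message, for a monomeric trace)
#' @export
detect_flips <- function(trace, debounce_frames = 10) {
  if (trace$n_regions < 2) {
    message("flip detection needs a dimeric (two-region) trace; none detected")
    return(numeric(0))
  }
  f1 <- .trace_region(trace, 1)
  f2 <- .trace_region(trace, 2)
  s <- sign(f1$Z - f2$Z)
  s[s == 0] <- NA
  nf <- length(s)
  flips <- numeric(0)
  cur <- s[which(!is.na(s))[1]]
  t <- 1
  while (t <= nf) {
    if (!is.na(s[t]) && s[t] != cur) {
      upto <- min(nf, t + debounce_frames - 1)
      window <- s[t:upto]
      if (sum(!is.na(window) & window == s[t]) == debounce_frames) {
        flips <- c(flips, f1$time_us[t])
        cur <- s[t]
        t <- upto + 1
        next
      }
    }
    t <- t + 1
  }
  flips
}

#' Aggregate event statistics
#'
#' Mean and standard deviation of durations and spans per event type, the
#' hopping frequency `k_hop` (hops per millisecond of 1D diffusion time),
#' the same frequency normalized by total trace time, and the frequency of
#' long hops (span above `long_hop_bp`).
#'
#' @param events event data frame from [segment_events()] (its `events`
#'   element)
#' @param total_time_us total trace duration, microseconds (used for the
#'   total-time-normalized frequency; optional)
#' @param long_hop_bp span threshold for the long-hop count (default 5:
#'   hops longer than five base pairs)
#' @return object of class `event_stats`: list with per-type `n`,
#'   `mean_duration_us`, `sd_duration_us`, `mean_span_bp`, `sd_span_bp`,
#'   plus `time_1d_us`, `k_hop_per_ms`, `k_hop_total_per_ms`,
#'   `long_hop_per_ms` (fields are `NA` when no event of a type exists)
#' @export
event_statistics <- function(events, total_time_us = NULL, long_hop_bp = 5) {
  per_type <- function(tp) {
    e <- events[events$type == tp, , drop = FALSE]
    if (!nrow(e))
      return(list(n = 0L, mean_duration_us = NA_real_,
                  sd_duration_us = NA_real_, mean_span_bp = NA_real_,
                  sd_span_bp = NA_real_))
    list(n = nrow(e),
         mean_duration_us = mean(e$duration_us),
         sd_duration_us = if (nrow(e) > 1) sd(e$duration_us) else NA_real_,
         mean_span_bp = mean(abs(e$span_bp)),
         sd_span_bp = if (nrow(e) > 1) sd(abs(e$span_bp)) else NA_real_)
  }
  time_1d_us <- sum(events$duration_us)
  n_hop <- sum(events$type == "hop")
  n_long <- sum(events$type == "hop" & abs(events$span_bp) > long_hop_bp)
  k_hop <- if (time_1d_us > 0) n_hop / (time_1d_us * 1e-3) else NA_real_
  if (time_1d_us <= 0 && n_hop == 0) k_hop <- NA_real_
  structure(list(
    groove = per_type("groove"), hop = per_type("hop"),
    time_1d_us = time_1d_us,
    k_hop_per_ms = k_hop,
    k_hop_total_per_ms = if (!is.null(total_time_us) && total_time_us > 0)
      n_hop / (total_time_us * 1e-3) else NA_real_,
    long_hop_per_ms = if (time_1d_us > 0) n_long / (time_1d_us * 1e-3)
      else NA_real_
  ), class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat("event_stats:\n")
  cat(sprintf("  groove: n=%d, duration %.3g +/- %.3g us, span %.3g +/- %.3g bp\n",
              x$groove$n, x$groove$mean_duration_us, x$groove$sd_duration_us,
              x$groove$mean_span_bp, x$groove$sd_span_bp))
  cat(sprintf("  hop:    n=%d, duration %.3g +/- %.3g us, span %.3g +/- %.3g bp\n",
              x$hop$n, x$hop$mean_duration_us, x$hop$sd_duration_us,
              x$hop$mean_span_bp, x$hop$sd_span_bp))
  cat(sprintf("  k_hop = %.3g /ms (1D time %.3g us), long hops %.3g /ms\n",
              x$k_hop_per_ms, x$time_1d_us, x$long_hop_per_ms))
  invisible(x)
}
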