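# Hand-constructed (Z, d, phi) traces with known labels. These are the
# ground-truth fixtures for the event classifier: groove segments obey the
# linear phi(Z) groove relation (plus optional sub-tolerance noise), hop
# segments advance Z with the rotation decoupled from the groove relation,
# and 3D segments sit beyond the axis-distance cutoff.

#' Describe one segment of an oracle trace plan
#'
#' @param type `"groove"`, `"hop"` or `"threeD"`
#' @param duration_us segment duration in microseconds
#' @param span_bp base pairs traversed along Z during the segment
#'   (ignored for `"threeD"`)
#' @param d distance from the DNA axis during the segment, Angstrom;
#'   defaults: 20 (groove), 28 (hop), 50 (threeD)
#' @return a list describing the segment
#' @export
oracle_segment <- function(type = c("groove", "hop", "threeD"),
                           duration_us, span_bp = 0, d = NULL) {
  type <- match.arg(type)
  if (duration_us <= 0) stop("duration_us must be positive")
  if (is.null(d)) d <- switch(type, groove = 20, hop = 28, threeD = 50)
  list(type = type, duration_us = duration_us, span_bp = span_bp, d = d)
}

#' Generate an oracle (Z, d, phi) trace with known event labels
#'
#' Builds a single-region helix trace by concatenating the planned
#' segments. Groove frames satisfy `phi = slope * Z + phase0` to within the
#' added noise; hop frames carry a half-turn rotational offset from the
#' groove relation (decoupled rotation) while Z advances by the planned
#' span; 3D frames lie beyond the `R_c` cutoff. With `regions = 2` a
#' second recognition region is emitted at `-region_offset_bp` base pairs
#' from the first, and the Z-order of the two regions inverts at each time
#' in `flip_times_us`.
#'
#' @param plan list of [oracle_segment()]s tiling the time axis
#' @param groove groove calibration: list with `slope` (rad/A), `phase0`,
#'   `repeat_bp`, `rise`; default the ideal B-DNA calibration
#' @param frame_ns frame spacing in nanoseconds (default 50)
#' @param noise_bp standard deviation, in base pairs, of the rotational
#'   noise added to groove frames (default 0: noise-free)
#' @param seed RNG seed for the noise
#' @param regions 1 or 2 recognition regions
#' @param region_offset_bp Z offset of region 2 from region 1, bp
#' @param flip_times_us times (microseconds) at which the two regions swap
#'   Z-order (requires `regions = 2`)
#' @param dna_length_bp available DNA length; a plan whose cumulative span
#'   exceeds it is a parameter error
#' @return object of class `helix_trace` with elements `frames`
#'   (`region`, `frame`, `time_us`, `Z`, `d`, `phi`), `groove`, `frame_ns`,
#'   `R_c`, plus oracle fields `true_labels` (per frame of region 1),
#'   `true_events` (planned segment table) and `true_flips` (times, us)
#' @export
generate_oracle_trace <- function(plan,
                                  groove = list(slope = 2 * pi / (.HELICAL_REPEAT * .BP_RISE),
                                                phase0 = 0,
                                                repeat_bp = .HELICAL_REPEAT,
                                                rise = .BP_RISE),
                                  frame_ns = 50, noise_bp = 0, seed = 1,
                                  regions = 1, region_offset_bp = 2,
                                  flip_times_us = numeric(),
                                  dna_length_bp = Inf) {
  stopifnot(length(plan) >= 1, regions %in% c(1, 2))
  spans <- vapply(plan, function(s) abs(s$span_bp), numeric(1))
  if (sum(spans) > dna_length_bp)
    stop("plan spans ", sum(spans), " bp, exceeding the DNA length of ",
         dna_length_bp, " bp")
  set.seed(as.integer(seed))
  frame_us <- frame_ns * 1e-3

  Z <- numeric(0); d <- numeric(0); phi <- numeric(0)
  lab <- character(0); seg_id <- integer(0)
  z_cur <- 0
  events <- vector("list", length(plan))
  for (s in seq_along(plan)) {
    seg <- plan[[s]]
    nf <- max(1L, round(seg$duration_us / frame_us))
    dz_total <- seg$span_bp * groove$rise
    if (seg$type == "threeD") {
      zseg <- rep(z_cur, nf)
      dseg <- rep(seg$d, nf)
      pseg <- runif(nf, -pi, pi)
      lseg <- rep("3D", nf)
    } else {
      zseg <- z_cur + dz_total * seq_len(nf) / nf
      dseg <- rep(seg$d, nf)
      on_groove <- groove$slope * zseg + groove$phase0
      if (seg$type == "groove") {
        noise <- if (noise_bp > 0)
          rnorm(nf, sd = noise_bp * 2 * pi / groove$repeat_bp) else 0
        pseg <- on_groove + noise
        lseg <- rep("groove", nf)
      } else {
        pseg <- on_groove + pi # half-turn off the groove: decoupled rotation
        lseg <- rep("hop", nf)
      }
      z_cur <- z_cur + dz_total
    }
    events[[s]] <- data.frame(type = seg$type, n_frames = nf,
                              duration_us = nf * frame_us,
                              span_bp = if (seg$type == "threeD") 0 else seg$span_bp)
    Z <- c(Z, zseg); d <- c(d, dseg); phi <- c(phi, pseg)
    lab <- c(lab, lseg); seg_id <- c(seg_id, rep(s, nf))
  }
  nfr <- length(Z)
  time_us <- (seq_len(nfr) - 1) * frame_us
  frames <- data.frame(region = 1L, frame = seq_len(nfr), time_us = time_us,
                       Z = Z, d = d, phi = .wrap_angle(phi),
                       phi_unwrapped = phi)
  if (regions == 2) {
    off <- region_offset_bp * groove$rise
    # region 2 sits below region 1 until a flip inverts the Z-order; the
    # side flips at every time in flip_times_us (parity of preceding flips)
    nflips <- vapply(time_us, function(t) sum(flip_times_us <= t), numeric(1))
    side <- ifelse(nflips %% 2 == 0, -1, 1)
    phi2 <- phi + groove$slope * (side * off)
    frames2 <- data.frame(region = 2L, frame = seq_len(nfr), time_us = time_us,
                          Z = Z + side * off, d = d,
                          phi = .wrap_angle(phi2), phi_unwrapped = phi2)
    frames <- rbind(frames, frames2)
  }
  structure(list(
    frames = frames, groove = groove, frame_ns = frame_ns, R_c = 32,
    n_regions = as.integer(regions),
    true_labels = lab, true_segments = seg_id,
    true_events = do.call(rbind, events),
    true_flips = flip_times_us
  ), class = "helix_trace")
}
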