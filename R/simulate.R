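#' Noise specification for the virtual instrument
#'
#' Background and noise model of the simulated detector chain: a constant
#' per-channel dark/background offset plus zero-mean i.i.d. Gaussian channel
#' noise. The noise amplitude is set from a target signal-to-noise ratio,
#' defined as (mean pulse peak intensity - background mean) / background
#' standard deviation on the channel sum. The instrument this emulates
#' guarantees SNR above 5 as its working floor; the default of 60 emulates
#' the bright-particle regime of a strong laser focused on micrometre-scale
#' scatterers, where individual samplings carry usable polarization
#' information. `snr = Inf` disables noise.
#'
#' @param snr target signal-to-noise ratio (> 0, may be `Inf`; default 60).
#' @param offset constant background level per channel (detector units),
#'   standing in for dark current, ambient light and water scattering.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(snr = 60, offset = 0.05) {
  stopifnot(snr > 0, offset >= 0)
  structure(list(snr = snr, offset = offset), class = "noise_spec")
}

new_channel_trace <- function(samples, sampling_rate, ground_truth, seed,
                              label = NA_character_, filtered = FALSE,
                              classes = character()) {
  colnames(samples) <- psa_channel_order()
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 ground_truth = ground_truth,
                 seed = seed,
                 label = label,
                 filtered = filtered,
                 classes = classes),
            class = "channel_trace")
}

empty_ground_truth <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf(
    "channel_trace: %d samples x 4 channels at %g kS/s (%.3g s), %d ground-truth pulses%s%s\n",
    nrow(x$samples), x$sampling_rate / 1e3,
    nrow(x$samples) / x$sampling_rate, nrow(x$ground_truth),
    if (!is.na(x$label)) sprintf(", label '%s'", x$label) else "",
    if (x$filtered) ", filtered" else ""))
  invisible(x)
}

# Synthesize the 4-channel signal of one particle transit.
# idx_len samples; Gaussian transit envelope truncated at +/-3 sigma;
# orientation phi(t) = theta0 + random walk (only for rotating classes).
# Returns an idx_len x 4 matrix of channel intensities (no background).
transit_channels <- function(particle, class, n, A, incident_state, sigma_phi,
                             flip_rate) {
  tau <- seq(-3, 3, length.out = n)
  g <- particle$brightness * exp(-tau^2 / 2)
  if (class$rotates) {
    steps <- stats::rnorm(n, 0, sigma_phi)
    if (flip_rate > 0) {
      flips <- stats::runif(n) < flip_rate
      steps[flips] <- steps[flips] + stats::runif(sum(flips), -pi, pi)
    }
    phi <- particle$theta0 + cumsum(steps)
  } else {
    phi <- rep(0, n)
  }
  # S(t) = R(-phi) M R(phi) S_in, vectorized over samples
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  S_in <- as.numeric(incident_state)
  Sr <- rbind(rep(S_in[1], n),
              c2 * S_in[2] + s2 * S_in[3],
              -s2 * S_in[2] + c2 * S_in[3],
              rep(S_in[4], n))
  W <- particle$M %*% Sr                       # 4 x n, body frame
  S_out <- rbind(W[1, ],
                 c2 * W[2, ] - s2 * W[3, ],
                 s2 * W[2, ] + c2 * W[3, ],
                 W[4, ])
  C <- unclass(A) %*% S_out                    # channels, 4 x n
  t(C * rep(g, each = 4L))
}

mean_peak_intensity <- function(classes) {
  mean(vapply(classes, function(cl) cl$brightness, numeric(1L)))
}

# Shared core: given per-event classes and start times (seconds), render the
# trace. Assumes events already non-overlapping and inside [0, duration].
render_trace <- function(events, classes, duration, sampling_rate,
                         incident_state, A, noise, sigma_phi_override, seed) {
  n_samp <- round(duration * sampling_rate)
  sigma_c <- if (is.finite(noise$snr)) {
    mean_peak_intensity(classes) * sum(unclass(A) %*% c(1, 0, 0, 0)) /
      (2 * noise$snr)  # channel-sum SNR -> per-channel sd (4 iid channels)
  } else 0
  samples <- matrix(stats::rnorm(n_samp * 4L, 0, sigma_c) + noise$offset,
                    nrow = n_samp, ncol = 4L)
  gt <- empty_ground_truth()
  if (nrow(events)) {
    events <- events[order(events$t0), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      cl <- classes[[events$class_idx[i]]]
      p <- events$particle[[i]]
      i0 <- max(0L, round((events$t0[i] - p$settling_s / 2) * sampling_rate))
      i1 <- min(n_samp, round((events$t0[i] + p$settling_s / 2) * sampling_rate))
      if (i1 - i0 < 2L) next
      if (is.null(sigma_phi_override)) {
        sp <- cl$sigma_phi
        fr <- cl$flip_rate
      } else {
        # an explicit override also governs the reorientation jumps:
        # sigma_phi = 0 freezes the orientation entirely within pulses
        sp <- sigma_phi_override
        fr <- if (sigma_phi_override > 0) cl$flip_rate else 0
      }
      ch <- transit_channels(p, cl, i1 - i0, A, events$incident[[i]], sp, fr)
      samples[(i0 + 1L):i1, ] <- samples[(i0 + 1L):i1, ] + ch
      gt <- rbind(gt, data.frame(start = i0, end = i1, label = cl$name,
                                 stringsAsFactors = FALSE))
    }
  }
  new_channel_trace(samples, sampling_rate, gt, seed,
                    classes = vapply(classes, `[[`, "", "name"))
}

# Rejection-sample event times so transit intervals never overlap and are
# separated by at least min_gap seconds of clean background: the
# single-particle operating condition, and what keeps the hysteresis
# extension of one detected pulse from running into the next.
place_events <- function(n, duration, widths, min_gap = 1e-3,
                         max_tries = 200L) {
  t0 <- numeric(0)
  w <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(1L, widths[i] / 2, duration - widths[i] / 2)
      if (!length(t0) ||
          all(abs(cand - t0) > (widths[i] + w) / 2 + min_gap)) {
        t0 <- c(t0, cand)
        w <- c(w, widths[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " non-overlapping pulses in ", duration,
           " s; lower the event rate or pulse count (single-particle ",
           "occupancy requires sparse events)")
    }
  }
  t0
}

#' Simulate a four-channel detector trace with Poisson particle transits
#'
#' Forward model of the instrument: particles of the given classes transit
#' the scattering volume as independent Poisson streams; each transit
#' scatters the incident polarization state through the particle's (possibly
#' orientation-drifting) Mueller matrix, is shaped by a peak-normalized
#' Gaussian transit envelope truncated at three envelope widths, projected to
#' four channel intensities by the instrument matrix, and superposed on a
#' noisy constant background. Transits never overlap (single-particle
#' operating condition); the expected temporal occupancy
#' `sum(rates) * mean settling time` must stay below `overlap_bound`.
#'
#' @param classes list of [particle_class] objects.
#' @param event_rates per-class transit rates (pulses/second), recycled to
#'   `length(classes)`.
#' @param duration trace duration in seconds.
#' @param incident_state incident (PSG) Stokes state; default right-circular.
#' @param A instrument matrix mapping Stokes states to channels.
#' @param noise a [noise_spec()].
#' @param sampling_rate samples per second (default 200,000).
#' @param sigma_phi optional global override of the per-class orientation
#'   drift step (radians/sample); `NULL` keeps class defaults, `0` freezes
#'   orientation within every pulse.
#' @param overlap_bound maximum allowed expected occupancy (default 0.2).
#' @param seed integer seed; identical seed and configuration give a
#'   bit-identical trace.
#' @return A `channel_trace`: list with `samples` (`T x 4` matrix),
#'   `sampling_rate`, `ground_truth` (data frame `start`, `end`, `label`,
#'   0-based half-open sample intervals), `seed`.
#' @examples
#' lib <- preset_class_library(c("DS", "CP"))
#' tr <- simulate_trace(lib, event_rates = 10, duration = 0.5, seed = 1)
#' tr
#' @export
simulate_trace <- function(classes, event_rates, duration,
                           incident_state = stokes(1, 0, 0, 1),
                           A = ideal_psa_matrix(),
                           noise = noise_spec(),
                           sampling_rate = 2e5,
                           sigma_phi = NULL,
                           overlap_bound = 0.2,
                           seed) {
  stopifnot(duration > 0, length(classes) >= 1L)
  if (missing(seed)) stop("seed is required; the simulator has no hidden randomness")
  rates <- rep_len(event_rates, length(classes))
  occ <- sum(rates) * mean(vapply(classes, function(cl) cl$settling_ms, 1) / 1e3)
  if (occ > overlap_bound) {
    stop(sprintf(paste0("expected pulse occupancy %.3f exceeds bound %.3f; ",
                        "lower the event rates to keep at most one particle ",
                        "in the scattering volume"), occ, overlap_bound))
  }
  set.seed(seed)
  counts <- stats::rpois(length(classes), rates * duration)
  build_events_and_render(classes, rep(seq_along(classes), counts), duration,
                          incident_state, A, noise, sampling_rate, sigma_phi,
                          seed)
}

build_events_and_render <- function(classes, class_idx, duration,
                                    incident_state, A, noise, sampling_rate,
                                    sigma_phi, seed) {
  n <- length(class_idx)
  if (n == 0L) {
    return(render_trace(data.frame(), classes, duration, sampling_rate,
                        incident_state, A, noise, sigma_phi, seed))
  }
  class_idx <- sample(class_idx)  # interleave classes in time
  particles <- lapply(class_idx, function(k) draw_particle(classes[[k]]))
  widths <- vapply(particles, `[[`, 0, "settling_s")
  if (sum(widths) > 0.5 * duration) {
    stop("requested pulses would fill more than half the trace; ",
         "increase duration or reduce counts")
  }
  t0 <- place_events(n, duration, widths)
  events <- data.frame(t0 = t0, class_idx = class_idx)
  events$particle <- particles
  events$incident <- rep(list(incident_state), n)
  render_trace(events, classes, duration, sampling_rate, incident_state, A,
               noise, sigma_phi, seed)
}

#' Simulate a mixed suspension with preset per-class pulse counts
#'
#' Like [simulate_trace()] but injects *exactly* the requested number of
#' pulses per class at uniformly random non-overlapping times — the in-silico
#' analog of preparing a mixture whose measured pulse count per species
#' matches a preset. The ground truth carries the preset counts.
#'
#' @inheritParams simulate_trace
#' @param counts integer vector of pulse counts, one per class (recycled).
#' @return A `channel_trace`.
#' @examples
#' lib <- preset_class_library(c("DS", "CP"))
#' tr <- simulate_mixture(lib, counts = c(5, 5), duration = 0.5, seed = 2)
#' table(tr$ground_truth$label)
#' @export
simulate_mixture <- function(classes, counts, duration,
                             incident_state = stokes(1, 0, 0, 1),
                             A = ideal_psa_matrix(),
                             noise = noise_spec(),
                             sampling_rate = 2e5,
                             sigma_phi = NULL,
                             seed) {
  stopifnot(duration > 0, all(counts >= 0))
  if (missing(seed)) stop("seed is required; the simulator has no hidden randomness")
  counts <- rep_len(counts, length(classes))
  set.seed(seed)
  build_events_and_render(classes, rep(seq_along(classes), counts), duration,
                          incident_state, A, noise, sampling_rate, sigma_phi,
                          seed)
}

#' Simulate a pure (single-class) suspension run
#'
#' Convenience wrapper around [simulate_mixture()] for the labeled
#' pure-suspension measurements used to build training data: one class,
#' exact pulse count, and the trace-level `label` set to the class name.
#'
#' @inheritParams simulate_mixture
#' @param class a single [particle_class].
#' @param n_pulses number of transits to inject.
#' @return A labeled `channel_trace`.
#' @export
simulate_pure <- function(class, n_pulses, duration, ..., seed) {
  tr <- simulate_mixture(list(class), counts = n_pulses, duration = duration,
                         ..., seed = seed)
  tr$label <- class$name
  tr
}

#' Read and write channel traces
#'
#' Two container formats, selected by the file extension: `.rds` (compact
#' binary, for large working traces) and `.tsv` (delimited text, one row per
#' sample, four channel columns). The text format carries a JSON sidecar
#' `<path>.json` with the sampling rate, channel order, seed and class
#' roster, and a ground-truth sidecar `<path>.truth.csv` with the 0-based
#' half-open pulse intervals and labels.
#'
#' @param trace a `channel_trace`.
#' @param path output path ending in `.rds` or `.tsv`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the `channel_trace`.
#' @export
write_trace <- function(trace, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(trace, path)
  } else if (ext == "tsv") {
    utils::write.table(trace$samples, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    meta <- list(sampling_rate = trace$sampling_rate,
                 channel_order = psa_channel_order(),
                 seed = trace$seed,
                 label = trace$label,
                 filtered = trace$filtered,
                 classes = trace$classes)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(trace$ground_truth, paste0(path, ".truth.csv"),
                     row.names = FALSE)
  } else {
    stop("unsupported trace extension: ", ext, " (use .rds or .tsv)")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    return(readRDS(path))
  }
  if (ext != "tsv") stop("unsupported trace extension: ", ext)
  samples <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gt_path <- paste0(path, ".truth.csv")
  gt <- if (file.exists(gt_path)) {
    utils::read.csv(gt_path, stringsAsFactors = FALSE)
  } else {
    empty_ground_truth()
  }
  if (!nrow(gt)) gt <- empty_ground_truth()
  new_channel_trace(samples, meta$sampling_rate, gt,
                    seed = meta$seed,
                    label = if (is.null(meta$label)) NA_character_ else meta$label,
                    filtered = isTRUE(meta$filtered),
                    classes = meta$classes)
}
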