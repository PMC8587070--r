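#' Zero-phase low-pass filtering of a channel trace
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter
#' independently to each channel, yielding the pulse envelope while
#' suppressing high-frequency electronic and ambient noise. The default
#' cutoff of 60 kHz sits two orders of magnitude above the ~500 Hz band of a
#' 2 ms transit envelope, so pulse shapes pass unchanged while broadband
#' noise is removed. The cutoff also sets the *temporal resolution* left to
#' dense sampling: a zero-phase low-pass averages over roughly
#' `sampling_rate / (2 * cutoff)` samples (~1.7 at the default for a
#' 200 kS/s record), and a cutoff low enough to average many samples would
#' silently collapse per-sample features onto coarse-segment features.
#' The DC level (background) is preserved.
#'
#' @param trace a `channel_trace`.
#' @param cutoff_hz cutoff frequency in Hz; must lie in `(0, Nyquist)`.
#' @param order Butterworth order (default 4).
#' @return The filtered `channel_trace` (same length, `filtered = TRUE`).
#' @export
lowpass_filter <- function(trace, cutoff_hz = 6e4, order = 4L) {
  nyq <- trace$sampling_rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop(sprintf("cutoff %g Hz must lie strictly between 0 and Nyquist (%g Hz)",
                 cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-reflection padding so the zero-phase pass has settled edges
  n <- nrow(trace$samples)
  npad <- min(n - 1L, max(50L, 6L * order * ceiling(nyq / cutoff_hz)))
  out <- trace
  out$samples <- apply(trace$samples, 2L, function(x) {
    head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(npad + 1L):(npad + n)]
  })
  colnames(out$samples) <- psa_channel_order()
  out$filtered <- TRUE
  out$cutoff_hz <- cutoff_hz
  out
}

#' Subtract the per-channel background from a trace
#'
#' Estimates each channel's background level (median over the head segment,
#' the same convention [detect_pulses()] uses) and subtracts it. Without
#' subtraction the constant background adds an unpolarized pedestal to every
#' inverted Stokes state, so the normalized features of one particle drift
#' with its transit envelope (heavily diluted in the pulse wings, clean at
#' the peak); after subtraction `q`, `u`, `v` and `DOP` depend only on the
#' particle, not on where in the transit a sample was taken.
#'
#' @param trace a `channel_trace` (normally filtered first).
#' @param bg_frac fraction of the trace head used for the estimate.
#' @return The trace with background removed; the estimated per-channel
#'   levels are stored in `trace$background_channels`.
#' @export
subtract_background <- function(trace, bg_frac = 0.1) {
  n_head <- max(100L, round(bg_frac * nrow(trace$samples)))
  n_head <- min(n_head, nrow(trace$samples))
  bg <- apply(trace$samples[seq_len(n_head), , drop = FALSE], 2L,
              stats::median)
  out <- trace
  out$samples <- sweep(trace$samples, 2L, bg, `-`)
  out$background_channels <- bg
  out
}

#' Pulse-detection threshold specification
#'
#' Detection operates on the channel sum (an intensity proxy). Background
#' statistics are estimated robustly (median and MAD) from a head segment of
#' the trace; a pulse starts when the sum crosses
#' `background + upper_sigma * sd` and extends outward to where it falls
#' below the hysteresis level `background + lower_sigma * sd`. Candidates
#' shorter than `min_width_s` (default 50 microseconds, i.e. 10 samples at
#' 200 kS/s) are rejected as noise spikes and counted.
#'
#' @param upper_sigma detection threshold in background s.d. units.
#' @param lower_sigma hysteresis drop-out level in background s.d. units.
#' @param min_width_s minimum pulse width in seconds.
#' @param merge_gap_s candidate regions separated by a gap at most this long
#'   are merged before the width filter (default equals `min_width_s`): the
#'   channel sum weights the linear Stokes components, so a fast
#'   reorientation can dip it below the hysteresis line for a few samples
#'   inside one transit.
#' @param bg_frac fraction of the trace head used for background statistics.
#' @param absolute optional absolute threshold level overriding the sigma
#'   rule (same units as the channel sum).
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(upper_sigma = 5, lower_sigma = 2,
                           min_width_s = 50e-6, merge_gap_s = min_width_s,
                           bg_frac = 0.1, absolute = NULL) {
  stopifnot(upper_sigma > lower_sigma, lower_sigma >= 0, min_width_s >= 0,
            merge_gap_s >= 0, bg_frac > 0, bg_frac <= 1)
  structure(list(upper_sigma = upper_sigma, lower_sigma = lower_sigma,
                 min_width_s = min_width_s, merge_gap_s = merge_gap_s,
                 bg_frac = bg_frac, absolute = absolute),
            class = "threshold_spec")
}

#' Detect polarized light pulses in a filtered trace
#'
#' Thresholds the channel sum of a (low-pass filtered) trace with hysteresis:
#' contiguous regions above the lower level that contain at least one sample
#' above the upper level become pulses; sub-minimum-width candidates are
#' discarded and counted. Each pulse's width in samples is its settling time
#' times the sampling rate — the duration the particle spent in the
#' scattering volume.
#'
#' @param trace a `channel_trace`, normally already passed through
#'   [lowpass_filter()] (a warning is issued otherwise).
#' @param threshold a [threshold_spec()].
#' @return A list of `plp_pulse` objects (fields `start`, `end` — 0-based
#'   half-open sample interval — `samples`, `width_samples`,
#'   `width_seconds`), with attributes `n_discarded_short` and
#'   `background` (the estimated background mean/sd of the channel sum).
#' @export
detect_pulses <- function(trace, threshold = threshold_spec()) {
  if (!isTRUE(trace$filtered)) {
    warning("trace does not appear to be low-pass filtered; ",
            "detection thresholds assume a filtered envelope")
  }
  s <- rowSums(trace$samples)
  n_head <- max(100L, round(threshold$bg_frac * length(s)))
  head_seg <- s[seq_len(min(n_head, length(s)))]
  bg_mean <- stats::median(head_seg)
  # MAD is robust to pulses inside the head segment. Floor the spread at a
  # ppm of the trace's dynamic range: on a noise-free record the
  # statistical spread vanishes and numerical filter residue (~1e-13 of a
  # pulse) would otherwise cross the threshold as phantom pulses.
  bg_sd <- stats::mad(head_seg)
  floor_sd <- 1e-6 * max(abs(s - bg_mean))
  bg_sd <- max(bg_sd, floor_sd, .Machine$double.eps, na.rm = TRUE)
  if (!is.null(threshold$absolute)) {
    upper <- threshold$absolute
    if (upper <= bg_mean) {
      stop(sprintf(paste0("absolute threshold %.4g is not above the background ",
                          "mean %.4g; every sample would merge into one pulse"),
                   upper, bg_mean))
    }
    lower <- bg_mean + (upper - bg_mean) * 0.4
  } else {
    upper <- bg_mean + threshold$upper_sigma * bg_sd
    lower <- bg_mean + threshold$lower_sigma * bg_sd
  }
  above_low <- s > lower
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  reg <- cbind(starts[keep], ends[keep])
  # bridge sub-merge-gap dropouts inside one transit
  merge_gap <- round(threshold$merge_gap_s * trace$sampling_rate)
  if (nrow(reg) > 1L && merge_gap > 0L) {
    merged <- reg[1L, , drop = FALSE]
    for (i in 2L:nrow(reg)) {
      if (reg[i, 1L] - merged[nrow(merged), 2L] - 1L <= merge_gap) {
        merged[nrow(merged), 2L] <- reg[i, 2L]
      } else {
        merged <- rbind(merged, reg[i, ])
      }
    }
    reg <- merged
  }
  min_w <- max(1L, round(threshold$min_width_s * trace$sampling_rate))
  pulses <- list()
  n_short <- 0L
  for (i in seq_len(nrow(reg))) {
    i0 <- reg[i, 1L]; i1 <- reg[i, 2L]
    if (max(s[i0:i1]) < upper) next
    if (i1 - i0 + 1L < min_w) {
      n_short <- n_short + 1L
      next
    }
    pulses[[length(pulses) + 1L]] <- structure(
      list(start = i0 - 1L, end = i1,
           samples = trace$samples[i0:i1, , drop = FALSE],
           width_samples = i1 - i0 + 1L,
           width_seconds = (i1 - i0 + 1L) / trace$sampling_rate),
      class = "plp_pulse")
  }
  attr(pulses, "n_discarded_short") <- n_short
  attr(pulses, "background") <- c(mean = bg_mean, sd = bg_sd,
                                  upper = upper, lower = lower)
  pulses
}

#' @export
print.plp_pulse <- function(x, ...) {
  cat(sprintf("plp_pulse: samples [%d, %d), width %d samples (%.3g ms)\n",
              x$start, x$end, x$width_samples, x$width_seconds * 1e3))
  invisible(x)
}

#' Dense-sampling schemes
#'
#' How many feature rows one pulse contributes: `"ave"` averages the whole
#' pulse into a single row (equivalent to `k = 1`); an integer `k` splits the
#' pulse into `k` contiguous, as-equal-as-possible segments and averages each
#' (`k = 4`, `10`, `100` are the conventional dense-sampling settings);
#' `"all"` keeps every sample as its own row.
#'
#' @param mode `"ave"`, `"all"`, or a positive integer segment count (also
#'   accepted as a string, e.g. `"4"`).
#' @return A `sampling_scheme` object with fields `mode` (`"ave"`,
#'   `"segment"` or `"all"`) and `k`.
#' @examples
#' sampling_scheme("ave"); sampling_scheme(10); sampling_scheme("all")
#' @export
sampling_scheme <- function(mode) {
  if (inherits(mode, "sampling_scheme")) return(mode)
  if (is.numeric(mode)) {
    k <- as.integer(mode)
    stopifnot(k >= 1L)
    return(structure(list(mode = if (k == 1L) "ave" else "segment", k = k),
                     class = "sampling_scheme"))
  }
  mode <- as.character(mode)
  if (mode %in% c("ave", "average")) {
    structure(list(mode = "ave", k = 1L), class = "sampling_scheme")
  } else if (mode == "all") {
    structure(list(mode = "all", k = NA_integer_), class = "sampling_scheme")
  } else if (grepl("^[0-9]+$", mode)) {
    sampling_scheme(as.integer(mode))
  } else {
    stop("unknown sampling scheme: ", mode)
  }
}

scheme_label <- function(scheme) {
  scheme <- sampling_scheme(scheme)
  switch(scheme$mode,
         ave = "PLP-Ave",
         all = "PLP-All",
         segment = sprintf("PLP-%d", scheme$k))
}

# Segment sizes: width split into k contiguous runs, as equal as possible;
# the first (width %% k) segments receive one extra sample.
segment_sizes <- function(width, k) {
  base <- width %/% k
  rem <- width %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Featurize one pulse under a dense-sampling scheme
#'
#' Splits the pulse according to `scheme`, averages the four channels over
#' each segment *in channel space*, inverts each averaged channel vector to a
#' Stokes state through the instrument matrix, and normalizes to the
#' `[I, q, u, v, DOP]` descriptor. Because the inversion is linear, averaging
#' before or after inversion gives identical Stokes means; channel-space
#' averaging is used (and matters only for the DOP of the averaged state,
#' which is a property of the mean state, not the mean of per-sample DOPs).
#'
#' Pulses narrower than `k` segments are skipped (return `NULL`) unless
#' `short_pulse = "pad"`, which falls back to one row per sample. Rows whose
#' inverted intensity is non-positive (deep-noise artifacts) are dropped and
#' counted in the `n_nonpositive` attribute.
#'
#' @param pulse a `plp_pulse` from [detect_pulses()].
#' @param scheme a [sampling_scheme()] (or something coercible to one).
#' @param A instrument matrix used for the Stokes inversion.
#' @param label class label to attach (`"unknown"` for mixtures).
#' @param pulse_id integer pulse identifier carried into the rows.
#' @param clip_tol DOP clipping tolerance, see [stokes_to_features()].
#' @param short_pulse `"skip"` (default) or `"pad"` policy for pulses
#'   narrower than `k`.
#' @param min_I intensity floor for a single-sample row (detector units,
#'   default 0): rows whose inverted `I` falls at or below the floor are
#'   deep-noise artifacts — in the extreme pulse wings the signal is
#'   comparable to the background noise, so the normalized (ratio) features
#'   are not just noisy but biased — and are dropped and counted, like rows
#'   with non-positive `I`. A row averaging `m` samples has its floor scaled
#'   by `1/sqrt(m)`, since its noise (and hence the ratio bias) shrinks
#'   accordingly. [build_dataset()] derives the per-sample floor from the
#'   detection background statistics.
#' @return A data frame of feature rows with columns `pulse_id`,
#'   `segment_index` (0-based), `I`, `q`, `u`, `v`, `DOP`, `unphysical`,
#'   `label`; or `NULL` for a skipped pulse.
#' @export
densify <- function(pulse, scheme, A = ideal_psa_matrix(),
                    label = "unknown", pulse_id = NA_integer_,
                    clip_tol = 0.05, short_pulse = c("skip", "pad"),
                    min_I = 0) {
  scheme <- sampling_scheme(scheme)
  short_pulse <- match.arg(short_pulse)
  w <- pulse$width_samples
  ch <- pulse$samples
  if (scheme$mode == "all") {
    means <- ch
    row_samples <- rep(1L, w)
  } else {
    k <- scheme$k
    if (w < k) {
      if (short_pulse == "skip") return(NULL)
      means <- ch
      row_samples <- rep(1L, w)
    } else {
      sizes <- segment_sizes(w, k)
      grp <- rep(seq_len(k), times = sizes)
      means <- rowsum(ch, grp) / sizes
      row_samples <- sizes
    }
  }
  S <- invert_stokes(means, A, tol = clip_tol)
  keep_row <- S[, 1] > pmax(0, min_I / sqrt(row_samples))
  S <- S[keep_row, , drop = FALSE]
  feats <- stokes_to_features(S, clip_tol = clip_tol)
  kept <- which(keep_row)
  out <- cbind(data.frame(pulse_id = rep(pulse_id, length(kept)),
                          segment_index = kept - 1L),
               feats,
               data.frame(label = rep(label, length(kept)),
                          stringsAsFactors = FALSE))
  attr(out, "n_nonpositive") <- sum(!keep_row)
  attr(out, "n_clipped") <- attr(feats, "n_clipped")
  rownames(out) <- NULL
  out
}

#' Build a feature table from traces
#'
#' The full processing chain for a set of traces: low-pass filter, detect
#' pulses, featurize each pulse under the chosen dense-sampling scheme, and
#' concatenate the rows with global pulse identifiers. Labeled traces
#' (pure-suspension runs) propagate their label to every pulse; unlabeled
#' traces yield `"unknown"` labels. An optional per-class row cap draws a
#' seeded subsample to build balanced datasets.
#'
#' @param traces a `channel_trace` or list of them.
#' @param scheme a [sampling_scheme()].
#' @param A instrument matrix.
#' @param cutoff_hz low-pass cutoff passed to [lowpass_filter()]; `NULL`
#'   skips filtering (for already-filtered traces).
#' @param threshold a [threshold_spec()].
#' @param cap_per_class optional maximum number of rows per class label
#'   (seeded subsample); `Inf` keeps everything.
#' @param seed seed for the capping subsample (required when capping).
#' @param subtract_bg remove the per-channel background level before
#'   inversion (default TRUE; see [subtract_background()]).
#' @param clip_tol,short_pulse passed to [densify()].
#' @return A `plp_features` data frame (columns as in [densify()]) with
#'   attributes `scheme`, `n_pulses` (per-label pulse counts), `n_skipped`,
#'   `n_nonpositive`, `n_discarded_short`.
#' @export
build_dataset <- function(traces, scheme, A = ideal_psa_matrix(),
                          cutoff_hz = 6e4, threshold = threshold_spec(),
                          cap_per_class = Inf, seed = NULL,
                          subtract_bg = TRUE,
                          clip_tol = 0.05, short_pulse = "skip") {
  if (inherits(traces, "channel_trace")) traces <- list(traces)
  scheme <- sampling_scheme(scheme)
  all_rows <- list()
  pulse_counter <- 0L
  n_skipped <- 0L
  n_nonpos <- 0L
  n_short <- 0L
  pulse_labels <- character()
  for (tr in traces) {
    ftr <- if (!is.null(cutoff_hz) && !isTRUE(tr$filtered)) {
      lowpass_filter(tr, cutoff_hz)
    } else tr
    if (subtract_bg && is.null(ftr$background_channels)) {
      ftr <- subtract_background(ftr, threshold$bg_frac)
    }
    pulses <- detect_pulses(ftr, threshold)
    n_short <- n_short + attr(pulses, "n_discarded_short")
    if (!length(pulses)) {
      stop("no pulses detected in trace",
           if (!is.na(tr$label)) paste0(" labeled '", tr$label, "'") else "",
           " (seed ", tr$seed, ")")
    }
    # noise floor for single rows: the hysteresis margin of the channel sum,
    # expressed as an intensity (sum ~ 2 I under the ideal analyzer)
    bg <- attr(pulses, "background")
    min_I <- 2 * (bg[["upper"]] - bg[["mean"]])
    lab <- if (!is.na(tr$label)) tr$label else "unknown"
    for (p in pulses) {
      pulse_counter <- pulse_counter + 1L
      rows <- densify(p, scheme, A, label = lab, pulse_id = pulse_counter,
                      clip_tol = clip_tol, short_pulse = short_pulse,
                      min_I = min_I)
      if (is.null(rows) || !nrow(rows)) {
        n_skipped <- n_skipped + 1L
        next
      }
      n_nonpos <- n_nonpos + attr(rows, "n_nonpositive")
      pulse_labels <- c(pulse_labels, lab)
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  tab <- do.call(rbind, all_rows)
  rownames(tab) <- NULL
  if (is.finite(cap_per_class)) {
    if (is.null(seed)) stop("cap_per_class requires a seed for the subsample")
    set.seed(seed)
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$label), function(ix) {
      if (length(ix) > cap_per_class) sort(sample(ix, cap_per_class)) else ix
    }), use.names = FALSE)
    tab <- tab[sort(keep), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab,
            scheme = scheme_label(scheme),
            n_pulses = table(pulse_labels),
            n_skipped = n_skipped,
            n_nonpositive = n_nonpos,
            n_discarded_short = n_short,
            class = c("plp_features", "data.frame"))
}

#' Read and write feature tables
#'
#' Delimited text (comma by default) with the header columns `pulse_id`,
#' `segment_index`, `I`, `q`, `u`, `v`, `DOP`, `unphysical`, `label`, plus a
#' JSON sidecar `<path>.json` recording the scheme and processing provenance.
#'
#' @param features a feature table from [build_dataset()].
#' @param path output path.
#' @param meta optional named list merged into the sidecar.
#' @param sep field delimiter.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the feature data frame (scheme restored from the sidecar when present).
#' @export
write_features <- function(features, path, meta = list(), sep = ",") {
  utils::write.table(features, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  side <- c(list(scheme = attr(features, "scheme"),
                 n_skipped = attr(features, "n_skipped"),
                 n_nonpositive = attr(features, "n_nonpositive")),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(tab, "scheme") <- side$scheme
  }
  class(tab) <- c("plp_features", "data.frame")
  tab
}
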