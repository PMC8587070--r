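# Shared builders for the test suite. Everything is generated in code;
# nothing is read from disk.

# A bare channel trace wrapping a sample matrix.
new_trace_from_matrix <- function(m, fs, filtered = FALSE) {
  tr <- pulsepol:::new_channel_trace(m, fs, pulsepol:::empty_ground_truth(),
                                     seed = 0L)
  tr$filtered <- filtered
  tr
}

# A pulse object with the given channel matrix (one row per sample).
make_pulse <- function(channels, start = 0L) {
  channels <- as.matrix(channels)
  structure(
    list(start = start, end = start + nrow(channels),
         samples = channels,
         width_samples = nrow(channels),
         width_seconds = nrow(channels) / 2e5),
    class = "plp_pulse")
}

# A constant-channel pulse: every sample equals A %*% S.
constant_pulse <- function(S, n, A = ideal_psa_matrix()) {
  ch <- as.numeric(unclass(A) %*% S)
  make_pulse(matrix(rep(ch, each = n), nrow = n))
}

# Random fully- or partially-polarized physical Stokes vectors.
random_physical_stokes <- function(n, seed) {
  set.seed(seed)
  t(replicate(n, {
    I <- runif(1, 0.5, 2)
    dop <- runif(1, 0, 1)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    c(I, I * dop * dir)
  }))
}

# Random well-conditioned invertible 4x4 instrument matrices.
random_instrument_matrix <- function(seed) {
  set.seed(seed)
  repeat {
    A <- matrix(runif(16, -1, 1), 4)
    if (is.finite(kappa(A, exact = TRUE)) && kappa(A, exact = TRUE) < 1e3) {
      return(A)
    }
  }
}

# Two well-separated noise-free-distinguishable classes for classifier tests
# (no parameter jitter, no drift): features differ strongly in DOP and v.
separable_pair <- function() {
  list(
    A = particle_class("A", "parametric", depol = 0.05, retardance_deg = 20,
                       jitter_depol = 0, jitter_ret_deg = 0,
                       sigma_phi = 0, flip_rate = 0, brightness = 1),
    B = particle_class("B", "parametric", depol = 0.7, retardance_deg = 80,
                       jitter_depol = 0, jitter_ret_deg = 0,
                       sigma_phi = 0, flip_rate = 0, brightness = 1)
  )
}

# Linearly separable synthetic feature rows (two labels, clean margins).
separable_feature_table <- function(n_per_class = 120, seed = 7) {
  set.seed(seed)
  mk <- function(label, dop, v) {
    data.frame(pulse_id = seq_len(n_per_class),
               segment_index = 0L,
               I = runif(n_per_class, 0.8, 1.2),
               q = rnorm(n_per_class, 0, 0.02),
               u = rnorm(n_per_class, 0, 0.02),
               v = rnorm(n_per_class, v, 0.02),
               DOP = rnorm(n_per_class, dop, 0.02),
               unphysical = FALSE,
               label = label, stringsAsFactors = FALSE)
  }
  a <- mk("A", 0.9, 0.8)
  b <- mk("B", 0.3, 0.1)
  b$pulse_id <- b$pulse_id + n_per_class
  rbind(a, b)
}

four_class_library <- function() {
  preset_class_library(c("DS", "CP", "CD", "PG"))
}
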