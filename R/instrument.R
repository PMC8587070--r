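#' Instrument (analyzer) matrices
#'
#' The polarization state analyzer (PSA) splits the scattered beam into four
#' channels; the instrument matrix `A` maps a Stokes vector to the four
#' channel intensities, `c = A %*% S`. Recovering the polarization state from
#' a measurement is the inverse map (see [invert_stokes()]).
#'
#' `ideal_psa_matrix()` returns the matrix of an ideal four-way analyzer:
#' a 0-degree linear analyzer, a 45-degree linear analyzer, a left-circular
#' analyzer (135-degree quarter-wave plate followed by a 90-degree polarizer)
#' and a right-circular analyzer (45-degree quarter-wave plate followed by a
#' 90-degree polarizer), each with throughput 1/2. Its rows are the analyzer
#' Stokes vectors `[1,1,0,0]/2`, `[1,0,1,0]/2`, `[1,0,0,-1]/2`, `[1,0,0,1]/2`
#' in the package's fixed channel order.
#'
#' @return An `instrument_matrix`: a 4x4 numeric matrix with attributes
#'   `provenance` (`"ideal"` or `"calibrated"`), `channel_order`, `cond`
#'   (condition number) and, for calibrated matrices, `residual_norm`.
#' @examples
#' A <- ideal_psa_matrix()
#' A %*% stokes(1, 0, 0, 0)  # unpolarized light: 0.5 in every channel
#' @export
ideal_psa_matrix <- function() {
  A <- 0.5 * matrix(c(1, 1, 0, 0,
                      1, 0, 1, 0,
                      1, 0, 0, -1,
                      1, 0, 0, 1), nrow = 4L, byrow = TRUE)
  new_instrument_matrix(A, provenance = "ideal")
}

psa_channel_order <- function() {
  c("lin0", "lin45", "circL", "circR")
}

new_instrument_matrix <- function(A, provenance, residual_norm = NA_real_) {
  dimnames(A) <- list(psa_channel_order(), c("I", "Q", "U", "V"))
  structure(A,
            provenance = provenance,
            channel_order = psa_channel_order(),
            cond = kappa(A, exact = TRUE),
            residual_norm = residual_norm,
            class = c("instrument_matrix", "matrix", "array"))
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat(sprintf("Instrument matrix (%s), condition number %.3g\n",
              attr(x, "provenance"), attr(x, "cond")))
  if (is.finite(attr(x, "residual_norm"))) {
    cat(sprintf("  calibration residual norm: %.3g\n", attr(x, "residual_norm")))
  }
  print(unclass(x)[, ])
  invisible(x)
}

#' Least-squares calibration of the instrument matrix
#'
#' Estimates the 4x4 instrument matrix from measurements of known reference
#' polarization states prepared by the polarization state generator. With
#' states as columns of `Smat` and the corresponding measured channel vectors
#' as columns of `Cmat`, the estimate minimizes the Frobenius norm of
#' `A %*% Smat - Cmat`; with at least four states spanning Stokes space the
#' system is determined and, for noise-free consistent inputs, exact.
#'
#' The default reference set used elsewhere in the package is
#' H (`[1,1,0,0]`), V (`[1,-1,0,0]`), +45 (`[1,0,1,0]`) and right-circular
#' (`[1,0,0,1]`); see [calibration_states()].
#'
#' @param known_states list of length-4 Stokes vectors (or a 4-column matrix,
#'   one state per row) prepared during calibration.
#' @param measured_channels list of length-4 channel intensity vectors (or a
#'   4-column matrix, one measurement per row), same length/order.
#' @param cond_bound condition-number bound above which the result is flagged
#'   (attribute `ill_conditioned`) with a warning.
#' @return An `instrument_matrix` with `provenance = "calibrated"`, storing
#'   the residual norm and condition number.
#' @export
calibrate_instrument <- function(known_states, measured_channels,
                                 cond_bound = 1e6) {
  Smat <- t(states_to_matrix(known_states))       # 4 x N, states as columns
  Cmat <- t(states_to_matrix(measured_channels))  # 4 x N
  if (ncol(Smat) != ncol(Cmat)) {
    stop("known_states and measured_channels must have the same length")
  }
  qr_s <- qr(t(Smat))
  if (qr_s$rank < 4L) {
    sv <- svd(Smat, nu = 4L)
    missing <- sv$u[, (qr_s$rank + 1L):4L, drop = FALSE]
    comp <- c("I", "Q", "U", "V")
    dominant <- comp[apply(abs(missing), 2L, which.max)]
    stop(sprintf(paste0("calibration states are rank-deficient (rank %d < 4); ",
                        "the unspanned Stokes subspace is dominated by: %s"),
                 qr_s$rank, paste(dominant, collapse = ", ")))
  }
  # A' solves the normal equations of c = A s over all reference states
  At <- solve(Smat %*% t(Smat), Smat %*% t(Cmat))
  A <- t(At)
  residual <- sqrt(sum((A %*% Smat - Cmat)^2))
  A <- new_instrument_matrix(A, provenance = "calibrated",
                             residual_norm = residual)
  if (attr(A, "cond") > cond_bound) {
    warning(sprintf("calibrated matrix condition number %.3g exceeds bound %.3g",
                    attr(A, "cond"), cond_bound))
    attr(A, "ill_conditioned") <- TRUE
  }
  A
}

states_to_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  as_stokes_matrix(x)
}

#' Default calibration reference states
#'
#' Horizontal, vertical, +45-degree linear and right-circular fully polarized
#' states: four states spanning Stokes space, so the least-squares system of
#' [calibrate_instrument()] is determined.
#'
#' @return A 4x4 matrix, one Stokes state per row.
#' @export
calibration_states <- function() {
  rbind(H   = c(1, 1, 0, 0),
        V   = c(1, -1, 0, 0),
        P45 = c(1, 0, 1, 0),
        RCP = c(1, 0, 0, 1))
}

#' Recover Stokes states from four-channel measurements
#'
#' Inverts the instrument map: `S = solve(A) %*% c` for each measured channel
#' vector. Noise can make recovered states mildly unphysical (DOP above 1);
#' such rows are flagged via the `unphysical` attribute but their values are
#' never modified, keeping the estimator linear.
#'
#' @param channels a length-4 channel vector or an `n x 4` matrix, one
#'   measurement per row (channel order `lin0, lin45, circL, circR`).
#' @param A an [instrument matrix][ideal_psa_matrix].
#' @param tol DOP tolerance used for the `unphysical` flag.
#' @return Stokes states in the same shape as the input (vector or `n x 4`
#'   matrix), with logical attribute `unphysical`.
#' @export
invert_stokes <- function(channels, A = ideal_psa_matrix(), tol = 0.05) {
  single <- is.null(dim(channels))
  C <- as_stokes_matrix(channels)
  Ainv <- tryCatch(solve(unclass(A)),
                   error = function(e) stop("instrument matrix is singular: ",
                                            conditionMessage(e)))
  S <- C %*% t(Ainv)
  colnames(S) <- c("I", "Q", "U", "V")
  flag <- !is_physical_stokes(S, tol = tol)
  if (single) {
    S <- drop(S)
    flag <- unname(flag)
  }
  attr(S, "unphysical") <- flag
  S
}

#' Read and write instrument-matrix files
#'
#' Plain-text format: `#`-prefixed header lines recording provenance
#' (`ideal` or `calibrated`), channel order and condition number, followed by
#' the four whitespace-separated matrix rows.
#'
#' @param A an `instrument_matrix`.
#' @param path file path.
#' @return `read_instrument_matrix()` returns an `instrument_matrix`;
#'   `write_instrument_matrix()` returns `path` invisibly.
#' @export
write_instrument_matrix <- function(A, path) {
  lines <- c(
    sprintf("# provenance: %s", attr(A, "provenance")),
    sprintf("# channel_order: %s", paste(attr(A, "channel_order"), collapse = ",")),
    sprintf("# cond: %.17g", attr(A, "cond")),
    sprintf("# residual_norm: %.17g", attr(A, "residual_norm")),
    apply(unclass(A), 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instrument_matrix
#' @export
read_instrument_matrix <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  vals <- t(vapply(body, function(l) scan(text = l, quiet = TRUE),
                   numeric(4L)))
  get_field <- function(name) {
    m <- grep(sprintf("^# %s:", name), header, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", name), "", m[1L]))
  }
  prov <- get_field("provenance")
  res <- suppressWarnings(as.numeric(get_field("residual_norm")))
  new_instrument_matrix(unname(vals), provenance = prov, residual_norm = res)
}
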