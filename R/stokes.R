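#' Stokes vectors and Mueller-matrix algebra
#'
#' A Stokes vector `[I, Q, U, V]` describes the polarization state of a light
#' beam: `I` is the total intensity, `Q` the residual 0-degree linear
#' component, `U` the residual 45-degree linear component and `V` the residual
#' right-circular component, all in the same (detector) units. Throughout the
#' package single states are plain numeric vectors of length 4 and collections
#' are `n x 4` matrices with one state per row.
#'
#' @param I,Q,U,V components of the state (same units; `I >= 0` for physical
#'   states).
#' @return A numeric vector of length 4.
#' @examples
#' stokes(1, 0, 0, 1)        # right-circular light
#' stokes_dop(stokes(2, 0.6, 0, 0.8))
#' @export
stokes <- function(I, Q = 0, U = 0, V = 0) {
  c(I = I, Q = Q, U = U, V = V)
}

# Coerce a single state or an n x 4 matrix to matrix form.
as_stokes_matrix <- function(S) {
  if (is.null(dim(S))) {
    stopifnot(length(S) == 4L)
    S <- matrix(S, nrow = 1L)
  }
  stopifnot(ncol(S) == 4L)
  S
}

#' Degree of polarization of Stokes states
#'
#' `DOP = sqrt(Q^2 + U^2 + V^2) / I`, the fraction of the light that is
#' polarized, in `[0, 1]` for physical states. Measurement noise can push
#' inverted states slightly past 1; callers decide how to treat such values
#' (see [stokes_to_features()]).
#'
#' @param S a length-4 Stokes vector or an `n x 4` matrix of states.
#' @return A numeric vector of DOP values (one per state).
#' @export
stokes_dop <- function(S) {
  S <- as_stokes_matrix(S)
  sqrt(rowSums(S[, 2:4, drop = FALSE]^2)) / S[, 1]
}

#' Physicality check for Stokes states
#'
#' A state is physically realizable when `sqrt(Q^2+U^2+V^2) <= I` (DOP at most
#' 1) and `I >= 0`. States violating the bound beyond `tol` are flagged, never
#' silently altered: linear inversion of noisy channel data legitimately
#' produces mildly unphysical states and projecting them onto the physical
#' cone would bias downstream statistics.
#'
#' @inheritParams stokes_dop
#' @param tol absolute tolerance on the DOP excess above 1 (default 0.05).
#' @return Logical vector, `TRUE` where the state is physical within `tol`.
#' @export
is_physical_stokes <- function(S, tol = 0.05) {
  S <- as_stokes_matrix(S)
  S[, 1] >= 0 & stokes_dop(S) <= 1 + tol
}

#' Mueller rotation operator about the beam axis
#'
#' The standard 4x4 rotation operator `R(phi)` that re-expresses a Stokes
#' vector in a frame rotated by `phi` about the propagation axis; it mixes
#' `(Q, U)` through the double angle `2*phi` and leaves `I` and `V` unchanged.
#' Rotating a scatterer's Mueller matrix by `phi` is the conjugation
#' `R(-phi) %*% M %*% R(phi)` (see [rotate_mueller()]).
#'
#' @param phi rotation angle in radians.
#' @return A 4x4 rotation Mueller matrix.
#' @export
rotation_mueller <- function(phi) {
  c2 <- cos(2 * phi)
  s2 <- sin(2 * phi)
  matrix(c(1, 0,   0,  0,
           0, c2,  s2, 0,
           0, -s2, c2, 0,
           0, 0,   0,  1), nrow = 4L, byrow = TRUE)
}

#' @rdname rotation_mueller
#' @param M a 4x4 Mueller matrix.
#' @export
rotate_mueller <- function(M, phi) {
  rotation_mueller(-phi) %*% M %*% rotation_mueller(phi)
}

#' Normalized polarization features of Stokes states
#'
#' Maps each state `[I, Q, U, V]` to the five-element descriptor used for
#' classification: total intensity `I`, the intensity-normalized parameters
#' `q = Q/I`, `u = U/I`, `v = V/I` (each in `[-1, 1]` for physical states) and
#' the degree of polarization `DOP = sqrt(Q^2+U^2+V^2)/I` in `[0, 1]`.
#'
#' Rows with `I <= 0` cannot be normalized; a single such state is an error,
#' while in matrix input they are dropped and counted (attribute
#' `n_nonpositive`). DOP values in `(1, 1 + clip_tol]` are clipped to 1 and
#' counted (`n_clipped`); larger excesses keep their value and set the
#' `unphysical` flag column.
#'
#' @inheritParams stokes_dop
#' @param clip_tol absolute tolerance for clipping mildly unphysical DOP
#'   values to 1 (default 0.05).
#' @return A data frame with columns `I`, `q`, `u`, `v`, `DOP`, `unphysical`,
#'   and attributes `n_nonpositive`, `n_clipped`.
#' @examples
#' stokes_to_features(stokes(2, 0.6, 0, 0.8))  # q=0.3, v=0.4, DOP=0.5
#' @export
stokes_to_features <- function(S, clip_tol = 0.05) {
  single <- is.null(dim(S))
  S <- as_stokes_matrix(S)
  bad <- S[, 1] <= 0
  if (single && bad) {
    stop("cannot normalize a Stokes vector with non-positive intensity I = ",
         format(S[1, 1]))
  }
  n_drop <- sum(bad)
  S <- S[!bad, , drop = FALSE]
  I <- S[, 1]
  q <- S[, 2] / I
  u <- S[, 3] / I
  v <- S[, 4] / I
  dop <- sqrt(q^2 + u^2 + v^2)
  clip <- dop > 1 & dop <= 1 + clip_tol
  unphys <- dop > 1 + clip_tol
  dop[clip] <- 1
  out <- data.frame(I = I, q = q, u = u, v = v, DOP = dop,
                    unphysical = unphys)
  attr(out, "n_nonpositive") <- n_drop
  attr(out, "n_clipped") <- sum(clip)
  out
}
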