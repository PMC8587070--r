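#' Lorenz-Mie scattering matrix of a homogeneous sphere
#'
#' Computes the normalized 4x4 scattering (Mueller) matrix of a homogeneous
#' dielectric sphere at a given scattering angle, using the standard Mie
#' series: the scattering coefficients `a_n`, `b_n` are evaluated with a
#' downward-recurrence logarithmic derivative, the angular functions `pi_n`,
#' `tau_n` by upward recurrence, and the amplitudes
#' `S1 = sum (2n+1)/(n(n+1)) (a_n pi_n + b_n tau_n)`,
#' `S2 = sum (2n+1)/(n(n+1)) (a_n tau_n + b_n pi_n)`.
#' For a sphere the matrix has the block form
#' `[[S11,S12,0,0],[S12,S11,0,0],[0,0,S33,S34],[0,0,-S34,S33]]` with
#' `S11 = (|S1|^2+|S2|^2)/2`, `S12 = (|S2|^2-|S1|^2)/2`,
#' `S33 = Re(S2 conj(S1))`, `S34 = Im(S2 conj(S1))`; it is returned
#' normalized so that `M[1,1] = 1`.
#'
#' @param diameter_um sphere diameter in micrometres.
#' @param wavelength_nm vacuum wavelength in nanometres (default 520, the
#'   green laser line used for low-absorbing microalgae).
#' @param n_particle real refractive index of the sphere (1.59 polystyrene,
#'   1.45 silica).
#' @param n_medium refractive index of the suspending medium (1.334,
#'   seawater).
#' @param angle_deg scattering angle in degrees (default 120, the side/back
#'   angle the instrument collects, sensitive to particle microstructure).
#' @return A normalized 4x4 Mueller matrix.
#' @examples
#' mie_scattering_matrix(10)          # 10-um polystyrene microsphere
#' mie_scattering_matrix(10, n_particle = 1.45)  # 10-um silica
#' @export
mie_scattering_matrix <- function(diameter_um, wavelength_nm = 520,
                                  n_particle = 1.59, n_medium = 1.334,
                                  angle_deg = 120) {
  stopifnot(diameter_um > 0, wavelength_nm > 0, angle_deg >= 0,
            angle_deg <= 180)
  x <- pi * diameter_um * 1e3 * n_medium / wavelength_nm  # size parameter
  m <- n_particle / n_medium
  amp <- mie_amplitudes(x, m, cos(angle_deg * pi / 180))
  s1 <- amp$S1
  s2 <- amp$S2
  s11 <- (Mod(s1)^2 + Mod(s2)^2) / 2
  s12 <- (Mod(s2)^2 - Mod(s1)^2) / 2
  s33 <- Re(s2 * Conj(s1))
  s34 <- Im(s2 * Conj(s1))
  M <- matrix(c(s11, s12, 0, 0,
                s12, s11, 0, 0,
                0, 0, s33, s34,
                0, 0, -s34, s33), nrow = 4L, byrow = TRUE)
  M / s11
}

# Mie scattering amplitudes S1(mu), S2(mu) for size parameter x and relative
# refractive index m (real), mu = cos(theta). Bohren & Huffman recurrences.
mie_amplitudes <- function(x, m, mu) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  # logarithmic derivative D_n(mx) by downward recurrence
  nmx <- max(nmax, ceiling(abs(m) * x)) + 16L
  D <- complex(length.out = nmx)
  mx <- m * x
  for (n in seq(nmx - 1L, 1L)) {
    D[n] <- (n + 1) / mx - 1 / (D[n + 1L] + (n + 1) / mx)
  }
  # Riccati-Bessel psi, chi by upward recurrence
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  an <- bn <- complex(length.out = nmax)
  psi_prev <- psi0; psi_cur <- psi1
  chi_prev <- chi0; chi_cur <- chi1
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_cur - psi_prev
    chi_n <- (2 * n - 1) / x * chi_cur - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    an[n] <- (da * psi_n - psi_cur) / (da * xi_n - xi_prev)
    bn[n] <- (db * psi_n - psi_cur) / (db * xi_n - xi_prev)
    psi_prev <- psi_cur; psi_cur <- psi_n
    chi_prev <- chi_cur; chi_cur <- chi_n
    xi_prev <- xi_n
  }
  # angular functions and amplitude sums
  S1 <- S2 <- 0 + 0i
  pi_prev <- 0; pi_cur <- 1
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_cur - (n + 1) * pi_prev
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (an[n] * pi_cur + bn[n] * tau_n)
    S2 <- S2 + fac * (an[n] * tau_n + bn[n] * pi_cur)
    pi_next <- ((2 * n + 1) * mu * pi_cur - (n + 1) * pi_prev) / n
    pi_prev <- pi_cur; pi_cur <- pi_next
  }
  list(S1 = S1, S2 = S2, nmax = nmax)
}
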