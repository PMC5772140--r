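# Pairwise-like re-parametrisations of the message-passing model for
# Markovian (Poisson, rate beta) transmission: the general
# configuration-model system, its degree-regular reduction, the Markovian
# (exponential recovery) ODE system, and the fixed-infectious-period delay
# system. All are exact re-parametrisations, not moment closures.

pairwise_state <- function(t, S, I, R, SI, H1, N, solver, SS = NULL) {
  out <- data.frame(t = t, S = S, I = I, R = R, SI = SI)
  if (!is.null(SS)) out$SS <- SS
  out$H1 <- H1
  attr(out, "N") <- N
  attr(out, "solver") <- solver
  class(out) <- c("pairwise_state", "data.frame")
  out
}

# [I](t) = beta * int_0^t [SI](t-a) xi_q(a) da + N(1-z) xi_q(t); the
# integral form avoids point evaluation of q at atoms. Survival jumps at
# recovery atoms are half-cell corrected (the grid node carries the right
# limit of xi_q).
pairwise_I_series <- function(SI, xi_q_grid, beta, N, z, h,
                              atom_lag = integer(0),
                              atom_w = numeric(0)) {
  n <- length(SI)
  I <- numeric(n)
  I[1] <- N * (1 - z)
  for (m in seq_len(n)[-1]) {
    v <- SI[m:1] * xi_q_grid[1:m]
    acc <- h * (sum(v) - (v[1] + v[m]) / 2)
    if (length(atom_lag) > 0) {
      ok <- atom_lag <= m - 1 & atom_lag >= 1
      if (any(ok))
        acc <- acc + h / 2 * sum(atom_w[ok] * SI[m - atom_lag[ok]])
    }
    I[m] <- beta * acc + N * (1 - z) * xi_q_grid[m]
  }
  I
}

#' Pairwise-like model on general configuration-model networks
#'
#' Integrates the closed (H1, \[SI\]) system for Poisson transmission at rate
#' \code{beta} and an arbitrary infectious-period law, using Heun's method
#' with trapezoidal evaluation of the history (convolution) integral on the
#' solver grid. Atoms of the recovery law enter as lagged terms and as
#' impulsive jumps of \[SI\] at the atom location. \[I\] is recovered by the
#' integral identity
#' \eqn{[I](t) = \beta\int_0^t [SI](t-a)\xi_q(a)\,da + N(1-z)\xi_q(t)},
#' \[S\] by \eqn{z N G_0(H_1)}, and \[R\] by conservation.
#'
#' @param gfs a \code{gf_set}.
#' @param beta Markovian transmission rate (> 0); non-exponential
#'   transmission is not representable in this hierarchy.
#' @param recovery a \code{delay_distribution} for the infectious period;
#'   atom locations must sit on the grid.
#' @param z initial susceptible fraction.
#' @param N population size.
#' @param tmax horizon.
#' @param h grid step.
#' @return a \code{pairwise_state} data frame (columns
#'   \code{t,S,I,R,SI,H1}) with attribute \code{N}.
#' @export
solve_pairwise_cm <- function(gfs, beta, recovery, z, N, tmax, h) {
  stopifnot(inherits(gfs, "gf_set"), inherits(recovery, "delay_distribution"))
  if (beta <= 0) stop("beta must be > 0")
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  mk <- gfs$mean_degree
  qd <- recovery$density(t)
  xq <- recovery$survival(t)
  qa <- recovery$atoms
  qa_lag <- if (nrow(qa) > 0) vapply(qa$location, atom_lag_index, integer(1),
                                     h = h) else integer(0)
  H1 <- numeric(n); SI <- numeric(n); W <- numeric(n)
  H1[1] <- 1
  SI[1] <- mk * N * z * (1 - z)
  W[1] <- SI[1] * gfs$G2(1) / gfs$G1(1)
  ebt <- exp(-beta * t)
  conv <- function(m, Wm) {
    # C(t_m) = int_0^{t_m} q(a) e^{-beta a} W(t_m - a) da  (+ atom terms)
    Wv <- c(W[1:(m - 1)], Wm)
    v <- qd[1:m] * ebt[1:m] * Wv[m:1]
    acc <- h * (sum(v) - (v[1] + v[m]) / 2)
    if (length(qa_lag) > 0) {
      ok <- qa_lag <= m - 1
      if (any(ok))
        acc <- acc + sum(qa$weight[ok] * ebt[qa_lag[ok] + 1] *
                           Wv[m - qa_lag[ok]])
    }
    acc
  }
  deriv <- function(m, H, P, Wm) {
    g1 <- gfs$G1(H); g2 <- gfs$G2(H)
    dH <- -beta * P / (z * mk * N * g1)
    dP <- -beta * P^2 * g2 / (z * mk * N * g1^2) - beta * P +
      z * beta * P * g2 -
      qd[m] * ebt[m] * (1 - z) * z * g1 * mk * N -
      z * beta * g1 * conv(m, Wm)
    c(dH, dP)
  }
  for (m in seq_len(n)[-1]) {
    k1 <- deriv(m - 1, H1[m - 1], SI[m - 1], W[m - 1])
    Hp <- H1[m - 1] + h * k1[1]
    Pp <- SI[m - 1] + h * k1[2]
    Wp <- Pp * gfs$G2(Hp) / gfs$G1(Hp)
    k2 <- deriv(m, Hp, Pp, Wp)
    H1[m] <- H1[m - 1] + h / 2 * (k1[1] + k2[1])
    SI[m] <- SI[m - 1] + h / 2 * (k1[2] + k2[2])
    # impulsive recovery of the initial cohort at recovery atoms
    if (length(qa_lag) > 0) {
      hit <- which(qa_lag == m - 1)
      for (s in hit)
        SI[m] <- SI[m] - qa$weight[s] * ebt[m] * (1 - z) * z *
          gfs$G1(H1[m]) * mk * N
    }
    SI[m] <- max(SI[m], 0)
    W[m] <- SI[m] * gfs$G2(H1[m]) / gfs$G1(H1[m])
  }
  S <- z * N * gfs$G0(H1)
  I <- pairwise_I_series(SI, xq, beta, N, z, h, qa_lag, qa$weight)
  pairwise_state(t, S, I, N - S - I, SI, H1, N, "pairwise_cm")
}

#' Pairwise model on degree-regular networks
#'
#' The closed (\[S\], \[SS\], \[SI\]) system for a k-regular network with
#' Poisson transmission and arbitrary infectious period. The exponential
#' memory factor \eqn{\exp(-\beta\int_{t-a}^t \frac{k-1}{k}
#' \frac{[SI]}{[S]}\,du)} is maintained incrementally from the running
#' integral of \eqn{[SI]/[S]}. Integration stops cleanly (with a warning and
#' a truncated series) if \[S\] reaches zero.
#'
#' @param k common degree (integer >= 2).
#' @inheritParams solve_pairwise_cm
#' @return a \code{pairwise_state} with an extra \code{SS} column.
#' @export
solve_pairwise_regular <- function(k, beta, recovery, z, N, tmax, h) {
  stopifnot(inherits(recovery, "delay_distribution"))
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  cc <- (k - 1) / k
  qd <- recovery$density(t)
  xq <- recovery$survival(t)
  qa <- recovery$atoms
  qa_lag <- if (nrow(qa) > 0) vapply(qa$location, atom_lag_index, integer(1),
                                     h = h) else integer(0)
  S <- numeric(n); SS <- numeric(n); SI <- numeric(n)
  J <- numeric(n); W <- numeric(n)
  S[1] <- z * N
  SS[1] <- k * N * z^2
  SI[1] <- k * N * z * (1 - z)
  W[1] <- cc * SS[1] * SI[1] / S[1]
  ebt <- exp(-beta * t)
  conv <- function(m, Wm, Jm) {
    Wv <- c(W[1:(m - 1)], Wm)
    Jv <- c(J[1:(m - 1)], Jm)
    damp <- exp(-beta * (Jm - Jv[m:1]))   # <= 1, evaluated stably
    v <- qd[1:m] * ebt[1:m] * Wv[m:1] * damp
    acc <- h * (sum(v) - (v[1] + v[m]) / 2)
    if (length(qa_lag) > 0) {
      ok <- qa_lag <= m - 1
      if (any(ok)) {
        jl <- qa_lag[ok]
        acc <- acc + sum(qa$weight[ok] * ebt[jl + 1] * Wv[m - jl] *
                           exp(-beta * (Jm - Jv[m - jl])))
      }
    }
    acc
  }
  deriv <- function(m, s, ss, p, jj, Wm) {
    ds <- -beta * p
    dss <- -2 * beta * cc * ss * p / s
    dj <- cc * p / s
    dp <- -beta * cc * p^2 / s - beta * p + beta * cc * ss * p / s -
      k * N * qd[m] * ebt[m] * (1 - z) * z * exp(-beta * jj) -
      beta * conv(m, Wm, jj)
    c(ds, dss, dp, dj)
  }
  last <- n
  for (m in seq_len(n)[-1]) {
    k1 <- deriv(m - 1, S[m - 1], SS[m - 1], SI[m - 1], J[m - 1], W[m - 1])
    sp <- S[m - 1] + h * k1[1]
    if (sp <= 0) { last <- m - 1; break }
    ssp <- SS[m - 1] + h * k1[2]
    pp <- SI[m - 1] + h * k1[3]
    jp <- J[m - 1] + h * k1[4]
    Wp <- cc * ssp * pp / sp
    k2 <- deriv(m, sp, ssp, pp, jp, Wp)
    S[m] <- S[m - 1] + h / 2 * (k1[1] + k2[1])
    if (S[m] <= 0) { last <- m - 1; break }
    SS[m] <- SS[m - 1] + h / 2 * (k1[2] + k2[2])
    SI[m] <- SI[m - 1] + h / 2 * (k1[3] + k2[3])
    J[m] <- J[m - 1] + h / 2 * (k1[4] + k2[4])
    if (length(qa_lag) > 0) {
      hit <- which(qa_lag == m - 1)
      for (s in hit)
        SI[m] <- SI[m] - qa$weight[s] * k * N * ebt[m] * (1 - z) * z *
          exp(-beta * J[m])
    }
    SI[m] <- max(SI[m], 0)
    W[m] <- cc * SS[m] * SI[m] / S[m]
  }
  if (last < n) {
    warning(sprintf(
      "solve_pairwise_regular: [S] reached 0 at t = %.4f; series truncated",
      t[last]))
    t <- t[1:last]; S <- S[1:last]; SS <- SS[1:last]; SI <- SI[1:last]
  }
  I <- pairwise_I_series(SI, xq[seq_along(t)], beta, N, z, h,
                         qa_lag, qa$weight)
  H1 <- (S / (z * N))^(1 / k)
  pairwise_state(t, S, I, N - S - I, SI, H1, N, "pairwise_regular", SS = SS)
}

#' Markovian pairwise-like ODE system
#'
#' Exponential recovery at rate \code{gamma} closes the history integrals,
#' leaving the plain ODE system in (H1, \[SI\], \[I\]):
#' \eqn{\dot{[I]} = \beta[SI] - \gamma[I]}, integrated by fixed-step RK4.
#'
#' @inheritParams solve_pairwise_cm
#' @param gamma recovery rate (> 0).
#' @return a \code{pairwise_state}.
#' @export
solve_pairwise_markovian <- function(gfs, beta, gamma, z, N, tmax, h) {
  stopifnot(inherits(gfs, "gf_set"))
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be > 0")
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  mk <- gfs$mean_degree
  y <- matrix(0, n, 3)                  # H1, SI, I
  y[1, ] <- c(1, mk * N * z * (1 - z), N * (1 - z))
  f <- function(v) {
    g1 <- gfs$G1(v[1]); g2 <- gfs$G2(v[1])
    c(-beta * v[2] / (z * mk * N * g1),
      -beta * v[2]^2 * g2 / (z * mk * N * g1^2) - (beta + gamma) * v[2] +
        z * beta * v[2] * g2,
      beta * v[2] - gamma * v[3])
  }
  for (m in seq_len(n)[-1]) {
    v <- y[m - 1, ]
    k1 <- f(v); k2 <- f(v + h / 2 * k1); k3 <- f(v + h / 2 * k2)
    k4 <- f(v + h * k3)
    y[m, ] <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  S <- z * N * gfs$G0(y[, 1])
  pairwise_state(t, S, y[, 3], N - S - y[, 3], y[, 2], y[, 1], N,
                 "pairwise_markovian")
}

#' Delay-differential pairwise system for a fixed infectious period
#'
#' With \eqn{q(a) = \delta(a - \sigma)} the history integrals collapse to
#' exact lags of length \code{sigma}, and the delta sources act as impulsive
#' jumps at \eqn{t = \sigma} (the initial cohort recovers then: \[I\] drops
#' by \eqn{N(1-z)} and \[SI\] by
#' \eqn{e^{-\beta\sigma}(1-z)z G_1(H_1(\sigma))\langle k\rangle N}).
#' \code{sigma} must be an integer multiple of \code{h}, so lags are exact
#' grid shifts; lagged terms are never interpolated.
#'
#' @inheritParams solve_pairwise_cm
#' @param sigma fixed infectious period (> 0), a multiple of \code{h}.
#' @return a \code{pairwise_state}.
#' @export
solve_pairwise_fixed_delay <- function(gfs, beta, sigma, z, N, tmax, h) {
  stopifnot(inherits(gfs, "gf_set"))
  if (beta <= 0) stop("beta must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  ns <- round(sigma / h)
  if (abs(sigma - ns * h) > 1e-9)
    stop("solve_pairwise_fixed_delay: sigma must be an integer multiple of h")
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  mk <- gfs$mean_degree
  H1 <- numeric(n); SI <- numeric(n)
  H1[1] <- 1
  SI[1] <- mk * N * z * (1 - z)
  ebs <- exp(-beta * sigma)
  deriv <- function(m, H, P) {
    g1 <- gfs$G1(H); g2 <- gfs$G2(H)
    dH <- -beta * P / (z * mk * N * g1)
    dP <- -beta * P^2 * g2 / (z * mk * N * g1^2) - beta * P +
      z * beta * P * g2
    if (m - ns >= 1) {
      Hl <- H1[m - ns]; Pl <- SI[m - ns]
      dP <- dP - z * beta * ebs * Pl * gfs$G2(Hl) * g1 / gfs$G1(Hl)
    }
    c(dH, dP)
  }
  for (m in seq_len(n)[-1]) {
    k1 <- deriv(m - 1, H1[m - 1], SI[m - 1])
    k2 <- deriv(m, H1[m - 1] + h * k1[1], SI[m - 1] + h * k1[2])
    H1[m] <- H1[m - 1] + h / 2 * (k1[1] + k2[1])
    SI[m] <- SI[m - 1] + h / 2 * (k1[2] + k2[2])
    if (m - 1 == ns)                    # initial cohort recovers now
      SI[m] <- SI[m] - ebs * (1 - z) * z * gfs$G1(H1[m]) * mk * N
    SI[m] <- max(SI[m], 0)
  }
  S <- z * N * gfs$G0(H1)
  # [I](t) = beta * int_{max(0, t - sigma)}^t [SI](u) du + N(1-z) 1_{t<sigma}
  I <- numeric(n)
  I[1] <- N * (1 - z)
  for (m in seq_len(n)[-1]) {
    lo <- max(1, m - ns)
    v <- SI[lo:m]
    I[m] <- beta * h * (sum(v) - (v[1] + v[length(v)]) / 2) +
      if (m - 1 < ns) N * (1 - z) else 0
  }
  pairwise_state(t, S, I, N - S - I, SI, H1, N, "pairwise_fixed_delay")
}
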