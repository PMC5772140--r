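# Message-passing mean-field solvers: the average-message Volterra model,
# its Markovian ODE special case, exact per-edge messages on finite trees,
# and final-size / threshold analytics.

mf_trajectory <- function(t, S, I, R, message, solver, z, h) {
  out <- data.frame(t = t, S = S, I = I, R = R, message = message)
  attr(out, "solver") <- solver
  attr(out, "z") <- z
  attr(out, "h") <- h
  class(out) <- c("mf_trajectory", "data.frame")
  out
}

#' Write a mean-field trajectory as CSV
#'
#' Header \code{t,S,I,R,message}, one row per grid point, full precision.
#'
#' @param traj an \code{mf_trajectory} (or pairwise state) data frame.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

time_grid <- function(tmax, h) {
  if (h <= 0) stop("step h must be positive")
  if (tmax < h) stop("horizon must be at least one step")
  n <- round(tmax / h)
  seq(0, by = h, length.out = n + 1)
}

# grid index (0-based lag count) of an atom location; atom lags are applied
# as exact grid shifts, so locations must sit on (or within rounding of) the
# grid
atom_lag_index <- function(location, h) {
  j <- round(location / h)
  if (abs(location - j * h) > 1e-8 * max(1, location))
    warning(sprintf(
      "atom at %.6g is not on the time grid (h = %.6g); using nearest grid lag",
      location, h))
  as.integer(j)
}

#' Solve the average-message Volterra model
#'
#' Integrates the renewal equation for the average message
#' \deqn{H_1(t) = 1 - \int_0^t f(a)\,[1 - z\,G_1(H_1(t-a))]\,da,}
#' with \eqn{f(a) = \tau(a)\xi_q(a)}, by trapezoidal quadrature on a uniform
#' grid; the implicit endpoint (the a = 0 term references \eqn{H_1(t)}) is
#' resolved by fixed-point iteration (tolerance 1e-10, at most 50 sweeps).
#' Atoms of the transmission delay enter as lagged point evaluations. The
#' compartment fractions follow as \eqn{S = z G_0(H_1)},
#' \eqn{R(t) = \int_0^t q(a)[1 - S(t-a)]\,da} (atoms of q evaluated
#' directly, e.g. a fixed period \eqn{\sigma} gives
#' \eqn{R(t) = 1 - S(t-\sigma)} for \eqn{t \ge \sigma}), and I by
#' complement.
#'
#' @param gfs a \code{gf_set}.
#' @param model a \code{disease_model}.
#' @param z initial susceptible fraction, 0 < z <= 1.
#' @param tmax horizon.
#' @param h grid step.
#' @return an \code{mf_trajectory}.
#' @export
solve_mp <- function(gfs, model, z, tmax, h) {
  stopifnot(inherits(gfs, "gf_set"), inherits(model, "disease_model"))
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  fv <- model$f(t)                       # continuous part of f at grid ages
  fa <- model$f_atoms
  fa_lag <- if (nrow(fa) > 0) vapply(fa$location, atom_lag_index, integer(1),
                                     h = h) else integer(0)
  # recovery atoms make f jump down by tau(loc) * weight; the trapezoid node
  # at the jump carries the right limit, so restore the missing half cell
  ja <- model$recovery$atoms
  j_lag <- if (nrow(ja) > 0) vapply(ja$location, atom_lag_index, integer(1),
                                    h = h) else integer(0)
  j_w <- if (nrow(ja) > 0)
    model$transmission$density(ja$location) * ja$weight else numeric(0)
  H <- numeric(n); H[1] <- 1
  psi <- numeric(n); psi[1] <- 1 - z     # psi = 1 - z G1(H)
  for (m in seq_len(n)[-1]) {
    base <- h / 2 * fv[m] * psi[1]
    if (m > 2)
      base <- base + h * sum(fv[2:(m - 1)] * psi[(m - 1):2])
    if (length(fa_lag) > 0) {
      ok <- fa_lag <= m - 1
      if (any(ok))
        base <- base + sum(fa$weight[ok] * psi[m - fa_lag[ok]])
    }
    if (length(j_lag) > 0) {
      ok <- j_lag <= m - 1 & j_lag >= 1
      if (any(ok))
        base <- base + h / 2 * sum(j_w[ok] * psi[m - j_lag[ok]])
    }
    c0 <- h / 2 * fv[1]                  # weight on the implicit endpoint
    x <- H[m - 1]
    converged <- FALSE
    for (it in 1:50) {
      xn <- 1 - (base + c0 * (1 - z * gfs$G1(x)))
      if (abs(xn - x) < 1e-10) { x <- xn; converged <- TRUE; break }
      x <- xn
    }
    if (!converged)
      stop(sprintf("solve_mp: inner iteration failed at t = %.4f (residual %.3g)",
                   t[m], abs(xn - x)))
    H[m] <- min(max(x, 0), 1)
    psi[m] <- 1 - z * gfs$G1(H[m])
  }
  S <- z * gfs$G0(H)
  qd <- model$recovery$density(t)
  qa <- model$recovery$atoms
  qa_lag <- if (nrow(qa) > 0) vapply(qa$location, atom_lag_index, integer(1),
                                     h = h) else integer(0)
  oneS <- 1 - S
  R <- numeric(n)
  for (m in seq_len(n)[-1]) {
    acc <- h / 2 * (qd[1] * oneS[m] + qd[m] * oneS[1])
    if (m > 2)
      acc <- acc + h * sum(qd[2:(m - 1)] * oneS[(m - 1):2])
    if (length(qa_lag) > 0) {
      ok <- qa_lag <= m - 1
      if (any(ok))
        acc <- acc + sum(qa$weight[ok] * oneS[m - qa_lag[ok]])
    }
    R[m] <- acc
  }
  I <- 1 - S - R
  mf_trajectory(t, S, I, R, H, solver = "mp", z = z, h = h)
}

#' Solve the Markovian message ODE
#'
#' The purely Markovian case (exponential transmission rate \code{beta} and
#' recovery rate \code{gamma}) reduces the Volterra model to
#' \deqn{dH_1/dt = \gamma - (\beta+\gamma) H_1 + \beta z G_1(H_1),}
#' integrated with the classical fixed-step fourth-order Runge-Kutta scheme;
#' R is integrated alongside via \eqn{dR/dt = \gamma I}.
#'
#' @inheritParams solve_mp
#' @param beta transmission rate (> 0).
#' @param gamma recovery rate (> 0).
#' @return an \code{mf_trajectory}.
#' @export
solve_mp_markovian_ode <- function(gfs, beta, gamma, z, tmax, h) {
  stopifnot(inherits(gfs, "gf_set"))
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be > 0")
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  t <- time_grid(tmax, h)
  n <- length(t)
  H <- numeric(n); R <- numeric(n)
  H[1] <- 1
  dH <- function(x) gamma - (beta + gamma) * x + beta * z * gfs$G1(x)
  dR <- function(x, r) gamma * (1 - z * gfs$G0(x) - r)
  for (m in seq_len(n)[-1]) {
    x <- H[m - 1]; r <- R[m - 1]
    k1h <- dH(x);               k1r <- dR(x, r)
    k2h <- dH(x + h / 2 * k1h); k2r <- dR(x + h / 2 * k1h, r + h / 2 * k1r)
    k3h <- dH(x + h / 2 * k2h); k3r <- dR(x + h / 2 * k2h, r + h / 2 * k2r)
    k4h <- dH(x + h * k3h);     k4r <- dR(x + h * k3h, r + h * k3r)
    H[m] <- x + h / 6 * (k1h + 2 * k2h + 2 * k3h + k4h)
    R[m] <- r + h / 6 * (k1r + 2 * k2r + 2 * k3r + k4r)
    if (H[m] < -1e-8 || H[m] > 1 + 1e-8)
      stop("solve_mp_markovian_ode: message left [0,1]; reduce the step h")
    H[m] <- min(max(H[m], 0), 1)
  }
  S <- z * gfs$G0(H)
  I <- 1 - S - R
  mf_trajectory(t, S, I, R, H, solver = "mp_ode", z = z, h = h)
}

#' Exact per-edge messages on a finite tree
#'
#' Solves one Volterra message per directed edge,
#' \deqn{H^{u \gets v}(t) = 1 - \int_0^t f(a)\big[1 - z \prod_{w \in
#'   N(v)\setminus u} H^{v \gets w}(t-a)\big]\,da,}
#' on a shared grid, and returns the per-node susceptibility probabilities
#' \eqn{P(u\ \mathrm{susceptible\ at}\ t) = z \prod_{v \in N(u)}
#' H^{u \gets v}(t)}. On a forest this is the exact expectation of the
#' stochastic epidemic with independent per-node initial susceptibility z.
#'
#' @param network a \code{static_network}; must be a forest unless
#'   \code{allow_cycles = TRUE} (in which case the result is the usual
#'   message-passing approximation, not exact).
#' @inheritParams solve_mp
#' @param allow_cycles set TRUE to run on cyclic networks as an
#'   approximation.
#' @return list with \code{t} (grid), \code{node_S} (N x length(t) matrix of
#'   per-node susceptibility probabilities, rows in node-id order) and
#'   \code{S} (their mean, the population susceptible fraction).
#' @export
solve_mp_per_edge <- function(network, model, z, tmax, h,
                              allow_cycles = FALSE) {
  stopifnot(inherits(network, "static_network"),
            inherits(model, "disease_model"))
  if (z <= 0 || z > 1) stop("z must be in (0, 1]")
  N <- network$N
  ne <- nrow(network$edges)
  ncomp <- if (ne > 0)
    igraph::count_components(as_igraph(network)) else N
  if (ne != N - ncomp && !allow_cycles)
    stop("solve_mp_per_edge: network contains cycles; ",
         "set allow_cycles = TRUE for the (approximate) loopy solution")
  t <- time_grid(tmax, h)
  n <- length(t)
  fv <- model$f(t)
  fa <- model$f_atoms
  fa_lag <- if (nrow(fa) > 0) vapply(fa$location, atom_lag_index, integer(1),
                                     h = h) else integer(0)
  # directed edges: dedge i is (to[i] <- from[i]); message into 'to'
  to <- c(network$edges[, 1], network$edges[, 2]) + 1L
  from <- c(network$edges[, 2], network$edges[, 1]) + 1L
  nd <- length(to)
  # predecessors of dedge (u <- v): all dedges (v <- w), w != u
  preds <- vector("list", nd)
  in_at <- split(seq_len(nd), factor(to, levels = seq_len(N)))
  for (i in seq_len(nd)) {
    cand <- in_at[[from[i]]]
    preds[[i]] <- cand[from[cand] != to[i]]
  }
  M <- matrix(1, nrow = max(nd, 1), ncol = n)
  psi <- matrix(1 - z, nrow = max(nd, 1), ncol = n)
  psi_of <- function(col) {
    pr <- vapply(seq_len(nd), function(i) prod(col[preds[[i]]]), numeric(1))
    1 - z * pr
  }
  if (nd > 0) {
    for (m in seq_len(n)[-1]) {
      base <- h / 2 * fv[m] * psi[, 1]
      if (m > 2)
        base <- base + h * as.numeric(psi[, (m - 1):2, drop = FALSE] %*%
                                        fv[2:(m - 1)])
      if (length(fa_lag) > 0) {
        ok <- fa_lag <= m - 1
        for (s in which(ok))
          base <- base + fa$weight[s] * psi[, m - fa_lag[s]]
      }
      c0 <- h / 2 * fv[1]
      x <- M[, m - 1]
      converged <- FALSE
      for (it in 1:50) {
        xn <- 1 - (base + c0 * psi_of(x))
        if (max(abs(xn - x)) < 1e-10) { x <- xn; converged <- TRUE; break }
        x <- xn
      }
      if (!converged)
        stop(sprintf("solve_mp_per_edge: inner iteration failed at t = %.4f",
                     t[m]))
      M[, m] <- pmin(pmax(x, 0), 1)
      psi[, m] <- psi_of(M[, m])
    }
  }
  node_S <- matrix(z, nrow = N, ncol = n)
  for (u in seq_len(N)) {
    inc <- if (nd > 0) in_at[[u]] else integer(0)
    if (length(inc) > 0)
      node_S[u, ] <- z * apply(M[inc, , drop = FALSE], 2, prod)
  }
  list(t = t, node_S = node_S, S = colMeans(node_S))
}

#' Final epidemic size
#'
#' Solves the fixed-point equation
#' \eqn{\Theta_\infty = 1 - \tilde T + \tilde T\,G_1(\Theta_\infty)} by
#' monotone iteration from 0 (converging to the smallest root in \[0, 1\])
#' and returns the attack rate \eqn{r_\infty = 1 - G_0(\Theta_\infty)} for a
#' vanishingly small initial infected fraction.
#'
#' @param gfs a \code{gf_set}.
#' @param model a \code{disease_model}; alternatively supply
#'   \code{transmissibility} directly.
#' @param transmissibility optional scalar in \[0, 1\] overriding the model.
#' @return list with \code{theta_inf}, \code{r_inf},
#'   \code{transmissibility}.
#' @export
final_size <- function(gfs, model = NULL, transmissibility = NULL) {
  stopifnot(inherits(gfs, "gf_set"))
  tfun <- get("transmissibility", mode = "function")  # arg shadows the fn
  Tt <- if (!is.null(transmissibility)) transmissibility else tfun(model)
  if (Tt < 0 || Tt > 1) stop("transmissibility must be in [0, 1]")
  theta <- 0
  repeat {
    nxt <- 1 - Tt + Tt * gfs$G1(theta)
    if (abs(nxt - theta) < 1e-12) { theta <- nxt; break }
    theta <- nxt
  }
  list(theta_inf = theta, r_inf = 1 - gfs$G0(theta), transmissibility = Tt)
}

#' Epidemic threshold ratio
#'
#' The percolation-style reproduction ratio: transmissibility times mean
#' excess degree. A large outbreak is possible iff the ratio exceeds 1.
#'
#' @inheritParams final_size
#' @return non-negative scalar.
#' @export
epidemic_threshold <- function(gfs, model = NULL, transmissibility = NULL) {
  tfun <- get("transmissibility", mode = "function")
  Tt <- if (!is.null(transmissibility)) transmissibility else tfun(model)
  Tt * mean_excess_degree(gfs)
}
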