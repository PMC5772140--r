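# Stochastically exact SIR simulation on explicit networks: the rejection
# method (Poisson transmission, general recovery) and an event-driven
# scheme for general transmission-delay and infectious-period laws, plus
# ensemble averaging and the burn-in/clock-reset protocol.

new_event_log <- function(time, node, event, source, N, init_nodes, seed) {
  log <- data.frame(time = time, node = node, event = event, source = source,
                    stringsAsFactors = FALSE)
  attr(log, "N") <- N
  attr(log, "init_nodes") <- init_nodes
  attr(log, "seed") <- seed
  class(log) <- c("epidemic_event_log", "data.frame")
  log
}

resolve_init <- function(init, N) {
  if (length(init) == 1 && init > 0 && init < 1) {
    # fraction: each node initially infected independently (fresh cohort);
    # an empty draw is a valid (eventless) realisation
    which(stats::runif(N) < init) - 1L
  } else {
    nodes <- as.integer(init)
    if (length(nodes) == 0) stop("initial condition selects no nodes")
    if (any(nodes < 0) || any(nodes > N - 1))
      stop("initial nodes out of range 0..N-1")
    sort(unique(nodes))
  }
}

#' Rejection-method SIR simulation
#'
#' Statistically exact sample path for Poisson (rate \code{beta} per S-I
#' edge) transmission and an arbitrary infectious-period law. Recovery times
#' are drawn at the moment of infection. The next putative transmission time
#' is exponential with rate \code{beta} times the current S-I edge count; if
#' the earliest scheduled recovery precedes it, that recovery is processed
#' instead and the putative transmission is discarded (valid by
#' memorylessness of the transmission process).
#'
#' @param network a \code{static_network}.
#' @param beta per-edge transmission rate (> 0).
#' @param recovery a \code{delay_distribution}.
#' @param init either a node-id vector (0-based) of initial infecteds, or a
#'   fraction in (0,1): each node starts infected independently with that
#'   probability (fresh cohort, infection age 0).
#' @param seed integer seed; the event log is a deterministic function of
#'   the arguments.
#' @return an \code{epidemic_event_log}: data frame
#'   \code{time,node,event,source} (\code{event} in \{"infection",
#'   "recovery"\}; \code{source} is the infector id or NA), ordered by time,
#'   with attributes \code{N}, \code{init_nodes}, \code{seed}.
#' @export
simulate_rejection <- function(network, beta, recovery, init, seed) {
  stopifnot(inherits(network, "static_network"),
            inherits(recovery, "delay_distribution"))
  if (beta <= 0) stop("beta must be > 0")
  set.seed(as.integer(seed))
  N <- network$N
  adj <- adjacency_list(network)
  status <- integer(N)                   # 0 S, 1 I, 2 R
  init_nodes <- resolve_init(init, N)
  seeds1 <- init_nodes + 1L
  status[seeds1] <- 1L
  rec_time <- rep(Inf, N)
  rec_time[seeds1] <- sample_delay(recovery, length(seeds1))
  nsus <- numeric(N)                     # susceptible-neighbour count per I
  for (v in seeds1) nsus[v] <- sum(status[adj[[v]]] == 0L)
  E <- sum(nsus[seeds1])
  cap <- 2L * N + 10L
  ev_t <- numeric(cap); ev_n <- integer(cap)
  ev_k <- character(cap); ev_s <- integer(cap)
  ne <- 0L
  push <- function(tt, nn, kk, ss) {
    ne <<- ne + 1L
    ev_t[ne] <<- tt; ev_n[ne] <<- nn; ev_k[ne] <<- kk; ev_s[ne] <<- ss
  }
  for (v in seeds1) push(0, v - 1L, "infection", NA_integer_)
  t <- 0
  ninf <- length(seeds1)
  while (ninf > 0L) {
    t_trans <- if (E > 0) t + stats::rexp(1, beta * E) else Inf
    vrec <- which.min(rec_time)
    t_rec <- rec_time[vrec]
    if (t_rec <= t_trans) {
      t <- t_rec
      status[vrec] <- 2L
      E <- E - nsus[vrec]
      nsus[vrec] <- 0
      rec_time[vrec] <- Inf
      ninf <- ninf - 1L
      push(t, vrec - 1L, "recovery", NA_integer_)
    } else {
      t <- t_trans
      # choose the transmitting S-I edge uniformly: infector with
      # probability proportional to its susceptible-neighbour count
      inf_nodes <- which(nsus > 0)
      v <- if (length(inf_nodes) == 1) inf_nodes else
        sample(inf_nodes, 1, prob = nsus[inf_nodes])
      sus_nb <- adj[[v]][status[adj[[v]]] == 0L]
      u <- if (length(sus_nb) == 1) sus_nb else sample(sus_nb, 1)
      status[u] <- 1L
      rec_time[u] <- t + sample_delay(recovery, 1)
      ninf <- ninf + 1L
      inb <- adj[[u]][status[adj[[u]]] == 1L]
      nsus[inb] <- nsus[inb] - 1
      nsus[u] <- sum(status[adj[[u]]] == 0L)
      E <- E - length(inb) + nsus[u]
      push(t, u - 1L, "infection", v - 1L)
    }
  }
  ii <- seq_len(ne)
  new_event_log(ev_t[ii], ev_n[ii], ev_k[ii], ev_s[ii],
                N, init_nodes, seed)
}

#' Event-driven SIR simulation for general delays
#'
#' Per-edge generalisation of the stochastic SIR process: when node v is
#' infected at time t, a recovery delay r ~ q is drawn and a recovery
#' scheduled at t + r; for each neighbour an independent transmission delay
#' d ~ tau is drawn and an attempt is scheduled at t + d iff d < r (so the
#' per-edge first-attempt age law is exactly f(a) = tau(a) xi_q(a)).
#' Attempts on non-susceptible targets are no-ops. Simultaneous events are
#' processed in (time, node id, kind) order with recoveries first.
#'
#' @param network a \code{static_network}.
#' @param transmission a \code{delay_distribution} for tau.
#' @param recovery a \code{delay_distribution} for q.
#' @inheritParams simulate_rejection
#' @return an \code{epidemic_event_log}.
#' @export
simulate_event_driven <- function(network, transmission, recovery, init,
                                  seed) {
  stopifnot(inherits(network, "static_network"),
            inherits(transmission, "delay_distribution"),
            inherits(recovery, "delay_distribution"))
  set.seed(as.integer(seed))
  N <- network$N
  adj <- adjacency_list(network)
  status <- integer(N)
  init_nodes <- resolve_init(init, N)
  # pending events: kind 1 = recovery, 2 = transmission attempt
  q_t <- numeric(0); q_node <- integer(0); q_kind <- integer(0)
  q_src <- integer(0)
  schedule_infection <- function(u, tt, src) {
    status[u] <<- 1L
    r <- sample_delay(recovery, 1)
    q_t <<- c(q_t, tt + r); q_node <<- c(q_node, u)
    q_kind <<- c(q_kind, 1L); q_src <<- c(q_src, NA_integer_)
    nb <- adj[[u]]
    if (length(nb) > 0) {
      d <- sample_delay(transmission, length(nb))
      ok <- d < r
      if (any(ok)) {
        q_t <<- c(q_t, tt + d[ok]); q_node <<- c(q_node, nb[ok])
        q_kind <<- c(q_kind, rep(2L, sum(ok)))
        q_src <<- c(q_src, rep(u, sum(ok)))
      }
    }
  }
  ev_t <- numeric(0); ev_n <- integer(0); ev_k <- character(0)
  ev_s <- integer(0)
  for (u in sort(init_nodes + 1L)) {
    schedule_infection(u, 0, NA_integer_)
    ev_t <- c(ev_t, 0); ev_n <- c(ev_n, u - 1L)
    ev_k <- c(ev_k, "infection"); ev_s <- c(ev_s, NA_integer_)
  }
  while (length(q_t) > 0 && any(is.finite(q_t))) {
    tmin <- min(q_t)
    if (!is.finite(tmin)) break
    cand <- which(q_t == tmin)
    if (length(cand) > 1) {
      ord <- order(q_node[cand], q_kind[cand])
      cand <- cand[ord]
    }
    i <- cand[1]
    tt <- q_t[i]; u <- q_node[i]; kind <- q_kind[i]; src <- q_src[i]
    q_t[i] <- Inf
    if (kind == 1L) {
      status[u] <- 2L
      ev_t <- c(ev_t, tt); ev_n <- c(ev_n, u - 1L)
      ev_k <- c(ev_k, "recovery"); ev_s <- c(ev_s, NA_integer_)
    } else if (status[u] == 0L) {
      schedule_infection(u, tt, src)
      ev_t <- c(ev_t, tt); ev_n <- c(ev_n, u - 1L)
      ev_k <- c(ev_k, "infection"); ev_s <- c(ev_s, src - 1L)
    }
  }
  new_event_log(ev_t, ev_n, ev_k, ev_s, N, init_nodes, seed)
}

# S/I/R counts immediately after each event, plus the initial state
log_count_series <- function(log) {
  N <- attr(log, "N")
  n0 <- length(attr(log, "init_nodes"))
  dS <- ifelse(log$event == "infection", -1L, 0L)
  dI <- ifelse(log$event == "infection", 1L, -1L)
  # seed infections at t=0 are already counted in the initial state
  seed0 <- log$time == 0 & log$event == "infection" & is.na(log$source)
  dS[seed0] <- 0L; dI[seed0] <- 0L
  S <- N - n0 + cumsum(dS)
  I <- n0 + cumsum(dI)
  list(time = log$time, S = S, I = I, R = N - S - I,
       S0 = N - n0, I0 = n0)
}

#' Average an ensemble of event logs on a grid
#'
#' Reconstructs each run's S/I/R fractions at every grid time (state after
#' the last event at or before t; right-continuous step functions) and
#' returns per-point means and standard errors over the retained runs.
#'
#' @param logs list of \code{epidemic_event_log}s (same N).
#' @param grid numeric vector of output times.
#' @param discard logical vector marking runs to drop (e.g. from
#'   [align_at_threshold()]); default keeps all.
#' @return Object of class \code{"ensemble_summary"}: data frame
#'   \code{t,S_mean,S_se,I_mean,I_se,R_mean,R_se} with attributes
#'   \code{n_retained}, \code{n_discarded}, and matrices \code{S}, \code{I},
#'   \code{R} (run x grid fractions) in attribute \code{runs}.
#' @export
ensemble_average <- function(logs, grid, discard = NULL) {
  if (is.null(discard)) discard <- rep(FALSE, length(logs))
  keep <- which(!discard)
  if (length(keep) == 0) stop("ensemble_average: zero retained runs")
  Ns <- vapply(logs[keep], function(l) attr(l, "N"), numeric(1))
  if (length(unique(Ns)) != 1)
    stop("ensemble_average: logs have differing network sizes")
  N <- Ns[1]
  ng <- length(grid)
  Sm <- matrix(0, length(keep), ng)
  Im <- matrix(0, length(keep), ng)
  for (r in seq_along(keep)) {
    cs <- log_count_series(logs[[keep[r]]])
    idx <- findInterval(grid, cs$time)   # 0 => before first event
    Sm[r, ] <- ifelse(idx == 0, cs$S0, cs$S[pmax(idx, 1)]) / N
    Im[r, ] <- ifelse(idx == 0, cs$I0, cs$I[pmax(idx, 1)]) / N
  }
  Rm <- 1 - Sm - Im
  se <- function(M) apply(M, 2, stats::sd) / sqrt(nrow(M))
  out <- data.frame(t = grid,
                    S_mean = colMeans(Sm), S_se = se(Sm),
                    I_mean = colMeans(Im), I_se = se(Im),
                    R_mean = colMeans(Rm), R_se = se(Rm))
  attr(out, "n_retained") <- length(keep)
  attr(out, "n_discarded") <- sum(discard)
  attr(out, "runs") <- list(S = Sm, I = Im, R = Rm)
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Write an ensemble summary as CSV
#'
#' @param summary an \code{ensemble_summary}.
#' @param path output path.
#' @export
write_ensemble_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Reset the clock when prevalence first reaches a threshold
#'
#' Burn-in protocol for comparing single-seed runs with mean-field curves:
#' the clock is shifted so that the first time the infected fraction reaches
#' \code{threshold_fraction} becomes t = 0. Runs that never reach the
#' threshold are flagged discarded. The susceptible fraction at the reset is
#' reported so the mean-field initial condition z can be matched.
#'
#' @param log an \code{epidemic_event_log}.
#' @param threshold_fraction prevalence threshold in (0, 1).
#' @return list with \code{log} (time-shifted, or the original when
#'   discarded), \code{discarded} flag, \code{shift} (the subtracted time),
#'   and \code{z_at_reset} (susceptible fraction at the new t = 0; NA when
#'   discarded).
#' @export
align_at_threshold <- function(log, threshold_fraction) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  N <- attr(log, "N")
  cs <- log_count_series(log)
  if (cs$I0 / N >= threshold_fraction) {
    return(list(log = log, discarded = FALSE, shift = 0,
                z_at_reset = cs$S0 / N))
  }
  hit <- which(cs$I / N >= threshold_fraction)
  if (length(hit) == 0)
    return(list(log = log, discarded = TRUE, shift = NA_real_,
                z_at_reset = NA_real_))
  k <- hit[1]
  shift <- cs$time[k]
  shifted <- log
  shifted$time <- log$time - shift
  list(log = shifted, discarded = FALSE, shift = shift,
       z_at_reset = cs$S[k] / N)
}

#' Derive a per-run seed from a master seed
#'
#' Deterministic splitting rule so ensembles are reproducible and runs are
#' independent by contract: \code{(master * 48271 + run) mod (2^31 - 1)}
#' (evaluated in double precision, exact below 2^53).
#'
#' @param master master integer seed.
#' @param run run index (1-based).
#' @return integer seed.
#' @export
derive_seed <- function(master, run) {
  as.integer((as.numeric(master) * 48271 + run) %% 2147483647)
}
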