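# Experiment configuration, fixtures, and the end-to-end runner that
# compares mean-field solvers against simulation ensembles on one shared
# grid.

#' Build or validate an experiment configuration
#'
#' A flat list describing one comparison experiment: degree spec, disease
#' spec (textual distribution strings, see [parse_delay_spec()]), initial
#' susceptible fraction, population size, grid, run count, master seed and
#' the solvers to run.
#'
#' @param degree either a \code{degree_distribution} or a spec list, e.g.
#'   \code{list(kind = "powerlaw_truncated", exponent = 2.5, kmin = 3,
#'   kmax = 60)}.
#' @param transmission,recovery textual delay specs (\code{"exp:0.3"},
#'   \code{"fixed:2"}, \code{"normal:2,0.75"}, ...).
#' @param z initial susceptible fraction.
#' @param N population size for simulations and pairwise counts.
#' @param tmax,h output grid.
#' @param runs simulation run count (>= 1).
#' @param seed master seed.
#' @param solvers character subset of
#'   \code{c("mp", "ebcm", "ode", "pairwise_cm", "pairwise_regular",
#'   "pairwise_markovian", "pairwise_fixed")}.
#' @param sim_method \code{"rejection"} or \code{"event"}.
#' @param network optional path to an edge-list TSV; overrides \code{degree}
#'   for the simulation (mean-field solvers still use \code{degree}).
#' @return validated config list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(degree, transmission, recovery, z = 0.99,
                              N = 1000, tmax = 15, h = 0.01, runs = 200,
                              seed = 1, solvers = c("mp", "ebcm"),
                              sim_method = "rejection", network = NULL) {
  if (runs < 1) stop("experiment_config: 'runs' must be >= 1")
  if (h <= 0 || tmax < h) stop("experiment_config: need h > 0 and tmax >= h")
  if (z <= 0 || z > 1) stop("experiment_config: z must be in (0, 1]")
  known <- c("mp", "ebcm", "ode", "pairwise_cm", "pairwise_regular",
             "pairwise_markovian", "pairwise_fixed")
  if (!all(solvers %in% known))
    stop("unknown solver(s): ", paste(setdiff(solvers, known), collapse = ", "))
  if (!sim_method %in% c("rejection", "event"))
    stop("sim_method must be 'rejection' or 'event'")
  cfg <- list(degree = degree, transmission = transmission,
              recovery = recovery, z = z, N = N, tmax = tmax, h = h,
              runs = runs, seed = seed, solvers = solvers,
              sim_method = sim_method, network = network)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from flat JSON
#'
#' @param path JSON file with the fields of [experiment_config()].
#' @return an \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, raw)
}

config_degree_distribution <- function(degree) {
  if (inherits(degree, "degree_distribution")) return(degree)
  kind <- degree$kind
  params <- degree[setdiff(names(degree), "kind")]
  make_degree_distribution(kind, params)
}

#' Run a full comparison experiment
#'
#' Runs every requested mean-field solver on the config grid, an ensemble
#' of stochastic simulations (fresh-cohort initial conditions, one freshly
#' sampled configuration-model network per run unless an explicit network is
#' supplied), pairwise equivalence reports for every solver pair, final-size
#' and threshold analytics, and writes everything to \code{outdir} as CSV /
#' JSON. Solver/model incompatibilities (e.g. a pairwise solver with
#' non-exponential transmission) are reported per solver without aborting
#' the rest. The whole bundle is a deterministic function of the config.
#'
#' @param config an \code{experiment_config}.
#' @param outdir output directory (created if missing); NULL returns results
#'   without writing.
#' @return (invisibly) list with \code{trajectories} (named list of
#'   \code{mf_trajectory}/per-capita pairwise data frames), \code{ensemble},
#'   \code{equivalence} (named list of gap reports), \code{final_size},
#'   \code{threshold}, \code{errors} (named character), \code{band_report}.
#' @export
run_experiment <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dd <- config_degree_distribution(config$degree)
  gfs <- generating_functions(dd)
  tau <- parse_delay_spec(config$transmission)
  q <- parse_delay_spec(config$recovery)
  model <- disease_model(tau, q)
  z <- config$z; N <- config$N; tmax <- config$tmax; h <- config$h
  beta <- if (tau$kind == "exponential") tau$params$rate else NA_real_
  trajs <- list(); errors <- character(0)
  as_percap <- function(ps) {
    mf_trajectory(ps$t, ps$S / N, ps$I / N, ps$R / N, ps$H1,
                  solver = attr(ps, "solver"), z = z, h = h)
  }
  for (sv in config$solvers) {
    res <- tryCatch(switch(sv,
      mp = solve_mp(gfs, model, z, tmax, h),
      ebcm = solve_ebcm(gfs, model, z, tmax, h)$trajectory,
      ode = {
        if (tau$kind != "exponential" || q$kind != "exponential")
          stop("ode solver requires exponential transmission and recovery")
        solve_mp_markovian_ode(gfs, tau$params$rate, q$params$rate, z,
                               tmax, h)
      },
      pairwise_cm = {
        if (tau$kind != "exponential")
          stop("pairwise hierarchy requires Poisson (exponential) transmission")
        as_percap(solve_pairwise_cm(gfs, beta, q, z, N, tmax, h))
      },
      pairwise_regular = {
        if (tau$kind != "exponential")
          stop("pairwise hierarchy requires Poisson (exponential) transmission")
        if (dd$kind != "regular")
          stop("pairwise_regular requires a regular degree distribution")
        as_percap(solve_pairwise_regular(dd$params$k, beta, q, z, N,
                                         tmax, h))
      },
      pairwise_markovian = {
        if (tau$kind != "exponential" || q$kind != "exponential")
          stop("pairwise_markovian requires exponential transmission and recovery")
        as_percap(solve_pairwise_markovian(gfs, beta, q$params$rate, z, N,
                                           tmax, h))
      },
      pairwise_fixed = {
        if (tau$kind != "exponential" || q$kind != "fixed")
          stop("pairwise_fixed requires exponential transmission and fixed recovery")
        as_percap(solve_pairwise_fixed_delay(gfs, beta, q$params$sigma, z,
                                             N, tmax, h))
      }), error = function(e) conditionMessage(e))
    if (is.character(res)) errors[sv] <- res else trajs[[sv]] <- res
  }
  # simulation ensemble, fresh-cohort seeding with fraction 1 - z
  fixed_net <- if (!is.null(config$network))
    read_edgelist_tsv(config$network) else NULL
  logs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    sd_r <- derive_seed(config$seed, r)
    net <- if (!is.null(fixed_net)) fixed_net else
      sample_configuration_network(dd, N, derive_seed(config$seed, 100000 + r))
    logs[[r]] <- if (config$sim_method == "rejection") {
      if (tau$kind != "exponential")
        stop("rejection simulation requires exponential transmission; ",
             "use sim_method = 'event'")
      simulate_rejection(net, tau$params$rate, q, init = 1 - z, seed = sd_r)
    } else {
      simulate_event_driven(net, tau, q, init = 1 - z, seed = sd_r)
    }
  }
  grid <- time_grid(tmax, h)
  # coarse output grid for the ensemble (every ~0.25 time units)
  stride <- max(1L, round(0.25 / h))
  egrid <- grid[seq(1, length(grid), by = stride)]
  ens <- ensemble_average(logs, egrid)
  # equivalence reports for each solver pair
  eq <- list()
  nm <- names(trajs)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      key <- paste(nm[i], nm[j], sep = "_vs_")
      eq[[key]] <- equivalence_report(trajs[[nm[i]]], trajs[[nm[j]]])
    }
  }
  fs <- final_size(gfs, model)
  th <- epidemic_threshold(gfs, transmissibility = fs$transmissibility)
  # CI band check of the first mean-field trajectory against the ensemble
  band <- NULL
  if (length(trajs) > 0) {
    tr <- trajs[[1]]
    idx <- match(round(egrid, 10), round(tr$t, 10))
    mfI <- tr$I[idx]
    lo <- ens$I_mean - 1.96 * ens$I_se
    hi <- ens$I_mean + 1.96 * ens$I_se
    band <- list(solver = nm[1],
                 coverage = mean(mfI >= lo & mfI <= hi),
                 n_points = length(egrid))
  }
  out <- list(trajectories = trajs, ensemble = ens, equivalence = eq,
              final_size = fs, threshold = th, errors = errors,
              band_report = band)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sv in names(trajs))
      write_trajectory_csv(trajs[[sv]],
                           file.path(outdir, paste0("trajectory_", sv, ".csv")))
    write_ensemble_csv(ens, file.path(outdir, "ensemble.csv"))
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config), "degree")],
           degree = if (inherits(config$degree, "degree_distribution"))
             config$degree$params else config$degree,
           final_size = fs, threshold = th,
           equivalence = eq, band_report = band,
           errors = as.list(errors)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Deterministic fixtures: small networks and standard configs
#'
#' Known kinds: networks \code{"path3"}, \code{"star5"}, \code{"btree3"}
#' (depth-3 binary tree, 15 nodes), \code{"cycle10"}; configs
#' \code{"fig3_exponential"}, \code{"fig3_normal"}, \code{"fig3_fixed"}
#' (truncated power-law degree 2.5 on 3..60, N = 1000, Poisson transmission
#' at rate 0.3 with mean infectious period 2 under the respective law) and
#' \code{"markovian_regular"} (k = 5, rates 0.3/0.5).
#'
#' @param kind fixture name.
#' @param dir output directory; NULL returns the object without writing.
#' @return the network or config object (invisibly if written).
#' @export
make_fixture <- function(kind, dir = NULL) {
  networks <- list(
    path3 = cbind(c(0, 1), c(1, 2)),
    star5 = cbind(rep(0, 4), 1:4),
    btree3 = cbind(rep(0:6, each = 2)[1:14],
                   c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14)),
    cycle10 = cbind(0:9, c(1:9, 0))
  )
  fig3_degree <- list(kind = "powerlaw_truncated", exponent = 2.5,
                      kmin = 3, kmax = 60)
  configs <- list(
    fig3_exponential = experiment_config(fig3_degree, "exp:0.3", "exp:0.5"),
    fig3_normal = experiment_config(fig3_degree, "exp:0.3", "normal:2,0.75"),
    fig3_fixed = experiment_config(fig3_degree, "exp:0.3", "fixed:2"),
    markovian_regular = experiment_config(list(kind = "regular", k = 5),
                                          "exp:0.3", "exp:0.5",
                                          solvers = c("mp", "ebcm", "ode"))
  )
  if (kind %in% names(networks)) {
    em <- networks[[kind]]
    net <- make_static_network(max(em) + 1L, em)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_edgelist_tsv(net, file.path(dir, paste0(kind, ".tsv")))
      return(invisible(net))
    }
    return(net)
  }
  if (kind %in% names(configs)) {
    cfg <- configs[[kind]]
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(unclass(cfg), file.path(dir, paste0(kind, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      return(invisible(cfg))
    }
    return(cfg)
  }
  stop("unknown fixture '", kind, "'; available: ",
       paste(c(names(networks), names(configs)), collapse = ", "))
}
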