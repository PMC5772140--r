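#' Construct a transmission-delay or infectious-period distribution
#'
#' Represents a non-negative delay as an absolutely continuous part
#' (density/survival/hazard evaluators) plus a list of point masses
#' (atoms). A fixed infectious period of length \code{sigma} is a pure atom
#' at \code{sigma}; an empirical table is a collection of atoms. All solvers
#' in the package handle atoms by direct evaluation, never by density
#' approximation.
#'
#' Supported kinds and parameters:
#' \describe{
#'   \item{\code{"exponential"}}{\code{rate}.}
#'   \item{\code{"fixed"}}{\code{sigma} > 0 (a single atom).}
#'   \item{\code{"truncated_normal"}}{\code{mean}, \code{sd}; the normal is
#'     restricted to \[0, Inf) and renormalised.}
#'   \item{\code{"gamma"}}{\code{shape}, \code{scale}.}
#'   \item{\code{"weibull"}}{\code{shape}, \code{scale}.}
#'   \item{\code{"empirical"}}{\code{delays}, \code{probs}: discrete table.}
#' }
#'
#' @param kind distribution family (see Details).
#' @param params named list of parameters.
#' @return Object of class \code{"delay_distribution"} with fields
#'   \code{kind}, \code{params}, \code{density(a)}, \code{survival(a)}
#'   (\eqn{\xi(a) = P(X > a)}), \code{hazard(a)} (continuous part, defined
#'   where survival > 0), \code{atoms} (data.frame \code{location},
#'   \code{weight}), \code{sample(n)} (draws using the current RNG state),
#'   and \code{upper} (effective support bound: survival < 1e-12 beyond it).
#' @examples
#' q <- make_delay_distribution("fixed", list(sigma = 2))
#' q$survival(c(1.9, 2, 2.1))   # 1 0 0
#' @export
make_delay_distribution <- function(kind = c("exponential", "fixed",
                                             "truncated_normal", "gamma",
                                             "weibull", "empirical"),
                                    params = list()) {
  kind <- match.arg(kind)
  atoms <- data.frame(location = numeric(0), weight = numeric(0))
  if (kind == "exponential") {
    rate <- params$rate
    if (is.null(rate) || rate <= 0) stop("exponential: 'rate' must be > 0")
    density <- function(a) stats::dexp(a, rate)
    survival <- function(a) stats::pexp(a, rate, lower.tail = FALSE)
    sampler <- function(n) stats::rexp(n, rate)
    upper <- stats::qexp(1e-12, rate, lower.tail = FALSE)
    m <- 1 / rate
  } else if (kind == "fixed") {
    sigma <- params$sigma
    if (is.null(sigma) || sigma <= 0) stop("fixed: 'sigma' must be > 0")
    atoms <- data.frame(location = sigma, weight = 1)
    density <- function(a) rep(0, length(a))
    survival <- function(a) as.numeric(a < sigma)
    sampler <- function(n) rep(sigma, n)
    upper <- sigma
    m <- sigma
  } else if (kind == "truncated_normal") {
    mu <- params$mean; sd <- params$sd
    if (is.null(mu) || is.null(sd) || sd <= 0)
      stop("truncated_normal: need 'mean' and 'sd' > 0")
    z0 <- stats::pnorm(0, mu, sd)         # mass below 0, removed
    norm <- 1 - z0
    if (norm <= 0) stop("truncated_normal: no mass on [0, Inf)")
    density <- function(a) ifelse(a >= 0, stats::dnorm(a, mu, sd) / norm, 0)
    survival <- function(a)
      ifelse(a <= 0, 1, stats::pnorm(a, mu, sd, lower.tail = FALSE) / norm)
    sampler <- function(n)
      stats::qnorm(z0 + stats::runif(n) * norm, mu, sd)
    upper <- stats::qnorm(1e-12 * norm, mu, sd, lower.tail = FALSE)
    m <- mu + sd * stats::dnorm(mu / sd) / (1 - z0) # truncated-normal mean
  } else if (kind == "gamma") {
    shape <- params$shape; scale <- params$scale
    if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0)
      stop("gamma: need 'shape' > 0 and 'scale' > 0")
    density <- function(a) stats::dgamma(a, shape, scale = scale)
    survival <- function(a) stats::pgamma(a, shape, scale = scale,
                                          lower.tail = FALSE)
    sampler <- function(n) stats::rgamma(n, shape, scale = scale)
    upper <- stats::qgamma(1e-12, shape, scale = scale, lower.tail = FALSE)
    m <- shape * scale
  } else if (kind == "weibull") {
    shape <- params$shape; scale <- params$scale
    if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0)
      stop("weibull: need 'shape' > 0 and 'scale' > 0")
    density <- function(a) stats::dweibull(a, shape, scale)
    survival <- function(a) stats::pweibull(a, shape, scale,
                                            lower.tail = FALSE)
    sampler <- function(n) stats::rweibull(n, shape, scale)
    upper <- stats::qweibull(1e-12, shape, scale, lower.tail = FALSE)
    m <- scale * gamma(1 + 1 / shape)
  } else { # empirical: discrete table of delays
    delays <- params$delays; probs <- params$probs
    if (is.null(delays) || is.null(probs) || length(delays) != length(probs))
      stop("empirical: 'delays' and 'probs' must have equal length")
    if (any(delays < 0)) stop("empirical: negative delays not allowed")
    if (any(probs < 0) || sum(probs) <= 0)
      stop("empirical: probabilities must be non-negative with positive sum")
    ord <- order(delays)
    delays <- delays[ord]; probs <- probs[ord] / sum(probs[ord])
    atoms <- data.frame(location = delays, weight = probs)
    density <- function(a) rep(0, length(a))
    survival <- function(a)
      vapply(a, function(x) sum(probs[delays > x]), numeric(1))
    sampler <- function(n) sample(delays, n, replace = TRUE, prob = probs)
    upper <- max(delays)
    m <- sum(delays * probs)
  }
  hazard <- function(a) {
    s <- survival(a)
    ifelse(s > 0, density(a) / s, NA_real_)
  }
  structure(list(kind = kind, params = params, density = density,
                 survival = survival, hazard = hazard, atoms = atoms,
                 sample = sampler, upper = upper, mean = m),
            class = "delay_distribution")
}

#' @export
print.delay_distribution <- function(x, ...) {
  cat(sprintf("Delay distribution (%s), mean %.6g", x$kind, x$mean))
  if (nrow(x$atoms) > 0)
    cat(sprintf(", %d atom(s)", nrow(x$atoms)))
  cat("\n")
  invisible(x)
}

#' Parse a textual delay-distribution spec
#'
#' Grammar: \code{"exp:rate"}, \code{"fixed:sigma"}, \code{"normal:mean,sd"},
#' \code{"gamma:shape,scale"}, \code{"weibull:shape,scale"},
#' \code{"empirical:path.tsv"} (two-column TSV: delay, probability).
#'
#' @param spec character scalar.
#' @return a \code{delay_distribution}.
#' @export
parse_delay_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("delay spec must be of the form 'kind:params'")
  key <- parts[1]
  if (key == "empirical") {
    tab <- utils::read.table(parts[2], sep = "\t", header = FALSE)
    return(make_delay_distribution("empirical",
                                   list(delays = tab[[1]], probs = tab[[2]])))
  }
  vals <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  switch(key,
         exp = make_delay_distribution("exponential", list(rate = vals[1])),
         fixed = make_delay_distribution("fixed", list(sigma = vals[1])),
         normal = make_delay_distribution("truncated_normal",
                                          list(mean = vals[1], sd = vals[2])),
         gamma = make_delay_distribution("gamma",
                                         list(shape = vals[1], scale = vals[2])),
         weibull = make_delay_distribution("weibull",
                                           list(shape = vals[1], scale = vals[2])),
         stop("unknown delay spec kind: ", key))
}

#' Draw delays from a distribution
#'
#' Uses R's global RNG stream; set a seed beforehand for reproducibility.
#'
#' @param dist a \code{delay_distribution}.
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
sample_delay <- function(dist, n = 1) {
  stopifnot(inherits(dist, "delay_distribution"))
  dist$sample(n)
}

#' Mean of a delay distribution by survival integration
#'
#' Computes \eqn{E[X] = \int_0^\infty \xi(a)\,da} by adaptive quadrature,
#' splitting the domain at atom locations where the survival function jumps.
#'
#' @param dist a \code{delay_distribution}.
#' @return the mean delay.
#' @export
delay_mean <- function(dist) {
  stopifnot(inherits(dist, "delay_distribution"))
  integrate_with_breaks(dist$survival, 0, dist$upper, dist$atoms$location)
}

# adaptive quadrature of a (piecewise-smooth) function, with the domain
# split at the given break points
integrate_with_breaks <- function(fun, lower, upper, breaks = numeric(0),
                                  tol = 1e-10) {
  pts <- sort(unique(c(lower, upper, breaks[breaks > lower & breaks < upper])))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    res <- stats::integrate(fun, pts[i], pts[i + 1], abs.tol = tol,
                            rel.tol = tol, subdivisions = 500L,
                            stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected"))
      stop("quadrature failed on [", pts[i], ", ", pts[i + 1], "]: ",
           res$message)
    total <- total + res$value
  }
  total
}

#' Bundle transmission and recovery into a disease model
#'
#' The two delays are assumed independent. The object carries the derived
#' kernels \eqn{f(a) = \tau(a)\,\xi_q(a)} (transmission attempt at infection
#' age a, before recovery) and \eqn{g(a) = q(a)\,\xi_\tau(a)} (recovery at
#' age a without a prior transmission attempt along the edge). Atoms of
#' \eqn{\tau} induce atoms of f with weight \eqn{w\,\xi_q(\mathrm{loc})};
#' atoms of q induce atoms of g with weight \eqn{w\,P(\tau \ge \mathrm{loc})}
#' (at an exact tie the recovery wins, so transmit-first and recover-first
#' remain exhaustive).
#'
#' @param transmission a \code{delay_distribution} for the per-edge
#'   transmission delay \eqn{\tau}.
#' @param recovery a \code{delay_distribution} for the infectious period q.
#' @return Object of class \code{"disease_model"} with \code{transmission},
#'   \code{recovery}, \code{f(a)}, \code{g(a)} (continuous parts),
#'   \code{f_atoms}, \code{g_atoms}, \code{upper}.
#' @export
disease_model <- function(transmission, recovery) {
  stopifnot(inherits(transmission, "delay_distribution"),
            inherits(recovery, "delay_distribution"))
  tau <- transmission; q <- recovery
  survival_incl <- function(d, a) {
    # P(X >= a): survival plus any atom sitting exactly at a
    s <- d$survival(a)
    if (nrow(d$atoms) > 0)
      s <- s + vapply(a, function(x)
        sum(d$atoms$weight[d$atoms$location == x]), numeric(1))
    s
  }
  f <- function(a) tau$density(a) * q$survival(a)
  g <- function(a) q$density(a) * tau$survival(a)
  f_atoms <- if (nrow(tau$atoms) > 0)
    data.frame(location = tau$atoms$location,
               weight = tau$atoms$weight * q$survival(tau$atoms$location))
  else data.frame(location = numeric(0), weight = numeric(0))
  g_atoms <- if (nrow(q$atoms) > 0)
    data.frame(location = q$atoms$location,
               weight = q$atoms$weight * survival_incl(tau, q$atoms$location))
  else data.frame(location = numeric(0), weight = numeric(0))
  structure(list(transmission = tau, recovery = q, f = f, g = g,
                 f_atoms = f_atoms, g_atoms = g_atoms,
                 upper = min(tau$upper, q$upper)),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Disease model: transmission %s, recovery %s, T = %.6g\n",
              x$transmission$kind, x$recovery$kind, transmissibility(x)))
  invisible(x)
}

#' Evaluate the competing-risk kernels f and g
#'
#' Continuous parts only; atoms are carried separately on the model object
#' (\code{model$f_atoms}, \code{model$g_atoms}).
#'
#' @param model a \code{disease_model}.
#' @param a infection age(s), >= 0.
#' @return list with numeric fields \code{f} and \code{g}.
#' @export
f_and_g <- function(model, a) {
  stopifnot(inherits(model, "disease_model"))
  if (any(a < 0)) stop("f_and_g: age must be non-negative")
  list(f = model$f(a), g = model$g(a))
}

#' Transmissibility of the disease
#'
#' The probability \eqn{\tilde T = \int_0^\infty f(a)\,da} that an infected
#' node attempts transmission across a given edge before recovering.
#' Computed by adaptive quadrature of the continuous part (domain split at
#' survival-function jumps of the recovery law) plus direct evaluation of
#' atoms of the transmission delay against the recovery survival.
#'
#' @param model a \code{disease_model}.
#' @return scalar in \[0, 1\].
#' @export
transmissibility <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  cap <- model$transmission$upper
  breaks <- c(model$recovery$atoms$location, model$f_atoms$location)
  cont <- if (cap > 0)
    integrate_with_breaks(model$f, 0, cap, breaks) else 0
  val <- cont + sum(model$f_atoms$weight)
  min(max(val, 0), 1)
}

# convenience constructor for the fully Markovian model
markovian_model <- function(beta, gamma) {
  disease_model(make_delay_distribution("exponential", list(rate = beta)),
                make_delay_distribution("exponential", list(rate = gamma)))
}
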