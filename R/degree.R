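#' Construct a degree distribution
#'
#' Builds the probability mass function \eqn{p_k} of the node degree for one
#' of the supported families, normalised on its support.
#'
#' Supported kinds:
#' \describe{
#'   \item{\code{"regular"}}{all nodes have degree \code{k} (\code{params$k >= 1}).}
#'   \item{\code{"poisson"}}{Poisson with mean \code{lambda}, truncated at
#'     \code{kmax} (default: smallest k with tail mass below 1e-10) and
#'     renormalised.}
#'   \item{\code{"powerlaw_truncated"}}{\eqn{p_k \propto k^{-\alpha}} on
#'     \code{kmin..kmax} (\code{exponent} > 1).}
#'   \item{\code{"empirical"}}{explicit masses: \code{params$support},
#'     \code{params$pmf} (non-negative, renormalised).}
#' }
#'
#' @param kind one of \code{"regular"}, \code{"poisson"},
#'   \code{"powerlaw_truncated"}, \code{"empirical"}.
#' @param params named list of family parameters (see Details).
#' @return An object of class \code{"degree_distribution"} with fields
#'   \code{support}, \code{pmf}, \code{kind}, \code{params},
#'   \code{mean_degree}.
#' @examples
#' dd <- make_degree_distribution("powerlaw_truncated",
#'                                list(exponent = 2.5, kmin = 3, kmax = 60))
#' dd$mean_degree
#' @export
make_degree_distribution <- function(kind = c("regular", "poisson",
                                              "powerlaw_truncated", "empirical"),
                                     params = list()) {
  kind <- match.arg(kind)
  if (kind == "regular") {
    k <- params$k
    if (is.null(k) || length(k) != 1L || k < 1 || k != round(k))
      stop("regular degree distribution: 'k' must be a single integer >= 1")
    support <- as.integer(k)
    pmf <- 1
  } else if (kind == "poisson") {
    lambda <- params$lambda
    if (is.null(lambda) || lambda <= 0)
      stop("poisson degree distribution: 'lambda' must be > 0")
    kmax <- params$kmax
    if (is.null(kmax)) {
      kmax <- stats::qpois(1 - 1e-10, lambda)
      while (stats::ppois(kmax, lambda, lower.tail = FALSE) >= 1e-10)
        kmax <- kmax + 1L
    }
    support <- 0:kmax
    pmf <- stats::dpois(support, lambda)
    pmf <- pmf / sum(pmf)
  } else if (kind == "powerlaw_truncated") {
    alpha <- params$exponent
    kmin <- params$kmin
    kmax <- params$kmax
    if (is.null(alpha) || alpha <= 1)
      stop("powerlaw_truncated: 'exponent' must be > 1")
    if (is.null(kmin) || is.null(kmax) || kmin < 1 || kmax < kmin)
      stop("powerlaw_truncated: need 1 <= kmin <= kmax")
    support <- as.integer(kmin):as.integer(kmax)
    pmf <- support^(-alpha)
    pmf <- pmf / sum(pmf)
  } else { # empirical
    support <- params$support
    pmf <- params$pmf
    if (is.null(support) || is.null(pmf) || length(support) != length(pmf))
      stop("empirical: 'support' and 'pmf' must have equal length")
    if (any(support < 0) || any(support != round(support)))
      stop("empirical: 'support' must contain non-negative integers")
    if (any(pmf < 0)) stop("empirical: 'pmf' must be non-negative")
    if (sum(pmf) <= 0) stop("empirical: 'pmf' sums to zero")
    ord <- order(support)
    support <- as.integer(support[ord])
    pmf <- pmf[ord] / sum(pmf)
  }
  structure(list(support = as.integer(support),
                 pmf = as.numeric(pmf),
                 kind = kind,
                 params = params,
                 mean_degree = sum(support * pmf)),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("Degree distribution (%s): support [%d, %d], <k> = %.6g\n",
              x$kind, min(x$support), max(x$support), x$mean_degree))
  invisible(x)
}

#' Probability generating functions of a degree distribution
#'
#' Returns evaluators for \eqn{G_0(x) = \sum_k p_k x^k}, the excess-degree
#' generating function \eqn{G_1(x) = \sum_k p_k k x^{k-1} / \langle k\rangle},
#' and its derivative
#' \eqn{G_2(x) = G_1'(x) = \sum_k p_k k (k-1) x^{k-2} / \langle k\rangle}.
#'
#' @param dd a \code{degree_distribution}.
#' @return Object of class \code{"gf_set"} with function fields \code{G0},
#'   \code{G1}, \code{G2}, plus \code{dd}, \code{mean_degree} and
#'   \code{mean_excess_degree} (\eqn{G_2(1)}).
#' @export
generating_functions <- function(dd) {
  stopifnot(inherits(dd, "degree_distribution"))
  k <- dd$support
  p <- dd$pmf
  mk <- dd$mean_degree
  # coefficient vectors of the three series
  w1 <- if (mk > 0) p * k / mk else p * 0
  w2 <- if (mk > 0) p * k * pmax(k - 1, 0) / mk else p * 0
  powsafe <- function(x, e) {
    # x^e with the convention 0^0 = 1 and x^negative at x=0 dropped with the
    # zero coefficient that always multiplies it
    out <- outer(x, e, function(a, b) ifelse(b == 0, 1, a^b))
    out
  }
  G0 <- function(x) as.numeric(powsafe(x, k) %*% p)
  G1 <- function(x) as.numeric(powsafe(x, pmax(k - 1, 0)) %*% w1)
  G2 <- function(x) as.numeric(powsafe(x, pmax(k - 2, 0)) %*% w2)
  structure(list(G0 = G0, G1 = G1, G2 = G2, dd = dd,
                 mean_degree = mk,
                 mean_excess_degree = sum(w2)),
            class = "gf_set")
}

#' Evaluate the generating-function triple at a point
#'
#' @param gfs a \code{gf_set} from [generating_functions()].
#' @param x evaluation point(s) in \[0, 1\].
#' @return list with numeric fields \code{G0}, \code{G1}, \code{G2}.
#' @export
evaluate_gfs <- function(gfs, x) {
  stopifnot(inherits(gfs, "gf_set"))
  if (any(x < 0 | x > 1)) stop("evaluate_gfs: x must lie in [0, 1]")
  list(G0 = gfs$G0(x), G1 = gfs$G1(x), G2 = gfs$G2(x))
}

#' Mean excess degree
#'
#' The expected number of further neighbours of a node reached along a random
#' edge, \eqn{G_1'(1) = G_2(1) = \sum_k p_k k (k-1) / \langle k\rangle}.
#'
#' @param gfs a \code{gf_set}.
#' @return non-negative scalar.
#' @export
mean_excess_degree <- function(gfs) {
  stopifnot(inherits(gfs, "gf_set"))
  if (gfs$mean_degree <= 0)
    stop("mean_excess_degree: undefined when the mean degree is zero")
  gfs$mean_excess_degree
}

#' Sample a configuration-model network
#'
#' Draws a degree sequence i.i.d. from \code{dd}, fixes stub-count parity by
#' redrawing the last node's degree if the total is odd, pairs stubs
#' uniformly at random, and erases self-loops and duplicate edges. The
#' erasure introduces a small negative bias in the realised edge count which
#' vanishes as N grows for bounded-degree distributions.
#'
#' @param dd a \code{degree_distribution}.
#' @param N number of nodes (>= 2). Node ids are 0-based.
#' @param seed integer seed; the network is a deterministic function of
#'   \code{(dd, N, seed)}.
#' @return Object of class \code{"static_network"}: fields \code{N},
#'   \code{edges} (2-column integer matrix, each row one undirected edge with
#'   \code{edges[,1] < edges[,2]}, lexicographically sorted) and
#'   \code{degrees} (realised, post-erasure).
#' @export
sample_configuration_network <- function(dd, N, seed) {
  stopifnot(inherits(dd, "degree_distribution"))
  if (N < 2) stop("sample_configuration_network: N must be >= 2")
  if (max(dd$support) > N - 1) {
    warning("degree support exceeds N-1; truncating the distribution")
    keep <- dd$support <= N - 1
    dd <- make_degree_distribution("empirical",
                                   list(support = dd$support[keep],
                                        pmf = dd$pmf[keep]))
  }
  set.seed(as.integer(seed))
  draw <- function(n)
    dd$support[sample.int(length(dd$support), n, replace = TRUE,
                          prob = dd$pmf)]
  deg <- draw(N)
  if (sum(deg) %% 2 == 1) {
    # redraw one node's degree until total stub count is even
    for (attempt in 1:1000) {
      deg[N] <- draw(1)
      if (sum(deg) %% 2 == 0) break
    }
    if (sum(deg) %% 2 == 1)
      stop("sample_configuration_network: could not achieve even stub count")
  }
  stubs <- rep.int(seq_len(N) - 1L, deg)
  stubs <- sample(stubs)
  m <- length(stubs) / 2
  a <- stubs[seq_len(m) * 2L - 1L]
  b <- stubs[seq_len(m) * 2L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi
  lo <- lo[keep]; hi <- hi[keep]
  key <- lo * N + hi
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- order(lo, hi)
  edges <- cbind(from = as.integer(lo[ord]), to = as.integer(hi[ord]))
  make_static_network(N, edges)
}

make_static_network <- function(N, edges) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) > 0) {
    if (any(edges < 0) || any(edges > N - 1))
      stop("static network: node ids must lie in 0..N-1")
    if (any(edges[, 1] == edges[, 2])) stop("static network: self-loop found")
    lo <- pmin(edges[, 1], edges[, 2]); hi <- pmax(edges[, 1], edges[, 2])
    if (anyDuplicated(lo * N + hi)) stop("static network: duplicate edge found")
    ord <- order(lo, hi)
    edges <- cbind(from = as.integer(lo[ord]), to = as.integer(hi[ord]))
  }
  degs <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = N)
  structure(list(N = as.integer(N), edges = edges, degrees = degs),
            class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  cat(sprintf("Static network: %d nodes, %d edges, mean degree %.3f\n",
              x$N, nrow(x$edges), mean(x$degrees)))
  invisible(x)
}

# adjacency as a list of 1-based integer neighbour vectors
adjacency_list <- function(net) {
  adj <- vector("list", net$N)
  for (i in seq_len(net$N)) adj[[i]] <- integer(0)
  if (nrow(net$edges) > 0) {
    f <- net$edges[, 1] + 1L; t <- net$edges[, 2] + 1L
    adj <- split(c(t, f), factor(c(f, t), levels = seq_len(net$N)))
    adj <- lapply(adj, as.integer)
  }
  adj
}

as_igraph <- function(net) {
  igraph::graph_from_edgelist(net$edges + 1L, directed = FALSE)
}

#' Read an undirected edge list from TSV
#'
#' Two tab-separated 0-based integer columns, one edge per line, no header.
#' Self-loops and duplicate edges are rejected.
#'
#' @param path file path.
#' @param N number of nodes; defaults to \code{max(id) + 1}.
#' @return a \code{static_network}.
#' @export
read_edgelist_tsv <- function(path, N = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "integer")
  if (ncol(df) != 2) stop("edge list must have exactly two columns")
  if (is.null(N)) N <- max(df) + 1L
  make_static_network(N, as.matrix(df))
}

#' Write a network as an edge-list TSV
#'
#' @param net a \code{static_network}.
#' @param path output path.
#' @export
write_edgelist_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
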