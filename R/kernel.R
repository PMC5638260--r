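#' Long-range (Levy-like) transition kernel on a fixed site set
#'
#' The mobility model is a discrete-time random walk over N fixed
#' locations. Each pair of sites a, b at distance l_ab gets an affinity
#'
#'   Omega_ab = 1               if 0 <= l_ab <= R,
#'   Omega_ab = (R / l_ab)^alpha  if l_ab > R,
#'
#' and the walker hops with probability W_ab = Omega_ab / sum_m Omega_am.
#' R sets the size of the local neighbourhood, inside which all sites
#' (including the boundary l_ab = R) are equally likely; alpha controls
#' how sharply the probability of a long jump decays with distance.
#' alpha = 0 makes every transition equally likely (W_ab = 1/N exactly);
#' alpha = Inf is handled symbolically, with affinities exactly 0 beyond
#' R, and confines the walker to its R-neighbourhood graph.
#'
#' @param distances symmetric distance matrix (see [pairwise_distances()]).
#' @param alpha nonnegative decay exponent, or `Inf` for the purely local
#'   walk.
#' @param R neighbourhood radius, in the units of `distances`; must be
#'   positive.
#' @param allow_self if `FALSE`, the diagonal affinity is zeroed before
#'   normalization so the walker must move at every step. The default
#'   keeps the self-term (l_aa = 0 lies inside any neighbourhood).
#' @return an object of class `levy_kernel` with elements `omega`
#'   (affinity matrix), `W` (row-stochastic transition matrix), `alpha`,
#'   `R`, `allow_self`, `n`.
#' @examples
#' loc <- generate_locations(50, seed = 1)
#' k <- levy_kernel(pairwise_distances(loc), alpha = 2, R = 0.1)
#' range(rowSums(k$W))
#' @export
levy_kernel <- function(distances, alpha, R, allow_self = TRUE) {
  omega <- affinity_matrix(distances, alpha, R)
  if (!allow_self) diag(omega) <- 0
  W <- transition_matrix(omega)
  structure(list(omega = omega, W = W, alpha = alpha, R = R,
                 allow_self = allow_self, n = nrow(W)),
            class = "levy_kernel")
}

#' @export
print.levy_kernel <- function(x, ...) {
  cat(sprintf("<levy_kernel> %d sites, alpha = %s, R = %g, self-hops %s\n",
              x$n, format(x$alpha), x$R,
              if (x$allow_self) "allowed" else "excluded"))
  invisible(x)
}

#' @rdname levy_kernel
#' @param distances symmetric nonnegative distance matrix.
#' @return `affinity_matrix()` returns the symmetric matrix Omega.
#' @export
affinity_matrix <- function(distances, alpha, R) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("`distances` must be a square matrix", call. = FALSE)
  if (length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a single positive number", call. = FALSE)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a nonnegative number or Inf", call. = FALSE)
  local <- distances <= R
  if (is.infinite(alpha)) {
    omega <- matrix(0, nrow(distances), ncol(distances))
    omega[local] <- 1
  } else {
    omega <- (R / distances)^alpha
    omega[local] <- 1
  }
  dimnames(omega) <- NULL
  omega
}

#' @rdname levy_kernel
#' @param omega nonnegative affinity matrix with positive row sums.
#' @return `transition_matrix()` returns the row-stochastic matrix W.
#' @export
transition_matrix <- function(omega) {
  s <- rowSums(omega)
  if (any(s <= 0)) {
    bad <- which(s <= 0)
    stop(sprintf("site(s) %s are isolated: zero total affinity (alpha = Inf with no neighbour within R)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  omega / s
}

#' Simulate discrete-time walks on a Levy kernel
#'
#' Runs one or more independent walkers, each an i.i.d. realization of
#' the Markov chain defined by the kernel's transition matrix. Sampling
#' uses inverse-CDF lookups on precomputed cumulative rows; each walker
#' consumes an independent substream derived from `seed`, so ensembles
#' are reproducible walker-by-walker.
#'
#' @param kernel a `levy_kernel`.
#' @param steps number of transitions T (>= 1); trajectories have T + 1
#'   states, t = 0..T.
#' @param walkers number of independent walkers.
#' @param start starting site index, vector of indices (recycled across
#'   walkers), or `NULL` for independent uniform random starts.
#' @param seed integer master seed.
#' @return an object of class `trajectory_ensemble`: a list with
#'   `states` (walkers x (T+1) integer matrix of site indices), `steps`,
#'   `walkers`, `seed`.
#' @export
simulate_walk <- function(kernel, steps, walkers = 1L, start = NULL, seed = NULL) {
  stopifnot(inherits(kernel, "levy_kernel"))
  if (length(steps) != 1L || steps < 1) stop("`steps` must be >= 1", call. = FALSE)
  n <- kernel$n
  if (!is.null(start)) {
    start <- as.integer(start)
    if (any(start < 1L | start > n))
      stop("`start` must index sites in 1..N", call. = FALSE)
    start <- rep_len(start, walkers)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
  }
  cum <- t(apply(kernel$W, 1L, cumsum))
  cum[, n] <- 1  # guard against rounding drift in the last column
  cum_rows <- asplit(cum, 1L)  # row list: cheap per-step access in the hot loop
  states <- matrix(NA_integer_, nrow = walkers, ncol = steps + 1L)
  for (w in seq_len(walkers)) {
    if (!is.null(seed)) set.seed(seed + w - 1L)
    s <- if (is.null(start)) sample.int(n, 1L) else start[w]
    path <- integer(steps + 1L)
    path[1L] <- s
    u <- stats::runif(steps)
    for (t in seq_len(steps)) {
      s <- findInterval(u[t], cum_rows[[s]]) + 1L
      path[t + 1L] <- s
    }
    states[w, ] <- path
  }
  structure(list(states = states, steps = as.integer(steps),
                 walkers = as.integer(walkers), seed = seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d walker(s), %d steps (t = 0..%d)\n",
              x$walkers, x$steps, x$steps))
  invisible(x)
}

#' Hop-length distribution of simulated trajectories
#'
#' Collects the spatial length of every hop in an ensemble and bins it
#' into a normalized histogram, by default over log-spaced bins (the
#' natural scale for a power-law tail: the model predicts
#' P(l) ~ l^-(alpha - 1) at intermediate l). Zero-length hops
#' (self-transitions or duplicate sites) are reported separately via the
#' `p_zero` element since they cannot enter a log-spaced bin.
#'
#' @param trajectories a `trajectory_ensemble`.
#' @param distances the distance matrix of the underlying location set.
#' @param bins number of log-spaced bins, or a numeric vector of bin
#'   edges.
#' @return a data.frame with columns `l_lo`, `l_hi`, `mid` (geometric
#'   midpoint), `count`, `density` (probability mass / bin width) and
#'   attribute `p_zero`; total mass (including `p_zero`) is 1.
#' @export
displacement_distribution <- function(trajectories, distances, bins = 50L) {
  stopifnot(inherits(trajectories, "trajectory_ensemble"))
  st <- trajectories$states
  if (ncol(st) < 2L) stop("trajectory has no hops", call. = FALSE)
  from <- as.vector(st[, -ncol(st)])
  to <- as.vector(st[, -1L])
  l <- distances[cbind(from, to)]
  n_tot <- length(l)
  pos <- l[l > 0]
  p_zero <- 1 - length(pos) / n_tot
  if (length(bins) == 1L) {
    if (length(pos) == 0L) {
      edges <- c(1e-3, 1)
    } else {
      edges <- exp(seq(log(min(pos)), log(max(pos)), length.out = bins + 1L))
      edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
    }
  } else {
    edges <- as.numeric(bins)
  }
  counts <- if (length(pos) == 0L)
    rep(0L, length(edges) - 1L)
  else
    graphics::hist(pos, breaks = edges, plot = FALSE, right = FALSE)$counts
  h <- list(counts = counts)
  out <- data.frame(l_lo = edges[-length(edges)], l_hi = edges[-1L],
                    mid = sqrt(edges[-length(edges)] * edges[-1L]),
                    count = h$counts,
                    density = h$counts / n_tot / diff(edges))
  attr(out, "p_zero") <- p_zero
  out
}

#' Fit the log-log slope of a hop-length histogram
#'
#' Least-squares slope of log density against log midpoint over a length
#' window, used to check the Levy scaling P(l) ~ l^-(alpha - 1) in the
#' intermediate regime (between the neighbourhood radius and the domain
#' size, where boundary effects cut the tail off).
#'
#' @param dist_df output of [displacement_distribution()].
#' @param l_range length-2 window of l values to fit over.
#' @return the fitted slope (a negative number near -(alpha - 1)).
#' @export
loglog_slope <- function(dist_df, l_range) {
  keep <- dist_df$mid >= l_range[1L] & dist_df$mid <= l_range[2L] & dist_df$count > 0
  if (sum(keep) < 3L) stop("fewer than 3 occupied bins in the fit window", call. = FALSE)
  fit <- stats::lm(log(density) ~ log(mid), data = dist_df[keep, ])
  unname(stats::coef(fit)[2L])
}
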