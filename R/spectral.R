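#' Exact Markov-chain analysis of a Levy kernel
#'
#' Because the affinity matrix Omega is symmetric, the transition matrix
#' W = D^-1 Omega (D = diag of row sums) is similar to the symmetric
#' operator S = D^-1/2 Omega D^-1/2. All eigenvalues are therefore real,
#' and the eigendecomposition of S yields both the right eigenvectors of
#' W (columns of Z = D^-1/2 V) and their duals (rows of Z^-1 = V' D^1/2)
#' without a general matrix inverse. From the spectrum we obtain:
#'
#' * the stationary distribution p_b = sum_l Omega_bl / sum_lm Omega_lm
#'   (also the lambda = 1 left eigenvector, by detailed balance);
#' * mean return times <T_a> = 1 / p_a;
#' * mean first-passage times T(b -> a) from the fundamental-matrix sum
#'   over the non-unit modes;
#' * per-site reach times tau_a: the average of T(b -> a) over a
#'   uniformly random start b, counting 0 steps when b = a;
#' * the global reach time tau = mean_a tau_a, the scalar that ranks
#'   navigation strategies (small tau = the walker finds every site
#'   quickly).
#'
#' @param kernel a `levy_kernel` (finite alpha, or alpha = Inf on a
#'   connected neighbourhood graph).
#' @return an object of class `spectral_solution`: list with `values`
#'   (eigenvalues, descending, first = 1), `Z` (right eigenvectors as
#'   columns), `Zinv`, `stationary`, `mean_return`, `mfpt` (N x N matrix,
#'   T[b, a] = mean steps from b to first arrival at a; 0 on the
#'   diagonal under the reach-time convention), `tau_per_site`,
#'   `tau_global`.
#' @examples
#' loc <- generate_locations(30, seed = 3)
#' sp <- spectral_solution(levy_kernel(pairwise_distances(loc), 2, 0.1))
#' sp$tau_global
#' @export
spectral_solution <- function(kernel) {
  stopifnot(inherits(kernel, "levy_kernel"))
  omega <- kernel$omega
  n <- nrow(omega)
  s <- rowSums(omega)
  if (any(s <= 0))
    stop("kernel has isolated sites; chain is not irreducible", call. = FALSE)
  d <- sqrt(s)
  S <- omega / outer(d, d)
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values
  if (abs(lambda[1L] - 1) > 1e-8)
    stop("leading eigenvalue is not 1; transition matrix is not stochastic",
         call. = FALSE)
  if (n >= 2L && lambda[2L] > 1 - 1e-12)
    stop("unit eigenvalue has multiplicity > 1: chain is reducible", call. = FALSE)
  lambda[1L] <- 1
  V <- eig$vectors
  Z <- V / d          # right eigenvectors of W
  Zinv <- t(V * d)    # duals, from orthogonality of the symmetric problem
  p <- s / sum(s)     # closed form for the stationary distribution

  # Fundamental-like matrix G_ba = sum_{m>=2} phi_m(b) dual_m(a) / (1 - lambda_m)
  w <- 1 / (1 - lambda[-1L])
  G <- Z[, -1L, drop = FALSE] %*% (w * Zinv[-1L, , drop = FALSE])
  # T(b -> a) = (G_aa - G_ba) / p_a for b != a; reach-time convention: 0 on diag
  mfpt <- (rep(1, n) %o% diag(G) - G) / (rep(1, n) %o% p)
  diag(mfpt) <- 0
  tau_a <- colMeans(mfpt)

  structure(list(values = lambda, Z = Z, Zinv = Zinv,
                 stationary = p, mean_return = 1 / p,
                 mfpt = mfpt, tau_per_site = tau_a,
                 tau_global = mean(tau_a)),
            class = "spectral_solution")
}

#' @export
print.spectral_solution <- function(x, ...) {
  cat(sprintf("<spectral_solution> %d modes, spectral gap %.4g, tau = %.4g steps\n",
              length(x$values), 1 - x$values[2L], x$tau_global))
  invisible(x)
}

#' Evolve an occupation distribution under the master equation
#'
#' Applies p(t + 1) = p(t) W the requested number of times. For an
#' aperiodic chain this converges to the stationary distribution.
#'
#' @param kernel a `levy_kernel`.
#' @param p0 initial probability vector (sums to 1).
#' @param steps number of applications (>= 0).
#' @return the evolved probability vector.
#' @export
evolve_distribution <- function(kernel, p0, steps) {
  stopifnot(inherits(kernel, "levy_kernel"))
  p0 <- as.numeric(p0)
  if (length(p0) != kernel$n || abs(sum(p0) - 1) > 1e-8 || any(p0 < 0))
    stop("`p0` must be a length-N probability vector", call. = FALSE)
  if (steps < 0) stop("`steps` must be >= 0", call. = FALSE)
  p <- p0
  for (i in seq_len(steps)) p <- as.vector(p %*% kernel$W)
  p
}

#' Stationary distribution of the walk
#'
#' Closed form from the symmetric affinities: p_b = sum_l Omega_bl /
#' sum_lm Omega_lm, i.e. each site's share of total affinity. Equals the
#' lambda = 1 left eigenvector of W, and the long-run fraction of time
#' the walker spends at each site.
#'
#' @param kernel a `levy_kernel`.
#' @return probability vector of length N.
#' @export
stationary_distribution <- function(kernel) {
  stopifnot(inherits(kernel, "levy_kernel"))
  s <- rowSums(kernel$omega)
  if (any(s <= 0))
    stop("kernel has isolated sites; no unique stationary distribution", call. = FALSE)
  if (is.infinite(kernel$alpha)) {
    g <- igraph::graph_from_adjacency_matrix(kernel$omega > 0, mode = "undirected",
                                             diag = FALSE)
    if (igraph::components(g)$no > 1L)
      stop("alpha = Inf kernel is disconnected; chain is not irreducible",
           call. = FALSE)
  }
  s / sum(s)
}

#' Mean first-return times
#'
#' By Kac's formula the expected number of steps for the walker to first
#' return to its starting site a is 1 / p_a under the stationary
#' distribution p.
#'
#' @param stationary probability vector with strictly positive entries.
#' @return vector of mean return times, in steps.
#' @export
mean_return_time <- function(stationary) {
  if (any(stationary <= 0))
    stop("stationary probabilities must be strictly positive (reducible chain?)",
         call. = FALSE)
  1 / stationary
}

#' @rdname spectral_solution
#' @param spec a `spectral_solution`.
#' @param site target site index (or indices).
#' @return `reach_time()` returns tau_a for the given site(s);
#'   `global_time()` returns the scalar tau.
#' @export
reach_time <- function(spec, site) {
  stopifnot(inherits(spec, "spectral_solution"))
  spec$tau_per_site[site]
}

#' @rdname spectral_solution
#' @export
global_time <- function(spec) {
  stopifnot(inherits(spec, "spectral_solution"))
  spec$tau_global
}

#' Monte Carlo first-passage oracle
#'
#' Estimates the mean number of steps to first reach a target site from
#' a uniformly random start by direct simulation, independently of the
#' spectral machinery. A start already at the target counts as 0 steps,
#' matching the reach-time convention. All replicate chains are advanced
#' in lockstep (vectorized over replicates) until absorbed.
#'
#' @param kernel a `levy_kernel`.
#' @param target target site index.
#' @param repeats number of replicate chains (>= 100).
#' @param seed integer seed.
#' @param max_steps cap on chain length; if any replicate has not
#'   reached the target by then (e.g. an unreachable target under
#'   alpha = Inf) an error is raised rather than returning a truncated
#'   mean.
#' @return list with `mean`, `se` (standard error), `repeats`.
#' @export
mc_first_passage <- function(kernel, target, repeats = 1e4, seed = NULL,
                             max_steps = 1e6) {
  stopifnot(inherits(kernel, "levy_kernel"))
  n <- kernel$n
  if (target < 1L || target > n) stop("invalid target site", call. = FALSE)
  if (repeats < 100) stop("`repeats` must be >= 100", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  cum <- t(apply(kernel$W, 1L, cumsum))
  cum[, n] <- 1
  state <- sample.int(n, repeats, replace = TRUE)
  steps <- numeric(repeats)
  active <- which(state != target)
  t <- 0L
  while (length(active) > 0L) {
    t <- t + 1L
    if (t > max_steps)
      stop(sprintf("%d chain(s) did not reach site %d within %g steps",
                   length(active), target, max_steps), call. = FALSE)
    u <- stats::runif(length(active))
    nxt <- rowSums(cum[state[active], , drop = FALSE] < u) + 1L
    state[active] <- nxt
    arrived <- nxt == target
    steps[active[arrived]] <- t
    active <- active[!arrived]
  }
  list(mean = mean(steps), se = stats::sd(steps) / sqrt(repeats),
       repeats = repeats)
}
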