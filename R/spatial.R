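#' Fixed spatial substrates for location-based random walks
#'
#' A `location_set` holds the N fixed sites a walker (or a city's venues)
#' can occupy, together with the metric used to measure distances between
#' them. Planar coordinates (typically in the unit square) use the
#' Euclidean or Manhattan metric; geographic coordinates in degrees use
#' great-circle (haversine) distances on a sphere of radius 6371 km, so
#' that metre/kilometre thresholds are reproducible.
#'
#' @param coords numeric matrix with N rows and 2 columns. For planar
#'   metrics the columns are `x, y`; for `"haversine"` they are
#'   `lat, lon` in degrees.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"haversine"`.
#' @return an object of class `location_set` with elements `coords`
#'   (numeric matrix), `n` and `metric`.
#' @seealso [generate_locations()], [pairwise_distances()]
#' @export
location_set <- function(coords, metric = c("euclidean", "manhattan", "haversine")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("`coords` must be a numeric matrix with two columns", call. = FALSE)
  if (nrow(coords) < 2L)
    stop("a location set needs at least 2 sites", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  if (metric == "haversine") {
    if (any(abs(coords[, 1L]) > 90) || any(abs(coords[, 2L]) > 180))
      stop("haversine coordinates must be (lat, lon) with |lat| <= 90, |lon| <= 180",
           call. = FALSE)
    colnames(coords) <- c("lat", "lon")
  } else {
    colnames(coords) <- c("x", "y")
  }
  structure(list(coords = coords, n = nrow(coords), metric = metric),
            class = "location_set")
}

#' @export
print.location_set <- function(x, ...) {
  cat(sprintf("<location_set> %d sites, %s metric\n", x$n, x$metric))
  invisible(x)
}

#' Sample uniform random locations in a rectangle
#'
#' Draws N independent uniform points inside a bounding box, the standard
#' substrate for simulation experiments (the default is the unit square).
#'
#' @param n number of sites (>= 2).
#' @param region bounding box `c(xmin, xmax, ymin, ymax)`.
#' @param seed integer seed; the same seed reproduces the same points.
#' @param metric metric passed on to [location_set()].
#' @return a `location_set`.
#' @examples
#' loc <- generate_locations(100, seed = 7)
#' range(loc$coords)
#' @export
generate_locations <- function(n, region = c(0, 1, 0, 1), seed = NULL,
                               metric = "euclidean") {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  region <- as.numeric(region)
  if (length(region) != 4L || region[2L] <= region[1L] || region[4L] <= region[3L])
    stop("`region` must be c(xmin, xmax, ymin, ymax) with positive area", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  coords <- cbind(stats::runif(n, region[1L], region[2L]),
                  stats::runif(n, region[3L], region[4L]))
  location_set(coords, metric = metric)
}

# Restore (or remove) .Random.seed after a locally seeded draw, so seeded
# helpers do not clobber the caller's RNG stream.
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pairwise distance matrix of a location set
#'
#' Computes the full symmetric matrix of distances l_ab between all pairs
#' of sites, under the set's metric. Geographic coordinates use the
#' haversine great-circle distance with Earth radius 6371 km; planar
#' coordinates use the Euclidean (L2) or Manhattan (L1) norm. Duplicate
#' points are allowed and yield zero off-diagonal distances.
#'
#' @param locations a `location_set`.
#' @return N x N numeric matrix; kilometres for `"haversine"`, the
#'   coordinate units otherwise. Symmetric with a zero diagonal.
#' @export
pairwise_distances <- function(locations) {
  stopifnot(inherits(locations, "location_set"))
  co <- locations$coords
  l <- switch(locations$metric,
    euclidean = as.matrix(stats::dist(co, method = "euclidean")),
    manhattan = as.matrix(stats::dist(co, method = "manhattan")),
    haversine = {
      # geosphere expects (lon, lat); radius fixed at 6371 km -> result in km
      m <- geosphere::distm(co[, c(2L, 1L)],
                            fun = function(p1, p2)
                              geosphere::distHaversine(p1, p2, r = 6371))
      m
    })
  dimnames(l) <- NULL
  # dist() is exact-symmetric; distm can leave tiny asymmetries from
  # argument order, so symmetrize defensively and zero the diagonal.
  l <- (l + t(l)) / 2
  diag(l) <- 0
  l
}

#' Haversine distance between points, in kilometres
#'
#' Great-circle distance on a sphere of radius 6371 km. Vectorized over
#' rows; inputs are in degrees.
#'
#' @param lat1,lon1,lat2,lon2 numeric vectors of coordinates in degrees.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Critical radius for random-geometric-graph connectivity
#'
#' For N uniform points in the unit square, the radius above which the
#' random geometric graph linking all pairs closer than R is connected
#' with high probability: r_c = sqrt(log N / (pi N)). A purely local walk
#' (alpha -> infinity) with R > r_c can therefore reach every site.
#'
#' @param n number of sites (>= 2).
#' @return the critical radius, in the units of the unit square.
#' @examples
#' rgg_critical_radius(100)  # ~0.121
#' @export
rgg_critical_radius <- function(n) {
  if (any(n < 2)) stop("`n` must be >= 2", call. = FALSE)
  sqrt(log(n) / (pi * n))
}

#' Read or write a location set as CSV
#'
#' The on-disk format is a CSV with header `id,x,y` (planar) or
#' `id,lat,lon` (geographic); the metric is inferred from the header on
#' read unless overridden.
#'
#' @param path file path.
#' @param locations a `location_set` (for writing).
#' @param metric optional metric override on read.
#' @return `read_locations()` returns a `location_set`;
#'   `write_locations()` returns `path` invisibly.
#' @export
read_locations <- function(path, metric = NULL) {
  df <- utils::read.csv(path)
  geo <- all(c("lat", "lon") %in% names(df))
  if (is.null(metric)) metric <- if (geo) "haversine" else "euclidean"
  cols <- if (geo) c("lat", "lon") else c("x", "y")
  if (!all(cols %in% names(df)))
    stop("location CSV must have columns id,x,y or id,lat,lon", call. = FALSE)
  location_set(as.matrix(df[, cols]), metric = metric)
}

#' @rdname read_locations
#' @export
write_locations <- function(locations, path) {
  stopifnot(inherits(locations, "location_set"))
  df <- data.frame(id = seq_len(locations$n), locations$coords)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
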