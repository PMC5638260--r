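#' Read a geotagged check-in table
#'
#' Parses tab-separated check-in streams in the dialect of the public
#' Foursquare NYC/Tokyo dumps: one row per check-in with columns
#' user id, venue id, venue category id, venue category name, latitude,
#' longitude, timezone offset (minutes from UTC) and a UTC time string
#' like `"Tue Apr 03 18:00:09 +0000 2012"`. Column order, separator and
#' time format are configurable through `dialect`. Malformed rows
#' (unparseable timestamp, coordinates out of range) are counted,
#' reported with their line numbers in a warning, and excluded from the
#' table — never silently dropped.
#'
#' @param path path to the file.
#' @param dialect list with elements `columns` (names in file order;
#'   must include `user_id`, `lat`, `lon`, `tz_offset`, `utc_time`),
#'   `sep`, `header`, `time_format` (a `strptime` format interpreted in
#'   the C locale, UTC).
#' @return a `checkin_table`: a data.table with columns `user_id`,
#'   `venue_id`, `venue_category`, `lat`, `lon`, `tz_offset` (minutes)
#'   and `utc_time` (POSIXct, UTC), with attribute `n_malformed`.
#' @export
read_checkins <- function(path, dialect = checkin_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty check-in file: ", path)
    return(.as_checkin_table(.empty_checkins(), 0L))
  }
  raw <- tryCatch(
    data.table::fread(path, sep = dialect$sep, header = dialect$header,
                      col.names = dialect$columns, quote = "",
                      colClasses = list(character = which(dialect$columns == "utc_time"))),
    error = function(e) stop("cannot read check-in file: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(raw) == 0L) {
    warning("empty check-in file: ", path)
    return(.as_checkin_table(.empty_checkins(), 0L))
  }
  need <- c("user_id", "lat", "lon", "tz_offset", "utc_time")
  if (!all(need %in% names(raw)))
    stop("dialect must map the columns ", paste(need, collapse = ", "),
         call. = FALSE)
  utc <- parse_checkin_time(raw$utc_time, dialect$time_format)
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad <- is.na(utc) | is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    lines <- which(bad) + as.integer(dialect$header)
    warning(sprintf("dropping %d malformed row(s) (lines %s%s)",
                    sum(bad), paste(utils::head(lines, 5L), collapse = ", "),
                    if (sum(bad) > 5L) ", ..." else ""))
  }
  tab <- data.table::data.table(
    user_id = as.character(raw$user_id),
    venue_id = if ("venue_id" %in% names(raw)) as.character(raw$venue_id) else NA_character_,
    venue_category = if ("venue_category" %in% names(raw)) as.character(raw$venue_category) else NA_character_,
    lat = lat, lon = lon,
    tz_offset = as.integer(raw$tz_offset),
    utc_time = utc)[!bad]
  .as_checkin_table(tab, sum(bad))
}

#' @rdname read_checkins
#' @export
checkin_dialect <- function(columns = c("user_id", "venue_id", "venue_category_id",
                                        "venue_category", "lat", "lon",
                                        "tz_offset", "utc_time"),
                            sep = "\t", header = FALSE,
                            time_format = "%a %b %d %H:%M:%S %z %Y") {
  list(columns = columns, sep = sep, header = header, time_format = time_format)
}

# Parse time strings in the C locale (month/day names are English in the
# Foursquare dialect regardless of the session locale).
parse_checkin_time <- function(x, format) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(try(Sys.setlocale("LC_TIME", old), silent = TRUE), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  as.POSIXct(strptime(x, format = format, tz = "UTC"))
}

format_checkin_time <- function(x) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(try(Sys.setlocale("LC_TIME", old), silent = TRUE), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  format(x, format = "%a %b %d %H:%M:%S +0000 %Y", tz = "UTC")
}

.empty_checkins <- function() {
  data.table::data.table(user_id = character(), venue_id = character(),
                         venue_category = character(), lat = numeric(),
                         lon = numeric(), tz_offset = integer(),
                         utc_time = as.POSIXct(character(), tz = "UTC"))
}

.as_checkin_table <- function(tab, n_malformed) {
  data.table::setattr(tab, "n_malformed", n_malformed)
  data.table::setattr(tab, "class",
                      unique(c("checkin_table", class(tab))))
  tab[]
}

#' Write a check-in table in the standard tab-separated dialect
#'
#' @param tab a `checkin_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checkins <- function(tab, path) {
  out <- data.table::data.table(
    user_id = tab$user_id,
    venue_id = tab$venue_id,
    venue_category_id = tab$venue_id,
    venue_category = tab$venue_category,
    lat = sprintf("%.8f", tab$lat),
    lon = sprintf("%.8f", tab$lon),
    tz_offset = tab$tz_offset,
    utc_time = format_checkin_time(tab$utc_time))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inter-event times between successive check-ins
#'
#' Within each user's chronologically sorted stream, the gap in hours
#' between consecutive check-ins; gaps are pooled over all users and
#' never taken across users. Users with a single check-in contribute
#' nothing.
#'
#' @param tab a `checkin_table`.
#' @return numeric vector of gaps tau, in hours.
#' @export
interevent_times <- function(tab) {
  user_id <- utc_time <- NULL
  if (nrow(tab) == 0L) return(numeric())
  dt <- data.table::as.data.table(tab)[order(user_id, utc_time)]
  gaps <- dt[, if (.N >= 2L) list(tau = diff(as.numeric(utc_time)) / 3600),
             by = user_id]
  if (nrow(gaps) == 0L) numeric() else gaps$tau
}

#' Displacements between successive check-ins
#'
#' Haversine (great-circle, Earth radius 6371 km) distance between the
#' coordinates of consecutive check-ins of the same user, pooled over
#' users.
#'
#' @param tab a `checkin_table`.
#' @return numeric vector of displacements r, in km.
#' @export
displacements <- function(tab) {
  user_id <- utc_time <- NULL
  if (nrow(tab) == 0L) return(numeric())
  dt <- data.table::as.data.table(tab)[order(user_id, utc_time)]
  hops <- dt[, if (.N >= 2L) list(
    r = haversine_km(lat[-.N], lon[-.N], lat[-1L], lon[-1L])), by = user_id]
  if (nrow(hops) == 0L) numeric() else hops$r
}

#' Hourly proximity co-coincidences between users
#'
#' Two users have a co-coincidence in an hour when both register a
#' check-in in that calendar hour at locations at most `delta_r` metres
#' apart (minimum over their check-in pairs in the hour). Hours are
#' binned in each check-in's local time (UTC + timezone offset) by
#' default, since daily routines are local-time phenomena; set
#' `local_time = FALSE` for UTC binning. Each (pair, hour) contributes
#' at most one co-coincidence regardless of how many check-in pairs fall
#' within range, so a pair's count n is the number of hours it was
#' co-located.
#'
#' @param tab a `checkin_table`.
#' @param delta_r proximity threshold in metres (> 0).
#' @param local_time bin hours in local (default) or UTC time.
#' @return a `coincidence_table`: list with `events` (data.table
#'   `i, j, bin`: user-index pair, i < j, and hour bin relative to the
#'   table's first hour), `counts` (`i, j, n`), `users` (index ->
#'   user id), `delta_r`, `origin_bin`.
#' @export
hourly_cocoincidences <- function(tab, delta_r, local_time = TRUE) {
  if (delta_r <= 0) stop("`delta_r` must be positive (metres)", call. = FALSE)
  i <- j <- NULL
  users <- sort(unique(tab$user_id))
  if (nrow(tab) == 0L || length(users) < 2L) {
    return(.coincidence_table(
      data.table::data.table(i = integer(), j = integer(), bin = integer()),
      users, delta_r, 0L))
  }
  epoch <- as.numeric(tab$utc_time)
  if (local_time) epoch <- epoch + as.numeric(tab$tz_offset) * 60
  bin <- as.integer(floor(epoch / 3600))
  origin <- min(bin)
  dt <- data.table::data.table(u = match(tab$user_id, users),
                               lat = tab$lat, lon = tab$lon,
                               bin = bin - origin)
  ev <- dt[, .pairs_within(.SD, delta_r), by = bin]
  if (nrow(ev) == 0L)
    ev <- data.table::data.table(bin = integer(), i = integer(), j = integer())
  ev <- ev[, list(i, j, bin)]
  data.table::setorder(ev, i, j, bin)
  .coincidence_table(ev, users, delta_r, origin)
}

# User pairs within delta_r metres inside one hour bin.
.pairs_within <- function(sd, delta_r) {
  if (length(unique(sd$u)) < 2L)
    return(data.table::data.table(i = integer(), j = integer()))
  k <- nrow(sd)
  a <- rep(seq_len(k), each = k)
  b <- rep(seq_len(k), times = k)
  keep <- sd$u[a] < sd$u[b]
  a <- a[keep]; b <- b[keep]
  d <- haversine_km(sd$lat[a], sd$lon[a], sd$lat[b], sd$lon[b]) * 1000
  hit <- d <= delta_r
  unique(data.table::data.table(i = sd$u[a[hit]], j = sd$u[b[hit]]))
}

.coincidence_table <- function(events, users, delta_r, origin) {
  i <- j <- NULL
  counts <- if (nrow(events) > 0L)
    events[, list(n = .N), by = list(i, j)]
  else
    data.table::data.table(i = integer(), j = integer(), n = integer())
  structure(list(events = events, counts = counts, users = users,
                 delta_r = delta_r, origin_bin = origin),
            class = "coincidence_table")
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat(sprintf("<coincidence_table> %d users, %d co-located pairs, delta_r = %g m\n",
              length(x$users), nrow(x$counts), x$delta_r))
  invisible(x)
}

#' Frequency spectrum of co-coincidence counts
#'
#' f(n) is the number of user pairs with exactly n co-coincident hours,
#' n = 1, 2, 3, ... Its sum equals the number of pairs with at least
#' one co-coincidence.
#'
#' @param co a `coincidence_table`.
#' @return data.frame with columns `n` and `f`.
#' @export
coincidence_frequency <- function(co) {
  stopifnot(inherits(co, "coincidence_table"))
  if (nrow(co$counts) == 0L) return(data.frame(n = integer(), f = integer()))
  tb <- table(co$counts$n)
  data.frame(n = as.integer(names(tb)), f = as.integer(tb))
}

#' Cumulative encounter network of users at a given time
#'
#' A link between two users at time t records at least c co-coincidences
#' in the interval [0, t] (hours since the table's first hour bin) —
#' the infinite-memory counterpart of the simulated walkers' windowed
#' rule, so links never disappear and the edge set is monotone in t and
#' nested across thresholds (c = 3 edges are a subset of c = 1 edges).
#'
#' @param co a `coincidence_table`.
#' @param min_contacts threshold c (>= 1).
#' @param t time in hours since the first bin; `Inf` for the final
#'   network.
#' @return sparse symmetric binary adjacency over `length(co$users)`
#'   nodes.
#' @export
cumulative_network <- function(co, min_contacts = 1L, t = Inf) {
  stopifnot(inherits(co, "coincidence_table"))
  if (min_contacts < 1) stop("`min_contacts` must be >= 1", call. = FALSE)
  i <- j <- NULL
  nu <- length(co$users)
  ev <- co$events[co$events$bin <= t]
  cnt <- if (nrow(ev) > 0L) ev[, list(n = .N), by = list(i, j)]
         else data.table::data.table(i = integer(), j = integer(), n = integer())
  cnt <- cnt[cnt$n >= min_contacts]
  Matrix::sparseMatrix(i = c(cnt$i, cnt$j), j = c(cnt$j, cnt$i), x = 1,
                       dims = c(nu, nu))
}

#' Mean degree and clustering of the cumulative network over time
#'
#' Evaluates <k(t)> and <C(t)> of [cumulative_network()] on a grid of
#' times, for one or several contact thresholds c.
#'
#' @param co a `coincidence_table`.
#' @param min_contacts vector of thresholds.
#' @param grid sorted vector of evaluation times (hours since first
#'   bin); defaults to every observed event hour.
#' @return data.frame with columns `t`, `c`, `mean_k`, `mean_C`.
#' @export
temporal_curves <- function(co, min_contacts = 1L, grid = NULL) {
  stopifnot(inherits(co, "coincidence_table"))
  if (is.null(grid)) {
    grid <- if (nrow(co$events) > 0L) sort(unique(co$events$bin)) else 0
  }
  if (is.unsorted(grid)) stop("`grid` must be sorted", call. = FALSE)
  out <- list()
  for (cc in min_contacts) {
    mk <- mc <- numeric(length(grid))
    for (g in seq_along(grid)) {
      A <- cumulative_network(co, cc, grid[g])
      mk[g] <- average_degree(A)
      mc[g] <- clustering_coefficient(A)$mean
    }
    out[[length(out) + 1L]] <- data.frame(t = grid, c = cc, mean_k = mk, mean_C = mc)
  }
  do.call(rbind, out)
}

#' Largest-connected-component summary of an encounter network
#'
#' Standard global statistics of the largest connected component:
#' number of nodes, number of edges, mean degree 2E/N, mean clustering
#' (local coefficients per [clustering_coefficient()], zero for degree
#' < 2), diameter and mean shortest-path distance <d> over all pairs in
#' the component. Components and path lengths are computed with igraph.
#'
#' @param A symmetric binary adjacency (dense or sparse).
#' @return list with `size`, `edges`, `mean_degree`, `mean_clustering`,
#'   `diameter`, `mean_distance`; all `NA` (size 0) for an empty graph.
#' @export
largest_component_summary <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "undirected",
                                           diag = FALSE, weighted = NULL)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (igraph::vcount(g) == 0L)
    return(list(size = 0L, edges = 0L, mean_degree = NA_real_,
                mean_clustering = NA_real_, diameter = NA_integer_,
                mean_distance = NA_real_))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  Asub <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  size <- igraph::vcount(sub)
  edges <- igraph::ecount(sub)
  list(size = size,
       edges = edges,
       mean_degree = 2 * edges / size,
       mean_clustering = clustering_coefficient(Asub)$mean,
       diameter = igraph::diameter(sub, unconnected = FALSE),
       mean_distance = igraph::mean_distance(sub, unconnected = FALSE))
}
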