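# Geospatial primitives: great-circle distance and density-based
# significant-place clustering of GPS fixes.

# IUGG mean Earth radius, km.
EARTH_RADIUS_KM <- 6371.0088

#' Haversine great-circle distance
#'
#' Distance between points on a sphere of radius 6371.0088 km (IUGG mean
#' Earth radius). Vectorized over coordinates; inputs are recycled.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_distance(0, 0, 0, 180)  # half the equator
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  # clamp guards tiny negative / >1 values from floating-point roundoff
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Exact DBSCAN over a haversine distance matrix. Returns integer labels,
# 0 = noise. Classic region-query + BFS expansion.
dbscan_exact <- function(lat, lon, eps_km, min_samples) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_distance(lat[i], lon[i], lat, lon)
  }
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps_km))
  core <- vapply(nb, length, integer(1)) >= min_samples
  dbscan_expand(nb, core)
}

# Cluster = connected component of core points within eps; border points
# join the first core neighbor's cluster. Frontier-based expansion.
dbscan_expand <- function(nb, core) {
  n <- length(nb)
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      expand <- frontier[core[frontier]]
      if (!length(expand)) break
      nbrs <- unique(unlist(nb[expand], use.names = FALSE))
      new <- nbrs[labels[nbrs] == 0L]
      labels[new] <- cl
      frontier <- new
    }
  }
  labels
}

# Grid-accelerated DBSCAN for large fix sets: snap points to cells of
# ~eps/4, cluster the weighted cell centroids exactly, and propagate cell
# labels back to points. Exact whenever occupied locations are well
# separated relative to eps (the regime of anchored human mobility);
# documented as an approximation otherwise.
dbscan_cells <- function(lat, lon, eps_km, min_samples) {
  cell_deg <- (eps_km / 4) / 111.32          # latitude degrees per cell
  lat_c <- floor(lat / cell_deg)
  lon_scale <- pmax(cos(mean(lat) * pi / 180), 0.05)
  lon_c <- floor(lon * lon_scale / cell_deg)
  cell_key <- paste(lat_c, lon_c)
  dt <- data.table::data.table(cell_key = cell_key, lat = lat, lon = lon)
  cells <- dt[, .(clat = mean(lat), clon = mean(lon), w = .N), by = cell_key]
  m <- nrow(cells)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    d[i, ] <- haversine_distance(cells$clat[i], cells$clon[i],
                                 cells$clat, cells$clon)
  }
  nb <- lapply(seq_len(m), function(i) which(d[i, ] <= eps_km))
  wt <- cells$w
  core <- vapply(nb, function(ix) sum(wt[ix]), numeric(1)) >= min_samples
  labels <- dbscan_expand(nb, core)
  cells[, label := labels]
  cells$label[match(cell_key, cells$cell_key)]
}

#' Cluster GPS fixes into significant places
#'
#' Density-based (DBSCAN) clustering of GPS fixes with the haversine
#' metric. The two clusters with the most member fixes become the
#' participant's primary and secondary locations; all remaining fixes
#' (smaller clusters and density noise) are grouped as "other".
#'
#' @param fixes A data.frame/data.table with columns `lat`, `lon`.
#' @param eps_km Neighbourhood radius in km (default 1).
#' @param min_samples Minimum fixes per cluster (default 10).
#' @param exact_max Fix count above which the grid-accelerated route is
#'   used instead of the exact O(n^2) one.
#' @return Object of class `sw_place_clustering`: list with `place`
#'   (factor per fix: primary/secondary/other), `cluster` (raw integer
#'   DBSCAN label, 0 = noise) and `centroids` (data.table per named place).
#' @export
cluster_locations <- function(fixes, eps_km = 1, min_samples = 10,
                              exact_max = 3000) {
  fixes <- data.table::as.data.table(fixes)
  assert_that(nrow(fixes) >= 1, "need at least one GPS fix")
  labels <- if (nrow(fixes) <= exact_max) {
    dbscan_exact(fixes$lat, fixes$lon, eps_km, min_samples)
  } else {
    dbscan_cells(fixes$lat, fixes$lon, eps_km, min_samples)
  }
  sizes <- sort(table(labels[labels > 0]), decreasing = TRUE)
  place <- rep("other", length(labels))
  top <- as.integer(names(sizes))
  if (length(top) >= 1) place[labels == top[1]] <- "primary"
  if (length(top) >= 2) place[labels == top[2]] <- "secondary"
  place <- factor(place, levels = c("primary", "secondary", "other"))
  cent <- data.table::data.table(place = place, lat = fixes$lat,
                                 lon = fixes$lon)[
    , .(lat = mean(lat), lon = mean(lon), n = .N), by = place]
  structure(list(place = place, cluster = labels, centroids = cent),
            class = "sw_place_clustering")
}
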