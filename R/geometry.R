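#' Project longitude/latitude to planar kilometre coordinates
#'
#' Equirectangular projection about a reference latitude: one degree of
#' latitude maps to 111.32 km everywhere, one degree of longitude to
#' \code{111.32 * cos(ref_lat)} km.  Adequate for regional extents up to a
#' couple of thousand kilometres, which is the scale a single climate-region
#' model covers.
#'
#' @param lon_deg,lat_deg Numeric vectors of coordinates in decimal degrees.
#' @param ref_lat Reference latitude (degrees) at which east-west distances
#'   are exact; typically the mean latitude of the study domain.
#' @return A two-column matrix with columns \code{x_km}, \code{y_km}.
#' @examples
#' project_lonlat(c(0, 1), c(0, 0), ref_lat = 60)
#' @export
project_lonlat <- function(lon_deg, lat_deg, ref_lat = mean(lat_deg)) {
  if (!all(is.finite(lon_deg)) || !all(is.finite(lat_deg)) ||
      !is.finite(ref_lat)) {
    stop("project_lonlat: coordinates must be finite")
  }
  if (any(abs(lat_deg) >= 90)) stop("project_lonlat: |lat| must be < 90")
  km_per_deg <- 111.32
  cbind(x_km = km_per_deg * cos(ref_lat * pi / 180) * lon_deg,
        y_km = km_per_deg * lat_deg)
}

#' Pairwise Euclidean distances between planar locations
#'
#' @param locations Matrix (or data frame) with two columns of planar
#'   kilometre coordinates; one row per location.
#' @param locations2 Optional second location set; if supplied the result is
#'   the rectangular cross-distance matrix.
#' @return Distance matrix in km; square, symmetric with zero diagonal when
#'   \code{locations2} is missing.
#' @export
pairwise_distances <- function(locations, locations2 = NULL) {
  x <- as.matrix(locations)
  if (ncol(x) != 2L) stop("pairwise_distances: locations need two columns")
  if (nrow(x) < 1L) stop("pairwise_distances: need at least one location")
  if (is.null(locations2)) {
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- NULL
    return(d)
  }
  y <- as.matrix(locations2)
  # |xi - yj|^2 = |xi|^2 + |yj|^2 - 2 xi.yj
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

#' Great-circle distances between longitude/latitude points
#'
#' Haversine distance on a spherical Earth (radius 6371 km); the
#' alternative to projecting and using planar distances when the domain
#' is large enough for equirectangular distortion to matter.
#'
#' @param lonlat Two-column matrix of longitude, latitude in degrees.
#' @param lonlat2 Optional second point set for a rectangular result.
#' @return Distance matrix in km.
#' @export
great_circle_distances <- function(lonlat, lonlat2 = lonlat) {
  a <- as.matrix(lonlat) * pi / 180
  b <- as.matrix(lonlat2) * pi / 180
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    dlat <- a[, 2] - b[j, 2]
    dlon <- a[, 1] - b[j, 1]
    h <- sin(dlat / 2)^2 + cos(a[, 2]) * cos(b[j, 2]) * sin(dlon / 2)^2
    out[, j] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  }
  out
}

#' Define a set of analysis regions
#'
#' Regions partition the monitors into independent model fits; a buffer
#' around each region lets neighbouring fits overlap so their predictions
#' can be averaged into a seamless surface.  Regions are given either as
#' polygons (a data frame of ordered vertices) or as site membership labels
#' (the polygon-free path used by synthetic experiments).
#'
#' @param polygons Data frame with columns \code{region_id},
#'   \code{vertex_order}, \code{x_km}, \code{y_km} (one ring per region), or
#'   \code{NULL}.
#' @param labels Named character vector mapping \code{site_id} to its core
#'   region, or \code{NULL}.  Exactly one of \code{polygons}/\code{labels}
#'   must be supplied.
#' @param buffer_km Nonnegative buffer width in km (default 100).
#' @return An object of class \code{region_set}.
#' @export
region_set <- function(polygons = NULL, labels = NULL, buffer_km = 100) {
  if (is.null(polygons) == is.null(labels)) {
    stop("region_set: supply exactly one of 'polygons' or 'labels'")
  }
  if (!is.numeric(buffer_km) || length(buffer_km) != 1L || buffer_km < 0) {
    stop("region_set: buffer_km must be a nonnegative scalar")
  }
  if (!is.null(polygons)) {
    need <- c("region_id", "vertex_order", "x_km", "y_km")
    if (!all(need %in% names(polygons))) {
      stop("region_set: polygon table needs columns ",
           paste(need, collapse = ", "))
    }
    polygons <- polygons[order(polygons$region_id, polygons$vertex_order), ]
    ids <- unique(as.character(polygons$region_id))
  } else {
    if (is.null(names(labels)) || anyNA(labels)) {
      stop("region_set: labels must be a named vector without NAs")
    }
    ids <- sort(unique(as.character(labels)))
  }
  structure(list(region_ids = ids, polygons = polygons,
                 labels = if (is.null(labels)) NULL else
                   stats::setNames(as.character(labels), names(labels)),
                 buffer_km = buffer_km),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", length(x$region_ids), "regions (",
      paste(x$region_ids, collapse = ", "), "), buffer",
      x$buffer_km, "km,",
      if (is.null(x$polygons)) "label-defined" else "polygon-defined", "\n")
  invisible(x)
}

# minimum distance from points to a closed polygon ring's boundary
dist_to_ring <- function(pts, ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1L), , drop = FALSE]
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_len(n)) {
    ab <- b[k, ] - a[k, ]
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((pts[, 1] - a[k, 1])^2 + (pts[, 2] - a[k, 2])^2)
    } else {
      tt <- ((pts[, 1] - a[k, 1]) * ab[1] + (pts[, 2] - a[k, 2]) * ab[2]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      d <- sqrt((pts[, 1] - (a[k, 1] + tt * ab[1]))^2 +
                (pts[, 2] - (a[k, 2] + tt * ab[2]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Assign monitors to core and buffered regions
#'
#' Each site gets exactly one core region (the region containing it, or its
#' labelled region) and belongs to the buffered set of every region it lies
#' in or within \code{buffer_km} of.  For label-defined regions the distance
#' to a region is taken as the distance to that region's nearest member
#' site.  Sites inside no region are dropped with a warning.
#'
#' @param sites Data frame with columns \code{site_id}, \code{x_km},
#'   \code{y_km}.
#' @param regions A \code{\link{region_set}}.
#' @return Data frame with one row per retained site: \code{site_id},
#'   \code{core} (region id) and \code{buffered} (list column of region ids,
#'   always including the core).
#' @export
assign_regions <- function(sites, regions) {
  stopifnot(inherits(regions, "region_set"))
  if (!all(c("site_id", "x_km", "y_km") %in% names(sites))) {
    stop("assign_regions: sites need columns site_id, x_km, y_km")
  }
  pts <- cbind(sites$x_km, sites$y_km)
  ids <- regions$region_ids
  n <- nrow(sites)
  inside <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  ddist <- matrix(Inf, n, length(ids), dimnames = list(NULL, ids))

  if (!is.null(regions$polygons)) {
    for (r in ids) {
      ring <- as.matrix(regions$polygons[regions$polygons$region_id == r,
                                         c("x_km", "y_km")])
      inside[, r] <- mgcv::in.out(rbind(ring, ring[1, ]), pts)
      ddist[, r] <- dist_to_ring(pts, ring)
    }
  } else {
    lab <- regions$labels[as.character(sites$site_id)]
    if (anyNA(lab)) {
      stop("assign_regions: sites missing from region labels: ",
           paste(sites$site_id[is.na(lab)], collapse = ", "))
    }
    for (r in ids) {
      inside[, r] <- lab == r
      members <- pts[lab == r, , drop = FALSE]
      if (nrow(members) > 0) {
        ddist[, r] <- apply(pairwise_distances(pts, members), 1, min)
      }
    }
  }

  orphan <- rowSums(inside) == 0
  if (any(orphan)) {
    warning("assign_regions: ", sum(orphan),
            " site(s) outside all regions, excluded: ",
            paste(utils::head(sites$site_id[orphan], 5), collapse = ", "))
  }
  keep <- which(!orphan)
  core <- ids[apply(inside[keep, , drop = FALSE], 1, which.max)]
  buffered <- lapply(keep, function(i) {
    ids[inside[i, ] | ddist[i, ] <= regions$buffer_km]
  })
  data.frame(site_id = sites$site_id[keep], core = core,
             buffered = I(buffered))
}
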