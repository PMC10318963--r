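## Earth radius (mean, IUGG) fixed so distances are bit-reproducible.
EARTH_RADIUS_KM <- 6371.0088

checkCoordinates <- function(lat, lon, what = "coordinate") {
  if (any(is.na(lat)) || any(is.na(lon)))
    stop(sprintf("missing %s: lat/lon must not be NA", what), call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop(sprintf("invalid %s: 'lat' outside [-90, 90]", what), call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop(sprintf("invalid %s: 'lon' outside [-180, 180]", what), call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance between points given as WGS84 decimal degrees, on a
#' sphere of radius 6371.0088 km. This is the built-in straight-line
#' stand-in for road distances; supply an external matrix to
#' [buildDistanceMatrix()] when network distances are available.
#'
#' Vectorised over coordinates (recycled as usual).
#'
#' @param lat1,lon1 origin latitude/longitude, degrees.
#' @param lat2,lon2 destination latitude/longitude, degrees.
#' @return numeric vector of distances in kilometres.
#' @examples
#' haversineKm(0, 0, 1, 0)   # one degree of latitude, ~111.195 km
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  checkCoordinates(lat1, lon1, "origin coordinate")
  checkCoordinates(lat2, lon2, "destination coordinate")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Build the woman-by-facility distance matrix
#'
#' Computes straight-line (haversine) distances between every woman and
#' every facility, or passes through a user-supplied external matrix (for
#' example road-network distances). The external matrix, when given, must
#' cover every woman and facility; its entries are used exactly as given.
#'
#' @param women data.frame with columns \code{woman_id, lat, lon}.
#' @param facilities data.frame with columns \code{facility_id, lat, lon}.
#' @param external optional \linkS4class{DistanceMatrix} (or plain matrix
#'   with woman-id rownames and facility-id colnames) standing in for the
#'   haversine computation.
#' @return a \linkS4class{DistanceMatrix} with rows ordered as \code{women}
#'   and columns as \code{facilities}.
#' @export
buildDistanceMatrix <- function(women, facilities, external = NULL) {
  wid <- as.character(women$woman_id)
  fid <- as.character(facilities$facility_id)
  if (anyDuplicated(wid)) stop("duplicated woman ids", call. = FALSE)
  if (anyDuplicated(fid)) stop("duplicated facility ids", call. = FALSE)
  if (!is.null(external)) {
    km <- if (is(external, "DistanceMatrix")) distances(external) else external
    missW <- setdiff(wid, rownames(km))
    missF <- setdiff(fid, colnames(km))
    if (length(missW) || length(missF))
      stop("external distance matrix does not cover: ",
        paste(c(missW, missF), collapse = ", "), call. = FALSE)
    out <- km[wid, fid, drop = FALSE]
    return(new("DistanceMatrix", km = out, source = "external"))
  }
  checkCoordinates(women$lat, women$lon, "woman coordinate")
  checkCoordinates(facilities$lat, facilities$lon, "facility coordinate")
  km <- outer(seq_along(wid), seq_along(fid), function(i, j)
    haversineKm(women$lat[i], women$lon[i],
                facilities$lat[j], facilities$lon[j]))
  dimnames(km) <- list(wid, fid)
  new("DistanceMatrix", km = km, source = "haversine")
}

#' Nearest-facility indicator matrix
#'
#' Flags, for every woman, the facility at minimal distance; this indicator
#' enters the choice model as the "nearest facility" attribute and, against
#' the chosen facility, quantifies bypassing. Ties go to the
#' lexicographically smallest facility id so the flag is deterministic.
#'
#' @param dm a \linkS4class{DistanceMatrix}.
#' @return 0/1 matrix of the same shape and dimnames; each row has exactly
#'   one 1.
#' @export
nearestFlags <- function(dm) {
  stopifnot(is(dm, "DistanceMatrix"))
  km <- distances(dm)
  if (nrow(km) == 0L || ncol(km) == 0L)
    stop("empty distance matrix", call. = FALSE)
  ord <- order(colnames(km))  # tie-break: smallest facility id
  flags <- matrix(0, nrow(km), ncol(km), dimnames = dimnames(km))
  idx <- apply(km[, ord, drop = FALSE], 1L, which.min)
  flags[cbind(seq_len(nrow(km)), ord[idx])] <- 1
  flags
}
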