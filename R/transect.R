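#' Project sampling sites onto a one-dimensional transect
#'
#' Computes cumulative great-circle distances (haversine, Earth radius
#' 6371.0088 km) along an ordered chain of sites, compressing the sampling
#' localities to a single line. The first site in `anchor_order` is the
#' origin (distance 0); distances are nondecreasing along the chain.
#'
#' @param sites Data frame with `site_id`, `latitude` and `longitude`
#'   (decimal degrees).
#' @param anchor_order Character or integer vector giving the site order,
#'   starting at the designated origin. Defaults to the row order.
#' @return The site table in anchor order with a `distance` column (km).
#' @export
project_transect <- function(sites, anchor_order = NULL) {
  stopifnot(all(c("site_id", "latitude", "longitude") %in% names(sites)))
  if (nrow(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("coordinates outside valid ranges", call. = FALSE)
  if (is.null(anchor_order)) anchor_order <- sites$site_id
  idx <- match(anchor_order, sites$site_id)
  if (anyNA(idx)) stop("anchor_order contains unknown site ids", call. = FALSE)
  ord <- sites[idx, , drop = FALSE]
  pts <- cbind(ord$longitude, ord$latitude)
  seg <- geosphere::distHaversine(pts[-nrow(pts), , drop = FALSE],
                                  pts[-1, , drop = FALSE],
                                  r = 6371008.8) / 1000
  ord$distance <- cumsum(c(0, seg))
  as_tibble(ord)
}
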