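## GeoJSON input/output and planar point-in-polygon.
##
## The study geography is a set of planar polygons (census block groups) with
## population and socioeconomic proportions attached as feature properties.
## Coordinates are abstract planar units: no CRS handling is done or implied.

#' @importFrom jsonlite toJSON fromJSON read_json
NULL

# Properties every geography feature must carry, in canonical column order.
.geo_required_props <- c(
  "cbg_id", "population",
  "p_nhblack", "p_female_headed", "p_public_assist", "p_poverty", "p_unemployed"
)

# Optional covariates used by the cluster-profiling regressions.
.geo_covariate_props <- c(
  "p_nonwhite", "p_less_hs", "p_poverty_cov", "p_married", "p_age_over65",
  "p_renter", "p_male"
)

#' Test points for containment in a closed planar ring
#'
#' Even-odd ray casting with an explicit boundary rule: a point lying on a
#' polygon edge or vertex counts as contained. Vectorized over points.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param ring numeric matrix with columns x, y; first vertex repeated as the
#'   last row (a closed, non-self-intersecting ring).
#' @param eps absolute snapping tolerance for the boundary test.
#' @return logical vector, `TRUE` where the point is inside or on the ring.
#' @export
point_in_ring <- function(px, py, ring, eps = 1e-9) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 4)
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    stop("malformed polygon: ring is not closed")
  }
  m <- length(px)
  inside <- rep(FALSE, m)
  on_boundary <- rep(FALSE, m)
  nseg <- nrow(ring) - 1L
  for (i in seq_len(nseg)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    scale <- abs(x2 - x1) + abs(y2 - y1) + 1
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) <= eps * scale &
      px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
      py >= min(y1, y2) - eps & py <= max(y1, y2) + eps
    on_boundary <- on_boundary | on_seg
    crosses <- (y1 > py) != (y2 > py)
    x_int <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    hit <- crosses & (px < x_int)
    hit[is.na(hit)] <- FALSE
    inside <- xor(inside, hit)
  }
  inside | on_boundary
}

#' Write a geography as a GeoJSON FeatureCollection
#'
#' One Polygon feature per census block group, with `cbg_id`, `population`,
#' the five deprivation-index proportions, the derived `nd` index and any
#' additional covariate proportions as properties. Output is deterministic:
#' the same geography always serializes to the same bytes.
#'
#' @param geography a `raap_geography` object (see [generate_geography()] or
#'   [read_geography_geojson()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geography_geojson <- function(geography, path) {
  stopifnot(inherits(geography, "raap_geography"))
  props <- setdiff(names(geography), "polygon")
  feats <- lapply(seq_len(nrow(geography)), function(i) {
    ring <- geography$polygon[[i]]
    prop <- as.list(geography[i, props, drop = FALSE])
    list(
      type = "Feature",
      properties = prop,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(k) ring[k, ]))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  txt <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read a geography from a GeoJSON FeatureCollection
#'
#' Accepts any FeatureCollection of Polygon features carrying `cbg_id`,
#' `population` and the five deprivation proportions as properties. The
#' neighborhood-disadvantage index is recomputed from the five proportions on
#' read, so `nd` is always consistent with its definition.
#'
#' @param path path to a GeoJSON file.
#' @return a `raap_geography`: a data.frame with one row per block group,
#'   centroid columns `cx`, `cy`, an `nd` column and a `polygon` list column
#'   of closed rings.
#' @export
read_geography_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  feats <- fc$features
  if (length(feats) == 0) stop("empty FeatureCollection: ", path)
  rows <- lapply(feats, function(f) {
    pr <- f$properties
    missing <- setdiff(.geo_required_props, names(pr))
    if (length(missing)) {
      stop("feature missing required properties: ", paste(missing, collapse = ", "))
    }
    pr
  })
  prop_names <- unique(unlist(lapply(rows, names)))
  prop_names <- setdiff(prop_names, c("cx", "cy", "nd"))
  df <- as.data.frame(
    lapply(prop_names, function(nm) {
      vals <- lapply(rows, function(r) if (is.null(r[[nm]])) NA else r[[nm]])
      unlist(vals)
    }),
    col.names = prop_names, stringsAsFactors = FALSE
  )
  polys <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g$type) || g$type != "Polygon") stop("non-Polygon geometry in geography")
    ring <- do.call(rbind, lapply(g$coordinates[[1]], function(xy) as.numeric(xy)))
    if (any(ring[1, ] != ring[nrow(ring), ])) stop("malformed polygon: ring is not closed")
    ring
  })
  new_geography(df, polys)
}

# Assemble and validate the raap_geography container.
new_geography <- function(df, polygons) {
  stopifnot(nrow(df) == length(polygons))
  if (anyDuplicated(df$cbg_id)) stop("duplicate cbg_id in geography")
  if (any(df$population < 0)) stop("negative population in geography")
  df$cbg_id <- as.character(df$cbg_id)
  cent <- t(vapply(polygons, ring_centroid, numeric(2)))
  df$cx <- cent[, 1]
  df$cy <- cent[, 2]
  df$nd <- compute_nd(df$p_nhblack, df$p_female_headed, df$p_public_assist,
                      df$p_poverty, df$p_unemployed)
  ord <- order(df$cbg_id)
  df <- df[ord, , drop = FALSE]
  polygons <- polygons[ord]
  rownames(df) <- NULL
  df$polygon <- polygons
  class(df) <- c("raap_geography", "data.frame")
  df
}

# Area-weighted polygon centroid (shoelace); falls back to the vertex mean
# for degenerate (zero-area) rings.
ring_centroid <- function(ring) {
  x <- ring[-nrow(ring), 1]; y <- ring[-nrow(ring), 2]
  x2 <- ring[-1, 1]; y2 <- ring[-1, 2]
  a <- x * y2 - x2 * y
  area <- sum(a) / 2
  if (abs(area) < 1e-300) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + x2) * a) / (6 * area), sum((y + y2) * a) / (6 * area))
}

#' @export
print.raap_geography <- function(x, ...) {
  cat(sprintf("raap_geography: %d census block groups\n", nrow(x)))
  cat(sprintf("  total population: %d\n", as.integer(sum(x$population))))
  cat(sprintf("  ND range: [%.3f, %.3f]\n", min(x$nd), max(x$nd)))
  invisible(x)
}
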