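# Geographic projection of a single site's allele states onto sample
# collection coordinates, with greedy merging of nearby accessions into
# circles rendered as pies.

EARTH_RADIUS_KM <- 6371

#' Pick the single site for a geographic map
#'
#' `"chrom:pos"` selects the exact position; a region selects its
#' lowest-position variant.
#'
#' @param matrix a `genotype_matrix`
#' @param site_spec a position or region string (or `region_query`)
#' @return list: `index` into the matrix sites plus `chrom, pos, ref, alt`
#' @export
select_site <- function(matrix, site_spec) {
  region <- if (inherits(site_spec, "region_query")) site_spec
            else parse_region_spec(site_spec)
  hit <- which(matrix$sites$chrom == region$chrom &
               matrix$sites$pos >= region$start &
               matrix$sites$pos <= region$end)
  if (!length(hit))
    ss_stop("empty-site", sprintf("no variant site in %s", format_region(region)))
  i <- hit[[which.min(matrix$sites$pos[hit])]]
  list(index = i, chrom = matrix$sites$chrom[[i]], pos = matrix$sites$pos[[i]],
       ref = matrix$sites$ref[[i]], alt = matrix$sites$alt[[i]])
}

#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371 km.
#' @param p,q numeric `c(latitude, longitude)` in degrees
#' @return distance in km
#' @export
haversine_km <- function(p, q) {
  rad <- pi / 180
  dlat <- (q[[1L]] - p[[1L]]) * rad
  dlon <- (q[[2L]] - p[[2L]]) * rad
  a <- sin(dlat / 2)^2 + cos(p[[1L]] * rad) * cos(q[[1L]] * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Geographic allele-state points for one site
#'
#' Joins the site's genotype classes onto catalog latitude/longitude;
#' samples lacking coordinates are excluded with a warning, and an
#' optional bounding box restricts the output window.
#'
#' @param matrix a `genotype_matrix`
#' @param site a [select_site()] result
#' @param catalog the sample catalog (needs `latitude`/`longitude` columns)
#' @param lat_range,lon_range optional numeric `c(min, max)` windows
#' @return data.frame `accessionName, latitude, longitude, alleleState`
#' @export
geo_points <- function(matrix, site, catalog, lat_range = NULL, lon_range = NULL) {
  ent <- catalog$entries
  if (!all(c("latitude", "longitude") %in% names(ent)))
    ss_stop("parameter", "catalog has no latitude/longitude columns")
  idx <- match(matrix$samples, ent$accessionName)
  pts <- data.frame(accessionName = matrix$samples,
                    latitude = ent$latitude[idx], longitude = ent$longitude[idx],
                    alleleState = matrix$klass[site$index, ],
                    stringsAsFactors = FALSE)
  nocoord <- is.na(pts$latitude) | is.na(pts$longitude)
  if (any(nocoord))
    ss_warn("no-coordinates", sprintf("%d sample(s) lack coordinates and are excluded",
                                      sum(nocoord)))
  pts <- pts[!nocoord, , drop = FALSE]
  bad <- abs(pts$latitude) > 90 | pts$longitude <= -180 | pts$longitude > 180
  if (any(bad))
    ss_stop("parameter", sprintf("coordinates out of bounds for: %s",
                                 paste(pts$accessionName[bad], collapse = ", ")))
  if (!is.null(lat_range))
    pts <- pts[pts$latitude >= lat_range[[1L]] & pts$latitude <= lat_range[[2L]], , drop = FALSE]
  if (!is.null(lon_range))
    pts <- pts[pts$longitude >= lon_range[[1L]] & pts$longitude <= lon_range[[2L]], , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Merge nearby points into circles
#'
#' Greedy procedure: repeatedly seed a circle at the unassigned point with
#' the most unassigned neighbours within `radius_km` (ties broken by
#' lexicographic accession name), absorb every unassigned point within the
#' radius of the seed, and use the seed's coordinates as the centre. The
#' circles partition the located points; `radius_km = 0` yields one circle
#' per distinct coordinate.
#'
#' @param points a [geo_points()] data.frame
#' @param radius_km non-negative merge radius
#' @return list of circles: `lat`, `lon`, `members`, `size`, `pie`
#'   (named allele-state fractions summing to 1)
#' @export
merge_points <- function(points, radius_km) {
  if (radius_km < 0) ss_stop("parameter", "radius_km must be >= 0")
  pts <- points[order(points$accessionName), , drop = FALSE]
  n <- nrow(pts)
  if (!n) return(list())
  dmat <- base::matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dmat[i, j] <- dmat[j, i] <- haversine_km(
      c(pts$latitude[[i]], pts$longitude[[i]]),
      c(pts$latitude[[j]], pts$longitude[[j]]))
  }
  unassigned <- rep(TRUE, n)
  circles <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    nb <- vapply(cand, function(i) sum(dmat[i, cand] <= radius_km), integer(1))
    seed <- cand[[which.max(nb)]]  # cand is accession-sorted, so ties pick the first
    mem <- cand[dmat[seed, cand] <= radius_km]
    states <- pts$alleleState[mem]
    pie <- table(factor(states, levels = c("REF_HOM", "HET", "ALT_HOM", "MISSING")))
    pie <- pie[pie > 0] / length(mem)
    circles[[length(circles) + 1L]] <- list(
      lat = pts$latitude[[seed]], lon = pts$longitude[[seed]],
      members = pts$accessionName[mem], size = length(mem),
      pie = setNames(as.numeric(pie), names(pie)))
    unassigned[mem] <- FALSE
  }
  circles
}

#' Serialize a geographic map to JSON
#' @param site a [select_site()] result
#' @param circles a [merge_points()] result
#' @param path optional output path
#' @export
write_geomap_json <- function(site, circles, path = NULL) {
  obj <- list(
    site = list(chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt),
    circles = lapply(circles, function(cc)
      list(lat = cc$lat, lon = cc$lon, size = cc$size,
           members = cc$members, pie = as.list(cc$pie))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
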