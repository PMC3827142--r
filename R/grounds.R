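# Spawning grounds of Northeast Arctic cod, indexed 1-15 from south to
# north along the Norwegian coast. Coordinates are approximate map
# digitisations (no coordinate table exists for the original study);
# positions are only used to seed particle releases and to check the
# south/north split against the section geometry.

#' Packaged spawning-ground table
#'
#' Fifteen spawning areas ordered south to north, with approximate
#' coordinates and a release radius. Grounds 1-12 lie south(-west) of the
#' entrance to the Barents Sea and are classed `southern`; 13-15 are
#' `northern`. The split is by index; [classify_grounds()] provides the
#' geometric cross-check against a section line.
#'
#' @return data.frame: index, name, lon, lat, radius_km, region
#' @export
spawning_grounds <- function() {
  path <- system.file("extdata", "spawning_grounds.csv",
                      package = "larvadrift")
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(g$index), all(diff(g$index) == 1L))
  g$region <- ifelse(g$index <= 12L, "southern", "northern")
  g
}

#' Default Barents Sea entrance section (Fugloeya-Bjoernoeya analogue)
#'
#' Endpoints near Fugloeya (south) and Bjoernoeya (north); used both for
#' the inflow transport diagnostic and as the dividing line between
#' southern and northern spawning grounds.
#'
#' @param max_depth deepest level integrated, m
#' @return a [section_definition()]
#' @export
fb_section <- function(max_depth = Inf) {
  section_definition(20.15, 70.25, 19.05, 74.43, max_depth = max_depth)
}

#' Geometric south/north classification of spawning grounds
#'
#' A ground is `southern` when it lies on the upstream (south-western) side
#' of the section line extended to infinity, i.e. to the left of the
#' south-to-north section direction. This reproduces the index-based split
#' for the packaged table: exactly grounds 1-12 are southern.
#'
#' @param grounds data.frame with lon, lat (e.g. [spawning_grounds()])
#' @param section a [section_definition()] (default [fb_section()])
#' @return character vector, "southern" or "northern" per ground
#' @export
classify_grounds <- function(grounds, section = fb_section()) {
  mid_lat <- (section$lat_a + section$lat_b) / 2
  kx <- km_per_deg_lon(mid_lat)
  bx <- (section$lon_b - section$lon_a) * kx
  by <- (section$lat_b - section$lat_a) * KM_PER_DEG_LAT
  px <- (grounds$lon - section$lon_a) * kx
  py <- (grounds$lat - section$lat_a) * KM_PER_DEG_LAT
  cross <- bx * py - by * px
  ifelse(cross > 0, "southern", "northern")
}
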