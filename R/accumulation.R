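# Foraging-box accumulation statistics: daily counts of larvae inside a
# square box around the colony, split by spawning-ground origin, plus the
# fraction-from-south statistic over the chick-rearing window and
# per-year arrival curves.

#' Foraging box around the colony
#'
#' Axis-aligned square of side `side_km` in a local equidistant projection
#' about the colony. Default centre is the Hornoeya analogue (70 deg 23' N,
#' 31 deg 10' E) and the default side is 100 km, approximating the foraging
#' range of chick-rearing common guillemots.
#'
#' @param centre_lon,centre_lat box centre (the colony), degrees
#' @param side_km box side length, km
#' @return a `foraging_box` list
#' @export
foraging_box <- function(centre_lon = 31 + 10 / 60,
                         centre_lat = 70 + 23 / 60,
                         side_km = 100) {
  stopifnot(side_km > 0)
  structure(list(centre_lon = centre_lon, centre_lat = centre_lat,
                 side_km = side_km),
            class = "foraging_box")
}

#' Chick-rearing window
#'
#' Default 9 June - 7 July, the approximate chick-rearing period of the
#' colony; month-day strings are resolved against the year of the data
#' they are applied to.
#'
#' @param start,end "MM-DD" strings or Dates
#' @return a `rearing_window` list
#' @export
rearing_window <- function(start = "06-09", end = "07-07") {
  structure(list(start = start, end = end), class = "rearing_window")
}

window_dates <- function(window, year) {
  d0 <- resolve_date(window$start, year)
  d1 <- resolve_date(window$end, year)
  stopifnot(d0 < d1)
  c(d0, d1)
}

#' Is a point inside the foraging box?
#'
#' Local-projection offsets from the centre are compared with half the
#' side; the boundary is inclusive.
#'
#' @param lon,lat point coordinates, degrees (vectors)
#' @param box a [foraging_box()]
#' @return logical vector
#' @export
in_box <- function(lon, lat, box = foraging_box()) {
  km <- lonlat_to_km(lon, lat, box$centre_lon, box$centre_lat)
  half <- box$side_km / 2
  abs(km$x) <= half & abs(km$y) <= half
}

#' Daily larval accumulation inside the foraging box
#'
#' Counts active larvae (stage `larva`, status `active`) inside the box on
#' each day, split by origin region (grounds 1-12 southern, 13-15
#' northern), with mean length and age per region. Days without larvae get
#' zero counts and NA means.
#'
#' @param traj trajectory table from [run_ibm()]
#' @param box a [foraging_box()]
#' @param window optional [rearing_window()]; when given, the series is
#'   restricted to it (error if the trajectories do not cover it)
#' @param southern_max highest ground index counted as southern
#' @return `data.table`: date, count_south, count_north,
#'   mean_length_south, mean_length_north, mean_age_south, mean_age_north
#' @export
daily_accumulation <- function(traj, box = foraging_box(), window = NULL,
                               southern_max = 12L) {
  traj <- data.table::as.data.table(traj)
  dates <- seq(min(traj$date), max(traj$date), by = "day")
  if (!is.null(window)) {
    wd <- window_dates(window, as.integer(format(min(traj$date), "%Y")))
    if (wd[1] < min(dates) || wd[2] > max(dates)) {
      stop("rearing window outside the trajectory dates")
    }
    dates <- seq(wd[1], wd[2], by = "day")
  }
  sel <- traj[traj$stage == "larva" & traj$status == "active" &
                traj$date %in% dates, ]
  sel <- sel[in_box(sel$lon, sel$lat, box), ]
  sel$region <- ifelse(sel$origin <= southern_max, "south", "north")
  agg <- sel[, list(count = .N, mean_len = mean(length_mm),
                    mean_age = mean(age_d)),
             by = list(date, region)]
  out <- data.table::data.table(date = dates)
  for (rg in c("south", "north")) {
    a <- agg[agg$region == rg, ]
    m <- match(out$date, a$date)
    out[[paste0("count_", rg)]] <- ifelse(is.na(m), 0L, a$count[m])
    out[[paste0("mean_length_", rg)]] <- a$mean_len[m]
    out[[paste0("mean_age_", rg)]] <- a$mean_age[m]
  }
  data.table::setnames(out, c("date", "count_south", "mean_length_south",
                              "mean_age_south", "count_north",
                              "mean_length_north", "mean_age_north"))
  data.table::setcolorder(out, c("date", "count_south", "count_north",
                                 "mean_length_south", "mean_length_north",
                                 "mean_age_south", "mean_age_north"))
  out[]
}

#' Fraction of in-box larvae of southern origin over a window
#'
#' Sum of southern daily counts divided by the sum of all daily counts
#' over the window days. Returns NA (with a warning) when no larvae were
#' in the box at all: an undefined fraction is reported as undefined, not
#' as zero.
#'
#' @param acc accumulation series from [daily_accumulation()]
#' @param window optional [rearing_window()] restricting the days used
#' @return fraction in [0, 1], or NA if undefined
#' @export
fraction_south <- function(acc, window = NULL) {
  d <- acc
  if (!is.null(window)) {
    wd <- window_dates(window, as.integer(format(min(acc$date), "%Y")))
    if (wd[1] < min(acc$date) || wd[2] > max(acc$date)) {
      stop("rearing window not covered by the accumulation series")
    }
    d <- acc[acc$date >= wd[1] & acc$date <= wd[2], ]
  }
  tot <- sum(d$count_south) + sum(d$count_north)
  if (tot == 0) {
    warning("no larvae in the box over the window; fraction undefined")
    return(NA_real_)
  }
  sum(d$count_south) / tot
}

#' Per-year cumulative arrival curves by origin
#'
#' Cumulative in-box counts against date for each year, per origin region.
#' When a per-year body-size series is supplied, years are flagged into
#' upper/lower quartile groups (floor(n/4) years each, e.g. 4 + 4 of 16)
#' by body size, mirroring the quartile-highlighted arrival-curve figure.
#'
#' @param acc_by_year named list of accumulation series (names are years),
#'   or a single series whose dates span several years
#' @param body_size optional named numeric vector of body size per year
#' @return `data.table`: year, date, cum_south, cum_north and (with
#'   `body_size`) `size_group` in {"upper", "lower", "mid"}
#' @export
arrival_curves <- function(acc_by_year, body_size = NULL) {
  if (!is.list(acc_by_year) || data.table::is.data.table(acc_by_year)) {
    acc <- data.table::as.data.table(acc_by_year)
    yr <- format(acc$date, "%Y")
    acc_by_year <- split(acc, yr)
  }
  years <- names(acc_by_year)
  if (length(years) < 1) stop("need at least one year")
  curves <- data.table::rbindlist(lapply(years, function(y) {
    a <- acc_by_year[[y]]
    data.table::data.table(year = as.integer(y), date = a$date,
                           cum_south = cumsum(a$count_south),
                           cum_north = cumsum(a$count_north))
  }))
  if (!is.null(body_size)) {
    if (is.null(names(body_size)) ||
        !all(years %in% names(body_size))) {
      stop("quartile grouping requires a body-size value for every year")
    }
    bs <- body_size[years]
    k <- floor(length(years) / 4)
    ord <- order(bs)
    grp <- rep("mid", length(years))
    if (k >= 1) {
      grp[ord[seq_len(k)]] <- "lower"
      grp[ord[seq.int(length(years) - k + 1, length(years))]] <- "upper"
    }
    names(grp) <- years
    curves$size_group <- grp[as.character(curves$year)]
  }
  curves[]
}
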