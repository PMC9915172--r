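# Seeded synthetic-city generator.
#
# Emulates the data sources of the exposure pipeline for a small
# self-consistent city with known ground truth: an orthogonal street grid with
# random diagonal shortcuts (so both zero-degree and oblique turns exist),
# addresses with canonical address strings and property reference numbers
# (UPRNs), classed urban features (greenspaces with entrances and areas,
# transit stops, food outlets), reflectance and pollutant rasters, per-street
# traffic records, buildings, EPC-style dwelling records, and corrupted
# free-text address strings paired with their true UPRNs. All coordinates are
# in a synthetic projected CRS with meter units. Regenerating with the same
# seed and parameters is deterministic.

STREET_NAMES <- c(
  "ACACIA", "BIRCH", "CEDAR", "DERWENT", "ELM", "FERN", "HAWTHORN", "IVY",
  "JASPER", "KESTREL", "LARCH", "MAPLE", "NELSON", "ORCHARD", "PENNINE",
  "QUARRY", "ROWAN", "SYCAMORE", "THORNTON", "ULLSWATER", "VICTORIA",
  "WHARFE", "YEWTREE", "AIREDALE", "BOWLING", "CLAYTON", "DENHOLME",
  "ECCLESHILL", "FAGLEY", "GIRLINGTON"
)
STREET_TYPES <- c("STREET", "ROAD", "AVENUE", "LANE", "DRIVE")

#' Synthetic-city generator settings
#'
#' Defaults describe the standard study city: a 1400 m square with a 100 m
#' street grid (roughly 2000 network segments after 20 m dissection), 500
#' residential addresses, a handful of greenspaces, two dozen bus stops, one
#' rail station, 40 food outlets, 30 m reflectance rasters and 5 m pollutant
#' rasters.
#'
#' @param extent Side length of the square city in meters.
#' @param spacing Street-grid spacing in meters.
#' @param n_addresses Number of residential addresses.
#' @param n_parks,n_play Greenspace feature counts (parks span 1, 2 or 4 grid
#'   cells; play spaces are small).
#' @param n_bus Bus stop count (plus one rail station with two entrances).
#' @param n_food Food outlet count.
#' @param p_fast_food Probability an outlet is fast food.
#' @param n_diagonals Number of diagonal shortcut streets across grid cells.
#' @param cell_pollutant,cell_reflectance Raster cell sizes in meters.
#' @param p_case,p_punct,p_abbrev,p_transpose Dirty-address corruption
#'   probabilities (case flips, punctuation insertion, street-type
#'   abbreviation, adjacent-token transposition).
#' @return A list of generator settings.
#' @export
city_params <- function(extent = 1400, spacing = 100, n_addresses = 500,
                        n_parks = 6, n_play = 4, n_bus = 24, n_food = 40,
                        p_fast_food = 0.4, n_diagonals = 12,
                        cell_pollutant = 5, cell_reflectance = 30,
                        p_case = 0.9, p_punct = 0.7, p_abbrev = 0.5,
                        p_transpose = 0) {
  if (extent <= 0 || spacing <= 0) {
    stop("extent and street spacing must be positive", call. = FALSE)
  }
  if (cell_pollutant <= 0 || cell_reflectance <= 0) {
    stop("raster cell sizes must be positive", call. = FALSE)
  }
  counts <- c(n_addresses, n_parks, n_play, n_bus, n_food, n_diagonals)
  if (any(counts < 0)) stop("feature counts must be >= 0", call. = FALSE)
  as.list(environment())
}

#' Generate a synthetic city
#'
#' @param seed Integer RNG seed; identical seed and parameters reproduce the
#'   city exactly.
#' @param params Settings from [city_params()].
#' @return A `synthetic_city` list: `streets` (geoms + attribute table),
#'   `addresses`, `features` (an [urban_features()] set), `rasters` (named
#'   `raster_surface` list: nir, red, pm10, pm25, nox), `traffic`,
#'   `buildings`, `dwellings`, `dirty_addresses`, `extent`, `seed`.
#' @export
generate_city <- function(seed = 1L, params = city_params()) {
  set.seed(seed)
  ext <- params$extent
  sp <- params$spacing
  nline <- floor(ext / sp)

  ## streets: orthogonal grid + diagonal shortcuts
  geoms <- list(); names_ <- character(0)
  for (i in 0:nline) {
    geoms[[length(geoms) + 1L]] <- cbind(c(i * sp, i * sp), c(0, ext))
  }
  for (i in 0:nline) {
    geoms[[length(geoms) + 1L]] <- cbind(c(0, ext), c(i * sp, i * sp))
  }
  n_cells <- nline * nline
  n_diag <- min(params$n_diagonals, n_cells)
  if (n_diag > 0) {
    cells <- sample.int(n_cells, n_diag)
    for (cix in cells) {
      cx <- (cix - 1L) %% nline
      cy <- (cix - 1L) %/% nline
      if (stats::runif(1) < 0.5) {
        g <- cbind(c(cx * sp, (cx + 1L) * sp), c(cy * sp, (cy + 1L) * sp))
      } else {
        g <- cbind(c(cx * sp, (cx + 1L) * sp), c((cy + 1L) * sp, cy * sp))
      }
      geoms[[length(geoms) + 1L]] <- g
    }
  }
  combos <- expand.grid(type = STREET_TYPES, name = STREET_NAMES,
                        stringsAsFactors = FALSE)
  street_names <- paste(combos$name, combos$type)[seq_along(geoms)]
  streets <- data.frame(street_id = sprintf("S%03d", seq_along(geoms)),
                        name = street_names, stringsAsFactors = FALSE)

  ## addresses along streets with perpendicular offsets
  n_addr <- params$n_addresses
  addr <- NULL
  if (n_addr > 0) {
    line_ix <- sample(seq_along(geoms), n_addr, replace = TRUE)
    tpos <- stats::runif(n_addr, 0.03, 0.97)
    side <- sample(c(-1, 1), n_addr, replace = TRUE)
    offs <- stats::runif(n_addr, 5, 15)
    xy <- t(vapply(seq_len(n_addr), function(i) {
      g <- geoms[[line_ix[i]]]
      L <- polyline_length(g)
      p <- interpolate_along(g, tpos[i] * L)
      d <- g[2L, ] - g[1L, ]
      nrm <- c(-d[2L], d[1L]) / sqrt(sum(d * d))
      p + side[i] * offs[i] * nrm
    }, numeric(2)))
    house_no <- pmax(1L, round(tpos * 100))
    quad <- 1L + (xy[, 1L] > ext / 2) + 2L * (xy[, 2L] > ext / 2)
    inward <- paste0(sample(1:9, n_addr, replace = TRUE),
                     sample(LETTERS, n_addr, replace = TRUE),
                     sample(LETTERS, n_addr, replace = TRUE))
    postcode <- paste0("BD", quad, " ", inward)
    addr <- data.frame(
      uprn = 100000L + seq_len(n_addr),
      x = xy[, 1L], y = xy[, 2L],
      address = paste(house_no, streets$name[line_ix], postcode),
      postcode = postcode,
      residential = TRUE,
      stringsAsFactors = FALSE
    )
  } else {
    addr <- data.frame(uprn = integer(0), x = numeric(0), y = numeric(0),
                       address = character(0), postcode = character(0),
                       residential = logical(0))
  }

  ## urban features
  feats <- list(); ents <- list(); fid <- 0L
  add_feature <- function(class, entrance_xy, fast_food = FALSE,
                          area = NA_real_) {
    fid <<- fid + 1L
    id <- sprintf("F%04d", fid)
    feats[[fid]] <<- data.frame(id = id, class = class, fast_food = fast_food,
                                area_m2 = area, stringsAsFactors = FALSE)
    ents[[fid]] <<- data.frame(feature_id = id,
                               x = entrance_xy[, 1L], y = entrance_xy[, 2L],
                               stringsAsFactors = FALSE)
    id
  }
  park_polys <- list()
  if (params$n_parks > 0 && nline >= 2) {
    sizes <- sample(c(1L, 2L, 4L), params$n_parks, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
    anchors <- sample.int((nline - 1L) * (nline - 1L), params$n_parks)
    for (i in seq_len(params$n_parks)) {
      ax <- (anchors[i] - 1L) %% (nline - 1L)
      ay <- (anchors[i] - 1L) %/% (nline - 1L)
      w <- if (sizes[i] >= 2L) 2L else 1L
      h <- if (sizes[i] == 4L) 2L else 1L
      x0 <- ax * sp + 10; y0 <- ay * sp + 10
      x1 <- (ax + w) * sp - 10; y1 <- (ay + h) * sp - 10
      ring <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
      park_polys[[length(park_polys) + 1L]] <- ring
      n_ent <- sample(1:3, 1L)
      exy <- ring[sample(1:4, n_ent), , drop = FALSE]
      add_feature("public park or garden", exy, area = polygon_area(ring))
    }
  }
  rand_street_point <- function(jitter = 0) {
    g <- geoms[[sample(seq_along(geoms), 1L)]]
    p <- interpolate_along(g, stats::runif(1, 0.05, 0.95) * polyline_length(g))
    p + stats::runif(2, -jitter, jitter)
  }
  for (i in seq_len(params$n_play)) {
    p <- rand_street_point(jitter = 12)
    add_feature("play space", matrix(p, ncol = 2L),
                area = stats::runif(1, 400, 2500))
  }
  for (i in seq_len(params$n_bus)) {
    add_feature("bus", matrix(rand_street_point(), ncol = 2L))
  }
  # one rail station near the center with two entrances
  cmid <- round(ext / 2 / sp) * sp
  add_feature("rail", rbind(c(cmid + 8, cmid), c(cmid - 8, cmid)))
  for (i in seq_len(params$n_food)) {
    # food clusters toward the center third of the city
    p <- rand_street_point(jitter = 10)
    if (stats::runif(1) < 0.6) {
      p <- (p + c(cmid, cmid)) / 2
    }
    ff <- stats::runif(1) < params$p_fast_food
    add_feature(if (ff) "fast-food outlet" else "non-fast-food food outlet",
                matrix(p, ncol = 2L), fast_food = ff)
  }
  features <- urban_features(do.call(rbind, feats), do.call(rbind, ents))

  ## rasters (margin of one grid cell beyond the street extent)
  margin <- sp
  mk_grid <- function(cellsize) {
    n <- ceiling((ext + 2 * margin) / cellsize)
    ax <- -margin + (seq_len(n) - 0.5) * cellsize
    list(n = n, x = ax, y = rev(ax), cell = cellsize)
  }
  gr <- mk_grid(params$cell_reflectance)
  greenness <- matrix(0, gr$n, gr$n)
  for (ring in park_polys) {
    cen <- polygon_centroid(ring)
    half <- sqrt(polygon_area(ring)) / 2
    for (r in seq_len(gr$n)) {
      dy <- abs(gr$y[r] - cen[2L])
      dx <- abs(gr$x - cen[1L])
      d <- pmax(dx, dy) - half
      greenness[r, ] <- pmax(greenness[r, ], exp(-pmax(d, 0) / 60))
    }
  }
  red <- 0.25 - 0.15 * greenness +
    matrix(stats::rnorm(gr$n^2, 0, 0.01), gr$n, gr$n)
  nir <- 0.30 + 0.35 * greenness +
    matrix(stats::rnorm(gr$n^2, 0, 0.01), gr$n, gr$n)
  red <- pmax(red, 0.01); nir <- pmax(nir, 0.01)
  gp <- mk_grid(params$cell_pollutant)
  dcen <- sqrt(outer((gp$y - ext / 2)^2, (gp$x - ext / 2)^2, "+"))
  pm25 <- 6 + 5 * exp(-dcen / 600) +
    matrix(stats::rnorm(gp$n^2, 0, 0.15), gp$n, gp$n)
  pm10 <- 12 + 9 * exp(-dcen / 600) +
    matrix(stats::rnorm(gp$n^2, 0, 0.3), gp$n, gp$n)
  nox <- 20 + 28 * exp(-dcen / 500) +
    matrix(stats::rnorm(gp$n^2, 0, 0.8), gp$n, gp$n)
  rasters <- list(
    nir = raster_surface(round(nir, 4), -margin, -margin, gr$cell),
    red = raster_surface(round(red, 4), -margin, -margin, gr$cell),
    pm10 = raster_surface(round(pm10, 3), -margin, -margin, gp$cell),
    pm25 = raster_surface(round(pm25, 3), -margin, -margin, gp$cell),
    nox = raster_surface(round(nox, 3), -margin, -margin, gp$cell)
  )

  ## traffic: street x period
  tr <- expand.grid(street_id = streets$street_id,
                    period = TRAFFIC_PERIODS, stringsAsFactors = FALSE)
  tr <- tr[order(tr$street_id, tr$period), , drop = FALSE]
  base_flow <- stats::rlnorm(nrow(streets), log(120), 0.6)
  period_mult <- c(am = 1.4, op = 0.8, pm = 1.5)
  tr$count <- round(base_flow[match(tr$street_id, streets$street_id)] *
                      period_mult[tr$period] *
                      stats::runif(nrow(tr), 0.85, 1.15))
  tr$freeflow_speed <- round(stats::runif(nrow(tr), 30, 60), 1)
  slow <- stats::runif(nrow(tr), 0.35, 1.1) *
    ifelse(tr$period == "op", 1.1, 0.85)
  tr$avg_speed <- round(pmin(tr$freeflow_speed * slow,
                             tr$freeflow_speed * 1.2), 1)
  rownames(tr) <- NULL

  ## buildings: one per address
  buildings <- NULL
  if (n_addr > 0) {
    h <- round(stats::runif(n_addr, 3, 12), 1)
    fl <- pmax(1L, round(h / 3))
    fp <- lapply(seq_len(n_addr), function(i) {
      cbind(addr$x[i] + c(-4, 4, 4, -4), addr$y[i] + c(-5, -5, 5, 5))
    })
    buildings <- data.frame(id = paste0("B", addr$uprn), uprn = addr$uprn,
                            height_m = h, floors = fl,
                            stringsAsFactors = FALSE)
    buildings$footprint <- fp
  } else {
    buildings <- data.frame(id = character(0), uprn = integer(0),
                            height_m = numeric(0), floors = integer(0))
    buildings$footprint <- list()
  }

  ## dwellings (EPC-style)
  dwellings <- NULL
  if (n_addr > 0) {
    age_bands <- c("before 1900", "1900-1929", "1930-1949", "1950-1975",
                   "1976-1995", "1996-2011", "2012 onwards")
    dwellings <- data.frame(
      uprn = addr$uprn,
      built_form = sample(DWELLING_VOCAB$built_form, n_addr, replace = TRUE,
                          prob = c(0.15, 0.25, 0.15, 0.35, 0.05, 0.05)),
      dwelling_type = sample(DWELLING_VOCAB$dwelling_type, n_addr,
                             replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.08, 0.02)),
      construction_age_band = sample(age_bands, n_addr, replace = TRUE),
      tenure = sample(DWELLING_VOCAB$tenure, n_addr, replace = TRUE,
                      prob = c(0.25, 0.2, 0.55)),
      storeys = buildings$floors,
      energy_consumption = round(stats::rlnorm(n_addr, log(15000), 0.4)),
      lighting_cost = round(stats::runif(n_addr, 40, 160)),
      heating_cost = round(stats::runif(n_addr, 300, 1400)),
      hot_water_cost = round(stats::runif(n_addr, 80, 320)),
      glazed_area = round(stats::runif(n_addr, 5, 40), 1),
      floor_area = round(80 * buildings$floors * stats::runif(n_addr, 0.7, 1.1)),
      floor_height = round(stats::runif(n_addr, 2.2, 3.2), 2),
      heated_rooms = sample(2:8, n_addr, replace = TRUE),
      habitable_rooms = sample(3:9, n_addr, replace = TRUE),
      extensions = sample(0:2, n_addr, replace = TRUE, prob = c(0.7, 0.25, 0.05)),
      stringsAsFactors = FALSE
    )
  }

  ## dirty address strings with known truth
  dirty <- NULL
  if (n_addr > 0) {
    dirty <- data.frame(
      raw_address = vapply(addr$address, corrupt_address, character(1),
                           p_case = params$p_case, p_punct = params$p_punct,
                           p_abbrev = params$p_abbrev,
                           p_transpose = params$p_transpose),
      true_uprn = addr$uprn, stringsAsFactors = FALSE)
    rownames(dirty) <- NULL
  }

  structure(
    list(streets = list(geoms = geoms, table = streets),
         addresses = addr, features = features, rasters = rasters,
         traffic = tr, buildings = buildings, dwellings = dwellings,
         dirty_addresses = dirty, extent = c(0, 0, ext, ext),
         seed = seed, params = params),
    class = "synthetic_city"
  )
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "synthetic_city (seed %d): %d streets, %d addresses, %d features, %d x %d m\n",
    x$seed, length(x$streets$geoms), nrow(x$addresses),
    nrow(x$features$features), x$extent[3L], x$extent[4L]))
  invisible(x)
}

# Apply seeded corruptions to a canonical address string.
corrupt_address <- function(address, p_case, p_punct, p_abbrev, p_transpose) {
  tokens <- strsplit(address, " ", fixed = TRUE)[[1L]]
  rev_abbrev <- stats::setNames(names(ADDRESS_ABBREV), ADDRESS_ABBREV)
  if (stats::runif(1) < p_abbrev) {
    hit <- which(!is.na(rev_abbrev[tokens]))
    if (length(hit) > 0L) {
      i <- hit[1L]
      tokens[i] <- paste0(rev_abbrev[tokens[i]],
                          if (stats::runif(1) < 0.5) "." else "")
    }
  }
  if (stats::runif(1) < p_transpose && length(tokens) >= 3L) {
    i <- sample(seq_len(length(tokens) - 1L), 1L)
    tokens[c(i, i + 1L)] <- tokens[c(i + 1L, i)]
  }
  if (stats::runif(1) < p_punct) {
    i <- sample(seq_along(tokens), 1L)
    tokens[i] <- paste0(tokens[i], sample(c(",", "."), 1L))
  }
  out <- paste(tokens, collapse = " ")
  u <- stats::runif(1)
  if (u < p_case / 2) out <- tolower(out)
  else if (u < p_case) {
    out <- paste0(toupper(substr(tolower(out), 1L, 1L)),
                  substr(tolower(out), 2L, nchar(out)))
  }
  out
}

#' Write a synthetic city to a directory
#'
#' Vector layers as GeoJSON, rasters as Esri ASCII grids, tabular layers as
#' CSV. File contents are deterministic for a given city.
#'
#' @param city A `synthetic_city`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geojson(city$streets$geoms, "LineString", city$streets$table,
                file.path(dir, "streets.geojson"))
  addr_geom <- lapply(seq_len(nrow(city$addresses)), function(i) {
    matrix(c(city$addresses$x[i], city$addresses$y[i]), ncol = 2L)
  })
  write_geojson(addr_geom, "Point",
                city$addresses[, c("uprn", "address", "postcode", "residential")],
                file.path(dir, "addresses.geojson"))
  ent <- city$features$entrances
  ent_geom <- lapply(seq_len(nrow(ent)), function(i) {
    matrix(c(ent$x[i], ent$y[i]), ncol = 2L)
  })
  write_geojson(ent_geom, "Point", ent["feature_id"],
                file.path(dir, "entrances.geojson"))
  utils::write.csv(city$features$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  for (nm in names(city$rasters)) {
    write_ascii_grid(city$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  utils::write.csv(city$traffic, file.path(dir, "traffic.csv"),
                   row.names = FALSE)
  utils::write.csv(city$dwellings, file.path(dir, "dwellings.csv"),
                   row.names = FALSE)
  utils::write.csv(city$dirty_addresses, file.path(dir, "dirty_addresses.csv"),
                   row.names = FALSE)
  bld_geom <- city$buildings$footprint
  bld_props <- city$buildings[, c("id", "uprn", "height_m", "floors")]
  write_geojson(lapply(bld_geom, list), "Polygon", bld_props,
                file.path(dir, "buildings.geojson"))
  invisible(dir)
}
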