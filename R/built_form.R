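# Built-form morphology: building-level metrics and Spacematrix block density
# indices, plus validation/passthrough of EPC-style dwelling records used as
# indoor-quality proxies.
#
# Spacematrix definitions (per block): GSI = sum footprint / block area;
# FSI = sum gross floor area / block area; OSR = (1 - GSI) / FSI (open space
# per unit floor area); L = FSI / GSI (mean number of floors). The identity
# OSR * L = (1 - GSI) / GSI holds for every non-empty block.

#' Building metrics
#'
#' @param footprint Footprint polygon (two-column coordinate matrix) or a
#'   precomputed footprint area in m2.
#' @param height Building height in meters (> 0).
#' @param floors Number of floors (integer >= 1).
#' @return Named vector: footprint (m2), height (m), volume (m3),
#'   floor_area (m2, gross = footprint x floors).
#' @export
building_metrics <- function(footprint, height, floors) {
  area <- if (is.matrix(footprint)) polygon_area(footprint) else footprint
  if (!is.finite(area) || area <= 0) {
    stop("degenerate building footprint", call. = FALSE)
  }
  if (height <= 0) stop("building height must be positive", call. = FALSE)
  if (floors < 1) stop("floor count must be >= 1", call. = FALSE)
  c(footprint = area, height = height, volume = area * height,
    floor_area = area * floors)
}

#' Spacematrix density indices for a block
#'
#' Buildings straddling the block boundary are clipped to it and their floor
#' area pro-rated by the clipped footprint fraction (convex blocks; a
#' non-convex block falls back to assigning each building by footprint
#' centroid). An empty block has FSI = GSI = 0 and missing OSR/L.
#'
#' @param block A block from [polygonize_blocks()] (or a list with `ring`,
#'   `area`).
#' @param buildings Data frame with `id`, `footprint` (list column of polygon
#'   matrices), `height_m`, `floors`.
#' @return Named numeric vector `c(fsi, gsi, osr, l)`; OSR and L are `NA` for
#'   empty blocks.
#' @export
block_density <- function(block, buildings) {
  if (is.null(block$area) || block$area <= 0) {
    stop("block area must be positive", call. = FALSE)
  }
  tot_fp <- 0; tot_gfa <- 0
  convex <- is_convex_ring(block$ring)
  for (i in seq_len(nrow(buildings))) {
    fp <- buildings$footprint[[i]]
    full_area <- polygon_area(fp)
    if (full_area <= 0) next
    if (convex) {
      clipped <- clip_polygon_convex(fp, block$ring)
      a <- if (nrow(clipped) >= 3L) polygon_area(clipped) else 0
    } else {
      cen <- polygon_centroid(fp)
      a <- if (point_in_polygon(cen[1L], cen[2L], block$ring)) full_area else 0
    }
    if (a <= 0) next
    if (a > block$area * (1 + 1e-6)) {
      stop("clipped footprint of building ", buildings$id[i],
           " exceeds block area", call. = FALSE)
    }
    frac <- a / full_area
    tot_fp <- tot_fp + a
    tot_gfa <- tot_gfa + full_area * buildings$floors[i] * frac
  }
  gsi <- tot_fp / block$area
  fsi <- tot_gfa / block$area
  if (tot_fp <= 0) {
    return(c(fsi = 0, gsi = 0, osr = NA_real_, l = NA_real_))
  }
  c(fsi = fsi, gsi = gsi, osr = (1 - gsi) / fsi, l = fsi / gsi)
}

## Dwelling records -----------------------------------------------------------

DWELLING_VOCAB <- list(
  built_form = c("detached", "semi-detached", "end-terrace", "mid-terrace",
                 "enclosed end-terrace", "enclosed mid-terrace"),
  dwelling_type = c("house", "bungalow", "flat", "maisonette", "park home"),
  tenure = c("rental (private)", "rental (social)", "owner-occupied")
)

# Common spelling variants mapped onto the canonical vocabulary.
DWELLING_ALIASES <- c(
  "semidetached" = "semi-detached", "semi detached" = "semi-detached",
  "endterrace" = "end-terrace", "end terrace" = "end-terrace",
  "midterrace" = "mid-terrace", "mid terrace" = "mid-terrace",
  "enclosed endterrace" = "enclosed end-terrace",
  "enclosed midterrace" = "enclosed mid-terrace",
  "owner occupied" = "owner-occupied", "owneroccupied" = "owner-occupied",
  "private rental" = "rental (private)", "social rental" = "rental (social)",
  "parkhome" = "park home"
)

DWELLING_NUMERIC <- c("storeys", "energy_consumption", "lighting_cost",
                      "heating_cost", "hot_water_cost", "glazed_area",
                      "floor_area", "floor_height", "heated_rooms",
                      "habitable_rooms", "extensions")

normalize_vocab <- function(x, field) {
  lx <- tolower(trimws(x))
  hit <- !is.na(DWELLING_ALIASES[lx])
  lx[hit] <- DWELLING_ALIASES[lx[hit]]
  ok <- lx %in% DWELLING_VOCAB[[field]] | is.na(x)
  list(value = lx, valid = ok)
}

#' Validate and pass through dwelling (EPC-style) records
#'
#' Checks categorical fields against controlled vocabularies (normalizing
#' common spelling variants), checks numeric fields for non-negativity, and
#' emits one long indicator row per (UPRN, field). Invalid categories are
#' flagged with a reason, never silently dropped; unknown UPRNs raise a
#' warning.
#'
#' @param records Data frame keyed by `uprn` with categorical columns
#'   `built_form`, `dwelling_type`, `tenure`, `construction_age_band` and the
#'   numeric columns storeys, energy_consumption, lighting/heating/hot-water
#'   costs, glazed_area, floor_area, floor_height, heated_rooms,
#'   habitable_rooms, extensions (any subset).
#' @param known_uprns Optional vector of valid UPRNs for orphan detection.
#' @return Long data frame: `uprn`, `field`, `value` (character), `numeric`
#'   (parsed value where applicable), `reason`.
#' @export
dwelling_passthrough <- function(records, known_uprns = NULL) {
  stopifnot("uprn" %in% names(records))
  if (!is.null(known_uprns)) {
    orphan <- setdiff(records$uprn, known_uprns)
    if (length(orphan) > 0L) {
      warning("orphan dwelling records for unknown UPRNs: ",
              paste(utils::head(orphan, 5L), collapse = ", "),
              if (length(orphan) > 5L) " ..." else "", call. = FALSE)
    }
  }
  rows <- list()
  emit <- function(field, value, numeric = NA_real_, reason = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      uprn = records$uprn, field = field, value = as.character(value),
      numeric = numeric, reason = reason, stringsAsFactors = FALSE)
  }
  for (field in intersect(names(DWELLING_VOCAB), names(records))) {
    nv <- normalize_vocab(records[[field]], field)
    emit(field, nv$value,
         reason = ifelse(nv$valid, NA_character_, "invalid-category"))
  }
  if ("construction_age_band" %in% names(records)) {
    emit("construction_age_band", records$construction_age_band)
  }
  for (field in intersect(DWELLING_NUMERIC, names(records))) {
    v <- records[[field]]
    bad <- !is.na(v) & v < 0
    emit(field, v, numeric = ifelse(bad, NA_real_, as.numeric(v)),
         reason = ifelse(bad, "negative-value", NA_character_))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$uprn, records$uprn)), , drop = FALSE]
}
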