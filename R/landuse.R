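# Land-use diversity and the walkability composite.
#
# Land-use intensity is Shannon's diversity index H = -sum p_i ln p_i over the
# land-use classes present in a neighborhood; the equitability variant H/ln(s)
# normalizes by the maximum attainable for s classes. The walkability surface
# is a simplified composite: an (equally) weighted mean of z-standardized
# component surfaces (land-use intensity, transit accessibility, street
# centrality, residential density) on a 25 m grid. It deliberately does not
# reproduce any calibrated pedestrian-demand model.

#' Shannon diversity index
#'
#' @param p Numeric vector of class proportions (must sum to 1) or raw
#'   non-negative class counts/areas (normalized internally when
#'   `normalize = TRUE`).
#' @param normalize Treat `p` as raw weights and normalize to proportions.
#' @return H in nats; 0 for a single class; at most `log(length(p))`.
#' @export
shannon_diversity <- function(p, normalize = FALSE) {
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0L) return(0)
  if (normalize) p <- p / sum(p)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("proportions must sum to 1 (or pass normalize = TRUE)", call. = FALSE)
  }
  -sum(p * log(p))
}

#' Shannon equitability
#'
#' H / ln(s): the diversity relative to the maximum for the s classes present;
#' defined as 0 when a single class is present.
#' @inheritParams shannon_diversity
#' @export
shannon_equitability <- function(p, normalize = FALSE) {
  p <- p[!is.na(p) & p > 0]
  s <- length(p)
  if (s <= 1L) return(0)
  shannon_diversity(p, normalize) / log(s)
}

#' Land-use intensity surface
#'
#' Rasterizes Shannon diversity of the feature-class mix: per 25 m cell, H of
#' the class composition (by feature counts) within a neighborhood radius of
#' the cell center. Cells with no features get 0.
#'
#' @param uf An `urban_features` object carrying land-use classes; feature
#'   locations are their first entrances.
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)`.
#' @param cell Cell size in meters (default 25).
#' @param neighborhood Neighborhood radius in meters (default 300).
#' @param equitability Return H / ln(s) instead of H.
#' @return A `raster_surface`.
#' @export
landuse_intensity_surface <- function(uf, extent, cell = 25,
                                      neighborhood = 300,
                                      equitability = FALSE) {
  pts <- feature_points(uf)
  nc <- max(1L, ceiling((extent[3L] - extent[1L]) / cell))
  nr <- max(1L, ceiling((extent[4L] - extent[2L]) / cell))
  vals <- matrix(0, nr, nc)
  cx <- extent[1L] + (seq_len(nc) - 0.5) * cell
  cy <- extent[2L] + (nr - seq_len(nr) + 0.5) * cell
  classes <- unique(pts$class)
  for (r in seq_len(nr)) {
    dy2 <- (pts$y - cy[r])^2
    for (cix in seq_len(nc)) {
      d2 <- (pts$x - cx[cix])^2 + dy2
      sel <- d2 <= neighborhood^2
      if (!any(sel)) next
      counts <- table(pts$class[sel])
      vals[r, cix] <- if (equitability) {
        shannon_equitability(as.numeric(counts), normalize = TRUE)
      } else {
        shannon_diversity(as.numeric(counts), normalize = TRUE)
      }
    }
  }
  raster_surface(vals, extent[1L], extent[2L], cell)
}

# One representative point per feature (its first entrance).
feature_points <- function(uf) {
  first <- !duplicated(uf$entrances$feature_id)
  e <- uf$entrances[first, , drop = FALSE]
  data.frame(x = e$x, y = e$y,
             class = uf$features$class[match(e$feature_id, uf$features$id)])
}

#' Walkability composite surface
#'
#' Weighted mean of z-standardized component surfaces. Components must be
#' co-registered; an all-constant component (zero variance) is dropped with a
#' warning. Each standardized component has mean 0 and sd 1 over its valid
#' cells.
#'
#' @param components Named list of co-registered `raster_surface` objects.
#' @param weights Numeric vector of per-component weights (default equal).
#' @return A list of class `walkability_surface` with `surface` (the
#'   composite `raster_surface`) and `components`.
#' @export
walkability_surface <- function(components, weights = NULL) {
  stopifnot(length(components) >= 1L)
  base <- components[[1L]]
  for (comp in components[-1L]) {
    if (!same_grid(base, comp)) {
      stop("walkability components are not co-registered", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  stopifnot(length(weights) == length(components))
  zs <- list(); ws <- numeric(0)
  for (i in seq_along(components)) {
    v <- raster_values(components[[i]])
    sdv <- stats::sd(v, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
      warning("dropping zero-variance walkability component: ",
              names(components)[i] %||% i, call. = FALSE)
      next
    }
    zs[[length(zs) + 1L]] <- (v - mean(v, na.rm = TRUE)) / sdv
    ws <- c(ws, weights[i])
  }
  out <- if (length(zs) == 0L) {
    matrix(0, nrow(base$values), ncol(base$values))
  } else {
    acc <- 0
    for (i in seq_along(zs)) acc <- acc + ws[i] * zs[[i]]
    acc / sum(ws)
  }
  out[is.na(out)] <- -9999
  structure(
    list(surface = raster_surface(out, base$xll, base$yll, base$cellsize,
                                  nodata = -9999),
         components = components),
    class = "walkability_surface"
  )
}
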