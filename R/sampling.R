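#' Street networks and audit links
#'
#' A street network is a tibble with one row per junction-to-junction edge:
#' `edge_id` (character) and `geometry`, a list column of two-column numeric
#' matrices of planar vertex coordinates in metres. Audit links are the
#' 50-300 m sections cut from those edges; a links tibble carries `link_id`,
#' `parent_edge`, `length_m` and `geometry`.
#'
#' Coordinates must be planar and in metres (project longitude/latitude
#' before use): all length thresholds of the audit design are metric.
#'
#' @param edge_id character vector of edge identifiers.
#' @param geometry list of n x 2 numeric coordinate matrices.
#' @return a `street_network` tibble.
#' @export
street_network <- function(edge_id, geometry) {
  stopifnot(length(edge_id) == length(geometry))
  for (i in seq_along(geometry)) {
    g <- geometry[[i]]
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 2 || !all(is.finite(g))) {
      stop_fv("edge '", edge_id[i], "': geometry must be a finite n x 2 ",
              "matrix with n >= 2")
    }
    if (polyline_length(g) <= 0) stop_fv("edge '", edge_id[i], "': zero length")
  }
  out <- tibble::tibble(edge_id = as.character(edge_id), geometry = geometry)
  class(out) <- c("street_network", class(out))
  out
}

#' @rdname street_network
#' @param path a GeoJSON file of LineString features; an `edge_id` property
#'   is used when present, otherwise feature order.
#' @export
read_network_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list(gj)
  geoms <- list()
  ids <- character()
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    geom <- ft$geometry %||% ft
    if (!identical(geom$type, "LineString")) next
    coords <- do.call(rbind, lapply(geom$coordinates, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    geoms[[length(geoms) + 1]] <- coords
    ids <- c(ids, as.character(ft$properties$edge_id %||% sprintf("E%04d", i)))
  }
  if (length(geoms) == 0) stop_fv("no LineString features in ", path)
  street_network(ids, geoms)
}

#' @rdname street_network
#' @param x a network or links tibble (rows with `geometry`; extra columns
#'   become feature properties).
#' @export
write_network_geojson <- function(x, path) {
  props <- setdiff(names(x), "geometry")
  feats <- lapply(seq_len(nrow(x)), function(i) {
    list(
      type = "Feature",
      properties = as.list(tibble::as_tibble(x)[i, props]),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(x$geometry[[i]])), function(j) {
          unname(x$geometry[[i]][j, ])
        })
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

polyline_length <- function(coords) {
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

# Point at arc-length distance d along a polyline (d clamped to [0, length]).
point_at <- function(coords, d) {
  seg <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(seg))
  d <- min(max(d, 0), cum[length(cum)])
  i <- max(which(cum <= d + 1e-12))
  if (i >= nrow(coords)) return(coords[nrow(coords), ])
  t <- (d - cum[i]) / seg[i]
  coords[i, ] + t * (coords[i + 1, ] - coords[i, ])
}

# Cut a polyline at arc-length breakpoints; returns list of sub-polylines.
split_polyline <- function(coords, breaks) {
  total <- polyline_length(coords)
  cuts <- sort(unique(pmin(pmax(breaks, 0), total)))
  cuts <- cuts[cuts > 1e-9 & cuts < total - 1e-9]
  bounds <- c(0, cuts, total)
  seg <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(seg))
  lapply(seq_len(length(bounds) - 1), function(k) {
    a <- bounds[k]; b <- bounds[k + 1]
    inner <- which(cum > a + 1e-9 & cum < b - 1e-9)
    pts <- rbind(point_at(coords, a),
                 coords[inner, , drop = FALSE],
                 point_at(coords, b))
    unname(pts)
  })
}

# Portions of a polyline inside the disc |p - centre| <= r, as a list of
# sub-polylines. Crossing points are found per segment by solving the
# quadratic |p1 + t (p2 - p1) - c|^2 = r^2 on t in [0, 1].
clip_polyline_disc <- function(coords, centre, r) {
  pieces <- list()
  current <- NULL
  push <- function(pt) {
    if (is.null(current)) current <<- matrix(pt, ncol = 2)
    else if (sum((current[nrow(current), ] - pt)^2) > 1e-18) {
      current <<- rbind(current, pt)
    }
  }
  flush <- function() {
    if (!is.null(current) && nrow(current) >= 2 &&
        polyline_length(current) > 1e-9) {
      pieces[[length(pieces) + 1]] <<- unname(current)
    }
    current <<- NULL
  }
  inside <- function(p) sum((p - centre)^2) <= r^2 + 1e-9

  for (i in seq_len(nrow(coords) - 1)) {
    p1 <- coords[i, ]; p2 <- coords[i + 1, ]
    d <- p2 - p1
    f <- p1 - centre
    a <- sum(d^2)
    bq <- 2 * sum(f * d)
    cq <- sum(f^2) - r^2
    disc <- bq^2 - 4 * a * cq
    ts <- numeric(0)
    if (disc > 0 && a > 0) {
      ts <- sort((-bq + c(-1, 1) * sqrt(disc)) / (2 * a))
      ts <- ts[ts > 1e-12 & ts < 1 - 1e-12]
    }
    pts_t <- c(0, ts, 1)
    for (k in seq_len(length(pts_t) - 1)) {
      ta <- pts_t[k]; tb <- pts_t[k + 1]
      mid <- p1 + (ta + tb) / 2 * d
      if (inside(mid)) {
        push(p1 + ta * d)
        push(p1 + tb * d)
      } else {
        flush()
      }
    }
  }
  flush()
  pieces
}

#' Clip a street network to a circular audit buffer
#'
#' Intersects every edge with the disc of the given radius around the study
#' centre point (in the original design, an 800 m buffer — roughly a
#' 10-minute walk — around the town's population-weighted centroid). Edge
#' portions outside the disc are removed; edges crossing the boundary are
#' split at the circle, and an edge that leaves and re-enters the disc
#' yields one clipped part per inside portion (ids suffixed `.1`, `.2`,
#' ...).
#'
#' @param network a `street_network`.
#' @param centroid numeric length-2 centre point `c(x, y)` in metres.
#' @param radius buffer radius in metres (default 800).
#' @return the clipped `street_network` (possibly empty, with a warning).
#' @export
clip_network <- function(network, centroid, radius = 800) {
  stopifnot(radius > 0, length(centroid) == 2)
  ids <- character(); geoms <- list()
  for (i in seq_len(nrow(network))) {
    parts <- clip_polyline_disc(network$geometry[[i]], as.numeric(centroid), radius)
    if (length(parts) == 0) next
    suffix <- if (length(parts) > 1) paste0(".", seq_along(parts)) else ""
    ids <- c(ids, paste0(network$edge_id[i], suffix))
    geoms <- c(geoms, parts)
  }
  if (length(ids) == 0) {
    warning("no edges intersect the buffer; returning an empty network",
            call. = FALSE)
    out <- tibble::tibble(edge_id = character(), geometry = list())
    class(out) <- c("street_network", class(out))
    return(out)
  }
  street_network(ids, geoms)
}

#' Segment network edges into audit links
#'
#' Cuts each junction-to-junction edge into audit links honouring the link
#' length rules: edges shorter than `min_length` are excluded from
#' eligibility (a message reports how many); edges up to `max_length` become
#' a single link; longer edges are split into `ceiling(L / max_length)`
#' links of equal length measured along the polyline, so that no link
#' exceeds the maximum and no dangling sub-minimum remainder is created.
#' Equal-length splitting keeps links homogeneous, the design goal behind
#' the maximum.
#'
#' @param network a `street_network` (typically already clipped).
#' @param max_length maximum link length in metres (default 300).
#' @param min_length minimum link length in metres (default 50).
#' @return a links tibble: `link_id` (deterministic, `"<edge>#<ordinal>"`),
#'   `parent_edge`, `length_m`, `geometry`.
#' @examples
#' net <- street_network("E1", list(cbind(c(0, 700), c(0, 0))))
#' segment_links(net) # 3 links of 233.33 m
#' @export
segment_links <- function(network, max_length = 300, min_length = 50) {
  stopifnot(min_length > 0, min_length < max_length)
  excluded <- 0L
  rows <- list()
  for (i in seq_len(nrow(network))) {
    g <- network$geometry[[i]]
    L <- polyline_length(g)
    if (L < min_length) {
      excluded <- excluded + 1L
      next
    }
    k <- max(1L, as.integer(ceiling(L / max_length - 1e-9)))
    parts <- if (k == 1) list(g) else split_polyline(g, (1:(k - 1)) * L / k)
    for (j in seq_along(parts)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        link_id = sprintf("%s#%02d", network$edge_id[i], j),
        parent_edge = network$edge_id[i],
        length_m = polyline_length(parts[[j]]),
        geometry = list(parts[[j]])
      )
    }
  }
  if (excluded > 0) {
    message(excluded, " edge(s) below the ", min_length, " m minimum excluded")
  }
  if (length(rows) == 0) {
    return(tibble::tibble(link_id = character(), parent_edge = character(),
                          length_m = numeric(), geometry = list()))
  }
  purrr::list_rbind(rows)
}

#' Draw a seeded random sample of audit links
#'
#' Simple random sample without replacement of
#' `round_half_up(fraction * n)` links (a 25% fraction of 216 eligible links
#' gives exactly 54, the original design's sample). The draw is
#' deterministic given the seed and leaves the caller's RNG state untouched.
#'
#' @param links a links tibble from [segment_links()].
#' @param fraction sampling fraction in (0, 1] (default 0.25).
#' @param seed integer RNG seed.
#' @return the sampled subset of `links`, sorted by `link_id`.
#' @export
sample_links <- function(links, fraction = 0.25, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(links) == 0) {
    warning("no links to sample from", call. = FALSE)
    return(links)
  }
  n <- as.integer(round_half_up(fraction * nrow(links)))
  idx <- withr::with_seed(seed, sample.int(nrow(links), n))
  out <- links[sort(idx), ]
  out[order(out$link_id), ]
}

#' Write a link manifest CSV
#'
#' One row per link: `link_id`, `parent_edge`, `length_m` and a `sampled`
#' flag.
#'
#' @param links a links tibble.
#' @param sampled a links tibble of the sampled subset (or character vector
#'   of sampled link ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_link_manifest <- function(links, sampled, path) {
  ids <- if (is.character(sampled)) sampled else sampled$link_id
  man <- tibble::tibble(
    link_id = links$link_id,
    parent_edge = links$parent_edge,
    length_m = links$length_m,
    sampled = links$link_id %in% ids
  )
  readr::write_csv(man, path)
  invisible(path)
}

#' Synthetic grid street network
#'
#' A square grid of streets (synthetic, for demonstrations, simulations and
#' tests): north-south and east-west streets every `spacing` metres over a
#' square of side `extent` centred on the origin, cut into
#' junction-to-junction edges of length `spacing`.
#'
#' @param spacing junction spacing in metres (default 120).
#' @param extent side of the covered square in metres (default 2000).
#' @return a `street_network`.
#' @export
grid_street_network <- function(spacing = 120, extent = 2000) {
  half <- extent / 2
  ticks <- seq(-half, half, by = spacing)
  ids <- character(); geoms <- list()
  add <- function(id, p1, p2) {
    ids <<- c(ids, id)
    geoms[[length(geoms) + 1]] <<- rbind(p1, p2)
  }
  for (i in seq_along(ticks)) {
    for (j in seq_len(length(ticks) - 1)) {
      add(sprintf("H%02d.%02d", i, j), c(ticks[j], ticks[i]), c(ticks[j + 1], ticks[i]))
      add(sprintf("V%02d.%02d", i, j), c(ticks[i], ticks[j]), c(ticks[i], ticks[j + 1]))
    }
  }
  street_network(ids, geoms)
}
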