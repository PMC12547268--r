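#' Zone geometry for aviary and litter camera views
#'
#' A `zone_map` describes one camera view as an ordered set of simple polygons
#' in pixel coordinates (origin top-left, x rightward, y downward). Zones are
#' indexed 1 (upmost tier) to K top-to-bottom; the side view of a three-tier
#' aviary uses K = 4 (three tiers plus the litter), the litter top view uses
#' K = 2 (system-side and wall-side). Exclusion polygons (for example the
#' stairs between zone 3 and the litter) override zone membership: points
#' inside them belong to no zone, so movement across them is never counted.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param zones list of zones, each `list(label =, polygon =)` where `polygon`
#'   is an n x 2 matrix (or coercible) of pixel vertices. Zones are re-ordered
#'   top-to-bottom by centroid y and indexed 1..K in that order.
#' @param exclusion_polygons list of polygons excluded from all zones.
#' @return an object of class `zone_map`.
#' @export
zone_map <- function(frame_width, frame_height, zones,
                     exclusion_polygons = list()) {
  stopifnot(frame_width > 0, frame_height > 0, length(zones) >= 1)
  zs <- lapply(zones, function(z) {
    poly <- as_polygon(z$polygon)
    list(label = as.character(z$label), polygon = poly,
         centroid = polygon_centroid(poly))
  })
  ord <- order(vapply(zs, function(z) z$centroid[2], numeric(1)))
  zs <- zs[ord]
  for (i in seq_along(zs)) zs[[i]]$index <- i
  ex <- lapply(exclusion_polygons, as_polygon)
  zm <- structure(list(frame_width = frame_width, frame_height = frame_height,
                       zones = zs, exclusion_polygons = ex,
                       zone_order = "top-to-bottom"),
                  class = "zone_map")
  validate_zone_map(zm)
  zm
}

as_polygon <- function(p) {
  m <- as.matrix(p)
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) < 3) stop("polygon needs >= 3 (x, y) vertices")
  # drop a repeated closing vertex if present
  if (all(m[1, ] == m[nrow(m), ]) && nrow(m) > 3) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("zone_map: %d x %d px, %d zones (%s), %d exclusion polygon(s)\n",
              x$frame_width, x$frame_height, length(x$zones), x$zone_order,
              length(x$exclusion_polygons)))
  for (z in x$zones)
    cat(sprintf("  [%d] %-14s %d vertices\n", z$index, z$label, nrow(z$polygon)))
  invisible(x)
}

n_zones <- function(zm) length(zm$zones)

zone_labels <- function(zm) vapply(zm$zones, `[[`, character(1), "label")

validate_zone_map <- function(zm) {
  W <- zm$frame_width; H <- zm$frame_height
  for (z in zm$zones) {
    p <- z$polygon
    if (any(p[, 1] < 0 | p[, 1] > W | p[, 2] < 0 | p[, 2] > H))
      stop(sprintf("zone '%s': vertex outside frame bounds", z$label))
    if (!polygon_is_simple(p))
      stop(sprintf("zone '%s': polygon is self-intersecting", z$label))
  }
  for (e in zm$exclusion_polygons)
    if (!polygon_is_simple(e)) stop("exclusion polygon is self-intersecting")
  k <- length(zm$zones)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (polygons_interiors_overlap(zm$zones[[i]]$polygon,
                                     zm$zones[[j]]$polygon))
        stop(sprintf("zones '%s' and '%s' have overlapping interiors",
                     zm$zones[[i]]$label, zm$zones[[j]]$label))
    }
  }
  invisible(zm)
}

# ---- polygon primitives ----------------------------------------------------

polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-9) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  if (abs(cross) > eps * max(1, abs(bx - ax) + abs(by - ay))) return(FALSE)
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  len2 <- (bx - ax)^2 + (by - ay)^2
  dot >= -eps && dot <= len2 + eps
}

# even-odd crossing number; returns "inside", "boundary" or "outside"
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (on_segment(x, y, xi, yi, xj, yj)) return("boundary")
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) "inside" else "outside"
}

segment_orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  if (abs(v) < 1e-12) 0 else sign(v)
}

segments_cross_properly <- function(a, b, c, d) {
  o1 <- segment_orient(a[1], a[2], b[1], b[2], c[1], c[2])
  o2 <- segment_orient(a[1], a[2], b[1], b[2], d[1], d[2])
  o3 <- segment_orient(c[1], c[2], d[1], d[2], a[1], a[2])
  o4 <- segment_orient(c[1], c[2], d[1], d[2], b[1], b[2])
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  edges <- lapply(seq_len(n), function(i) rbind(p[i, ], p[if (i == n) 1 else i + 1, ]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    # skip adjacent edges (share a vertex)
    if (j == i + 1 || (i == 1 && j == n)) next
    if (segments_cross_properly(edges[[i]][1, ], edges[[i]][2, ],
                                edges[[j]][1, ], edges[[j]][2, ]))
      return(FALSE)
  }
  TRUE
}

# Overlapping interiors for two simple polygons that may share boundary edges:
# a proper edge crossing, or a vertex/centroid of one strictly inside the other.
polygons_interiors_overlap <- function(p, q) {
  np <- nrow(p); nq <- nrow(q)
  for (i in seq_len(np)) {
    a <- p[i, ]; b <- p[if (i == np) 1 else i + 1, ]
    for (j in seq_len(nq)) {
      c <- q[j, ]; d <- q[if (j == nq) 1 else j + 1, ]
      if (segments_cross_properly(a, b, c, d)) return(TRUE)
    }
  }
  # vertices and edge midpoints strictly inside the other polygon catch
  # overlaps whose edge intersections are all collinear or endpoint touches
  probe_pts <- function(poly) {
    n <- nrow(poly)
    nxt <- poly[c(2:n, 1), , drop = FALSE]
    rbind(poly, (poly + nxt) / 2)
  }
  pp <- probe_pts(p); qq <- probe_pts(q)
  for (i in seq_len(nrow(pp)))
    if (point_in_polygon(pp[i, 1], pp[i, 2], q) == "inside") return(TRUE)
  for (j in seq_len(nrow(qq)))
    if (point_in_polygon(qq[j, 1], qq[j, 2], p) == "inside") return(TRUE)
  cp <- polygon_centroid(p); cq <- polygon_centroid(q)
  if (point_in_polygon(cp[1], cp[2], q) == "inside") return(TRUE)
  if (point_in_polygon(cq[1], cq[2], p) == "inside") return(TRUE)
  FALSE
}

# ---- zone assignment -------------------------------------------------------

#' Assign a pixel point to a zone
#'
#' Points inside an exclusion polygon (boundary included) belong to no zone and
#' return `NA`. Otherwise the point is assigned to the unique zone whose closed
#' region contains it; a point exactly on a boundary shared by two zones is
#' assigned to the lower zone index (deterministic tie-break). Points in no
#' zone return `NA`.
#'
#' @param point numeric `(x, y)` in pixels; must lie within frame bounds.
#' @param zonemap a [zone_map()].
#' @return integer zone index, or `NA_integer_`.
#' @export
assign_zone <- function(point, zonemap) {
  x <- point[1]; y <- point[2]
  if (is.na(x) || is.na(y) ||
      x < 0 || x > zonemap$frame_width || y < 0 || y > zonemap$frame_height)
    stop(sprintf("point (%.1f, %.1f) outside frame bounds", x, y))
  for (e in zonemap$exclusion_polygons)
    if (point_in_polygon(x, y, e) != "outside") return(NA_integer_)
  for (z in zonemap$zones)
    if (point_in_polygon(x, y, z$polygon) != "outside") return(z$index)
  NA_integer_
}

#' Vectorised [assign_zone()] over an n x 2 matrix of points
#' @param points n x 2 matrix of pixel coordinates.
#' @inheritParams assign_zone
#' @return integer vector of zone indices (`NA` where unassigned).
#' @export
assign_zones <- function(points, zonemap) {
  points <- matrix(as.numeric(points), ncol = 2)
  vapply(seq_len(nrow(points)),
         function(i) assign_zone(points[i, ], zonemap), integer(1))
}

# ---- Labelme-dialect annotation I/O ---------------------------------------

#' Read a zone annotation file (Labelme-style JSON)
#'
#' Expects the dialect `{"imageWidth", "imageHeight", "shapes": [{"label",
#' "points": [[x, y], ...], "shape_type": "polygon"}]}`. Shapes whose label
#' starts with `"exclude:"` become exclusion polygons (such as the stairs
#' region between the lowest tier and the litter); all other shapes become
#' zones, ordered top-to-bottom by centroid.
#'
#' @param path path to the JSON file.
#' @return a validated [zone_map()].
#' @export
read_zone_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed annotation JSON: ",
                                         conditionMessage(e)))
  need <- c("imageWidth", "imageHeight", "shapes")
  if (!all(need %in% names(j)))
    stop("annotation JSON missing fields: ",
         paste(setdiff(need, names(j)), collapse = ", "))
  zones <- list(); excl <- list()
  for (s in j$shapes) {
    if (!identical(s$shape_type, "polygon"))
      stop("unsupported shape_type: ", s$shape_type)
    pts <- do.call(rbind, lapply(s$points, unlist))
    if (startsWith(s$label, "exclude:")) {
      excl[[length(excl) + 1L]] <- pts
    } else {
      zones[[length(zones) + 1L]] <- list(label = s$label, polygon = pts)
    }
  }
  zone_map(j$imageWidth, j$imageHeight, zones, excl)
}

#' Write a [zone_map()] as Labelme-style JSON
#' @param zonemap a [zone_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zone_annotation <- function(zonemap, path) {
  shapes <- lapply(zonemap$zones, function(z) {
    list(label = z$label,
         points = lapply(seq_len(nrow(z$polygon)),
                         function(i) as.numeric(z$polygon[i, ])),
         shape_type = "polygon")
  })
  for (e in zonemap$exclusion_polygons) {
    shapes[[length(shapes) + 1L]] <-
      list(label = "exclude:region",
           points = lapply(seq_len(nrow(e)), function(i) as.numeric(e[i, ])),
           shape_type = "polygon")
  }
  jsonlite::write_json(list(imageWidth = zonemap$frame_width,
                            imageHeight = zonemap$frame_height,
                            shapes = shapes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stacked-band zone map for the aviary side view
#'
#' Convenience constructor: K horizontal bands of equal height spanning the
#' frame, indexed 1 (top tier) to K (litter), with an optional stairs
#' exclusion rectangle between the two lowest zones.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param k number of zones (4 for the aviary side view).
#' @param labels optional zone labels, top to bottom.
#' @param stairs optional exclusion rectangle `c(x1, y1, x2, y2)`.
#' @return a [zone_map()].
#' @export
stacked_zone_map <- function(frame_width, frame_height, k = 4,
                             labels = NULL, stairs = NULL) {
  if (is.null(labels))
    labels <- if (k == 4) c("tier-3", "tier-2", "tier-1", "litter")
              else paste0("zone-", seq_len(k))
  h <- frame_height / k
  zones <- lapply(seq_len(k), function(i) {
    y0 <- (i - 1) * h; y1 <- i * h
    list(label = labels[i],
         polygon = rbind(c(0, y0), c(frame_width, y0),
                         c(frame_width, y1), c(0, y1)))
  })
  excl <- list()
  if (!is.null(stairs))
    excl <- list(rbind(c(stairs[1], stairs[2]), c(stairs[3], stairs[2]),
                       c(stairs[3], stairs[4]), c(stairs[1], stairs[4])))
  zone_map(frame_width, frame_height, zones, excl)
}

#' Two-zone litter map (system side / wall side), split vertically
#' @param frame_width,frame_height frame size in pixels.
#' @param split_x x pixel of the boundary between system side and wall side
#'   (default: mid-frame).
#' @return a [zone_map()] with zones labelled `"system"` and `"wall"`.
#' @export
litter_zone_map <- function(frame_width, frame_height,
                            split_x = frame_width / 2) {
  # top-to-bottom ordering is degenerate for side-by-side zones; nudge the
  # system zone centroid up by listing it first and relying on stable order
  zones <- list(
    list(label = "system",
         polygon = rbind(c(0, 0), c(split_x, 0),
                         c(split_x, frame_height), c(0, frame_height))),
    list(label = "wall",
         polygon = rbind(c(split_x, 0), c(frame_width, 0),
                         c(frame_width, frame_height), c(split_x, frame_height))))
  zone_map(frame_width, frame_height, zones)
}
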