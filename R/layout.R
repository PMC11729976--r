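# On-screen support layouts and the planar regions they are built from.
# All lengths are centimetres in a y-up physical frame whose origin is the
# bottom-left corner of the screen.

#' Planar regions with a drawn outline
#'
#' The supports are drawn with lines of finite width; contact classification
#' therefore distinguishes the region interior, a boundary band around the
#' drawn outline, and the outside. `region_disc()` and `region_rect()` build
#' the two shapes used by the item layouts.
#'
#' @param x,y disc centre (cm).
#' @param r disc radius to the nominal outline (cm).
#' @param x0,y0,x1,y1 rectangle corners (cm), `x0 < x1`, `y0 < y1`.
#' @param line_w drawn line width (cm).
#' @return an object of class `mfm_region`.
#' @seealso [region_contacts()]
#' @export
region_disc <- function(x, y, r, line_w = 0.1) {
  stopifnot(is_scalar_number(x), is_scalar_number(y),
            is_scalar_number(r), r > 0,
            is_scalar_number(line_w), line_w > 0)
  structure(list(shape = "disc", x = x, y = y, r = r, line_w = line_w),
            class = "mfm_region")
}

#' @rdname region_disc
#' @export
region_rect <- function(x0, y0, x1, y1, line_w = 0.1) {
  stopifnot(is_scalar_number(x0), is_scalar_number(y0),
            is_scalar_number(x1), is_scalar_number(y1),
            x0 < x1, y0 < y1, is_scalar_number(line_w), line_w > 0)
  structure(list(shape = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 line_w = line_w),
            class = "mfm_region")
}

# Signed distance from points to the nominal outline: negative inside the
# region, positive outside. Vectorised over points.
signed_edge_distance <- function(region, x, y) {
  stopifnot(inherits(region, "mfm_region"))
  if (region$shape == "disc") {
    sqrt((x - region$x)^2 + (y - region$y)^2) - region$r
  } else {
    ddx <- pmax(region$x0 - x, x - region$x1)
    ddy <- pmax(region$y0 - y, y - region$y1)
    ifelse(ddx > 0 | ddy > 0,
           sqrt(pmax(ddx, 0)^2 + pmax(ddy, 0)^2),
           pmax(ddx, ddy))
  }
}

region_bbox <- function(region) {
  h <- region$line_w / 2
  if (region$shape == "disc") {
    c(region$x - region$r - h, region$y - region$r - h,
      region$x + region$r + h, region$y + region$r + h)
  } else {
    c(region$x0 - h, region$y0 - h, region$x1 + h, region$y1 + h)
  }
}

#' Item support layouts
#'
#' Physical geometry of the on-screen support for each item, in cm:
#'
#' * item 18 - the CD: a small centre circle (diameter 3.5 cm) and the outer
#'   edge of the disc (`r_large_cm`, default 6 cm, the radius of a standard
#'   12 cm CD);
#' * item 19 - the frame: a rectangle 4 cm long and 1 cm high drawn with a
#'   0.1 cm line;
#' * item 22 - the diagram: a central start zone plus 8 target drawings,
#'   by default discs of radius 0.8 cm evenly spaced on a ring. The real
#'   diagram's drawings are pictograms; the disc ring is a configurable
#'   stand-in with the same lift-and-place semantics, and arbitrary target
#'   regions can be supplied via `targets`.
#'
#' Layouts are user-movable on screen, so all constructors take their anchor
#' point; defaults centre the support on the default tablet.
#'
#' @param center_cm support centre `c(x, y)` in cm.
#' @param r_small_cm,r_large_cm small-circle and disc-edge radii (cm).
#' @param origin_cm lower-left corner of the frame interior `c(x, y)` (cm).
#' @param width_cm,height_cm frame interior size (cm).
#' @param line_w_cm drawn line width (cm).
#' @param start_radius_cm radius of the central start zone (cm).
#' @param target_radius_cm radius of each default disc target (cm).
#' @param ring_radius_cm radius of the ring the default targets sit on (cm).
#' @param n_targets number of default targets.
#' @param targets optional list of [region_disc()]/[region_rect()] regions
#'   overriding the default ring.
#' @return an object of class `item_layout`.
#' @examples
#' item_layout_18()
#' item_layout_19(origin_cm = c(4, 9))
#' item_layout_22(n_targets = 8)
#' @export
item_layout_18 <- function(center_cm = c(7.4, 9.85), r_small_cm = 1.75,
                           r_large_cm = 6, line_w_cm = 0.1) {
  stopifnot(is.numeric(center_cm), length(center_cm) == 2,
            is_scalar_number(r_small_cm), r_small_cm > 0,
            is_scalar_number(r_large_cm), is_scalar_number(line_w_cm),
            line_w_cm > 0)
  if (r_small_cm >= r_large_cm) {
    stop_validation("item 18 layout: r_small_cm must be smaller than r_large_cm")
  }
  structure(
    list(item_id = 18L, center = as.numeric(center_cm),
         r_small = r_small_cm, r_large = r_large_cm, line_w = line_w_cm),
    class = "item_layout"
  )
}

#' @rdname item_layout_18
#' @export
item_layout_19 <- function(origin_cm = c(5.4, 9.35), width_cm = 4,
                           height_cm = 1, line_w_cm = 0.1) {
  stopifnot(is.numeric(origin_cm), length(origin_cm) == 2,
            is_scalar_number(width_cm), is_scalar_number(height_cm),
            is_scalar_number(line_w_cm))
  if (!(width_cm > height_cm && height_cm > line_w_cm && line_w_cm > 0)) {
    stop_validation("item 19 layout requires width > height > line width > 0")
  }
  structure(
    list(item_id = 19L, origin = as.numeric(origin_cm),
         width = width_cm, height = height_cm, line_w = line_w_cm),
    class = "item_layout"
  )
}

#' @rdname item_layout_18
#' @export
item_layout_22 <- function(center_cm = c(7.4, 9.85), start_radius_cm = 1,
                           target_radius_cm = 0.8, ring_radius_cm = 4.5,
                           n_targets = 8, line_w_cm = 0.1, targets = NULL) {
  stopifnot(is.numeric(center_cm), length(center_cm) == 2,
            is_scalar_number(start_radius_cm), start_radius_cm > 0,
            is_scalar_number(line_w_cm), line_w_cm > 0)
  if (is.null(targets)) {
    stopifnot(is_scalar_number(target_radius_cm), target_radius_cm > 0,
              is_scalar_number(ring_radius_cm), ring_radius_cm > 0,
              is_scalar_number(n_targets), n_targets >= 1)
    ang <- 2 * pi * (seq_len(n_targets) - 1) / n_targets + pi / 2
    targets <- lapply(ang, function(a) {
      region_disc(center_cm[1] + ring_radius_cm * cos(a),
                  center_cm[2] + ring_radius_cm * sin(a),
                  target_radius_cm, line_w = line_w_cm)
    })
  }
  if (!length(targets) || !all(vapply(targets, inherits, logical(1), "mfm_region"))) {
    stop_validation("item 22 targets must be a non-empty list of mfm_region objects")
  }
  start <- region_disc(center_cm[1], center_cm[2], start_radius_cm,
                       line_w = line_w_cm)
  layout <- structure(
    list(item_id = 22L, center = as.numeric(center_cm), start_zone = start,
         targets = targets, line_w = line_w_cm),
    class = "item_layout"
  )
  check_disjoint_targets(layout)
  layout
}

# Target interiors must be pairwise disjoint and disjoint from the start zone.
check_disjoint_targets <- function(layout) {
  regs <- c(list(layout$start_zone), layout$targets)
  nb <- length(regs)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      a <- regs[[i]]; b <- regs[[j]]
      if (a$shape == "disc" && b$shape == "disc") {
        gap <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2) -
          (a$r + b$r + (a$line_w + b$line_w) / 2)
      } else {
        ba <- region_bbox(a); bb <- region_bbox(b)
        gap <- max(bb[1] - ba[3], ba[1] - bb[3], bb[2] - ba[4], ba[2] - bb[4])
      }
      if (gap <= 0) {
        stop_validation("item 22 layout: regions %d and %d overlap", i - 1, j - 1)
      }
    }
  }
  invisible(layout)
}

# Bounding box of everything drawn for the layout, c(xmin, ymin, xmax, ymax).
layout_bbox <- function(layout) {
  stopifnot(inherits(layout, "item_layout"))
  switch(as.character(layout$item_id),
    "18" = {
      h <- layout$line_w / 2
      c(layout$center[1] - layout$r_large - h, layout$center[2] - layout$r_large - h,
        layout$center[1] + layout$r_large + h, layout$center[2] + layout$r_large + h)
    },
    "19" = {
      h <- layout$line_w / 2
      c(layout$origin[1] - h, layout$origin[2] - h,
        layout$origin[1] + layout$width + h, layout$origin[2] + layout$height + h)
    },
    "22" = {
      boxes <- vapply(c(list(layout$start_zone), layout$targets), region_bbox,
                      numeric(4))
      c(min(boxes[1, ]), min(boxes[2, ]), max(boxes[3, ]), max(boxes[4, ]))
    }
  )
}

#' @export
print.item_layout <- function(x, ...) {
  desc <- switch(as.character(x$item_id),
    "18" = sprintf("CD at (%.2f, %.2f), r_small %.2f, r_large %.2f cm",
                   x$center[1], x$center[2], x$r_small, x$r_large),
    "19" = sprintf("frame %.1f x %.1f cm at (%.2f, %.2f), line %.2f cm",
                   x$width, x$height, x$origin[1], x$origin[2], x$line_w),
    "22" = sprintf("start zone r %.2f + %d targets around (%.2f, %.2f)",
                   x$start_zone$r, length(x$targets), x$center[1], x$center[2])
  )
  cat(sprintf("<item_layout> item %d: %s\n", x$item_id, desc))
  invisible(x)
}

region_to_list <- function(region) unclass(region)

region_from_list <- function(x) {
  if (identical(x$shape, "disc")) {
    region_disc(x$x, x$y, x$r, line_w = x$line_w)
  } else if (identical(x$shape, "rect")) {
    region_rect(x$x0, x$y0, x$x1, x$y1, line_w = x$line_w)
  } else {
    stop_input("unknown region shape '%s'", as.character(x$shape))
  }
}

layout_to_list <- function(layout) {
  switch(as.character(layout$item_id),
    "18" = list(item_id = 18L, center_cm = layout$center,
                r_small_cm = layout$r_small, r_large_cm = layout$r_large,
                line_w_cm = layout$line_w),
    "19" = list(item_id = 19L, origin_cm = layout$origin,
                width_cm = layout$width, height_cm = layout$height,
                line_w_cm = layout$line_w),
    "22" = list(item_id = 22L, center_cm = layout$center,
                start_zone = region_to_list(layout$start_zone),
                targets = lapply(layout$targets, region_to_list),
                line_w_cm = layout$line_w)
  )
}

layout_from_list <- function(x) {
  id <- as.integer(x$item_id)
  if (id == 18L) {
    item_layout_18(center_cm = as.numeric(unlist(x$center_cm)),
                   r_small_cm = x$r_small_cm, r_large_cm = x$r_large_cm,
                   line_w_cm = x$line_w_cm)
  } else if (id == 19L) {
    item_layout_19(origin_cm = as.numeric(unlist(x$origin_cm)),
                   width_cm = x$width_cm, height_cm = x$height_cm,
                   line_w_cm = x$line_w_cm)
  } else if (id == 22L) {
    layout <- structure(
      list(item_id = 22L, center = as.numeric(unlist(x$center_cm)),
           start_zone = region_from_list(x$start_zone),
           targets = lapply(x$targets, region_from_list),
           line_w = x$line_w_cm),
      class = "item_layout"
    )
    check_disjoint_targets(layout)
    layout
  } else {
    stop_input("unknown item_id %s in layout", as.character(x$item_id))
  }
}

#' Read or write an item layout as JSON
#'
#' Layout files are versioned JSON documents with all lengths in cm.
#'
#' @param layout an `item_layout`.
#' @param path file path.
#' @return `read_layout_json()` returns an `item_layout`;
#'   `write_layout_json()` returns `path` invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "item_layout"))
  obj <- c(list(format_version = "1.0"), layout_to_list(layout))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  if (!file.exists(path)) stop_input("layout file not found: %s", path)
  layout_from_list(jsonlite::read_json(path))
}
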