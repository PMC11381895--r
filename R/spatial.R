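#' Named polygonal tissue regions
#'
#' A set of named, simple (non-self-intersecting) polygons in pixel
#' coordinates (origin top-left, y down) plus the image scale. Space not
#' covered by any polygon is the implicit remainder region
#' `"whole_tissue"`.
#'
#' @param regions named list of polygons; each polygon a two-column
#'   numeric matrix (or data.frame) of vertices in pixels, or a rectangle
#'   given as `c(xmin, ymin, xmax, ymax)`.
#' @param um_per_px image scale in microns per pixel.
#' @return an object of class `"region_set"`.
#' @export
region_set <- function(regions, um_per_px = 0.5) {
  if (is.null(names(regions)) || any(names(regions) == "") ||
      anyDuplicated(names(regions)))
    stop_arg("regions must have unique non-empty names")
  if ("whole_tissue" %in% names(regions))
    stop_arg("'whole_tissue' is reserved for the implicit remainder region")
  polys <- lapply(names(regions), function(nm) {
    p <- regions[[nm]]
    if (is.numeric(p) && is.null(dim(p)) && length(p) == 4L)
      p <- rect_poly(p)
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop_arg("region '%s': a polygon needs >= 3 two-column vertices", nm)
    # drop an explicitly closed last vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (!polygon_is_simple(p))
      stop_arg("geometry error: region '%s' polygon self-intersects", nm)
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  names(polys) <- names(regions)
  structure(list(regions = polys, um_per_px = um_per_px),
            class = "region_set")
}

rect_poly <- function(r) {
  cbind(x = c(r[1], r[3], r[3], r[1]), y = c(r[2], r[2], r[4], r[4]))
}

#' Generate a synthetic region layout
#'
#' With `layout = NULL`, places `n_regions` disjoint axis-aligned
#' rectangles on a grid inside the image (seeded jitter), emulating a
#' pathologist's annotation of a few tumor areas; otherwise validates the
#' given layout.
#'
#' @param layout named list of polygons/rectangles (see [region_set()]),
#'   or `NULL` to generate.
#' @param n_regions number of generated regions when `layout` is `NULL`.
#' @param image_size_px image width and height in pixels.
#' @param seed integer seed for the generated layout.
#' @param um_per_px image scale.
#' @return a [region_set()].
#' @export
gen_regions <- function(layout = NULL, n_regions = 3,
                        image_size_px = c(2000, 2000), seed = 1,
                        um_per_px = 0.5) {
  if (!is.null(layout)) return(region_set(layout, um_per_px))
  set.seed(derive_seed(seed, "regions"))
  w <- image_size_px[1]; h <- image_size_px[2]
  cells <- ceiling(sqrt(n_regions))
  slots <- utils::head(expand.grid(i = seq_len(cells) - 1,
                                   j = seq_len(cells) - 1), n_regions)
  cw <- w / cells; ch <- h / cells
  layout <- lapply(seq_len(n_regions), function(k) {
    x0 <- slots$i[k] * cw; y0 <- slots$j[k] * ch
    mx <- runif(1, 0.05, 0.15) * cw; my <- runif(1, 0.05, 0.15) * ch
    c(x0 + mx, y0 + my, x0 + cw - mx, y0 + ch - my)
  })
  names(layout) <- sprintf("region_%d", seq_len(n_regions))
  region_set(layout, um_per_px)
}

# segment-intersection test for polygon simplicity (O(n^2), fine at
# annotation scale)
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    cross2(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, q1) || on_seg(p1, p2, q2) ||
    on_seg(q1, q2, p1) || on_seg(q1, q2, p2)
}

#' Edge-inclusive point-in-polygon test
#'
#' Winding-number test, vectorized over points; a point exactly on a
#' polygon edge (or vertex) counts as inside.
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix of a simple polygon.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  m <- length(px)
  wn <- integer(m)
  on_edge <- logical(m)
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_edge <- on_edge | (cr == 0 &
                            px >= pmin(x1, x2) & px <= pmax(x1, x2) &
                            py >= pmin(y1, y2) & py <= pmax(y1, y2))
    up <- y1 <= py & y2 > py & cr > 0
    dn <- y1 > py & y2 <= py & cr < 0
    wn <- wn + up - dn
  }
  wn != 0L | on_edge
}

#' Assign each cell to an annotated region
#'
#' Labels every cell with the first region (in declaration order) whose
#' polygon contains its centroid; centroids on an edge count as inside;
#' cells in no polygon get the implicit remainder label `"whole_tissue"`.
#' Coordinates must share the pixel frame of the region polygons — a
#' frame mismatch cannot be detected.
#'
#' @param cells `data.frame` with `x_px` and `y_px`.
#' @param regions a [region_set()].
#' @return the table with a `region` column appended.
#' @export
assign_regions <- function(cells, regions) {
  stopifnot(inherits(regions, "region_set"))
  lab <- rep("whole_tissue", nrow(cells))
  undecided <- rep(TRUE, nrow(cells))
  for (nm in names(regions$regions)) {
    if (!any(undecided)) break
    inside <- point_in_polygon(cells$x_px[undecided], cells$y_px[undecided],
                               regions$regions[[nm]])
    lab[which(undecided)[inside]] <- nm
    undecided[undecided] <- !inside
  }
  cells$region <- lab
  attr(cells, "region_levels") <- c(names(regions$regions), "whole_tissue")
  cells
}

#' Class-by-region distribution table
#'
#' For each cell class, the percentage of its cells found in each region:
#' entry `(c, r) = 100 * #{class c in region r} / #{class c}`; each class
#' row sums to 100 up to rounding. Classes with zero cells give a row of
#' `NA` with a warning.
#'
#' @param cells `data.frame` with `assigned_class` and `region` columns
#'   (outlier rows, whose class is `NA`, are ignored).
#' @param classes classes to tabulate; defaults to the three stain
#'   classes.
#' @param digits rounding for the `display` copy (integer percent, as
#'   percentages are conventionally reported rounded).
#' @return `data.frame` of percentages, one row per class, one column per
#'   region (annotated regions in declaration order, then
#'   `whole_tissue`); attributes `counts` (the raw table) and `display`
#'   (rounded).
#' @export
class_region_distribution <- function(cells,
                                      classes = c("CDX2++", "CDX2+", "CDX2-"),
                                      digits = 0) {
  if (!all(c("assigned_class", "region") %in% names(cells)))
    stop_arg("'cells' needs 'assigned_class' and 'region' columns")
  regs <- attr(cells, "region_levels") %||%
    unique(c(setdiff(unique(cells$region), "whole_tissue"),
             "whole_tissue"))
  pct <- matrix(NA_real_, length(classes), length(regs),
                dimnames = list(classes, regs))
  counts <- matrix(0L, length(classes), length(regs),
                   dimnames = list(classes, regs))
  for (cl in classes) {
    rows <- !is.na(cells$assigned_class) & cells$assigned_class == cl
    tot <- sum(rows)
    counts[cl, ] <- vapply(regs, function(r) sum(cells$region[rows] == r),
                           integer(1))
    if (tot == 0L) {
      warning(sprintf("class '%s' has no cells; emitting missing row", cl))
      next
    }
    pct[cl, ] <- 100 * counts[cl, ] / tot
  }
  out <- as.data.frame(pct)
  attr(out, "counts") <- counts
  attr(out, "display") <- round(pct, digits)
  out
}

#' Polygonal cell contours around nucleus centroids
#'
#' Builds an n-gon of the given radius around every cell centroid, the
#' shape a cutting contour takes when only centroid and area are known.
#' The radius defaults to the circle-equivalent radius of each nucleus
#' area.
#'
#' @param cells `data.frame` with `cell_id`, `x_px`, `y_px` and (for the
#'   default radius) `area_px2`.
#' @param radius_um fixed contour radius in microns, or `NULL` to use each
#'   nucleus's circle-equivalent radius.
#' @param n_vertices vertices per contour polygon.
#' @param um_per_px image scale.
#' @return a `contour_set`: list with `shapes` (each `shape_id`,
#'   `cell_id`, `vertices`), `offset_um` (0) and `wells` (empty).
#' @export
cell_contours <- function(cells, radius_um = NULL, n_vertices = 16,
                          um_per_px = 0.5) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  shapes <- lapply(seq_len(nrow(cells)), function(i) {
    r_px <- if (is.null(radius_um)) sqrt(cells$area_px2[i] / pi)
            else radius_um / um_per_px
    list(shape_id = sprintf("shape_%06d", i), cell_id = cells$cell_id[i],
         vertices = cbind(x = cells$x_px[i] + r_px * cos(ang),
                          y = cells$y_px[i] + r_px * sin(ang)))
  })
  structure(list(shapes = shapes, offset_um = 0, um_per_px = um_per_px,
                 wells = character(0)), class = "contour_set")
}

#' Dilate cutting contours by a fixed micron offset
#'
#' Offsets every contour polygon outward by `offset_um` microns (converted
#' to pixels by `um_per_px`) with round joins at convex vertices and miter
#' intersections at reflex vertices — the Minkowski sum of the polygon
#' with a disc, up to the polygonal arc approximation. Used to include a
#' rim of cytoplasm around segmented nuclei before laser microdissection;
#' the conventional offset is 2 microns. The dilated polygon contains the
#' original and its area strictly increases for a positive offset.
#'
#' @param contours a `contour_set` (see [cell_contours()]).
#' @param offset_um outward offset in microns (>= 0).
#' @param um_per_px image scale; defaults to the contour set's own.
#' @param arc_step maximum angular step of the round-join arc, radians.
#' @return the dilated `contour_set` with `offset_um` recorded.
#' @export
dilate_contours <- function(contours, offset_um = 2, um_per_px = NULL,
                            arc_step = pi / 16) {
  stopifnot(inherits(contours, "contour_set"))
  if (offset_um < 0) stop_arg("'offset_um' must be >= 0")
  um_per_px <- um_per_px %||% contours$um_per_px
  if (um_per_px <= 0) stop_arg("'um_per_px' must be positive")
  d <- offset_um / um_per_px
  contours$shapes <- lapply(contours$shapes, function(sh) {
    if (is.null(sh$vertices) || nrow(sh$vertices) < 3L)
      stop_arg("geometry error: shape '%s' has fewer than 3 vertices",
               sh$shape_id %||% "?")
    if (d > 0) sh$vertices <- offset_polygon(sh$vertices, d, arc_step)
    sh
  })
  contours$offset_um <- contours$offset_um + offset_um
  contours
}

# outward offset of a simple polygon: round joins at convex corners,
# miter at reflex corners; exact for convex polygons, local (no global
# self-intersection cleanup) for small offsets on concave ones
offset_polygon <- function(p, d, arc_step = pi / 16) {
  n <- nrow(p)
  # orient counter-clockwise in standard axes so edge normals (dy, -dx)
  # point outward
  a2 <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  if (a2 < 0) { p <- p[n:1, , drop = FALSE] }
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  e <- p[nxt, , drop = FALSE] - p          # edge i: p[i] -> p[i+1]
  len <- sqrt(rowSums(e^2))
  keep <- len > 0
  if (!all(keep)) {                        # drop duplicated vertices
    p <- p[keep, , drop = FALSE]
    return(offset_polygon(p, d, arc_step))
  }
  u <- e / len                             # unit directions
  nrm <- cbind(u[, 2], -u[, 1])            # outward normals (CCW polygon)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ip <- prv[i]
    # offset endpoints of the two edges meeting at vertex i
    end_prev <- p[i, ] + d * nrm[ip, ]
    beg_this <- p[i, ] + d * nrm[i, ]
    turn <- u[ip, 1] * u[i, 2] - u[ip, 2] * u[i, 1]  # z of cross product
    if (turn >= 0) {
      # convex corner: round join, arc from prev normal to this normal
      a0 <- atan2(nrm[ip, 2], nrm[ip, 1])
      a1 <- atan2(nrm[i, 2], nrm[i, 1])
      dang <- (a1 - a0) %% (2 * pi)
      k <- max(1L, ceiling(dang / arc_step))
      ang <- a0 + dang * seq(0, 1, length.out = k + 1)
      out[[i]] <- cbind(p[i, 1] + d * cos(ang), p[i, 2] + d * sin(ang))
    } else {
      # reflex corner: intersect the two offset edge lines
      denom <- u[ip, 1] * u[i, 2] - u[ip, 2] * u[i, 1]
      rhs <- beg_this - end_prev
      t <- (rhs[1] * u[i, 2] - rhs[2] * u[i, 1]) / denom
      out[[i]] <- matrix(end_prev + t * u[ip, ], 1)
    }
  }
  v <- do.call(rbind, out)
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

# shoelace area of a polygon (absolute)
polygon_area <- function(p) {
  n <- nrow(p)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

#' Sample cells per class into 384-well replicates
#'
#' Draws `per_class` cells per replicate, without replacement across the
#' `replicates` of each class (seeded), and assigns every (class,
#' replicate) pool to one well of a 384-well plate, skipping the
#' outermost rows (A, P) and columns (1, 24) where evaporation and edge
#' effects degrade low-input samples.
#'
#' @param cells classified `data.frame` with `assigned_class` and
#'   `cell_id`.
#' @param per_class shapes per replicate (conventionally 1000).
#' @param replicates replicates per class.
#' @param classes classes to collect.
#' @param seed integer seed.
#' @param allow_fewer if a class cannot fill all replicates, fill what is
#'   possible (short final replicate) with a warning instead of erroring.
#' @return `data.frame` with `cell_id`, `class`, `replicate`, `well`.
#' @export
sample_shapes <- function(cells, per_class = 1000, replicates = 3,
                          classes = c("CDX2++", "CDX2+", "CDX2-"), seed,
                          allow_fewer = FALSE) {
  if (missing(seed)) stop_arg("'seed' is required")
  avail <- vapply(classes, function(cl)
    sum(!is.na(cells$assigned_class) & cells$assigned_class == cl),
    integer(1))
  need <- per_class * replicates
  deficit <- pmax(0L, need - avail)
  if (any(deficit > 0) && !allow_fewer)
    stop_arg("capacity error in sample_shapes: %s",
             paste(sprintf("%s short by %d (have %d, need %d)",
                           classes[deficit > 0], deficit[deficit > 0],
                           avail[deficit > 0], need), collapse = "; "))
  wells <- inner_wells_384()
  if (length(classes) * replicates > length(wells))
    stop_arg("more pools than inner wells available")
  set.seed(derive_seed(seed, "sample_shapes"))
  out <- list(); wi <- 0L
  for (cl in classes) {
    ids <- cells$cell_id[!is.na(cells$assigned_class) &
                           cells$assigned_class == cl]
    take <- min(length(ids), need)
    picked <- sample(ids, take)
    if (take < need)
      warning(sprintf("class '%s': only %d of %d shapes available; %s",
                      cl, take, need, "final replicate(s) run short"))
    rep_idx <- ceiling(seq_along(picked) / per_class)
    for (r in unique(rep_idx)) {
      wi <- wi + 1L
      sel <- picked[rep_idx == r]
      out[[length(out) + 1L]] <- data.frame(cell_id = sel, class = cl,
                                            replicate = r,
                                            well = wells[wi],
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# wells of a 384-well plate excluding rows A/P and columns 1/24
inner_wells_384 <- function() {
  rows <- LETTERS[2:15]                     # B..O
  cols <- 2:23
  as.vector(t(outer(rows, cols, function(r, c) sprintf("%s%d", r, c))))
}

#' Area sampled by a circular biopsy puncher
#'
#' The tissue area excised by a puncher of the given diameter:
#' `pi * (diameter_mm * 1000 / 2)^2` square microns. A 1.5 mm puncher
#' samples about 1.7 million square microns.
#'
#' @param diameter_mm puncher diameter in millimetres (>= 0).
#' @return area in square microns.
#' @export
#' @examples
#' macrodissection_area(1.5)  # ~1.77e6 um^2
macrodissection_area <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || any(diameter_mm < 0))
    stop_arg("'diameter_mm' must be >= 0")
  pi * (diameter_mm * 1000 / 2)^2
}
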