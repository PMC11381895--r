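#' Export / read cutting contours in the LMD XML dialect
#'
#' Writes a contour set as the XML dialect understood by laser
#' microdissection software: a `CalibrationPoint` block with exactly three
#' non-collinear reference points (used by the instrument to align slide
#' and stage coordinates; they are stored verbatim), a `ShapeCount`, and
#' one `Shape_k` element per contour with `PointCount`, the collection
#' well in `CapID`, and integer vertex coordinates `X_1..X_n / Y_1..Y_n`.
#' Coordinates are rounded half-away-from-zero to integers on export, so a
#' write-read round trip is exact for integer inputs.
#'
#' @param contours a `contour_set` (see [cell_contours()]); well labels
#'   are taken from `contours$wells` (named by `shape_id`) when present.
#' @param calibration numeric 3x2 matrix of reference points in pixels;
#'   must not be collinear.
#' @param path output file.
#' @return `export_lmd` returns `path` invisibly; `read_lmd` a
#'   `contour_set`.
#' @export
export_lmd <- function(contours, calibration, path) {
  stopifnot(inherits(contours, "contour_set"))
  calibration <- as.matrix(calibration)
  if (!all(dim(calibration) == c(3L, 2L)))
    stop_arg("'calibration' must be a 3x2 matrix of reference points")
  tri2 <- cross2(calibration[1, ], calibration[2, ], calibration[3, ])
  if (abs(tri2) < 1e-9)
    stop_arg("geometry error: calibration points are collinear")

  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<ImageData>",
             "  <GlobalCoordinates>1</GlobalCoordinates>")
  for (i in 1:3) {
    lines <- c(lines,
               sprintf("  <X_CalibrationPoint_%d>%d</X_CalibrationPoint_%d>",
                       i, round_half_away(calibration[i, 1]), i),
               sprintf("  <Y_CalibrationPoint_%d>%d</Y_CalibrationPoint_%d>",
                       i, round_half_away(calibration[i, 2]), i))
  }
  lines <- c(lines, sprintf("  <ShapeCount>%d</ShapeCount>",
                            length(contours$shapes)))
  for (k in seq_along(contours$shapes)) {
    sh <- contours$shapes[[k]]
    v <- sh$vertices
    if (is.null(v) || nrow(v) < 3L)
      stop_arg("geometry error: shape '%s' has fewer than 3 vertices",
               sh$shape_id %||% as.character(k))
    well <- ""
    if (length(contours$wells) && !is.null(sh$shape_id))
      well <- contours$wells[sh$shape_id] %||% ""
    if (is.na(well)) well <- ""
    xi <- round_half_away(v[, 1]); yi <- round_half_away(v[, 2])
    lines <- c(lines,
               sprintf("  <Shape_%d>", k),
               sprintf("    <PointCount>%d</PointCount>", nrow(v)),
               sprintf("    <CapID>%s</CapID>", well),
               sprintf("    <ShapeID>%s</ShapeID>", sh$shape_id %||% ""),
               sprintf("    <CellID>%s</CellID>", sh$cell_id %||% ""),
               sprintf("    <X_%d>%d</X_%d>", seq_len(nrow(v)), xi,
                       seq_len(nrow(v))),
               sprintf("    <Y_%d>%d</Y_%d>", seq_len(nrow(v)), yi,
                       seq_len(nrow(v))),
               sprintf("  </Shape_%d>", k))
  }
  lines <- c(lines, "</ImageData>")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_lmd
#' @export
read_lmd <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_arg("parse error in %s: %s", path, conditionMessage(e)))
  root <- doc
  kids <- xml2::xml_children(root)
  nms <- xml2::xml_name(kids)
  val <- function(nm) xml2::xml_text(kids[which(nms == nm)[1]])
  calibration <- cbind(
    x = as.numeric(vapply(1:3, function(i)
      val(sprintf("X_CalibrationPoint_%d", i)), character(1))),
    y = as.numeric(vapply(1:3, function(i)
      val(sprintf("Y_CalibrationPoint_%d", i)), character(1))))
  n_shapes <- as.integer(val("ShapeCount"))
  if (is.na(n_shapes))
    stop_arg("parse error in %s: missing ShapeCount", path)
  shapes <- vector("list", n_shapes)
  wells <- character(0)
  shape_nodes <- kids[grepl("^Shape_[0-9]+$", nms)]
  if (length(shape_nodes) != n_shapes)
    stop_arg("parse error in %s: ShapeCount %d but %d Shape elements",
             path, n_shapes, length(shape_nodes))
  for (k in seq_len(n_shapes)) {
    sk <- xml2::xml_children(shape_nodes[[k]])
    sn <- xml2::xml_name(sk)
    sv <- xml2::xml_text(sk)
    getf <- function(nm) sv[match(nm, sn)]
    np <- as.integer(getf("PointCount"))
    xs <- as.numeric(sv[match(sprintf("X_%d", seq_len(np)), sn)])
    ys <- as.numeric(sv[match(sprintf("Y_%d", seq_len(np)), sn)])
    if (anyNA(xs) || anyNA(ys))
      stop_arg("parse error in %s: shape %d has %d points declared but coordinates are incomplete",
               path, k, np)
    sid <- getf("ShapeID"); if (is.na(sid) || sid == "") sid <- sprintf("shape_%06d", k)
    shapes[[k]] <- list(shape_id = sid, cell_id = getf("CellID"),
                        vertices = cbind(x = xs, y = ys))
    cap <- getf("CapID")
    if (!is.na(cap) && nzchar(cap)) wells[sid] <- cap
  }
  structure(list(shapes = shapes, offset_um = NA_real_, um_per_px = NA_real_,
                 wells = wells, calibration = calibration),
            class = "contour_set")
}
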