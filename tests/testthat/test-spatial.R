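test_that("region assignment matches a ray-casting oracle", {
  set.seed(7)
  polys <- list(
    tri = cbind(c(10, 80, 40), c(10, 20, 90)),
    quad = cbind(c(50, 95, 90, 55), c(50, 55, 95, 90)),
    pent = cbind(c(5, 30, 35, 20, 2), c(60, 62, 80, 95, 82)))
  regions <- region_set(polys)
  pts <- data.frame(x_px = runif(1000, 0, 100), y_px = runif(1000, 0, 100))
  lab <- assign_regions(pts, regions)$region
  oracle <- vapply(seq_len(1000), function(i) {
    for (nm in names(polys))
      if (ray_cast_inside(pts$x_px[i], pts$y_px[i], polys[[nm]]))
        return(nm)
    "whole_tissue"
  }, character(1))
  expect_identical(lab, oracle)
})

test_that("points on edges and interiors honour the inclusive convention", {
  sq <- region_set(list(sq = c(0, 0, 10, 10)))
  pts <- data.frame(x_px = c(5, 10, 0, 10, 11), y_px = c(5, 5, 0, 10, 5))
  lab <- assign_regions(pts, sq)$region
  expect_identical(lab, c("sq", "sq", "sq", "sq", "whole_tissue"))
  # first-match-wins on overlapping regions
  over <- region_set(list(a = c(0, 0, 10, 10), b = c(5, 0, 15, 10)))
  expect_identical(assign_regions(data.frame(x_px = 7, y_px = 5),
                                  over)$region, "a")
})

test_that("class-by-region distribution reproduces constructed counts", {
  cells <- data.frame(
    assigned_class = c(rep("CDX2++", 50), rep("CDX2+", 10),
                       rep("CDX2-", 5), NA),
    region = c(rep(c("r1", "r2", "r3", "whole_tissue"), c(26, 10, 8, 6)),
               rep("r1", 10), rep("r2", 5), "r1"),
    stringsAsFactors = FALSE)
  tab <- class_region_distribution(cells)
  expect_equal(unlist(tab["CDX2++", c("r1", "r2", "r3", "whole_tissue")],
                      use.names = FALSE), c(52, 20, 16, 12))
  expect_equal(sum(tab["CDX2++", ]), 100)
  expect_equal(unname(unlist(tab["CDX2+", "r1"])), 100)

  # single region covering everything
  one <- data.frame(assigned_class = rep("CDX2++", 4),
                    region = rep("r1", 4), stringsAsFactors = FALSE)
  t1 <- class_region_distribution(one, classes = "CDX2++")
  expect_equal(unname(unlist(t1["CDX2++", "r1"])), 100)

  expect_warning(class_region_distribution(cells,
                                           classes = c("CDX2++", "ghost")),
                 "no cells")
})

test_that("contour dilation: identity at 0, annulus area law, containment", {
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  disc <- structure(list(shapes = list(list(
    shape_id = "s1", cell_id = "c1",
    vertices = cbind(x = 10 * cos(ang), y = 10 * sin(ang)))),
    offset_um = 0, um_per_px = 1, wells = character(0)),
    class = "contour_set")

  same <- dilate_contours(disc, offset_um = 0)
  expect_equal(same$shapes[[1]]$vertices, disc$shapes[[1]]$vertices)

  # 2 um offset of a 10 um-radius disc: area ratio (12/10)^2 within 1%
  big <- dilate_contours(disc, offset_um = 2, um_per_px = 1)
  a0 <- dvpflow:::polygon_area(disc$shapes[[1]]$vertices)
  a1 <- dvpflow:::polygon_area(big$shapes[[1]]$vertices)
  expect_equal(a1 / a0, 1.44, tolerance = 0.01)
  expect_equal(big$offset_um, 2)

  # dilated polygon contains every original vertex (convex case)
  v0 <- disc$shapes[[1]]$vertices
  expect_true(all(point_in_polygon(v0[, 1], v0[, 2],
                                   big$shapes[[1]]$vertices)))

  # monotone in the offset
  mid <- dilate_contours(disc, offset_um = 1, um_per_px = 1)
  expect_lt(dvpflow:::polygon_area(mid$shapes[[1]]$vertices), a1)
  expect_gt(dvpflow:::polygon_area(mid$shapes[[1]]$vertices), a0)

  bad <- disc; bad$shapes[[1]]$vertices <- cbind(c(0, 1), c(0, 1))
  expect_error(dilate_contours(bad, 1), "s1")
})

test_that("dilation handles concave polygons without shrinking", {
  # L-shaped (concave) contour
  L <- cbind(x = c(0, 20, 20, 8, 8, 0), y = c(0, 0, 8, 8, 20, 20))
  cs <- structure(list(shapes = list(list(shape_id = "L", cell_id = "c",
                                          vertices = L)),
                       offset_um = 0, um_per_px = 1, wells = character(0)),
                  class = "contour_set")
  out <- dilate_contours(cs, offset_um = 1, um_per_px = 1)$shapes[[1]]$vertices
  expect_true(all(point_in_polygon(L[, 1], L[, 2], out)))
  expect_gt(dvpflow:::polygon_area(out), dvpflow:::polygon_area(L))
})

test_that("shape sampling fills disjoint replicates into inner wells", {
  cells <- data.frame(cell_id = sprintf("c%04d", 1:3500),
                      assigned_class = rep(c("CDX2++", "CDX2-"),
                                           c(3000, 500)),
                      stringsAsFactors = FALSE)
  pools <- sample_shapes(cells, per_class = 1000, replicates = 3,
                         classes = "CDX2++", seed = 1)
  expect_equal(nrow(pools), 3000L)
  expect_equal(unname(table(pools$replicate)), rep(1000L, 3),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(pools$cell_id) > 0)
  # reproducible under the seed
  pools2 <- sample_shapes(cells, per_class = 1000, replicates = 3,
                          classes = "CDX2++", seed = 1)
  expect_identical(pools, pools2)

  # wells never touch the outermost rows/columns of the 384-well plate
  rows <- substr(pools$well, 1, 1)
  cols <- as.integer(sub("^[A-P]", "", pools$well))
  expect_false(any(rows %in% c("A", "P")))
  expect_false(any(cols %in% c(1L, 24L)))

  expect_error(sample_shapes(cells, 1000, 3, classes = "CDX2-", seed = 1),
               "short by 2500")
  expect_warning(
    short <- sample_shapes(cells, 200, 3, classes = "CDX2-", seed = 1,
                           allow_fewer = TRUE),
    "500 of 600")
  expect_equal(sum(short$replicate == 3), 100L)
})

test_that("LMD XML export/read is a lossless round trip", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  mk <- function(i) list(shape_id = sprintf("shape_%06d", i),
                         cell_id = sprintf("cell_%06d", i),
                         vertices = cbind(
                           x = round(500 + 400 * cos(ang + i)),
                           y = round(500 + 400 * sin(ang + i))))
  cs <- structure(list(shapes = lapply(1:25, mk), offset_um = 2,
                       um_per_px = 1,
                       wells = setNames(sprintf("B%d", 2:26),
                                        sprintf("shape_%06d", 1:25))),
                  class = "contour_set")
  calib <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  path <- withr::local_tempfile(fileext = ".xml")
  export_lmd(cs, calib, path)
  back <- read_lmd(path)
  expect_equal(length(back$shapes), 25L)
  for (i in c(1, 13, 25)) {
    expect_identical(back$shapes[[i]]$vertices,
                     cbind(x = as.numeric(cs$shapes[[i]]$vertices[, 1]),
                           y = as.numeric(cs$shapes[[i]]$vertices[, 2])))
    expect_identical(back$shapes[[i]]$cell_id, cs$shapes[[i]]$cell_id)
  }
  expect_identical(unname(back$wells["shape_000001"]), "B2")
  expect_equal(back$calibration, cbind(x = calib[, 1], y = calib[, 2]))

  # empty contour set still yields a valid calibration-only file
  empty <- structure(list(shapes = list(), offset_um = 0, um_per_px = 1,
                          wells = character(0)), class = "contour_set")
  p2 <- withr::local_tempfile(fileext = ".xml")
  export_lmd(empty, calib, p2)
  expect_equal(length(read_lmd(p2)$shapes), 0L)

  expect_error(export_lmd(cs, rbind(c(0, 0), c(1, 1), c(2, 2)), path),
               "collinear")
  p3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<ImageData>", "<oops>"), p3)
  expect_error(read_lmd(p3), "parse error")
})

test_that("macrodissection area follows the circle formula", {
  expect_equal(macrodissection_area(1.5), pi * 750^2, tolerance = 1e-12)
  expect_equal(macrodissection_area(0), 0)
  expect_equal(macrodissection_area(2), pi * 1000^2, tolerance = 1e-12)
  expect_error(macrodissection_area(-1), ">= 0")
})
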