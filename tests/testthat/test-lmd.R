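make_doc <- function() {
  tp <- teaching_points(c(100, 200), c(900, 220), c(150, 950))
  b1 <- roi_boundary_set(list(rbind(c(150, 250), c(152, 250), c(152, 252),
                                    c(150, 252), c(150, 250)),
                              rbind(c(400, 400), c(400, 400))),
                         segment_id = 1, frame = "optical")
  b2 <- roi_boundary_set(list(rbind(c(300.4, 300.5), c(305.6, 300.5),
                                    c(305.6, 308.4), c(300.4, 300.5))),
                         segment_id = 2, frame = "optical")
  to_lmd_coordinates(list(b1, b2), tp)
}

test_that("teaching points must be non-collinear", {
  expect_error(teaching_points(c(0, 0), c(1, 1), c(2, 2)), "collinear")
  expect_error(teaching_points(c(0, 0), c(0, 0), c(1, 0)), "collinear")
  expect_s3_class(teaching_points(c(0, 0), c(1, 0), c(0, 1)),
                  "teaching_points")
})

test_that("to_lmd_coordinates recenters on the origin and rounds half-up", {
  tp0 <- teaching_points(c(0, 0), c(10, 0), c(0, 10))
  b <- roi_boundary_set(list(rbind(c(5, 7), c(6, 7), c(5, 7))), 1, "optical")
  doc0 <- to_lmd_coordinates(b, tp0)
  expect_equal(unname(doc0$calibration_points[1, ]), c(0, 0))
  expect_equal(unname(doc0$shapes[[1]]$vertices[1, ]), c(5, 7))

  tp <- teaching_points(c(100, 200), c(110, 200), c(100, 210))
  bb <- roi_boundary_set(list(rbind(c(150, 250), c(150.5, 249.5), c(150, 250))),
                         1, "optical")
  doc <- to_lmd_coordinates(bb, tp)
  expect_equal(unname(doc$shapes[[1]]$vertices[1, ]), c(50, 50))
  # 0.5 rounds up (floor(v + 0.5)): 50.5 -> 51, 49.5 -> 50
  expect_equal(unname(doc$shapes[[1]]$vertices[2, ]), c(51, 50))

  # translation preserves pairwise differences exactly before rounding;
  # after rounding the per-axis distortion is at most 0.5
  set.seed(19)
  poly <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  poly <- rbind(poly, poly[1, ])
  d <- to_lmd_coordinates(roi_boundary_set(list(poly), 1, "optical"), tp)
  expect_lte(max(abs(d$shapes[[1]]$vertices -
                       sweep(poly, 2, c(100, 200)))), 0.5)

  # y flip negates the recentered y axis
  df <- to_lmd_coordinates(bb, tp, flip_y = TRUE)
  expect_equal(unname(df$shapes[[1]]$vertices[1, ]), c(50, -50))
})

test_that("lmd XML serialization is structural, byte-deterministic, and lossless", {
  doc <- make_doc()
  f1 <- withr::local_tempfile(fileext = ".xml")
  write_lmd_xml(doc, f1)
  txt <- readLines(f1)
  expect_true(any(grepl("<ShapeCount>3</ShapeCount>", txt)))
  expect_equal(sum(grepl("<PointCount>", txt)), 3)
  expect_equal(grep("<PointCount>", txt, value = TRUE),
               c("    <PointCount>5</PointCount>",
                 "    <PointCount>2</PointCount>",
                 "    <PointCount>4</PointCount>"))

  # round trip is field-exact
  rt <- read_lmd_xml(f1)
  expect_equal(rt$calibration_points, doc$calibration_points)
  expect_equal(length(rt$shapes), length(doc$shapes))
  for (i in seq_along(doc$shapes)) {
    expect_equal(unname(rt$shapes[[i]]$vertices),
                 unname(doc$shapes[[i]]$vertices))
    expect_equal(rt$shapes[[i]]$segment_id, doc$shapes[[i]]$segment_id)
  }
  expect_identical(rt$global_coordinates, doc$global_coordinates)

  # write -> read -> write produces byte-identical files
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_lmd_xml(rt, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # zero shapes
  empty <- lmd_document(rbind(c(0, 0), c(10, 0), c(0, 10)))
  f3 <- withr::local_tempfile(fileext = ".xml")
  write_lmd_xml(empty, f3)
  expect_true(any(grepl("<ShapeCount>0</ShapeCount>", readLines(f3))))
})

test_that("a frozen golden LMD file parses to the committed expectation", {
  golden <- test_path("lmd-golden.xml")
  doc <- read_lmd_xml(golden)
  expect_equal(unname(doc$calibration_points),
               rbind(c(0, 0), c(800, 20), c(50, 750)))
  expect_length(doc$shapes, 3)
  expect_equal(vapply(doc$shapes, function(s) nrow(s$vertices), integer(1)),
               c(5L, 2L, 4L))
  expect_equal(unname(doc$shapes[[1]]$vertices[1, ]), c(50, 50))
  # and the writer reproduces the golden bytes
  f <- withr::local_tempfile(fileext = ".xml")
  write_lmd_xml(doc, f)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(golden, "raw", file.size(golden)))
})

test_that("schema violations are reported by element name", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<ImageData>", "<GlobalCoordinates>1</GlobalCoordinates>",
               "<X_CalibrationPoint_1>0</X_CalibrationPoint_1>",
               "</ImageData>"), f)
  expect_error(read_lmd_xml(f), "Y_CalibrationPoint_1")

  g <- withr::local_tempfile(fileext = ".xml")
  doc <- make_doc()
  write_lmd_xml(doc, g)
  txt <- readLines(g)
  txt <- sub("<ShapeCount>3</ShapeCount>", "<ShapeCount>4</ShapeCount>", txt)
  writeLines(txt, g)
  expect_error(read_lmd_xml(g), "Shape_4")

  # unknown extra elements are ignored with a warning
  h <- withr::local_tempfile(fileext = ".xml")
  write_lmd_xml(doc, h)
  txt2 <- readLines(h)
  txt2 <- append(txt2, "  <Comment>hello</Comment>", after = 2)
  writeLines(txt2, h)
  expect_warning(rt <- read_lmd_xml(h), "Comment")
  expect_length(rt$shapes, 3)
})

test_that("full phantom chain: MSI boundary -> optical -> LMD equals a hand-chained oracle", {
  spec <- phantom_spec(seed = 5)
  Tmo <- spec$true_transforms$msi_optical
  poly <- rbind(c(3, 4), c(10, 4), c(10, 9), c(3, 4))
  b_msi <- roi_boundary_set(list(poly), 1, "msi")
  b_opt <- transform_boundaries(b_msi, Tmo)
  tp <- teaching_points(c(40, 60), c(500, 80), c(60, 700))
  doc <- to_lmd_coordinates(b_opt, tp)
  # oracle: chain each vertex by hand
  p <- Tmo$params
  hand <- t(apply(poly, 1, function(v) {
    ov <- c(p["a"] * v[1] + p["b"] * v[2] + p["tx"],
            p["c"] * v[1] + p["d"] * v[2] + p["ty"])
    floor(ov - c(40, 60) + 0.5)
  }))
  expect_equal(unname(doc$shapes[[1]]$vertices), unname(hand))
})
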