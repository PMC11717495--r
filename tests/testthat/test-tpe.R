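square_roi <- function(side = 10, x0 = 0, y0 = 0)
  roi_set(list(rbind(c(x0, y0), c(x0 + side, y0),
                     c(x0 + side, y0 + side), c(x0, y0 + side))))

detections_df <- function(x, y, cls, confidence = 1)
  data.frame(x = x, y = y,
             cls = factor(cls, levels = c("tumour", "background")),
             confidence = confidence)

test_that("cells are counted only inside the ROI", {
  rois <- square_roi(10)
  det <- detections_df(
    x = c(1, 2, 3, 4, 5, 50, 60, 70, 80),
    y = c(1, 2, 3, 4, 5, 50, 60, 70, 80),
    cls = c("tumour", "tumour", "tumour", "background", "background",
            "tumour", "tumour", "background", "background"))
  s <- count_cells_in_roi(det, rois, "slideA")
  expect_equal(s$tc, 3L)
  expect_equal(s$bc, 2L)
  expect_equal(s$area_mm2, 100 / 1e6)
})

test_that("boundary points count as inside", {
  rois <- square_roi(10)
  det <- detections_df(c(0, 10, 5), c(0, 5, 10), rep("tumour", 3))
  expect_true(all(points_in_roi(det, rois)))
})

test_that("a fully populated 1 mm^2 ROI reports its cell density", {
  # 19,000 cells placed deterministically on a grid inside 1 mm^2
  k <- 19000
  g <- ceiling(sqrt(k))
  xy <- expand.grid(x = seq(1, 999, length.out = g),
                    y = seq(1, 999, length.out = g))[seq_len(k), ]
  det <- detections_df(xy$x, xy$y, rep("tumour", k))
  s <- count_cells_in_roi(det, square_roi(1000), "dense")
  expect_equal(s$tc, k)
  expect_equal(s$density, 19000)
})

test_that("ROI membership matches an independent ray-casting oracle", {
  set.seed(7)
  ring <- rbind(c(0, 0), c(8, 2), c(10, 10), c(4, 12), c(-2, 6))
  rois <- roi_set(list(ring))
  px <- runif(400, -4, 14); py <- runif(400, -4, 14)
  got <- points_in_roi(data.frame(x = px, y = py), rois)
  want <- vapply(seq_along(px), function(i)
    oracle_point_in_polygon(px[i], py[i], ring), logical(1))
  expect_identical(got, want)
})

test_that("ROI membership agrees with mgcv::in.out for interior points", {
  skip_if_not_installed("mgcv")
  set.seed(8)
  ring <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  rois <- roi_set(list(ring))
  px <- runif(300, -5, 15); py <- runif(300, -5, 15)
  # keep points clearly off the boundary, where semantics coincide
  off <- abs(px) > 0.01 & abs(px - 10) > 0.01 &
    abs(py) > 0.01 & abs(py - 10) > 0.01
  got <- points_in_roi(data.frame(x = px, y = py)[off, ], rois)
  want <- mgcv::in.out(rbind(ring, ring[1, ]),
                       cbind(px[off], py[off]))
  expect_identical(got, as.vector(want))
})

test_that("polygons with holes exclude the hole interior", {
  outer <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  hole <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6))
  rois <- roi_set(list(list(outer, hole)))
  expect_equal(rois$area_mm2, (100 - 4) / 1e6)
  det <- data.frame(x = c(5, 2), y = c(5, 2))
  expect_identical(points_in_roi(det, rois), c(FALSE, TRUE))
})

test_that("tumour purity is the tumour fraction of counted cells", {
  expect_equal(tumour_purity(60, 40), 60)
  expect_equal(tumour_purity(0, 10), 0)
  expect_equal(tumour_purity(2066, 0), 100)
  expect_error(tumour_purity(0, 0), "undefined purity")
  s <- data.frame(tc = 30, bc = 10)
  expect_equal(tumour_purity(s), 75)
})

test_that("purity counting is invariant under coordinate scaling", {
  set.seed(11)
  det <- detections_df(runif(200, 0, 10), runif(200, 0, 10),
                       sample(c("tumour", "background"), 200, TRUE))
  rois1 <- square_roi(6, 2, 2)
  s1 <- count_cells_in_roi(det, rois1, "a")
  k <- 3.5
  det2 <- det; det2$x <- det2$x * k; det2$y <- det2$y * k
  rois2 <- roi_set(list(rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8)) * k))
  s2 <- count_cells_in_roi(det2, rois2, "a")
  expect_equal(s2$tc, s1$tc)
  expect_equal(s2$bc, s1$bc)
  expect_equal(s2$area_mm2, s1$area_mm2 * k^2)
})

test_that("adding a tumour detection inside the ROI never lowers purity", {
  set.seed(12)
  det <- detections_df(runif(50, 0, 10), runif(50, 0, 10),
                       sample(c("tumour", "background"), 50, TRUE))
  rois <- square_roi(10)
  for (i in 1:10) {
    before <- tumour_purity(count_cells_in_roi(det, rois, "s"))
    det <- rbind(det, detections_df(runif(1, 0, 10), runif(1, 0, 10),
                                    "tumour"))
    after <- tumour_purity(count_cells_in_roi(det, rois, "s"))
    expect_gte(after, before)
  }
})

test_that("purity is stable under binomial thinning in expectation", {
  set.seed(13)
  sim <- simulate_cell_detections(60, density_per_mm2 = 5000)
  full <- tumour_purity(count_cells_in_roi(sim$detections, sim$rois, "s"))
  thinned <- replicate(40, {
    keep <- runif(nrow(sim$detections)) < 0.3
    tumour_purity(count_cells_in_roi(sim$detections[keep, ], sim$rois, "s"))
  })
  expect_lt(abs(mean(thinned) - full), 1.5)
})

test_that("detection CSV reader normalises class synonyms and filters by confidence", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("x,y,class,confidence",
               "1,1,Tumor,0.9", "2,2,TC,0.8", "3,3,bc,0.7",
               "4,4,background,0.2"), path)
  expect_message(det <- read_detections(path), "normalised")
  expect_equal(as.character(det$cls),
               c("tumour", "tumour", "background", "background"))
  s <- count_cells_in_roi(det, square_roi(10), "s", min_confidence = 0.5)
  expect_equal(s$tc + s$bc, 3)

  badpath <- tempfile(fileext = ".csv")
  writeLines(c("x,y,class,confidence", "1,1,stroma,0.5"), badpath)
  expect_error(read_detections(badpath), "unknown detection class")
})

test_that("GeoJSON ROIs load as polygons with correct area", {
  path <- tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = NULL,
    geometry = list(type = "Polygon", coordinates = list(
      list(list(0, 0), list(1000, 0), list(1000, 1000), list(0, 1000),
           list(0, 0)))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  rois <- read_roi_geojson(path)
  expect_s3_class(rois, "roi_set")
  expect_equal(rois$area_mm2, 1)
})

test_that("paired-slide concordance behaves at the extremes and checks matching", {
  x <- c(10, 25, 40, 70, 90)
  r1 <- paired_slide_concordance(x, x)
  expect_equal(r1$r, 1.0)
  r2 <- paired_slide_concordance(1:10, 10:1)
  expect_equal(r2$r, -1.0)
  a <- setNames(x, paste0("S", 1:5))
  b <- setNames(x, paste0("S", c(1:4, 9)))
  expect_error(paired_slide_concordance(a, b), "S9")
})

test_that("paired-slide correlation matches the analytic attenuation", {
  set.seed(14)
  cfg <- simulation_config(seed = 14, n_samples = 300, replicate_sd = 5)
  truth <- simulate_true_purity(cfg)
  slides <- simulate_paired_slides(truth, cfg$replicate_sd)
  r <- paired_slide_concordance(slides[, "he1"], slides[, "he2"])
  v <- var(truth)
  expected <- v / (v + 25)
  # Fisher-z Monte-Carlo band
  z <- atanh(r$r) - atanh(expected)
  expect_lt(abs(z), 2.5 / sqrt(300 - 3))
})
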