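test_that("sensor field matches the closed-form Gaussian sum", {
  w <- world(40, list(gaussian_object(10, 0.8, 1)))
  expect_equal(sense(w, 10), 0.8)                       # field peak is h
  w2 <- unit_gaussian_world(h = 1, w = 1, center = 0)
  expect_equal(sense(w2, 3), exp(-4.5))
  expect_equal(sense(world(40), c(0, 7.3, 39)), c(0, 0, 0))
  # clipping: two stacked objects saturate at 1
  wc <- suppressWarnings(world(40, list(gaussian_object(10, 0.9, 1),
                                        gaussian_object(10.2, 0.9, 1))))
  expect_equal(sense(wc, 10.1), 1)
  expect_equal(sense_gradient(wc, 10.1), 0)  # clipped region is flat
})

test_that("sense is exactly periodic in the circumference", {
  w <- world(40, list(gaussian_object(5, 0.7, 2)))
  p <- runif(200, -80, 80)
  expect_identical(sense(w, p), sense(w, p + 40))
  expect_identical(sense(w, p), sense(w, p - 40))
})

test_that("analytic gradient agrees with a finite difference of sense", {
  set.seed(42)
  w <- world(40, list(gaussian_object(8, 0.9, 1),
                      gaussian_object(30, 0.6, 3)))
  p <- runif(1000, 0, 40)
  h <- 1e-6
  fd <- (sense(w, p + h) - sense(w, p - h)) / (2 * h)
  expect_lt(max(abs(fd - sense_gradient(w, p))), 1e-6)
})

test_that("gradient is antisymmetric about an isolated peak and extremal at +/- w", {
  w <- unit_gaussian_world(h = 1, w = 1, center = 0)
  expect_equal(sense_gradient(w, 0), 0)
  expect_equal(sense_gradient(w, 1), -exp(-0.5))
  d <- seq(0.1, 2.9, by = 0.2)
  expect_equal(sense_gradient(w, d), -sense_gradient(w, -d))
  # extrema of the gradient at p = c +/- w, to grid resolution
  p <- seq(-3, 3, by = 1e-3)
  g <- sense_gradient(w, p)
  expect_equal(p[which.max(g)], -1, tolerance = 2e-3)
  expect_equal(p[which.min(g)], 1, tolerance = 2e-3)
})

test_that("wrapping and wrapped distance follow the stated conventions", {
  expect_equal(wrap_position(41, 40), 1)
  expect_equal(wrap_position(-1, 40), 39)
  expect_equal(wrapped_distance(1, 39, 40), 2)     # shorter way around
  expect_equal(wrapped_distance(39, 1, 40), -2)    # antisymmetry
  expect_equal(wrapped_distance(0, 20, 40), 20)    # antipode fixed positive
  expect_error(wrap_position(1, 0), "L")
  expect_error(wrapped_distance(1, 2, -3), "L")
  a <- runif(100, 0, 40); b <- runif(100, 0, 40)
  ok <- abs(abs(wrapped_distance(a, b, 40)) - 20) > 1e-9
  expect_equal(wrapped_distance(a, b, 40)[ok], -wrapped_distance(b, a, 40)[ok])
})

test_that("world construction enforces invariants and warns on overlap", {
  expect_error(gaussian_object(0, 1.5, 1), "height")
  expect_error(gaussian_object(0, 0.5, -1), "width")
  expect_error(world(-1), "circumference")
  expect_warning(world(40, list(gaussian_object(10, 0.8, 3),
                                gaussian_object(15, 0.8, 3))),
                 "separated")
  # centers wrapped into [0, L)
  w <- world(40, list(gaussian_object(45, 0.8, 1)))
  expect_equal(w$objects[[1]]$center, 5)
})

test_that("world files round-trip through JSON and YAML", {
  w <- two_shape_world()
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_world(w, f)
    w2 <- read_world(f)
    expect_equal(w2$circumference, w$circumference)
    expect_equal(w2$objects, w$objects)
  }
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(circumference = 40,
                            objects = list(list(center = 1, height = 1.5,
                                                width = 1))),
                       f, auto_unbox = TRUE)
  expect_error(read_world(f), "height")
})
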