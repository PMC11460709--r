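test_that("plug surface area matches the capped-cylinder closed form", {
  dev <- build_device(device_spec("plug", 24, lobe_length = 20))
  expect_equal(mesh_area(dev), pi * 24 * 20 + 2 * pi * 12^2,
               tolerance = 0.02)
})

test_that("pacifier carries labelled lobe and disk components", {
  dev <- build_device(device_spec("pacifier", 25, disk_diameter = 32))
  expect_setequal(unique(dev$labels), c("device_lobe", "device_disk"))
  expect_error(device_spec("pacifier", 25), "disk_diameter")
  expect_error(device_spec("pacifier", 25, disk_diameter = 20), ">=")
  expect_error(device_spec("plug", 0), "positive")
})

test_that("deployment places the proximal face at the requested depth", {
  m <- fix_atrium()
  oc <- attr(m, "ostium_center")
  ax <- attr(m, "laa_axis")
  dev <- build_device(device_spec("plug", 24))
  p0 <- place_device(dev, m, 0)
  expect_equal(drop(attr(p0, "proximal_face")$center), oc, tolerance = 1e-6)
  p8 <- place_device(dev, m, 8)
  expect_equal(drop(attr(p8, "proximal_face")$center), oc + 8 * ax,
               tolerance = 1e-6)
  expect_error(place_device(dev, m, 99), "exceeds appendage length")
})

test_that("placement is rigid: area and volume preserved to 1e-9", {
  m <- fix_atrium()
  dev <- build_device(device_spec("pacifier", 22, disk_diameter = 28))
  placed <- place_device(dev, m, 5)
  expect_equal(mesh_area(placed), mesh_area(dev), tolerance = 1e-9)
  expect_equal(mesh_volume(placed), mesh_volume(dev), tolerance = 1e-9)
})

test_that("ostium metrics reproduce circle, square and ellipse closed forms", {
  circ <- ostium_metrics(circle_contour(12.8, 256))
  expect_equal(circ$area, 514.7, tolerance = 0.5 / 514.7)
  expect_equal(circ$perimeter, 80.4, tolerance = 0.1 / 80.4)
  sq <- ostium_metrics(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)
  ell <- ostium_metrics(ellipse_contour(10, 5))
  expect_equal(ell$area, pi * 50, tolerance = 0.005)
  expect_true(ell$perimeter^2 >= 4 * pi * ell$area)
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(ostium_metrics(bow), "self-intersecting")
})

test_that("landing-zone diagonals follow circle and ellipse calipers", {
  lz <- landing_zone_diagonals(circle_contour(12, 128))
  expect_equal(lz$d_max, 24, tolerance = 0.1 / 24)
  expect_equal(lz$d_min, 24, tolerance = 0.1 / 24)
  expect_equal(lz$d_mean, 24, tolerance = 0.1 / 24)
  le <- landing_zone_diagonals(ellipse_contour(15, 10))
  expect_equal(le$d_max, 30, tolerance = 0.2 / 30)
  expect_equal(le$d_min, 20, tolerance = 0.2 / 20)
  expect_equal(le$d_mean, 25, tolerance = 0.2 / 25)
  expect_true(le$d_min <= le$d_mean && le$d_mean <= le$d_max)
  expect_error(landing_zone_diagonals(rbind(c(0, 0, 0), c(1, 0, 0))),
               "geometry error")
})

test_that("pulmonary-ridge coverage uses an inclusive 10 mm threshold", {
  m <- fix_atrium()
  oc <- attr(m, "ostium_center")
  dev <- build_device(device_spec("plug", 24))
  # device face passing through the probe point
  p0 <- place_device(dev, m, 0)
  cov0 <- pr_coverage(m, p0, lspv_endpoint = oc)
  expect_equal(cov0$min_distance_to_device, 0, tolerance = 1e-6)
  expect_true(cov0$covered)
  # deep pose, fold at the ostium plane: distance equals the depth
  p12 <- place_device(dev, m, 12)
  cov12 <- pr_coverage(m, p12, lspv_endpoint = oc)
  expect_equal(cov12$min_distance_to_device, 12, tolerance = 0.1)
  expect_false(cov12$covered)
  expect_gt(cov12$uncovered_region_area, 0)
  # boundary: exactly at threshold counts as covered
  p10 <- place_device(dev, m, 10)
  cov10 <- pr_coverage(m, p10, lspv_endpoint = oc)
  expect_true(cov10$covered)
  expect_error(pr_coverage(m, NULL), "missing device")
})

test_that("coverage distance is monotone in depth on the straight centerline", {
  m <- fix_atrium()
  oc <- attr(m, "ostium_center")
  dev <- build_device(device_spec("plug", 24))
  d <- vapply(c(0, 4, 8, 12, 16), function(dep) {
    pr_coverage(m, place_device(dev, m, dep),
                lspv_endpoint = oc)$min_distance_to_device
  }, 0)
  expect_true(all(diff(d) >= -1e-9))
})

test_that("size recommendation uses intervals with larger-size tie-break", {
  tab <- default_sizing_table()
  expect_equal(recommend_size(list(d_mean = 21), "plug", tab), 27)
  # boundary value belongs to the upper interval (larger size)
  expect_equal(recommend_size(list(d_mean = 20), "plug", tab), 27)
  expect_equal(recommend_size(list(d_mean = 19.99), "plug", tab), 24)
  expect_error(recommend_size(list(d_mean = 60), "plug", tab),
               "out-of-range")
  expect_error(recommend_size(list(d_mean = 20), "plug",
                              tab[tab$device_type == "pacifier", ]),
               "empty sizing table")
})
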