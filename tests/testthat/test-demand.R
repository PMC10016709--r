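test_that("reef radius inverts disc area with km2 to m2 conversion", {
  expect_equal(reef_radius(pi * 200^2 * 1e-6), 200)
  expect_equal(reef_radius(1e-6), sqrt(1 / pi)) # 1 m2 reef
  expect_error(reef_radius(0), "area")
  expect_error(reef_radius(-2), "area")
})

test_that("reef demand uses the annulus beyond the disc threshold", {
  p <- demand_params() # d_c = 1, r_width = 20, threshold 100 m
  big <- data.frame(id = "b", lat = -17, lon = 146, area_km2 = pi * 200^2 * 1e-6)
  expect_equal(reef_demand(big, p), pi * (210^2 - 190^2))
  small <- data.frame(id = "s", lat = -17, lon = 146, area_km2 = pi * 50^2 * 1e-6)
  expect_equal(reef_demand(small, p), pi * 60^2)
  # demand scales linearly with planting density
  expect_equal(reef_demand(big, demand_params(d_c = 2.5)),
               2.5 * reef_demand(big, p))
})

test_that("annulus demand is monotone in radius and continuous off-threshold", {
  p <- demand_params()
  r <- seq(101, 2000, by = 7)
  d <- reef_demand(data.frame(id = seq_along(r), lat = -17, lon = 146,
                              area_km2 = pi * r^2 * 1e-6), p)
  expect_true(all(diff(d) > 0))
  expect_equal(d, 2 * pi * r * p$r_width, tolerance = 1e-10)
})

test_that("north-to-south sweep respects vessel capacity", {
  reefs <- data.frame(
    id = c("r1", "r2", "r3"),
    lat = c(-10, -12, -14), lon = c(146, 146, 146),
    # areas chosen so annulus demands are ~100k, 200k, 400k corals
    area_km2 = pi * (c(1e5, 2e5, 4e5) / (2 * pi * 20))^2 * 1e-6
  )
  cl <- sweep_cluster(reefs, s_c = 432000)
  expect_equal(nrow(cl), 2)
  expect_equal(attr(cl, "members"), list(c("r1", "r2"), "r3"))
  expect_equal(cl$annual_demand, as.numeric(tapply(reef_demand(reefs), c(1, 1, 2), sum)),
               tolerance = 1e-12)

  # a reef whose own demand exceeds capacity forms a singleton cluster
  huge <- data.frame(id = "h", lat = -15, lon = 147,
                     area_km2 = pi * (9e5 / (2 * pi * 20))^2 * 1e-6)
  cl2 <- sweep_cluster(huge, s_c = 432000)
  expect_equal(nrow(cl2), 1)
  expect_gt(cl2$annual_demand, 432000)
})

test_that("sweep clustering conserves demand and orders north to south", {
  reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 60, seed = 3))
  cl <- sweep_cluster(reefs, s_c = 432000)
  expect_equal(sum(cl$annual_demand), sum(reef_demand(reefs)), tolerance = 1e-12)
  expect_true(all(diff(order(-cl$centroid_lat)) > 0) ||
                all(diff(cl$centroid_lat) < 1)) # sweep order, small overlaps ok
  members <- attr(cl, "members")
  expect_setequal(unlist(members), reefs$id)
  singleton <- cl$n_reefs == 1
  expect_true(all(cl$annual_demand[!singleton] <= 432000 + 1e-9))
  # empty input is not an error
  expect_equal(nrow(sweep_cluster(reefs[0, ], s_c = 432000)), 0)
})

test_that("zero-demand reefs collapse into a single cluster", {
  # planting density scaled down so every demand rounds to ~0 relative to s_c
  reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 12, seed = 5))
  cl <- sweep_cluster(reefs, s_c = 432000, params = demand_params(d_c = 1e-9))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_reefs, 12)
})

test_that("intra-cluster allowance is a round-trip star tour", {
  # singleton: centroid coincides with the reef
  expect_equal(intra_cluster_allowance(-17, 146, -17, 146), 0)
  # two reefs 10 km apart along a meridian, centroid midway: 2*(5+5) = 20
  a <- c(-17, 146); b <- offset_south(-17, 146, 10)
  mid <- (a[1] + b[1]) / 2
  expect_equal(intra_cluster_allowance(mid, 146, c(a[1], b[1]), c(146, 146)),
               20, tolerance = 1e-9)
  # three collinear reefs at 0, 10, 20 km: 2*(10+0+10) = 40
  lats <- c(-17, offset_south(-17, 146, 10)[1], offset_south(-17, 146, 20)[1])
  expect_equal(intra_cluster_allowance(lats[2], 146, lats, rep(146, 3)),
               40, tolerance = 1e-9)
  expect_error(intra_cluster_allowance(-17, 146, numeric(0), numeric(0)),
               "member")
})

test_that("reef subset selection is seeded and without replacement", {
  reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 200, seed = 9))
  s1 <- select_reef_subset(reefs, 50, seed = 123)
  s2 <- select_reef_subset(reefs, 50, seed = 123)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$id)), 50)
  s3 <- select_reef_subset(reefs, 50, seed = 124)
  expect_false(identical(s1$id, s3$id))
  expect_setequal(select_reef_subset(reefs, nrow(reefs), seed = 1)$id, reefs$id)
  expect_error(select_reef_subset(reefs, 201, seed = 1), "exceeds")
})
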