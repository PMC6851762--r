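test_that("daily-to-monthly aggregation is the arithmetic mean per cell", {
  d <- data.frame(l3 = "A", year = 2000, month = 1, value = rep(2, 30))
  expect_equal(aggregateDailyToMonthly(d)$value, 2)
  d2 <- data.frame(l3 = "A", year = 2000, month = 1, value = c(1, 2, 3))
  expect_equal(aggregateDailyToMonthly(d2)$value, 2)
  # two regions with disjoint values aggregate independently
  d3 <- rbind(data.frame(l3 = "A", year = 2000, month = 1, value = c(1, 3)),
              data.frame(l3 = "B", year = 2000, month = 1, value = c(10, 30)))
  out <- aggregateDailyToMonthly(d3)
  expect_equal(out$value[match(c("A", "B"), out$l3)], c(2, 20))
  # a region-month with no values is an explicit error naming the cell
  d4 <- rbind(d2, data.frame(l3 = "B", year = 2000, month = 2, value = 5))
  expect_error(aggregateDailyToMonthly(d4), "cell")
})

test_that("rolling prior-12-month sum excludes the current month", {
  r <- rollingPriorPrecip(rep(1, 24))
  expect_true(all(is.na(r[1:12])))
  expect_true(all(r[13:24] == 12))
  ramp <- rollingPriorPrecip(1:24)
  expect_equal(ramp[13], sum(1:12))  # 78
  expect_equal(ramp[20], sum(8:19))
  expect_error(rollingPriorPrecip(1:12), "length >= 13")
})

test_that("housing interpolation is linear inside and beyond the anchors", {
  expect_equal(interpolateHousing(c(2000, 2010), c(10, 20), 2005), 15)
  expect_equal(interpolateHousing(c(2000, 2010), c(10, 20), 2016), 26)
  expect_equal(interpolateHousing(c(2000, 2010, 2020), c(7, 7, 7),
                                  c(2003.2, 2012, 2025)), c(7, 7, 7))
  expect_error(interpolateHousing(2000, 10, 2005), "two anchor")
})

test_that("event filtering uses a strict threshold and computes exceedances", {
  raw <- data.frame(event_id = c("a", "b", "c"), year = 2000, month = 6,
                    l3 = "L3_01", size_ha = c(1000, 300, 500))
  cat <- filterEvents(raw, 405)
  expect_equal(catalogEvents(cat)$size_ha, c(1000, 500))
  expect_equal(catalogEvents(cat)$exceedance_ha, c(595, 95))
  # exactly at the threshold is removed (exceedance must be positive)
  at <- filterEvents(transform(raw, size_ha = c(405, 405, 406)), 405)
  expect_equal(catalogEvents(at)$exceedance_ha, 1)
  # all below the threshold leaves a valid empty catalog
  none <- filterEvents(transform(raw, size_ha = c(5, 10, 20)), 405)
  expect_equal(length(none), 0)
  expect_error(filterEvents(transform(raw, size_ha = c(-1, 10, 20))),
               "positive")
})

test_that("panel assembly tallies counts and splits on a time cut", {
  h <- generateHierarchy(1, 1, 2, seed = 1)
  cv <- simulateCovariates(h, 15, seed = 2)
  l3 <- l3Regions(h)
  raw <- data.frame(event_id = c("e1", "e2", "e3"),
                    year = cv$year[1], month = 5,
                    l3 = c(l3[2], l3[2], l3[1]), size_ha = c(500, 600, 700))
  cat <- filterEvents(raw)
  panel <- assemblePanel(cat, cv, h, splitMonth = 12)
  cnt <- panelCounts(panel)
  expect_equal(cnt[l3[2], "t5"], 2)
  expect_equal(cnt[l3[1], "t5"], 1)
  expect_equal(sum(cnt), 3)                       # conservation
  expect_equal(sum(panelSplit(panel) == "train"), 12)
  expect_equal(sum(panelSplit(panel) == "test"), 3)
  # split-cell arithmetic: S cells per train/test month
  fp <- flattenPanel(panel)
  expect_equal(sum(fp$split == "train"), 12 * 2)
  expect_equal(sum(fp$split == "test"), 3 * 2)
  # events in unknown regions or months are listed
  bad <- filterEvents(data.frame(event_id = "x", year = 1900, month = 1,
                                 l3 = l3[1], size_ha = 999))
  expect_error(assemblePanel(bad, cv, h, 12), "x")
})

test_that("panel assembly is idempotent through its own serialization", {
  sim <- fixtureSim
  path <- tempfile(fileext = ".csv")
  writePanel(sim$panel, path)
  back <- readPanel(path, sim$hierarchy)
  expect_equal(panelCounts(back), panelCounts(sim$panel))
  expect_equal(panelCovariate(back, "humidity"),
               panelCovariate(sim$panel, "humidity"), tolerance = 1e-12)
  expect_identical(panelSplit(back), panelSplit(sim$panel))
})

test_that("catalog, hierarchy and parameter serialization round-trips", {
  sim <- fixtureSim
  p1 <- tempfile(fileext = ".csv")
  writeFireCatalog(sim$catalog, p1)
  back <- readFireCatalog(p1)
  expect_equal(catalogEvents(back)$exceedance_ha,
               catalogEvents(sim$catalog)$exceedance_ha, tolerance = 1e-9)
  p2 <- tempfile(fileext = ".csv"); p3 <- tempfile(fileext = ".txt")
  writeHierarchy(sim$hierarchy, p2, p3)
  h2 <- readHierarchy(p2, p3)
  expect_identical(l3Regions(h2), l3Regions(sim$hierarchy))
  expect_equal(sort(paste(adjacencyEdges(h2)[, 1], adjacencyEdges(h2)[, 2])),
               sort(paste(adjacencyEdges(sim$hierarchy)[, 1],
                          adjacencyEdges(sim$hierarchy)[, 2])))
  p4 <- tempfile(fileext = ".json")
  writeTrueParameters(sim$truth, p4)
  t2 <- readTrueParameters(p4)
  expect_equal(t2@betaMu, sim$truth@betaMu)
  expect_equal(t2@aux, sim$truth@aux)
})
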