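test_that("age bands are contiguous, sorted, with correct midpoints", {
  g <- make_age_groups(30, 84)
  expect_equal(nrow(g), 11L)
  expect_equal(g$lower, seq(30, 80, by = 5))
  expect_equal(g$upper, g$lower + 4)
  expect_equal(g$midpoint, (g$lower + g$upper) / 2)
  expect_equal(g$index, 0:10)
  expect_error(make_age_groups(30, 83), "not divisible")

  expect_equal(age_group_index(c(30, 34, 35, 84), g), c(0L, 0L, 1L, 10L))
  expect_equal(age_group_index(c(29, 85), g), c(NA_integer_, NA_integer_))
  expect_equal(age_group_index(c("30-34", "80-84", "junk"), g),
               c(0L, 10L, NA_integer_))
})

test_that("incidence reader aggregates duplicate keys and validates columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,histology,area_id,year,age_group,count",
               "male,adenocarcinoma,A1,2000,30-34,2",
               "male,adenocarcinoma,A1,2000,30-34,3",
               "male,adenocarcinoma,A2,2000,30-34,1"), f)
  tab <- read_incidence(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$count[tab$area_id == "A1"], 5)

  # empty file with header is legal
  writeLines("sex,histology,area_id,year,age_group,count", f)
  expect_equal(nrow(read_incidence(f)), 0L)

  # missing required column is a fatal config error naming the column
  writeLines(c("sex,histology,area_id,year,age_group",
               "male,adenocarcinoma,A1,2000,30-34"), f)
  expect_error(read_incidence(f), "count")

  # negative count names the row
  writeLines(c("sex,histology,area_id,year,age_group,count",
               "male,adenocarcinoma,A1,2000,30-34,-2"), f)
  expect_error(read_incidence(f), "row")
})

test_that("morphology column is classified on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,morphology,area_id,year,age_group,count",
               "male,8140,A1,2000,30-34,2",
               "male,8070,A1,2000,30-34,3"), f)
  tab <- read_incidence(f)
  expect_setequal(tab$histology,
                  c("adenocarcinoma", "squamous cell carcinoma"))
})

test_that("incidence tables round-trip through CSV key-for-key", {
  tt <- tiny_tables()
  f <- withr::local_tempfile(fileext = ".csv")
  write_incidence(tt$incidence, f)
  again <- read_incidence(f)
  expect_equal(as.data.frame(again), as.data.frame(tt$incidence))

  g <- withr::local_tempfile(fileext = ".csv")
  write_person_years(tt$person_years, g)
  expect_equal(as.data.frame(read_person_years(g)),
               as.data.frame(tt$person_years))
})

test_that("person-years coverage of incidence keys is enforced", {
  tt <- tiny_tables()
  expect_true(check_coverage(tt$incidence, tt$person_years))
  short <- tt$person_years[tt$person_years$area_id != "A2", ]
  expect_error(check_coverage(tt$incidence, short), "A2")
})

test_that("histology classification matches canonical codes and is total", {
  expect_equal(classify_histology(8140), "adenocarcinoma")
  expect_equal(classify_histology(8070), "squamous cell carcinoma")
  expect_equal(classify_histology(8041), "small cell carcinoma")
  expect_equal(classify_histology(8012), "large cell carcinoma")
  expect_equal(classify_histology(9999),
               "other specified or unspecified carcinoma")
  expect_error(classify_histology("80x0"), "non-numeric")

  # totality: every 4-digit code maps to exactly one of the five labels
  labs <- classify_histology(8000:9999)
  expect_equal(length(labs), 2000L)
  expect_true(all(labs %in% c("adenocarcinoma", "squamous cell carcinoma",
                              "large cell carcinoma", "small cell carcinoma",
                              "other specified or unspecified carcinoma")))
})

test_that("histology map is overrideable from a YAML config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("my adeno:", "  - 8140-8141", "my squam:", "  - 8070"), f)
  m <- read_histology_map(f)
  expect_equal(classify_histology(8141, m), "my adeno")
  expect_equal(classify_histology(8070, m), "my squam")
  expect_equal(classify_histology(8050, m),
               "other specified or unspecified carcinoma")
  # overlapping code sets are rejected
  writeLines(c("a:", "  - 8140-8141", "b:", "  - 8141"), f)
  expect_error(read_histology_map(f), "disjoint")
})

test_that("topography filter matches by 3-character site prefix", {
  rec <- data.frame(topography = c("C34.1", "C16.0", "C33", "C34.9"),
                    count = 1:4)
  expect_message(kept <- filter_topography(rec, c("C33", "C34")), "dropped 1")
  expect_equal(kept$topography, c("C34.1", "C33", "C34.9"))
  expect_error(filter_topography(rec, character()), "empty topography filter")
  all_lung <- rec[rec$topography != "C16.0", ]
  expect_silent(out <- filter_topography(all_lung, c("C33", "C34")))
  expect_identical(out, all_lung)
})

test_that("area geometries round-trip through GeoJSON with centroids intact", {
  geom <- area_grid_geometry(3, 2)
  expect_equal(nrow(geom$areas), 6L)
  # unit squares: centroid at cell center
  expect_equal(geom$areas$cx[1], 0.5)
  expect_equal(geom$areas$cy[6], 1.5)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_area_geojson(geom, f)
  back <- read_area_geojson(f)
  expect_equal(back$areas, geom$areas)
  expect_equal(back$polygons[["A0001"]][, 1], geom$polygons[["A0001"]][, 1])
})
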