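test_that("ESRI ASCII grids round-trip and honor nodata semantics", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 3", "NROWS 3", "XLLCORNER 10", "YLLCORNER 20",
               "CELLSIZE 0.5", "NODATA_value -9999",
               "1 2 3", "4 -9999 6", "7 8 9.25"), p)
  g <- read_grid(p)
  expect_s3_class(g, "enm_grid")
  expect_equal(sum(g$mask), 1)
  expect_true(g$mask[2, 2])
  expect_equal(g$values[1, ], c(1, 2, 3))
  expect_equal(g$xll, 10)
  expect_equal(g$cellsize, 0.5)

  p2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, p2)
  g2 <- read_grid(p2)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$mask, g$mask)
  expect_equal(g2$xll, g$xll)

  # fractional values survive the 6-significant-digit writer
  g3 <- enm_grid(matrix(c(0.123456789, 1e-4, 123456.7, 0.5), 2, 2))
  p3 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g3, p3)
  expect_equal(read_grid(p3)$values, g3$values, tolerance = 1e-5)
})

test_that("malformed ASCII headers are rejected", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 0", "NODATA_value -9999", "1 2", "3 4"), p)
  expect_error(read_grid(p), "CELLSIZE")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 1", "NODATA_value -9999", "1 2 3 4 5"), p)
  expect_error(read_grid(p), "expected 4 values")
  expect_error(read_grid(file.path(tempdir(), "nope_missing.asc")),
               "no such file")
  expect_error(enm_grid(matrix(1, 2, 2), cellsize = 0), "cellsize")
})

test_that("XLLCENTER headers are converted to the corner convention", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCENTER 1", "YLLCENTER 1",
               "CELLSIZE 2", "NODATA_value -9999", "1 2", "3 4"), p)
  g <- read_grid(p)
  expect_equal(g$xll, 0)
  expect_equal(g$yll, 0)
})

test_that("occurrence CSVs are parsed with informative failures", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,longitude,latitude", "sp,1.5,2.5", "sp,3.5,4.5"), p)
  occ <- read_occurrences(p, "train")
  expect_equal(nrow(occ$records), 2)
  expect_equal(occ$role, "train")
  expect_equal(occ$records$longitude, c(1.5, 3.5))

  writeLines("species,longitude,latitude", p)
  expect_error(read_occurrences(p), "no occurrences")
  writeLines(c("species,lon,lat", "sp,1,2"), p)
  expect_error(read_occurrences(p), "missing column")
  writeLines(c("species,longitude,latitude", "sp,1,2", "sp,oops,4"), p)
  expect_error(read_occurrences(p), "row 2")
  writeLines(c("species,longitude,latitude", "sp,181.0,0"), p)
  expect_warning(read_occurrences(p), "bounds")
})

test_that("stacking enforces alignment and unions the masks", {
  a <- enm_grid(matrix(1, 4, 4))
  b <- enm_grid(matrix(2, 4, 4), mask = matrix(c(TRUE, rep(FALSE, 15)), 4, 4))
  s <- enm_stack(list(x = a, y = b))
  expect_equal(sum(s$mask), 1)
  expect_true(all(is.na(s$layers$x$values[s$mask])))
  expect_error(enm_stack(list(x = a, y = enm_grid(matrix(1, 3, 3)))),
               "not aligned")
  expect_error(enm_stack(list(x = a, y = enm_grid(matrix(1, 4, 4),
                                                  cellsize = 2))),
               "not aligned")
  expect_error(enm_stack(list(a, b)), "name")
})

test_that("extraction assigns points to containing cells, drops masked ones", {
  # 1x1 grid: any interior point returns its value
  g1 <- enm_grid(matrix(7), xll = 0, yll = 0, cellsize = 1)
  s1 <- enm_stack(list(v = g1))
  occ <- enm_occurrences("sp", 0.4, 0.6)
  expect_equal(unname(extract_values(s1, occ)[1, 1]), 7)

  s <- fixture_stack(8)
  occ2 <- enm_occurrences("sp", c(0.5, 3.5), c(7.5, 4.5))
  v <- extract_values(s, occ2)
  expect_equal(dim(v), c(2, 2))
  # cell centers map back onto the very cells they name
  expect_equal(unname(v[1, "env_a"]), s$layers$env_a$values[1, 1])
  expect_equal(unname(v[2, "env_a"]), s$layers$env_a$values[4, 4])

  sm <- fixture_stack(8, masked_cell = cbind(1, 1))
  occ3 <- enm_occurrences("sp", c(0.5, 3.5), c(7.5, 4.5))
  expect_warning(vm <- extract_values(sm, occ3), "masked")
  expect_equal(nrow(vm), 1)
  expect_equal(unname(attr(vm, "report")["masked"]), 1)
  occ4 <- enm_occurrences("sp", -5, -5)
  expect_error(extract_values(s, occ4), "off-grid|masked")
})

test_that("points on shared edges go to the east/south cell", {
  g <- enm_grid(matrix(1:16, 4, 4, byrow = TRUE), xll = 0, yll = 0,
                cellsize = 1)
  idx <- nichecal:::cell_index_from_xy(g, c(1, 1), c(3, 2.5))
  # x = 1 is the shared edge between columns 1 and 2 -> east cell (col 2)
  expect_equal(unname(idx[1, "col"]), 2L)
  # y = 3 is the shared edge between rows 1 and 2 (from top) -> south cell
  expect_equal(unname(idx[1, "row"]), 2L)
  expect_equal(unname(idx[2, "row"]), 2L)
})

test_that("extraction is independent of record order", {
  s <- fixture_stack(8)
  set.seed(3)
  lon <- runif(12, 0.1, 7.9)
  lat <- runif(12, 0.1, 7.9)
  v1 <- extract_values(s, enm_occurrences("sp", lon, lat))
  perm <- sample(12)
  v2 <- extract_values(s, enm_occurrences("sp", lon[perm], lat[perm]))
  expect_equal(v1[perm, ], v2, ignore_attr = TRUE)
})

test_that("layout validation catches missing pieces and mismatched scenarios", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "M_variables", "Set_1"), recursive = TRUE)
  write_grid(enm_grid(matrix(1:4, 2, 2)),
             file.path(root, "M_variables", "Set_1", "env_1.asc"))
  lay <- project_layout(root)
  expect_error(validate_layout(lay), "sp_joint")
  for (f in c("sp_joint.csv", "sp_train.csv", "sp_test.csv"))
    writeLines(c("species,longitude,latitude", "sp,0.5,0.5"),
               file.path(root, f))
  expect_silent(validate_layout(project_layout(root)))
  # scenario with wrong layer names fails
  dir.create(file.path(root, "G_variables", "Set_1", "future"),
             recursive = TRUE)
  write_grid(enm_grid(matrix(1:4, 2, 2)),
             file.path(root, "G_variables", "Set_1", "future", "other.asc"))
  expect_error(validate_layout(project_layout(root)), "does not match")
})
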