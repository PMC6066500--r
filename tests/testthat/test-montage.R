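test_that("hexagonal montage has centered-hexagonal lead counts", {
  expect_length(build_synthetic_montage(2)$lead_ids, 7)
  expect_length(build_synthetic_montage(5)$lead_ids, 61)   # 1 + 3*5*4
  for (r in c(3, 4, 7))
    expect_length(build_synthetic_montage(r)$lead_ids, 1 + 3 * r * (r - 1))
  expect_error(build_synthetic_montage(1), "n_rings")
})

test_that("montage neighbor counts: interior 6, edge fewer", {
  m <- build_synthetic_montage(3)
  deg <- rowSums(m$adjacency)
  rad <- sqrt(rowSums(m$positions^2))
  interior <- rad < 1.5                 # rings 0 and 1 of a 3-ring grid
  expect_true(all(deg[interior] == 6))
  expect_true(all(deg[!interior] < 6))
  expect_true(isSymmetric(m$adjacency))
  expect_true(all(!diag(m$adjacency)))
})

test_that("seed ROI is the center plus its six neighbors", {
  roi <- seed_roi_from_neighbors(hex5, "C3")
  expect_length(roi, 7)
  expect_identical(roi[1], "C3")
  expect_true(all(roi[-1] %in% montage_neighbors(hex5, "C3")))
  # an edge lead lacks six neighbors
  edge <- hex5$lead_ids[which(rowSums(hex5$adjacency) == 3)[1]]
  expect_error(seed_roi_from_neighbors(hex5, edge), "neighbors")
  expect_error(seed_roi_from_neighbors(hex5, "nope"), "not in montage")
})

test_that("equidistant surplus neighbors are tie-broken by label order", {
  # center with 7 neighbors, all at distance exactly 1
  ang <- 2 * pi * (0:6) / 7
  df <- data.frame(lead_id = c("CTR", paste0("N", 1:7)),
                   x = c(0, cos(ang)), y = c(0, sin(ang)))
  # ring spacing 2*sin(pi/7) ~ 0.87 is the minimum distance; factor 1.2
  # makes the seven unit-radius spokes adjacent too, all tied on distance
  m <- montage_from_positions(df, neighbor_factor = 1.2)
  roi <- seed_roi_from_neighbors(m, "CTR")
  # brute-force oracle: all 7 tie on distance, so the first 6 labels win
  expect_identical(roi, c("CTR", sort(paste0("N", 1:7))[1:6]))
})

test_that("ROI config loading validates leads and structure", {
  cfgfile <- withr::local_tempfile(fileext = ".json")
  write_roi_config(hex5_rois, cfgfile)
  rs <- load_roi_config(cfgfile, hex5)
  expect_s3_class(rs, "fpcoh_roiset")
  expect_length(rs$rois$iPAR, 21)
  expect_length(rs$rois$iM1, 7)
  expect_identical(rs$primary_pair, c("iM1", "iPAR"))
  expect_length(rs$control_pairs, 6)

  bad <- list(rois = list(iM1 = c("C3", "ZZ9"), iPAR = c("E010")),
              primary_pair = c("iM1", "iPAR"))
  jsonlite::write_json(bad, cfgfile, auto_unbox = FALSE)
  expect_error(load_roi_config(cfgfile, hex5), "ZZ9")

  bad$rois$iM1 <- character(0)
  jsonlite::write_json(bad, cfgfile, auto_unbox = FALSE)
  expect_error(load_roi_config(cfgfile, hex5), "empty ROI")

  bad$rois <- list(iPAR = c("E010"))
  jsonlite::write_json(bad, cfgfile, auto_unbox = FALSE)
  expect_error(load_roi_config(cfgfile, hex5), "iM1")
})

test_that("a lead may sit in two ROIs but not twice in one", {
  rois <- hex5_rois$rois
  rois$extra <- c(rois$iM1[1], rois$iPAR[1])      # overlap across ROIs: fine
  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(rois = rois, primary_pair = c("iM1", "iPAR")),
                       cfgfile, auto_unbox = FALSE)
  expect_no_error(load_roi_config(cfgfile, hex5))
  rois$extra <- c("C3", "C3")                     # duplicate within one ROI
  jsonlite::write_json(list(rois = rois, primary_pair = c("iM1", "iPAR")),
                       cfgfile, auto_unbox = FALSE)
  expect_error(load_roi_config(cfgfile, hex5), "twice")
})

test_that("the shipped default configuration loads against its montage", {
  mfile <- system.file("extdata", "montage_hex61.csv", package = "fpcoh")
  rfile <- system.file("extdata", "roi_default_hex61.json", package = "fpcoh")
  m <- read_montage_csv(mfile, neighbor_factor = 1.001)
  rs <- load_roi_config(rfile, m)
  expect_length(rs$rois$iM1, 7)
  expect_length(rs$rois$iPAR, 21)
  expect_setequal(names(rs$rois),
                  c("iM1", "iPAR", "cM1", "cPAR", "iPMd", "iPf", "iMedPr",
                    "iV1"))
})

test_that("montage CSV round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_montage_csv(hex5, f)
  m2 <- read_montage_csv(f, neighbor_factor = 1.001)
  expect_identical(m2$lead_ids, hex5$lead_ids)
  expect_equal(unname(m2$positions), unname(hex5$positions),
               tolerance = 1e-12)
  expect_identical(m2$adjacency, hex5$adjacency)
})
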