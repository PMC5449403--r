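test_that("survey CSV round-trips exactly, including on generated data", {
  # minimal hand-written pair
  sv <- tempfile(fileext = ".csv"); ly <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,transect_id,species,count,cover_pct",
               "p1,T1,Stipa sp.,3,12.5",
               "p1,T1,Allium sp.,1,2.0",
               "p2,T1,Stipa sp.,5,20.0"), sv)
  writeLines(c("transect_id,zone,distance_m,n_plots",
               "T1,distance,10,2"), ly)
  x <- readCommunityCSV(sv, ly)
  expect_s4_class(x, "CommunityDataset")
  expect_equal(dim(x), c(2L, 2L))
  expect_equal(speciesNames(x), c("Stipa sp.", "Allium sp."))
  expect_equal(unname(plotCounts(x)["Stipa sp.", ]), c(3L, 5L))

  # write(read(x)) == x on synthetic surveys
  for (seed in c(1, 7)) {
    x <- generateSurvey(syntheticConfig("s1_like"), seed = seed)
    s2 <- tempfile(fileext = ".csv"); l2 <- tempfile(fileext = ".csv")
    writeCommunityCSV(x, s2, l2)
    y <- readCommunityCSV(s2, l2)
    # long format fixes the registry to first-appearance order; data are
    # preserved exactly up to that row order
    expect_setequal(speciesNames(y), speciesNames(x))
    expect_equal(plotCounts(y)[speciesNames(x), ], plotCounts(x))
    expect_equal(plotCovers(y)[speciesNames(x), ], plotCovers(x),
                 tolerance = 1e-12)
    expect_equal(transectLayout(y), transectLayout(x))
    expect_equal(SummarizedExperiment::colData(y)$total_cover,
                 SummarizedExperiment::colData(x)$total_cover,
                 tolerance = 1e-12)
  }
})

test_that("malformed surveys are rejected with informative errors", {
  sv <- tempfile(fileext = ".csv"); ly <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,transect_id,species,count,cover_pct",
               "p1,T9,Stipa sp.,3,12.5"), sv)
  writeLines(c("transect_id,zone,distance_m,n_plots",
               "T1,distance,10,1"), ly)
  expect_error(readCommunityCSV(sv, ly), "T9")

  writeLines(c("plot_id,transect_id,count,cover_pct",
               "p1,T1,3,12.5"), sv)
  expect_error(readCommunityCSV(sv, ly), "species")

  writeLines(c("plot_id,transect_id,species,count,cover_pct",
               "p1,T1,Stipa sp.,-3,12.5"), sv)
  expect_error(readCommunityCSV(sv, ly), "negative")

  # cover-only records are rejected unless explicitly allowed
  writeLines(c("plot_id,transect_id,species,count,cover_pct",
               "p1,T1,Stipa sp.,0,12.5"), sv)
  expect_error(readCommunityCSV(sv, ly), "cover but zero stalks")
  expect_s4_class(readCommunityCSV(sv, ly, allowCoverOnly = TRUE),
                  "CommunityDataset")
})

test_that("survey-design builders match the published transect counts", {
  s1 <- buildDesign("S1")
  expect_equal(nrow(s1), 13L)
  expect_equal(sum(s1$n_plots), 78L)
  expect_true(all(s1$n_plots == 6L))
  expect_equal(sum(s1$zone == "pipeline_area"), 3L)
  expect_equal(sum(s1$zone == "inter_pipeline"), 2L)
  expect_equal(s1$distance_m[s1$zone == "distance"],
               c(10, 30, 50, 100, 300, 500, 800, 1000))

  s2 <- buildDesign("S2")
  expect_equal(nrow(s2), 9L)
  expect_equal(sum(s2$n_plots), 54L)
  expect_true(all(s2$n_plots == 6L))

  ck <- buildDesign("S1", control = TRUE)
  expect_equal(ck$zone[nrow(ck)], "control")
  expect_equal(ck$distance_m[nrow(ck)], 2000)
  expect_error(buildDesign("S9"))
})

test_that("species filtering matches a brute-force occurrence tally", {
  x <- generateSurvey(syntheticConfig("s1_like"), seed = 11)
  expect_equal(filterSpecies(x), x)  # identity case

  # dropping one species removes it everywhere
  drop1 <- filterSpecies(x, exclude = speciesNames(x)[1])
  expect_false(speciesNames(x)[1] %in% speciesNames(drop1))
  expect_equal(nrow(drop1), nrow(x) - 1L)

  for (minOcc in c(5, 20, 50)) {
    kept <- filterSpecies(x, minPlotOccurrence = minOcc)
    occ <- apply(plotCounts(x), 1, function(v) sum(v > 0))  # brute force
    expect_setequal(speciesNames(kept), names(occ)[occ >= minOcc])
  }
  expect_error(filterSpecies(x, exclude = speciesNames(x)), "every species")
})

test_that("dataset invariants are enforced by the validity method", {
  x <- makeTinyDataset()
  expect_s4_class(x, "CommunityDataset")
  # plot count must match the layout
  expect_error(
    CommunityDataset(plotCounts(x), plotCovers(x),
                     data.frame(plot_id = c("p1", "p2"),
                                transect_id = "T1",
                                total_cover = c(40, 20)),
                     data.frame(transect_id = "T1", zone = "distance",
                                distance_m = 10, n_plots = 3)),
    "plot")
  # species covers may not sum above the recorded plot total
  expect_error(
    CommunityDataset(plotCounts(x), plotCovers(x) * 3,
                     data.frame(plot_id = c("p1", "p2"),
                                transect_id = "T1",
                                total_cover = c(40, 20)),
                     data.frame(transect_id = "T1", zone = "distance",
                                distance_m = 10, n_plots = 2)),
    "total_cover")
})
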