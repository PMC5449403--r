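#' Construct a CommunityDataset
#'
#' Binds plot-level stalk counts and percent covers to a transect layout and
#' validates the survey invariants (see [CommunityDataset-class]).
#'
#' @param counts species x plots matrix of non-negative integer stalk counts
#'   per 2 x 2 m plot; rownames are species, colnames are plot ids.
#' @param cover species x plots matrix of percent cover (0--100 scale), same
#'   dimnames as `counts`.
#' @param plotData data.frame with one row per plot: `plot_id`, `transect_id`,
#'   `total_cover` (visually estimated total percent cover of the plot).
#' @param layout transect layout data.frame:
#'   `transect_id, zone, distance_m, n_plots`. Zones are `pipeline_area`,
#'   `inter_pipeline`, `distance` or `control`.
#' @param allowCoverOnly keep species recorded with cover but zero stalks
#'   (count stays 0)? By default such records are rejected.
#' @param coverSlack rounding slack (percent) allowed when checking that
#'   species covers do not sum above the plot total.
#' @return a validated [CommunityDataset-class]
#' @seealso [readCommunityCSV()] for file input, [generateSurvey()] for
#'   simulated surveys
#' @export
CommunityDataset <- function(counts, cover, plotData, layout,
                             allowCoverOnly = FALSE, coverSlack = 0.5) {
  counts <- as.matrix(counts); cover <- as.matrix(cover)
  if (!identical(dim(counts), dim(cover)))
    .stopf("counts and cover must have identical dimensions")
  if (!allowCoverOnly && any(cover > 0 & counts == 0)) {
    bad <- which(cover > 0 & counts == 0, arr.ind = TRUE)[1, ]
    .stopf(paste0("species '%s' in plot '%s' has cover but zero stalks; ",
                  "set allowCoverOnly = TRUE to keep such records"),
           rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  layout <- as.data.frame(layout)
  msg <- .checkLayout(layout)
  if (!is.null(msg)) .stopf("invalid layout: %s", msg)
  plotData <- as.data.frame(plotData)
  se <- SummarizedExperiment(
    assays = list(counts = counts, cover = cover),
    colData = DataFrame(plotData, row.names = plotData$plot_id))
  metadata(se)$layout <- layout
  metadata(se)$cover_slack <- coverSlack
  obj <- methods::new("CommunityDataset", se)
  methods::validObject(obj)
  obj
}

#' @describeIn CommunityDataset species registry, in first-appearance order
#' @param x a CommunityDataset
#' @export
setMethod("speciesNames", "CommunityDataset", function(x) rownames(x))

#' @rdname transectLayout
#' @export
setMethod("transectLayout", "CommunityDataset",
          function(x) metadata(x)$layout)

#' @rdname plotCounts
#' @export
setMethod("plotCounts", "CommunityDataset", function(x) assay(x, "counts"))

#' @rdname plotCovers
#' @export
setMethod("plotCovers", "CommunityDataset", function(x) assay(x, "cover"))

setMethod("show", "CommunityDataset", function(object) {
  lay <- transectLayout(object)
  cat(sprintf("CommunityDataset: %d species, %d plots, %d transects\n",
              nrow(object), ncol(object), nrow(lay)))
  cat(sprintf("  zones: %s\n",
              paste(sprintf("%s (%d)", names(table(lay$zone)), table(lay$zone)),
                    collapse = ", ")))
})

#' Read a belt-transect survey from CSV
#'
#' The survey file is long format with one row per (plot, species):
#' `plot_id,transect_id,species,count,cover_pct`. The layout file has one row
#' per belt transect: `transect_id,zone,distance_m,n_plots`. Per-plot total
#' cover is taken from an optional `total_cover_pct` column (constant within a
#' plot); when absent it defaults to the sum of the plot's species covers.
#'
#' @param surveyPath path to the long-format survey CSV
#' @param layoutPath path to the transect layout CSV
#' @param allowCoverOnly,coverSlack passed to [CommunityDataset()]
#' @return a [CommunityDataset-class]
#' @export
readCommunityCSV <- function(surveyPath, layoutPath, allowCoverOnly = FALSE,
                             coverSlack = 0.5) {
  if (!file.exists(surveyPath)) .stopf("survey file not found: %s", surveyPath)
  if (!file.exists(layoutPath)) .stopf("layout file not found: %s", layoutPath)
  sv <- utils::read.csv(surveyPath, check.names = FALSE,
                        stringsAsFactors = FALSE)
  lay <- utils::read.csv(layoutPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("plot_id", "transect_id", "species", "count", "cover_pct")
  miss <- setdiff(need, colnames(sv))
  if (length(miss))
    .stopf("survey file is missing column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(c("transect_id", "zone", "distance_m", "n_plots"),
                  colnames(lay))
  if (length(miss))
    .stopf("layout file is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(sv$count < 0)) .stopf("negative count in survey file")
  if (any(sv$cover_pct < 0)) .stopf("negative cover in survey file")
  sv$species <- trimws(gsub("[[:space:]]+", " ", sv$species))
  species <- unique(sv$species)          # first-appearance order
  plots <- unique(sv$plot_id)
  counts <- matrix(0L, length(species), length(plots),
                   dimnames = list(species, plots))
  cover <- matrix(0, length(species), length(plots),
                  dimnames = list(species, plots))
  i <- cbind(match(sv$species, species), match(sv$plot_id, plots))
  counts[i] <- as.integer(sv$count)
  cover[i] <- sv$cover_pct
  tr <- sv$transect_id[match(plots, sv$plot_id)]
  bad <- setdiff(tr, lay$transect_id)
  if (length(bad))
    .stopf("survey references transect(s) absent from layout: %s",
           paste(unique(bad), collapse = ", "))
  total <- if ("total_cover_pct" %in% colnames(sv))
    sv$total_cover_pct[match(plots, sv$plot_id)] else colSums(cover)
  CommunityDataset(counts, cover,
                   data.frame(plot_id = plots, transect_id = tr,
                              total_cover = total),
                   lay, allowCoverOnly = allowCoverOnly,
                   coverSlack = coverSlack)
}

#' Write a CommunityDataset back to survey + layout CSV
#'
#' Inverse of [readCommunityCSV()]: emits the long-format survey file (rows
#' for species with a positive count or cover in a plot) and the layout file.
#'
#' @param x a [CommunityDataset-class]
#' @param surveyPath,layoutPath output paths
#' @return invisibly, the survey data.frame written
#' @export
writeCommunityCSV <- function(x, surveyPath, layoutPath) {
  cnt <- plotCounts(x); cov <- plotCovers(x)
  keep <- which(cnt > 0 | cov > 0, arr.ind = TRUE)
  keep <- keep[order(keep[, 2], keep[, 1]), , drop = FALSE]
  cd <- colData(x)
  sv <- data.frame(
    plot_id = colnames(x)[keep[, 2]],
    transect_id = cd$transect_id[keep[, 2]],
    species = rownames(x)[keep[, 1]],
    count = cnt[keep],
    cover_pct = cov[keep],
    total_cover_pct = cd$total_cover[keep[, 2]])
  utils::write.csv(sv, surveyPath, row.names = FALSE)
  utils::write.csv(transectLayout(x), layoutPath, row.names = FALSE)
  invisible(sv)
}

#' Build a standard belt-transect survey design
#'
#' `"S1"` is the three-pipeline corridor design: 3 pipeline-area transects
#' (I, Oil, II), 2 inter-pipeline transects (I-O, O-II) and 8 distance
#' transects at 10, 30, 50, 100, 300, 500, 800 and 1000 m from the outermost
#' pipeline edge -- 13 transects, 78 plots. `"S2"` is the single-pipeline
#' design: 1 pipeline-area transect plus the same 8 distance transects -- 9
#' transects, 54 plots. Every transect holds 6 plots of 2 x 2 m; an optional
#' far-field control (CK) at 2000 m can be appended.
#'
#' @param preset `"S1"` or `"S2"`
#' @param control append a control transect (zone `"control"`, 2000 m)?
#' @return layout data.frame (`transect_id, zone, distance_m, n_plots`)
#' @examples
#' nrow(buildDesign("S1"))        # 13
#' sum(buildDesign("S2")$n_plots) # 54
#' @export
buildDesign <- function(preset = c("S1", "S2"), control = FALSE) {
  preset <- match.arg(preset)
  dist <- c(10, 30, 50, 100, 300, 500, 800, 1000)
  if (preset == "S1") {
    lay <- data.frame(
      transect_id = c("I", "I-O", "Oil", "O-II", "II", paste0(dist, "m")),
      zone = c("pipeline_area", "inter_pipeline", "pipeline_area",
               "inter_pipeline", "pipeline_area", rep("distance", 8)),
      distance_m = c(rep(0, 5), dist))
  } else {
    lay <- data.frame(
      transect_id = c("II", paste0(dist, "m")),
      zone = c("pipeline_area", rep("distance", 8)),
      distance_m = c(0, dist))
  }
  if (control)
    lay <- rbind(lay, data.frame(transect_id = "CK", zone = "control",
                                 distance_m = 2000))
  lay$n_plots <- 6L
  lay
}

#' Filter species from a survey
#'
#' Removes named species (e.g. a sparse large-crown shrub that would skew
#' importance values) and "accidental" species occurring in fewer than
#' `minPlotOccurrence` plots; the registry and all plot records are updated
#' consistently.
#'
#' @param x a [CommunityDataset-class]
#' @param exclude character vector of species names to drop
#' @param minPlotOccurrence drop species present (count > 0) in fewer than
#'   this many plots; 0 keeps everything
#' @return the filtered [CommunityDataset-class]
#' @export
filterSpecies <- function(x, exclude = character(), minPlotOccurrence = 0) {
  if (minPlotOccurrence < 0) .stopf("minPlotOccurrence must be >= 0")
  occ <- rowSums(plotCounts(x) > 0)
  keep <- !(rownames(x) %in% exclude) & occ >= minPlotOccurrence
  if (!any(keep)) .stopf("filter would remove every species")
  cd <- colData(x)
  CommunityDataset(plotCounts(x)[keep, , drop = FALSE],
                   plotCovers(x)[keep, , drop = FALSE],
                   data.frame(plot_id = cd$plot_id,
                              transect_id = cd$transect_id,
                              total_cover = cd$total_cover),
                   transectLayout(x),
                   allowCoverOnly = TRUE,
                   coverSlack = metadata(x)$cover_slack %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The published 8-species x 13-transect importance-value table
#'
#' Returns the importance values of the eight desert-steppe species recorded
#' across the three-pipeline (S1-type) belt-transect survey, exactly as
#' printed, as an [IVTable-class] (assay `"IV"` only -- the Rd/Rf/Rc
#' components were not published). Transects are ordered I, I-O, Oil, O-II,
#' II, then 10 m ... 1000 m. `metadata(x)$members` carries the published
#' three-cluster species classification and `metadata(x)$printedIIV` the
#' published cluster x transect integrated importance values (3-decimal,
#' half-up rounded).
#'
#' @return an [IVTable-class]
#' @examples
#' fx <- table1Fixture()
#' ivMatrix(fx)["Phragmites australis", "I"]  # 0.622
#' @export
table1Fixture <- function() {
  ext <- system.file("extdata", package = "ecoextent")
  iv <- utils::read.csv(file.path(ext, "table1_iv.csv"), check.names = FALSE)
  lay <- utils::read.csv(file.path(ext, "table1_layout.csv"),
                         check.names = FALSE)
  m <- as.matrix(iv[, lay$transect_id])
  rownames(m) <- iv$species
  members <- split(iv$species, iv$cluster)
  iivRaw <- utils::read.csv(file.path(ext, "table1_iiv.csv"),
                            check.names = FALSE)
  printed <- as.matrix(iivRaw[, lay$transect_id])
  rownames(printed) <- iivRaw$cluster
  se <- SummarizedExperiment(
    assays = list(IV = m),
    colData = DataFrame(lay, row.names = lay$transect_id))
  metadata(se)$members <- members
  metadata(se)$printedIIV <- printed
  methods::new("IVTable", se)
}
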