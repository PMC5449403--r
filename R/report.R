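#' End-to-end effect-extent report
#'
#' Runs the full pipeline -- validate, importance values, TWINSPAN species
#' classification, integrated importance values, response-group assignment,
#' K-point extent estimation, and community indices -- on one of three
#' inputs: a [CommunityDataset-class], a pair of survey/layout CSV paths, or
#' the packaged published IV table (`fixture = "table1"`, which skips the
#' survey-level stages and classifies the printed IVs directly). All
#' parameters are echoed into the report for provenance. When a stage cannot
#' proceed for a scientific reason (e.g. an undisturbed community yields no
#' indicator group), the report records the condition instead of failing.
#'
#' @param dataset a [CommunityDataset-class] (optional)
#' @param surveyPath,layoutPath CSV inputs (optional alternative)
#' @param fixture `"table1"` to analyse the packaged published IV table
#' @param excludeSpecies,minPlotOccurrence species filter, see
#'   [filterSpecies()]
#' @param nClusters,cutLevels TWINSPAN parameters, see [modifiedTwinspan()]
#' @param groupParams named list overriding [assignGroups()] defaults
#' @param farWindow,tolerance K-point parameters, see [effectExtent()]
#' @param outDir when given, writes `report.json` plus `iv.csv`, `iiv.csv`,
#'   `partition.csv` and `diversity.csv` there
#' @return the report, an invisible list
#' @examples
#' rep <- runReport(fixture = "table1")
#' rep$extent$K2
#' @export
runReport <- function(dataset = NULL, surveyPath = NULL, layoutPath = NULL,
                      fixture = NULL, excludeSpecies = character(),
                      minPlotOccurrence = 0, nClusters = 3,
                      cutLevels = c(0, 0.02, 0.05, 0.10, 0.20),
                      groupParams = list(), farWindow = 3, tolerance = 0.15,
                      outDir = NULL) {
  report <- list(
    tool = "ecoextent",
    version = as.character(utils::packageVersion("ecoextent")),
    parameters = list(nClusters = nClusters, cutLevels = cutLevels,
                      groupParams = groupParams, farWindow = farWindow,
                      tolerance = tolerance,
                      excludeSpecies = excludeSpecies,
                      minPlotOccurrence = minPlotOccurrence),
    warnings = character())
  note <- function(msg) report$warnings <<- c(report$warnings, msg)

  diversity <- NULL
  if (!is.null(fixture)) {
    if (!identical(fixture, "table1")) .stopf("unknown fixture '%s'", fixture)
    iv <- table1Fixture()
    report$input <- "table1 fixture"
  } else {
    if (is.null(dataset)) {
      if (is.null(surveyPath) || is.null(layoutPath))
        .stopf("provide a dataset, CSV paths, or a fixture")
      dataset <- readCommunityCSV(surveyPath, layoutPath)
    }
    methods::validObject(dataset)
    if (length(excludeSpecies) || minPlotOccurrence > 0)
      dataset <- filterSpecies(dataset, exclude = excludeSpecies,
                               minPlotOccurrence = minPlotOccurrence)
    iv <- importanceValues(dataset)
    diversity <- diversityIndices(dataset)
    report$input <- sprintf("%d species x %d plots", nrow(dataset),
                            ncol(dataset))
  }

  clustering <- withCallingHandlers(
    modifiedTwinspan(ivMatrix(iv), nClusters = nClusters,
                     cutLevels = cutLevels),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  iiv <- integratedIV(iv, clustering)
  groups <- do.call(assignGroups, c(list(iiv), groupParams))
  report$clusters <- clusterMembers(clustering)
  report$groups <- as.list(groupOf(groups))
  report$diagnostics <- groups@diagnostics
  report$iiv <- as.data.frame(iivMatrix(iiv))

  if ("G2" %in% groupOf(groups)) {
    ext <- effectExtent(iiv, groups, farWindow = farWindow,
                        tolerance = tolerance)
    report$extent <- list(K1 = ext@K1, K2 = ext@K2, K3 = ext@K3,
                          dominance = ext@dominance)
    for (w in ext@warnings) note(w)
  } else {
    report$extent <- NULL
    note("no indicator group: no cluster qualifies as G2; extent undefined")
  }
  if (!is.null(diversity)) report$diversity <- diversity

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeIVTable(iv, file.path(outDir, "iv.csv"))
    writeIVTable(iiv, file.path(outDir, "iiv.csv"))
    utils::write.csv(data.frame(species = names(clustering@partition),
                                cluster = unname(clustering@partition)),
                     file.path(outDir, "partition.csv"), row.names = FALSE)
    if (!is.null(diversity))
      utils::write.csv(diversity, file.path(outDir, "diversity.csv"),
                       row.names = FALSE)
  }
  invisible(report)
}
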