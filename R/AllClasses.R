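#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   colData rowData
NULL

.ZONES <- c("pipeline_area", "inter_pipeline", "distance", "control")

.checkLayout <- function(layout) {
  need <- c("transect_id", "zone", "distance_m", "n_plots")
  miss <- setdiff(need, colnames(layout))
  if (length(miss))
    return(sprintf("layout is missing column(s): %s", paste(miss, collapse = ", ")))
  if (!all(layout$zone %in% .ZONES))
    return(sprintf("unknown zone(s): %s",
                   paste(setdiff(layout$zone, .ZONES), collapse = ", ")))
  if (anyDuplicated(layout$transect_id))
    return("duplicated transect_id in layout")
  if (any(layout$distance_m < 0)) return("distance_m must be >= 0")
  if (any(layout$n_plots < 1)) return("n_plots must be positive")
  d <- layout$distance_m[layout$zone == "distance"]
  if (length(d) && (any(d <= 0) || any(duplicated(d))))
    return("distance-zone transects need strictly positive, distinct distances")
  NULL
}

#' CommunityDataset: plot-level belt-transect survey
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a vegetation survey:
#' rows are species (in first-appearance order), columns are 2 x 2 m sampling
#' plots. Assay `"counts"` holds per-plot stalk counts, assay `"cover"` holds
#' per-plot percent cover on the 0--100 scale. `colData` carries `plot_id`,
#' `transect_id` and the visually estimated `total_cover` of each plot;
#' `metadata(x)$layout` is the transect layout table
#' (`transect_id, zone, distance_m, n_plots`).
#'
#' @section Invariants:
#' counts are non-negative integers; covers lie in \[0, 100\]; per plot, the
#' sum of species covers may not exceed `total_cover` plus a small rounding
#' slack (canopy overlap is not modelled); every plot's transect exists in the
#' layout and each transect holds exactly its `n_plots` plots.
#'
#' @seealso [CommunityDataset()], [readCommunityCSV()], [generateSurvey()]
#' @export
setClass("CommunityDataset", contains = "SummarizedExperiment")

setValidity("CommunityDataset", function(object) {
  a <- assays(object)
  if (!all(c("counts", "cover") %in% names(a)))
    return("assays 'counts' and 'cover' are required")
  cnt <- a$counts; cov <- a$cover
  if (any(cnt < 0)) return("negative stalk counts")
  if (any(cnt != round(cnt))) return("stalk counts must be integers")
  if (any(cov < 0) || any(cov > 100)) return("species covers must lie in [0, 100]")
  cd <- colData(object)
  need <- c("plot_id", "transect_id", "total_cover")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData is missing: %s", paste(miss, collapse = ", ")))
  layout <- metadata(object)$layout
  if (is.null(layout)) return("metadata(x)$layout is required")
  msg <- .checkLayout(layout)
  if (!is.null(msg)) return(msg)
  bad <- setdiff(cd$transect_id, layout$transect_id)
  if (length(bad))
    return(sprintf("plot(s) reference unknown transect(s): %s",
                   paste(unique(bad), collapse = ", ")))
  tab <- table(factor(cd$transect_id, levels = layout$transect_id))
  off <- which(as.integer(tab) != layout$n_plots)
  if (length(off))
    return(sprintf("transect %s has %d plot(s), layout says %d",
                   layout$transect_id[off[1]], as.integer(tab)[off[1]],
                   layout$n_plots[off[1]]))
  slack <- metadata(object)$cover_slack
  if (is.null(slack)) slack <- 0.5
  over <- colSums(cov) > cd$total_cover + slack
  if (any(over))
    return(sprintf("plot %s: species covers sum above total_cover (+%g slack)",
                   cd$plot_id[which(over)[1]], slack))
  TRUE
})

#' IVTable: species x transect importance values
#'
#' A [SummarizedExperiment::SummarizedExperiment] with species as rows and
#' belt transects as columns. Assay `"IV"` is always present; tables computed
#' by [importanceValues()] also carry `"Rd"` (relative density), `"Rf"`
#' (relative frequency) and `"Rc"` (relative cover), with
#' `IV = (Rd + Rf + Rc) / 3` elementwise. `colData` holds the transect layout
#' columns (`zone`, `distance_m`, `n_plots`).
#'
#' @seealso [importanceValues()], [table1Fixture()]
#' @export
setClass("IVTable", contains = "SummarizedExperiment")

setValidity("IVTable", function(object) {
  a <- assays(object)
  if (!("IV" %in% names(a))) return("assay 'IV' is required")
  iv <- a$IV
  if (any(iv < -1e-9) || any(iv > 1 + 1e-9)) return("IV values must lie in [0, 1]")
  if (all(c("Rd", "Rf", "Rc") %in% names(a))) {
    recon <- (a$Rd + a$Rf + a$Rc) / 3
    if (max(abs(recon - iv)) > 1e-9)
      return("IV must equal (Rd + Rf + Rc) / 3")
  }
  cd <- colData(object)
  miss <- setdiff(c("zone", "distance_m"), colnames(cd))
  if (length(miss))
    return(sprintf("colData is missing: %s", paste(miss, collapse = ", ")))
  TRUE
})

#' IIVTable: cluster x transect integrated importance values
#'
#' A [SummarizedExperiment::SummarizedExperiment] with species clusters as
#' rows and belt transects as columns; assay `"IIV"` holds the integrated
#' importance value of each cluster, i.e. the arithmetic mean of the member
#' species' importance values (zeros included for members absent from a
#' transect). `metadata(x)$members` is the named list of member species.
#'
#' @seealso [integratedIV()], [groupIIV()]
#' @export
setClass("IIVTable", contains = "SummarizedExperiment")

setValidity("IIVTable", function(object) {
  if (!("IIV" %in% assayNames(object))) return("assay 'IIV' is required")
  v <- assay(object, "IIV")
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) return("IIV values must lie in [0, 1]")
  mem <- metadata(object)$members
  if (is.null(mem)) return("metadata(x)$members is required")
  if (!setequal(names(mem), rownames(object)))
    return("metadata(x)$members must name every cluster row")
  if (any(lengths(mem) == 0)) return("empty cluster")
  miss <- setdiff(c("zone", "distance_m"), colnames(colData(object)))
  if (length(miss))
    return(sprintf("colData is missing: %s", paste(miss, collapse = ", ")))
  TRUE
})

#' SpeciesClustering: divisive TWINSPAN dendrogram and flat partition
#'
#' Result of [modifiedTwinspan()]. `partition` maps each classified species to
#' a terminal cluster label; `divisions` records every dichotomy in the order
#' it was made (parent members, the two sides, correspondence-analysis
#' eigenvalue, parent heterogeneity, indicator pseudospecies); `labels` lists
#' terminal cluster labels in dendrogram (leaf) order.
#'
#' @slot partition named character; species -> cluster label.
#' @slot labels character; terminal cluster labels in dendrogram order.
#' @slot divisions list of division records.
#' @slot params list; parameters the clustering was run with.
#' @export
setClass("SpeciesClustering",
         representation(partition = "character", labels = "character",
                        divisions = "list", params = "list"))

setValidity("SpeciesClustering", function(object) {
  if (!length(object@partition)) return("empty partition")
  if (is.null(names(object@partition))) return("partition must be named by species")
  if (!setequal(unique(object@partition), object@labels))
    return("labels must list exactly the clusters used in the partition")
  TRUE
})

#' GroupAssignment: clusters mapped to response groups G1/G2/G3
#'
#' Result of [assignGroups()]. G1 holds disturbance-promoted clusters
#' (dominant near the corridor, declining outward), G2 the suppressed original
#' dominants (the indicator group), G3 everything else. `diagnostics` records
#' the near-zone mean IIV, far-zone mean IIV and outward trend statistic each
#' decision was based on.
#'
#' @slot assignment named character; cluster -> "G1"/"G2"/"G3".
#' @slot diagnostics data.frame of per-cluster decision statistics.
#' @slot params list of thresholds used.
#' @export
setClass("GroupAssignment",
         representation(assignment = "character", diagnostics = "data.frame",
                        params = "list"))

setValidity("GroupAssignment", function(object) {
  if (!length(object@assignment)) return("empty assignment")
  if (!all(object@assignment %in% c("G1", "G2", "G3")))
    return("groups must be G1, G2 or G3")
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    return("every cluster must be assigned exactly once")
  TRUE
})

#' ExtentEstimate: K-point summary of the effect extent
#'
#' Result of [effectExtent()]. `K1` and `K2` are the distances (m) at which
#' the summed G1 and G2 group trajectories stabilise around their far-field
#' reference (`K2` is the headline effect extent); `K3` is the half-open
#' distance interval (last G1-dominant transect, first G2-dominant transect]
#' bracketing the dominance crossover, i.e. the edge-effect transition zone.
#' Unresolved quantities are `NA` with an explanatory entry in `warnings`.
#'
#' @slot K1 numeric; stabilisation distance of the G1 group (m), NA if unresolved.
#' @slot K2 numeric; stabilisation distance of the G2 group (m), NA if unresolved.
#' @slot K3 numeric length 2; crossover interval `c(lower, upper)` in m.
#' @slot dominance character; dominance pattern when no crossover exists.
#' @slot params list; parameters (far window, tolerance, thresholds) used.
#' @slot warnings character; notes and warnings accumulated.
#' @export
setClass("ExtentEstimate",
         representation(K1 = "numeric", K2 = "numeric", K3 = "numeric",
                        dominance = "character", params = "list",
                        warnings = "character"))

#' SyntheticConfig: parameters of the synthetic survey generator
#'
#' Bundles a survey design (transect layout), a list of species archetypes
#' (see [speciesArchetype()]), the true effect extent `effectExtent` (m, the
#' ground truth for parameter-recovery experiments; NA for the undisturbed
#' null scenario) and the negative-binomial count dispersion.
#'
#' @slot design data.frame; transect layout.
#' @slot archetypes list of species archetypes.
#' @slot effectExtent numeric; true extent in metres (NA for null).
#' @slot dispersion numeric; NB dispersion (0 gives Poisson counts).
#' @slot preset character; preset name, or "custom".
#' @export
setClass("SyntheticConfig",
         representation(design = "data.frame", archetypes = "list",
                        effectExtent = "numeric", dispersion = "numeric",
                        preset = "character"))

setValidity("SyntheticConfig", function(object) {
  msg <- .checkLayout(object@design)
  if (!is.null(msg)) return(msg)
  if (!length(object@archetypes)) return("empty archetype list")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  TRUE
})
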