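#' Species names of a dataset or table
#' @param x a CommunityDataset or IVTable
#' @return character vector of species names in registry order
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Transect layout of an object
#' @param x an object carrying a transect layout
#' @return data.frame with columns `transect_id, zone, distance_m, n_plots`
#' @export
setGeneric("transectLayout", function(x) standardGeneric("transectLayout"))

#' Stalk-count matrix (species x plots)
#' @param x a CommunityDataset
#' @return integer matrix
#' @export
setGeneric("plotCounts", function(x) standardGeneric("plotCounts"))

#' Percent-cover matrix (species x plots, 0--100 scale)
#' @param x a CommunityDataset
#' @return numeric matrix
#' @export
setGeneric("plotCovers", function(x) standardGeneric("plotCovers"))

#' Importance-value matrix (species x transects)
#' @param x an IVTable
#' @return numeric matrix of IV fractions
#' @export
setGeneric("ivMatrix", function(x) standardGeneric("ivMatrix"))

#' Integrated-importance-value matrix (clusters x transects)
#' @param x an IIVTable
#' @return numeric matrix of IIV fractions
#' @export
setGeneric("iivMatrix", function(x) standardGeneric("iivMatrix"))

#' Member species of each cluster
#' @param x a SpeciesClustering or IIVTable
#' @return named list of character vectors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' Number of terminal clusters
#' @param x a SpeciesClustering
#' @return integer
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Group of each cluster
#' @param x a GroupAssignment
#' @return named character vector, cluster -> "G1"/"G2"/"G3"
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))

#' True effect extent of a synthetic scenario
#'
#' Ground truth for parameter-recovery experiments.
#' @param x a SyntheticConfig
#' @return distance in metres; `NA` (with a message) for an undisturbed
#'   scenario, where no extent is defined
#' @export
setGeneric("trueExtent", function(x) standardGeneric("trueExtent"))
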