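#' Importance values per species and belt transect
#'
#' For each belt transect, pools the transect's plots and computes, per
#' species, the relative density `Rd = d / D` (summed stalk counts over total
#' stalks), relative frequency `Rf = f / F` (number of plots holding the
#' species over the sum of that count across species) and relative cover
#' `Rc = c / C` (summed percent cover over total cover); the importance value
#' is `IV = (Rd + Rf + Rc) / 3`. Species absent from a transect get 0.
#' Pooling before ratio-taking makes each component sum to 1 over the species
#' present in a transect.
#'
#' @param x a [CommunityDataset-class]
#' @param rcDenominator `"plot_total"` (default) divides summed species cover
#'   by the summed per-plot `total_cover`; `"species_sum"` divides by the sum
#'   of all species covers. The two agree whenever the recorded plot totals
#'   equal the species sums; `species_sum` guarantees that Rc sums to exactly
#'   1 even when the visually estimated totals differ.
#' @param includeControl include control (CK) transects? They are excluded by
#'   default and kept as far-field reference for inference.
#' @return an [IVTable-class] with assays `Rd`, `Rf`, `Rc`, `IV`
#' @examples
#' cfg <- syntheticConfig("s1_like")
#' iv <- importanceValues(generateSurvey(cfg, seed = 1))
#' colSums(ivMatrix(iv))  # each transect sums to 1
#' @export
importanceValues <- function(x, rcDenominator = c("plot_total", "species_sum"),
                             includeControl = FALSE) {
  rcDenominator <- match.arg(rcDenominator)
  lay <- transectLayout(x)
  if (!includeControl) lay <- lay[lay$zone != "control", , drop = FALSE]
  cnt <- plotCounts(x); cov <- plotCovers(x)
  cd <- colData(x)
  sp <- rownames(x)
  mk <- function() matrix(0, length(sp), nrow(lay),
                          dimnames = list(sp, lay$transect_id))
  Rd <- mk(); Rf <- mk(); Rc <- mk()
  for (j in seq_len(nrow(lay))) {
    tid <- lay$transect_id[j]
    pl <- which(cd$transect_id == tid)
    if (!length(pl)) .stopf("transect '%s' has no plots", tid)
    d <- rowSums(cnt[, pl, drop = FALSE])
    D <- sum(d)
    if (D == 0) .stopf("degenerate transect '%s': zero total individuals", tid)
    f <- rowSums(cnt[, pl, drop = FALSE] > 0)
    cc <- rowSums(cov[, pl, drop = FALSE])
    C <- if (rcDenominator == "plot_total") sum(cd$total_cover[pl]) else sum(cc)
    if (C == 0) .stopf("transect '%s': zero total cover with nonzero counts", tid)
    Rd[, j] <- d / D
    Rf[, j] <- f / sum(f)
    Rc[, j] <- cc / C
  }
  se <- SummarizedExperiment(
    assays = list(Rd = Rd, Rf = Rf, Rc = Rc, IV = (Rd + Rf + Rc) / 3),
    colData = DataFrame(lay, row.names = lay$transect_id))
  methods::new("IVTable", se)
}

#' @rdname ivMatrix
#' @export
setMethod("ivMatrix", "IVTable", function(x) assay(x, "IV"))

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "IVTable", function(x) rownames(x))

#' @rdname transectLayout
#' @export
setMethod("transectLayout", "IVTable",
          function(x) as.data.frame(colData(x)))

setMethod("show", "IVTable", function(object) {
  cat(sprintf("IVTable: %d species x %d transects (assays: %s)\n",
              nrow(object), ncol(object),
              paste(assayNames(object), collapse = ", ")))
})

.memberList <- function(clustering, species) {
  members <- if (methods::is(clustering, "SpeciesClustering"))
    clusterMembers(clustering)
  else if (is.list(clustering)) clustering
  else .stopf("clustering must be a SpeciesClustering or a named list")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    .stopf("clusters must be named")
  if (any(lengths(members) == 0)) .stopf("empty cluster")
  unknown <- setdiff(unlist(members), species)
  if (length(unknown))
    .stopf("cluster member(s) absent from the IV table: %s",
           paste(unknown, collapse = ", "))
  dup <- unlist(members)[duplicated(unlist(members))]
  if (length(dup))
    .stopf("species in more than one cluster: %s", paste(dup, collapse = ", "))
  members
}

#' Integrated importance value of each cluster
#'
#' The IIV of a cluster in a transect is the arithmetic mean of its member
#' species' importance values in that transect, zeros included for members
#' absent there.
#'
#' @param iv an [IVTable-class]
#' @param clustering a [SpeciesClustering-class] or a named list of member
#'   species (a partition of a subset of the IV table's species)
#' @return an [IIVTable-class]
#' @examples
#' fx <- table1Fixture()
#' iiv <- integratedIV(fx, metadata(fx)$members)
#' iivMatrix(iiv)["Cluster 1", "I"]  # 0.2813...
#' @export
integratedIV <- function(iv, clustering) {
  members <- .memberList(clustering, rownames(iv))
  m <- ivMatrix(iv)
  out <- t(vapply(members,
                  function(sp) colMeans(m[sp, , drop = FALSE]),
                  numeric(ncol(m))))
  se <- SummarizedExperiment(assays = list(IIV = out), colData = colData(iv))
  metadata(se)$members <- members
  methods::new("IIVTable", se)
}

#' @rdname iivMatrix
#' @export
setMethod("iivMatrix", "IIVTable", function(x) assay(x, "IIV"))

#' @rdname clusterMembers
#' @export
setMethod("clusterMembers", "IIVTable", function(x) metadata(x)$members)

#' @rdname transectLayout
#' @export
setMethod("transectLayout", "IIVTable",
          function(x) as.data.frame(colData(x)))

setMethod("show", "IIVTable", function(object) {
  cat(sprintf("IIVTable: %d clusters x %d transects\n",
              nrow(object), ncol(object)))
  for (k in rownames(object))
    cat(sprintf("  %s: %s\n", k,
                paste(metadata(object)$members[[k]], collapse = ", ")))
})

#' Group-level integrated importance values
#'
#' The IIV of a response group is the sum of the IIVs of the clusters
#' assigned to it, per transect.
#'
#' @param iiv an [IIVTable-class]
#' @param groups a [GroupAssignment-class] or a named character vector
#'   mapping every cluster of `iiv` to a group label
#' @return group x transect numeric matrix
#' @export
groupIIV <- function(iiv, groups) {
  if (methods::is(groups, "GroupAssignment")) groups <- groupOf(groups)
  miss <- setdiff(rownames(iiv), names(groups))
  if (length(miss))
    .stopf("unassigned cluster(s): %s", paste(miss, collapse = ", "))
  g <- groups[rownames(iiv)]
  m <- iivMatrix(iiv)
  rowsum(m, group = g, reorder = TRUE)
}

#' Write an IV or IIV table as CSV
#'
#' Transects are written as columns in layout order; values are rounded half
#' up at the requested precision (matching how such tables are printed).
#'
#' @param x an [IVTable-class] or [IIVTable-class]
#' @param path output path
#' @param precision printed decimal places
#' @return invisibly, the data.frame written
#' @export
writeIVTable <- function(x, path, precision = 3) {
  m <- roundHalfUp(assay(x, assayNames(x)[assayNames(x) %in% c("IV", "IIV")][1]),
                   precision)
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- if (methods::is(x, "IIVTable")) "cluster" else "species"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
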