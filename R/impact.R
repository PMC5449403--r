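#' Assign clusters to disturbance response groups G1/G2/G3
#'
#' Classifies each cluster's IIV trajectory against the transect layout.
#' The near zone comprises the pipeline-area and inter-pipeline transects
#' plus distance transects at most `nearMaxDistance` out; the far zone is the
#' `farWindow` outermost distance transects (or the control transect when one
#' is present). A cluster is **G1** (disturbance-promoted) when its near-zone
#' mean IIV is at least `ratio` times its far-zone mean, reaches the
#' dominance floor `dominanceFloor`, and its IIV declines outward (rank
#' correlation with distance <= `-trendThreshold`); **G2**
#' (disturbance-suppressed original dominants, the indicator group) under the
#' mirrored conditions; otherwise **G3**. The dominance floor keeps sparse
#' accompanying species -- present mainly far-field but never dominant -- out
#' of G2.
#'
#' @param iiv an [IIVTable-class]
#' @param nearMaxDistance near-zone limit in metres (default 50)
#' @param farWindow number of outermost distance transects forming the
#'   far-field reference (default 3)
#' @param ratio near/far (or far/near) mean IIV ratio required (default 1.5)
#' @param trendThreshold minimum |rank correlation| of IIV with distance
#'   across the distance transects (default 0.5)
#' @param dominanceFloor minimum mean IIV in the favoured zone (default 0.2)
#' @param distanceScale `"rank"` (default; robust to the geometric transect
#'   spacing) or `"metric"` for the trend statistic
#' @return a [GroupAssignment-class]
#' @examples
#' fx <- table1Fixture()
#' groupOf(assignGroups(integratedIV(fx, metadata(fx)$members)))
#' @export
assignGroups <- function(iiv, nearMaxDistance = 50, farWindow = 3,
                         ratio = 1.5, trendThreshold = 0.5,
                         dominanceFloor = 0.2,
                         distanceScale = c("rank", "metric")) {
  distanceScale <- match.arg(distanceScale)
  lay <- transectLayout(iiv)
  m <- iivMatrix(iiv)
  isDist <- lay$zone == "distance"
  if (sum(isDist) < 2) .stopf("need at least 2 distance transects")
  near <- lay$zone %in% c("pipeline_area", "inter_pipeline") |
    (isDist & lay$distance_m <= nearMaxDistance)
  if (any(lay$zone == "control")) {
    far <- lay$zone == "control"
  } else {
    dOrd <- order(lay$distance_m[isDist], decreasing = TRUE)
    far <- seq_len(nrow(lay)) %in%
      which(isDist)[dOrd[seq_len(min(farWindow, sum(isDist)))]]
  }
  dvals <- lay$distance_m[isDist]
  dstat <- if (distanceScale == "rank") rank(dvals) else dvals
  diag <- do.call(rbind, lapply(rownames(m), function(k) {
    v <- m[k, ]
    nearMean <- mean(v[near]); farMean <- mean(v[far])
    vd <- v[isDist]
    trend <- if (stats::sd(vd) == 0) 0 else
      stats::cor(dstat, if (distanceScale == "rank") rank(vd) else vd)
    g1 <- nearMean >= ratio * farMean && nearMean >= dominanceFloor &&
      trend <= -trendThreshold
    g2 <- farMean >= ratio * nearMean && farMean >= dominanceFloor &&
      trend >= trendThreshold
    data.frame(cluster = k, near_mean = nearMean, far_mean = farMean,
               trend = trend,
               group = if (g1) "G1" else if (g2) "G2" else "G3")
  }))
  methods::new("GroupAssignment",
               assignment = stats::setNames(diag$group, diag$cluster),
               diagnostics = diag,
               params = list(nearMaxDistance = nearMaxDistance,
                             farWindow = farWindow, ratio = ratio,
                             trendThreshold = trendThreshold,
                             dominanceFloor = dominanceFloor,
                             distanceScale = distanceScale))
}

#' @rdname groupOf
#' @export
setMethod("groupOf", "GroupAssignment", function(x) x@assignment)

setMethod("show", "GroupAssignment", function(object) {
  cat("GroupAssignment:\n")
  d <- object@diagnostics
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s -> %s (near %.3f, far %.3f, trend %+.2f)\n",
                d$cluster[i], d$group[i], d$near_mean[i], d$far_mean[i],
                d$trend[i]))
})

#' Stabilisation distance of an IIV trajectory
#'
#' Operationalises "the trajectory becomes smooth and steady": the reference
#' level is the mean of the `farWindow` outermost values (or an explicitly
#' supplied far-field value, e.g. from a control transect), and K is the
#' smallest distance from which every value outward stays within
#' `tolerance * reference` of the reference. A trajectory already inside the
#' band at the nearest transect gives K = the nearest distance; one that
#' never settles is flagged unresolved (extent beyond the survey).
#'
#' @param values IIV at each distance transect
#' @param distances matching distances in metres (any order; sorted
#'   internally)
#' @param farWindow number of outermost values averaged into the reference
#' @param tolerance half-width of the acceptance band, as a fraction of the
#'   reference (default 0.15)
#' @param reference optional explicit far-field reference value
#' @return list with `K` (metres, `NA` when unresolved), `resolved`,
#'   `reference`, `band` (`c(lower, upper)`), `tolerance`, `farWindow`
#' @examples
#' detectStabilization(c(0.2, 0.4, 0.42, 0.41), c(10, 100, 300, 1000))
#' @export
detectStabilization <- function(values, distances, farWindow = 3,
                                tolerance = 0.15, reference = NULL) {
  if (length(values) != length(distances)) .stopf("length mismatch")
  if (length(values) < farWindow + 1)
    .stopf("need at least farWindow + 1 = %d distance transects", farWindow + 1)
  o <- order(distances)
  values <- values[o]; distances <- distances[o]
  n <- length(values)
  if (is.null(reference))
    reference <- mean(values[(n - farWindow + 1):n])
  if (reference == 0 && any(values != 0))
    .stopf("far-field reference is zero but the trajectory is not")
  band <- reference + c(-1, 1) * tolerance * abs(reference)
  inBand <- values >= band[1] & values <= band[2]
  # smallest d* with every value at distance >= d* inside the band
  ok <- rev(cumprod(rev(inBand))) == 1
  if (!any(ok))
    return(list(K = NA_real_, resolved = FALSE, reference = reference,
                band = band, tolerance = tolerance, farWindow = farWindow))
  list(K = distances[which(ok)[1]], resolved = TRUE, reference = reference,
       band = band, tolerance = tolerance, farWindow = farWindow)
}

#' Dominance crossover interval (K3)
#'
#' Scans the transects outward and finds the first at which the
#' disturbance-suppressed group's IIV strictly exceeds the
#' disturbance-promoted group's: the community's dominant position changes
#' inside the half-open interval (previous transect's distance, crossover
#' transect's distance]. No crossover yields an empty interval with a
#' dominance report; a crossover already at the nearest transect means G2 was
#' dominant throughout (also empty, flagged); several sign changes return the
#' first with a multiplicity warning.
#'
#' @param g1 IIV trajectory of the promoted (G1) group, in outward scan order
#' @param g2 IIV trajectory of the suppressed (G2) group, same transects
#' @param distances matching distances in metres (outward scan order)
#' @return list with `interval` (`c(lower, upper)` in m, `NA`s when empty),
#'   `crossed`, `dominance` (`"G1"`/`"G2"`/`"mixed"`), and `nCrossings`
#' @export
crossingInterval <- function(g1, g2, distances) {
  if (length(g1) != length(g2) || length(g1) != length(distances))
    .stopf("length mismatch between series and distances")
  above <- g2 > g1
  flips <- sum(diff(above) != 0)
  if (flips > 1)
    .warnf("dominance changes %d times along the gradient; reporting the first crossover",
           flips)
  if (!any(above))
    return(list(interval = c(NA_real_, NA_real_), crossed = FALSE,
                dominance = "G1", nCrossings = 0L))
  i <- which(above)[1]
  if (i == 1)
    return(list(interval = c(NA_real_, NA_real_), crossed = FALSE,
                dominance = "G2", nCrossings = as.integer(flips)))
  list(interval = c(lower = distances[i - 1], upper = distances[i]),
       crossed = TRUE, dominance = "mixed", nCrossings = as.integer(flips))
}

#' Effect extent of a linear construction (K1, K2, K3)
#'
#' Composes the response-group trajectories into the K-point summary: K1 is
#' the stabilisation distance of the summed G1 (promoted) group IIV, K2 --
#' the headline effect extent -- the stabilisation distance of the summed G2
#' (suppressed original dominants) group IIV, and K3 the dominance crossover
#' interval of the two group curves, the edge-effect transition zone. When
#' the stabilisation point and the crossover disagree, a transition-zone note
#' is attached rather than forcing them to agree.
#'
#' @param iiv an [IIVTable-class]
#' @param groups a [GroupAssignment-class] (or named cluster -> group vector)
#'   covering all clusters; at least one G2 cluster is required -- without an
#'   indicator group no extent is defined
#' @param farWindow,tolerance stabilisation parameters, see
#'   [detectStabilization()]
#' @return an [ExtentEstimate-class]
#' @examples
#' fx <- table1Fixture()
#' iiv <- integratedIV(fx, metadata(fx)$members)
#' effectExtent(iiv, assignGroups(iiv))
#' @export
effectExtent <- function(iiv, groups, farWindow = 3, tolerance = 0.15) {
  ga <- if (methods::is(groups, "GroupAssignment")) groupOf(groups) else groups
  gm <- groupIIV(iiv, ga)
  if (!("G2" %in% rownames(gm)))
    .stopf("no indicator group: no cluster was assigned to G2")
  lay <- transectLayout(iiv)
  ord <- .scanOrder(lay)
  isDist <- lay$zone[ord] == "distance"
  dDist <- lay$distance_m[ord][isDist]
  warnings <- character()
  stab <- function(series) {
    s <- detectStabilization(series[ord][isDist], dDist,
                             farWindow = farWindow, tolerance = tolerance)
    s
  }
  k2 <- stab(gm["G2", ])
  if (!k2$resolved)
    warnings <- c(warnings, "K2 unresolved: G2 never stabilises within the survey")
  if ("G1" %in% rownames(gm)) {
    k1 <- stab(gm["G1", ])
    if (!k1$resolved)
      warnings <- c(warnings, "K1 unresolved: G1 never stabilises within the survey")
    cross <- withCallingHandlers(
      crossingInterval(gm["G1", ord], gm["G2", ord], lay$distance_m[ord]),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    k3 <- unname(cross$interval)
    dominance <- cross$dominance
    if (!cross$crossed)
      warnings <- c(warnings,
                    sprintf("no dominance crossover: %s dominant throughout",
                            cross$dominance))
  } else {
    k1 <- list(K = NA_real_, resolved = FALSE)
    k3 <- c(NA_real_, NA_real_)
    dominance <- "G2"
    warnings <- c(warnings, "no G1 cluster: K1 and K3 undefined")
  }
  if (isTRUE(k2$resolved) && !is.na(k3[2]) && k2$K != k3[2])
    warnings <- c(warnings, sprintf(
      "transition zone: stabilisation (K2 = %g m) and dominance crossover (%g m) disagree",
      k2$K, k3[2]))
  methods::new("ExtentEstimate",
               K1 = k1$K, K2 = k2$K, K3 = k3, dominance = dominance,
               params = list(farWindow = farWindow, tolerance = tolerance,
                             groups = ga),
               warnings = warnings)
}

setMethod("show", "ExtentEstimate", function(object) {
  fmtK <- function(k) if (is.na(k)) "unresolved" else sprintf("%g m", k)
  cat("ExtentEstimate:\n")
  cat("  K1 (G1 stabilisation):", fmtK(object@K1), "\n")
  cat("  K2 (effect extent):   ", fmtK(object@K2), "\n")
  if (all(is.na(object@K3)))
    cat("  K3 (crossover):        none (", object@dominance,
        " dominant)\n", sep = "")
  else
    cat(sprintf("  K3 (crossover):        (%g m, %g m]\n",
                object@K3[1], object@K3[2]))
  for (w in object@warnings) cat("  note:", w, "\n")
})

#' Pearson correlation with a permutation test
#'
#' Correlates an indicator-group IIV series against a community index and
#' assesses significance by a two-sided permutation test: one series is
#' shuffled `nPerm` times, and the p-value is the add-one-corrected fraction
#' of permutations with `|r|` at least the observed value.
#'
#' @param x,y numeric vectors of equal length (>= 3), nonzero variance
#' @param nPerm number of permutations (>= 99)
#' @param seed optional integer seed; the caller's RNG state is untouched
#' @return list with `r` (Pearson), `p` (permutation p-value), `nPerm`
#' @examples
#' indicatorCorrelation(1:10, (1:10) + rnorm(10), nPerm = 999, seed = 1)
#' @export
indicatorCorrelation <- function(x, y, nPerm = 9999, seed = NULL) {
  if (length(x) != length(y)) .stopf("length mismatch")
  if (length(x) < 3) .stopf("need at least 3 observations")
  if (nPerm < 99) .stopf("nPerm must be >= 99")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("zero variance in input series")
  r <- stats::cor(x, y)
  n <- length(x)
  xc <- x - mean(x)
  denomX <- sqrt(sum(xc^2))
  count <- .withSeed(seed, {
    perms <- replicate(nPerm, sample.int(n))
    yp <- matrix(y[perms], n, nPerm)
    ypc <- sweep(yp, 2, colMeans(yp))
    rp <- drop(crossprod(ypc, xc)) / (denomX * sqrt(colSums(ypc^2)))
    sum(abs(rp) >= abs(r) - 1e-12)
  })
  list(r = r, p = (1 + count) / (nPerm + 1), nPerm = nPerm)
}
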