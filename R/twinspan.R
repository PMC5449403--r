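#' Pseudospecies expansion of a quantitative profile matrix
#'
#' Expands each quantitative attribute into binary presence indicators at
#' ascending cut levels: the (attribute, level) cell is 1 iff the value
#' strictly exceeds the level. Presence at a level implies presence at all
#' lower levels (nested columns), the classical TWINSPAN device that lets a
#' presence/absence method see abundance.
#'
#' @param profiles item x attribute numeric matrix (here: species x transect
#'   importance values, fractions in \[0, 1\])
#' @param cutLevels strictly ascending cut levels, first one 0. The default
#'   `c(0, 0.02, 0.05, 0.10, 0.20)` is the classical 0/2/5/10/20 percent
#'   ladder rescaled to the IV's 0--1 range.
#' @return binary matrix with `ncol(profiles) * length(cutLevels)` columns,
#'   named `attribute|level`; attribute blocks are ordered level by level
#' @examples
#' toPseudospecies(matrix(0.07, 1, 1, dimnames = list("sp", "t")))[1, ]
#' @export
toPseudospecies <- function(profiles,
                            cutLevels = c(0, 0.02, 0.05, 0.10, 0.20)) {
  profiles <- as.matrix(profiles)
  if (is.unsorted(cutLevels, strictly = TRUE))
    .stopf("cutLevels must be strictly ascending")
  if (cutLevels[1] != 0) .stopf("first cut level must be 0")
  out <- do.call(cbind, lapply(seq_along(cutLevels), function(k) {
    m <- (profiles > cutLevels[k]) + 0
    colnames(m) <- paste0(colnames(profiles), "|", k)
    m
  }))
  rownames(out) <- rownames(profiles)
  out
}

#' First correspondence-analysis axis by reciprocal averaging
#'
#' Iterates "row score = weighted mean of column scores" and its transpose on
#' a non-negative matrix, centring and rescaling to unit weighted variance
#' each pass, until the scores stabilise -- the classical reciprocal-averaging
#' construction of the first non-trivial CA axis. The per-pass shrink factor
#' at convergence is the axis eigenvalue. Signs are oriented so that the
#' first row (input order) with nonzero weight scores >= 0.
#'
#' @param m non-negative item x attribute matrix; all-zero rows and columns
#'   are trimmed before iteration
#' @param tol convergence threshold on the maximum score change
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   residual
#' @return list with `rowScores` and `colScores` (named, trimmed entries
#'   only), `eigenvalue`, and `iterations`
#' @export
caFirstAxis <- function(m, tol = 1e-10, maxIter = 10000) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 1 || nrow(unique(m)) < 2)
    .stopf("degenerate matrix: need at least two non-identical nonzero rows")
  r <- rowSums(m); cc <- colSums(m); tot <- sum(m)
  x <- seq_len(nrow(m))
  x <- x - sum(r * x) / tot
  x <- x / sqrt(sum(r * x^2) / tot)
  lam <- NA_real_
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    u <- drop(crossprod(m, x)) / cc
    xn <- drop(m %*% u) / r
    xn <- xn - sum(r * xn) / tot
    lam <- sqrt(sum(r * xn^2) / tot)
    if (lam == 0)
      .stopf("degenerate matrix: axis has zero variance")
    xn <- xn / lam
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    .stopf("reciprocal averaging did not converge in %d iterations (residual %.3g)",
           maxIter, delta)
  # orient so the first row with a non-negligible score is positive (a row
  # sitting exactly at the centroid cannot fix the sign)
  anchor <- which(abs(x) > 1e-8)[1]
  if (!is.na(anchor) && x[anchor] < 0) x <- -x
  u <- drop(crossprod(m, x)) / cc
  list(rowScores = stats::setNames(x, rownames(m)),
       colScores = stats::setNames(u, colnames(m)),
       eigenvalue = lam, iterations = it)
}

# Preferential pseudospecies of a dichotomy: columns whose within-side
# frequency is at least `ratio` times the other side's. Returns the capped
# indicator set, strongest (largest frequency difference) first, with signs
# +1 toward the right side, -1 toward the left; ties broken by column order.
.indicators <- function(A, left, maxIndicators, ratio = 2) {
  fL <- colMeans(A[left, , drop = FALSE])
  fR <- colMeans(A[!left, , drop = FALSE])
  prefL <- fL >= ratio * fR & fL > 0
  prefR <- fR >= ratio * fL & fR > 0
  pref <- which(prefL | prefR)
  if (!length(pref)) return(NULL)
  pref <- pref[order(-abs(fL - fR)[pref], pref)]
  pref <- pref[seq_len(min(maxIndicators, length(pref)))]
  list(columns = pref, sign = ifelse(prefR[pref], 1L, -1L))
}

#' One TWINSPAN dichotomy of a cluster
#'
#' Orders the cluster's items on the first correspondence-analysis axis of
#' their pseudospecies sub-matrix and splits near the axis middle: items
#' strictly below the weighted-median score form one side, items strictly
#' above the other, and the weighted-median item itself joins the side
#' already carrying more weight (a deterministic, orientation-independent
#' convention). The split is then refined: pseudospecies at least twice as
#' frequent on one side as the other are preferential; each item is scored by
#' its net count of the `maxIndicators` strongest preferentials, and items
#' whose indicator score contradicts their side by at least
#' `misclassThreshold` are reassigned, for up to `refinePasses` rounds.
#'
#' @param items character vector of item names (a cluster)
#' @param pseudo the full pseudospecies matrix from [toPseudospecies()]
#' @param minGroupSize smallest allowed side; clusters smaller than
#'   `2 * minGroupSize` are not divided
#' @param maxIndicators cap on the number of indicator pseudospecies
#' @param refinePasses refinement rounds
#' @param misclassThreshold net indicator score at which an item is moved
#'   across the dichotomy
#' @return `NULL` when the cluster cannot be divided (too small, or all items
#'   identical); otherwise a list with `left`, `right` (item names, left =
#'   lower axis scores), `eigenvalue`, `scores`, and `indicators`
#' @export
twinspanDivide <- function(items, pseudo, minGroupSize = 1, maxIndicators = 7,
                           refinePasses = 2, misclassThreshold = 1) {
  if (length(items) < 2 * minGroupSize || length(items) < 2) return(NULL)
  A <- pseudo[items, , drop = FALSE]
  A <- A[, colSums(A) > 0, drop = FALSE]
  if (!ncol(A) || nrow(unique(A)) < 2) return(NULL)  # zero-variance cluster
  ca <- caFirstAxis(A)
  sc <- ca$rowScores[items]
  if (anyNA(sc)) .stopf("item with all-zero pseudospecies row: %s",
                        paste(items[is.na(sc)], collapse = ", "))
  w <- rowSums(A)
  mi <- .weightedMedianIndex(sc, w)
  left <- sc < sc[mi]
  right <- sc > sc[mi]
  atMedian <- !left & !right
  # the median-tied block joins the heavier strict side; if that would empty
  # the dichotomy (e.g. duplicated rows sharing the median score), it joins
  # the other side instead
  toLeft <- sum(w[left]) >= sum(w[right])
  if (toLeft && !any(right)) toLeft <- FALSE
  if (!toLeft && !any(left)) toLeft <- TRUE
  if (toLeft) left[atMedian] <- TRUE else right[atMedian] <- TRUE
  if (!any(left) || !any(right)) return(NULL)
  ind <- NULL
  for (p in seq_len(refinePasses)) {
    ind <- .indicators(A, left, maxIndicators)
    if (is.null(ind)) break
    score <- drop(A[, ind$columns, drop = FALSE] %*% ind$sign)
    newLeft <- left
    newLeft[left & score >= misclassThreshold] <- FALSE
    newLeft[!left & score <= -misclassThreshold] <- TRUE
    if (!any(newLeft) || all(newLeft) || identical(newLeft, left)) break
    left <- newLeft
  }
  if (min(sum(left), sum(!left)) < minGroupSize) return(NULL)
  indNames <- if (is.null(ind)) character() else
    stats::setNames(ind$sign, colnames(A)[ind$columns])
  list(left = items[left], right = items[!left],
       eigenvalue = ca$eigenvalue, scores = sc, indicators = indNames)
}

# Heterogeneity of a cluster on the raw profiles: mean pairwise Bray-Curtis
# dissimilarity (default), or the total chi-square inertia of the
# pseudospecies sub-matrix.
.heterogeneity <- function(items, profiles, pseudo, measure) {
  if (length(items) < 2) return(-Inf)
  if (measure == "bray") {
    d <- vegan::vegdist(profiles[items, , drop = FALSE], method = "bray")
    mean(d)
  } else {
    A <- pseudo[items, , drop = FALSE]
    A <- A[, colSums(A) > 0, drop = FALSE]
    tot <- sum(A)
    if (tot == 0) return(-Inf)
    E <- outer(rowSums(A), colSums(A)) / tot
    sum((A - E)^2 / E) / tot
  }
}

#' Modified TWINSPAN classification of species by their IV profiles
#'
#' Divisive classification in the two-way-indicator-species-analysis family:
#' items (species, described by their importance-value profile across belt
#' transects) are repeatedly dichotomised by [twinspanDivide()], and -- the
#' modification -- at every step the cluster with the greatest heterogeneity
#' (mean pairwise Bray-Curtis dissimilarity of the raw profiles, by default)
#' is divided next, so the dendrogram can be cut at any number of terminal
#' clusters. The procedure is fully deterministic.
#'
#' @param profiles species x transect matrix of importance values; species
#'   with an all-zero profile are dropped with a warning (they cannot be
#'   ordinated)
#' @param nClusters requested number of terminal clusters (>= 2); if fewer
#'   are reachable a warning reports the achieved count
#' @param cutLevels pseudospecies cut levels, see [toPseudospecies()]
#' @param heterogeneity `"bray"` (default) or `"inertia"`
#' @inheritParams twinspanDivide
#' @return a [SpeciesClustering-class]; terminal clusters are labelled
#'   `"Cluster 1"`, `"Cluster 2"`, ... in dendrogram (leaf) order
#' @examples
#' fx <- table1Fixture()
#' cl <- modifiedTwinspan(ivMatrix(fx), nClusters = 3)
#' clusterMembers(cl)
#' @export
modifiedTwinspan <- function(profiles, nClusters = 3,
                             cutLevels = c(0, 0.02, 0.05, 0.10, 0.20),
                             heterogeneity = c("bray", "inertia"),
                             minGroupSize = 1, maxIndicators = 7,
                             refinePasses = 2, misclassThreshold = 1) {
  heterogeneity <- match.arg(heterogeneity)
  profiles <- as.matrix(profiles)
  if (nClusters < 2) .stopf("nClusters must be >= 2")
  zero <- rowSums(profiles) == 0
  if (any(zero)) {
    .warnf("dropping species with all-zero profiles: %s",
           paste(rownames(profiles)[zero], collapse = ", "))
    profiles <- profiles[!zero, , drop = FALSE]
  }
  if (nrow(profiles) < 2) .stopf("need at least two species to classify")
  pseudo <- toPseudospecies(profiles, cutLevels)
  clusters <- list(rownames(profiles))
  divisible <- TRUE
  divisions <- list()
  while (length(clusters) < nClusters && any(divisible)) {
    het <- vapply(seq_along(clusters), function(i) {
      if (!divisible[i]) return(-Inf)
      .heterogeneity(clusters[[i]], profiles, pseudo, heterogeneity)
    }, numeric(1))
    k <- which.max(het)             # ties: first (dendrogram order) wins
    if (!is.finite(het[k])) break
    d <- twinspanDivide(clusters[[k]], pseudo, minGroupSize = minGroupSize,
                        maxIndicators = maxIndicators,
                        refinePasses = refinePasses,
                        misclassThreshold = misclassThreshold)
    if (is.null(d)) { divisible[k] <- FALSE; next }
    divisions[[length(divisions) + 1]] <-
      list(parent = clusters[[k]], left = d$left, right = d$right,
           eigenvalue = d$eigenvalue, heterogeneity = het[k],
           indicators = d$indicators)
    clusters <- append(clusters[-k], list(d$left, d$right), after = k - 1)
    divisible <- append(divisible[-k], c(TRUE, TRUE), after = k - 1)
  }
  if (length(clusters) < nClusters)
    .warnf("requested %d clusters but only %d are reachable",
           nClusters, length(clusters))
  labels <- paste("Cluster", seq_along(clusters))
  partition <- stats::setNames(
    rep(labels, lengths(clusters)), unlist(clusters))
  partition <- partition[rownames(profiles)]   # registry order
  methods::new("SpeciesClustering",
               partition = partition, labels = labels, divisions = divisions,
               params = list(nClusters = nClusters, cutLevels = cutLevels,
                             heterogeneity = heterogeneity,
                             minGroupSize = minGroupSize,
                             maxIndicators = maxIndicators,
                             refinePasses = refinePasses,
                             misclassThreshold = misclassThreshold))
}

#' @rdname clusterMembers
#' @export
setMethod("clusterMembers", "SpeciesClustering", function(x) {
  out <- split(names(x@partition), x@partition)
  out[x@labels]
})

#' @rdname nClusters
#' @export
setMethod("nClusters", "SpeciesClustering", function(x) length(x@labels))

setMethod("show", "SpeciesClustering", function(object) {
  cat(sprintf("SpeciesClustering: %d species in %d clusters (%d divisions)\n",
              length(object@partition), length(object@labels),
              length(object@divisions)))
  mem <- clusterMembers(object)
  for (k in names(mem))
    cat(sprintf("  %s: %s\n", k, paste(mem[[k]], collapse = ", ")))
})

#' Indented-text dendrogram of a species clustering
#'
#' @param x a [SpeciesClustering-class]
#' @return character vector of lines (also printed)
#' @export
formatDendrogram <- function(x) {
  lines <- character()
  recurse <- function(items, depth) {
    pad <- strrep("  ", depth)
    div <- Filter(function(d) setequal(d$parent, items), x@divisions)
    if (length(div)) {
      d <- div[[1]]
      lines <<- c(lines, sprintf("%s+ division (eigenvalue %.3f)", pad,
                                 d$eigenvalue))
      recurse(d$left, depth + 1)
      recurse(d$right, depth + 1)
    } else {
      lab <- unique(x@partition[items])
      lines <<- c(lines, sprintf("%s- %s: %s", pad, lab,
                                 paste(items, collapse = ", ")))
    }
  }
  root <- names(x@partition)
  recurse(root, 0)
  cat(lines, sep = "\n")
  invisible(lines)
}
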