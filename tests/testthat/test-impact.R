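table1IIV <- function() integratedIV(table1Fixture(), table1Members())

test_that("published clusters map onto response groups 1:1", {
  ga <- assignGroups(table1IIV())
  expect_equal(groupOf(ga),
               c("Cluster 1" = "G1", "Cluster 2" = "G2", "Cluster 3" = "G3"))
  d <- ga@diagnostics
  expect_true(d$trend[d$cluster == "Cluster 1"] <= -0.5)
  expect_true(d$trend[d$cluster == "Cluster 2"] >= 0.5)
})

test_that("group rules equal a brute-force evaluation of the predicate", {
  bruteforce <- function(iiv, tau = 1.5, rho = 0.5, theta = 0.2,
                         nearMax = 50, fw = 3) {
    lay <- transectLayout(iiv); m <- iivMatrix(iiv)
    near <- lay$zone %in% c("pipeline_area", "inter_pipeline") |
      (lay$zone == "distance" & lay$distance_m <= nearMax)
    dist <- which(lay$zone == "distance")
    far <- dist[order(lay$distance_m[dist], decreasing = TRUE)][1:fw]
    sapply(rownames(m), function(k) {
      nm <- mean(m[k, near]); fm <- mean(m[k, far])
      vd <- m[k, dist]
      tr <- if (sd(vd) == 0) 0 else
        cor(rank(lay$distance_m[dist]), rank(vd))
      if (nm >= tau * fm && nm >= theta && tr <= -rho) "G1"
      else if (fm >= tau * nm && fm >= theta && tr >= rho) "G2"
      else "G3"
    })
  }
  lay <- transectLayout(table1IIV())
  set.seed(17)
  for (i in 1:15) {
    m <- matrix(runif(5 * nrow(lay), 0, 0.6), 5, nrow(lay),
                dimnames = list(paste0("K", 1:5), lay$transect_id))
    # make some rows trending to exercise every branch
    m[1, ] <- seq(0.6, 0.05, length.out = ncol(m)) + runif(ncol(m), 0, 0.05)
    m[2, ] <- seq(0.02, 0.55, length.out = ncol(m)) + runif(ncol(m), 0, 0.05)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(IIV = m),
      colData = S4Vectors::DataFrame(lay, row.names = lay$transect_id))
    S4Vectors::metadata(se)$members <-
      setNames(as.list(paste0("sp", 1:5)), rownames(m))
    iiv <- new("IIVTable", se)
    expect_equal(groupOf(assignGroups(iiv)), bruteforce(iiv))
  }
  # constant trajectory: no trend, no ratio -> G3
  mc <- matrix(0.3, 1, nrow(lay), dimnames = list("K", lay$transect_id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(IIV = mc),
    colData = S4Vectors::DataFrame(lay, row.names = lay$transect_id))
  S4Vectors::metadata(se)$members <- list(K = "sp")
  expect_equal(unname(groupOf(assignGroups(new("IIVTable", se)))), "G3")
})

test_that("group assignment and K detection are scale-equivariant", {
  iiv <- table1IIV()
  scaled <- iiv
  SummarizedExperiment::assay(scaled, "IIV") <-
    SummarizedExperiment::assay(iiv, "IIV") * 0.37
  # ratio and trend rules carry no units; the dominance floor is on the IIV
  # scale and must be co-scaled
  expect_equal(groupOf(assignGroups(scaled, dominanceFloor = 0.2 * 0.37)),
               groupOf(assignGroups(iiv)))
  lay <- transectLayout(iiv)
  dist <- lay$zone == "distance"
  v <- iivMatrix(iiv)["Cluster 2", dist]
  d <- lay$distance_m[dist]
  expect_equal(detectStabilization(v * 5, d)$K, detectStabilization(v, d)$K)
})

test_that("stabilisation matches a brute-force scan and is monotone in tolerance", {
  bruteK <- function(v, d, fw = 3, eps = 0.15) {
    o <- order(d); v <- v[o]; d <- d[o]
    ref <- mean(v[(length(v) - fw + 1):length(v)])
    for (i in seq_along(d))
      if (all(abs(v[i:length(v)] - ref) <= eps * abs(ref))) return(d[i])
    NA_real_
  }
  lay <- transectLayout(table1IIV())
  dist <- lay$zone == "distance"
  d <- lay$distance_m[dist]
  v <- iivMatrix(table1IIV())["Cluster 2", dist]
  got <- detectStabilization(v, d)
  expect_equal(got$K, bruteK(v, d))
  expect_equal(got$K, 100)          # the suppressed dominants settle at 100 m
  expect_true(got$resolved)

  # constant series settles at the nearest transect
  expect_equal(detectStabilization(rep(0.3, 8), d)$K, 10)
  # strictly rising series entering the band only at the last point
  expect_equal(detectStabilization(c(1:7 / 100, 10), d, farWindow = 1)$K, 1000)
  # zero far-field reference with a live trajectory is an error
  expect_error(detectStabilization(c(1, 0, 0), c(10, 30, 50), farWindow = 2),
               "reference is zero")

  # shrinking the band never moves K inward
  set.seed(31)
  for (i in 1:20) {
    v <- abs(cumsum(rnorm(8, 0, 0.05))) + 0.2
    ks <- sapply(c(0.5, 0.3, 0.15, 0.08, 0.04), function(eps)
      detectStabilization(v, d, tolerance = eps)$K)
    ks[is.na(ks)] <- 1e9   # unresolved counts as beyond the survey
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("the dominance crossover is located with its interval semantics", {
  iiv <- table1IIV()
  lay <- transectLayout(iiv)
  m <- iivMatrix(iiv)
  cr <- crossingInterval(m["Cluster 1", ], m["Cluster 2", ], lay$distance_m)
  expect_true(cr$crossed)
  expect_equal(unname(cr$interval), c(50, 100))

  expect_false(crossingInterval(c(1, 1), c(0.5, 0.6), c(10, 30))$crossed)
  expect_equal(crossingInterval(c(1, 1), c(0.5, 0.6), c(10, 30))$dominance, "G1")
  g2first <- crossingInterval(c(0.2, 0.2), c(0.5, 0.6), c(10, 30))
  expect_false(g2first$crossed)                   # G2 dominant throughout
  expect_equal(g2first$dominance, "G2")
  expect_warning(
    alt <- crossingInterval(c(1, 0, 1, 0), c(0, 1, 0, 1), c(10, 30, 50, 100)),
    "first crossover")
  expect_equal(unname(alt$interval), c(10, 30))   # first crossing reported
  expect_error(crossingInterval(1:3, 1:2, 1:3), "length mismatch")
})

test_that("effect extent composes stabilisation and crossover on the fixture", {
  iiv <- table1IIV()
  est <- effectExtent(iiv, assignGroups(iiv))
  expect_equal(est@K2, 100)
  expect_equal(unname(est@K3), c(50, 100))
  # without an indicator group there is no extent
  expect_error(
    effectExtent(iiv, c("Cluster 1" = "G1", "Cluster 2" = "G3",
                        "Cluster 3" = "G3")),
    "no indicator group")
})

test_that("permutation correlation is exact on closed-form cases", {
  # hand-computed five-point Pearson r
  x <- c(1, 2, 4, 5, 8); y <- c(2, 1, 5, 4, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- indicatorCorrelation(x, y, nPerm = 199, seed = 1)
  expect_equal(got$r, r_hand)

  # perfect collinearity: r = 1, p at the add-one floor
  col <- indicatorCorrelation(1:20, 2 + 3 * (1:20), nPerm = 999, seed = 2)
  expect_equal(col$r, 1)
  expect_equal(col$p, 1 / 1000)

  # seed-reproducible, and the caller's RNG stream is untouched
  u <- rnorm(30); v <- rnorm(30)
  a <- indicatorCorrelation(u, v, nPerm = 199, seed = 7)
  b <- indicatorCorrelation(u, v, nPerm = 199, seed = 7)
  expect_identical(a, b)
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(indicatorCorrelation(u, v, nPerm = 199, seed = 7))
  expect_equal(runif(1), before)
  expect_error(indicatorCorrelation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(indicatorCorrelation(1:10, 1:9), "length mismatch")
})
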