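# Independent oracles and fixture builders used across the suite.

# Dense-eigendecomposition oracle for the first non-trivial correspondence
# analysis axis: eigenvectors of the symmetrised transition operator
# Dr^-1/2 A Dc^-1 A' Dr^-1/2, standardised the same way as the
# reciprocal-averaging implementation (weighted centring, unit weighted
# variance, first-row sign >= 0).
caEigenOracle <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  r <- rowSums(m); cc <- colSums(m); tot <- sum(m)
  K <- diag(1 / sqrt(r)) %*% m %*% diag(1 / cc) %*% t(m) %*% diag(1 / sqrt(r))
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  x <- e$vectors[, 2] / sqrt(r)
  x <- x - sum(r * x) / tot
  x <- x / sqrt(sum(r * x^2) / tot)
  anchor <- which(abs(x) > 1e-8)[1]
  if (!is.na(anchor) && x[anchor] < 0) x <- -x
  list(scores = stats::setNames(x, rownames(m)), eigenvalue = e$values[2])
}

# Random binary matrix with no zero rows/columns, at least two distinct
# rows, and a well-separated first axis (the compared eigenvector is only
# defined when the second and third eigenvalues are distinct); redrawn until
# valid.
randBinaryMatrix <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc,
                dimnames = list(paste0("r", seq_len(nr)),
                                paste0("c", seq_len(nc))))
    if (!(all(rowSums(m) > 0) && all(colSums(m) > 0) &&
          nrow(unique(m)) >= 2)) next
    r <- rowSums(m); cc <- colSums(m)
    K <- diag(1 / sqrt(r)) %*% m %*% diag(1 / cc) %*% t(m) %*% diag(1 / sqrt(r))
    ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    gap <- if (length(ev) >= 3) (ev[2] - ev[3]) / ev[2] else 1
    if (ev[2] > 0.05 && gap > 0.05) return(m)
  }
}

# The two-plot worked example: species A in one plot only, species B in both
# at the same density; every IV component of A is 1/3.
makeTinyDataset <- function() {
  counts <- rbind(A = c(4L, 0L), B = c(4L, 4L))
  cover <- rbind(A = c(20, 0), B = c(20, 20))
  colnames(counts) <- colnames(cover) <- c("p1", "p2")
  CommunityDataset(
    counts, cover,
    data.frame(plot_id = c("p1", "p2"), transect_id = "T1",
               total_cover = c(40, 20)),
    data.frame(transect_id = "T1", zone = "distance", distance_m = 10,
               n_plots = 2))
}

# Published-survey fixture pieces used by several files.
table1Members <- function() S4Vectors::metadata(table1Fixture())$members
table1PrintedIIV <- function() S4Vectors::metadata(table1Fixture())$printedIIV

# Flat-partition comparison up to cluster relabelling.
samePartition <- function(a, b) {
  key <- function(mem) sort(vapply(mem, function(m)
    paste(sort(m), collapse = "+"), character(1)))
  identical(unname(key(a)), unname(key(b)))
}
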