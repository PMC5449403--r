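#' Round half away from zero
#'
#' Fixed-precision rounding in which exact halves round up (0.0775 -> 0.078),
#' the convention used for printed importance-value tables; `base::round()`
#' rounds halves to even. A tiny epsilon absorbs binary representation error
#' so that values intended as exact halves are treated as such.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @examples
#' roundHalfUp(c(0.0775, 0.4305), 3)
#' @export
roundHalfUp <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Weighted median item: index of the smallest value whose cumulative weight
# reaches half the total. Ties in value share an index order (stable).
.weightedMedianIndex <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  o[which(cw >= sum(w) / 2)[1]]
}

# Run code with a private RNG stream: seeds if asked, always restores the
# caller's .Random.seed.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

# Transects in outward scan order: layout order for zone transects, then
# distance transects by increasing distance, control last.
.scanOrder <- function(layout) {
  grp <- ifelse(layout$zone %in% c("pipeline_area", "inter_pipeline"), 1L,
         ifelse(layout$zone == "distance", 2L, 3L))
  order(grp, ifelse(grp == 2L, layout$distance_m, seq_len(nrow(layout))))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
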