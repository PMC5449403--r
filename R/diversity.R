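#' Shannon-Wiener diversity index
#'
#' `H = -sum (n_i/N) log(n_i/N)` over species with `n_i > 0`. The default
#' base is 10 ("lg"), the convention of the printed belt-transect equations;
#' `base = exp(1)` gives the classical nat-based index. Changing base rescales
#' H by a constant factor.
#'
#' @param abundances non-negative counts, at least one positive
#' @param base logarithm base: 10 (default) or `exp(1)`
#' @return H (dimensionless); 0 for a single species
#' @examples
#' shannonIndex(c(10, 10))            # lg 2 = 0.30103
#' shannonIndex(c(10, 10), exp(1))    # ln 2
#' @export
shannonIndex <- function(abundances, base = 10) {
  if (any(abundances < 0)) .stopf("negative abundance")
  if (all(abundances == 0)) .stopf("all-zero abundances")
  p <- abundances[abundances > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Pielou's evenness index
#'
#' `Evenness = H / ln S`, with H in the chosen base. The default follows the
#' printed belt-transect equations verbatim: H in base 10 divided by the
#' natural log of S -- a mixed-base form under which evenness is bounded by
#' `1/ln 10`, not 1. `base = exp(1)` restores the classical Pielou index with
#' its unit upper bound. A single species returns 0 by convention.
#'
#' @inheritParams shannonIndex
#' @return evenness (dimensionless)
#' @examples
#' pielouEvenness(c(10, 10))          # 0.30103 / ln 2 = 1 / ln 10
#' pielouEvenness(c(10, 10), exp(1))  # 1
#' @export
pielouEvenness <- function(abundances, base = 10) {
  if (any(abundances < 0)) .stopf("negative abundance")
  if (all(abundances == 0)) .stopf("all-zero abundances")
  S <- sum(abundances > 0)
  if (S < 2) return(0)
  shannonIndex(abundances, base = base) / log(S)
}

#' Margalef's richness index
#'
#' `Richness = (S - 1) / ln N` for `S` species among `N` individuals;
#' 0 when a single species is present (including the forced case N = 1).
#'
#' @param S number of species (>= 1)
#' @param N total number of individuals (>= S requirement: a plot cannot hold
#'   more species than individuals)
#' @return richness (dimensionless)
#' @examples
#' margalefRichness(3, 20)  # 2 / ln 20
#' @export
margalefRichness <- function(S, N) {
  if (any(S < 1) || any(N < 1)) .stopf("S and N must be >= 1")
  if (any(S > N)) .stopf("S cannot exceed N")
  ifelse(S == 1, 0, (S - 1) / log(N))
}

#' Mean percent cover of vegetation in a belt transect
#'
#' Arithmetic mean of the plots' visually estimated total cover.
#'
#' @param x a [CommunityDataset-class]
#' @param transectId transect identifier
#' @return percent cover (0--100 scale)
#' @export
percentCover <- function(x, transectId) {
  cd <- colData(x)
  pl <- which(cd$transect_id == transectId)
  if (!length(pl)) .stopf("transect '%s' has no plots", transectId)
  mean(cd$total_cover[pl])
}

#' Community indices per belt transect (or per plot)
#'
#' Shannon-Wiener H, Pielou evenness, Margalef richness and mean percent
#' cover. `mode = "pooled"` (default) pools each transect's plots into one
#' abundance vector; `mode = "plot"` returns one row per plot (the form used
#' when correlating indices against per-plot indicator values).
#'
#' @param x a [CommunityDataset-class]
#' @param mode `"pooled"` or `"plot"`
#' @param base logarithm base for H (and the numerator of evenness)
#' @return data.frame with columns `transect_id` (and `plot_id` in plot
#'   mode), `H`, `evenness`, `richness`, `percent_cover`
#' @export
diversityIndices <- function(x, mode = c("pooled", "plot"), base = 10) {
  mode <- match.arg(mode)
  cnt <- plotCounts(x)
  cd <- colData(x)
  one <- function(v, pc) {
    S <- sum(v > 0); N <- sum(v)
    if (N == 0)   # bare plot: all indices are zero by convention
      return(data.frame(H = 0, evenness = 0, richness = 0,
                        percent_cover = pc))
    data.frame(H = shannonIndex(v, base = base),
               evenness = pielouEvenness(v, base = base),
               richness = if (N >= 1) margalefRichness(max(S, 1), N) else 0,
               percent_cover = pc)
  }
  if (mode == "pooled") {
    lay <- transectLayout(x)
    out <- do.call(rbind, lapply(lay$transect_id, function(tid) {
      pl <- which(cd$transect_id == tid)
      cbind(data.frame(transect_id = tid),
            one(rowSums(cnt[, pl, drop = FALSE]),
                mean(cd$total_cover[pl])))
    }))
  } else {
    out <- do.call(rbind, lapply(seq_len(ncol(cnt)), function(j) {
      cbind(data.frame(plot_id = cd$plot_id[j],
                       transect_id = cd$transect_id[j]),
            one(cnt[, j], cd$total_cover[j]))
    }))
  }
  rownames(out) <- NULL
  out
}
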