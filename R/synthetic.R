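#' Species archetype for the synthetic survey generator
#'
#' Describes one species' distance response. Expected stalk count per plot at
#' distance `d` is `lambda(d) = baseline * (1 + (multiplier - 1) * sigma(d))`
#' with `sigma(d) = 1 / (1 + (d / midpoint)^steepness)`, a decreasing
#' logistic in log distance (`sigma(0) = 1`, `sigma -> 0` far out). Pioneers
#' (`multiplier > 1`) are boosted near the corridor; original dominants
#' (`multiplier < 1`) are suppressed near and recover to `baseline` beyond
#' the true effect extent; accompanying species combine a small baseline,
#' near-field suppression and partial plot occupancy.
#'
#' @param name species name
#' @param role `"pioneer"`, `"original_dominant"` or `"accompanying"`
#' @param baseline far-field mean stalks per plot (lambda-infinity, >= 0)
#' @param multiplier near-field multiplier (> 0; 1 = no response)
#' @param midpoint response midpoint in metres (> 0)
#' @param steepness logistic steepness in log distance (> 0)
#' @param coverPerStalk mean percent cover contributed per stalk
#' @param coverShape gamma shape of the per-stalk cover draw
#' @param occupancy per-plot presence probability
#' @return a `speciesArchetype` list
#' @export
speciesArchetype <- function(name,
                             role = c("pioneer", "original_dominant",
                                      "accompanying"),
                             baseline, multiplier = 1, midpoint = 100,
                             steepness = 2.5, coverPerStalk = 0.5,
                             coverShape = 4, occupancy = 1) {
  role <- match.arg(role)
  if (baseline < 0) .stopf("baseline must be >= 0")
  if (multiplier <= 0) .stopf("multiplier must be > 0")
  if (midpoint <= 0 || steepness <= 0)
    .stopf("midpoint and steepness must be > 0")
  if (coverPerStalk <= 0 || coverShape <= 0)
    .stopf("cover parameters must be positive")
  if (occupancy < 0 || occupancy > 1) .stopf("occupancy must be in [0, 1]")
  structure(list(name = name, role = role, baseline = baseline,
                 multiplier = multiplier, midpoint = midpoint,
                 steepness = steepness, coverPerStalk = coverPerStalk,
                 coverShape = coverShape, occupancy = occupancy),
            class = "speciesArchetype")
}

.loadPresets <- function() {
  jsonlite::read_json(system.file("extdata", "synthetic-presets.json",
                                  package = "ecoextent"))
}

#' Configure a synthetic belt-transect scenario
#'
#' Named presets (shipped as a version-controlled parameter file) bundle a
#' survey design, species archetypes, the true effect extent and the count
#' dispersion: `"s1_like"` emulates a multi-pipeline corridor (8 species --
#' 3 pioneers, 2 original dominants, 3 accompanying -- on the S1 design, true
#' extent 300 m), `"s2_like"` a single younger pipeline (6 species on S2,
#' true extent 100 m), and `"null"` an undisturbed community (all responses
#' flat; no extent defined). Pass `design`/`archetypes` for a custom
#' scenario.
#'
#' @param preset `"s1_like"`, `"s2_like"`, `"null"` or `"custom"`
#' @param design custom layout data.frame (required for `"custom"`)
#' @param archetypes custom list of [speciesArchetype()] (for `"custom"`)
#' @param effectExtent custom true extent in metres (for `"custom"`)
#' @param dispersion negative-binomial dispersion phi
#'   (`Var = lambda + phi * lambda^2`); 0 gives Poisson counts
#' @return a [SyntheticConfig-class]
#' @export
syntheticConfig <- function(preset = c("s1_like", "s2_like", "null", "custom"),
                            design = NULL, archetypes = NULL,
                            effectExtent = NA_real_, dispersion = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(design) || is.null(archetypes))
      .stopf("custom scenarios need both design and archetypes")
    return(methods::new("SyntheticConfig", design = as.data.frame(design),
                        archetypes = archetypes,
                        effectExtent = as.numeric(effectExtent),
                        dispersion = dispersion %||% 0.3, preset = "custom"))
  }
  p <- .loadPresets()[[preset]]
  arch <- lapply(p$archetypes, function(a)
    speciesArchetype(a$name, a$role, a$baseline, a$multiplier, a$midpoint_m,
                     a$steepness, a$cover_per_stalk, a$cover_shape,
                     a$occupancy))
  methods::new("SyntheticConfig",
               design = buildDesign(p$design),
               archetypes = arch,
               effectExtent = if (is.null(p$effect_extent_m)) NA_real_
                              else as.numeric(p$effect_extent_m),
               dispersion = dispersion %||% p$dispersion,
               preset = preset)
}

#' @rdname trueExtent
#' @export
setMethod("trueExtent", "SyntheticConfig", function(x) {
  if (is.na(x@effectExtent))
    message("undisturbed scenario: no effect extent is defined")
  x@effectExtent
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig '%s': %d species, %d transects, true extent %s\n",
              object@preset, length(object@archetypes), nrow(object@design),
              if (is.na(object@effectExtent)) "undefined"
              else paste0(object@effectExtent, " m")))
})

#' Generate a synthetic belt-transect survey
#'
#' Draws a plot-level survey from a [SyntheticConfig-class]: per plot and
#' species, expected count `lambda(d)` follows the archetype's logistic
#' distance response (see [speciesArchetype()]), counts are negative binomial
#' (Poisson when `dispersion = 0`) thinned by plot occupancy, and covers are
#' the count times a per-plot gamma per-stalk cover -- correlated with, but
#' not identical to, abundance, as in field data. Plot total cover is the sum
#' of species covers (rescaled in the rare event it exceeds 99%). The result
#' is fully determined by the seed.
#'
#' @param config a [SyntheticConfig-class]
#' @param seed integer seed (mandatory: scenarios must be reproducible)
#' @return a [CommunityDataset-class]
#' @examples
#' x <- generateSurvey(syntheticConfig("s1_like"), seed = 1)
#' @export
generateSurvey <- function(config, seed) {
  if (missing(seed) || is.null(seed)) .stopf("seed is mandatory")
  methods::validObject(config)
  lay <- config@design
  arch <- config@archetypes
  phi <- config@dispersion
  nsp <- length(arch)
  spNames <- vapply(arch, `[[`, character(1), "name")
  .withSeed(seed, {
    plots <- data.frame(
      plot_id = unlist(lapply(seq_len(nrow(lay)), function(i)
        sprintf("%s_p%d", lay$transect_id[i], seq_len(lay$n_plots[i])))),
      transect_id = rep(lay$transect_id, lay$n_plots),
      stringsAsFactors = FALSE)
    d <- lay$distance_m[match(plots$transect_id, lay$transect_id)]
    np <- nrow(plots)
    counts <- matrix(0L, nsp, np, dimnames = list(spNames, plots$plot_id))
    cover <- matrix(0, nsp, np, dimnames = list(spNames, plots$plot_id))
    for (s in seq_len(nsp)) {
      a <- arch[[s]]
      sigma <- 1 / (1 + (d / a$midpoint)^a$steepness)
      lambda <- a$baseline * (1 + (a$multiplier - 1) * sigma)
      occ <- stats::rbinom(np, 1, a$occupancy)
      n <- if (phi > 0)
        stats::rnbinom(np, mu = lambda, size = 1 / phi)
      else stats::rpois(np, lambda)
      n <- n * occ
      perStalk <- stats::rgamma(np, shape = a$coverShape,
                                rate = a$coverShape / a$coverPerStalk)
      counts[s, ] <- n
      cover[s, ] <- n * perStalk
    }
    tot <- colSums(cover)
    over <- tot > 99
    if (any(over))
      cover[, over] <- sweep(cover[, over, drop = FALSE], 2,
                             99 / tot[over], `*`)
    plots$total_cover <- colSums(cover)
    CommunityDataset(counts, cover, plots, lay)
  })
}
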