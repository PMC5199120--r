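# Log-uniform Latin hypercube sampling of the kinetic parameter space.

#' Specification of a Latin hypercube parameter sample
#'
#' Each sampled parameter is drawn log-uniformly over `span` decades centered
#' on its reference value (the default span of 8 decades means +/- 4 decades).
#' Non-sampled parameters stay at their reference value. The default sampled
#' set is the 12 kinetic parameters, including the occupied-receptor
#' hydrolysis rate as an independent dimension; receptor and G-protein totals
#' are not sampled (robustness classification varies receptor abundance
#' deliberately).
#'
#' @param n number of points.
#' @param span width of each parameter's range, decades.
#' @param sampled character vector of parameter names to sample.
#' @param center a [carousel_params()] object giving the reference values.
#' @param seed integer seed making the draw reproducible.
#' @return A list of class `lhs_spec`.
#' @export
lhs_spec <- function(n = 1e5, span = 8, sampled = kinetic_parameter_names(),
                     center = carousel_params(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (span <= 0) stop("span must be positive")
  if (!length(sampled)) stop("sampled set must be non-empty")
  bad <- setdiff(sampled, kinetic_parameter_names())
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  center <- as_carousel_params(center)
  structure(list(n = as.integer(n), span = span, sampled = sampled,
                 center = center, seed = as.integer(seed)),
            class = "lhs_spec")
}

#' Draw a Latin hypercube sample of kinetic parameters
#'
#' In each sampled dimension, log10(value) is stratified over
#' `[log10(center) - span/2, log10(center) + span/2]` with exactly one point
#' per equal-width stratum.
#'
#' @param spec an [lhs_spec()].
#' @return A data frame with one row per point and one column per primary
#'   kinetic parameter (sampled or fixed), attribute `spec` attached.
#' @export
lhs_sample <- function(spec) {
  stopifnot(inherits(spec, "lhs_spec"))
  u <- with_seed(spec$seed, lhs::randomLHS(spec$n, length(spec$sampled)))
  colnames(u) <- spec$sampled
  draws <- as.data.frame(
    matrix(rep(unlist(spec$center[kinetic_parameter_names()]),
               each = spec$n),
           nrow = spec$n,
           dimnames = list(NULL, kinetic_parameter_names())))
  for (nm in spec$sampled) {
    ctr <- spec$center[[nm]]
    draws[[nm]] <- ctr * 10^(spec$span * (u[, nm] - 0.5))
  }
  attr(draws, "spec") <- spec
  draws
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Provenance manifest of a parameter sample
#'
#' Serializes everything needed to regenerate the draws: the spec (n, span,
#' seed, sampled set, center values), the per-parameter ranges, and the
#' package version.
#'
#' @param spec an [lhs_spec()].
#' @param draws the data frame returned by [lhs_sample()] (optional; used
#'   only to record the realized row count).
#' @return A list suitable for JSON serialization.
#' @export
sample_manifest <- function(spec, draws = NULL) {
  centers <- unlist(spec$center[kinetic_parameter_names()])
  ranges <- lapply(spec$sampled, function(nm) {
    c(lo = unname(centers[nm]) * 10^(-spec$span / 2),
      hi = unname(centers[nm]) * 10^(spec$span / 2))
  })
  names(ranges) <- spec$sampled
  list(
    n = spec$n,
    span_decades = spec$span,
    seed = spec$seed,
    sampled = spec$sampled,
    centers = as.list(centers),
    ranges = ranges,
    n_drawn = if (!is.null(draws)) nrow(draws) else spec$n,
    package = "carousel",
    version = as.character(utils::packageVersion("carousel"))
  )
}

#' Rebuild draws from a manifest
#'
#' @param manifest a list produced by [sample_manifest()] (possibly
#'   round-tripped through JSON).
#' @return The identical draws data frame.
#' @export
draws_from_manifest <- function(manifest) {
  spec <- lhs_spec(n = manifest$n, span = manifest$span_decades,
                   sampled = unlist(manifest$sampled),
                   center = as_carousel_params(manifest$centers),
                   seed = manifest$seed)
  lhs_sample(spec)
}
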