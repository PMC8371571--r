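#' Specify a parameter's uncertainty distribution
#'
#' Distributions follow the published parameter table: triangular
#' `(min, mode, max)` for compliances, test characteristics and the
#' surveillance-tier utilities; beta `(shape1, shape2)` for treatment
#' compliances and disease-state utilities; gamma `(shape, rate)` for
#' costs. Some published cost gammas are printed in units of 10^4 US$;
#' a power-of-ten `unit_scale` reconciling the distribution mean with the
#' base-case value is inferred at load and applied to draws.
#'
#' @param kind `"fixed"`, `"triangular"`, `"beta"` or `"gamma"`.
#' @param params Numeric parameter vector: triangular `(min, mode, max)`,
#'   beta `(shape1, shape2)`, gamma `(shape, rate)`, fixed `(value)`.
#' @param range Optional `(low, high)` limits for one-way sweeps.
#' @param base Optional base-case value; used to infer `unit_scale` for
#'   gammas and to sanity-check the distribution mean (warning beyond 20%).
#' @param domain Semantic domain draws are clamped to, e.g. `c(0, 1)` for
#'   probabilities; default unbounded.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("fixed", "triangular", "beta", "gamma"),
                      params, range = NULL, base = NULL,
                      domain = c(-Inf, Inf)) {
  kind <- match.arg(kind)
  params <- as.numeric(params)
  unit_scale <- 1
  switch(kind,
         fixed = stopifnot(length(params) == 1),
         triangular = {
           stopifnot(length(params) == 3)
           if (!(params[1] <= params[2] && params[2] <= params[3]))
             stop("triangular needs min <= mode <= max", call. = FALSE)
         },
         beta = stopifnot(length(params) == 2, all(params > 0)),
         gamma = {
           stopifnot(length(params) == 2, all(params > 0))
           if (!is.null(base) && base > 0) {
             mean_raw <- params[1] / params[2]
             unit_scale <- 10^round(log10(base / mean_raw))
           }
         })
  if (!is.null(base) && kind %in% c("beta", "gamma") && base > 0) {
    m <- if (kind == "beta") params[1] / sum(params)
         else params[1] / params[2] * unit_scale
    if (abs(m - base) / base > 0.2)
      warning("distribution mean ", signif(m, 4),
              " far from base case ", base)
  }
  structure(list(kind = kind, params = params, range = range, base = base,
                 domain = domain, unit_scale = unit_scale),
            class = "dist_spec")
}

#' Closed-form mean of a distribution spec
#'
#' @param spec A `dist_spec`.
#' @return The mean (unit scale applied for gammas).
#' @export
dist_mean <- function(spec) {
  switch(spec$kind,
         fixed = spec$params[1],
         triangular = mean(spec$params),
         beta = spec$params[1] / sum(spec$params),
         gamma = spec$params[1] / spec$params[2] * spec$unit_scale)
}

# Inverse-CDF triangular sampler (a = min, c = mode, b = max).
rtriangular <- function(n, a, c, b) {
  u <- stats::runif(n)
  fc <- if (b > a) (c - a) / (b - a) else 0
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Draw from a parameter distribution
#'
#' Gamma draws are scaled by the spec's `unit_scale`; all draws are
#' clamped to the spec's semantic domain (probabilities and utilities to
#' `[0, 1]`). Uses the session RNG stream, so set a seed for
#' reproducibility.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  x <- switch(spec$kind,
              fixed = rep(spec$params[1], n),
              triangular = rtriangular(n, spec$params[1], spec$params[2],
                                       spec$params[3]),
              beta = stats::rbeta(n, spec$params[1], spec$params[2]),
              gamma = stats::rgamma(n, shape = spec$params[1],
                                    rate = spec$params[2]) * spec$unit_scale)
  pmin(pmax(x, spec$domain[1]), spec$domain[2])
}
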