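#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef nls optimize uniroot approxfun rnorm rlnorm
#'   predict median sd setNames vcov fitted residuals cor smooth.spline
#' @importFrom utils head tail modifyList
NULL

## Multiplicative mean-one log-normal noise with coefficient of variation cv.
## sdlog chosen so that sd/mean = cv and E[factor] = 1, so averaging many
## replicates converges on the noiseless value.
lognormal_factors <- function(n, cv) {
  stopifnot(cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

apply_noise <- function(x, cv) x * lognormal_factors(length(x), cv)

## Seed scoping: generators set the seed themselves so a fixed config is
## byte-reproducible, while leaving the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Generator configuration
#'
#' Shared configuration for all synthetic-data generators: the random seed,
#' the coefficient of variation of the multiplicative (log-normal, mean-one)
#' measurement noise, and the replicate count.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 disables noise).
#' @param replicate_count number of technical replicates per design point.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, noise_cv = 0, replicate_count = 1L) {
  assert_that(is_number(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  assert_that(is_number(replicate_count) && replicate_count >= 1,
              "replicate_count must be >= 1")
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 replicate_count = as.integer(replicate_count)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Generator config: seed", x$seed, "| noise CV", x$noise_cv,
      "| replicates", x$replicate_count, "\n")
  invisible(x)
}
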