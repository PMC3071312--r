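#' Simulation configuration for the synthetic-data generators
#'
#' Bundles the global integer seed, a per-generator noise level and replicate
#' counts.  All generators in the package are pure functions of their
#' parameters and this configuration: the same \code{sim_config} yields
#' byte-identical output.
#'
#' The global seed is split into independent per-generator substreams by a
#' fixed label hash (see \code{\link{substream_seed}}), so that e.g. adding
#' wells to a growth plate does not perturb the expression generator.
#'
#' @param seed single integer, global seed.
#' @param noise_sd nonnegative numeric, noise standard deviation in the
#'   units of the generator that consumes this configuration (OD for growth
#'   plates, log-units for expression, fluorescence for qPCR, and the
#'   standard deviation of the log for multiplicative fitness noise).
#' @param replicates named or unnamed list/vector of replicate counts per
#'   design cell (generator specific; optional).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, noise_sd = 0, replicates = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be a single nonnegative number")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 replicates = replicates),
            class = "sim_config")
}

#' Derive a per-generator substream seed
#'
#' Hashes a fixed character label together with the global seed into an
#' integer below 2^31, so independent generators draw from independent
#' random streams under one global seed.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stream.
#' @return a single integer suitable for \code{set.seed}.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid R integer
  h <- as.double(seed %% m)
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% m
  as.integer(h)
}

#' Evaluate an expression under a seeded substream
#'
#' Runs \code{expr} with the RNG seeded from
#' \code{\link{substream_seed}(seed, label)}, restoring the caller's RNG
#' state afterwards, so generators never disturb user-level randomness.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stream.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}
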