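#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so package functions are reproducible without
#' clobbering the caller's random stream. `seed = NULL` leaves the RNG alone.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed-splitting so pipeline stages and per-subject generators
#' can be re-run independently yet reproducibly. Mixes the master seed and a
#' stream index through a fixed linear-congruential step modulo the Mersenne
#' prime 2^31 - 1, keeping results in valid 32-bit integer range.
#'
#' @param seed master seed (integer, < 2^31).
#' @param stream non-negative integer stream index (or vector of indices).
#' @return integer seed(s) in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), all(stream >= 0))
  # doubles are exact up to 2^53; terms stay far below that
  x <- (abs(seed) %% 2147483647) * 48271 + (stream + 1) * 16807
  as.integer(x %% 2147483646 + 1)
}

# shared band definitions: 25 one-hertz bins centred 4..28 Hz, bands split by
# bin centre at the conventional theta/alpha/beta edges
plv_bin_grid <- function() 4:28

band_edges <- function(band) {
  switch(band,
    theta = c(4, 8),
    alpha = c(8, 12),
    beta  = c(12, 30),
    stop("unknown band: ", band)
  )
}

#' Frequency bins belonging to a band
#'
#' The PLV bin grid is 25 one-hertz bins with centres 4..28 Hz; a bin belongs
#' to theta for centres in \[4,8), alpha \[8,12), beta \[12,30).
#'
#' @param band one of `"theta"`, `"alpha"`, `"beta"`.
#' @param bins optional bin-centre grid, default `4:28`.
#' @return numeric vector of bin centres in the band.
#' @export
band_bins <- function(band, bins = plv_bin_grid()) {
  band <- match.arg(band, c("theta", "alpha", "beta"))
  e <- band_edges(band)
  out <- bins[bins >= e[1] & bins < e[2]]
  if (length(out) == 0L) stop("band '", band, "' has no assigned bins")
  out
}
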