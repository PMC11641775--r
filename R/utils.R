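# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Stochastic pipeline stages each take their own seed, derived from the study
#' master seed by a stable polynomial hash of a character key (typically
#' `(module, entity id)`). The result is always a positive integer below
#' 2^31 - 1 and does not depend on platform or locale.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/numeric key components identifying the entity.
#' @return A positive integer seed.
#' @examples
#' derive_seed(1, "activity", "DD", 3)
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(master_seed %% 2147483647)
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483563
  as.integer(h) + 1L
}

# Runs of TRUE in a logical vector: start index, end index, length.
true_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Clock hour-of-day (0-24) of a POSIXct instant.
clock_hours <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
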