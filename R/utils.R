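#' Derive a reproducible stage seed from a master seed
#'
#' Stochastic stages draw their seeds from one master seed through a stable
#' string hash, so each stage is reproducible in isolation and no stage
#' perturbs another's random stream.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name (e.g. \code{"battery"}).
#' @return An integer seed in \code{[0, 2^31)}.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((abs(master_seed) %% 1048573) * 2039 + h) %% 2147483647)
}

# validate a scalar numeric in a closed range
.check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# coerce an EBImage-friendly matrix back to plain base matrix
.as_matrix <- function(x) {
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}
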