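#' Derive a reproducible sub-stream seed
#'
#' Mixes a base seed with one or more integer keys (animal index, measurement
#' index, channel, replicate, ...) into a new seed below 2^31, so that every
#' simulated unit draws from its own independent, reproducible random stream.
#' Changing one unit's key never perturbs another unit's draws.
#'
#' @param seed base integer seed.
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed.
#' @export
substream <- function(seed, ...) {
  keys <- c(...)
  # multiplier kept small so products stay within exact double range
  h <- abs(as.numeric(seed)) %% 2147483629
  for (k in keys) {
    h <- (h * 7919 + (abs(as.numeric(k)) %% 2147483629) * 104729 + 12345) %%
      2147483629
  }
  as.integer(h)
}

# circular shift right by k bins (k may be negative)
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1:(n - k)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
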