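#' Community quantile rule
#'
#' Single quantile code path shared by all modules: linear interpolation
#' between order statistics (R's type 7). Fixed once for reproducibility.
#'
#' @param x numeric vector.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles.
#' @export
ct_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

#' Derive a named substream seed from a root seed
#'
#' All random streams in the synthetic-data module are derived from one root
#' seed via named substreams, so adding a generator does not perturb the
#' draws of the others. The derivation is a small deterministic integer hash
#' of the stream name folded into the root seed; results stay within the
#' 32-bit signed range accepted by [set.seed()].
#'
#' @param seed root integer seed.
#' @param name character stream name.
#' @return integer seed for the substream.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483629 + 1)
}

# internal: stop with a classed condition so callers/tests can match on class
stop_classed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "thermotree_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# internal: left join on a key column, base R
join_on <- function(x, y, by) {
  merge(x, y, by = by, all.x = TRUE, sort = FALSE)
}
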