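# shared internal helpers

# round half away from zero (base round() is banker's); used wherever a pixel
# coordinate or display value must round deterministically
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive a bounded sub-seed from a parent seed and an index; keeps every
# derived seed in [0, 2^31) so it is a valid R/C seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed %% 2147483647L) * 48271 + 1000003 * as.numeric(index)) %%
    2147483647)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# empty detections table with canonical columns
empty_detections <- function() {
  data.frame(
    x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
    confidence = numeric(0)
  )
}

as_detections <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(empty_detections())
  }
  d <- as.data.frame(m)
  names(d) <- c("x0", "y0", "x1", "y1", "confidence")
  d
}
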