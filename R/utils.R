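# shared internal helpers

# round-half-up: round(2.5) in R is banker's rounding, the split/apportionment
# contracts require 0.5 to always round away from zero (positive inputs only)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emaclass <- function(..., class = "emaclass_error") {
  stop(structure(
    class = unique(c(class, "emaclass_error", "error", "condition")),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), EMA_CLASSES)
  if (length(bad) > 0) {
    stop_emaclass("unknown class label(s): ", paste(bad, collapse = ", "),
                  class = "emaclass_validation_error")
  }
  factor(labels, levels = EMA_CLASSES)
}

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
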