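#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific 31-bit seed from a master seed, so that pipeline
# stages draw from independent, reproducible streams.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offsets <- c(
    dataset  = 104729L,
    split    = 130363L,
    hidden   = 15485863L,
    pso      = 32452843L,
    trainer  = 49979687L
  )
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream)
  }
  (as.integer(master) %% 1000000000L) + offsets[[stream]]
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
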