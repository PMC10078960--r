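# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a fixed RNG seed, restoring global RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_s_range <- function(s, range = c(-2, 2), name = "s") {
  if (!is.numeric(s) || any(!is.finite(s))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  if (any(s < range[1] - 1e-12) || any(s > range[2] + 1e-12)) {
    stop(sprintf("'%s' outside the scaling range [%g, %g]", name,
                 range[1], range[2]), call. = FALSE)
  }
  invisible(s)
}
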