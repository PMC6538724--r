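# internal helpers: argument checks and seeded evaluation

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_bad_arg("`", name, "` must be a single non-missing number")
  }
  if (finite && !is.finite(x)) stop_bad_arg("`", name, "` must be finite")
  ok <- if (strict_min) x > min else x >= min
  if (!ok) {
    stop_bad_arg("`", name, "` must be ", if (strict_min) "> " else ">= ", min,
                 " (got ", format(x), ")")
  }
  invisible(x)
}

check_counts <- function(n, name = "n") {
  if (!is.numeric(n) || length(n) < 1L || anyNA(n)) {
    stop_bad_arg("`", name, "` must be non-missing numeric")
  }
  if (any(n < 0) || any(n != floor(n))) {
    stop_bad_arg("`", name, "` must contain non-negative integers")
  }
  invisible(n)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit sub-seed for stream i of a master seed.
derive_seed <- function(master, i) {
  if (is.null(master)) return(NULL)
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 1664525) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
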