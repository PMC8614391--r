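# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded package
#' operations never disturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# ISO weekday index, Monday = 1 ... Sunday = 7 (1970-01-01 was a Thursday)
iso_weekday <- function(date) ((as.integer(as.Date(date)) + 3L) %% 7L) + 1L

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) stop("could not parse ", what, ": ", paste(x, collapse = ", "),
                     call. = FALSE)
  d
}

# truncated-normal draw by clipping (documented behaviour of the generator:
# draws are Gaussian then clipped to a plausible range, not resampled)
rnorm_clip <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(n, mean, sd)))

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]", call. = FALSE)
  invisible(x)
}

warn_count <- function(n, what) {
  if (n > 0L) warning(sprintf("%d %s", n, what), call. = FALSE)
  n
}
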