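#' Segmentation specification
#'
#' Controls the piecewise linear-regression segmentation: the within-segment
#' design, the minimum admissible segment length as a fraction of the series
#' length, and the maximum number of breaks considered.
#'
#' @param design `"constant"` (intercept-only, piecewise level shifts; the
#'   default) or `"trend"` (intercept plus linear time within each segment).
#' @param min_segment_frac minimum segment length as a fraction of `n`
#'   (`h = ceiling(frac * n)`, never below the number of regressors).
#' @param m_max maximum number of breaks examined.
#' @return object of class `segment_spec`.
#' @export
segment_spec <- function(design = c("constant", "trend"),
                         min_segment_frac = 0.15, m_max = 5L) {
  design <- match.arg(design)
  stopifnot_scalar_num(min_segment_frac, "min_segment_frac", 1e-6, 0.5)
  stopifnot_scalar_num(m_max, "m_max", 0)
  structure(list(design = design, min_segment_frac = min_segment_frac,
                 m_max = as.integer(m_max)), class = "segment_spec")
}

design_matrix <- function(design, n) {
  switch(design,
         constant = matrix(1, n, 1),
         trend = cbind(1, seq_len(n)),
         stop("unknown design '", design, "'"))
}

# cumulative cross-product arrays for O(1) segment least squares
.xprefix <- function(y, X) {
  n <- length(y); p <- ncol(X)
  list(
    n = n, p = p,
    cyy = c(0, cumsum(y * y)),
    cXy = rbind(0, apply(X * y, 2, cumsum)),
    cXX = vapply(seq_len(p), function(a)
      vapply(seq_len(p), function(b) c(0, cumsum(X[, a] * X[, b])),
             numeric(n + 1)), matrix(0, n + 1, p))  # (n+1) x p x p
  )
}

# RSS of the least-squares fit on y[i..j]; vectorised over j for fixed i
# (or over i for fixed j)
.rss_seg <- function(pf, i, j) {
  p <- pf$p
  if (p == 1L) {
    len <- j - i + 1
    s1 <- pf$cXy[j + 1, 1] - pf$cXy[i, 1]
    s2 <- pf$cyy[j + 1] - pf$cyy[i]
    return(pmax(0, s2 - s1^2 / len))
  }
  # general small-p path (scalar i, j)
  stopifnot(length(i) == 1L, length(j) == 1L)
  XX <- matrix(pf$cXX[j + 1, , ] - pf$cXX[i, , ], p, p)
  Xy <- pf$cXy[j + 1, ] - pf$cXy[i, ]
  yy <- pf$cyy[j + 1] - pf$cyy[i]
  beta <- tryCatch(solve(XX, Xy), error = function(e) qr.solve(XX, Xy))
  max(0, yy - sum(beta * Xy))
}

.rss_seg_vec <- function(pf, i, js) {
  if (pf$p == 1L) return(.rss_seg(pf, i, js))
  vapply(js, function(j) .rss_seg(pf, i, j), numeric(1))
}

#' Residual sum of squares of one segment fit
#'
#' Least-squares fit of `y[i..j]` on the design restricted to those rows;
#' for the intercept-only design this is the sum of squared deviations from
#' the segment mean.
#'
#' @param y numeric series.
#' @param design design matrix (n x p) or a design name as in
#'   [segment_spec()].
#' @param i,j segment bounds (1-based, inclusive); requires
#'   `j - i + 1 >= p`.
#' @return the segment RSS (scalar).
#' @export
segment_rss <- function(y, design = "constant", i = 1L, j = length(y)) {
  X <- if (is.matrix(design)) design else design_matrix(design, length(y))
  stopifnot(i >= 1L, j <= length(y), i <= j)
  if (j - i + 1L < ncol(X)) stop("segment shorter than the number of regressors")
  .rss_seg(.xprefix(y, X), i, j)
}

#' Optimal m-break partition by dynamic programming
#'
#' Finds exactly the `m` break positions minimising the total within-segment
#' RSS over all partitions whose segments each have at least `h`
#' observations, by dynamic programming over suffix optima. Ties are broken
#' toward the lexicographically earliest break vector.
#'
#' @param y numeric series.
#' @param design design matrix or design name.
#' @param m number of breaks (>= 0).
#' @param h minimum segment length.
#' @return list: `breaks` (1-based last index of each of the first `m`
#'   segments; integer(0) for `m = 0`) and `rss` (total RSS).
#' @export
optimal_partition <- function(y, design = "constant", m, h) {
  n <- length(y)
  X <- if (is.matrix(design)) design else design_matrix(design, n)
  p <- ncol(X)
  h <- max(as.integer(h), p)
  m <- as.integer(m)
  if (m < 0L) stop("m must be >= 0")
  if ((m + 1L) * h > n)
    stop("infeasible: ", m, " breaks with minimum segment length ", h,
         " need more than ", n, " observations")
  pf <- .xprefix(y, X)
  if (m == 0L) return(list(breaks = integer(0), rss = .rss_seg(pf, 1L, n)))

  # B[s, i]: optimal cost of splitting y[i..n] into s segments
  S <- m + 1L
  B <- matrix(Inf, S, n + 1L)
  istart <- n - h + 1L
  if (p == 1L) {
    # vectorised fill of the single-segment row
    is <- 1:istart
    len <- n - is + 1
    s1 <- pf$cXy[n + 1, 1] - pf$cXy[is, 1]
    s2 <- pf$cyy[n + 1] - pf$cyy[is]
    B[1L, is] <- pmax(0, s2 - s1^2 / len)
  } else {
    for (i in 1:istart) B[1L, i] <- .rss_seg(pf, i, n)
  }
  for (s in 2:S) {
    imax <- n - s * h + 1L
    for (i in 1:imax) {
      ks <- (i + h - 1L):(n - (s - 1L) * h)  # candidate first-segment ends
      B[s, i] <- min(.rss_seg_vec(pf, i, ks) + B[s - 1L, ks + 1L])
    }
  }
  # reconstruct from the front; which.min takes the first (earliest) optimum
  breaks <- integer(m)
  i <- 1L
  for (s in S:2L) {
    ks <- (i + h - 1L):(n - (s - 1L) * h)
    tot <- .rss_seg_vec(pf, i, ks) + B[s - 1L, ks + 1L]
    k <- ks[which.min(tot)]
    breaks[S - s + 1L] <- k
    i <- k + 1L
  }
  list(breaks = breaks, rss = B[S, 1L])
}

#' Select the number of breaks by BIC over RSS-optimal partitions
#'
#' Computes the RSS-optimal partition for each `m = 0..m_max` and selects
#' the `m` minimising `BIC_m = n * log(RSS_m / n) + k_m * log(n)` with
#' `k_m = (m + 1) * p + m` (segment coefficients plus break positions).
#' Ties in BIC go to the smaller `m`. If some partition fits exactly
#' (RSS numerically zero) the BIC is undefined from that point on; the
#' smallest exactly-fitting `m` is selected and flagged.
#'
#' @param y numeric series (a [build_series()] result may be passed
#'   directly, in which case its mean column and dates are used).
#' @param spec a [segment_spec()].
#' @param dates optional Date vector labelling the observations.
#' @return object of class `segmentation`: selected `m`, integer `breaks`
#'   (last index of each segment), `break_dates`, `table`
#'   (m, rss, bic), per-segment coefficient estimates, `exact_fit` flag,
#'   plus the inputs needed by [break_intervals()].
#' @export
select_breaks <- function(y, spec = segment_spec(), dates = NULL) {
  if (inherits(y, "cohort_series")) {
    dates <- dates %||% y$date
    y <- y$mean
  }
  y <- as.numeric(y)
  n <- length(y)
  X <- design_matrix(spec$design, n)
  p <- ncol(X)
  h <- max(as.integer(ceiling(spec$min_segment_frac * n)), p)
  m_feasible <- min(spec$m_max, n %/% h - 1L)
  if (n < 2L * h)
    stop("series too short for segmentation: n = ", n, ", h = ", h)
  ms <- 0:m_feasible
  parts <- lapply(ms, function(m) optimal_partition(y, X, m, h))
  rss <- vapply(parts, `[[`, numeric(1), "rss")
  # RSS must be nonincreasing wherever the m-optimum still has a segment of
  # length >= 2h (that segment could host the extra break); where the
  # minimum-segment constraint binds, a larger m can genuinely fit worse,
  # and such entries can never win the BIC comparison anyway.
  seg_lens <- lapply(parts, function(pp) diff(c(0L, pp$breaks, n)))
  refinable <- vapply(seg_lens, function(l) max(l) >= 2L * h, logical(1))
  refinable[length(refinable)] <- FALSE
  stopifnot(all(diff(rss)[refinable[-length(rss)]] <=
                  1e-8 * (1 + rss[-length(rss)][refinable[-length(rss)]])))
  eps <- 1e-10 * max(1, sum(y^2) / n)
  exact <- rss <= eps
  bic <- ifelse(exact, NA_real_,
                n * log(pmax(rss, eps) / n) + ((ms + 1) * p + ms) * log(n))
  if (any(exact)) {
    m_star <- ms[which(exact)[1]]
    exact_fit <- TRUE
  } else {
    m_star <- ms[which.min(bic)]  # first minimum -> smaller m on ties
    exact_fit <- FALSE
  }
  chosen <- parts[[m_star + 1L]]
  bounds <- c(0L, chosen$breaks, n)
  coefs <- lapply(seq_len(m_star + 1L), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    fit <- lm.fit(X[idx, , drop = FALSE], y[idx])
    coef(fit)
  })
  structure(list(
    m = m_star, breaks = chosen$breaks,
    break_dates = if (!is.null(dates)) dates[chosen$breaks] else NULL,
    table = data.frame(m = ms, rss = rss, bic = bic),
    segments = coefs, exact_fit = exact_fit,
    y = y, dates = dates, design = spec$design, h = h, p = p
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> n = %d, design = %s, h = %d\n",
              length(x$y), x$design, x$h))
  cat(sprintf("  selected m = %d%s\n", x$m,
              if (x$exact_fit) " (exact fit; BIC undefined)" else ""))
  if (x$m > 0) {
    cat("  breaks at index:", paste(x$breaks, collapse = ", "), "\n")
    if (!is.null(x$break_dates))
      cat("  break dates:", paste(format(x$break_dates), collapse = ", "), "\n")
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}

# piecewise fitted values for a given break vector
.piecewise_fit <- function(y, X, breaks) {
  n <- length(y)
  bounds <- c(0L, breaks, n)
  fit <- numeric(n)
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    f <- lm.fit(X[idx, , drop = FALSE], y[idx])
    fit[idx] <- f$fitted.values
  }
  fit
}

# moving-block bootstrap of a residual vector (within one segment)
.block_resample <- function(res, block) {
  len <- length(res)
  b <- min(block, len)
  nstart <- len - b + 1L
  nblocks <- ceiling(len / b)
  starts <- sample.int(nstart, nblocks, replace = TRUE)
  idx <- as.vector(outer(0:(b - 1L), starts, `+`))[seq_len(len)]
  res[idx]
}

#' Bootstrap confidence intervals for break dates
#'
#' Moving-block bootstrap of within-segment residuals: residuals from the
#' selected piecewise fit are resampled in contiguous blocks (block length
#' shrinks, with a warning, for segments shorter than the block), added back
#' to the fitted values, and the breaks re-estimated with `m` fixed at the
#' selected value. Percentile intervals of the replicated break positions
#' are reported, mapped to dates when the segmentation carries them.
#'
#' @param result a [select_breaks()] result with `m >= 1`.
#' @param level interval level (default 0.95).
#' @param block_length residual block length in observations (default 7,
#'   one week for daily series).
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed (intervals are deterministic given the seed).
#' @return data.frame: break_index, lo_index, hi_index and (when dated)
#'   break_date, lo_date, hi_date; attribute `level`.
#' @export
break_intervals <- function(result, level = 0.95, block_length = 7L,
                            n_boot = 200L, seed = 1L) {
  stopifnot(inherits(result, "segmentation"))
  if (result$m < 1L) stop("no breaks selected; nothing to interval-estimate")
  y <- result$y
  n <- length(y)
  X <- design_matrix(result$design, n)
  fit <- .piecewise_fit(y, X, result$breaks)
  res <- y - fit
  bounds <- c(0L, result$breaks, n)
  seg_idx <- lapply(seq_len(length(bounds) - 1L),
                    function(s) (bounds[s] + 1L):bounds[s + 1L])
  short <- vapply(seg_idx, length, integer(1)) < block_length
  if (any(short))
    warning(sum(short), " segment(s) shorter than the block length; ",
            "block shrunk to the segment length there")

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      rstar <- numeric(n)
      for (idx in seg_idx)
        rstar[idx] <- .block_resample(res[idx], block_length)
      optimal_partition(fit + rstar, X, result$m, result$h)$breaks
    }, integer(result$m))
  })
  reps <- matrix(reps, nrow = result$m)
  alpha <- (1 - level) / 2
  lo <- apply(reps, 1, function(v) as.integer(quantile(v, alpha, type = 1)))
  hi <- apply(reps, 1, function(v) as.integer(quantile(v, 1 - alpha, type = 1)))
  out <- data.frame(break_index = result$breaks, lo_index = lo, hi_index = hi)
  if (!is.null(result$dates)) {
    out$break_date <- result$dates[out$break_index]
    out$lo_date <- result$dates[out$lo_index]
    out$hi_date <- result$dates[out$hi_index]
  }
  attr(out, "level") <- level
  out
}
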