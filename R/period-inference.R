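#' Construct a mixed-model fit object from known quantities
#'
#' Mostly internal, but exported so that published period means (with a
#' covariance, possibly diagonal) can be pushed through the same contrast
#' machinery as fitted models.
#'
#' @param coefficients named numeric vector of cell (period) means.
#' @param vcov covariance matrix of the coefficients.
#' @param sigma2,sigma_b2 residual and between-participant variances.
#' @param n_obs,n_participants sample sizes.
#' @param converged,boundary optimiser flags.
#' @return object of class `wear_mixed_fit`.
#' @export
mixed_fit <- function(coefficients, vcov = diag(0, length(coefficients)),
                      sigma2 = NA_real_, sigma_b2 = NA_real_,
                      n_obs = NA_integer_, n_participants = NA_integer_,
                      converged = TRUE, boundary = FALSE) {
  k <- length(coefficients)
  stopifnot(is.matrix(vcov), nrow(vcov) == k, ncol(vcov) == k)
  if (is.null(names(coefficients)))
    names(coefficients) <- paste0("P", seq_len(k))
  dimnames(vcov) <- list(names(coefficients), names(coefficients))
  structure(list(coefficients = coefficients, vcov = vcov,
                 sigma2 = sigma2, sigma_b2 = sigma_b2,
                 n_obs = n_obs, n_participants = n_participants,
                 converged = converged, boundary = boundary),
            class = "wear_mixed_fit")
}

#' @export
coef.wear_mixed_fit <- function(object, ...) object$coefficients

#' @export
vcov.wear_mixed_fit <- function(object, ...) object$vcov

#' @export
print.wear_mixed_fit <- function(x, ...) {
  cat("<random-intercept fit>\n")
  cat(sprintf("  %s obs, %s participants\n", x$n_obs, x$n_participants))
  est <- data.frame(mean = x$coefficients, se = sqrt(diag(x$vcov)))
  print(round(est, 3))
  cat(sprintf("  sigma_b = %.4g, sigma = %.4g%s\n",
              sqrt(x$sigma_b2), sqrt(x$sigma2),
              if (isTRUE(x$boundary)) " (variance ratio at boundary 0)" else ""))
  invisible(x)
}

# profiled REML for y = mu_cell + b_id + e, b ~ N(0, sigma_b2), e ~ N(0, sigma2).
# For lambda = sigma_b2/sigma2, V = I + lambda * Z Z' is block diagonal per
# participant with (I + lambda J)^{-1} = I - lambda/(1 + lambda n_i) J, so all
# GLS quantities reduce to per-participant and per-(participant, cell) sums.
.reml_profile <- function(y, cell, id) {
  cell <- droplevels(as.factor(cell))
  id <- droplevels(as.factor(id))
  K <- nlevels(cell)
  n <- length(y)
  ni <- as.vector(table(id))                      # obs per participant
  Ti <- as.vector(rowsum(y, id))                  # per-participant totals
  Nik <- stats::xtabs(~ id + cell)                # counts per (participant, cell)
  Sik <- rowsum(stats::model.matrix(~ cell - 1) * y, id)  # sums per (i, k)
  nk <- colSums(Nik)
  sk <- colSums(Sik)
  Syy <- sum(y * y)
  Nik <- matrix(as.numeric(Nik), nrow(Nik), K)
  Sik <- matrix(as.numeric(Sik), nrow(Sik), K)

  eval_lambda <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- diag(nk, K) - crossprod(Nik * sqrt(ci))       # X' V^-1 X
    u <- sk - colSums(Nik * (ci * Ti))                 # X' V^-1 y
    q <- Syy - sum(ci * Ti^2)                          # y' V^-1 y
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), u))
    rss <- max(q - sum(beta * u), 1e-300)
    logdetV <- sum(log1p(lambda * ni))
    logdetA <- 2 * sum(log(diag(ch)))
    crit <- (n - K) * log(rss) + logdetV + logdetA     # profiled -2 REML + const
    list(crit = crit, beta = beta, rss = rss, chol = ch)
  }

  # coarse grid then Brent refinement on log-lambda; check the boundary too
  grid <- c(-Inf, seq(-12, 12, length.out = 49))
  crits <- vapply(grid, function(g) eval_lambda(if (is.finite(g)) exp(g) else 0)$crit,
                  numeric(1))
  gbest <- which.min(crits)
  if (gbest == 1L) {
    lam <- 0; converged <- TRUE
  } else {
    lo <- grid[max(2L, gbest - 1L)]; hi <- grid[min(length(grid), gbest + 1L)]
    opt <- optimize(function(g) eval_lambda(exp(g))$crit, c(lo, hi))
    converged <- opt$objective <= min(crits) + 1e-8 * abs(min(crits))
    lam <- exp(opt$minimum)
    if (eval_lambda(0)$crit <= opt$objective) { lam <- 0 }
  }
  fin <- eval_lambda(lam)
  sigma2 <- fin$rss / (n - K)
  Ainv <- chol2inv(fin$chol)
  beta <- as.vector(fin$beta)
  names(beta) <- levels(cell)
  mixed_fit(beta, vcov = sigma2 * Ainv,
            sigma2 = sigma2, sigma_b2 = lam * sigma2,
            n_obs = n, n_participants = length(ni),
            converged = converged, boundary = (lam == 0))
}

#' Fit the participant-level random-intercept model
#'
#' Fits `y_it = mu_period(t) + b_i + e_it` with `b_i ~ N(0, sigma_b^2)` and
#' `e_it ~ N(0, sigma^2)` by restricted maximum likelihood, profiling out
#' both variances so that only the variance ratio is optimised (bounded
#' Brent search on the log scale after a coarse grid). Fixed effects are
#' parameterised as per-period cell means, so `coef()` returns the marginal
#' period means directly.
#'
#' @param observations data.frame with columns participant_id, period,
#'   value (see [make_long_observations()]).
#' @return a `wear_mixed_fit`; for degenerate input (a single participant)
#'   the variance ratio is pinned at 0 and `boundary` is set.
#' @export
fit_random_intercept <- function(observations) {
  stopifnot(all(c("participant_id", "period", "value") %in% names(observations)))
  obs <- observations[complete.cases(observations[c("participant_id", "period",
                                                    "value")]), ]
  if (nlevels(droplevels(as.factor(obs$period))) < 2L)
    stop("need at least 2 periods present in the observations")
  if (length(unique(obs$participant_id)) < 2L) {
    # degenerate: no between-participant information; OLS with flag
    cell <- droplevels(as.factor(obs$period))
    mm <- stats::model.matrix(~ cell - 1)
    fit <- lm.fit(mm, obs$value)
    s2 <- sum(fit$residuals^2) / max(1, length(obs$value) - ncol(mm))
    v <- s2 * chol2inv(chol(crossprod(mm)))
    return(mixed_fit(setNames(coef(fit), levels(cell)), vcov = v,
                     sigma2 = s2, sigma_b2 = 0,
                     n_obs = nrow(obs), n_participants = 1L,
                     converged = TRUE, boundary = TRUE))
  }
  .reml_profile(obs$value, obs$period, obs$participant_id)
}

#' Pairwise period contrasts with Bonferroni adjustment
#'
#' All pairwise differences of the fitted period means, with standard
#' errors from the fixed-effect covariance, normal-approximation confidence
#' intervals at level `1 - alpha / C`, and p-values multiplied by the
#' number of comparisons `C` (capped at 1).
#'
#' @param fit a `wear_mixed_fit` (from [fit_random_intercept()] or
#'   [mixed_fit()]).
#' @param level family-wise confidence level (default 0.95).
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return a `contrast_table` data.frame: contrast, estimate, se, lo, hi,
#'   z, p_adj. Estimates are `mu_later - mu_earlier` in coefficient order.
#' @export
pairwise_contrasts <- function(fit, level = 0.95,
                               adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  mu <- coef(fit)
  V <- vcov(fit)
  K <- length(mu)
  stopifnot(K >= 2L)
  pairs <- utils::combn(K, 2)
  C <- if (adjustment == "bonferroni") ncol(pairs) else 1L
  alpha <- (1 - level) / C
  zq <- qnorm(1 - alpha / 2)
  out <- apply(pairs, 2, function(pr) {
    k <- pr[1]; l <- pr[2]
    d <- mu[l] - mu[k]
    se <- sqrt(V[k, k] + V[l, l] - 2 * V[k, l])
    z <- if (se > 0) d / se else NA_real_
    p <- if (is.na(z)) NA_real_ else min(1, C * 2 * pnorm(-abs(z)))
    c(estimate = unname(d), se = se, lo = unname(d - zq * se),
      hi = unname(d + zq * se), z = unname(z), p_adj = p)
  })
  res <- as.data.frame(t(out))
  res <- cbind(contrast = paste(names(mu)[pairs[2, ]], "-", names(mu)[pairs[1, ]]),
               res, stringsAsFactors = FALSE)
  attr(res, "level") <- level
  attr(res, "adjustment") <- adjustment
  attr(res, "n_comparisons") <- C
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("<contrast table> %s-adjusted, %d comparison(s), level %.2f\n",
              attr(x, "adjustment"), attr(x, "n_comparisons"),
              attr(x, "level")))
  NextMethod()
}

#' Between-group differences within each period
#'
#' Fits the random-intercept model with period-by-group cell means and
#' returns the group difference (second group level minus first) within
#' each period, with unadjusted normal-approximation confidence intervals.
#' Periods in which a group has no observations are flagged unavailable
#' (NA row) rather than dropped.
#'
#' @param observations data.frame with participant_id, period, value and a
#'   two-level `group` column.
#' @param level confidence level (default 0.95).
#' @return data.frame: period, group_contrast, estimate, se, lo, hi plus
#'   the underlying `wear_mixed_fit` as attribute `fit`.
#' @export
group_period_contrasts <- function(observations, level = 0.95) {
  stopifnot("group" %in% names(observations))
  obs <- observations[complete.cases(observations[c("participant_id", "period",
                                                    "value", "group")]), ]
  g <- droplevels(as.factor(obs$group))
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  for (lev in levels(g))
    if (length(unique(obs$participant_id[g == lev])) < 2L)
      stop("each group needs at least 2 participants")
  per <- droplevels(as.factor(obs$period))
  cell <- interaction(per, g, sep = ":", drop = FALSE)
  fit <- .reml_profile(obs$value, droplevels(cell), obs$participant_id)
  mu <- coef(fit); V <- vcov(fit)
  zq <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(levels(per), function(pk) {
    c1 <- paste(pk, levels(g)[1], sep = ":")
    c2 <- paste(pk, levels(g)[2], sep = ":")
    if (!(c1 %in% names(mu)) || !(c2 %in% names(mu)))
      return(data.frame(period = pk,
                        group_contrast = paste(levels(g)[2], "-", levels(g)[1]),
                        estimate = NA_real_, se = NA_real_,
                        lo = NA_real_, hi = NA_real_, available = FALSE))
    d <- mu[c2] - mu[c1]
    se <- sqrt(V[c1, c1] + V[c2, c2] - 2 * V[c1, c2])
    data.frame(period = pk,
               group_contrast = paste(levels(g)[2], "-", levels(g)[1]),
               estimate = unname(d), se = se,
               lo = unname(d - zq * se), hi = unname(d + zq * se),
               available = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "level") <- level
  out
}
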