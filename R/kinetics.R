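#' @include AllClasses.R utils.R
NULL

#' Build a fraction-uncleaved time series
#'
#' @param t time points (minutes), strictly increasing, non-negative.
#' @param f fraction full-length per time point, in [0, 1].
#' @param construct,replicate identifiers carried along.
#' @return a \code{data.frame} of class \code{"permotif_timeseries"} with
#'   columns \code{t} and \code{f} and attributes \code{construct} and
#'   \code{replicate}.
#' @export
timeSeries <- function(t, f, construct = NA_character_,
                       replicate = NA_character_) {
  t <- as.numeric(t); f <- as.numeric(f)
  if (length(t) != length(f)) .stopf("t and f differ in length")
  if (any(t < 0)) .stopf("time points must be non-negative")
  if (any(diff(t) <= 0)) .stopf("time points must be strictly increasing")
  if (any(f < -1e-12 | f > 1 + 1e-12))
    .stopf("fractions must lie in [0, 1]")
  out <- data.frame(t = t, f = pmin(pmax(f, 0), 1))
  attr(out, "construct") <- construct
  attr(out, "replicate") <- replicate
  class(out) <- c("permotif_timeseries", "data.frame")
  out
}

#' Fraction full-length from band intensities
#'
#' The fraction of uncleaved transcript at each time point is L/(L+S),
#' where L is the full-length band intensity and S the cleaved-product
#' intensity.
#'
#' @param L full-length intensities.
#' @param S cleaved intensities.
#' @param t time points (minutes).
#' @inheritParams timeSeries
#' @return a time series (see [timeSeries()]).
#' @examples
#' fractionSeries(c(9, 1), c(1, 9), c(0, 10))$f  # 0.9 0.1
#' @export
fractionSeries <- function(L, S, t, construct = NA_character_,
                           replicate = NA_character_) {
  if (length(L) != length(S) || length(L) != length(t))
    .stopf("L, S and t must have equal length")
  if (any(L < 0) || any(S < 0)) .stopf("intensities must be non-negative")
  tot <- L + S
  if (any(tot == 0)) {
    bad <- which(tot == 0)[1]
    .stopf("L + S is zero at point %d (t = %g)", bad, t[bad])
  }
  timeSeries(t, L / tot, construct, replicate)
}

#' Fit a one-phase exponential decay to a time course
#'
#' Fits f(t) = (y0 - plateau) exp(-k t) + plateau by nonlinear least
#' squares, initialized from a log-linear regression of f - min(f). Bounds:
#' k > 0 and 0 <= plateau, y0 <= 1. The plateau and/or y0 can be fixed
#' (e.g. \code{plateau = 0} mirrors a two-parameter decay to baseline).
#'
#' @param series a time series (see [timeSeries()]), or anything with
#'   numeric columns \code{t} and \code{f}.
#' @param fixPlateau fix the plateau at this value instead of fitting it.
#' @param fixY0 fix y0 instead of fitting it.
#' @return a \linkS4class{DecayFit}. Non-convergence and degenerate inputs
#'   (no decay) yield \code{converged = FALSE} with a diagnostic message,
#'   never a silent fallback.
#' @examples
#' ts <- simulateDecay(k = 0.13, t = seq(0, 30, 2), sigma = 0)
#' kObs(fitDecay(ts))
#' @export
fitDecay <- function(series, fixPlateau = NULL, fixY0 = NULL) {
  t <- series$t; f <- series$f
  n <- length(t)
  fail <- function(msg) new("DecayFit", k = NA_real_, y0 = NA_real_,
                            plateau = NA_real_, r2 = NA_real_,
                            converged = FALSE, nPoints = as.integer(n),
                            message = msg)
  if (n < 4L) return(fail("need at least 4 time points"))
  if (stats::sd(f) == 0) return(fail("constant series: no decay to fit"))

  fmin <- min(f); fmax <- max(f)
  eps <- max(1e-4, diff(range(f)) * 1e-3)
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(f - fmin + eps) ~ t))[2]
    max(-sl, 1e-4)
  }, error = function(e) 0.1)

  start <- c(k = as.numeric(k0))
  lower <- c(k = 1e-9); upper <- c(k = Inf)
  if (is.null(fixY0)) {
    start <- c(start, y0 = fmax)
    lower <- c(lower, y0 = 0); upper <- c(upper, y0 = 1)
  }
  if (is.null(fixPlateau)) {
    start <- c(start, plateau = max(fmin, 0))
    lower <- c(lower, plateau = 0); upper <- c(upper, plateau = 1)
  }
  model <- function(par) {
    y0 <- if (is.null(fixY0)) par[["y0"]] else fixY0
    pl <- if (is.null(fixPlateau)) par[["plateau"]] else fixPlateau
    (y0 - pl) * exp(-par[["k"]] * t) + pl
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(par) f - model(par),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(out)) return(fail("optimizer failed"))
  if (!out$info %in% 1:3)
    return(fail(sprintf("no convergence (%s)", out$message)))
  par <- out$par
  k <- par[["k"]]
  y0 <- if (is.null(fixY0)) par[["y0"]] else fixY0
  plateau <- if (is.null(fixPlateau)) par[["plateau"]] else fixPlateau
  res <- f - model(par)
  ssTot <- sum((f - mean(f))^2)
  r2 <- 1 - sum(res^2) / ssTot
  seK <- tryCatch({
    dof <- n - length(par)
    vc <- solve(out$hessian) * sum(res^2) / max(dof, 1L)
    sqrt(diag(vc))[["k"]]
  }, error = function(e) NA_real_)
  if (k <= 1e-8)
    return(fail("k at lower bound: no resolvable decay"))
  new("DecayFit", k = k, y0 = y0, plateau = plateau, r2 = r2, seK = seK,
      converged = TRUE, nPoints = as.integer(n), message = "")
}

#' Average replicate rate constants
#'
#' Arithmetic mean and sample standard deviation of k over converged
#' replicate fits, reported at full precision alongside a 2-significant-
#' figure formatted value (the convention used for published rate tables).
#'
#' @param fits list of \linkS4class{DecayFit} objects.
#' @return list with \code{meanK}, \code{sdK} (NA for a single replicate),
#'   \code{n}, \code{meanR2} and \code{formatted} (e.g. \code{"0.026"}).
#' @examples
#' # two replicates at 0.024 and 0.028 / min average to 0.026
#' @export
summarizeReplicates <- function(fits) {
  if (is(fits, "DecayFit")) fits <- list(fits)
  conv <- Filter(isConverged, fits)
  if (!length(conv)) .stopf("no converged replicate fits")
  ks <- vapply(conv, kObs, 0)
  r2 <- vapply(conv, rSquared, 0)
  m <- mean(ks)
  s <- if (length(ks) > 1L) stats::sd(ks) else NA_real_
  list(meanK = m, sdK = s, n = length(ks), meanR2 = mean(r2),
       formatted = format(signif(m, 2), scientific = FALSE,
                          drop0trailing = TRUE))
}

#' Fit every construct/replicate in a kinetics table
#'
#' @param tab data.frame with columns \code{construct}, \code{replicate},
#'   \code{t_min} and either \code{L} and \code{S} or \code{f}.
#' @param ... passed to [fitDecay()].
#' @return data.frame with one row per construct: \code{construct},
#'   \code{k_obs}, \code{sd}, \code{R2} (mean across replicates), \code{n}.
#' @export
fitKineticsTable <- function(tab, ...) {
  need <- c("construct", "replicate", "t_min")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss,
                                                          collapse = ", "))
  hasF <- "f" %in% names(tab)
  if (!hasF && !all(c("L", "S") %in% names(tab)))
    .stopf("missing column(s): f (or L and S)")
  out <- list()
  for (cid in unique(tab$construct)) {
    sub <- tab[tab$construct == cid, , drop = FALSE]
    fits <- lapply(unique(sub$replicate), function(rid) {
      r <- sub[sub$replicate == rid, , drop = FALSE]
      r <- r[order(r$t_min), , drop = FALSE]
      ts <- if (hasF) timeSeries(r$t_min, r$f, cid, rid)
            else fractionSeries(r$L, r$S, r$t_min, cid, rid)
      fitDecay(ts, ...)
    })
    sm <- summarizeReplicates(fits)
    out[[length(out) + 1L]] <- data.frame(
      construct = cid, k_obs = sm$meanK, sd = sm$sdK, R2 = sm$meanR2,
      n = sm$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
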