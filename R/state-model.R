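#' Logistic membership function
#'
#' `1 / (1 + exp(-s * (x - x0)))` with slope `s` and turning point `x0`.
#' Increasing for `s > 0`, decreasing for `s < 0`; equals 0.5 at `x0`.
#'
#' @param x descriptor value(s)
#' @param s slope (1/descriptor-unit, signed)
#' @param x0 turning point (descriptor units)
#' @return membership value(s) in (0, 1)
#' @export
sigmoid <- function(x, s, x0) 1 / (1 + exp(-s * (x - x0)))

#' Fit a sigmoid to one half of a bound-state descriptor distribution
#'
#' Builds a density histogram of the bound-window values
#' (Freedman-Diaconis bin width), locates the mode, takes the half at and
#' beyond the mode on the requested side, rescales that half to \[0,1\]
#' (mode bin -> 1, far tail -> 0) and least-squares fits the logistic to
#' (bin centre, rescaled height). A right-side fit yields a decreasing
#' membership (s < 0), a left-side fit an increasing one (s > 0): the
#' membership is ~1 in the bound basin and falls off in the direction the
#' descriptor moves during dissociation.
#'
#' @param values numeric vector (or [descriptor_series()]) from the bound
#'   reference window; at least 100 samples
#' @param side "right" (descriptor increases on dissociation, e.g. distance,
#'   SASA) or "left" (descriptor decreases, e.g. Q)
#' @return object of class `sigmoid_fit`: list (s, x0, side, fit_residual)
#' @export
fit_half_bell <- function(values, side = c("right", "left")) {
  side <- match.arg(side)
  if (inherits(values, "descriptor_series")) values <- values$value
  values <- values[is.finite(values)]
  if (length(values) < 100)
    stop("insufficient data: need >= 100 samples for the half-bell fit")
  if (diff(range(values)) < .Machine$double.eps^0.5)
    stop("degenerate fit: constant descriptor series")

  ih <- graphics::hist(values, breaks = "FD", plot = FALSE)
  y <- ih$density; xm <- ih$mids
  if (sum(y > 0) < 3)
    stop("degenerate fit: histogram too narrow for a fit")
  # tie-break: leftmost mode for right-side fits, rightmost for left-side,
  # maximizing the span of the fitted half
  mode_cands <- which(y == max(y))
  imode <- if (side == "right") min(mode_cands) else max(mode_cands)
  sel <- if (side == "right") imode:length(y) else 1:imode
  xs <- xm[sel]; ys <- y[sel]
  if (length(xs) < 3)
    stop("degenerate fit: fewer than 3 bins on the requested side")
  ys <- (ys - min(ys)) / (max(ys) - min(ys))

  # anchor the mode bin at membership 1: the bound basin is defined to have
  # membership ~1, so the mode point carries a large weight in the fit
  w <- rep(1, length(ys))
  w[which.max(ys)] <- 5 * length(ys)
  fit <- fit_sigmoid(xs, ys, side = side, weights = w)
  structure(c(fit, list(side = side)), class = "sigmoid_fit")
}

#' Least-squares logistic fit to (x, y) curve data
#'
#' Fits `y ~ 1/(1 + exp(-s (x - x0)))` by (optionally weighted) nonlinear
#' least squares. Used by [fit_half_bell()] on rescaled histogram halves;
#' also usable directly on a noisy membership curve.
#'
#' @param x,y curve samples, y in \[0, 1\] up to noise
#' @param side optional "right"/"left": constrains (and seeds) the slope
#'   sign, decreasing for right, increasing for left
#' @param weights optional least-squares weights
#' @return list (s, x0, fit_residual)
#' @export
fit_sigmoid <- function(x, y, side = NULL, weights = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.null(weights)) weights <- rep(1, length(y))
  span <- max(diff(range(x)), .Machine$double.eps)
  s0 <- 4 / span
  if (!is.null(side) && side == "right") s0 <- -s0
  if (is.null(side) && cor(x, y) < 0) s0 <- -s0
  x_half <- x[which.min(abs(y - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-s * (x - x0))),
                      start = list(s = s0, x0 = x_half), weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("degenerate fit: ", conditionMessage(e)))
  cf <- coef(fit)
  s <- unname(cf["s"]); x0 <- unname(cf["x0"])
  if (!is.null(side) &&
      ((side == "right" && s >= 0) || (side == "left" && s <= 0)))
    stop("degenerate fit: slope sign inconsistent with the requested side")
  list(s = s, x0 = x0, fit_residual = sum(residuals(fit)^2))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> side=%s s=%.4g x0=%.4g rss=%.3g\n",
              x$side, x$s, x$x0, x$fit_residual))
  invisible(x)
}

#' Product state curve from two descriptor memberships
#'
#' Applies each fitted sigmoid to its descriptor series and multiplies the
#' two memberships frame by frame. 1 is the bound state; the curve smoothly
#' approaches 0 as the complex dissociates.
#'
#' @param series1,series2 [descriptor_series()] of equal length
#' @param fit1,fit2 matching [fit_half_bell()] fits
#' @return data.frame (time, state) of class `state_series`
#' @export
state_curve <- function(series1, fit1, series2, fit2) {
  if (nrow(series1) != nrow(series2))
    stop("alignment error: descriptor series lengths differ")
  m1 <- sigmoid(series1$value, fit1$s, fit1$x0)
  m2 <- sigmoid(series2$value, fit2$s, fit2$x0)
  out <- data.frame(time = series1$time, state = m1 * m2)
  attr(out, "descriptors_used") <- c(attr(series1, "name"),
                                     attr(series2, "name"))
  attr(out, "frame_spacing") <- attr(series1, "frame_spacing")
  class(out) <- c("state_series", "data.frame")
  out
}

#' Detect the transition frame of a state curve
#'
#' First frame at which the state drops below `threshold` and stays below it
#' for at least `min_dwell` consecutive frames; `NA` if no such frame.
#'
#' @param state a `state_series` (or numeric vector of state values)
#' @param threshold state threshold in (0, 1)
#' @param min_dwell minimum consecutive frames below threshold
#' @return frame index (1-based) or `NA`
#' @export
detect_transition <- function(state, threshold = 0.5, min_dwell = 10) {
  if (!(threshold > 0 && threshold < 1))
    stop("invalid parameter: threshold must be in (0,1)")
  if (min_dwell < 1) stop("invalid parameter: min_dwell must be >= 1")
  v <- if (is.data.frame(state)) state$state else as.numeric(state)
  below <- v < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_dwell)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]]
}

#' Plateau levels of a descriptor time series
#'
#' Fits a four-parameter logistic `lo + (hi - lo) / (1 + exp(-s (t - t0)))`
#' to (time, value), giving the plateau levels between which the descriptor
#' moves during dissociation; falls back to robust quantiles when the curve
#' has no sigmoidal transition (e.g. a bound-only run).
#'
#' @param series a [descriptor_series()]
#' @return list (lo, hi, s, t0, fallback)
#' @export
fit_plateau_sigmoid <- function(series) {
  t <- series$time; v <- series$value
  lo0 <- unname(quantile(v, 0.02)); hi0 <- unname(quantile(v, 0.98))
  fit <- tryCatch({
    s0 <- 8 / max(diff(range(t)), .Machine$double.eps)
    if (cor(t, v) < 0) s0 <- -s0
    f <- minpack.lm::nlsLM(
      v ~ lo + (hi - lo) / (1 + exp(-s * (t - t0))),
      start = list(lo = lo0, hi = hi0, s = s0,
                   t0 = t[which.min(abs(v - (lo0 + hi0) / 2))]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(f)
    rng <- sort(c(unname(cf["lo"]), unname(cf["hi"])))
    list(lo = rng[1], hi = rng[2], s = unname(cf["s"]),
         t0 = unname(cf["t0"]), rsd = sd(residuals(f)), fallback = FALSE)
  }, error = function(e) NULL)
  if (is.null(fit) || anyNA(c(fit$lo, fit$hi)) ||
      fit$hi - fit$lo < .Machine$double.eps^0.5)
    fit <- list(lo = lo0, hi = hi0, s = NA, t0 = NA,
                rsd = stats::mad(v), fallback = TRUE)
  fit
}

# normalize a series to a [0,1] membership between fitted plateaus;
# direction "fall": high values -> 1 (e.g. Q); "rise": high values -> 0
plateau_membership <- function(series, direction = c("fall", "rise")) {
  direction <- match.arg(direction)
  pf <- fit_plateau_sigmoid(series)
  # a fitted plateau separation within the noise means the series never
  # transitions: the run stays bound, membership 1 throughout
  if (!pf$fallback && (pf$hi - pf$lo) < 3 * pf$rsd)
    return(rep(1, nrow(series)))
  m <- (series$value - pf$lo) / max(pf$hi - pf$lo, .Machine$double.eps)
  m <- pmin(1, pmax(0, m))
  if (direction == "rise") m <- 1 - m
  m
}

#' Classify frames into bound / encounter / unbound states
#'
#' The bound-to-encounter transition is detected on the product of the
#' centre-of-mass-distance and Q memberships fitted on the bound reference
#' distributions (threshold `th_dissociation`). The encounter-to-unbound
#' transition uses the Q and SASA series themselves: both reach a plateau
#' once the complex is fully dissociated, so each series is normalized
#' between its fitted plateau levels (Q falling, SASA rising), the two
#' normalized curves are multiplied, and the first time this product
#' approaches zero (threshold `th_unbound`) marks the unbound state. The
#' dwell window defaults to 1% of the trajectory length, at least 10 frames.
#'
#' @param descriptors named list from [descriptor_timeseries()]
#' @param fits named list with [fit_half_bell()] elements `com_distance`
#'   (side right) and `q_native` (side left)
#' @param th_dissociation threshold for the bound-to-encounter transition
#' @param th_unbound threshold for the encounter-to-unbound transition
#' @param min_dwell dwell frames; default `max(10, 0.01 * n_frames)`
#' @return list of class `state_classification`: `labels` (factor per frame),
#'   `t_dissociation`, `t_unbound`, `state_bound` and `state_unbound`
#'   (the two `state_series`), and the thresholds used
#' @export
classify_states <- function(descriptors, fits, th_dissociation = 0.5,
                            th_unbound = 0.05, min_dwell = NULL) {
  need <- c("com_distance", "q_native")
  if (!all(need %in% names(fits)))
    stop("fits must contain: ", paste(need, collapse = ", "))
  nf <- nrow(descriptors$com_distance)
  if (is.null(min_dwell)) min_dwell <- max(10, ceiling(0.01 * nf))
  min_dwell <- min(min_dwell, nf)

  s_bound <- state_curve(descriptors$com_distance, fits$com_distance,
                         descriptors$q_native, fits$q_native)
  m_q <- plateau_membership(descriptors$q_native, "fall")
  m_sasa <- plateau_membership(descriptors$sasa, "rise")
  s_unb <- data.frame(time = descriptors$q_native$time,
                      state = m_q * m_sasa)
  attr(s_unb, "descriptors_used") <- c("q_native", "sasa")
  class(s_unb) <- c("state_series", "data.frame")
  t_diss <- detect_transition(s_bound, th_dissociation, min_dwell)
  t_unb <- detect_transition(s_unb, th_unbound, min_dwell)
  if (!is.na(t_diss) && !is.na(t_unb) && t_unb < t_diss) t_unb <- t_diss

  lab <- rep("bound", nf)
  if (!is.na(t_diss)) lab[seq_len(nf) >= t_diss] <- "encounter"
  if (!is.na(t_unb)) lab[seq_len(nf) >= t_unb] <- "unbound"
  structure(list(labels = factor(lab, c("bound", "encounter", "unbound")),
                 t_dissociation = t_diss, t_unbound = t_unb,
                 state_bound = s_bound, state_unbound = s_unb,
                 thresholds = c(dissociation = th_dissociation,
                                unbound = th_unbound),
                 min_dwell = min_dwell),
            class = "state_classification")
}

#' @export
print.state_classification <- function(x, ...) {
  cat(sprintf("<state_classification> t_dissociation=%s t_unbound=%s (%s)\n",
              x$t_dissociation, x$t_unbound,
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}
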