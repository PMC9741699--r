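#' Free-energy profile container
#'
#' Gridded free energy along the collective variable, min-shifted to zero.
#'
#' @param grid strictly increasing CV values (nm)
#' @param F free energy per grid point (kJ/mol)
#' @param temperature K
#' @param truncation_frame frame index up to which data contributed (or NA)
#' @return data.frame (cv, F) of class `fes`
#' @export
free_energy_profile <- function(grid, F, temperature = 300,
                                truncation_frame = NA) {
  stopifnot(length(grid) == length(F), all(diff(grid) > 0))
  out <- data.frame(cv = grid, F = F - min(F[is.finite(F)]))
  attr(out, "temperature") <- temperature
  attr(out, "truncation_frame") <- truncation_frame
  class(out) <- c("fes", "data.frame")
  out
}

#' Uniform CV grid spanning sampled values plus a hill-width margin
#'
#' 200 uniform points over `[min(cv) - 2*sigma, max(cv) + 2*sigma]`.
#'
#' @param cv_values sampled CV values (nm)
#' @param sigma hill width (nm)
#' @param n grid size
#' @export
default_grid <- function(cv_values, sigma = 0.05, n = 200) {
  seq(min(cv_values) - 2 * sigma, max(cv_values) + 2 * sigma, length.out = n)
}

#' Metadynamics bias potential on a grid
#'
#' `V(s, t) = sum over deposited hills with time <= until_time of
#' height * exp(-(s - center)^2 / (2 sigma^2))`.
#'
#' @param hills a [hills_record()]
#' @param grid CV values (nm)
#' @param until_time only hills deposited at or before this time (ps)
#' @return bias values, kJ/mol, one per grid point
#' @export
bias_potential <- function(hills, grid, until_time = Inf) {
  if (!length(grid)) stop("invalid parameter: empty grid")
  keep <- hills$time <= until_time
  V <- numeric(length(grid))
  if (any(keep)) {
    h <- hills[keep, , drop = FALSE]
    for (k in seq_len(nrow(h)))
      V <- V + h$height[k] *
        exp(-(grid - h$center[k])^2 / (2 * h$sigma[k]^2))
  }
  V
}

#' Free-energy profile from the accumulated bias
#'
#' Standard (non-well-tempered, constant hill height) metadynamics
#' estimator: `F(s) = -V(s, until_time)`, min-shifted to zero.
#'
#' @inheritParams bias_potential
#' @param temperature K (carried as context)
#' @return a [free_energy_profile()]
#' @export
fes_from_bias <- function(hills, grid, until_time = Inf, temperature = 300) {
  V <- bias_potential(hills, grid, until_time)
  free_energy_profile(grid, -V, temperature)
}

#' Time-dependent bias offset c(t)
#'
#' For each hill event time t, `c(t) = (1/beta) * ln( mean over the grid of
#' exp(beta * V(s, t)) )` — the standard-metadynamics (gamma -> infinity)
#' limit of the time-dependent-bias estimator with a flat reference measure
#' over the grid. Evaluated incrementally per event; log-sum-exp guarded.
#'
#' @param hills a [hills_record()]
#' @param grid CV values (nm)
#' @param temperature K
#' @return object of class `reweight_context`: data.frame (time, c) with
#'   attributes `beta` and `temperature`
#' @export
compute_c_of_t <- function(hills, grid, temperature = 300) {
  if (!length(grid)) stop("invalid parameter: empty grid")
  beta <- 1 / (.kB * temperature)
  n <- nrow(hills)
  cvals <- numeric(n)
  V <- numeric(length(grid))
  for (k in seq_len(n)) {
    V <- V + hills$height[k] *
      exp(-(grid - hills$center[k])^2 / (2 * hills$sigma[k]^2))
    m <- max(beta * V)
    cvals[k] <- (m + log(mean(exp(beta * V - m)))) / beta
  }
  out <- data.frame(time = hills$time, c = cvals)
  attr(out, "beta") <- beta
  attr(out, "temperature") <- temperature
  class(out) <- c("reweight_context", "data.frame")
  out
}

# c(t) evaluated at arbitrary times: piecewise-constant, 0 before first event
c_at_time <- function(ctx, times) {
  if (!nrow(ctx)) return(numeric(length(times)))
  idx <- findInterval(times, ctx$time)
  ifelse(idx == 0, 0, ctx$c[pmax(idx, 1)])
}

#' Reweighted CV histogram of a biased run
#'
#' Each frame is weighted by `exp(beta * (V(s_i, t_i) - c(t_i)))`, undoing
#' the metadynamics bias; the weighted histogram on the grid (interpreted as
#' uniform bin centres) is normalized to sum to 1. Frames outside the grid
#' are counted into the boundary bins and reported via the
#' `boundary_count` attribute. With no hills the result equals the plain
#' normalized histogram.
#'
#' @param cv a `cv_series` (data.frame time, cv)
#' @param hills a [hills_record()]
#' @param ctx a [compute_c_of_t()] context (recomputed if NULL)
#' @param grid uniform CV grid, nm
#' @param until_frame use only the first `until_frame` CV samples (NA = all)
#' @param temperature K
#' @return numeric probability vector over the grid, summing to 1, with
#'   attributes `total_weight` and `boundary_count`
#' @export
reweighted_histogram <- function(cv, hills, ctx = NULL, grid,
                                 until_frame = NA, temperature = 300) {
  stopifnot(all(diff(grid) > 0))
  if (!is.na(until_frame)) cv <- cv[seq_len(min(until_frame, nrow(cv))), ]
  beta <- 1 / (.kB * temperature)
  if (is.null(ctx)) ctx <- compute_c_of_t(hills, grid, temperature)

  # bias felt by each frame at its own time: advance hills in lockstep
  n <- nrow(cv)
  Vframe <- numeric(n)
  if (nrow(hills)) {
    Vg <- numeric(length(grid))
    ev_frame <- findInterval(hills$time, cv$time + 1e-12) # frames before event
    ord_frames <- order(cv$time)
    done <- 0L
    for (k in seq_len(nrow(hills) + 1)) {
      upto <- if (k <= nrow(hills)) ev_frame[k] else n
      if (upto > done) {
        ii <- ord_frames[(done + 1):upto]
        Vframe[ii] <- approx(grid, Vg, xout = cv$cv[ii], rule = 2)$y
        done <- upto
      }
      if (k <= nrow(hills))
        Vg <- Vg + hills$height[k] *
          exp(-(grid - hills$center[k])^2 / (2 * hills$sigma[k]^2))
    }
  }
  cfr <- c_at_time(ctx, cv$time)
  logw <- beta * (Vframe - cfr)
  w <- exp(logw - max(logw))

  half <- diff(grid)[1] / 2
  edges <- c(grid[1] - half, grid + half)
  bin <- findInterval(cv$cv, edges, all.inside = FALSE)
  boundary <- sum(bin == 0 | bin > length(grid))
  bin[bin == 0] <- 1L
  bin[bin > length(grid)] <- length(grid)
  dens <- vapply(seq_along(grid), function(b) sum(w[bin == b]), numeric(1))
  total_w <- sum(exp(logw))
  dens <- dens / sum(dens)
  attr(dens, "total_weight") <- total_w
  attr(dens, "boundary_count") <- boundary
  if (boundary > 0)
    warning(boundary, " frame(s) outside the grid counted in boundary bins")
  dens
}

#' Combine run densities and Boltzmann-invert to a free-energy profile
#'
#' Weighted sum of the per-run probability distributions, renormalized, then
#' `F = -(1/beta) ln P`, min-shifted to zero.
#'
#' @param densities list of probability vectors on a common grid
#' @param run_weights positive scalars, one per run (default: the
#'   `total_weight` attribute of each density, i.e. frame-weight totals)
#' @param grid the common CV grid
#' @param temperature K
#' @return a [free_energy_profile()]
#' @export
combine_runs <- function(densities, run_weights = NULL, grid,
                         temperature = 300) {
  stopifnot(length(densities) >= 1)
  if (is.null(run_weights))
    run_weights <- vapply(densities, function(d)
      attr(d, "total_weight") %||% 1, numeric(1))
  if (any(run_weights < 0) || sum(run_weights) <= 0)
    stop("invalid parameter: run weights must be positive in total")
  P <- Reduce(`+`, Map(function(d, w) as.numeric(d) * w,
                       densities, run_weights))
  P <- P / sum(P)
  beta <- 1 / (.kB * temperature)
  F <- ifelse(P > 0, -log(P) / beta, Inf)
  free_energy_profile(grid, F, temperature)
}

#' Depth of the bound free-energy minimum
#'
#' `F(transition level) - F(minimum within bound_region)`, where the
#' transition level is the maximum of F on the grid between the bound
#' minimum and the largest sampled CV value, excluding a short margin at
#' the upper grid edge (grid points within `edge_exclude` of the edge see a
#' one-sided Gaussian deposition deficit and would otherwise inflate the
#' level). Always >= 0.
#'
#' The transition level is taken on a lightly smoothed F (moving average of
#' width `smooth_window`): hill deposition leaves kJ/mol-scale oscillations
#' on the profile, and a raw per-bin maximum would systematically pick their
#' upward extremes.
#'
#' @param profile a [free_energy_profile()]
#' @param bound_region CV interval `c(lo, hi)` containing the bound minimum
#' @param edge_exclude margin at the upper grid edge excluded from the
#'   transition-level search, nm (three default hill widths)
#' @param smooth_window moving-average width for the transition-level
#'   search, nm (one default hill width)
#' @return depth in kJ/mol
#' @export
minimum_depth <- function(profile, bound_region, edge_exclude = 0.15,
                          smooth_window = 0.05) {
  g <- profile$cv
  inb <- g >= bound_region[1] & g <= bound_region[2]
  if (!any(inb)) stop("invalid parameter: bound_region outside the grid")
  Fb <- profile$F
  fin <- is.finite(Fb)
  # both the minimum and the transition level are read off the smoothed
  # profile, so deposition oscillations do not bias the difference
  Fs <- Fb
  k <- max(1L, round(smooth_window / max(diff(g)[1], 1e-12)))
  if (k > 1 && sum(fin) >= k) {
    sm <- stats::filter(ifelse(fin, Fb, 0), rep(1 / k, k), sides = 2)
    cnt <- stats::filter(as.numeric(fin), rep(1 / k, k), sides = 2)
    ok <- !is.na(sm) & cnt > 0.5
    Fs <- ifelse(ok, sm / pmax(cnt, 1e-12), Fb)
    Fs[!fin] <- Inf
  }
  if (!any(is.finite(Fs[inb]))) return(0)
  imin <- which(inb)[which.min(Fs[inb])]
  sel <- imin:length(g)
  trimmed <- sel[g[sel] <= max(g) - edge_exclude]
  if (length(trimmed) >= 2) sel <- trimmed
  upper <- Fs[sel][is.finite(Fs[sel])]
  if (!length(upper)) return(0)
  max(max(upper) - Fs[imin], 0)
}

#' Per-run probability density from the truncated free-energy curve
#'
#' Boltzmann density obtained from a run's bias-based free-energy estimate
#' at its truncation time: `P(s) proportional to exp(beta * V(s, t_trunc))`,
#' restricted to the CV range the run actually sampled before truncation
#' and normalized to sum 1. The run's scalar weight `exp(beta * c(t_trunc))`
#' (time-dependent bias offset) is attached as the `total_weight` attribute.
#'
#' @param cv a `cv_series`
#' @param hills a [hills_record()]
#' @param grid uniform CV grid, nm
#' @param until_frame truncation (NA = full run)
#' @param temperature K
#' @return probability vector on the grid with attribute `total_weight`
#' @export
fes_density <- function(cv, hills, grid, until_frame = NA,
                        temperature = 300) {
  if (!is.na(until_frame)) cv <- cv[seq_len(min(until_frame, nrow(cv))), ]
  beta <- 1 / (.kB * temperature)
  t_end <- if (nrow(cv)) max(cv$time) else Inf
  V <- bias_potential(hills, grid, until_time = t_end)
  P <- exp(beta * (V - max(V)))
  P[grid < min(cv$cv) | grid > max(cv$cv)] <- 0
  if (sum(P) == 0) P[which.min(abs(grid - mean(cv$cv)))] <- 1
  P <- P / sum(P)
  ctx <- compute_c_of_t(hills[hills$time <= t_end, , drop = FALSE], grid,
                        temperature)
  cw <- if (nrow(ctx)) ctx$c[nrow(ctx)] else 0
  attr(P, "total_weight") <- exp(beta * cw)
  attr(P, "c_trunc") <- cw
  P
}

#' Combined depth with leave-one-out error bounds
#'
#' Builds each run's probability density (optionally truncated at its
#' dissociation frame), combines all runs for the mean depth, and recombines
#' leaving one run out at a time for the leave-one-out minimum and maximum.
#' Densities come either from the run's truncated free-energy curve with a
#' scalar c(t) run weight ("fes", default — matching the estimation route
#' described for the antibody systems) or from per-frame reweighted
#' histograms ("histogram").
#'
#' @param runs list of runs; each a list with elements `cv` (cv_series),
#'   `hills` ([hills_record()]) and optional `until_frame`
#' @param bound_region CV interval of the bound minimum
#' @param temperature K
#' @param grid common grid (default: [default_grid()] over all runs)
#' @param density "fes" or "histogram"
#' @return object of class `depth_estimate`: list (mean_depth, loo_min,
#'   loo_max, loo_depths, n_runs, profile)
#' @export
loo_depth <- function(runs, bound_region, temperature = 300, grid = NULL,
                      density = c("fes", "histogram")) {
  density <- match.arg(density)
  if (length(runs) < 3)
    stop("insufficient replicates: need >= 3 runs for leave-one-out")
  if (is.null(grid)) {
    allcv <- unlist(lapply(runs, function(r) {
      uf <- r$until_frame %||% NA
      v <- r$cv$cv
      if (!is.na(uf)) v <- v[seq_len(min(uf, length(v)))]
      v
    }))
    sig <- max(vapply(runs, function(r)
      if (nrow(r$hills)) max(r$hills$sigma) else 0.05, numeric(1)))
    grid <- default_grid(allcv, sig)
  }
  dens <- lapply(runs, function(r)
    if (density == "fes")
      fes_density(r$cv, r$hills, grid, until_frame = r$until_frame %||% NA,
                  temperature = temperature)
    else
      reweighted_histogram(r$cv, r$hills, NULL, grid,
                           until_frame = r$until_frame %||% NA,
                           temperature = temperature))
  full <- combine_runs(dens, NULL, grid, temperature)
  mean_depth <- minimum_depth(full, bound_region)
  loo <- vapply(seq_along(dens), function(i) {
    prof <- combine_runs(dens[-i], NULL, grid, temperature)
    minimum_depth(prof, bound_region)
  }, numeric(1))
  structure(list(mean_depth = mean_depth, loo_min = min(loo),
                 loo_max = max(loo), loo_depths = loo,
                 n_runs = length(runs), profile = full),
            class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf("<depth_estimate> %.3g kJ/mol [LOO %.3g, %.3g], n=%d\n",
              x$mean_depth, x$loo_min, x$loo_max, x$n_runs))
  invisible(x)
}

#' Correlate bound-minimum depths with melting temperatures
#'
#' Pearson and Spearman correlation of per-system depths against
#' experimental melting temperatures; systems without a Tm are excluded
#' from the fit and reported.
#'
#' @param depths numeric vector of depths (kJ/mol) or list of
#'   `depth_estimate` objects
#' @param tm melting temperatures, degrees C; NA marks systems without one
#' @param labels optional system labels
#' @return list (pearson, spearman, n_used, excluded)
#' @export
correlate_depth_tm <- function(depths, tm, labels = NULL) {
  if (is.list(depths) && !is.numeric(depths))
    depths <- vapply(depths, function(d) d$mean_depth, numeric(1))
  stopifnot(length(depths) == length(tm))
  if (is.null(labels)) labels <- as.character(seq_along(depths))
  use <- !is.na(tm)
  if (sum(use) < 3)
    stop("need >= 3 systems with melting temperatures")
  if (sd(depths[use]) < .Machine$double.eps^0.5)
    stop("undefined correlation: all depths equal")
  list(pearson = cor(depths[use], tm[use], method = "pearson"),
       spearman = cor(depths[use], tm[use], method = "spearman"),
       n_used = sum(use), excluded = labels[!use])
}

#' Write / read a free-energy profile as CSV
#' @param profile a [free_energy_profile()]
#' @param path file path
#' @export
write_fes <- function(profile, path) {
  utils::write.csv(data.frame(cv = profile$cv, F = profile$F), path,
                   row.names = FALSE)
  invisible(path)
}
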