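#' Inverse CA-CA distance features
#'
#' One column per designated inter-chain residue pair, entries
#' `1 / distance(CA_i, CA_j)` (1/Angstrom) per frame. Inverse distances
#' emphasize changes at small separations and damp changes far apart.
#'
#' @param traj a `traj` object
#' @param pairs data.frame (resno_a, resno_b), e.g. interface contacts of
#'   the first frame
#' @return numeric matrix frames x pairs, column names `a<ra>-b<rb>`
#' @export
featurize_inverse_ca_distances <- function(traj, pairs) {
  stopifnot(nrow(pairs) >= 1)
  at <- traj$atoms
  row_ca <- function(label, resno) {
    r <- which(chain_mask(traj, label) & at$elety == "CA" & at$resno == resno)
    if (!length(r))
      stop(sprintf("topology error: no CA atom for chain %s residue %d",
                   label, resno))
    r[1]
  }
  ia <- vapply(pairs$resno_a, function(r) row_ca("a", r), integer(1))
  ib <- vapply(pairs$resno_b, function(r) row_ca("b", r), integer(1))
  nf <- n_frames(traj)
  X <- matrix(0, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    X[f, ] <- 1 / sqrt(rowSums((co[ia, , drop = FALSE] -
                                  co[ib, , drop = FALSE])^2))
  }
  colnames(X) <- paste0("a", pairs$resno_a, "-b", pairs$resno_b)
  X
}

#' Time-lagged independent component analysis
#'
#' Solves the symmetrized time-lagged covariance generalized eigenproblem
#' on mean-free features: `C(tau) v = lambda C(0) v` with
#' `C(tau) <- (C(tau) + C(tau)')/2` and a small ridge on `C(0)`.
#' Components are C(0)-orthonormal and sorted by eigenvalue.
#'
#' @param features frames x features matrix (a single trajectory)
#' @param lag lag in frames (> 0)
#' @param n_components components to retain
#' @param ridge regularization added to the diagonal of C(0)
#' @return object of class `tica_model`: list (lag, mean, eigenvalues,
#'   components, kept, dropped)
#' @export
tica <- function(features, lag, n_components = 2, ridge = 1e-8) {
  if (lag < 1) stop("invalid parameter: lag must be >= 1 frame")
  n <- nrow(features)
  if (n <= 2 * lag) stop("invalid parameter: need frames > 2*lag")
  v <- apply(features, 2, stats::var)
  kept <- which(v > .Machine$double.eps)
  dropped <- colnames(features)[setdiff(seq_along(v), kept)]
  X <- features[, kept, drop = FALSE]
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  C0 <- crossprod(X) / (n - 1)
  Ct <- crossprod(X[seq_len(n - lag), , drop = FALSE],
                  X[(lag + 1):n, , drop = FALSE]) / (n - lag - 1)
  Ct <- (Ct + t(Ct)) / 2
  C0 <- C0 + diag(ridge, ncol(C0))
  e0 <- eigen(C0, symmetric = TRUE)
  if (min(e0$values) <= 0)
    stop("numerical error: instantaneous covariance not positive definite")
  L <- e0$vectors %*% diag(1 / sqrt(e0$values), ncol(C0))
  M <- t(L) %*% Ct %*% L
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ncomp <- min(n_components, ncol(C0))
  comp <- L %*% em$vectors[, seq_len(ncomp), drop = FALSE]
  structure(list(lag = lag, mean = mu, eigenvalues = em$values,
                 components = comp, kept = kept, dropped = dropped),
            class = "tica_model")
}

#' Project features onto tICA components
#' @param model a [tica()] model
#' @param features frames x features matrix (same columns as fitted)
#' @return frames x n_components matrix
#' @export
tica_project <- function(model, features) {
  X <- sweep(features[, model$kept, drop = FALSE], 2, model$mean)
  X %*% model$components
}

#' k-means microstates with deterministic k-means++ seeding
#'
#' k-means++ initialization (ties broken by lowest index) followed by Lloyd
#' iteration, repeated `n_restarts` times with seeds derived from `seed`;
#' the restart with the lowest total within-cluster sum of squares wins.
#'
#' @param projected frames x dims matrix (e.g. tICA projections)
#' @param k number of microstates
#' @param seed integer seed
#' @param n_restarts restarts
#' @return list (labels, centers, tot_withinss)
#' @export
kmeans_microstates <- function(projected, k, seed = 1, n_restarts = 10) {
  projected <- as.matrix(projected)
  ndist <- nrow(unique(projected))
  if (k > ndist)
    stop("invalid parameter: k exceeds the number of distinct points")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    init <- kmeanspp_centers(projected, k)
    km <- suppressWarnings(
      kmeans(projected, centers = init, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(labels = best$cluster, centers = best$centers,
       tot_withinss = best$tot.withinss)
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ], `-`)^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    idx[j] <- if (all(d2 == 0)) which.min(seq_len(n) %in% idx) else
      sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ], `-`)^2))
  }
  X[idx, , drop = FALSE]
}

# lagged transition counts within each trajectory (no cross-boundary pairs)
count_transitions <- function(labels, lag, states) {
  if (!is.list(labels)) labels <- list(labels)
  ns <- length(states)
  C <- matrix(0, ns, ns, dimnames = list(states, states))
  for (tr in labels) {
    tr <- match(tr, states)
    n <- length(tr)
    if (n <= lag) next
    from <- tr[seq_len(n - lag)]
    to <- tr[(lag + 1):n]
    ok <- !is.na(from) & !is.na(to)
    tb <- table(factor(from[ok], seq_len(ns)), factor(to[ok], seq_len(ns)))
    C <- C + as.matrix(tb)
  }
  C
}

#' Estimate a Markov state model at a fixed lag
#'
#' Transition counts are collected at the lag within each trajectory,
#' restricted to the largest strongly connected set of states (full
#' connectivity is required to speak of transition probabilities). The
#' default estimator symmetrizes the counts, `(C + C')/2` row-normalized,
#' which guarantees reversibility with stationary distribution proportional
#' to the symmetrized row sums; a reversible maximum-likelihood iteration is
#' available via `estimator = "mle"`.
#'
#' @param labels integer vector of per-frame microstates, or a list of such
#'   vectors (one per trajectory)
#' @param lag lag in frames
#' @param estimator "symmetrized" or "mle"
#' @return object of class `msm_model`: list (lag, states,
#'   transition_matrix, stationary, eigenvalues, implied_timescales,
#'   counts, removed_states)
#' @export
estimate_msm <- function(labels, lag, estimator = c("symmetrized", "mle")) {
  estimator <- match.arg(estimator)
  if (lag < 1) stop("invalid parameter: lag must be >= 1")
  all_lab <- unlist(labels)
  states <- sort(unique(all_lab))
  C <- count_transitions(labels, lag, states)

  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  tot <- rowSums(C) + colSums(C)
  nstates <- tabulate(memb, comp$no)
  ccounts <- vapply(seq_len(comp$no), function(ci) sum(tot[memb == ci]),
                    numeric(1))
  big <- order(-nstates, -ccounts)[1]  # most states, then most counts
  keep <- which(memb == big)
  if (!length(keep)) stop("connectivity error: no connected state set")
  removed <- states[-keep]
  C <- C[keep, keep, drop = FALSE]
  states <- states[keep]

  if (estimator == "symmetrized") {
    Cs <- (C + t(C)) / 2
    T <- Cs / rowSums(Cs)
    pi_st <- rowSums(Cs) / sum(Cs)
  } else {
    fit <- reversible_mle(C)
    T <- fit$T; pi_st <- fit$pi
  }
  ev <- reversible_spectrum(T, pi_st)
  its <- implied_from_eigen(ev$values, lag)
  structure(list(lag = lag, states = states, transition_matrix = T,
                 stationary = pi_st, eigenvalues = ev$values,
                 right_eigenvectors = ev$right,
                 implied_timescales = its, counts = C,
                 removed_states = removed, estimator = estimator),
            class = "msm_model")
}

# spectrum of a reversible T via the symmetric similarity D^1/2 T D^-1/2
reversible_spectrum <- function(T, pi_st) {
  s <- sqrt(pi_st)
  S <- sweep(sweep(T, 1, s, `*`), 2, s, `/`)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  right <- sweep(e$vectors, 1, s, `/`)
  # normalize sign and scale: first right eigenvector ~ constant 1
  right <- sweep(right, 2, right[1, ], `/`)
  list(values = e$values, right = right)
}

implied_from_eigen <- function(values, lag) {
  lam <- values[-1]
  out <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  out[ok] <- -lag / log(lam[ok])
  out
}

# reversible maximum-likelihood transition matrix (fixed-point iteration)
reversible_mle <- function(C, maxit = 500, tol = 1e-12) {
  X <- (C + t(C)) / 2
  ci <- rowSums(C)
  for (it in seq_len(maxit)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- (C + t(C)) / denom
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  xi <- rowSums(X)
  list(T = X / xi, pi = xi / sum(xi))
}

#' Implied timescales across a set of lags
#'
#' @param labels per-frame microstates (vector or list of vectors)
#' @param lags integer lags in frames
#' @param n_timescales timescales reported per lag
#' @param ... passed to [estimate_msm()]
#' @return data.frame (lag, timescale_index, timescale), sorted by lag
#' @export
implied_timescales_scan <- function(labels, lags, n_timescales = 3, ...) {
  lags <- sort(unique(as.integer(lags)))
  out <- lapply(lags, function(l) {
    m <- estimate_msm(labels, l, ...)
    its <- m$implied_timescales[seq_len(min(n_timescales,
                                            length(m$implied_timescales)))]
    data.frame(lag = l, timescale_index = seq_along(its) + 1,
               timescale = its)
  })
  do.call(rbind, out)
}

#' PCCA+ coarse-graining of an MSM into macrostates
#'
#' Spectral clustering of microstates on the dominant right-eigenvector
#' simplex (inner simplex vertex search): memberships are non-negative and
#' row-stochastic; the crisp assignment is the argmax membership.
#'
#' @param msm an [estimate_msm()] model (reversible)
#' @param n_macrostates number of macrostates
#' @return list (memberships, assignment, n_macrostates)
#' @export
pcca <- function(msm, n_macrostates) {
  m <- n_macrostates
  ns <- length(msm$states)
  if (m < 2 || m > ns)
    stop("invalid parameter: n_macrostates must be in [2, n_states]")
  if (msm$eigenvalues[m] < 0.5)
    warning("requested macrostates exceed the spectral gap support; ",
            "proceeding anyway")
  Psi <- msm$right_eigenvectors[, seq_len(m), drop = FALSE]
  Psi[, 1] <- 1
  # inner simplex vertex search
  idx <- integer(m)
  idx[1] <- which.max(rowSums(Psi^2))
  Y <- sweep(Psi, 2, Psi[idx[1], ])
  for (j in 2:m) {
    nr <- sqrt(rowSums(Y^2))
    idx[j] <- which.max(nr)
    if (nr[idx[j]] < 1e-12) stop("numerical error: degenerate eigenvector simplex")
    v <- Y[idx[j], ] / nr[idx[j]]
    Y <- Y - outer(as.vector(Y %*% v), v)
  }
  A <- solve(Psi[idx, , drop = FALSE])
  chi <- Psi %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  assignment <- max.col(chi, ties.method = "first")
  list(memberships = chi, assignment = assignment, n_macrostates = m)
}

#' Macrostate populations and mean first-passage times
#'
#' Populations aggregate the microstate stationary distribution over the
#' crisp assignment. MFPTs solve the standard linear system on the
#' microstate chain, then average over the source macrostate with
#' stationary weights; values are in frames (multiply by the frame spacing
#' for time units).
#'
#' @param msm an [estimate_msm()] model
#' @param pcca_out a [pcca()] result
#' @return list (populations, mfpt) where `mfpt[i, j]` is the mean
#'   first-passage time from macrostate i to j in frames
#' @export
macrostate_kinetics <- function(msm, pcca_out) {
  asg <- pcca_out$assignment
  m <- pcca_out$n_macrostates
  T <- msm$transition_matrix
  pi_st <- msm$stationary
  pop <- vapply(seq_len(m), function(a) sum(pi_st[asg == a]), numeric(1))
  mfpt <- matrix(0, m, m)
  for (b in seq_len(m)) {
    target <- which(asg == b)
    h <- numeric(length(pi_st))
    Q <- which(asg != b)
    if (length(Q)) {
      A <- diag(length(Q)) - T[Q, Q, drop = FALSE]
      h[Q] <- solve(A, rep(1, length(Q)))
    }
    for (a in seq_len(m)) {
      if (a == b) next
      src <- which(asg == a)
      mfpt[a, b] <- sum(pi_st[src] * h[src]) / sum(pi_st[src]) * msm$lag
    }
  }
  list(populations = pop, mfpt = mfpt)
}

#' Chapman-Kolmogorov test
#'
#' For each factor k, compares the macrostate self- and cross-transition
#' probabilities predicted by the model, `T(tau)^k`, against a model
#' re-estimated from the data at lag `k*tau`, with bootstrap confidence
#' bands from resampled trajectories.
#'
#' @param labels per-frame microstates (vector or list of vectors)
#' @param msm the reference [estimate_msm()] model at lag tau
#' @param pcca_out a [pcca()] result on `msm`
#' @param factors integer multipliers k
#' @param n_boot bootstrap replicates
#' @param seed integer seed for the bootstrap
#' @return data.frame (factor, from, to, p_pred, p_est, lo, hi, within);
#'   attribute `pass` gives the per-factor verdict on the diagonal entries
#' @export
ck_test <- function(labels, msm, pcca_out, factors = 2:4, n_boot = 50,
                    seed = 1) {
  if (!is.list(labels)) labels <- list(labels)
  asg <- pcca_out$assignment
  m <- pcca_out$n_macrostates
  pi_st <- msm$stationary
  macro_prob <- function(T, states) {
    # aggregate a microstate matrix to macrostates with stationary weights
    loc <- match(states, msm$states)
    ok <- !is.na(loc)
    P <- matrix(0, m, m)
    for (a in seq_len(m)) {
      src <- which(ok & asg[loc] == a)
      if (!length(src)) { P[a, ] <- NA; next }
      w <- pi_st[loc[src]]; w <- w / sum(w)
      for (b in seq_len(m)) {
        dst <- which(ok & asg[loc] == b)
        P[a, b] <- sum(w * rowSums(T[src, dst, drop = FALSE]))
      }
    }
    P
  }
  est_at <- function(lab_list, lag) {
    mm <- tryCatch(estimate_msm(lab_list, lag), error = function(e) NULL)
    if (is.null(mm)) return(NULL)
    macro_prob(mm$transition_matrix, mm$states)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list(); pass <- logical(0)
  for (k in factors) {
    lagk <- k * msm$lag
    if (all(vapply(labels, length, numeric(1)) <= lagk)) {
      warning("factor ", k, " truncated: lag exceeds trajectory length")
      next
    }
    Tk <- msm$transition_matrix
    if (k > 1) for (i in seq_len(k - 1)) Tk <- Tk %*% msm$transition_matrix
    P_pred <- macro_prob(Tk, msm$states)
    P_est <- est_at(labels, lagk)
    if (is.null(P_est)) next
    # bootstrap over trajectories; a single trajectory is resampled in
    # contiguous blocks so the bands have nonzero width
    units <- labels
    if (length(units) < 10) {
      units <- unlist(lapply(labels, function(tr) {
        bl <- max(10 * lagk, ceiling(length(tr) / 20))
        split(tr, ceiling(seq_along(tr) / bl))
      }), recursive = FALSE)
    }
    boots <- array(NA_real_, c(n_boot, m, m))
    for (b in seq_len(n_boot)) {
      res <- units[sample.int(length(units), replace = TRUE)]
      Pb <- est_at(res, lagk)
      if (!is.null(Pb)) boots[b, , ] <- Pb
    }
    lo <- apply(boots, c(2, 3), quantile, 0.025, na.rm = TRUE)
    hi <- apply(boots, c(2, 3), quantile, 0.975, na.rm = TRUE)
    for (a in seq_len(m)) for (b2 in seq_len(m))
      rows[[length(rows) + 1]] <- data.frame(
        factor = k, from = a, to = b2, p_pred = P_pred[a, b2],
        p_est = P_est[a, b2], lo = lo[a, b2], hi = hi[a, b2],
        within = P_pred[a, b2] >= lo[a, b2] & P_pred[a, b2] <= hi[a, b2])
    diag_ok <- vapply(seq_len(m), function(a)
      isTRUE(P_pred[a, a] >= lo[a, a] && P_pred[a, a] <= hi[a, a]),
      logical(1))
    pass <- c(pass, stats::setNames(all(diag_ok), as.character(k)))
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- pass
  out
}

#' Average-linkage hierarchical clustering of frames by RMSD
#'
#' Frames are aligned on the chain-a selection (Kabsch onto the first
#' frame), the pairwise RMSD matrix over `rmsd_mask` atoms is clustered
#' with average linkage, and the dendrogram is cut at the distance cutoff.
#' The representative of each cluster is the frame with the lowest mean
#' RMSD to its members.
#'
#' @param traj a `traj` object
#' @param cutoff dendrogram height cutoff, Angstrom
#' @param align_mask logical atom mask used for superposition (default:
#'   chain-a CA atoms)
#' @param rmsd_mask logical atom mask entering the RMSD (default: all heavy
#'   atoms)
#' @return list (labels, representatives, n_clusters, rmsd)
#' @export
hierarchical_cluster_rmsd <- function(traj, cutoff = 0.1,
                                      align_mask = NULL, rmsd_mask = NULL) {
  nf <- n_frames(traj)
  if (is.null(align_mask))
    align_mask <- chain_mask(traj, "a") & traj$atoms$elety == "CA"
  if (is.null(rmsd_mask)) rmsd_mask <- heavy_mask(traj)
  if (nf == 1)
    return(list(labels = 1L, representatives = 1L, n_clusters = 1L,
                rmsd = matrix(0, 1, 1)))
  ref <- frame_coords(traj, 1)[align_mask, , drop = FALSE]
  ref_cen <- colMeans(ref)
  aligned <- vector("list", nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    sel <- co[align_mask, , drop = FALSE]
    R <- kabsch_rotation(sel, ref)
    co <- sweep(co, 2, colMeans(sel)) %*% R
    aligned[[f]] <- sweep(co, 2, ref_cen, `+`)[rmsd_mask, , drop = FALSE]
  }
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
    D[i, j] <- D[j, i] <- sqrt(mean(rowSums((aligned[[i]] - aligned[[j]])^2)))
  hc <- hclust(stats::as.dist(D), method = "average")
  labels <- cutree(hc, h = cutoff)
  reps <- vapply(seq_len(max(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, integer(1))
  list(labels = labels, representatives = reps,
       n_clusters = max(labels), rmsd = D)
}
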