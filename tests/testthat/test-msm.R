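test_that("inverse CA-distance features match direct geometry", {
  d <- fix_dimer(8, 3, seed = 1)
  pairs <- as.data.frame(define_native_contacts(d$traj, 1))
  X <- featurize_inverse_ca_distances(d$traj, pairs)
  expect_equal(ncol(X), nrow(pairs))
  expect_true(all(X > 0))
  co <- frame_coords(d$traj, 1)
  at <- d$traj$atoms
  i <- which(at$chain == "A" & at$elety == "CA" & at$resno == pairs$resno_a[1])
  j <- which(at$chain == "B" & at$elety == "CA" & at$resno == pairs$resno_b[1])
  expect_equal(unname(X[1, 1]), 1 / sqrt(sum((co[i, ] - co[j, ])^2)))
  bad <- data.frame(resno_a = 999, resno_b = 1)
  expect_error(featurize_inverse_ca_distances(d$traj, bad),
               "topology error.*999")
})

test_that("separating chains monotonically shrinks inverse distances", {
  d <- fix_dimer(10, 4, seed = 2)
  sch <- dissociation_schedule(30, 12, 24, noise_sigma = 0.05, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  pairs <- as.data.frame(define_native_contacts(d$traj, 1))
  X <- featurize_inverse_ca_distances(tr, pairs)
  w1 <- colMeans(X[1:11, , drop = FALSE])
  w2 <- colMeans(X[12:23, , drop = FALSE])
  w3 <- colMeans(X[24:30, , drop = FALSE])
  expect_true(all(w2 <= w1 + 2e-3))   # pinned pairs are unchanged +- jitter
  expect_true(all(w3 <= w2 + 2e-3))
  expect_lt(mean(w3), mean(w1))
})

test_that("tICA separates a slow two-state process from noise", {
  set.seed(3)
  ns <- 4000
  s <- numeric(ns); cur <- 0
  for (i in 2:ns) {
    if (runif(1) < 0.005) cur <- 1 - cur
    s[i] <- cur
  }
  X <- cbind(s + rnorm(ns, 0, 0.3), matrix(rnorm(ns * 4), ns, 4))
  tm <- tica(X, lag = 10, n_components = 2)
  pr <- tica_project(tm, X)
  pooled <- sqrt(0.5 * (var(pr[s == 0, 1]) + var(pr[s == 1, 1])))
  expect_gt(abs(mean(pr[s == 0, 1]) - mean(pr[s == 1, 1])) / pooled, 3)
  # C0-orthonormality of the components
  Xc <- sweep(X[, tm$kept], 2, tm$mean)
  C0 <- crossprod(Xc) / (ns - 1)
  G <- t(tm$components) %*% C0 %*% tm$components
  expect_equal(G, diag(2), tolerance = 1e-6)
  expect_true(all(tm$eigenvalues <= 1 + 1e-8))
})

test_that("tICA on white noise has near-zero eigenvalues", {
  set.seed(4)
  X <- matrix(rnorm(5000 * 3), 5000, 3)
  tm <- tica(X, lag = 5)
  expect_lt(max(abs(tm$eigenvalues)), 3 / sqrt(5000))
  expect_error(tica(X, lag = 0), "invalid parameter")
})

test_that("k-means microstates recover separated blobs deterministically", {
  set.seed(5)
  B <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2),
             matrix(rnorm(60, 12), 30, 2))
  k1 <- kmeans_microstates(B, 3, seed = 9)
  k2 <- kmeans_microstates(B, 3, seed = 9)
  expect_identical(k1$labels, k2$labels)
  expect_equal(length(unique(k1$labels[1:30])), 1L)
  expect_equal(length(unique(k1$labels[31:60])), 1L)
  expect_equal(length(unique(k1$labels[61:90])), 1L)
  expect_error(kmeans_microstates(B[1:5, ], 90), "invalid parameter")
})

test_that("MSM estimation recovers an analytic 3-state chain", {
  T0 <- matrix(c(0.95, 0.04, 0.01,
                 0.03, 0.94, 0.03,
                 0.02, 0.08, 0.90), 3, 3, byrow = TRUE)
  lab <- sim_markov(T0, 1e5, seed = 6)
  m <- estimate_msm(lab, lag = 1)
  expect_lt(max(abs(m$transition_matrix - T0)), 0.02)
  ev2 <- sort(Re(eigen(T0)$values), decreasing = TRUE)[2]
  expect_equal(m$implied_timescales[1], -1 / log(ev2), tolerance = 0.05)
  expect_lt(max(abs(rowSums(m$transition_matrix) - 1)), 1e-10)
  # detailed balance of the symmetrized estimator
  flux <- m$stationary * m$transition_matrix
  expect_lt(max(abs(flux - t(flux))), 1e-8)
})

test_that("absorbing states are excluded by strong connectivity", {
  T0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  lab <- c(sim_markov(T0, 5000, seed = 7), rep(3L, 100))
  m <- estimate_msm(lab, 1)
  expect_equal(m$removed_states, 3)
  expect_equal(length(m$states), 2L)
})

test_that("estimation error shrinks roughly as 1/sqrt(n)", {
  T0 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  err <- vapply(c(2e3, 8e3, 32e3), function(n) {
    lab <- sim_markov(T0, n, seed = 8)
    max(abs(estimate_msm(lab, 1)$transition_matrix - T0))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("implied timescales are flat across lags for a Markov chain", {
  T0 <- matrix(c(0.97, 0.03, 0.05, 0.95), 2, 2, byrow = TRUE)
  lab <- sim_markov(T0, 2e5, seed = 9)
  its <- implied_timescales_scan(lab, lags = c(4, 1, 2, 8), n_timescales = 1)
  expect_equal(its$lag, sort(its$lag))
  ts <- its$timescale
  expect_lt(max(ts) / min(ts), 1.25)
  expect_true(all(ts > 0))
})

test_that("PCCA recovers block structure and the reversible MLE agrees", {
  pi_t <- c(0.97, 0.02, 0.01)
  Tm <- metropolis_chain(pi_t, base = 0.05)
  # two microstates per macro-block: refine each state into a fast pair
  lab_macro <- sim_markov(Tm, 3e5, seed = 10)
  set.seed(11)
  lab_micro <- 2 * lab_macro - (runif(length(lab_macro)) < 0.5)
  m <- estimate_msm(lab_micro, 1)
  p <- pcca(m, 3)
  expect_lt(max(abs(rowSums(p$memberships) - 1)), 1e-10)
  grp <- split(m$states, p$assignment)
  expect_setequal(vapply(grp, function(g) paste(sort(g), collapse = ","),
                         character(1)),
                  c("1,2", "3,4", "5,6"))
  kin <- macrostate_kinetics(m, p)
  expect_equal(sum(kin$populations), 1, tolerance = 1e-10)
  expect_lt(max(abs(sort(kin$populations, decreasing = TRUE) - pi_t)),
            0.01)
  # designed rate ordering: the 97% block is hardest to leave
  asg <- p$assignment
  big <- which.max(vapply(1:3, function(a)
    sum(m$stationary[asg == a]), numeric(1)))
  others <- setdiff(1:3, big)
  for (o in others)  # the dominant state is the hardest to leave
    expect_gt(kin$mfpt[big, o], kin$mfpt[o, big])

  mle <- estimate_msm(lab_micro, 1, estimator = "mle")
  expect_lt(max(abs(mle$transition_matrix - m$transition_matrix)), 0.05)
  flux <- mle$stationary * mle$transition_matrix
  expect_lt(max(abs(flux - t(flux))), 1e-8)
})

test_that("two-state MFPT matches the closed form lag/p", {
  T0 <- matrix(c(0.8, 0.2, 0.05, 0.95), 2, 2, byrow = TRUE)
  lab <- sim_markov(T0, 5e4, seed = 12)
  m <- estimate_msm(lab, 1)
  kin <- macrostate_kinetics(m, list(assignment = 1:2, n_macrostates = 2))
  expect_equal(kin$mfpt[1, 2], 1 / m$transition_matrix[1, 2],
               tolerance = 1e-10)
  expect_equal(kin$mfpt[2, 1], 1 / m$transition_matrix[2, 1],
               tolerance = 1e-10)
})

test_that("CK test accepts Markovian data and flags a periodic cycle", {
  T0 <- matrix(c(0.95, 0.04, 0.01,
                 0.03, 0.94, 0.03,
                 0.02, 0.08, 0.90), 3, 3, byrow = TRUE)
  lab <- sim_markov(T0, 1e5, seed = 13)
  m <- estimate_msm(lab, 1)
  p <- suppressWarnings(pcca(m, 2))
  ck <- ck_test(lab, m, p, factors = c(1, 2, 3, 5), n_boot = 30)
  pass <- attr(ck, "pass")
  expect_true(all(pass))
  expect_true(all(abs(ck$p_pred[ck$factor == 1] -
                        ck$p_est[ck$factor == 1]) < 1e-10))

  # near-deterministic dwell-3 cycle: not Markovian at lag 1
  set.seed(14)
  lab2 <- rep(rep(1:3, each = 3), length.out = 3e4)
  flip <- sample(length(lab2), 300)
  lab2[flip] <- sample.int(3, 300, replace = TRUE)
  m2 <- estimate_msm(lab2, 1)
  p2 <- suppressWarnings(pcca(m2, 3))
  ck2 <- suppressWarnings(ck_test(lab2, m2, p2, factors = c(2, 3),
                                  n_boot = 30))
  expect_false(all(attr(ck2, "pass")))
})

test_that("average-linkage RMSD clustering equals a brute-force oracle", {
  d <- fix_dimer(8, 3, seed = 15)
  sch <- dissociation_schedule(20, 9, 16, noise_sigma = 0.3, seed = 16)
  tr <- generate_dissociation_trajectory(d, sch)
  hc <- hierarchical_cluster_rmsd(tr, cutoff = 2.0)
  D <- hc$rmsd
  # brute-force average linkage on the same distance matrix
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- c()
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    if (best[1] > 2.0) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  oracle <- integer(n)
  for (ci in seq_along(clusters)) oracle[clusters[[ci]]] <- ci
  # same partition up to label permutation
  expect_equal(length(unique(oracle)), hc$n_clusters)
  tab <- table(oracle, hc$labels)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("duplicated frames collapse into clusters; distinct poses split", {
  d <- fix_dimer(8, 3, seed = 17)
  sch <- dissociation_schedule(6, 3, 5, noise_sigma = 0, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  # frames 1-2 identical (bound, zero noise), frames 5-6 identical (unbound)
  hc <- hierarchical_cluster_rmsd(tr, cutoff = 0.1)
  expect_equal(hc$labels[1], hc$labels[2])
  expect_equal(hc$labels[5], hc$labels[6])
  expect_true(hc$labels[1] != hc$labels[5])
  expect_true(all(hc$representatives %in% seq_len(6)))
  one <- hierarchical_cluster_rmsd(subset_frames(tr, 1), cutoff = 0.1)
  expect_equal(one$n_clusters, 1L)
})

test_that("macrostates from the full stack match generator state labels", {
  # pooled short runs hopping between the bound, encounter and unbound
  # poses under a designed metastable chain
  d <- build_toy_dimer(16, 6, seed = 6)
  T_meta <- matrix(c(0.96, 0.03, 0.01,
                     0.05, 0.92, 0.03,
                     0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  hop <- make_state_hopping_trajs(d, T_meta, n_frames = 150, n_traj = 6,
                                  noise = 0.4, seed = 7)
  pairs <- as.data.frame(define_native_contacts(d$traj, 1))
  X <- do.call(rbind, lapply(hop$trajs, featurize_inverse_ca_distances,
                             pairs = pairs))
  tm <- tica(X, lag = 2, n_components = 2)
  pr <- tica_project(tm, X)
  km <- kmeans_microstates(pr, k = 12, seed = 1)
  micro <- split(km$labels, rep(seq_along(hop$trajs), each = 150))
  m <- estimate_msm(micro, lag = 1)
  p <- suppressWarnings(pcca(m, 3))
  frame_macro <- p$assignment[match(unlist(micro), m$states)]
  truth <- unlist(hop$truth)
  ok <- !is.na(frame_macro)
  expect_gte(perm_agreement(frame_macro[ok], truth[ok]), 0.9)
})
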