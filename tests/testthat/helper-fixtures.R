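# Shared fixtures, built in code at test time.

kB <- 0.008314463
kT300 <- kB * 300

# small dimer reused across files (deterministic)
fix_dimer <- function(n = 10, pairs = 5, seed = 1)
  build_toy_dimer(n, pairs, seed = seed)

# a single-frame trajectory from raw coordinates (two chains)
raw_traj <- function(coords, chain, resno, resid, elety) {
  atoms <- data.frame(chain = chain, resno = resno, resid = resid,
                      elety = elety, stringsAsFactors = FALSE)
  atoms$elem <- dissockit:::element_from_name(elety)
  new_trajectory(matrix(t(coords), nrow = 1), atoms)
}

# simulate a discrete Markov chain from a transition matrix
sim_markov <- function(T, n, s0 = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(T)
  s <- integer(n)
  s[1] <- s0
  for (i in 2:n) s[i] <- sample.int(k, 1, prob = T[s[i - 1], ])
  s
}

# reversible 3-state chain with a designed stationary distribution
# (Metropolis construction)
metropolis_chain <- function(pi_t, base = 0.01) {
  k <- length(pi_t)
  T <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    T[i, j] <- base * min(1, pi_t[j] / pi_t[i])
  diag(T) <- 1 - rowSums(T)
  T
}

# best macrostate-label agreement over label permutations
perm_agreement <- function(pred, truth, k = 3) {
  tt <- table(factor(pred, 1:k), factor(truth, 1:k))
  perms <- if (k == 3)
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
         c(3, 2, 1))
  else list(seq_len(k))
  max(vapply(perms, function(p) sum(tt[cbind(p, 1:k)]) / sum(tt),
             numeric(1)))
}

# pooled short trajectories hopping between the three poses of a programmed
# dissociation (bound / encounter / unbound) under a designed metastable
# chain -- the setting an MSM over short runs is meant for
make_state_hopping_trajs <- function(d, T_meta, n_frames, n_traj,
                                     noise = 0.4, seed = 1) {
  sch <- dissociation_schedule(3, 2, 3, torsion_deg = 25, noise_sigma = 0,
                               seed = 1)
  poses <- generate_dissociation_trajectory(d, sch)  # frames: bound/enc/unb
  set.seed(seed)
  trajs <- list(); truth <- list()
  for (tr in seq_len(n_traj)) {
    lab <- sim_markov(T_meta, n_frames, s0 = ((tr - 1) %% 3) + 1,
                      seed = seed + 100 * tr)
    xyz <- poses$xyz[lab, , drop = FALSE] +
      matrix(rnorm(n_frames * ncol(poses$xyz), sd = noise),
             n_frames, ncol(poses$xyz))
    trajs[[tr]] <- new_trajectory(xyz, poses$atoms, chain_map = poses$chain_map)
    truth[[tr]] <- lab
  }
  list(trajs = trajs, truth = truth)
}
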