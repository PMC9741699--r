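#' Build a toy two-chain dimer
#'
#' Constructs a synthetic dimer of two mirror-symmetric chains ("A" and "B")
#' whose residues are pseudo-residues (atoms N, CA, C, O plus one side-chain
#' pseudo-atom) placed on a regular lattice. A designated set of inter-chain
#' residue pairs is built to be in contact (minimum heavy-atom distance
#' 3.0 Angstrom across the interface plane); all other inter-chain distances
#' exceed 5 Angstrom, so the native-contact set at the conventional 4.5
#' Angstrom cutoff is exactly the designed pairs.
#'
#' Interface pairs alternate between a hydrophobic pairing (LEU side-chain
#' carbon against LEU side-chain carbon) and a salt-bridge pairing (LYS NZ
#' against ASP OD1), so the typed-contact machinery has something to find.
#'
#' @param residues_per_chain residues per chain (>= 4); the convention for the
#'   antibody CH3 domain systems this emulates is 100
#' @param n_interface_pairs number of designed contact pairs (>= 1)
#' @param seed integer seed; the dimer is a pure function of its arguments
#' @return an object of class `toy_dimer` with elements `traj` (a one-frame
#'   [new_trajectory()]), `interface_pairs` (data.frame resno_a, resno_b,
#'   kind, break_first), and `contact_cutoff`
#' @export
build_toy_dimer <- function(residues_per_chain = 100, n_interface_pairs = 5,
                            seed = 1) {
  if (residues_per_chain < 4)
    stop("invalid parameter: residues_per_chain must be >= 4")
  if (n_interface_pairs < 1)
    stop("invalid parameter: n_interface_pairs must be >= 1")
  if (n_interface_pairs > residues_per_chain)
    stop("invalid parameter: more interface pairs than residues")
  n <- residues_per_chain
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ncol_l <- ceiling(sqrt(n))
  site <- cbind(y = 6.0 * ((seq_len(n) - 1) %% ncol_l),
                z = 5.5 * ((seq_len(n) - 1) %/% ncol_l))

  iface <- sort(sample.int(n, n_interface_pairs))
  kind <- rep(c("hydrophobic", "salt_bridge"), length.out = n_interface_pairs)

  # per-residue atom template, chain a (x toward interface plane at x = 0)
  tmpl <- rbind(N  = c(-5.0,  1.3, 0.0),
                CA = c(-5.5,  0.0, 0.0),
                C  = c(-4.4, -1.1, 0.2),
                O  = c(-3.2, -1.0, 0.4),
                SC = c(-6.9, -0.3, 0.6))
  tmpl_iface <- tmpl
  tmpl_iface["SC", ] <- c(-1.5, 0.2, 0.1)

  coords_a <- matrix(0, n * 5, 3)
  resno <- integer(n * 5); aname <- character(n * 5); rname <- character(n * 5)
  for (i in seq_len(n)) {
    is_if <- i %in% iface
    tm <- if (is_if) tmpl_iface else tmpl
    rows <- (i - 1) * 5 + 1:5
    coords_a[rows, ] <- tm + rep(c(0, site[i, 1], site[i, 2]), each = 5)
    resno[rows] <- i
    if (is_if && kind[match(i, iface)] == "salt_bridge") {
      rname[rows] <- "LYS"; aname[rows] <- c("N", "CA", "C", "O", "NZ")
    } else if (is_if) {
      rname[rows] <- "LEU"; aname[rows] <- c("N", "CA", "C", "O", "CB")
    } else {
      rname[rows] <- "ALA"; aname[rows] <- c("N", "CA", "C", "O", "CB")
    }
  }
  # truncated jitter, mirrored to chain b so the dimer stays mirror-symmetric
  jit <- matrix(rnorm(length(coords_a), sd = 0.15), ncol = 3)
  jit <- pmin(pmax(jit, -0.45), 0.45)
  coords_a <- coords_a + jit

  coords_b <- coords_a
  coords_b[, 1] <- -coords_b[, 1]
  rname_b <- rname; aname_b <- aname
  for (i in iface[kind == "salt_bridge"]) {
    rows <- (i - 1) * 5 + 1:5
    rname_b[rows] <- "ASP"; aname_b[rows] <- c("N", "CA", "C", "O", "OD1")
  }

  atoms <- data.frame(
    chain = rep(c("A", "B"), each = n * 5),
    resno = c(resno, resno),
    resid = c(rname, rname_b),
    elety = c(aname, aname_b),
    stringsAsFactors = FALSE)
  atoms$elem <- element_from_name(atoms$elety)

  xyz <- matrix(t(rbind(coords_a, coords_b)), nrow = 1)
  traj <- new_trajectory(xyz, atoms, frame_spacing = 1,
                         chain_map = c(a = "A", b = "B"))
  # peripheral pairs (far from the chain axis) are the first to break under
  # an interdomain torsion; central pairs persist into the encounter complex
  ctr <- colMeans(site)  # the torsion axis passes near the chain centroid
  radius <- sqrt(rowSums(sweep(site[iface, , drop = FALSE], 2, ctr)^2))
  nb <- ceiling(length(iface) / 2)
  pairs <- data.frame(resno_a = iface, resno_b = iface, kind = kind,
                      break_first = rank(-radius, ties.method = "first") <= nb)
  structure(list(traj = traj, interface_pairs = pairs, contact_cutoff = 4.5,
                 residues_per_chain = n, seed = seed),
            class = "toy_dimer")
}

#' @export
print.toy_dimer <- function(x, ...) {
  cat(sprintf("<toy_dimer> %d residues/chain, %d interface pairs (%d break first)\n",
              x$residues_per_chain, nrow(x$interface_pairs),
              sum(x$interface_pairs$break_first)))
  invisible(x)
}

# save/restore the global RNG state so generators are pure in their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Programmed dissociation schedule
#'
#' Describes a two-step synthetic dissociation: bound fluctuation until
#' `t_encounter`, an encounter-complex window in which a designated subset of
#' interface contacts is released and a torsion is applied to chain b, and
#' full separation from `t_unbound` on.
#'
#' @param n_frames total frames
#' @param t_encounter first frame (1-based) of the encounter window
#' @param t_unbound first frame of the unbound window
#' @param separation_axis unit 3-vector along which chain b leaves
#' @param torsion_deg torsion applied to chain b about the interdomain axis
#'   during the encounter window (degrees)
#' @param torsion_mode "constant" (the full torsion from `t_encounter` on)
#'   or "ramp" (linear build-up across the encounter window)
#' @param noise_sigma per-coordinate Gaussian jitter, Angstrom
#' @param seed integer seed
#' @param encounter_shift chain-b displacement in the encounter window, Angstrom
#' @param unbound_shift chain-b displacement from `t_unbound` on, Angstrom
#' @return object of class `dissociation_schedule`
#' @export
dissociation_schedule <- function(n_frames, t_encounter, t_unbound,
                                  separation_axis = c(1, 0, 0),
                                  torsion_deg = 0, noise_sigma = 0.05,
                                  seed = 1, encounter_shift = 2,
                                  unbound_shift = 30,
                                  torsion_mode = c("constant", "ramp")) {
  torsion_mode <- match.arg(torsion_mode)
  if (!(t_encounter > 1 && t_encounter < t_unbound && t_unbound <= n_frames))
    stop("invalid parameter: need 1 < t_encounter < t_unbound <= n_frames")
  if (noise_sigma < 0) stop("invalid parameter: noise_sigma must be >= 0")
  structure(list(n_frames = n_frames, t_encounter = t_encounter,
                 t_unbound = t_unbound,
                 separation_axis = unit_vec(separation_axis),
                 torsion_deg = torsion_deg, torsion_mode = torsion_mode,
                 noise_sigma = noise_sigma,
                 seed = seed, encounter_shift = encounter_shift,
                 unbound_shift = unbound_shift),
            class = "dissociation_schedule")
}

#' Generate a programmed dissociation trajectory
#'
#' Frames before `t_encounter` jitter about the bound pose. In the encounter
#' window chain b is rigidly rotated by `torsion_deg` about the interdomain
#' axis and displaced by `encounter_shift`; the side chains of pairs flagged
#' `break_first` are retracted out of contact while the remaining pairs are
#' kept pinned in contact (a hinge-like staged loss). From `t_unbound` on,
#' chain b is displaced so that every inter-chain heavy-atom distance exceeds
#' twice the contact cutoff.
#'
#' @param dimer a [build_toy_dimer()] object
#' @param schedule a [dissociation_schedule()]
#' @return a [new_trajectory()] with `schedule$n_frames` frames
#' @export
generate_dissociation_trajectory <- function(dimer, schedule) {
  stopifnot(inherits(dimer, "toy_dimer"),
            inherits(schedule, "dissociation_schedule"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(schedule$seed)

  ref <- frame_coords(dimer$traj, 1)
  at <- dimer$traj$atoms
  na <- sum(at$chain == "A")
  idx_b <- which(at$chain == "B")
  axis <- schedule$separation_axis

  # chain-b side-chain atom row (within full coords) for each interface pair
  sc_row <- function(chain, resno) {
    which(at$chain == chain & at$resno == resno &
            !(at$elety %in% c("N", "CA", "C", "O")))
  }
  pairs <- dimer$interface_pairs
  rows_b_sc <- vapply(pairs$resno_b, function(r) sc_row("B", r), integer(1))
  rows_b_res <- lapply(pairs$resno_b,
                       function(r) which(at$chain == "B" & at$resno == r))

  # retracted chain-b pose: breaking side chains swung outward, clear of both
  # the interface and their own backbone shell
  ref_retract <- ref
  ref_retract[rows_b_sc[pairs$break_first], 1] <- 8.0

  cb <- colMeans(ref[idx_b, ])
  R <- rotation_about_axis(axis, schedule$torsion_deg)
  rows_pinned <- unlist(rows_b_res[!pairs$break_first])

  nfr <- schedule$n_frames
  xyz <- matrix(0, nfr, 3 * nrow(at))
  for (f in seq_len(nfr)) {
    co <- ref
    Rf <- if (schedule$torsion_mode == "ramp" && f < schedule$t_unbound)
      rotation_about_axis(axis, schedule$torsion_deg *
                            (f - schedule$t_encounter + 1) /
                            (schedule$t_unbound - schedule$t_encounter))
    else R
    if (f >= schedule$t_unbound) {
      co[idx_b, ] <- rotate_coords(ref_retract[idx_b, ], R, cb)
      co[idx_b, ] <- co[idx_b, ] +
        rep(axis * schedule$unbound_shift, each = length(idx_b))
    } else if (f >= schedule$t_encounter) {
      co[idx_b, ] <- rotate_coords(ref_retract[idx_b, ], Rf, cb)
      co[idx_b, ] <- co[idx_b, ] +
        rep(axis * schedule$encounter_shift, each = length(idx_b))
      # persisting pairs act as intact hinge anchors: whole residues keep
      # their bound pose while the rest of chain b twists away
      co[rows_pinned, ] <- ref[rows_pinned, ]
    }
    if (schedule$noise_sigma > 0)
      co <- co + matrix(rnorm(length(co), sd = schedule$noise_sigma), ncol = 3)
    xyz[f, ] <- as.vector(t(co))
  }
  new_trajectory(xyz, at, frame_spacing = dimer$traj$frame_spacing,
                 chain_map = dimer$traj$chain_map)
}

#' Build a toy trajectory driven by a collective-variable series
#'
#' Maps a 1-D centre-of-mass distance CV (nm) onto the toy dimer by rigidly
#' displacing chain b along the interface normal so that the mass-weighted
#' centre-of-mass distance of each frame equals `10 * cv` Angstrom. Contacts
#' break naturally as the displacement grows, so descriptor, state and
#' contact analyses behave as on a dissociating complex.
#'
#' @param dimer a [build_toy_dimer()] object
#' @param cv numeric vector of CV values (nm)
#' @param frame_spacing ns per frame
#' @param noise_sigma coordinate jitter, Angstrom
#' @param seed integer seed for the jitter
#' @return a [new_trajectory()]; attribute `bound_cv_nm` holds the CV value
#'   corresponding to the unshifted bound pose
#' @export
trajectory_from_cv <- function(dimer, cv, frame_spacing = 1,
                               noise_sigma = 0.05, seed = 1) {
  stopifnot(inherits(dimer, "toy_dimer"), length(cv) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- frame_coords(dimer$traj, 1)
  at <- dimer$traj$atoms
  idx_a <- which(at$chain == "A"); idx_b <- which(at$chain == "B")
  m <- element_mass(at$elem)
  com <- function(ix, co) colSums(co[ix, ] * m[ix]) / sum(m[ix])
  d0 <- vec_norm(com(idx_b, ref) - com(idx_a, ref))
  ax <- unit_vec(com(idx_b, ref) - com(idx_a, ref))
  delta <- pmax(10 * cv - d0, -2)   # never drive the chains into each other
  xyz <- matrix(0, length(cv), 3 * nrow(at))
  for (f in seq_along(cv)) {
    co <- ref
    co[idx_b, ] <- co[idx_b, ] + rep(ax * delta[f], each = length(idx_b))
    if (noise_sigma > 0)
      co <- co + matrix(rnorm(length(co), sd = noise_sigma), ncol = 3)
    xyz[f, ] <- as.vector(t(co))
  }
  out <- new_trajectory(xyz, at, frame_spacing, dimer$traj$chain_map)
  attr(out, "bound_cv_nm") <- d0 / 10
  out
}
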