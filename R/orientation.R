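#' Define per-domain reference frames for orientation analysis
#'
#' Builds a deterministic coordinate system on a reference structure: for
#' each chain the origin is the centroid of the core selection and the two
#' unit vectors (A1, A2 for chain a; B1, B2 for chain b) are the first two
#' principal axes of the core coordinates, signs fixed by pointing toward
#' the core's highest-numbered residue.
#'
#' @param traj a `traj` object holding the reference structure
#' @param frame reference frame index
#' @param core_a,core_b residue numbers forming each chain's core
#'   (default: all residues), measured on CA atoms
#' @return object of class `domain_frame_def`
#' @export
define_reference_frames <- function(traj, frame = 1, core_a = NULL,
                                    core_b = NULL) {
  co <- frame_coords(traj, frame)
  one <- function(label, core) {
    m <- chain_mask(traj, label) & traj$atoms$elety == "CA"
    if (!is.null(core)) m <- m & traj$atoms$resno %in% core
    rows <- which(m)
    if (length(rows) < 3)
      stop("degenerate frame: need >= 3 core atoms per chain")
    X <- co[rows, , drop = FALSE]
    origin <- colMeans(X)
    Xc <- sweep(X, 2, origin)
    sv <- svd(Xc)
    if (sv$d[2] < 1e-6 * sv$d[1])
      stop("degenerate frame: collinear core coordinates")
    ax1 <- sv$v[, 1]; ax2 <- sv$v[, 2]
    # deterministic sign: point toward the highest-numbered core residue
    ref_vec <- X[which.max(traj$atoms$resno[rows]), ] - origin
    if (sum(ax1 * ref_vec) < 0) ax1 <- -ax1
    if (sum(ax2 * ref_vec) < 0) ax2 <- -ax2
    list(rows = rows, origin = origin, ax1 = ax1, ax2 = ax2, coords = X)
  }
  structure(list(a = one("a", core_a), b = one("b", core_b)),
            class = "domain_frame_def")
}

#' Interdomain orientation metrics of one frame
#'
#' Each domain's reference frame is transported onto the observed frame by
#' least-squares rigid superposition (Kabsch) of its core. With C the
#' vector from the chain-a origin to the chain-b origin: dC = |C| (Angstrom),
#' AC1 = angle(A1, C), AC2 = angle(A2, C), BC1 = angle(B1, -C),
#' BC2 = angle(B2, -C) (degrees, \[0, 180\]), and AB the signed torsion
#' between the planes (A1, C) and (C, B1), right-handed about C pointing
#' a to b, degrees in (-180, 180\].
#'
#' @param traj a `traj` object
#' @param frame frame index
#' @param def a [define_reference_frames()] definition
#' @return named numeric vector (dC, AB, AC1, AC2, BC1, BC2)
#' @export
orientation_metrics <- function(traj, frame, def) {
  co <- frame_coords(traj, frame)
  transport <- function(d) {
    Y <- co[d$rows, , drop = FALSE]
    R <- kabsch_rotation(d$coords, Y)
    list(origin = colMeans(Y),
         ax1 = as.vector(d$ax1 %*% R),
         ax2 = as.vector(d$ax2 %*% R))
  }
  A <- transport(def$a); B <- transport(def$b)
  C <- B$origin - A$origin
  dC <- vec_norm(C)
  c(dC = dC,
    AB = signed_torsion_deg(A$ax1, B$ax1, C),
    AC1 = angle_deg(A$ax1, C), AC2 = angle_deg(A$ax2, C),
    BC1 = angle_deg(B$ax1, -C), BC2 = angle_deg(B$ax2, -C))
}

#' Orientation metrics for every frame of a trajectory
#'
#' @param traj a `traj` object
#' @param def a [define_reference_frames()] definition
#' @return data.frame (frame, dC, AB, AC1, AC2, BC1, BC2)
#' @export
orientation_timeseries <- function(traj, def) {
  mets <- t(vapply(seq_len(n_frames(traj)),
                   function(f) orientation_metrics(traj, f, def),
                   numeric(6)))
  data.frame(frame = seq_len(n_frames(traj)), mets)
}

#' Per-window variability of the orientation metrics
#'
#' Standard deviation of each metric within each state window; circular
#' statistics for the AB torsion (which wraps at +/-180 degrees), ordinary
#' standard deviations for dC and the tilt angles. Reports which angle has
#' the largest variability per window.
#'
#' @param metrics an [orientation_timeseries()] data.frame
#' @param windows factor or character vector of per-frame state labels
#' @return data.frame (window, n, sd_dC, sd_AB, sd_AC1, sd_AC2, sd_BC1,
#'   sd_BC2, dominant_angle)
#' @export
variability_summary <- function(metrics, windows) {
  stopifnot(nrow(metrics) == length(windows))
  windows <- as.factor(windows)
  out <- lapply(levels(windows), function(w) {
    sel <- windows == w
    if (sum(sel) < 2) stop("invalid parameter: window '", w,
                           "' has fewer than 2 frames")
    m <- metrics[sel, ]
    sds <- c(sd_dC = sd(m$dC), sd_AB = circ_sd_deg(m$AB),
             sd_AC1 = sd(m$AC1), sd_AC2 = sd(m$AC2),
             sd_BC1 = sd(m$BC1), sd_BC2 = sd(m$BC2))
    ang <- sds[c("sd_AB", "sd_AC1", "sd_AC2", "sd_BC1", "sd_BC2")]
    data.frame(window = w, n = sum(sel), as.list(sds),
               dominant_angle = sub("^sd_", "", names(ang)[which.max(ang)]))
  })
  do.call(rbind, out)
}
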