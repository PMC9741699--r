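#' Per-frame scalar descriptor series
#'
#' Holds one scalar per frame with its name, units and frame spacing. The
#' three descriptors used for state definition are the centre-of-mass
#' distance of the two chains (Angstrom), the fraction of native contacts Q
#' (dimensionless, in \[0,1\]) and the solvent accessible surface area
#' (Angstrom^2).
#'
#' @param name descriptor name
#' @param values numeric vector, one value per frame
#' @param frame_spacing ns per frame
#' @param units unit string
#' @return data.frame (time, value) of class `descriptor_series`
#' @export
descriptor_series <- function(name, values, frame_spacing = 1, units = "") {
  out <- data.frame(time = (seq_along(values) - 1) * frame_spacing,
                    value = as.numeric(values))
  attr(out, "name") <- name
  attr(out, "units") <- units
  attr(out, "frame_spacing") <- frame_spacing
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' Write / read a descriptor series as CSV
#'
#' The first line is a comment naming the descriptor, its units and the
#' frame spacing; then a regular `time,value` CSV body.
#'
#' @param ds a [descriptor_series()]
#' @param path file path
#' @export
write_descriptor_series <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name=%s units=%s frame_spacing_ns=%g",
                     attr(ds, "name"), attr(ds, "units"),
                     attr(ds, "frame_spacing")), con)
  writeLines("time,value", con)
  writeLines(sprintf("%.10g,%.10g", ds$time, ds$value), con)
  invisible(path)
}

#' @rdname write_descriptor_series
#' @export
read_descriptor_series <- function(path) {
  raw <- readLines(path)
  meta <- raw[1]
  gx <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", meta)
  tb <- read.table(text = raw[-1], header = TRUE, sep = ",")
  descriptor_series(gx("name"), tb$value,
                    frame_spacing = as.numeric(gx("frame_spacing_ns")),
                    units = gx("units"))
}

#' Centre-of-mass distance between two chain selections
#'
#' Euclidean distance between the (mass- or equal-)weighted centroids of the
#' two selections in one frame.
#'
#' @param traj a `traj` object
#' @param frame frame index
#' @param chain_a,chain_b chain labels ("a"/"b" or raw identifiers)
#' @param weighting "mass" or "geometric"
#' @return distance in Angstrom
#' @export
com_distance <- function(traj, frame = 1, chain_a = "a", chain_b = "b",
                         weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  co <- frame_coords(traj, frame)
  ma <- chain_mask(traj, chain_a)
  mb <- chain_mask(traj, chain_b)
  if (!any(ma) || !any(mb)) stop("selection error: empty chain selection")
  w <- if (weighting == "mass") element_mass(traj$atoms$elem) else
    rep(1, nrow(traj$atoms))
  ca <- colSums(co[ma, , drop = FALSE] * w[ma]) / sum(w[ma])
  cb <- colSums(co[mb, , drop = FALSE] * w[mb]) / sum(w[mb])
  vec_norm(cb - ca)
}

# minimum heavy-atom distance for each inter-chain residue pair of a frame;
# returns data.frame(resno_a, resno_b, dmin)
residue_pair_min_dist <- function(traj, frame) {
  co <- frame_coords(traj, frame)
  hv <- heavy_mask(traj)
  ia <- which(chain_mask(traj, "a") & hv)
  ib <- which(chain_mask(traj, "b") & hv)
  A <- co[ia, , drop = FALSE]; B <- co[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  key <- interaction(rep(traj$atoms$resno[ia], times = length(ib)),
                     rep(traj$atoms$resno[ib], each = length(ia)),
                     drop = TRUE)
  mins <- tapply(as.vector(d2), key, min)
  parts <- do.call(rbind, strsplit(names(mins), "\\."))
  data.frame(resno_a = as.integer(parts[, 1]),
             resno_b = as.integer(parts[, 2]),
             dmin = sqrt(as.numeric(mins)))
}

#' Define the native contact set from a reference frame
#'
#' All inter-chain residue pairs whose minimum heavy-atom distance is below
#' `cutoff` in the reference frame. 4.5 Angstrom is the common heavy-atom
#' contact convention.
#'
#' @param traj a `traj` object
#' @param frame reference frame index
#' @param cutoff heavy-atom distance cutoff, Angstrom
#' @return object of class `native_contact_set`: data.frame (resno_a,
#'   resno_b) with attributes `cutoff` and `reference_frame`
#' @export
define_native_contacts <- function(traj, frame = 1, cutoff = 4.5) {
  if (cutoff <= 0) stop("invalid parameter: cutoff must be positive")
  pd <- residue_pair_min_dist(traj, frame)
  out <- pd[pd$dmin < cutoff, c("resno_a", "resno_b")]
  out <- out[order(out$resno_a, out$resno_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "reference_frame") <- frame
  class(out) <- c("native_contact_set", "data.frame")
  out
}

#' Fraction of native contacts Q in a frame
#'
#' Share of native inter-chain residue pairs whose minimum heavy-atom
#' distance is below the native cutoff in this frame. 1 means fully bound,
#' 0 means no native contact remains.
#'
#' @param traj a `traj` object
#' @param frame frame index
#' @param native a [define_native_contacts()] set
#' @return fraction in \[0, 1\]
#' @export
fraction_native_contacts <- function(traj, frame, native) {
  if (!nrow(native)) stop("invalid parameter: empty native contact set")
  cutoff <- attr(native, "cutoff")
  co <- frame_coords(traj, frame)
  hv <- heavy_mask(traj)
  ca <- chain_mask(traj, "a"); cb <- chain_mask(traj, "b")
  resa <- traj$atoms$resno
  formed <- vapply(seq_len(nrow(native)), function(k) {
    ia <- which(ca & hv & resa == native$resno_a[k])
    ib <- which(cb & hv & resa == native$resno_b[k])
    A <- co[ia, , drop = FALSE]; B <- co[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    min(d2) < cutoff^2
  }, logical(1))
  mean(formed)
}

#' Shrake-Rupley solvent accessible surface area of raw atoms
#'
#' Deterministic golden-spiral test points on each atom's extended sphere
#' (van der Waals radius + probe); per-atom exposed area sums to the total.
#' Bondi van der Waals radii; unknown elements raise an error naming the
#' element.
#'
#' @param coords n x 3 coordinate matrix, Angstrom
#' @param elem character vector of element symbols
#' @param probe_radius probe radius, Angstrom (water: 1.4)
#' @param n_sphere_points test points per atom
#' @return list with `total` (Angstrom^2) and `per_atom`
#' @export
sasa_atoms <- function(coords, elem, probe_radius = 1.4,
                       n_sphere_points = 960) {
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3)
  stopifnot(nrow(coords) == length(elem))
  r <- element_vdw(elem) + probe_radius
  pa <- shrake_rupley_cpp(coords, r, as.integer(n_sphere_points))
  list(total = sum(pa), per_atom = pa)
}

#' Solvent accessible surface area of a trajectory frame
#'
#' Heavy atoms only unless `include_hydrogens` is set (if the input carries
#' no hydrogens this is the declared heavy-atom-only mode).
#'
#' @param traj a `traj` object
#' @param frame frame index
#' @param probe_radius probe radius, Angstrom
#' @param n_sphere_points test points per atom
#' @param include_hydrogens include H atoms if present
#' @return list with `total`, `per_chain` (named a/b) and `per_atom`
#' @export
sasa <- function(traj, frame = 1, probe_radius = 1.4, n_sphere_points = 960,
                 include_hydrogens = FALSE) {
  keep <- if (include_hydrogens) rep(TRUE, nrow(traj$atoms)) else
    heavy_mask(traj)
  co <- frame_coords(traj, frame)[keep, , drop = FALSE]
  res <- sasa_atoms(co, traj$atoms$elem[keep], probe_radius, n_sphere_points)
  cha <- chain_mask(traj, "a")[keep]
  res$per_chain <- c(a = sum(res$per_atom[cha]),
                     b = sum(res$per_atom[!cha]))
  res
}

#' Compute the three descriptor time series of a trajectory
#'
#' Per-frame centre-of-mass distance, fraction of native contacts and SASA,
#' aligned on the same time axis.
#'
#' @param traj a `traj` object
#' @param native a [define_native_contacts()] set
#' @param probe_radius SASA probe radius, Angstrom
#' @param n_sphere_points SASA test points per atom
#' @return named list of three [descriptor_series()]: `com_distance`,
#'   `q_native`, `sasa`
#' @export
descriptor_timeseries <- function(traj, native, probe_radius = 1.4,
                                  n_sphere_points = 960) {
  nf <- n_frames(traj)
  dcom <- numeric(nf); q <- numeric(nf); sa <- numeric(nf)
  for (f in seq_len(nf)) {
    dcom[f] <- com_distance(traj, f)
    q[f] <- fraction_native_contacts(traj, f, native)
    sa[f] <- sasa(traj, f, probe_radius, n_sphere_points)$total
  }
  fs <- traj$frame_spacing
  list(com_distance = descriptor_series("com_distance", dcom, fs, "Angstrom"),
       q_native = descriptor_series("q_native", q, fs, "fraction"),
       sasa = descriptor_series("sasa", sa, fs, "Angstrom^2"))
}
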