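# Typed noncovalent inter-chain contact detection and occurrence analysis.
#
# Geometric criteria (explicit restatement of the common defaults, all
# configurable through `contact_criteria()`):
#   hydrogen bond  donor-acceptor heavy-atom distance <= 3.5 A (no-angle
#                  mode when hydrogens are absent), subclassified
#                  backbone/backbone, side-chain/backbone, side-chain/side-chain
#   salt bridge    anionic O (Asp/Glu) to cationic N (Lys/Arg/His+) <= 4.0 A
#   pi-cation      cationic N within 6.0 A of ring centroid, <= 60 deg off
#                  the ring normal
#   pi-stack       ring centroid distance <= 7.0 A, normals within 30 deg
#   T-stack        ring centroid distance 5-7 A, normals 60-90 deg
#   hydrophobic    side-chain C to side-chain C <= 4.5 A, apolar residues
# Distance-only van der Waals pairs are never emitted.

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")
.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PRO", "PHE", "TRP")
.sc_donor <- list(ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
                  HIS = c("ND1", "NE2"), HIP = c("ND1", "NE2"),
                  HSP = c("ND1", "NE2"), LYS = "NZ", SER = "OG",
                  THR = "OG1", TRP = "NE1", TYR = "OH")
.sc_acceptor <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
                     SER = "OG", THR = "OG1", TYR = "OH")
.anionic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.cationic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIP = c("ND1", "NE2"), HSP = c("ND1", "NE2"))
.ring_atoms <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
                    HIP = c("CG", "ND1", "CD2", "CE1", "NE2"),
                    HSP = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Geometric criteria for typed contacts
#'
#' @param hbond_dist,salt_bridge_dist,hydrophobic_dist heavy-atom distance
#'   cutoffs, Angstrom
#' @param pi_cation_dist,pi_cation_angle cation-to-centroid cutoff and
#'   maximum angle off the ring normal, degrees
#' @param pi_stack_dist,pi_stack_angle centroid cutoff and maximum
#'   normal-normal angle for parallel stacking
#' @param t_stack_dist_min,t_stack_dist_max,t_stack_angle_min,t_stack_angle_max
#'   centroid window and normal-normal angle window for T-stacking
#' @return named list of thresholds
#' @export
contact_criteria <- function(hbond_dist = 3.5, salt_bridge_dist = 4.0,
                             hydrophobic_dist = 4.5,
                             pi_cation_dist = 6.0, pi_cation_angle = 60,
                             pi_stack_dist = 7.0, pi_stack_angle = 30,
                             t_stack_dist_min = 5.0, t_stack_dist_max = 7.0,
                             t_stack_angle_min = 60, t_stack_angle_max = 90) {
  as.list(environment())
}

# rows of atoms belonging to (chain, resno) whose elety is in `names`
.rows_named <- function(atoms, mask, names_list) {
  ok <- logical(nrow(atoms))
  resid <- atoms$resid; elety <- atoms$elety
  for (rn in names(names_list))
    ok <- ok | (resid == rn & elety %in% names_list[[rn]])
  which(mask & ok)
}

# ring centroid and unit normal for each aromatic residue in a chain mask;
# returns list of lists (resno, centroid, normal)
.rings <- function(co, atoms, mask) {
  out <- list()
  arom <- which(mask & atoms$resid %in% names(.ring_atoms))
  if (!length(arom)) return(out)
  for (r in unique(atoms$resno[arom])) {
    rows <- arom[atoms$resno[arom] == r]
    rn <- atoms$resid[rows[1]]
    rows <- rows[atoms$elety[rows] %in% .ring_atoms[[rn]]]
    if (length(rows) < 3) next
    X <- co[rows, , drop = FALSE]
    cen <- colMeans(X)
    sv <- svd(sweep(X, 2, cen))
    out[[length(out) + 1]] <- list(resno = r, centroid = cen,
                                   normal = sv$v[, 3])
  }
  out
}

#' Detect typed inter-chain contacts in one frame
#'
#' Evaluates the geometric criteria for the eight contact types between the
#' two chains of a frame. Hydrogen bonds are found by donor/acceptor
#' heavy-atom distance (declared no-angle mode when the input carries no
#' hydrogens) and subclassified by backbone or side-chain membership of
#' donor and acceptor. Distance-only van der Waals pairs are excluded by
#' construction. Nonstandard residues without typing rules are silently
#' outside every rule table.
#'
#' @param traj a `traj` object
#' @param frame frame index
#' @param criteria a [contact_criteria()] list
#' @return data.frame (type, chain_a, resno_a, resid_a, chain_b, resno_b,
#'   resid_b), one row per (pair, type)
#' @export
detect_contacts <- function(traj, frame = 1, criteria = contact_criteria()) {
  co <- frame_coords(traj, frame)
  at <- traj$atoms
  ma <- chain_mask(traj, "a"); mb <- chain_mask(traj, "b")
  res <- list()
  add <- function(type, ra, rb) {
    if (!length(ra)) return()
    res[[length(res) + 1]] <<- data.frame(type = type, resno_a = ra,
                                          resno_b = rb)
  }
  pair_hits <- function(rows_a, rows_b, dmax) {
    if (!length(rows_a) || !length(rows_b)) return(NULL)
    A <- co[rows_a, , drop = FALSE]; B <- co[rows_b, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    hit <- which(d2 <= dmax^2, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    unique(data.frame(ra = at$resno[rows_a[hit[, 1]]],
                      rb = at$resno[rows_b[hit[, 2]]]))
  }

  # hydrogen bonds (donor-acceptor heavy atoms, both directions)
  don_bb <- function(m) which(m & at$elety == "N")
  acc_bb <- function(m) which(m & at$elety %in% c("O", "OXT"))
  don_sc <- function(m) .rows_named(at, m, .sc_donor)
  acc_sc <- function(m) .rows_named(at, m, .sc_acceptor)
  hb <- list(
    hbond_bb_bb = list(list(don_bb(ma), acc_bb(mb)),
                       list(acc_bb(ma), don_bb(mb))),
    hbond_sc_bb = list(list(don_sc(ma), acc_bb(mb)),
                       list(acc_bb(ma), don_sc(mb)),
                       list(don_bb(ma), acc_sc(mb)),
                       list(acc_sc(ma), don_bb(mb))),
    hbond_sc_sc = list(list(don_sc(ma), acc_sc(mb)),
                       list(acc_sc(ma), don_sc(mb))))
  for (ty in names(hb))
    for (pp in hb[[ty]]) {
      h <- pair_hits(pp[[1]], pp[[2]], criteria$hbond_dist)
      if (!is.null(h)) add(ty, h$ra, h$rb)
    }

  # salt bridges
  h1 <- pair_hits(.rows_named(at, ma, .anionic),
                  .rows_named(at, mb, .cationic), criteria$salt_bridge_dist)
  h2 <- pair_hits(.rows_named(at, ma, .cationic),
                  .rows_named(at, mb, .anionic), criteria$salt_bridge_dist)
  if (!is.null(h1)) add("salt_bridge", h1$ra, h1$rb)
  if (!is.null(h2)) add("salt_bridge", h2$ra, h2$rb)

  # hydrophobic: side-chain carbons of apolar residues
  scc <- function(m) which(m & at$resid %in% .apolar_residues &
                             at$elem == "C" &
                             !(at$elety %in% .backbone_atoms))
  h <- pair_hits(scc(ma), scc(mb), criteria$hydrophobic_dist)
  if (!is.null(h)) add("hydrophobic", h$ra, h$rb)

  # aromatic geometry
  ring_a <- .rings(co, at, ma); ring_b <- .rings(co, at, mb)
  cat_rows <- function(m) .rows_named(at, m, .cationic)
  pi_cat <- function(rings, cats, swap) {
    for (rg in rings) for (rc in cats) {
      v <- co[rc, ] - rg$centroid
      d <- vec_norm(v)
      if (d <= criteria$pi_cation_dist) {
        ang <- angle_deg(v, rg$normal)
        ang <- min(ang, 180 - ang)
        if (ang <= criteria$pi_cation_angle) {
          if (swap) add("pi_cation", rg$resno, at$resno[rc])
          else add("pi_cation", at$resno[rc], rg$resno)
        }
      }
    }
  }
  pi_cat(ring_b, cat_rows(ma), swap = FALSE)  # cation in a, ring in b
  pi_cat(ring_a, cat_rows(mb), swap = TRUE)   # ring in a, cation in b
  for (ra in ring_a) for (rb in ring_b) {
    d <- vec_norm(ra$centroid - rb$centroid)
    ang <- angle_deg(ra$normal, rb$normal)
    ang <- min(ang, 180 - ang)
    if (d <= criteria$pi_stack_dist && ang <= criteria$pi_stack_angle)
      add("pi_stack", ra$resno, rb$resno)
    if (d >= criteria$t_stack_dist_min && d <= criteria$t_stack_dist_max &&
        ang >= criteria$t_stack_angle_min && ang <= criteria$t_stack_angle_max)
      add("t_stack", ra$resno, rb$resno)
  }

  if (!length(res))
    return(data.frame(type = character(), resno_a = integer(),
                      resno_b = integer()))
  out <- unique(do.call(rbind, res))
  out <- out[order(out$type, out$resno_a, out$resno_b), ]
  rownames(out) <- NULL
  out
}

#' Contact occurrence over a frame window
#'
#' Fraction of the window's frames in which each (residue pair, type)
#' contact occurs. Sparse: pairs that never occur are absent.
#'
#' @param traj a `traj` object
#' @param window integer vector of frame indices
#' @param criteria a [contact_criteria()] list
#' @return data.frame (type, resno_a, resno_b, occurrence) of class
#'   `occurrence_matrix`, with attribute `n_frames`
#' @export
occurrence <- function(traj, window = seq_len(n_frames(traj)),
                       criteria = contact_criteria()) {
  if (!length(window)) stop("invalid parameter: empty window")
  stopifnot(all(window >= 1), all(window <= n_frames(traj)))
  tabs <- lapply(window, function(f) detect_contacts(traj, f, criteria))
  all_c <- do.call(rbind, tabs)
  if (!nrow(all_c)) {
    out <- data.frame(type = character(), resno_a = integer(),
                      resno_b = integer(), occurrence = numeric())
  } else {
    key <- paste(all_c$type, all_c$resno_a, all_c$resno_b, sep = "|")
    tb <- table(key)
    parts <- do.call(rbind, strsplit(names(tb), "\\|"))
    out <- data.frame(type = parts[, 1],
                      resno_a = as.integer(parts[, 2]),
                      resno_b = as.integer(parts[, 3]),
                      occurrence = as.numeric(tb) / length(window))
    out <- out[order(-out$occurrence, out$type), ]
    rownames(out) <- NULL
  }
  attr(out, "n_frames") <- length(window)
  class(out) <- c("occurrence_matrix", "data.frame")
  out
}

#' Filter an occurrence matrix by minimum occurrence
#'
#' Keeps entries with occurrence strictly greater than `min_occurrence`
#' ("higher than" is strict: at a 0.20 threshold, 0.21 survives and 0.20
#' does not).
#'
#' @param matrix an [occurrence()] result
#' @param min_occurrence fraction in \[0, 1\]
#' @return filtered `occurrence_matrix`
#' @export
filter_occurrence <- function(matrix, min_occurrence = 0.2) {
  stopifnot(min_occurrence >= 0, min_occurrence <= 1)
  out <- matrix[matrix$occurrence > min_occurrence, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_frames") <- attr(matrix, "n_frames")
  class(out) <- class(matrix)
  out
}

#' Coarse-grain an occurrence matrix by secondary-structure element
#'
#' Residues belonging to the same loop or beta-strand are merged; the
#' element-pair occurrence is the maximum over member residue pairs
#' (preserving the strongest contact; "mean" and "sum" available). Node
#' labels are chain letter + residue-range + element letter (e.g. `a_G`).
#'
#' @param matrix an [occurrence()] result
#' @param ss data.frame (chain, resno, element) covering every residue in
#'   the matrix; chain given as "a"/"b"
#' @param aggregate "max", "mean" or "sum"
#' @return data.frame (element_a, element_b, type, occurrence) of class
#'   `occurrence_matrix`
#' @export
coarse_grain <- function(matrix, ss, aggregate = c("max", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  lookup <- function(chain, resno) {
    hit <- ss$element[ss$chain == chain & ss$resno == resno]
    if (!length(hit))
      stop(sprintf("annotation error: residue %s/%d has no element label",
                   chain, resno))
    hit[1]
  }
  if (!nrow(matrix)) {
    out <- data.frame(element_a = character(), element_b = character(),
                      type = character(), occurrence = numeric())
    class(out) <- c("occurrence_matrix", "data.frame")
    return(out)
  }
  ea <- vapply(matrix$resno_a, function(r) lookup("a", r), character(1))
  eb <- vapply(matrix$resno_b, function(r) lookup("b", r), character(1))
  key <- paste(paste0("a_", ea), paste0("b_", eb), matrix$type, sep = "|")
  fun <- switch(aggregate, max = max, mean = mean, sum = sum)
  occ <- tapply(matrix$occurrence, key, fun)
  parts <- do.call(rbind, strsplit(names(occ), "\\|"))
  out <- data.frame(element_a = parts[, 1], element_b = parts[, 2],
                    type = parts[, 3], occurrence = as.numeric(occ))
  out <- out[order(-out$occurrence), ]
  rownames(out) <- NULL
  attr(out, "n_frames") <- attr(matrix, "n_frames")
  class(out) <- c("occurrence_matrix", "data.frame")
  out
}

#' Export contacts as flareplot-compatible JSON
#'
#' Writes an edge list with per-frame presence, the format circular contact
#' diagrams consume. Node names are `chain:resno` (or coarse-grained
#' element labels when `ss` is given).
#'
#' @param traj a `traj` object
#' @param window frame indices
#' @param path output JSON path
#' @param ss optional secondary-structure annotation (chain, resno, element)
#' @param criteria a [contact_criteria()] list
#' @export
write_flareplot_json <- function(traj, window, path, ss = NULL,
                                 criteria = contact_criteria()) {
  tabs <- lapply(window, function(f) detect_contacts(traj, f, criteria))
  edges <- list()
  lab <- function(chain, resno) {
    if (is.null(ss)) return(paste0(chain, ":", resno))
    el <- ss$element[ss$chain == chain & ss$resno == resno]
    if (!length(el)) paste0(chain, ":", resno)
    else paste0(chain, "_", el[1])
  }
  acc <- new.env()
  for (i in seq_along(tabs)) {
    tb <- tabs[[i]]
    if (!nrow(tb)) next
    for (k in seq_len(nrow(tb))) {
      key <- paste(lab("a", tb$resno_a[k]), lab("b", tb$resno_b[k]),
                   sep = "~")
      cur <- acc[[key]] %||% integer()
      acc[[key]] <- unique(c(cur, i - 1L))
    }
  }
  edges <- lapply(ls(acc), function(k) {
    nm <- strsplit(k, "~")[[1]]
    list(name1 = nm[1], name2 = nm[2], frames = sort(acc[[k]]))
  })
  jsonlite::write_json(list(edges = edges), path, auto_unbox = TRUE)
  invisible(path)
}

#' Write an occurrence matrix as tidy CSV
#' @param matrix an [occurrence()] result
#' @param path file path
#' @export
write_occurrence <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix), path, row.names = FALSE)
  invisible(path)
}
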