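# helper: build a two-residue (one per chain) frame from atom tables
two_res_frame <- function(a, b) {
  coords <- rbind(a$xyz, b$xyz)
  raw_traj(coords,
           chain = c(rep("A", nrow(a$xyz)), rep("B", nrow(b$xyz))),
           resno = c(rep(1, nrow(a$xyz)), rep(1, nrow(b$xyz))),
           resid = c(rep(a$resid, nrow(a$xyz)), rep(b$resid, nrow(b$xyz))),
           elety = c(a$elety, b$elety))
}

ring_atoms <- function(center, normal = c(0, 0, 1), r = 1.4,
                       names = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")) {
  n <- dissockit:::unit_vec(normal)
  u <- if (abs(n[1]) < 0.9) dissockit:::unit_vec(pracma_cross(n, c(1, 0, 0)))
  else dissockit:::unit_vec(pracma_cross(n, c(0, 1, 0)))
  v <- pracma_cross(n, u)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  xyz <- t(vapply(th, function(t)
    center + r * (cos(t) * u + sin(t) * v), numeric(3)))
  list(xyz = xyz, elety = names)
}
pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

test_that("each designed geometry yields exactly its contact type", {
  # salt bridge: Lys NZ 3.5 A from Asp OD1
  tr <- two_res_frame(
    list(resid = "LYS", elety = c("N", "CA", "NZ"),
         xyz = rbind(c(-8, 0, 0), c(-6, 0, 0), c(0, 0, 0))),
    list(resid = "ASP", elety = c("N", "CA", "OD1"),
         xyz = rbind(c(11, 0, 0), c(9, 0, 0), c(3.5, 0, 0))))
  ct <- detect_contacts(tr, 1)
  expect_true("salt_bridge" %in% ct$type)
  expect_false(any(c("pi_stack", "t_stack", "hydrophobic") %in% ct$type))

  # backbone-backbone hydrogen bond: N to O at 3.0 A
  tr <- two_res_frame(
    list(resid = "ALA", elety = c("N", "CA", "C", "O"),
         xyz = rbind(c(0, 0, 0), c(-1.5, 0, 0), c(-3, 0, 0), c(-4, 0, 0))),
    list(resid = "ALA", elety = c("N", "CA", "C", "O"),
         xyz = rbind(c(9, 0, 0), c(7.5, 0, 0), c(6, 0, 0), c(3, 0, 0))))
  ct <- detect_contacts(tr, 1)
  expect_equal(ct$type, "hbond_bb_bb")

  # side-chain/backbone hydrogen bond: Ser OG to backbone O
  tr <- two_res_frame(
    list(resid = "SER", elety = c("N", "CA", "OG"),
         xyz = rbind(c(-6, 0, 0), c(-4.5, 0, 0), c(0, 0, 0))),
    list(resid = "ALA", elety = c("N", "CA", "C", "O"),
         xyz = rbind(c(10, 0, 0), c(8.5, 0, 0), c(7, 0, 0), c(3.2, 0, 0))))
  expect_true("hbond_sc_bb" %in% detect_contacts(tr, 1)$type)

  # side-chain/side-chain hydrogen bond: Ser OG to Thr OG1
  tr <- two_res_frame(
    list(resid = "SER", elety = c("N", "CA", "OG"),
         xyz = rbind(c(-6, 0, 0), c(-4.5, 0, 0), c(0, 0, 0))),
    list(resid = "THR", elety = c("N", "CA", "OG1"),
         xyz = rbind(c(9, 0, 0), c(7.5, 0, 0), c(3.1, 0, 0))))
  expect_true("hbond_sc_sc" %in% detect_contacts(tr, 1)$type)

  # hydrophobic: Leu CD1 to Val CG1 at 4.0 A
  tr <- two_res_frame(
    list(resid = "LEU", elety = c("N", "CA", "CD1"),
         xyz = rbind(c(-8, 0, 0), c(-6, 0, 0), c(0, 0, 0))),
    list(resid = "VAL", elety = c("N", "CA", "CG1"),
         xyz = rbind(c(12, 0, 0), c(10, 0, 0), c(4, 0, 0))))
  ct <- detect_contacts(tr, 1)
  expect_equal(ct$type, "hydrophobic")
})

test_that("aromatic geometries split into pi-stack, T-stack and pi-cation", {
  # parallel rings 4 A apart -> pi_stack
  ra <- ring_atoms(c(0, 0, 0)); rb <- ring_atoms(c(0, 0, 4))
  tr <- two_res_frame(list(resid = "PHE", elety = c("N", ra$elety),
                           xyz = rbind(c(-9, 0, 0), ra$xyz)),
                      list(resid = "PHE", elety = c("N", rb$elety),
                           xyz = rbind(c(9, 0, 4), rb$xyz)))
  ct <- detect_contacts(tr, 1)
  expect_true("pi_stack" %in% ct$type)
  expect_false("t_stack" %in% ct$type)

  # perpendicular rings 5.5 A apart -> t_stack
  rb2 <- ring_atoms(c(0, 0, 5.5), normal = c(0, 1, 0))
  tr <- two_res_frame(list(resid = "PHE", elety = c("N", ra$elety),
                           xyz = rbind(c(-9, 0, 0), ra$xyz)),
                      list(resid = "PHE", elety = c("N", rb2$elety),
                           xyz = rbind(c(9, 0, 5.5), rb2$xyz)))
  ct <- detect_contacts(tr, 1)
  expect_true("t_stack" %in% ct$type)
  expect_false("pi_stack" %in% ct$type)

  # cation 4 A above a ring centre -> pi_cation
  tr <- two_res_frame(list(resid = "PHE", elety = c("N", ra$elety),
                           xyz = rbind(c(-9, 0, 0), ra$xyz)),
                      list(resid = "LYS", elety = c("N", "CA", "NZ"),
                           xyz = rbind(c(10, 0, 4), c(8, 0, 4), c(0, 0, 4))))
  expect_true("pi_cation" %in% detect_contacts(tr, 1)$type)

  # cation far off the ring axis (80 degrees) -> no pi_cation
  tr <- two_res_frame(list(resid = "PHE", elety = c("N", ra$elety),
                           xyz = rbind(c(-9, 0, 0), ra$xyz)),
                      list(resid = "LYS", elety = c("N", "CA", "NZ"),
                         xyz = rbind(c(12, 0, 0.9), c(10, 0, 0.9),
                                     c(5, 0, 0.9))))
  expect_false("pi_cation" %in% detect_contacts(tr, 1)$type)
})

test_that("distant chains yield no contacts and never intra-chain pairs", {
  d <- fix_dimer(10, 4, seed = 1)
  co <- frame_coords(d$traj, 1)
  cb <- d$traj$atoms$chain == "B"
  co[cb, 1] <- co[cb, 1] + 100
  tr <- new_trajectory(matrix(t(co), nrow = 1), d$traj$atoms)
  expect_equal(nrow(detect_contacts(tr, 1)), 0L)
  ct <- detect_contacts(d$traj, 1)
  expect_gt(nrow(ct), 0)
})

test_that("detect_contacts equals a brute-force oracle on the toy dimer", {
  d <- fix_dimer(12, 6, seed = 3)
  ct <- detect_contacts(d$traj, 1)
  # brute force: scan all inter-chain atom pairs for the two rule families
  # present in the fixture (salt bridges, hydrophobic side-chain carbons)
  co <- frame_coords(d$traj, 1)
  at <- d$traj$atoms
  sb <- character(); hp <- character()
  for (i in which(at$chain == "A")) for (j in which(at$chain == "B")) {
    dij <- sqrt(sum((co[i, ] - co[j, ])^2))
    if (at$elety[i] == "NZ" && at$elety[j] == "OD1" && dij <= 4.0)
      sb <- c(sb, paste(at$resno[i], at$resno[j]))
    if (at$resid[i] %in% c("LEU", "ALA") && at$resid[j] %in% c("LEU", "ALA") &&
        at$elety[i] == "CB" && at$elety[j] == "CB" && dij <= 4.5)
      hp <- c(hp, paste(at$resno[i], at$resno[j]))
  }
  got_sb <- with(ct[ct$type == "salt_bridge", ], paste(resno_a, resno_b))
  got_hp <- with(ct[ct$type == "hydrophobic", ], paste(resno_a, resno_b))
  expect_setequal(got_sb, unique(sb))
  expect_setequal(got_hp, unique(hp))
})

test_that("occurrence counts window fractions and is order invariant", {
  d <- fix_dimer(10, 4, seed = 5)
  sch <- dissociation_schedule(10, 4, 8, noise_sigma = 0, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  occ_all <- occurrence(tr, 1:10)
  occ_rev <- occurrence(tr, 10:1)
  expect_equal(occ_all[order(occ_all$type, occ_all$resno_a), ],
               occ_rev[order(occ_rev$type, occ_rev$resno_a), ],
               ignore_attr = TRUE)
  # persisting designed pair: bound + encounter frames = 7 of 10
  keep <- d$interface_pairs[!d$interface_pairs$break_first, ]
  sel <- occ_all$resno_a %in% keep$resno_a
  expect_true(all(abs(occ_all$occurrence[sel] - 0.7) < 1e-9))
  # breaking pair: present only in the 3 bound frames
  brk <- d$interface_pairs[d$interface_pairs$break_first, ]
  selb <- occ_all$resno_a %in% brk$resno_a
  expect_true(all(abs(occ_all$occurrence[selb] - 0.3) < 1e-9))
  # bound-window occurrence >= all-frame occurrence for persistent pairs
  occ_b <- occurrence(tr, 1:3)
  for (k in which(sel))
    expect_gte(occ_b$occurrence[match(paste(occ_all$type[k],
                                            occ_all$resno_a[k]),
                                      paste(occ_b$type, occ_b$resno_a))],
               occ_all$occurrence[k])
  expect_error(occurrence(tr, integer()), "invalid parameter")
})

test_that("the occurrence filter is strictly greater-than", {
  m <- structure(data.frame(type = rep("salt_bridge", 3),
                            resno_a = 1:3, resno_b = 1:3,
                            occurrence = c(0.19, 0.20, 0.21)),
                 class = c("occurrence_matrix", "data.frame"))
  f <- filter_occurrence(m, 0.20)
  expect_equal(f$occurrence, 0.21)
  expect_equal(nrow(filter_occurrence(m, 0)), 3L)
  expect_equal(nrow(filter_occurrence(m, 1)), 0L)
})

test_that("coarse-graining aggregates by max and labels chain + element", {
  m <- structure(data.frame(type = rep("salt_bridge", 2),
                            resno_a = c(5, 6), resno_b = c(40, 41),
                            occurrence = c(0.6, 0.9)),
                 class = c("occurrence_matrix", "data.frame"))
  ss <- data.frame(chain = rep(c("a", "b"), each = 2),
                   resno = c(5, 6, 40, 41),
                   element = c("G", "G", "AB", "AB"))
  cg <- coarse_grain(m, ss)
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$occurrence, 0.9)
  expect_equal(cg$element_a, "a_G")
  expect_equal(cg$element_b, "b_AB")
  expect_equal(coarse_grain(m, ss, aggregate = "mean")$occurrence, 0.75)
  ss_bad <- ss[-1, ]
  expect_error(coarse_grain(m, ss_bad), "annotation error")
})

test_that("filter-then-coarse-grain commutes with coarse-grain-then-filter", {
  set.seed(6)
  m <- structure(data.frame(type = "hydrophobic",
                            resno_a = rep(1:4, each = 2),
                            resno_b = rep(1:2, 4),
                            occurrence = runif(8)),
                 class = c("occurrence_matrix", "data.frame"))
  ss <- data.frame(chain = rep(c("a", "b"), c(4, 2)),
                   resno = c(1:4, 1:2),
                   element = c("A", "A", "G", "G", "D", "D"))
  a <- coarse_grain(filter_occurrence(m, 0.5), ss)
  b <- filter_occurrence(coarse_grain(m, ss), 0.5)
  key <- function(x) paste(x$element_a, x$element_b, x$type)
  expect_setequal(key(a), key(b))
  expect_equal(a$occurrence[order(key(a))], b$occurrence[order(key(b))])
})

test_that("staged dissociation loses peripheral elements first", {
  d <- fix_dimer(16, 6, seed = 7)
  sch <- dissociation_schedule(30, 11, 25, noise_sigma = 0.1, seed = 2)
  tr <- generate_dissociation_trajectory(d, sch)
  ss <- data.frame(chain = rep(c("a", "b"), each = 16),
                   resno = rep(1:16, 2),
                   element = rep(ifelse(1:16 %in%
                     d$interface_pairs$resno_a[d$interface_pairs$break_first],
                     "G", "DE"), 2))
  occ_bound <- coarse_grain(occurrence(tr, 1:10), ss)
  occ_enc <- coarse_grain(occurrence(tr, 11:24), ss)
  gkey <- occ_bound$element_a == "a_G"
  expect_true(any(gkey))                       # G-analogs present when bound
  expect_false(any(occ_enc$element_a == "a_G")) # lost in the encounter
  expect_true(any(occ_enc$element_a == "a_DE")) # core persists
})

test_that("flareplot JSON export lists edges with frame indices", {
  d <- fix_dimer(8, 3, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_flareplot_json(d$traj, 1, f)
  j <- jsonlite::read_json(f)
  expect_true(length(j$edges) >= 1)
  expect_true(all(vapply(j$edges, function(e)
    grepl("^a:", e$name1) && grepl("^b:", e$name2), logical(1))))
})
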