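identity_map <- function(n) correspondence_map(cbind(1:n, 1:n))

sub_site <- function(i, label = sprintf("X%d", i))
  site_spec("substitution", wt_index = i, label = label)

test_that("local windows clip at the termini", {
  m <- make_helix(256)
  expect_equal(local_window(m, sub_site(100), 5), 95:105)
  expect_equal(local_window(m, sub_site(1), 5), 1:6)
  expect_equal(local_window(m, sub_site(12), 5), 7:17)  # the A12S window
  expect_equal(local_window(m, sub_site(256), 5), 251:256)
  expect_equal(local_window(m, sub_site(100), 0), 100L)
})

test_that("local RMSD is zero for identical structures and equals a pure shift", {
  wt <- make_helix(60)
  map <- identity_map(60)
  s0 <- superpose(wt, wt, map)
  for (i in c(1, 30, 60))
    expect_equal(local_rmsd(wt, wt, map, s0, sub_site(i))$value, 0,
                 tolerance = 1e-10)

  # a rigidly displaced window registers exactly its displacement norm when
  # the fit is restricted to the untouched remainder
  v <- c(3, 0, 4)  # norm 5
  pert <- apply_perturbation(wt, perturbation_plan(30:40, v))
  s <- superpose(wt, pert$mutant, map, fit_subset = setdiff(1:60, 30:40))
  lr <- local_rmsd(wt, pert$mutant, map, s, sub_site(35))
  expect_equal(lr$value, 5, tolerance = 1e-6)
  expect_equal(lr$n_pairs, 11L)
})

test_that("the whole chain as one window reproduces the global RMSD", {
  wt <- make_helix(40)
  pert <- apply_perturbation(wt, perturbation_plan(10:20, c(2, -1, 3),
                                                   jitter_sigma = 0.2, seed = 5))
  map <- identity_map(40)
  s <- superpose(wt, pert$mutant, map)
  lr <- local_rmsd(wt, pert$mutant, map, s, sub_site(20), metric_config(flank = 40))
  expect_equal(lr$value, s$rmsd_all, tolerance = 1e-12)
})

test_that("neighbor finding matches forced geometry and a brute-force scan", {
  # straight line, 4 A spacing: cutoff 8 reaches exactly i +/- 2
  line <- structure_model("A", rep("A", 11), cbind(4 * (0:10), 0, 0))
  expect_equal(find_neighbors(line, sub_site(6), metric_config()),
               c(4L, 5L, 7L, 8L))

  helix <- make_helix(80)
  xyz <- ca_coords(helix)
  for (i in c(1, 40, 80)) {
    want <- sort(setdiff(
      which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) <= 8), i))
    expect_equal(find_neighbors(helix, sub_site(i)), want)
  }
  # monotone in the cutoff
  n8 <- find_neighbors(helix, sub_site(40), metric_config(neighbor_cutoff = 8))
  n10 <- find_neighbors(helix, sub_site(40), metric_config(neighbor_cutoff = 10))
  expect_true(all(n8 %in% n10))
})

test_that("delta-D is zero for identical inputs and exact on generated displacements", {
  wt <- make_helix(60)
  map <- identity_map(60)
  dd0 <- compute_delta_d(wt, wt, map, sub_site(30),
                         find_neighbors(wt, sub_site(30)))
  expect_true(all(dd0$delta_d == 0))
  expect_true(all(!dd0$flagged))

  # displace a segment containing the site; cross-boundary neighbors move
  pert <- apply_perturbation(wt, perturbation_plan(30:40, c(5, 0, 0)))
  site <- sub_site(31)
  nb <- find_neighbors(wt, site)
  dd <- compute_delta_d(wt, pert$mutant, map, site, nb)
  for (r in seq_len(nrow(dd)))
    expect_equal(dd$delta_d[r],
                 expected_delta_d(pert$expected, 31, dd$neighbor[r]),
                 tolerance = 1e-9)
  # neighbors outside the segment must have moved relative to the site
  outside <- dd$neighbor < 30
  expect_true(any(outside))
  expect_true(all(abs(dd$delta_d[outside]) > 0))
  expect_true(all(dd$delta_d[!outside] == 0))
})

test_that("delta-D is invariant under rigid motion and antisymmetric under swap", {
  set.seed(12)
  wt <- make_helix(50)
  map <- identity_map(50)
  pert <- apply_perturbation(wt, perturbation_plan(20:28, c(4, -3, 0),
                                                   jitter_sigma = 0.1, seed = 3))
  site <- sub_site(24)
  nb <- find_neighbors(wt, site)
  dd <- compute_delta_d(wt, pert$mutant, map, site, nb)

  R <- random_rotation(); t_vec <- stats::rnorm(3, sd = 30)
  moved <- structure_model("A", pert$mutant$residues$aa,
                           sweep(ca_coords(pert$mutant) %*% t(R), 2, t_vec, `+`))
  dd_moved <- compute_delta_d(wt, moved, map, site, nb)
  expect_equal(dd_moved$delta_d, dd$delta_d, tolerance = 1e-9)

  dd_swap <- compute_delta_d(pert$mutant, wt, map, site, nb)
  expect_equal(dd_swap$delta_d, -dd$delta_d, tolerance = 1e-12)
  expect_equal(dd_swap$d_wt, dd$d_mut)
})

test_that("insertion sites anchor on the preceding wild-type residue", {
  wt <- make_helix(40)
  # mutant: one residue inserted after position 20 (midpoint coordinates)
  wt_xyz <- ca_coords(wt)
  ins_xyz <- rbind(wt_xyz[1:20, ], (wt_xyz[20, ] + wt_xyz[21, ]) / 2,
                   wt_xyz[21:40, ])
  mut <- structure_model("A", c(rep("A", 20), "Y", rep("A", 20)), ins_xyz)
  map <- map_from_effects(
    data.frame(variant_id = "i", effect_class = "inframe_insertion",
               residue_index = 20L, wt_aa = "", mut_aa = "Y",
               notation = "A20_A21insY"), 40, 41)
  site <- site_spec("insertion", mut_index = 21L, label = "insY21")

  win <- local_window(wt, site, 5, map = map, mut = mut)
  expect_equal(win, c(16:20, 21:25))  # inserted residue has no WT member

  nb <- find_neighbors(wt, site, mut = mut, map = map)
  expect_true(length(nb) > 0)
  dd <- compute_delta_d(wt, mut, map, site, nb)
  # D_WT from WT residue 20 (preceding the insertion), D_MUT from mutant 21
  j <- nb[1]
  jm <- mut_partner(map, j)
  expect_equal(dd$d_wt[1], sqrt(sum((wt_xyz[20, ] - wt_xyz[j, ])^2)))
  expect_equal(dd$d_mut[1], sqrt(sum((ins_xyz[21, ] - ins_xyz[jm, ])^2)))
})

test_that("unmatched neighbors are skipped with a warning", {
  wt <- make_helix(30)
  mut_xyz <- ca_coords(wt)[-15, ]
  mut <- structure_model("A", rep("A", 29), mut_xyz)
  map <- map_from_effects(
    data.frame(variant_id = "d", effect_class = "inframe_deletion",
               residue_index = 15L, wt_aa = "A", mut_aa = "",
               notation = "A15del"), 30, 29)
  site <- sub_site(14)
  nb <- find_neighbors(wt, site)
  expect_true(15 %in% nb)
  expect_warning(dd <- compute_delta_d(wt, mut, map, site, nb),
                 class = "varstruct_unmatched_neighbor")
  expect_false(15 %in% dd$neighbor)
})

test_that("the assembled report has deterministic shape, zeros and flags", {
  wt <- make_helix(60)
  map <- identity_map(60)

  zero <- perturbation_report(wt, wt, map, list(sub_site(10), sub_site(30)))
  expect_equal(zero$global$rmsd_all, 0, tolerance = 1e-10)
  expect_lt(max(zero$local$rmsd), 1e-9)
  expect_true(all(zero$delta_d$delta_d == 0))
  expect_false(any(zero$delta_d$flagged))

  pert <- apply_perturbation(wt, perturbation_plan(30:40, c(5, 0, 0)))
  sites <- list(sub_site(45), sub_site(30), sub_site(5))  # unsorted on purpose
  rep <- perturbation_report(wt, pert$mutant, map, sites,
                             fit_subset = setdiff(1:60, 30:40))
  expect_equal(nrow(rep$local), 3L)
  expect_equal(rep$local$site, c("X5", "X30", "X45"))  # sorted by index
  n_neighbors <- vapply(c(5, 30, 45), function(i)
    length(find_neighbors(wt, sub_site(i))), 0L)
  expect_equal(nrow(rep$delta_d), sum(n_neighbors))
  # flagged records are exactly those the generator says moved >= 3 A
  want_flag <- abs(vapply(seq_len(nrow(rep$delta_d)), function(r) {
    i <- as.integer(sub("X", "", rep$delta_d$site[r]))
    expected_delta_d(pert$expected, i, rep$delta_d$neighbor[r])
  }, 0)) >= 3
  expect_equal(rep$delta_d$flagged, want_flag)
  expect_true(any(rep$delta_d$flagged))
})
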