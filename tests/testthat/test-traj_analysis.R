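test_that("resolve_pairs binds the four-pair rule and fails loudly", {
  trs <- simulate_trajectory(frames = 2, seed = 1)
  rule <- resolve_pairs(trs[[1]])
  expect_s3_class(rule, "pair_rule")
  expect_length(rule$pairs, 4L)
  expect_true(all(vapply(rule$pairs, length, 0L) == 2L))

  # topology lacking ligand O6 -> error naming the selector
  top2 <- trs[[1]]$topology
  top2 <- top2[!(top2$role == "ligand" & top2$name == "O6"), ]
  expect_error(resolve_pairs(top2), "O6")

  # duplicated atom -> ambiguity error
  top3 <- rbind(trs[[1]]$topology,
                data.frame(resno = 900, resname = "MEL", name = "O5",
                           element = "O", role = "ligand"))
  expect_error(resolve_pairs(top3), "ambiguous")
  expect_error(resolve_pairs(trs[[1]], outer = 3, inner = 4), "inner")
})

test_that("water occupancy follows the two-cutoff rule on constructed frames", {
  # geometry: pair members at known positions; single water per case
  base <- simulate_trajectory(frames = 2, n_waters = 1,
                              target_occupancy = 0, seed = 2)[[1]]
  rule <- resolve_pairs(base)
  p1 <- rule$pairs[[1]]
  place_water <- function(traj, xyz) {
    w <- which(traj$topology$role == "water")[1]
    for (k in seq_len(dim(traj$coords)[3])) traj$coords[w, , k] <- xyz
    traj
  }
  m1 <- base$coords[p1[1], , 1]; m2 <- base$coords[p1[2], , 1]

  # both distances 3.0 A (on the perpendicular bisector) -> occupied
  mid <- (m1 + m2) / 2
  half <- sqrt(sum((m1 - m2)^2)) / 2
  perp <- c(0, 0, 1)
  w_in <- mid + perp * sqrt(3.0^2 - half^2)
  t_in <- place_water(base, w_in)
  expect_equal(water_site_occupancy(t_in, rule)$occupancy, 1.0)

  # 3.8 / 3.9 A from the pair (no closer pair): fails the inner clause
  d1 <- 3.8; d2 <- 3.9
  a <- (d1^2 - d2^2 + (2 * half)^2) / (2 * (2 * half))
  w_out <- m1 + (m2 - m1) / (2 * half) * a + perp * sqrt(d1^2 - a^2)
  t_out <- place_water(base, w_out)
  # verify construction, then the rule
  expect_equal(sqrt(sum((w_out - m1)^2)), 3.8, tolerance = 1e-10)
  expect_equal(sqrt(sum((w_out - m2)^2)), 3.9, tolerance = 1e-10)
  occ_out <- water_site_occupancy(t_out, rule)
  expect_equal(occ_out$occupancy, 0.0)

  # no waters at all -> occupancy 0 with warning
  nowat <- base
  keep <- nowat$topology$role != "water"
  nowat <- trajectory(nowat$topology[keep, ],
                      nowat$coords[keep, , , drop = FALSE])
  expect_warning(occ0 <- water_site_occupancy(nowat, rule), "no water")
  expect_equal(occ0$occupancy, 0.0)
})

test_that("vectorized occupancy equals the naive double loop on random fixtures", {
  set.seed(4)
  for (trial in 1:3) {
    trs <- simulate_trajectory(frames = 200, n_waters = 8,
                               target_occupancy = runif(1, 0.2, 0.8),
                               seed = 100 + trial)[[1]]
    # scatter some waters near the site so marginal distances occur
    wat <- which(trs$topology$role == "water")
    nf <- dim(trs$coords)[3]
    for (k in seq_len(nf)) {
      jitter_w <- sample(wat, 3)
      trs$coords[jitter_w, , k] <-
        matrix(runif(9, -6, 6), ncol = 3) +
        matrix(rep(c(1.4, 0, 1.5), each = 3), ncol = 3)
    }
    rule <- resolve_pairs(trs)
    occ <- water_site_occupancy(trs, rule)
    expect_identical(occ$occupancy, naive_occupancy(trs, rule))
    # loosening cutoffs never decreases occupancy
    rule_loose <- resolve_pairs(trs, outer = 5.0, inner = 4.5)
    expect_gte(water_site_occupancy(trs, rule_loose)$occupancy,
               occ$occupancy)
  }
})

test_that("occupancy pools replicas as a frame-weighted average", {
  trs <- simulate_trajectory(frames = 120, replicas = 3,
                             target_occupancy = 0.5, seed = 6)
  rule <- resolve_pairs(trs[[1]])
  pooled <- water_site_occupancy(trs, rule)
  per <- vapply(trs, function(t) water_site_occupancy(t, rule)$occupancy, 0)
  expect_equal(pooled$occupancy, mean(per), tolerance = 1e-12)
  expect_equal(pooled$n_frames, 360L)
  expect_equal(unname(pooled$per_replica), per, tolerance = 1e-12)
})

test_that("side-chain RMSF: static, two-point closed form, and direct-formula oracle", {
  # static trajectory -> RMSF 0 everywhere
  trs <- simulate_trajectory(frames = 2, sigma = 0.4, seed = 7)[[1]]
  static <- trs
  for (k in 2:dim(static$coords)[3]) static$coords[, , k] <- static$coords[, , 1]
  r0 <- sidechain_rmsf(static, fit_selection = NULL)
  expect_true(all(r0$rmsf[!is.na(r0$rmsf)] < 1e-12))

  # one atom alternating between two points d apart -> RMSF d/2 (no fit)
  d <- 1.6
  co <- array(0, dim = c(2, 3, 10))
  co[1, 1, ] <- rep(c(0, d), 5)   # CB of residue 1 alternates along x
  co[2, , ] <- 5                  # another residue's CB, static
  tr <- toy_trajectory(co, roles = c("protein", "protein"),
                       names = c("CB", "CB"), elements = c("C", "C"),
                       resnos = c(1L, 2L))
  r2 <- sidechain_rmsf(tr, fit_selection = NULL)
  expect_equal(r2$rmsf[r2$resno == 1], d / 2, tolerance = 1e-12)
  expect_equal(r2$rmsf[r2$resno == 2], 0)

  # random toy trajectory vs independent direct-formula computation
  traj <- simulate_trajectory(frames = 50, sigma = 0.6, seed = 8)[[1]]
  got <- sidechain_rmsf(traj, fit_selection = NULL)
  top <- traj$topology
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (r in unique(top$resno[top$role == "protein"])) {
    idx <- which(top$role == "protein" & top$resno == r &
                 !(top$name %in% backbone) & top$element != "H")
    if (length(idx) == 0L) next
    ss <- 0; cnt <- 0
    for (i in idx) {
      mu <- rowMeans(traj$coords[i, , ])
      ss <- ss + sum((traj$coords[i, , ] - mu)^2)
      cnt <- cnt + dim(traj$coords)[3]
    }
    expect_equal(got$rmsf[got$resno == r], sqrt(ss / cnt), tolerance = 1e-8)
  }

  # glycine-like residue (no side-chain heavy atoms) is flagged absent
  co3 <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5))
  tr3 <- toy_trajectory(co3, roles = rep("protein", 4),
                        names = c("N", "CA", "C", "O"),
                        elements = c("N", "C", "C", "O"),
                        resnos = rep(1L, 4))
  r3 <- sidechain_rmsf(tr3, fit_selection = NULL)
  expect_true(is.na(r3$rmsf))
})

test_that("RMSF is invariant to a global rigid transform when frames are fitted", {
  traj <- simulate_trajectory(frames = 40, sigma = 0.5, seed = 9)[[1]]
  r_ref <- sidechain_rmsf(traj, fit_selection = "CA")
  R <- random_rotation(10)
  moved <- traj
  for (k in seq_len(dim(traj$coords)[3]))
    moved$coords[, , k] <- sweep(traj$coords[, , k] %*% t(R), 2,
                                 c(20, -5, 3), "+")
  r_mov <- sidechain_rmsf(moved, fit_selection = "CA")
  expect_equal(r_mov$rmsf, r_ref$rmsf, tolerance = 1e-8)
})

test_that("replica state comparison reproduces the reference Welch test", {
  mk <- function(vals, state) do.call(rbind, lapply(seq_along(vals),
    function(i) data.frame(resno = 1L, resname = "ALA", rmsf = vals[i],
                           n_atoms = 2L, replica = i, state = state)))
  apo <- mk(c(1.0, 1.1, 0.9, 1.0, 1.05), "apo")
  holo <- mk(c(0.5, 0.55, 0.45, 0.5, 0.52), "mel")
  cmp <- compare_states(apo, holo)
  ref <- t.test(c(1.0, 1.1, 0.9, 1.0, 1.05), c(0.5, 0.55, 0.45, 0.5, 0.52))
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(cmp$t_stat, unname(ref$statistic), tolerance = 1e-10)

  # identical replica sets with spread -> t 0, p 1
  same <- compare_states(apo, mk(c(1.0, 1.1, 0.9, 1.0, 1.05), "mel"))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # swapping the states negates t, preserves p
  rev <- compare_states(holo, apo)
  expect_equal(rev$t_stat, -cmp$t_stat, tolerance = 1e-12)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("trajectories round-trip through multi-model PDB", {
  trs <- simulate_trajectory(frames = 5, n_waters = 3, seed = 11,
                             target_occupancy = 1)[[1]]
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(trs, f)
  back <- read_trajectory_pdb(f, state = trs$state, replica = trs$replica)
  expect_equal(dim(back$coords), dim(trs$coords))
  expect_equal(back$coords, trs$coords, tolerance = 1e-3)  # PDB precision
  expect_equal(back$topology$role, trs$topology$role)
  # occupancy computed on the re-read trajectory matches
  rule <- resolve_pairs(trs)
  rule_back <- resolve_pairs(back)
  expect_equal(water_site_occupancy(back, rule_back)$occupancy,
               water_site_occupancy(trs, rule)$occupancy)
})

test_that("minimum-image option recovers waters imaged into a neighboring cell", {
  base <- simulate_trajectory(frames = 2, n_waters = 1,
                              target_occupancy = 1, seed = 12)[[1]]
  rule <- resolve_pairs(base)
  expect_equal(water_site_occupancy(base, rule)$occupancy, 1)
  # translate the in-site water by one box vector: lost without imaging,
  # recovered with the orthorhombic minimum-image option
  box <- c(60, 60, 60)
  w <- which(base$topology$role == "water")[1]
  shifted <- base
  for (k in 1:2) shifted$coords[w, , k] <- shifted$coords[w, , k] + box
  expect_equal(water_site_occupancy(shifted, rule)$occupancy, 0)
  expect_equal(water_site_occupancy(shifted, rule, box = box)$occupancy, 1)
})
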