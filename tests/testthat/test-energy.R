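# Coulomb + Lennard-Jones decomposition

test_that("pair_energy matches the analytic forms", {
  # unit opposite charges at 1 nm, no LJ
  e <- pair_energy(1, -1, 0.3, 0.3, 0, 0, r = 1)
  expect_equal(e$coulomb, -138.935458, tolerance = 1e-12)
  expect_equal(e$lj, 0)
  expect_equal(e$total, e$coulomb + e$lj)
  # LJ zero-crossing at r = combined sigma, minimum -eps at 2^(1/6) sigma
  e0 <- pair_energy(0, 0, 0.3, 0.4, 0.5, 0.8, r = 0.35)
  expect_equal(e0$lj, 0, tolerance = 1e-12)
  emin <- pair_energy(0, 0, 0.3, 0.4, 0.5, 0.8, r = 2^(1 / 6) * 0.35)
  expect_equal(emin$lj, -sqrt(0.5 * 0.8), tolerance = 1e-12)
  # plain truncation: both terms exactly zero beyond the cutoff
  far <- pair_energy(1, -1, 0.3, 0.3, 1, 1, r = 1.51)
  expect_identical(far$total, 0)
  expect_error(pair_energy(1, -1, 0.3, 0.3, 0, 0, r = 0), "positive")
})

test_that("residue_pair_energy is analytic, symmetric, and truncated", {
  s <- point_charge_structure(1, -1, 0.5)
  e <- residue_pair_energy(s, "A:1", "B:1")
  expect_equal(e$coulomb, -277.870916, tolerance = 1e-6)
  # symmetry is exact
  e2 <- residue_pair_energy(s, "B:1", "A:1")
  expect_identical(e$total, e2$total)
  # beyond the cutoff everything vanishes
  sfar <- point_charge_structure(1, -1, 2.0)
  expect_identical(residue_pair_energy(sfar, "A:1", "B:1")$total, 0)
  # brute-force double loop on a multi-atom pair
  toy <- make_toy_complex(plant_spec(list(plant_feature("salt_bridge")),
                                     seed = 1))
  sp <- assign_parameters(toy$structure, toy$forcefield)
  keys <- unique(residue_keys(sp))
  tox_key <- keys[startsWith(keys, "A:")][1L]
  cha_key <- keys[!startsWith(keys, "A:")][1L]
  got <- residue_pair_energy(sp, tox_key, cha_key)
  xyz <- coords_matrix(sp)
  rk <- residue_keys(sp)
  brute <- c(coulomb = 0, lj = 0)
  for (i in which(rk == tox_key)) {
    for (j in which(rk == cha_key)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > 1.5) next
      brute["coulomb"] <- brute["coulomb"] +
        138.935458 * sp$atoms$charge[i] * sp$atoms$charge[j] / r
      sg <- (sp$atoms$sigma[i] + sp$atoms$sigma[j]) / 2
      ep <- sqrt(sp$atoms$epsilon[i] * sp$atoms$epsilon[j])
      brute["lj"] <- brute["lj"] + 4 * ep * ((sg / r)^12 - (sg / r)^6)
    }
  }
  expect_equal(got$coulomb, unname(brute["coulomb"]), tolerance = 1e-9)
  expect_equal(got$lj, unname(brute["lj"]), tolerance = 1e-9)
})

test_that("coulomb term scales as charge^2", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("salt_bridge"),
                                          plant_feature("repulsion")),
                                     seed = 2))
  sp <- assign_parameters(toy$structure, toy$forcefield)
  base <- interaction_profile(new_trajectory(sp, list(coords_matrix(sp))))
  for (c_scale in c(0.5, 2)) {
    sp2 <- sp
    sp2$atoms$charge <- sp2$atoms$charge * c_scale
    scaled <- interaction_profile(new_trajectory(sp2,
                                                 list(coords_matrix(sp2))))
    expect_equal(scaled$residues$mean_coulomb,
                 base$residues$mean_coulomb * c_scale^2, tolerance = 1e-9)
    expect_equal(scaled$residues$mean_lj, base$residues$mean_lj,
                 tolerance = 1e-12)
  }
})

test_that("interaction_profile is additive and consistent", {
  toy <- make_toy_complex(full_plant_spec(seed = 3))
  traj <- make_toy_trajectory(toy, 6L)$trajectory
  prof <- interaction_profile(traj)
  # marginal equals the sum over channel partners, pairwise
  for (tr in prof$residues$toxin_res) {
    expect_equal(prof$residues$mean_total[prof$residues$toxin_res == tr],
                 sum(prof$pairs$mean_total[prof$pairs$toxin_res == tr]),
                 tolerance = 1e-6)
  }
  # total = coulomb + lj everywhere
  expect_equal(prof$pairs$mean_total,
               prof$pairs$mean_coulomb + prof$pairs$mean_lj,
               tolerance = 1e-9)
  # sum of residue means equals the mean total interface energy
  e_frames <- vapply(traj$frames, function(xyz) {
    s <- traj$topology
    total <- 0
    keys <- unique(residue_keys(s))
    tox <- keys[startsWith(keys, "A:")]
    cha <- setdiff(keys, tox)
    for (a in tox) for (b in cha) {
      total <- total + residue_pair_energy(s, a, b, coords = xyz)$total
    }
    total
  }, numeric(1))
  expect_equal(sum(prof$residues$mean_total), mean(e_frames),
               tolerance = 1e-6)
})

test_that("static trajectories have zero energy sd", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("salt_bridge")),
                                     jitter = 0, seed = 1))
  traj <- make_toy_trajectory(toy, 2L)$trajectory
  prof <- interaction_profile(traj)
  expect_true(all(prof$residues$sd_total == 0))
  expect_true(all(prof$pairs$sd_total == 0))
})

test_that("a planted like-charge pair yields a positive mean coulomb term", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("repulsion"),
                                          plant_feature("salt_bridge")),
                                     seed = 4))
  traj <- make_toy_trajectory(toy, 5L)$trajectory
  prof <- interaction_profile(traj)
  rep_res <- toy$ground_truth$energy_signs$toxin_res
  row <- prof$residues[prof$residues$toxin_res == rep_res, ]
  expect_gt(row$mean_coulomb, 0)
  expect_gt(row$mean_total, 0)
})

test_that("raising the cutoff only changes pairs beyond 1.5 nm", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("hbond"),
                                          plant_feature("repulsion")),
                                     seed = 5))
  sp <- assign_parameters(toy$structure, toy$forcefield)
  traj <- new_trajectory(sp, list(coords_matrix(sp)))
  p15 <- interaction_profile(traj, cutoff = 1.5)
  pinf <- interaction_profile(traj, cutoff = Inf)
  xyz <- coords_matrix(sp)
  rk <- residue_keys(sp)
  for (i in seq_len(nrow(p15$pairs))) {
    ia <- which(rk == p15$pairs$toxin_res[i])
    ib <- which(rk == p15$pairs$channel_res[i])
    dmax <- max(sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                           rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                       2 * xyz[ia, , drop = FALSE] %*%
                         t(xyz[ib, , drop = FALSE])))
    if (dmax <= 1.5) {
      expect_equal(p15$pairs$mean_total[i], pinf$pairs$mean_total[i],
                   tolerance = 1e-12)
    }
  }
  # fillers sit wholly beyond the cutoff: zero at 1.5, nonzero at Inf
  filler <- grep("A:10", p15$residues$toxin_res)
  expect_true(all(p15$residues$mean_total[filler] == 0))
  expect_true(any(pinf$residues$mean_total[filler] != 0))
})
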