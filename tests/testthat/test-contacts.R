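# geometric contact detectors and trajectory occupancy

# minimal hand-built interface: one toxin serine donor over one channel
# glycine acceptor, with tunable D-A distance and D-H-A angle
hbond_pair <- function(da = 0.30, angle = 180) {
  # donor OG above the acceptor O; H placed (numerically) to realize the
  # requested D-H-A angle at the hydrogen, |D-H| = 0.1 nm
  a <- c(0, 0, 0)
  d <- c(0, 0, da)
  bond <- 0.10
  h_at <- function(phi) d + bond * c(sin(phi), 0, -cos(phi))
  ang_at <- function(phi) {
    h <- h_at(phi)
    u <- d - h
    v <- a - h
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  phi <- if (angle >= 180) 0 else
    stats::uniroot(function(p) ang_at(p) - angle, c(1e-9, pi * 0.9),
                   tol = 1e-12)$root
  h <- h_at(phi)
  atoms <- data.frame(
    serial = 1:5,
    name = c("OG", "HG", "CB", "O", "C"),
    element = c("O", "H", "C", "O", "C"),
    resname = c("SER", "SER", "SER", "GLY", "GLY"),
    chain = c("A", "A", "A", "B", "B"), resno = c(1L, 1L, 1L, 2L, 2L),
    x = c(d[1], h[1], 0, a[1], 0.12),
    y = c(d[2], h[2], 0, a[2], 0),
    z = c(d[3], h[3], da + 0.15, a[3], -0.08),
    stringsAsFactors = FALSE)
  s <- new_structure(atoms, entity_map = c(A = "toxin", B = "channel"))
  list(s = s, ann = annotate_chemistry(s))
}

test_that("hydrogen bond thresholds are enforced exactly as stated", {
  cases <- list(list(da = 0.30, ang = 165, n = 1L),   # inside both
                list(da = 0.36, ang = 170, n = 0L),   # distance fails
                list(da = 0.34, ang = 149, n = 0L),   # angle fails
                list(da = 0.35, ang = 180, n = 1L),   # distance boundary (exact)
                list(da = 0.30, ang = 150.5, n = 1L)) # just above angle cut
  for (cs in cases) {
    hp <- hbond_pair(cs$da, cs$ang)
    hits <- detect_hbonds(hp$ann, coords_matrix(hp$s))
    expect_equal(nrow(hits), cs$n,
                 info = sprintf("da=%.2f ang=%g", cs$da, cs$ang))
    if (cs$n == 1L) {
      expect_equal(hits$distance, cs$da, tolerance = 1e-9)
      expect_equal(hits$angle, cs$ang, tolerance = 1e-6)
    }
  }
})

test_that("salt bridges require opposite signs within the cutoff", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("salt_bridge")),
                                     seed = 1))
  xyz <- coords_matrix(toy$structure)
  hits <- detect_salt_bridges(toy$annotation, xyz)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 0.32, tolerance = 1e-9)
  # same-sign groups at the same distance: nothing
  toy2 <- make_toy_complex(plant_spec(list(plant_feature("repulsion")),
                                      seed = 1))
  expect_equal(nrow(detect_salt_bridges(toy2$annotation,
                                        coords_matrix(toy2$structure))), 0L)
})

test_that("cation-pi detection follows the distance x angle grid", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("cation_pi")),
                                     seed = 1))
  s <- toy$structure
  ann <- toy$annotation
  base <- coords_matrix(s)
  nz <- which(s$atoms$name == "NZ")
  ring_center <- colMeans(base[ann$residues[[2]]$rings[[1]], ])
  cr <- contact_criteria()
  for (dist in c(0.45, 0.55, 0.65)) {
    for (ang in c(0, 30, 60, 90)) {
      xyz <- base
      rad <- ang * pi / 180
      xyz[nz, ] <- ring_center + dist * c(sin(rad), 0, cos(rad))
      # keep the lysine hydrogens near their nitrogen
      hz <- which(s$atoms$name %in% c("HZ1", "HZ2", "HZ3"))
      xyz[hz, ] <- sweep(base[hz, ] - rep(base[nz, ], each = 3),
                         2L, xyz[nz, ], "+")
      hits <- detect_cation_pi(ann, xyz)
      expected <- dist <= cr$cationpi_max && ang <= cr$cationpi_angle_max
      expect_equal(nrow(hits), as.integer(expected),
                   info = sprintf("dist=%.2f ang=%g", dist, ang))
    }
  }
})

test_that("stacking windows separate parallel, T-shaped and none", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("stacking")), seed = 1))
  hits <- detect_stacking(toy$annotation, coords_matrix(toy$structure))
  expect_equal(hits$atoms, "parallel")
  expect_equal(hits$angle, 0, tolerance = 1e-6)

  toyT <- make_toy_complex(plant_spec(list(plant_feature("stacking_t")),
                                      seed = 1))
  hitsT <- detect_stacking(toyT$annotation, coords_matrix(toyT$structure))
  expect_equal(hitsT$atoms, "t-shaped")
  expect_equal(hitsT$angle, 90, tolerance = 1e-6)

  # centroids beyond the cutoff: nothing
  s <- toy$structure
  xyz <- coords_matrix(s)
  tox <- atom_entities(s) == "toxin"
  xyz[tox, 3L] <- xyz[tox, 3L] + 0.25   # centroid separation 0.50 -> 0.75
  expect_equal(nrow(detect_stacking(toy$annotation, xyz)), 0L)
})

test_that("hydrophobic contacts: one per residue pair within the cutoff", {
  toy <- make_toy_complex(plant_spec(list(plant_feature("hydrophobic")),
                                     seed = 1))
  hits <- detect_hydrophobic(toy$annotation, coords_matrix(toy$structure))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 0.40, tolerance = 1e-9)
  xyz <- coords_matrix(toy$structure)
  tox <- atom_entities(toy$structure) == "toxin"
  xyz[tox, 3L] <- xyz[tox, 3L] + 0.10   # 0.40 -> 0.50 > 0.45
  expect_equal(nrow(detect_hydrophobic(toy$annotation, xyz)), 0L)
})

test_that("all detectors agree with the brute-force oracle (exhaustive)", {
  # planted structures of every kind, plus perturbed variants
  specs <- list(full_plant_spec(seed = 1),
                plant_spec(list(plant_feature("hbond", toxin_resname = "LYS",
                                              channel_resname = "GLU"),
                                plant_feature("cation_pi",
                                              channel_resname = "HIS"),
                                plant_feature("salt_bridge",
                                              channel_resname = "ASP")),
                           n_channel_chains = 3L, seed = 2))
  set.seed(123)
  for (spec in specs) {
    toy <- make_toy_complex(spec)
    expect_lte(nrow(toy$structure$atoms), 200L)
    base <- coords_matrix(toy$structure)
    for (rep in 1:4) {
      xyz <- base + matrix(rnorm(length(base), 0, 0.03 * (rep - 1)),
                           ncol = 3L)
      got <- contact_key_set(frame_contacts(toy$annotation, xyz))
      expect_identical(got, oracle_contacts(toy$annotation, xyz))
    }
  }
})

test_that("no intra-entity contact is ever reported", {
  # two toxin residues close together: planted features plus a duplicated
  # toxin-side donor near another toxin acceptor must stay silent
  toy <- make_toy_complex(full_plant_spec(seed = 3))
  cc <- frame_contacts(toy$annotation, coords_matrix(toy$structure))
  ent <- toy$structure$entity_map
  expect_true(all(ent[sub(":.*", "", cc$toxin_res)] == "toxin"))
  expect_true(all(ent[sub(":.*", "", cc$channel_res)] == "channel"))
})

test_that("detections are invariant under a global rigid transform", {
  toy <- make_toy_complex(full_plant_spec(seed = 4))
  base <- coords_matrix(toy$structure)
  ref <- frame_contacts(toy$annotation, base)
  set.seed(21)
  for (rep in 1:3) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                  2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
                3L, byrow = TRUE)
    moved <- sweep(base %*% t(R), 2L, rnorm(3), "+")
    got <- frame_contacts(toy$annotation, moved)
    expect_identical(contact_key_set(got), contact_key_set(ref))
    expect_equal(sort(got$distance), sort(ref$distance), tolerance = 1e-9)
  }
})

test_that("contact occupancy counts frames exactly", {
  # planted 7-of-10 schedule
  toy <- make_toy_complex(plant_spec(list(plant_feature("hbond",
                                                        occupancy = 0.7)),
                                     jitter = 0, seed = 1))
  traj <- make_toy_trajectory(toy, 10L)
  cm <- contact_occupancy(traj$trajectory, toy$annotation)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$occupancy, 0.7)
  expect_equal(cm$count, 7L)
  expect_equal(cm$occupancy * attr(cm, "n_frames"), round(cm$occupancy * 10))
  # absent contacts are absent keys, not zero rows
  toy0 <- make_toy_complex(plant_spec(list(plant_feature("hbond",
                                                         occupancy = 0)),
                                      jitter = 0, seed = 1))
  cm0 <- contact_occupancy(make_toy_trajectory(toy0, 10L)$trajectory,
                           toy0$annotation)
  expect_equal(nrow(cm0), 0L)
  # burn-in must leave at least one frame
  expect_error(contact_occupancy(traj$trajectory, toy$annotation,
                                 burn_in = 10L), "burn_in")
  # bit-exact reproducibility on identical input
  cm2 <- contact_occupancy(traj$trajectory, toy$annotation)
  expect_identical(as.data.frame(cm), as.data.frame(cm2))
})

test_that("criteria validation and contact-map TSV round trip", {
  expect_error(contact_criteria(hbond_da_max = -1), "positive")
  expect_error(contact_criteria(hbond_dha_min = 200), "0, 180")
  toy <- make_toy_complex(full_plant_spec(seed = 6))
  cm <- contact_occupancy(make_toy_trajectory(toy, 5L)$trajectory,
                          toy$annotation)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, path)
  back <- read_contact_map(path)
  expect_equal(as.data.frame(back), as.data.frame(cm), ignore_attr = TRUE)
  expect_equal(attr(back, "criteria")$hbond_da_max, 0.35)
})
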