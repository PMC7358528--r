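# differential contacts, repulsive residues, mutation design

ledger_set <- function(target = "Kv1.3") {
  ledger_to_isoform_set(paper_fixture_ledger(), target = target,
                        isoforms = c("Kv1.1", "Kv1.2", "Kv1.3"))
}

test_that("the curated ledger flags Gln12, Lys15, Lys18 against Kv1.3", {
  diff <- differential_contacts(ledger_set())
  expect_setequal(unique(diff$toxin_resno), c(12L, 15L, 18L))
  # Lys15: H-bond and salt bridge with Kv1.1 Glu353
  k15 <- diff[diff$toxin_resno == 15L, ]
  expect_setequal(k15$kind, c("hbond", "salt_bridge"))
  expect_true(all(k15$isoform == "Kv1.1"))
  expect_true(all(k15$channel_resno == 353L))
  # Lys18 contacts both off-target isoforms, including the His355 cation-pi
  k18 <- diff[diff$toxin_resno == 18L, ]
  expect_setequal(k18$isoform, c("Kv1.1", "Kv1.2"))
  expect_true(any(k18$kind == "cation_pi" & k18$channel_resno == 355L))
  # nothing is flagged for the target isoform itself
  expect_false("Kv1.3" %in% diff$isoform)
})

test_that("identical maps across isoforms yield no differential contacts", {
  set <- ledger_set()
  same <- set$entries[["Kv1.1"]]
  set2 <- isoform_set(list("Kv1.1" = same, "Kv1.2" = same, "Kv1.3" = same),
                      target = "Kv1.3")
  expect_equal(nrow(differential_contacts(set2)), 0L)
})

test_that("differential contacts honor the occupancy threshold monotonically", {
  toy1 <- make_toy_complex(plant_spec(list(
    plant_feature("hbond", occupancy = 0.6, toxin_resno = 5),
    plant_feature("salt_bridge", occupancy = 0.2, toxin_resno = 7)), seed = 1))
  toy3 <- make_toy_complex(plant_spec(list(
    plant_feature("hbond", occupancy = 0, toxin_resno = 5),
    plant_feature("salt_bridge", occupancy = 0, toxin_resno = 7)), seed = 2))
  mk <- function(toy) {
    traj <- make_toy_trajectory(toy, 10L)
    list(contacts = contact_occupancy(traj$trajectory,
                                      annotate_chemistry(traj$trajectory$topology)),
         energy = interaction_profile(traj$trajectory))
  }
  set <- isoform_set(list(off = mk(toy1), target = mk(toy3)),
                     target = "target")
  prev <- Inf
  for (thr in c(0.1, 0.3, 0.7, 1.0)) {
    n <- nrow(differential_contacts(set, occupancy_threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
  # the planted off-target-only H-bond is exactly what is returned at 0.5
  d <- differential_contacts(set, occupancy_threshold = 0.5)
  expect_equal(unique(d$toxin_resno), 5L)
  expect_equal(unique(d$kind), "hbond")
})

test_that("repulsive_residues requires positivity in every isoform", {
  set <- ledger_set()
  rep <- repulsive_residues(set)
  expect_equal(rep$resno, 33L)
  expect_equal(rep$resname, "ASP")
  expect_true(all(rep[, grep("^mean_total_", names(rep))] > 0))
  # all-negative profiles: empty
  neg <- set
  for (iso in names(neg$entries)) {
    neg$entries[[iso]]$energy$mean_total <- -1
  }
  expect_equal(nrow(repulsive_residues(neg)), 0L)
  # positive in one isoform only: excluded
  one <- neg
  one$entries[["Kv1.1"]]$energy$mean_total <- 5
  expect_equal(nrow(repulsive_residues(one)), 0L)
})

test_that("propose_mutations applies the paper-style rules deterministically", {
  seqs <- toxin_sequence()[["parent"]]
  set <- ledger_set()
  diff <- differential_contacts(set)
  reps <- repulsive_residues(set)
  prop <- propose_mutations(diff, reps, seqs)
  expect_equal(nrow(prop), 4L)
  expect_equal(prop$position, c(12L, 15L, 18L, 33L))
  expect_equal(prop$from, c("Q", "K", "K", "D"))
  expect_equal(prop$to, c("A", "A", "A", "R"))
  expect_true(all(nchar(prop$rationale) > 0))
  # pure function: bit-reproducible
  expect_identical(as.data.frame(prop),
                   as.data.frame(propose_mutations(diff, reps, seqs)))
  # charge reversal is configurable
  propK <- propose_mutations(diff, reps, seqs, charge_reversal_to = "K")
  expect_equal(propK$to[propK$position == 33L], "K")
  # empty inputs yield an empty proposal
  empty <- propose_mutations(diff[0, ], reps[0, ], seqs)
  expect_equal(nrow(empty), 0L)
})

test_that("rule collisions collapse to a single substitution", {
  set <- ledger_set()
  diff <- differential_contacts(set)
  reps <- repulsive_residues(set)
  # force residue 15 to also be repulsive (as a K it is skipped by the
  # acid-only reversal rule; use 12 rewritten as an acid instead)
  reps2 <- rbind(reps, reps)
  reps2$resno[2L] <- 12L
  reps2$resname[2L] <- "GLN"
  sq <- toxin_sequence()[["parent"]]
  # Gln is not acidic: no reversal row is added, the Ala row stands alone
  prop <- propose_mutations(diff, reps2, sq)
  expect_equal(sum(prop$position == 12L), 1L)
  expect_equal(prop$to[prop$position == 12L], "A")
  # an acidic residue that is also polar-specific gets one combined row
  sq2 <- sub("Q", "E", sq, fixed = TRUE)  # position 12 -> Glu
  diff2 <- diff
  diff2$toxin_resname[diff2$toxin_resno == 12L] <- "GLU"
  reps3 <- reps2
  reps3$resname[2L] <- "GLU"
  prop2 <- propose_mutations(diff2, reps3, sq2)
  row12 <- prop2[prop2$position == 12L, ]
  expect_equal(nrow(row12), 1L)
  expect_equal(row12$to, "A")
  expect_match(row12$rationale, "polar")
  expect_match(row12$rationale, "repulsive")
})

test_that("apply_mutations guards and inverts correctly", {
  sq <- toxin_sequence()[["parent"]]
  expect_equal(nchar(sq), 37L)
  set <- ledger_set()
  prop <- propose_mutations(differential_contacts(set),
                            repulsive_residues(set), sq)
  mut <- apply_mutations(sq, prop)
  expect_equal(nchar(mut), 37L)
  expect_equal(sum(strsplit(sq, "")[[1L]] != strsplit(mut, "")[[1L]]), 4L)
  # reversal restores the original
  back <- prop
  back$from <- prop$to
  back$to <- prop$from
  expect_identical(apply_mutations(mut, back), sq)
  # empty proposal is the identity
  expect_identical(apply_mutations(sq, prop[0, ]), sq)
  # from-mismatch and cysteine guard
  badpos <- prop
  badpos$from[1L] <- "W"
  expect_error(apply_mutations(sq, badpos), "position 12")
  cys <- data.frame(position = 7L, from = "C", to = "A")
  expect_error(apply_mutations(sq, cys), "cysteine")
})

test_that("the ledger matches its curated facts and round-trips YAML", {
  led <- paper_fixture_ledger()
  expect_true(any(led$toxin_resno == 15L & led$isoform == "Kv1.1" &
                    led$channel_resno == 353L &
                    led$kinds == "hbond,salt_bridge"))
  polar <- led[led$kinds != "repulsion", ]
  expect_false("Kv1.3" %in% polar$isoform)
  expect_equal(sort(unique(led$channel_resno[led$kinds == "repulsion"])),
               c(375L, 377L, 399L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ledger_yaml(led, path)
  back <- read_ledger_yaml(path)
  expect_equal(as.data.frame(back), as.data.frame(led), ignore_attr = TRUE)
})
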