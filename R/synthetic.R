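# Synthetic toy complexes, trajectories and dose-response data with
# recorded ground truth. The generator states a world: every planted
# feature satisfies its geometric criterion with margin (>= 0.02 nm / 5
# degrees), occupancies are planted by frame counting (never Bernoulli
# draws), and everything is a pure function of (spec, seed).

PLANT_KINDS <- c("hbond", "salt_bridge", "salt_bridge_hbond", "cation_pi",
                 "stacking", "stacking_t", "hydrophobic", "repulsion")

#' Describe one planted interface feature
#'
#' @param kind one of `"hbond"`, `"salt_bridge"`, `"salt_bridge_hbond"`
#'   (a salt bridge whose ammonium also donates a hydrogen bond, the
#'   Lys15-Glu353 situation), `"cation_pi"`, `"stacking"` (parallel),
#'   `"stacking_t"` (T-shaped; geometrically implies a hydrophobic contact,
#'   which the ground truth records), `"hydrophobic"`, or `"repulsion"` (a
#'   like-charge pair planting a positive energy contribution, no contact).
#' @param occupancy target fraction of trajectory frames in \[0, 1\] in
#'   which the feature is present (default 1).
#' @param toxin_resno,channel_resno residue numbers (defaults assigned by
#'   slot: toxin 10+i, channel 350+i).
#' @param toxin_resname,channel_resname residue types; defaults per kind
#'   (e.g. SER donor on GLY acceptor for `"hbond"`, LYS on GLU for salt
#'   bridges, LYS on PHE for `"cation_pi"`). Supported donors: SER, LYS,
#'   GLN; acceptors: GLY, SER, THR, ASP, GLU, GLN; rings: PHE, HIS.
#' @return a feature description list.
#' @export
plant_feature <- function(kind, occupancy = 1, toxin_resno = NULL,
                          toxin_resname = NULL, channel_resno = NULL,
                          channel_resname = NULL) {
  kind <- match.arg(kind, PLANT_KINDS)
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]")
  defaults <- list(
    hbond = c("SER", "GLY"), salt_bridge = c("LYS", "GLU"),
    salt_bridge_hbond = c("LYS", "GLU"), cation_pi = c("LYS", "PHE"),
    stacking = c("PHE", "PHE"), stacking_t = c("PHE", "PHE"),
    hydrophobic = c("LEU", "VAL"), repulsion = c("ASP", "ASP"))[[kind]]
  list(kind = kind, occupancy = occupancy,
       toxin_resname = toxin_resname %||% defaults[1L],
       channel_resname = channel_resname %||% defaults[2L],
       toxin_resno = toxin_resno, channel_resno = channel_resno)
}

#' Specification of a toy toxin-channel complex
#'
#' @param features list of [plant_feature()] descriptions.
#' @param n_channel_chains number of channel chains (>= 1); planted channel
#'   residues are distributed round-robin, mimicking the tetrameric
#'   vestibule.
#' @param n_toxin_filler extra inert Ala residues on the toxin chain.
#' @param jitter per-coordinate uniform jitter half-width for trajectory
#'   frames, nm; bounded so that jitter below the planted geometric margin
#'   can never flip a detection (default 0.005, >= 0).
#' @param seed integer seed (used only for trajectory jitter).
#' @return a `toxsel_plantspec`.
#' @export
plant_spec <- function(features, n_channel_chains = 2L, n_toxin_filler = 2L,
                       jitter = 0.005, seed = 1L) {
  if (jitter < 0) stop("jitter must be >= 0")
  if (n_channel_chains < 1L) stop("need at least one channel chain")
  features <- lapply(features, function(f) {
    stopifnot(is.list(f), !is.null(f$kind))
    f
  })
  structure(list(features = features, n_channel_chains = n_channel_chains,
                 n_toxin_filler = n_toxin_filler, jitter = jitter,
                 seed = as.integer(seed)),
            class = "toxsel_plantspec")
}

# residue builders ----------------------------------------------------------
# key atom sits at `key`; `up` is +1 for toxin (backbone above the
# interface) and -1 for channel (backbone below)

res_atoms <- function(resname, chain, resno, coords) {
  nm <- names(coords)
  data.frame(serial = NA_integer_, name = nm,
             element = substr(gsub("[0-9]", "", nm), 1L, 1L),
             resname = resname, chain = chain, resno = resno,
             x = vapply(coords, `[`, 0, 1L),
             y = vapply(coords, `[`, 0, 2L),
             z = vapply(coords, `[`, 0, 3L),
             stringsAsFactors = FALSE)
}

off <- function(key, dx, dy, dz) key + c(dx, dy, dz)

backbone_block <- function(key, up, dz0 = 0.30) {
  u <- up
  list(CA = off(key, 0, 0.02, u * dz0),
       N = off(key, 0.12, 0.02, u * (dz0 + 0.10)),
       H = off(key, 0.12, 0.02, u * (dz0 + 0.20)),
       C = off(key, -0.12, 0.02, u * (dz0 + 0.10)),
       O = off(key, -0.12, 0.02, u * (dz0 + 0.20)))
}

donor_residue <- function(resname, chain, resno, key, hb = TRUE) {
  # key = donor heavy atom; partner acceptor sits 0.30 nm straight below
  hz_flat <- list(c(0.097, 0, 0.025), c(-0.0485, 0.084, 0.025),
                  c(-0.0485, -0.084, 0.025))
  side <- switch(resname,
    SER = {
      s <- list(OG = key, HG = off(key, 0, 0, -0.10), CB = off(key, 0, 0, 0.15))
      c(s, backbone_block(key, +1, 0.30))
    },
    LYS = {
      h1 <- if (hb) off(key, 0, 0, -0.10) else key + hz_flat[[1L]]
      s <- list(NZ = key, HZ1 = h1, HZ2 = key + hz_flat[[2L]],
                HZ3 = key + hz_flat[[3L]], CB = off(key, 0, 0.02, 0.15))
      c(s, backbone_block(key, +1, 0.30))
    },
    GLN = {
      s <- list(NE2 = key, HE21 = off(key, 0, 0, -0.10),
                HE22 = key + hz_flat[[1L]], OE1 = off(key, 0.15, 0, 0.08),
                CD = off(key, 0.08, 0, 0.10), CG = off(key, 0.04, 0.02, 0.24),
                CB = off(key, 0, 0.02, 0.36))
      c(s, backbone_block(key, +1, 0.50))
    },
    stop("unsupported donor residue: ", resname))
  res_atoms(resname, chain, resno, side)
}

acceptor_residue <- function(resname, chain, resno, key) {
  # key = acceptor atom, pointing up at the toxin
  side <- switch(resname,
    GLY = list(O = key, C = off(key, 0, 0, -0.12), CA = off(key, 0.12, 0, -0.20),
               N = off(key, 0.24, 0, -0.28), H = off(key, 0.24, 0, -0.38)),
    SER = c(list(OG = key, HG = off(key, 0.097, 0, -0.025),
                 CB = off(key, 0, 0, -0.15)), backbone_block(key, -1, 0.30)),
    THR = c(list(OG1 = key, HG1 = off(key, 0.097, 0, -0.025),
                 CG2 = off(key, 0.14, 0, -0.12), CB = off(key, 0, 0, -0.15)),
            backbone_block(key, -1, 0.30)),
    ASP = c(list(OD1 = key, OD2 = off(key, 0.12, 0, -0.02),
                 CG = off(key, 0.06, 0, -0.10), CB = off(key, 0.06, 0.02, -0.24)),
            backbone_block(key, -1, 0.38)),
    GLU = c(list(OE1 = key, OE2 = off(key, 0.12, 0, -0.02),
                 CD = off(key, 0.06, 0, -0.10), CG = off(key, 0.06, 0.02, -0.24),
                 CB = off(key, 0.06, 0.02, -0.36)),
            backbone_block(key, -1, 0.50)),
    GLN = c(list(OE1 = key, NE2 = off(key, 0.12, 0, -0.04),
                 HE21 = off(key, 0.12, 0.097, -0.065),
                 HE22 = off(key, 0.217, 0, -0.065),
                 CD = off(key, 0.06, 0, -0.10), CG = off(key, 0.06, 0.02, -0.24),
                 CB = off(key, 0.06, 0.02, -0.36)),
            backbone_block(key, -1, 0.50)),
    stop("unsupported acceptor residue: ", resname))
  res_atoms(resname, chain, resno, side)
}

ring_coords <- function(center, radius, phase, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  ang <- phase + seq(0, 300, by = 60) * pi / 180
  lapply(ang, function(a) {
    if (plane == "xy") center + radius * c(cos(a), sin(a), 0)
    else center + radius * c(cos(a), 0, sin(a))
  })
}

ring_residue <- function(resname, chain, resno, center, entity,
                         plane = "xy", phase = 0) {
  u <- if (entity == "toxin") +1 else -1
  if (resname == "PHE") {
    rc <- ring_coords(center, 0.14, phase, plane)
    names(rc) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    side <- c(rc, list(CB = off(center, 0.26, 0, u * 0.12)),
              backbone_block(center, u, 0.30))
  } else if (resname == "HIS") {
    ang <- phase + seq(0, 288, by = 72) * pi / 180
    rc <- lapply(ang, function(a) center + 0.12 * c(cos(a), sin(a), 0))
    names(rc) <- c("CG", "ND1", "CE1", "NE2", "CD2")
    he2 <- rc$NE2 + 0.10 * (rc$NE2 - center) / sqrt(sum((rc$NE2 - center)^2))
    side <- c(rc, list(HE2 = he2, CB = off(center, 0.24, 0, u * 0.12)),
              backbone_block(center, u, 0.30))
  } else {
    stop("unsupported ring residue: ", resname)
  }
  res_atoms(resname, chain, resno, side)
}

cation_residue <- function(chain, resno, key) {
  donor_residue("LYS", chain, resno, key, hb = FALSE)
}

anion_residue <- function(resname, chain, resno, key, entity) {
  u <- if (entity == "toxin") +1 else -1
  side <- switch(resname,
    ASP = c(list(OD1 = key, OD2 = off(key, 0.12, 0, u * 0.02),
                 CG = off(key, 0.06, 0, u * 0.12),
                 CB = off(key, 0.06, 0.02, u * 0.26)),
            backbone_block(key, u, 0.40)),
    GLU = c(list(OE1 = key, OE2 = off(key, 0.12, 0, u * 0.02),
                 CD = off(key, 0.06, 0, u * 0.12),
                 CG = off(key, 0.06, 0.02, u * 0.26),
                 CB = off(key, 0.06, 0.02, u * 0.38)),
            backbone_block(key, u, 0.52)),
    stop("unsupported anion residue: ", resname))
  res_atoms(resname, chain, resno, side)
}

apolar_residue <- function(resname, chain, resno, key, entity) {
  u <- if (entity == "toxin") +1 else -1
  side <- switch(resname,
    LEU = c(list(CD1 = key, CD2 = off(key, 0.12, 0, u * 0.08),
                 CG = off(key, 0.06, 0, u * 0.12),
                 CB = off(key, 0.06, 0.02, u * 0.26)),
            backbone_block(key, u, 0.40)),
    VAL = c(list(CG1 = key, CG2 = off(key, 0.12, 0, u * 0.08),
                 CB = off(key, 0.06, 0, u * 0.12)),
            backbone_block(key, u, 0.26)),
    stop("unsupported apolar residue: ", resname))
  res_atoms(resname, chain, resno, side)
}

filler_residue <- function(chain, resno, key) {
  side <- c(list(CB = key), backbone_block(key, +1, 0.15))
  res_atoms("ALA", chain, resno, side)
}

# which contacts a planted feature must produce, given its residue types
feature_truth_kinds <- function(f) {
  switch(f$kind,
    hbond = if (f$toxin_resname %in% c("LYS", "ARG") &&
                f$channel_resname %in% c("ASP", "GLU"))
      c("hbond", "salt_bridge") else "hbond",
    salt_bridge = "salt_bridge",
    salt_bridge_hbond = c("hbond", "salt_bridge"),
    cation_pi = "cation_pi",
    stacking = "stacking",
    stacking_t = c("stacking", "hydrophobic"),
    hydrophobic = "hydrophobic",
    repulsion = character(0))
}

#' Build a toy toxin-channel complex with planted interface features
#'
#' Constructs a toxin chain (chain `A`) posed over a multi-chain channel
#' vestibule (chains `B`, `C`, ...). Each planted feature occupies its own
#' angular slot on a circle wide enough that slots cannot interact; its key
#' atoms satisfy the corresponding geometric criterion with margin (>= 0.02
#' nm in distance, >= 5 degrees in angle), so sub-margin jitter never flips
#' a detection. Deterministic: the seed is only consumed later, by
#' [make_toy_trajectory()].
#'
#' @param spec a `toxsel_plantspec`.
#' @return list with `structure` (entity-mapped `toxsel_structure`),
#'   `annotation`, `forcefield` (the bundled reduced table) and
#'   `ground_truth` (expected contacts with occupancies, expected energy
#'   signs, spec echo).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toxsel_plantspec"))
  feats <- spec$features
  m <- length(feats)
  chains <- LETTERS[1L + seq_len(spec$n_channel_chains)]
  radius <- if (m >= 2L) max(0.8, 0.5 / sin(pi / m)) else 0.8
  atoms <- list()
  truth_contacts <- list()
  truth_energy <- list()
  seen_tox <- character(0)
  seen_cha <- character(0)
  for (i in seq_len(max(m, 0L))) {
    f <- feats[[i]]
    f$toxin_resno <- f$toxin_resno %||% (10L + i)
    f$channel_resno <- f$channel_resno %||% (350L + i)
    cha_chain <- chains[(i - 1L) %% length(chains) + 1L]
    tox_id <- paste0("A:", f$toxin_resno)
    cha_id <- paste0(cha_chain, ":", f$channel_resno)
    if (tox_id %in% seen_tox || cha_id %in% seen_cha) {
      stop("infeasible plant: two features demand residue ", tox_id,
           " or ", cha_id)
    }
    seen_tox <- c(seen_tox, tox_id)
    seen_cha <- c(seen_cha, cha_id)
    theta <- 2 * pi * (i - 1L) / max(m, 1L)
    p <- radius * c(cos(theta), sin(theta), 0)
    tox <- switch(f$kind,
      hbond = donor_residue(f$toxin_resname, "A", f$toxin_resno,
                            off(p, 0, 0, 0.40)),
      salt_bridge = cation_residue("A", f$toxin_resno, off(p, 0, 0, 0.42)),
      salt_bridge_hbond = donor_residue("LYS", "A", f$toxin_resno,
                                        off(p, 0, 0, 0.42), hb = TRUE),
      cation_pi = cation_residue("A", f$toxin_resno, off(p, 0, 0, 0.55)),
      stacking = ring_residue(f$toxin_resname, "A", f$toxin_resno,
                              off(p, 0, 0, 0.60), "toxin", plane = "xy",
                              phase = pi / 6),
      stacking_t = ring_residue(f$toxin_resname, "A", f$toxin_resno,
                                off(p, 0, 0, 0.60), "toxin", plane = "xz"),
      hydrophobic = apolar_residue(f$toxin_resname, "A", f$toxin_resno,
                                   off(p, 0, 0, 0.50), "toxin"),
      repulsion = anion_residue(f$toxin_resname, "A", f$toxin_resno,
                                off(p, 0, 0, 0.60), "toxin"))
    key_c <- off(p, 0, 0, 0.10)
    cha <- switch(f$kind,
      hbond = acceptor_residue(f$channel_resname, cha_chain,
                               f$channel_resno, key_c),
      salt_bridge = anion_residue(f$channel_resname, cha_chain,
                                  f$channel_resno, key_c, "channel"),
      salt_bridge_hbond = anion_residue(f$channel_resname, cha_chain,
                                        f$channel_resno, key_c, "channel"),
      cation_pi = ring_residue(f$channel_resname, cha_chain, f$channel_resno,
                               key_c, "channel"),
      stacking = ring_residue(f$channel_resname, cha_chain, f$channel_resno,
                              key_c, "channel"),
      stacking_t = ring_residue(f$channel_resname, cha_chain, f$channel_resno,
                                key_c, "channel"),
      hydrophobic = apolar_residue(f$channel_resname, cha_chain,
                                   f$channel_resno, key_c, "channel"),
      repulsion = anion_residue(f$channel_resname, cha_chain,
                                f$channel_resno, key_c, "channel"))
    atoms[[length(atoms) + 1L]] <- tox
    atoms[[length(atoms) + 1L]] <- cha
    for (kind in feature_truth_kinds(f)) {
      truth_contacts[[length(truth_contacts) + 1L]] <- data.frame(
        toxin_res = tox_id, toxin_resname = f$toxin_resname,
        toxin_resno = f$toxin_resno, channel_res = cha_id,
        channel_resname = f$channel_resname, channel_resno = f$channel_resno,
        kind = kind, occupancy = f$occupancy, feature = i,
        stringsAsFactors = FALSE)
    }
    if (f$kind == "repulsion") {
      truth_energy[[length(truth_energy) + 1L]] <- data.frame(
        toxin_res = tox_id, sign = +1, stringsAsFactors = FALSE)
    }
    feats[[i]] <- f
  }
  # fillers sit beyond the 1.5 nm interaction cutoff: zero contacts and
  # exactly zero interface energy by construction
  for (j in seq_len(spec$n_toxin_filler)) {
    ang <- 2 * pi * (j - 0.5) / max(spec$n_toxin_filler, 1L)
    atoms[[length(atoms) + 1L]] <-
      filler_residue("A", 100L + j, c(0.3 * cos(ang), 0.3 * sin(ang), 1.9))
  }
  # every declared channel chain gets at least one (inert, distant) residue
  used_chains <- unique(unlist(lapply(atoms, function(a) a$chain)))
  for (ch in setdiff(chains, used_chains)) {
    k <- match(ch, chains)
    atoms[[length(atoms) + 1L]] <- acceptor_residue(
      "GLY", ch, 400L + k, c(2.2 * cos(k), 2.2 * sin(k), -0.5))
  }
  tab <- do.call(rbind, atoms)
  tab$serial <- seq_len(nrow(tab))
  emap <- stats::setNames(rep("channel", length(chains) + 1L),
                          c("A", chains))
  emap["A"] <- "toxin"
  s <- new_structure(tab, entity_map = emap)
  ann <- annotate_chemistry(s)
  truth <- list(
    contacts = if (length(truth_contacts)) do.call(rbind, truth_contacts)
      else NULL,
    energy_signs = if (length(truth_energy)) do.call(rbind, truth_energy)
      else NULL,
    features = feats, seed = spec$seed, spec = spec)
  list(structure = s, annotation = ann, forcefield = default_forcefield(),
       ground_truth = truth)
}

#' Expand a toy complex into a trajectory with planted occupancies
#'
#' Occupancy is planted by frame counting: a feature with target occupancy
#' `o` over `n` frames is present in exactly `round(o * n)` frames (the
#' leading ones) and broken in the rest by translating its toxin residue
#' 0.6 nm away from the interface. Per-atom uniform jitter of half-width
#' `spec$jitter` nm is applied to every frame (seeded, reproducible); with
#' the default 0.005 nm it stays below every planted margin.
#'
#' @param toy output of [make_toy_complex()].
#' @param n_frames number of frames.
#' @return list with `trajectory` (topology parameterized from the bundled
#'   table) and `ground_truth` (expected occupancies now exact counts).
#' @export
make_toy_trajectory <- function(toy, n_frames) {
  spec <- toy$ground_truth$spec
  s <- assign_parameters(toy$structure, toy$forcefield)
  base <- coords_matrix(s)
  keys <- residue_keys(s)
  feats <- toy$ground_truth$features
  on_counts <- vapply(feats, function(f) as.integer(round(f$occupancy * n_frames)),
                      integer(1))
  set.seed(spec$seed)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    xyz <- base
    for (i in seq_along(feats)) {
      if (t > on_counts[i]) {
        idx <- which(keys == paste0("A:", feats[[i]]$toxin_resno))
        xyz[idx, 3L] <- xyz[idx, 3L] + 0.6
      }
    }
    if (spec$jitter > 0) {
      xyz <- xyz + matrix(stats::runif(length(xyz), -spec$jitter, spec$jitter),
                          ncol = 3L)
    }
    frames[[t]] <- xyz
  }
  truth <- toy$ground_truth
  if (!is.null(truth$contacts)) {
    truth$contacts$occupancy <- on_counts[truth$contacts$feature] / n_frames
    truth$contacts$count <- on_counts[truth$contacts$feature]
  }
  truth$n_frames <- n_frames
  list(trajectory = new_trajectory(s, frames,
                                   times = 0.1 * seq_len(n_frames)),
       ground_truth = truth)
}

#' Simulate a concentration-response dataset
#'
#' Hill-curve responses plus Gaussian noise, clipped to \[0, 100\];
#' seed-deterministic. A stand-in for two-electrode voltage-clamp
#' measurements.
#'
#' @param ic50,h Hill parameters (nM, dimensionless).
#' @param concentrations tested concentrations, nM.
#' @param noise_sd Gaussian noise sd in percentage points (default 0).
#' @param n_replicates replicates per concentration.
#' @param seed integer seed.
#' @return data frame with `conc`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(ic50, h, concentrations, noise_sd = 0,
                                   n_replicates = 1L, seed = 1L) {
  set.seed(seed)
  conc <- rep(concentrations, each = n_replicates)
  y <- hill_response(conc, ic50, h) +
    stats::rnorm(length(conc), 0, noise_sd)
  data.frame(conc = conc, response = pmin(100, pmax(0, y)),
             replicate = rep(seq_len(n_replicates),
                             times = length(concentrations)))
}

#' Curated isoform-specific contact ledger
#'
#' The bundled machine-readable transcription of the isoform-specific
#' interface facts for the parent toxin on Kv1.1-1.3: Lys15 H-bond + salt
#' bridge with Kv1.1 Glu353; Lys18 H-bond with Kv1.1 Ser354 and cation-pi
#' with His355, H-bond with Kv1.2 Gln353; Gln12 H-bond with Kv1.2 Asp351;
#' no polar contacts in the Kv1.3 complex; and Asp33 electrostatically
#' repelled by the conserved vestibule aspartate (Asp377/375/399 in
#' Kv1.1/1.2/1.3) in every isoform.
#'
#' @return a `toxsel_contact_ledger`.
#' @export
paper_fixture_ledger <- function() {
  read_contact_ledger(system.file("extdata", "contact_ledger.tsv",
                                  package = "toxsel", mustWork = TRUE))
}

#' Bundled toxin sequence (synthetic stand-in)
#'
#' A 37-residue CS-alpha/beta scaffold stand-in for the parent toxin,
#' honouring the documented positional constraints (Gln12 immediately
#' before the second Cys, Lys15 between the second and third Cys, Lys18
#' immediately after the third Cys, pore-blocking Lys26, Asp33 between the
#' fifth and sixth Cys; six cysteines pairing C1-C4, C2-C5, C3-C6). The
#' true toxin sequence is not bundled; every shipped numeric result is
#' independent of it.
#'
#' @return named character vector with element `parent` (one-letter
#'   sequence).
#' @export
toxin_sequence <- function() {
  fa <- Biostrings::readAAStringSet(
    system.file("extdata", "mektx13_3_synthetic.fasta", package = "toxsel",
                mustWork = TRUE))
  stats::setNames(as.character(fa), "parent")
}
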