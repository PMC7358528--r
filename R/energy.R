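# Short-range non-bonded interaction energy (Coulomb + Lennard-Jones,
# plain truncation at a distance cutoff) decomposed per residue pair and
# per toxin residue, averaged over trajectory frames.

#' Non-bonded pair energy
#'
#' Coulomb term `f * qi * qj / r` and Lennard-Jones term
#' `4 eps [(sig/r)^12 - (sig/r)^6]` with Lorentz-Berthelot combination
#' (`sig = (sig_i + sig_j)/2`, `eps = sqrt(eps_i * eps_j)`). Both terms are
#' exactly zero beyond the cutoff (plain truncation, no shift or switch).
#'
#' @param qi,qj partial charges (e).
#' @param sigma_i,sigma_j LJ sigma (nm).
#' @param epsilon_i,epsilon_j LJ epsilon (kJ/mol).
#' @param r inter-atomic distance (nm), > 0. Vectorized.
#' @param cutoff truncation distance, nm (default 1.5).
#' @param coulomb_constant kJ mol-1 nm e-2 (default [COULOMB_CONSTANT]).
#' @return list with numeric `coulomb`, `lj`, `total` (kJ/mol).
#' @export
pair_energy <- function(qi, qj, sigma_i, sigma_j, epsilon_i, epsilon_j, r,
                        cutoff = 1.5, coulomb_constant = COULOMB_CONSTANT) {
  if (any(r <= 0)) stop("inter-atomic distance must be positive")
  within <- r <= cutoff
  coulomb <- ifelse(within, coulomb_constant * qi * qj / r, 0)
  sig <- (sigma_i + sigma_j) / 2
  eps <- sqrt(epsilon_i * epsilon_j)
  sr6 <- (sig / r)^6
  lj <- ifelse(within, 4 * eps * (sr6^2 - sr6), 0)
  list(coulomb = coulomb, lj = lj, total = coulomb + lj)
}

#' Interaction energy between two residues in one frame
#'
#' Sums [pair_energy()] over all atom pairs (one atom from each residue).
#' Intra-residue and intra-entity pairs are never computed anywhere in the
#' package; this is an interface decomposition, not a force field engine.
#'
#' @param s a parameterized `toxsel_structure` (see [assign_parameters()]).
#' @param res_a,res_b residue keys `"chain:resno"`.
#' @param coords optional n x 3 frame coordinates (nm); defaults to the
#'   structure's own.
#' @param cutoff nm.
#' @return list with `coulomb`, `lj`, `total` (kJ/mol).
#' @export
residue_pair_energy <- function(s, res_a, res_b, coords = NULL, cutoff = 1.5) {
  if (!is_parameterized(s)) stop("structure atoms are not parameterized")
  if (is.null(coords)) coords <- coords_matrix(s)
  keys <- residue_keys(s)
  ia <- which(keys == res_a)
  ib <- which(keys == res_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("residue key not found")
  a <- coords[ia, , drop = FALSE]
  b <- coords[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-12)) stop("coincident atoms (r = 0) between residues")
  e <- pair_energy(rep(s$atoms$charge[ia], times = length(ib)),
                   rep(s$atoms$charge[ib], each = length(ia)),
                   rep(s$atoms$sigma[ia], times = length(ib)),
                   rep(s$atoms$sigma[ib], each = length(ia)),
                   rep(s$atoms$epsilon[ia], times = length(ib)),
                   rep(s$atoms$epsilon[ib], each = length(ia)),
                   as.vector(r), cutoff = cutoff)
  list(coulomb = sum(e$coulomb), lj = sum(e$lj), total = sum(e$total))
}

#' Per-residue interaction energy profile over a trajectory
#'
#' For every frame after `burn_in`, computes the Coulomb and LJ energy of
#' every cross-entity (toxin residue, channel residue) pair, then averages
#' over frames. The per-toxin-residue profile is the sum over that residue's
#' channel partners, so profile marginals and the pair matrix are consistent
#' by construction. Positive mean totals flag toxin residues that repel the
#' channel (e.g. an acidic toxin residue facing a conserved vestibule
#' aspartate).
#'
#' @param traj a `toxsel_trajectory` whose topology is parameterized and has
#'   an entity map.
#' @param burn_in frames to discard (default 0).
#' @param cutoff nm (default 1.5).
#' @return a `toxsel_energyprofile`: list with `pairs` (per residue pair:
#'   mean coulomb / lj / total and sd of total), `residues` (per toxin
#'   residue marginals, mean and sd), `cutoff_nm`, `n_frames`, `burn_in`.
#' @export
interaction_profile <- function(traj, burn_in = 0L, cutoff = 1.5) {
  stopifnot(inherits(traj, "toxsel_trajectory"))
  s <- traj$topology
  if (!is_parameterized(s)) stop("trajectory topology is not parameterized")
  nf <- length(traj$frames)
  if (burn_in >= nf) stop("burn_in must leave at least one frame")
  use <- seq.int(burn_in + 1L, nf)
  ent <- atom_entities(s)
  it <- which(ent == "toxin")
  ic <- which(ent == "channel")
  if (length(it) == 0L || length(ic) == 0L) {
    stop("profile needs both toxin and channel atoms")
  }
  keys <- residue_keys(s)
  tox_res <- factor(keys[it], levels = unique(keys[it]))
  cha_res <- factor(keys[ic], levels = unique(keys[ic]))
  # pair index of every cross atom pair -> (toxin residue, channel residue)
  pair_tox <- rep(as.integer(tox_res), times = length(ic))
  pair_cha <- rep(as.integer(cha_res), each = length(it))
  pair_id <- (pair_cha - 1L) * nlevels(tox_res) + pair_tox
  n_pairs <- nlevels(tox_res) * nlevels(cha_res)
  qi <- rep(s$atoms$charge[it], times = length(ic))
  qj <- rep(s$atoms$charge[ic], each = length(it))
  si <- rep(s$atoms$sigma[it], times = length(ic))
  sj <- rep(s$atoms$sigma[ic], each = length(it))
  ei <- rep(s$atoms$epsilon[it], times = length(ic))
  ej <- rep(s$atoms$epsilon[ic], each = length(it))
  acc_c <- matrix(0, n_pairs, length(use))
  acc_l <- matrix(0, n_pairs, length(use))
  for (f in seq_along(use)) {
    xyz <- traj$frames[[use[f]]]
    a <- xyz[it, , drop = FALSE]
    b <- xyz[ic, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    r <- sqrt(pmax(as.vector(d2), 0))
    if (any(r < 1e-12)) stop("coincident cross-entity atoms in frame ", use[f])
    e <- pair_energy(qi, qj, si, sj, ei, ej, r, cutoff = cutoff)
    acc_c[, f] <- as.vector(rowsum(e$coulomb, pair_id,
                                   reorder = FALSE)[as.character(seq_len(n_pairs)), ])
    acc_l[, f] <- as.vector(rowsum(e$lj, pair_id,
                                   reorder = FALSE)[as.character(seq_len(n_pairs)), ])
  }
  sd0 <- function(m) apply(m, 1L, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  pairs <- data.frame(
    toxin_res = levels(tox_res)[(seq_len(n_pairs) - 1L) %% nlevels(tox_res) + 1L],
    channel_res = levels(cha_res)[(seq_len(n_pairs) - 1L) %/% nlevels(tox_res) + 1L],
    mean_coulomb = rowMeans(acc_c), mean_lj = rowMeans(acc_l),
    mean_total = rowMeans(acc_c + acc_l), sd_total = sd0(acc_c + acc_l),
    stringsAsFactors = FALSE)
  # toxin-residue marginals: per frame, sum pair energies over channel partners
  res_c <- rowsum(acc_c, pairs$toxin_res, reorder = FALSE)
  res_l <- rowsum(acc_l, pairs$toxin_res, reorder = FALSE)
  ord <- match(levels(tox_res), rownames(res_c))
  res_c <- res_c[ord, , drop = FALSE]
  res_l <- res_l[ord, , drop = FALSE]
  info <- s$atoms[it, ][!duplicated(keys[it]), c("chain", "resno", "resname")]
  residues <- data.frame(
    toxin_res = levels(tox_res), resname = info$resname, resno = info$resno,
    mean_coulomb = rowMeans(res_c), mean_lj = rowMeans(res_l),
    mean_total = rowMeans(res_c + res_l), sd_total = sd0(res_c + res_l),
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  structure(list(pairs = pairs, residues = residues, cutoff_nm = cutoff,
                 n_frames = length(use), burn_in = burn_in),
            class = "toxsel_energyprofile")
}

#' @export
print.toxsel_energyprofile <- function(x, ...) {
  cat(sprintf("<toxsel_energyprofile> %d toxin residues x %d channel residues, %d frames, cutoff %.2f nm\n",
              nrow(x$residues), nrow(x$pairs) / max(1L, nrow(x$residues)),
              x$n_frames, x$cutoff_nm))
  invisible(x)
}

#' Write / read an energy profile as TSV
#'
#' Writes the per-toxin-residue profile to `path` and the full pair matrix
#' to `<path>.pairs.tsv`.
#'
#' @param profile a `toxsel_energyprofile`.
#' @param path TSV file for the residue profile.
#' @export
write_energy_profile <- function(profile, path) {
  utils::write.table(profile$residues, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(profile$pairs, paste0(path, ".pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
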