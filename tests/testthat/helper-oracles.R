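# Independent brute-force oracles and shared fixtures. Oracles deliberately
# use different geometric machinery than the package (cross products instead
# of SVD normals, exhaustive loops, Euler-grid rotation search).

contact_key_set <- function(df) {
  sort(unique(paste(df$toxin_res, df$channel_res, df$kind)))
}

# a spec exercising every planted feature kind
full_plant_spec <- function(seed = 1L, occupancies = NULL) {
  kinds <- c("hbond", "salt_bridge", "salt_bridge_hbond", "cation_pi",
             "stacking", "stacking_t", "hydrophobic", "repulsion")
  if (is.null(occupancies)) occupancies <- rep(1, length(kinds))
  plant_spec(mapply(function(k, o) plant_feature(k, occupancy = o),
                    kinds, occupancies, SIMPLIFY = FALSE),
             n_channel_chains = 4L, seed = seed)
}

oracle_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oracle_ring_normal <- function(coords, ring) {
  # least-squares plane normal via the covariance eigenproblem (the package
  # uses svd of the centered coordinates; same definition, different routine)
  p <- coords[ring, , drop = FALSE]
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  ev <- eigen(crossprod(pc), symmetric = TRUE)
  list(centroid = ctr, normal = ev$vectors[, 3L])
}

fold90 <- function(ang) min(ang, 180 - ang)

# exhaustive all-pairs contact detection straight from the annotation
oracle_contacts <- function(annotation, coords, cr = contact_criteria()) {
  res <- annotation$residues
  ent <- vapply(res, function(r) r$entity, character(1))
  out <- character(0)
  dist2 <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (ti in names(res)[ent == "toxin"]) {
    for (ci in names(res)[ent == "channel"]) {
      ri <- res[[ti]]
      rj <- res[[ci]]
      hit <- function(kind) out <<- c(out, paste(ti, ci, kind))
      for (dir in 1:2) {
        dres <- if (dir == 1L) ri else rj
        ares <- if (dir == 1L) rj else ri
        if (nrow(dres$donors) > 0L) {
          for (k in seq_len(nrow(dres$donors))) {
            for (a in ares$acceptors) {
              d <- dres$donors[k, "D"]
              h <- dres$donors[k, "H"]
              if (dist2(d, a) <= cr$hbond_da_max &&
                  oracle_angle(coords[d, ], coords[h, ], coords[a, ]) >=
                    cr$hbond_dha_min) hit("hbond")
            }
          }
        }
      }
      for (g1 in ri$charged) for (g2 in rj$charged) {
        if (g1$sign * g2$sign < 0L) {
          dm <- Inf
          for (a in g1$atoms) for (b in g2$atoms) dm <- min(dm, dist2(a, b))
          if (dm <= cr$saltbridge_max) hit("salt_bridge")
        }
      }
      for (dir in 1:2) {
        cres <- if (dir == 1L) ri else rj
        rres <- if (dir == 1L) rj else ri
        for (g in cres$charged) {
          if (g$sign <= 0L) next
          cat_pos <- colMeans(coords[g$atoms, , drop = FALSE])
          for (ring in rres$rings) {
            geo <- oracle_ring_normal(coords, ring)
            v <- cat_pos - geo$centroid
            if (sqrt(sum(v^2)) <= cr$cationpi_max &&
                fold90(oracle_angle(geo$normal + geo$centroid, geo$centroid,
                                    cat_pos)) <= cr$cationpi_angle_max)
              hit("cation_pi")
          }
        }
      }
      for (r1 in ri$rings) for (r2 in rj$rings) {
        g1 <- oracle_ring_normal(coords, r1)
        g2 <- oracle_ring_normal(coords, r2)
        if (sqrt(sum((g1$centroid - g2$centroid)^2)) >
            cr$stacking_centroid_max) next
        ang <- fold90(oracle_angle(g1$normal, c(0, 0, 0), g2$normal))
        if (ang <= cr$stacking_parallel_max ||
            (ang >= cr$stacking_tshape_min && ang <= cr$stacking_tshape_max))
          hit("stacking")
      }
      if (length(ri$apolar) > 0L && length(rj$apolar) > 0L) {
        dm <- Inf
        for (a in ri$apolar) for (b in rj$apolar) dm <- min(dm, dist2(a, b))
        if (dm <= cr$hydrophobic_cc_max) hit("hydrophobic")
      }
    }
  }
  sort(unique(out))
}

# rotation-grid + Nelder-Mead RMSD minimization, independent of Kabsch/SVD
oracle_min_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  euler <- function(a) {
    cz1 <- cos(a[1]); sz1 <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz2 <- cos(a[3]); sz2 <- sin(a[3])
    Rz1 <- matrix(c(cz1, -sz1, 0, sz1, cz1, 0, 0, 0, 1), 3L, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, byrow = TRUE)
    Rz2 <- matrix(c(cz2, -sz2, 0, sz2, cz2, 0, 0, 0, 1), 3L, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  f <- function(a) sqrt(mean(rowSums((Pc %*% t(euler(a)) - Qc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13L)[-13L]
  gridy <- seq(0, pi, length.out = 7L)
  best <- NULL
  for (a1 in grid) for (a2 in gridy) for (a3 in grid) {
    v <- f(c(a1, a2, a3))
    if (is.null(best) || v < best$value) best <- list(par = c(a1, a2, a3),
                                                     value = v)
  }
  op <- stats::optim(best$par, f, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  min(best$value, op$value)
}

# in-memory force-field object for hand-built test structures
toy_forcefield <- function(tab) {
  structure(list(table = tab, coulomb_constant = COULOMB_CONSTANT,
                 combination_rule = "lorentz-berthelot"),
            class = "toxsel_forcefield")
}

# two single-atom "residues" (one toxin, one channel) at distance r_nm
point_charge_structure <- function(q1, q2, r_nm, sigma = 0.3, eps = 0) {
  atoms <- data.frame(serial = 1:2, name = c("Q1", "Q2"),
                      element = c("N", "N"), resname = c("XA", "XB"),
                      chain = c("A", "B"), resno = c(1L, 1L),
                      x = c(0, r_nm), y = 0, z = 0, stringsAsFactors = FALSE)
  s <- new_structure(atoms, entity_map = c(A = "toxin", B = "channel"))
  ff <- toy_forcefield(data.frame(
    resname = c("XA", "XB"), atomname = c("Q1", "Q2"), charge = c(q1, q2),
    sigma_nm = sigma, epsilon_kJmol = eps, stringsAsFactors = FALSE))
  assign_parameters(s, ff)
}

# alanine "dipeptide": two consecutive ALA residues from the bundled rosters
ala_dipeptide <- function() {
  mk <- function(resno, z) {
    data.frame(serial = NA_integer_,
               name = c("N", "H", "CA", "C", "O", "CB"),
               element = c("N", "H", "C", "C", "O", "C"), resname = "ALA",
               chain = "A", resno = resno,
               x = c(0, 0.05, 0.12, 0.25, 0.3, 0.1),
               y = c(0, 0.09, 0.1, 0.05, 0.12, 0.24), z = z,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(1L, 0), mk(2L, 0.38))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, entity_map = c(A = "toxin"))
}
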