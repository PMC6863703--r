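# Shared helpers: small sampling schemes, brute-force oracles, synthetic
# placement generators.  Oracles deliberately use plain nested loops and
# exhaustive pairwise comparisons, independent of the vectorized/hashed
# production code paths they check.

# a mid-density scheme that keeps toy pipelines fast but still yields
# hundreds of placements per interaction at g = 0.4
toy_scheme <- function() {
  sampling_scheme(distances = seq(2.6, 3.2, by = 0.2),
                  donor_angles = seq(140, 180, by = 10),
                  acceptor_angles = seq(100, 180, by = 10),
                  base_torsions = seq(0, 340, by = 20),
                  hbond_torsions = seq(0, 340, by = 20),
                  spins = seq(0, 300, by = 60),
                  orientation_angle_samples = 3,
                  orientation_torsion_samples = 5)
}

# diol two-group instance used across network/realize/match tests
toy_instance <- function(g = 0.4, scheme = toy_scheme()) {
  lig <- make_toy_ligand("diol")
  spec <- make_toy_spec("diol_pair")
  ligc <- canonical_ligand(attach_sites(lig, spec$ligand_sites))
  ps <- lapply(spec$groups$label, function(l)
    group_candidates(ligc, spec, l, scheme = scheme, g = g))
  names(ps) <- spec$groups$label
  fp <- filter_pairs(spec$edges[["e_g2_g1"]], ps$G2, ps$G1)
  nets <- assemble_networks(spec, ps, list(e_g2_g1 = fp$table), ligand = ligc)
  list(ligand = ligc, spec = spec, placements = ps, pairs = fp, networks = nets)
}

# deterministic pseudo-random rigid pose of a template (plain R arithmetic)
random_placement <- function(template, seed_vals, label = "R", edge = "rnd") {
  ax <- unit_vec_test(seed_vals[1:3])
  ang <- seed_vals[4] * 360
  R <- rot_axis_angle(ax, ang)
  t <- (seed_vals[5:7] - 0.5) * 12
  atoms <- template$atoms %*% t(R)
  atoms <- sweep(atoms, 2, t, `+`)
  rownames(atoms) <- rownames(template$atoms)
  hbnetforge:::new_placement(label, template$fg_name, rigid_transform(R, t), atoms,
                             grid_key = c(0L, 0L, 0L), source_edge = edge,
                             score = -seed_vals[8], ref_atom = template$heavy_atoms[1],
                             role_atom = template$heavy_atoms[1])
}

unit_vec_test <- function(v) v / sqrt(sum(v^2))

# place_atom with the documented degenerate-torsion rule: a collinear (a,b,c)
# reference triple is replaced by a deterministic perpendicular substitute
place_atom_safe_test <- function(a, b, c, bond, angle, dihedral) {
  cr <- c((b - a)[2] * (c - b)[3] - (b - a)[3] * (c - b)[2],
          (b - a)[3] * (c - b)[1] - (b - a)[1] * (c - b)[3],
          (b - a)[1] * (c - b)[2] - (b - a)[2] * (c - b)[1])
  if (sqrt(sum(cr^2)) < 1e-8)
    a <- b + as.numeric(hbnetforge:::arbitrary_perp(c - b))
  place_atom(a, b, c, bond, angle, dihedral)
}

rot_axis_angle <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# apply one global rigid motion to a ligand_model (before canonicalization)
move_ligand <- function(lig, R, t) {
  lig$atoms <- sweep(lig$atoms %*% t(R), 2, t, `+`)
  lig$canonical <- FALSE
  lig$frame <- NULL
  lig
}

move_scaffold <- function(sc, R, t) {
  mv <- function(m) {
    ok <- stats::complete.cases(m)
    m[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(R), 2, t, `+`)
    m
  }
  sc$N <- mv(sc$N); sc$CA <- mv(sc$CA); sc$C <- mv(sc$C); sc$O <- mv(sc$O)
  sc$canonical <- FALSE
  sc$frame <- NULL
  sc
}

## brute-force enumeration oracle ---------------------------------------------

# all-DOF-combination loop enumeration of hydrogen-bond placements with
# exhaustive pairwise grid dedup; returns list(keys = character, score = best
# score per key) sorted by key
oracle_hbond_keys <- function(ligand, site_id, fg, scheme, params = hbond_params(),
                              g = 1.0, clash_min = 2.7) {
  lig <- canonical_ligand(ligand)
  site <- lig$sites[[site_id]]
  tpl <- fg_template(fg)
  ss <- scheme_samples(scheme, site$role)
  lig_heavy <- lig$atoms[lig$elements != "H", , drop = FALSE]
  kept_keys <- character(0); kept_scores <- numeric(0)
  consider <- function(atoms, anchor) {
    # hydrogen-bond audit
    if (site$role == "acceptor") {
      geomL <- hbnetforge:::ligand_acceptor_geometry(lig, site)
      evs <- lapply(tpl$donors, function(en)
        hbond_eval(atoms[en[["heavy"]], ], atoms[en[["h"]], ], geomL$A, geomL$bases,
                   params, overlap = "reject"))
      ev_anchor <- evs[[which(vapply(tpl$donors, function(en) en[["heavy"]], "") == anchor)[1]]]
    } else {
      geomL <- hbnetforge:::ligand_donor_geometry(lig, site)
      accs <- Filter(function(en) en$heavy == anchor, tpl$acceptors)
      ev_anchor <- hbond_eval(geomL$D, geomL$H, atoms[accs[[1]]$heavy, ],
                              atoms[accs[[1]]$bases, , drop = FALSE], params,
                              overlap = "reject")
    }
    if (!ev_anchor$ok) return(invisible())
    # clash (interacting pair exempt)
    for (k in tpl$heavy_atoms) for (j in rownames(lig_heavy)) {
      if (k == anchor && j == site$atom) next
      if (sqrt(sum((atoms[k, ] - lig_heavy[j, ])^2)) < clash_min) return(invisible())
    }
    key <- paste(snap_to_grid(atoms[anchor, ], g), collapse = ",")
    hit <- match(key, kept_keys)
    if (is.na(hit)) {
      kept_keys <<- c(kept_keys, key); kept_scores <<- c(kept_scores, ev_anchor$score)
    } else if (ev_anchor$score < kept_scores[hit]) {
      kept_scores[hit] <<- ev_anchor$score
    }
    invisible()
  }
  if (site$role == "acceptor") {
    geomL <- hbnetforge:::ligand_acceptor_geometry(lig, site)
    A <- geomL$A; B <- geomL$bases[1, ]
    ref <- B + as.numeric(hbnetforge:::arbitrary_perp(A - B))
    for (en in tpl$donors) {
      Dt <- en[["heavy"]]; Ht <- en[["h"]]
      rDH <- sqrt(sum((tpl$atoms[Ht, ] - tpl$atoms[Dt, ])^2))
      perp_t <- as.numeric(hbnetforge:::arbitrary_perp(tpl$atoms[Ht, ] - tpl$atoms[Dt, ]))
      src <- rbind(tpl$atoms[Dt, ], tpl$atoms[Ht, ], tpl$atoms[Dt, ] + perp_t)
      for (d in ss$distances) for (psi in ss$acceptor_angles) for (phi1 in ss$base_torsions) {
        D <- place_atom(ref, B, A, d, psi, phi1)
        for (theta in ss$donor_angles) for (phi2 in ss$hbond_torsions) {
          beta <- asin(min(1, rDH * sin(theta * pi / 180) / d)) * 180 / pi
          H <- place_atom_safe_test(B, A, D, rDH, 180 - theta - beta, phi2)
          u <- (H - D) / sqrt(sum((H - D)^2))
          p0 <- as.numeric(hbnetforge:::arbitrary_perp(u))
          for (spin in ss$spins) {
            p <- as.numeric(rotate_about_axis(p0, c(0, 0, 0), u, spin))
            tr <- superpose_frames(src, rbind(D, H, D + p))
            consider(apply_transform(tr, tpl$atoms), Dt)
          }
        }
      }
    }
  } else {
    geomL <- hbnetforge:::ligand_donor_geometry(lig, site)
    D <- geomL$D; H <- geomL$H
    rDH <- sqrt(sum((H - D)^2))
    ref <- D + as.numeric(hbnetforge:::arbitrary_perp(H - D))
    for (en in tpl$acceptors) {
      At <- en$heavy; Bt <- en$bases[1]
      rAB <- sqrt(sum((tpl$atoms[Bt, ] - tpl$atoms[At, ])^2))
      perp_t <- as.numeric(hbnetforge:::arbitrary_perp(tpl$atoms[Bt, ] - tpl$atoms[At, ]))
      src <- rbind(tpl$atoms[At, ], tpl$atoms[Bt, ], tpl$atoms[At, ] + perp_t)
      for (d in ss$distances) for (theta in ss$donor_angles) for (phi2 in ss$hbond_torsions) {
        disc <- d^2 - (rDH * sin(theta * pi / 180))^2
        if (disc <= 0) next
        hh <- rDH * cos(theta * pi / 180) + sqrt(disc)
        A <- place_atom(ref, D, H, hh, theta, phi2)
        for (psi in ss$acceptor_angles) for (phi1 in ss$base_torsions) {
          Bw <- place_atom_safe_test(D, H, A, rAB, psi, phi1)
          u <- (Bw - A) / sqrt(sum((Bw - A)^2))
          p0 <- as.numeric(hbnetforge:::arbitrary_perp(u))
          for (spin in ss$spins) {
            p <- as.numeric(rotate_about_axis(p0, c(0, 0, 0), u, spin))
            tr <- superpose_frames(src, rbind(A, Bw, A + p))
            consider(apply_transform(tr, tpl$atoms), At)
          }
        }
      }
    }
  }
  ord <- order(kept_keys)
  list(keys = kept_keys[ord], score = kept_scores[ord])
}

# loop-and-pairwise-dedup oracle for covalent placements
oracle_covalent_keys <- function(ligand, site_id, fg, scheme, g = 1.0, clash_min = 2.7) {
  lig <- canonical_ligand(ligand)
  site <- lig$sites[[site_id]]
  tpl <- fg_template(fg)
  Cst <- lig$atoms[site$atom, ]
  aux1 <- lig$atoms[site$aux[1], ]
  aux2 <- if (length(site$aux) >= 2) lig$atoms[site$aux[2], ]
          else aux1 + as.numeric(hbnetforge:::arbitrary_perp(Cst - aux1))
  lig_heavy <- lig$atoms[lig$elements != "H", , drop = FALSE]
  keys <- character(0)
  for (tor in scheme$covalent_torsions) {
    Nx <- place_atom(aux2, aux1, Cst, scheme$covalent_length, scheme$covalent_angle, tor)
    CE <- place_atom(aux1, Cst, Nx, 1.49, 109.5, 180)
    ok <- TRUE
    for (j in rownames(lig_heavy)) {
      if (!(j %in% c(site$atom, site$aux)) &&
          sqrt(sum((Nx - lig_heavy[j, ])^2)) < clash_min) ok <- FALSE
      if (j != site$atom && sqrt(sum((CE - lig_heavy[j, ])^2)) < clash_min) ok <- FALSE
    }
    if (!ok) next
    key <- paste(snap_to_grid(Nx, g), collapse = ",")
    if (!key %in% keys) keys <- c(keys, key)
  }
  sort(keys)
}

# all-pairs O(n^2) oracle for filter_pairs
oracle_pairs <- function(edge, placements_a, placements_b, params = hbond_params()) {
  tpl_a <- fg_template(placements_a[[1]]$fg_name)
  tpl_b <- fg_template(placements_b[[1]]$fg_name)
  rows <- list()
  for (i in seq_along(placements_a)) for (j in seq_along(placements_b)) {
    best <- NULL
    for (dn in tpl_a$donors) {
      if (!all(c(dn[["heavy"]], dn[["h"]]) %in% rownames(placements_a[[i]]$atoms))) next
      for (ac in tpl_b$acceptors) {
        ev <- hbond_eval(placements_a[[i]]$atoms[dn[["heavy"]], ],
                         placements_a[[i]]$atoms[dn[["h"]], ],
                         placements_b[[j]]$atoms[ac$heavy, ],
                         placements_b[[j]]$atoms[ac$bases, , drop = FALSE],
                         params, overlap = "reject")
        if (ev$ok && (is.null(best) || ev$score < best)) best <- ev$score
      }
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(ia = i, ib = j, score = best)
  }
  if (!length(rows)) return(data.frame(ia = integer(0), ib = integer(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$ia, out$ib), , drop = FALSE]
}

# Cartesian-product oracle for assemble_networks: returns sorted signature
# strings "i1,i2,..." of all valid assignments
oracle_networks <- function(spec, placement_sets, pair_tables, clash_threshold = 2.7) {
  labels <- spec$groups$label
  gg <- Filter(function(e) !hbnetforge:::edge_touches_ligand(e), spec$edges)
  grids <- lapply(labels, function(l) seq_along(placement_sets[[l]]))
  if (any(!lengths(grids))) return(character(0))
  combos <- do.call(expand.grid, grids)
  sig <- character(0)
  for (r in seq_len(nrow(combos))) {
    idx <- as.integer(combos[r, ])
    ok <- TRUE
    pair_atoms <- list()
    for (e in gg) {
      ia <- idx[match(e$a$label, labels)]; ib <- idx[match(e$b$label, labels)]
      tab <- pair_tables[[e$edge_id]]$pairs
      hit <- which(tab$ia == ia & tab$ib == ib)
      if (!length(hit)) { ok <- FALSE; break }
      key <- paste(sort(c(e$a$label, e$b$label)), collapse = "~")
      pair_atoms[[key]] <- rbind(pair_atoms[[key]],
                                 c(tab$donor_atom[hit[1]], tab$acceptor_atom[hit[1]]))
    }
    if (ok && clash_threshold > 0) {
      for (i in seq_along(labels)) for (j in seq_len(i - 1)) {
        key <- paste(sort(c(labels[i], labels[j])), collapse = "~")
        if (clash_check(placement_sets[[labels[i]]][[idx[i]]]$atoms,
                        placement_sets[[labels[j]]][[idx[j]]]$atoms,
                        clash_threshold, exempt_pairs = pair_atoms[[key]])) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) sig <- c(sig, paste(idx, collapse = ","))
  }
  sort(sig)
}
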