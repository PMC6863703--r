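# Grid-complete enumeration of functional-group placements.
#
# A placement is one rigid pose of a functional-group template satisfying one
# specified interaction with the ligand.  The continuous degrees of freedom of
# a hydrogen bond are discretized by a sampling scheme:
#
#   distance        donor-heavy -- acceptor-heavy separation
#   donor angle     D-H...A
#   acceptor angle  base-A...H
#   two torsions    about the acceptor-base axis and about the H-bond axis
#   spin            rotation of the group about its own interacting bond
#
# Candidate poses are generated in the ligand's canonical local frame,
# audited against the hydrogen-bond criteria, clash-filtered against the
# ligand, and deduplicated on the grid cell of the group's interacting heavy
# atom (the placement's reference atom) at the user-specified grid spacing.

#' Sampling scheme for placement enumeration
#'
#' Of the six degrees of freedom of a hydrogen-bonded pose, three determine
#' the position of the group's contact atom and three only rotate the group
#' about it.  Which three are positional depends on the direction of the
#' bond: when the ligand accepts, the contact (donor) atom is moved by
#' (distance, acceptor angle, base torsion); when the ligand donates, the
#' contact (acceptor) atom is moved by (distance, donor angle, H-bond-axis
#' torsion).  The positional triple is always sampled at the full density of
#' its lists, so the accessible shell of contact-atom grid cells is
#' saturated; the remaining orientational degrees of freedom are subsampled
#' (evenly spaced over their lists) to \code{orientation_angle_samples} and
#' \code{orientation_torsion_samples} values, and only the best-scoring pose
#' per grid cell survives deduplication.  The defaults are calibrated so one
#' interaction enumerated at a 0.2 A grid yields on the order of 10^3-10^4
#' unique placements.
#'
#' @param distances donor-heavy to acceptor-heavy distance samples (Angstrom)
#' @param donor_angles D-H...A angle samples (degrees)
#' @param acceptor_angles base-A...H angle samples (degrees)
#' @param base_torsions torsion samples about the acceptor-base axis (degrees)
#' @param hbond_torsions torsion samples about the H-bond axis (degrees)
#' @param spins spin samples of the group about its interacting bond (degrees)
#' @param orientation_angle_samples values kept from the orientational angle
#'   list (NULL keeps all)
#' @param orientation_torsion_samples values kept from the orientational
#'   torsion list (NULL keeps all)
#' @param covalent_torsions torsion samples for covalent attachments (degrees)
#' @param covalent_length covalent bond length (Angstrom)
#' @param covalent_angle covalent bond angle at the ligand atom (degrees)
#' @return object of class \code{sampling_scheme}
#' @export
sampling_scheme <- function(distances = seq(2.6, 3.2, by = 0.1),
                            donor_angles = seq(124, 180, by = 4),
                            acceptor_angles = seq(100, 180, by = 5),
                            base_torsions = seq(0, 355, by = 5),
                            hbond_torsions = seq(0, 355, by = 5),
                            spins = seq(0, 300, by = 60),
                            orientation_angle_samples = 3L,
                            orientation_torsion_samples = 6L,
                            covalent_torsions = seq(0, 330, by = 30),
                            covalent_length = 1.5,
                            covalent_angle = 109.5) {
  for (v in list(distances, donor_angles, acceptor_angles, base_torsions,
                 hbond_torsions, spins, covalent_torsions))
    if (!length(v) || !all(is.finite(v)))
      stop("hbnetforge value error: all sampling lists must be non-empty and finite")
  if (any(donor_angles <= 0 | donor_angles > 180) || any(acceptor_angles <= 0 | acceptor_angles > 180))
    stop("hbnetforge value error: angle samples must lie in (0, 180]")
  structure(list(distances = distances, donor_angles = donor_angles,
                 acceptor_angles = acceptor_angles, base_torsions = base_torsions,
                 hbond_torsions = hbond_torsions, spins = spins,
                 orientation_angle_samples = orientation_angle_samples,
                 orientation_torsion_samples = orientation_torsion_samples,
                 covalent_torsions = covalent_torsions,
                 covalent_length = covalent_length, covalent_angle = covalent_angle),
            class = "sampling_scheme")
}

# evenly spaced subsample of a sampling list (NULL or >= length keeps all)
subsample_list <- function(v, m) {
  if (is.null(m) || m >= length(v)) return(v)
  v[unique(round(seq(1L, length(v), length.out = m)))]
}

#' The concrete sample lists a scheme uses against a ligand site
#'
#' Resolves the positional/orientational split of \code{sampling_scheme} for
#' a given site role, returning the exact lists the enumeration sweeps.
#'
#' @param scheme a \code{sampling_scheme}
#' @param site_role "acceptor" or "donor" (the ligand side of the bond)
#' @return named list: distances, donor_angles, acceptor_angles,
#'   base_torsions, hbond_torsions, spins
#' @export
scheme_samples <- function(scheme, site_role) {
  oa <- scheme$orientation_angle_samples
  ot <- scheme$orientation_torsion_samples
  if (site_role == "acceptor") {
    list(distances = scheme$distances,
         donor_angles = subsample_list(scheme$donor_angles, oa),
         acceptor_angles = scheme$acceptor_angles,
         base_torsions = scheme$base_torsions,
         hbond_torsions = subsample_list(scheme$hbond_torsions, ot),
         spins = scheme$spins)
  } else {
    list(distances = scheme$distances,
         donor_angles = scheme$donor_angles,
         acceptor_angles = subsample_list(scheme$acceptor_angles, oa),
         base_torsions = subsample_list(scheme$base_torsions, ot),
         hbond_torsions = scheme$hbond_torsions,
         spins = scheme$spins)
  }
}

#' A deliberately coarse scheme for small exactly-checkable instances
#' @param n samples per degree of freedom
#' @return a \code{sampling_scheme}
#' @export
coarse_scheme <- function(n = 2) {
  sampling_scheme(distances = seq(2.7, 3.1, length.out = n),
                  donor_angles = seq(180, 150, length.out = n),
                  acceptor_angles = seq(170, 120, length.out = n),
                  base_torsions = seq(0, 180, length.out = n),
                  hbond_torsions = seq(0, 180, length.out = n),
                  spins = seq(0, 180, length.out = n),
                  orientation_angle_samples = NULL,
                  orientation_torsion_samples = NULL,
                  covalent_torsions = seq(0, 180, length.out = n))
}

new_placement <- function(group_label, fg_name, transform, atoms, grid_key,
                          source_edge, score, ref_atom, role_atom, variant = "template") {
  structure(list(group_label = group_label, fg_name = fg_name,
                 transform = transform, atoms = atoms, grid_key = grid_key,
                 source_edge = source_edge, score = score, ref_atom = ref_atom,
                 role_atom = role_atom, variant = variant),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("Placement of %s (%s) via edge %s; key (%s); score %.3f\n",
              x$fg_name, x$group_label, x$source_edge,
              paste(x$grid_key, collapse = ","), x$score))
  invisible(x)
}

# local coordinates of template atoms in the frame anchored at `origin_atom`
# with primary axis toward `axis_atom`
template_local_coords <- function(template, origin_atom, axis_atom) {
  o <- template$atoms[origin_atom, ]
  e1 <- unit_vec(template$atoms[axis_atom, ] - o)
  e2 <- as.numeric(arbitrary_perp(e1))
  E <- cbind(e1, e2, vcross(e1, e2))
  sweep(template$atoms, 2L, o) %*% E   # rows: local coords
}

# world coordinates of every template atom for n poses given anchor positions
# P (n x 3), primary axis u (n x 3 unit), secondary axis f2 (n x 3 unit)
realize_template_rows <- function(local, P, u, f2) {
  f3 <- row_cross(u, f2)
  out <- vector("list", nrow(local))
  names(out) <- rownames(local)
  for (k in seq_len(nrow(local))) {
    l <- local[k, ]
    out[[k]] <- P + l[1L] * u + l[2L] * f2 + l[3L] * f3
  }
  out
}

# minimum-distance clash filter of realized group heavy atoms against ligand
# heavy atoms; the interacting heavy pair is exempt
clash_ok_rows <- function(atom_rows, template, ligand, anchor_atom, site_atom, clash_min) {
  lig_heavy <- rownames(ligand$atoms)[ligand$elements != "H"]
  n <- nrow(atom_rows[[1L]])
  ok <- rep(TRUE, n)
  for (k in template$heavy_atoms) {
    W <- atom_rows[[k]]
    for (j in lig_heavy) {
      if (k == anchor_atom && j == site_atom) next
      L <- ligand$atoms[j, ]
      dx <- W[, 1L] - L[1L]; dy <- W[, 2L] - L[2L]; dz <- W[, 3L] - L[3L]
      ok <- ok & (dx * dx + dy * dy + dz * dz >= clash_min^2)
    }
  }
  ok
}

# deterministic best-per-key dedup; returns indices of survivors ordered
# lexicographically by integer key
dedupe_indices <- function(key_mat, score) {
  key_cols <- lapply(seq_len(ncol(key_mat)), function(j) key_mat[, j])
  ks <- key_string(key_mat)
  ord <- do.call(order, c(key_cols, list(score, seq_along(score))))
  keep <- ord[!duplicated(ks[ord])]
  keep
}

# candidate pose block for one (site, donor-or-acceptor template atom) option;
# returns parallel vectors/matrices for all scheme combinations that pass the
# hydrogen-bond audit and the ligand clash filter
generate_hbond_candidates <- function(ligand, site, template, role_entry,
                                      scheme, params, clash_min) {
  site_is_acceptor <- site$role == "acceptor"
  ss <- scheme_samples(scheme, site$role)
  if (site_is_acceptor) {
    geomL <- ligand_acceptor_geometry(ligand, site)
    A <- geomL$A; B <- geomL$bases[1L, ]
    Dt <- role_entry[["heavy"]]; Ht <- role_entry[["h"]]
    rDH <- vnorm(template$atoms[Ht, ] - template$atoms[Dt, ])
    ref <- B + as.numeric(arbitrary_perp(A - B))
    g1 <- expand.grid(d = ss$distances, psi = ss$acceptor_angles,
                      phi1 = ss$base_torsions, KEEP.OUT.ATTRS = FALSE)
    D1 <- place_atoms_n(ref, B, A, g1$d, g1$psi, g1$phi1)
    g2 <- expand.grid(i1 = seq_len(nrow(g1)), theta = ss$donor_angles,
                      phi2 = ss$hbond_torsions, KEEP.OUT.ATTRS = FALSE)
    # place H so the realized donor angle D-H...A equals the sample exactly
    # (law of sines in the D-H-A triangle)
    dvec <- g1$d[g2$i1]
    beta <- rad2deg(asin(pmin(1, rDH * sin(deg2rad(g2$theta)) / dvec)))
    alpha <- 180 - g2$theta - beta    # angle A-D-H at the donor heavy atom
    H2 <- place_atoms_safe(B, A, D1[g2$i1, , drop = FALSE], rDH, alpha, g2$phi2)
    g3 <- expand.grid(i2 = seq_len(nrow(g2)), spin = ss$spins, KEEP.OUT.ATTRS = FALSE)
    Dx <- D1[g2$i1[g3$i2], , drop = FALSE]
    Hx <- H2[g3$i2, , drop = FALSE]
    u <- row_unit(Hx - Dx)
    f2 <- rotate_rows(arbitrary_perp(u), u, g3$spin)
    local <- template_local_coords(template, Dt, Ht)
    rows <- realize_template_rows(local, Dx, u, f2)
    ev <- hbond_geom_n(Dx, Hx, A,
                       lapply(seq_len(nrow(geomL$bases)), function(i) geomL$bases[i, , drop = FALSE]),
                       params)
    anchor <- Dt
  } else {
    geomL <- ligand_donor_geometry(ligand, site)
    D <- geomL$D; H <- geomL$H
    rDH <- vnorm(H - D)
    At <- role_entry$heavy; Bt <- role_entry$bases[1L]
    rAB <- vnorm(template$atoms[Bt, ] - template$atoms[At, ])
    ref <- D + as.numeric(arbitrary_perp(H - D))
    g1 <- expand.grid(d = ss$distances, theta = ss$donor_angles,
                      phi2 = ss$hbond_torsions, KEEP.OUT.ATTRS = FALSE)
    th <- deg2rad(g1$theta)
    disc <- g1$d^2 - (rDH * sin(th))^2
    hh <- rDH * cos(th) + sqrt(pmax(disc, 0))
    A1 <- place_atoms_n(ref, D, H, hh, g1$theta, g1$phi2)
    keep1 <- disc > 0
    g2 <- expand.grid(i1 = which(keep1), psi = ss$acceptor_angles,
                      phi1 = ss$base_torsions, KEEP.OUT.ATTRS = FALSE)
    Ax <- A1[g2$i1, , drop = FALSE]
    B2 <- place_atoms_safe(D, H, Ax, rAB, g2$psi, g2$phi1)
    g3 <- expand.grid(i2 = seq_len(nrow(g2)), spin = ss$spins, KEEP.OUT.ATTRS = FALSE)
    Ax <- Ax[g3$i2, , drop = FALSE]
    Bx <- B2[g3$i2, , drop = FALSE]
    u <- row_unit(Bx - Ax)
    f2 <- rotate_rows(arbitrary_perp(u), u, g3$spin)
    local <- template_local_coords(template, At, Bt)
    rows <- realize_template_rows(local, Ax, u, f2)
    base_names <- role_entry$bases
    ev <- hbond_geom_n(D, H, Ax, rows[base_names], params)
    anchor <- At
  }
  axis_atom <- if (site_is_acceptor) role_entry[["h"]] else role_entry$bases[1L]
  ok <- ev$ok & clash_ok_rows(rows, template, ligand, anchor, site$atom, clash_min)
  list(rows = lapply(rows, function(m) m[ok, , drop = FALSE]),
       score = ev$score[ok], anchor = anchor, axis_atom = axis_atom,
       u = u[ok, , drop = FALSE], f2 = f2[ok, , drop = FALSE])
}

#' Enumerate hydrogen-bond placements of a functional group at a ligand site
#'
#' Generates every combination of the sampling scheme's degrees of freedom for
#' each role-compatible template atom, audits each candidate against the
#' hydrogen-bond criteria and a ligand clash filter, and deduplicates on the
#' grid cell of the group's interacting heavy atom at spacing \code{g},
#' retaining the best-scoring pose per cell.  Output is ordered
#' lexicographically by grid key.
#'
#' @param ligand a \code{ligand_model} with sites attached
#' @param site a ligand site id or \code{interaction_site} (role donor or
#'   acceptor)
#' @param group group descriptor: a functional-group name, or a list with
#'   \code{label}, \code{fg} and optionally \code{atom} (a specific template
#'   atom; default "auto" tries all role-compatible atoms)
#' @param scheme a \code{\link{sampling_scheme}}
#' @param params an \code{\link{hbond_params}}
#' @param g grid spacing (Angstrom)
#' @param clash_min minimum allowed heavy-atom distance to the ligand
#'   (Angstrom), the interacting pair exempt
#' @param edge_id recorded as the placement's source edge
#' @return list of \code{placement} objects (in the ligand canonical frame)
#' @export
enumerate_hbond_placements <- function(ligand, site, group, scheme = sampling_scheme(),
                                       params = hbond_params(), g = 0.2,
                                       clash_min = 2.7, edge_id = NULL) {
  if (is.character(group)) group <- list(label = group, fg = group)
  if (is.null(group$atom)) group$atom <- "auto"
  if (is.character(site)) site <- ligand_site(ligand, site)
  ligand <- canonical_ligand(ligand)
  template <- fg_template(group$fg)
  if (!site$role %in% c("donor", "acceptor"))
    stop("hbnetforge spec error: hbond enumeration needs a donor or acceptor ligand site")
  group_role <- if (site$role == "acceptor") "donor" else "acceptor"
  entries <- fg_role_atoms(template, group_role)
  if (!identical(group$atom, "auto")) {
    keep <- vapply(entries, function(en) en[["heavy"]] == group$atom, TRUE)
    entries <- entries[keep]
  }
  if (!length(entries))
    stop(sprintf("hbnetforge spec error: group '%s' (%s) has no %s atom%s for this site",
                 group$label, group$fg, group_role,
                 if (identical(group$atom, "auto")) "" else sprintf(" named '%s'", group$atom)))
  if (is.null(edge_id)) edge_id <- sprintf("%s:%s", site$site_id, group$label)

  all_keys <- NULL; all_scores <- numeric(0)
  blocks <- list()
  for (ei in seq_along(entries)) {
    cand <- generate_hbond_candidates(ligand, site, template, entries[[ei]],
                                      scheme, params, clash_min)
    n <- length(cand$score)
    if (n == 0L) next
    keys <- snap_to_grid(cand$rows[[cand$anchor]], g)
    blocks[[length(blocks) + 1L]] <- list(cand = cand, keys = keys, entry = ei)
    all_keys <- rbind(all_keys, keys)
    all_scores <- c(all_scores, cand$score)
  }
  if (is.null(all_keys)) return(list())
  keep <- dedupe_indices(all_keys, all_scores)
  # map flat indices back into blocks
  sizes <- vapply(blocks, function(b) length(b$cand$score), 1L)
  offsets <- cumsum(c(0L, sizes))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    bi <- max(which(offsets < i))
    local_i <- i - offsets[bi]
    b <- blocks[[bi]]
    out[[j]] <- build_placement(b$cand, template, local_i, b$keys[local_i, ],
                                group$label, edge_id)
  }
  # order lexicographically on grid key (dedupe_indices already orders by key)
  out
}

build_placement <- function(cand, template, i, key, group_label, edge_id) {
  atoms <- do.call(rbind, lapply(cand$rows, function(m) m[i, ]))
  rownames(atoms) <- names(cand$rows)
  f3 <- vcross(cand$u[i, ], cand$f2[i, ])
  Fw <- cbind(cand$u[i, ], cand$f2[i, ], f3)
  o <- template$atoms[cand$anchor, ]
  # template frame axes (same construction as template_local_coords)
  e1t <- unit_vec(template$atoms[cand$axis_atom, ] - o)
  e2t <- as.numeric(arbitrary_perp(e1t))
  Et <- cbind(e1t, e2t, vcross(e1t, e2t))
  R <- Fw %*% t(Et)
  sv <- svd(R); R <- sv$u %*% t(sv$v)
  tr <- rigid_transform(R, atoms[cand$anchor, ] - as.numeric(R %*% o))
  new_placement(group_label, template$fg_name, tr, atoms, as.integer(key),
                edge_id, cand$score[i], cand$anchor,
                role_atom = cand$anchor)
}

#' Enumerate covalent placements of a functional group at a ligand site
#'
#' The covalent bond is built at a fixed length and ideal tetrahedral angle;
#' only the torsion about the framing bond of the attachment site is sampled.
#' For the primary amine, one hydrogen is replaced by the bond to the ligand
#' and the remaining substituents are staggered against the ligand frame.
#'
#' @inheritParams enumerate_hbond_placements
#' @param site a ligand site with role \code{covalent_attachment}
#' @return list of \code{placement} objects
#' @export
enumerate_covalent_placements <- function(ligand, site, group, scheme = sampling_scheme(),
                                          g = 0.2, clash_min = 2.7, edge_id = NULL) {
  if (is.character(group)) group <- list(label = group, fg = group)
  if (is.character(site)) site <- ligand_site(ligand, site)
  if (site$role != "covalent_attachment")
    stop("hbnetforge spec error: covalent enumeration needs a covalent_attachment site")
  ligand <- canonical_ligand(ligand)
  template <- fg_template(group$fg)
  if (is.null(template$covalent_atom))
    stop(sprintf("hbnetforge spec error: group '%s' (%s) has no attachment-capable atom",
                 group$label, group$fg))
  if (is.null(edge_id)) edge_id <- sprintf("%s:%s", site$site_id, group$label)
  Cst <- ligand$atoms[site$atom, ]
  aux1 <- ligand$atoms[site$aux[1L], ]
  aux2 <- if (length(site$aux) >= 2L) ligand$atoms[site$aux[2L], ]
          else aux1 + as.numeric(arbitrary_perp(Cst - aux1))
  tor <- scheme$covalent_torsions
  Nx <- place_atoms_n(aux2, aux1, Cst, scheme$covalent_length, scheme$covalent_angle, tor)
  n <- nrow(Nx)
  cov <- template$covalent_atom
  att <- template$attachment
  # substituents staggered about the new bond (anti attachment, gauche hydrogens)
  CEx <- place_atoms_n(aux1, Cst, Nx, 1.49, 109.5, 180)
  H1x <- place_atoms_n(aux1, Cst, Nx, 1.01, 109.5, 60)
  H2x <- place_atoms_n(aux1, Cst, Nx, 1.01, 109.5, -60)
  rows <- list(Nx, CEx, H1x, H2x)
  names(rows) <- c(cov, att, "HZ1", "HZ2")
  ok <- rep(TRUE, n)
  lig_heavy <- setdiff(rownames(ligand$atoms)[ligand$elements != "H"], site$atom)
  # atoms bonded to the attachment carbon are legitimate 1-3 contacts of the
  # newly bonded nucleophile
  exempt_cov <- c(site$atom, site$aux)
  for (k in c(cov, att)) {
    W <- rows[[k]]
    lig_check <- if (k == cov) setdiff(lig_heavy, exempt_cov) else lig_heavy
    for (j in lig_check) {
      L <- ligand$atoms[j, ]
      d2 <- (W[, 1L] - L[1L])^2 + (W[, 2L] - L[2L])^2 + (W[, 3L] - L[3L])^2
      ok <- ok & (d2 >= clash_min^2)
    }
  }
  score <- rep(0, n)
  keys <- snap_to_grid(Nx, g)
  idx_ok <- which(ok)
  if (!length(idx_ok)) return(list())
  keep <- idx_ok[dedupe_indices(keys[idx_ok, , drop = FALSE], score[idx_ok])]
  lapply(keep, function(i) {
    atoms <- do.call(rbind, lapply(rows, function(m) m[i, ]))
    rownames(atoms) <- names(rows)
    src <- rbind(template$atoms[cov, ], template$atoms[att, ],
                 template$atoms[template$donors[[1L]][["h"]], ])
    dst <- rbind(atoms[cov, ], atoms[att, ], atoms["HZ1", ])
    tr <- superpose_frames(src, dst)
    new_placement(group$label, template$fg_name, tr, atoms,
                  as.integer(keys[i, ]), edge_id, 0, cov, cov,
                  variant = "covalent")
  })
}

#' Deduplicate placements on the grid
#'
#' At most one placement is retained per distinct grid key; the survivor is
#' the best-scoring (most negative) pose for its cell, with deterministic
#' tie-breaking, and the output is ordered lexicographically by key.
#'
#' @param placements list of \code{placement} objects of one functional group
#' @param g grid spacing (Angstrom)
#' @return deduplicated list of placements with keys recomputed at \code{g}
#' @export
dedupe_on_grid <- function(placements, g) {
  if (!length(placements)) return(placements)
  fgs <- unique(vapply(placements, function(p) p$fg_name, ""))
  if (length(fgs) != 1L)
    stop("hbnetforge error: dedupe_on_grid expects placements of a single functional group")
  keys <- do.call(rbind, lapply(placements, function(p)
    snap_to_grid(p$atoms[p$ref_atom, ], g)))
  scores <- vapply(placements, function(p) p$score, 1)
  keep <- dedupe_indices(keys, scores)
  out <- placements[keep]
  for (j in seq_along(out)) out[[j]]$grid_key <- as.integer(keys[keep[j], ])
  out
}

## Per-edge audit of a realized placement -------------------------------------

# evaluate one group-ligand edge for a concrete placement (used for post-hoc
# audits and for groups participating in several ligand edges)
placement_edge_ok <- function(placement, edge, ligand, params = hbond_params(),
                              cov_window = c(1.2, 1.8)) {
  ligand <- canonical_ligand(ligand)
  template <- fg_template(placement$fg_name)
  if (edge$kind == "covalent") {
    site <- ligand$sites[[edge$a$site]]
    d <- vnorm(placement$atoms[template$covalent_atom, ] - ligand$atoms[site$atom, ])
    return(list(ok = d >= cov_window[1L] && d <= cov_window[2L], score = 0))
  }
  lig_end <- if (edge$a$type == "ligand") edge$a else edge$b
  grp_end <- if (edge$a$type == "ligand") edge$b else edge$a
  site <- ligand$sites[[lig_end$site]]
  best <- list(ok = FALSE, score = 0)
  if (site$role == "acceptor") {
    geomL <- ligand_acceptor_geometry(ligand, site)
    entries <- template$donors
    if (!identical(grp_end$atom, "auto"))
      entries <- Filter(function(en) en[["heavy"]] == grp_end$atom, entries)
    for (en in entries) {
      if (!en[["heavy"]] %in% rownames(placement$atoms) ||
          !en[["h"]] %in% rownames(placement$atoms)) next
      ev <- hbond_eval(placement$atoms[en[["heavy"]], ], placement$atoms[en[["h"]], ],
                       geomL$A, geomL$bases, params)
      if (ev$ok && ev$score < best$score) best <- list(ok = TRUE, score = ev$score)
    }
  } else {
    geomL <- ligand_donor_geometry(ligand, site)
    entries <- template$acceptors
    if (!identical(grp_end$atom, "auto"))
      entries <- Filter(function(en) en$heavy == grp_end$atom, entries)
    for (en in entries) {
      if (!en$heavy %in% rownames(placement$atoms)) next
      bases <- placement$atoms[intersect(en$bases, rownames(placement$atoms)), , drop = FALSE]
      ev <- hbond_eval(geomL$D, geomL$H, placement$atoms[en$heavy, ], bases, params)
      if (ev$ok && ev$score < best$score) best <- list(ok = TRUE, score = ev$score)
    }
  }
  best
}

#' Candidate placements of one group across all of its ligand edges
#'
#' Enumerates placements from each ligand edge of the group, keeps only
#' placements satisfying every other ligand edge of that group (a group must
#' satisfy all of its specified interactions with a single pose), pools them
#' and deduplicates on the grid.
#'
#' @param ligand a \code{ligand_model}
#' @param spec an \code{active_site_spec}
#' @param label group label
#' @param scheme,params,g,clash_min see \code{\link{enumerate_hbond_placements}}
#' @return list of placements
#' @export
group_candidates <- function(ligand, spec, label, scheme = sampling_scheme(),
                             params = hbond_params(), g = 0.2, clash_min = 2.7) {
  ligand <- canonical_ligand(attach_sites(ligand, spec$ligand_sites))
  edges <- group_edges(spec, label, ligand_only = TRUE)
  if (!length(edges))
    stop(sprintf("hbnetforge spec error: group '%s' has no ligand edge to enumerate from", label))
  fg <- group_fg(spec, label)
  pool <- list()
  for (edge in edges) {
    grp_end <- if (edge$a$type == "group") edge$a else edge$b
    lig_end <- if (edge$a$type == "ligand") edge$a else edge$b
    site <- ligand$sites[[lig_end$site]]
    grp <- list(label = label, fg = fg, atom = grp_end$atom)
    pl <- if (edge$kind == "covalent")
      enumerate_covalent_placements(ligand, site, grp, scheme, g, clash_min,
                                    edge_id = edge$edge_id)
    else
      enumerate_hbond_placements(ligand, site, grp, scheme, params, g, clash_min,
                                 edge_id = edge$edge_id)
    others <- Filter(function(e) e$edge_id != edge$edge_id, edges)
    if (length(others)) {
      keep <- vapply(pl, function(p)
        all(vapply(others, function(e) placement_edge_ok(p, e, ligand, params)$ok, TRUE)), TRUE)
      pl <- pl[keep]
    }
    pool <- c(pool, pl)
  }
  dedupe_on_grid(pool, g)
}
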