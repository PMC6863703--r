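# Deterministic generators of toy ligands, ideal helical scaffolds and
# planted-network scaffolds.  Every stage of the pipeline is testable from
# these generators alone; no external structure files are required.

#' Catalogue of built-in fixture recipes
#'
#' @return data.frame of fixture names with their expected properties
#' @export
fixture_recipes <- function() {
  data.frame(
    name = c("diol", "keto_phosphate", "carbinolamine_ts"),
    kind = "ligand",
    n_donor_sites = c(2L, 1L, 1L),
    n_acceptor_sites = c(2L, 3L, 2L),
    n_covalent_sites = c(0L, 0L, 1L),
    stringsAsFactors = FALSE)
}

#' Build a toy ligand
#'
#' Three hand-built minimal molecules with annotated interaction sites:
#' \describe{
#'   \item{diol}{a vicinal diol; 2 hydroxyl donors + 2 acceptors}
#'   \item{keto_phosphate}{a ketone + phosphate monoester; >= 3 acceptors}
#'   \item{carbinolamine_ts}{a tetrahedral carbon mimicking a carbinolamine
#'     intermediate: 1 covalent attachment point for a nucleophilic amine,
#'     an oxyanion-like acceptor and a distal hydroxyl}
#' }
#' Coordinates are chemically sensible ideal geometry; repeated calls return
#' identical coordinates.
#'
#' @param name one of \code{fixture_recipes()$name}
#' @return a \code{ligand_model} with sites attached
#' @export
make_toy_ligand <- function(name) {
  if (name == "diol") {
    C1 <- c(0, 0, 0)
    C2 <- c(1.53, 0, 0)
    O1 <- C1 + 1.42 * c(cos(deg2rad(109.47)), sin(deg2rad(109.47)), 0)
    H1 <- place_atom(C2, C1, O1, 0.98, 108, 180)
    O2 <- place_atom(O1, C1, C2, 1.42, 109.47, 60)
    H2 <- place_atom(C1, C2, O2, 0.98, 108, 180)
    C0 <- place_atom(O1, C1, C2, 1.53, 109.47, 180)
    atoms <- rbind(C1 = C1, C2 = C2, O1 = O1, H1 = H1, O2 = O2, H2 = H2, C0 = C0)
    sites <- list(
      interaction_site("o1_don", "O1", "donor", "H1"),
      interaction_site("o1_acc", "O1", "acceptor", "C1"),
      interaction_site("o2_don", "O2", "donor", "H2"),
      interaction_site("o2_acc", "O2", "acceptor", "C2"))
    return(ligand_model("diol", atoms, sites = sites))
  }
  if (name == "keto_phosphate") {
    C1 <- c(0, 0, 0)
    C2 <- c(1.52, 0, 0)
    OK <- place_atom(c(-1, 0, 0.5), C1, C2, 1.23, 120, 90)
    C3 <- place_atom(OK, C1, C2, 1.52, 120, 180)
    # hydroxymethyl oxygen on C1 (in-plane, away from the carbonyl)
    O1 <- C1 + 1.43 * c(cos(deg2rad(120)), -sin(deg2rad(120)), 0)
    H1 <- place_atom(C2, C1, O1, 0.98, 108, 180)
    O3 <- place_atom(OK, C2, C3, 1.43, 109.47, 60)
    P  <- place_atom(C2, C3, O3, 1.61, 120, 180)
    O1P <- place_atom(C3, O3, P, 1.49, 109.47, 60)
    O2P <- place_atom(C3, O3, P, 1.49, 109.47, 180)
    O3P <- place_atom(C3, O3, P, 1.49, 109.47, -60)
    atoms <- rbind(C1 = C1, C2 = C2, OK = OK, C3 = C3, O1 = O1, H1 = H1,
                   O3 = O3, P = P, O1P = O1P, O2P = O2P, O3P = O3P)
    sites <- list(
      interaction_site("keto_acc", "OK", "acceptor", "C2"),
      interaction_site("p1_acc", "O1P", "acceptor", "P"),
      interaction_site("p2_acc", "O2P", "acceptor", "P"),
      interaction_site("oh_don", "O1", "donor", "H1"))
    return(ligand_model("keto_phosphate", atoms, sites = sites))
  }
  if (name == "carbinolamine_ts") {
    C1 <- c(0, 0, 0)
    O1 <- 1.40 * c(cos(deg2rad(109.47)), sin(deg2rad(109.47)), 0)
    C2 <- c(1.53, 0, 0)
    HC <- place_atom(C2, C1, O1, 1.09, 109.47, 120)
    C3 <- place_atom(O1, C1, C2, 1.53, 111, 180)
    O3 <- place_atom(C1, C2, C3, 1.42, 109.47, 60)
    H3 <- place_atom(C2, C3, O3, 0.98, 108, 180)
    atoms <- rbind(C1 = C1, O1 = O1, C2 = C2, HC = HC, C3 = C3, O3 = O3, H3 = H3)
    sites <- list(
      interaction_site("nuc_c", "C1", "covalent_attachment", c("O1", "C2")),
      interaction_site("oxy_acc", "O1", "acceptor", "C1"),
      interaction_site("oh_don", "O3", "donor", "H3"),
      interaction_site("oh_acc", "O3", "acceptor", "C3"))
    return(ligand_model("carbinolamine_ts", atoms, sites = sites))
  }
  stop(sprintf("hbnetforge error: unknown toy ligand '%s'", name))
}

#' Built-in toy active-site specifications
#'
#' \describe{
#'   \item{diol_pair}{2 groups on the diol ligand: a hydroxyl donating to O1
#'     and a carboxamide donating to O2, hydrogen-bonded to each other}
#'   \item{diol_triplet}{the pair plus an imidazole donating to the
#'     carboxamide carbonyl}
#'   \item{carbinolamine_quartet}{an amine covalently bonded to the
#'     carbinolamine carbon plus three polar groups, in the style of an
#'     evolved retro-aldolase catalytic quartet}
#' }
#'
#' @param name fixture spec name
#' @return an \code{active_site_spec}
#' @export
make_toy_spec <- function(name) {
  if (name == "diol_pair") {
    return(active_site_spec(
      "diol_pair",
      groups = data.frame(label = c("G1", "G2"), fg = c("hydroxyl", "carboxamide"),
                          stringsAsFactors = FALSE),
      edges = list(
        spec_edge("e_g1_lig", "hbond", edge_end_group("G1", role = "donor"),
                  edge_end_ligand("o1_acc")),
        spec_edge("e_g2_lig", "hbond", edge_end_group("G2", role = "donor"),
                  edge_end_ligand("o2_acc")),
        spec_edge("e_g2_g1", "hbond", edge_end_group("G2", role = "donor"),
                  edge_end_group("G1", role = "acceptor"))),
      ligand_sites = make_toy_ligand("diol")$sites))
  }
  if (name == "diol_triplet") {
    return(active_site_spec(
      "diol_triplet",
      groups = data.frame(label = c("G1", "G2", "G3"),
                          fg = c("hydroxyl", "carboxamide", "imidazole"),
                          stringsAsFactors = FALSE),
      edges = list(
        spec_edge("e_g1_lig", "hbond", edge_end_group("G1", role = "donor"),
                  edge_end_ligand("o1_acc")),
        spec_edge("e_g2_lig", "hbond", edge_end_group("G2", role = "donor"),
                  edge_end_ligand("o2_acc")),
        spec_edge("e_g2_g1", "hbond", edge_end_group("G2", role = "donor"),
                  edge_end_group("G1", role = "acceptor")),
        spec_edge("e_g3_lig", "hbond", edge_end_group("G3", role = "donor"),
                  edge_end_ligand("o1_acc")),
        spec_edge("e_g3_g2", "hbond", edge_end_group("G3", role = "donor"),
                  edge_end_group("G2", role = "acceptor"))),
      ligand_sites = make_toy_ligand("diol")$sites))
  }
  if (name == "carbinolamine_quartet") {
    # every group contacts the ligand directly (enumeration is ligand-anchored)
    # and the polar groups form a connected chain among themselves
    return(active_site_spec(
      "carbinolamine_quartet",
      groups = data.frame(label = c("K1", "Y1", "Y2", "N1"),
                          fg = c("primary_amine", "phenol", "phenol", "carboxamide"),
                          stringsAsFactors = FALSE),
      edges = list(
        spec_edge("e_cov", "covalent", edge_end_ligand("nuc_c"), edge_end_group("K1")),
        spec_edge("e_y1_lig", "hbond", edge_end_group("Y1", role = "donor"),
                  edge_end_ligand("oxy_acc")),
        spec_edge("e_k1_y1", "hbond", edge_end_group("K1", role = "donor"),
                  edge_end_group("Y1", role = "acceptor")),
        spec_edge("e_n1_lig", "hbond", edge_end_group("N1", role = "donor"),
                  edge_end_ligand("oh_acc")),
        spec_edge("e_y2_lig", "hbond", edge_end_ligand("oh_don"),
                  edge_end_group("Y2", role = "acceptor")),
        spec_edge("e_n1_y2", "hbond", edge_end_group("N1", role = "donor"),
                  edge_end_group("Y2", role = "acceptor"))),
      require_ligand_contact = TRUE,
      ligand_sites = make_toy_ligand("carbinolamine_ts")$sites))
  }
  stop(sprintf("hbnetforge error: unknown toy spec '%s'", name))
}

#' Generate an ideal alpha-helix poly-alanine scaffold
#'
#' Backbone built from ideal geometry at phi = -57, psi = -47, omega = 180.
#'
#' @param n_res number of residues (>= 4)
#' @param id scaffold identifier
#' @return a \code{scaffold_model}
#' @export
make_helix_scaffold <- function(n_res, id = sprintf("helix%d", n_res)) {
  if (n_res < 4L) stop("hbnetforge value error: a helix fixture needs at least 4 residues")
  phi <- -57; psi <- -47; omega <- 180
  N <- matrix(NA_real_, n_res, 3L); CA <- N; C <- N; O <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  C[1L, ] <- place_atom(c(0, 1, 0), N[1L, ], CA[1L, ], 1.525, 111.0, -60)
  for (i in seq_len(n_res - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.6, psi)
    O[i, ] <- place_atom(N[i + 1L, ], CA[i, ], C[i, ], 1.231, 120.5, 180)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525, 111.0, phi)
  }
  O[n_res, ] <- place_atom(N[n_res, ], CA[n_res, ], C[n_res, ], 1.231, 120.5, psi + 180)
  scaffold_model(id, chain = rep("A", n_res), resnum = seq_len(n_res),
                 N = N, CA = CA, C = C, O = O)
}

# grow an ideal alpha-helical segment outward from an exact central N/CA/C
# frame (n_flank residues on each side); returns n x 3 matrices
helix_segment_from_frame <- function(frame, n_flank = 2L,
                                     phi = -57, psi = -47, omega = 180) {
  n_res <- 2L * n_flank + 1L
  N <- matrix(NA_real_, n_res, 3L); CA <- N; C <- N; O <- N
  mid <- n_flank + 1L
  N[mid, ] <- frame[1L, ]; CA[mid, ] <- frame[2L, ]; C[mid, ] <- frame[3L, ]
  for (i in mid:(n_res - 1L)) {       # forward
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.6, psi)
    O[i, ] <- place_atom(N[i + 1L, ], CA[i, ], C[i, ], 1.231, 120.5, 180)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525, 111.0, phi)
  }
  for (i in mid:2L) {                 # backward
    C[i - 1L, ] <- place_atom(C[i, ], CA[i, ], N[i, ], 1.329, 121.7, phi)
    CA[i - 1L, ] <- place_atom(CA[i, ], N[i, ], C[i - 1L, ], 1.525, 116.6, omega)
    N[i - 1L, ] <- place_atom(N[i, ], C[i - 1L, ], CA[i - 1L, ], 1.458, 111.0, psi)
    O[i - 1L, ] <- place_atom(N[i, ], CA[i - 1L, ], C[i - 1L, ], 1.231, 120.5, 180)
  }
  O[n_res, ] <- place_atom(N[n_res, ], CA[n_res, ], C[n_res, ], 1.231, 120.5, psi + 180)
  list(N = N, CA = CA, C = C, O = O)
}

#' Build a scaffold with a network planted in it
#'
#' For each group of the network, a short ideal helical segment is grown
#' outward from the backbone N/CA/C frame of that group's side-chain
#' realization, so the central residue carries the frame exactly.  The
#' resulting scaffold is guaranteed (by construction) to host the network,
#' which makes parameter-recovery tests of the matcher possible.  Segments
#' are checked for clashes against the ligand, each other, and the planted
#' side chains; unplaceable frames raise a construction error with
#' diagnostics.
#'
#' @param network a \code{network_configuration}
#' @param realizations named list (by group label), one
#'   \code{side_chain_realization} per group
#' @param ligand the \code{ligand_model} (canonical frame)
#' @param segment_len residues per segment (odd, default 5)
#' @param clash_min minimum allowed heavy-atom separation for the placed
#'   segments (Angstrom)
#' @param id scaffold identifier
#' @return a \code{scaffold_model} in the ligand canonical frame
#' @export
plant_network_scaffold <- function(network, realizations, ligand,
                                   segment_len = 5L, clash_min = 2.8,
                                   id = "planted") {
  labels <- names(network$assignment)
  if (!all(labels %in% names(realizations)))
    stop("hbnetforge error: one realization per group is required for planting")
  ligand <- canonical_ligand(ligand)
  if (segment_len %% 2L != 1L || segment_len < 3L)
    stop("hbnetforge value error: segment_len must be an odd number >= 3")
  mid <- (segment_len + 1L) %/% 2L
  chains <- LETTERS[seq_along(labels)]
  placed <- list()
  for (k in seq_along(labels)) {
    r <- realizations[[labels[k]]]
    seg <- helix_segment_from_frame(r$backbone_frame, n_flank = mid - 1L)
    placed[[k]] <- c(list(chain = chains[k]), seg)
  }
  lig_heavy <- ligand$atoms[ligand$elements != "H", , drop = FALSE]
  seg_atoms <- function(p, drop_center = FALSE) {
    keep <- if (drop_center) setdiff(seq_len(segment_len), mid) else seq_len(segment_len)
    rbind(p$N[keep, , drop = FALSE], p$CA[keep, , drop = FALSE],
          p$C[keep, , drop = FALSE], p$O[keep, , drop = FALSE])
  }
  min_d <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(Inf)
    min(vapply(seq_len(nrow(a)), function(i)
      min((b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2 + (b[, 3L] - a[i, 3L])^2), 1))^0.5
  }
  for (k in seq_along(placed)) {
    d_lig <- min_d(seg_atoms(placed[[k]]), lig_heavy)
    if (d_lig < clash_min)
      stop(sprintf("hbnetforge construction error: segment for group '%s' clashes with the ligand (min distance %.2f A)",
                   labels[k], d_lig))
    # the matcher excludes only the host residue from its backbone clash
    # check, so flanking residues must clear the planted side chains too
    for (m in seq_along(placed)) {
      r <- realizations[[labels[m]]]
      side <- r$atoms[setdiff(rownames(r$atoms), c("N", "CA", "C")), , drop = FALSE]
      side <- side[element_of(rownames(side)) != "H", , drop = FALSE]
      d_side <- min_d(seg_atoms(placed[[k]], drop_center = (m == k)), side)
      if (d_side < clash_min)
        stop(sprintf("hbnetforge construction error: segment for group '%s' clashes with the side chain of '%s' (min distance %.2f A)",
                     labels[k], labels[m], d_side))
    }
    for (j in seq_len(k - 1L)) {
      d_seg <- min_d(seg_atoms(placed[[k]]), seg_atoms(placed[[j]]))
      if (d_seg < clash_min)
        stop(sprintf("hbnetforge construction error: segments for groups '%s' and '%s' overlap (min distance %.2f A)",
                     labels[k], labels[j], d_seg))
    }
  }
  scaffold_model(id,
                 chain = rep(chains, each = segment_len),
                 resnum = rep(seq_len(segment_len), times = length(labels)),
                 N = do.call(rbind, lapply(placed, `[[`, "N")),
                 CA = do.call(rbind, lapply(placed, `[[`, "CA")),
                 C = do.call(rbind, lapply(placed, `[[`, "C")),
                 O = do.call(rbind, lapply(placed, `[[`, "O")))
}

#' Plant a network using the first clash-free rotamer combination
#'
#' Iterates deterministically over combinations of inverse rotamers (one per
#' group) and returns the first combination whose planted scaffold passes all
#' clash checks.
#'
#' @param network a \code{network_configuration}
#' @param ligand the \code{ligand_model}
#' @param identities named character vector group label -> residue identity
#'   (default: first allowed identity per group)
#' @param chi_samples torsion samples for \code{\link{inverse_rotamers}}
#' @param segment_len,clash_min,id passed to \code{\link{plant_network_scaffold}}
#' @return list with \code{scaffold} and \code{realizations}, or \code{NULL}
#'   when no combination is plantable
#' @export
plant_first_fit <- function(network, ligand, identities = NULL,
                            chi_samples = c(-60, 60, 180), segment_len = 5L,
                            clash_min = 2.8, id = "planted") {
  labels <- names(network$assignment)
  if (is.null(identities)) {
    identities <- vapply(labels, function(lab)
      fg_template(network$assignment[[lab]]$fg_name)$residues[1L], "")
    names(identities) <- labels
  }
  rot_sets <- lapply(labels, function(lab)
    inverse_rotamers(network$assignment[[lab]], identities[[lab]], chi_samples,
                     ligand = ligand))
  names(rot_sets) <- labels
  if (any(!lengths(rot_sets))) return(NULL)
  combos <- do.call(expand.grid, lapply(rot_sets, seq_along))
  for (r in seq_len(nrow(combos))) {
    rs <- lapply(labels, function(lab) rot_sets[[lab]][[combos[r, lab]]])
    names(rs) <- labels
    sc <- tryCatch(plant_network_scaffold(network, rs, ligand,
                                          segment_len = segment_len,
                                          clash_min = clash_min, id = id),
                   error = function(e) NULL)
    if (!is.null(sc)) return(list(scaffold = sc, realizations = rs))
  }
  NULL
}
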