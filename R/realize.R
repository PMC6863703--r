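# Expansion of functional-group placements into full side chains (inverse
# rotamers) with backbone anchor frames.

new_realization <- function(residue_identity, chi, backbone, atoms, placement) {
  structure(list(residue_identity = residue_identity, chi_angles = chi,
                 backbone_frame = backbone, atoms = atoms,
                 placement = placement),
            class = "side_chain_realization")
}

#' @export
print.side_chain_realization <- function(x, ...) {
  cat(sprintf("Inverse rotamer: %s carrying %s; chi = (%s)\n",
              x$residue_identity, x$placement$fg_name,
              paste(round(x$chi_angles, 1), collapse = ", ")))
  invisible(x)
}

#' Build inverse rotamers for a placement
#'
#' Starting from the fixed functional-group pose, the side chain is grown
#' backward toward the backbone with ideal bond lengths and angles, sampling
#' each rotatable bond at \code{chi_samples} (staggered values for sp3 bonds
#' by default) and completing the backbone with ideal N-CA-C geometry.
#' Realizations whose chain atoms clash with the ligand are removed.
#' Output order is deterministic (lexicographic over the chi sample grid).
#'
#' @param placement a \code{placement}
#' @param residue_identity amino-acid identity carrying the functional group
#'   (must be one of the template's \code{residues})
#' @param chi_samples numeric vector of torsion samples (degrees) applied to
#'   every rotatable bond
#' @param ligand optional \code{ligand_model} (canonical frame) for clash
#'   filtering of the grown chain
#' @param clash_min minimum allowed heavy-atom distance to the ligand (Angstrom)
#' @return list of \code{side_chain_realization} objects
#' @export
inverse_rotamers <- function(placement, residue_identity,
                             chi_samples = c(-60, 60, 180),
                             ligand = NULL, clash_min = 2.7) {
  template <- fg_template(placement$fg_name)
  if (!residue_identity %in% template$residues)
    stop(sprintf("hbnetforge spec error: residue '%s' cannot carry a %s group (allowed: %s)",
                 residue_identity, placement$fg_name,
                 paste(template$residues, collapse = ", ")))
  steps <- template$chains[[residue_identity]]
  missing_ref <- setdiff(unlist(lapply(steps, function(s) c(s$a, s$b, s$c))),
                         c(rownames(placement$atoms),
                           vapply(steps, function(s) s$atom, "")))
  if (length(missing_ref))
    stop(sprintf("hbnetforge error: chain recipe references atoms absent from the placement: %s",
                 paste(missing_ref, collapse = ", ")))
  chi_steps <- which(vapply(steps, function(s) identical(s$dihedral, "chi"), TRUE))
  n_chi <- length(chi_steps)
  grids <- rep(list(chi_samples), n_chi)
  combos <- if (n_chi) as.matrix(do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE)))
            else matrix(numeric(0), 1L, 0L)
  lig_heavy <- if (!is.null(ligand)) {
    lg <- canonical_ligand(ligand)
    lg$atoms[lg$elements != "H", , drop = FALSE]
  } else NULL

  out <- list()
  for (ri in seq_len(nrow(combos))) {
    coords <- placement$atoms
    chi <- numeric(0)
    ci <- 0L
    ok <- TRUE
    for (s in steps) {
      dih <- if (identical(s$dihedral, "chi")) {
        ci <- ci + 1L
        chi[ci] <- combos[ri, ci]
        combos[ri, ci]
      } else s$dihedral
      pos <- place_atom(coords[s$a, ], coords[s$b, ], coords[s$c, ],
                        s$bond, s$angle, dih)
      coords <- rbind(coords, matrix(pos, 1L, dimnames = list(s$atom)))
    }
    if (!is.null(lig_heavy)) {
      chain_atoms <- setdiff(rownames(coords), rownames(placement$atoms))
      heavy <- chain_atoms[element_of(chain_atoms) != "H"]
      for (k in heavy) {
        d2 <- (lig_heavy[, 1L] - coords[k, 1L])^2 +
              (lig_heavy[, 2L] - coords[k, 2L])^2 +
              (lig_heavy[, 3L] - coords[k, 3L])^2
        if (any(d2 < clash_min^2)) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    backbone <- coords[c("N", "CA", "C"), ]
    out[[length(out) + 1L]] <- new_realization(residue_identity, chi, backbone,
                                               coords, placement)
  }
  out
}

#' Number of full side-chain realizations of a network (product rule)
#'
#' The total number of full side-chain 3D realizations of a network is the
#' product over its groups of the per-group side-chain placement counts.
#'
#' @param network a \code{network_configuration} (only its group count is
#'   used; pass \code{NULL} to treat \code{per_group_counts} as-is)
#' @param per_group_counts non-negative integer vector of side-chain placement
#'   counts, one per group
#' @return the product, as a double (counts can exceed integer range)
#' @export
count_full_realizations <- function(network, per_group_counts) {
  stopifnot(all(per_group_counts >= 0))
  if (!is.null(network) && length(per_group_counts) != length(network$assignment))
    stop("hbnetforge error: one count per group is required")
  prod(as.numeric(per_group_counts))
}

#' Export a realized network as a PDB file
#'
#' Writes the ligand as HETATM records and one realized side chain per group
#' as ATOM records with unique residue numbering, re-parsable by
#' \code{\link{load_scaffold}} and \code{bio3d::read.pdb}.
#'
#' @param network a \code{network_configuration}
#' @param realizations named list (by group label) with one
#'   \code{side_chain_realization} per group
#' @param ligand the \code{ligand_model} (canonical frame is used)
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
export_network_pdb <- function(network, realizations, ligand, path) {
  if (!length(network$assignment))
    stop("hbnetforge error: cannot export an empty network")
  labels <- names(network$assignment)
  if (!all(labels %in% names(realizations)))
    stop("hbnetforge error: one realization per group is required")
  ligand <- canonical_ligand(ligand)
  res3 <- c(ser = "SER", thr = "THR", tyr = "TYR", asp = "ASP", glu = "GLU",
            asn = "ASN", gln = "GLN", his = "HIS", arg = "ARG", lys = "LYS")
  xyz <- c(); elety <- c(); resid <- c(); resno <- c(); chain <- c(); type <- c(); elesy <- c()
  for (k in seq_along(labels)) {
    r <- realizations[[labels[k]]]
    xyz <- c(xyz, as.numeric(t(r$atoms)))
    elety <- c(elety, rownames(r$atoms))
    resid <- c(resid, rep(res3[[r$residue_identity]], nrow(r$atoms)))
    resno <- c(resno, rep(k, nrow(r$atoms)))
    chain <- c(chain, rep("A", nrow(r$atoms)))
    type <- c(type, rep("ATOM", nrow(r$atoms)))
    elesy <- c(elesy, unname(element_of(rownames(r$atoms))))
  }
  xyz <- c(xyz, as.numeric(t(ligand$atoms)))
  elety <- c(elety, rownames(ligand$atoms))
  resid <- c(resid, rep("LIG", nrow(ligand$atoms)))
  resno <- c(resno, rep(length(labels) + 1L, nrow(ligand$atoms)))
  chain <- c(chain, rep("X", nrow(ligand$atoms)))
  type <- c(type, rep("HETATM", nrow(ligand$atoms)))
  elesy <- c(elesy, unname(ligand$elements))
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = resno,
                   resid = resid, elety = elety, chain = chain, elesy = elesy)
  invisible(path)
}
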