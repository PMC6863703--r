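test_that("inverse rotamers anchor the functional group and count as sampled", {
  inst <- toy_instance()
  p <- inst$networks[[1]]$assignment$G1   # a hydroxyl placement
  # serine has two sampled rotatable bonds: <= 3^2 realizations
  rs <- inverse_rotamers(p, "ser", c(-60, 60, 180))
  expect_lte(length(rs), 9)
  expect_gt(length(rs), 0)
  for (r in rs) {
    # FG atoms coincide with the parent placement
    expect_lt(max(abs(r$atoms[rownames(p$atoms), ] - p$atoms)), 0.1)
    # ideal chain geometry: CB-CA bond and backbone frame present
    expect_equal(sqrt(sum((r$atoms["CA", ] - r$atoms["CB", ])^2)), 1.53,
                 tolerance = 1e-6)
    expect_identical(rownames(r$backbone_frame), c("N", "CA", "C"))
    expect_equal(sqrt(sum((r$backbone_frame["N", ] - r$backbone_frame["CA", ])^2)),
                 1.458, tolerance = 1e-6)
  }
  # one sample per bond -> at most one realization
  expect_lte(length(inverse_rotamers(p, "ser", 180)), 1)
  # incompatible identity is a spec error
  expect_error(inverse_rotamers(p, "tyr", 180), "cannot carry")
  # emitted count equals the chi-grid size minus clash rejections
  rs_all <- inverse_rotamers(p, "ser", c(-60, 60, 180), ligand = NULL)
  rs_fil <- inverse_rotamers(p, "ser", c(-60, 60, 180), ligand = inst$ligand)
  expect_identical(length(rs_all), 9L)
  expect_lte(length(rs_fil), length(rs_all))
})

test_that("chi samples map deterministically onto the realized torsions", {
  inst <- toy_instance()
  p <- inst$networks[[1]]$assignment$G2   # carboxamide -> asn
  rs <- inverse_rotamers(p, "asn", c(-60, 60, 180))
  expect_gt(length(rs), 0)
  r <- rs[[1]]
  expect_length(r$chi_angles, 2)
  # realized dihedral equals the recorded chi (first chain torsion)
  got <- dihedral_deg(r$atoms["OD1", ], r$atoms["CG", ], r$atoms["CB", ], r$atoms["CA", ])
  expect_equal(((got - r$chi_angles[1] + 180) %% 360) - 180, 0, tolerance = 1e-6)
  # repeated calls are identical
  expect_identical(rs, inverse_rotamers(p, "asn", c(-60, 60, 180)))
})

test_that("the realization product rule holds exactly", {
  expect_identical(count_full_realizations(NULL, c(12, 9, 6)), 648)
  expect_identical(count_full_realizations(NULL, c(12, 0, 6)), 0)
  expect_identical(count_full_realizations(NULL, 7), 7)
  inst <- toy_instance()
  net <- inst$networks[[1]]
  rs1 <- inverse_rotamers(net$assignment$G1, "ser", c(-60, 60, 180), ligand = inst$ligand)
  rs2 <- inverse_rotamers(net$assignment$G2, "asn", c(-60, 60, 180), ligand = inst$ligand)
  # direct enumeration of all combinations vs the product formula
  combos <- expand.grid(seq_along(rs1), seq_along(rs2))
  expect_identical(nrow(combos),
                   as.integer(count_full_realizations(net, c(length(rs1), length(rs2)))))
  expect_error(count_full_realizations(net, c(1, 2, 3)), "one count per group")
  expect_error(count_full_realizations(NULL, c(-1, 2)))
})

test_that("exported network PDB files round-trip through the PDB parsers", {
  inst <- toy_instance()
  net <- inst$networks[[1]]
  rs <- list(G1 = inverse_rotamers(net$assignment$G1, "ser", 180)[[1]],
             G2 = inverse_rotamers(net$assignment$G2, "asn", 180)[[1]])
  path <- tempfile(fileext = ".pdb")
  export_network_pdb(net, rs, inst$ligand, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  expect_identical(sum(pdb$atom$type == "HETATM"), nrow(inst$ligand$atoms))
  expect_identical(length(unique(pdb$atom$resno[pdb$atom$type == "ATOM"])), 2L)
  # coordinates survive at PDB precision
  het <- pdb$atom[pdb$atom$type == "HETATM", ]
  expect_equal(cbind(het$x, het$y, het$z), unname(inst$ligand$atoms),
               tolerance = 1e-3)
  # re-parsable by the scaffold loader (backbone N/CA/C present per residue)
  sc <- load_scaffold(path)
  expect_identical(length(sc$resnum), 2L)
  # empty network is an error
  empty <- structure(list(assignment = list()), class = "network_configuration")
  expect_error(export_network_pdb(empty, rs, inst$ligand, tempfile()), "empty")
})
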