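test_that("functional-group templates carry the expected chemistry", {
  hy <- fg_template("hydroxyl")
  expect_length(hy$donors, 1)
  expect_length(hy$acceptors, 1)
  expect_setequal(hy$residues, c("ser", "thr"))
  cx <- fg_template("carboxylate")
  expect_length(cx$acceptors, 2)
  expect_length(cx$donors, 0)
  gu <- fg_template("guanidinium")
  expect_gte(length(gu$donors), 3)
  expect_length(gu$acceptors, 0)
  am <- fg_template("primary_amine")
  expect_identical(am$covalent_atom, "NZ")
  expect_error(fg_template("sulfhydryl"), "unknown functional group")
  # template rigidity: all referenced atoms exist with finite coordinates
  for (nm in fg_names()) {
    tpl <- fg_template(nm)
    expect_true(all(is.finite(tpl$atoms)))
    refs <- c(unlist(tpl$donors), unlist(lapply(tpl$acceptors, function(a) c(a$heavy, a$bases))),
              tpl$attachment)
    expect_true(all(refs %in% rownames(tpl$atoms)), info = nm)
  }
})

test_that("ligand models validate names, sites and coordinates", {
  atoms <- rbind(C1 = c(0, 0, 0), O1 = c(1.4, 0, 0), H1 = c(1.8, 0.9, 0))
  lig <- ligand_model("t", atoms,
                      sites = list(interaction_site("s1", "O1", "donor", "H1")))
  expect_s3_class(lig, "ligand_model")
  bad <- atoms; rownames(bad) <- c("C1", "C1", "H1")
  expect_error(ligand_model("t", bad), "unique")
  expect_error(ligand_model("t", rbind(C1 = c(0, 0, NA))), "finite")
  expect_error(attach_sites(lig, list(interaction_site("s2", "OX", "donor", "H1"))),
               "unknown atom")
  expect_error(interaction_site("s3", "O1", "donor", character(0)), "aux")
})

test_that("toy ligand fixtures have the annotated site inventory and are deterministic", {
  rec <- fixture_recipes()
  for (i in seq_len(nrow(rec))) {
    lig <- make_toy_ligand(rec$name[i])
    roles <- vapply(lig$sites, function(s) s$role, "")
    expect_identical(sum(roles == "donor"), as.integer(rec$n_donor_sites[i]), info = rec$name[i])
    expect_identical(sum(roles == "acceptor"), as.integer(rec$n_acceptor_sites[i]))
    expect_identical(sum(roles == "covalent_attachment"), as.integer(rec$n_covalent_sites[i]))
    expect_identical(lig$atoms, make_toy_ligand(rec$name[i])$atoms)
  }
  expect_error(make_toy_ligand("nope"), "unknown")
})

test_that("PDB and SDF ligand input round-trips atoms and rejects bad files", {
  lig <- make_toy_ligand("diol")
  path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = path, xyz = as.numeric(t(lig$atoms)),
                   type = rep("HETATM", nrow(lig$atoms)),
                   resno = rep(1, nrow(lig$atoms)), resid = rep("LIG", nrow(lig$atoms)),
                   elety = rownames(lig$atoms), chain = rep("X", nrow(lig$atoms)),
                   elesy = unname(lig$elements))
  back <- load_ligand(path, "pdb", sites = lig$sites)
  expect_identical(rownames(back$atoms), rownames(lig$atoms))
  expect_equal(unname(back$atoms), unname(lig$atoms), tolerance = 1e-3)
  expect_length(back$sites, 4)
  # duplicate atom names are a parse error
  dup <- readLines(path)
  atom_lines <- grep("^HETATM", dup)
  dup[atom_lines[2]] <- dup[atom_lines[1]]
  path2 <- tempfile(fileext = ".pdb")
  writeLines(dup, path2)
  expect_error(load_ligand(path2, "pdb"), "duplicate")
  # empty file is a format error
  path3 <- tempfile(fileext = ".pdb")
  writeLines(character(0), path3)
  expect_error(load_ligand(path3, "pdb"), "format error")
  expect_error(load_ligand(tempfile(), "pdb"), "not found")
})

test_that("SDF V2000 input is parsed when ChemmineR is available", {
  skip_if_not_installed("ChemmineR")
  sdf_path <- system.file("extdata", "toy_diol_synthetic.sdf", package = "hbnetforge")
  expect_true(nzchar(sdf_path))
  lig <- load_ligand(sdf_path, "sdf")
  expect_gte(nrow(lig$atoms), 4)
  expect_true(any(lig$elements == "O"))
})

test_that("active-site specs resolve edges, enforce connectivity and round-trip", {
  spec <- make_toy_spec("diol_pair")
  # every hbond edge ends up with one donor end and one acceptor end
  for (e in spec$edges) {
    if (e$kind != "hbond") next
    role_a <- if (e$a$type == "ligand") spec$ligand_sites[[e$a$site]]$role else e$a$role
    role_b <- if (e$b$type == "ligand") spec$ligand_sites[[e$b$site]]$role else e$b$role
    expect_identical(role_a, "donor")
    expect_identical(role_b, "acceptor")
  }
  # serialize -> parse round trip is identity
  path <- tempfile(fileext = ".yaml")
  write_active_site_spec(spec, path)
  spec2 <- parse_active_site_spec(path)
  expect_equal(spec2, spec)
  # quartet in the style of an evolved retro-aldolase: amine covalently
  # bonded to the ligand plus three hydrogen-bonded polar groups
  q <- make_toy_spec("carbinolamine_quartet")
  expect_identical(nrow(q$groups), 4L)
  expect_identical(q$edges[["e_cov"]]$kind, "covalent")
  expect_true(q$require_ligand_contact)
  path2 <- tempfile(fileext = ".yaml")
  write_active_site_spec(q, path2)
  expect_equal(parse_active_site_spec(path2), q)
})

test_that("invalid specs are rejected with informative validation errors", {
  sites <- make_toy_ligand("diol")$sites
  # a group with no edges leaves the graph disconnected
  expect_error(active_site_spec("bad",
    groups = data.frame(label = c("G1", "G2"), fg = c("hydroxyl", "phenol")),
    edges = list(spec_edge("e1", "hbond", edge_end_group("G1", role = "donor"),
                           edge_end_ligand("o1_acc"))),
    ligand_sites = sites), "not connected.*G2")
  # unknown functional group
  expect_error(active_site_spec("bad2",
    groups = data.frame(label = "G1", fg = "thiolate"),
    edges = list(), ligand_sites = sites), "unknown functional group")
  # ambiguous donor/acceptor assignment must be made explicit
  expect_error(active_site_spec("bad3",
    groups = data.frame(label = c("G1", "G2"), fg = c("hydroxyl", "hydroxyl")),
    edges = list(spec_edge("e1", "hbond", edge_end_group("G1"), edge_end_ligand("o1_acc")),
                 spec_edge("e2", "hbond", edge_end_group("G2"), edge_end_ligand("o2_acc")),
                 spec_edge("e3", "hbond", edge_end_group("G1"), edge_end_group("G2"))),
    ligand_sites = sites), "ambiguous")
  # a guanidinium cannot accept
  expect_error(active_site_spec("bad4",
    groups = data.frame(label = c("G1", "G2"), fg = c("guanidinium", "guanidinium")),
    edges = list(spec_edge("e1", "hbond", edge_end_group("G1"), edge_end_group("G2"))),
    ligand_sites = sites), "no consistent donor/acceptor")
  # single group with a single ligand hydrogen bond is a valid 1-group spec
  s1 <- active_site_spec("ok1",
    groups = data.frame(label = "G1", fg = "hydroxyl"),
    edges = list(spec_edge("e1", "hbond", edge_end_group("G1", role = "donor"),
                           edge_end_ligand("o1_acc"))),
    ligand_sites = sites)
  expect_s3_class(s1, "active_site_spec")
})

test_that("the bundled example spec file parses against its schema", {
  path <- system.file("extdata", "quartet_example.yaml", package = "hbnetforge")
  expect_true(nzchar(path))
  spec <- parse_active_site_spec(path)
  expect_identical(nrow(spec$groups), 4L)
  expect_true(any(vapply(spec$edges, function(e) e$kind == "covalent", TRUE)))
})
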