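test_that("scaffold loading keeps complete backbones and flags degenerate input", {
  h <- make_helix_scaffold(20)
  path <- tempfile(fileext = ".pdb")
  write_scaffold_pdb(h, path)
  sc <- load_scaffold(path)
  expect_identical(length(sc$resnum), 20L)
  expect_equal(sc$CA, h$CA, tolerance = 1e-3)
  # CA-only trace: no usable residues
  ca_only <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(5), seq_len(5), h$CA[1:5, 1], h$CA[1:5, 2], h$CA[1:5, 3])
  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(ca_only, "END"), path2)
  expect_warning(expect_error(load_scaffold(path2), "format error"), "incomplete")
  # altloc records: first kept with a warning
  lines <- readLines(path)
  atom_idx <- grep("^ATOM", lines)[1]
  alt_line <- lines[atom_idx]
  substr(alt_line, 17, 17) <- "B"
  writeLines(append(lines, alt_line, after = atom_idx), path2)
  expect_warning(sc2 <- load_scaffold(path2), "altloc")
  expect_identical(length(sc2$resnum), 20L)
})

test_that("transform-hash entries reproduce their own ligand-pose bin", {
  inst <- toy_instance()
  net <- inst$networks[[1]]
  fit <- plant_first_fit(net, inst$ligand)
  rs_all <- inverse_rotamers(net$assignment$G1, "ser", c(-60, 60, 180),
                             ligand = inst$ligand)
  params <- match_params()
  h <- build_transform_hash(fit$scaffold, "G1", rs_all, params)
  expect_gt(length(h), 0)
  for (key in names(h)) for (e in h[[key]])
    expect_identical(hbnetforge:::pose_bin_key(e$transform, params), key)
  # empty scaffold position set -> empty table
  empty_sc <- fit$scaffold
  empty_sc$designable <- rep(FALSE, length(empty_sc$designable))
  expect_length(build_transform_hash(empty_sc, "G1", rs_all, params), 0)
  # the per-bin cap truncates deterministically
  p1 <- match_params(per_bin_cap = 1)
  h1 <- build_transform_hash(fit$scaffold, "G1", rs_all, p1)
  expect_true(all(lengths(h1) <= 1))
})

test_that("per-network matching recovers a planted network as a complete match", {
  inst <- toy_instance()
  net <- inst$networks[[1]]
  fit <- plant_first_fit(net, inst$ligand)
  ms <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = list(net),
                     mode = "per_network", params = fine_match_params())
  expect_gt(length(ms), 0)
  expect_true(all(vapply(ms, function(m) m$complete, TRUE)))
  # the planted central residues host the match
  planted_pos <- which(fit$scaffold$resnum == 3)
  hit <- vapply(ms, function(m) setequal(m$assignments$position, planted_pos), TRUE)
  expect_true(any(hit))
  # no match assigns two groups to one position
  for (m in ms)
    expect_false(anyDuplicated(m$assignments$position) > 0)
})

test_that("a scaffold with fewer designable positions than groups yields no matches", {
  inst <- toy_instance()
  net <- inst$networks[[1]]
  fit <- plant_first_fit(net, inst$ligand)
  sc <- fit$scaffold
  sc$designable <- c(TRUE, rep(FALSE, length(sc$designable) - 1))
  expect_length(find_matches(sc, inst$spec, inst$ligand, networks = list(net),
                             mode = "per_network", params = fine_match_params()), 0)
  expect_error(find_matches(fit$scaffold, inst$spec, inst$ligand,
                            networks = list(net), mode = "nonsense"))
  expect_error(find_matches(fit$scaffold, inst$spec, inst$ligand,
                            networks = list(net), mode = "clustered"),
               "cluster_set")
})

test_that("completeness evaluation flags exactly the broken interactions", {
  inst <- toy_instance()
  net <- inst$networks[[1]]
  fit <- plant_first_fit(net, inst$ligand)
  ms <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = list(net),
                     mode = "per_network", params = fine_match_params())
  m <- ms[[1]]
  ev <- evaluate_completeness(m, inst$spec, inst$ligand)
  expect_true(ev$complete)
  expect_true(all(ev$flags))
  expect_identical(ev$complete, all(ev$flags))
  # translating one group away breaks precisely its edges
  m2 <- m
  m2$group_atoms$G1 <- m2$group_atoms$G1 + 5
  ev2 <- evaluate_completeness(m2, inst$spec, inst$ligand)
  expect_false(ev2$complete)
  expect_false(ev2$flags[["e_g1_lig"]])
  expect_false(ev2$flags[["e_g2_g1"]])
  expect_true(ev2$flags[["e_g2_lig"]])
})

test_that("pooled and clustered modes include the per-network solution set", {
  inst <- toy_instance()
  nets <- inst$networks[seq_len(4)]
  fit <- plant_first_fit(nets[[1]], inst$ligand)
  params <- fine_match_params()
  ms_pool <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = nets,
                          mode = "pooled", params = params)
  expect_gt(sum(vapply(ms_pool, function(m) m$complete, TRUE)), 0)
  feats <- do.call(rbind, lapply(nets, network_features, spec = inst$spec))
  cl <- cluster_networks(feats, nrow(feats))
  ms_cl <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = nets,
                        mode = "clustered", clusters = cl, params = params)
  expect_gt(sum(vapply(ms_cl, function(m) m$complete, TRUE)), 0)
  # dedup key: no two results share (scaffold, bin, position set)
  sig <- vapply(ms_pool, function(m)
    paste(m$scaffold_id, m$bin, paste(sort(m$assignments$position), collapse = "/")), "")
  expect_false(anyDuplicated(sig) > 0)
})

test_that("residue-based matching runs from ligand interactions alone", {
  inst <- toy_instance()
  fit <- plant_first_fit(inst$networks[[1]], inst$ligand)
  ms <- find_matches(fit$scaffold, inst$spec, inst$ligand, mode = "residue",
                     params = match_params(trans_bin = 1, orient_bin = 15,
                                           combo_cap = 200),
                     chi_samples = 180,
                     enum_opts = list(scheme = coarse_scheme(3), g = 1.0))
  # matches may be complete or partial; each must be evaluated and
  # positionally valid
  for (m in ms) {
    expect_false(anyDuplicated(m$assignments$position) > 0)
    expect_identical(m$complete, all(m$edge_flags))
  }
  succeed()
})

test_that("disabling pruning never loses complete matches in pooled mode", {
  inst <- toy_instance()
  nets <- inst$networks[seq_len(4)]
  fit <- plant_first_fit(nets[[1]], inst$ligand)
  capped <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = nets,
                         mode = "pooled",
                         params = match_params(trans_bin = 0.25, orient_bin = 2.5,
                                               per_bin_cap = 2))
  uncapped <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = nets,
                           mode = "pooled",
                           params = match_params(trans_bin = 0.25, orient_bin = 2.5,
                                                 per_bin_cap = 0))
  n_complete <- function(ms) sum(vapply(ms, function(m) m$complete, TRUE))
  expect_gte(n_complete(uncapped), n_complete(capped))
})

test_that("the completion report reproduces printed completion-rate arithmetic", {
  counts <- data.frame(label = c("residue", "network_all", "network_clustered"),
                       n_incomplete = c(7455L, 3991L, 3031L),
                       n_complete = c(1L, 47L, 98L))
  rep <- completion_report(counts = counts)
  expect_identical(rep$rate_fmt, c("0.013%", "1.18%", "3.23%"))
  expect_equal(rep$rate, 100 * counts$n_complete / counts$n_incomplete)
  # zero complete -> 0%; zero incomplete -> n/a
  z <- completion_report(counts = data.frame(label = "z", n_incomplete = 10L,
                                             n_complete = 0L))
  expect_identical(z$rate, 0)
  na <- completion_report(counts = data.frame(label = "n", n_incomplete = 0L,
                                              n_complete = 0L))
  expect_identical(na$rate_fmt, "n/a")
  expect_output(print(rep), "3.23%")
  # from match lists
  inst <- toy_instance()
  net <- inst$networks[[1]]
  fit <- plant_first_fit(net, inst$ligand)
  ms <- find_matches(fit$scaffold, inst$spec, inst$ligand, networks = list(net),
                     mode = "per_network", params = fine_match_params())
  rep2 <- completion_report(ms)
  expect_identical(rep2$n_complete, length(ms))
  path <- tempfile(fileext = ".tsv")
  write_completion_tsv(rep, path)
  expect_identical(nrow(utils::read.delim(path)), 3L)
})
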