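test_that("filter_pairs finds exactly the hydrogen-bonded pairs", {
  spec <- make_toy_spec("diol_pair")
  e <- spec$edges[["e_g2_g1"]]
  tpl_d <- fg_template("carboxamide")  # donor end (a)
  tpl_a <- fg_template("hydroxyl")     # acceptor end (b)
  # hand-built compatible pair: carboxamide N-H donating to a hydroxyl oxygen
  pa <- random_placement(tpl_d, c(0.3, 0.7, 0.2, 0.0, 0.5, 0.5, 0.5, 0.1), "G2")
  # place the acceptor hydroxyl at ideal geometry from the donor's first N-H
  dn <- tpl_d$donors[[1]]
  Dh <- pa$atoms[dn[["heavy"]], ]; Hh <- pa$atoms[dn[["h"]], ]
  u <- (Hh - Dh) / sqrt(sum((Hh - Dh)^2))
  A_target <- Dh + 2.8 * u
  # orient the hydroxyl so its base atom makes a 120-degree acceptor angle
  perp <- as.numeric(hbnetforge:::arbitrary_perp(u))
  v <- 0.5 * u + sqrt(3) / 2 * perp     # O -> CB direction
  Ft <- hbnetforge:::frame_axes(tpl_a$atoms["OG", ], tpl_a$atoms["CB", ],
                                tpl_a$atoms["HG", ])
  w <- as.numeric(hbnetforge:::arbitrary_perp(v))
  Fw <- cbind(v, w, hbnetforge:::vcross(v, w))
  R <- Fw %*% t(Ft)
  tr <- rigid_transform(R, A_target - as.numeric(R %*% tpl_a$atoms["OG", ]))
  atoms_b <- apply_transform(tr, tpl_a$atoms)
  pb <- hbnetforge:::new_placement("G1", "hydroxyl", tr, atoms_b, c(0L, 0L, 0L),
                                   "x", -0.5, "OG", "OG")
  fp <- filter_pairs(e, list(pa), list(pb))
  expect_identical(nrow(fp$table$pairs), 1L)
  expect_identical(fp$surviving_a, 1L)
  expect_identical(fp$surviving_b, 1L)
  # far-apart sets are fully discarded (empty result, not an error)
  pb_far <- pb; pb_far$atoms <- pb_far$atoms + 50
  fp2 <- filter_pairs(e, list(pa), list(pb_far))
  expect_identical(nrow(fp2$table$pairs), 0L)
  expect_length(fp2$surviving_a, 0)
  fp3 <- filter_pairs(e, list(), list(pb))
  expect_identical(nrow(fp3$table$pairs), 0L)
})

test_that("filter_pairs equals the all-pairs oracle on random 50x50 sets", {
  spec <- make_toy_spec("diol_pair")
  e <- spec$edges[["e_g2_g1"]]
  set.seed(401)
  tpl_d <- fg_template("carboxamide"); tpl_a <- fg_template("hydroxyl")
  pas <- lapply(seq_len(50), function(i) random_placement(tpl_d, runif(8), "G2"))
  pbs <- lapply(seq_len(50), function(i) {
    p <- random_placement(tpl_a, runif(8), "G1")
    p$atoms <- p$atoms / 2.5  # compress the box so some pairs fall in range
    p
  })
  # recentre acceptors into the same box as donors
  fp <- filter_pairs(e, pas, pbs)
  oracle <- oracle_pairs(e, pas, pbs)
  expect_identical(fp$table$pairs$ia, oracle$ia)
  expect_identical(fp$table$pairs$ib, oracle$ib)
  expect_equal(fp$table$pairs$score, oracle$score, tolerance = 1e-12)
  expect_identical(fp$surviving_a, sort(unique(oracle$ia)))
  expect_identical(fp$surviving_b, sort(unique(oracle$ib)))
})

test_that("clash detection respects the threshold and hydrogen-bond exemptions", {
  a <- rbind(O1 = c(0, 0, 0), C1 = c(1.4, 0, 0))
  expect_true(clash_check(a, a, 2.7))
  b_far <- a + 100
  expect_false(clash_check(a, b_far, 2.7))
  # a hydrogen-bonded donor/acceptor pair inside the threshold is exempt
  b <- rbind(N1 = c(0, 2.5, 0), C2 = c(0, 3.9, 0))
  expect_true(clash_check(a, b, 2.7))
  expect_false(clash_check(a, b, 2.7, exempt_pairs = rbind(c("O1", "N1"))))
  # hydrogens never count
  h <- rbind(H1 = c(0.5, 0, 0))
  expect_false(clash_check(a, h, 2.7))
  expect_error(clash_check(a, b, -1))
})

test_that("two-group assembly without constraints is the full product", {
  inst <- toy_instance()
  spec <- inst$spec
  pa <- inst$placements$G1[1:3]
  pb <- inst$placements$G2[1:4]
  # a permissive pair table connecting everything, no clashes (spread apart)
  for (i in seq_along(pa)) pa[[i]]$atoms <- pa[[i]]$atoms + 40 * i
  for (j in seq_along(pb)) pb[[j]]$atoms <- pb[[j]]$atoms - 40 * j
  tab <- structure(list(edge_id = "e_g2_g1",
                        pairs = data.frame(ia = rep(1:4, each = 3), ib = rep(1:3, 4),
                                           score = -0.5, donor_atom = "ND2",
                                           acceptor_atom = "OG",
                                           stringsAsFactors = FALSE)),
                   class = "pair_table")
  nets <- assemble_networks(spec, list(G1 = pa, G2 = pb), list(e_g2_g1 = tab))
  expect_length(nets, 12)
  # an empty pair table on any edge collapses the count to zero
  tab0 <- structure(list(edge_id = "e_g2_g1",
                         pairs = tab$pairs[0, ]), class = "pair_table")
  expect_length(assemble_networks(spec, list(G1 = pa, G2 = pb),
                                  list(e_g2_g1 = tab0)), 0)
})

test_that("assembly equals the Cartesian-product oracle on coarse instances", {
  inst <- toy_instance(g = 1.0, scheme = coarse_scheme(3))
  spec <- inst$spec
  ps <- lapply(inst$placements, function(p) p[seq_len(min(10, length(p)))])
  fp <- filter_pairs(spec$edges[["e_g2_g1"]], ps$G2, ps$G1)
  tabs <- list(e_g2_g1 = fp$table)
  nets <- assemble_networks(spec, ps, tabs, ligand = inst$ligand)
  labels <- spec$groups$label
  sig <- sort(vapply(nets, function(n) paste(n$indices[labels], collapse = ","), ""))
  expect_identical(sig, oracle_networks(spec, ps, tabs))
  # scores are sorted ascending (best first)
  scores <- vapply(nets, function(n) n$total_score, 1)
  expect_true(all(diff(scores) >= -1e-12))
  # soundness: every emitted network re-passes every specified interaction
  for (n in nets)
    expect_true(all(audit_network(n, spec, inst$ligand)))
})

test_that("a triangle spec with one empty pair table yields no networks", {
  spec <- make_toy_spec("diol_triplet")
  inst <- toy_instance(g = 1.0, scheme = coarse_scheme(2))
  ligc <- canonical_ligand(attach_sites(make_toy_ligand("diol"), spec$ligand_sites))
  ps <- lapply(spec$groups$label, function(l)
    group_candidates(ligc, spec, l, scheme = coarse_scheme(2), g = 1.0))
  names(ps) <- spec$groups$label
  gg <- Filter(function(e) !hbnetforge:::edge_touches_ligand(e), spec$edges)
  tabs <- lapply(gg, function(e) filter_pairs(e, ps[[e$a$label]], ps[[e$b$label]])$table)
  names(tabs) <- vapply(gg, function(e) e$edge_id, "")
  tabs[["e_g3_g2"]]$pairs <- tabs[["e_g3_g2"]]$pairs[0, ]
  expect_length(assemble_networks(spec, ps, tabs), 0)
  expect_error(assemble_networks(spec, ps, tabs[1]), "missing pair table")
})

test_that("tightening the hydrogen-bond window never increases the network count", {
  inst <- toy_instance()
  spec <- inst$spec
  loose <- hbond_params()
  tight <- hbond_params(d_min = 2.7, d_max = 3.0, theta_min = 150, psi_min = 110)
  count_nets <- function(params) {
    fp <- filter_pairs(spec$edges[["e_g2_g1"]], inst$placements$G2,
                       inst$placements$G1, params = params)
    length(assemble_networks(spec, inst$placements, list(e_g2_g1 = fp$table)))
  }
  expect_lte(count_nets(tight), count_nets(loose))
})

test_that("pair filtering never discards a placement used by any oracle network", {
  inst <- toy_instance(g = 1.0, scheme = coarse_scheme(3))
  spec <- inst$spec
  ps <- lapply(inst$placements, function(p) p[seq_len(min(8, length(p)))])
  fp <- filter_pairs(spec$edges[["e_g2_g1"]], ps$G2, ps$G1)
  tabs <- list(e_g2_g1 = fp$table)
  sigs <- oracle_networks(spec, ps, tabs)
  if (length(sigs)) {
    used <- do.call(rbind, lapply(strsplit(sigs, ","), as.integer))
    colnames(used) <- spec$groups$label
    expect_true(all(used[, "G2"] %in% fp$surviving_a))
    expect_true(all(used[, "G1"] %in% fp$surviving_b))
  }
  succeed()
})

test_that("assembly truncates at max_networks with a warning", {
  inst <- toy_instance()
  spec <- inst$spec
  expect_warning(
    nets <- assemble_networks(spec, inst$placements,
                              list(e_g2_g1 = inst$pairs$table),
                              ligand = inst$ligand, max_networks = 5),
    "truncated")
  expect_length(nets, 5)
})
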