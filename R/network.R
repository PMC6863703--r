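# Pairwise hydrogen-bond filtering between placement sets and assembly of
# complete, clash-free catalytic networks.

## generic edge evaluation on concrete coordinates ----------------------------

# Evaluate one spec edge given a lookup `atoms_of(label)` returning the named
# coordinate matrix of each group.  Tries every role-compatible atom pair
# (unless the edge pins atoms) and returns the best passing combination.
edge_eval_concrete <- function(edge, spec, ligand, atoms_of,
                               params = hbond_params(), cov_window = c(1.2, 1.8)) {
  ligand <- canonical_ligand(ligand)
  if (edge$kind == "covalent") {
    site <- ligand$sites[[edge$a$site]]
    tpl <- fg_template(group_fg(spec, edge$b$label))
    atoms <- atoms_of(edge$b$label)
    d <- vnorm(atoms[tpl$covalent_atom, ] - ligand$atoms[site$atom, ])
    ok <- d >= cov_window[1L] && d <= cov_window[2L]
    return(list(ok = ok, score = 0,
                donor_atom = tpl$covalent_atom, acceptor_atom = site$atom))
  }
  # donor side (end a)
  if (edge$a$type == "ligand") {
    geomD <- ligand_donor_geometry(ligand, ligand$sites[[edge$a$site]])
    donors <- list(list(D = geomD$D, H = geomD$H, name = edge$a$site))
  } else {
    tpl <- fg_template(group_fg(spec, edge$a$label))
    atoms <- atoms_of(edge$a$label)
    entries <- tpl$donors
    if (!identical(edge$a$atom, "auto"))
      entries <- Filter(function(en) en[["heavy"]] == edge$a$atom, entries)
    entries <- Filter(function(en)
      all(c(en[["heavy"]], en[["h"]]) %in% rownames(atoms)), entries)
    donors <- lapply(entries, function(en)
      list(D = atoms[en[["heavy"]], ], H = atoms[en[["h"]], ], name = en[["heavy"]]))
  }
  # acceptor side (end b)
  if (edge$b$type == "ligand") {
    geomA <- ligand_acceptor_geometry(ligand, ligand$sites[[edge$b$site]])
    acceptors <- list(list(A = geomA$A, bases = geomA$bases, name = edge$b$site))
  } else {
    tpl <- fg_template(group_fg(spec, edge$b$label))
    atoms <- atoms_of(edge$b$label)
    entries <- tpl$acceptors
    if (!identical(edge$b$atom, "auto"))
      entries <- Filter(function(en) en$heavy == edge$b$atom, entries)
    entries <- Filter(function(en)
      all(c(en$heavy, en$bases) %in% rownames(atoms)), entries)
    acceptors <- lapply(entries, function(en)
      list(A = atoms[en$heavy, ], bases = atoms[en$bases, , drop = FALSE], name = en$heavy))
  }
  best <- list(ok = FALSE, score = 0, donor_atom = NA_character_, acceptor_atom = NA_character_)
  for (dn in donors) for (ac in acceptors) {
    ev <- hbond_eval(dn$D, dn$H, ac$A, ac$bases, params, overlap = "reject")
    if (ev$ok && (!best$ok || ev$score < best$score))
      best <- list(ok = TRUE, score = ev$score, donor_atom = dn$name, acceptor_atom = ac$name)
  }
  best
}

## spatial bucketing ----------------------------------------------------------

# candidate index pairs (i in A, j in B) with |A_i - B_j| <= cutoff, found via
# cell lists; exactly the pairs an all-pairs scan within the cutoff would give
neighbor_pairs <- function(A, B, cutoff) {
  if (!nrow(A) || !nrow(B)) return(cbind(integer(0), integer(0)))
  cellB <- floor(B / cutoff)
  keyB <- key_string(cellB)
  buckets <- split(seq_len(nrow(B)), keyB)
  cellA <- floor(A / cutoff)
  out_i <- integer(0); out_j <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    neigh <- sweep(offs, 2L, as.numeric(cellA[i, ]), `+`)
    keys <- key_string(neigh)
    js <- unlist(buckets[keys], use.names = FALSE)
    if (length(js)) {
      d2 <- (B[js, 1L] - A[i, 1L])^2 + (B[js, 2L] - A[i, 2L])^2 + (B[js, 3L] - A[i, 3L])^2
      js <- js[d2 <= cutoff^2]
      out_i <- c(out_i, rep.int(i, length(js)))
      out_j <- c(out_j, js)
    }
  }
  cbind(out_i, out_j)
}

## pair filtering -------------------------------------------------------------

#' Filter two placement sets on a group-group hydrogen-bond edge
#'
#' Every pair of placements for the edge's two endpoints is queried for the
#' presence of the specified hydrogen bond; placements that make the bond with
#' no placement of the partner group are discarded.  Spatial bucketing keeps
#' the scan near-linear, but the output is exactly that of an all-pairs scan.
#'
#' @param edge a resolved group-group hydrogen-bond edge (end a = donor)
#' @param placements_a placements of the donor-end group
#' @param placements_b placements of the acceptor-end group
#' @param params an \code{\link{hbond_params}}
#' @return list with \code{table} (a \code{pair_table}: data.frame ia, ib,
#'   score, donor_atom, acceptor_atom), \code{surviving_a}, \code{surviving_b}
#'   (index vectors)
#' @export
filter_pairs <- function(edge, placements_a, placements_b, params = hbond_params()) {
  empty <- list(
    table = structure(list(edge_id = edge$edge_id,
                           pairs = data.frame(ia = integer(0), ib = integer(0),
                                              score = numeric(0),
                                              donor_atom = character(0),
                                              acceptor_atom = character(0),
                                              stringsAsFactors = FALSE)),
                      class = "pair_table"),
    surviving_a = integer(0), surviving_b = integer(0))
  if (!length(placements_a) || !length(placements_b)) return(empty)
  if (edge$kind != "hbond")
    stop("hbnetforge error: filter_pairs applies to hydrogen-bond edges")
  tpl_a <- fg_template(placements_a[[1L]]$fg_name)
  tpl_b <- fg_template(placements_b[[1L]]$fg_name)
  donor_entries <- tpl_a$donors
  if (!identical(edge$a$atom, "auto"))
    donor_entries <- Filter(function(en) en[["heavy"]] == edge$a$atom, donor_entries)
  acc_entries <- tpl_b$acceptors
  if (!identical(edge$b$atom, "auto"))
    acc_entries <- Filter(function(en) en$heavy == edge$b$atom, acc_entries)
  if (!length(donor_entries) || !length(acc_entries))
    stop(sprintf("hbnetforge spec error: edge '%s' has no role-compatible atoms", edge$edge_id))

  best <- new.env(parent = emptyenv())
  for (dn in donor_entries) {
    has_d <- vapply(placements_a, function(p)
      all(c(dn[["heavy"]], dn[["h"]]) %in% rownames(p$atoms)), TRUE)
    if (!any(has_d)) next
    Da <- do.call(rbind, lapply(placements_a, function(p)
      if (all(c(dn[["heavy"]], dn[["h"]]) %in% rownames(p$atoms)))
        p$atoms[dn[["heavy"]], ] else c(Inf, Inf, Inf)))
    Ha <- do.call(rbind, lapply(placements_a, function(p)
      if (all(c(dn[["heavy"]], dn[["h"]]) %in% rownames(p$atoms)))
        p$atoms[dn[["h"]], ] else c(Inf, Inf, Inf)))
    for (ac in acc_entries) {
      Ab <- do.call(rbind, lapply(placements_b, function(p) p$atoms[ac$heavy, ]))
      idx <- neighbor_pairs(Da[has_d, , drop = FALSE], Ab, cutoff = params$d_max)
      if (!nrow(idx)) next
      map_a <- which(has_d)
      ia <- map_a[idx[, 1L]]; ib <- idx[, 2L]
      bases <- lapply(ac$bases, function(bn)
        do.call(rbind, lapply(placements_b[ib], function(p) p$atoms[bn, ])))
      ev <- hbond_geom_n(Da[ia, , drop = FALSE], Ha[ia, , drop = FALSE],
                         Ab[ib, , drop = FALSE], bases, params, overlap = "reject")
      hit <- which(ev$ok)
      for (h in hit) {
        key <- paste(ia[h], ib[h], sep = ":")
        prev <- best[[key]]
        if (is.null(prev) || ev$score[h] < prev$score)
          best[[key]] <- list(ia = ia[h], ib = ib[h], score = ev$score[h],
                              donor_atom = dn[["heavy"]], acceptor_atom = ac$heavy)
      }
    }
  }
  keys <- ls(best)
  if (!length(keys)) return(empty)
  rows <- lapply(keys, function(k) best[[k]])
  pairs <- data.frame(ia = vapply(rows, function(r) r$ia, 1L),
                      ib = vapply(rows, function(r) r$ib, 1L),
                      score = vapply(rows, function(r) r$score, 1),
                      donor_atom = vapply(rows, function(r) r$donor_atom, ""),
                      acceptor_atom = vapply(rows, function(r) r$acceptor_atom, ""),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$ia, pairs$ib), , drop = FALSE]
  rownames(pairs) <- NULL
  list(table = structure(list(edge_id = edge$edge_id, pairs = pairs), class = "pair_table"),
       surviving_a = sort(unique(pairs$ia)),
       surviving_b = sort(unique(pairs$ib)))
}

## clash checking -------------------------------------------------------------

#' Heavy-atom clash check between two atom sets
#'
#' @param atoms_a,atoms_b coordinate matrices with atom-name rownames
#' @param threshold minimum allowed heavy-atom separation (Angstrom)
#' @param exempt_pairs optional 2-column character matrix of (name in a, name
#'   in b) pairs that may be close (hydrogen-bonded partners)
#' @return TRUE iff any non-exempt heavy-atom pair is below the threshold
#' @export
clash_check <- function(atoms_a, atoms_b, threshold = 2.7, exempt_pairs = NULL) {
  stopifnot(threshold > 0)
  ha <- atoms_a[element_of(rownames(atoms_a)) != "H", , drop = FALSE]
  hb <- atoms_b[element_of(rownames(atoms_b)) != "H", , drop = FALSE]
  if (!nrow(ha) || !nrow(hb)) return(FALSE)
  for (i in seq_len(nrow(ha))) {
    d2 <- (hb[, 1L] - ha[i, 1L])^2 + (hb[, 2L] - ha[i, 2L])^2 + (hb[, 3L] - ha[i, 3L])^2
    close_j <- which(d2 < threshold^2)
    for (j in close_j) {
      nm_a <- rownames(ha)[i]; nm_b <- rownames(hb)[j]
      exempt <- !is.null(exempt_pairs) && any(
        (exempt_pairs[, 1L] == nm_a & exempt_pairs[, 2L] == nm_b) |
        (exempt_pairs[, 1L] == nm_b & exempt_pairs[, 2L] == nm_a))
      if (!exempt) return(TRUE)
    }
  }
  FALSE
}

## network assembly ------------------------------------------------------------

new_network <- function(assignment, indices, edge_scores, total_score) {
  structure(list(assignment = assignment, indices = indices,
                 edge_scores = edge_scores, total_score = total_score,
                 clash = FALSE),
            class = "network_configuration")
}

#' @export
print.network_configuration <- function(x, ...) {
  cat(sprintf("Network configuration: %d group(s), total score %.3f\n",
              length(x$assignment), x$total_score))
  invisible(x)
}

#' Assemble complete hydrogen-bond networks from filtered placement sets
#'
#' Backtracking search over groups in spec order (candidate placements in
#' best-score-first order): one placement per group such that every
#' group-group edge is realized by a pair listed in its pair table and no two
#' groups clash (hydrogen-bonded partner atoms exempt).  Ligand-edge validity
#' is already encoded in the placement sets.  Output networks are sorted by
#' ascending total score (sum of all edge scores) and truncated at
#' \code{max_networks} with a warning.
#'
#' @param spec an \code{active_site_spec}
#' @param placement_sets named list (by group label) of placement lists
#' @param pair_tables named list (by edge id) of \code{pair_table}s for every
#'   group-group edge
#' @param clash_threshold heavy-atom clash threshold between groups (Angstrom);
#'   \code{0} disables the steric filter (pure connectivity enumeration)
#' @param max_networks cap on the number of returned networks
#' @param ligand optional \code{ligand_model}; when supplied, per-ligand-edge
#'   scores are included in the total score
#' @param params an \code{\link{hbond_params}} (ligand-edge rescoring)
#' @return list of \code{network_configuration} objects
#' @export
assemble_networks <- function(spec, placement_sets, pair_tables,
                              clash_threshold = 2.7, max_networks = 2e6,
                              ligand = NULL, params = hbond_params()) {
  labels <- spec$groups$label
  stopifnot(all(labels %in% names(placement_sets)))
  gg_edges <- Filter(function(e) !edge_touches_ligand(e), spec$edges)
  for (e in gg_edges)
    if (is.null(pair_tables[[e$edge_id]]))
      stop(sprintf("hbnetforge error: missing pair table for edge '%s'", e$edge_id))

  # candidate order: best score first, then index (deterministic)
  cand_order <- lapply(labels, function(lab) {
    ps <- placement_sets[[lab]]
    if (!length(ps)) return(integer(0))
    sc <- vapply(ps, function(p) p$score, 1)
    order(sc, seq_along(sc))
  })
  names(cand_order) <- labels

  # pair lookup sets and per-edge score/atom maps
  pair_env <- new.env(parent = emptyenv())
  for (e in gg_edges) {
    tab <- pair_tables[[e$edge_id]]$pairs
    for (r in seq_len(nrow(tab)))
      assign(paste(e$edge_id, tab$ia[r], tab$ib[r], sep = "|"),
             list(score = tab$score[r], donor_atom = tab$donor_atom[r],
                  acceptor_atom = tab$acceptor_atom[r]),
             envir = pair_env)
  }
  # per-group ligand edge scores (cached per candidate)
  lig_scores <- lapply(labels, function(lab) {
    edges <- group_edges(spec, lab, ligand_only = TRUE)
    ps <- placement_sets[[lab]]
    sapply(edges, function(e) {
      if (is.null(ligand)) return(rep(0, length(ps)))
      vapply(ps, function(p) placement_edge_ok(p, e, ligand, params)$score, 1)
    }, simplify = FALSE)
  })
  names(lig_scores) <- labels

  # edges between group k and previously assigned groups, with donor side flag
  edges_to_prev <- lapply(seq_along(labels), function(k) {
    lab <- labels[k]
    prev <- labels[seq_len(k - 1L)]
    out <- list()
    for (e in gg_edges) {
      gl <- edge_group_labels(e)
      if (lab %in% gl) {
        other <- setdiff(gl, lab)
        if (length(other) == 1L && other %in% prev)
          out[[length(out) + 1L]] <- list(edge = e, other = other,
                                          this_is_a = (e$a$label == lab))
      }
    }
    out
  })

  results <- list()
  n_found <- 0L
  truncated <- FALSE
  assign_idx <- integer(length(labels))

  recurse <- function(k) {
    if (truncated) return(invisible())
    if (k > length(labels)) {
      idx <- assign_idx
      names(idx) <- labels
      assignment <- lapply(seq_along(labels), function(j)
        placement_sets[[labels[j]]][[idx[j]]])
      names(assignment) <- labels
      edge_scores <- numeric(0)
      for (e in gg_edges) {
        rec <- get(paste(e$edge_id, idx[[e$a$label]], idx[[e$b$label]], sep = "|"),
                   envir = pair_env)
        edge_scores[e$edge_id] <- rec$score
      }
      for (j in seq_along(labels)) {
        lab <- labels[j]
        les <- lig_scores[[lab]]
        if (length(les))
          for (m in seq_along(les)) {
            eid <- group_edges(spec, lab, ligand_only = TRUE)[[m]]$edge_id
            edge_scores[eid] <- les[[m]][idx[j]]
          }
      }
      results[[length(results) + 1L]] <<- new_network(
        assignment, idx, edge_scores, sum(edge_scores))
      n_found <<- n_found + 1L
      if (n_found >= max_networks) truncated <<- TRUE
      return(invisible())
    }
    lab <- labels[k]
    for (ci in cand_order[[lab]]) {
      if (truncated) return(invisible())
      p <- placement_sets[[lab]][[ci]]
      ok <- TRUE
      exempts <- list()
      for (ep in edges_to_prev[[k]]) {
        oi <- assign_idx[match(ep$other, labels)]
        key <- if (ep$this_is_a) paste(ep$edge$edge_id, ci, oi, sep = "|")
               else paste(ep$edge$edge_id, oi, ci, sep = "|")
        rec <- pair_env[[key]]
        if (is.null(rec)) { ok <- FALSE; break }
        exempts[[ep$other]] <- rbind(exempts[[ep$other]],
                                     c(rec$donor_atom, rec$acceptor_atom))
      }
      if (ok && clash_threshold > 0) {
        for (j in seq_len(k - 1L)) {
          pj <- placement_sets[[labels[j]]][[assign_idx[j]]]
          if (clash_check(p$atoms, pj$atoms, clash_threshold,
                          exempt_pairs = exempts[[labels[j]]])) { ok <- FALSE; break }
        }
      }
      if (ok) {
        assign_idx[k] <<- ci
        recurse(k + 1L)
        assign_idx[k] <<- 0L
      }
    }
    invisible()
  }
  recurse(1L)
  if (truncated)
    warning(sprintf("assemble_networks: output truncated at max_networks = %d", max_networks))
  ord <- order(vapply(results, function(n) n$total_score, 1),
               vapply(results, function(n) paste(n$indices, collapse = ","), ""))
  results[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-audit a network against every specified interaction
#'
#' @param network a \code{network_configuration}
#' @param spec an \code{active_site_spec}
#' @param ligand the \code{ligand_model}
#' @param params an \code{\link{hbond_params}}
#' @return named logical vector, one flag per spec edge
#' @export
audit_network <- function(network, spec, ligand, params = hbond_params()) {
  atoms_of <- function(label) network$assignment[[label]]$atoms
  flags <- vapply(spec$edges, function(e)
    edge_eval_concrete(e, spec, ligand, atoms_of, params)$ok, TRUE)
  names(flags) <- names(spec$edges)
  flags
}
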