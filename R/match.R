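# Placement of networks into scaffold backbones via rigid-body transform
# hashing, and evaluation of network completeness.
#
# For every (designable position, inverse rotamer) combination the rotamer's
# backbone frame is superposed onto the scaffold position; the implied ligand
# pose is quantized into a 6-D bin (translation grid + quantized quaternion
# cells).  A match is a bin holding at least one entry for every group at
# pairwise-distinct positions; each combination is rebuilt in full
# coordinates, clash-checked and completeness-evaluated.

#' Matcher parameters
#'
#' @param trans_bin translation bin size of the ligand-pose hash (Angstrom)
#' @param orient_bin orientation bin size (degrees)
#' @param per_bin_cap maximum rotamer entries retained per bin per group
#'   (pruning; 0 disables the cap)
#' @param bb_clash backbone clash threshold (Angstrom)
#' @param combo_cap maximum full-coordinate rebuilds per bin
#' @return object of class \code{match_params}
#' @export
match_params <- function(trans_bin = 1.0, orient_bin = 10, per_bin_cap = 100,
                         bb_clash = 2.8, combo_cap = 1000) {
  stopifnot(trans_bin > 0, orient_bin > 0, per_bin_cap >= 0, combo_cap >= 1)
  structure(list(trans_bin = trans_bin, orient_bin = orient_bin,
                 per_bin_cap = per_bin_cap, bb_clash = bb_clash,
                 combo_cap = combo_cap), class = "match_params")
}

#' Fine-binned matcher parameters (per-network verification regime)
#' @return a \code{match_params} with 0.25 A / 2.5 degree bins
#' @export
fine_match_params <- function() match_params(trans_bin = 0.25, orient_bin = 2.5)

# 6-D bin key of a ligand pose: rounded translation bins + quantized
# canonical-sign quaternion cells.  Values are pre-rounded to 1e-9 so keys
# are bit-stable under the canonical-frame convention.
pose_bin_key <- function(transform, params) {
  tk <- round_half_away(round(transform$t, 9L) / params$trans_bin)
  q <- quat_from_rotation(transform$R)
  delta <- deg2rad(params$orient_bin) / 2
  qk <- round_half_away(round(q, 9L) / delta)
  paste(c(tk, qk), collapse = ",")
}

#' Build the transform hash for one group on one scaffold
#'
#' For each designable position and each realization, the realization's
#' backbone frame is superposed onto the scaffold residue (least squares), the
#' implied ligand pose is derived and quantized into a 6-D bin, and the entry
#' (position, realization, transform) is recorded.  Entries whose side-chain
#' atoms clash with the scaffold backbone (host residue excluded) are
#' dropped; an optional per-bin cap keeps the best-scoring entries in
#' deterministic order.
#'
#' @param scaffold a \code{scaffold_model} (canonicalised internally)
#' @param group group label (recorded in the entries)
#' @param realizations list of \code{side_chain_realization}s
#' @param params a \code{\link{match_params}}
#' @return named list: bin key -> list of entries
#' @export
build_transform_hash <- function(scaffold, group, realizations, params = match_params()) {
  scaffold <- canonical_scaffold(scaffold)
  npos <- n_residues(scaffold)
  bins <- new.env(parent = emptyenv())
  order_keys <- character(0)
  positions <- which(scaffold$designable)
  for (pi in positions) {
    frame_s <- residue_frame(scaffold, pi)
    bb_other <- scaffold_backbone_atoms(scaffold, exclude = pi)
    for (ri in seq_along(realizations)) {
      r <- realizations[[ri]]
      ds <- as.numeric(stats::dist(frame_s)); dr <- as.numeric(stats::dist(r$backbone_frame))
      if (max(abs(ds - dr)) > 0.3) next  # grossly incompatible backbone geometry
      tr <- superpose_lsq(r$backbone_frame, frame_s)
      side <- r$atoms[setdiff(rownames(r$atoms), c("N", "CA", "C")), , drop = FALSE]
      side <- side[element_of(rownames(side)) != "H", , drop = FALSE]
      sw <- apply_transform(tr, side)
      clash <- FALSE
      if (nrow(bb_other)) {
        for (i in seq_len(nrow(sw))) {
          d2 <- (bb_other[, 1L] - sw[i, 1L])^2 + (bb_other[, 2L] - sw[i, 2L])^2 +
                (bb_other[, 3L] - sw[i, 3L])^2
          if (any(d2 < params$bb_clash^2)) { clash <- TRUE; break }
        }
      }
      if (clash) next
      key <- pose_bin_key(tr, params)
      entry <- list(group = group, position = pi, realization = ri, transform = tr,
                    score = r$placement$score)
      cur <- bins[[key]]
      if (is.null(cur)) order_keys <- c(order_keys, key)
      bins[[key]] <- c(cur, list(entry))
    }
  }
  out <- stats::setNames(lapply(order_keys, function(k) bins[[k]]), order_keys)
  if (params$per_bin_cap > 0L) {
    out <- lapply(out, function(entries) {
      sc <- vapply(entries, function(e) e$score, 1)
      pos <- vapply(entries, function(e) e$position, 1L)
      ri <- vapply(entries, function(e) e$realization, 1L)
      entries[order(sc, pos, ri)][seq_len(min(length(entries), params$per_bin_cap))]
    })
  }
  out[order(names(out))]
}

new_match_result <- function(scaffold_id, bin, ligand_pose, assignments,
                             group_atoms, edge_flags, complete) {
  structure(list(scaffold_id = scaffold_id, bin = bin, ligand_pose = ligand_pose,
                 assignments = assignments, group_atoms = group_atoms,
                 edge_flags = edge_flags, complete = complete),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match on %s [%s]: positions %s; %d/%d edges realized; %s\n",
              x$scaffold_id, x$bin,
              paste(x$assignments$position, collapse = ","),
              sum(x$edge_flags), length(x$edge_flags),
              if (x$complete) "COMPLETE" else "incomplete"))
  invisible(x)
}

#' Evaluate the completeness of a rebuilt match
#'
#' A match is complete iff every spec edge (ligand-group and group-group,
#' hydrogen-bond or covalent) is realized in the placed geometry.
#'
#' @param match a \code{match_result} (with rebuilt group coordinates)
#' @param spec an \code{active_site_spec}
#' @param ligand the \code{ligand_model}
#' @param params an \code{\link{hbond_params}}
#' @return list with \code{complete} and named per-edge logical \code{flags}
#' @export
evaluate_completeness <- function(match, spec, ligand, params = hbond_params()) {
  atoms_of <- function(label) match$group_atoms[[label]]
  flags <- vapply(spec$edges, function(e)
    edge_eval_concrete(e, spec, ligand, atoms_of, params)$ok, TRUE)
  names(flags) <- names(spec$edges)
  list(complete = all(flags), flags = flags)
}

# enumerate index combinations (one entry per group) with distinct positions,
# in deterministic order, capped
combo_indices <- function(entry_lists, cap) {
  n_groups <- length(entry_lists)
  out <- list()
  idx <- integer(n_groups)
  recurse <- function(k, used) {
    if (length(out) >= cap) return(invisible())
    if (k > n_groups) { out[[length(out) + 1L]] <<- idx; return(invisible()) }
    for (i in seq_along(entry_lists[[k]])) {
      p <- entry_lists[[k]][[i]]$position
      if (p %in% used) next
      idx[k] <<- i
      recurse(k + 1L, c(used, p))
      if (length(out) >= cap) return(invisible())
    }
    invisible()
  }
  recurse(1L, integer(0))
  out
}

# core matcher: one scaffold, named realization sets per group.
# Results are deduplicated on (scaffold, ligand bin, position set); the
# representative kept for each signature is the combination realizing the
# most specified interactions (a complete one whenever any combination in the
# bin is complete), so a placement is judged by its best rotamer combination.
match_rotamer_sets <- function(scaffold, spec, ligand, realization_sets,
                               params, hb_params, results_env = NULL) {
  scaffold <- canonical_scaffold(scaffold)
  ligand <- canonical_ligand(attach_sites(ligand, spec$ligand_sites))
  labels <- spec$groups$label
  own <- is.null(results_env)
  if (own) {
    results_env <- new.env(parent = emptyenv())
    results_env$by_key <- new.env(parent = emptyenv())
    results_env$order <- character(0)
  }
  if (sum(scaffold$designable) < length(labels)) {
    if (own) return(collect_matches(results_env)) else return(invisible())
  }
  hashes <- lapply(labels, function(lab)
    build_transform_hash(scaffold, lab, realization_sets[[lab]], params))
  names(hashes) <- labels
  common <- Reduce(intersect, lapply(hashes, names))
  lig_heavy <- ligand$atoms[ligand$elements != "H", , drop = FALSE]
  for (key in sort(common)) {
    entry_lists <- lapply(hashes, function(h) h[[key]])
    combos <- combo_indices(entry_lists, params$combo_cap)
    for (cmb in combos) {
      entries <- lapply(seq_along(labels), function(k) entry_lists[[k]][[cmb[k]]])
      positions <- vapply(entries, function(e) e$position, 1L)
      dkey <- paste(scaffold$id, key, paste(sort(positions), collapse = "/"), sep = "|")
      prev <- results_env$by_key[[dkey]]
      if (!is.null(prev) && prev$complete) next  # cannot be improved
      T1 <- entries[[1L]]$transform
      T1inv <- transform_inverse(T1)
      # ligand placed by the first group's pose: clash vs scaffold backbone
      ligw <- apply_transform(T1, lig_heavy)
      bb <- scaffold_backbone_atoms(scaffold, exclude = positions)
      clash <- FALSE
      if (nrow(bb)) {
        for (i in seq_len(nrow(ligw))) {
          d2 <- (bb[, 1L] - ligw[i, 1L])^2 + (bb[, 2L] - ligw[i, 2L])^2 +
                (bb[, 3L] - ligw[i, 3L])^2
          if (any(d2 < params$bb_clash^2)) { clash <- TRUE; break }
        }
      }
      if (clash) next
      # rebuild all groups in the ligand frame implied by the first entry
      group_atoms <- lapply(seq_along(labels), function(k) {
        r <- realization_sets[[labels[k]]][[entries[[k]]$realization]]
        apply_transform(transform_compose(T1inv, entries[[k]]$transform), r$atoms)
      })
      names(group_atoms) <- labels
      assignments <- data.frame(
        group = labels,
        chain = scaffold$chain[positions],
        resnum = scaffold$resnum[positions],
        position = positions,
        identity = vapply(seq_along(labels), function(k)
          realization_sets[[labels[k]]][[entries[[k]]$realization]]$residue_identity, ""),
        chi = vapply(seq_along(labels), function(k)
          paste(round(realization_sets[[labels[k]]][[entries[[k]]$realization]]$chi_angles, 1),
                collapse = ";"), ""),
        stringsAsFactors = FALSE)
      m <- new_match_result(scaffold$id, key, T1, assignments, group_atoms,
                            edge_flags = logical(0), complete = NA)
      ev <- evaluate_completeness(m, spec, ligand, hb_params)
      m$edge_flags <- ev$flags
      m$complete <- ev$complete
      if (is.null(prev)) {
        results_env$by_key[[dkey]] <- m
        results_env$order <- c(results_env$order, dkey)
      } else if (sum(m$edge_flags) > sum(prev$edge_flags)) {
        results_env$by_key[[dkey]] <- m
      }
    }
  }
  if (own) collect_matches(results_env) else invisible()
}

collect_matches <- function(results_env) {
  lapply(results_env$order, function(k) results_env$by_key[[k]])
}

# deduplicate realizations pooled across networks: one entry per distinct
# (rounded atom coordinates) rotamer
dedupe_realizations <- function(rs) {
  if (!length(rs)) return(rs)
  sig <- vapply(rs, function(r)
    paste(round(as.numeric(r$atoms) * 1e3), collapse = ","), "")
  rs[!duplicated(sig)]
}

#' Find placements of networks in a scaffold
#'
#' Four matching modes are supported:
#' \describe{
#'   \item{per_network}{a separate matching calculation per network, using
#'     only that network's side-chain conformations; by construction, any
#'     match that realizes all groups tends to be fully connected}
#'   \item{pooled}{side-chain conformations from all networks pooled into one
#'     calculation; efficient, but conformations from different networks can
#'     be remixed, producing partial networks}
#'   \item{clustered}{a separate pooled calculation per cluster of networks,
#'     retaining most intra-network side-chain dependencies}
#'   \item{residue}{each group's rotamers regenerated independently from its
#'     ligand interaction alone (no network information), the classical
#'     residue-based matching baseline}
#' }
#'
#' @param scaffold a \code{scaffold_model}
#' @param spec an \code{active_site_spec}
#' @param ligand the \code{ligand_model}
#' @param networks list of \code{network_configuration}s (ignored in
#'   \code{residue} mode)
#' @param mode one of "per_network", "pooled", "clustered", "residue"
#' @param params a \code{\link{match_params}}
#' @param hb_params an \code{\link{hbond_params}}
#' @param clusters a \code{cluster_set} (required for \code{clustered} mode)
#' @param identities named character vector group label -> residue identity
#'   (default: first allowed identity of each group's template)
#' @param chi_samples torsion samples for \code{\link{inverse_rotamers}}
#' @param enum_opts list of enumeration options for \code{residue} mode
#'   (\code{scheme}, \code{g}, \code{clash_min})
#' @return list of \code{match_result}s, deduplicated on
#'   (scaffold, ligand bin, position set), in deterministic order
#' @export
find_matches <- function(scaffold, spec, ligand, networks = NULL,
                         mode = c("per_network", "pooled", "clustered", "residue"),
                         params = match_params(), hb_params = hbond_params(),
                         clusters = NULL, identities = NULL,
                         chi_samples = c(-60, 60, 180),
                         enum_opts = list()) {
  mode <- match.arg(mode)
  labels <- spec$groups$label
  ligand <- canonical_ligand(attach_sites(ligand, spec$ligand_sites))
  if (is.null(identities)) {
    identities <- vapply(labels, function(lab)
      fg_template(group_fg(spec, lab))$residues[1L], "")
    names(identities) <- labels
  }
  realize_net <- function(net) {
    rs <- lapply(labels, function(lab)
      inverse_rotamers(net$assignment[[lab]], identities[[lab]], chi_samples,
                       ligand = ligand))
    names(rs) <- labels
    rs
  }
  if (mode == "residue") {
    scheme <- enum_opts$scheme %||% sampling_scheme()
    g <- enum_opts$g %||% 0.2
    clash_min <- enum_opts$clash_min %||% 2.7
    sets <- lapply(labels, function(lab) {
      pls <- group_candidates(ligand, spec, lab, scheme = scheme,
                              params = hb_params, g = g, clash_min = clash_min)
      dedupe_realizations(unlist(lapply(pls, function(p)
        inverse_rotamers(p, identities[[lab]], chi_samples, ligand = ligand)),
        recursive = FALSE))
    })
    names(sets) <- labels
    return(match_rotamer_sets(scaffold, spec, ligand, sets, params, hb_params))
  }
  if (is.null(networks) || !length(networks)) return(list())
  if (mode == "pooled") {
    all_rs <- lapply(networks, realize_net)
    sets <- lapply(labels, function(lab)
      dedupe_realizations(unlist(lapply(all_rs, `[[`, lab), recursive = FALSE)))
    names(sets) <- labels
    return(match_rotamer_sets(scaffold, spec, ligand, sets, params, hb_params))
  }
  results_env <- new.env(parent = emptyenv())
  results_env$by_key <- new.env(parent = emptyenv())
  results_env$order <- character(0)
  if (mode == "per_network") {
    for (net in networks)
      match_rotamer_sets(scaffold, spec, ligand, realize_net(net), params,
                         hb_params, results_env = results_env)
    return(collect_matches(results_env))
  }
  # clustered
  if (is.null(clusters))
    stop("hbnetforge value error: clustered mode requires a cluster_set")
  all_rs <- lapply(networks, realize_net)
  for (cid in seq_len(clusters$k)) {
    members <- which(clusters$assignment == cid)
    if (!length(members)) next
    sets <- lapply(labels, function(lab)
      dedupe_realizations(unlist(lapply(all_rs[members], `[[`, lab), recursive = FALSE)))
    names(sets) <- labels
    match_rotamer_sets(scaffold, spec, ligand, sets, params, hb_params,
                       results_env = results_env)
  }
  collect_matches(results_env)
}

## completion reporting --------------------------------------------------------

fmt_rate <- function(rate) {
  if (!is.finite(rate)) return("n/a")
  if (abs(rate) >= 0.1) sprintf("%.2f%%", rate) else sprintf("%.3f%%", rate)
}

#' Completion report over matches (or over printed counts)
#'
#' For each simulation the report gives the number of incomplete and complete
#' matches and the completion rate, defined as 100 * complete / incomplete
#' count (the ratio of the two table columns); the rate relative to the total
#' (complete / (complete + incomplete)) is also reported as
#' \code{rate_total}.  Division by zero yields "n/a".
#'
#' @param matches list of \code{match_result}s, or a named list of such lists
#'   (one per simulation); alternatively NULL when counts are given directly
#' @param counts optional data.frame with columns \code{label},
#'   \code{n_incomplete}, \code{n_complete} (e.g. printed literature counts)
#' @return object of class \code{completion_report}: a data.frame with counts,
#'   numeric rates and formatted rates
#' @export
completion_report <- function(matches = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(matches)) stop("hbnetforge error: provide matches or counts")
    if (length(matches) && inherits(matches[[1L]], "match_result"))
      matches <- list(matches = matches)
    counts <- do.call(rbind, lapply(names(matches), function(nm) {
      comp <- vapply(matches[[nm]], function(m) isTRUE(m$complete), TRUE)
      data.frame(label = nm, n_incomplete = sum(!comp), n_complete = sum(comp),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(counts))
      counts <- data.frame(label = character(0), n_incomplete = integer(0),
                           n_complete = integer(0), stringsAsFactors = FALSE)
  }
  rate <- ifelse(counts$n_incomplete > 0,
                 100 * counts$n_complete / counts$n_incomplete, NA_real_)
  total <- counts$n_incomplete + counts$n_complete
  rate_total <- ifelse(total > 0, 100 * counts$n_complete / total, NA_real_)
  rate[counts$n_complete == 0 & counts$n_incomplete > 0] <- 0
  out <- data.frame(counts,
                    rate = rate, rate_total = rate_total,
                    rate_fmt = vapply(rate, fmt_rate, ""),
                    rate_total_fmt = vapply(rate_total, fmt_rate, ""),
                    stringsAsFactors = FALSE)
  class(out) <- c("completion_report", "data.frame")
  out
}

#' @export
print.completion_report <- function(x, ...) {
  cat("Completion report\n")
  cat(sprintf("%-28s %12s %12s %12s %12s\n", "simulation", "incomplete",
              "complete", "rate", "rate(total)"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s %12d %12d %12s %12s\n", x$label[i], x$n_incomplete[i],
                x$n_complete[i], x$rate_fmt[i], x$rate_total_fmt[i]))
  invisible(x)
}

#' Write a completion report as TSV
#' @param report a \code{completion_report}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_completion_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report)[, c("label", "n_incomplete", "n_complete",
                                               "rate", "rate_total")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
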