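# End-to-end pipeline driver and run-level reporting.

#' Pipeline configuration
#'
#' One configuration object governs every stage; a serialized copy is embedded
#' in each run summary for provenance.
#'
#' @param grid grid spacing g for placement deduplication (Angstrom)
#' @param hbond an \code{\link{hbond_params}}
#' @param scheme a \code{\link{sampling_scheme}}
#' @param clash_threshold inter-group heavy-atom clash threshold (Angstrom;
#'   0 disables the steric filter)
#' @param max_networks cap on assembled networks
#' @param cluster_k target cluster count
#' @param cluster_seed k-means seed
#' @param match a \code{\link{match_params}}
#' @param chi_samples torsion samples for inverse rotamers
#' @param identities optional named vector group label -> residue identity
#' @param realize_report_max number of best networks for which full
#'   realization counts are enumerated in the summary
#' @param stages named logical toggles: \code{realize}, \code{cluster},
#'   \code{match}
#' @param match_mode default matching mode for \code{\link{run_pipeline}}
#' @return object of class \code{run_config}
#' @export
run_config <- function(grid = 0.2, hbond = hbond_params(), scheme = sampling_scheme(),
                       clash_threshold = 2.7, max_networks = 2e6,
                       cluster_k = 250, cluster_seed = 2019,
                       match = match_params(), chi_samples = c(-60, 60, 180),
                       identities = NULL, realize_report_max = 100,
                       stages = list(realize = TRUE, cluster = TRUE, match = TRUE),
                       match_mode = "pooled") {
  stopifnot(grid > 0, cluster_k >= 1)
  structure(list(grid = grid, hbond = hbond, scheme = scheme,
                 clash_threshold = clash_threshold, max_networks = max_networks,
                 cluster_k = cluster_k, cluster_seed = cluster_seed,
                 match = match, chi_samples = chi_samples, identities = identities,
                 realize_report_max = realize_report_max,
                 stages = utils::modifyList(list(realize = TRUE, cluster = TRUE,
                                                 match = TRUE), stages),
                 match_mode = match_mode),
            class = "run_config")
}

#' Run the full pipeline: enumerate, filter, assemble, realize, cluster, match
#'
#' @param config a \code{\link{run_config}}
#' @param ligand a \code{ligand_model}
#' @param spec an \code{active_site_spec}
#' @param scaffolds optional list of \code{scaffold_model}s to match into
#' @return object of class \code{run_summary} with per-stage counts, the
#'   assembled networks, matches and the completion report
#' @export
run_pipeline <- function(config, ligand, spec, scaffolds = NULL) {
  stopifnot(inherits(config, "run_config"))
  ligand <- canonical_ligand(attach_sites(ligand, spec$ligand_sites))
  labels <- spec$groups$label
  summary <- list(config = config, spec_name = spec$name, ligand_name = ligand$name)

  # enumerate ------------------------------------------------------------------
  placement_sets <- withCallingHandlers(
    lapply(labels, function(lab)
      group_candidates(ligand, spec, lab, scheme = config$scheme,
                       params = config$hbond, g = config$grid,
                       clash_min = config$clash_threshold)),
    error = function(e) stop(sprintf("pipeline stage 'enumerate' failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  names(placement_sets) <- labels
  summary$placements <- vapply(placement_sets, length, 1L)

  # pair filtering -------------------------------------------------------------
  gg_edges <- Filter(function(e) !edge_touches_ligand(e), spec$edges)
  pair_tables <- list()
  surviving <- lapply(placement_sets, function(ps) seq_along(ps))
  names(surviving) <- labels
  for (e in gg_edges) {
    fp <- filter_pairs(e, placement_sets[[e$a$label]], placement_sets[[e$b$label]],
                       params = config$hbond)
    pair_tables[[e$edge_id]] <- fp$table
    surviving[[e$a$label]] <- intersect(surviving[[e$a$label]], fp$surviving_a)
    surviving[[e$b$label]] <- intersect(surviving[[e$b$label]], fp$surviving_b)
  }
  summary$pair_counts <- vapply(pair_tables, function(t) nrow(t$pairs), 1L)
  summary$surviving <- vapply(surviving, length, 1L)

  # assemble -------------------------------------------------------------------
  networks <- assemble_networks(spec, placement_sets, pair_tables,
                                clash_threshold = config$clash_threshold,
                                max_networks = config$max_networks,
                                ligand = ligand, params = config$hbond)
  summary$n_networks <- length(networks)
  summary$networks <- networks

  # realize --------------------------------------------------------------------
  if (isTRUE(config$stages$realize) && length(networks)) {
    identities <- config$identities
    if (is.null(identities)) {
      identities <- vapply(labels, function(lab)
        fg_template(group_fg(spec, lab))$residues[1L], "")
      names(identities) <- labels
    }
    n_report <- min(length(networks), config$realize_report_max)
    per_network <- vapply(seq_len(n_report), function(i) {
      counts <- vapply(labels, function(lab)
        length(inverse_rotamers(networks[[i]]$assignment[[lab]], identities[[lab]],
                                config$chi_samples, ligand = ligand)), 1L)
      count_full_realizations(networks[[i]], counts)
    }, 1)
    summary$realizations_per_network <- per_network
    summary$total_realizations <- sum(per_network)
    summary$realize_networks_counted <- n_report
  }

  # cluster --------------------------------------------------------------------
  if (isTRUE(config$stages$cluster) && length(networks)) {
    feats <- do.call(rbind, lapply(networks, network_features, spec = spec))
    k <- min(config$cluster_k, nrow(feats))
    summary$clusters <- cluster_networks(feats, k, seed = config$cluster_seed)
    summary$n_clusters <- summary$clusters$k
  }

  # match ----------------------------------------------------------------------
  if (isTRUE(config$stages$match) && !is.null(scaffolds) && length(scaffolds)) {
    if (inherits(scaffolds, "scaffold_model")) scaffolds <- list(scaffolds)
    matches <- list()
    for (sc in scaffolds) {
      ms <- withCallingHandlers(
        find_matches(sc, spec, ligand, networks = networks,
                     mode = config$match_mode, params = config$match,
                     hb_params = config$hbond, clusters = summary$clusters,
                     identities = config$identities,
                     chi_samples = config$chi_samples,
                     enum_opts = list(scheme = config$scheme, g = config$grid,
                                      clash_min = config$clash_threshold)),
        error = function(e) stop(sprintf("pipeline stage 'match' failed: %s",
                                         conditionMessage(e)), call. = FALSE))
      matches <- c(matches, ms)
    }
    summary$matches <- matches
    summary$n_matches <- length(matches)
    summary$n_complete <- sum(vapply(matches, function(m) isTRUE(m$complete), TRUE))
    summary$completion <- completion_report(list(run = matches))
  }
  class(summary) <- "run_summary"
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Pipeline run: spec '%s' on ligand '%s'\n", x$spec_name, x$ligand_name))
  cat("  placements per group: ",
      paste(sprintf("%s=%d", names(x$placements), x$placements), collapse = ", "), "\n")
  if (length(x$pair_counts))
    cat("  pair-table sizes:     ",
        paste(sprintf("%s=%d", names(x$pair_counts), x$pair_counts), collapse = ", "), "\n")
  cat(sprintf("  networks assembled:    %d\n", x$n_networks))
  if (!is.null(x$total_realizations))
    cat(sprintf("  full realizations:     %s (over %d network(s), product rule)\n",
                format(x$total_realizations, big.mark = ","), x$realize_networks_counted))
  if (!is.null(x$n_clusters))
    cat(sprintf("  clusters:              %d\n", x$n_clusters))
  if (!is.null(x$n_matches)) {
    cat(sprintf("  matches:               %d (%d complete)\n", x$n_matches, x$n_complete))
    print(x$completion)
  }
  invisible(x)
}

#' Tabular summaries of a pipeline run
#'
#' @param summary a \code{run_summary}
#' @param dir optional output directory; when given, writes
#'   \code{summary.txt} and TSV tables there
#' @return named list of data.frames (stage counts, completion table)
#' @export
summarize_counts <- function(summary, dir = NULL) {
  stopifnot(inherits(summary, "run_summary"))
  stage_counts <- data.frame(
    stage = c(paste0("placements.", names(summary$placements)),
              if (length(summary$pair_counts)) paste0("pairs.", names(summary$pair_counts)),
              "networks",
              if (!is.null(summary$total_realizations)) "total_realizations",
              if (!is.null(summary$n_clusters)) "clusters",
              if (!is.null(summary$n_matches)) c("matches", "complete_matches")),
    count = c(unname(summary$placements),
              if (length(summary$pair_counts)) unname(summary$pair_counts),
              summary$n_networks,
              if (!is.null(summary$total_realizations)) summary$total_realizations,
              if (!is.null(summary$n_clusters)) summary$n_clusters,
              if (!is.null(summary$n_matches)) c(summary$n_matches, summary$n_complete)),
    stringsAsFactors = FALSE)
  out <- list(stage_counts = stage_counts)
  if (!is.null(summary$completion)) out$completion <- as.data.frame(summary$completion)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(stage_counts, file.path(dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(out$completion))
      write_completion_tsv(summary$completion, file.path(dir, "completion.tsv"))
    con <- file(file.path(dir, "summary.txt"), "w")
    sink(con); print(summary); sink(); close(con)
  }
  out
}

## JSON serialization ----------------------------------------------------------

placement_to_list <- function(p) {
  list(group_label = p$group_label, fg_name = p$fg_name,
       rotation = unname(p$transform$R), translation = p$transform$t,
       atoms = list(names = rownames(p$atoms), xyz = unname(p$atoms)),
       grid_key = p$grid_key, source_edge = p$source_edge, score = p$score,
       ref_atom = p$ref_atom, variant = p$variant)
}

placement_from_list <- function(x) {
  atoms <- do.call(rbind, lapply(x$atoms$xyz, as.numeric))
  rownames(atoms) <- unlist(x$atoms$names)
  R <- do.call(rbind, lapply(x$rotation, as.numeric))
  new_placement(x$group_label, x$fg_name, rigid_transform(R, as.numeric(x$translation)),
                atoms, as.integer(x$grid_key), x$source_edge, x$score, x$ref_atom,
                x$ref_atom, variant = x$variant)
}

#' Serialize placements to JSON
#' @param placements list of \code{placement}s
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_placements_json <- function(placements, path) {
  jsonlite::write_json(lapply(placements, placement_to_list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read placements from JSON
#' @param path JSON file written by \code{\link{write_placements_json}}
#' @return list of \code{placement}s
#' @export
read_placements_json <- function(path) {
  lapply(jsonlite::read_json(path), placement_from_list)
}

#' Serialize networks (with transforms and edge scores) to a hierarchical JSON
#' document
#' @param networks list of \code{network_configuration}s
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_networks_json <- function(networks, path) {
  jsonlite::write_json(lapply(networks, function(n) {
    list(groups = lapply(n$assignment, placement_to_list),
         edge_scores = as.list(n$edge_scores),
         total_score = n$total_score)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read networks from JSON
#' @param path JSON file written by \code{\link{write_networks_json}}
#' @return list of \code{network_configuration}s
#' @export
read_networks_json <- function(path) {
  lapply(jsonlite::read_json(path), function(x) {
    assignment <- lapply(x$groups, placement_from_list)
    es <- unlist(x$edge_scores)
    new_network(assignment, stats::setNames(rep(NA_integer_, length(assignment)),
                                            names(assignment)),
                es, x$total_score)
  })
}
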