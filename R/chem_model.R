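# Ligand models and the 2D active-site specification (the "wiring diagram").

#' Construct an interaction site on a ligand
#'
#' @param site_id unique identifier
#' @param atom name of the ligand atom carrying the site
#' @param role one of "donor", "acceptor", "covalent_attachment"
#' @param aux 1-2 atom names defining the site's local frame: an acceptor's
#'   base atom(s); a donor's hydrogen or antecedent heavy atom; the
#'   substituents framing a covalent attachment point
#' @return object of class \code{interaction_site}
#' @export
interaction_site <- function(site_id, atom, role, aux) {
  role <- match.arg(role, c("donor", "acceptor", "covalent_attachment"))
  aux <- as.character(aux)
  if (length(aux) < 1L || length(aux) > 2L)
    stop(sprintf("hbnetforge validation error: site '%s' needs 1-2 aux atoms", site_id))
  structure(list(site_id = site_id, atom = atom, role = role, aux = aux),
            class = "interaction_site")
}

#' Construct a ligand model
#'
#' @param name identifier
#' @param atoms n x 3 coordinate matrix (Angstrom) with unique atom-name rownames
#' @param elements named character vector of element symbols (defaults inferred
#'   from the first letter of each atom name)
#' @param sites list of \code{\link{interaction_site}} objects
#' @return object of class \code{ligand_model}
#' @export
ligand_model <- function(name, atoms, elements = NULL, sites = list()) {
  atoms <- as.matrix(atoms)
  if (is.null(rownames(atoms)) || anyDuplicated(rownames(atoms)))
    stop("hbnetforge parse error: ligand atom names must be present and unique")
  if (!all(is.finite(atoms)))
    stop("hbnetforge parse error: non-finite ligand coordinates")
  if (is.null(elements)) {
    elements <- element_of(rownames(atoms))
    names(elements) <- rownames(atoms)
  }
  lig <- structure(list(name = name, atoms = atoms, elements = elements,
                        sites = list(), canonical = FALSE),
                   class = "ligand_model")
  if (length(sites)) lig <- attach_sites(lig, sites)
  lig
}

#' Attach interaction sites to a ligand
#'
#' @param ligand a \code{ligand_model}
#' @param sites list of \code{\link{interaction_site}} objects (or the site
#'   declarations of a parsed \code{active_site_spec})
#' @return the ligand with validated sites attached
#' @export
attach_sites <- function(ligand, sites) {
  stopifnot(inherits(ligand, "ligand_model"))
  ids <- vapply(sites, function(s) s$site_id, "")
  if (anyDuplicated(ids))
    stop("hbnetforge validation error: duplicate ligand site ids")
  for (s in sites) {
    if (!s$atom %in% rownames(ligand$atoms))
      stop(sprintf("hbnetforge validation error: site '%s' references unknown atom '%s'",
                   s$site_id, s$atom))
    missing_aux <- setdiff(s$aux, rownames(ligand$atoms))
    if (length(missing_aux))
      stop(sprintf("hbnetforge validation error: site '%s' aux atom(s) %s not in ligand",
                   s$site_id, paste(missing_aux, collapse = ", ")))
    if (s$role == "acceptor" &&
        !any(ligand$elements[s$aux] != "H"))
      stop(sprintf("hbnetforge validation error: acceptor site '%s' needs a heavy base atom",
                   s$site_id))
  }
  ligand$sites <- sites
  names(ligand$sites) <- ids
  ligand
}

ligand_site <- function(ligand, site_id) {
  s <- ligand$sites[[site_id]]
  if (is.null(s))
    stop(sprintf("hbnetforge spec error: ligand has no site '%s'", site_id))
  s
}

# donor heavy atom + hydrogen coordinates for a ligand donor site; the
# hydrogen is taken from aux when present, otherwise placed at ideal geometry
# extending the bond from the antecedent heavy atom (crystal structures
# usually lack hydrogens).
ligand_donor_geometry <- function(ligand, site) {
  D <- ligand$atoms[site$atom, ]
  h_aux <- site$aux[ligand$elements[site$aux] == "H"]
  if (length(h_aux)) {
    H <- ligand$atoms[h_aux[1L], ]
  } else {
    B <- ligand$atoms[site$aux[1L], ]
    H <- D + 0.98 * unit_vec(D - B)
  }
  list(D = D, H = H)
}

ligand_acceptor_geometry <- function(ligand, site) {
  heavy_aux <- site$aux[ligand$elements[site$aux] != "H"]
  list(A = ligand$atoms[site$atom, ],
       bases = ligand$atoms[heavy_aux, , drop = FALSE])
}

## Ligand-local canonical frame ----------------------------------------------

# frame defined by the first three non-collinear ligand atoms in file order
ligand_frame <- function(ligand) {
  n <- nrow(ligand$atoms)
  if (n < 3L) stop("hbnetforge geometry error: ligand needs at least 3 atoms for a local frame")
  p1 <- ligand$atoms[1L, ]
  p2 <- ligand$atoms[2L, ]
  k <- 3L
  repeat {
    if (k > n) stop("hbnetforge geometry error: all ligand atoms are collinear")
    p3 <- ligand$atoms[k, ]
    cr <- vcross(p2 - p1, p3 - p1)
    if (vnorm(cr) > 1e-6) break
    k <- k + 1L
  }
  R <- frame_axes(p1, p2, p3)
  # world -> local: x_local = R^T (x - p1)
  rigid_transform(t(R), as.numeric(-t(R) %*% p1))
}

#' Express a ligand in its own canonical local frame
#'
#' The frame is defined by the first three non-collinear ligand atoms in file
#' order; coordinates are then rounded to 1e-9 A.  All enumeration and grid
#' hashing runs in this frame, which makes every downstream count exactly
#' invariant under a global rigid motion of the input.
#'
#' @param ligand a \code{ligand_model}
#' @return the ligand in canonical coordinates, with the world-to-local
#'   transform stored in \code{$frame}
#' @export
canonical_ligand <- function(ligand) {
  if (isTRUE(ligand$canonical)) return(ligand)
  tr <- ligand_frame(ligand)
  ligand$atoms <- round(apply_transform(tr, ligand$atoms) / 1e-9) * 1e-9
  ligand$frame <- tr
  ligand$canonical <- TRUE
  ligand
}

## Ligand file input ----------------------------------------------------------

#' Load a ligand from a PDB (HETATM) or SDF V2000 file
#'
#' @param path file path
#' @param format "pdb" or "sdf"
#' @param sites optional list of \code{\link{interaction_site}} annotations to
#'   attach (sites are normally declared in the active-site specification)
#' @param name ligand name (defaults to the file base name)
#' @return a \code{ligand_model}
#' @export
load_ligand <- function(path, format = c("pdb", "sdf"), sites = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("hbnetforge error: file not found: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "pdb") {
    pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                    error = function(e) stop(sprintf(
                      "hbnetforge format error: cannot read PDB file %s (%s)", path, conditionMessage(e))))
    at <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
    if (nrow(at) == 0L) at <- pdb$atom  # accept plain ATOM ligands too
    if (nrow(at) == 0L) stop("hbnetforge format error: no atoms in PDB file")
    nm <- trimws(at$elety)
    if (anyDuplicated(nm))
      stop("hbnetforge parse error: duplicate atom names in ligand PDB")
    xyz <- cbind(at$x, at$y, at$z)
    rownames(xyz) <- nm
    el <- trimws(at$elesy)
    el[is.na(el) | el == ""] <- element_of(nm[is.na(el) | el == ""])
    names(el) <- nm
    lig <- ligand_model(name, xyz, elements = el)
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("hbnetforge format error: SDF input requires the ChemmineR package")
    sdf <- tryCatch(ChemmineR::read.SDFset(path),
                    error = function(e) stop(sprintf(
                      "hbnetforge format error: cannot read SDF file %s (%s)", path, conditionMessage(e))))
    ab <- ChemmineR::atomblock(sdf[[1]])
    el <- sub("_.*$", "", rownames(ab))
    nm <- paste0(el, seq_along(el))
    xyz <- unname(ab[, 1:3, drop = FALSE])
    rownames(xyz) <- nm
    names(el) <- nm
    lig <- ligand_model(name, xyz, elements = el)
  }
  if (!is.null(sites)) lig <- attach_sites(lig, sites)
  lig
}

## Active-site specification ---------------------------------------------------

spec_edge <- function(edge_id, kind, a, b) {
  kind <- match.arg(kind, c("hbond", "covalent"))
  structure(list(edge_id = edge_id, kind = kind, a = a, b = b),
            class = "interaction_edge")
}

edge_end_ligand <- function(site_id) list(type = "ligand", site = site_id)
edge_end_group <- function(label, role = NULL, atom = "auto")
  list(type = "group", label = label, role = role, atom = atom)

#' Construct and validate an active-site specification
#'
#' The 2D wiring diagram: which functional groups the site contains, which
#' ligand sites and groups they hydrogen-bond or covalently bond to.  The
#' interaction graph over the groups plus the ligand node must form a single
#' connected component; hydrogen-bond edges must resolve to exactly one donor
#' end and one acceptor end.
#'
#' @param name spec name
#' @param groups data.frame with columns \code{label}, \code{fg}
#' @param edges list of edges (see \code{parse_active_site_spec} for the file
#'   format)
#' @param ligand_sites list of \code{\link{interaction_site}} declarations
#' @param require_ligand_contact if TRUE, every group must have at least one
#'   edge to the ligand
#' @return object of class \code{active_site_spec} with resolved edges
#' @export
active_site_spec <- function(name, groups, edges, ligand_sites = list(),
                             require_ligand_contact = FALSE) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "fg") %in% names(groups)))
  if (anyDuplicated(groups$label))
    stop("hbnetforge validation error: group labels must be unique")
  for (fg in groups$fg) fg_template(fg)  # errors on unknown fg
  site_ids <- vapply(ligand_sites, function(s) s$site_id, "")
  names(ligand_sites) <- site_ids
  spec <- structure(list(name = name, groups = groups, edges = edges,
                         ligand_sites = ligand_sites,
                         require_ligand_contact = isTRUE(require_ligand_contact)),
                    class = "active_site_spec")
  spec$edges <- lapply(edges, resolve_edge, spec = spec)
  names(spec$edges) <- vapply(spec$edges, function(e) e$edge_id, "")
  if (anyDuplicated(names(spec$edges)))
    stop("hbnetforge validation error: duplicate edge ids")
  validate_spec_connectivity(spec)
  spec
}

group_fg <- function(spec, label) {
  i <- match(label, spec$groups$label)
  if (is.na(i)) stop(sprintf("hbnetforge validation error: unknown group '%s'", label))
  spec$groups$fg[i]
}

# assign donor/acceptor roles to the two ends of an hbond edge; check a
# covalent edge connects an attachment-capable group atom to a
# covalent_attachment ligand site
resolve_edge <- function(edge, spec) {
  ends <- list(edge$a, edge$b)
  for (e in ends) {
    if (e$type == "ligand") {
      if (!e$site %in% names(spec$ligand_sites))
        stop(sprintf("hbnetforge validation error: edge '%s' references unknown ligand site '%s'",
                     edge$edge_id, e$site))
    } else {
      group_fg(spec, e$label)
    }
  }
  if (edge$kind == "covalent") {
    lig_end <- Filter(function(e) e$type == "ligand", ends)
    grp_end <- Filter(function(e) e$type == "group", ends)
    if (length(lig_end) != 1L || length(grp_end) != 1L)
      stop(sprintf("hbnetforge validation error: covalent edge '%s' must join a group to a ligand site",
                   edge$edge_id))
    site <- spec$ligand_sites[[lig_end[[1L]]$site]]
    if (site$role != "covalent_attachment")
      stop(sprintf("hbnetforge validation error: covalent edge '%s' requires a covalent_attachment site",
                   edge$edge_id))
    tpl <- fg_template(group_fg(spec, grp_end[[1L]]$label))
    if (is.null(tpl$covalent_atom))
      stop(sprintf("hbnetforge validation error: group '%s' (%s) has no attachment-capable atom for covalent edge '%s'",
                   grp_end[[1L]]$label, tpl$fg_name, edge$edge_id))
    edge$a <- lig_end[[1L]]; edge$b <- grp_end[[1L]]
    return(edge)
  }
  # hbond: fix roles
  can <- lapply(ends, function(e) {
    if (e$type == "ligand") {
      role <- spec$ligand_sites[[e$site]]$role
      if (role == "covalent_attachment")
        stop(sprintf("hbnetforge validation error: hbond edge '%s' cannot use covalent site '%s'",
                     edge$edge_id, e$site))
      c(donor = role == "donor", acceptor = role == "acceptor")
    } else {
      tpl <- fg_template(group_fg(spec, e$label))
      av <- c(donor = length(tpl$donors) > 0L, acceptor = length(tpl$acceptors) > 0L)
      if (!is.null(e$role)) {
        if (!av[[e$role]])
          stop(sprintf("hbnetforge validation error: group '%s' cannot act as %s on edge '%s'",
                       e$label, e$role, edge$edge_id))
        av[setdiff(names(av), e$role)] <- FALSE
      }
      av
    }
  })
  feas_ab <- can[[1L]][["donor"]] && can[[2L]][["acceptor"]]
  feas_ba <- can[[2L]][["donor"]] && can[[1L]][["acceptor"]]
  if (!feas_ab && !feas_ba)
    stop(sprintf("hbnetforge validation error: edge '%s' has no consistent donor/acceptor assignment",
                 edge$edge_id))
  if (feas_ab && feas_ba)
    stop(sprintf("hbnetforge validation error: edge '%s' is ambiguous; specify donor/acceptor roles",
                 edge$edge_id))
  donor_end <- if (feas_ab) ends[[1L]] else ends[[2L]]
  acceptor_end <- if (feas_ab) ends[[2L]] else ends[[1L]]
  if (donor_end$type == "group") donor_end$role <- "donor"
  if (acceptor_end$type == "group") acceptor_end$role <- "acceptor"
  edge$a <- donor_end; edge$b <- acceptor_end
  edge
}

edge_group_labels <- function(edge) {
  labs <- character(0)
  for (e in list(edge$a, edge$b)) if (e$type == "group") labs <- c(labs, e$label)
  labs
}

edge_touches_ligand <- function(edge) {
  edge$a$type == "ligand" || edge$b$type == "ligand"
}

validate_spec_connectivity <- function(spec) {
  nodes <- c("..ligand..", spec$groups$label)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (edge in spec$edges) {
    ga <- if (edge$a$type == "ligand") "..ligand.." else edge$a$label
    gb <- if (edge$b$type == "ligand") "..ligand.." else edge$b$label
    adj[[ga]] <- c(adj[[ga]], gb)
    adj[[gb]] <- c(adj[[gb]], ga)
  }
  seen <- c(nodes[1L])
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  missing <- setdiff(nodes, seen)
  if (length(missing))
    stop(sprintf("hbnetforge validation error: interaction graph is not connected; disconnected component: %s",
                 paste(setdiff(missing, "..ligand.."), collapse = ", ")))
  if (spec$require_ligand_contact) {
    for (lab in spec$groups$label) {
      touches <- any(vapply(spec$edges, function(e)
        edge_touches_ligand(e) && lab %in% edge_group_labels(e), TRUE))
      if (!touches)
        stop(sprintf("hbnetforge validation error: require_ligand_contact is set but group '%s' has no ligand edge",
                     lab))
    }
  }
  invisible(spec)
}

# edges of the spec touching a given group
group_edges <- function(spec, label, ligand_only = FALSE, group_only = FALSE) {
  keep <- vapply(spec$edges, function(e) {
    hit <- label %in% edge_group_labels(e)
    if (ligand_only) hit <- hit && edge_touches_ligand(e)
    if (group_only) hit <- hit && !edge_touches_ligand(e)
    hit
  }, TRUE)
  spec$edges[keep]
}

## YAML input / output ---------------------------------------------------------

end_from_yaml <- function(x, edge_id) {
  if (!is.null(x$ligand)) return(edge_end_ligand(x$ligand))
  if (!is.null(x$group))
    return(edge_end_group(x$group, role = x$role,
                          atom = if (is.null(x$atom)) "auto" else x$atom))
  stop(sprintf("hbnetforge validation error: edge '%s' end must name a ligand site or a group", edge_id))
}

#' Parse an active-site specification file
#'
#' The file is a YAML document with sections \code{groups:} (label + fg),
#' \code{edges:} (kind, two ends, optional roles/atoms) and
#' \code{ligand_sites:} (id, atom, role, aux), plus optional \code{name:} and
#' \code{require_ligand_contact:}.  Donor/acceptor roles left implicit are
#' resolved from the ligand site roles and group capabilities; ambiguous or
#' infeasible edges are validation errors.
#'
#' @param path YAML file path
#' @return an \code{\link{active_site_spec}}
#' @export
parse_active_site_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("hbnetforge error: file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "hbnetforge format error: cannot parse YAML in %s (%s)", path, conditionMessage(e))))
  if (is.null(doc$groups) || !length(doc$groups))
    stop("hbnetforge validation error: spec has no groups")
  groups <- data.frame(
    label = vapply(doc$groups, function(g) as.character(g$label), ""),
    fg = vapply(doc$groups, function(g) as.character(g$fg), ""),
    stringsAsFactors = FALSE)
  sites <- lapply(doc$ligand_sites, function(s)
    interaction_site(s$site_id, s$atom, s$role, unlist(s$aux)))
  edges <- lapply(seq_along(doc$edges), function(i) {
    e <- doc$edges[[i]]
    id <- if (is.null(e$id)) sprintf("edge_%d", i) else as.character(e$id)
    spec_edge(id, if (is.null(e$kind)) "hbond" else e$kind,
              end_from_yaml(e$a, id), end_from_yaml(e$b, id))
  })
  active_site_spec(
    name = if (is.null(doc$name)) sub("\\.[^.]*$", "", basename(path)) else doc$name,
    groups = groups, edges = edges, ligand_sites = sites,
    require_ligand_contact = isTRUE(doc$require_ligand_contact))
}

end_to_yaml <- function(e) {
  if (e$type == "ligand") list(ligand = e$site)
  else {
    out <- list(group = e$label)
    if (!is.null(e$role)) out$role <- e$role
    if (!identical(e$atom, "auto")) out$atom <- e$atom
    out
  }
}

#' Serialize an active-site specification to YAML
#'
#' \code{parse_active_site_spec(write_active_site_spec(spec, path))} yields a
#' spec identical to \code{spec}.
#'
#' @param spec an \code{active_site_spec}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_active_site_spec <- function(spec, path) {
  doc <- list(
    name = spec$name,
    require_ligand_contact = spec$require_ligand_contact,
    ligand_sites = lapply(unname(spec$ligand_sites), function(s)
      list(site_id = s$site_id, atom = s$atom, role = s$role, aux = as.list(s$aux))),
    groups = lapply(seq_len(nrow(spec$groups)), function(i)
      list(label = spec$groups$label[i], fg = spec$groups$fg[i])),
    edges = lapply(unname(spec$edges), function(e)
      list(id = e$edge_id, kind = e$kind, a = end_to_yaml(e$a), b = end_to_yaml(e$b))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.active_site_spec <- function(x, ...) {
  cat(sprintf("Active-site specification '%s': %d group(s), %d edge(s), %d ligand site(s)\n",
              x$name, nrow(x$groups), length(x$edges), length(x$ligand_sites)))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  group %-8s %s\n", x$groups$label[i], x$groups$fg[i]))
  for (e in x$edges) {
    fmt_end <- function(en) if (en$type == "ligand") paste0("ligand:", en$site)
      else paste0(en$label, if (!is.null(en$role)) paste0("(", en$role, ")") else "")
    cat(sprintf("  edge %-8s %-8s %s -> %s\n", e$edge_id, e$kind, fmt_end(e$a), fmt_end(e$b)))
  }
  invisible(x)
}
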