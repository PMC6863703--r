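# Protein scaffold backbones: loading, validation, canonical frames.

#' Construct a scaffold model from backbone coordinates
#'
#' @param id scaffold identifier
#' @param chain character vector, one entry per residue
#' @param resnum integer residue numbers (unique within a chain)
#' @param N,CA,C n x 3 backbone coordinate matrices
#' @param O optional n x 3 carbonyl-oxygen matrix (NA rows allowed)
#' @param designable logical vector marking positions the matcher may use
#'   (default: all)
#' @return object of class \code{scaffold_model}
#' @export
scaffold_model <- function(id, chain, resnum, N, CA, C, O = NULL, designable = NULL) {
  n <- length(resnum)
  stopifnot(length(chain) == n, nrow(N) == n, nrow(CA) == n, nrow(C) == n)
  if (anyDuplicated(paste(chain, resnum)))
    stop("hbnetforge validation error: duplicate residue numbering within a chain")
  # backbone bond lengths within 20% of ideal
  dNCA <- sqrt(rowSums((CA - N)^2)); dCAC <- sqrt(rowSums((C - CA)^2))
  if (any(abs(dNCA - 1.458) > 0.2 * 1.458) || any(abs(dCAC - 1.525) > 0.2 * 1.525))
    stop("hbnetforge validation error: backbone bond lengths deviate more than 20% from ideal")
  if (is.null(O)) O <- matrix(NA_real_, n, 3L)
  if (is.null(designable)) designable <- rep(TRUE, n)
  structure(list(id = id, chain = chain, resnum = as.integer(resnum),
                 N = unname(N), CA = unname(CA), C = unname(C), O = unname(O),
                 designable = designable, canonical = FALSE),
            class = "scaffold_model")
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat(sprintf("Scaffold '%s': %d residue(s), %d chain(s), %d designable\n",
              x$id, length(x$resnum), length(unique(x$chain)), sum(x$designable)))
  invisible(x)
}

n_residues <- function(scaffold) length(scaffold$resnum)

residue_frame <- function(scaffold, i) {
  rbind(scaffold$N[i, ], scaffold$CA[i, ], scaffold$C[i, ])
}

# all backbone atoms as one matrix (rownames chain_resnum_atom)
scaffold_backbone_atoms <- function(scaffold, exclude = integer(0)) {
  keep <- setdiff(seq_len(n_residues(scaffold)), exclude)
  if (!length(keep)) return(matrix(numeric(0), 0L, 3L))
  m <- rbind(scaffold$N[keep, , drop = FALSE], scaffold$CA[keep, , drop = FALSE],
             scaffold$C[keep, , drop = FALSE],
             scaffold$O[keep, , drop = FALSE])
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Express a scaffold in a canonical local frame
#'
#' The frame of the first residue's N/CA/C defines the canonical coordinates;
#' coordinates are rounded to 1e-9 A so all matcher arithmetic (and hence all
#' match counts) is exactly invariant under a global rigid motion of the input.
#'
#' @param scaffold a \code{scaffold_model}
#' @return the scaffold in canonical coordinates
#' @export
canonical_scaffold <- function(scaffold) {
  if (isTRUE(scaffold$canonical)) return(scaffold)
  fr <- residue_frame(scaffold, 1L)
  R <- frame_axes(fr[1L, ], fr[2L, ], fr[3L, ])
  tr <- rigid_transform(t(R), as.numeric(-t(R) %*% fr[1L, ]))
  snap9 <- function(m) {
    out <- round(apply_transform(tr, m) / 1e-9) * 1e-9
    out[!stats::complete.cases(m), ] <- NA_real_
    out
  }
  scaffold$N <- snap9(scaffold$N); scaffold$CA <- snap9(scaffold$CA)
  scaffold$C <- snap9(scaffold$C)
  okO <- stats::complete.cases(scaffold$O)
  if (any(okO)) scaffold$O[okO, ] <- round(apply_transform(tr, scaffold$O[okO, , drop = FALSE]) / 1e-9) * 1e-9
  scaffold$frame <- tr
  scaffold$canonical <- TRUE
  scaffold
}

#' Load a scaffold backbone from a PDB file
#'
#' Residues with complete N/CA/C backbone atoms are retained; incomplete
#' residues are skipped with a warning.  For alternate locations the first
#' altloc is kept (with a warning).
#'
#' @param path PDB file path
#' @param id scaffold identifier (defaults to the file base name)
#' @return a \code{scaffold_model}
#' @export
load_scaffold <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("hbnetforge error: file not found: %s", path))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop(sprintf(
                    "hbnetforge format error: cannot read PDB file %s (%s)", path, conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("hbnetforge format error: no ATOM records in scaffold PDB")
  alt <- trimws(at$alt); alt[is.na(alt)] <- ""
  if (any(!alt %in% c("", "A"))) {
    warning(sprintf("load_scaffold: alternate locations in %s; keeping first altloc", basename(path)))
  }
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  rows <- list()
  skipped <- 0L
  for (rk in res_keys) {
    sub <- at[key == rk, , drop = FALSE]
    nm <- trimws(sub$elety)
    need <- c("N", "CA", "C")
    if (!all(need %in% nm)) { skipped <- skipped + 1L; next }
    take <- function(a) { i <- which(nm == a)[1L]; c(sub$x[i], sub$y[i], sub$z[i]) }
    o <- if ("O" %in% nm) take("O") else c(NA_real_, NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <- list(chain = sub$chain[1L], resno = sub$resno[1L],
                                      N = take("N"), CA = take("CA"), C = take("C"), O = o)
  }
  if (skipped > 0L)
    warning(sprintf("load_scaffold: skipped %d residue(s) with incomplete N/CA/C backbone", skipped))
  if (!length(rows))
    stop("hbnetforge format error: no residues with complete N/CA/C backbone in scaffold PDB")
  scaffold_model(id,
                 chain = vapply(rows, function(r) as.character(r$chain), ""),
                 resnum = vapply(rows, function(r) as.integer(r$resno), 1L),
                 N = do.call(rbind, lapply(rows, function(r) r$N)),
                 CA = do.call(rbind, lapply(rows, function(r) r$CA)),
                 C = do.call(rbind, lapply(rows, function(r) r$C)),
                 O = do.call(rbind, lapply(rows, function(r) r$O)))
}

#' Write a scaffold backbone to a PDB file
#'
#' @param scaffold a \code{scaffold_model}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_scaffold_pdb <- function(scaffold, path) {
  n <- n_residues(scaffold)
  xyz <- c(); elety <- c(); resno <- c(); chain <- c(); elesy <- c()
  for (i in seq_len(n)) {
    atoms <- list(N = scaffold$N[i, ], CA = scaffold$CA[i, ], C = scaffold$C[i, ])
    if (all(is.finite(scaffold$O[i, ]))) atoms$O <- scaffold$O[i, ]
    for (a in names(atoms)) {
      xyz <- c(xyz, atoms[[a]])
      elety <- c(elety, a)
      resno <- c(resno, scaffold$resnum[i])
      chain <- c(chain, scaffold$chain[i])
      elesy <- c(elesy, substr(a, 1L, 1L))
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", length(elety)),
                   resno = resno, resid = rep("ALA", length(elety)),
                   elety = elety, chain = chain, elesy = elesy)
  invisible(path)
}

# least-squares (Kabsch) superposition of point sets, used by the matcher
# where backbone triples are only approximately congruent
superpose_lsq <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2L, cs)) %*% sweep(dst, 2L, cd)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cd - R %*% cs))
}
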