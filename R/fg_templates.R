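# Built-in library of side-chain functional-group templates.
#
# Each template is a small rigid body: atoms with ideal internal geometry,
# annotated hydrogen-bond donor pairs (heavy atom + hydrogen), acceptor atoms
# (heavy atom + lone-pair base atoms), and the attachment atom where the rest
# of the side chain continues.  Chain recipes describe how to grow the side
# chain backward from the template toward the backbone for each amino-acid
# identity that can carry the group (the inverse-rotamer construction).
#
# Atom naming follows PDB side-chain conventions of a representative residue.

fg_library_env <- new.env(parent = emptyenv())

chain_step <- function(atom, a, b, c, bond, angle, dihedral) {
  list(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle, dihedral = dihedral)
}

# standard backbone completion: N and C around CA; dihedral "chi" = sampled
backbone_steps <- function(a_ca, b_ca, c_ca) {
  list(
    chain_step("N", a_ca, b_ca, c_ca, 1.458, 110.5, "chi"),
    chain_step("C", "N", b_ca, c_ca, 1.525, 110.1, -122.9)
  )
}

element_of <- function(atom_names) {
  ifelse(substr(atom_names, 1L, 1L) == "H", "H",
         ifelse(substr(atom_names, 1L, 1L) == "O", "O",
                ifelse(substr(atom_names, 1L, 1L) == "N", "N",
                       ifelse(substr(atom_names, 1L, 1L) == "P", "P", "C"))))
}

make_template <- function(fg_name, atoms, donors, acceptors, attachment_atom,
                          residues, chains, covalent_atom = NULL) {
  elements <- element_of(rownames(atoms))
  names(elements) <- rownames(atoms)
  list(fg_name = fg_name,
       atoms = atoms,
       elements = elements,
       heavy_atoms = rownames(atoms)[elements != "H"],
       donors = donors,
       acceptors = acceptors,
       attachment = attachment_atom,
       covalent_atom = covalent_atom,
       residues = residues,
       chains = chains)
}

build_fg_library <- function() {
  lib <- list()

  ## hydroxyl (Ser/Thr) --------------------------------------------------------
  OG <- c(0, 0, 0)
  CB <- c(1.417, 0, 0)
  HG <- 0.96 * c(cos(deg2rad(109.5)), sin(deg2rad(109.5)), 0)
  atoms <- rbind(OG = OG, CB = CB, HG = HG)
  lib$hydroxyl <- make_template(
    "hydroxyl", atoms,
    donors = list(c(heavy = "OG", h = "HG")),
    acceptors = list(list(heavy = "OG", bases = "CB")),
    attachment_atom = "CB",
    residues = c("ser", "thr"),
    chains = list(
      ser = c(list(chain_step("CA", "HG", "OG", "CB", 1.530, 110.5, "chi")),
              backbone_steps("OG", "CB", "CA")),
      thr = c(list(chain_step("CA", "HG", "OG", "CB", 1.530, 110.5, "chi")),
              backbone_steps("OG", "CB", "CA"))
    ))

  ## phenol (Tyr) --------------------------------------------------------------
  r <- 1.39
  hexa <- function(th) r * c(cos(deg2rad(th)), sin(deg2rad(th)), 0)
  CG <- hexa(180); CD1 <- hexa(120); CD2 <- hexa(240)
  CE1 <- hexa(60); CE2 <- hexa(300); CZ <- hexa(0)
  OH <- c(r + 1.36, 0, 0)
  HH <- place_atom(CE1, CZ, OH, 0.96, 110, 0)
  atoms <- rbind(CG = CG, CD1 = CD1, CD2 = CD2, CE1 = CE1, CE2 = CE2,
                 CZ = CZ, OH = OH, HH = HH)
  lib$phenol <- make_template(
    "phenol", atoms,
    donors = list(c(heavy = "OH", h = "HH")),
    acceptors = list(list(heavy = "OH", bases = "CZ")),
    attachment_atom = "CG",
    residues = "tyr",
    chains = list(
      tyr = c(list(chain_step("CB", "CE1", "CD1", "CG", 1.51, 120.0, 180),
                   chain_step("CA", "CD1", "CG", "CB", 1.530, 113.9, "chi")),
              backbone_steps("CG", "CB", "CA"))
    ))

  ## carboxylate (Asp/Glu) -----------------------------------------------------
  CG <- c(0, 0, 0)
  CB <- c(-1.52, 0, 0)
  OD1 <- 1.25 * c(cos(deg2rad(62.65)), sin(deg2rad(62.65)), 0)
  OD2 <- 1.25 * c(cos(deg2rad(-62.65)), sin(deg2rad(-62.65)), 0)
  atoms <- rbind(CG = CG, CB = CB, OD1 = OD1, OD2 = OD2)
  asp_chain <- c(list(chain_step("CA", "OD1", "CG", "CB", 1.530, 112.6, "chi")),
                 backbone_steps("CG", "CB", "CA"))
  glu_chain <- c(list(chain_step("CB2", "OD1", "CG", "CB", 1.52, 112.0, "chi"),
                      chain_step("CA", "CG", "CB", "CB2", 1.530, 114.0, "chi")),
                 backbone_steps("CB", "CB2", "CA"))
  lib$carboxylate <- make_template(
    "carboxylate", atoms,
    donors = list(),
    acceptors = list(list(heavy = "OD1", bases = "CG"),
                     list(heavy = "OD2", bases = "CG")),
    attachment_atom = "CB",
    residues = c("asp", "glu"),
    chains = list(asp = asp_chain, glu = glu_chain))

  ## carboxamide (Asn/Gln) -----------------------------------------------------
  CG <- c(0, 0, 0)
  CB <- c(-1.52, 0, 0)
  OD1 <- 1.23 * c(cos(deg2rad(59.5)), sin(deg2rad(59.5)), 0)
  ND2 <- 1.33 * c(cos(deg2rad(-63.5)), sin(deg2rad(-63.5)), 0)
  HD21 <- place_atom(CB, CG, ND2, 1.01, 120, 0)
  HD22 <- place_atom(CB, CG, ND2, 1.01, 120, 180)
  atoms <- rbind(CG = CG, CB = CB, OD1 = OD1, ND2 = ND2, HD21 = HD21, HD22 = HD22)
  asn_chain <- c(list(chain_step("CA", "OD1", "CG", "CB", 1.530, 112.6, "chi")),
                 backbone_steps("CG", "CB", "CA"))
  gln_chain <- c(list(chain_step("CB2", "OD1", "CG", "CB", 1.52, 112.0, "chi"),
                      chain_step("CA", "CG", "CB", "CB2", 1.530, 114.0, "chi")),
                 backbone_steps("CB", "CB2", "CA"))
  lib$carboxamide <- make_template(
    "carboxamide", atoms,
    donors = list(c(heavy = "ND2", h = "HD21"), c(heavy = "ND2", h = "HD22")),
    acceptors = list(list(heavy = "OD1", bases = "CG")),
    attachment_atom = "CB",
    residues = c("asn", "gln"),
    chains = list(asn = asn_chain, gln = gln_chain))

  ## imidazole (His) -----------------------------------------------------------
  rp <- 1.37 / (2 * sin(deg2rad(36)))
  penta <- function(th) rp * c(cos(deg2rad(th)), sin(deg2rad(th)), 0)
  CG <- penta(90); ND1 <- penta(162); CE1 <- penta(234)
  NE2 <- penta(306); CD2 <- penta(18)
  HD1 <- ND1 * ((rp + 1.01) / rp)
  CB <- CG * ((rp + 1.50) / rp)
  atoms <- rbind(CG = CG, ND1 = ND1, CE1 = CE1, NE2 = NE2, CD2 = CD2,
                 HD1 = HD1, CB = CB)
  lib$imidazole <- make_template(
    "imidazole", atoms,
    donors = list(c(heavy = "ND1", h = "HD1")),
    acceptors = list(list(heavy = "NE2", bases = c("CE1", "CD2"))),
    attachment_atom = "CB",
    residues = "his",
    chains = list(
      his = c(list(chain_step("CA", "ND1", "CG", "CB", 1.530, 113.8, "chi")),
              backbone_steps("CG", "CB", "CA"))
    ))

  ## guanidinium (Arg) ---------------------------------------------------------
  CZ <- c(0, 0, 0)
  NE <- c(1.33, 0, 0)
  NH1 <- 1.33 * c(cos(deg2rad(120)), sin(deg2rad(120)), 0)
  NH2 <- 1.33 * c(cos(deg2rad(-120)), sin(deg2rad(-120)), 0)
  HE <- place_atom(NH2, CZ, NE, 1.01, 118, 0)
  CD <- place_atom(NH1, CZ, NE, 1.46, 124, 0)
  HH11 <- place_atom(NE, CZ, NH1, 1.01, 120, 0)
  HH12 <- place_atom(NE, CZ, NH1, 1.01, 120, 180)
  HH21 <- place_atom(NE, CZ, NH2, 1.01, 120, 0)
  HH22 <- place_atom(NE, CZ, NH2, 1.01, 120, 180)
  atoms <- rbind(CZ = CZ, NE = NE, NH1 = NH1, NH2 = NH2, HE = HE, CD = CD,
                 HH11 = HH11, HH12 = HH12, HH21 = HH21, HH22 = HH22)
  lib$guanidinium <- make_template(
    "guanidinium", atoms,
    donors = list(c(heavy = "NE", h = "HE"),
                  c(heavy = "NH1", h = "HH11"), c(heavy = "NH1", h = "HH12"),
                  c(heavy = "NH2", h = "HH21"), c(heavy = "NH2", h = "HH22")),
    acceptors = list(),
    attachment_atom = "CD",
    residues = "arg",
    chains = list(
      arg = c(list(chain_step("CG", "CZ", "NE", "CD", 1.52, 111.3, "chi"),
                   chain_step("CB", "NE", "CD", "CG", 1.52, 111.3, "chi"),
                   chain_step("CA", "CD", "CG", "CB", 1.530, 114.0, "chi")),
              backbone_steps("CG", "CB", "CA"))
    ))

  ## primary amine (Lys) -------------------------------------------------------
  NZ <- c(0, 0, 0)
  CE <- c(1.49, 0, 0)
  hz <- function(phi) 1.01 * c(cos(deg2rad(109.5)),
                               sin(deg2rad(109.5)) * cos(deg2rad(phi)),
                               sin(deg2rad(109.5)) * sin(deg2rad(phi)))
  atoms <- rbind(NZ = NZ, CE = CE, HZ1 = hz(0), HZ2 = hz(120), HZ3 = hz(240))
  lib$primary_amine <- make_template(
    "primary_amine", atoms,
    donors = list(c(heavy = "NZ", h = "HZ1"), c(heavy = "NZ", h = "HZ2"),
                  c(heavy = "NZ", h = "HZ3")),
    acceptors = list(),
    attachment_atom = "CE",
    residues = "lys",
    covalent_atom = "NZ",
    chains = list(
      lys = c(list(chain_step("CD", "HZ1", "NZ", "CE", 1.52, 111.7, "chi"),
                   chain_step("CG", "NZ", "CE", "CD", 1.52, 111.3, "chi"),
                   chain_step("CB", "CE", "CD", "CG", 1.52, 111.3, "chi"),
                   chain_step("CA", "CD", "CG", "CB", 1.530, 114.0, "chi")),
              backbone_steps("CG", "CB", "CA"))
    ))

  lib
}

get_fg_library <- function() {
  if (is.null(fg_library_env$lib)) fg_library_env$lib <- build_fg_library()
  fg_library_env$lib
}

#' Names of the built-in functional groups
#' @return character vector of functional-group names
#' @export
fg_names <- function() names(get_fg_library())

#' Retrieve a built-in functional-group template
#'
#' Templates are rigid bodies with ideal internal geometry, annotated donor
#' (heavy atom, hydrogen) pairs, acceptor (heavy atom, base atoms) entries,
#' the attachment atom where the side chain continues, and per-residue chain
#' recipes used by \code{\link{inverse_rotamers}}.
#'
#' @param fg_name one of \code{fg_names()}: hydroxyl, phenol, carboxylate,
#'   carboxamide, imidazole, guanidinium, primary_amine
#' @return the template (a list); modifying the returned copy has no effect on
#'   the library
#' @export
fg_template <- function(fg_name) {
  lib <- get_fg_library()
  if (!fg_name %in% names(lib))
    stop(sprintf("hbnetforge lookup error: unknown functional group '%s' (known: %s)",
                 fg_name, paste(names(lib), collapse = ", ")))
  lib[[fg_name]]
}

# role-compatible template atoms for an edge end
fg_role_atoms <- function(template, role) {
  if (role == "donor") template$donors
  else if (role == "acceptor") template$acceptors
  else stop("hbnetforge spec error: role must be donor or acceptor")
}
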