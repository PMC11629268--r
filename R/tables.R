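#' Bundled reference tables
#'
#' Element van der Waals radii (Bondi-style, nm), atomic masses (Da),
#' per-residue-type maximal solvent accessibilities (Gly-X-Gly tripeptide
#' convention, nm^2), side-chain torsion definitions (chi1..chi5 atom
#' quadruples), and the residue chemistry used by contact classification.
#' All tables are plain R objects so they can be overridden by the caller.
#'
#' @name gpcrtraj-tables
#' @keywords internal
NULL

# Bondi radii, nm; "X" is the fallback for unrecognised elements.
.vdw_radii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  F = 0.147, CL = 0.175, BR = 0.185, I = 0.198,
  "NA" = 0.227, K = 0.275, MG = 0.173, ZN = 0.139, CA = 0.231, FE = 0.156,
  X = 0.170
)

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, ZN = 65.38, CA = 40.078, FE = 55.845,
  X = 12.011
)

#' @keywords internal
element_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_radii[["X"]]
  unname(r)
}

#' @keywords internal
element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- .atomic_masses[["X"]]
  unname(m)
}

# Theoretical maximum accessible surface area per residue type, nm^2
# (Gly-X-Gly tripeptide convention, theoretical column of the standard
# normalisation table).  "BLK" is the synthetic blocker pseudo-residue.
.sasa_max <- c(
  ALA = 1.29, ARG = 2.74, ASN = 1.95, ASP = 1.93, CYS = 1.67,
  GLU = 2.23, GLN = 2.25, GLY = 1.04, HIS = 2.24, ILE = 1.97,
  LEU = 2.01, LYS = 2.36, MET = 2.24, PHE = 2.40, PRO = 1.59,
  SER = 1.55, THR = 1.72, TRP = 2.85, TYR = 2.63, VAL = 1.74,
  BLK = 3.00
)

#' Maximal accessible surface areas
#'
#' Returns the bundled table of theoretical maximum solvent-accessible
#' surface areas per residue type (nm^2), used to normalise per-residue
#' delta-SASA in the interface protocol.
#'
#' @return Named numeric vector, names are three-letter residue codes.
#' @export
sasa_max_table <- function() .sasa_max

.water_resnames <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "H2O")
.ion_resnames   <- c("NA", "SOD", "CL", "CLA", "K", "POT", "MG", "ZN", "CAL")

.backbone_names <- c("N", "CA", "C", "O", "OXT")

# chi1..chi5 atom-name quadruples per residue type (standard definitions).
.chi_atoms <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ"),
             c("CD","NE","CZ","NH1")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' @keywords internal
chi_definitions <- function(resname) {
  .chi_atoms[[toupper(resname)]]
}

# Side-chain heavy-atom templates as internal-coordinate rows.  Each row
# places `atom` from three previously placed atoms (a, b, c = parent) at
# bond length `r` (nm), angle `ang` (deg, atom-c-b) and torsion `tor`
# (deg, atom-c-b-a).  `tor` may be a number or "chiK" / "chiK+delta".
# Rings built this way are planar to the stated angles, which is all the
# downstream geometry (centroids, normals, torsion reading) needs.
.sc_row <- function(atom, a, b, c, r, ang, tor) {
  list(atom = atom, a = a, b = b, c = c, r = r, ang = ang, tor = tor)
}

.sidechain_templates <- local({
  cb <- .sc_row("CB", "C", "N", "CA", 0.153, 110.5, -122)
  t <- list()
  t$GLY <- list()
  t$ALA <- list(cb)
  t$SER <- list(cb, .sc_row("OG",  "N", "CA", "CB", 0.142, 110.5, "chi1"))
  t$CYS <- list(cb, .sc_row("SG",  "N", "CA", "CB", 0.181, 110.5, "chi1"))
  t$THR <- list(cb, .sc_row("OG1", "N", "CA", "CB", 0.142, 110.5, "chi1"),
                    .sc_row("CG2", "N", "CA", "CB", 0.152, 110.5, "chi1-120"))
  t$VAL <- list(cb, .sc_row("CG1", "N", "CA", "CB", 0.152, 110.5, "chi1"),
                    .sc_row("CG2", "N", "CA", "CB", 0.152, 110.5, "chi1+122"))
  t$LEU <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("CD1", "CA", "CB", "CG", 0.152, 110.5, "chi2"),
                    .sc_row("CD2", "CA", "CB", "CG", 0.152, 110.5, "chi2+122"))
  t$ILE <- list(cb, .sc_row("CG1", "N", "CA", "CB", 0.152, 110.5, "chi1"),
                    .sc_row("CG2", "N", "CA", "CB", 0.152, 110.5, "chi1-122"),
                    .sc_row("CD1", "CA", "CB", "CG1", 0.152, 113.0, "chi2"))
  t$MET <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("SD",  "CA", "CB", "CG", 0.181, 112.7, "chi2"),
                    .sc_row("CE",  "CB", "CG", "SD", 0.179, 100.9, "chi3"))
  t$PRO <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 104.5, "chi1"),
                    .sc_row("CD",  "CA", "CB", "CG", 0.152, 104.5, "chi2"))
  t$ASP <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 112.6, "chi1"),
                    .sc_row("OD1", "CA", "CB", "CG", 0.125, 118.5, "chi2"),
                    .sc_row("OD2", "CA", "CB", "CG", 0.125, 118.5, "chi2+180"))
  t$ASN <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 112.6, "chi1"),
                    .sc_row("OD1", "CA", "CB", "CG", 0.123, 120.8, "chi2"),
                    .sc_row("ND2", "CA", "CB", "CG", 0.133, 116.4, "chi2+180"))
  t$GLU <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("CD",  "CA", "CB", "CG", 0.152, 112.6, "chi2"),
                    .sc_row("OE1", "CB", "CG", "CD", 0.125, 118.5, "chi3"),
                    .sc_row("OE2", "CB", "CG", "CD", 0.125, 118.5, "chi3+180"))
  t$GLN <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("CD",  "CA", "CB", "CG", 0.152, 112.6, "chi2"),
                    .sc_row("OE1", "CB", "CG", "CD", 0.123, 120.8, "chi3"),
                    .sc_row("NE2", "CB", "CG", "CD", 0.133, 116.4, "chi3+180"))
  t$LYS <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("CD",  "CA", "CB", "CG", 0.152, 111.3, "chi2"),
                    .sc_row("CE",  "CB", "CG", "CD", 0.152, 111.3, "chi3"),
                    .sc_row("NZ",  "CG", "CD", "CE", 0.149, 111.3, "chi4"))
  t$ARG <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.152, 114.0, "chi1"),
                    .sc_row("CD",  "CA", "CB", "CG", 0.152, 111.3, "chi2"),
                    .sc_row("NE",  "CB", "CG", "CD", 0.146, 112.0, "chi3"),
                    .sc_row("CZ",  "CG", "CD", "NE", 0.133, 124.2, "chi4"),
                    .sc_row("NH1", "CD", "NE", "CZ", 0.133, 120.0, "chi5"),
                    .sc_row("NH2", "CD", "NE", "CZ", 0.133, 120.0, "chi5+180"))
  t$PHE <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.151, 113.8, "chi1"),
                    .sc_row("CD1", "CA", "CB", "CG", 0.139, 120.0, "chi2"),
                    .sc_row("CD2", "CA", "CB", "CG", 0.139, 120.0, "chi2+180"),
                    .sc_row("CE1", "CB", "CG", "CD1", 0.139, 120.0, 180),
                    .sc_row("CE2", "CB", "CG", "CD2", 0.139, 120.0, 180),
                    .sc_row("CZ",  "CG", "CD1", "CE1", 0.139, 120.0, 0))
  t$TYR <- c(t$PHE, list(.sc_row("OH", "CD1", "CE1", "CZ", 0.138, 120.0, 180)))
  t$HIS <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.150, 113.8, "chi1"),
                    .sc_row("ND1", "CA", "CB", "CG", 0.138, 122.7, "chi2"),
                    .sc_row("CD2", "CA", "CB", "CG", 0.136, 131.0, "chi2+180"),
                    .sc_row("CE1", "CB", "CG", "ND1", 0.132, 109.0, 180),
                    .sc_row("NE2", "CB", "CG", "CD2", 0.137, 107.0, 180))
  t$TRP <- list(cb, .sc_row("CG",  "N", "CA", "CB", 0.150, 113.8, "chi1"),
                    .sc_row("CD1", "CA", "CB", "CG", 0.137, 127.0, "chi2"),
                    .sc_row("CD2", "CA", "CB", "CG", 0.143, 126.0, "chi2+180"),
                    .sc_row("NE1", "CB", "CG", "CD1", 0.138, 110.0, 180),
                    .sc_row("CE2", "CB", "CG", "CD2", 0.140, 107.0, 180),
                    .sc_row("CE3", "CB", "CG", "CD2", 0.140, 133.0, 0),
                    .sc_row("CZ2", "CG", "CD2", "CE2", 0.140, 122.0, 180),
                    .sc_row("CZ3", "CG", "CD2", "CE3", 0.139, 118.0, 180),
                    .sc_row("CH2", "CD2", "CE2", "CZ2", 0.137, 117.0, 0))
  # synthetic blocker pseudo-residue: one carbon, positioned like CB
  t$BLK <- list(cb)
  t
})

#' @keywords internal
sidechain_template <- function(resname) {
  .sidechain_templates[[toupper(resname)]]
}

# --- residue chemistry for contact classification ------------------------

# atoms carrying formal charge (heavy atoms of the charged group)
.charged_pos <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.charged_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# heavy-atom hydrogen-bond donors / acceptors (side chain; backbone N/O
# handled separately so bb/sc subtypes can be labelled)
.hb_donors_sc <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG"
)
.hb_acceptors_sc <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD", SER = "OG", THR = "OG1", TYR = "OH"
)

.aromatic_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# side-chain carbons counted as apolar for hydrophobic contacts
.hydrophobic_carbons <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG", "CD"), CYS = "CB",
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), THR = "CG2"
)

.known_protein_resnames <- c(names(.sidechain_templates))

#' @keywords internal
residue_chemistry <- function(resname) {
  rn <- toupper(resname)
  if (!rn %in% .known_protein_resnames) {
    stop("unknown residue type for contact chemistry: ", resname, call. = FALSE)
  }
  list(
    pos = .charged_pos[[rn]] %||% character(),
    neg = .charged_neg[[rn]] %||% character(),
    donors = .hb_donors_sc[[rn]] %||% character(),
    acceptors = .hb_acceptors_sc[[rn]] %||% character(),
    ring = .aromatic_rings[[rn]] %||% character(),
    hydrophobic = .hydrophobic_carbons[[rn]] %||% character()
  )
}
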