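# shared toy layouts; everything is generated in code at test time

two_helix_layout <- function(n_receptor = 15, n_partner = 8, gap = 2.5) {
  seqs <- rep(c("ALA", "LEU", "ARG", "ASP", "PHE"), length.out = n_receptor)
  list(
    list(chain = "A", role = "receptor", sequence = seqs,
         origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(chain = "B", role = "partner",
         sequence = rep("LYS", n_partner),
         origin = c(gap, 0, 0), axis = c(0, 0, 1))
  )
}

# minimal hand-built complex: residues given as list(chain, resnum, resname,
# atoms = tibble(name, element, x, y, z))
build_manual_complex <- function(residues, chain_roles = NULL) {
  atoms <- purrr::imap(residues, function(r, i) {
    a <- tibble::as_tibble(r$atoms)
    a$chain <- r$chain
    a$resnum <- r$resnum
    a$resname <- r$resname
    a$icode <- ""
    a
  }) %>% dplyr::bind_rows()
  atoms$serial <- seq_len(nrow(atoms))
  annotated_complex(atoms, chain_roles = chain_roles)
}

# single-frame ensemble from a complex's own coordinates (optionally edited)
manual_ensemble <- function(complex, frames = NULL, box = NULL, dt = 1,
                            replica_id = "rep1") {
  if (is.null(frames)) {
    frames <- list(as.matrix(complex$atoms[, c("x", "y", "z")]))
  }
  xyz <- do.call(rbind, lapply(frames, function(X) as.vector(t(X))))
  bx <- if (!is.null(box)) matrix(box, nrow(xyz), 3, byrow = TRUE)
  trajectory_ensemble(list(list(id = replica_id, xyz = xyz, box = bx,
                                time = (seq_len(nrow(xyz)) - 1) * dt)))
}

toy_pdb_lines <- function() {
  c("CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.458  10.000  10.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.009  11.423  10.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      11.251  12.389  10.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2      13.325  11.551  10.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2      13.970  12.862  10.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2      15.480  12.712  10.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2      16.012  11.601  10.000  1.00  0.00           O",
    "ATOM      9  N   SER A   3      16.180  13.841  10.000  1.00  0.00           N",
    "ATOM     10  CA  SER A   3      17.630  13.849  10.000  1.00  0.00           C",
    "ATOM     11  C   SER A   3      18.189  15.264  10.000  1.00  0.00           C",
    "ATOM     12  O   SER A   3      17.432  16.236  10.000  1.00  0.00           O",
    "END")
}
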