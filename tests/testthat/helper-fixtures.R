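# shared small fixtures

# path of 3 nodes: Kirchhoff eigenvalues {0, 1, 3}, pseudo-inverse
# (1/9) [[5,-1,-4],[-1,2,-1],[-4,-1,5]]
path3_topology <- function() {
  new_topo(3, rbind(c(1, 2), c(2, 3)), NULL)
}

path3_pinv_exact <- matrix(c(5, -1, -4, -1, 2, -1, -4, -1, 5), 3, 3) / 9

new_topo <- function(n, covalent, noncovalent) {
  # exercise build_topology-compatible objects without coordinates
  enmfold:::new_contact_topology(n, covalent, noncovalent, cutoff = 7.3)
}

path3_spectrum <- function() {
  decompose_modes(kirchhoff_matrix(path3_topology()))
}

# hand-written PDB text: 5 GLY residues with CA (+ extra N on residue 1,
# an altloc B duplicate on residue 2) and one ZN HETATM
pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     b = 0, alt = " ", elem = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z, 1.00, b,
          elem)
}

toy_pdb_text <- function(bvals = rep(0, 5)) {
  c(
    pdb_line("ATOM", 1, " N", "GLY", "A", 1, 0, 1.2, 0, bvals[1], elem = "N"),
    pdb_line("ATOM", 2, " CA", "GLY", "A", 1, 0, 0, 0, bvals[1], elem = "C"),
    pdb_line("ATOM", 3, " CA", "GLY", "A", 2, 3.8, 0, 0, bvals[2], alt = "A",
             elem = "C"),
    pdb_line("ATOM", 4, " CA", "GLY", "A", 2, 99, 99, 99, bvals[2], alt = "B",
             elem = "C"),
    pdb_line("ATOM", 5, " CA", "GLY", "A", 3, 7.6, 0, 0, bvals[3], elem = "C"),
    pdb_line("ATOM", 6, " CA", "GLY", "A", 4, 9.5, 3.3, 0, bvals[4], elem = "C"),
    pdb_line("ATOM", 7, " CA", "GLY", "A", 5, 9.5, 7.1, 0, bvals[5], elem = "C"),
    pdb_line("HETATM", 8, "ZN", "ZN", "A", 6, 5.0, 3.0, 1.0, 0, elem = "ZN"),
    pdb_line("HETATM", 9, " O", "HOH", "A", 7, 20, 20, 20, 0, elem = "O"),
    "END"
  )
}

# two-model ensemble: model 2 displaces residue 3 by 1.0 A, constant B column
two_model_pdb_text <- function(dz3 = 1.0) {
  ca <- function(resno, x, y, z) {
    pdb_line("ATOM", resno, " CA", "GLY", "A", resno, x, y, z, 0, elem = "C")
  }
  m1 <- c(ca(1, 0, 0, 0), ca(2, 3.8, 0, 0), ca(3, 7.6, 0, 0),
          ca(4, 11.4, 0, 0))
  m2 <- c(ca(1, 0, 0, 0), ca(2, 3.8, 0, 0), ca(3, 7.6, 0, dz3),
          ca(4, 11.4, 0, 0))
  c("MODEL        1", m1, "ENDMDL", "MODEL        2", m2, "ENDMDL", "END")
}

straight_chain <- function(n, step = 3.8) {
  xyz <- cbind((seq_len(n) - 1) * step, 0, 0)
  cg_structure(data.frame(chain = "A", resno = seq_len(n), resname = "GLY",
                          insert = ""),
               xyz, rep(FALSE, n))
}

two_node_structure <- function(d = 5) {
  cg_structure(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                          insert = ""),
               rbind(c(0, 0, 0), c(d, 0, 0)), c(FALSE, FALSE))
}
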