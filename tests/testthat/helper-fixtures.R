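# Inline text fixtures and generators shared across test files.

# A minimal 3-atom PDB fixture; optionally with two alternate locations
# for the phosphate (A at occupancy 0.6, B at 0.4).
writeMiniPDB <- function(path, altlocs = FALSE) {
  lines <- character(0)
  fmt <- "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  add <- function(no, name, alt, resid, chain, resno, x, y, z, occ, el)
    sprintf(fmt, no, paste0(" ", name), alt, resid, chain, resno,
            x, y, z, occ, 0, el)
  if (altlocs) {
    lines <- c(lines,
               add(1, "P", "A", "G", "A", 1, 11.104, 2.354, 0.120, 0.60, "P"),
               add(2, "P", "B", "G", "A", 1, 11.500, 2.600, 0.300, 0.40, "P"))
  } else {
    lines <- c(lines,
               add(1, "P", " ", "G", "A", 1, 11.104, 2.354, 0.120, 1.00, "P"))
  }
  lines <- c(lines,
             add(3, "C1'", " ", "G", "A", 1, 9.400, 0.000, 0.000, 1.00, "C"),
             add(4, "N9", " ", "G", "A", 1, 7.950, 0.350, 0.010, 1.00, "N"),
             "END")
  writeLines(lines, path)
  path
}

# The same 3-atom content as a minimal mmCIF file.
writeMiniCIF <- function(path) {
  hdr <- c("data_test", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- c(
    "ATOM 1 P P . G A 1 1 ? 11.104 2.354 0.120 1.00 0.00 ? 1 G A P 1",
    "ATOM 2 C \"C1'\" . G A 1 1 ? 9.400 0.000 0.000 1.00 0.00 ? 1 G A \"C1'\" 1",
    "ATOM 3 N N9 . G A 1 1 ? 7.950 0.350 0.010 1.00 0.00 ? 1 G A N9 1",
    "#")
  writeLines(c(hdr, rows), path)
  path
}

# Random rigid transform (uniform random rotation via the quaternion
# oracle helpers, translation ~ N(0, 10)).
randomRigidTransform <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  new("RigidTransform", rotation = quatToMatrix(q),
      translation = stats::rnorm(3, sd = 10))
}

# Directory of real (downloaded) ribosome coordinate files, laid out as
# <dir>/manifest.yaml plus the coordinate files it references. The
# reproduction tests need the PDB entries named in the dataset manifest
# (reference 4GD2 plus closed/intermediate/open group members); without
# them those tests fail here.
realDataDir <- function() {
  cand <- c("structures", file.path("..", "structures"),
            file.path("..", "..", "structures"),
            file.path("..", "..", "..", "structures"))
  for (d in cand)
    if (file.exists(file.path(d, "manifest.yaml"))) return(d)
  stop("no structures/manifest.yaml found: the published-measurement ",
       "reproduction tests need locally downloaded ribosome coordinate files ",
       "(reference 4GD2 plus P/E, pe/E and E/E group members, e.g. 4V90, ",
       "4V9H, 4V9K, 4V67) listed in a runDataset manifest; they cannot ",
       "run from synthetic data")
}
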