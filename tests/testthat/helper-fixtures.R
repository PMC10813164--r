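# Shared fixture builders: tiny structure models, ligand poses, and cohorts
# built in code at test time.

make_model <- function(ca, letters = NULL, id = "toy", resno = NULL,
                       chain = "A") {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (is.null(letters)) letters <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(chain = chain, resno = resno,
                      resname = ditps3d:::AA_123[letters], atom = "CA",
                      element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  ditps3d:::new_structure_model(id, atoms)
}

make_ligand <- function(xyz = matrix(0, 1, 3), id = "LIG") {
  if (length(xyz) == 0) xyz <- matrix(numeric(0), 0, 3)
  else xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  structure(list(ligand_id = id,
                 atoms = data.frame(atom = sprintf("C%d", seq_len(n)),
                                    element = rep("C", n),
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    stringsAsFactors = FALSE)),
            class = "ligand_pose")
}

make_shell_direct <- function(ca, letters, id = "shell", resno = NULL) {
  m <- make_model(ca, letters, id, resno)
  structure(list(structure_id = id, radius_A = NA_real_, atoms = m$atoms),
            class = "residue_shell")
}

random_aa <- function(n) {
  paste(sample(ditps3d:::AA_LETTERS, n, replace = TRUE), collapse = "")
}

write_test_annotation <- function(path, rows) {
  header <- c("accession", "class", "species", "sequence", "substrate",
              "products", "skeletons")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"), character(1)))
  writeLines(lines, path)
  path
}

# cohort used by several motif/structure tests
motif_test_config <- function(seed) {
  cohort_config(n_enzymes = 9, n_families = 1, seed = seed,
                family_pocket_residues = 0, decoys_per_structure = 2,
                class_mix = c(I = 1, II = 0, I_II = 0))
}

load_cohort_shells <- function(dir, accs, radius = 6) {
  shells <- list()
  for (a in accs) {
    sm <- read_structure(file.path(dir, "structures", paste0(a, ".pdb")),
                         ligand_codes = "LIG")
    shells[[a]] <- extract_shell(sm$model, sm$ligand, radius)
  }
  shells
}

truth_accessions <- function(truth) {
  vapply(truth$enzymes, function(e) e$accession, character(1))
}

truth_held_out <- function(truth) {
  vapply(truth$enzymes, function(e) isTRUE(e$held_out), logical(1))
}
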