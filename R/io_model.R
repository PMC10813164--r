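#' @useDynLib ditps3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile pnorm pt cor.test rnorm runif setNames median sd
#' @importFrom utils read.delim write.table head combn
NULL

# 3-letter -> 1-letter residue map; anything else becomes X (kept with coordinates,
# skipped by composition statistics).
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- setNames(names(AA_321), unname(AA_321))
AA_LETTERS <- unname(AA_321)

aa_three_to_one <- function(resnames) {
  out <- AA_321[toupper(resnames)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Construct a curated enzyme record
#'
#' One row of the curated diterpene-synthase annotation: accession, sequence,
#' mechanistic class, optional N/C domain ranges, substrate name, and the
#' product set with SMILES and skeleton labels.
#'
#' @param accession character id.
#' @param sequence 1-letter amino-acid string (standard 20 letters plus X).
#' @param class_label one of `"I"`, `"II"`, `"I_II"`, `"unknown"`.
#' @param species,family,genus optional taxonomy strings.
#' @param domain_ranges optional list with elements `N` and/or `C`, each a
#'   length-2 integer vector of 1-based inclusive sequence positions.
#' @param substrate substrate name (e.g. `"GGPP"`, `"ent-CPP"`).
#' @param products data frame with columns `name`, `smiles`, `skeleton`
#'   (label or `"unassigned"`), and logical `valid`.
#' @return An object of class `enzyme_record`.
#' @export
enzyme_record <- function(accession, sequence, class_label = "unknown",
                          species = NA_character_, family = NA_character_,
                          genus = NA_character_, domain_ranges = NULL,
                          substrate = NA_character_, products = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty for ", accession)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_LETTERS, "X"))
  if (length(bad) > 0)
    stop("sequence of ", accession, " contains non-amino-acid letters: ",
         paste(unique(bad), collapse = ","))
  class_label <- match.arg(class_label, c("I", "II", "I_II", "unknown"))
  if (!is.null(domain_ranges)) {
    for (dom in names(domain_ranges)) {
      rng <- domain_ranges[[dom]]
      if (length(rng) != 2 || rng[1] < 1 || rng[2] > nchar(sequence) || rng[1] > rng[2])
        stop("domain range ", dom, " of ", accession, " outside [1, ",
             nchar(sequence), "]")
    }
  }
  if (is.null(products)) {
    products <- data.frame(name = character(), smiles = character(),
                           skeleton = character(), valid = logical(),
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "smiles", "skeleton") %in% names(products)))
    if (is.null(products$valid)) products$valid <- TRUE
    products$skeleton[is.na(products$skeleton) | !nzchar(products$skeleton)] <- "unassigned"
  }
  structure(list(accession = accession, sequence = sequence,
                 class_label = class_label, species = species,
                 family = family, genus = genus,
                 domain_ranges = domain_ranges, substrate = substrate,
                 products = products),
            class = "enzyme_record")
}

#' @export
print.enzyme_record <- function(x, ...) {
  cat("<enzyme_record>", x$accession, " class:", x$class_label,
      " len:", nchar(x$sequence), " products:", nrow(x$products), "\n")
  invisible(x)
}

parse_class_label <- function(x) {
  x <- gsub("[[:space:]]", "", toupper(x))
  if (x %in% c("I/II", "I-II", "I_II", "II/I")) return("I_II")
  if (x == "I") return("I")
  if (x == "II") return("II")
  "unknown"
}

parse_range <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  parts <- as.integer(strsplit(x, "[-:]")[[1]])
  if (length(parts) != 2 || anyNA(parts)) return(NULL)
  parts
}

#' Read a curated annotation table
#'
#' Reads the canonical tab-separated annotation layout: required columns
#' `accession`, `class`, `sequence` (or `fasta_key`, resolved against
#' `fasta`), `substrate`, `products` (semicolon-separated SMILES) and
#' `skeletons` (semicolon-separated labels aligned with products). Optional
#' columns: `species`, `family`, `genus`, `domain_N`, `domain_C`
#' ("start-end", 1-based inclusive). Other layouts can be adapted with
#' `col_map`, a named character vector mapping canonical names to the file's
#' column names.
#'
#' Malformed rows are collected in the `errors` attribute of the result and do
#' not prevent valid rows from being returned; unparseable product SMILES are
#' flagged per product (`valid = FALSE`) with a warning.
#'
#' @param path TSV file with a header line.
#' @param fasta optional named character vector (from [read_fasta()]) used to
#'   resolve `fasta_key` columns.
#' @param col_map optional named character vector renaming columns.
#' @param validate_smiles parse every product SMILES (slower); default TRUE.
#' @return List of `enzyme_record`, with attribute `errors` (data frame of
#'   row number and message for rows that could not be read).
#' @export
read_annotation <- function(path, fasta = NULL, col_map = NULL,
                            validate_smiles = TRUE) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(tab))
        names(tab)[names(tab) == col_map[[canon]]] <- canon
    }
  }
  required <- c("accession", "class", "substrate", "products", "skeletons")
  missing_cols <- setdiff(required, names(tab))
  if (!("sequence" %in% names(tab)) && !("fasta_key" %in% names(tab)))
    missing_cols <- c(missing_cols, "sequence (or fasta_key)")
  if (length(missing_cols) > 0)
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  records <- list()
  errors <- data.frame(row = integer(), message = character(),
                       stringsAsFactors = FALSE)
  n_bad_smiles <- 0L
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    rec <- tryCatch({
      seq <- if ("sequence" %in% names(tab) && nzchar(row$sequence %||% "")) {
        row$sequence
      } else {
        key <- row$fasta_key
        if (is.null(fasta) || is.na(key) || !(key %in% names(fasta)))
          stop("fasta_key '", key, "' not found")
        fasta[[key]]
      }
      smiles <- strsplit(row$products, ";", fixed = TRUE)[[1]]
      smiles <- trimws(smiles)
      smiles <- smiles[nzchar(smiles)]
      skel <- trimws(strsplit(row$skeletons %||% "", ";", fixed = TRUE)[[1]])
      if (length(skel) < length(smiles))
        skel <- c(skel, rep("unassigned", length(smiles) - length(skel)))
      valid <- rep(TRUE, length(smiles))
      if (validate_smiles && length(smiles) > 0) {
        for (k in seq_along(smiles)) {
          ok <- tryCatch({ parse_smiles(smiles[k]); TRUE },
                         error = function(e) FALSE)
          valid[k] <- ok
        }
      }
      n_bad_smiles <- n_bad_smiles + sum(!valid)
      products <- data.frame(
        name = if (length(smiles) > 0) paste0(row$accession, "_P", seq_along(smiles)) else character(),
        smiles = smiles, skeleton = skel[seq_along(smiles)], valid = valid,
        stringsAsFactors = FALSE)
      dr <- list()
      if ("domain_N" %in% names(tab)) dr$N <- parse_range(as.character(row$domain_N))
      if ("domain_C" %in% names(tab)) dr$C <- parse_range(as.character(row$domain_C))
      if (length(dr) == 0) dr <- NULL
      enzyme_record(
        accession = row$accession, sequence = seq,
        class_label = parse_class_label(row$class),
        species = row$species %||% NA_character_,
        family = row$family %||% NA_character_,
        genus = row$genus %||% NA_character_,
        domain_ranges = dr, substrate = row$substrate, products = products)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors <- rbind(errors, data.frame(row = i, message = conditionMessage(rec),
                                         stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (n_bad_smiles > 0)
    warning(n_bad_smiles, " product SMILES could not be parsed; flagged invalid")
  names(records) <- vapply(records, function(r) r$accession, character(1))
  attr(records, "errors") <- errors
  records
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a FASTA file of protein sequences
#'
#' The header token before the first whitespace is the key; sequences are
#' uppercased. Duplicate keys are an error.
#'
#' @param path FASTA file.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  keys <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0)
    stop("duplicate FASTA keys: ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(set)), keys)
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), filepath = path)
  invisible(path)
}

new_structure_model <- function(structure_id, atoms) {
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  res <- residue_table(x)
  cat("<structure_model>", x$structure_id, ":", nrow(res), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose>", x$ligand_id, ":", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Residue table of a structure or shell
#'
#' Unique residues in (chain, number) order with 1-letter codes.
#' @param x `structure_model` or `residue_shell`.
#' @return Data frame with columns chain, resno, resname, letter.
#' @export
residue_table <- function(x) {
  atoms <- x$atoms
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    resname = atoms$resname[first], stringsAsFactors = FALSE)
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  res$letter <- aa_three_to_one(res$resname)
  rownames(res) <- NULL
  res
}

#' Ordered Calpha coordinates of a structure or shell
#' @param x `structure_model` or `residue_shell`.
#' @return Matrix n x 3 (one row per residue with a CA atom, chain order).
#' @export
ca_coords <- function(x) {
  atoms <- x$atoms
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste(ca$chain, ca$resno, sep = "|")
  m
}

is_hydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    h <- !is.na(elesy) & toupper(trimws(elesy)) == "H"
    miss <- is.na(elesy) | !nzchar(trimws(elesy))
    h[miss] <- grepl("^[0-9]*H", trimws(elety[miss]))
    h
  } else {
    grepl("^[0-9]*H", trimws(elety))
  }
}

#' Read a PDB structure and optional bound-ligand pose
#'
#' ATOM records become the protein model; HETATM records whose residue name is
#' in `ligand_codes` become the ligand pose. Waters (HOH) are ignored and
#' hydrogens dropped everywhere. Nonstandard residues are retained (1-letter
#' code X).
#'
#' @param path PDB file.
#' @param ligand_codes character vector of 3-letter HETATM residue names to
#'   collect as the ligand.
#' @param structure_id id for the model; defaults to the file base name.
#' @return List with elements `model` (`structure_model`) and `ligand`
#'   (`ligand_pose`, possibly with zero atoms, or `NULL` when no codes given).
#' @export
read_structure <- function(path, ligand_codes = character(),
                           structure_id = NULL) {
  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at <- at[!is_hydrogen(at$elety, at$elesy), , drop = FALSE]
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0) stop("no ATOM records in ", path)
  elem <- function(d) {
    e <- toupper(trimws(d$elesy))
    miss <- is.na(e) | !nzchar(e)
    e[miss] <- substr(gsub("[0-9']", "", trimws(d$elety[miss])), 1, 1)
    e
  }
  atoms <- data.frame(chain = ifelse(is.na(prot$chain), "A", prot$chain),
                      resno = prot$resno, resname = toupper(prot$resid),
                      atom = trimws(prot$elety), element = elem(prot),
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  model <- new_structure_model(structure_id, atoms)

  ligand <- NULL
  if (length(ligand_codes) > 0) {
    het <- at[at$type == "HETATM" & toupper(at$resid) %in% toupper(ligand_codes), ,
              drop = FALSE]
    if (nrow(het) == 0) {
      warning("ligand code(s) ", paste(ligand_codes, collapse = ","),
              " not found in ", path, "; returning empty pose")
      lat <- data.frame(atom = character(), element = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        stringsAsFactors = FALSE)
    } else {
      lat <- data.frame(atom = trimws(het$elety), element = elem(het),
                        x = het$x, y = het$y, z = het$z,
                        stringsAsFactors = FALSE)
    }
    ligand <- structure(list(ligand_id = paste(toupper(ligand_codes), collapse = "+"),
                             atoms = lat), class = "ligand_pose")
  }
  list(model = model, ligand = ligand)
}

#' Write a residue shell (or structure model) as PDB
#'
#' Residues are written in original chain order with original numbering, so
#' that reading the file back reproduces the residue set and coordinates to
#' PDB precision (1e-3 A).
#'
#' @param shell `residue_shell` or `structure_model` with at least one atom.
#' @param path output PDB path.
#' @export
write_shell_pdb <- function(shell, path) {
  atoms <- shell$atoms
  if (is.null(atoms) || nrow(atoms) == 0) stop("refusing to write an empty shell")
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   resid = atoms$resname, chain = atoms$chain,
                   eleno = seq_len(nrow(atoms)), elety = atoms$atom,
                   elesy = atoms$element)
  invisible(path)
}

#' Summarize a curated cohort
#'
#' Aggregate counts over a list of enzyme records: total records, class
#' partition, number of species, numbers of distinct class II products
#' (diterpene intermediates) and class I / I-II products (diterpene
#' precursors), and the number of skeleton types among class I + I-II
#' products.
#'
#' @param records list of `enzyme_record`.
#' @return Named list of counts.
#' @export
dataset_summary <- function(records) {
  classes <- vapply(records, function(r) r$class_label, character(1))
  species <- vapply(records, function(r) as.character(r$species), character(1))
  prod_of <- function(keep) {
    unique(unlist(lapply(records[keep], function(r) r$products$smiles)))
  }
  skel_of <- function(keep) {
    sk <- unlist(lapply(records[keep], function(r) r$products$skeleton))
    unique(sk[!is.na(sk) & sk != "unassigned"])
  }
  list(
    n_records = length(records),
    n_class_I = sum(classes == "I"),
    n_class_II = sum(classes == "II"),
    n_class_I_II = sum(classes == "I_II"),
    n_species = length(unique(species[!is.na(species)])),
    n_intermediates = length(prod_of(classes == "II")),
    n_precursors = length(prod_of(classes %in% c("I", "I_II"))),
    n_skeleton_types_I = length(skel_of(classes %in% c("I", "I_II")))
  )
}
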