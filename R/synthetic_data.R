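# Built-in product sub-libraries: one scaffold family per entry, each with
# structural variants of the same carbon skeleton, plus one shared "bridge"
# molecule. Between-family Dice similarity is tuned by how often the bridge
# molecule is included in an enzyme's product set.
PRODUCT_LIBRARY <- list(
  linear = c("CC(C)CCCC(C)CCCC(C)CCCC(C)C",
             "CC(C)CCCC(C)CCCC(C)CCCC(C)CO",
             "CC(C)CCCC(C)CCCC(C)CCCC(C)CC",
             "CC(C)=CCCC(C)CCCC(C)CCCC(C)C",
             "CC(C)CCCC(C)CCCC(C)CCCC(C)C=C"),
  cyclohexane = c("CC1CCC(C(C)C)CC1",
                  "CC1CCC(C(C)C)CC1C",
                  "CC1CCC(C(C)CO)CC1",
                  "CC1CCC(C(C)C)C(C)C1",
                  "CC1(C)CCC(C(C)C)CC1"),
  decalin = c("CC1CCC2CCCCC2C1",
              "CC1CCC2CCCCC2C1C",
              "CC1(C)CCC2CCCCC2C1",
              "CC1CCC2CC(C)CCC2C1",
              "OCC1CCC2CCCCC2C1"),
  cyclopentane = c("CC1CCCC1CCCC(C)C",
                   "CC1CCCC1CCCC(C)CO",
                   "CC1CCCC1CCC(C)C",
                   "CC1(C)CCCC1CCCC(C)C",
                   "CC1CCCC1CCCC(C)C=C"),
  bicyclic = c("CC12CCCC1CCCC2",
               "CC12CCCC1CCCC2C",
               "OCC12CCCC1CCCC2",
               "CC12CCC(C)C1CCCC2",
               "CC12CCCC1CC(C)CC2"),
  cycloheptane = c("CC1CCCCCC1C(C)C",
                   "CC1CCCCCC1C(C)CO",
                   "CC1CCCCC(C)C1C(C)C",
                   "CC1(C)CCCCCC1C(C)C",
                   "CC1CCCCCC1C(C)C=C")
)
BRIDGE_SMILES <- "CC(C)=CCCC(C)=CCO"

#' Configuration of a synthetic diterpene-synthase cohort
#'
#' The generator plants (i) a cohort-wide conserved residue geometry (the 3D
#' motif) around a ligand placed at the pocket centroid, (ii) family-specific
#' pocket residues and backbones inducing correlated structural similarity,
#' (iii) class signature motifs (DDXXD / DXDD) in the sequences, and (iv)
#' family product sub-libraries with a shared bridge molecule controlling the
#' planted sequence-product coupling. One designated held-out enzyme per
#' family carries a single substitution at a motif position.
#'
#' @param n_enzymes cohort size.
#' @param n_families number of families (recycled over the product library).
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @param motif_letters residue letters of the planted motif (>= 3).
#' @param motif_template Calpha template (one row per motif residue, A);
#'   default: octahedron of radius 5 A around the ligand.
#' @param jitter_sigma_A per-axis Gaussian jitter on planted coordinates.
#' @param decoys_per_structure random extra pocket residues per structure.
#' @param family_pocket_residues family-specific pocket residues.
#' @param class_mix named proportions over classes I, II, I_II (sum 1).
#' @param seq_length sequence length.
#' @param mutations_range integer range of per-enzyme substitutions from the
#'   family ancestor.
#' @param products_per_enzyme family-scaffold products per enzyme.
#' @param bridge_every every k-th enzyme of a family also carries the shared
#'   bridge molecule (controls between-family product similarity).
#' @param promiscuity probability that an enzyme's last product is drawn
#'   from another family's scaffold library (product promiscuity decouples
#'   product chemistry from sequence family and tunes the planted coupling).
#' @param rho_target planted sequence-product coupling recorded in the truth.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_enzymes = 50, n_families = 5, seed = 1,
                          motif_letters = c("D", "D", "W", "F", "S", "Y"),
                          motif_template = NULL, jitter_sigma_A = 0.3,
                          decoys_per_structure = 2,
                          family_pocket_residues = 3,
                          class_mix = c(I = 0.45, II = 0.40, I_II = 0.15),
                          seq_length = 180,
                          mutations_range = c(4, 70),
                          products_per_enzyme = 2,
                          bridge_every = 2,
                          promiscuity = 0.39,
                          rho_target = 0.5) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (length(motif_letters) < 3) stop("motif needs >= 3 residues")
  if (is.null(motif_template)) {
    # irregular pocket arrangement: every vertex pair has well-separated
    # distance profiles (swapping any two residues costs >= 3.1 A of distance
    # misfit somewhere), as in real pockets; a symmetric template would make
    # the site-alignment problem degenerate
    irr <- rbind(c(0.79, 2.43, 2.76), c(0.97, -1.91, 4.54),
                 c(-4.31, -0.56, -1.57), c(-3.33, -3.36, 2.15),
                 c(2.12, 3.70, -0.79), c(-1.21, 2.01, -3.03))
    if (length(motif_letters) > nrow(irr))
      stop("provide motif_template for motifs with > 6 residues")
    motif_template <- irr[seq_along(motif_letters), , drop = FALSE]
  }
  if (seed >= 2^31) stop("seed must be below 2^31")
  structure(list(n_enzymes = n_enzymes, n_families = n_families, seed = seed,
                 motif_letters = motif_letters,
                 motif_template = motif_template,
                 jitter_sigma_A = jitter_sigma_A,
                 decoys_per_structure = decoys_per_structure,
                 family_pocket_residues = family_pocket_residues,
                 class_mix = class_mix, seq_length = seq_length,
                 mutations_range = mutations_range,
                 products_per_enzyme = products_per_enzyme,
                 bridge_every = bridge_every, promiscuity = promiscuity,
                 rho_target = rho_target),
            class = "cohort_config")
}

# replace accidental signature-motif occurrences outside the protected
# windows, leaving protected positions untouched
scrub_signatures <- function(chars, protected, patterns) {
  for (round in 1:100) {
    s <- paste(chars, collapse = "")
    hit_found <- FALSE
    for (pat in patterns) {
      m <- gregexpr(pat, s)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (h in seq_along(m)) {
        window <- seq(m[h], m[h] + lens[h] - 1L)
        free <- setdiff(window, protected)
        if (length(free) == 0) next # planted occurrence
        # pick a free position whose replacement destroys this match
        # (wildcard positions of the pattern would leave it intact)
        for (cand in free) {
          tmp <- chars
          tmp[cand] <- "G"
          still <- regexpr(pat, paste(tmp[window], collapse = "")) == 1
          if (!still) {
            chars <- tmp
            hit_found <- TRUE
            break
          }
        }
      }
      if (hit_found) break
    }
    if (!hit_found) return(chars)
  }
  stop("could not scrub accidental signature motifs")
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# self-avoiding Calpha walk with 3.8 A steps staying clear of the pocket
generate_walk <- function(n, start = c(25, 0, 0), step = 3.8,
                          pocket_clear = 12, self_clear = 3.5,
                          max_attempts = 1000) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- start
  for (i in seq_len(n - 1)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- pts[i, ] + step * as.numeric(random_unit_vectors(1))
      if (sqrt(sum(cand^2)) < pocket_clear) next
      prev <- pts[seq_len(max(1, i - 1)), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (any(d2 < self_clear^2)) next
      pts[i + 1, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible walk geometry after ", max_attempts,
                      " placement attempts")
  }
  pts
}

# jittered copy of the motif template whose pairwise distances stay within
# 4*sigma of the template's
jitter_template <- function(template, sigma, max_attempts = 1000) {
  if (sigma == 0) return(template)
  td <- as.matrix(dist(template))
  for (att in seq_len(max_attempts)) {
    j <- template + matrix(rnorm(length(template), 0, sigma),
                           ncol = 3)
    if (max(abs(as.matrix(dist(j)) - td)) <= 4 * sigma) return(j)
  }
  stop("infeasible motif jitter after ", max_attempts, " attempts")
}

place_pocket_points <- function(n, existing, r_min = 4, r_max = 5.5,
                                clearance = 2.5, max_attempts = 1000,
                                avoid = NULL, avoid_clearance = 2.2) {
  # `existing` is a hard steric constraint within the structure; `avoid` is a
  # best-effort cross-structure constraint: decoy positions of other cohort
  # members are avoided so that planted "non-conserved" residues really are
  # non-conserved (coinciding decoys would make the ground truth ambiguous).
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- runif(1, r_min, r_max) * as.numeric(random_unit_vectors(1))
      ref <- rbind(existing, out[seq_len(k - 1), , drop = FALSE])
      ref <- ref[stats::complete.cases(ref), , drop = FALSE]
      if (nrow(ref) > 0 && min(rowSums(sweep(ref, 2, cand)^2)) < clearance^2)
        next
      if (!is.null(avoid) && nrow(avoid) > 0 && att <= max_attempts / 2 &&
          min(rowSums(sweep(avoid, 2, cand)^2)) < avoid_clearance^2)
        next
      out[k, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible pocket geometry after ", max_attempts,
                      " attempts")
  }
  out
}

#' @importFrom stats complete.cases ave
NULL

write_cohort_pdb <- function(path, resno, letters, ca, lig_xyz) {
  # glycine-like stubs (N, CA, C, O) around each Calpha
  offs <- rbind(N = c(-0.8, 0.6, 0), CA = c(0, 0, 0), C = c(0.8, 0.6, 0),
                O = c(1.2, 1.6, 0))
  n <- length(resno)
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- character(0)
  eleno <- 0L
  for (i in seq_len(n)) {
    for (a in seq_len(nrow(offs))) {
      eleno <- eleno + 1L
      xyz <- ca[i, ] + offs[a, ]
      nm <- rownames(offs)[a]
      lines <- c(lines, sprintf(
        fmt, "ATOM", eleno, paste0(" ", formatC(nm, width = 3, flag = "-")),
        "", AA_123[[letters[i]]], "A", resno[i], "",
        xyz[1], xyz[2], xyz[3], 1, 0,
        substr(nm, 1, 1)))
    }
  }
  lig_names <- c("C1", "C2", "C3", "O1")
  lig_elem <- c("C", "C", "C", "O")
  for (a in seq_len(nrow(lig_xyz))) {
    eleno <- eleno + 1L
    lines <- c(lines, sprintf(
      fmt, "HETATM", eleno,
      paste0(" ", formatC(lig_names[a], width = 3, flag = "-")), "",
      "LIG", "L", 999L, "", lig_xyz[a, 1], lig_xyz[a, 2], lig_xyz[a, 3],
      1, 0, lig_elem[a]))
  }
  writeLines(c(lines, "END"), path)
}

#' Generate a synthetic diterpene-synthase cohort
#'
#' Emits, per enzyme, a PDB structure (Calpha-trace backbone with glycine-like
#' atom stubs and a ligand HETATM block at the pocket centroid; planted motif
#' residues at the template coordinates plus Gaussian jitter), a FASTA entry
#' embedding the class signature motifs, and an annotation row with
#' family-assigned products. The last enzyme of each family is held out with
#' a single substitution at a planted motif position. All randomness comes
#' from `config$seed`.
#'
#' @param config `cohort_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the ground-truth list (also written to `truth.json`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dir.create(file.path(out_dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  n <- config$n_enzymes
  nf <- config$n_families
  L <- config$seq_length
  nm <- length(config$motif_letters)

  fam_id <- rep(seq_len(nf), length.out = n)
  fam_id <- sort(fam_id)
  acc <- sprintf("SYN%03d", seq_len(n))
  # last enzyme of each family is the held-out carrier of the motif mutation
  held_out <- !duplicated(fam_id, fromLast = TRUE) &
    ave(fam_id, fam_id, FUN = length) > 1

  classes <- sample(rep(names(config$class_mix),
                        times = round(config$class_mix * n) + 1)[seq_len(n)])

  # reserved sequence positions (cohort-wide)
  motif_pos <- pmin(L - 2, pmax(3, round(L * c(0.32, 0.42, 0.52, 0.60,
                                               0.80, 0.90))))[seq_len(nm)]
  fam_pocket_pos <- round(L * c(0.36, 0.47, 0.84))[
    seq_len(config$family_pocket_residues)]
  sig_II_pos <- round(L * 0.20) # DXDD, in the N half
  sig_I_pos <- round(L * 0.70)  # DDXXD, in the C half
  sig_windows <- c(sig_II_pos:(sig_II_pos + 3), sig_I_pos:(sig_I_pos + 4))
  reserved <- unique(c(motif_pos, fam_pocket_pos, sig_windows))

  non_d <- setdiff(AA_LETTERS, "D")
  scrub_pats <- unname(SIGNATURE_MOTIFS[c("DDXXD", "DXDD", "NSE_DTE")])

  # family-level material
  fam_anc <- list()
  fam_pocket_xyz <- list()
  fam_pocket_letters <- list()
  fam_walk <- list()
  for (f in seq_len(nf)) {
    anc <- sample(AA_LETTERS, L, replace = TRUE)
    anc[motif_pos] <- config$motif_letters
    fam_pocket_letters[[f]] <- sample(non_d, config$family_pocket_residues,
                                      replace = TRUE)
    anc[fam_pocket_pos] <- fam_pocket_letters[[f]]
    # signature windows are not yet planted at the ancestor stage, so they
    # stay scrubbable
    anc <- scrub_signatures(anc, c(motif_pos, fam_pocket_pos), scrub_pats)
    fam_anc[[f]] <- anc
    fam_pocket_xyz[[f]] <- place_pocket_points(
      config$family_pocket_residues, config$motif_template)
    fam_walk[[f]] <- generate_walk(L)
  }

  lib <- PRODUCT_LIBRARY[((seq_len(nf) - 1) %% length(PRODUCT_LIBRARY)) + 1]
  lig_xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0), c(0, 0, 1.2))

  mut_pos_idx <- 3L # motif position mutated in held-out enzymes
  mutation_letter <- if (config$motif_letters[mut_pos_idx] == "K") "E" else "K"

  seqs <- character(n)
  products <- character(n)
  skeletons <- character(n)
  species <- character(n)
  idx_in_fam <- stats::ave(seq_len(n), fam_id, FUN = seq_along)
  truth_rows <- list()
  cohort_decoy_xyz <- matrix(numeric(0), 0, 3)

  for (i in seq_len(n)) {
    f <- fam_id[i]
    chars <- fam_anc[[f]]
    # class signatures
    xs <- sample(non_d, 2, replace = TRUE)
    if (classes[i] %in% c("II", "I_II"))
      chars[sig_II_pos:(sig_II_pos + 3)] <- c("D", sample(non_d, 1), "D", "D")
    if (classes[i] %in% c("I", "I_II"))
      chars[sig_I_pos:(sig_I_pos + 4)] <- c("D", "D", xs, "D")
    # family divergence
    k <- sample(config$mutations_range[1]:config$mutations_range[2], 1)
    free <- setdiff(seq_len(L), reserved)
    targets <- sample(free, min(k, length(free)))
    for (t in targets) chars[t] <- sample(setdiff(AA_LETTERS, chars[t]), 1)
    if (held_out[i])
      chars[motif_pos[mut_pos_idx]] <- mutation_letter
    protected <- if (classes[i] == "I") {
      setdiff(reserved, sig_II_pos:(sig_II_pos + 3))
    } else if (classes[i] == "II") {
      setdiff(reserved, sig_I_pos:(sig_I_pos + 4))
    } else reserved
    chars <- scrub_signatures(chars, protected, switch(
      classes[i],
      I = SIGNATURE_MOTIFS[["DXDD"]],
      II = SIGNATURE_MOTIFS[["DDXXD"]],
      I_II = character(0)))
    seqs[i] <- paste(chars, collapse = "")

    # structure
    ca <- fam_walk[[f]] + matrix(rnorm(3 * L, 0, 0.5), ncol = 3)
    ca[motif_pos, ] <- jitter_template(config$motif_template,
                                       config$jitter_sigma_A)
    ca[fam_pocket_pos, ] <- fam_pocket_xyz[[f]] +
      matrix(rnorm(3 * config$family_pocket_residues, 0,
                   config$jitter_sigma_A), ncol = 3)
    decoy_pos <- sample(setdiff(seq_len(L), reserved),
                        config$decoys_per_structure)
    # decoys fill the pocket volume (not just its outer rim) and keep
    # clearance from ligand and planted residues
    decoy_xyz <- place_pocket_points(
      config$decoys_per_structure,
      rbind(config$motif_template, fam_pocket_xyz[[f]], lig_xyz),
      r_min = 2.5, r_max = 5.8, clearance = 2.0,
      avoid = cohort_decoy_xyz)
    ca[decoy_pos, ] <- decoy_xyz
    cohort_decoy_xyz <- rbind(cohort_decoy_xyz, decoy_xyz)
    write_cohort_pdb(file.path(out_dir, "structures", paste0(acc[i], ".pdb")),
                     resno = seq_len(L), letters = chars, ca = ca,
                     lig_xyz = lig_xyz)

    # products: family scaffold variants, deterministic per index, plus the
    # shared bridge molecule every bridge_every-th family member
    fam_lib <- lib[[f]]
    pick <- ((idx_in_fam[i] - 1L + seq_len(config$products_per_enzyme) - 1L) %%
               length(fam_lib)) + 1L
    prods <- fam_lib[pick]
    skels <- rep(paste0("SK", f), length(prods))
    if (nf > 1 && config$promiscuity > 0 &&
        runif(1) < config$promiscuity) {
      # promiscuous enzyme: last product comes from another family's
      # scaffold library
      other <- sample(setdiff(seq_len(nf), f), 1)
      j <- sample(length(lib[[other]]), 1)
      prods[length(prods)] <- lib[[other]][j]
      skels[length(skels)] <- paste0("SK", other)
    }
    if (idx_in_fam[i] %% config$bridge_every == 0) {
      prods <- c(prods, BRIDGE_SMILES)
      skels <- c(skels, "SK_bridge")
    }
    products[i] <- paste(prods, collapse = ";")
    skeletons[i] <- paste(skels, collapse = ";")
    species[i] <- paste0("Synthoplantus sp", f, "_", 1 + (idx_in_fam[i] %% 3))

    truth_rows[[i]] <- list(
      accession = acc[i], family = f, class_label = classes[i],
      held_out = unname(held_out[i]),
      motif_positions = motif_pos,
      decoy_positions = sort(decoy_pos),
      mutated_position = if (held_out[i]) motif_pos[mut_pos_idx] else NA,
      species = species[i])
  }

  substrate <- ifelse(classes == "I", "ent-CPP", "GGPP")
  ann <- data.frame(
    accession = acc, class = sub("I_II", "I/II", classes),
    species = species, family = paste0("Family", fam_id),
    genus = "Synthoplantus", sequence = seqs, substrate = substrate,
    products = products, skeletons = skeletons,
    domain_N = paste0(1, "-", L %/% 2),
    domain_C = paste0(L %/% 2 + 1, "-", L), stringsAsFactors = FALSE)
  write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(setNames(seqs, acc), file.path(out_dir, "sequences.fasta"))

  truth <- list(seed = config$seed, n_enzymes = n, n_families = nf,
                motif_letters = config$motif_letters,
                motif_positions = motif_pos,
                mutation_letter = mutation_letter,
                rho_target = config$rho_target,
                jitter_sigma_A = config$jitter_sigma_A,
                enzymes = truth_rows)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Check analysis outputs against a cohort's planted ground truth
#'
#' @param truth truth list from [generate_cohort()] (or read from
#'   `truth.json`).
#' @param outputs named list with any of: `class_labels` (named character,
#'   accession -> class), `motif_positions` (integer vector of recovered
#'   motif residue numbers), `r` (recovered sequence-product correlation).
#' @return List with the recovery metrics for the outputs supplied:
#'   `class_agreement`, `motif_recovered` / `motif_recall` /
#'   `motif_precision`, `correlation_error`.
#' @export
truth_check <- function(truth, outputs) {
  if (length(outputs) == 0 ||
      !any(c("class_labels", "motif_positions", "r") %in% names(outputs)))
    stop("missing outputs: supply class_labels, motif_positions and/or r")
  res <- list()
  enz <- truth$enzymes
  if (!is.null(outputs$class_labels)) {
    planted <- setNames(vapply(enz, function(e) e$class_label, character(1)),
                        vapply(enz, function(e) e$accession, character(1)))
    got <- outputs$class_labels[names(planted)]
    res$class_agreement <- mean(got == planted)
  }
  if (!is.null(outputs$motif_positions)) {
    planted <- sort(unlist(truth$motif_positions))
    got <- sort(unique(as.integer(outputs$motif_positions)))
    res$motif_recovered <- setequal(got, planted)
    res$motif_recall <- mean(planted %in% got)
    res$motif_precision <- if (length(got) > 0) mean(got %in% planted) else 0
  }
  if (!is.null(outputs$r)) {
    res$correlation_error <- abs(outputs$r - truth$rho_target)
  }
  res
}
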