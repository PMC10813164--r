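#' TM-score distance scale d0
#'
#' d0(L) = 1.24 (L - 15)^(1/3) - 1.8, clamped below at 0.5 A.
#' @param L normalizing length (number of residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  if (L < 1) stop("L_norm must be >= 1")
  x <- L - 15
  d0 <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  max(0.5, d0)
}

#' Extract the residue shell around a ligand pose
#'
#' "byres within r" selection: a residue is included iff the minimum distance
#' between any of its (heavy) atoms and any ligand atom is <= `radius_A`; the
#' whole residue is then retained.
#'
#' @param structure `structure_model`.
#' @param ligand `ligand_pose` with at least one atom.
#' @param radius_A selection radius in Angstrom (> 0).
#' @return Object of class `residue_shell` with the member residues in chain
#'   order; may be empty (with a warning) if nothing is within range.
#' @export
extract_shell <- function(structure, ligand, radius_A) {
  if (is.null(ligand) || nrow(ligand$atoms) == 0) stop("ligand pose is empty")
  if (radius_A <= 0) stop("radius_A must be positive")
  at <- structure$atoms
  lig <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  pm <- as.matrix(at[, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2min <- rep(Inf, nrow(pm))
  for (k in seq_len(nrow(lig))) {
    d2 <- (pm[, 1] - lig[k, 1])^2 + (pm[, 2] - lig[k, 2])^2 +
      (pm[, 3] - lig[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  near <- d2min <= radius_A^2
  keys <- paste(at$chain, at$resno, sep = "|")
  keep_keys <- unique(keys[near])
  atoms <- at[keys %in% keep_keys, , drop = FALSE]
  if (nrow(atoms) == 0)
    warning("no residues within ", radius_A, " A of the ligand in ",
            structure$structure_id)
  shell <- structure(list(structure_id = structure$structure_id,
                          radius_A = radius_A,
                          atoms = atoms[order(atoms$chain, atoms$resno), ,
                                        drop = FALSE]),
                     class = "residue_shell")
  shell
}

#' @export
print.residue_shell <- function(x, ...) {
  cat("<residue_shell>", x$structure_id, "r =", x$radius_A, "A:",
      nrow(residue_table(x)), "residues\n")
  invisible(x)
}

#' Shell sequence (1-letter, chain order)
#' @param shell `residue_shell`.
#' @return Character string.
#' @export
shell_sequence <- function(shell) {
  paste(residue_table(shell)$letter, collapse = "")
}

#' Kabsch least-squares superposition
#'
#' Rigid proper rotation (det = +1) and translation minimizing the RMSD of
#' `coords_a` onto `coords_b` (row-per-point matrices).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, non-collinear.
#' @return List with `rotation` (3 x 3, applied on the right to centered
#'   coordinates), `translation`, `rmsd_A`, and `transform(x)` mapping points
#'   from frame A to frame B.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets differ in size")
  if (nrow(coords_a) < 3) stop("need >= 3 points for superposition")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  Ac <- sweep(coords_a, 2, ca)
  Bc <- sweep(coords_b, 2, cb)
  sv_a <- svd(Ac)$d
  sv_b <- svd(Bc)$d
  if (sv_a[2] < 1e-8 || sv_b[2] < 1e-8)
    stop("degenerate (collinear) geometry; superposition undefined")
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  mapped <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((mapped - Bc)^2)))
  translation <- cb - as.numeric(ca %*% R)
  transform <- function(x) sweep(sweep(as.matrix(x), 2, ca) %*% R, 2, cb, `+`)
  list(rotation = R, translation = translation, rmsd_A = rmsd,
       transform = transform)
}

#' TM-score of a superposed pairing
#'
#' TM = (1/L_norm) sum_i 1 / (1 + (d_i/d0(L_norm))^2) over aligned pairs,
#' where coordinates are assumed already superposed by the TM-maximizing
#' transform.
#'
#' @param pairs k x 2 matrix of row indices into `coords_a` / `coords_b`.
#' @param coords_a,coords_b superposed coordinate matrices.
#' @param L_norm normalizing length (>= 1).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(pairs, coords_a, coords_b, L_norm) {
  if (L_norm < 1) stop("L_norm must be >= 1")
  pairs <- matrix(as.integer(pairs), ncol = 2)
  d0 <- tm_d0(L_norm)
  d <- sqrt(rowSums((coords_a[pairs[, 1], , drop = FALSE] -
                       coords_b[pairs[, 2], , drop = FALSE])^2))
  sum(1 / (1 + (d / d0)^2)) / L_norm
}

# iterate Kabsch on the d < d0 subset of a fixed pairing to (locally)
# maximize the TM kernel sum; returns the kernel sum
refine_tm_fixed_pairs <- function(A, B, pairs, d0, L_norm, max_iter = 20) {
  pa <- A[pairs[, 1], , drop = FALSE]
  pb <- B[pairs[, 2], , drop = FALSE]
  sel_prev <- NULL
  fit <- kabsch(pa, pb)
  best <- -Inf
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((fit$transform(pa) - pb)^2))
    tm <- sum(1 / (1 + (d / d0)^2)) / L_norm
    best <- max(best, tm)
    sel <- which(d < d0)
    if (length(sel) < 3) sel <- order(d)[seq_len(min(3, length(d)))]
    if (!is.null(sel_prev) && identical(sel, sel_prev)) break
    sel_prev <- sel
    fit2 <- tryCatch(kabsch(pa[sel, , drop = FALSE], pb[sel, , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(fit2)) break
    fit <- fit2
  }
  best
}

align_input_ca <- function(x) {
  if (inherits(x, c("structure_model", "residue_shell"))) {
    m <- ca_coords(x)
    list(coords = m, id = x$structure_id, keys = rownames(m))
  } else if (is.matrix(x)) {
    list(coords = x, id = paste0("m", nrow(x)), keys = rownames(x))
  } else stop("cannot extract Calpha coordinates from this object")
}

#' Sequence-order-dependent structural alignment with TM-scores
#'
#' TM-align-style heuristic: correspondences are seeded from gapless
#' threading of fragments (lengths 5, L/2, L), then refined by iterating
#' Kabsch superposition on close pairs with dynamic programming over the TM
#' kernel score matrix (gap penalty -0.6) until the pair set repeats (at most
#' 30 iterations). Reports TM normalized by each structure's length and
#' their mean; `tm_mean` is symmetric in the argument order.
#'
#' @param a,b `structure_model`, `residue_shell`, or n x 3 Calpha matrices
#'   with >= 4 residues.
#' @return Object of class `struct_alignment`: `pairs` (k x 2 residue
#'   indices), `rotation`, `translation`, `rmsd_A`, `tm_by_a`, `tm_by_b`,
#'   `tm_mean`.
#' @export
align_structures <- function(a, b) {
  ia <- align_input_ca(a)
  ib <- align_input_ca(b)
  if (nrow(ia$coords) < 4 || nrow(ib$coords) < 4)
    stop("too small to align (need >= 4 residues with Calpha)")
  # canonical argument order makes tm_mean exactly symmetric
  key <- function(z) paste(nrow(z$coords), z$id,
                           paste(round(z$coords[1, ], 3), collapse = ","))
  swapped <- key(ib) < key(ia)
  if (swapped) { tmp <- ia; ia <- ib; ib <- tmp }
  A <- unname(ia$coords)
  B <- unname(ib$coords)
  la <- nrow(A)
  lb <- nrow(B)
  d0s <- tm_d0(min(la, lb))
  core <- .tm_align_core(A, B, d0s)
  if (nrow(core$pairs) == 0) stop("alignment failed: no correspondences found")
  pairs <- core$pairs
  R <- core$rotation
  cA <- as.numeric(core$centroid_a)
  cB <- as.numeric(core$centroid_b)
  Am <- sweep(sweep(A, 2, cA) %*% R, 2, cB, `+`)
  d <- sqrt(rowSums((Am[pairs[, 1], , drop = FALSE] -
                       B[pairs[, 2], , drop = FALSE])^2))
  tm_a <- refine_tm_fixed_pairs(A, B, pairs, tm_d0(la), la)
  tm_b <- refine_tm_fixed_pairs(A, B, pairs, tm_d0(lb), lb)
  out <- list(id_a = ia$id, id_b = ib$id, pairs = pairs, rotation = R,
              translation = cB - as.numeric(cA %*% R),
              rmsd_A = sqrt(mean(d^2)),
              tm_by_a = tm_a, tm_by_b = tm_b, tm_mean = (tm_a + tm_b) / 2,
              keys_a = ia$keys, keys_b = ib$keys)
  if (swapped) {
    out <- list(id_a = out$id_b, id_b = out$id_a,
                pairs = out$pairs[, 2:1, drop = FALSE],
                rotation = t(out$rotation),
                translation = -as.numeric(out$translation %*% t(out$rotation)),
                rmsd_A = out$rmsd_A, tm_by_a = out$tm_by_b,
                tm_by_b = out$tm_by_a, tm_mean = out$tm_mean,
                keys_a = out$keys_b, keys_b = out$keys_a)
  }
  class(out) <- "struct_alignment"
  out
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat("<struct_alignment>", x$id_a, "vs", x$id_b, ":", nrow(x$pairs),
      "pairs, rmsd", round(x$rmsd_A, 3), "A, TM mean",
      round(x$tm_mean, 4), "\n")
  invisible(x)
}

#' Pairwise TM-score matrix over structures or shells
#'
#' Symmetric matrix of `tm_mean` from [align_structures()]. Entries where
#' either object has fewer than 4 Calpha residues are recorded as missing
#' (NA); the diagonal of usable objects is 1.
#'
#' @param objects named list of `structure_model` or `residue_shell`.
#' @param kind matrix kind label, e.g. `"tm_global"` or `"tm_shell_6"`.
#' @return `similarity_matrix` on the \[0, 1\] scale.
#' @export
tm_similarity_matrix <- function(objects, kind = "tm_global") {
  ids <- names(objects)
  if (is.null(ids))
    ids <- vapply(objects, function(o) o$structure_id, character(1))
  n <- length(objects)
  usable <- vapply(objects, function(o) nrow(ca_coords(o)) >= 4, logical(1))
  if (!any(usable)) stop("no object has >= 4 residues; matrix would be empty")
  vals <- matrix(NA_real_, n, n)
  diag(vals) <- ifelse(usable, 1, NA_real_)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!usable[i] || !usable[j]) next
      al <- align_structures(objects[[i]], objects[[j]])
      vals[i, j] <- vals[j, i] <- al$tm_mean
    }
  }
  new_similarity_matrix(ids, vals, kind, 1)
}

#' Shell TM-score matrix at a given radius
#'
#' @param shells named list of `residue_shell` extracted at `radius_A`.
#' @param radius_A radius used (labels the matrix kind `tm_shell_<r>`).
#' @return `similarity_matrix`.
#' @export
shell_tm_matrix <- function(shells, radius_A) {
  tm_similarity_matrix(shells, kind = paste0("tm_shell_", radius_A))
}

#' Write a similarity matrix as square TSV with accession headers
#' @param m `similarity_matrix`.
#' @param path output file.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- data.frame(accession = m$ids, m$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#' @param path TSV file.
#' @param kind matrix kind label.
#' @param scale_max scale maximum (100 for percent identity, 1 for TM/DSC).
#' @return `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path, kind, scale_max = 1) {
  df <- read.delim(path, check.names = FALSE)
  ids <- as.character(df$accession)
  vals <- as.matrix(df[, -1, drop = FALSE])
  new_similarity_matrix(ids, unname(vals), kind, scale_max)
}
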