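# atomic numbers and default valences for the elements that occur in terpene
# product chemistry; used for the initial ECFP atom invariant and implicit
# hydrogen counting
ELEMENT_NUMBERS <- c(B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                     CL = 17, BR = 35, I = 53)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 2,
                     CL = 1, BR = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' Uses OpenBabel (through ChemmineR) to interpret the SMILES; returns the
#' heavy-atom graph with kekulized bond orders. Implicit hydrogen counts are
#' derived from default valences. Formal charges are read from the MOL block
#' when present.
#'
#' @param smiles a single SMILES string.
#' @return List with `elements` (symbols), `bonds` (data frame a, b, order),
#'   `charges`, `n_atoms`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  # single-heavy-atom molecules don't survive the SDF round trip; build the
  # one-atom graph directly
  m1 <- regmatches(smiles,
                   regexec("^(?:\\[)?([A-Z][a-z]?)(?:H\\d*)?([+-]?\\d*)(?:\\])?$",
                           smiles))[[1]]
  if (length(m1) == 3 && toupper(m1[2]) %in% names(ELEMENT_NUMBERS)) {
    chg <- if (m1[3] %in% c("", "0")) 0L else if (m1[3] == "+") 1L
      else if (m1[3] == "-") -1L else as.integer(m1[3])
    return(list(elements = toupper(m1[2]),
                bonds = data.frame(a = integer(), b = integer(),
                                   order = integer()),
                charges = chg, n_atoms = 1L))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf))
    stop("unparseable SMILES: ", smiles)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0 || ncol(ab) < 3)
    stop("unparseable SMILES: ", smiles)
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  if (!all(elements %in% names(ELEMENT_NUMBERS)))
    stop("SMILES ", smiles, " contains unsupported element(s): ",
         paste(setdiff(elements, names(ELEMENT_NUMBERS)), collapse = ","))
  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  } else {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  charges <- rep(0L, length(elements))
  # old-style MOL charge codes in atom block column 5: 1..3 -> +3..+1, 5..7 -> -1..-3
  if (ncol(ab) >= 5) {
    code <- as.integer(ab[, 5])
    code[is.na(code)] <- 0L
    charges <- ifelse(code >= 1 & code <= 3, 4L - code,
                      ifelse(code >= 5 & code <= 7, -(code - 4L), 0L))
  }
  list(elements = elements, bonds = bonds, charges = as.integer(charges),
       n_atoms = length(elements))
}

mol_degree <- function(mol) {
  deg <- rep(0L, mol$n_atoms)
  if (nrow(mol$bonds) > 0) {
    t1 <- table(factor(mol$bonds$a, levels = seq_len(mol$n_atoms)))
    t2 <- table(factor(mol$bonds$b, levels = seq_len(mol$n_atoms)))
    deg <- as.integer(t1 + t2)
  }
  deg
}

mol_h_count <- function(mol) {
  bond_sum <- rep(0L, mol$n_atoms)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      bond_sum[mol$bonds$a[k]] <- bond_sum[mol$bonds$a[k]] + o
      bond_sum[mol$bonds$b[k]] <- bond_sum[mol$bonds$b[k]] + o
    }
  }
  val <- DEFAULT_VALENCE[mol$elements] + ifelse(mol$elements %in% c("N", "P"),
                                                pmax(mol$charges, 0),
                                                -abs(mol$charges))
  pmax(0L, as.integer(val - bond_sum))
}

mol_ring_atoms <- function(mol) {
  inring <- rep(FALSE, mol$n_atoms)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::make_graph(t(as.matrix(mol$bonds[, c("a", "b")])),
                            n = mol$n_atoms, directed = FALSE)
    bridge <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(bridge))
    if (length(ring_edges) > 0) {
      inring[unique(c(mol$bonds$a[ring_edges], mol$bonds$b[ring_edges]))] <- TRUE
    }
  }
  inring
}

# deterministic integer hash of an integer vector (mod 2^31 - 1)
hash_ints <- function(v) {
  p <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% p) + 1) %% p
  as.integer(h)
}

#' ECFP (Morgan) circular fingerprint
#'
#' Radius-2 extended-connectivity fingerprint folded to `n_bits` bit
#' positions. The initial atom invariant is (element, heavy degree, attached
#' hydrogen count, formal charge, ring membership); neighborhoods are then
#' iteratively hashed over (bond order, neighbor identifier) lists in sorted
#' order, so the result is independent of atom input order and deterministic
#' across runs.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius (default 2, i.e. ECFP4).
#' @param n_bits folding width (default 2048).
#' @return Object of class `ecfp_fingerprint` with sorted `bits`.
#' @export
fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  mol <- parse_smiles(smiles)
  deg <- mol_degree(mol)
  nh <- mol_h_count(mol)
  ring <- mol_ring_atoms(mol)
  ids <- vapply(seq_len(mol$n_atoms), function(i) {
    hash_ints(c(ELEMENT_NUMBERS[[mol$elements[i]]], deg[i], nh[i],
                mol$charges[i] + 16L, as.integer(ring[i])))
  }, integer(1))
  nbrs <- vector("list", mol$n_atoms)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
  }
  all_ids <- ids
  for (it in seq_len(radius)) {
    new_ids <- vapply(seq_len(mol$n_atoms), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb)) return(hash_ints(c(it, ids[i])))
      env <- cbind(nb[, 2], ids[nb[, 1]])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      hash_ints(c(it, ids[i], as.integer(t(env))))
    }, integer(1))
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }
  structure(list(bits = sort(unique(all_ids %% as.integer(n_bits))),
                 radius = radius, n_bits = n_bits),
            class = "ecfp_fingerprint")
}

#' @export
print.ecfp_fingerprint <- function(x, ...) {
  cat("<ecfp_fingerprint> radius", x$radius, ",", length(x$bits), "of",
      x$n_bits, "bits set\n")
  invisible(x)
}

#' Dice similarity coefficient between fingerprints
#'
#' DSC = 2 |A intersect B| / (|A| + |B|). Two empty fingerprints give 0 with
#' a warning.
#'
#' @param a,b `ecfp_fingerprint` with identical `n_bits`.
#' @return Similarity in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits")
  na <- length(a$bits); nb <- length(b$bits)
  if (na + nb == 0) {
    warning("both fingerprints empty; Dice defined as 0")
    return(0)
  }
  2 * length(intersect(a$bits, b$bits)) / (na + nb)
}

record_fingerprints <- function(record, radius = 2, n_bits = 2048) {
  prods <- record$products
  prods <- prods[prods$valid, , drop = FALSE]
  fps <- list()
  for (k in seq_len(nrow(prods))) {
    fp <- tryCatch(fingerprint(prods$smiles[k], radius, n_bits),
                   error = function(e) NULL)
    if (!is.null(fp)) fps[[length(fps) + 1L]] <- fp
  }
  fps
}

#' Product similarity between two enzymes
#'
#' Mean Dice similarity over the full cross-product of the two enzymes'
#' product fingerprints (multi-product averaging); single-product pairs
#' reduce to one Dice value.
#'
#' @param a,b `enzyme_record` with at least one parseable product each.
#' @param radius,n_bits fingerprint parameters.
#' @return Mean Dice similarity in \[0, 1\].
#' @export
product_similarity <- function(a, b, radius = 2, n_bits = 2048) {
  fa <- record_fingerprints(a, radius, n_bits)
  fb <- record_fingerprints(b, radius, n_bits)
  bad <- c(if (length(fa) == 0) a$accession, if (length(fb) == 0) b$accession)
  if (length(bad) > 0)
    stop("no valid products for: ", paste(bad, collapse = ", "))
  vals <- numeric(0)
  for (x in fa) for (y in fb) vals <- c(vals, dice(x, y))
  mean(vals)
}

#' Product Dice similarity matrix over a cohort
#'
#' Symmetric matrix of [product_similarity()]. The diagonal is computed like
#' any pair (self cross-product over the enzyme's own products), so
#' multi-product enzymes with dissimilar products can have self-similarity
#' below 1; correlation analyses exclude the diagonal.
#'
#' @param records list of `enzyme_record` with valid products.
#' @param radius,n_bits fingerprint parameters.
#' @return `similarity_matrix` of kind `product_dsc`.
#' @export
product_similarity_matrix <- function(records, radius = 2, n_bits = 2048) {
  ids <- vapply(records, function(r) r$accession, character(1))
  fps <- lapply(records, record_fingerprints, radius = radius, n_bits = n_bits)
  bad <- ids[vapply(fps, length, integer(1)) == 0]
  if (length(bad) > 0)
    stop("no valid products for: ", paste(bad, collapse = ", "))
  n <- length(records)
  vals <- matrix(NA_real_, n, n)
  pairmean <- function(fa, fb) {
    v <- numeric(0)
    for (x in fa) for (y in fb) v <- c(v, dice(x, y))
    mean(v)
  }
  for (i in seq_len(n)) {
    vals[i, i] <- pairmean(fps[[i]], fps[[i]])
    if (i < n) for (j in (i + 1):n) {
      vals[i, j] <- vals[j, i] <- pairmean(fps[[i]], fps[[j]])
    }
  }
  new_similarity_matrix(ids, vals, "product_dsc", 1)
}

skeleton_graph <- function(smiles) {
  mol <- parse_smiles(smiles)
  carbons <- which(mol$elements == "C")
  if (length(carbons) == 0) stop("no carbon atoms in ", smiles)
  remap <- match(seq_len(mol$n_atoms), carbons)
  keep <- mol$bonds$a %in% carbons & mol$bonds$b %in% carbons
  edges <- cbind(remap[mol$bonds$a[keep]], remap[mol$bonds$b[keep]])
  g <- igraph::make_graph(t(edges), n = length(carbons), directed = FALSE)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  igraph::induced_subgraph(g, which(comp$membership == biggest))
}

#' Reduce a product to its canonical carbon skeleton
#'
#' Deletes all heteroatoms (and their bonds), sets every remaining bond to
#' single order, drops stereochemistry, keeps the largest connected carbon
#' component, and returns a canonical string form of that graph (BLISS
#' canonical labeling). Two products share a skeleton class iff their
#' skeletonize outputs are equal.
#'
#' @param smiles SMILES string of a molecule with at least one carbon.
#' @return Canonical skeleton key, e.g. `"C6:1-2,1-6,2-3,..."`.
#' @export
skeletonize <- function(smiles) {
  g <- skeleton_graph(smiles)
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("C", igraph::vcount(gc), ":",
         paste(paste(el[, 1], el[, 2], sep = "-"), collapse = ","))
}

#' SMILES representative of a molecule's carbon skeleton
#'
#' Writes a (saturated, all-carbon) SMILES for the skeleton graph returned by
#' [skeletonize()]; `skeletonize(skeleton_smiles(x)) == skeletonize(x)`.
#'
#' @param smiles SMILES string.
#' @return SMILES of the skeleton.
#' @export
skeleton_smiles <- function(smiles) {
  g <- skeleton_graph(smiles)
  n <- igraph::vcount(g)
  if (n == 1) return("C")
  adj <- igraph::as_adj_list(g)
  visited <- rep(FALSE, n)
  ring_closures <- vector("list", n) # digits to emit at each atom
  tree_children <- vector("list", n)
  closure_id <- 0L
  seen_edge <- new.env()
  order_dfs <- integer(0)
  parent <- rep(NA_integer_, n)
  stack <- 1L
  visited[1] <- TRUE
  # iterative DFS building spanning tree + ring closure bonds
  dfs <- function(v) {
    order_dfs <<- c(order_dfs, v)
    for (w in as.integer(adj[[v]])) {
      ek <- paste(sort(c(v, w)), collapse = "-")
      if (!is.null(seen_edge[[ek]])) next
      seen_edge[[ek]] <- TRUE
      if (!visited[w]) {
        visited[w] <<- TRUE
        parent[w] <<- v
        tree_children[[v]] <<- c(tree_children[[v]], w)
        dfs(w)
      } else {
        closure_id <<- closure_id + 1L
        ring_closures[[v]] <<- c(ring_closures[[v]], closure_id)
        ring_closures[[w]] <<- c(ring_closures[[w]], closure_id)
      }
    }
  }
  dfs(1L)
  digit <- function(k) if (k < 10) as.character(k) else paste0("%", k)
  emit <- function(v) {
    s <- paste0("C", paste(vapply(ring_closures[[v]], digit, character(1)),
                           collapse = ""))
    kids <- tree_children[[v]]
    if (length(kids) > 0) {
      sub <- vapply(kids, emit, character(1))
      s <- paste0(s, paste(vapply(seq_along(sub), function(i)
        if (i < length(sub)) paste0("(", sub[i], ")") else sub[i],
        character(1)), collapse = ""))
    }
    s
  }
  emit(1L)
}

#' Skeleton class table for a cohort's products
#'
#' Annotation-table skeleton labels take precedence; [skeletonize()] is the
#' fallback for unlabeled products.
#'
#' @param records list of `enzyme_record`.
#' @return Data frame (accession, product, smiles, skeleton).
#' @export
skeleton_table <- function(records) {
  rows <- lapply(records, function(r) {
    p <- r$products
    if (nrow(p) == 0) return(NULL)
    skel <- p$skeleton
    for (k in seq_len(nrow(p))) {
      if ((is.na(skel[k]) || skel[k] == "unassigned") && p$valid[k]) {
        skel[k] <- tryCatch(skeletonize(p$smiles[k]), error = function(e) "unassigned")
      }
    }
    data.frame(accession = r$accession, product = p$name, smiles = p$smiles,
               skeleton = skel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
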