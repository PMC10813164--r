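# GAAC physicochemical groups: a partition of the 20 standard letters
GAAC_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

#' Amino-acid and grouped amino-acid composition
#'
#' AAC: frequency of each of the 20 standard residues; GAAC: frequencies over
#' the five physicochemical groups (aliphatic, aromatic, positive, negative,
#' uncharged). X letters are skipped (their count is reported).
#'
#' @param x sequence string or character vector of 1-letter codes.
#' @return List with `aac` (20-vector), `gaac` (5-vector), `n` residues
#'   counted, `n_skipped` X residues, `empty` flag. Both vectors sum to 1
#'   unless empty (all zero).
#' @export
composition <- function(x) {
  letters_in <- if (length(x) == 1 && nchar(x[1]) > 1) strsplit(x, "")[[1]] else x
  letters_in <- toupper(letters_in)
  n_skipped <- sum(letters_in == "X")
  letters_in <- letters_in[letters_in %in% AA_LETTERS]
  aac <- setNames(numeric(20), sort(AA_LETTERS))
  gaac <- setNames(numeric(5), names(GAAC_GROUPS))
  if (length(letters_in) > 0) {
    tab <- table(factor(letters_in, levels = sort(AA_LETTERS)))
    aac[] <- as.numeric(tab) / length(letters_in)
    for (g in names(GAAC_GROUPS)) gaac[g] <- sum(aac[GAAC_GROUPS[[g]]])
  }
  list(aac = aac, gaac = gaac, n = length(letters_in),
       n_skipped = n_skipped, empty = length(letters_in) == 0)
}

#' Residue preferential values of a substrate shell
#'
#' Per-letter ratio of the residue frequency in the shell to its frequency in
#' the full sequence. Letters absent from the full sequence get an undefined
#' flag instead of a division.
#'
#' @param shell_letters shell residues (string or character vector).
#' @param full_sequence full sequence (non-empty).
#' @return List with `ratio` (20-vector, 0 where the shell lacks the letter),
#'   `undefined` (logical 20-vector: shell letter unseen in full sequence).
#' @export
preference <- function(shell_letters, full_sequence) {
  if (!nzchar(paste(full_sequence, collapse = ""))) stop("empty full sequence")
  shell <- composition(shell_letters)
  full <- composition(full_sequence)
  undefined <- full$aac == 0 & shell$aac > 0
  ratio <- ifelse(full$aac > 0, shell$aac / full$aac, 0)
  ratio[undefined] <- NA_real_
  list(ratio = ratio, undefined = undefined)
}

#' Condense a similarity matrix to its upper-triangle pair vector
#'
#' Values for unordered pairs (i < j in the shared id order), diagonal
#' excluded. Missing (NA) entries are dropped, with their pair indices
#' reported in the `masked` attribute.
#'
#' @param m `similarity_matrix`.
#' @param id_subset optional ids to restrict (and order) the pair universe.
#' @return Numeric vector with attributes `pairs` (2-column id matrix) and
#'   `masked`.
#' @export
condense <- function(m, id_subset = NULL) {
  ids <- m$ids
  if (!is.null(id_subset)) {
    if (!all(id_subset %in% ids))
      stop("ids not in matrix: ",
           paste(setdiff(id_subset, ids), collapse = ", "))
    ids <- id_subset
  }
  sel <- match(ids, m$ids)
  vals <- m$values[sel, sel, drop = FALSE]
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  v <- vals[ut]
  pairs <- cbind(ids[ut[, 1]], ids[ut[, 2]])
  masked <- which(is.na(v))
  keep <- !is.na(v)
  if (sum(keep) < 3) stop("fewer than 3 surviving pairs")
  out <- v[keep]
  attr(out, "pairs") <- pairs[keep, , drop = FALSE]
  attr(out, "masked") <- pairs[masked, , drop = FALSE]
  out
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment r; two-sided p from t = r sqrt((n-2)/(1-r^2)) with n-2
#' degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, nonzero variance.
#' @return List (r, p, n).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate factor (zero variance)")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cross-factor Pearson correlation report
#'
#' For every pair of similarity factors (sequence regions, TM matrices,
#' product Dice), correlates their values over the shared unordered enzyme
#' pairs (diagonal excluded, listwise deletion of pairs missing in either
#' factor).
#'
#' @param factors named list of `similarity_matrix`.
#' @param bh apply Benjamini-Hochberg correction across the factor pairs
#'   (default FALSE, mirroring an uncorrected report).
#' @return Data frame of class `correlation_report`: factor_a, factor_b, r,
#'   p (and p_adj when `bh`), n.
#' @export
correlation_report <- function(factors, bh = FALSE) {
  if (length(factors) < 2) stop("need >= 2 factors")
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    names(factors) <- vapply(factors, function(f) f$kind, character(1))
  shared <- Reduce(intersect, lapply(factors, function(f) f$ids))
  if (length(shared) < 3) stop("fewer than 3 shared enzymes across factors")
  combos <- combn(names(factors), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    fa <- combos[1, k]; fb <- combos[2, k]
    va <- condense(factors[[fa]], shared)
    vb <- condense(factors[[fb]], shared)
    key <- function(p) paste(p[, 1], p[, 2], sep = "~")
    common <- intersect(key(attr(va, "pairs")), key(attr(vb, "pairs")))
    if (length(common) < 3)
      stop("fewer than 3 shared pairs for factors ", fa, " / ", fb)
    xa <- va[match(common, key(attr(va, "pairs")))]
    xb <- vb[match(common, key(attr(vb, "pairs")))]
    pr <- tryCatch(pearson(xa, xb), error = function(e)
      stop("correlation failed for factors ", fa, " / ", fb, ": ",
           conditionMessage(e)))
    data.frame(factor_a = fa, factor_b = fb, r = pr$r, p = pr$p, n = pr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("correlation_report", class(out))
  out
}

#' @importFrom stats p.adjust
NULL

five_number <- function(v) {
  q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

mann_whitney_u <- function(x, y) {
  # U for x relative to y, with midranks for ties
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Compare same-group versus different-group similarity values
#'
#' Two-sided Mann-Whitney U test: exact permutation p (full enumeration of
#' group assignments, valid under ties) for combined n <= 20, normal
#' approximation with tie correction otherwise. Also returns five-number
#' summaries of both groups.
#'
#' @param values_same,values_different numeric vectors, each with >= 3
#'   values.
#' @param exact_limit combined size up to which enumeration is used (20).
#' @return List (U, p, method, summary_same, summary_different).
#' @export
group_compare <- function(values_same, values_different, exact_limit = 20) {
  if (length(values_same) < 3 || length(values_different) < 3)
    stop("each group needs >= 3 values")
  n1 <- length(values_same)
  n2 <- length(values_different)
  u <- mann_whitney_u(values_same, values_different)
  if (n1 + n2 <= exact_limit) {
    pooled <- c(values_same, values_different)
    r <- rank(pooled)
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(wilcox.test(values_same, values_different,
                                       exact = FALSE, correct = FALSE))
    p <- wt$p.value
    method <- "normal approximation (tie-corrected)"
  }
  list(U = u, p = p, method = method,
       summary_same = five_number(values_same),
       summary_different = five_number(values_different))
}

#' @importFrom stats wilcox.test dist
NULL

record_key_set <- function(record, key) {
  if (key == "substrate") {
    s <- record$substrate
    if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
    return(unique(s))
  }
  sk <- record$products$skeleton
  sk <- unique(sk[!is.na(sk) & sk != "unassigned"])
  if (length(sk) == 0) return(NULL)
  sk
}

#' Partition enzyme pairs into same-key and different-key sets
#'
#' Unordered pairs are "same" iff the two enzymes' key sets intersect (any
#' shared substrate, or any shared product skeleton label). Records without
#' the key are excluded with a warning.
#'
#' @param records list of `enzyme_record`.
#' @param key `"substrate"` or `"product_skeleton"`.
#' @return List with `same` and `different`, each a 2-column accession
#'   matrix.
#' @export
pair_partition <- function(records, key = c("substrate", "product_skeleton")) {
  key <- match.arg(key)
  sets <- lapply(records, record_key_set, key = key)
  ids <- vapply(records, function(r) r$accession, character(1))
  missing <- ids[vapply(sets, is.null, logical(1))]
  if (length(missing) > 0)
    warning("excluded records without ", key, ": ",
            paste(missing, collapse = ", "))
  keep <- !vapply(sets, is.null, logical(1))
  ids <- ids[keep]
  sets <- sets[keep]
  same <- NULL
  different <- NULL
  n <- length(ids)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      row <- c(ids[i], ids[j])
      if (length(intersect(sets[[i]], sets[[j]])) > 0)
        same <- rbind(same, row)
      else different <- rbind(different, row)
    }
  }
  fix <- function(m) {
    if (is.null(m)) m <- matrix(character(), ncol = 2)
    dimnames(m) <- list(NULL, c("a", "b"))
    m
  }
  list(same = fix(same), different = fix(different))
}

#' Similarity values of a pair partition
#'
#' Looks up a similarity matrix at the same/different pairs from
#' [pair_partition()].
#'
#' @param m `similarity_matrix`.
#' @param partition result of [pair_partition()].
#' @return List with numeric `same` and `different` (NA entries dropped).
#' @export
partition_values <- function(m, partition) {
  pick <- function(pairs) {
    keep <- pairs[, 1] %in% m$ids & pairs[, 2] %in% m$ids
    pairs <- pairs[keep, , drop = FALSE]
    v <- m$values[cbind(match(pairs[, 1], m$ids), match(pairs[, 2], m$ids))]
    v[!is.na(v)]
  }
  list(same = pick(partition$same), different = pick(partition$different))
}

#' Composition and preference tables for a cohort of shells
#'
#' @param shells named list of `residue_shell` (accession -> shell).
#' @param records list of `enzyme_record` supplying full sequences.
#' @return Data frame keyed by accession and radius with per-letter shell
#'   frequencies and preferential values.
#' @export
preference_table <- function(shells, records) {
  recs <- setNames(records, vapply(records, function(r) r$accession,
                                   character(1)))
  rows <- lapply(names(shells), function(acc) {
    sh <- shells[[acc]]
    if (is.null(recs[[acc]])) return(NULL)
    letters_sh <- strsplit(shell_sequence(sh), "")[[1]]
    pr <- preference(letters_sh, recs[[acc]]$sequence)
    comp <- composition(letters_sh)
    df <- data.frame(accession = acc, radius_A = sh$radius_A,
                     letter = names(comp$aac),
                     shell_frequency = as.numeric(comp$aac),
                     preference = as.numeric(pr$ratio),
                     undefined = pr$undefined, stringsAsFactors = FALSE)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
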