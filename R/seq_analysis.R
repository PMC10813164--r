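# Signature motifs of the two diterpene-synthase mechanistic classes, as
# regular expressions over the 1-letter alphabet. X positions are wildcards;
# NSE/DTE is the permissive triad pattern spanning both spellings.
SIGNATURE_MOTIFS <- c(
  DDXXD  = "DD..D",
  DXDD   = "D.DD",
  NSE_DTE = "[ND]D..[ST].[ED]",
  LHS    = "LHS",
  PNV    = "PNV",
  PIX    = "PI.",
  FEHXW  = "FEH.W",
  FERLW  = "FERLW"
)

#' Scan a sequence for class I/II signature motifs
#'
#' Finds all non-overlapping matches of the diterpene-synthase signature
#' motifs: DDXXD and NSE/DTE (class I, alpha domain), DXDD (class II,
#' beta-gamma interface), and the CPS-associated LHS, PNV, PIX, FEHXW and
#' FERLW patterns.
#'
#' @param sequence uppercase amino-acid string.
#' @param motifs subset of motif names to scan (default all).
#' @return Data frame with columns `motif`, `start` (1-based), `text`,
#'   sorted by start position.
#' @export
scan_signature_motifs <- function(sequence, motifs = names(SIGNATURE_MOTIFS)) {
  empty <- data.frame(motif = character(), start = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (is.na(sequence) || !nzchar(sequence)) return(empty)
  sequence <- toupper(sequence)
  out <- lapply(motifs, function(m) {
    hits <- gregexpr(SIGNATURE_MOTIFS[[m]], sequence)[[1]]
    if (hits[1] == -1) return(NULL)
    len <- attr(hits, "match.length")
    data.frame(motif = m, start = as.integer(hits),
               text = substring(sequence, hits, hits + len - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the mechanistic class from signature motifs
#'
#' Class I enzymes carry the ionization motif DDXXD (or the NSE/DTE triad)
#' and lack DXDD; class II carry the protonation motif DXDD and lack DDXXD;
#' bifunctional I/II enzymes carry both DDXXD and DXDD.
#'
#' @param sequence amino-acid string.
#' @return `"I"`, `"II"`, `"I_II"`, or `"unknown"`.
#' @export
classify_class <- function(sequence) {
  if (is.na(sequence) || !nzchar(sequence)) return("unknown")
  hits <- scan_signature_motifs(sequence, c("DDXXD", "DXDD", "NSE_DTE"))
  has_ddxxd <- any(hits$motif == "DDXXD")
  has_nse <- any(hits$motif == "NSE_DTE")
  has_dxdd <- any(hits$motif == "DXDD")
  if ((has_ddxxd || has_nse) && !has_dxdd) return("I")
  if (has_dxdd && !has_ddxxd) return("II")
  if (has_ddxxd && has_dxdd) return("I_II")
  "unknown"
}

#' Split a sequence into N- and C-terminal domains
#'
#' Provided domain ranges take precedence. Without ranges, the boundary is
#' anchored on the signature motifs: the midpoint between the position just
#' after the last class II anchor (DXDD or LHS) and the start of the first
#' class I anchor (DDXXD or NSE/DTE); N = \[1, boundary\], C = (boundary, len\].
#'
#' @param record `enzyme_record`.
#' @return List with character elements `N` and `C`.
#' @export
split_domains <- function(record) {
  seq <- record$sequence
  len <- nchar(seq)
  rng <- record$domain_ranges
  if (!is.null(rng) && !is.null(rng$N) && !is.null(rng$C)) {
    return(list(N = substr(seq, rng$N[1], rng$N[2]),
                C = substr(seq, rng$C[1], rng$C[2])))
  }
  hits <- scan_signature_motifs(seq, c("DXDD", "LHS", "DDXXD", "NSE_DTE"))
  anchors_II <- hits[hits$motif %in% c("DXDD", "LHS"), , drop = FALSE]
  anchors_I <- hits[hits$motif %in% c("DDXXD", "NSE_DTE"), , drop = FALSE]
  if (nrow(anchors_II) == 0 || nrow(anchors_I) == 0)
    stop("cannot split ", record$accession,
         ": no domain ranges and signature anchors not found")
  end_II <- max(anchors_II$start + nchar(anchors_II$text) - 1L)
  start_I <- min(anchors_I$start)
  if (end_II >= start_I)
    stop("cannot split ", record$accession, ": anchors overlap")
  boundary <- (end_II + 1L + start_I) %/% 2L
  list(N = substr(seq, 1L, boundary), C = substr(seq, boundary + 1L, len))
}

#' Percent identity from global pairwise alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gaps (open 10,
#' extend 0.5). Identity is 100 x identical aligned columns divided by the
#' alignment length including internal gaps; terminal gap columns are
#' excluded from the denominator.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  identity_from_aligned(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln)))
}

# identity over aligned strings, terminal gap columns excluded from the
# denominator, internal gaps included
identity_from_aligned <- function(pa, sa) {
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(sa, "")[[1]]
  gap <- a == "-" | b == "-"
  non_gap <- which(!gap)
  if (length(non_gap) == 0) return(0)
  keep <- seq(min(non_gap), max(non_gap))
  # terminal gap columns are those before the first / after the last column
  # where both sequences have residues
  both <- which(a != "-" & b != "-")
  if (length(both) == 0) return(0)
  keep <- seq(min(both), max(both))
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / length(keep)
}

new_similarity_matrix <- function(ids, values, kind,
                                  scale_max = if (startsWith(kind, "seq")) 100 else 1) {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind, scale_max = scale_max),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix>", x$kind, ":", length(x$ids), "ids, scale [0,",
      x$scale_max, "]\n")
  invisible(x)
}

#' Pairwise sequence identity matrix over a cohort
#'
#' @param records list of `enzyme_record`.
#' @param region `"N"`, `"C"`, `"NC"` (concatenated N+C) or `"full"`.
#' @return `similarity_matrix` (kind `seq_<region>`, percent scale).
#' @export
similarity_matrix <- function(records, region = c("full", "N", "C", "NC")) {
  region <- match.arg(region)
  ids <- vapply(records, function(r) r$accession, character(1))
  seqs <- if (region == "full") {
    vapply(records, function(r) r$sequence, character(1))
  } else {
    failed <- character()
    out <- vapply(records, function(r) {
      sp <- tryCatch(split_domains(r), error = function(e) NULL)
      if (is.null(sp)) { failed <<- c(failed, r$accession); return(NA_character_) }
      switch(region, N = sp$N, C = sp$C, NC = paste0(sp$N, sp$C))
    }, character(1))
    if (length(failed) > 0)
      stop("cannot compute ", region, "-region matrix; split_domains failed for: ",
           paste(failed, collapse = ", "))
    out
  }
  n <- length(seqs)
  vals <- diag(100, n)
  if (n > 1) {
    for (j in 2:n) {
      # one vectorized alignment call per subject column
      pats <- Biostrings::AAStringSet(seqs[1:(j - 1)])
      aln <- Biostrings::pairwiseAlignment(
        pats, Biostrings::AAString(seqs[j]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
        type = "global")
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
      for (i in 1:(j - 1)) {
        v <- identity_from_aligned(pa[i], sa[i])
        vals[i, j] <- v
        vals[j, i] <- v
      }
    }
  }
  new_similarity_matrix(ids, vals, paste0("seq_", region), 100)
}

#' Karlin-Altschul E-value for a gapped local alignment score
#'
#' E = K m n exp(-lambda S) with the standard gapped BLOSUM62 constants.
#'
#' @param score raw alignment score.
#' @param m,n sequence lengths (search space = m x n).
#' @param lambda,K Karlin-Altschul parameters (gapped BLOSUM62 defaults).
#' @return E-value.
#' @export
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Build a sequence similarity network
#'
#' Nodes are all enzymes (isolated nodes retained); an edge joins a pair iff
#' it passes the threshold: minimum percent identity in `"identity"` mode, or
#' maximum E-value in `"evalue"` mode (for a matrix of Karlin-Altschul
#' E-values).
#'
#' @param matrix `similarity_matrix` (identity mode) or square E-value matrix.
#' @param threshold cutoff on the matrix scale.
#' @param mode `"identity"` or `"evalue"`.
#' @param records optional list of `enzyme_record` supplying node attributes
#'   (class, skeletons).
#' @return List of class `ssn_graph` with elements `graph` (igraph),
#'   `threshold`, `mode`.
#' @export
build_ssn <- function(matrix, threshold, mode = c("identity", "evalue"),
                      records = NULL) {
  mode <- match.arg(mode)
  if (inherits(matrix, "similarity_matrix")) {
    ids <- matrix$ids
    vals <- matrix$values
    if (mode == "identity" && (threshold < 0 || threshold > matrix$scale_max))
      stop("threshold ", threshold, " outside the matrix scale [0, ",
           matrix$scale_max, "]")
  } else {
    vals <- as.matrix(matrix)
    ids <- rownames(vals)
    if (mode == "evalue" && threshold < 0) stop("E-value threshold must be >= 0")
  }
  n <- length(ids)
  edges <- NULL
  if (n > 1) {
    idx <- which(upper.tri(vals), arr.ind = TRUE)
    pass <- if (mode == "identity") vals[idx] >= threshold else vals[idx] <= threshold
    idx <- idx[pass, , drop = FALSE]
    edges <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                        score = vals[idx], stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(records)) {
    recs <- records[match(ids, vapply(records, function(r) r$accession, character(1)))]
    igraph::V(g)$class <- vapply(recs, function(r) r$class_label, character(1))
    igraph::V(g)$skeletons <- vapply(recs, function(r)
      paste(unique(r$products$skeleton), collapse = ";"), character(1))
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    igraph::E(g)$score <- edges$score
  }
  structure(list(graph = g, threshold = threshold, mode = mode),
            class = "ssn_graph")
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat("<ssn_graph>", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges, threshold", x$threshold,
      paste0("(", x$mode, ")\n"))
  invisible(x)
}

#' Export an SSN as edge-list TSV and GraphML
#' @param ssn `ssn_graph`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.graphml`.
#' @export
write_ssn <- function(ssn, prefix) {
  el <- igraph::as_data_frame(ssn$graph, what = "edges")
  names(el)[1:2] <- c("a", "b")
  write.table(el, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(ssn$graph, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}

#' Export motif hits for a cohort as a table
#' @param records list of `enzyme_record`.
#' @return Data frame (accession, motif, start, text).
#' @export
motif_hit_table <- function(records) {
  out <- lapply(records, function(r) {
    h <- scan_signature_motifs(r$sequence)
    if (nrow(h) == 0) return(NULL)
    cbind(accession = r$accession, h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(accession = character(), motif = character(),
                      start = integer(), text = character())
  rownames(out) <- NULL
  out
}
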