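# Independent Gotoh (affine-gap) global alignment oracle over BLOSUM62, used
# to pin pairwise_identity: computes the optimal score and the identity range
# over all co-optimal alignments (terminal gap columns excluded from the
# denominator, as in the implementation's stated contract).
data(BLOSUM62, package = "Biostrings", envir = environment())

gotoh_oracle <- function(a, b, open = 10, ext = 0.5, max_paths = 20000) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- BLOSUM62[av[i - 1], bv[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # enumerate co-optimal alignments, tracking identity of each
  ids <- c()
  n_paths <- 0
  walk <- function(i, j, state, cols) {
    if (n_paths > max_paths) return()
    if (i == 0 && j == 0) {
      n_paths <<- n_paths + 1
      both <- which(cols[1, ] != "-" & cols[2, ] != "-")
      keep <- seq(min(both), max(both))
      ids <<- c(ids, 100 * sum(cols[1, keep] == cols[2, keep] &
                                 cols[1, keep] != "-") / length(keep))
      return()
    }
    eps <- 1e-9
    if (state == "M") {
      if (i == 0 || j == 0) return()
      s <- BLOSUM62[av[i], bv[j]]
      val <- M[i + 1, j + 1]
      col <- cbind(c(av[i], bv[j]), cols)
      if (i == 1 && j == 1 && abs(val - s) < eps) walk(0, 0, "done0", col)
      for (st in c("M", "X", "Y")) {
        prev <- switch(st, M = M[i, j], X = X[i, j], Y = Y[i, j])
        if (abs(val - (prev + s)) < eps && prev > NEG / 2)
          walk(i - 1, j - 1, st, col)
      }
    } else if (state == "X") {
      val <- X[i + 1, j + 1]
      col <- cbind(c(av[i], "-"), cols)
      if (j == 0) {
        if (i >= 1) walk(i - 1, j, if (i == 1) "done0" else "X", col)
        return()
      }
      if (abs(val - (M[i, j + 1] - open - ext)) < eps && M[i, j + 1] > NEG / 2)
        walk(i - 1, j, "M", col)
      if (abs(val - (X[i, j + 1] - ext)) < eps && X[i, j + 1] > NEG / 2)
        walk(i - 1, j, "X", col)
    } else if (state == "Y") {
      val <- Y[i + 1, j + 1]
      col <- cbind(c("-", bv[j]), cols)
      if (i == 0) {
        if (j >= 1) walk(i, j - 1, if (j == 1) "done0" else "Y", col)
        return()
      }
      if (abs(val - (M[i + 1, j] - open - ext)) < eps && M[i + 1, j] > NEG / 2)
        walk(i, j - 1, "M", col)
      if (abs(val - (Y[i + 1, j] - ext)) < eps && Y[i + 1, j] > NEG / 2)
        walk(i, j - 1, "Y", col)
    } else {
      # done0: consumed everything via initial boundary
      if (i == 0 && j == 0) walk(0, 0, "M", cols)
    }
  }
  eps <- 1e-9
  cols0 <- matrix(character(0), 2, 0)
  if (abs(best - M[n + 1, m + 1]) < eps) walk(n, m, "M", cols0)
  if (abs(best - X[n + 1, m + 1]) < eps) walk(n, m, "X", cols0)
  if (abs(best - Y[n + 1, m + 1]) < eps) walk(n, m, "Y", cols0)
  list(score = best, id_min = min(ids), id_max = max(ids))
}


# Exhaustive monotone-correspondence oracle for the TM aligner: enumerate
# every strictly increasing pairing (>= 3 pairs), superpose by Kabsch with
# iterative d0 trimming, and keep the best TM.
oracle_tm <- function(A, B, L_norm, min_pairs = 3) {
  d0 <- tm_d0(L_norm)
  la <- nrow(A); lb <- nrow(B)
  best <- 0
  pairings <- list()
  grow <- function(i, j, cur) {
    if (length(cur) >= min_pairs) pairings[[length(pairings) + 1L]] <<- cur
    if (i > la || j > lb) return()
    for (ii in i:la) for (jj in j:lb) {
      grow(ii + 1, jj + 1, c(cur, list(c(ii, jj))))
    }
  }
  grow(1, 1, list())
  for (p in pairings) {
    idx <- do.call(rbind, p)
    if (nrow(idx) < 3) next
    pa <- A[idx[, 1], , drop = FALSE]
    pb <- B[idx[, 2], , drop = FALSE]
    fit <- tryCatch(kabsch(pa, pb), error = function(e) NULL)
    if (is.null(fit)) next
    for (it in 1:10) {
      d <- sqrt(rowSums((fit$transform(pa) - pb)^2))
      tm <- sum(1 / (1 + (d / d0)^2)) / L_norm
      best <- max(best, tm)
      sel <- which(d < d0)
      if (length(sel) < 3) break
      fit2 <- tryCatch(kabsch(pa[sel, , drop = FALSE],
                              pb[sel, , drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(fit2)) break
      fit <- fit2
    }
  }
  best
}


# Brute-force motif search oracle: every injective ordered residue tuple,
# filtered by letter policy, template distance compatibility, and RMSD.
brute_search <- function(motif, query, policy) {
  q <- ditps3d:::shell_residue_data(query)
  np <- nrow(motif$positions)
  nq <- length(q$keys)
  budget <- if (policy == "relaxed") 1L else 0L
  allowed <- lapply(seq_len(np), function(p)
    unique(c(motif$positions$consensus[p], motif$alternatives[[p]])))
  Dq <- as.matrix(dist(q$ca))
  out <- list()
  tuples <- utils::combn(nq, np, simplify = FALSE)
  for (cmb in tuples) {
    for (perm in ditps3d_perms(np)) {
      tup <- cmb[perm]
      mism <- sum(!vapply(seq_len(np), function(p)
        q$letters[tup[p]] %in% allowed[[p]], logical(1)))
      if (mism > budget) next
      ok <- TRUE
      for (p1 in 1:(np - 1)) for (p2 in (p1 + 1):np) {
        if (abs(Dq[tup[p1], tup[p2]] - motif$template_distances[p1, p2]) >
            motif$tol_distance_A) { ok <- FALSE; break }
      }
      if (!ok) next
      fit <- tryCatch(kabsch(q$ca[tup, , drop = FALSE], motif$template_ca),
                      error = function(e) NULL)
      if (is.null(fit) || fit$rmsd_A > motif$tol_rmsd_A) next
      out[[length(out) + 1L]] <- list(tuple = tup, rmsd = fit$rmsd_A,
                                      mismatches = mism)
    }
  }
  out
}

ditps3d_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(ditps3d_perms(n - 1), function(p) c(i, p + (p >= i)))
  }))
}


fp_of_bits <- function(bits, n_bits = 2048) {
  structure(list(bits = sort(as.integer(bits)), radius = 2, n_bits = n_bits),
            class = "ecfp_fingerprint")
}

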