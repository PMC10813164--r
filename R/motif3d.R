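shell_residue_data <- function(x) {
  res <- residue_table(x)
  ca <- ca_coords(x)
  keys <- paste(res$chain, res$resno, sep = "|")
  if (!all(keys %in% rownames(ca)))
    stop("residue(s) without Calpha in ", x$structure_id)
  list(id = x$structure_id, keys = keys, letters = res$letter,
       ca = unname(ca[keys, , drop = FALSE]))
}

# Greedy agreement between two sorted distance-descriptor vectors: fraction of
# entries matched within tol, walking both vectors in order.
descriptor_agreement <- function(u, v, tol) {
  p <- 1L; q <- 1L; hits <- 0L
  nu <- length(u); nv <- length(v)
  while (p <= nu && q <= nv) {
    if (abs(u[p] - v[q]) <= tol) {
      hits <- hits + 1L; p <- p + 1L; q <- q + 1L
    } else if (u[p] < v[q]) p <- p + 1L else q <- q + 1L
  }
  hits / max(nu, nv)
}

# Returns the capped pair score matrix (reported as agreement) and the
# uncapped assignment weights. In dense shells the descriptor fraction
# saturates at 1 for many residue pairs, so the assignment objective must see
# the residue-identity bonus uncapped or letters stop breaking ties.
site_score_matrix <- function(ref, site, tol, bonus) {
  Dr <- as.matrix(dist(ref$ca))
  Ds <- as.matrix(dist(site$ca))
  nr <- length(ref$keys); ns <- length(site$keys)
  S <- matrix(0, nr, ns)
  W <- matrix(0, nr, ns)
  desc_r <- lapply(seq_len(nr), function(i) sort(Dr[i, -i]))
  desc_s <- lapply(seq_len(ns), function(j) sort(Ds[j, -j]))
  for (i in seq_len(nr)) for (j in seq_len(ns)) {
    s <- descriptor_agreement(desc_r[[i]], desc_s[[j]], tol)
    if (ref$letters[i] == site$letters[j]) s <- s + bonus
    W[i, j] <- s
    S[i, j] <- min(1, s)
  }
  list(score = S, weight = W)
}

# maximum-weight bipartite assignment with deterministic tie-breaking
# (lowest (reference index, site index) pair wins among equal scores)
assign_bipartite <- function(S) {
  nr <- nrow(S); ns <- ncol(S)
  eps <- 1e-9 / (nr * (ns + 1) + ns + 1)
  idx <- expand.grid(i = seq_len(nr), j = seq_len(ns))
  w <- S[cbind(idx$i, idx$j)] - eps * ((idx$i - 1) * (ns + 1) + idx$j)
  g <- igraph::make_bipartite_graph(c(rep(0, nr), rep(1, ns)), directed = FALSE,
                                    edges = rbind(idx$i, nr + idx$j))
  m <- igraph::max_bipartite_match(g, weights = pmax(w, 1e-12))$matching
  map <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    j <- m[i]
    if (!is.na(j)) map[i] <- as.integer(j) - nr
  }
  map
}

# Greedy maximal subset of matched pairs that is mutually distance-compatible
# (|d_ref(i,i') - d_site(j,j')| <= tol for every selected pair of pairs),
# taken in decreasing assignment-weight order. Seeds the first superposition
# from rigid-consistent correspondences only.
consistent_subset <- function(map, Dr, Ds, weights, tol, anchor = 1L) {
  got <- which(!is.na(map))
  if (length(got) == 0) return(integer(0))
  ord <- got[order(-weights[cbind(got, map[got])])]
  if (anchor > 1L && anchor <= length(ord))
    ord <- c(ord[anchor], ord[-anchor])
  sel <- integer(0)
  for (i in ord) {
    ok <- all(abs(Dr[i, sel] - Ds[map[i], map[sel]]) <= tol)
    if (ok) sel <- c(sel, i)
  }
  sort(sel)
}

# greedy unique re-assignment by spatial proximity after superposition
proximity_assign <- function(ref_ca, site_mapped, cutoff = 3) {
  nr <- nrow(ref_ca); ns <- nrow(site_mapped)
  D <- matrix(Inf, nr, ns)
  for (j in seq_len(ns))
    D[, j] <- sqrt(rowSums(sweep(ref_ca, 2, site_mapped[j, ])^2))
  map <- rep(NA_integer_, nr)
  used <- rep(FALSE, ns)
  ord <- order(D)
  for (k in ord) {
    if (D[k] > cutoff) break
    i <- (k - 1) %% nr + 1
    j <- (k - 1) %/% nr + 1
    if (is.na(map[i]) && !used[j]) { map[i] <- j; used[j] <- TRUE }
  }
  map
}

#' Sequence-order-independent alignment of binding-site shells
#'
#' Aligns substrate shells of several structures onto the largest shell
#' (the reference) without assuming any sequence order: residues are first
#' matched by their sorted intra-shell Calpha distance descriptors (with a
#' bonus for identical residue type) via maximum-weight bipartite assignment,
#' then the match is iteratively refined geometrically (Kabsch superposition,
#' dropping pairs deviating > 3 A, re-assignment by spatial proximity, up to
#' 10 rounds).
#'
#' @param shells list of `residue_shell` (>= 2 usable sites of >= 4 residues;
#'   smaller shells are skipped with a warning).
#' @param tol_descriptor_A descriptor agreement tolerance (default 1.5 A).
#' @param letter_bonus score bonus for identical residue letters (0.2).
#' @param max_rounds geometric refinement rounds (10).
#' @param accept_radius_A Calpha radius for the final conservative
#'   assignment pass (default 2 A, between the descriptor tolerance and the
#'   3 A drop cutoff of the refinement loop: wide enough for genuinely
#'   equivalent residues under placement noise, narrow enough that unrelated
#'   pocket residues rarely coincide).
#' @return Object of class `site_alignment`: one column per reference
#'   residue, per-site matched residues, per-column agreement scores.
#' @export
align_sites <- function(shells, tol_descriptor_A = 1.5, letter_bonus = 0.2,
                        max_rounds = 10, accept_radius_A = 2) {
  data <- lapply(shells, shell_residue_data)
  sizes <- vapply(data, function(d) length(d$keys), integer(1))
  skipped <- vapply(data, function(d) d$id, character(1))[sizes < 4]
  if (length(skipped) > 0)
    warning("skipping site(s) with < 4 residues: ",
            paste(skipped, collapse = ", "))
  data <- data[sizes >= 4]
  if (length(data) < 2) stop("need >= 2 usable sites to align")
  ref_idx <- which.max(vapply(data, function(d) length(d$keys), integer(1)))
  ref <- data[[ref_idx]]
  nc <- length(ref$keys)
  site_ids <- vapply(data, function(d) d$id, character(1))
  ns <- length(data)

  match_keys <- matrix(NA_character_, ns, nc,
                       dimnames = list(site_ids, ref$keys))
  match_letters <- matrix(NA_character_, ns, nc,
                          dimnames = list(site_ids, ref$keys))
  scores <- matrix(NA_real_, ns, nc, dimnames = list(site_ids, ref$keys))
  deviations <- matrix(NA_real_, ns, nc, dimnames = list(site_ids, ref$keys))

  for (s in seq_len(ns)) {
    site <- data[[s]]
    if (s == ref_idx) {
      match_keys[s, ] <- ref$keys
      match_letters[s, ] <- ref$letters
      scores[s, ] <- 1
      deviations[s, ] <- 0
      next
    }
    sm <- site_score_matrix(ref, site, tol_descriptor_A, letter_bonus)
    S <- sm$score
    hungarian <- assign_bipartite(sm$weight)
    Dr <- as.matrix(dist(ref$ca))
    Ds <- as.matrix(dist(site$ca))
    refit <- function(m) {
      got <- which(!is.na(m))
      if (length(got) < 3) return(NULL)
      tryCatch(
        kabsch(site$ca[m[got], , drop = FALSE], ref$ca[got, , drop = FALSE]),
        error = function(e) NULL)
    }
    refine_from <- function(map) {
      # geometric refinement: Kabsch on current pairs, drop deviations > 3 A,
      # re-assign by spatial proximity, iterate; then a conservative final
      # phase that only keeps pairs within accept_radius_A, so chance matches
      # of non-conserved pocket residues are suppressed
      fit <- NULL
      for (round in seq_len(max_rounds)) {
        fit_new <- refit(map)
        if (is.null(fit_new)) break
        fit <- fit_new
        mapped <- fit$transform(site$ca)
        got <- which(!is.na(map))
        dev <- sqrt(rowSums((ref$ca[got, , drop = FALSE] -
                               mapped[map[got], , drop = FALSE])^2))
        map[got[dev > 3]] <- NA_integer_
        new_map <- proximity_assign(ref$ca, mapped, cutoff = 3)
        if (identical(new_map, map)) { map <- new_map; break }
        map <- new_map
      }
      if (!is.null(fit)) {
        for (round in seq_len(max_rounds)) {
          new_map <- proximity_assign(ref$ca, fit$transform(site$ca),
                                      cutoff = accept_radius_A)
          fit_new <- refit(new_map)
          if (is.null(fit_new)) break
          fit <- fit_new
          if (identical(new_map, map)) { map <- new_map; break }
          map <- new_map
        }
      }
      got <- which(!is.na(map))
      if (length(got) < 3 || is.null(fit)) return(NULL)
      mapped <- fit$transform(site$ca)
      dev <- sqrt(rowSums((ref$ca[got, , drop = FALSE] -
                             mapped[map[got], , drop = FALSE])^2))
      # solution quality: distance kernel (1 A scale) plus residue-identity
      # term, so a tight letter-consistent solution beats a sloppy congruence
      # that happens to cover more residues
      same <- ref$letters[got] == site$letters[map[got]]
      objective <- sum(1 / (1 + dev^2) + 0.2 * same)
      list(map = map, fit = fit, n = length(got), mean_dev = mean(dev),
           objective = objective)
    }
    # multi-start: the full assignment plus rigid-consistent subsets anchored
    # on different high-weight pairs; keep the solution matching the most
    # pairs at the smallest mean deviation
    starts <- list(hungarian)
    n_anchor <- min(6L, sum(!is.na(hungarian)))
    for (t in seq_len(n_anchor)) {
      seed <- consistent_subset(hungarian, Dr, Ds, sm$weight,
                                tol_descriptor_A, anchor = t)
      if (length(seed) >= 3) {
        m <- hungarian
        m[setdiff(seq_along(m), seed)] <- NA_integer_
        starts[[length(starts) + 1L]] <- m
      }
    }
    starts <- unique(starts)
    best <- NULL
    for (st in starts) {
      sol <- refine_from(st)
      if (is.null(sol)) next
      if (is.null(best) || sol$objective > best$objective + 1e-12)
        best <- sol
    }
    if (is.null(best)) {
      warning("site ", site$id, " could not be aligned; left as gaps")
      next
    }
    map <- best$map
    fit <- best$fit
    got <- which(!is.na(map))
    mapped <- fit$transform(site$ca)
    match_keys[s, got] <- site$keys[map[got]]
    match_letters[s, got] <- site$letters[map[got]]
    scores[s, got] <- S[cbind(got, map[got])]
    deviations[s, got] <- sqrt(rowSums((ref$ca[got, , drop = FALSE] -
                                          mapped[map[got], , drop = FALSE])^2))
  }
  agreement <- colMeans(ifelse(is.na(scores), 0, scores))
  structure(list(reference_id = ref$id, site_ids = site_ids,
                 ref_keys = ref$keys, ref_letters = ref$letters,
                 ref_ca = ref$ca, match_keys = match_keys,
                 match_letters = match_letters, scores = scores,
                 deviations = deviations, agreement = agreement,
                 skipped = skipped),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("<site_alignment> ref", x$reference_id, ":", length(x$ref_keys),
      "columns,", length(x$site_ids), "sites\n")
  invisible(x)
}

#' Extract a conserved 3D motif from a site alignment
#'
#' Each reference column is scored by coverage c (fraction of sites with a
#' matched residue) and geometric tightness g = 1 - mean Calpha deviation / 3 A
#' (floored at 0); columns with c > `m_dist_min` and g > `m_dist_max` are
#' retained. The motif stores consensus residue letters, allowed alternatives
#' (letters in >= 20% of sites), and the reference Calpha distance template.
#'
#' @param alignment `site_alignment` over >= 2 sites.
#' @param m_dist_min coverage gate (default 0.6).
#' @param m_dist_max tightness gate (default 0.4).
#' @param tol_distance_A pairwise-distance tolerance stored for search
#'   (default 2.5 A: the template is itself one noisy instance of the motif,
#'   so the pruning band must cover placement noise on both the template and
#'   the query side; with per-structure distance deviations bounded by 4
#'   sigma = 1.2 A at the default jitter, 2.5 A never prunes a true match).
#' @param tol_rmsd_A superposition RMSD tolerance stored for search (2.0).
#' @param alt_frequency letter frequency for the alternatives set (0.2).
#' @return Object of class `motif3d`.
#' @export
extract_motif <- function(alignment, m_dist_min = 0.6, m_dist_max = 0.4,
                          tol_distance_A = 2.5, tol_rmsd_A = 2.0,
                          alt_frequency = 0.2) {
  mk <- alignment$match_keys
  ml <- alignment$match_letters
  ns <- nrow(mk)
  nc <- ncol(mk)
  is_ref <- alignment$site_ids == alignment$reference_id
  # the reference residue defines the column, so coverage is measured over
  # the other sites only
  cov <- colMeans(!is.na(mk[!is_ref, , drop = FALSE]))
  dev <- alignment$deviations[!is_ref, , drop = FALSE]
  mean_dev <- apply(dev, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  tight <- ifelse(is.na(mean_dev), 0, pmax(0, 1 - mean_dev / 3))
  keep <- which(cov > m_dist_min & tight > m_dist_max)
  if (length(keep) < 3) stop("no representative motif (< 3 retained columns)")
  consensus <- character(length(keep))
  alternatives <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    letters_k <- ml[, keep[k]]
    letters_k <- letters_k[!is.na(letters_k)]
    tab <- sort(table(letters_k), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    consensus[k] <- sort(top)[1]
    alternatives[[k]] <- sort(names(tab)[tab / ns >= alt_frequency])
  }
  ca <- alignment$ref_ca[keep, , drop = FALSE]
  structure(list(positions = data.frame(key = alignment$ref_keys[keep],
                                        consensus = consensus,
                                        stringsAsFactors = FALSE),
                 alternatives = alternatives,
                 template_distances = as.matrix(dist(ca)),
                 template_ca = ca,
                 tol_distance_A = tol_distance_A, tol_rmsd_A = tol_rmsd_A,
                 support = ns, m_dist_min = m_dist_min,
                 m_dist_max = m_dist_max, coverage = cov[keep],
                 tightness = tight[keep],
                 reference_id = alignment$reference_id),
            class = "motif3d")
}

#' @export
print.motif3d <- function(x, ...) {
  cat("<motif3d>", nrow(x$positions), "positions (",
      paste(x$positions$consensus, collapse = ""), ") support",
      x$support, "sites, ref", x$reference_id, "\n")
  invisible(x)
}

#' Per-column residue conservation profile of a site alignment
#'
#' @param alignment `site_alignment`.
#' @return List with `profile` (per column, named frequency vector over
#'   matched residues, summing to 1) and `gap_fraction` (per column).
#' @export
conservation_profile <- function(alignment) {
  ml <- alignment$match_letters
  profile <- lapply(seq_len(ncol(ml)), function(k) {
    v <- ml[, k]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(numeric(0))
    tab <- table(v)
    out <- as.numeric(tab) / length(v)
    names(out) <- names(tab)
    out
  })
  names(profile) <- alignment$ref_keys
  gap_fraction <- colMeans(is.na(ml))
  names(gap_fraction) <- alignment$ref_keys
  list(profile = profile, gap_fraction = gap_fraction)
}

#' Conservation profile as a long table (logo data)
#' @param alignment `site_alignment`.
#' @return Data frame (column, letter, frequency).
#' @export
conservation_table <- function(alignment) {
  cp <- conservation_profile(alignment)
  rows <- lapply(seq_along(cp$profile), function(k) {
    p <- cp$profile[[k]]
    if (length(p) == 0) return(NULL)
    data.frame(column = names(cp$profile)[k], letter = names(p),
               frequency = as.numeric(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Search a 3D motif in a query structure
#'
#' Enumerates candidate residue tuples by residue identity (strict: every
#' position must carry the consensus letter or a stored alternative; relaxed:
#' at most one position may violate), prunes by pairwise Calpha distance
#' compatibility with the motif template (each pair within `tol_distance_A`),
#' and keeps tuples whose Kabsch superposition onto the template has RMSD
#' <= `tol_rmsd_A`.
#'
#' @param motif `motif3d`.
#' @param query `structure_model` or `residue_shell`.
#' @param policy `"strict"` or `"relaxed"` (at most one residue mutation).
#' @return List of class `motif_matches`; each match has `residues`
#'   (position-to-residue mapping), `rmsd_A`, `mismatches`. Sorted by
#'   (mismatches, rmsd).
#' @export
search_motif <- function(motif, query, policy = c("strict", "relaxed")) {
  policy <- match.arg(policy)
  budget <- if (policy == "relaxed") 1L else 0L
  q <- shell_residue_data(query)
  np <- nrow(motif$positions)
  nq <- length(q$keys)
  matches <- list()
  if (np > nq) {
    return(structure(list(), class = "motif_matches",
                     query = q$id, policy = policy))
  }
  allowed <- lapply(seq_len(np), function(p)
    unique(c(motif$positions$consensus[p], motif$alternatives[[p]])))
  ok_letter <- vapply(seq_len(np), function(p) q$letters %in% allowed[[p]],
                      logical(nq))
  ok_letter <- matrix(ok_letter, nrow = nq)
  # process positions with the fewest strict candidates first
  ord <- order(colSums(ok_letter))
  Dq <- as.matrix(dist(q$ca))
  Tm <- motif$template_distances
  tol <- motif$tol_distance_A

  chosen <- integer(np) # query residue index per position (template order)
  recurse <- function(step, used, mism) {
    if (step > np) {
      fit <- tryCatch(
        kabsch(q$ca[chosen, , drop = FALSE], motif$template_ca),
        error = function(e) NULL)
      if (is.null(fit) || fit$rmsd_A > motif$tol_rmsd_A) return()
      res <- residue_table(query)
      keys <- paste(res$chain, res$resno, sep = "|")
      sel <- match(q$keys[chosen], keys)
      matches[[length(matches) + 1L]] <<- list(
        residues = data.frame(position = motif$positions$key,
                              chain = res$chain[sel], resno = res$resno[sel],
                              letter = res$letter[sel],
                              stringsAsFactors = FALSE),
        rmsd_A = fit$rmsd_A, mismatches = mism)
      return()
    }
    p <- ord[step]
    for (r in seq_len(nq)) {
      if (used[r]) next
      mm <- mism + !ok_letter[r, p]
      if (mm > budget) next
      compatible <- TRUE
      if (step > 1) {
        for (prev in seq_len(step - 1)) {
          pp <- ord[prev]
          if (abs(Dq[r, chosen[pp]] - Tm[p, pp]) > tol) {
            compatible <- FALSE
            break
          }
        }
      }
      if (!compatible) next
      chosen[p] <<- r
      used[r] <- TRUE
      recurse(step + 1, used, mm)
      used[r] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nq), 0L)
  o <- order(vapply(matches, function(m) m$mismatches, numeric(1)),
             vapply(matches, function(m) m$rmsd_A, numeric(1)))
  structure(matches[o], class = "motif_matches", query = q$id, policy = policy)
}

#' @export
print.motif_matches <- function(x, ...) {
  cat("<motif_matches>", length(x), "match(es) in", attr(x, "query"),
      "policy", attr(x, "policy"), "\n")
  invisible(x)
}

#' Motif match report as a table
#' @param matches `motif_matches`.
#' @return Data frame (query, rank, mismatches, rmsd_A, residues).
#' @export
motif_match_table <- function(matches) {
  if (length(matches) == 0)
    return(data.frame(query = character(), rank = integer(),
                      mismatches = integer(), rmsd_A = numeric(),
                      residues = character(), stringsAsFactors = FALSE))
  data.frame(
    query = attr(matches, "query"), rank = seq_along(matches),
    mismatches = vapply(matches, function(m) m$mismatches, numeric(1)),
    rmsd_A = vapply(matches, function(m) m$rmsd_A, numeric(1)),
    residues = vapply(matches, function(m)
      paste(paste0(m$residues$letter, m$residues$resno), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Serialize a 3D motif to JSON
#' @param motif `motif3d`.
#' @param path output file.
#' @export
write_motif <- function(motif, path) {
  obj <- list(positions = motif$positions,
              alternatives = motif$alternatives,
              template_distances = motif$template_distances,
              template_ca = motif$template_ca,
              tol_distance_A = motif$tol_distance_A,
              tol_rmsd_A = motif$tol_rmsd_A,
              support = motif$support, m_dist_min = motif$m_dist_min,
              m_dist_max = motif$m_dist_max,
              reference_id = motif$reference_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D motif from JSON written by [write_motif()]
#' @param path JSON file.
#' @return `motif3d`.
#' @export
read_motif <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alts <- obj$alternatives
  if (!is.list(alts)) alts <- as.list(alts)
  alts <- lapply(alts, as.character)
  structure(list(positions = as.data.frame(obj$positions,
                                           stringsAsFactors = FALSE),
                 alternatives = alts,
                 template_distances = as.matrix(obj$template_distances),
                 template_ca = as.matrix(obj$template_ca),
                 tol_distance_A = obj$tol_distance_A,
                 tol_rmsd_A = obj$tol_rmsd_A, support = obj$support,
                 m_dist_min = obj$m_dist_min, m_dist_max = obj$m_dist_max,
                 reference_id = obj$reference_id),
            class = "motif3d")
}
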