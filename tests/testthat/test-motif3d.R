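toy_motif <- function() {
  ca <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 7, 0), c(3, 3, 5))
  structure(list(
    positions = data.frame(key = sprintf("A|%d", 1:4),
                           consensus = c("D", "W", "F", "S"),
                           stringsAsFactors = FALSE),
    alternatives = list("D", "W", "F", "S"),
    template_distances = as.matrix(dist(ca)), template_ca = ca,
    tol_distance_A = 2.5, tol_rmsd_A = 2.0, support = 5,
    m_dist_min = 0.6, m_dist_max = 0.4, reference_id = "toy"),
    class = "motif3d")
}

test_that("identical shells align to the identity mapping", {
  set.seed(31)
  ca <- matrix(rnorm(18, sd = 4), ncol = 3)
  letters <- c("D", "D", "W", "F", "S", "Y")
  s1 <- make_shell_direct(ca, letters, "s1")
  s2 <- make_shell_direct(ca, letters, "s2")
  aln <- align_sites(list(s1, s2))
  expect_equal(unname(aln$match_keys["s2", ]), aln$ref_keys)
  expect_equal(unname(aln$agreement), rep(1, 6))
})

test_that("site alignment is independent of residue input order", {
  set.seed(32)
  ca <- matrix(rnorm(27, sd = 4), ncol = 3)
  letters <- c("D", "W", "F", "S", "Y", "M", "R", "T", "C")
  s1 <- make_shell_direct(ca, letters, "s1")
  s2 <- make_shell_direct(ca + rnorm(27, 0, 0.2), letters, "s2")
  perm <- sample(9)
  # same residues presented in permuted order, numbering preserved
  s2p <- make_shell_direct((ca + rnorm(27, 0, 0))[perm, ],
                           letters[perm], "s2p", resno = perm)
  aln <- align_sites(list(s1, s2))
  alnp <- align_sites(list(s1, s2p))
  # both recover position-i -> position-i correspondences
  expect_equal(unname(aln$match_keys["s2", ]), sprintf("A|%d", 1:9))
  expect_equal(unname(alnp$match_keys["s2p", ]), sprintf("A|%d", 1:9))
})

test_that("planted cohorts: correspondences, extraction, conservation", {
  td <- tempfile()
  truth <- generate_cohort(motif_test_config(401), td)
  held <- truth_held_out(truth)
  accs <- truth_accessions(truth)
  shells <- load_cohort_shells(td, accs[!held])
  aln <- suppressWarnings(align_sites(shells))
  planted <- sprintf("A|%d", unlist(truth$motif_positions))
  # >= 90% of planted correspondences recovered across sites
  ref_cols <- match(planted, aln$ref_keys)
  hits <- vapply(setdiff(aln$site_ids, aln$reference_id), function(s)
    sum(aln$match_keys[s, ref_cols] == planted, na.rm = TRUE), numeric(1))
  expect_gte(mean(hits) / length(planted), 0.9)

  motif <- extract_motif(aln)
  expect_setequal(motif$positions$key, planted)
  expect_equal(motif$positions$consensus[order(match(motif$positions$key,
                                                     planted))],
               unlist(truth$motif_letters))
  expect_true(all(vapply(motif$alternatives, length, integer(1)) == 1))

  cp <- conservation_profile(aln)
  sums <- vapply(cp$profile, sum, numeric(1))
  expect_true(all(abs(sums[vapply(cp$profile, length, integer(1)) > 0] - 1)
                  < 1e-9))
  unlink(td, recursive = TRUE)
})

test_that("column gates drop sparse columns; tiny alignments fail", {
  # hand-built alignment: 10 sites, reference + 9; one column matched in
  # only 40% of the non-reference sites -> coverage 0.4 fails the 0.6 gate
  ns <- 10
  nc <- 4
  ids <- sprintf("s%d", 1:ns)
  mk <- matrix("A|1", ns, nc, dimnames = list(ids, sprintf("A|%d", 1:nc)))
  ml <- matrix("D", ns, nc, dimnames = dimnames(mk))
  dev <- matrix(0.3, ns, nc, dimnames = dimnames(mk))
  sc <- matrix(1, ns, nc, dimnames = dimnames(mk))
  gap <- 2:7 # 6 of 9 non-reference sites unmatched in column 4
  mk[gap, 4] <- NA; ml[gap, 4] <- NA; dev[gap, 4] <- NA; sc[gap, 4] <- NA
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 6, 0), c(2, 3, 4))
  aln <- structure(list(reference_id = "s1", site_ids = ids,
                        ref_keys = sprintf("A|%d", 1:nc),
                        ref_letters = rep("D", nc), ref_ca = ca,
                        match_keys = mk, match_letters = ml, scores = sc,
                        deviations = dev,
                        agreement = colMeans(ifelse(is.na(sc), 0, sc)),
                        skipped = character(0)),
                   class = "site_alignment")
  motif <- extract_motif(aln)
  expect_setequal(motif$positions$key, sprintf("A|%d", 1:3))
  # all-identical alignment keeps everything
  mk[, 4] <- "A|4"; ml[, 4] <- "D"; dev[, 4] <- 0.1; sc[, 4] <- 1
  aln$match_keys <- mk; aln$match_letters <- ml
  aln$deviations <- dev; aln$scores <- sc
  expect_equal(nrow(extract_motif(aln)$positions), 4)
  # fewer than 3 surviving columns is an error
  mk[2:10, 2:4] <- NA; ml[2:10, 2:4] <- NA; dev[2:10, 2:4] <- NA
  aln$match_keys <- mk; aln$match_letters <- ml; aln$deviations <- dev
  expect_error(extract_motif(aln), "no representative motif")
})

test_that("conservation profile frequencies and gap fractions", {
  ids <- sprintf("s%d", 1:4)
  mk <- matrix("A|1", 4, 2, dimnames = list(ids, c("A|1", "A|2")))
  ml <- matrix(c("W", "W", "W", "W", "F", "F", "Y", "Y"), 4, 2,
               dimnames = dimnames(mk))
  aln <- structure(list(reference_id = "s1", site_ids = ids,
                        ref_keys = c("A|1", "A|2"), ref_letters = c("W", "F"),
                        ref_ca = matrix(rnorm(6), 2), match_keys = mk,
                        match_letters = ml,
                        scores = matrix(1, 4, 2), deviations = matrix(0, 4, 2),
                        agreement = c(1, 1), skipped = character(0)),
                   class = "site_alignment")
  cp <- conservation_profile(aln)
  expect_equal(cp$profile[["A|1"]], c(W = 1))
  expect_equal(sort(cp$profile[["A|2"]]), sort(c(F = 0.5, Y = 0.5)))
  expect_equal(unname(cp$gap_fraction), c(0, 0))
})

test_that("motif search: self-recovery, policies, decoys, brute force", {
  motif <- toy_motif()
  ca <- motif$template_ca
  # query carrying the motif plus distractor residues
  qca <- rbind(ca, c(20, 20, 20), c(25, 20, 20), c(20, 26, 21), c(28, 25, 24))
  qletters <- c("D", "W", "F", "S", "A", "D", "W", "K")
  query <- make_model(qca, qletters, "q1")
  hits <- search_motif(motif, query, "strict")
  expect_gte(length(hits), 1)
  expect_equal(hits[[1]]$mismatches, 0)
  expect_lt(hits[[1]]$rmsd_A, 0.5)
  expect_equal(hits[[1]]$residues$resno, 1:4)

  # one planted substitution: found only under relaxed, as 1 mismatch
  qletters2 <- qletters
  qletters2[2] <- "K"
  query2 <- make_model(qca, qletters2, "q2")
  strict2 <- search_motif(motif, query2, "strict")
  relax2 <- search_motif(motif, query2, "relaxed")
  found <- Filter(function(m) identical(m$residues$resno, 1:4), relax2)
  expect_length(Filter(function(m) identical(m$residues$resno, 1:4), strict2), 0)
  expect_length(found, 1)
  expect_equal(found[[1]]$mismatches, 1)

  # scrambled geometry decoy: same letters, distances perturbed +5 A
  qca3 <- ca * 2.2
  query3 <- make_model(qca3, c("D", "W", "F", "S"), "q3")
  expect_length(search_motif(motif, query3, "relaxed"), 0)

  # strict matches are a subset of relaxed matches
  sig <- function(m) paste(m$residues$resno, collapse = ",")
  set.seed(33)
  qca4 <- rbind(ca + matrix(rnorm(12, 0, 0.2), ncol = 3),
                matrix(rnorm(24, sd = 8), ncol = 3))
  query4 <- make_model(qca4, c("D", "W", "F", "S",
                               sample(c("D", "W", "F", "S", "A", "K"), 8,
                                      replace = TRUE)), "q4")
  s4 <- vapply(search_motif(motif, query4, "strict"), sig, character(1))
  r4 <- vapply(search_motif(motif, query4, "relaxed"), sig, character(1))
  expect_true(all(s4 %in% r4))

  # enumeration soundness on a <= 15-residue query
  for (pol in c("strict", "relaxed")) {
    mine <- search_motif(motif, query4, pol)
    brute <- brute_search(motif, query4, pol)
    key <- function(tup) paste(sort(tup), collapse = "_")
    mine_keys <- vapply(mine, function(m)
      paste(m$residues$resno, collapse = "_"), character(1))
    brute_keys <- vapply(brute, function(b)
      paste(b$tuple, collapse = "_"), character(1))
    expect_setequal(mine_keys, brute_keys)
  }

  # motif larger than the query yields an empty result
  tiny <- make_model(ca[1:3, ], c("D", "W", "F"), "tiny")
  expect_length(search_motif(motif, tiny, "relaxed"), 0)
})

test_that("motif JSON serialization round-trips", {
  motif <- toy_motif()
  p <- tempfile(fileext = ".json")
  write_motif(motif, p)
  back <- read_motif(p)
  expect_equal(back$positions$consensus, motif$positions$consensus)
  expect_equal(back$template_distances, motif$template_distances,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$tol_distance_A, motif$tol_distance_A)
  expect_equal(back$support, motif$support)
})
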