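test_that("signature motif scanner finds the class anchors", {
  h <- scan_signature_motifs("AADDYYDAA", "DDXXD")
  expect_equal(h$start, 3L)
  expect_equal(h$text, "DDYYD")
  h <- scan_signature_motifs("MDIDDA")
  expect_true(any(h$motif == "DXDD" & h$start == 2))
  expect_false(any(scan_signature_motifs("AAAAAA")$motif == "PNV"))
  expect_equal(nrow(scan_signature_motifs("")), 0)
  # PIX and FEHXW carry wildcard positions; FERLW and LHS are literal
  expect_true(any(scan_signature_motifs("APIKA")$motif == "PIX"))
  expect_true(any(scan_signature_motifs("AFEHLWA")$motif == "FEHXW"))
  expect_true(any(scan_signature_motifs("AFERLWA")$motif == "FERLW"))
})

test_that("class assignment follows the DDXXD/DXDD signature rules", {
  expect_equal(classify_class("AAADDYYDAAA"), "I")
  expect_equal(classify_class("AAADIDDAAA"), "II")
  expect_equal(classify_class("AADIDDAAKKDDYYDAA"), "I_II")
  expect_equal(classify_class("AAAKKKAAA"), "unknown")
  # NSE/DTE triad also marks class I
  expect_equal(classify_class("AAANDAASAEAAA"), "I")
})

test_that("domain splitting honors ranges, else the motif-anchor midpoint", {
  rec <- enzyme_record("R", strrep("A", 480),
                       domain_ranges = list(N = c(1, 200), C = c(201, 480)))
  sp <- split_domains(rec)
  expect_equal(nchar(sp$N), 200)
  expect_equal(nchar(sp$C), 280)

  seqv <- rep("A", 300)
  seqv[50:53] <- c("D", "I", "D", "D")
  seqv[150:154] <- c("D", "D", "Y", "Y", "D")
  rec2 <- enzyme_record("R2", paste(seqv, collapse = ""))
  sp2 <- split_domains(rec2)
  expect_equal(nchar(sp2$N), 102) # midpoint of DXDD end + 1 and DDXXD start
  expect_equal(nchar(sp2$C), 198)

  expect_error(split_domains(enzyme_record("R3", strrep("A", 50))),
               "cannot split")
})

test_that("percent identity: identity, substitution, symmetry", {
  expect_equal(pairwise_identity("MKLV", "MKLV"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  expect_equal(pairwise_identity("mklv", "MKLV"), 100)
  expect_error(pairwise_identity("", "MK"), "empty")
  set.seed(4)
  for (k in 1:5) {
    a <- random_aa(sample(6:12, 1))
    b <- random_aa(sample(6:12, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("pairwise identity agrees with an exhaustive affine-gap oracle", {
  set.seed(7)
  for (k in 1:12) {
    a <- random_aa(sample(5:12, 1))
    b <- random_aa(sample(5:12, 1))
    orc <- gotoh_oracle(a, b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), orc$score, tolerance = 1e-9)
    id <- pairwise_identity(a, b)
    expect_gte(id, orc$id_min - 1e-9)
    expect_lte(id, orc$id_max + 1e-9)
  }
  # unrelated length-20 random sequences stay clearly below high identity
  set.seed(8)
  a <- strrep("W", 20)
  b <- strrep("P", 20)
  expect_lt(pairwise_identity(a, b), 30)
})

test_that("similarity matrices are symmetric with a full-scale diagonal", {
  recs <- list(enzyme_record("A", "MKLVWD"), enzyme_record("B", "MKLVWD"))
  m <- similarity_matrix(recs, "full")
  expect_equal(unname(m$values), matrix(100, 2, 2))
  set.seed(10)
  recs5 <- lapply(1:5, function(i)
    enzyme_record(paste0("E", i), random_aa(30),
                  domain_ranges = list(N = c(1, 15), C = c(16, 30))))
  mf <- similarity_matrix(recs5, "full")
  expect_true(isSymmetric(mf$values))
  expect_equal(unname(diag(mf$values)), rep(100, 5))
  mn <- similarity_matrix(recs5, "N")
  expect_equal(mn$kind, "seq_N")
  expect_true(all(mn$values >= 0 & mn$values <= 100))
  # records without ranges or anchors make region matrices fail loudly
  recs_bad <- list(enzyme_record("A", "MKLVWD"), enzyme_record("B", "MKLVWD"))
  expect_error(similarity_matrix(recs_bad, "C"), "A, B")
})

test_that("SSN thresholding keeps isolated nodes and nests across cutoffs", {
  vals <- matrix(c(100, 90, 20,
                   90, 100, 20,
                   20, 20, 100), 3, byrow = TRUE)
  m <- ditps3d:::new_similarity_matrix(c("A", "B", "C"), vals, "seq_full", 100)
  ssn <- build_ssn(m, 50)
  expect_equal(igraph::vcount(ssn$graph), 3)
  expect_equal(igraph::ecount(ssn$graph), 1)
  el <- igraph::as_edgelist(ssn$graph)
  expect_setequal(as.vector(el), c("A", "B"))
  expect_equal(igraph::ecount(build_ssn(m, 0)$graph), 3) # complete K3
  expect_error(build_ssn(m, 101), "outside")
  # nested thresholds: edges(t2) subset of edges(t1) for t1 < t2
  set.seed(2)
  rv <- matrix(runif(64, 0, 100), 8)
  rv <- (rv + t(rv)) / 2
  diag(rv) <- 100
  mr <- ditps3d:::new_similarity_matrix(paste0("N", 1:8), rv, "seq_full", 100)
  ekey <- function(g) apply(igraph::as_edgelist(g), 1, paste, collapse = "~")
  e1 <- ekey(build_ssn(mr, 30)$graph)
  e2 <- ekey(build_ssn(mr, 60)$graph)
  expect_true(all(e2 %in% e1))
})

test_that("E-value mode thresholds a Karlin-Altschul score table", {
  expect_lt(ka_evalue(100, 300, 300), ka_evalue(50, 300, 300))
  ev <- matrix(c(0, 1e-50, 1e-3,
                 1e-50, 0, 1e-3,
                 1e-3, 1e-3, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ssn <- build_ssn(ev, 1e-10, mode = "evalue")
  expect_equal(igraph::ecount(ssn$graph), 1)
})
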