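test_that("d0 follows the cube-root law with the 0.5 A floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(tm_d0(10), 0.5)
  expect_equal(tm_d0(15), 0.5)
  expect_error(tm_d0(0), ">= 1")
})

test_that("shell selection uses inclusive byres semantics", {
  lig <- make_ligand(matrix(0, 1, 3))
  # residue 1: atom at 3.9 (in at r=4); residue 2: atom at 4.05 (out at r=4);
  # residue 3: side-chain at 3.0 but CA at 9.0 (in, whole residue)
  atoms <- data.frame(
    chain = "A", resno = c(1, 2, 3, 3),
    resname = c("ALA", "GLY", "TRP", "TRP"),
    atom = c("CA", "CA", "CB", "CA"), element = "C",
    x = c(3.9, 4.05, 3.0, 9.0), y = 0, z = 0, stringsAsFactors = FALSE)
  model <- ditps3d:::new_structure_model("toy", atoms)
  s4 <- extract_shell(model, lig, 4)
  expect_equal(residue_table(s4)$resno, c(1, 3))
  expect_equal(sum(s4$atoms$resno == 3), 2) # whole residue kept
  s6 <- extract_shell(model, lig, 6)
  expect_equal(residue_table(s6)$resno, c(1, 2, 3))
  expect_error(extract_shell(model, make_ligand(matrix(0, 0, 3)), 4), "empty")
  expect_warning(extract_shell(model, make_ligand(c(100, 100, 100)), 4),
                 "no residues")
})

test_that("shells nest across radii on generated structures", {
  td <- tempfile()
  truth <- generate_cohort(cohort_config(n_enzymes = 4, n_families = 2,
                                         seed = 21), td)
  for (a in truth_accessions(truth)) {
    sm <- read_structure(file.path(td, "structures", paste0(a, ".pdb")),
                         ligand_codes = "LIG")
    prev <- NULL
    for (r in c(4, 6, 8, 10)) {
      sh <- extract_shell(sm$model, sm$ligand, r)
      keys <- paste(residue_table(sh)$chain, residue_table(sh)$resno)
      if (!is.null(prev)) expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
  unlink(td, recursive = TRUE)
})

test_that("Kabsch recovers rigid transforms with proper rotations only", {
  set.seed(5)
  A <- matrix(rnorm(15, sd = 4), ncol = 3)
  f0 <- kabsch(A, A)
  expect_lt(f0$rmsd_A, 1e-8)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  R90 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
  B <- A %*% t(R90)
  f1 <- kabsch(A, B)
  expect_lt(f1$rmsd_A, 1e-6)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-8)
  expect_equal(max(abs(t(f1$rotation) %*% f1$rotation - diag(3))), 0,
               tolerance = 1e-8)

  # reflection-related sets cannot be superposed by a proper rotation
  C <- A
  C[, 1] <- -C[, 1]
  f2 <- kabsch(A, C)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-8)
  expect_gt(f2$rmsd_A, 0.1)

  expect_error(kabsch(A[1:2, ], A[1:2, ]), ">= 3")
  coll <- cbind(1:4, 0, 0)
  expect_error(kabsch(coll, coll), "degenerate")
})

test_that("TM-score kernel: perfect superposition and the d0 midpoint", {
  A <- matrix(rnorm(24, sd = 4), ncol = 3)
  pairs <- cbind(1:8, 1:8)
  expect_equal(tm_score(pairs, A, A, 8), 1)
  B <- A
  B[, 1] <- B[, 1] + tm_d0(8) # every aligned distance exactly d0
  expect_equal(tm_score(pairs, A, B, 8), 0.5, tolerance = 1e-12)
  expect_error(tm_score(pairs, A, A, 0), ">= 1")
})

test_that("structural alignment: self-identity, jitter, symmetry", {
  set.seed(6)
  # 80-residue self-avoiding-ish walk (d0 ~ 3.2 A at this length)
  A <- t(sapply(cumsum(rep(1, 80)), function(i)
    c(3 * cos(i / 3) * (1 + i / 40), 3 * sin(i / 3) * (1 + i / 40), 0.9 * i)))
  al <- align_structures(A, A)
  expect_equal(al$tm_mean, 1, tolerance = 1e-9)
  expect_equal(al$pairs[, 1], al$pairs[, 2])
  expect_true(all(diff(al$pairs[, 1]) > 0))

  B <- A + matrix(rnorm(240, 0, 0.3), ncol = 3)
  ab <- align_structures(A, B)
  expect_gt(ab$tm_mean, 0.9)
  ba <- align_structures(B, A)
  expect_equal(ab$tm_mean, ba$tm_mean, tolerance = 1e-6)
  expect_equal(max(abs(t(ab$rotation) %*% ab$rotation - diag(3))), 0,
               tolerance = 1e-8)
  expect_error(align_structures(A[1:3, ], A), "too small")
})

test_that("TM aligner matches the exhaustive monotone-pairing oracle", {
  set.seed(9)
  for (k in 1:2) {
    A <- matrix(cumsum(rnorm(24, sd = 1.5)), ncol = 3)
    B <- A + matrix(rnorm(24, 0, 0.05), ncol = 3)
    if (k == 2) {
      # displace one residue far away so the optimum may skip it
      B[4, ] <- B[4, ] + c(8, 0, 0)
      th <- 0.7
      R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, byrow = TRUE)
      B <- B %*% t(R) + matrix(rep(c(3, -2, 5), each = 8), ncol = 3)
    }
    # a pairing with k pairs has TM <= k/8, and these near-rigid toys reach
    # TM > 6/8 = 0.75, so enumeration restricted to k >= 6 is still
    # exhaustive for the argmax
    orc <- oracle_tm(A, B, 8, min_pairs = 6)
    al <- align_structures(A, B)
    expect_gt(al$tm_by_a, 0.75)
    expect_equal(al$tm_by_a, orc, tolerance = 1e-3)
  }
})

test_that("TM matrices are symmetric with unit diagonal; families separate", {
  set.seed(12)
  base1 <- matrix(cumsum(rnorm(36, sd = 2)), ncol = 3)
  base2 <- matrix(cumsum(rnorm(36, sd = 2)), ncol = 3)
  objs <- list(a1 = base1, a2 = base1 + matrix(rnorm(36, 0, 0.3), ncol = 3),
               b1 = base2, b2 = base2 + matrix(rnorm(36, 0, 0.3), ncol = 3))
  models <- lapply(names(objs), function(nm) make_model(objs[[nm]], id = nm))
  names(models) <- names(objs)
  m <- tm_similarity_matrix(models)
  expect_true(isSymmetric(m$values))
  expect_equal(unname(diag(m$values)), rep(1, 4))
  within <- c(m$values["a1", "a2"], m$values["b1", "b2"])
  between <- c(m$values["a1", "b1"], m$values["a1", "b2"],
               m$values["a2", "b1"], m$values["a2", "b2"])
  expect_gt(mean(within), mean(between))
})

test_that("shell TM matrix flags too-small shells as missing", {
  set.seed(13)
  ca <- matrix(rnorm(18, sd = 4), ncol = 3)
  sh_ok1 <- make_shell_direct(ca, rep("A", 6), "s1")
  sh_ok2 <- make_shell_direct(ca + rnorm(18, 0, 0.1), rep("A", 6), "s2")
  sh_small <- make_shell_direct(ca[1:3, ], rep("A", 3), "s3")
  m <- shell_tm_matrix(list(s1 = sh_ok1, s2 = sh_ok2, s3 = sh_small), 6)
  expect_true(is.na(m$values["s3", "s1"]))
  expect_gt(m$values["s1", "s2"], 0.8)
  expect_error(shell_tm_matrix(list(s3 = sh_small), 6), "empty")
})
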