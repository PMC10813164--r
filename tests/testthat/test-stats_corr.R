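test_that("AAC/GAAC composition normalizes over the counted letters", {
  c1 <- composition("AAW")
  expect_equal(c1$aac[["A"]], 2 / 3)
  expect_equal(c1$aac[["W"]], 1 / 3)
  expect_equal(c1$gaac[["aliphatic"]], 2 / 3)
  expect_equal(c1$gaac[["aromatic"]], 1 / 3)
  expect_equal(composition("DEDE")$gaac[["negative"]], 1)
  set.seed(41)
  for (k in 1:5) {
    cc <- composition(random_aa(sample(5:60, 1)))
    expect_equal(sum(cc$aac), 1)
    expect_equal(sum(cc$gaac), 1)
  }
  # the five groups partition the 20 standard letters exactly
  groups <- ditps3d:::GAAC_GROUPS
  expect_setequal(unlist(groups), ditps3d:::AA_LETTERS)
  expect_equal(length(unlist(groups)), 20)
  # X skipped with count; empty input flagged
  cx <- composition("AXA")
  expect_equal(cx$n_skipped, 1)
  expect_equal(cx$aac[["A"]], 1)
  ce <- composition("")
  expect_true(ce$empty)
  expect_equal(sum(ce$aac), 0)
})

test_that("residue preference is the shell/full frequency ratio", {
  p1 <- preference(c("A", "W"), "AAWW")
  expect_equal(p1$ratio[["A"]], 1)
  expect_equal(p1$ratio[["W"]], 1)
  p2 <- preference(c("A", "W"), "AAAW")
  expect_equal(p2$ratio[["W"]], 2)
  expect_equal(p2$ratio[["A"]], 2 / 3)
  p3 <- preference(c("C"), "AAAW")
  expect_true(p3$undefined[["C"]])
  expect_true(is.na(p3$ratio[["C"]]))
  # a sequence against itself gives ratio 1 for every present letter
  s <- "MKWLVDDE"
  p4 <- preference(s, s)
  present <- strsplit(s, "")[[1]]
  expect_true(all(abs(p4$ratio[unique(present)] - 1) < 1e-12))
  expect_error(preference("A", ""), "empty")
})

test_that("condense linearizes the upper triangle deterministically", {
  vals <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3)
  m <- ditps3d:::new_similarity_matrix(c("A", "B", "C"), vals, "tm_global", 1)
  v <- condense(m)
  expect_equal(as.numeric(v), c(.1, .2, .3))
  expect_equal(attr(v, "pairs"),
               cbind(c("A", "A", "B"), c("B", "C", "C")))
  expect_identical(as.numeric(condense(m)), as.numeric(v))
  # masked entries drop synchronously and are reported
  vals2 <- vals
  vals2[1, 2] <- vals2[2, 1] <- NA
  m2 <- ditps3d:::new_similarity_matrix(c("A", "B", "C", "D"),
                                        rbind(cbind(vals2, c(.4, .5, .6)),
                                              c(.4, .5, .6, 1)),
                                        "tm_global", 1)
  v2 <- condense(m2)
  expect_length(v2, 5)
  expect_equal(attr(v2, "masked"), cbind("A", "B"))
  expect_error(condense(m2, c("A", "B")), "fewer than 3")
})

test_that("pearson matches the closed form and a two-pass oracle", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)
  p <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(p$r, 0.8)
  set.seed(42)
  for (k in 1:5) {
    x <- rnorm(30)
    y <- 0.4 * x + rnorm(30)
    got <- pearson(x, y)
    # naive two-pass covariance oracle
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_stat <- r_oracle * sqrt((length(x) - 2) / (1 - r_oracle^2))
    p_oracle <- 2 * pt(-abs(t_stat), length(x) - 2)
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    expect_equal(got$p, p_oracle, tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "degenerate")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("correlation report: self-correlation, null factors, invariance", {
  set.seed(43)
  ids <- sprintf("E%d", 1:12)
  rnd_matrix <- function() {
    v <- matrix(runif(144), 12)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    ditps3d:::new_similarity_matrix(ids, v, "tm_global", 1)
  }
  m <- rnd_matrix()
  rep1 <- correlation_report(list(f1 = m, f2 = m))
  expect_equal(rep1$r, 1)
  expect_equal(rep1$n, 66)
  # independent random factors: |r| < 0.3 in at least 19 of 20 runs
  # (105 pairs per run)
  ids15 <- sprintf("E%d", 1:15)
  small <- function() {
    v <- matrix(runif(225), 15)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    ditps3d:::new_similarity_matrix(ids15, v, "tm_global", 1)
  }
  hits <- sum(replicate(20, {
    abs(correlation_report(list(a = small(), b = small()))$r) < 0.3
  }))
  expect_gte(hits, 19)
  # invariance to enzyme input order
  m2 <- rnd_matrix()
  perm <- sample(12)
  mp <- ditps3d:::new_similarity_matrix(ids[perm],
                                        m2$values[perm, perm], "tm_global", 1)
  r1 <- correlation_report(list(a = m, b = m2))$r
  r2 <- correlation_report(list(a = m, b = mp))$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(correlation_report(list(a = m)), ">= 2")
})

test_that("Mann-Whitney comparisons: exact enumeration and summaries", {
  g <- group_compare(c(10, 11, 12), c(1, 2, 3))
  expect_equal(g$U, 9)
  expect_equal(g$p, 0.1)
  expect_equal(g$method, "exact enumeration")
  gid <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gt(gid$p, 0.9)
  q <- group_compare(c(1, 2, 3, 4, 5), c(2, 3, 4))$summary_same
  expect_equal(unname(q[c("q1", "median", "q3")]), c(2, 3, 4))
  expect_error(group_compare(c(1, 2), c(1, 2, 3)), ">= 3")
  # exact mode agrees with wilcox.test's exact p on tie-free groups <= 6+6
  set.seed(44)
  for (k in 1:5) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(seq(1, 100), n1)
    y <- sample(seq(101, 200), n2) / 2.7
    got <- group_compare(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # large tied groups fall back to the tie-corrected normal approximation
  x <- rep(1:8, 3); y <- rep(2:9, 3)
  got <- group_compare(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("pair partition uses set intersection on the key attribute", {
  recs <- list(
    enzyme_record("A", "MKL", substrate = "GGPP",
                  products = data.frame(name = "p1", smiles = "CCO",
                                        skeleton = "labdane", valid = TRUE)),
    enzyme_record("B", "MKL", substrate = "GGPP",
                  products = data.frame(name = "p2", smiles = "CCO",
                                        skeleton = "kaurane", valid = TRUE)),
    enzyme_record("C", "MKL", substrate = "ent-CPP",
                  products = data.frame(
                    name = c("p3", "p4"), smiles = c("CCO", "CCC"),
                    skeleton = c("labdane", "abietane"), valid = TRUE)))
  ps <- pair_partition(recs, "substrate")
  expect_true(any(ps$same[, 1] == "A" & ps$same[, 2] == "B"))
  expect_equal(nrow(ps$same), 1)
  expect_equal(nrow(ps$different), 2)
  pk <- pair_partition(recs, "product_skeleton")
  # {labdane} vs {kaurane} differ; {labdane} vs {labdane, abietane} intersect
  expect_true(any(pk$different[, 1] == "A" & pk$different[, 2] == "B"))
  expect_true(any(pk$same[, 1] == "A" & pk$same[, 2] == "C"))
  # records missing the key are excluded with a warning
  recs2 <- c(recs, list(enzyme_record("D", "MKL")))
  expect_warning(pd <- pair_partition(recs2, "substrate"), "D")
  expect_false(any(pd$same == "D") || any(pd$different == "D"))
})

test_that("partition values look up the matrix at partition pairs", {
  vals <- matrix(c(1, .9, .2, .9, 1, .3, .2, .3, 1), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- ditps3d:::new_similarity_matrix(c("A", "B", "C"), unname(vals),
                                       "tm_global", 1)
  part <- list(same = cbind(a = "A", b = "B"),
               different = rbind(c("A", "C"), c("B", "C")))
  pv <- partition_values(m, part)
  expect_equal(pv$same, 0.9)
  expect_equal(sort(pv$different), c(0.2, 0.3))
})
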