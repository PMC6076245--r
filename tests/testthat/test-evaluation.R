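test_that("precision and recall handle the degenerate empty cases", {
  u <- paste0("i", 1:10)
  expect_equal(unname(precisionRecall(u[1:4], u[1:3], u)),
               c(3 / 4, 1))
  expect_equal(unname(precisionRecall(u[1:3], u[1:3], u)), c(1, 1))
  pr <- precisionRecall(character(), u[1:3], u)
  expect_equal(as.numeric(pr), c(0, 0))
  expect_equal(attr(pr, "degenerate"), "precision")
})

test_that("AUROC matches hand cases and rejects degenerate rankings", {
  s <- c(a = 0.9, b = 0.8, c = 0.4, d = 0.1)
  expect_equal(aurocScore(s, c("a", "b")), 1)
  expect_equal(aurocScore(s, c("c", "d")), 0)
  expect_equal(aurocScore(s, c("a", "c")), 0.75)
  expect_error(aurocScore(s, names(s)), "positive and")
  # ties midranked: all-equal scores give 0.5
  expect_equal(aurocScore(c(a = 1, b = 1, c = 1), "a"), 0.5)
})

test_that("AUPR follows the non-interpolated step rule", {
  s <- c(a = 0.9, b = 0.8)
  expect_equal(auprScore(s, "a"), 1)
  expect_equal(auprScore(s, "b"), 0.5)
  expect_error(auprScore(s, character()), "positive")
  # random rankings converge to the positive fraction in expectation
  set.seed(31)
  n <- 200; pos <- paste0("x", 1:40)
  vals <- replicate(50, {
    sc <- setNames(runif(n), paste0("x", 1:n))
    auprScore(sc, pos)
  })
  expect_lt(abs(mean(vals) - 0.2), 0.03)
})

test_that("ranking metrics equal brute-force enumeration with ties", {
  set.seed(12)
  for (n in c(4, 6, 9)) {
    scores <- setNames(sample(seq(0, 1, 0.25), n, replace = TRUE),
                       paste0("t", seq_len(n)))
    for (rep in 1:20) {
      pos <- sample(names(scores), sample(n - 1, 1))
      expect_equal(aurocScore(scores, pos), oracleAuroc(scores, pos))
      expect_equal(auprScore(scores, pos), oracleAupr(scores, pos))
    }
  }
})

test_that("averaged metrics respect the axis and skip rules", {
  S <- rbind(cmpA = c(0.9, 0.1, 0.2), cmpB = c(0.1, 0.8, 0.3))
  colnames(S) <- c("ph1", "ph2", "ph3")
  gold <- data.frame(compound_id = c("cmpA", "cmpB"),
                     concept_id = c("ph1", "ph3"))
  m <- averagedMetrics(S, gold, axis = "compound")
  expect_equal(m$auroc_mean, mean(c(1, 0.5)))
  expect_equal(m$n_units, 2L)
  # phenotype axis ranks compounds within each phenotype; ph2 has no
  # positives and is skipped
  mp <- averagedMetrics(S, gold, axis = "phenotype")
  expect_equal(mp$n_units, 2L)
  expect_equal(mp$n_skipped, 1L)
  expect_equal(mp$auroc_mean, mean(c(1, 1)))
  # gold labels can restrict the positive set
  gold$label <- c("therapeutic", "candidate")
  mt <- averagedMetrics(S, gold, axis = "compound", labels = "therapeutic")
  expect_equal(mt$n_units, 1L)
  expect_error(averagedMetrics(S, gold[0, ], axis = "compound"),
               "no evaluable")
})

test_that("the F1 scan finds the separating cutoff", {
  S <- rbind(cmpA = c(0.9, 0.95, 0.1), cmpB = c(0.85, 0.05, 0.1))
  colnames(S) <- c("ph1", "ph2", "ph3")
  gold <- data.frame(compound_id = c("cmpA", "cmpA", "cmpB"),
                     concept_id = c("ph1", "ph2", "ph1"))
  scan <- f1Scan(S, gold)
  expect_equal(max(scan$table$f1), 1)
  expect_gt(scan$best, 0.1)
  expect_lte(scan$best, 0.85)
  # ties resolved toward the smaller threshold
  expect_equal(scan$best,
               min(scan$table$threshold[scan$table$f1 == 1]))
  # harmonic mean: P = R = 0.5 gives F1 = 0.5
  r <- scan$table[scan$table$precision == 0.5 &
                  scan$table$recall == 0.5, ]
  if (nrow(r)) expect_equal(r$f1, rep(0.5, nrow(r)))
})

test_that("rank correlation and Tanimoto overlap match set arithmetic", {
  a <- c(w = 4, x = 3, y = 2, z = 1)
  expect_equal(rankCorrelation(a, a), 1)
  expect_equal(rankCorrelation(a, -a), -1)
  b <- c(w = 3, x = 4, y = 1, z = 2)   # ranks (2,1,4,3) vs (1,2,3,4)
  expect_equal(rankCorrelation(a, b), 0.6)
  expect_error(rankCorrelation(a, c(q = 1)), "shared")

  s1 <- c(a = 5, b = 4, c = 3, d = 0.2, e = 0.1,
          f = 0.05, g = 0.04, h = 0.03, i = 0.02, j = 0.01)
  expect_equal(topFractionTanimoto(s1, s1, 0.3), 1)
  s2 <- s1[c(4:10, 1:3)]
  names(s2) <- names(s1)
  expect_equal(topFractionTanimoto(s1, s2, 0.3), 0)  # disjoint top sets
  s3 <- s1; s3["d"] <- 10               # top-3 {d,a,b} vs {a,b,c}
  expect_equal(topFractionTanimoto(s1, s3, 0.3), 2 / 4)
})

test_that("target closeness measures network distance with a permutation p", {
  path <- data.frame(from = c("a", "b"), to = c("b", "c"))
  res <- targetCloseness("a", "c", path, nPerm = 200, seed = 2)
  expect_equal(res$distance, 2)
  expect_equal(targetCloseness("c", "c", path, nPerm = 10)$distance, 0)
  # star with one far arm: coincident targets are maximally close
  edges <- data.frame(
    from = c("hub", "hub", "hub", "g1", "g2", "g3", "g4", "g5", "g6"),
    to   = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9"))
  res2 <- targetCloseness("g7", "g7", edges, nPerm = 500, seed = 4)
  expect_equal(res2$distance, 0)
  # zero distance can only be tied, never beaten
  expect_lte(res2$p_value, 1 / 10 + 0.2)
  expect_error(targetCloseness("nowhere", "c", path), "map onto")
})
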