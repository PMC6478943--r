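# fully independent re-execution of the kernel-rank random walk
gsvaOracle <- function(x, set, tau = 1) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(0, p, n)
  for (i in 1:p) {
    h <- sd(x[i, ]) / 4
    for (j in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + pnorm((x[i, j] - x[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  sapply(1:n, function(j) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- 1:p
    w <- abs(p / 2 - rk)
    inSet <- rownames(x) %in% set
    num <- 0; v <- numeric(p); cum <- 0
    wSum <- sum(w[inSet]^tau)
    for (pos in 1:p) {
      g <- ord[pos]
      cum <- cum + if (inSet[g]) w[g]^tau / wSum else -1 / (p - sum(inSet))
      v[pos] <- cum
    }
    max(c(0, v)) + min(c(0, v))
  })
}

test_that("gene-set scores match a hand-executed random walk", {
  set.seed(1)
  x <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  le <- makeLE(x)
  sets <- list(top = c("g1", "g2"), other = c("g3", "g4", "g5"))
  got <- gsvaScores(le, sets)
  expect_equal(unname(got["top", ]), gsvaOracle(x, sets$top),
               tolerance = 1e-12)
  expect_equal(unname(got["other", ]), gsvaOracle(x, sets$other),
               tolerance = 1e-12)
})

test_that("identical samples get identical scores and small sets are marked
          undefined", {
  set.seed(2)
  x <- matrix(rnorm(20 * 5), 20, 5)
  x[, 5] <- x[, 4]
  le <- makeLE(x)
  gn <- rownames(exprValues(le))
  sc <- gsvaScores(le, list(a = gn[1:6], tiny = gn[7]))
  expect_equal(sc["a", 4], sc["a", 5])
  expect_true(all(is.na(sc["tiny", ])))
})

test_that("complementary set scores have opposite signs", {
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(12 * 8), 12, 8)
    x[1:6, ] <- x[1:6, ] + rep(rnorm(8, 0, 2), each = 6)
    le <- makeLE(x)
    gn <- rownames(exprValues(le))
    sc <- gsvaScores(le, list(s = gn[1:6], comp = gn[7:12]))
    nz <- abs(sc["s", ]) > 0.05 & abs(sc["comp", ]) > 0.05
    expect_true(all(sign(sc["s", nz]) == -sign(sc["comp", nz])))
  }
})

test_that("raising in-set expression never lowers the set score", {
  set.seed(4)
  x <- matrix(rnorm(30 * 8), 30, 8)
  le <- makeLE(x)
  gn <- rownames(exprValues(le))
  set <- gn[1:8]
  s0 <- gsvaScores(le, list(s = set))["s", 1]
  x2 <- x
  x2[1:8, 1] <- x2[1:8, 1] + 1.5
  s1 <- gsvaScores(makeLE(x2), list(s = set))["s", 1]
  expect_gte(s1, s0)
})

test_that("batch adjustment is identity for one batch and preserves signal", {
  set.seed(5)
  x <- matrix(rnorm(40 * 30), 40, 30)
  md <- data.frame(batch = factor(rep(1, 30)))
  le <- makeLE(x, md)
  expect_equal(exprValues(combatAdjust(le)), exprValues(le))
  ## a strong mean shift is mostly removed
  md2 <- data.frame(batch = factor(rep(c(1, 2), each = 15)))
  x2 <- x; x2[, 16:30] <- x2[, 16:30] + 4
  adj <- exprValues(combatAdjust(makeLE(x2, md2)))
  resid <- rowMeans(adj[, 1:15]) - rowMeans(adj[, 16:30])
  expect_lt(max(abs(resid)), 0.2 * 4)
  ## batch-free data pass through essentially unchanged
  xb <- matrix(rnorm(40 * 100), 40, 100)
  mdb <- data.frame(batch = factor(rep(c(1, 2), each = 50)))
  adj0 <- exprValues(combatAdjust(makeLE(xb, mdb)))
  cors <- sapply(1:40, function(i) cor(adj0[i, ], xb[i, ]))
  expect_true(all(cors >= 0.99))
  expect_error(combatAdjust(makeLE(x, data.frame(
    batch = factor(c(1, rep(2, 29)))))), "2 samples")
})

test_that("with singleton subjects the mixed association is ordinary least
          squares", {
  set.seed(6)
  n <- 40
  Y <- matrix(rnorm(5 * n), 5, n)
  grp <- factor(rep(c("a", "b"), n / 2))
  subj <- paste0("s", 1:n)
  out <- mixedAssociation(Y, grp, subj)
  expect_equal(attr(out, "consensusRho"), 0)
  for (i in 1:5) {
    f <- summary(lm(Y[i, ] ~ grp))
    expect_equal(out$estimate[i], f$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(out$tstat[i], f$coefficients[2, 3], tolerance = 1e-8)
    expect_equal(out$pvalue[i], f$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("consensus correlation and tests agree with the established
          duplicate-correlation route", {
  skip_if_not_installed("limma")
  skip_if_not_installed("statmod")
  set.seed(7)
  nSub <- 40; m <- 3; n <- nSub * m
  subj <- rep(paste0("p", 1:nSub), each = m)
  u <- rnorm(nSub, 0, sqrt(0.3))
  Y <- matrix(u[rep(1:nSub, each = m)], 60, n, byrow = TRUE) +
    matrix(rnorm(60 * n, 0, sqrt(0.7)), 60, n)
  grp <- factor(sample(c("a", "b"), n, TRUE))
  out <- mixedAssociation(Y, grp, subj)
  X <- model.matrix(~ grp)
  dc <- limma::duplicateCorrelation(Y, X, block = subj)
  fit <- limma::lmFit(Y, X, block = subj,
                      correlation = dc$consensus.correlation)
  tRef <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  expect_equal(attr(out, "consensusRho"), dc$consensus.correlation,
               tolerance = 0.02)
  expect_gt(cor(out$tstat, tRef), 0.999)
  expect_lt(max(abs(out$estimate - fit$coefficients[, 2])), 0.02)
})

test_that("planted group effects are recovered", {
  set.seed(8)
  nSub <- 40; m <- 3; n <- nSub * m
  subj <- rep(paste0("p", 1:nSub), each = m)
  ests <- replicate(30, {
    u <- rnorm(nSub, 0, sqrt(0.3))
    y <- u[rep(1:nSub, each = m)] + rnorm(n, 0, sqrt(0.7))
    grp <- factor(rep(c("a", "b"), length.out = n))
    y[grp == "b"] <- y[grp == "b"] + 1
    mixedAssociation(rbind(y), grp, subj)$estimate
  })
  expect_equal(mean(ests), 1, tolerance = 0.1)
})

test_that("BH q-values follow the hand step-up and never drop below p", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  p <- rep(0.2, 6)
  expect_equal(bhFdr(p), p)
  set.seed(9)
  pr <- runif(50)
  expect_true(all(bhFdr(pr) >= pr))
  expect_identical(bhFdr(numeric(0)), numeric(0))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("rank AUC equals exhaustive pair counting and is monotone
          invariant", {
  s <- c(0.1, 0.4, 0.4, 0.7, 0.2, 0.9)
  lab <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  wins <- 0
  for (i in which(lab)) for (j in which(!lab))
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(rankAuc(s, lab), wins / (sum(lab) * sum(!lab)))
  expect_equal(rankAuc(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(rankAuc(exp(3 * s), lab), rankAuc(s, lab))
  set.seed(10)
  perms <- replicate(1000, rankAuc(s, sample(lab)))
  expect_equal(mean(perms), 0.5, tolerance = 0.02)
  expect_error(rankAuc(s, rep(TRUE, 6)), "non-empty")
})

test_that("Fisher exact p-values match enumeration oracles", {
  ## 2x2 diagonal table: two extreme tables of probability 1/252 each
  out <- fisherExact(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(out$pvalue, 2 / 252, tolerance = 1e-12)
  expect_identical(out$method, "exact")
  ## perfectly proportional table: everything is as extreme
  expect_equal(fisherExact(matrix(c(4, 2, 6, 3), 2, 2))$pvalue, 1)
  ## degenerate margin
  expect_identical(fisherExact(matrix(c(0, 0, 3, 4), 2, 2,
                                      byrow = TRUE))$method, "degenerate")
  ## 2x3 with total 20 vs exhaustive fixed-margin enumeration
  tab <- matrix(c(5, 2, 1, 2, 4, 6), 2, 3, byrow = TRUE)
  rs <- rowSums(tab); cs <- colSums(tab)
  logProb <- function(t) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(sum(t) + 1) - sum(lgamma(t + 1))
  p0 <- logProb(tab)
  tot <- 0
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
    cc <- rs[1] - a - b
    if (cc < 0 || cc > cs[3]) next
    t <- rbind(c(a, b, cc), c(cs[1] - a, cs[2] - b, cs[3] - cc))
    lp <- logProb(t)
    if (lp <= p0 + log(1 + 1e-7)) tot <- tot + exp(lp)
  }
  expect_equal(fisherExact(tab)$pvalue, tot, tolerance = 1e-10)
  ## large tables switch to seeded Monte-Carlo and are reproducible
  big <- matrix(c(200, 150, 120, 180), 2, 2)
  mc1 <- fisherExact(big, exactMax = 100, mcReplicates = 2e4, seed = 3)
  mc2 <- fisherExact(big, exactMax = 100, mcReplicates = 2e4, seed = 3)
  expect_identical(mc1$method, "monte-carlo")
  expect_equal(mc1$pvalue, mc2$pvalue)
})

test_that("pathway enrichment follows the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  module <- paste0("g", 1:10)
  paths <- list(same = module, none = paste0("g", 90:95),
                all = universe)
  out <- setEnrichment(module, paths, universe)
  ## P(all 10 drawn genes fall in the 10-gene pathway) = 1 / C(100, 10)
  expect_equal(out$pvalue[out$pathway == "same"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_gt(out$pvalue[out$pathway == "none"], 0.45)
  expect_equal(out$pvalue[out$pathway == "all"], 1)
  out2 <- setEnrichment(universe, paths, universe)
  expect_true(all(out2$pvalue == 1))
  skipped <- setEnrichment(module, list(off = c("zz1", "zz2")), universe)
  expect_equal(nrow(skipped), 0)
  expect_identical(attr(skipped, "skipped"), "off")
  expect_error(setEnrichment(c("g1", "nope"), paths, universe), "subset")
})
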