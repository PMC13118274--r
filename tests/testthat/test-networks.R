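# Partial correlations, tail-quantile edge selection, and the annotation
# partitioning ratio.

test_that("partial correlations invert simple analytic structures", {
  ids <- c("a", "b", "c")
  # identity in, identity out
  I3 <- diag(3); dimnames(I3) <- list(ids, ids)
  expect_equal(unname(partialCorrelations(I3)), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # chain: corr(a, c) fully explained by b  =>  partial(a, c) = 0
  r1 <- 0.7; r2 <- 0.6
  C <- matrix(c(1, r1, r1 * r2,
                r1, 1, r2,
                r1 * r2, r2, 1), 3, 3, dimnames = list(ids, ids))
  pc <- partialCorrelations(C)
  expect_equal(pc["a", "c"], 0, tolerance = 1e-10)
  expect_equal(attr(pc, "shrinkage"), 0)
  # 2x2: the partial correlation IS the correlation (no conditioning set)
  C2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
               dimnames = list(ids[1:2], ids[1:2]))
  expect_equal(partialCorrelations(C2)["a", "b"], 0.4, tolerance = 1e-10)
})

test_that("singular matrices are shrunk just enough to invert", {
  set.seed(2)
  # 30 features, 5 samples: rank-deficient correlation matrix
  m <- matrix(rnorm(150), 5, 30)
  C <- cor(m)
  dimnames(C) <- list(paste0("f", 1:30), paste0("f", 1:30))
  pc <- partialCorrelations(C)
  lam <- attr(pc, "shrinkage")
  expect_gt(lam, 0)
  expect_lt(lam, 1)
  expect_true(all(is.finite(pc)))
  expect_equal(pc, t(pc), tolerance = 1e-12)
  # NA cells are imputed with a message
  C[2, 3] <- C[3, 2] <- NA
  expect_message(partialCorrelations(C), "imputed")
})

test_that("edge selection matches a sort-based oracle", {
  set.seed(6)
  k <- 46                                # 1035 off-diagonal values
  vals <- rnorm(k * (k - 1) / 2, 0, 0.2)
  pm <- matrix(0, k, k, dimnames = list(paste0("f", 1:k), paste0("f", 1:k)))
  pm[upper.tri(pm)] <- vals
  pm <- pm + t(pm); diag(pm) <- 1
  el <- selectEdges(pm, tailFraction = 0.025)
  lo <- quantile(vals, 0.025); hi <- quantile(vals, 0.975)
  oracle <- vals[(vals <= lo | vals >= hi) & vals > 0]
  expect_equal(sort(el$weight), sort(oracle), tolerance = 1e-12)
  # both tails selected pre-trim: at most 2 * 2.5% of entries
  expect_lte(sum(vals <= lo | vals >= hi), ceiling(0.05 * length(vals)) + 1)
  # symmetric-about-zero values: roughly half the selection survives the
  # positivity trim
  expect_gt(nrow(el), 0.3 * sum(vals <= lo | vals >= hi))
  expect_lt(nrow(el), 0.7 * sum(vals <= lo | vals >= hi))
  # canonical ordering, no self edges
  expect_true(all(el$feature_a < el$feature_b))
})

test_that("partition ratio reproduces analytic graph values", {
  # one annotation holding every endpoint: Q = 1
  edges <- data.frame(feature_a = c("a", "b"), feature_b = c("b", "c"),
                      weight = c(2, 3))
  expect_equal(partitionRatio(edges, list(A = c("a", "b", "c")))$q_ratio, 1)
  # two disjoint annotations, all edges within: Q = 1
  edges2 <- data.frame(feature_a = c("a", "c"), feature_b = c("b", "d"),
                       weight = c(1, 5))
  expect_equal(
    partitionRatio(edges2, list(A = c("a", "b"), B = c("c", "d")))$q_ratio,
    1)
  # two disjoint annotations, all weight crossing: Q = -2
  edges3 <- data.frame(feature_a = c("a", "a"), feature_b = c("c", "d"),
                       weight = c(1, 2))
  expect_equal(
    partitionRatio(edges3, list(A = c("a", "b"), B = c("c", "d")))$q_ratio,
    -2)
  # crossing edges counted once under the alternative convention
  pr1 <- partitionRatio(edges3, list(A = c("a", "b"), B = c("c", "d")),
                        crossCounting = "once")
  expect_equal(pr1$q_ratio, -1)
})

test_that("Q is invariant to uniform weight rescaling", {
  set.seed(9)
  edges <- data.frame(
    feature_a = paste0("f", sample(1:10, 20, replace = TRUE)),
    feature_b = paste0("g", sample(1:10, 20, replace = TRUE)),
    weight = runif(20, 0.1, 2))
  ann <- list(A = c(paste0("f", 1:5), paste0("g", 1:3)),
              B = c(paste0("f", 6:10), paste0("g", 4:10)))
  q1 <- partitionRatio(edges, ann)$q_ratio
  edges$weight <- edges$weight * 37.5
  expect_equal(partitionRatio(edges, ann)$q_ratio, q1, tolerance = 1e-12)
})

test_that("no annotated edge yields an undefined Q", {
  edges <- data.frame(feature_a = "a", feature_b = "b", weight = 1)
  expect_warning(pr <- partitionRatio(edges, list(A = "zzz")), "undefined")
  expect_true(is.na(pr$q_ratio))
})

test_that("block-structured data partitions better than permuted labels", {
  set.seed(123)
  nBlock <- 4; perBlock <- 10; nSamp <- 20
  wins <- 0L; reps <- 100L
  for (r in seq_len(reps)) {
    z <- matrix(rnorm(nBlock * nSamp), nBlock, nSamp)
    m <- do.call(rbind, lapply(seq_len(nBlock), function(b) {
      t(sapply(seq_len(perBlock), function(f)
        z[b, ] + rnorm(nSamp, 0, 0.4)))
    }))
    rownames(m) <- paste0("f", seq_len(nBlock * perBlock))
    colnames(m) <- paste0("s", seq_len(nSamp))
    cs <- iciKtMatrix(m, axis = "features")
    pc <- partialCorrelations(tauMatrix(cs))
    el <- selectEdges(pc, 0.025)
    if (nrow(el) == 0) next
    ann <- split(rownames(m), rep(seq_len(nBlock), each = perBlock))
    names(ann) <- paste0("block", seq_len(nBlock))
    qTrue <- partitionRatio(el, ann)$q_ratio
    annPerm <- lapply(ann, function(x) sample(rownames(m), length(x)))
    qPerm <- partitionRatio(el, annPerm)$q_ratio
    if (!is.na(qTrue) && !is.na(qPerm) && qTrue > qPerm) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * reps)
})

test_that("GMT files round trip", {
  ann <- list(setA = c("f1", "f2", "f3"), setB = c("f2", "f9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(ann, path, descriptions = c("first", "second"))
  back <- readGmt(path)
  expect_equal(back, ann, ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["setA"]], "first")
  # malformed lines are rejected
  writeLines("onlyid\tdesc", path)
  expect_error(readGmt(path), "without members")
})
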