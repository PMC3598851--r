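# hand-built raw score matrix for arithmetic oracles
raw_fixture <- function(bits, hits = bits > 0) {
  diag(hits) <- TRUE
  dendroblast:::new_raw_scores(bits, hits, rownames(bits))
}

test_that("missing-score repair uses s_min/2 and never enlarges hit sets", {
  bits <- matrix(c(100, 40, 0,
                   38, 90, 50,
                   0, 52, 80), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m <- raw_fixture(bits)
  r <- fill_missing_scores(m)
  expect_equal(r$bits["a", "c"], 40 / 2)   # s_min(a) = 40
  expect_equal(r$bits["c", "a"], 52 / 2)   # s_min(c) = 52
  # non-zero entries untouched, hits and n_A unchanged by repair
  expect_equal(r$bits["b", "a"], 38)
  expect_identical(r$hits, m$hits)
  expect_identical(n_hits(r), n_hits(m))

  # a matrix with no zeros is returned unchanged
  m2 <- raw_fixture(matrix(c(10, 5, 4, 9), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  expect_identical(fill_missing_scores(m2)$bits, m2$bits)
})

test_that("overlap weight follows the Dice form and errors on no overlap", {
  h <- matrix(FALSE, 7, 7, dimnames = rep(list(paste0("s", 1:7)), 2))
  b <- matrix(0, 7, 7, dimnames = dimnames(h))
  # s1 and s2 hit the same 7 sequences: perfect overlap -> weight 1
  h[1, ] <- TRUE; h[2, ] <- TRUE; diag(h) <- TRUE
  b[h] <- 50
  m <- raw_fixture(b, h)
  expect_equal(overlap_weight(m, "s1", "s2"), 1)

  # n_A = 10, n_B = 30, n_AB = 10 -> 2*10/(10+30) = 0.5
  ids <- paste0("q", 1:30)
  h2 <- matrix(FALSE, 30, 30, dimnames = list(ids, ids))
  h2["q1", 1:10] <- TRUE
  h2["q2", 1:30] <- TRUE
  diag(h2) <- TRUE
  b2 <- matrix(0, 30, 30, dimnames = dimnames(h2)); b2[h2] <- 50
  m2 <- raw_fixture(b2, h2)
  expect_equal(overlap_weight(m2, "q1", "q2"), 0.5)
  expect_equal(overlap_weight(m2, "q1", "q2", form = "max"), 10 / 30)

  # disjoint hit profiles: inference cannot be completed
  h3 <- diag(TRUE, 4); dimnames(h3) <- rep(list(letters[1:4]), 2)
  b3 <- diag(50, 4); dimnames(b3) <- dimnames(h3)
  m3 <- raw_fixture(b3, h3)
  expect_error(overlap_weight(m3, "a", "b"), "cannot be completed")
  expect_error(similarity(m3), "cannot be completed")
})

test_that("similarity symmetrises weighted normalised scores", {
  # score(a,b)=60, score(b,a)=55, s_max(a)=100, s_max(b)=90, weights 1:
  # S = (60/100 + 55/90)/2
  bits <- matrix(c(100, 60, 55, 90), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  S <- similarity(raw_fixture(bits))
  expect_equal(S["a", "b"], (0.60 + 55 / 90) / 2)
  expect_equal(S["a", "b"], S["b", "a"])
  expect_equal(diag(unclass(S)), c(a = 1, b = 1))
})

test_that("identical mutually-top-scoring pair reaches S = 1 and d = 0", {
  fam <- duplicated_pair_family(seed = 4)
  m <- compute_scores_internal(fam)
  S <- similarity(fill_missing_scores(m))
  first <- names(fam)[1L]
  expect_identical(S[first, "twin"], 1)
  d <- to_distance(S)
  expect_identical(d[first, "twin"], 0)
})

test_that("negative-log transform: boundary values and monotonicity", {
  bits <- matrix(c(10, 8, 7, 9), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  S <- similarity(raw_fixture(bits))
  d <- to_distance(S)
  expect_equal(diag(d), c(a = 0, b = 0))

  # S = exp(-1) maps to exactly 1; larger S maps to smaller d
  S2 <- structure(matrix(c(1, exp(-1), exp(-1), 1), 2, 2,
                         dimnames = dimnames(bits)),
                  class = c("sim_matrix", "matrix", "array"))
  expect_equal(to_distance(S2)["a", "b"], 1)
  svals <- sort(stats::runif(50, 0.01, 1))
  dvals <- -log(svals)
  expect_true(all(diff(dvals) < 0))
})

test_that("end-to-end distance matrices are valid and order-invariant", {
  fam <- simulate_family(n_taxa = 8, length = 150, seed = 9)
  d <- blast_distances(fam$seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(is.finite(d)) && all(d >= 0))

  # permuting input order permutes, but does not change, the matrix
  perm <- rev(seq_along(fam$seqs))
  d2 <- blast_distances(fam$seqs[perm])
  expect_equal(d2[rownames(d), colnames(d)], d)

  # triangle inequality on a gap-free simulated family: report violations
  n <- nrow(d); viol <- 0L; total <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    total <- total + 3L
    viol <- viol + sum(d[i, j] > d[i, k] + d[k, j] + 1e-12,
                       d[i, k] > d[i, j] + d[j, k] + 1e-12,
                       d[j, k] > d[j, i] + d[i, k] + 1e-12)
  }
  testthat::expect_lte(viol, total)   # recorded, not asserted strict
  message(sprintf("triangle-inequality violations: %d of %d triples",
                  viol, total))
})

test_that("PHYLIP square distance matrices round-trip", {
  d <- blast_distances(simulate_family(n_taxa = 5, length = 80,
                                       seed = 6)$seqs)
  f <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_dist(d, f)
  back <- read_phylip_dist(f)
  expect_equal(back, d, tolerance = 1e-8)
  expect_error(read_phylip_dist(textConnection("x")), "malformed|cannot")
})
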