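test_that("bipartition extraction counts non-trivial splits", {
  tr8 <- rand_tree(8, seed = 1)
  expect_length(bipartitions(tr8), 5L)          # n - 3
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_length(bipartitions(star), 0L)
  quartet <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(bipartitions(quartet), "c,d")
  # matches the independent edge-removal oracle
  expect_setequal(bipartitions(tr8), oracle_bipartitions(tr8))
})

test_that("majority-rule consensus keeps strictly-majority splits only", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  trees51 <- c(rep(list(t1), 51), rep(list(t2), 49))
  cons51 <- majority_consensus(trees51)
  expect_true(all(bipartitions(t1) %in% bipartitions(cons51)))
  expect_false(any(bipartitions(t2) %in% bipartitions(cons51)))

  # exactly 50% is excluded; two incompatible 50% splits -> star
  trees50 <- c(rep(list(t1), 50), rep(list(t2), 50))
  expect_length(bipartitions(majority_consensus(trees50)), 0L)

  # all replicates identical -> that tree
  same <- majority_consensus(rep(list(t1), 10))
  expect_setequal(bipartitions(same), bipartitions(t1))

  t3 <- ape::read.tree(text = "((a,b),(c,z),e);")
  expect_error(majority_consensus(list(t1, t3)), "leaf set")
})

test_that("consensus splits are pairwise compatible and majority-supported", {
  base <- rand_tree(7, seed = 401)
  trees <- c(rep(list(base), 13),
             lapply(1:8, function(i) rand_tree(7, seed = 410 + i)))
  cons <- majority_consensus(trees)
  keys <- bipartitions(cons)
  tips <- sort(trees[[1]]$tip.label)
  if (length(keys) > 1)
    for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys))
      expect_true(splits_compatible(keys[i], keys[j], tips))
  # every retained split occurs in > half of the input trees
  counts <- table(unlist(lapply(trees, bipartitions)))
  expect_true(all(counts[keys] > length(trees) / 2))
})

test_that("tree comparison yields TP/FP/FN, RF, precision and recall", {
  tr <- rand_tree(8, seed = 3)
  same <- compare_trees(tr, tr)
  expect_identical(c(same$fp, same$fn, same$rf), c(0L, 0L, 0L))
  expect_identical(c(same$precision, same$recall), c(1, 1))

  # star inferred against a binary 10-leaf reference
  ref <- rand_tree(10, seed = 4)
  star <- ape::read.tree(
    text = paste0("(", paste(ref$tip.label, collapse = ","), ");"))
  cmp <- compare_trees(star, ref)
  expect_identical(c(cmp$tp, cmp$fp, cmp$fn), c(0L, 0L, 7L))
  expect_identical(cmp$recall, 0)
  expect_identical(cmp$precision, 1)
  expect_false(cmp$precision_defined)

  expect_error(compare_trees(tr, ref), "leaf set")
})

test_that("RF agrees with brute-force split sets and with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(1)
  for (s in 1:25) {
    t1 <- rand_tree(sample(5:12, 1), seed = 500 + s)
    t2 <- dendroblast:::with_seed(600 + s, {
      ape::rtopology(ape::Ntip(t1), rooted = FALSE)
    })
    t2$tip.label <- sample(t1$tip.label)
    cmp <- compare_trees(t1, t2)
    b1 <- oracle_bipartitions(t1); b2 <- oracle_bipartitions(t2)
    expect_identical(cmp$rf, length(setdiff(b1, b2)) +
                              length(setdiff(b2, b1)))
    expect_identical(cmp$rf, cmp$fp + cmp$fn)
    expect_identical(cmp$rf, as.integer(phangorn::RF.dist(t1, t2)))
    expect_lte(cmp$rf, 2L * (ape::Ntip(t1) - 3L))
  }
})

test_that("RF behaves as a metric on binary trees", {
  for (s in 1:10) {
    n <- 8
    ts <- lapply(1:3, function(i) rand_tree(n, seed = 700 + 3 * s + i))
    r12 <- compare_trees(ts[[1]], ts[[2]])$rf
    r13 <- compare_trees(ts[[1]], ts[[3]])$rf
    r23 <- compare_trees(ts[[2]], ts[[3]])$rf
    expect_identical(compare_trees(ts[[1]], ts[[1]])$rf, 0L)
    expect_identical(r12, compare_trees(ts[[2]], ts[[1]])$rf)
    expect_lte(r13, r12 + r23)
  }
})

test_that("polynomial RF-curve fit finds the analytic minimum", {
  theta <- seq(0, 5, by = 0.5)
  rf <- 3 * (theta - 2.2)^2 + 40        # convex parabola, vertex at 2.2
  out <- fit_rf_curve(theta, rf, degree = 2)
  expect_equal(out$theta_opt, 2.2, tolerance = 1e-4)
  out4 <- fit_rf_curve(theta, rf, degree = 4)
  expect_equal(out4$theta_opt, 2.2, tolerance = 1e-3)

  expect_warning(flat <- fit_rf_curve(theta, rep(10, length(theta))),
                 "flat")
  expect_identical(flat$theta_opt, 0)
  expect_error(fit_rf_curve(0:3, 1:4, degree = 4), "grid points")
})

test_that("theta calibration runs the full pipeline over a grid", {
  fams <- lapply(1:2, function(i)
    simulate_family(n_taxa = 5, length = 90, branch_mean = 0.4,
                    seed = 800 + i))
  # a flat mean-RF curve (perfect recovery at every theta) legitimately
  # triggers the documented tie-rule warning on easy families
  suppressWarnings(
    cal <- calibrate_theta(fams, theta_grid = c(0, 1, 2, 3.5),
                           replicates = 5, poly_degree = 2, seed = 13))
  expect_s3_class(cal, "theta_calibration")
  expect_identical(nrow(cal$table), 4L)
  expect_equal(cal$table$mean_rf,
               cal$table$mean_fp + cal$table$mean_fn)
  expect_gte(cal$theta_opt, 0)
  expect_lte(cal$theta_opt, 3.5)
  expect_error(calibrate_theta(fams, theta_grid = c(0, 1),
                               poly_degree = 4), "grid points")
})
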