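test_that("Newick reading preserves tips, heights and round-trips", {
  tr <- toy_tree()
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tree_height(tr), 2)
  rt <- read_newick(write_newick(tr))
  expect_equal(mrca_depth_matrix(rt), mrca_depth_matrix(tr))
  one <- read_newick("(A:1);")
  expect_equal(one$tip.label, "A")
  expect_error(read_newick("((A:1,B:1):1;"), "unbalanced")
  expect_error(read_newick("((A,B),C);"), "branch length")
})

test_that("pruning preserves path lengths and validates labels", {
  tr <- toy_tree()
  pr <- prune_tree(tr, c("A", "C"))
  expect_equal(patristic_matrix(pr)["A", "C"], 4)
  full <- prune_tree(tr, tr$tip.label)
  expect_equal(patristic_matrix(full), patristic_matrix(tr))
  expect_error(prune_tree(tr, "A"), "at least 2")
  expect_error(prune_tree(tr, c("A", "Z")), "Z")
})

test_that("pruning commutes with the MRCA-depth matrix on random trees", {
  for (seed in 1:6) {
    tr <- rand_coal_tree(8, seed)
    keep <- sample(tr$tip.label, 4)
    sub <- mrca_depth_matrix(prune_tree(tr, keep))
    full <- mrca_depth_matrix(tr)[sub |> rownames(), colnames(sub)]
    expect_equal(sub, full, tolerance = 1e-12)
  }
})

test_that("MRCA-depth matrix holds shared path lengths", {
  C <- mrca_depth_matrix(toy_tree())
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["C", "C"], 2)
  expect_true(isSymmetric(C))
  # ultrametric tree: constant diagonal and d_ij = 2 (depth - t_ij)
  tr <- rand_coal_tree(10, 3)
  C <- mrca_depth_matrix(tr)
  expect_equal(max(diag(C)) - min(diag(C)), 0, tolerance = 1e-8)
  D <- patristic_matrix(tr)
  expect_equal(D, 2 * (max(diag(C)) - C), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("star-like covariance: tips diverging at the root share nothing", {
  tr <- read_newick("(A:1.5,B:1.5,C:1.5);")
  C <- mrca_depth_matrix(tr)
  expect_equal(C, diag(1.5, 3), ignore_attr = TRUE)
})

test_that("OU covariance matches its closed form and its Brownian limit", {
  tr <- toy_tree()  # ultrametric: all depths 2
  V <- ou_cov(tr, alpha = 1, sigma2 = 2)
  # depth-1 shared history at alpha 1, sigma2 2: diagonal = 1 - exp(-4)
  expect_equal(unname(diag(V)), rep(1 - exp(-4), 3), tolerance = 1e-12)
  # tips diverging at the root are uncorrelated
  expect_equal(V["A", "C"], 0)
  # sisters: t = 1, d = 2
  expect_equal(V["A", "B"], exp(-2) * (1 - exp(-2)), tolerance = 1e-12)
  # alpha -> 0 recovers sigma2 * shared path lengths
  expect_equal(ou_cov(tr, 1e-8, sigma2 = 3), 3 * mrca_depth_matrix(tr),
               tolerance = 1e-5)
  expect_error(ou_cov(tr, 0), "alpha")
  expect_warning(ou_cov(read_newick("((A:1,B:2):1,C:2);"), 1), "ultrametric")
})

test_that("diagonal OU entry matches the fixed-root variance at depth 1", {
  tr <- read_newick("(A:1,B:1);")
  V <- ou_cov(tr, alpha = 1, sigma2 = 2)
  expect_equal(V["A", "A"], 1 - exp(-2), tolerance = 1e-12)
})

test_that("lambda transform scales only the off-diagonal", {
  C <- mrca_depth_matrix(rand_coal_tree(6, 5))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  off <- row(C) != col(C)
  expect_equal(half[off], C[off] / 2)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
})

test_that("transformed structures stay positive definite on random trees", {
  for (seed in 1:5) {
    tr <- rand_coal_tree(12, seed + 20)
    C <- mrca_depth_matrix(tr)
    expect_no_error(chol(lambda_transform(C, 0.7)))
    expect_no_error(chol(ou_cov(tr, alpha = 5 / tree_height(tr))))
  }
})

test_that("strong selection decorrelates root-split pairs", {
  tr <- rand_coal_tree(20, 9)
  h <- tree_height(tr)
  V <- ou_cov(tr, alpha = 20 / h)
  R <- stats::cov2cor(V)
  tmat <- mrca_depth_matrix(tr)
  split_at_root <- tmat < 1e-12 & row(tmat) != col(tmat)
  expect_true(all(abs(R[split_at_root]) < exp(-2)))
})

test_that("species matching normalizes underscores and reports mismatches", {
  tr <- toy_tree()
  tr$tip.label <- c("Larus_argentatus", "Larus_fuscus", "Pagophila_eburnea")
  d <- tibble::tibble(species = c("Larus argentatus", "Pagophila eburnea", "Larus fuscus"),
                      y = 1:3)
  m <- larimorph:::match_species_to_tree(d, tr)
  expect_equal(gsub(" ", "_", m$data$species), m$tree$tip.label)
  bad <- tibble::tibble(species = c("Larus argentatus", "Larus unknownii"), y = 1:2)
  expect_error(larimorph:::match_species_to_tree(bad, tr), "Larus unknownii")
})
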