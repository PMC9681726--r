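# Shared fixtures, all generated in code.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# random ultrametric tree with seeded labels sp001..spN
rand_coal_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# standard synthetic study: 50-species tree + derived morphology table
fixture_study <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      tree <- simulate_tree(50, 0.21, seed = seed)
      tab <- suppressMessages(simulate_species_table(tree, generator_config(seed = seed)))
      cache <<- list(tree = tree,
                     morph = derive_morphology(tab),
                     config = generator_config(seed = seed))
    }
    cache
  }
})

mantle_formula <- mantle_kgs ~ wing_loading_std + abs_latitude

# dense multivariate-normal log-density, used as an independent likelihood oracle
dmvn_log <- function(y, mu, V) {
  U <- chol(V)
  z <- forwardsolve(t(U), y - mu)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

# cached BM and OU fits on the synthetic study, shared across files
adequacy_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- fixture_study()
      d <- prepare_analysis(st$morph)
      cache <<- list(
        bm = pgls_fit(d, st$tree, mantle_formula, "BM"),
        ou = pgls_fit(d, st$tree, mantle_formula, "OU"))
    }
    cache
  }
})
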