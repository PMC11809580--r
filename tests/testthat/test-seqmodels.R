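jc <- subst_model("JC69")

test_that("JC69 corrected distances follow the closed form", {
  ## 10 sites, 3 mismatches: p = 0.3
  aln <- aln_from_strings(c(X = "aaaaaaaaaa", Y = "cccaaaaaaa"))
  D <- corrected_distance_matrix(aln, jc)
  expect_equal(D["X", "Y"], -0.75 * log(1 - 4 / 3 * 0.3), tolerance = 1e-6)
  expect_equal(D["X", "Y"], 0.383119, tolerance = 1e-5)
  same <- aln_from_strings(c(X = "acgtacgt", Y = "acgtacgt"))
  expect_equal(corrected_distance_matrix(same, jc)["X", "Y"], 0)
})

test_that("saturated pairs are capped with a warning, empty overlap errors", {
  sat <- aln_from_strings(c(X = "aaaacccc", Y = "ccccaaaa"))  # p = 1
  expect_warning(D <- corrected_distance_matrix(sat, jc), "capped")
  expect_equal(D["X", "Y"], 10)
  gap <- aln_from_strings(c(X = "aa--", Y = "--cc", Z = "aacc"))
  expect_error(corrected_distance_matrix(gap, jc), "X / Y")
})

test_that("model strings parse case-insensitively with +F and +G parts", {
  m <- parse_model_string("gtr{1.2,2.3,0.8,1.1,3.0,1.0}+f{0.3,0.2,0.25,0.25}+g{0.5}")
  expect_equal(m$family, "GTR")
  expect_equal(unname(m$freqs["a"]), 0.3)
  expect_equal(m$gamma_shape, 0.5)
  expect_equal(m$n_cat, 4L)
  expect_equal(parse_model_string("JC69")$family, "JC69")
  expect_equal(parse_model_string("K2P{4}")$rates[["ag"]], 4)
  expect_error(parse_model_string("GTR{1,2}"), "6 exchangeability")
  expect_error(parse_model_string("JC+Q{1}"), "unrecognized")
})

test_that("discrete-gamma category rates have mean one", {
  for (alpha in c(0.2, 0.7, 2)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
})

test_that("rate matrix rows sum to zero and the mean rate is one", {
  m <- subst_model("GTR",
                   rates = c(ac = 1.2, ag = 2.3, at = 0.8, cg = 1.1,
                             ct = 3.0, gt = 1.0),
                   freqs = c(a = 0.3, c = 0.2, g = 0.25, t = 0.25))
  expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
  P <- transition_probs(m, 0.37)[[1]]
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("site log-likelihoods match reference cases", {
  tr <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- aln_from_strings(c(A = "a", B = "a", C = "a", D = "a"))
  expect_equal(site_log_likelihoods(tr, aln, jc)$site[1], log(1 / 4),
               tolerance = 1e-12, ignore_attr = TRUE)
  gaps <- aln_from_strings(c(A = "-", B = "-", C = "-", D = "-"))
  expect_equal(site_log_likelihoods(tr, aln = gaps, jc)$site[1], 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(site_log_likelihoods(tr, aln_from_strings(c(A = "a", B = "a",
                                                           C = "a")), jc),
               "without a sequence")
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  mg <- subst_model("GTR",
                    rates = c(ac = 1.2, ag = 2.3, at = 0.8, cg = 1.1,
                              ct = 3.0, gt = 1.0),
                    freqs = c(a = 0.3, c = 0.2, g = 0.25, t = 0.25),
                    gamma_shape = 0.7)
  tr4 <- parse_newick("((A:0.1,B:0.23):0.31,(C:0.12,D:0.4):0.05);")
  aln4 <- aln_from_strings(c(A = "acgtg", B = "accta", C = "gcgta",
                             D = "acnt-"))
  expect_lt(max(abs(site_log_likelihoods(tr4, aln4, mg)$site -
                      enum_site_loglik(tr4, aln4, mg))), 1e-10)
  tr5 <- parse_newick(
    "(((A:0.2,B:0.1):0.15,C:0.3):0.12,D:0.25,E:0.08);")
  aln5 <- aln_from_strings(c(A = "acg", B = "acg", C = "gta", D = "g-a",
                             E = "gya"))
  expect_lt(max(abs(site_log_likelihoods(tr5, aln5, mg)$site -
                      enum_site_loglik(tr5, aln5, mg))), 1e-10)
})

test_that("total log-likelihood is invariant under re-rooting", {
  for (seed in 1:3) {
    tr <- sample_tree(6, seed = seed)
    aln <- simulate_alignment(tr, jc, 200, seed = seed)
    ref <- tree_loglik(tr, aln, jc)
    for (tip in sample(tr$tip.label, 2)) {
      rr <- as_unrooted_tree(ape::root(tr, tip, resolve.root = TRUE))
      expect_equal(tree_loglik(rr, aln, jc), ref, tolerance = 1e-8)
    }
  }
})

test_that("total log-likelihood matches phangorn on a fixture", {
  skip_if_not_installed("phangorn")
  tr <- sample_tree(8, seed = 4)
  aln <- simulate_alignment(tr, jc, 300, seed = 4)
  fit <- phangorn::pml(tr, phangorn::phyDat(as.character(aln)))
  expect_equal(tree_loglik(tr, aln, jc), as.numeric(stats::logLik(fit)),
               tolerance = 1e-6)
})

test_that("corrected distances converge to patristic distances with length", {
  tr <- sample_tree(6, seed = 11, branch_mean = 0.08)
  pat <- ape::cophenetic.phylo(tr)
  err <- vapply(c(500, 5000, 50000), function(L) {
    aln <- simulate_alignment(tr, jc, L, seed = 11)
    D <- corrected_distance_matrix(aln, jc)
    stats::median(abs(D - pat[rownames(D), colnames(D)])[upper.tri(D)])
  }, numeric(1))
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.02)
})

test_that("branch-length optimization improves towards the generating value", {
  tr <- sample_tree(6, seed = 21)
  aln <- simulate_alignment(tr, jc, 2000, seed = 21)
  f <- function(scale) {
    t2 <- tr
    t2$edge.length <- tr$edge.length * scale
    tree_loglik(t2, aln, jc)
  }
  ## coarse monotonicity away from the generating lengths
  expect_gt(f(1), f(4))
  expect_gt(f(1), f(0.25))
})

test_that("alignment deduplication keeps first occurrences byte-exactly", {
  aln <- aln_from_strings(c(a1 = "acgt", a2 = "acgt", b = "ggga",
                            c1 = "ttta", d = "acga", e = "cccc"))
  out <- dedupe_alignment(aln, min_taxa = 5)
  expect_equal(rownames(out), c("a1", "b", "c1", "d", "e"))
  expect_equal(attr(out, "removed"), c(a2 = "a1"))
  expect_error(dedupe_alignment(aln, min_taxa = 6), "need at least 6")
})
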