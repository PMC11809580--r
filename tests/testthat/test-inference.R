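k2p <- subst_model("K2P", kappa = 2)

test_that("NJ recovers topology and branch lengths from additive matrices", {
  tr <- parse_newick("((A:1,B:2):1,(C:3,D:4));")
  njt <- nj_tree(ape::cophenetic.phylo(tr))
  expect_equal(rf_distance(njt, tr), 0L)
  expect_equal(sort(njt$edge.length), sort(tr$edge.length),
               tolerance = 1e-10)
  for (seed in 1:6) {
    truth <- sample_tree(sample(5:12, 1), seed = seed + 300)
    njt <- nj_tree(ape::cophenetic.phylo(truth))
    expect_equal(rf_distance(njt, truth), 0L)
    expect_equal(sort(njt$edge.length), sort(truth$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("NJ three-taxon lengths follow the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  njt <- nj_tree(D)
  lens <- setNames(njt$edge.length, njt$tip.label[njt$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ rejects asymmetric or non-finite matrices", {
  D <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(nj_tree(D), "asymmetric")
  D2 <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(nj_tree(D2))
})

test_that("ML search is a strict hill climb from the NJ start", {
  sc <- make_scenario("clean", n = 8, L = 500, seed = 31)
  start <- nj_tree(corrected_distance_matrix(sc$aln, k2p))
  start_lnl <- optimize_branch_lengths(start, sc$aln, k2p)$loglik
  res <- ml_search(sc$aln, k2p)
  expect_gte(res$loglik, start_lnl - 1e-6)
})

test_that("ML search keeps a start at the generating topology", {
  sc <- make_scenario("clean", n = 8, L = 2000, seed = 32)
  res <- ml_search(sc$aln, k2p, start = sc$tree)
  expect_equal(rf_distance(res$tree, sc$tree), 0L)
  bl <- optimize_branch_lengths(sc$tree, sc$aln, k2p)
  expect_equal(res$loglik, bl$loglik, tolerance = 1e-4)
})

test_that("ML search recovers strong-signal topologies", {
  hits <- 0L
  for (seed in 1:5) {
    sc <- make_scenario("clean", n = 10, L = 1500, seed = 40 + seed)
    res <- ml_search(sc$aln, k2p)
    hits <- hits + (rf_distance(res$tree, sc$tree) == 0L)
  }
  expect_gte(hits, 4L)
})

test_that("bootstrap supports are percentages, deterministic, and saturate
           on a clean synapomorphy", {
  sc <- make_scenario("clean", n = 8, L = 400, seed = 51)
  cfg <- inference_config("nj", k2p, bootstrap = 30, seed = 5)
  tr <- nj_tree(corrected_distance_matrix(sc$aln, k2p))
  b1 <- bootstrap_supports(sc$aln, tr, cfg)
  sup <- edge_supports(b1)[internal_edges(b1)]
  expect_true(all(sup >= 0 & sup <= 100))
  b2 <- bootstrap_supports(sc$aln, tr, cfg)
  expect_identical(edge_supports(b1), edge_supports(b2))

  ## every site the same clean synapomorphy for AB|CD
  syn <- aln_from_strings(c(A = strrep("a", 30), B = strrep("a", 30),
                            C = strrep("g", 30), D = strrep("g", 30)))
  suppressWarnings({
    trs <- nj_tree(corrected_distance_matrix(syn, k2p))
    bs <- bootstrap_supports(syn, trs, inference_config("nj", k2p,
                                                        bootstrap = 20,
                                                        seed = 2))
  })
  expect_equal(edge_supports(bs)[internal_edges(bs)], 100,
               ignore_attr = TRUE)
  expect_error(bootstrap_supports(syn, trs,
                                  inference_config("nj", k2p, bootstrap = 0)),
               ">= 1")
})

test_that("supports are low when sequences carry no tree signal", {
  set.seed(99)
  rnd <- aln_from_strings(setNames(
    vapply(1:8, function(i) paste(sample(c("a", "c", "g", "t"), 300,
                                         TRUE), collapse = ""),
           character(1)), sprintf("t%02d", 1:8)))
  suppressWarnings({   # saturated pairs are expected for tree-free data
    tr <- nj_tree(corrected_distance_matrix(rnd, k2p))
    bs <- bootstrap_supports(rnd, tr, inference_config("nj", k2p,
                                                       bootstrap = 50,
                                                       seed = 3))
  })
  expect_lt(mean(edge_supports(bs)[internal_edges(bs)]), 90)
})

test_that("noisier distances do not improve NJ accuracy on average", {
  rf_at_noise <- function(eps) {
    mean(vapply(1:20, function(seed) {
      truth <- sample_tree(12, seed = seed + 700)
      D <- ape::cophenetic.phylo(truth)
      set.seed(seed)
      noise <- matrix(rnorm(length(D), sd = eps), nrow(D))
      noise <- (noise + t(noise)) / 2
      diag(noise) <- 0
      Dn <- pmax(D + noise, 0)
      diag(Dn) <- 0
      rf_distance(nj_tree(Dn), truth)
    }, numeric(1)))
  }
  expect_lte(rf_at_noise(0.001), rf_at_noise(0.2))
})

test_that("the external backend reads trees from the documented layout", {
  dir <- withr::local_tempdir()
  tr <- sample_tree(6, seed = 61)
  write_newick(tr, file.path(dir, "full.nw"))
  red <- prune_taxon(tr, "t03")
  write_newick(red, file.path(dir, "t03.nw"))
  cfg <- inference_config("external", k2p, external_dir = dir)
  expect_equal(rf_distance(infer_tree(NULL, cfg), tr), 0L)
  expect_equal(rf_distance(infer_tree(NULL, cfg, taxon_removed = "t03"),
                           red), 0L)
  expect_error(infer_tree(NULL, cfg, taxon_removed = "t04"), "not found")
})
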