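k2p <- subst_model("K2P", kappa = 2)

fake_placement <- function(tree, edges, lwr = NULL, pendant = 0.1,
                           distal = NULL) {
  if (is.null(lwr)) lwr <- rep(1 / length(edges), length(edges))
  if (is.null(distal)) distal <- tree$edge.length[edges] / 2
  structure(
    data.frame(edge = edges, lwr = lwr, loglik = 0,
               pendant_length = pendant, distal_length = distal),
    class = c("placement_set", "data.frame"), tree = tree, taxon = "Q")
}

edge_by_split <- function(tree, block) {
  sp <- tree_splits(tree)
  as.integer(names(sp)[sp == canonical_split(block, tree$tip.label)])
}

test_that("insertion-distance stats follow the hand-computed star case", {
  star <- parse_newick("((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);")
  single <- fake_placement(star, leaf_edge(star, "A"), lwr = 1)
  expect_equal(insertion_distance_stats(single, star),
               list(insertion_dist_mean = 0, insertion_dist_sd = 0))
  ## A and B pendant edges are adjacent (distance 1); the edge-pair
  ## diameter of this tree is 3 (e.g. A-pendant to C-pendant)
  two <- fake_placement(star, c(leaf_edge(star, "A"), leaf_edge(star, "B")))
  got <- insertion_distance_stats(two, star)
  expect_equal(got$insertion_dist_mean, 1 / 3)
  expect_equal(got$insertion_dist_sd, 0)
  three <- fake_placement(star, c(leaf_edge(star, "A"), leaf_edge(star, "B"),
                                  leaf_edge(star, "C")))
  perm <- fake_placement(star, c(leaf_edge(star, "C"), leaf_edge(star, "A"),
                                 leaf_edge(star, "B")))
  expect_equal(insertion_distance_stats(three, star),
               insertion_distance_stats(perm, star))
})

test_that("branch features are normalized by the augmented-tree mean length", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  e <- internal_edges(tr)[1]
  b <- tr$edge.length[e]     # 2: the two root edges merge on unrooting
  pl <- fake_placement(tr, e, lwr = 1, pendant = 0.5, distal = 0.3 * b)
  tplus <- best_placement_tree(tr, pl, "Q")
  bf <- branch_features(tr, pl, tplus)
  expect_equal(bf$norm_dist_nearest_node, 0.3)
  mean_bl <- mean(tplus$edge.length)
  expect_equal(bf$insertion_branch_length, b / mean_bl)
  expect_equal(bf$pendant_length, 0.5 / mean_bl)
  mid <- fake_placement(tr, e, lwr = 1, pendant = 0.5, distal = b / 2)
  expect_equal(branch_features(tr, mid, tplus)$norm_dist_nearest_node, 0.5)
})

test_that("branch and height features are scale invariant", {
  tr <- parse_newick("((A:1,B:2):1.5,(C:1,D:0.5):1);")
  e <- internal_edges(tr)[1]
  for (scale in c(1, 7)) {
    t2 <- tr
    t2$edge.length <- tr$edge.length * scale
    pl <- fake_placement(t2, e, lwr = 1, pendant = 0.4 * scale,
                         distal = 0.3 * scale)
    tplus <- best_placement_tree(t2, pl, "Q")
    bf <- branch_features(t2, pl, tplus)
    if (scale == 1) {
      ref <- bf
      ref_h <- insertion_height(tplus, "Q")
    } else {
      expect_equal(bf, ref, tolerance = 1e-10)
      expect_equal(insertion_height(tplus, "Q"), ref_h, tolerance = 1e-10)
    }
  }
})

test_that("support features use population SD and the self-distance rule", {
  star <- parse_newick("((A,B),(C,D),(E,F));")
  sup <- rep(NA_real_, nrow(star$edge))
  eAB <- edge_by_split(star, c("A", "B"))
  eCD <- edge_by_split(star, c("C", "D"))
  eEF <- edge_by_split(star, c("E", "F"))
  sup[c(eAB, eCD, eEF)] <- c(100, 60, 80)
  tr <- set_edge_supports(star, sup)
  pl <- fake_placement(tr, eCD, lwr = 1)
  sf <- support_features(tr, pl)
  expect_equal(sf$bootstrap_mean, 80)
  expect_equal(sf$bootstrap_sd, sqrt(mean((c(100, 60, 80) - 80)^2)))
  expect_equal(round(sf$bootstrap_sd, 2), 16.33)
  expect_equal(sf$dist_low_bootstrap_edge, 0)   # insertion edge is low
  sup[c(eAB, eCD, eEF)] <- 100
  tr100 <- set_edge_supports(star, sup)
  expect_equal(support_features(tr100, pl)$dist_low_bootstrap_edge, 1)
  expect_error(support_features(star, pl), "no support")
})

test_that("sequence distance ratios are near one under clock-like data", {
  sc <- make_scenario("clean", n = 8, L = 20000, seed = 181)
  s <- sc$focal
  tr <- prune_taxon(sc$tree, s)
  pl <- placement_candidates(tr, sc$aln, s, k2p)
  tplus <- best_placement_tree(tr, pl, s)
  sq <- sequence_distance_features(sc$aln, s, tr, pl, tplus, k2p)
  expect_equal(sq$distance_ratio_mean, 1, tolerance = 0.1)
  expect_lt(sq$distance_ratio_sd, 0.05)
  expect_equal(sq$ratio_diff_closest_mean, 1, tolerance = 0.1)
})

test_that("a mosaic taxon inflates the distance-ratio SD", {
  wins <- 0L
  for (seed in 1:3) {
    sc <- make_scenario("mosaic_taxon", n = 10, L = 1200,
                        seed = 190 + seed)
    cfg <- run_config(backend = "nj", bootstrap = 20, au_B = 200,
                      seed = seed, significance = FALSE)
    res <- suppressWarnings(run_leave_one_out(sc$aln, cfg))
    f <- res$features
    focal_sd <- f$distance_ratio_sd[f$taxon == sc$focal]
    others <- f$distance_ratio_sd[f$taxon != sc$focal]
    wins <- wins + (length(focal_sd) == 1 && !is.na(focal_sd) &&
                      focal_sd > stats::median(others, na.rm = TRUE))
  }
  expect_gte(wins, 2L)
})

test_that("the sibling ratio is one for a symmetric distance construction", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  taxa <- c("A", "B", "C", "D", "Q")
  D <- matrix(1, 5, 5, dimnames = list(taxa, taxa))
  diag(D) <- 0
  e <- edge_by_split(tr, c("C", "D"))
  pl <- fake_placement(tr, e, lwr = 1)
  ## C = {C, D} (far side from reference leaf A); the candidate sisters at
  ## the other endpoint are {A, B} and each singleton -- with all
  ## distances equal, as/aC is exactly 1
  expect_equal(taxonstab:::insertion_sibling_ratio(NULL, "Q", tr, pl, D), 1)
})

test_that("insertion height measures the path to the nearest leaf", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  eA <- leaf_edge(tr, "A")
  pl <- fake_placement(tr, eA, lwr = 1, pendant = 0.3, distal = 0.2)
  tplus <- best_placement_tree(tr, pl, "Q")
  nd <- ape::dist.nodes(tplus)
  tips <- match(setdiff(tplus$tip.label, "Q"), tplus$tip.label)
  diam <- max(nd[tips, tips])
  expect_equal(insertion_height(tplus, "Q"), 0.2 / (diam / 2))
  at_node <- fake_placement(tr, eA, lwr = 1, pendant = 0.3, distal = 0)
  tplus0 <- best_placement_tree(tr, at_node, "Q")
  expect_equal(insertion_height(tplus0, "Q"), 0)
  for (seed in 1:4) {
    sc <- sample_tree(8, seed = 200 + seed)
    e <- sample(nrow(sc$edge), 1)
    plr <- fake_placement(sc, e, lwr = 1, pendant = 0.1,
                          distal = sc$edge.length[e] / 3)
    h <- insertion_height(best_placement_tree(sc, plr, "Q"), "Q")
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
})

test_that("NJ TII is zero for additive distances and bounded in general", {
  tr <- sample_tree(8, seed = 211)
  aln <- simulate_alignment(tr, k2p, 100, seed = 211)
  D <- ape::cophenetic.phylo(tr)
  for (s in tr$tip.label[1:4]) {
    expect_equal(nj_tii_feature(aln, s, k2p, D = D), 0)
  }
  small <- aln[1:4, ]
  expect_true(is.na(nj_tii_feature(small, rownames(small)[1], k2p)))
  sc <- make_scenario("low_support_region", n = 8, L = 400, seed = 212)
  v <- nj_tii_feature(sc$aln, sc$focal, k2p)
  expect_gte(v, 0)
  expect_lte(v, 1)
})

test_that("assembled feature rows carry the placement-derived fields", {
  sc <- make_scenario("clean", n = 8, L = 400, seed = 221)
  s <- sc$focal
  alns <- drop_taxon(sc$aln, s)
  cfg <- inference_config("nj", k2p, bootstrap = 20, seed = 1)
  tr <- bootstrap_supports(alns, infer_tree(alns, cfg), cfg)
  pl <- placement_candidates(tr, sc$aln, s, k2p)
  tplus <- best_placement_tree(tr, pl, s)
  row <- assemble_features(sc$aln, s, tr, pl, tplus, k2p,
                           pythia_difficulty = 0.42)
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_insertion_locations, nrow(pl))
  expect_equal(row$lwr, pl$lwr[1])
  expect_equal(row$pythia_difficulty, 0.42)
  row2 <- assemble_features(sc$aln, s, tr, pl, tplus, k2p)
  expect_true(is.na(row2$pythia_difficulty))
  expect_equal(row[setdiff(names(row), "pythia_difficulty")],
               row2[setdiff(names(row2), "pythia_difficulty")])
})
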