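#' Sample a random unrooted binary tree
#'
#' Uniform topology over labeled unrooted binary trees (each leaf is
#' attached in turn to a uniformly chosen edge, which makes all
#' (2n-5)!! topologies equally likely); branch lengths are drawn i.i.d.
#' from an exponential distribution.
#'
#' @param n number of leaves (>= 4).
#' @param seed integer seed.
#' @param branch_mean mean branch length in substitutions/site
#'   (default 0.1).
#' @param labels optional leaf labels (default `t01`, `t02`, ...).
#' @return an unrooted binary `phylo`.
#' @export
sample_tree <- function(n, seed = 1L, branch_mean = 0.1, labels = NULL) {
  if (n < 4L) stop("need at least 4 leaves")
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  set.seed(seed)
  tree <- structure(list(
    edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3, 2, byrow = TRUE),
    edge.length = rep(1, 3), Nnode = 1L, tip.label = labels[1:3]
  ), class = "phylo")
  for (k in 4:n) {
    e <- sample.int(nrow(tree$edge), 1L)
    tree <- attach_taxon_at(tree, e, labels[k],
                            distal = tree$edge.length[e] / 2, pendant = 1)
  }
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / branch_mean)
  validate_unrooted_tree(tree)
  tree
}

#' Simulate an alignment along a tree
#'
#' Root states drawn from the model's stationary frequencies, then
#' evolved edge-wise by the transition probabilities; with discrete
#' gamma, each site draws its rate category independently. Columns are
#' independent.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a [subst_model].
#' @param L number of sites (>= 1).
#' @param seed integer seed.
#' @return a `DNAbin` matrix, taxa in tree tip order.
#' @export
simulate_alignment <- function(tree, model, L, seed = 1L) {
  stopifnot(L >= 1)
  set.seed(seed)
  states <- simulate_states(tree, model, L)
  n <- length(tree$tip.label)
  chars <- matrix(c("a", "c", "g", "t")[states[seq_len(n), ]], nrow = n)
  rownames(chars) <- tree$tip.label
  ape::as.DNAbin(chars)
}

## integer state matrix (all nodes x sites); categories resampled per site
simulate_states <- function(tree, model, L) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  k <- model$n_cat
  cats <- if (k > 1) sample.int(k, L, replace = TRUE) else rep(1L, L)
  states <- matrix(NA_integer_, nn, L)
  po <- reorder(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1]
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$freqs)
  E <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  len <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1]; ch <- E[i, 2]
    P <- transition_probs(model, len[i])
    states[ch, ] <- evolve_states(states[p, ], cats, P)
  }
  states
}

evolve_states <- function(parent, cats, P) {
  out <- integer(length(parent))
  for (cc in unique(cats)) {
    for (x in 1:4) {
      idx <- which(cats == cc & parent == x)
      if (length(idx)) {
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = P[[cc]][x, ])
      }
    }
  }
  out
}

#' Generate a labelled stability scenario
#'
#' Produces a tree with strong internal signal, an alignment simulated on
#' it, and a focal taxon, optionally engineering one of the instability
#' regimes the stability analysis targets:
#' \describe{
#'   \item{clean}{long internal branches (>= 0.05), no tampering;
#'     leave-one-out inferences are expected to be stable.}
#'   \item{low_support_region}{a contiguous pair of internal edges shrunk
#'     to 1e-3 expected substitutions, creating a region of low bootstrap
#'     support where topology changes concentrate.}
#'   \item{mosaic_taxon}{the focal taxon's sequence is re-simulated in two
#'     halves, each conditionally evolved from a different donor leaf, so
#'     the taxon's evolution is non-treelike while remaining under the
#'     substitution model marginally.}
#'   \item{long_pendant}{the focal taxon's pendant branch is multiplied
#'     by `pendant_factor` before simulating.}
#' }
#'
#' @param kind scenario kind (see above).
#' @param n taxa count.
#' @param L sites.
#' @param model a [subst_model].
#' @param seed integer seed (fully determines the output).
#' @param pendant_factor multiplier for `long_pendant` (default 10).
#' @param mosaic_branch branch length from donor to focal for
#'   `mosaic_taxon` halves (default 0.05).
#' @return list with `aln`, `tree` (generating tree), `focal`, `kind`,
#'   and kind-specific fields (`shrunk_edges`, `donors`, `breakpoint`).
#' @export
make_scenario <- function(kind = c("clean", "low_support_region",
                                   "mosaic_taxon", "long_pendant"),
                          n = 16L, L = 1000L,
                          model = subst_model("K2P", kappa = 2),
                          seed = 1L, pendant_factor = 10,
                          mosaic_branch = 0.05) {
  kind <- match.arg(kind)
  set.seed(seed)
  tree <- sample_tree(n, seed = seed)
  ## strong internal signal: internal edges at least 0.05
  ie <- internal_edges(tree)
  tree$edge.length[ie] <- 0.05 + rexp(length(ie), rate = 1 / 0.05)
  tree$edge.length[-ie] <- 0.02 + rexp(nrow(tree$edge) - length(ie),
                                       rate = 1 / 0.08)
  focal <- sample(tree$tip.label, 1L)
  out <- list(kind = kind, tree = tree, focal = focal, seed = seed)

  if (kind == "low_support_region") {
    ## grow a contiguous region covering about half the internal edges
    ## and collapse it to near-zero length, so the local resolution
    ## carries no signal and leave-one-out outcomes flip there
    hops <- node_hop_matrix(tree)
    region_size <- max(3L, ceiling(length(ie) / 2))
    e1 <- sample(ie, 1L)
    shrunk <- e1
    while (length(shrunk) < region_size) {
      nbr <- setdiff(ie[vapply(ie, function(e) {
        min(vapply(shrunk, function(g)
          edge_node_distance(tree, g, e, hops), integer(1)))
      }, integer(1)) == 1L], shrunk)
      if (!length(nbr)) break
      shrunk <- c(shrunk, nbr[1])
    }
    tree$edge.length[shrunk] <- 1e-3
    out$tree <- tree
    out$shrunk_edges <- shrunk
  }
  if (kind == "long_pendant") {
    pe <- leaf_edge(tree, focal)
    tree$edge.length[pe] <- tree$edge.length[pe] * pendant_factor
    out$tree <- tree
    out$pendant_factor <- pendant_factor
  }

  aln_seed <- seed + 10000L
  if (kind == "mosaic_taxon") {
    pd <- ape::cophenetic.phylo(tree)
    others <- setdiff(tree$tip.label, focal)
    pdo <- pd[others, others]
    far <- which(pdo == max(pdo), arr.ind = TRUE)[1, ]
    donors <- c(others[far[1]], others[far[2]])
    set.seed(aln_seed)
    states <- simulate_states(tree, model, L)
    bp <- floor(L / 2)
    P <- transition_probs(model, mosaic_branch)
    cats <- if (model$n_cat > 1) sample.int(model$n_cat, L, replace = TRUE)
            else rep(1L, L)
    d1 <- states[match(donors[1], tree$tip.label), ]
    d2 <- states[match(donors[2], tree$tip.label), ]
    foc <- c(evolve_states(d1[seq_len(bp)], cats[seq_len(bp)], P),
             evolve_states(d2[(bp + 1):L], cats[(bp + 1):L], P))
    states[match(focal, tree$tip.label), ] <- foc
    chars <- matrix(c("a", "c", "g", "t")[states[seq_len(n), ]], nrow = n)
    rownames(chars) <- tree$tip.label
    out$aln <- ape::as.DNAbin(chars)
    out$donors <- donors
    out$breakpoint <- bp
  } else {
    out$aln <- simulate_alignment(out$tree, model, L, seed = aln_seed)
  }
  out
}

#' Write a scenario to a directory (FASTA, true tree, manifest)
#' @param scenario output of [make_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(scenario$aln, file.path(dir, "alignment.fasta"))
  write_newick(scenario$tree, file.path(dir, "true_tree.nw"))
  manifest <- c(
    paste0("kind: ", scenario$kind),
    paste0("focal: ", scenario$focal),
    paste0("seed: ", scenario$seed),
    paste0("n_taxa: ", length(scenario$tree$tip.label)),
    paste0("n_sites: ", ncol(scenario$aln))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Build a labelled feature table from a suite of synthetic scenarios
#'
#' Generates a mixture of scenarios (by default 40 alignments, 8-16 taxa,
#' 500-2000 sites, about half with engineered instability), pushes each
#' through the full leave-one-out pipeline, and returns one labelled row
#' per analyzed taxon: the feature battery plus the targets `unstable`
#' (TII nonzero), `significant`, `tii_norm`, `disruption_radius`, and the
#' source-alignment group key.
#'
#' @param seed integer seed; fully determines the table.
#' @param n_alignments number of synthetic alignments (default 40).
#' @param backend inference backend for the pipeline (default `"nj"`).
#' @param bootstrap bootstrap replicates per inferred tree (default 50).
#' @param au_B AU/SH replicates per scale (default 500).
#' @param n_range,L_range ranges for taxa count and sites.
#' @return data frame (one row per taxon) with attribute `failed` listing
#'   taxa whose rows could not be computed.
#' @export
fixture_suite <- function(seed = 1L, n_alignments = 40L, backend = "nj",
                          bootstrap = 50L, au_B = 500L,
                          n_range = c(8L, 16L), L_range = c(500L, 2000L)) {
  set.seed(seed)
  kinds <- sample(c(rep("clean", ceiling(n_alignments / 2)),
                    sample(c("low_support_region", "mosaic_taxon",
                             "long_pendant"),
                           floor(n_alignments / 2), replace = TRUE,
                           prob = c(0.4, 0.4, 0.2))))
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  ns <- resample(seq(n_range[1], n_range[2]), n_alignments)
  Ls <- resample(seq(L_range[1], L_range[2]), n_alignments)
  rows <- vector("list", n_alignments)
  for (i in seq_len(n_alignments)) {
    sc <- make_scenario(kinds[i], n = ns[i], L = Ls[i],
                        seed = seed * 1000L + i)
    cfg <- run_config(backend = backend, bootstrap = bootstrap,
                      au_B = au_B, seed = seed * 1000L + i)
    res <- run_leave_one_out(sc$aln, cfg)
    tab <- merge(res$features, res$stability[, c("taxon", "tii", "tii_norm",
                                                 "disruption_radius",
                                                 "significant_instability")],
                 by = "taxon")
    tab$unstable <- as.integer(tab$tii != 0)
    tab$significant <- as.integer(tab$significant_instability)
    tab$significant_instability <- NULL
    tab$alignment <- sprintf("aln%03d_%s", i, kinds[i])
    rows[[i]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
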