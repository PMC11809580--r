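#' Inference backend configuration
#'
#' @param backend `"nj"` (neighbor joining on model-corrected distances),
#'   `"ml"` (NNI hill-climbing maximum-likelihood search), or
#'   `"external"` (read externally inferred trees from a directory
#'   containing `full.nw` plus one `<taxon>.nw` per reduced tree).
#' @param model a [subst_model].
#' @param bootstrap number of nonparametric bootstrap replicates B for
#'   support values; 0 disables supports.
#' @param seed integer seed fixing all stochastic behavior.
#' @param external_dir directory of Newick files when `backend = "external"`.
#' @return an `inference_config` object.
#' @export
inference_config <- function(backend = c("nj", "ml", "external"),
                             model = subst_model("JC69"),
                             bootstrap = 0L, seed = 1L,
                             external_dir = NULL) {
  backend <- match.arg(backend)
  if (backend == "external" && is.null(external_dir)) {
    stop("external backend requires external_dir")
  }
  structure(list(backend = backend, model = model,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 external_dir = external_dir),
            class = "inference_config")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj]); negative branch lengths are
#' clamped to 0. Recovers topology and branch lengths exactly from
#' additive matrices.
#'
#' @param D symmetric finite matrix with taxa dimnames (>= 3 taxa).
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("non-finite distance matrix")
  if (max(abs(D - t(D))) > 1e-12) stop("asymmetric distance matrix")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  as_unrooted_tree(tr)
}

## sanitize a taxon label into a file name (external backend layout)
sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Infer a tree with the configured backend
#'
#' For the `external` backend, reads `full.nw` (or
#' `<sanitized taxon>.nw` when `taxon_removed` is given) from the
#' configured directory, enabling use of externally inferred trees
#' without invoking the external tool.
#'
#' @param aln a `DNAbin` matrix (ignored by the external backend).
#' @param cfg an [inference_config].
#' @param taxon_removed the left-out taxon for reduced inferences.
#' @return an unrooted `phylo`.
#' @export
infer_tree <- function(aln, cfg, taxon_removed = NULL) {
  if (cfg$backend == "external") {
    fn <- if (is.null(taxon_removed)) "full.nw"
          else paste0(sanitize_label(taxon_removed), ".nw")
    path <- file.path(cfg$external_dir, fn)
    if (!file.exists(path)) stop("external tree not found: ", path)
    tr <- parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
    return(tr)
  }
  if (cfg$backend == "nj") {
    return(nj_tree(corrected_distance_matrix(aln, cfg$model)))
  }
  ml_search(aln, cfg$model, seed = cfg$seed)$tree
}

## the two NNI rearrangements around internal edge e, as rewired trees
nni_neighbors_edge <- function(tree, e) {
  n <- length(tree$tip.label)
  p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
  if (ch <= n) return(list())
  rows_c <- which(tree$edge[, 1] == ch)
  rows_p <- setdiff(which(tree$edge[, 1] == p), e)
  if (!length(rows_p)) return(list())
  s1 <- rows_p[1]
  lapply(rows_c, function(r) {
    t2 <- tree
    t2$edge[r, 1] <- p
    t2$edge[s1, 1] <- ch
    t2$node.label <- NULL
    reorder(t2, "cladewise")
  })
}

#' NNI hill-climbing maximum-likelihood tree search
#'
#' Desk-scale ML inference: starting from a neighbor-joining tree (or a
#' supplied start tree), alternates full branch-length optimization with
#' sweeps over all nearest-neighbor interchanges, accepting only strictly
#' improving rearrangements. Deterministic given the inputs.
#'
#' @param aln a `DNAbin` matrix.
#' @param model a [subst_model].
#' @param start optional starting `phylo` on the alignment's taxa;
#'   default is the NJ tree on model-corrected distances.
#' @param seed integer seed (kept for interface symmetry; the search
#'   itself is deterministic).
#' @param tol log-likelihood convergence tolerance.
#' @param max_rounds maximum number of NNI sweeps.
#' @return list with `tree` and `loglik`.
#' @export
ml_search <- function(aln, model, start = NULL, seed = 1L, tol = 1e-6,
                      max_rounds = 50L) {
  if (is.null(start)) {
    start <- nj_tree(corrected_distance_matrix(aln, model))
  }
  tree <- start
  tree$node.label <- NULL
  opt <- optimize_branch_lengths(tree, aln, model, tol = tol)
  tree <- opt$tree
  cur <- opt$loglik
  if (!is.finite(cur)) stop("non-finite starting likelihood")
  pat <- aln_patterns(aln, tree$tip.label)

  for (round in seq_len(max_rounds)) {
    cands <- list()
    scores <- numeric(0)
    for (e in internal_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      for (t2 in nni_neighbors_edge(tree, e)) {
        ## quick score: optimize only the central edge of the swap
        fp <- full_pass(t2, pat, model)
        f <- edge_loglik_fun(fp, model, pat, ch)
        qs <- optimize(f, interval = c(1e-8, 10), maximum = TRUE,
                       tol = tol)$objective
        cands <- c(cands, list(list(tree = t2, edge_child = ch)))
        scores <- c(scores, qs)
      }
    }
    if (!length(cands)) break
    improved <- FALSE
    ## the central-edge score is a lower bound on the fully optimized
    ## score, so the top candidates are re-scored with a branch sweep
    for (idx in head(order(scores, decreasing = TRUE), 3L)) {
      refit <- optimize_branch_lengths(cands[[idx]]$tree, aln, model,
                                       tol = tol, max_sweeps = 2L)
      if (refit$loglik > cur + tol) {
        tree <- refit$tree
        cur <- refit$loglik
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  opt <- optimize_branch_lengths(tree, aln, model, tol = tol)
  list(tree = opt$tree, loglik = opt$loglik)
}

#' Nonparametric bootstrap supports for a tree
#'
#' Standard Felsenstein bootstrap: B site-resampled alignments are each
#' re-inferred with the configured backend, and every internal edge of
#' `tree` is annotated with the percentage of replicate trees containing
#' its split. Deterministic given the config seed.
#'
#' @param aln a `DNAbin` matrix.
#' @param tree a `phylo` on the alignment's taxa.
#' @param cfg an [inference_config] with `bootstrap >= 1`.
#' @return the tree with supports attached (see [edge_supports]).
#' @export
bootstrap_supports <- function(aln, tree, cfg) {
  if (cfg$bootstrap < 1L) stop("bootstrap replicates must be >= 1")
  aln <- aln[tree$tip.label, , drop = FALSE]
  keys <- tree_splits(tree)
  counts <- setNames(numeric(length(keys)), names(keys))
  set.seed(cfg$seed)
  n_ok <- 0L
  for (b in seq_len(cfg$bootstrap)) {
    idx <- sample.int(ncol(aln), replace = TRUE)
    rep_tree <- tryCatch(infer_tree(aln[, idx, drop = FALSE], cfg),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    n_ok <- n_ok + 1L
    counts <- counts + (keys %in% tree_splits(rep_tree))
  }
  if (n_ok == 0L) stop("all bootstrap replicates failed")
  sup <- rep(NA_real_, nrow(tree$edge))
  sup[as.integer(names(keys))] <- 100 * counts / n_ok
  set_edge_supports(tree, sup)
}
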