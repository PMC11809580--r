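## Likelihood engine: Felsenstein pruning over unique site patterns, with
## per-edge two-sided partial vectors so that single-branch and attachment
## likelihoods are cheap. Partials are kept per rate category; categories
## are averaged with equal weights. Gaps and IUPAC ambiguities enter as
## partial state vectors (all-ones for missing data). Trees at this
## package's scale (tens of taxa) stay far from double underflow, so no
## per-node rescaling is applied.

## down partials D[[node]][[cat]] (4 x patterns), messages M[[child]] =
## P_e %*% D[[child]], rooted at the phylo root node for traversal only
down_pass <- function(tree, pat, model) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  k <- model$n_cat
  po <- reorder(tree, "postorder")
  E <- po$edge
  len <- po$edge.length
  D <- vector("list", nn)
  M <- vector("list", nn)      # message through the edge above each node
  Pm <- vector("list", nn)     # P matrices of the edge above each node
  for (i in seq_len(n)) D[[i]] <- rep(list(pat$tips[[tree$tip.label[i]]]), k)
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1]; ch <- E[i, 2]
    P <- transition_probs(model, len[i])
    Pm[[ch]] <- P
    msg <- lapply(seq_len(k), function(cc) P[[cc]] %*% D[[ch]][[cc]])
    M[[ch]] <- msg
    if (is.null(D[[p]])) {
      D[[p]] <- msg
    } else {
      D[[p]] <- lapply(seq_len(k), function(cc) D[[p]][[cc]] * msg[[cc]])
    }
  }
  root <- E[nrow(E), 1]
  list(D = D, M = M, P = Pm, E = E, root = root, k = k)
}

## add up-vectors: U[[node]] such that site L = colSums(U[[v]] * D[[v]]),
## and W[[child]] = the complement-side vector at the parent of the edge
## above `child` (L = colSums((t(P_e) %*% W) * D[[child]]))
full_pass <- function(tree, pat, model) {
  dp <- down_pass(tree, pat, model)
  k <- dp$k
  E <- dp$E
  nn <- length(dp$D)
  children <- vector("list", nn)
  for (i in seq_len(nrow(E))) {
    children[[E[i, 1]]] <- c(children[[E[i, 1]]], E[i, 2])
  }
  U <- vector("list", nn)
  W <- vector("list", nn)
  np <- pat$n_patterns
  U[[dp$root]] <- rep(list(matrix(model$freqs, 4, np)), k)
  for (i in rev(seq_len(nrow(E)))) {     # preorder
    p <- E[i, 1]; ch <- E[i, 2]
    sibs <- setdiff(children[[p]], ch)
    w <- lapply(seq_len(k), function(cc) {
      v <- U[[p]][[cc]]
      for (s in sibs) v <- v * dp$M[[s]][[cc]]
      v
    })
    W[[ch]] <- w
    U[[ch]] <- lapply(seq_len(k), function(cc) {
      crossprod(dp$P[[ch]][[cc]], w[[cc]])
    })
  }
  c(dp, list(U = U, W = W))
}

## pattern-level log-likelihoods from root partials
pattern_loglik <- function(fp, model) {
  k <- fp$k
  L <- 0
  for (cc in seq_len(k)) {
    L <- L + colSums(model$freqs * fp$D[[fp$root]][[cc]])
  }
  log(L / k)
}

#' Per-site log-likelihoods of a tree
#'
#' Felsenstein pruning under the supplied model; rate categories are
#' averaged with equal weights. Gap/ambiguity characters contribute
#' partial state vectors (an all-gap column has likelihood 1).
#'
#' @param tree a `phylo` whose leaves all have sequences in `aln`.
#' @param aln a `DNAbin` matrix (may contain extra taxa).
#' @param model a [subst_model].
#' @return list with `total` (log-likelihood) and `site` (per-site vector).
#' @export
site_log_likelihoods <- function(tree, aln, model) {
  pat <- aln_patterns(aln, tree$tip.label)
  fp <- down_pass(tree, pat, model)
  lnl <- pattern_loglik(fp, model)
  site <- lnl[pat$pattern_index]
  list(total = sum(site), site = site)
}

#' Total log-likelihood of a tree
#' @inheritParams site_log_likelihoods
#' @return a number.
#' @export
tree_loglik <- function(tree, aln, model) {
  site_log_likelihoods(tree, aln, model)$total
}

## log-likelihood of the tree as a function of one branch length, given
## the two-sided partials at that edge (child node `ch`)
edge_loglik_fun <- function(fp, model, pat, ch) {
  k <- fp$k
  W <- fp$W[[ch]]
  D <- fp$D[[ch]]
  w <- pat$weights
  function(t) {
    Ps <- transition_probs(model, t)
    L <- 0
    for (cc in seq_len(k)) {
      L <- L + colSums(crossprod(Ps[[cc]], W[[cc]]) * D[[cc]])
    }
    sum(w * log(L / k))
  }
}

#' Optimize all branch lengths of a tree under a model
#'
#' Round-robin single-branch optimization (derivative-free, golden
#' section via [stats::optimize] on `[min_len, max_len]`), sweeping until
#' the total log-likelihood improves by less than `tol`.
#'
#' @param tree a `phylo` object.
#' @param aln alignment containing all leaves of `tree`.
#' @param model a [subst_model].
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps maximum number of round-robin sweeps.
#' @param min_len,max_len branch-length search bounds.
#' @return list with `tree` (optimized lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 8L, min_len = 1e-8,
                                    max_len = 10) {
  pat <- aln_patterns(aln, tree$tip.label)
  cur <- tree_loglik_pat(tree, pat, model)
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      fp <- full_pass(tree, pat, model)
      ch <- tree$edge[e, 2]
      f <- edge_loglik_fun(fp, model, pat, ch)
      opt <- optimize(f, interval = c(min_len, max_len), maximum = TRUE,
                      tol = tol)
      if (opt$objective > f(tree$edge.length[e])) {
        tree$edge.length[e] <- opt$maximum
      }
    }
    new <- tree_loglik_pat(tree, pat, model)
    if (!is.finite(new)) stop("non-finite likelihood during branch optimization")
    if (new - cur < tol) {
      cur <- new
      break
    }
    cur <- new
  }
  list(tree = tree, loglik = cur)
}

## total lnL from precompressed patterns
tree_loglik_pat <- function(tree, pat, model) {
  fp <- down_pass(tree, pat, model)
  sum(pat$weights * pattern_loglik(fp, model))
}
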