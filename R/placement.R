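#' Maximum-likelihood placement of a query taxon on a tree
#'
#' For every edge of the tree, the query taxon is attached at an
#' optimized point along the edge (distal position and pendant branch
#' length optimized by coordinate descent; all other branch lengths
#' fixed), and the attachment log-likelihood is computed. Likelihood
#' weight ratios (LWR) are the per-edge likelihoods normalized over all
#' edges (log-sum-exp). Candidates are returned sorted by decreasing LWR
#' (ties broken by a canonical edge key) and truncated at the first
#' candidate whose cumulative LWR exceeds 0.99; a single dominant
#' location with LWR > 0.99 is therefore returned alone.
#'
#' `distal_length` is measured from the child endpoint of the edge
#' (`tree$edge[e, 2]`).
#'
#' @param tree the inferred tree (not containing `s`).
#' @param aln alignment containing `s` and all tree leaves.
#' @param s the query taxon.
#' @param model a [subst_model].
#' @param tol optimization tolerance.
#' @param truncate keep only the high-quality prefix (cumulative LWR
#'   rule); set `FALSE` to return all edges.
#' @return a `placement_set`: data frame with columns `edge`, `lwr`,
#'   `loglik`, `pendant_length`, `distal_length`, plus attributes `tree`
#'   and `taxon`.
#' @export
placement_candidates <- function(tree, aln, s, model, tol = 1e-6,
                                 truncate = TRUE) {
  if (s %in% tree$tip.label) stop("taxon '", s, "' already in tree")
  if (!s %in% rownames(aln)) stop("taxon '", s, "' not in alignment")
  pat <- aln_patterns(aln, c(tree$tip.label, s))
  fp <- full_pass(tree, pat, model)
  Qv <- pat$tips[[s]]
  k <- model$n_cat
  w <- pat$weights
  m <- nrow(tree$edge)

  att_loglik <- function(e, x, plen) {
    ch <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    L <- 0
    Px <- transition_probs(model, x)
    Pr <- transition_probs(model, b - x)
    Pp <- transition_probs(model, plen)
    for (cc in seq_len(k)) {
      Dm <- Px[[cc]] %*% fp$D[[ch]][[cc]]
      Um <- crossprod(Pr[[cc]], fp$W[[ch]][[cc]])
      Qm <- Pp[[cc]] %*% Qv
      L <- L + colSums(Um * Dm * Qm)
    }
    sum(w * log(L / k))
  }

  res <- data.frame(edge = seq_len(m), lwr = NA_real_, loglik = NA_real_,
                    pendant_length = NA_real_, distal_length = NA_real_)
  for (e in seq_len(m)) {
    b <- tree$edge.length[e]
    x <- b / 2
    plen <- 0.05
    lnl <- att_loglik(e, x, plen)
    for (cycle in 1:3) {
      if (b > 0) {
        ox <- optimize(function(z) att_loglik(e, z, plen),
                       interval = c(0, b), maximum = TRUE, tol = tol)
        x <- ox$maximum
      }
      op <- optimize(function(z) att_loglik(e, x, z),
                     interval = c(0, 10), maximum = TRUE, tol = tol)
      plen <- op$maximum
      if (op$objective - lnl < tol) {
        lnl <- op$objective
        break
      }
      lnl <- op$objective
    }
    res$loglik[e] <- lnl
    res$pendant_length[e] <- plen
    res$distal_length[e] <- x
  }
  mx <- max(res$loglik)
  res$lwr <- exp(res$loglik - (mx + log(sum(exp(res$loglik - mx)))))

  key <- edge_canonical_keys(tree)
  ord <- order(-res$lwr, key)
  res <- res[ord, , drop = FALSE]
  ncand <- if (truncate) which(cumsum(res$lwr) > 0.99)[1] else m
  if (is.na(ncand)) ncand <- m
  out <- res[seq_len(ncand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("placement_set", "data.frame"),
            tree = tree, taxon = s)
}

## a deterministic key per edge: the canonical form of the (possibly
## trivial) bipartition the edge induces
edge_canonical_keys <- function(tree) {
  below <- tips_below(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    block <- tree$tip.label[below[tree$edge[e, 2], ]]
    canonical_split(block, tree$tip.label)
  }, character(1))
}

#' Build the augmented tree Ts+ from the best placement
#'
#' Splits the insertion branch at the optimized distal position and
#' attaches the query taxon by its pendant edge; all other edges are
#' unchanged.
#'
#' @param tree the tree the placement was computed on.
#' @param placement a `placement_set` from [placement_candidates()].
#' @param s the query taxon (defaults to the placement's taxon).
#' @return an unrooted binary `phylo` with leaf set `leaves(tree) + s`.
#' @export
best_placement_tree <- function(tree, placement, s = attr(placement, "taxon")) {
  best <- placement[1, ]
  attach_taxon_at(tree, best$edge, s,
                  distal = best$distal_length,
                  pendant = best$pendant_length)
}

## edge surgery: attach tip `s` on edge e at `distal` from the child end
attach_taxon_at <- function(tree, e, s, distal, pendant) {
  n <- length(tree$tip.label)
  b <- tree$edge.length[e]
  stopifnot(distal >= 0, distal <= b + 1e-12, pendant >= 0)
  distal <- min(distal, b)
  remap <- function(v) ifelse(v <= n, v, v + 1L)
  E <- cbind(remap(tree$edge[, 1]), remap(tree$edge[, 2]))
  len <- tree$edge.length
  new_tip <- n + 1L
  new_node <- 2L * n  # one past the shifted internal ids (n+2 .. 2n-1)
  p <- E[e, 1]; ch <- E[e, 2]
  E[e, ] <- c(p, new_node)
  len[e] <- b - distal
  E <- rbind(E, c(new_node, ch), c(new_node, new_tip))
  len <- c(len, distal, pendant)
  lab <- tree$node.label
  if (!is.null(lab)) lab <- c(lab, "")
  out <- structure(list(edge = E, edge.length = len,
                        tip.label = c(tree$tip.label, s),
                        Nnode = tree$Nnode + 1L,
                        node.label = lab), class = "phylo")
  out <- reorder(out, "cladewise")
  validate_unrooted_tree(out)
  out
}

#' Write a placement set in jplace (v3) format
#'
#' The reference tree is written with `{k}` edge numbers (0-based row
#' index into `tree$edge`); fields are `edge_num`, `likelihood`,
#' `like_weight_ratio`, `distal_length`, `pendant_length`.
#'
#' @param placement a `placement_set`.
#' @param file output path.
#' @export
write_jplace <- function(placement, file) {
  tree <- attr(placement, "tree")
  s <- attr(placement, "taxon")
  obj <- list(
    version = 3L,
    tree = jplace_tree_string(tree),
    fields = c("edge_num", "likelihood", "like_weight_ratio",
               "distal_length", "pendant_length"),
    placements = list(list(
      p = lapply(seq_len(nrow(placement)), function(i) {
        r <- placement[i, ]
        list(r$edge - 1L, r$loglik, r$lwr, r$distal_length,
             r$pendant_length)
      }),
      n = list(s)
    )),
    metadata = list(invocation = "taxonstab::write_jplace")
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

## newick with {edge_num} annotations after each branch length
jplace_tree_string <- function(tree) {
  n <- length(tree$tip.label)
  children <- vector("list", n + tree$Nnode)
  erow <- integer(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    children[[p]] <- c(children[[p]], ch)
    erow[ch] <- i
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  rec <- function(v) {
    inner <- if (v <= n) tree$tip.label[v]
             else paste0("(", paste(vapply(children[[v]], rec, character(1)),
                                    collapse = ","), ")")
    if (v == root) return(paste0(inner, ";"))
    e <- erow[v]
    paste0(inner, ":", format(tree$edge.length[e], digits = 12),
           "{", e - 1L, "}")
  }
  rec(root)
}
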