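#' Model-corrected pairwise distance matrix
#'
#' Pairwise sequence distances corrected under the substitution model.
#' JC69 and K2P use their closed forms (through [ape::dist.dna] with
#' pairwise deletion); HKY and GTR use the pairwise maximum-likelihood
#' distance under the model. Comparisons use sites where both residues
#' are unambiguous non-gaps. Saturated pairs (correction undefined, e.g.
#' mismatch proportion >= 3/4 under JC69) are capped at `max_dist` with a
#' warning, which keeps neighbor joining well-defined on noisy pairs.
#'
#' @param aln a `DNAbin` matrix with >= 2 taxa.
#' @param model a [subst_model].
#' @param max_dist saturation cap in substitutions/site (default 10).
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
corrected_distance_matrix <- function(aln, model, max_dist = 10) {
  stopifnot(nrow(aln) >= 2L)
  chars <- tolower(as.character(aln))
  ok <- matrix(chars %in% c("a", "c", "g", "t"), nrow = nrow(chars))
  comparable <- tcrossprod(ok * 1)
  taxa <- rownames(aln)
  bad <- which(comparable == 0 & row(comparable) < col(comparable),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("no comparable sites for pair: ", taxa[bad[1, 1]], " / ",
         taxa[bad[1, 2]])
  }
  if (model$family %in% c("JC69", "K2P")) {
    dd <- ape::dist.dna(aln, model = if (model$family == "JC69") "JC69" else "K80",
                        pairwise.deletion = TRUE, as.matrix = TRUE)
    dd <- dd[taxa, taxa]
  } else {
    dd <- pairwise_ml_distances(aln, model, max_dist)
  }
  if (any(!is.finite(dd))) {
    warning("distance correction undefined for ",
            sum(!is.finite(dd[upper.tri(dd)])),
            " saturated pair(s); capped at ", max_dist)
    dd[!is.finite(dd)] <- max_dist
  }
  dd[dd > max_dist] <- max_dist
  diag(dd) <- 0
  dd
}

## pairwise ML distance: optimize the single branch of a 2-taxon tree
pairwise_ml_distances <- function(aln, model, max_dist) {
  taxa <- rownames(aln)
  n <- length(taxa)
  chars <- tolower(as.character(aln))
  plain <- matrix(chars %in% c("a", "c", "g", "t"), nrow = n)
  dd <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- plain[i, ] & plain[j, ]
      sub <- aln[c(i, j), use, drop = FALSE]
      pat <- aln_patterns(sub)
      tr <- structure(list(
        edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
        edge.length = c(0.1, 0), Nnode = 1L, tip.label = taxa[c(i, j)]
      ), class = "phylo")
      f <- function(t) {
        tr$edge.length[1] <- t
        tree_loglik_pat(tr, pat, model)
      }
      opt <- optimize(f, interval = c(0, max_dist), maximum = TRUE,
                      tol = 1e-8)
      d <- opt$maximum
      if (f(max_dist) >= opt$objective - 1e-10) d <- Inf  # saturated
      dd[i, j] <- dd[j, i] <- d
    }
  }
  dd
}
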