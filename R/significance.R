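#' Build a per-site log-likelihood table for a set of trees
#'
#' @param trees list of `phylo` objects (topologies to compare), branch
#'   lengths assumed already optimized.
#' @param aln alignment covering all leaves.
#' @param model a [subst_model].
#' @return matrix trees x sites with tree names as rownames.
#' @export
site_lnl_table <- function(trees, aln, model) {
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  tab <- t(vapply(trees, function(tr) site_log_likelihoods(tr, aln, model)$site,
                  numeric(ncol(aln))))
  if (any(!is.finite(tab))) stop("non-finite site log-likelihood")
  tab
}

#' RELL replicate totals
#'
#' Resampling estimated log-likelihoods: per replicate, a multinomial
#' site-weight vector of size `round(scale * n_sites)` reweights the
#' per-site log-likelihoods; replicate totals are the weighted sums.
#'
#' @param table trees x sites matrix of per-site log-likelihoods.
#' @param B number of replicates (>= 1).
#' @param scale resample-size multiplier (> 0).
#' @param seed integer seed.
#' @return trees x B matrix of replicate total log-likelihoods.
#' @export
rell_totals <- function(table, B, scale = 1, seed = 1L) {
  stopifnot(B >= 1)
  if (scale <= 0) stop("scale must be > 0")
  S <- ncol(table)
  m <- max(1L, round(scale * S))
  set.seed(seed)
  Wt <- rmultinom(B, m, rep(1 / S, S))   # sites x B
  table %*% Wt
}

#' Shimodaira-Hasegawa topology test
#'
#' Centered RELL replicates form the null distribution of the maximum
#' log-likelihood difference; for each tree the p-value is the
#' proportion of replicates whose centered maximum difference reaches
#' (ties count) the observed difference to the best tree.
#'
#' @param table trees x sites matrix of per-site log-likelihoods.
#' @param B replicates (default 1000; below 100 a warning is issued).
#' @param seed integer seed.
#' @return named numeric vector of p-values, one per tree.
#' @export
sh_test <- function(table, B = 1000L, seed = 1L) {
  stopifnot(nrow(table) >= 2)
  if (B < 100) warning("SH test with B < 100 replicates is unstable")
  obs <- rowSums(table)
  delta <- max(obs) - obs
  R <- rell_totals(table, B, scale = 1, seed = seed)
  Rc <- R - rowMeans(R)
  Dmax <- apply(Rc, 2, max)
  p <- vapply(seq_len(nrow(table)), function(i) {
    mean(Dmax - Rc[i, ] >= delta[i])
  }, numeric(1))
  setNames(p, rownames(table))
}

#' Approximately unbiased test via multiscale bootstrap
#'
#' For each scale r, the RELL bootstrap proportion of replicates in which
#' the tree attains the maximum total log-likelihood ("equally good or
#' better": ties are awarded to the tree under test) is computed; the
#' probit-transformed proportions are fitted by weighted least squares to
#' z(r) = d*sqrt(r) + c/sqrt(r) (weights from the binomial variance), and
#' p = 1 - Phi(d - c). A tree that is the maximum in every replicate at
#' every scale gets p = 1; never the maximum, p = 0. With fewer than two
#' non-degenerate scales the SH p-value is returned with a warning.
#'
#' @param table trees x sites matrix of per-site log-likelihoods.
#' @param scales resample-size multipliers (default 0.5 to 1.4 by 0.1).
#' @param B replicates per scale.
#' @param seed integer seed.
#' @return named numeric vector of p-values, one per tree.
#' @export
au_test <- function(table, scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                    seed = 1L) {
  stopifnot(nrow(table) >= 2, length(scales) >= 2)
  ntree <- nrow(table)
  bp <- matrix(NA_real_, ntree, length(scales))
  for (si in seq_along(scales)) {
    R <- rell_totals(table, B, scale = scales[si], seed = seed + si)
    mx <- apply(R, 2, max)
    for (i in seq_len(ntree)) {
      bp[i, si] <- mean(R[i, ] >= mx - 1e-12)   # ties to the tree under test
    }
  }
  p <- numeric(ntree)
  sh <- NULL
  for (i in seq_len(ntree)) {
    if (all(bp[i, ] >= 1)) { p[i] <- 1; next }
    if (all(bp[i, ] <= 0)) { p[i] <- 0; next }
    ok <- bp[i, ] > 0 & bp[i, ] < 1
    if (sum(ok) < 2) {
      warning("fewer than 2 non-degenerate scales for tree ", i,
              "; falling back to the SH p-value")
      if (is.null(sh)) sh <- sh_test(table, B = B, seed = seed)
      p[i] <- sh[i]
      next
    }
    r <- scales[ok]
    z <- qnorm(1 - bp[i, ok])
    var_bp <- bp[i, ok] * (1 - bp[i, ok]) / B
    wts <- dnorm(z)^2 / var_bp          # delta-method precision of z
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- stats::lm.wfit(X, z, wts)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    p[i] <- 1 - pnorm(d - cc)
  }
  setNames(p, rownames(table))
}

#' Test significance of an unstable taxon addition
#'
#' Optimizes branch lengths of the pruned and the inferred tree under
#' the model, builds the two-tree site log-likelihood table, and returns
#' the pruned tree's AU and SH p-values. Downstream, instability is
#' labelled significant when the AU p-value is below 0.05.
#'
#' @param pruned,inferred `phylo` objects with differing topologies.
#' @param aln the reduced alignment (without the focal taxon).
#' @param model a [subst_model].
#' @param B bootstrap replicates for both tests.
#' @param seed integer seed.
#' @return list with `au_p` and `sh_p` for the pruned tree.
#' @export
assess_significance <- function(pruned, inferred, aln, model, B = 1000L,
                                seed = 1L) {
  if (rf_distance(pruned, inferred) == 0L) {
    stop("topologies are identical; the test applies to unstable cases only")
  }
  pr <- optimize_branch_lengths(pruned, aln, model)$tree
  inf <- optimize_branch_lengths(inferred, aln, model)$tree
  tab <- site_lnl_table(list(pruned = pr, inferred = inf), aln, model)
  au <- suppressWarnings(au_test(tab, B = B, seed = seed))
  sh <- sh_test(tab, B = B, seed = seed)
  list(au_p = unname(au["pruned"]), sh_p = unname(sh["pruned"]))
}

#' Export a site log-likelihood table as tab-separated text
#' @param table trees x sites matrix.
#' @param file output path.
#' @export
write_site_lnl <- function(table, file) {
  ids <- rownames(table)
  if (is.null(ids)) ids <- paste0("tree", seq_len(nrow(table)))
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(ids[i], format(table[i, ], digits = 12)), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
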