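## shared fixtures, built in code; the labelled feature table is expensive
## and memoised so acceptance tests can share one computation

.fixture_env <- new.env(parent = emptyenv())

get_fixture_table <- function() {
  if (is.null(.fixture_env$tab)) {
    .fixture_env$tab <- suppressWarnings(fixture_suite(seed = 1))
  }
  .fixture_env$tab
}

## independent split-set computation: delete an edge, find the two
## connected components by BFS on the remaining edges (never calls
## tree_splits / rf_distance internals)
brute_split_set <- function(tree) {
  n <- length(tree$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    if (tree$edge[e, 2] <= n) next
    E <- tree$edge[-e, , drop = FALSE]
    comp <- bfs_component(E, tree$edge[e, 2], n + tree$Nnode)
    block <- tree$tip.label[intersect(comp, seq_len(n))]
    other <- setdiff(tree$tip.label, block)
    if (length(block) < 2 || length(other) < 2) next
    if (min(tree$tip.label) %in% block) block <- other
    keys <- c(keys, paste(sort(block), collapse = "/"))
  }
  sort(keys)
}

bfs_component <- function(E, start, nn) {
  seen <- rep(FALSE, nn)
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    hit <- unique(c(E[E[, 1] == v, 2], E[E[, 2] == v, 1]))
    new <- hit[!seen[hit]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  which(seen)
}

brute_rf <- function(t1, t2) {
  s1 <- brute_split_set(t1)
  s2 <- brute_split_set(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

## exhaustive per-site likelihood by summing over all internal-state
## assignments (the enumeration oracle for the pruning algorithm)
enum_site_loglik <- function(tree, aln, model) {
  chars <- tolower(as.character(aln))[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  k <- model$n_cat
  vapply(seq_len(ncol(chars)), function(s) {
    tot <- 0
    for (cc in seq_len(k)) {
      Ps <- lapply(tree$edge.length,
                   function(t) transition_probs(model, t)[[cc]])
      states <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
      for (r in seq_len(nrow(states))) {
        st <- states[r, ]
        pr <- model$freqs[st[1]]
        for (e in seq_len(nrow(tree$edge))) {
          sp <- st[tree$edge[e, 1] - n]
          ch <- tree$edge[e, 2]
          pr <- pr * if (ch <= n) {
            sum(Ps[[e]][sp, ] * taxonstab:::iupac_vectors(chars[ch, s]))
          } else {
            Ps[[e]][sp, st[ch - n]]
          }
        }
        tot <- tot + pr
      }
    }
    log(tot / k)
  }, numeric(1))
}

## synthetic table whose label is a known threshold function of
## dist_low_bootstrap_edge and distance_ratio_sd (planted-signal check)
planted_table <- function(n_rows = 400, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    insertion_dist_mean = runif(n_rows), insertion_dist_sd = runif(n_rows),
    lwr = runif(n_rows), n_insertion_locations = sample(1:8, n_rows, TRUE),
    insertion_branch_length = rexp(n_rows), norm_dist_nearest_node = runif(n_rows, 0, 0.5),
    pendant_length = rexp(n_rows), dist_low_bootstrap_edge = runif(n_rows),
    bootstrap_mean = runif(n_rows, 50, 100), bootstrap_sd = runif(n_rows, 0, 30),
    distance_ratio_mean = runif(n_rows, 0.8, 1.2), distance_ratio_sd = runif(n_rows, 0, 0.4),
    ratio_diff_closest_mean = runif(n_rows, 0.8, 1.2),
    ratio_diff_closest_sd = runif(n_rows, 0, 0.4),
    dist_diff_insertion_sibling = runif(n_rows, 0.5, 1.5),
    insertion_height = runif(n_rows), nj_tii = runif(n_rows, 0, 0.2)
  )
  flip <- runif(n_rows) < 0.05
  lab <- as.integer(tab$dist_low_bootstrap_edge < 0.35 &
                    tab$distance_ratio_sd > 0.15)
  tab$unstable <- ifelse(flip, 1L - lab, lab)
  tab$alignment <- sample(sprintf("a%02d", 1:20), n_rows, TRUE)
  tab
}
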