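#' Configuration for a leave-one-out stability run
#'
#' @param backend inference backend (`"nj"`, `"ml"`, `"external"`).
#' @param model a [subst_model] or a best-model string for
#'   [parse_model_string()]. The model is fixed once per alignment and
#'   reused for every reduced inference.
#' @param bootstrap bootstrap replicates B for supports (0 disables;
#'   support-dependent features are then `NA`).
#' @param au_B replicates per scale for the AU/SH tests.
#' @param alpha significance level for the instability label.
#' @param seed integer seed propagated to every stochastic stage.
#' @param significance run the AU/SH tests on unstable taxa (default
#'   TRUE; they are never run for stable taxa).
#' @param pythia optional named numeric vector (or path to a two-column
#'   CSV `taxon,difficulty`) of externally computed difficulty scores.
#' @param external_dir tree directory for the external backend.
#' @param out_dir optional output directory for CSVs/Newick/jplace;
#'   reruns with an identical config and alignment reuse cached outputs.
#' @param low_support_threshold bootstrap percentage under which an edge
#'   counts as low-support (default 70).
#' @return a `run_config` object.
#' @export
run_config <- function(backend = "nj", model = subst_model("K2P", kappa = 2),
                       bootstrap = 100L, au_B = 1000L, alpha = 0.05,
                       seed = 1L, significance = TRUE, pythia = NULL,
                       external_dir = NULL, out_dir = NULL,
                       low_support_threshold = 70) {
  if (is.character(model)) model <- parse_model_string(model)
  if (is.character(pythia) && length(pythia) == 1L && file.exists(pythia)) {
    tab <- read.csv(pythia, stringsAsFactors = FALSE)
    pythia <- setNames(tab[[2]], tab[[1]])
  }
  structure(list(backend = backend, model = model,
                 bootstrap = as.integer(bootstrap), au_B = as.integer(au_B),
                 alpha = alpha, seed = as.integer(seed),
                 significance = isTRUE(significance), pythia = pythia,
                 external_dir = external_dir, out_dir = out_dir,
                 low_support_threshold = low_support_threshold),
            class = "run_config")
}

## content hash of alignment + config, for stage caching
run_hash <- function(aln, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), "out_dir")]
  saveRDS(list(a = as.character(aln), c = cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Leave-one-out stability analysis of an alignment
#'
#' Deduplicates the alignment, infers the full tree, and for every taxon
#' s: re-infers the tree on the alignment without s (with bootstrap
#' supports), prunes s from the full tree, computes the stability record
#' (TII, disruption radius, distance of unstable edges to low-support
#' edges, AU/SH p-values for unstable cases), places s on the inferred
#' tree and computes the feature battery from the inferred tree, the
#' placement and the augmented tree only. Per-taxon failures are flagged
#' and the run continues.
#'
#' @param aln a `DNAbin` matrix with at least 5 unique sequences.
#' @param config a [run_config].
#' @return list with `stability` and `features` data frames, `full_tree`,
#'   and `failed` (character vector of failed taxa). When
#'   `config$out_dir` is set, results are also written there
#'   (`stability.csv`, `features.csv`, trees, jplace files) and reruns
#'   with an unchanged input are read back from the cache.
#' @export
run_leave_one_out <- function(aln, config = run_config()) {
  aln <- dedupe_alignment(validate_alignment(aln))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    hash <- run_hash(aln, config)
    hfile <- file.path(out_dir, "config_hash.txt")
    sfile <- file.path(out_dir, "stability.csv")
    ffile <- file.path(out_dir, "features.csv")
    if (file.exists(hfile) && readLines(hfile, warn = FALSE)[1] == hash &&
        file.exists(sfile) && file.exists(ffile)) {
      return(list(
        stability = read.csv(sfile, stringsAsFactors = FALSE),
        features = read.csv(ffile, stringsAsFactors = FALSE),
        full_tree = parse_newick(
          paste(readLines(file.path(out_dir, "full_tree.nw")), collapse = "")),
        failed = character(0), cached = TRUE))
    }
  }
  model <- config$model
  cfg_full <- inference_config(config$backend, model,
                               bootstrap = config$bootstrap,
                               seed = config$seed,
                               external_dir = config$external_dir)
  full <- infer_tree(aln, cfg_full)
  if (config$bootstrap >= 1L && config$backend != "external") {
    full <- bootstrap_supports(aln, full, cfg_full)
  }
  D_full <- corrected_distance_matrix(aln, model)
  taxa <- rownames(aln)
  stab_rows <- list()
  feat_rows <- list()
  failed <- character(0)

  for (i in seq_along(taxa)) {
    s <- taxa[i]
    res <- tryCatch({
      aln_s <- drop_taxon(aln, s)
      cfg_s <- inference_config(config$backend, model,
                                bootstrap = config$bootstrap,
                                seed = config$seed + i,
                                external_dir = config$external_dir)
      inferred <- infer_tree(aln_s, cfg_s, taxon_removed = s)
      if (config$bootstrap >= 1L && config$backend != "external") {
        inferred <- bootstrap_supports(aln_s, inferred, cfg_s)
      }
      pruned <- prune_taxon(full, s)
      au_p <- NA_real_; sh_p <- NA_real_
      if (config$significance && rf_distance(pruned, inferred) > 0L) {
        sig <- assess_significance(pruned, inferred, aln_s, model,
                                   B = config$au_B, seed = config$seed + i)
        au_p <- sig$au_p; sh_p <- sig$sh_p
      }
      stab <- stability_record(s, full, inferred, pruned,
                               au_p = au_p, sh_p = sh_p,
                               alpha = config$alpha)
      placement <- placement_candidates(inferred, aln, s, model)
      tplus <- best_placement_tree(inferred, placement, s)
      pd <- if (!is.null(config$pythia) && s %in% names(config$pythia)) {
        config$pythia[[s]]
      } else NA_real_
      feats <- assemble_features(aln, s, inferred, placement, tplus, model,
                                 pythia_difficulty = pd,
                                 D = D_full[c(inferred$tip.label, s),
                                            c(inferred$tip.label, s)])
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_newick(inferred,
                     file.path(out_dir, paste0(sanitize_label(s), ".nw")))
        write_jplace(placement,
                     file.path(out_dir,
                               paste0(sanitize_label(s), ".jplace")))
      }
      list(stab = stab, feats = feats)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("taxon '", s, "' failed: ", conditionMessage(res))
      failed <- c(failed, s)
      stab_rows[[i]] <- data.frame(
        taxon = s, tii = NA_integer_, tii_norm = NA_real_,
        disruption_radius = NA_real_,
        mean_unstable_low_support_dist = NA_real_, au_p = NA_real_,
        sh_p = NA_real_, stable = NA, significant_instability = NA,
        stringsAsFactors = FALSE)
    } else {
      stab_rows[[i]] <- res$stab
      feat_rows[[i]] <- res$feats
    }
  }
  stability <- do.call(rbind, stab_rows)
  features <- do.call(rbind, feat_rows)
  rownames(stability) <- rownames(features) <- NULL
  out <- list(stability = stability, features = features, full_tree = full,
              failed = failed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(stability, file.path(out_dir, "stability.csv"),
              row.names = FALSE, na = "")
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE, na = "")
    write_newick(full, file.path(out_dir, "full_tree.nw"))
    writeLines(run_hash(aln, config), file.path(out_dir, "config_hash.txt"))
  }
  out
}
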