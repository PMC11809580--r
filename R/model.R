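#' Substitution model container
#'
#' Time-reversible nucleotide substitution models (JC69, K2P, HKY, GTR)
#' with optional discrete-gamma rate heterogeneity. The rate matrix is
#' scaled so that the mean substitution rate at stationarity is 1, i.e.
#' branch lengths are in expected substitutions per site.
#'
#' @param family one of `"JC69"`, `"K2P"`, `"HKY"`, `"GTR"`.
#' @param rates exchangeability rates, named `ac, ag, at, cg, ct, gt`
#'   (GTR); for K2P/HKY supply `kappa` instead.
#' @param freqs stationary base frequencies, named `a, c, g, t`; must be
#'   positive and sum to 1.
#' @param kappa transition/transversion rate ratio (K2P, HKY).
#' @param gamma_shape discrete-gamma shape alpha (> 0), or `NULL` for
#'   rate homogeneity.
#' @param n_cat number of discrete-gamma categories (default 4).
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(family = c("JC69", "K2P", "HKY", "GTR"),
                        rates = NULL, freqs = NULL, kappa = 2,
                        gamma_shape = NULL, n_cat = 4L) {
  family <- match.arg(family)
  if (is.null(freqs) || family %in% c("JC69", "K2P")) {
    freqs <- c(a = 0.25, c = 0.25, g = 0.25, t = 0.25)
  }
  freqs <- freqs[c("a", "c", "g", "t")]
  stopifnot(all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-12) stop("base frequencies must sum to 1")
  if (family == "JC69") {
    rates <- c(ac = 1, ag = 1, at = 1, cg = 1, ct = 1, gt = 1)
  } else if (family %in% c("K2P", "HKY")) {
    stopifnot(kappa > 0)
    rates <- c(ac = 1, ag = kappa, at = 1, cg = 1, ct = kappa, gt = 1)
  } else {
    rates <- rates[c("ac", "ag", "at", "cg", "ct", "gt")]
    stopifnot(all(rates > 0))
  }
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0, n_cat >= 2L)

  Q <- build_q_matrix(rates, freqs)
  ## symmetric eigendecomposition via the pi^(1/2) similarity transform
  sq <- sqrt(freqs)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(
    family = family, rates = rates, freqs = freqs,
    gamma_shape = gamma_shape, n_cat = if (is.null(gamma_shape)) 1L else as.integer(n_cat),
    Q = Q,
    eval = eig$values,
    U = diag(1 / sq) %*% eig$vectors,        # P(t) = U exp(L t) Uinv
    Uinv = t(eig$vectors) %*% diag(sq),
    rate_cats = if (is.null(gamma_shape)) 1
                else discrete_gamma_rates(gamma_shape, n_cat)
  ), class = "subst_model")
}

## GTR rate matrix, rows summing to zero, mean rate scaled to 1
build_q_matrix <- function(rates, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(names(freqs), names(freqs)))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (i in seq_len(6)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    Q[a, b] <- rates[i] * freqs[b]
    Q[b, a] <- rates[i] * freqs[a]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

#' Discrete-gamma rate categories (equal-probability bin means)
#'
#' k categories with equal probability 1/k; the representative rate of
#' each bin is its conditional mean under Gamma(alpha, alpha), so the
#' category rates average to 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @return numeric vector of k relative rates.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  upper <- pgamma(q[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(q[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

#' Transition probability matrices P(t) for each rate category
#' @param model a [subst_model].
#' @param t branch length (expected substitutions/site at rate 1).
#' @return list of 4x4 matrices, one per rate category.
#' @export
transition_probs <- function(model, t) {
  lapply(model$rate_cats, function(r) {
    P <- model$U %*% (exp(model$eval * t * r) * model$Uinv)
    P[P < 0] <- 0
    P
  })
}

#' Parse a best-model specification string
#'
#' Accepts, case-insensitively, strings of the form
#' `"GTR{ac,ag,at,cg,ct,gt}+F{fa,fc,fg,ft}+G{alpha}"`,
#' `"HKY{kappa}+F{...}+G{alpha}"`, `"K2P{kappa}"`, `"JC69"`; the `+F` and
#' `+G` parts are optional.
#'
#' @param spec the model string.
#' @param n_cat gamma categories when `+G` is present.
#' @return a [subst_model].
#' @export
parse_model_string <- function(spec, n_cat = 4L) {
  parts <- strsplit(gsub(" ", "", spec), "+", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty model string")
  grab <- function(s) {
    if (!grepl("\\{", s)) return(numeric(0))
    as.numeric(strsplit(sub("^.*\\{(.*)\\}$", "\\1", s), ",")[[1]])
  }
  fam_part <- parts[1]
  fam <- toupper(sub("\\{.*$", "", fam_part))
  if (fam == "JC") fam <- "JC69"
  if (fam == "K80") fam <- "K2P"
  freqs <- NULL; alpha <- NULL
  for (p in parts[-1]) {
    key <- toupper(sub("\\{.*$", "", p))
    if (key == "F") {
      v <- grab(p)
      if (length(v) != 4) stop("+F requires 4 frequencies")
      freqs <- setNames(v / sum(v), c("a", "c", "g", "t"))
    } else if (key == "G") {
      v <- grab(p)
      if (length(v) != 1) stop("+G requires one shape value")
      alpha <- v
    } else {
      stop("unrecognized model component: ", p)
    }
  }
  if (fam == "JC69") {
    subst_model("JC69", gamma_shape = alpha, n_cat = n_cat)
  } else if (fam %in% c("K2P", "HKY")) {
    kv <- grab(fam_part)
    subst_model(fam, kappa = if (length(kv)) kv else 2,
                freqs = freqs, gamma_shape = alpha, n_cat = n_cat)
  } else if (fam == "GTR") {
    rv <- grab(fam_part)
    if (length(rv) != 6) stop("GTR requires 6 exchangeability rates")
    subst_model("GTR",
                rates = setNames(rv, c("ac", "ag", "at", "cg", "ct", "gt")),
                freqs = freqs, gamma_shape = alpha, n_cat = n_cat)
  } else {
    stop("unknown model family: ", fam)
  }
}
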