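#' Covariance to correlation
#'
#' `rho_ij = M_ij / sqrt(M_ii M_jj)`.
#'
#' @param M Symmetric matrix with strictly positive diagonal.
#' @return Correlation matrix of the same dimension.
#' @export
cov_to_corr <- function(M) {
  d <- diag(M)
  if (any(d <= 0)) stop("nonpositive diagonal element")
  M / sqrt(outer(d, d))
}

#' Heritabilities
#'
#' `h2_t = G_tt / (G_tt + R_tt)` --- the model has no variance components
#' beyond the additive genetic and residual ones, so the denominator is the
#' phenotypic variance.
#'
#' @param G,R Genetic and residual covariance matrices (or their
#'   transformed counterparts `G*`, `R*`, in which case the heritability is
#'   conditional on the traits of earlier blocks).
#' @return Named vector of heritabilities.
#' @examples
#' pc <- pirenaica_components()
#' round(heritability(pc$G, pc$R), 3)
#' @export
heritability <- function(G, R) {
  stopifnot(identical(dim(G), dim(R)))
  tot <- diag(G) + diag(R)
  if (any(tot <= 0)) stop("zero total variance")
  setNames(diag(G) / tot, colnames(G))
}

#' Effective sample size by Geyer's initial positive sequence
#'
#' Sums autocovariances in adjacent pairs and truncates at the first
#' nonpositive pair sum, then `ESS = n / tau` capped at `n`. A constant
#' chain returns `n` (zero autocorrelation by convention) with a warning.
#'
#' @param x Numeric scalar chain.
#' @return Effective sample size (numeric scalar).
#' @export
ess_ips <- function(x) {
  n <- length(x)
  if (n < 2) return(n)
  if (sd(x) == 0) {
    warning("constant chain; ESS set to chain length")
    return(n)
  }
  rho <- as.numeric(acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                        demean = TRUE)$acf)
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ...
  npair <- floor(length(rho) / 2)
  tau <- 0
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  tau <- tau - 1  # rho_0 counted twice in the pair sums
  tau <- max(tau, 1e-12)
  min(n, n / tau)
}

summary_row <- function(mat, component, type, from, to = NA_character_) {
  tibble::tibble(
    parameter = if (all(is.na(to))) from else paste0(from, ":", to),
    component = component, type = type, from = from, to = to,
    mean = unname(colMeans(mat)), sd = unname(apply(mat, 2, sd)),
    ess = apply(mat, 2, function(v) suppressWarnings(ess_ips(v)))
  )
}

# long summary of a set of chain columns holding a symmetric matrix,
# with per-sample correlations for the off-diagonals
summarize_sym_chain <- function(chain, traits, prefix, component) {
  m <- length(traits)
  nm <- tri_names(traits, prefix)
  M <- as.matrix(chain[nm])
  out <- list()
  c <- 0L
  var_cols <- integer(m)
  for (j in seq_len(m)) for (i in seq_len(j)) {
    c <- c + 1L
    if (i == j) var_cols[j] <- c
  }
  c <- 0L
  for (j in seq_len(m)) {
    for (i in seq_len(j)) {
      c <- c + 1L
      if (i == j) {
        out[[length(out) + 1L]] <-
          summary_row(M[, c, drop = FALSE], component, "variance", traits[i])
      } else {
        out[[length(out) + 1L]] <-
          summary_row(M[, c, drop = FALSE], component, "covariance",
                      traits[i], traits[j])
        denom <- sqrt(M[, var_cols[i]] * M[, var_cols[j]])
        ok <- denom > 0
        rho <- matrix(M[ok, c] / denom[ok], ncol = 1)
        out[[length(out) + 1L]] <-
          summary_row(rho, component, "correlation", traits[i], traits[j])
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Posterior summaries of a chain
#'
#' Element-wise posterior means and standard deviations, with derived
#' quantities (correlations, heritabilities, structural coefficients)
#' computed per sample and then averaged. For an `mtm_fit` the components
#' are the multiple-trait G and R; for an `rm_chain` they are the
#' transformed `G*`, `R*` plus the `lambda` coefficients and recursive
#' heritabilities.
#'
#' @param x An `mtm_fit` or `rm_chain`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `component`
#'   (`"genetic"`/`"residual"`/`"lambda"`/`"heritability"`), `type`,
#'   `from`, `to`, `mean`, `sd`, `ess`.
#' @export
summarize_chain <- function(x, ...) UseMethod("summarize_chain")

#' @export
summarize_chain.mtm_fit <- function(x, ...) {
  if (nrow(x$chain) == 0) stop("empty chain")
  traits <- x$traits
  g <- summarize_sym_chain(x$chain, traits, "G", "genetic")
  r <- summarize_sym_chain(x$chain, traits, "R", "residual")
  gd <- as.matrix(x$chain[tri_names(traits, "G")[tri_diag_pos(length(traits))]])
  rd <- as.matrix(x$chain[tri_names(traits, "R")[tri_diag_pos(length(traits))]])
  h2 <- gd / (gd + rd)
  h <- summary_row(h2, "heritability", "heritability", traits)
  dplyr::bind_rows(g, r, h)
}

tri_diag_pos <- function(m) cumsum(seq_len(m))

#' @export
summarize_chain.rm_chain <- function(x, ...) {
  traits <- attr(x, "traits")
  chain <- tibble::as_tibble(x)
  if (nrow(chain) == 0) stop("empty chain")
  g <- summarize_sym_chain(chain, traits, "Gs", "genetic")
  r <- summarize_sym_chain(chain, traits, "Rs", "residual")
  h <- summary_row(as.matrix(chain[paste0("h2_", traits)]),
                   "heritability", "heritability", traits)
  lam_cols <- grep("^lambda_", names(chain), value = TRUE)
  out <- dplyr::bind_rows(g, r, h)
  if (length(lam_cols) > 0) {
    ft <- do.call(rbind, strsplit(sub("^lambda_", "", lam_cols), "_to_"))
    l <- summary_row(as.matrix(chain[lam_cols]), "lambda", "lambda",
                     ft[, 1], ft[, 2])
    out <- dplyr::bind_rows(out, l)
  }
  out
}

#' Paper-style summary matrix
#'
#' Lays a component summary out the way multi-trait variance-component
#' tables are usually printed: variances on the diagonal, covariances above
#' it, correlations below it.
#'
#' @param summary A tibble from [summarize_chain()].
#' @param component `"genetic"` or `"residual"`.
#' @param value `"mean"` or `"sd"`.
#' @param digits Rounding for display.
#' @return A square matrix with trait dimnames.
#' @export
summary_matrix <- function(summary, component = c("genetic", "residual"),
                           value = c("mean", "sd"), digits = 2) {
  component <- match.arg(component)
  value <- match.arg(value)
  sub <- summary[summary$component == component, ]
  traits <- unique(sub$from[sub$type == "variance"])
  m <- length(traits)
  M <- matrix(NA_real_, m, m, dimnames = list(traits, traits))
  for (k in seq_len(nrow(sub))) {
    i <- match(sub$from[k], traits)
    j <- match(sub$to[k], traits)
    v <- sub[[value]][k]
    if (sub$type[k] == "variance") M[i, i] <- v
    else if (sub$type[k] == "covariance") M[i, j] <- v
    else if (sub$type[k] == "correlation") M[j, i] <- v
  }
  round(M, digits)
}
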