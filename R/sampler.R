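#' Prior specification for the (co)variance matrices
#'
#' Inverse-Wishart priors `IW(S0, nu0)` for both G and R; the fixed effects
#' carry a flat prior. The default is the improper flat limit
#' `nu0 = -(m + 1)`, `S0 = 0` (uniform over symmetric positive-definite
#' matrices, the customary default of animal-model Gibbs software), under
#' which the full conditionals are `IW(S_u, s - m - 1)` and
#' `IW(S_e, n - m - 1)`. A proper inverse-Wishart prior can be requested by
#' supplying `nu` and `S`; note that even a small proper scale like
#' `0.01 I` with `nu0 = m + 2` is strongly informative about `log det G`
#' and can dominate when many pedigree individuals carry no record.
#'
#' @param nu_g,nu_r Degrees of freedom added to the data degrees of freedom
#'   (`NULL` = `-(m + 1)`, the flat limit).
#' @param S_g,S_r Scale matrices (`NULL` = `0`; a scalar is expanded to
#'   `scalar * I`).
#' @return An object of class `mtm_priors`.
#' @export
mtm_priors <- function(nu_g = NULL, S_g = NULL, nu_r = NULL, S_r = NULL) {
  structure(list(nu_g = nu_g, S_g = S_g, nu_r = nu_r, S_r = S_r),
            class = "mtm_priors")
}

resolve_priors <- function(priors, m) {
  fix_nu <- function(nu) if (is.null(nu)) -(m + 1) else nu
  fix_S <- function(S) {
    if (is.null(S)) S <- 0
    if (length(S) == 1) S <- diag(as.numeric(S), m)
    stopifnot(identical(dim(S), c(m, m)))
    S
  }
  list(nu_g = fix_nu(priors$nu_g), S_g = fix_S(priors$S_g),
       nu_r = fix_nu(priors$nu_r), S_r = fix_S(priors$S_r))
}

tri_names <- function(traits, prefix) {
  m <- length(traits)
  out <- character(0)
  for (j in seq_len(m)) {
    for (i in seq_len(j)) out <- c(out, paste(prefix, traits[i], traits[j], sep = "_"))
  }
  out
}

# upper-triangle (column-major, diagonal included) <-> symmetric matrix
sym_from_tri <- function(v, traits) {
  m <- length(traits)
  M <- matrix(0, m, m, dimnames = list(traits, traits))
  c <- 0L
  for (j in seq_len(m)) {
    for (i in seq_len(j)) {
      c <- c + 1L
      M[i, j] <- v[c]
      M[j, i] <- v[c]
    }
  }
  M
}

tri_from_sym <- function(M) M[upper.tri(M, diag = TRUE)]

#' Fit the multiple-trait animal model by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler for
#' `y_i = X_i b + u_i + e_i`, `u ~ N(0, A (x) G)`, `e ~ N(0, I (x) R)`,
#' with per-iteration data augmentation of missing trait records from their
#' conditional Gaussian given the observed traits. Full conditionals are
#' Gaussian for the augmented records, the fixed effects and the breeding
#' values, and inverse Wishart for G (scale `U'A^-1 U + S0`, df `s + nu0`,
#' over all `s` pedigree individuals) and R (scale `sum_i e_i e_i' + S0`
#' over observed-plus-augmented residuals, df `n + nu0`).
#'
#' @param pheno Phenotype tibble: an `id` column, the model's fixed-effect
#'   columns, and one numeric column per trait (`NA` = missing). Records
#'   with every trait missing are dropped (with a message); individuals in
#'   the pedigree without records still carry breeding values, updated from
#'   their pedigree-conditional distribution.
#' @param ped A `ped_tbl` containing every phenotyped individual.
#' @param model An [mtm_model()]; if `NULL`, built as `mtm_model(traits)`.
#' @param traits Trait names (needed only when `model` is `NULL`).
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning interval for
#'   stored (G, R) samples.
#' @param seed Integer seed; given the seed the chain is bit-reproducible.
#' @param priors An [mtm_priors()].
#' @param update Character subset of `c("miss", "b", "G", "R")`; dropping
#'   `"G"` or `"R"` freezes that matrix at its starting value and dropping
#'   `"b"` freezes the fixed effects (used for validation against direct
#'   mixed-model-equation solutions and for joint-distribution tests).
#' @param joint_u_every Interval (in iterations) at which all breeding
#'   values are re-drawn jointly from their full multivariate Gaussian
#'   conditional via a sparse Cholesky factorization of
#'   `A^-1 (x) G^-1 + D (x) R^-1` (0 = never). The single-site
#'   individual-by-individual scan mixes very slowly across the
#'   genetic-vs-residual ridge when many pedigree individuals carry no
#'   record; the periodic joint draw restores mixing at modest cost.
#'   Must divide `thin` evenly (or vice versa); burn-in is rounded up to a
#'   multiple of the chunk size.
#' @param start Optional named list with any of `G`, `R`, `b`, `u`, `Y`
#'   starting values.
#' @param verbose Print progress every `verbose` iterations (0 = silent).
#' @return An object of class `mtm_fit`: posterior chain of (G, R) in a
#'   tibble (columns `G_<t1>_<t2>`, `R_<t1>_<t2>` over the upper triangle),
#'   posterior means of fixed effects and breeding values, run metadata,
#'   and the final sampler state.
#' @seealso [transform_chain()] to convert the fit into recursive-model
#'   parameters, [summarize_chain()] for posterior summaries.
#' @export
fit_mtm <- function(pheno, ped, model = NULL, traits = NULL,
                    n_iter = 10000, burn_in = 2000, thin = 10,
                    seed = NULL, priors = mtm_priors(),
                    update = c("miss", "b", "G", "R"), start = NULL,
                    joint_u_every = 10, verbose = 0) {
  stopifnot(inherits(ped, "ped_tbl"), n_iter > burn_in, thin >= 1)
  if (is.null(model)) {
    if (is.null(traits)) stop("supply `model` or `traits`")
    model <- mtm_model(traits)
  }
  traits <- model$traits
  m <- length(traits)
  miss_tr <- setdiff(traits, names(pheno))
  if (length(miss_tr) > 0) stop("trait column(s) missing from data: ",
                                paste(miss_tr, collapse = ", "))

  Y <- as.matrix(pheno[traits])
  all_na <- rowSums(!is.na(Y)) == 0
  if (any(all_na)) {
    message("dropping ", sum(all_na), " record(s) with no observed trait")
    pheno <- pheno[!all_na, , drop = FALSE]
    Y <- Y[!all_na, , drop = FALSE]
  }
  n <- nrow(Y)
  if (n == 0) stop("no phenotype records")
  rec_of <- match(as.character(pheno$id), ped$id)
  if (anyNA(rec_of)) stop("phenotyped individual(s) absent from pedigree: ",
                          paste(head(pheno$id[is.na(rec_of)], 5), collapse = ", "))
  if (anyDuplicated(rec_of)) stop("multiple records for one individual")
  OBS <- !is.na(Y)
  storage.mode(OBS) <- "integer"
  for (j in seq_len(m)) {    # initialize augmented values at trait means
    mu_j <- mean(Y[OBS[, j] == 1L, j])
    Y[OBS[, j] == 0L, j] <- mu_j
  }

  des <- build_design(model, pheno)
  pr <- resolve_priors(priors, m)
  if (nrow(ped) + pr$nu_g <= m - 1 || n + pr$nu_r <= m - 1) {
    stop("too few records/individuals for a proper posterior ",
         "with this prior (need df > m - 1)")
  }

  s <- nrow(ped)
  vr <- vapply(seq_len(m), function(j) var(Y[OBS[, j] == 1L, j]), 0)
  G0 <- diag(pmax(vr, 1e-6) / 2, m)
  R0 <- diag(pmax(vr, 1e-6) / 2, m)
  b0 <- matrix(0, ncol(des$X), m)
  u0 <- matrix(0, s, m)
  if (!is.null(start)) {
    if (!is.null(start$G)) G0 <- unname(start$G)
    if (!is.null(start$R)) R0 <- unname(start$R)
    if (!is.null(start$b)) b0 <- unname(start$b)
    if (!is.null(start$u)) u0 <- unname(start$u)
    if (!is.null(start$Y)) Y[OBS == 0L] <- start$Y[OBS == 0L]
  }

  Ainv <- ped_inverse(ped)
  if (!is.null(seed)) set.seed(seed)
  upd <- c("miss" %in% update, "b" %in% update, "G" %in% update,
           "R" %in% update)

  if (joint_u_every <= 0) {
    res <- cpp_mtm_gibbs(
      Y, OBS, des$X, des$coef_traits, rec_of, Ainv,
      G0, R0, pr$nu_g, pr$S_g, pr$nu_r, pr$S_r,
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      upd[1], upd[2], upd[3], upd[4], b0, u0, as.integer(verbose))
    G_samp <- res$G
    R_samp <- res$R
    b_mean <- res$b_mean
    u_mean <- res$u_mean
  } else {
    # hybrid scan: chunks of single-site iterations, then one joint draw
    # of all breeding values from N(Q^-1 rhs, Q^-1),
    # Q = A^-1 (x) G^-1 + D (x) R^-1
    K <- as.integer(joint_u_every)
    if (thin %% K != 0 && K %% thin != 0) {
      stop("`joint_u_every` must divide `thin` or be a multiple of it")
    }
    chunk_thin <- max(thin, K)     # chunk length; a multiple of both
    burn_in <- ceiling(burn_in / chunk_thin) * chunk_thin
    stopifnot(n_iter > burn_in)
    n_chunks <- floor(n_iter / chunk_thin)
    n_iter <- n_chunks * chunk_thin

    has_rec <- numeric(s)
    has_rec[rec_of] <- 1
    # symbolic factorization on the full (dense-block) pattern, reused
    # for every numeric update
    pat <- matrix(0.5, m, m); diag(pat) <- m
    Qpat <- Matrix::forceSymmetric(
      kronecker(Ainv, pat) + kronecker(Matrix::Diagonal(x = has_rec), pat))
    chsym <- Matrix::Cholesky(Qpat, LDL = FALSE, super = TRUE)

    G <- G0; R <- R0; b <- b0; U <- u0
    G_samp <- NULL; R_samp <- NULL
    b_mean <- matrix(0, ncol(des$X), m); u_mean <- matrix(0, s, m)
    n_mean <- 0L
    for (ch in seq_len(n_chunks)) {
      res <- cpp_mtm_gibbs(
        Y, OBS, des$X, des$coef_traits, rec_of, Ainv,
        G, R, pr$nu_g, pr$S_g, pr$nu_r, pr$S_r,
        as.integer(chunk_thin), 0L, as.integer(thin),
        upd[1], upd[2], upd[3], upd[4], b, U, 0L)
      st <- res$state
      G <- st$G; R <- st$R; b <- st$b; U <- st$u; Y <- st$Y
      if (ch * chunk_thin > burn_in) {
        G_samp <- rbind(G_samp, res$G)
        R_samp <- rbind(R_samp, res$R)
        b_mean <- b_mean + res$b_mean
        u_mean <- u_mean + res$u_mean
        n_mean <- n_mean + 1L
      }
      # joint breeding-value draw (all s individuals at once)
      Ginv <- solve(G); Rinv <- solve(R)
      Q <- Matrix::forceSymmetric(
        kronecker(Ainv, Ginv) +
        kronecker(Matrix::Diagonal(x = has_rec), Rinv))
      chQ <- Matrix::.updateCHMfactor(chsym, parent = Q, mult = 0)
      D <- Y - des$X %*% b
      RHS <- matrix(0, s, m)
      RHS[rec_of, ] <- D %*% Rinv
      rhs <- as.numeric(t(RHS))
      mu <- as.numeric(Matrix::solve(chQ, rhs, system = "A"))
      zz <- as.numeric(Matrix::solve(
        chQ, Matrix::solve(chQ, rnorm(s * m), system = "Lt"),
        system = "Pt"))
      U <- matrix(mu + zz, s, m, byrow = TRUE)
      if (verbose > 0 && (ch * chunk_thin) %% verbose == 0) {
        message("iter ", ch * chunk_thin, " diag(G): ",
                paste(signif(diag(G), 4), collapse = " "))
      }
    }
    if (n_mean > 0) {
      b_mean <- b_mean / n_mean
      u_mean <- u_mean / n_mean
    }
    res <- list(state = list(b = b, u = U, G = G, R = R, Y = Y))
  }

  chain <- tibble::as_tibble(
    setNames(as.data.frame(cbind(G_samp, R_samp)),
             c(tri_names(traits, "G"), tri_names(traits, "R"))))
  chain <- dplyr::bind_cols(
    tibble::tibble(iter = burn_in + thin * seq_len(nrow(chain))), chain)

  dimnames(b_mean) <- list(colnames(des$X), traits)
  dimnames(u_mean) <- list(ped$id, traits)

  structure(list(
    chain = chain, traits = traits, model = model, priors = pr,
    b_mean = b_mean, u_mean = u_mean, state = res$state,
    meta = list(n = n, s = s, n_iter = n_iter, burn_in = burn_in,
                thin = thin, seed = seed, n_dropped = sum(all_na),
                trait_counts = colSums(OBS),
                update = update)
  ), class = "mtm_fit")
}

#' Posterior-mean covariance matrices of a fit
#'
#' @param fit An `mtm_fit`.
#' @return List with symmetric matrices `G` and `R` (element-wise posterior
#'   means over the stored chain).
#' @export
posterior_components <- function(fit) {
  stopifnot(inherits(fit, "mtm_fit"))
  gm <- colMeans(fit$chain[tri_names(fit$traits, "G")])
  rm_ <- colMeans(fit$chain[tri_names(fit$traits, "R")])
  list(G = sym_from_tri(gm, fit$traits), R = sym_from_tri(rm_, fit$traits))
}

# (G, R) matrices of one stored sample
chain_sample <- function(fit, i) {
  list(G = sym_from_tri(as.numeric(fit$chain[i, tri_names(fit$traits, "G")]),
                        fit$traits),
       R = sym_from_tri(as.numeric(fit$chain[i, tri_names(fit$traits, "R")]),
                        fit$traits))
}

#' @export
print.mtm_fit <- function(x, ...) {
  cat("Multiple-trait animal model fit (Gibbs)\n")
  cat("  traits:  ", paste(x$traits, collapse = ", "), "\n")
  cat("  records: ", x$meta$n, " of ", x$meta$s, " pedigree individuals\n",
      sep = "")
  cat("  chain:   ", x$meta$n_iter, " iterations, burn-in ", x$meta$burn_in,
      ", thin ", x$meta$thin, " (", nrow(x$chain), " stored)\n", sep = "")
  pc <- posterior_components(x)
  cat("  posterior mean h2:",
      paste(sprintf("%s=%.3f", x$traits, heritability(pc$G, pc$R)),
            collapse = " "), "\n")
  invisible(x)
}

#' @rdname fit_mtm
#' @param x An `mtm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.mtm_fit <- function(x, ...) {
  ess <- vapply(x$chain[-1], ess_ips, 0)
  tibble::tibble(
    n = x$meta$n, s = x$meta$s, n_iter = x$meta$n_iter,
    burn_in = x$meta$burn_in, thin = x$meta$thin,
    n_samples = nrow(x$chain),
    min_ess = min(ess), median_ess = stats::median(ess)
  )
}

#' @rdname fit_mtm
#' @exportS3Method generics::tidy
tidy.mtm_fit <- function(x, ...) summarize_chain(x)
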