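#' Simulate a multi-generation pedigree
#'
#' Discrete, non-overlapping generations. Founders are unrelated; in each
#' later generation every offspring draws a random sire among the previous
#' generation's males and a random dam among its females, so related matings
#' (and hence inbreeding) can arise by chance.
#'
#' @param n_founders Number of founders (>= 2; both sexes forced present).
#' @param n_generations Number of generations bred after the founders
#'   (0 = founders only).
#' @param n_offspring Offspring produced per generation (defaults to
#'   `n_founders`, keeping the population size roughly constant).
#' @param n_sires Number of males from the previous generation used as
#'   sires each generation (`NULL` = every male is eligible). Livestock
#'   populations use few sires with large half-sib families; this both
#'   mirrors practice and concentrates the co-parent graph.
#' @param seed Optional integer seed; the simulation is bit-reproducible
#'   given the seed.
#' @return A `ped_tbl` with extra columns `generation` and `sex`
#'   ("M"/"F").
#' @examples
#' ped <- simulate_pedigree(20, 3, seed = 1)
#' table(ped$generation)
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              n_offspring = n_founders, n_sires = NULL,
                              seed = NULL) {
  stopifnot(n_founders >= 2, n_generations >= 0, n_offspring >= 1)
  if (!is.null(seed)) set.seed(seed)
  sex <- sample(c("M", "F"), n_founders, replace = TRUE)
  sex[1:2] <- c("M", "F")  # both sexes guaranteed
  recs <- tibble::tibble(
    id = paste0("G0_", seq_len(n_founders)),
    sire = NA_character_, dam = NA_character_,
    generation = 0L, sex = sex
  )
  prev <- recs
  for (g in seq_len(n_generations)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (!is.null(n_sires) && length(males) > n_sires) {
      males <- sample(males, n_sires)
    }
    off_sex <- sample(c("M", "F"), n_offspring, replace = TRUE)
    if (n_offspring >= 2) off_sex[1:2] <- c("M", "F")
    gen <- tibble::tibble(
      id = paste0("G", g, "_", seq_len(n_offspring)),
      sire = sample(males, n_offspring, replace = TRUE),
      dam = sample(females, n_offspring, replace = TRUE),
      generation = g, sex = off_sex
    )
    recs <- dplyr::bind_rows(recs, gen)
    prev <- gen
  }
  ped <- as_pedigree(recs[c("id", "sire", "dam")])
  extra <- recs[match(ped$id, recs$id), c("generation", "sex")]
  ped$generation <- extra$generation
  ped$sex <- extra$sex
  ped
}

#' Default genetic and residual covariance matrices
#'
#' Posterior-mean additive genetic (G) and residual (R) covariance matrices
#' for five sequentially recorded traits of Pirenaica beef cattle --- birth
#' weight (BW, kg), weight at 90 days (W90, kg), weight at 210 days (W210,
#' kg), cold carcass weight (CCW, kg) and SEUROP conformation score (CONF,
#' points) --- from a routine multiple-trait genetic evaluation. They serve
#' as realistic defaults for the simulator and as worked-example inputs for
#' the recursive-model transformations.
#'
#' @return A list with elements `G` and `R` (5 x 5 symmetric matrices with
#'   trait dimnames) and `traits`.
#' @examples
#' pc <- pirenaica_components()
#' heritability(pc$G, pc$R)
#' @export
pirenaica_components <- function() {
  traits <- c("BW", "W90", "W210", "CCW", "CONF")
  mk <- function(diag, upper) {
    M <- base::diag(diag)
    M[upper.tri(M)] <- upper
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(traits, traits)
    M
  }
  # upper triangle in column-major order:
  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4) (1,5) (2,5) (3,5) (4,5)
  G <- mk(c(4.85, 297.46, 629.70, 540.36, 0.86),
          c(9.85, 16.50, 288.29, 20.70, 171.06, 347.78,
            -0.01, 1.69, -0.76, 6.10))
  R <- mk(c(8.93, 452.24, 1268.18, 791.88, 0.65),
          c(11.85, 14.91, 452.16, 13.64, 228.91, 482.62,
            0.37, 1.16, 5.06, 10.33))
  list(G = G, R = R, traits = traits)
}

check_spd <- function(M, name = deparse(substitute(M))) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop(name, " must be symmetric")
  }
  ev <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ev)) stop(name, " must be positive definite")
  invisible(TRUE)
}

#' Simulate multivariate phenotypes on a pedigree
#'
#' Forward simulation of the multiple-trait animal model
#' `y_i = X_i b + u_i + e_i`: breeding values are generated by the pedigree
#' recursion `u_i = 0.5 (u_s + u_d) + m_i` with Mendelian-sampling
#' covariance `(0.5 - 0.25 (F_s + F_d)) G` (terms dropped for unknown
#' parents), which realizes `u ~ N(0, A (x) G)` at linear cost in the
#' pedigree size; residuals are iid `N(0, R)`.
#'
#' The default fixed-effect structure mirrors a routine beef-cattle
#' evaluation at desk scale: a "herd-year-season"-like factor with `n_hys`
#' levels, sex, and an age-at-recording covariate that applies to every
#' trait except the first (birth weight is recorded at a fixed age).
#'
#' @param ped A `ped_tbl`; a `sex` column is used if present.
#' @param G,R Trait covariance matrices (symmetric positive definite, with
#'   matching dimnames naming the traits). Defaults are the Pirenaica
#'   matrices of [pirenaica_components()].
#' @param model An [mtm_model()]; the default model is built from the trait
#'   names with `n_hys` herd-year-season levels.
#' @param b True fixed-effect coefficients: named list of matrices (one row
#'   per design column of the term, one column per trait the term applies
#'   to). Missing terms are drawn once from `N(0, 0.25 diag(R))` scaled
#'   effects; intercepts default to typical trait means.
#' @param n_hys Number of herd-year-season levels in the default model.
#' @param seed Optional seed.
#' @return A tibble with `id`, the fixed-effect columns (`hys`, `sex`,
#'   `age`) and one column per trait (complete records; apply
#'   [apply_missingness()] afterwards). The simulated breeding values
#'   (matrix `u`), the coefficient list `b_true`, `G` and `R` are attached
#'   as attributes.
#' @export
simulate_phenotypes <- function(ped, G = NULL, R = NULL, model = NULL,
                                b = NULL, n_hys = 25, seed = NULL) {
  stopifnot(inherits(ped, "ped_tbl"))
  if (is.null(G) || is.null(R)) {
    pc <- pirenaica_components()
    if (is.null(G)) G <- pc$G
    if (is.null(R)) R <- pc$R
  }
  check_spd(G, "G"); check_spd(R, "R")
  stopifnot(identical(dim(G), dim(R)))
  traits <- colnames(G)
  if (is.null(traits)) traits <- paste0("T", seq_len(ncol(G)))
  m <- length(traits)
  if (!is.null(seed)) set.seed(seed)
  s <- nrow(ped)

  # breeding values via Mendelian-sampling recursion (exact N(0, A (x) G))
  founders_only <- all(ped$sire_code == 0L & ped$dam_code == 0L)
  Fcoef <- if (founders_only) rep(0, s) else ped_inbreeding(ped)
  Lg <- t(chol(G))
  u <- matrix(0, s, m, dimnames = list(ped$id, traits))
  for (i in seq_len(s)) {
    si <- ped$sire_code[i]; di <- ped$dam_code[i]
    pm <- numeric(m); w <- 1
    if (si > 0L) { pm <- pm + 0.5 * u[si, ]; w <- w - 0.25 * (1 + Fcoef[si]) }
    if (di > 0L) { pm <- pm + 0.5 * u[di, ]; w <- w - 0.25 * (1 + Fcoef[di]) }
    u[i, ] <- pm + sqrt(w) * as.numeric(Lg %*% rnorm(m))
  }

  dat <- tibble::tibble(
    id = ped$id,
    hys = factor(sample.int(n_hys, s, replace = TRUE),
                 levels = seq_len(n_hys)),
    sex = factor(if ("sex" %in% names(ped)) ped$sex
                 else sample(c("M", "F"), s, replace = TRUE)),
    age = round(runif(s, -30, 30))  # days, centred on the trait's target age
  )
  if (is.null(model)) model <- mtm_model(traits, n_hys = n_hys)

  des <- build_design(model, dat)
  b <- sim_coefficients(model, des, b, traits, R)
  Xb <- matrix(0, s, m, dimnames = list(NULL, traits))
  for (k in seq_len(ncol(des$X))) {
    tk <- des$coef_traits[[k]]
    Xb[, tk] <- Xb[, tk] + outer(des$X[, k], b[k, tk])
  }

  e <- matrix(rnorm(s * m), s, m) %*% chol(R)
  Y <- Xb + u + e
  colnames(Y) <- traits
  out <- dplyr::bind_cols(dat, tibble::as_tibble(Y))
  attr(out, "u") <- u
  attr(out, "b_true") <- b
  attr(out, "G") <- G
  attr(out, "R") <- R
  attr(out, "model") <- model
  out
}

# Fill a p x m coefficient matrix for the design; user values win.
sim_coefficients <- function(model, des, b, traits, R) {
  p <- ncol(des$X)
  m <- length(traits)
  B <- matrix(0, p, m, dimnames = list(colnames(des$X), traits))
  means <- c(BW = 41.12, W90 = 134.46, W210 = 250.71, CCW = 300.29,
             CONF = 11.86)
  for (k in seq_len(p)) {
    tk <- des$coef_traits[[k]]
    nm <- colnames(des$X)[k]
    if (nm == "(Intercept)") {
      B[k, tk] <- ifelse(traits[tk] %in% names(means),
                         means[traits[tk]], 10)
    } else if (grepl("^age", nm)) {
      B[k, tk] <- 0.02 * sqrt(diag(R)[tk])
    } else {
      B[k, tk] <- rnorm(length(tk), 0, 0.3 * sqrt(diag(R)[tk]))
    }
  }
  if (!is.null(b)) {
    stopifnot(is.matrix(b), identical(dim(b), dim(B)))
    B <- b
  }
  B
}

#' Missingness patterns
#'
#' An observed-trait pattern set: each individual is assigned one pattern
#' (completely at random); traits outside the assigned pattern are set to
#' `NA`. Probabilities must sum to at most 1; the remainder is the
#' fully-observed pattern.
#'
#' @param patterns List of character vectors of observed trait names; each
#'   must be non-empty.
#' @param prob Numeric vector of the same length, in `[0, 1]`, summing to
#'   at most 1.
#' @return A tibble with list-column `traits` and column `prob`, of class
#'   `missing_patterns`.
#' @export
missing_patterns <- function(patterns, prob) {
  stopifnot(is.list(patterns), length(patterns) == length(prob),
            all(prob >= 0), all(prob <= 1), sum(prob) <= 1 + 1e-12)
  if (any(lengths(patterns) == 0)) stop("empty observed set in a pattern")
  out <- tibble::tibble(traits = patterns, prob = as.numeric(prob))
  class(out) <- c("missing_patterns", class(out))
  out
}

#' Recording patterns mimicking a beef-cattle evaluation
#'
#' The most common observed-trait combinations of the Pirenaica dataset
#' (all five traits; BW-W90; BW-CCW-CONF; BW-W90-W210; BW-W210;
#' BW-W90-CCW-CONF; BW-W210-CCW-CONF; BW only), with probabilities
#' proportional to the published group sizes. Birth weight is recorded for
#' every individual.
#'
#' @return A `missing_patterns` tibble.
#' @export
pirenaica_patterns <- function() {
  counts <- c(8629, 22550, 20528, 14548, 14188, 12859, 8443)
  total <- 149029
  missing_patterns(
    list(c("BW", "W90", "W210", "CCW", "CONF"),
         c("BW", "W90"),
         c("BW", "CCW", "CONF"),
         c("BW", "W90", "W210"),
         c("BW", "W210"),
         c("BW", "W90", "CCW", "CONF"),
         c("BW", "W210", "CCW", "CONF"),
         "BW"),
    c(counts, total - sum(counts)) / total
  )
}

#' Mask phenotypes according to a pattern set
#'
#' @param pheno Phenotype tibble (e.g. from [simulate_phenotypes()]).
#' @param patterns A [missing_patterns()] tibble. Trait names must be
#'   columns of `pheno`; every column of `pheno` named in any pattern is
#'   treated as a trait.
#' @param seed Optional seed for the pattern assignment.
#' @param traits The full trait universe (columns of `pheno` subject to
#'   masking); defaults to the union of the pattern traits, so pass it
#'   explicitly when some trait appears in no pattern.
#' @return `pheno` with masked entries set to `NA`; the assignment counts
#'   are attached as attribute `pattern_counts` and the per-trait record
#'   counts as `trait_counts`.
#' @export
apply_missingness <- function(pheno, patterns, seed = NULL, traits = NULL) {
  stopifnot(inherits(patterns, "missing_patterns"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(traits)) traits <- unique(unlist(patterns$traits))
  extra <- setdiff(unique(unlist(patterns$traits)), traits)
  if (length(extra) > 0) stop("pattern trait(s) outside `traits`: ",
                              paste(extra, collapse = ", "))
  miss <- setdiff(traits, names(pheno))
  if (length(miss) > 0) stop("pattern trait(s) not in data: ",
                             paste(miss, collapse = ", "))
  n <- nrow(pheno)
  full <- traits
  pats <- c(patterns$traits, list(full))
  prob <- c(patterns$prob, 1 - sum(patterns$prob))
  assign <- sample.int(length(pats), n, replace = TRUE, prob = prob)
  for (k in seq_along(pats)) {
    hide <- setdiff(full, pats[[k]])
    rows <- assign == k
    for (tr in hide) pheno[[tr]][rows] <- NA_real_
  }
  if (all(vapply(full, function(tr) all(is.na(pheno[[tr]])), logical(1)))) {
    stop("masking left no observed records")
  }
  labs <- vapply(pats, paste, "", collapse = "-")
  attr(pheno, "pattern_counts") <- setNames(tabulate(assign, length(pats)), labs)
  attr(pheno, "trait_counts") <-
    vapply(full, function(tr) sum(!is.na(pheno[[tr]])), integer(1))
  pheno
}
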