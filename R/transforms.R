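#' Ordered causal block structure
#'
#' An ordered partition of the traits into blocks; traits in earlier blocks
#' are taken to exert a phenotypic (recursive) effect on traits in later
#' blocks, while traits within a block stay linked by residual covariance.
#' Singleton blocks for every trait give the fully recursive model.
#'
#' @param blocks List of character vectors of trait names, in causal order.
#' @return An object of class `causal_structure`.
#' @examples
#' causal_structure(list(c("BW", "W90", "W210"), c("CCW", "CONF")))
#' @export
causal_structure <- function(blocks) {
  if (is.character(blocks)) blocks <- as.list(blocks)
  stopifnot(is.list(blocks), length(blocks) >= 1,
            all(vapply(blocks, is.character, TRUE)),
            all(lengths(blocks) >= 1))
  traits <- unlist(blocks)
  if (anyDuplicated(traits)) stop("blocks must be disjoint")
  structure(list(blocks = blocks, traits = traits),
            class = "causal_structure")
}

#' @export
print.causal_structure <- function(x, ...) {
  lab <- vapply(x$blocks, function(b) {
    if (length(b) == 1) b else paste0("{", paste(b, collapse = ","), "}")
  }, "")
  cat("Causal structure: ", paste(lab, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# block index sets (in order) for a covariance matrix; blocks must cover
# the matrix's traits exactly and be contiguous in its trait order
structure_indices <- function(structure, traits) {
  stopifnot(inherits(structure, "causal_structure"))
  if (!setequal(structure$traits, traits)) {
    stop("structure traits do not match matrix traits")
  }
  idx <- lapply(structure$blocks, function(b) match(b, traits))
  flat <- unlist(idx)
  if (!identical(flat, seq_along(traits))) {
    stop("blocks must follow the trait order of the matrix ",
         "(earlier blocks first, traits contiguous within blocks)")
  }
  idx
}

#' Scalar LDL' factorization
#'
#' Factorizes a symmetric positive-definite matrix as `R = L D L'` with `L`
#' unit lower triangular and `D` positive diagonal, by the classic pivot
#' recurrence. Under the fully recursive model `D` is the residual
#' covariance matrix `R*` and `L` is `Lambda^-1`.
#'
#' @param R Symmetric positive-definite matrix.
#' @param tol Pivot tolerance, scaled by `trace(R)/m`.
#' @return List with `L` (unit lower triangular), `d` (vector of pivots),
#'   and `Lambda = solve(L)`.
#' @examples
#' f <- ldl(pirenaica_components()$R)
#' round(f$d, 2)
#' @export
ldl <- function(R, tol = 1e-10) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) stop("R must be symmetric")
  m <- nrow(R)
  L <- diag(m)
  d <- numeric(m)
  guard <- tol * sum(diag(R)) / m
  for (j in seq_len(m)) {
    k <- seq_len(j - 1L)
    d[j] <- R[j, j] - sum(L[j, k]^2 * d[k])
    if (d[j] <= guard) {
      stop("matrix not positive definite: pivot ", j, " = ",
           format(d[j], digits = 4))
    }
    i <- seq_len(m)[-seq_len(j)]
    if (length(i) > 0) {
      L[i, j] <- (R[i, j] - L[i, k, drop = FALSE] %*% (L[j, k] * d[k])) / d[j]
    }
  }
  dimnames(L) <- dimnames(R)
  Lambda <- backsolve(L, diag(m), upper.tri = FALSE)
  dimnames(Lambda) <- dimnames(R)
  list(L = L, d = setNames(d, colnames(R)), Lambda = Lambda)
}

#' Block LDL' factorization
#'
#' Factorizes `R = Lambda^-1 R* Lambda^-1'` for an ordered block structure:
#' with leading block `E`, cross block `B` and trailing block `C`,
#' `Lambda^-1` carries `B E^-1` below the diagonal and
#' `R* = blockdiag(E, C - B E^-1 B')` (the Schur complement). Applied
#' recursively over the leading blocks for an arbitrary number of blocks;
#' the off-diagonal cross-block entries of `R*` are exactly zero by
#' construction. Singleton blocks for every trait reduce to [ldl()].
#'
#' @param R Symmetric positive-definite matrix with trait dimnames.
#' @param structure A [causal_structure()] over the traits of `R`.
#' @return List with `Lambda` (unit lower triangular, within-block
#'   off-diagonals zero) and `Rstar` (block diagonal).
#' @export
block_ldl <- function(R, structure) {
  idx <- structure_indices(structure, rownames(R) %||% as.character(seq_len(nrow(R))))
  res <- block_ldl_rec(R, lengths(idx))
  dimnames(res$Lambda) <- dimnames(R)
  dimnames(res$Rstar) <- dimnames(R)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

block_ldl_rec <- function(R, sizes) {
  m <- nrow(R)
  if (length(sizes) == 1) {
    return(list(Lambda = diag(m), Rstar = R))
  }
  e <- seq_len(sizes[1])
  r <- setdiff(seq_len(m), e)
  E <- R[e, e, drop = FALSE]
  B <- R[r, e, drop = FALSE]
  C <- R[r, r, drop = FALSE]
  BEinv <- tryCatch(t(solve(E, t(B))), error = function(err) {
    stop("leading block singular: ", conditionMessage(err))
  })
  S <- C - BEinv %*% t(B)
  S <- (S + t(S)) / 2
  sub <- block_ldl_rec(S, sizes[-1])
  Lambda <- matrix(0, m, m)
  Lambda[e, e] <- diag(length(e))
  Lambda[r, r] <- sub$Lambda
  Lambda[r, e] <- -sub$Lambda %*% BEinv
  Rstar <- matrix(0, m, m)       # cross-block zeros set exactly
  Rstar[e, e] <- E
  Rstar[r, r] <- sub$Rstar
  list(Lambda = Lambda, Rstar = Rstar)
}

#' Sequential block LDL' factorization
#'
#' Performs a cascade of two-block LDL' steps, each refining the trailing
#' block of the previous one: the first split peels off the leading `s1`
#' traits, the second the leading `s2 > s1` traits of the resulting
#' block-diagonal matrix, and so on. The composite `Lambda` is the product
#' of the per-step factors and equals the direct [block_ldl()] with the
#' final partition.
#'
#' @param R Symmetric positive-definite matrix.
#' @param splits Strictly increasing integer vector of leading-set sizes
#'   (each `< nrow(R)`); e.g. `c(1, 3)` for blocks `{1}, {2,3}, {4,5}`.
#' @return List with `Lambda` and `Rstar` as in [block_ldl()].
#' @export
sequential_block_ldl <- function(R, splits) {
  m <- nrow(R)
  splits <- as.integer(splits)
  if (length(splits) < 1 || any(diff(splits) <= 0) ||
      any(splits < 1) || any(splits >= m)) {
    stop("splits must be strictly increasing leading-set sizes in [1, m-1] ",
         "(each later split must refine the trailing block)")
  }
  Lambda <- diag(m)
  Rcur <- R
  for (sz in splits) {
    e <- seq_len(sz)
    r <- setdiff(seq_len(m), e)
    E <- Rcur[e, e, drop = FALSE]
    B <- Rcur[r, e, drop = FALSE]
    C <- Rcur[r, r, drop = FALSE]
    BEinv <- t(solve(E, t(B)))
    Lk <- diag(m)
    Lk[r, e] <- -BEinv
    S <- C - BEinv %*% t(B)
    Rcur[r, e] <- 0
    Rcur[e, r] <- 0
    Rcur[r, r] <- (S + t(S)) / 2
    Lambda <- Lk %*% Lambda
  }
  dimnames(Lambda) <- dimnames(R)
  dimnames(Rcur) <- dimnames(R)
  list(Lambda = Lambda, Rstar = Rcur)
}

#' Convert (G, R) into recursive-model parameters
#'
#' The core transformation: factorize the residual covariance matrix as
#' `R = Lambda^-1 R* Lambda^-1'` by the (block-)LDL' decomposition implied
#' by the causal structure, then carry the genetic covariances along as
#' `G* = Lambda G Lambda'`. The structural coefficients are read off as
#' `lambda[i -> j] = -Lambda[j, i]` for trait `i` in an earlier block than
#' trait `j`. The recursive model `(Lambda, G*, R*)` is likelihood
#' equivalent to the multiple-trait model `(G, R)`.
#'
#' @param G,R Symmetric positive-definite matrices with matching trait
#'   dimnames.
#' @param structure A [causal_structure()] over the traits.
#' @return Object of class `recursive_decomposition`: `Lambda`, `Gstar`,
#'   `Rstar`, and `lambda`, a tibble with columns `from`, `to`, `value`.
#' @examples
#' pc <- pirenaica_components()
#' rd <- transform_components(pc$G, pc$R,
#'   causal_structure(list(c("BW", "W90", "W210"), c("CCW", "CONF"))))
#' rd$lambda
#' @export
transform_components <- function(G, R, structure) {
  stopifnot(identical(dim(G), dim(R)))
  f <- block_ldl(R, structure)
  Gstar <- f$Lambda %*% G %*% t(f$Lambda)
  Gstar <- (Gstar + t(Gstar)) / 2
  dimnames(Gstar) <- dimnames(G)
  traits <- rownames(R) %||% as.character(seq_len(nrow(R)))
  idx <- structure_indices(structure, traits)
  blk <- rep(seq_along(idx), lengths(idx))
  pairs <- which(outer(blk, blk, "<"), arr.ind = TRUE)  # i earlier block than j
  lam <- tibble::tibble(
    from = traits[pairs[, 1]],
    to = traits[pairs[, 2]],
    value = -f$Lambda[cbind(pairs[, 2], pairs[, 1])]
  )
  base::structure(list(Lambda = f$Lambda, Gstar = Gstar, Rstar = f$Rstar,
                       lambda = lam, structure = structure, traits = traits),
                  class = "recursive_decomposition")
}

#' @export
print.recursive_decomposition <- function(x, ...) {
  print(x$structure)
  cat("Structural coefficients (lambda i->j):\n")
  print(as.data.frame(x$lambda), row.names = FALSE)
  cat("Recursive residual variances (diag R*):\n")
  print(round(diag(x$Rstar), 3))
  invisible(x)
}

#' Transform every posterior sample of a chain
#'
#' Applies [transform_components()] to each stored (G, R) sample of a fit,
#' yielding the posterior chain of the likelihood-equivalent recursive
#' model: transformed covariances `Gs_*`/`Rs_*`, structural coefficients
#' `lambda_<from>_to_<to>`, and per-sample heritabilities `h2_<trait>`
#' computed from the transformed diagonals. Samples whose R fails the SPD
#' factorization are dropped with a warning (count reported).
#'
#' @param fit An `mtm_fit`.
#' @param structure A [causal_structure()]; a single block containing all
#'   traits returns the untransformed components.
#' @return Object of class `rm_chain`: a tibble with one row per retained
#'   sample, plus attributes `structure`, `traits`, `n_dropped`.
#' @export
transform_chain <- function(fit, structure) {
  stopifnot(inherits(fit, "mtm_fit"))
  traits <- fit$traits
  K <- nrow(fit$chain)
  if (K == 0) stop("empty chain")
  rows <- vector("list", K)
  dropped <- integer(0)
  for (i in seq_len(K)) {
    smp <- chain_sample(fit, i)
    rd <- tryCatch(transform_components(smp$G, smp$R, structure),
                   error = function(e) NULL)
    if (is.null(rd)) {
      dropped <- c(dropped, i)
      next
    }
    h2 <- diag(rd$Gstar) / (diag(rd$Gstar) + diag(rd$Rstar))
    rows[[i]] <- c(
      setNames(tri_from_sym(rd$Gstar), tri_names(traits, "Gs")),
      setNames(tri_from_sym(rd$Rstar), tri_names(traits, "Rs")),
      setNames(rd$lambda$value,
               if (nrow(rd$lambda) > 0) {
                 paste0("lambda_", rd$lambda$from, "_to_", rd$lambda$to)
               } else character(0)),
      setNames(h2, paste0("h2_", traits))
    )
  }
  if (length(dropped) > 0) {
    warning(length(dropped), " sample(s) failed the SPD factorization and ",
            "were dropped (first index: ", dropped[1], ")")
    rows <- rows[-dropped]
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(iter = fit$chain$iter[setdiff(seq_len(K), dropped)]), out)
  base::structure(out, structure = structure, traits = traits,
                  n_dropped = length(dropped),
                  class = c("rm_chain", class(out)))
}
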