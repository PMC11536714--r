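#' Build a validated, topologically sorted pedigree
#'
#' Takes raw individual-sire-dam triples and returns a pedigree tibble in
#' which every parent precedes its offspring. Unknown parents may be coded
#' `0`, `"0"`, `""` or `NA`. Identifiers are arbitrary strings; they are
#' mapped to contiguous integer codes (1..s in topological order) carried in
#' the `code`, `sire_code` and `dam_code` columns, with the original labels
#' preserved.
#'
#' @param x A data frame whose first three columns are individual, sire and
#'   dam identifiers (columns named `id`, `sire`, `dam` are used if present).
#' @param strict If `TRUE`, a parent identifier that never appears as an
#'   individual is an error; the default adds such parents as founders with
#'   a warning.
#' @return A tibble of class `ped_tbl` with columns `id`, `sire`, `dam`
#'   (character; `NA` = unknown parent) and `code`, `sire_code`, `dam_code`
#'   (integer; 0 = unknown parent), in topological order. Founders keep
#'   their relative input order.
#' @examples
#' ped <- as_pedigree(data.frame(id = c(3, 1, 2), sire = c(1, 0, 0),
#'                               dam = c(2, 0, 0)))
#' ped$id  # "1" "2" "3"
#' @export
as_pedigree <- function(x, strict = FALSE) {
  stopifnot(is.data.frame(x), ncol(x) >= 3)
  nms <- names(x)
  if (all(c("id", "sire", "dam") %in% nms)) {
    x <- x[c("id", "sire", "dam")]
  } else {
    x <- x[, 1:3]
    names(x) <- c("id", "sire", "dam")
  }
  unk <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v %in% c("0", "")] <- NA_character_
    trimws(v)
  }
  id <- trimws(as.character(x$id))
  sire <- unk(x$sire)
  dam <- unk(x$dam)
  if (anyNA(id) || any(id == "")) stop("missing individual id")
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents) > 0) {
    if (strict) {
      stop("parent id(s) never defined as individuals: ",
           paste(parents, collapse = ", "))
    }
    warning(length(parents), " parent id(s) not listed as individuals; ",
            "added as founders")
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }

  ord <- toposort_ids(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  code <- seq_along(id)
  names(code) <- id
  out <- tibble::tibble(
    id = id, sire = sire, dam = dam,
    code = code,
    sire_code = ifelse(is.na(sire), 0L, unname(code[sire])),
    dam_code = ifelse(is.na(dam), 0L, unname(code[dam]))
  )
  class(out) <- c("ped_tbl", class(out))
  out
}

# Kahn's algorithm; stable (input order) among individuals whose parents are
# all placed, so founders keep their relative order.
toposort_ids <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  ps <- ifelse(is.na(sire), 0L, idx[sire])
  pd <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- (ps > 0L) + (pd > 0L)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(ps[i], pd[i])) {
      if (p > 0L) children[[p]] <- c(children[[p]], i)
    }
  }
  out <- integer(0)
  # priority queue keyed on input index keeps the order stable
  ready <- sort(idx[indeg == 0L])
  while (length(ready) > 0) {
    i <- ready[1]
    ready <- ready[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(out) < n) {
    bad <- id[setdiff(idx, out)]
    stop("pedigree cycle involving id(s): ", paste(head(bad, 5), collapse = ", "))
  }
  unname(out)
}

#' Numerator relationship matrix A
#'
#' Computes the additive (numerator) relationship matrix by the tabular
#' method, including inbreeding: `A[i,i] = 1 + 0.5 A[s,d]` and
#' `A[i,j] = 0.5 (A[j,s] + A[j,d])` for `j` earlier than `i`, with unknown
#' parents contributing zero. Dense storage; intended for pedigrees up to a
#' few thousand individuals.
#'
#' @param ped A `ped_tbl` from [as_pedigree()].
#' @param max_size Guard against accidental dense construction for very
#'   large pedigrees.
#' @return A dense symmetric s x s matrix with `ped$id` as dimnames.
#' @export
ped_relationship <- function(ped, max_size = 5000L) {
  stopifnot(inherits(ped, "ped_tbl"))
  s <- nrow(ped)
  if (s > max_size) {
    stop("pedigree has ", s, " individuals; dense A is limited to ", max_size)
  }
  A <- matrix(0, s, s)
  sire <- ped$sire_code
  dam <- ped$dam_code
  for (i in seq_len(s)) {
    j <- seq_len(i - 1L)
    if (i > 1L) {
      row <- 0.5 * ((if (sire[i] > 0L) A[j, sire[i]] else 0) +
                    (if (dam[i] > 0L) A[j, dam[i]] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + (if (sire[i] > 0L && dam[i] > 0L) 0.5 * A[sire[i], dam[i]] else 0)
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Inbreeding coefficients
#'
#' `F = diag(A) - 1` from the tabular relationship matrix.
#'
#' @inheritParams ped_relationship
#' @return Named numeric vector of inbreeding coefficients.
#' @export
ped_inbreeding <- function(ped, max_size = 5000L) {
  diag(ped_relationship(ped, max_size = max_size)) - 1
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson-style assembly of A^-1 from per-individual contributions
#' `1/d_i` at the (individual, parent) positions, where the
#' Mendelian-sampling variance is
#' `d_i = 1 - 0.25 (A[s,s] + A[d,d]) = 0.5 - 0.25 (F_s + F_d)` with
#' unknown-parent terms dropped (`0.75 - 0.25 F_s` for one known parent, 1
#' for founders). Inbreeding enters through the exact diagonal of A.
#'
#' @inheritParams ped_relationship
#' @return A sparse symmetric matrix (`Matrix::dgCMatrix`) with `ped$id`
#'   dimnames.
#' @export
ped_inverse <- function(ped, max_size = 5000L) {
  stopifnot(inherits(ped, "ped_tbl"))
  s <- nrow(ped)
  adiag <- diag(ped_relationship(ped, max_size = max_size))
  sire <- ped$sire_code
  dam <- ped$dam_code
  pdiag <- function(p) ifelse(p > 0L, adiag[pmax(p, 1L)], 0)
  d <- 1 - 0.25 * (pdiag(sire) + pdiag(dam))
  if (any(d <= 0)) {
    stop("nonpositive Mendelian-sampling variance for id(s): ",
         paste(ped$id[d <= 0], collapse = ", "), " (corrupt pedigree?)")
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(s)) {
    b <- 1 / d[i]
    par <- c(sire[i], dam[i])
    par <- par[par > 0L]
    add(i, i, b)
    for (p in par) {
      add(i, p, -b / 2); add(p, i, -b / 2)
    }
    if (length(par) == 2L) {
      add(par[1], par[2], b / 4); add(par[2], par[1], b / 4)
      add(par[1], par[1], b / 4); add(par[2], par[2], b / 4)
    } else if (length(par) == 1L) {
      add(par[1], par[1], b / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(s, s),
                               dimnames = list(ped$id, ped$id))
  Matrix::drop0(Ainv)
}

#' @export
print.ped_tbl <- function(x, ...) {
  founders <- sum(x$sire_code == 0L & x$dam_code == 0L)
  cat("# Pedigree: ", nrow(x), " individuals (", founders, " founders)\n",
      sep = "")
  NextMethod()
}

#' Read a pedigree file
#'
#' Three-column whitespace- or comma-separated text (individual, sire, dam),
#' optionally with a header line; unknown parents coded 0.
#'
#' @param path File path.
#' @inheritParams as_pedigree
#' @return A `ped_tbl`, see [as_pedigree()].
#' @export
read_pedigree <- function(path, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- lengths(parts) < 3
  if (any(bad)) stop("line(s) with fewer than 3 fields: ",
                     paste(head(which(bad), 3), collapse = ", "))
  m <- do.call(rbind, lapply(parts, `[`, 1:3))
  if (identical(tolower(m[1, ]), c("id", "sire", "dam"))) m <- m[-1, , drop = FALSE]
  df <- data.frame(id = m[, 1], sire = m[, 2], dam = m[, 3])
  as_pedigree(df, strict = strict)
}

#' Write a pedigree file
#'
#' @param ped A `ped_tbl`.
#' @param path Output path; comma-separated `id,sire,dam` with header,
#'   unknown parents written as 0.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "ped_tbl"))
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
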