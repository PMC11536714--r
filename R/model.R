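#' Fixed-effect model specification for a multiple-trait analysis
#'
#' Describes which systematic effects enter the model for which traits.
#' Every trait always receives an intercept; factors are reference-coded
#' (first level dropped) so the per-trait design is full rank.
#'
#' @param traits Character vector of trait names (defines the causal/trait
#'   order used throughout).
#' @param terms List of terms built with [model_term()]. The default (used
#'   when `terms` is `NULL`) is a herd-year-season factor (`hys`) and `sex`
#'   on all traits plus an `age` covariate on every trait but the first ---
#'   the shape of a routine weight/carcass evaluation.
#' @param n_hys Retained for documentation of the default; the actual level
#'   count comes from the data.
#' @return An object of class `mtm_model`.
#' @examples
#' mod <- mtm_model(c("BW", "W90"),
#'                  terms = list(model_term("sex", "factor", c("BW", "W90")),
#'                               model_term("age", "covariate", "W90")))
#' @export
mtm_model <- function(traits, terms = NULL, n_hys = 25) {
  stopifnot(is.character(traits), length(traits) >= 1, !anyDuplicated(traits))
  if (is.null(terms)) {
    terms <- list(
      model_term("hys", "factor", traits),
      model_term("sex", "factor", traits)
    )
    if (length(traits) > 1) {
      terms <- c(terms, list(model_term("age", "covariate", traits[-1])))
    }
  }
  for (tm in terms) {
    bad <- setdiff(tm$traits, traits)
    if (length(bad) > 0) stop("term '", tm$name, "' references unknown trait(s): ",
                              paste(bad, collapse = ", "))
  }
  structure(list(traits = traits, terms = terms), class = "mtm_model")
}

#' @rdname mtm_model
#' @param name Column name of the variable in the phenotype table.
#' @param type `"factor"` or `"covariate"`.
#' @export
model_term <- function(name, type = c("factor", "covariate"), traits) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1,
            is.character(traits), length(traits) >= 1)
  list(name = name, type = type, traits = traits)
}

#' @export
print.mtm_model <- function(x, ...) {
  cat("Multiple-trait model spec:", length(x$traits), "traits (",
      paste(x$traits, collapse = ", "), ")\n")
  cat("  intercept: all traits\n")
  for (tm in x$terms) {
    cat("  ", tm$name, " (", tm$type, "): ",
        paste(tm$traits, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Build the global design matrix and the per-column trait map.
# Returns X (n x p), coef_traits (list of integer trait-index vectors),
# term_of (term name per column). Each factor level (reference coding) is
# one column, sampled as one multivariate block across its traits.
build_design <- function(model, data) {
  stopifnot(inherits(model, "mtm_model"))
  traits <- model$traits
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  traitmap <- list(`(Intercept)` = seq_along(traits))
  termof <- c("(Intercept)")
  for (tm in model$terms) {
    if (!tm$name %in% names(data)) {
      stop("model term '", tm$name, "' not found in data")
    }
    v <- data[[tm$name]]
    ti <- match(tm$traits, traits)
    if (tm$type == "covariate") {
      cols[[tm$name]] <- as.numeric(v)
      traitmap[[tm$name]] <- ti
      termof <- c(termof, tm$name)
    } else {
      f <- droplevels(factor(v))
      if (nlevels(f) < 2) {
        stop("factor '", tm$name, "' has a single level; ",
             "confounded with the intercept")
      }
      mm <- model.matrix(~f, data = data.frame(f = f))[, -1, drop = FALSE]
      colnames(mm) <- paste0(tm$name, levels(f)[-1])
      for (k in seq_len(ncol(mm))) {
        cols[[colnames(mm)[k]]] <- mm[, k]
        traitmap[[colnames(mm)[k]]] <- ti
        termof <- c(termof, tm$name)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, coef_traits = unname(traitmap[colnames(X)]), term_of = termof)
}
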