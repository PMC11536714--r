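#' Read a phenotype table
#'
#' Comma-separated text with a header; `NA` marks missing trait records.
#' Rows in which every trait is missing are dropped (count reported), and
#' per-trait record counts are attached.
#'
#' @param path File path.
#' @param traits Character vector naming the trait columns; all must be
#'   present in the file.
#' @return A tibble with attributes `trait_counts` and `n_dropped`.
#' @export
read_phenotypes <- function(path, traits) {
  dat <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(traits, names(dat))
  if (length(miss) > 0) stop("trait column(s) not in file: ",
                             paste(miss, collapse = ", "))
  for (tr in traits) dat[[tr]] <- as.numeric(dat[[tr]])
  all_na <- rowSums(!is.na(as.matrix(dat[traits]))) == 0
  if (any(all_na)) {
    message("dropping ", sum(all_na), " record(s) with no observed trait")
    dat <- dat[!all_na, , drop = FALSE]
  }
  attr(dat, "trait_counts") <-
    vapply(traits, function(tr) sum(!is.na(dat[[tr]])), integer(1))
  attr(dat, "n_dropped") <- sum(all_na)
  dat
}

#' Write a phenotype table
#'
#' @param pheno Phenotype tibble.
#' @param path Output path (CSV, `NA` for missing, full precision).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a posterior chain
#'
#' The chain is stored as CSV (one row per stored sample, full precision)
#' next to a JSON metadata file carrying traits, chain settings and the
#' seed, so a chain written by [fit_mtm()] round-trips losslessly.
#'
#' @param fit An `mtm_fit` (or `rm_chain` for `write_chain`).
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `write_chain`: `path` invisibly. `read_chain`: an `mtm_fit`-like
#'   object (chain, traits and metadata; no sampler state), usable with
#'   [summarize_chain()], [transform_chain()] and [posterior_components()].
#' @export
write_chain <- function(fit, path) {
  if (inherits(fit, "mtm_fit")) {
    chain <- fit$chain
    meta <- c(fit$meta, list(traits = fit$traits, kind = "mtm"))
  } else if (inherits(fit, "rm_chain")) {
    chain <- tibble::as_tibble(fit)
    meta <- list(traits = attr(fit, "traits"), kind = "rm",
                 blocks = attr(fit, "structure")$blocks,
                 n_dropped = attr(fit, "n_dropped"))
  } else stop("unsupported object")
  utils::write.csv(as.data.frame(chain), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  chain <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  if (identical(meta$kind, "rm")) {
    blocks <- meta$blocks
    if (!is.list(blocks)) blocks <- as.list(blocks)
    return(base::structure(chain,
                           structure = causal_structure(blocks),
                           traits = meta$traits,
                           n_dropped = meta$n_dropped %||% 0L,
                           class = c("rm_chain", class(chain))))
  }
  base::structure(list(chain = chain, traits = meta$traits,
                       meta = meta[setdiff(names(meta), c("traits", "kind"))]),
                  class = "mtm_fit")
}

#' Run the full simulate/fit/transform/summarize pipeline
#'
#' Executes the whole analysis from one declarative configuration:
#' optionally simulate pedigree and phenotypes (or read them from files),
#' fit the multiple-trait model, then apply every configured causal
#' structure and write per-scenario summary tables, the chains, and a
#' manifest with seeds and counts sufficient for exact re-execution.
#'
#' @param config A named list or path to a YAML file with entries:
#'   `traits` (required); either `simulate` (list: `n_founders`,
#'   `n_generations`, `patterns` as list of list(traits, prob)) or
#'   `pedigree`/`phenotypes` file paths; `sampler` (list: `n_iter`,
#'   `burn_in`, `thin`, `seed`); `structures` (named list of block lists).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fit, per-structure chains and
#'   summaries, and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$traits))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- config$traits
  sc <- config$sampler %||% list()
  seed <- sc$seed %||% 1L

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      ped <- simulate_pedigree(sim$n_founders %||% 200,
                               sim$n_generations %||% 3,
                               sim$n_offspring %||% sim$n_founders %||% 200,
                               seed = seed)
      pc <- pirenaica_components()
      G <- if (setequal(traits, pc$traits)) pc$G[traits, traits] else NULL
      R <- if (setequal(traits, pc$traits)) pc$R[traits, traits] else NULL
      pheno <- simulate_phenotypes(ped, G = G, R = R)
      if (!is.null(sim$patterns)) {
        pat <- missing_patterns(lapply(sim$patterns, `[[`, "traits"),
                                vapply(sim$patterns, function(p) p$prob, 0))
        pheno <- apply_missingness(pheno, pat)
      }
      write_pedigree(ped, file.path(out_dir, "pedigree.csv"))
      write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    } else {
      ped <- read_pedigree(config$pedigree)
      pheno <- read_phenotypes(config$phenotypes, traits)
    }

    stage <- "fit"
    fit <- fit_mtm(pheno, ped, traits = traits,
                   n_iter = sc$n_iter %||% 10000,
                   burn_in = sc$burn_in %||% 2000,
                   thin = sc$thin %||% 10, seed = seed)
    write_chain(fit, file.path(out_dir, "chain_sm.csv"))
    sm_sum <- summarize_chain(fit)
    utils::write.csv(as.data.frame(sm_sum),
                     file.path(out_dir, "summary_sm.csv"), row.names = FALSE)

    stage <- "transform"
    scen <- list()
    structs <- config$structures %||% list()
    for (nm in names(structs)) {
      st <- causal_structure(lapply(structs[[nm]], as.character))
      tc <- transform_chain(fit, st)
      write_chain(tc, file.path(out_dir, paste0("chain_", nm, ".csv")))
      su <- summarize_chain(tc)
      utils::write.csv(as.data.frame(su),
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
      scen[[nm]] <- list(chain = tc, summary = su)
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("ldlrm")),
      r_version = R.version.string,
      seed = seed,
      traits = traits,
      n_records = fit$meta$n, n_individuals = fit$meta$s,
      trait_counts = as.list(fit$meta$trait_counts),
      sampler = list(n_iter = fit$meta$n_iter, burn_in = fit$meta$burn_in,
                     thin = fit$meta$thin),
      structures = structs,
      files = list.files(out_dir)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(fit = fit, summary = sm_sum, scenarios = scen, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
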