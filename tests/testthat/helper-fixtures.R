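# shared fixtures: random SPD matrices, random pedigrees, small oracles

rand_spd <- function(m, scale = 1) {
  A <- matrix(rnorm(m * m), m)
  M <- crossprod(A) + diag(m) * 0.5
  dimnames(M) <- list(paste0("T", seq_len(m)), paste0("T", seq_len(m)))
  M * scale
}

# random multi-generation pedigree triples, returned shuffled
rand_ped_df <- function(n_founders = 10, n_gen = 3, per_gen = 15) {
  ids <- paste0("F", seq_len(n_founders))
  recs <- data.frame(id = ids, sire = "0", dam = "0")
  pool <- ids
  for (g in seq_len(n_gen)) {
    new <- paste0("g", g, "_", seq_len(per_gen))
    recs <- rbind(recs, data.frame(
      id = new,
      sire = sample(pool, per_gen, replace = TRUE),
      dam = sample(pool, per_gen, replace = TRUE)
    ))
    pool <- c(pool, new)
  }
  recs[sample.int(nrow(recs)), ]
}

# independent coding of the relationship matrix: memoized kinship recursion
# (top-down), as opposed to the package's iterative bottom-up tabular fill
oracle_A <- function(ped) {
  s <- nrow(ped)
  memo <- matrix(NA_real_, s, s)
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (j > i) { tmp <- i; i <- j; j <- tmp }
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == j) {
      1 + 0.5 * rel(ped$sire_code[i], ped$dam_code[i])
    } else {
      0.5 * (rel(ped$sire_code[i], j) + rel(ped$dam_code[i], j))
    }
    memo[i, j] <<- v
    v
  }
  A <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- rel(i, j)
  A
}

# minimal stand-in fit holding a hand-made chain (for transform/summary tests)
fake_fit <- function(chain_G, chain_R, traits) {
  K <- nrow(chain_G)
  chain <- tibble::as_tibble(as.data.frame(cbind(chain_G, chain_R)))
  names(chain) <- c(ldlrm:::tri_names(traits, "G"), ldlrm:::tri_names(traits, "R"))
  chain <- dplyr::bind_cols(tibble::tibble(iter = seq_len(K)), chain)
  structure(list(chain = chain, traits = traits,
                 meta = list(n = NA, s = NA)), class = "mtm_fit")
}

tri_of <- function(M) M[upper.tri(M, diag = TRUE)]

pc_fixture <- ldlrm::pirenaica_components()
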