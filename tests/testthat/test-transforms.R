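test_that("scalar LDL' factorizes SPD matrices exactly", {
  expect_equal(ldl(diag(4)), list(L = diag(4), d = rep(1, 4),
                                  Lambda = diag(4)))
  set.seed(101)
  for (rep in 1:5) {
    R <- rand_spd(6)
    f <- ldl(R)
    expect_equal(f$L %*% diag(f$d) %*% t(f$L), R, ignore_attr = TRUE,
                 tolerance = 1e-12)
    # Cholesky oracle: d equals the squared diagonal of the upper factor
    expect_equal(unname(f$d), unname(diag(chol(R))^2), tolerance = 1e-12)
    expect_true(all(diag(f$L) == 1))
    expect_true(all(f$L[upper.tri(f$L)] == 0))
    expect_equal(f$Lambda %*% f$L, diag(6), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("LDL' rejects non-positive-definite input, reporting the pivot", {
  M <- diag(3)
  M[2, 2] <- -1
  expect_error(ldl(M), "pivot 2")
  expect_error(ldl(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("block LDL' reduces to the identity and to scalar LDL'", {
  R <- rand_spd(5)
  traits <- rownames(R)
  one <- block_ldl(R, causal_structure(list(traits)))
  expect_equal(one$Lambda, diag(5), ignore_attr = TRUE)
  expect_equal(one$Rstar, R)

  singletons <- block_ldl(R, causal_structure(as.list(traits)))
  f <- ldl(R)
  expect_equal(singletons$Lambda, f$Lambda, tolerance = 1e-12)
  expect_equal(diag(singletons$Rstar), f$d, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("block LDL' round-trips and zeroes cross blocks exactly", {
  set.seed(111)
  structures <- list(list(1:2, 3:5), list(1, 2:3, 4:5), list(1:4, 5),
                     as.list(1:5))
  for (rep in 1:4) {
    R <- rand_spd(5)
    traits <- rownames(R)
    for (bl in structures) {
      st <- causal_structure(lapply(bl, function(i) traits[i]))
      f <- block_ldl(R, st)
      Li <- solve(f$Lambda)
      expect_lt(norm(Li %*% f$Rstar %*% t(Li) - R, "F") / norm(R, "F"), 1e-10)
      # exact zeros, not merely small
      blk <- rep(seq_along(bl), lengths(bl))
      cross <- outer(blk, blk, "!=")
      expect_true(all(f$Rstar[cross] == 0))
      # within-block off-diagonals of Lambda are zero, diagonal is 1
      expect_true(all(diag(f$Lambda) == 1))
      same_blk <- outer(blk, blk, "==") & !diag(5)
      expect_true(all(f$Lambda[same_blk] == 0))
    }
  }
})

test_that("leading-block parameters pass through untransformed", {
  set.seed(121)
  R <- rand_spd(5)
  G <- rand_spd(5, 3)
  traits <- rownames(R)
  st <- causal_structure(list(traits[1:3], traits[4:5]))
  rd <- transform_components(G, R, st)
  expect_equal(rd$Rstar[1:3, 1:3], R[1:3, 1:3])
  expect_equal(rd$Gstar[1:3, 1:3], G[1:3, 1:3], tolerance = 1e-12)
  expect_equal(rd$Lambda[1:3, 1:3], diag(3), ignore_attr = TRUE)
})

test_that("sequential block LDL' equals the direct factorization", {
  set.seed(131)
  for (rep in 1:4) {
    R <- rand_spd(6)
    traits <- rownames(R)
    # one split only: identical to the two-block case
    sq <- sequential_block_ldl(R, 2)
    bl <- block_ldl(R, causal_structure(list(traits[1:2], traits[3:6])))
    expect_equal(sq$Lambda, bl$Lambda, tolerance = 1e-12)
    expect_equal(sq$Rstar, bl$Rstar, tolerance = 1e-12)

    # random nested splits vs direct multi-block factorization
    splits <- sort(sample(1:5, sample(2:3, 1)))
    sizes <- diff(c(0, splits, 6))
    blocks <- split(traits, rep(seq_along(sizes), sizes))
    sq2 <- sequential_block_ldl(R, splits)
    bl2 <- block_ldl(R, causal_structure(unname(blocks)))
    expect_lt(max(abs(sq2$Lambda - bl2$Lambda)), 1e-10)
    expect_lt(max(abs(sq2$Rstar - bl2$Rstar)), 1e-10)
  }
  expect_error(sequential_block_ldl(rand_spd(4), c(3, 2)), "increasing")
  expect_error(sequential_block_ldl(rand_spd(4), 4), "increasing|\\[1, m-1\\]")
})

test_that("structural coefficients follow the sign and scaling conventions", {
  set.seed(141)
  R <- rand_spd(4)
  G <- rand_spd(4)
  traits <- rownames(R)
  st <- causal_structure(list(traits[1:2], traits[3:4]))
  rd <- transform_components(G, R, st)
  # lambda[i -> j] = -Lambda[j, i] for cross-block pairs
  for (k in seq_len(nrow(rd$lambda))) {
    i <- match(rd$lambda$from[k], traits)
    j <- match(rd$lambda$to[k], traits)
    expect_equal(rd$lambda$value[k], -rd$Lambda[j, i])
  }
  expect_identical(nrow(rd$lambda), 4L)  # 2 sources x 2 targets

  # unit change: scaling a later-block trait by c scales lambda[. -> j] by c,
  # scaling an earlier trait by c scales lambda[i -> .] by 1/c
  cfac <- 10
  rescale <- function(M, D) { out <- D %*% M %*% D; dimnames(out) <- dimnames(M); out }
  Dj <- diag(c(1, 1, cfac, 1))
  rd_j <- transform_components(rescale(G, Dj), rescale(R, Dj), st)
  Di <- diag(c(cfac, 1, 1, 1))
  rd_i <- transform_components(rescale(G, Di), rescale(R, Di), st)
  base <- rd$lambda$value[rd$lambda$from == traits[1] &
                          rd$lambda$to == traits[3]]
  expect_equal(rd_j$lambda$value[rd_j$lambda$from == traits[1] &
                                 rd_j$lambda$to == traits[3]],
               cfac * base, tolerance = 1e-10)
  expect_equal(rd_i$lambda$value[rd_i$lambda$from == traits[1] &
                                 rd_i$lambda$to == traits[3]],
               base / cfac, tolerance = 1e-10)
})

test_that("nesting invariance: trailing-block parameters ignore refinements", {
  # conditioning set of the last block is the same whether the predecessors
  # form one block or are split further
  pc <- pc_fixture
  st2 <- causal_structure(list(c("BW", "W90", "W210"), c("CCW", "CONF")))
  st3 <- causal_structure(list("BW", c("W90", "W210"), c("CCW", "CONF")))
  rd2 <- transform_components(pc$G, pc$R, st2)
  rd3 <- transform_components(pc$G, pc$R, st3)
  expect_equal(rd2$Rstar[4:5, 4:5], rd3$Rstar[4:5, 4:5], tolerance = 1e-12)
  expect_equal(rd2$Gstar[4:5, 4:5], rd3$Gstar[4:5, 4:5], tolerance = 1e-12)
  # and the fully recursive model agrees on the CCW conditional variance
  rd1 <- transform_components(pc$G, pc$R,
                              causal_structure(as.list(pc$traits)))
  expect_equal(rd1$Gstar["CCW", "CCW"], rd2$Gstar["CCW", "CCW"],
               tolerance = 1e-12)
})

test_that("chain transformation maps samples one by one", {
  pc <- pc_fixture
  traits <- pc$traits
  # constant chain: zero posterior SD, mean equals the single transform
  K <- 5
  chain_G <- matrix(rep(tri_of(pc$G), each = K), K)
  chain_R <- matrix(rep(tri_of(pc$R), each = K), K)
  fit <- fake_fit(chain_G, chain_R, traits)
  st <- causal_structure(as.list(traits))
  tc <- transform_chain(fit, st)
  su <- summarize_chain(tc)
  expect_true(all(su$sd[su$component != "correlation"] < 1e-12))
  rd <- transform_components(pc$G, pc$R, st)
  expect_equal(su$mean[su$component == "residual" & su$type == "variance"],
               unname(diag(rd$Rstar)), tolerance = 1e-10)

  # single all-trait block: output equals input components
  tc_id <- transform_chain(fit, causal_structure(list(traits)))
  expect_equal(as.numeric(tc_id[1, ldlrm:::tri_names(traits, "Gs")]),
               tri_of(pc$G), tolerance = 1e-12)
  expect_equal(as.numeric(tc_id[1, ldlrm:::tri_names(traits, "Rs")]),
               tri_of(pc$R), tolerance = 1e-12)
})

test_that("averaging per-sample transforms sits close to transforming the mean", {
  # Jensen gap experiment: IW scatter around the residual matrix
  pc <- pc_fixture
  traits <- pc$traits
  set.seed(151)
  K <- 400
  df <- 600
  draws_R <- t(replicate(K, tri_of(ldlrm:::cpp_riwish(df, pc$R * (df - 6)))))
  draws_G <- t(replicate(K, tri_of(ldlrm:::cpp_riwish(df, pc$G * (df - 6)))))
  fit <- fake_fit(draws_G, draws_R, traits)
  tc <- transform_chain(fit, causal_structure(as.list(traits)))
  su <- summarize_chain(tc)
  d_mean_of <- su[su$component == "residual" & su$type == "variance", ]
  d_of_mean <- ldl(ldlrm:::sym_from_tri(colMeans(draws_R), traits))$d
  for (t in seq_along(traits)) {
    se <- d_mean_of$sd[t] / sqrt(K)
    gap <- abs(d_mean_of$mean[t] - d_of_mean[t])
    # the Jensen gap at posterior-like scatter stays within a few MC SEs
    # and well below the 0.5% relative band used for table comparisons
    expect_lt(gap, max(3 * se + 3 * d_mean_of$sd[t] / sqrt(df),
                       0.005 * d_of_mean[t]))
  }
  expect_identical(attr(tc, "n_dropped"), 0L)
})
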