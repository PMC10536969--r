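test_that("the metric orthogonalizer is a canonical inverse square root", {
  expect_equal(orthogonalizer(diag(2)), diag(2))
  expect_equal(orthogonalizer(diag(c(4, 1))), diag(c(0.5, 1)))
  # rank-deficient metric: X V X is the projector onto the retained space
  V <- matrix(1, 2, 2)
  X <- orthogonalizer(V, lindep = 1e-7)
  P <- X %*% V %*% X
  expect_equal(sort(eigen(P, symmetric = TRUE)$values), c(0, 1),
               tolerance = 1e-9)
  expect_equal(P %*% V %*% P, V, tolerance = 1e-9)
  expect_error(orthogonalizer(matrix(0, 2, 2)), "degenerate")
})

test_that("a single s product against a single s auxiliary gives L = J^2", {
  obs <- element_basis("H", list(gaussian_shell(0, 1.0, 1)))
  ab <- element_basis("H", list(gaussian_shell(0, 2.0, 1)), role = "ABS")
  blk <- build_importance_subblock(obs, ab, 0, method = "analytic")
  # hand evaluation: J = G(00,00;00) (ss|A) / sqrt((A|A))
  fo <- autoabs:::radial_contraction(1.0, 1, 0)
  prod <- radial_product(fo, fo, 0)
  A <- radial_function(1, 0, 2.0)
  J_hand <- (1 / sqrt(4 * pi)) * radial_coulomb_analytic(prod, A, 0) /
    sqrt(radial_coulomb_analytic(A, A, 0))
  expect_equal(as.numeric(blk$L), J_hand^2, tolerance = 1e-10)
})

test_that("the importance matrix W is (l, m) block diagonal with m-independent blocks", {
  obs <- make_fixture("toy-sp")
  ab <- element_basis("He", list(
    gaussian_shell(0, 2.5, 1), gaussian_shell(0, 0.9, 1),
    gaussian_shell(1, 1.3, 1), gaussian_shell(2, 1.6, 1)), role = "ABS")
  full <- build_importance_full(obs, ab, method = "analytic")
  expect_lt(full$offblock, 1e-8 * max(diag(full$W)))
  for (l in 0:2) {
    ref <- full$W[full$l == l & full$m == 0, full$l == l & full$m == 0,
                  drop = FALSE]
    for (m in seq(-l, l)) {
      sub <- full$W[full$l == l & full$m == m, full$l == l & full$m == m,
                    drop = FALSE]
      expect_lt(max(abs(sub - ref)), 1e-10 * max(1, max(abs(ref))))
    }
    # the radial fast path reproduces the explicit m = 0 subblock
    blk <- build_importance_subblock(obs, ab, l, method = "analytic")
    expect_equal(blk$L, ref, tolerance = 1e-9)
  }
})

test_that("an s-only orbital basis gives a vanishing d importance block", {
  obs <- element_basis("H", list(gaussian_shell(0, c(2, 0.5), c(0.6, 0.5))))
  ab <- element_basis("H", list(gaussian_shell(0, 1.0, 1),
                                gaussian_shell(2, 1.0, 1)), role = "ABS")
  blk <- build_importance_subblock(obs, ab, 2, method = "analytic")
  expect_equal(as.numeric(blk$L), 0)
})

test_that("eigenvalues of W equal the squared singular values of J", {
  obs <- make_fixture("toy-sp")
  ab <- element_basis("He", list(gaussian_shell(0, 2.5, 1),
                                 gaussian_shell(0, 0.9, 1),
                                 gaussian_shell(1, 1.3, 1)), role = "ABS")
  for (l in 0:1) {
    blk <- build_importance_subblock(obs, ab, l, method = "analytic")
    sv <- svd(blk$J)$d
    ev <- eigen(blk$L, symmetric = TRUE, only.values = TRUE)$values
    n <- min(length(sv), length(ev))
    expect_equal(ev[seq_len(n)], sv[seq_len(n)]^2, tolerance = 1e-9)
  }
})

test_that("contraction keeps eigenvectors above epsilon with the exact Frobenius guarantee", {
  # random 5x5 case in an identity metric
  set.seed(17)
  J <- matrix(rnorm(40), 8, 5)
  blk <- list(L = crossprod(J), V = diag(5), J = J)
  eps <- 1.0
  cb <- contract_block(blk, eps)
  expect_true(all(cb$values[cb$kept] >= eps))
  frob <- sum((J - J %*% cb$U %*% t(cb$U))^2)
  expect_equal(frob, sum(cb$values[-cb$kept]), tolerance = 1e-9)
  # epsilon = 0 keeps everything and reproduces J exactly
  cb0 <- contract_block(blk, 0)
  expect_length(cb0$kept, 5)
  expect_equal(sum((J - J %*% cb0$U %*% t(cb0$U))^2), 0, tolerance = 1e-18)
  # epsilon above the largest eigenvalue empties the block
  expect_warning(cbe <- contract_block(blk, 2 * max(cb$values)), "dropped")
  expect_length(cbe$kept, 0)
})

test_that("back-transformed contractions are orthonormal in the Coulomb metric", {
  obs <- make_fixture("toy-sp")
  ab <- select_primitive_abs(enumerate_candidates(obs), analytic_config(),
                             symbol = obs$symbol, Z = obs$Z)
  for (l in sort(unique(vapply(ab$shells, `[[`, integer(1), "l")))) {
    blk <- build_importance_subblock(obs, ab, l, method = "analytic")
    cb <- contract_block(blk, 1e-8)
    if (length(cb$kept) == 0) next
    CtVC <- t(cb$C) %*% blk$V %*% cb$C
    expect_equal(CtVC, diag(length(cb$kept)), tolerance = 1e-8)
    expect_equal(crossprod(cb$U), diag(length(cb$kept)), tolerance = 1e-10)
  }
})

test_that("kept sets are nested as epsilon decreases", {
  obs <- make_fixture("toy-sp")
  ab <- select_primitive_abs(enumerate_candidates(obs), analytic_config(),
                             symbol = obs$symbol, Z = obs$Z)
  blk <- build_importance_subblock(obs, ab, 0, method = "analytic")
  kept <- lapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(eps)
    suppressWarnings(contract_block(blk, eps)$kept))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
    expect_lte(length(kept[[i]]), length(kept[[i + 1]]))
  }
  # contracted count never exceeds the primitive count
  expect_lte(length(kept[[4]]), nrow(blk$V))
})

test_that("tabulation rescaling preserves the fitting span through file round-trips", {
  # single-primitive column tabulates to coefficient 1
  expect_equal(as.numeric(rescale_to_overlap_convention(
    matrix(0.37), 1.9, 0)), 1.0)
  # doubling all exponents scales pre-normalization coefficients by
  # sqrt(2), which the (ratio-invariant) tabulation normalization absorbs
  C <- matrix(c(0.8, 0.3), 2, 1)
  a <- c(2.0, 0.5)
  expect_equal(C * sqrt(2 * a), sqrt(2) * (C * sqrt(a)))
  expect_equal(rescale_to_overlap_convention(C, 2 * a, 1),
               rescale_to_overlap_convention(C, a, 1), tolerance = 1e-12)
  # two-primitive contraction: write, read back, rebuild the Coulomb
  # metric and check the span is unchanged
  obs <- make_fixture("toy-H")
  res <- contract_abs(obs, select_primitive_abs(
    enumerate_candidates(obs), analytic_config(),
    symbol = "H", Z = 1), epsilon = 1e-6, method = "analytic")
  path <- withr::local_tempfile(fileext = ".g94")
  write_basis(res$basis, path)
  back <- read_basis(path, role = "ABS")
  fn_a <- lapply(autoabs:::basis_radial_functions(res$basis),
                 function(r) r$fn)
  fn_b <- lapply(autoabs:::basis_radial_functions(back), function(r) r$fn)
  pool <- c(fn_a, fn_b)
  G <- coulomb_gram(lapply(pool, coulomb_normalize, L = 0,
                           method = "analytic"), 0, method = "analytic")
  idx_a <- seq_along(fn_a)
  for (j in seq_along(fn_b))
    expect_lt(projection_residual(G, idx_a, length(fn_a) + j), 1e-8)
})

test_that("contracted auxiliary functions are mutually Coulomb orthogonal after tabulation", {
  obs <- make_fixture("toy-sp")
  res <- generate_abs(obs, preset = "large", config = analytic_config())
  for (sh in res$basis$shells) {
    if (ncol(sh$coefficients) < 2) next
    fns <- lapply(seq_len(ncol(sh$coefficients)), function(j)
      autoabs:::radial_contraction(sh$exponents, sh$coefficients[, j], sh$l))
    G <- coulomb_gram(fns, sh$l, method = "analytic")
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
  }
})
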