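test_that("candidate enumeration follows the angular coupling and parity rules", {
  # single 1-primitive s shell: one product, L = 0, exponent 2
  c1 <- enumerate_candidates(element_basis("H", list(gaussian_shell(0, 1, 1))))
  expect_identical(names(c1), "0")
  expect_equal(c1[["0"]]$exponent, 2)
  # s(alpha=1) + p(alpha=2): s.s at L=0, s.p at L=1 only, p.p at L=0,2
  c2 <- enumerate_candidates(element_basis("He", list(
    gaussian_shell(0, 1, 1), gaussian_shell(1, 2, 1))))
  expect_identical(names(c2), c("0", "1", "2"))
  expect_equal(c2[["0"]]$exponent, c(2, 4))   # s.s and p.p
  expect_equal(c2[["1"]]$exponent, 3)         # s.p
  expect_equal(c2[["2"]]$exponent, 4)         # p.p
  # candidates are Coulomb-normalized at their L
  for (key in names(c2))
    for (fn in c2[[key]]$fn)
      expect_equal(radial_coulomb_analytic(fn, fn, as.integer(key)), 1,
                   tolerance = 1e-10)
  # an l_max = 5 orbital basis produces candidates up to L = 10
  sh <- lapply(0:5, function(l) gaussian_shell(l, 1 + l, 1))
  c3 <- enumerate_candidates(element_basis("Ne", sh))
  expect_identical(max(as.integer(names(c3))), 10L)
  expect_error(enumerate_candidates(element_basis("H", list())), "empty")
})

test_that("pivoted Cholesky selects to the threshold with the residual guarantee", {
  expect_identical(as.integer(pivoted_cholesky(diag(3), 0.5)), c(1L, 2L, 3L))
  expect_length(pivoted_cholesky(matrix(1, 2, 2), 1e-7), 1)
  # random PSD of known rank: selection count equals the rank and every
  # rejected column is reproduced to the threshold (projector oracle)
  G <- random_psd(8, 4, seed = 5)
  piv <- pivoted_cholesky(G, 1e-10)
  expect_length(piv, 4)
  expect_lt(max_rejected_residual(G, piv), 1e-10)
  expect_error(pivoted_cholesky(matrix(c(1, 2, 2, 1), 2), 1e-7), "symmetric|PSD")
  D <- diag(c(1, -1e-3))
  expect_error(pivoted_cholesky(D, 1e-7), "PSD")
})

test_that("pivot order is deterministic and nested across thresholds", {
  ob <- make_fixture("toy-H")
  cand <- enumerate_candidates(ob)
  G <- coulomb_gram(cand[["0"]]$fn, 0, method = "analytic")
  p_loose <- as.integer(pivoted_cholesky(G, 1e-2))
  p_tight <- as.integer(pivoted_cholesky(G, 1e-7))
  expect_identical(p_loose, p_tight[seq_along(p_loose)])
  # the loose selection still reproduces all rejected candidates to tau
  expect_lt(max_rejected_residual(G, p_loose), 1e-2)
})

test_that("primitive selection reproduces the whole candidate pool to tau", {
  ob <- make_fixture("toy-H")
  cand <- enumerate_candidates(ob)
  # 3 primitives -> 6 pairwise exponent sums at L = 0
  expect_length(cand[["0"]]$exponent, 6)
  expect_equal(cand[["0"]]$exponent,
               sort(unique(as.vector(outer(c(13, 1.96, 0.444),
                                           c(13, 1.96, 0.444), `+`)))))
  cfg <- analytic_config(tau = 1e-7)
  ab <- select_primitive_abs(cand, cfg, symbol = "H", Z = 1)
  sel_exp <- vapply(ab$shells, function(s) s$exponents, numeric(1))
  G <- coulomb_gram(cand[["0"]]$fn, 0, method = "analytic")
  sel_idx <- match(sort(sel_exp), cand[["0"]]$exponent)
  expect_lt(max_rejected_residual(G, sel_idx), 1e-7)
  # a looser tau selects a subset of the tighter selection
  ab2 <- select_primitive_abs(cand, analytic_config(tau = 1e-2),
                              symbol = "H", Z = 1)
  sel2 <- vapply(ab2$shells, function(s) s$exponents, numeric(1))
  expect_true(all(sel2 %in% sel_exp))
  expect_lt(length(sel2), length(sel_exp))
})

test_that("the unpruned auxiliary basis reaches twice the orbital angular momentum", {
  ob <- make_fixture("toy-sp")
  ab <- select_primitive_abs(enumerate_candidates(ob), analytic_config(),
                             symbol = ob$symbol, Z = ob$Z)
  expect_identical(l_max(ab), 2L * l_max(ob))
})

test_that("prescreening drops redundant candidates and preserves the span to tau", {
  # prescreen = FALSE is the identity
  ob <- make_fixture("toy-sp")
  cand <- enumerate_candidates(ob)
  expect_identical(prescreen_products(cand, analytic_config(prescreen = FALSE)),
                   cand)
  # duplicate exponents from distinct shell pairs are merged already at
  # enumeration; near-duplicates survive dedup but not the Cholesky
  ob2 <- element_basis("He", list(gaussian_shell(0, c(1, 1.001), c(0.7, 0.4)),
                                  gaussian_shell(0, 5, 1)))
  cand2 <- enumerate_candidates(ob2)
  cfg <- analytic_config(tau = 1e-4)
  kept <- prescreen_products(cand2, cfg)
  G <- coulomb_gram(cand2[["0"]]$fn, 0, method = "analytic")
  # surviving count equals the tau eigen-rank of the product Gram
  expect_identical(nrow(kept[["0"]]),
                   sum(eigen(G, symmetric = TRUE)$values >= cfg$tau))
  # every dropped candidate is reproduced by the survivors to tau
  sel <- match(kept[["0"]]$exponent, cand2[["0"]]$exponent)
  expect_lt(max_rejected_residual(G, sel), cfg$tau)
})

test_that("prescreened and unprescreened selections span the same pool to tau", {
  ob <- make_fixture("toy-sp")
  cfg_on <- analytic_config(tau = 1e-5, prescreen = TRUE)
  cfg_off <- analytic_config(tau = 1e-5, prescreen = FALSE)
  cand <- enumerate_candidates(ob, cfg_on)
  ab_on <- select_primitive_abs(prescreen_products(cand, cfg_on), cfg_on,
                                symbol = ob$symbol, Z = ob$Z)
  ab_off <- select_primitive_abs(cand, cfg_off, symbol = ob$symbol, Z = ob$Z)
  # mutual projection residuals of each selection against the union pool
  for (key in names(cand)) {
    L <- as.integer(key)
    pool <- cand[[key]]$fn
    G <- coulomb_gram(pool, L, method = "analytic")
    for (ab in list(ab_on, ab_off)) {
      exps <- unlist(lapply(Filter(function(s) s$l == L, ab$shells),
                            function(s) s$exponents))
      sel <- match(sort(exps), cand[[key]]$exponent)
      expect_lt(max_rejected_residual(G, sel), 2 * cfg_on$tau)
    }
  }
})
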