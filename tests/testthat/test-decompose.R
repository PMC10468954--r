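# Conic decomposition into few low-degree EFMs; Caratheodory reduction.

test_that("the interior EFM decomposes into the two extreme rays", {
  d <- decompose_flux(tiny_cone, tiny_e3, tiny_efms)
  expect_length(d$coefficients, 2)
  expect_equal(d$degree, 2)
  expect_equal(sort(d$coefficients), c("1", "1"))
  used <- abs(d$efm_indices)
  expect_setequal(used, c(find_efm(tiny_efms, tiny_e1),
                          find_efm(tiny_efms, tiny_e2)))
  expect_true(all(unlist(verify_decomposition(tiny_cone, d))))
})

test_that("a vector on an extreme ray is its own decomposition", {
  d <- decompose_flux(tiny_cone, 5 * tiny_e1, tiny_efms)
  expect_length(d$coefficients, 1)
  expect_equal(d$coefficients, "5")
  expect_true(all(unlist(verify_decomposition(tiny_cone, d))))
})

test_that("Caratheodory reduction eliminates dependencies exactly", {
  # e1 + e2 - e3 = 0: three terms for 2*e3 reduce to at most two
  terms <- list(list(coef = list(n = 1, d = 1), vector = tiny_e1),
                list(coef = list(n = 1, d = 1), vector = tiny_e2),
                list(coef = list(n = 1, d = 1), vector = tiny_e3))
  target <- fluxcone:::as_rq(2 * tiny_e3)
  red <- caratheodory_reduce(terms, target)
  expect_lte(length(red), 2)
  fluxcone:::.assert_sum_equals(red, target)
  # already independent input is unchanged
  terms2 <- list(list(coef = list(n = 1, d = 1), vector = tiny_e1),
                 list(coef = list(n = 1, d = 1), vector = tiny_e2))
  red2 <- caratheodory_reduce(terms2, fluxcone:::as_rq(tiny_e3))
  expect_length(red2, 2)
  # collinear terms merge to one
  terms3 <- list(list(coef = list(n = 1, d = 1), vector = tiny_e1),
                 list(coef = list(n = 2, d = 1), vector = tiny_e1))
  red3 <- caratheodory_reduce(terms3, fluxcone:::as_rq(3 * tiny_e1))
  expect_length(red3, 1)
  expect_equal(red3[[1]]$coef$n, 3)
  # mismatched input is rejected
  expect_error(caratheodory_reduce(terms2, fluxcone:::as_rq(tiny_e1)),
               "does not sum")
})

test_that("decomposition counting matches the examples", {
  expect_equal(count_minimal_decompositions(tiny_cone, tiny_e3, tiny_efms), 1)
  expect_equal(count_minimal_decompositions(tiny_cone, 4 * tiny_e1,
                                            tiny_efms), 1)
  # square cone (extreme rays (1,0,1,0),(1,0,0,1),(0,1,1,0),(0,1,0,1)):
  # by hand, (2,1,2,1) = 1*(1,0,1,0) + 1*(1,0,0,1) + 1*(0,1,1,0) is the only
  # strictly positive 3-subset solution, so the count is 1; the central ray
  # (1,1,1,1) is degenerate (it equals a sum of 2 rays in two ways) and
  # admits no strictly positive independent 3-subset at all
  sq <- square_cone()
  esq <- enumerate_efms(sq)
  expect_equal(count_minimal_decompositions(sq, c(2, 1, 2, 1), esq), 1)
  expect_equal(count_minimal_decompositions(sq, c(1, 1, 1, 1), esq), 0)
})

test_that("random cone points decompose within their minimal face", {
  for (pair in list(list(tiny_cone, tiny_efms),
                    list(branched_cone, branched_efms))) {
    cone <- pair[[1]]; efms <- pair[[2]]
    t <- cone$dim_lineality
    for (s in 1:25) {
      v <- random_cone_point(cone, efms, seed = 400 + s)
      if (all(v == 0)) next
      d <- decompose_flux(cone, v, efms)
      expect_lte(length(d$coefficients), d$degree)
      expect_true(all(unlist(verify_decomposition(cone, d))))
      for (i in seq_along(d$efm_indices))
        expect_lte(degree(cone, d$vectors[, i]), t + 1)
    }
  }
})

test_that("high-degree EFMs split into at least two strictly lower ones", {
  # tiny e3: degree 2 = t + 2, so the split clause is active
  d <- decompose_flux(tiny_cone, tiny_e3, tiny_efms)
  rep <- verify_decomposition(tiny_cone, d)
  expect_true(rep$efm_split)
  # every branched EFM of degree >= t + 2 decomposes accordingly
  t <- branched_cone$dim_lineality
  for (i in which(branched_efms$degrees >= t + 2)) {
    e <- branched_efms$vectors[, i]
    d <- decompose_flux(branched_cone, e, branched_efms)
    expect_gte(length(d$coefficients), 2)
    degs <- vapply(seq_along(d$efm_indices), function(k)
      degree(branched_cone, d$vectors[, k]), integer(1))
    expect_true(all(degs < branched_efms$degrees[i]))
  }
})

test_that("a relative-interior point uses at most dim C terms", {
  pd <- pointed_decomposition(branched_canon, branched_efms_canon)
  v <- Reduce(`+`, c(pd$lineality_basis, pd$generators))
  expect_equal(degree(branched_canon, v), 5)
  d <- decompose_flux(branched_canon, v, branched_efms_canon)
  expect_lte(length(d$coefficients), 5)
  expect_true(all(unlist(verify_decomposition(branched_canon, d))))
})

test_that("invalid decompositions are rejected clause by clause", {
  d <- decompose_flux(tiny_cone, tiny_e1, tiny_efms)
  # corrupt: term outside the minimal face of e1 (e3 has v3 > 0)
  bad <- d
  bad$vectors <- matrix(tiny_e3, ncol = 1)
  expect_error(verify_decomposition(tiny_cone, bad), "sum|face")
  bad2 <- d
  bad2$coefficients_rq <- list(list(n = -5, d = 1))
  bad2$coefficients <- "-5"
  expect_error(verify_decomposition(tiny_cone, bad2), "")
  expect_error(decompose_flux(tiny_cone, c(0, 0, 0, 0), tiny_efms), "zero")
  expect_error(decompose_flux(tiny_cone, -tiny_e1, tiny_efms),
               "irreversibility")
})

test_that("minimal decompositions are generically not smaller than deg(v)", {
  # points sampled with all generators of their face active never admit a
  # decomposition into fewer than deg(v) EFMs (checked exhaustively)
  for (s in 1:5) {
    set.seed(500 + s)
    lam <- sample(1:5, 1)
    lam <- c(lam, lam + sample(1:3, 1)) # distinct weights: v generic
    v <- as.numeric(cbind(tiny_e1, tiny_e2) %*% lam)
    k <- degree(tiny_cone, v)
    if (k < 2) next
    cand <- fluxcone:::.decomposition_candidates(
      tiny_cone, flux_vector(tiny_net, v), tiny_efms)
    smaller <- 0
    for (subset in utils::combn(ncol(cand$vectors), k - 1, simplify = FALSE)) {
      sol <- fluxcone:::rq_solve(fluxcone:::rq_mat(
        cand$vectors[, subset, drop = FALSE]), v)
      if (sol$status == "unique" && all(sol$x$n > 0)) smaller <- smaller + 1
    }
    expect_equal(smaller, 0)
  }
})
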