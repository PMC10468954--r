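# Flux cone construction, blocked/redundant detection, canonicalization,
# degree, faces, pointed decomposition, FBA.

test_that("cone dimensions match the worked examples", {
  expect_equal(tiny_cone$dim_cone, 2)
  expect_equal(tiny_cone$dim_lineality, 0)
  expect_equal(branched_cone$dim_cone, 5)
  expect_equal(branched_cone$dim_lineality, 2)
  # without irreversibility the cone is the nullspace of S
  net <- metabolic_network(matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE),
                           irr = integer(0))
  cone <- flux_cone(net)
  expect_equal(cone$dim_cone, cone$dim_lineality)
  expect_equal(cone$dim_cone, 3 - 2)
})

test_that("blocked reactions are detected and certified", {
  expect_equal(branched_cone$blocked_irr, 13L)
  expect_equal(branched_cone$blocked_rev, integer(0))
  expect_equal(tiny_cone$blocked_irr, integer(0))
  # a single irreversible reaction consuming an unreplenished metabolite
  net <- metabolic_network(matrix(1, 1, 1), irr = 1)
  expect_equal(flux_cone(net)$blocked_irr, 1L)
  # blocked reversible reaction: A <-> B with nothing else touching B
  net2 <- metabolic_network(matrix(c(-1, 1), 2, 1), irr = integer(0))
  expect_equal(flux_cone(net2)$blocked_rev, 1L)
})

test_that("redundancy detection matches the worked example", {
  expect_equal(redundant_irr_constraints(branched_cone), 6L)
  expect_equal(redundant_irr_constraints(tiny_cone), integer(0))
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  expect_equal(redundant_irr_constraints(flux_cone(net)), integer(0))
})

test_that("lexicographic canonicalization shifts redundant constraints", {
  expect_equal(branched_canon$irr, c(2, 7, 8))
  expect_equal(branched_canon$shift_history, 6L)
  expect_equal(branched_canon$blocked_irr, 13L)
  expect_true(6 %in% branched_canon$rev)
  # idempotent
  again <- canonicalize(branched_canon)
  expect_equal(again$irr, branched_canon$irr)
  # tiny cone: nothing to do
  expect_equal(tiny_canon$irr, tiny_cone$irr)
  expect_equal(tiny_canon$shift_history, integer(0))
  # the cone itself is unchanged: same EFMs, same dimensions
  expect_equal(branched_canon$dim_cone, branched_cone$dim_cone)
  expect_identical(branched_efms_canon$vectors, branched_efms$vectors)
})

test_that("canonicalization preserves membership", {
  for (s in 1:25) {
    v <- random_cone_point(branched_cone, branched_efms, seed = s)
    expect_true(in_cone(branched_cone, v))
    expect_true(in_cone(branched_canon, v))
  }
  # and non-members stay non-members
  expect_false(in_cone(branched_cone, c(-1, rep(0, 11), 1)))
  expect_false(in_cone(branched_canon, c(-1, rep(0, 11), 1)))
})

test_that("facets require canonicality and have dimension dim C - 1", {
  expect_error(facets(branched_cone), "canonicalize")
  f <- facets(branched_canon)
  expect_length(f, 3)
  expect_equal(sort(vapply(f, function(x) x$zero_set[1], numeric(1))),
               c(2, 7, 8))
  expect_true(all(vapply(f, `[[`, integer(1), "dim") == 4))
  ft <- facets(tiny_canon)
  expect_length(ft, 2)
  expect_true(all(vapply(ft, `[[`, integer(1), "dim") == 1))
  # no irreversible constraints: no proper faces
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  expect_length(facets(canonicalize(flux_cone(net))), 0)
})

test_that("degree matches the worked examples and rejects outsiders", {
  expect_equal(degree(tiny_cone, tiny_e3), 2)
  expect_equal(degree(tiny_cone, tiny_e1), 1)
  expect_equal(degree(tiny_cone, tiny_e2), 1)
  expect_equal(degree(tiny_cone, c(0, 0, 0, 0)), 0) # dim L
  expect_equal(degree(branched_cone, rep(0, 13)), 2)
  expect_error(degree(tiny_cone, -tiny_e1), "irreversibility")
  expect_error(degree(tiny_cone, c(1, 0, 0, 0)), "steady-state")
  # degree is invariant under the description: original vs canonical
  for (i in seq_len(branched_efms$count)) {
    v <- branched_efms$vectors[, i]
    expect_equal(degree(branched_cone, v), degree(branched_canon, v))
  }
})

test_that("minimal_face and relative interior behave as in the examples", {
  f3 <- minimal_face(tiny_cone, tiny_e3)
  expect_equal(f3$canonical_zero_set, integer(0))
  expect_equal(f3$dim, 2)
  f1 <- minimal_face(tiny_cone, tiny_e1)
  expect_equal(f1$canonical_zero_set, 3L)
  expect_equal(f1$dim, 1)
  f0 <- minimal_face(tiny_cone, c(0, 0, 0, 0))
  expect_equal(f0$dim, tiny_cone$dim_lineality)
  expect_true(in_relative_interior(tiny_cone, tiny_e3))
  expect_false(in_relative_interior(tiny_cone, tiny_e1))
  # linear-space cone: everything is in the relative interior
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  cone <- flux_cone(net)
  expect_true(in_relative_interior(cone, c(1, 1)))
  expect_true(in_relative_interior(cone, c(0, 0)))
})

test_that("degree respects the lineality and irr-support bounds", {
  t <- branched_cone$dim_lineality
  for (b in branched_cone$lineality_basis)
    expect_equal(degree(branched_cone, b), t)
  for (i in seq_len(branched_efms$count)) {
    v <- branched_efms$vectors[, i]
    expect_lte(degree(branched_cone, v),
               t + length(branched_efms$irr_support[[i]]))
  }
  for (s in 1:20) {
    v <- random_cone_point(branched_cone, branched_efms, seed = 100 + s)
    vi <- flux_vector(branched_net, v)
    expect_lte(degree(branched_cone, v), t + length(vi$irr_support))
  }
})

test_that("pointed decomposition splits C into L plus a pointed cone", {
  pd <- pointed_decomposition(tiny_cone, tiny_efms)
  expect_length(pd$lineality_basis, 0)
  expect_length(pd$generators, 2)
  gens <- do.call(cbind, pd$generators)
  e1 <- find_efm(tiny_efms, tiny_e1); e2 <- find_efm(tiny_efms, tiny_e2)
  expect_true(all(apply(gens, 2, function(g)
    any(vapply(list(tiny_e1, tiny_e2), function(e) all(g == e),
               logical(1))))))
  pd2 <- pointed_decomposition(branched_canon, branched_efms_canon)
  expect_length(pd2$lineality_basis, 2)
  expect_length(pd2$generators, 3)
  # dim C = dim L + dim P
  G <- do.call(cbind, pd2$generators)
  expect_equal(branched_canon$dim_cone,
               2 + fluxcone:::int_rank(t(G)))
  # generators have degree t + 1 and stay in the cone
  for (g in pd2$generators) {
    expect_true(in_cone(branched_canon, g))
    expect_equal(degree(branched_canon, g), 3)
  }
  # no minimal proper faces at all
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  cone <- flux_cone(net)
  pd3 <- pointed_decomposition(cone, enumerate_efms(cone))
  expect_length(pd3$generators, 0)
})

test_that("both complements give pointed parts with the same combinatorics", {
  for (cone_efms in list(list(tiny_cone, tiny_efms),
                         list(branched_canon, branched_efms_canon))) {
    cone <- cone_efms[[1]]; efms <- cone_efms[[2]]
    po <- pointed_decomposition(cone, efms, complement = "orthogonal")
    pc <- pointed_decomposition(cone, efms, complement = "coordinate")
    expect_equal(length(po$generators), length(pc$generators))
    expect_equal(po$mmbs, pc$mmbs)
    # same independence structure and the same Minkowski reconstruction:
    # every EFM decomposes over lineality (+/-) and the generators
    for (p in list(po, pc)) {
      B <- p$lineality_basis
      G <- do.call(cbind, c(p$generators, list(rep(0, cone$network$n))))
      cols <- cbind(if (length(B)) do.call(cbind, B),
                    if (length(B)) -do.call(cbind, B), G)
      for (i in seq_len(efms$count)) {
        r <- solve_nonneg(cols, efms$vectors[, i])
        expect_true(r$feasible)
      }
    }
  }
})

test_that("FBA finds exact optima and reports degeneracies", {
  # cap reactions 1..3 at 10; the objective v4 = v2 + v3 then reaches 20
  b <- data.frame(id = tiny_net$reaction_ids,
                  lb = c(-10, -10, 0, 0), ub = c(10, 10, 10, NA))
  r <- fba(tiny_net, "4", b)
  expect_equal(r$status, "optimal")
  expect_equal(r$value_num, 20)
  expect_true(in_cone(tiny_cone, r$flux))
  # objective on a blocked reaction: optimum 0
  netb <- metabolic_network(matrix(1, 1, 1), irr = 1)
  rb <- fba(netb, "1", data.frame(id = "1", lb = 0, ub = 5))
  expect_equal(rb$value_num, 0)
  # missing upper bound on an unbounded direction
  r2 <- fba(tiny_net, "4", data.frame(id = tiny_net$reaction_ids,
                                      lb = c(NA, NA, 0, 0),
                                      ub = rep(NA, 4)))
  expect_equal(r2$status, "unbounded")
})
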