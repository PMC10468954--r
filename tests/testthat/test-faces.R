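# Metabolic behaviors, MMBs, the face lattice and its combinatorics.

test_that("metabolic behaviors are exact irreversible supports", {
  expect_equal(metabolic_behavior(tiny_cone, tiny_e1)$reactions, 4L)
  expect_equal(metabolic_behavior(tiny_cone, tiny_e3)$reactions, c(3L, 4L))
  lin <- branched_cone$lineality_basis[[1]]
  mb <- metabolic_behavior(branched_cone, lin)
  expect_equal(mb$reactions, integer(0))
  expect_true(mb$in_lineality)
  expect_error(metabolic_behavior(tiny_cone, -tiny_e1),
               "irreversibility")
})

test_that("MMBs match the worked example in both descriptions", {
  m0 <- mmbs(branched_cone, branched_efms)
  expect_equal(lapply(m0, `[[`, "reactions"),
               list(2L, c(6L, 7L), c(6L, 8L)))
  m1 <- mmbs(branched_canon, branched_efms_canon)
  expect_equal(lapply(m1, `[[`, "reactions"), list(2L, 7L, 8L))
  mt <- mmbs(tiny_cone, tiny_efms)
  expect_equal(lapply(mt, `[[`, "reactions"), list(3L, 4L))
  # every MMB witness sits in a minimal proper face: degree t + 1
  for (m in c(m0, m1))
    expect_equal(m$witness_degree, branched_cone$dim_lineality + 1)
})

test_that("every realized behavior is a union of MMBs", {
  m1 <- mmbs(branched_canon, branched_efms_canon)
  for (i in seq_len(branched_efms_canon$count)) {
    beh <- branched_efms_canon$irr_support[[i]]
    if (length(beh) == 0) next
    expect_true(is_union_of_mmbs(beh, m1))
  }
  expect_true(is_union_of_mmbs(c(3, 4), mmbs(tiny_cone, tiny_efms)))
  expect_true(is_union_of_mmbs(c(2, 7), m1))
  # a set that is not a union of MMBs
  sq <- square_cone()
  msq <- mmbs(sq, enumerate_efms(sq))
  expect_false(is_union_of_mmbs(c(1, 2), msq))
})

test_that("the face lattice reproduces the figure's structure", {
  fl <- face_lattice(branched_canon, branched_efms_canon)
  dims <- vapply(fl$faces, `[[`, integer(1), "dim")
  expect_equal(sort(dims), c(2, 3, 3, 3, 4, 4, 4, 5))
  expect_equal(sum(dims == 2), 1) # the lineality space is the only 2-face
  expect_equal(sum(dims == 5), 1) # the cone itself is the only 5-face
  expect_equal(fl$faces[[fl$bottom]]$dim, branched_canon$dim_lineality)
  expect_equal(fl$faces[[fl$top]]$dim, branched_canon$dim_cone)
  # top face behavior: all free irreversible reactions
  expect_equal(fl$faces[[fl$top]]$behavior, c(2, 7, 8))
  expect_equal(fl$faces[[fl$bottom]]$behavior, integer(0))
  # dims increase strictly along cover edges
  for (k in seq_len(nrow(fl$edges)))
    expect_lt(dims[fl$edges[k, 1]], dims[fl$edges[k, 2]])
  flt <- face_lattice(tiny_canon, tiny_efms)
  expect_equal(sort(vapply(flt$faces, `[[`, integer(1), "dim")),
               c(0, 1, 1, 2))
  expect_error(face_lattice(branched_cone, branched_efms), "canonical")
  # a cone that is all lineality has a single face
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  cone <- canonicalize(flux_cone(net))
  fl1 <- face_lattice(cone, enumerate_efms(cone))
  expect_length(fl1$faces, 1)
})

test_that("MMBs biject with the minimal proper faces of the lattice", {
  fl <- face_lattice(branched_canon, branched_efms_canon)
  m1 <- mmbs(branched_canon, branched_efms_canon)
  t <- branched_canon$dim_lineality
  minimal_faces <- Filter(function(f) f$dim == t + 1, fl$faces)
  expect_equal(length(minimal_faces), length(m1))
  expect_setequal(vapply(minimal_faces, function(f)
    paste(f$behavior, collapse = ","), character(1)),
    vapply(m1, function(m) paste(m$reactions, collapse = ","), character(1)))
})

test_that("the lattice is meet-closed and every k-face holds >= k EFMs", {
  for (pair in list(list(branched_canon, branched_efms_canon),
                    list(tiny_canon, tiny_efms))) {
    fl <- face_lattice(pair[[1]], pair[[2]])
    zsets <- lapply(fl$faces, `[[`, "zero_set")
    keys <- vapply(zsets, paste, character(1), collapse = ",")
    for (i in seq_along(zsets)) for (j in seq_along(zsets)) {
      meet <- sort(union(zsets[[i]], zsets[[j]]))
      # canonicalize the candidate zero set through the EFM supports
      inside <- Filter(function(k)
        !any(pair[[2]]$irr_support[[k]] %in% meet),
        seq_len(pair[[2]]$count))
      active <- sort(unique(unlist(pair[[2]]$irr_support[inside])))
      canon <- sort(setdiff(pair[[1]]$irr, active))
      expect_true(paste(canon, collapse = ",") %in% keys)
    }
    t <- pair[[1]]$dim_lineality
    for (f in fl$faces)
      expect_gte(length(f$efm_indices), f$dim)
  }
})

test_that("relint behaviors agree with the face witnesses", {
  for (f in facets(branched_canon)) {
    beh <- relint_behavior(f)
    expect_equal(beh, sort(setdiff(c(2, 7, 8), f$canonical_zero_set)))
  }
  f3 <- minimal_face(tiny_cone, tiny_e3)
  expect_equal(relint_behavior(f3), c(3L, 4L))
  f0 <- minimal_face(branched_cone, rep(0, 13))
  expect_equal(relint_behavior(f0), integer(0))
})

test_that("l-simplicity is 1 for both example cones", {
  expect_equal(l_simplicity(face_lattice(tiny_canon, tiny_efms)), 1)
  expect_equal(l_simplicity(face_lattice(branched_canon,
                                         branched_efms_canon)), 1)
  net <- metabolic_network(matrix(c(1, -1), 1, 2), irr = integer(0))
  cone <- canonicalize(flux_cone(net))
  expect_equal(l_simplicity(face_lattice(cone, enumerate_efms(cone))), 1)
})

test_that("the MMB cardinality bound holds on both descriptions", {
  expect_equal(mmb_cardinality_bound(tiny_cone), 1)
  expect_equal(max(vapply(mmbs(tiny_cone, tiny_efms),
                          function(m) length(m$reactions), integer(1))), 1)
  # original description: |Irr| = 5, dim C = 5, dim L = 2 -> bound 3
  expect_equal(mmb_cardinality_bound(branched_cone), 3)
  expect_equal(max(vapply(mmbs(branched_cone, branched_efms),
                          function(m) length(m$reactions), integer(1))), 2)
  # canonical description: bound 1, attained
  expect_equal(mmb_cardinality_bound(branched_canon), 1)
})

test_that("facet count equals dim C - dim L iff all MMBs are singletons", {
  r1 <- check_facet_mmb_criterion(tiny_canon, mmbs(tiny_canon, tiny_efms))
  expect_true(r1$facet_criterion && r1$all_singleton)
  r2 <- check_facet_mmb_criterion(branched_canon,
                                  mmbs(branched_canon, branched_efms_canon))
  expect_true(r2$facet_criterion && r2$all_singleton)
  # a canonical cone with two-element MMBs fails both sides coherently
  sq <- square_cone()
  esq <- enumerate_efms(sq)
  expect_equal(sq$irr, 1:4) # nothing was redundant
  r3 <- check_facet_mmb_criterion(sq, mmbs(sq, esq))
  expect_false(r3$facet_criterion)
  expect_false(r3$all_singleton)
  expect_error(check_facet_mmb_criterion(branched_cone,
                                         mmbs(branched_cone, branched_efms)),
               "canonical")
})

test_that("face lattice export writes nodes and edges", {
  fl <- face_lattice(tiny_canon, tiny_efms)
  path <- tempfile(fileext = ".json")
  write_face_lattice(fl, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(obj$nodes, 4)
  expect_true(length(obj$edges) >= 4)
})
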