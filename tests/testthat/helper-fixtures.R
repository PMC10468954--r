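# Shared fixtures, computed once per test run.

tiny_net <- example_network("tiny")
tiny_cone <- flux_cone(tiny_net)
tiny_canon <- canonicalize(tiny_cone)
tiny_efms <- enumerate_efms(tiny_cone)

branched_net <- example_network("branched")
branched_cone <- flux_cone(branched_net)
branched_canon <- canonicalize(branched_cone)
branched_efms <- enumerate_efms(branched_cone)
branched_efms_canon <- enumerate_efms(branched_canon)

# the three EFMs of the tiny network as printed vectors
tiny_e1 <- c(1, 1, 0, 1)
tiny_e2 <- c(-1, -1, 1, 0)
tiny_e3 <- c(0, 0, 1, 1)

# locate a printed EFM (up to positive scaling) in an efm_set; NA if absent
find_efm <- function(efms, v) {
  v <- fluxcone:::rq_primitive(list(n = v, d = rep(1, length(v))))
  for (i in seq_len(efms$count)) {
    if (all(efms$vectors[, i] == v) || all(efms$vectors[, i] == -v)) return(i)
  }
  NA_integer_
}

# deterministic random point of the cone: nonnegative integer combination of
# EFMs plus an integer combination of the lineality basis
random_cone_point <- function(cone, efms, seed) {
  set.seed(seed)
  k <- max(1, efms$count)
  lam <- sample(0:3, efms$count, replace = TRUE)
  if (all(lam == 0) && efms$count > 0) lam[sample.int(efms$count, 1)] <- 1
  v <- if (efms$count > 0) as.numeric(efms$vectors %*% lam)
       else rep(0, cone$network$n)
  for (b in cone$lineality_basis) v <- v + sample(-2:2, 1) * b
  v
}

# a canonical pointed cone whose MMBs all have cardinality two:
# one balance constraint v1 + v2 = v3 + v4, all reactions irreversible
square_cone <- function() {
  net <- metabolic_network(matrix(c(1, 1, -1, -1), 1, 4), irr = 1:4)
  canonicalize(flux_cone(net))
}
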