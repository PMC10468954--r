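# Conic decomposition of flux vectors into few, low-degree EFMs.
#
# Any flux vector of degree k can be written as a positive combination of at
# most k EFMs of degree at most t+1 (t = dim of the lineality space), all
# lying in the vector's minimal face: start from any feasible nonnegative
# combination over the admissible candidates and eliminate linear
# dependencies Caratheodory-style until the active EFMs are linearly
# independent.

#' Decompose a flux vector into EFMs
#'
#' Computes an exact conic decomposition \eqn{v = \sum_i \lambda_i e^i},
#' \eqn{\lambda_i > 0}, with at most \eqn{\deg(v)} terms, every EFM of
#' degree at most \eqn{\dim L + 1} and contained in the minimal face of
#' \eqn{v}.  Candidates are the low-degree EFMs vanishing on the zero set of
#' \eqn{v}; EFMs supported on reversible reactions only enter with both
#' signs.  The initial feasible combination is found by one exact
#' non-negative solve over all candidates at once, then Caratheodory-reduced.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a nonzero vector in the cone (checked exactly).
#' @param efms the complete \code{efm_set} of the cone.
#' @return An object of class \code{flux_decomposition}: list with
#'   \code{coefficients} (exact rational strings), \code{coefficients_rq},
#'   \code{efm_indices} (columns of \code{efms$vectors}; negative index
#'   means the negated reversible-pair EFM), \code{vectors} (the signed EFM
#'   columns used), \code{degree} (of the target), \code{target}.
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' efms <- enumerate_efms(cone)
#' d <- decompose_flux(cone, c(0, 0, 1, 1), efms)
#' d$coefficients # two terms, matching deg = 2
#' @export
decompose_flux <- function(cone, v, efms) {
  v <- flux_vector(cone$network, v)
  if (length(v$support) == 0)
    stop("cannot decompose the zero vector", call. = FALSE)
  .assert_in_cone(cone, v)
  k <- degree(cone, v)
  cand <- .decomposition_candidates(cone, v, efms)
  if (ncol(cand$vectors) == 0)
    stop("no admissible low-degree EFMs in the minimal face; ",
         "is the EFM set complete?", call. = FALSE)
  sol <- .solve_exact_nonneg_combination(cand$vectors, v$v)
  if (!sol$feasible)
    stop("no non-negative combination of low-degree EFMs reproduces the ",
         "target; is the EFM set complete?", call. = FALSE)
  active <- which(sol$x$n != 0)
  terms <- lapply(active, function(i)
    list(coef = list(n = sol$x$n[i], d = sol$x$d[i]),
         vector = cand$vectors[, i], index = cand$indices[i]))
  terms <- caratheodory_reduce(terms, v$v)
  # at most one sign of a reversible-pair EFM may remain active
  idx <- vapply(terms, `[[`, numeric(1), "index")
  stopifnot(!any(duplicated(abs(idx))))
  structure(list(
    coefficients = vapply(terms, function(t)
      rq_format(t$coef$n, t$coef$d), character(1)),
    coefficients_rq = lapply(terms, `[[`, "coef"),
    efm_indices = idx,
    vectors = vapply(terms, `[[`, numeric(nrow(cand$vectors)), "vector"),
    degree = k, target = v),
    class = "flux_decomposition")
}

#' @export
print.flux_decomposition <- function(x, ...) {
  cat("Conic decomposition into", length(x$coefficients),
      "EFMs (target degree", paste0(x$degree, "):"), "\n")
  for (i in seq_along(x$coefficients))
    cat("  ", x$coefficients[i], "* EFM", x$efm_indices[i], "\n")
  invisible(x)
}

# candidate matrix: EFMs with degree <= t+1, vanishing on the zero set of v;
# reversible-pair EFMs contribute both signs (negative index = negated)
.decomposition_candidates <- function(cone, v, efms) {
  t <- cone$dim_lineality
  # containment in the minimal face of v only constrains the irreversible
  # zero set; reversible coordinates outside supp(v) may cancel in the sum
  zero <- setdiff(cone$irr, v$support)
  ok <- which(efms$degrees <= t + 1 &
              vapply(seq_len(efms$count), function(i)
                all(efms$vectors[zero, i] == 0), logical(1)))
  vecs <- efms$vectors[, ok, drop = FALSE]
  indices <- ok
  pairs <- ok[efms$reversible_pair[ok]]
  if (length(pairs) > 0) {
    vecs <- cbind(vecs, -efms$vectors[, pairs, drop = FALSE])
    indices <- c(indices, -pairs)
  }
  list(vectors = vecs, indices = indices)
}

# exact nonneg solve of  V x = target  (x >= 0), V integer matrix
.solve_exact_nonneg_combination <- function(V, target) {
  res <- rq_lp(rq_mat(V), target,
               list(n = rep(0, ncol(V)), d = rep(1, ncol(V))),
               nonneg = seq_len(ncol(V)), maximize = FALSE)
  if (res$status != "optimal") return(list(feasible = FALSE))
  list(feasible = TRUE, x = res$v)
}

#' Caratheodory reduction of a conic combination
#'
#' Given terms with \eqn{\sum_i \lambda_i v^i = } \code{target} exactly and
#' all \eqn{\lambda_i > 0}, repeatedly finds an exact linear dependency
#' \eqn{\sum_i \mu_i v^i = 0} among the active vectors and shifts
#' \eqn{\lambda \leftarrow \lambda - \theta\mu} with the largest \eqn{\theta}
#' keeping all coefficients non-negative, dropping the terms that hit zero.
#' Terminates with a linearly independent active set; the sum is preserved
#' exactly at every step and the term count never increases.
#'
#' @param terms list of terms, each a list with \code{coef} (rq scalar:
#'   list(n, d)) and \code{vector} (integer vector); extra fields are kept.
#' @param target rq vector (list with \code{n}, \code{d}) or coercible.
#' @return The reduced term list.
#' @export
caratheodory_reduce <- function(terms, target) {
  target <- as_rq(target)
  .assert_sum_equals(terms, target)
  repeat {
    if (length(terms) <= 1) break
    V <- vapply(terms, `[[`, numeric(length(target$n)), "vector")
    ker <- rq_nullspace(rq_mat(V))
    if (length(ker) == 0) break # linearly independent: done
    mu <- ker[[1]]
    if (all(mu <= 0)) mu <- -mu
    # theta = min over mu_i > 0 of lambda_i / mu_i; ties -> lowest index
    pos <- which(mu > 0)
    theta <- NULL; drop_i <- NA
    for (i in pos) {
      r <- rq_div(terms[[i]]$coef$n, terms[[i]]$coef$d, mu[i], 1)
      if (is.null(theta) || rq_cmp(r$n, r$d, theta$n, theta$d) < 0) {
        theta <- r; drop_i <- i
      }
    }
    newterms <- list()
    for (i in seq_along(terms)) {
      if (mu[i] == 0) { newterms <- c(newterms, terms[i]); next }
      shift <- rq_mul(theta$n, theta$d, mu[i], 1)
      lam <- rq_sub(terms[[i]]$coef$n, terms[[i]]$coef$d, shift$n, shift$d)
      if (lam$n < 0)
        stop("internal error: Caratheodory step produced a negative ",
             "coefficient")
      if (lam$n == 0) next
      t2 <- terms[[i]]
      t2$coef <- lam
      newterms <- c(newterms, list(t2))
    }
    if (length(newterms) >= length(terms))
      stop("internal error: Caratheodory step did not drop a term")
    terms <- newterms
    .assert_sum_equals(terms, target)
  }
  terms
}

.assert_sum_equals <- function(terms, target) {
  n <- length(target$n)
  s <- list(n = rep(0, n), d = rep(1, n))
  for (t in terms) {
    pr <- rq_mul(t$vector, rep(1, n), t$coef$n, t$coef$d)
    s <- rq_add(s$n, s$d, pr$n, pr$d)
  }
  if (!(all(s$n == target$n) && all(s$d == target$d)))
    stop("conic combination does not sum to the target", call. = FALSE)
  invisible(TRUE)
}

#' Count minimal decompositions of a flux vector
#'
#' Counts the unordered \eqn{k}-subsets (\eqn{k = \deg(v)}, recomputed) of
#' the candidate set — EFMs of degree \eqn{\le \dim L + 1} in the minimal
#' face of \eqn{v}, reversible pairs contributing both signs — for which
#' \eqn{v} is an exact strictly positive combination.  Subsets whose vectors
#' are linearly dependent are disqualified (no unique coefficient vector).
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a nonzero vector in the cone.
#' @param efms the complete \code{efm_set}.
#' @param max_candidates guard on the candidate count (the scan is over
#'   \eqn{\binom{c}{k}} subsets).
#' @return Integer count.
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' efms <- enumerate_efms(cone)
#' count_minimal_decompositions(cone, c(0, 0, 1, 1), efms) # 1
#' @export
count_minimal_decompositions <- function(cone, v, efms, max_candidates = 25) {
  v <- flux_vector(cone$network, v)
  .assert_in_cone(cone, v)
  k <- degree(cone, v)
  cand <- .decomposition_candidates(cone, v, efms)
  nc <- ncol(cand$vectors)
  if (nc > max_candidates)
    stop(nc, " candidate EFMs exceed the guard (", max_candidates, ")",
         call. = FALSE)
  if (nc < k) return(0L)
  count <- 0L
  for (subset in utils::combn(nc, k, simplify = FALSE)) {
    # both signs of one reversible pair can never combine positively
    if (any(duplicated(abs(cand$indices[subset])))) next
    V <- cand$vectors[, subset, drop = FALSE]
    sol <- rq_solve(rq_mat(V), v$v$n, v$v$d)
    if (sol$status != "unique") next
    if (all(sol$x$n > 0)) count <- count + 1L
  }
  count
}

#' Verify a decomposition against the degree theory
#'
#' Asserts, exactly: the terms sum to the target; all coefficients are
#' positive; the term count is at most the target's degree; every EFM used
#' lies in the target's minimal face and has degree at most \eqn{\dim L + 1};
#' and, when the target is itself an EFM of degree \eqn{\ge \dim L + 2},
#' that there are at least two terms, each of degree strictly below the
#' target's.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param d a \code{flux_decomposition}.
#' @return A list of logical clause results (all \code{TRUE}); any violated
#'   clause raises an error naming it.
#' @export
verify_decomposition <- function(cone, d) {
  v <- d$target
  k <- degree(cone, v)
  t <- cone$dim_lineality
  clauses <- list()
  fail <- function(what) stop("decomposition verification failed: ", what,
                              call. = FALSE)
  terms <- lapply(seq_along(d$coefficients), function(i)
    list(coef = d$coefficients_rq[[i]], vector = d$vectors[, i]))
  ok <- tryCatch({ .assert_sum_equals(terms, v$v); TRUE },
                 error = function(e) FALSE)
  if (!ok) fail("terms do not sum to the target")
  clauses$exact_sum <- TRUE
  if (!all(vapply(d$coefficients_rq, function(c) c$n > 0, logical(1))))
    fail("non-positive coefficient")
  clauses$positive <- TRUE
  if (length(d$coefficients) > k) fail("more than deg(target) terms")
  clauses$count <- TRUE
  zero <- setdiff(cone$irr, v$support)
  degs <- integer(length(terms))
  for (i in seq_along(terms)) {
    e <- terms[[i]]$vector
    if (any(e[zero] != 0)) fail("term outside the minimal face of the target")
    degs[i] <- degree(cone, e)
    if (degs[i] > t + 1) fail("term of degree above dim(L) + 1")
  }
  clauses$in_face <- TRUE
  clauses$low_degree <- TRUE
  if (is_efm(cone, rq_primitive(v$v)) && k >= t + 2) {
    if (length(terms) < 2) fail("EFM of high degree decomposed into < 2 terms")
    if (any(degs >= k)) fail("EFM decomposition term of degree >= deg(target)")
    clauses$efm_split <- TRUE
  }
  clauses
}
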