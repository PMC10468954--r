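# Elementary flux modes: verification, enumeration, degree analysis.
#
# An EFM is a nonzero flux vector of inclusionwise minimal support.  The rank
# test certifies EFM-ness: v in C is an EFM iff
# rank(S_{*,supp(v)}) = |supp(v)| - 1.  Enumeration splits every reversible
# reaction into a forward/backward pair, which makes the cone pointed in the
# lifted space; the extreme rays of the lifted cone map onto the EFMs of the
# original cone (futile two-cycles excepted).  The degree of each EFM is
# always computed back in the original cone: in the lifted cone every
# extreme ray trivially has degree 1, which says nothing about the geometry
# of C itself.

#' Rank test for elementary flux modes
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a nonzero vector (coerced by \code{\link{flux_vector}}).
#' @return \code{TRUE} iff \code{v} lies in the cone and
#'   \eqn{\mathrm{rank}(S_{\ast,\mathrm{supp}(v)}) = |\mathrm{supp}(v)| - 1}
#'   (both checked exactly).
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' is_efm(cone, c(1, 1, 0, 1))   # TRUE
#' is_efm(cone, c(1, 1, 1, 2))   # FALSE: support is not minimal
#' @export
is_efm <- function(cone, v) {
  v <- flux_vector(cone$network, v)
  if (length(v$support) == 0)
    stop("the zero vector is not an elementary flux mode", call. = FALSE)
  if (!in_cone(cone, v)) return(FALSE)
  Ssub <- rq_mat_clear_denominators(cone$network$S)[, v$support, drop = FALSE]
  int_rank(Ssub) == length(v$support) - 1L
}

# ---- double description ----------------------------------------------------

# Extreme rays of { w in R^N | E w = 0, w >= 0 } for an integer matrix E.
# Rays are maintained as primitive integer columns.  Equality rows are
# inserted in ascending index order; adjacency is decided by an exact rank
# test on the common zero set.
.dd_extreme_rays <- function(E) {
  N <- ncol(E)
  rays <- diag(1, N)
  processed <- matrix(0, 0, N)
  for (r in seq_len(nrow(E))) {
    a <- E[r, ]
    s <- as.numeric(a %*% rays)
    .rq_check(s)
    zero <- which(s == 0)
    pos <- which(s > 0)
    neg <- which(s < 0)
    newrays <- rays[, zero, drop = FALSE]
    if (length(pos) > 0 && length(neg) > 0) {
      for (p in pos) for (q in neg) {
        if (!.dd_adjacent(rays, p, q, processed)) next
        comb <- s[p] * rays[, q] - s[q] * rays[, p]
        .rq_check(comb)
        comb <- rq_primitive(list(n = comb, d = rep(1, N)))
        newrays <- cbind(newrays, comb)
      }
    }
    rays <- newrays
    processed <- rbind(processed, a)
    if (ncol(rays) == 0) break
  }
  rays
}

# rank-based adjacency: rays p, q of the current cone are adjacent iff the
# common zero set (coordinate zeros plus all processed equality rows) fixes a
# two-dimensional subspace
.dd_adjacent <- function(rays, p, q, processed) {
  N <- nrow(rays)
  Z <- which(rays[, p] == 0 & rays[, q] == 0)
  units <- matrix(0, length(Z), N)
  if (length(Z) > 0) units[cbind(seq_along(Z), Z)] <- 1
  M <- rbind(processed, units)
  if (nrow(M) == 0) return(N == 2)
  int_rank(M) == N - 2L
}

#' Enumerate all elementary flux modes
#'
#' Splits each reversible reaction \eqn{j} into nonnegative forward and
#' backward parts \eqn{w_j^+ , w_j^-}, enumerates the extreme rays of the
#' lifted pointed cone \eqn{\{w \ge 0 \mid [S, -S_{\ast,Rev}]\, w = 0\}} with
#' the double description method in exact arithmetic, maps each ray back via
#' \eqn{v_j = w_j^+ - w_j^-}, discards futile two-cycle rays (an artifact of
#' the splitting whose support is a single forward/backward pair) and
#' deduplicates to canonical primitive vectors.  An EFM whose support
#' contains no irreversible reaction lies in the lineality space and is
#' reported once, with its implied negation flagged
#' (\code{reversible_pair}).
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param max_split_size guard on the lifted dimension \eqn{n + |Rev|}
#'   (configuration value, not a hard algorithmic bound).
#' @return An object of class \code{efm_set}: list with \code{vectors}
#'   (n-by-k integer matrix, one primitive column per EFM), \code{degrees}
#'   (in the original cone), \code{irr_support} (list, indices w.r.t. the
#'   cone's current description), \code{reversible_pair} (logical),
#'   \code{count}, \code{count_with_pairs_doubled}.
#' @examples
#' efms <- enumerate_efms(flux_cone(example_network("tiny")))
#' efms$vectors
#' @export
enumerate_efms <- function(cone, max_split_size = 60) {
  net <- cone$network
  n <- net$n
  split <- sort(setdiff(seq_len(n), union(cone$irr, cone$blocked_irr)))
  if (n + length(split) > max_split_size)
    stop("lifted dimension ", n + length(split), " exceeds the guard (",
         max_split_size, "); raise max_split_size or use a smaller network",
         call. = FALSE)
  S <- rq_mat_clear_denominators(net$S)
  # lifted system: original columns, then one negated column per split
  # reaction; blocked irreversible reactions of a canonical description are
  # implicit equalities, enforced as extra unit rows
  E <- cbind(S, -S[, split, drop = FALSE])
  if (length(cone$blocked_irr) > 0 && !all(cone$blocked_irr %in% cone$irr)) {
    bl <- setdiff(cone$blocked_irr, cone$irr)
    units <- matrix(0, length(bl), ncol(E))
    units[cbind(seq_along(bl), bl)] <- 1
    E <- rbind(E, units)
  }
  rays <- .dd_extreme_rays(E)
  vecs <- list()
  for (k in seq_len(ncol(rays))) {
    w <- rays[, k]
    v <- w[seq_len(n)]
    if (length(split) > 0) {
      wneg <- w[n + seq_along(split)]
      # futile two-cycle: support is exactly one split pair
      supp_w <- which(w != 0)
      both <- split[v[split] != 0 & wneg != 0]
      if (length(supp_w) == 2 && length(both) == 1 &&
          all(supp_w %in% c(both, n + match(both, split)))) next
      if (length(both) > 0)
        stop("internal error: extreme ray activates both directions of a ",
             "split reaction")
      v[split] <- v[split] - wneg
    }
    if (all(v == 0)) next
    vecs[[length(vecs) + 1]] <- v
  }
  .efm_set(cone, vecs)
}

# assemble an efm_set from raw candidate vectors: canonicalize the sign of
# lineality-space EFMs, deduplicate, sort columns lexicographically
.efm_set <- function(cone, vecs) {
  net <- cone$network
  irr_orig <- net$irr
  canon <- lapply(vecs, function(v) {
    # primitive scaling; the sign convention is first-nonzero-positive for
    # reversible-pair EFMs, while an active irreversible reaction fixes the
    # orientation outright
    p <- rq_primitive(list(n = v, d = rep(1, net$n)))
    if (any(v[irr_orig] != 0) && any(p * sign(v) < 0)) {
      p <- -p
      p[p == 0] <- 0
    }
    stopifnot(all(p[irr_orig] >= 0))
    p
  })
  keys <- vapply(canon, paste, character(1), collapse = ",")
  canon <- canon[!duplicated(keys)]
  if (length(canon) > 1) { # numeric column-lexicographic order (locale-free)
    M <- do.call(rbind, canon)
    canon <- canon[do.call(order, as.data.frame(M))]
  }
  V <- if (length(canon) > 0) do.call(cbind, canon)
       else matrix(0, net$n, 0)
  revpair <- vapply(canon, function(v) !any(v[irr_orig] != 0), logical(1))
  degs <- vapply(canon, function(v) degree(cone, v), integer(1))
  irrsupp <- lapply(canon, function(v) sort(intersect(which(v != 0),
                                                      cone$irr)))
  structure(list(vectors = V, degrees = degs, irr_support = irrsupp,
                 reversible_pair = revpair,
                 count = length(canon),
                 count_with_pairs_doubled = length(canon) + sum(revpair),
                 cone = cone, network = net),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  cat("Set of", x$count, "elementary flux modes",
      if (any(x$reversible_pair))
        paste0("(", sum(x$reversible_pair),
               " reversible pairs counted once; ",
               x$count_with_pairs_doubled, " with pairs doubled)"), "\n")
  if (x$count > 0)
    cat("  degree distribution:",
        paste(names(table(x$degrees)), table(x$degrees),
              sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Brute-force EFM enumeration (independent oracle)
#'
#' Scans all \eqn{2^n} support candidates and accepts a support \eqn{R'} iff
#' the support-restricted stoichiometric matrix has a one-dimensional kernel
#' (\eqn{\mathrm{rank}(S_{\ast,R'}) = |R'| - 1}) whose kernel vector has no
#' zero entry and is sign-feasible on the irreversible reactions.  Entirely
#' independent of the double description path; used to cross-validate
#' \code{\link{enumerate_efms}}.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param max_n guard on the subset scan (default 14).
#' @return An \code{efm_set}, canonically ordered like
#'   \code{\link{enumerate_efms}}.
#' @export
efms_brute_force <- function(cone, max_n = 14) {
  net <- cone$network
  n <- net$n
  if (n > max_n)
    stop("brute-force enumeration scans 2^n supports; n = ", n,
         " exceeds the guard (", max_n, ")", call. = FALSE)
  S <- rq_mat_clear_denominators(net$S)
  vecs <- list()
  for (code in seq_len(2^n - 1)) {
    supp <- which(bitwAnd(code, bitwShiftL(1, 0:(n - 1))) != 0)
    Ssub <- S[, supp, drop = FALSE]
    if (int_rank(Ssub) != length(supp) - 1L) next
    ker <- rq_nullspace(rq_mat(Ssub))
    if (length(ker) != 1L) next
    z <- ker[[1]]
    if (any(z == 0)) next # kernel vector must realize the full support
    v <- rep(0, n)
    v[supp] <- z
    irr_active <- intersect(supp, net$irr)
    if (length(irr_active) > 0) {
      if (all(v[irr_active] > 0)) {
        vecs[[length(vecs) + 1]] <- v
      } else if (all(v[irr_active] < 0)) {
        vecs[[length(vecs) + 1]] <- -v
      }
      # mixed signs on Irr: no feasible orientation
    } else {
      vecs[[length(vecs) + 1]] <- v # reversible pair, canonical sign
    }
  }
  .efm_set(cone, vecs)
}

#' Degree histogram of an EFM set
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param efms an \code{efm_set}.
#' @return Named integer vector: counts per degree value; empty for an empty
#'   set.
#' @export
degree_distribution <- function(cone, efms) {
  if (efms$count == 0) return(integer(0))
  tab <- table(efms$degrees)
  stats::setNames(as.integer(tab), names(tab))
}

#' Verify the degree and support bounds on an EFM set
#'
#' Checks, exactly and per EFM:
#' \itemize{
#'   \item the rank test (EFM certificate),
#'   \item \eqn{|\mathrm{irr.supp}(e)| \le \mathrm{rank}(S_{\ast,Irr}) + 1},
#'   \item \eqn{\deg(e) \le \dim L + |\mathrm{irr.supp}(e)|},
#'   \item \eqn{\deg(e) \le \dim L + \mathrm{rank}(S_{\ast,Irr}) + 1},
#'   \item on canonical cones with \eqn{|Irr| > \mathrm{rank}(S_{\ast,Irr}) +
#'     q} for \eqn{q \in \{1,2,3\}}: \eqn{\deg(e) \le \dim C - q},
#'   \item if \code{l} is given (canonical cones):
#'     \eqn{\deg(e) \le \dim C - (|Irr| - \mathrm{rank}(S_{\ast,Irr}) - 1)/l}.
#' }
#' A violation indicates an implementation bug, not a property of the
#' network, and raises an error.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param efms an \code{efm_set}.
#' @param l optional simplicity parameter of the cone (see
#'   \code{\link{l_simplicity}}).
#' @return A list of summary statistics: \code{max_irr_supp},
#'   \code{rank_S_irr}, \code{max_degree}, \code{bound_irr_supp},
#'   \code{bound_degree_supp} (per-EFM, reported as max), \code{bound_degree},
#'   \code{q_applied}, \code{all_pass}.
#' @export
check_degree_bounds <- function(cone, efms, l = NULL) {
  net <- cone$network
  irr <- cone$irr
  S <- rq_mat_clear_denominators(net$S)
  rank_irr <- if (length(irr) > 0) int_rank(S[, irr, drop = FALSE]) else 0L
  t <- cone$dim_lineality
  q_applied <- 0L
  if (cone$canonical) {
    for (q in 3:1) {
      if (length(irr) > rank_irr + q) { q_applied <- q; break }
    }
  }
  max_is <- 0L; max_deg <- t
  for (i in seq_len(efms$count)) {
    v <- efms$vectors[, i]
    is_size <- length(efms$irr_support[[i]])
    deg <- efms$degrees[i]
    max_is <- max(max_is, is_size)
    max_deg <- max(max_deg, deg)
    fail <- function(what)
      stop("degree-bound verification failed (", what, ") for EFM ", i,
           call. = FALSE)
    if (!is_efm(cone, v)) fail("rank test")
    if (is_size > rank_irr + 1) fail("irr-support bound")
    if (deg > t + is_size) fail("degree vs irr-support")
    if (deg > t + rank_irr + 1) fail("degree vs rank bound")
    if (q_applied > 0 && deg > cone$dim_cone - q_applied)
      fail(paste0("facet-count bound, q = ", q_applied))
    if (!is.null(l) && cone$canonical) {
      if (deg > cone$dim_cone - (length(irr) - (rank_irr + 1)) / l)
        fail("l-simplicity bound")
    }
  }
  list(max_irr_supp = max_is, rank_S_irr = rank_irr, max_degree = max_deg,
       dim_lineality = t, dim_cone = cone$dim_cone,
       bound_irr_supp = rank_irr + 1L,
       bound_degree_supp = t + max_is,
       bound_degree = t + rank_irr + 1L,
       q_applied = q_applied, all_pass = TRUE)
}
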