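# The steady-state flux cone and its core geometry.
#
# The cone of a network N = (M, R, S, Irr) is
#   C = { v in R^n | S v = 0, v_j >= 0 for j in Irr }.
# Irreversibility constraints that hold with equality everywhere on C mark
# blocked reactions; constraints implied by the others are redundant and can
# be shifted to Rev without changing C.  Both are detected by exact LPs.

# integer matrix of the equality system: S rows + unit rows for `zero_rows`
.eq_system <- function(net, zero_rows = integer(0)) {
  S <- rq_mat_clear_denominators(net$S)
  if (length(zero_rows) > 0) {
    units <- matrix(0, length(zero_rows), net$n)
    units[cbind(seq_along(zero_rows), zero_rows)] <- 1
    S <- rbind(S, units)
  }
  S
}

# LP over the flux cone: optimize v_j subject to Sv = 0, v_i >= 0 for
# i in irr_set, plus box rows (|v_j| <= 1 style) given as list(idx, rhs, sense)
# with sense "<=" or ">=".  Returns rq_lp result on the v variables only.
.cone_lp <- function(net, obj_idx, irr_set, bound_rows = list(),
                     maximize = TRUE) {
  n <- net$n
  m <- net$m
  nb <- length(bound_rows)
  # columns: v (n), slacks (nb)
  An <- cbind(net$S$n, matrix(0, m, nb))
  Ad <- cbind(net$S$d, matrix(1, m, nb))
  bn <- rep(0, m); bd <- rep(1, m)
  for (i in seq_along(bound_rows)) {
    br <- bound_rows[[i]]
    row_n <- rep(0, n + nb); row_d <- rep(1, n + nb)
    row_n[br$idx] <- 1
    row_n[n + i] <- if (br$sense == "<=") 1 else -1
    An <- rbind(An, row_n); Ad <- rbind(Ad, row_d)
    r <- .parse_rational_one(br$rhs)
    bn <- c(bn, r[1]); bd <- c(bd, r[2])
  }
  cn <- rep(0, n + nb); cd <- rep(1, n + nb)
  cn[obj_idx] <- 1
  res <- rq_lp(list(n = An, d = Ad), list(n = bn, d = bd),
               list(n = cn, d = cd),
               nonneg = c(irr_set, n + seq_len(nb)), maximize = maximize)
  if (res$status == "optimal")
    res$v <- list(n = res$v$n[seq_len(n)], d = res$v$d[seq_len(n)])
  res
}

#' Build the steady-state flux cone of a network
#'
#' Constructs \eqn{C = \{v \mid Sv = 0,\; v_j \ge 0 \ \forall j \in Irr\}},
#' detects blocked reactions (both irreversible and reversible) by exact LPs,
#' and computes the lineality space \eqn{L = \{v \mid Sv = 0, v_{Irr} = 0\}}
#' and the dimensions \eqn{\dim C} and \eqn{t = \dim L}.
#'
#' The returned cone keeps the network's original description (all of
#' \code{Irr} as inequality constraints); \code{\link{canonicalize}} turns it
#' into an irredundant description without implicit equalities.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @return An object of class \code{flux_cone} with fields \code{network},
#'   \code{irr} (current irreversibility-constraint set), \code{rev},
#'   \code{blocked_irr}, \code{blocked_rev}, \code{lineality_basis} (list of
#'   primitive integer vectors), \code{dim_lineality}, \code{dim_cone},
#'   \code{canonical}, \code{shift_history}.
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' cone$dim_cone
#' @export
flux_cone <- function(net) {
  cone <- structure(list(network = net, irr = net$irr, rev = net$rev,
                         blocked_irr = integer(0), blocked_rev = integer(0),
                         canonical = FALSE, shift_history = integer(0)),
                    class = "flux_cone")
  bl <- blocked_reactions(cone)
  cone$blocked_irr <- bl$blocked_irr
  cone$blocked_rev <- bl$blocked_rev
  # lineality space: Sv = 0, v_Irr = 0
  Lmat <- .eq_system(net, net$irr)
  cone$lineality_basis <- rq_nullspace(rq_mat(Lmat))
  cone$dim_lineality <- length(cone$lineality_basis)
  # dim C = n - rank of the implicit-equality system (S plus blocked rows;
  # blocked reversible reactions are forced to zero by S and the blocked
  # irreversible ones, so adding their rows changes nothing)
  cone$dim_cone <- net$n - int_rank(.eq_system(net, cone$blocked_irr))
  cone
}

#' @export
print.flux_cone <- function(x, ...) {
  cat("Flux cone on", x$network$n, "reactions\n")
  cat("  dim C =", x$dim_cone, ", dim L =", x$dim_lineality, "\n")
  cat("  irreversibility constraints:",
      paste(x$network$reaction_ids[x$irr], collapse = ", "), "\n")
  if (length(x$blocked_irr))
    cat("  blocked irreversible:",
        paste(x$network$reaction_ids[x$blocked_irr], collapse = ", "), "\n")
  if (length(x$blocked_rev))
    cat("  blocked reversible:",
        paste(x$network$reaction_ids[x$blocked_rev], collapse = ", "), "\n")
  cat("  canonical:", x$canonical, "\n")
  invisible(x)
}

#' Detect blocked reactions
#'
#' A reaction is blocked if it carries zero flux in every steady-state flux
#' vector.  For an irreversible reaction \code{j} this means
#' \eqn{\max\{v_j \mid v \in C, v_j \le 1\} = 0}; a reversible reaction is
#' blocked iff both that maximum and the corresponding minimum are zero.  All
#' verdicts come from the exact rational simplex.
#'
#' @param cone a \code{\link{flux_cone}} (or a \code{metabolic_network}).
#' @return A list with integer index sets \code{blocked_irr} and
#'   \code{blocked_rev}.
#' @export
blocked_reactions <- function(cone) {
  net <- if (inherits(cone, "flux_cone")) cone$network else cone
  irr <- net$irr
  blocked_irr <- integer(0)
  for (j in irr) {
    r <- .cone_lp(net, j, irr,
                  list(list(idx = j, rhs = 1, sense = "<=")), maximize = TRUE)
    stopifnot(r$status == "optimal")
    if (r$value$n == 0) blocked_irr <- c(blocked_irr, j)
  }
  blocked_rev <- integer(0)
  for (j in net$rev) {
    up <- .cone_lp(net, j, irr,
                   list(list(idx = j, rhs = 1, sense = "<=")), maximize = TRUE)
    if (up$value$n != 0) next
    lo <- .cone_lp(net, j, irr,
                   list(list(idx = j, rhs = -1, sense = ">=")),
                   maximize = FALSE)
    if (lo$value$n == 0) blocked_rev <- c(blocked_rev, j)
  }
  list(blocked_irr = blocked_irr, blocked_rev = blocked_rev)
}

#' Detect redundant irreversibility constraints
#'
#' The constraint \eqn{v_j \ge 0} is redundant if dropping it does not change
#' the cone, i.e. if \eqn{\min\{v_j \mid Sv = 0,\; v_i \ge 0\ \forall i \in
#' Irr\setminus\{j\},\; v_j \ge -1\} = 0}.  Constraints that are implicit
#' equalities (blocked reactions) are classified as blocked, not redundant,
#' and are skipped here.  The test is one-at-a-time against the cone's
#' current constraint set.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @return Integer indices of the redundant constraints.
#' @export
redundant_irr_constraints <- function(cone) {
  net <- cone$network
  out <- integer(0)
  candidates <- setdiff(cone$irr, cone$blocked_irr)
  for (j in candidates) {
    if (.irr_constraint_redundant(net, cone$irr, j)) out <- c(out, j)
  }
  out
}

.irr_constraint_redundant <- function(net, irr_set, j) {
  r <- .cone_lp(net, j, setdiff(irr_set, j),
                list(list(idx = j, rhs = -1, sense = ">=")), maximize = FALSE)
  stopifnot(r$status == "optimal")
  r$value$n == 0
}

#' Canonicalize a flux cone description
#'
#' Produces an equivalent description of the same cone with no implicit
#' equalities and no redundant inequalities among the irreversibility
#' constraints: blocked irreversible constraints are recorded as implicit
#' equalities, and redundant constraints are shifted to the reversible set
#' one at a time, re-testing after each shift (the resulting irredundant
#' description depends on the removal order; the default removes the
#' redundant constraint with the smallest reaction index first).
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param order \code{"lexicographic"} (default) or an integer vector giving
#'   the order in which candidate constraints are examined.
#' @return A canonical \code{flux_cone}; the shifted reactions are recorded
#'   in \code{shift_history}.  Idempotent.
#' @export
canonicalize <- function(cone, order = "lexicographic") {
  if (cone$canonical) return(cone)
  net <- cone$network
  irr <- setdiff(cone$irr, cone$blocked_irr)
  if (identical(order, "lexicographic")) order <- sort(irr)
  order <- intersect(as.integer(order), irr)
  if (!setequal(order, irr))
    stop("order must be a permutation of the unblocked irreversible set",
         call. = FALSE)
  shifted <- integer(0)
  repeat {
    moved <- FALSE
    for (j in order) {
      if (!(j %in% irr)) next
      if (.irr_constraint_redundant(net, irr, j)) {
        irr <- setdiff(irr, j)
        shifted <- c(shifted, j)
        moved <- TRUE
        break # re-test remaining constraints against the new description
      }
    }
    if (!moved) break
  }
  cone$irr <- irr
  cone$rev <- setdiff(seq_len(net$n), union(irr, cone$blocked_irr))
  cone$shift_history <- shifted
  cone$canonical <- TRUE
  cone
}

# ---- membership ------------------------------------------------------------

#' Exact cone membership
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a \code{\link{flux_vector}} or coercible vector.
#' @return \code{TRUE}/\code{FALSE} (exact test: \eqn{Sv = 0} and
#'   \eqn{v_{Irr} \ge 0}).
#' @export
in_cone <- function(cone, v) {
  is.null(.cone_violation(cone, v))
}

# NULL if v in C, else a message naming the violated constraint
.cone_violation <- function(cone, v) {
  net <- cone$network
  v <- flux_vector(net, v)
  for (i in seq_len(net$m)) {
    s <- list(n = 0, d = 1)
    for (j in v$support) {
      pr <- rq_mul(net$S$n[i, j], net$S$d[i, j], v$v$n[j], v$v$d[j])
      s <- rq_add(s$n, s$d, pr$n, pr$d)
    }
    if (s$n != 0)
      return(paste0("steady-state constraint violated for metabolite ",
                    net$metabolite_ids[i]))
  }
  bad <- net$irr[v$v$n[net$irr] < 0]
  if (length(bad) > 0)
    return(paste0("irreversibility constraint violated for reaction ",
                  net$reaction_ids[bad[1]]))
  NULL
}

.assert_in_cone <- function(cone, v) {
  msg <- .cone_violation(cone, v)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# ---- degree and faces ------------------------------------------------------

#' Degree of a flux vector
#'
#' The degree of \eqn{v \in C} is the dimension of the inclusionwise minimal
#' face of the cone containing \eqn{v}:
#' \eqn{\deg(v) = n - \mathrm{rank}(A_v^=)}, where \eqn{A_v^=} stacks the
#' stoichiometric rows with a unit row for every irreversible reaction that
#' is inactive in \eqn{v}.  Vectors in the lineality space have degree
#' \eqn{\dim L}, vectors in minimal proper faces degree \eqn{\dim L + 1} and
#' vectors in the relative interior degree \eqn{\dim C}.  The value is a
#' property of the cone itself, not of its description, so it must be (and
#' is) computed in the original cone, never in the reconfigured cone used for
#' enumeration.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a \code{\link{flux_vector}} or coercible vector; must lie in the
#'   cone (checked exactly).
#' @return Integer degree.
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' degree(cone, c(0, 0, 1, 1)) # relative interior: degree = dim C = 2
#' degree(cone, c(1, 1, 0, 1)) # extreme ray: degree 1
#' @export
degree <- function(cone, v) {
  v <- flux_vector(cone$network, v)
  .assert_in_cone(cone, v)
  zero <- union(cone$blocked_irr, cone$irr[!(cone$irr %in% v$support)])
  cone$network$n - int_rank(.eq_system(cone$network, zero))
}

# construct a face from a requested zero set Z over the current Irr:
# F = { v in C | v_Z = 0 }.  The canonical zero set adds every unblocked
# irreversible reaction that is forced to zero on F; a relint witness with
# strictly positive flux on all remaining irreversible reactions is built
# from one exact LP witness per coordinate.
.make_face <- function(cone, zero_set, witness = NULL) {
  net <- cone$network
  free <- setdiff(cone$irr, union(zero_set, cone$blocked_irr))
  zero <- setdiff(intersect(zero_set, cone$irr), cone$blocked_irr)
  if (is.null(witness)) {
    wit_n <- rep(0, net$n); wit_d <- rep(1, net$n)
    forced <- integer(0)
    for (j in free) {
      r <- .cone_lp(net, j, union(cone$irr, cone$blocked_irr),
                    c(lapply(union(zero, cone$blocked_irr), function(z)
                        list(idx = z, rhs = 0, sense = "<=")),
                      list(list(idx = j, rhs = 1, sense = "<="))),
                    maximize = TRUE)
      stopifnot(r$status == "optimal")
      if (r$value$n == 0) {
        forced <- c(forced, j)
      } else {
        s <- rq_add(wit_n, wit_d, r$v$n, r$v$d)
        wit_n <- s$n; wit_d <- s$d
      }
    }
    zero <- sort(union(zero, forced))
    witness <- list(n = wit_n, d = wit_d)
  } else {
    witness <- flux_vector(net, witness)$v
    zero <- sort(setdiff(setdiff(cone$irr, which(witness$n != 0)),
                         cone$blocked_irr))
  }
  dim <- net$n - int_rank(.eq_system(net, union(cone$blocked_irr, zero)))
  structure(list(cone = cone, zero_set = sort(zero_set),
                 canonical_zero_set = zero, dim = dim,
                 relint_witness = witness),
            class = "cone_face")
}

#' @export
print.cone_face <- function(x, ...) {
  ids <- x$cone$network$reaction_ids
  cat("Face of dimension", x$dim, "\n")
  cat("  zero set (irreversible):",
      if (length(x$canonical_zero_set))
        paste(ids[x$canonical_zero_set], collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Facets of a canonical flux cone
#'
#' On an irredundant description without implicit equalities, the cone has
#' exactly one facet \eqn{F = \{v \in C \mid v_j = 0\}} per remaining
#' irreversible reaction \eqn{j}, each of dimension \eqn{\dim C - 1}.
#'
#' @param cone a canonical \code{\link{flux_cone}} (see
#'   \code{\link{canonicalize}}).
#' @return List of \code{cone_face} objects.
#' @export
facets <- function(cone) {
  if (!cone$canonical)
    stop("facets() requires a canonical cone; call canonicalize() first",
         call. = FALSE)
  lapply(cone$irr, function(j) .make_face(cone, j))
}

#' Minimal face containing a flux vector
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a vector in the cone (checked exactly).
#' @return A \code{cone_face} with zero set \eqn{\{j \in Irr \mid v_j = 0\}},
#'   dimension \code{degree(cone, v)}, and \code{v} as relative-interior
#'   witness.
#' @export
minimal_face <- function(cone, v) {
  v <- flux_vector(cone$network, v)
  .assert_in_cone(cone, v)
  zero <- sort(cone$irr[!(cone$irr %in% v$support)])
  f <- .make_face(cone, zero, witness = v)
  f
}

#' Relative-interior test
#'
#' \eqn{v \in \mathrm{relint}(C)} iff every unblocked irreversible reaction is
#' strictly active in \eqn{v}, equivalently iff
#' \code{degree(cone, v) == cone$dim_cone}.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a vector in the cone (checked exactly).
#' @return Logical.
#' @export
in_relative_interior <- function(cone, v) {
  v <- flux_vector(cone$network, v)
  .assert_in_cone(cone, v)
  free <- setdiff(cone$irr, cone$blocked_irr)
  all(free %in% v$support)
}

# ---- pointed decomposition C = L + P --------------------------------------

#' Decompose the cone into lineality space plus a pointed cone
#'
#' Writes \eqn{C = L + P} with \eqn{P = \mathrm{cone}(\{g^1, \ldots, g^s\})}
#' pointed and \eqn{L \cap P = \{0\}}.  One generator is taken per minimal
#' proper face (equivalently per minimal metabolic behavior), projected onto
#' the orthogonal complement of \eqn{L} and rescaled to primitive integer
#' form, which guarantees \eqn{\dim C = \dim L + \dim P}.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param efms optional \code{\link{enumerate_efms}} result; enumerated on
#'   demand.
#' @param complement which complement of \eqn{L} the generators are chosen
#'   in: \code{"orthogonal"} (default) projects each witness onto
#'   \eqn{L^\perp}; \code{"coordinate"} zeroes the witness on a pivot
#'   coordinate set of \eqn{L} by subtracting a lineality vector.  The
#'   combinatorics of the pointed part do not depend on this choice.
#' @return A list with \code{lineality_basis}, \code{generators} (list of
#'   primitive integer vectors, one per minimal proper face), \code{mmbs}
#'   (their irreversible supports) and \code{complement}.
#' @export
pointed_decomposition <- function(cone, efms = NULL,
                                  complement = c("orthogonal", "coordinate")) {
  complement <- match.arg(complement)
  if (is.null(efms)) efms <- enumerate_efms(cone)
  beh <- mmbs(cone, efms)
  B <- cone$lineality_basis
  project <- if (complement == "orthogonal") .project_off_lineality
             else .project_off_lineality_coord
  gens <- lapply(beh, function(b) {
    g <- efms$vectors[, b$witness_index]
    p <- project(g, B)
    # primitive rescaling may flip the sign; the MMB fixes the orientation
    if (any(p[cone$irr] < 0)) {
      p <- -p
      p[p == 0] <- 0
    }
    p
  })
  if (length(gens) > 0) {
    G <- do.call(cbind, gens)
    rkG <- int_rank(t(G))
    full <- if (length(B) > 0) int_rank(t(cbind(do.call(cbind, B), G)))
            else rkG
    stopifnot(full == length(B) + rkG)
  }
  list(lineality_basis = B, generators = gens,
       mmbs = lapply(beh, `[[`, "reactions"), complement = complement)
}

# project integer vector g onto the orthogonal complement of span(B),
# exactly, returning a primitive integer vector
.project_off_lineality <- function(g, B) {
  if (length(B) == 0) {
    v <- list(n = g, d = rep(1, length(g)))
    return(rq_primitive(v))
  }
  Bm <- do.call(cbind, B) # n x t integer
  BtB <- crossprod(Bm)
  Btg <- as.numeric(crossprod(Bm, g))
  .rq_check(BtB, Btg)
  sol <- rq_solve(rq_mat(BtB), Btg)
  stopifnot(sol$status == "unique")
  # g - B x
  res <- list(n = g, d = rep(1, length(g)))
  for (k in seq_along(B)) {
    term <- rq_mul(Bm[, k], rep(1, nrow(Bm)), sol$x$n[k], sol$x$d[k])
    res <- rq_sub(res$n, res$d, term$n, term$d)
  }
  rq_primitive(res)
}

# coordinate complement: L' = {x | x_P = 0} for a pivot column set P of the
# lineality basis; subtract the unique l in L with l_P = g_P
.project_off_lineality_coord <- function(g, B) {
  if (length(B) == 0)
    return(rq_primitive(list(n = g, d = rep(1, length(g)))))
  Bm <- do.call(cbind, B)
  piv <- rq_rref(rq_mat(t(Bm)))$pivots
  sol <- rq_solve(rq_mat(Bm[piv, , drop = FALSE]), g[piv])
  stopifnot(sol$status == "unique")
  res <- list(n = g, d = rep(1, length(g)))
  for (k in seq_along(B)) {
    term <- rq_mul(Bm[, k], rep(1, nrow(Bm)), sol$x$n[k], sol$x$d[k])
    res <- rq_sub(res$n, res$d, term$n, term$d)
  }
  rq_primitive(res)
}

# ---- flux balance analysis -------------------------------------------------

#' Flux balance analysis by exact simplex
#'
#' Maximizes the flux through \code{objective} over \eqn{\{Sv = 0\}}
#' intersected with the given box bounds, using the exact rational simplex,
#' so the optimal value is exact and the returned vertex is a rational
#' vector whose degree can be computed reliably.  Irreversible reactions get
#' an effective lower bound of \eqn{\max(0, \mathrm{stated\ lower})}.  The
#' optimal value is unique; the optimal vector in general is not.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param objective a reaction id (or 1-based index).
#' @param bounds a data frame with columns \code{id}, \code{lb}, \code{ub}
#'   (numeric or rational strings; \code{NA} = unbounded on that side).
#' @return A list with \code{status}, \code{value} (exact rational string),
#'   \code{value_num}, and \code{flux} (a \code{\link{flux_vector}}).
#' @examples
#' net <- example_network("tiny")
#' b <- data.frame(id = net$reaction_ids, lb = c(-10, -10, 0, 0),
#'                 ub = c(10, 10, 10, NA))
#' fba(net, "4", b)$value_num # 20 = the two capped inflows combined
#' @export
fba <- function(net, objective, bounds) {
  obj <- if (is.numeric(objective)) as.integer(objective)
         else match(as.character(objective), net$reaction_ids)
  if (is.na(obj) || obj < 1 || obj > net$n)
    stop("unknown objective reaction: ", objective, call. = FALSE)
  bound_rows <- list()
  for (i in seq_len(nrow(bounds))) {
    j <- match(as.character(bounds$id[i]), net$reaction_ids)
    if (is.na(j)) stop("unknown reaction id in bounds: ", bounds$id[i],
                       call. = FALSE)
    lb <- bounds$lb[i]; ub <- bounds$ub[i]
    if (j %in% net$irr) {
      lb <- if (is.na(lb)) 0 else {
        if (rq_cmp(.parse_rational_one(lb)[1], .parse_rational_one(lb)[2],
                   0, 1) < 0) 0 else lb
      }
    }
    if (!is.na(ub))
      bound_rows <- c(bound_rows, list(list(idx = j, rhs = ub, sense = "<=")))
    if (!is.na(lb))
      bound_rows <- c(bound_rows, list(list(idx = j, rhs = lb, sense = ">=")))
  }
  res <- .cone_lp(net, obj, irr_set = net$irr, bound_rows = bound_rows,
                  maximize = TRUE)
  if (res$status != "optimal")
    return(list(status = res$status, value = NULL, flux = NULL))
  list(status = "optimal",
       value = rq_format(res$value$n, res$value$d),
       value_num = res$value$n / res$value$d,
       flux = flux_vector(net, rq_format(res$v$n, res$v$d)))
}
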