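# Metabolic behaviors, MMBs and the face lattice.
#
# A metabolic behavior is the set of irreversible reactions active in some
# flux vector; the inclusion-minimal behaviors (MMBs) are in one-to-one
# correspondence with the minimal proper faces of the flux cone, which have
# dimension dim(L) + 1 and generalize extreme rays to non-pointed cones.
# All relative-interior points of a face share one behavior, so a face can
# be identified with its canonical zero set of irreversible reactions.

#' Metabolic behavior of a flux vector
#'
#' The set of irreversible reactions active in \code{v}.  An empty behavior
#' means \code{v} lies in the lineality space (flagged, since behaviors are
#' nonempty by definition).
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param v a vector in the cone (checked exactly).
#' @return A list with \code{reactions} (integer indices into the cone's
#'   current irreversible set) and \code{in_lineality} (logical).
#' @export
metabolic_behavior <- function(cone, v) {
  v <- flux_vector(cone$network, v)
  .assert_in_cone(cone, v)
  beh <- sort(intersect(v$support, cone$irr))
  list(reactions = beh, in_lineality = length(beh) == 0)
}

#' Minimal metabolic behaviors
#'
#' The inclusion-minimal elements of the set of behaviors realized by the
#' EFMs.  Every behavior is a union of MMBs, and MMBs correspond one-to-one
#' to the minimal proper faces of the cone, so each MMB is returned with a
#' witness EFM (which necessarily has degree \eqn{\dim L + 1}).
#'
#' Note that MMBs depend on the cone's description: shifting a redundant
#' irreversibility constraint to the reversible set (see
#' \code{\link{canonicalize}}) can shrink the behaviors even though the cone
#' itself is unchanged.
#'
#' @param cone a \code{\link{flux_cone}}.
#' @param efms the complete \code{efm_set} of the cone.
#' @return A list of MMBs, each a list with \code{reactions} (sorted integer
#'   indices), \code{witness_index} (column in \code{efms$vectors}) and
#'   \code{witness_degree}.
#' @examples
#' cone <- flux_cone(example_network("tiny"))
#' efms <- enumerate_efms(cone)
#' lapply(mmbs(cone, efms), `[[`, "reactions") # {3} and {4}
#' @export
mmbs <- function(cone, efms) {
  beh <- efms$irr_support
  nonempty <- which(vapply(beh, length, integer(1)) > 0)
  if (length(nonempty) == 0) return(list())
  uniq <- unique(beh[nonempty])
  minimal <- Filter(function(b) {
    !any(vapply(uniq, function(o)
      length(o) < length(b) && all(o %in% b), logical(1)))
  }, uniq)
  minimal <- minimal[order(vapply(minimal, function(b) # locale-free key
    paste(sprintf("%04d", b), collapse = ""), character(1)))]
  lapply(minimal, function(b) {
    wit <- nonempty[vapply(beh[nonempty], identical, logical(1), b)][1]
    list(reactions = b, witness_index = wit,
         witness_degree = efms$degrees[wit])
  })
}

#' Is a behavior a union of MMBs?
#'
#' Every realized metabolic behavior is the union of the MMBs it contains;
#' this checks that property for a candidate set.
#'
#' @param behavior integer set of irreversible reaction indices.
#' @param mmb_list result of \code{\link{mmbs}}.
#' @return \code{TRUE} iff the union of all MMBs contained in
#'   \code{behavior} reconstructs it exactly.
#' @export
is_union_of_mmbs <- function(behavior, mmb_list) {
  behavior <- sort(unique(as.integer(behavior)))
  inside <- Filter(function(m) all(m$reactions %in% behavior), mmb_list)
  covered <- sort(unique(unlist(lapply(inside, `[[`, "reactions"))))
  identical(covered, behavior)
}

#' Relative-interior behavior of a face
#'
#' All points in the relative interior of a face share the same irreversible
#' support: the unblocked irreversible reactions outside the face's canonical
#' zero set.  Verified against the face's stored witness.
#'
#' @param face a \code{cone_face}.
#' @return Sorted integer vector of irreversible reaction indices.
#' @export
relint_behavior <- function(face) {
  cone <- face$cone
  beh <- sort(setdiff(setdiff(cone$irr, cone$blocked_irr),
                      face$canonical_zero_set))
  wit_active <- which(face$relint_witness$n != 0)
  stopifnot(identical(beh, sort(intersect(wit_active, cone$irr))))
  beh
}

#' Face lattice of a small canonical flux cone
#'
#' Enumerates all faces as intersections of facets: the candidate zero sets
#' are the closure of the facet singletons under union, each canonicalized to
#' the maximal zero set defining the same face and deduplicated.  Faces are
#' annotated with dimension, relative-interior behavior and the EFMs they
#' contain (an EFM lies in a face iff its irreversible support avoids the
#' face's zero set).  The bottom of the lattice is the lineality space, the
#' top the cone itself.
#'
#' @param cone a canonical \code{\link{flux_cone}} (see
#'   \code{\link{canonicalize}}); MMBs and hence facets differ between
#'   descriptions, so the caller must pick the description explicitly.
#' @param efms the complete \code{efm_set} of the cone.
#' @param max_facets guard on the number of facets (the closure can have up
#'   to \eqn{2^{|Irr|}} candidates).
#' @return An object of class \code{face_lattice}: list with \code{faces}
#'   (each: \code{zero_set}, \code{dim}, \code{behavior}, \code{efm_indices},
#'   \code{witness}), \code{edges} (two-column matrix of cover relations,
#'   child containing parent), \code{bottom}, \code{top}.
#' @export
face_lattice <- function(cone, efms, max_facets = 25) {
  if (!cone$canonical)
    stop("face_lattice() requires a canonical cone; call canonicalize() ",
         "first", call. = FALSE)
  irr <- cone$irr
  if (length(irr) > max_facets)
    stop(length(irr), " facets exceed the guard (", max_facets, ")",
         call. = FALSE)
  # candidate zero sets: all subsets of Irr (meet closure of the facets),
  # canonicalized via the EFMs the face contains
  nIrr <- length(irr)
  seen <- new.env(parent = emptyenv())
  faces <- list()
  for (code in 0:(2^nIrr - 1)) {
    zset <- irr[bitwAnd(code, bitwShiftL(1, seq_len(nIrr) - 1)) != 0]
    inside <- which(vapply(efms$irr_support, function(s)
      !any(s %in% zset), logical(1)))
    # canonical zero set: irreversible reactions inactive in every EFM of
    # the face (EFMs generate the face, so their union of supports is the
    # relint behavior)
    active <- sort(unique(unlist(efms$irr_support[inside])))
    canon <- sort(setdiff(irr, active))
    key <- paste0("z:", paste(canon, collapse = ","))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    zero_rows <- union(cone$blocked_irr, canon)
    dim <- cone$network$n - int_rank(.eq_system(cone$network, zero_rows))
    witness <- if (length(inside) > 0)
      rowSums(efms$vectors[, inside, drop = FALSE]) else
      rep(0, cone$network$n)
    faces[[length(faces) + 1]] <-
      list(zero_set = canon, dim = dim, behavior = setdiff(irr, canon),
           efm_indices = inside, witness = witness)
  }
  ord <- order(vapply(faces, `[[`, integer(1), "dim"),
               vapply(faces, function(f)
                 paste(sprintf("%04d", f$zero_set), collapse = ""),
                 character(1)))
  faces <- faces[ord]
  dims <- vapply(faces, `[[`, integer(1), "dim")
  # cover relations: F < G iff zero(F) superset of zero(G); cover if no face
  # strictly between
  nf <- length(faces)
  leq <- matrix(FALSE, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (i != j && all(faces[[j]]$zero_set %in% faces[[i]]$zero_set) &&
        dims[i] < dims[j])
      leq[i, j] <- TRUE
  }
  edges <- NULL
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (!leq[i, j]) next
    between <- any(leq[i, ] & leq[, j])
    if (!between) edges <- rbind(edges, c(i, j))
  }
  structure(list(faces = faces, edges = edges,
                 bottom = which.min(dims), top = which.max(dims),
                 cone = cone),
            class = "face_lattice")
}

#' @export
print.face_lattice <- function(x, ...) {
  dims <- vapply(x$faces, `[[`, integer(1), "dim")
  cat("Face lattice with", length(x$faces), "faces; dimensions:",
      paste(dims, collapse = ", "), "\n")
  invisible(x)
}

#' Simplicity parameter of a face lattice
#'
#' The smallest integer \eqn{l \ge 1} such that every \eqn{k}-face lies in at
#' most \eqn{l (\dim C - k)} facets.  Facet membership is counted via zero-set
#' containment.
#'
#' @param lattice a \code{\link{face_lattice}}.
#' @return Integer \eqn{l}.
#' @export
l_simplicity <- function(lattice) {
  dims <- vapply(lattice$faces, `[[`, integer(1), "dim")
  dimC <- max(dims)
  facet_zero <- lapply(lattice$faces[dims == dimC - 1],
                       `[[`, "zero_set")
  l <- 1L
  for (f in lattice$faces) {
    k <- f$dim
    if (k == dimC) next
    cnt <- sum(vapply(facet_zero, function(z) all(z %in% f$zero_set),
                      logical(1)))
    l <- max(l, as.integer(ceiling(cnt / (dimC - k))))
  }
  l
}

#' Upper bound on MMB cardinality
#'
#' \eqn{|D| \le |Irr| - (\dim C - \dim L) + 1} for every MMB \eqn{D},
#' evaluated on the cone's current description (the bound applies both before
#' and after redundancy removal, with different \eqn{|Irr|}).
#'
#' @param cone a \code{\link{flux_cone}}.
#' @return Integer bound.
#' @export
mmb_cardinality_bound <- function(cone) {
  length(cone$irr) - (cone$dim_cone - cone$dim_lineality) + 1L
}

#' Facet-count criterion for singleton MMBs
#'
#' On an irredundant description without implicit equalities, the number of
#' facets equals \eqn{\dim C - \dim L} if and only if every MMB is a
#' singleton.  Both sides are evaluated independently; a disagreement would
#' indicate an implementation bug and raises an error.
#'
#' @param cone a canonical \code{\link{flux_cone}}.
#' @param mmb_list result of \code{\link{mmbs}} on the canonical cone.
#' @return A list with \code{facet_criterion} (facet count equals
#'   \eqn{\dim C - \dim L}) and \code{all_singleton}; always equal.
#' @export
check_facet_mmb_criterion <- function(cone, mmb_list) {
  if (!cone$canonical)
    stop("check_facet_mmb_criterion() requires a canonical cone",
         call. = FALSE)
  facet_criterion <- length(cone$irr) == cone$dim_cone - cone$dim_lineality
  all_singleton <- length(mmb_list) > 0 &&
    all(vapply(mmb_list, function(m) length(m$reactions), integer(1)) == 1L)
  if (length(mmb_list) == 0) all_singleton <- length(cone$irr) == 0
  if (facet_criterion != all_singleton)
    stop("facet-count criterion and MMB cardinalities disagree: ",
         "this indicates an implementation bug", call. = FALSE)
  list(facet_criterion = facet_criterion, all_singleton = all_singleton)
}
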