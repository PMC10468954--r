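# End-to-end analysis: build -> blocked -> (canonicalize) -> EFMs -> MMBs ->
# degree bounds, summarized the way the in-package examples are tabulated.

#' Full geometric analysis of a metabolic network
#'
#' Runs the whole pipeline: cone construction with blocked-reaction
#' detection, optional lexicographic canonicalization, EFM enumeration,
#' degree distribution, minimal metabolic behaviors, degree/support bound
#' verification, and (for small cones) the face lattice.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param canonical if \code{TRUE} (default) analyze the canonicalized
#'   description; MMBs in particular depend on this choice.
#' @param with_lattice enumerate the face lattice when the facet count
#'   permits (canonical descriptions only).
#' @return An object of class \code{fluxcone_report}: nested list with
#'   \code{network}, \code{cone}, \code{efm} and \code{mmb} summaries plus
#'   the underlying objects (\code{cone_obj}, \code{efms_obj}, ...).
#' @examples
#' rep <- analyze_network(example_network("tiny"))
#' rep$cone$dim_cone
#' @export
analyze_network <- function(net, canonical = TRUE, with_lattice = TRUE) {
  cone <- flux_cone(net)
  if (canonical) cone <- canonicalize(cone)
  efms <- enumerate_efms(cone)
  beh <- mmbs(cone, efms)
  bounds <- check_degree_bounds(cone, efms)
  S <- rq_mat_clear_denominators(net$S)
  lattice <- NULL
  if (with_lattice && canonical && length(cone$irr) <= 12)
    lattice <- face_lattice(cone, efms)
  mmb_sizes <- vapply(beh, function(m) length(m$reactions), integer(1))
  report <- list(
    network = list(m = net$m, n = net$n,
                   n_irr = length(net$irr), n_rev = length(net$rev),
                   rank_S = int_rank(S)),
    cone = list(dim_cone = cone$dim_cone,
                dim_lineality = cone$dim_lineality,
                dim_pointed = cone$dim_cone - cone$dim_lineality,
                n_facets = if (cone$canonical) length(cone$irr) else NA,
                blocked_irr = cone$blocked_irr,
                blocked_rev = cone$blocked_rev,
                shifted_to_rev = cone$shift_history,
                canonical = cone$canonical),
    efm = list(count = efms$count,
               count_with_pairs_doubled = efms$count_with_pairs_doubled,
               degree_distribution = degree_distribution(cone, efms),
               max_irr_supp = bounds$max_irr_supp,
               rank_S_irr = bounds$rank_S_irr,
               max_degree = bounds$max_degree,
               bound_irr_supp = bounds$bound_irr_supp,
               bound_degree = bounds$bound_degree),
    mmb = list(count = length(beh),
               cardinalities = mmb_sizes,
               cardinality_bound = mmb_cardinality_bound(cone)),
    cone_obj = cone, efms_obj = efms, mmbs_obj = beh, lattice_obj = lattice)
  class(report) <- "fluxcone_report"
  report
}

#' @export
print.fluxcone_report <- function(x, ...) {
  cat("Flux cone analysis\n")
  cat(sprintf("  network: %d metabolites x %d reactions (%d irr, %d rev), rank(S) = %d\n",
              x$network$m, x$network$n, x$network$n_irr, x$network$n_rev,
              x$network$rank_S))
  cat(sprintf("  cone: dim C = %d, dim L = %d, dim P = %d%s\n",
              x$cone$dim_cone, x$cone$dim_lineality, x$cone$dim_pointed,
              if (!is.na(x$cone$n_facets))
                sprintf(", %d facets", x$cone$n_facets) else ""))
  if (length(x$cone$blocked_irr))
    cat("  blocked irreversible:", paste(x$cone$blocked_irr, collapse = ", "),
        "\n")
  if (length(x$cone$shifted_to_rev))
    cat("  redundant constraints shifted to Rev:",
        paste(x$cone$shifted_to_rev, collapse = ", "), "\n")
  cat(sprintf("  EFMs: %d (%d with reversible pairs doubled), max degree %d (bound %d), max |irr.supp| %d (bound %d)\n",
              x$efm$count, x$efm$count_with_pairs_doubled, x$efm$max_degree,
              x$efm$bound_degree, x$efm$max_irr_supp, x$efm$bound_irr_supp))
  dd <- x$efm$degree_distribution
  if (length(dd))
    cat("  degree distribution:",
        paste(names(dd), dd, sep = ":", collapse = "  "), "\n")
  cat(sprintf("  MMBs: %d, max cardinality %s (bound %d)\n", x$mmb$count,
              if (length(x$mmb$cardinalities)) max(x$mmb$cardinalities)
              else "-", x$mmb$cardinality_bound))
  invisible(x)
}

#' Export an EFM set to TSV (+ JSON sidecar)
#'
#' Writes the EFM matrix as TSV (rows = reactions by network id, one column
#' per EFM, primitive integer entries) and a JSON sidecar with per-EFM
#' degree, irreversible support and reversible-pair flag.
#'
#' @param efms an \code{efm_set}.
#' @param path output TSV path; the sidecar goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_efms <- function(efms, path) {
  net <- efms$network
  tab <- data.frame(reaction = net$reaction_ids, efms$vectors,
                    check.names = FALSE)
  colnames(tab) <- c("reaction", paste0("efm", seq_len(efms$count)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(seq_len(efms$count), function(i)
    list(id = paste0("efm", i),
         degree = efms$degrees[i],
         irr_support = as.list(net$reaction_ids[efms$irr_support[[i]]]),
         reversible_pair = efms$reversible_pair[i]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a face lattice to JSON
#'
#' Nodes carry the canonical zero set, dimension, relative-interior behavior
#' and contained EFM ids; edges are the cover relations.
#'
#' @param lattice a \code{\link{face_lattice}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_face_lattice <- function(lattice, path) {
  ids <- lattice$cone$network$reaction_ids
  nodes <- lapply(seq_along(lattice$faces), function(i) {
    f <- lattice$faces[[i]]
    list(id = i, zero_set = as.list(ids[f$zero_set]), dim = f$dim,
         behavior = as.list(ids[f$behavior]),
         efms = as.list(paste0("efm", f$efm_indices)))
  })
  edges <- if (is.null(lattice$edges)) list() else
    lapply(seq_len(nrow(lattice$edges)), function(k)
      list(from = lattice$edges[k, 1], to = lattice$edges[k, 2]))
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE)
  invisible(path)
}
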