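# Metabolic network data model, file I/O and instance generators.

#' Construct a metabolic network
#'
#' A metabolic network is a stoichiometric matrix \code{S} (metabolites in
#' rows, reactions in columns) together with a partition of the reactions into
#' reversible and irreversible ones.  All stoichiometric coefficients are kept
#' as exact rationals.
#'
#' @param S stoichiometric matrix: an integer-valued numeric matrix, or a
#'   character matrix with entries such as \code{"2"}, \code{"-1/3"} or
#'   \code{"0.5"} (parsed exactly).
#' @param irr indices (1-based) of the irreversible reactions.
#' @param reaction_ids,metabolite_ids optional identifier vectors; default to
#'   \code{"1"}, \code{"2"}, ... and \code{"M1"}, \code{"M2"}, ...
#' @return An object of class \code{metabolic_network} with fields \code{S}
#'   (exact rational matrix), \code{irr}, \code{rev}, \code{reaction_ids},
#'   \code{metabolite_ids}, \code{m}, \code{n}.
#' @examples
#' net <- metabolic_network(matrix(c(1, -1, 0, 0, 0, 1, 1, -1), 2, 4,
#'                                 byrow = TRUE), irr = c(3, 4))
#' net$n
#' @export
metabolic_network <- function(S, irr, reaction_ids = NULL,
                              metabolite_ids = NULL) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  vals <- vapply(as.vector(S), .parse_rational_one, numeric(2))
  Srq <- list(n = matrix(vals[1, ], m, n), d = matrix(vals[2, ], m, n))
  irr <- sort(unique(as.integer(irr)))
  if (length(irr) > 0 && (min(irr) < 1 || max(irr) > n))
    stop("irr indices out of range 1..", n, call. = FALSE)
  if (is.null(reaction_ids)) reaction_ids <- as.character(seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  if (length(reaction_ids) != n)
    stop("need one reaction id per column of S", call. = FALSE)
  if (length(metabolite_ids) != m)
    stop("need one metabolite id per row of S", call. = FALSE)
  structure(list(S = Srq, m = m, n = n,
                 irr = irr, rev = setdiff(seq_len(n), irr),
                 reaction_ids = as.character(reaction_ids),
                 metabolite_ids = as.character(metabolite_ids)),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", x$m, "metabolites,", x$n, "reactions\n")
  cat("  irreversible:", if (length(x$irr)) paste(x$reaction_ids[x$irr],
                                                  collapse = ", ") else "none", "\n")
  cat("  reversible:  ", if (length(x$rev)) paste(x$reaction_ids[x$rev],
                                                  collapse = ", ") else "none", "\n")
  invisible(x)
}

# dense numeric view of S (exact when entries are integers)
network_S_double <- function(net) net$S$n / net$S$d

#' Built-in example networks
#'
#' Two small networks used throughout the documentation and tests:
#' \describe{
#'   \item{\code{"tiny"}}{2 metabolites, 4 reactions, reactions 3 and 4
#'     irreversible.  Its flux cone is pointed and two-dimensional, spanned by
#'     two elementary flux modes, and it carries a third EFM in the relative
#'     interior of the cone — the smallest example in which an EFM attains
#'     the degree bound \eqn{\dim L + \mathrm{rank}(S_{\ast,Irr}) + 1}.}
#'   \item{\code{"branched"}}{8 metabolites (A..H), 13 reactions, with
#'     \code{Irr} = \{2, 6, 7, 8, 13\}.  It exhibits a blocked irreversible
#'     reaction (13: metabolite H is produced but never consumed), a
#'     redundant irreversibility constraint (reaction 6), a two-dimensional
#'     lineality space and a five-dimensional flux cone.}
#' }
#'
#' @param name which example to return.
#' @return A \code{\link{metabolic_network}}.
#' @examples
#' example_network("tiny")
#' @export
example_network <- function(name = c("tiny", "branched")) {
  name <- match.arg(name)
  if (name == "tiny") {
    S <- matrix(c(1, -1, 0, 0,
                  0, 1, 1, -1), 2, 4, byrow = TRUE)
    return(metabolic_network(S, irr = c(3, 4),
                             metabolite_ids = c("A", "B")))
  }
  S <- matrix(c(
    1, -1, 0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,
    0,  1, 1,  0, -1,  0,  0,  0,  0,  0,  0,  0,  0,
    0,  1, 0, -1,  0, -1,  0,  0,  0,  0,  0,  0,  0,
    0,  0, 0,  0,  1,  0,  0,  1, -1,  0, -1,  0,  0,
    0,  0, 0,  0,  0,  1, -1, -1,  0,  0,  0,  0,  0,
    0,  0, 0,  0,  0,  0,  0,  0,  0,  0,  1, -1,  0,
    0,  0, 0,  0,  0,  0,  0,  0,  1, -1,  0,  0, -1,
    0,  0, 0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  1),
    8, 13, byrow = TRUE)
  metabolic_network(S, irr = c(2, 6, 7, 8, 13),
                    metabolite_ids = c("A", "B", "C", "D", "E", "F", "G", "H"))
}

#' Random test network generator
#'
#' Draws an integer stoichiometric matrix with entries uniform on
#' \code{-entry_range..entry_range}, each entry nonzero with probability
#' \code{density}, resampling until every row and every column has at least
#' one nonzero entry, and picks a random subset of \code{n_irr} reactions as
#' irreversible.  Fully determined by \code{seed}; intended for property
#' tests and cross-validation of the two EFM enumerators.
#'
#' @param m,n numbers of metabolites and reactions.
#' @param n_irr number of irreversible reactions (0..n).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param density probability that an entry is nonzero, in (0, 1].
#' @param entry_range entries are drawn from \code{-entry_range..entry_range}.
#' @return A \code{\link{metabolic_network}}.
#' @examples
#' random_network(4, 8, n_irr = 4, seed = 1)
#' @export
random_network <- function(m, n, n_irr, seed, density = 0.5, entry_range = 2) {
  if (m < 1 || n < 1) stop("need m >= 1 and n >= 1", call. = FALSE)
  if (n_irr < 0 || n_irr > n) stop("need 0 <= n_irr <= n", call. = FALSE)
  if (density <= 0 || density > 1) stop("need 0 < density <= 1", call. = FALSE)
  if (entry_range < 1) stop("need entry_range >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (attempt in seq_len(1000)) {
    mask <- matrix(stats::runif(m * n) < density, m, n)
    vals <- matrix(sample(c(seq_len(entry_range), -seq_len(entry_range)),
                          m * n, replace = TRUE), m, n)
    S <- ifelse(mask, vals, 0)
    if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0)) {
      irr <- if (n_irr > 0) sort(sample.int(n, n_irr)) else integer(0)
      return(metabolic_network(S, irr = irr))
    }
  }
  stop("could not generate a network with a nonzero entry in every row and ",
       "column; increase density", call. = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- file I/O --------------------------------------------------------------

.format_S_entry <- function(n, d) {
  if (d == 1) n else paste0(n, "/", d)
}

#' Read a metabolic network from a file
#'
#' Supported formats:
#' \describe{
#'   \item{\code{json}}{\code{{"metabolites": [...], "reactions":
#'     [{"id": ..., "reversible": ...}, ...], "S": [[...], ...]}} with
#'     \code{S} in metabolite-major (row) order; non-integer entries encoded
#'     as strings \code{"p/q"} or decimal strings, parsed exactly.}
#'   \item{\code{tsv}}{matrix file (rows = metabolites, first column =
#'     metabolite id, header = reaction ids) plus a sidecar file
#'     \code{<path>.rev.tsv} with columns \code{id} and \code{reversible}
#'     (0/1).}
#'   \item{\code{sbml}}{SBML level 3 via the \pkg{xml2} package (must be
#'     installed); reaction reversibility flags map to the Rev/Irr partition
#'     and only non-boundary species become rows of \code{S}.}
#' }
#'
#' @param path file path.
#' @param format one of \code{"json"}, \code{"tsv"}, \code{"sbml"}; guessed
#'   from the extension by default.
#' @return A \code{\link{metabolic_network}} with reaction order as in the
#'   file.
#' @seealso \code{\link{write_network}}
#' @export
read_network <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         json = .read_network_json(path),
         tsv = .read_network_tsv(path),
         sbml = .read_network_sbml(path))
}

.read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions", "S"))
    if (is.null(obj[[field]]))
      stop("network JSON is missing field '", field, "'", call. = FALSE)
  mets <- vapply(obj$metabolites, as.character, character(1))
  ids <- vapply(obj$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry missing field 'id'", call. = FALSE)
    as.character(r$id)
  }, character(1))
  rev_flags <- vapply(obj$reactions, function(r) {
    if (is.null(r$reversible) || !is.logical(r$reversible))
      stop("reaction '", r$id, "': field 'reversible' must be true/false",
           call. = FALSE)
    r$reversible
  }, logical(1))
  if (anyDuplicated(ids))
    stop("duplicate reaction ids in network JSON", call. = FALSE)
  # a redundant 'irreversible' field is tolerated only when consistent
  for (r in obj$reactions) {
    if (!is.null(r$irreversible) && identical(r$irreversible, r$reversible))
      stop("reaction '", r$id, "' is marked both reversible and irreversible",
           call. = FALSE)
  }
  # allow mixed numeric/string rows: normalize everything to character
  Schr <- do.call(rbind, lapply(obj$S, function(row)
    vapply(row, function(x) as.character(x), character(1))))
  if (nrow(Schr) != length(mets) || ncol(Schr) != length(ids))
    stop("S has shape ", nrow(Schr), "x", ncol(Schr), " but there are ",
         length(mets), " metabolites and ", length(ids), " reactions",
         call. = FALSE)
  metabolic_network(Schr, irr = which(!rev_flags),
                    reaction_ids = ids, metabolite_ids = mets)
}

.read_network_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  mets <- tab[[1]]
  ids <- colnames(tab)[-1]
  Schr <- as.matrix(tab[, -1, drop = FALSE])
  side <- paste0(path, ".rev.tsv")
  if (!file.exists(side))
    stop("sidecar reversibility file not found: ", side, call. = FALSE)
  revtab <- utils::read.table(side, sep = "\t", header = TRUE,
                              colClasses = c("character", "integer"))
  if (!all(c("id", "reversible") %in% colnames(revtab)))
    stop("sidecar file needs columns 'id' and 'reversible'", call. = FALSE)
  if (!setequal(revtab$id, ids))
    stop("sidecar reaction ids do not match the matrix header", call. = FALSE)
  rev_flags <- revtab$reversible[match(ids, revtab$id)] == 1
  metabolic_network(Schr, irr = which(!rev_flags),
                    reaction_ids = ids, metabolite_ids = mets)
}

.read_network_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML import requires the 'xml2' package", call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition")
  internal <- is.na(boundary) | boundary %in% c("false", "0")
  mets <- sp_id[internal]
  reactions <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(reactions, "id")
  rev_attr <- xml2::xml_attr(reactions, "reversible")
  rev_flags <- is.na(rev_attr) | rev_attr %in% c("true", "1")
  S <- matrix("0", length(mets), length(reactions))
  for (j in seq_along(reactions)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(reactions[[j]],
                                 paste0("./", side, "/speciesReference"))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        if (is.na(st)) st <- "1"
        i <- match(sp, mets)
        if (is.na(i)) next # boundary species: not a row of S
        cur <- .parse_rational_one(S[i, j])
        add <- .parse_rational_one(st)
        r <- rq_add(cur[1], cur[2], sgn * add[1], add[2])
        S[i, j] <- .format_S_entry(r$n, r$d)
      }
    }
  }
  metabolic_network(S, irr = which(!rev_flags),
                    reaction_ids = ids, metabolite_ids = mets)
}

#' Write a metabolic network to a file
#'
#' Inverse of \code{\link{read_network}} for the \code{json} and \code{tsv}
#' formats; round-trips are exact, including entries with denominators
#' greater than one.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  Sn <- net$S$n; Sd <- net$S$d
  if (format == "json") {
    rows <- lapply(seq_len(net$m), function(i)
      lapply(seq_len(net$n), function(j) {
        if (Sd[i, j] == 1) Sn[i, j] else paste0(Sn[i, j], "/", Sd[i, j])
      }))
    obj <- list(
      metabolites = as.list(net$metabolite_ids),
      reactions = lapply(seq_len(net$n), function(j)
        list(id = net$reaction_ids[j], reversible = j %in% net$rev)),
      S = rows)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    Schr <- matrix(mapply(.format_S_entry, Sn, Sd), net$m, net$n)
    tab <- data.frame(metabolite = net$metabolite_ids, Schr,
                      check.names = FALSE)
    colnames(tab) <- c("metabolite", net$reaction_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    revtab <- data.frame(id = net$reaction_ids,
                         reversible = as.integer(seq_len(net$n) %in% net$rev))
    utils::write.table(revtab, paste0(path, ".rev.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- flux vectors ----------------------------------------------------------

#' Exact flux vector
#'
#' Wraps a length-\code{n} rational vector together with its network, with
#' exact support accessors (no tolerances: an entry is active iff it is
#' exactly nonzero).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param x numeric (integer-valued) or character vector of length
#'   \code{net$n}; strings such as \code{"1/3"} are parsed exactly.
#' @return An object of class \code{flux_vector} with fields \code{v} (rq
#'   vector), \code{support}, \code{irr_support}, \code{rev_support}
#'   (1-based reaction indices).
#' @examples
#' net <- example_network("tiny")
#' flux_vector(net, c(0, 0, 1, 1))$irr_support
#' @export
flux_vector <- function(net, x) {
  if (inherits(x, "flux_vector")) return(x)
  v <- as_rq(x)
  if (length(v$n) != net$n)
    stop("flux vector has length ", length(v$n), ", expected ", net$n,
         call. = FALSE)
  supp <- which(v$n != 0)
  structure(list(v = v, network = net,
                 support = supp,
                 irr_support = intersect(supp, net$irr),
                 rev_support = intersect(supp, net$rev)),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("Flux vector:", paste(rq_format(x$v$n, x$v$d), collapse = " "), "\n")
  cat("  support:", paste(x$network$reaction_ids[x$support], collapse = ", "),
      "\n")
  invisible(x)
}
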