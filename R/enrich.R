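#' Normalize metabolite names for set matching
#'
#' Lowercases, strips leading D-/L- stereo prefixes, removes punctuation and
#' whitespace, then applies the editable alias table. The same normalization
#' is applied to queries, set members and universe, so matching is robust to
#' capitalization and hyphenation variants.
#'
#' @param x character vector of metabolite names.
#' @param aliases alias table path (two tab-separated columns `alias`,
#'   `canonical`; default: bundled).
#' @return normalized character vector, same length.
#' @export
normalize_metabolite_names <- function(x,
    aliases = system.file("extdata", "metabolite_aliases.tsv",
                          package = "psametab")) {
  out <- tolower(x)
  out <- sub("^[dl]-", "", out)
  out <- gsub("[^a-z0-9]", "", out)
  if (nzchar(aliases) && file.exists(aliases)) {
    al <- utils::read.delim(aliases, stringsAsFactors = FALSE,
                            comment.char = "#")
    hit <- match(out, al$alias)
    out[!is.na(hit)] <- al$canonical[hit[!is.na(hit)]]
  }
  out
}

#' Read a GMT-format metabolite-set library
#'
#' Tab-separated, one set per line: name, description, then members. Empty
#' member fields (e.g. from trailing tabs) are dropped per GMT convention.
#'
#' @param path GMT file (default: the bundled curated library of ~20 serum
#'   metabolite sets).
#' @return object of class `metabolite_set_library`: list with `sets` (named
#'   list of member vectors), `descriptions`, and normalized member index.
#' @export
read_gmt <- function(path = system.file("extdata", "metabolite_sets.gmt",
                                        package = "psametab")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need name, description, ",
                            "members): ", substr(ln, 1, 40))
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (length(members) == 0) stop("empty set in GMT: ", f[1])
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc,
                 normalized = lapply(sets, normalize_metabolite_names)),
            class = "metabolite_set_library")
}

#' @export
print.metabolite_set_library <- function(x, ...) {
  cat("metabolite_set_library:", length(x$sets), "sets,",
      length(unique(unlist(x$normalized))), "distinct metabolites\n")
  invisible(x)
}

#' Hypergeometric over-representation analysis of a metabolite list
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the realized number of query hits, given the set size and universe;
#' one-tailed (over-representation only). Raw p-values are BH-adjusted across
#' sets. The enrichment ratio is observed hits over expected hits
#' `k / (n * K / N)`. Sets are ranked by raw p, ties broken by ratio.
#'
#' @param query character vector of metabolite names (e.g. the significant
#'   panel); every query name must map into the universe.
#' @param library a `metabolite_set_library`.
#' @param universe universe of measurable metabolites; default: all library
#'   members plus the query.
#' @return data.frame of class `enrichment_result`: per set `set`, `hits`,
#'   `set_size` (within-universe), `query_size`, `universe_size`, `p`,
#'   `p_adj`, `enrichment_ratio`, `members_hit`.
#' @export
hypergeometric_ora <- function(query, library = read_gmt(), universe = NULL) {
  stopifnot(inherits(library, "metabolite_set_library"))
  qn <- unique(normalize_metabolite_names(query))
  un <- if (is.null(universe))
    unique(c(unlist(library$normalized), qn))
  else unique(normalize_metabolite_names(universe))
  unmapped <- setdiff(qn, un)
  if (length(unmapped) > 0)
    stop("query metabolite(s) absent from universe: ",
         paste(unmapped, collapse = ", "))
  N <- length(un); n <- length(qn)
  rows <- lapply(names(library$sets), function(s) {
    members <- intersect(library$normalized[[s]], un)
    K <- length(members)
    hit <- intersect(members, qn)
    k <- length(hit)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, hits = k, set_size = K, query_size = n,
               universe_size = N, p = p,
               enrichment_ratio = if (K == 0) 0 else k / (n * K / N),
               members_hit = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, -out$enrichment_ratio), ]
  rownames(out) <- NULL
  out <- out[, c("set", "hits", "set_size", "query_size", "universe_size",
                 "p", "p_adj", "enrichment_ratio", "members_hit")]
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "library") <- library
  out
}

#' Pathway network of enriched sets sharing member metabolites
#'
#' Nodes are sets with at least one query hit; an edge joins two sets sharing
#' at least `min_shared` member metabolites (within the analysis universe),
#' weighted by the overlap count. Node attributes carry the enrichment ratio
#' (figure size channel) and p-value (color channel).
#'
#' @param result an `enrichment_result` from [hypergeometric_ora()].
#' @param min_shared minimum shared members for an edge (default 1).
#' @return list with `nodes` (set, enrichment_ratio, p, p_adj, hits) and
#'   `edges` (set_i, set_j, n_shared, shared members).
#' @export
pathway_network <- function(result, min_shared = 1) {
  stopifnot(inherits(result, "enrichment_result"))
  library <- attr(result, "library")
  if (nrow(result) < 2) stop("need at least 2 scored sets")
  keep <- result$set[result$hits >= 1]
  nodes <- result[result$set %in% keep,
                  c("set", "enrichment_ratio", "p", "p_adj", "hits")]
  edges <- list()
  if (length(keep) >= 2) {
    cmb <- utils::combn(keep, 2)
    for (i in seq_len(ncol(cmb))) {
      a <- cmb[1, i]; b <- cmb[2, i]
      shared <- intersect(library$normalized[[a]], library$normalized[[b]])
      if (length(shared) >= min_shared)
        edges[[length(edges) + 1]] <-
          data.frame(set_i = a, set_j = b, n_shared = length(shared),
                     shared = paste(shared, collapse = ";"),
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(set_i = character(0), set_j = character(0),
               n_shared = integer(0), shared = character(0))
  list(nodes = nodes, edges = edges)
}
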