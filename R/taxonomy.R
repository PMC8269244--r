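#' In-memory taxonomy with lineage and least-common-ancestor queries
#'
#' A `taxonomy_tree` holds a rank-labelled hierarchy (root, superkingdom,
#' phylum, class, order, family, genus, species) and supports the two queries
#' the read classifier needs: full lineage extraction and the least common
#' ancestor (LCA) of a set of taxa. Taxon identifiers are opaque strings.
#'
#' @name taxonomy
NULL

.RANKS <- c("root", "superkingdom", "phylum", "class", "order",
            "family", "genus", "species")

#' Build a taxonomy tree from node rows
#'
#' @param records data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`. Exactly one row must be the root (its own parent, rank "root").
#'   Every other row's parent must be present. Ranks along any root-to-leaf
#'   path must follow the canonical order root > superkingdom > phylum >
#'   class > order > family > genus > species, with gaps allowed.
#' @return a `taxonomy_tree` object.
#' @examples
#' tr <- build_taxonomy(data.frame(
#'   taxid = c("root", "s1"), parent_taxid = c("root", "root"),
#'   rank = c("root", "species"), name = c("root", "Examplea specifica")))
#' lineage(tr, "s1")
#' @export
build_taxonomy <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(records)))
    stop("taxonomy records need columns: ", paste(need, collapse = ", "))
  taxid <- as.character(records$taxid)
  parent <- as.character(records$parent_taxid)
  rank <- as.character(records$rank)
  if (anyDuplicated(taxid))
    stop("duplicate taxid(s): ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  bad_rank <- setdiff(unique(rank), .RANKS)
  if (length(bad_rank))
    stop("unknown rank(s): ", paste(bad_rank, collapse = ", "))
  is_root <- taxid == parent
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root (a node that is its own parent); found ",
         sum(is_root))
  if (rank[is_root] != "root") stop("the root node must have rank 'root'")
  orphan <- !(parent %in% taxid)
  if (any(orphan))
    stop("parent taxid(s) not present: ",
         paste(unique(parent[orphan]), collapse = ", "))

  idx <- seq_along(taxid)
  names(idx) <- taxid
  parent_idx <- unname(idx[parent])

  # cycle + rank-order check by walking each node to the root
  root_i <- which(is_root)
  rank_num <- match(rank, .RANKS)
  n <- length(taxid)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (j != root_i) {
      p <- parent_idx[j]
      if (rank_num[p] >= rank_num[j])
        stop("rank order violated: ", taxid[j], " (", rank[j],
             ") under ", taxid[p], " (", rank[p], ")")
      j <- p
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy involving ", taxid[i])
    }
  }

  structure(
    list(taxid = taxid, parent_idx = parent_idx, rank = rank,
         name = as.character(records$name), index = idx, root = root_i),
    class = "taxonomy_tree")
}

#' Read a taxonomy node table (TSV with taxid, parent_taxid, rank, name)
#' @param path file path
#' @return a `taxonomy_tree`
#' @export
read_taxonomy <- function(path) {
  build_taxonomy(utils::read.delim(path, colClasses = "character"))
}

#' Write a taxonomy tree back to its TSV node-table form
#' @param tree a `taxonomy_tree`
#' @param path output file
#' @export
write_taxonomy <- function(tree, path) {
  utils::write.table(
    data.frame(taxid = tree$taxid,
               parent_taxid = tree$taxid[tree$parent_idx],
               rank = tree$rank, name = tree$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", length(x$taxid), "nodes;",
      sum(x$rank == "species"), "species,",
      sum(x$rank == "genus"), "genera\n")
  invisible(x)
}

.tax_idx <- function(tree, taxid) {
  i <- tree$index[as.character(taxid)]
  if (anyNA(i))
    stop("unknown taxid(s): ",
         paste(taxid[is.na(i)], collapse = ", "))
  unname(i)
}

# root-first vector of node indices
.lineage_idx <- function(tree, i) {
  out <- i
  while (i != tree$root) {
    i <- tree$parent_idx[i]
    out <- c(i, out)
  }
  out
}

#' Lineage of a taxon, root first
#'
#' @param tree a `taxonomy_tree`
#' @param taxid single taxon identifier present in the tree
#' @return data.frame with columns `rank`, `name`, `taxid`, ordered from the
#'   root down to the queried node.
#' @export
lineage <- function(tree, taxid) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(taxid) == 1L)
  path <- .lineage_idx(tree, .tax_idx(tree, taxid))
  data.frame(rank = tree$rank[path], name = tree$name[path],
             taxid = tree$taxid[path], stringsAsFactors = FALSE)
}

#' Least common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon. Ties to
#' multiple species are resolved with this during read classification.
#'
#' @param tree a `taxonomy_tree`
#' @param taxids non-empty vector of taxon identifiers, all present in the tree
#' @return the LCA's taxid (character scalar)
#' @export
lca <- function(tree, taxids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxids <- unique(as.character(taxids))
  if (length(taxids) == 0L) stop("lca() needs a non-empty set of taxids")
  idx <- .tax_idx(tree, taxids)
  common <- .lineage_idx(tree, idx[1L])
  for (i in idx[-1L]) {
    p <- .lineage_idx(tree, i)
    keep <- min(length(common), length(p))
    same <- common[seq_len(keep)] == p[seq_len(keep)]
    common <- common[seq_len(if (all(same)) keep else which(!same)[1L] - 1L)]
  }
  tree$taxid[common[length(common)]]
}

#' Rank of a taxon
#' @param tree a `taxonomy_tree`
#' @param taxid taxon identifier(s)
#' @return character vector of ranks
#' @export
taxon_rank <- function(tree, taxid) {
  tree$rank[.tax_idx(tree, taxid)]
}

#' Name of a taxon
#' @param tree a `taxonomy_tree`
#' @param taxid taxon identifier(s)
#' @return character vector of names
#' @export
taxon_name <- function(tree, taxid) {
  tree$name[.tax_idx(tree, taxid)]
}

#' Build a pragmatic taxonomy from database labels
#'
#' Reference databases carry (kingdom, genus, species) labels per genome; this
#' helper lifts them into a four-level `taxonomy_tree`
#' (root > superkingdom > genus > species) with string taxids `k__`, `g__`,
#' `s__`. Missing intermediate ranks are deliberate: LCA operates on tree
#' structure, not rank names.
#'
#' @param labels data.frame with columns `kingdom`, `genus`, `species`
#' @return a `taxonomy_tree`
#' @export
taxonomy_from_labels <- function(labels) {
  labels <- unique(as.data.frame(labels)[, c("kingdom", "genus", "species")])
  kings <- unique(labels$kingdom)
  gen <- unique(labels[, c("kingdom", "genus")])
  rows <- rbind(
    data.frame(taxid = "root", parent_taxid = "root",
               rank = "root", name = "root"),
    data.frame(taxid = paste0("k__", kings), parent_taxid = "root",
               rank = "superkingdom", name = kings),
    data.frame(taxid = paste0("g__", gen$genus),
               parent_taxid = paste0("k__", gen$kingdom),
               rank = "genus", name = gen$genus),
    data.frame(taxid = paste0("s__", labels$species),
               parent_taxid = paste0("g__", labels$genus),
               rank = "species", name = labels$species))
  build_taxonomy(unique(rows))
}
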