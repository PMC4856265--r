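# Loading gene-tree data and taxon maps; GeneTreeData construction.

#' Build a GeneTreeData object from per-locus tree multisets
#'
#' Trees within one locus are typically bootstrap (or posterior) estimates
#' of the same gene tree; the likelihood averages over them. Tip labels
#' are allele names; `taxonMap` sends alleles to species (identity when
#' `NULL`, i.e. one individual per species labeled by the species name).
#' Topologies are keyed at the species level (alleles of the same species
#' are exchangeable under the coalescent), pooled across loci and stored
#' once each with per-locus multiplicities.
#'
#' @param loci list with one element per locus; each element a list of
#'   rooted binary gene trees (`phylo` objects or Newick strings) or a
#'   `multiPhylo`.
#' @param taxonMap optional named character vector, allele -> species.
#' @return a [GeneTreeData-class] object.
#' @export
makeGeneTreeData <- function(loci, taxonMap = NULL) {
  stopifnot(length(loci) >= 1L)
  topo <- list()
  lw <- vector("list", length(loci))
  alleles <- character(0)
  for (i in seq_along(loci)) {
    trs <- loci[[i]]
    if (inherits(trs, "multiPhylo")) trs <- unclass(trs)
    if (inherits(trs, "phylo") || is.character(trs)) trs <- as.list(trs)
    if (!length(trs)) stop(sprintf("locus %d has no trees", i))
    keys <- character(length(trs))
    for (j in seq_along(trs)) {
      phy <- as_phylo_tree(trs[[j]])
      alleles <- unique(c(alleles, phy$tip.label))
      key <- tree_topology_key(phy, taxonMap)
      keys[j] <- key
      if (is.null(topo[[key]]))
        topo[[key]] <- encode_gene_tree(phy, taxonMap)
    }
    tab <- table(keys)
    lw[[i]] <- structure(as.numeric(tab), names = names(tab))
  }
  species <- if (is.null(taxonMap)) alleles else {
    miss <- setdiff(alleles, names(taxonMap))
    if (length(miss))
      stop(sprintf("allele '%s' is missing from the taxon map", miss[1]))
    unique(unname(taxonMap[alleles]))
  }
  new("GeneTreeData", topologies = topo, lociWeights = lw,
      taxonMap = if (is.null(taxonMap)) character(0) else taxonMap,
      species = sort(species))
}

#' Read a two-column taxon map
#'
#' Whitespace-delimited text, two columns: allele label, species label.
#' Lines starting with `#` are ignored.
#'
#' @param file path.
#' @return named character vector, allele -> species.
#' @export
readTaxonMap <- function(file) {
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("allele", "species"))
  if (anyDuplicated(tab$allele))
    stop("duplicate allele label in taxon map")
  structure(tab$species, names = tab$allele)
}

#' Load gene-tree data from files
#'
#' Two layouts are accepted: a single file with one Newick tree per line
#' and lines starting with `#locus` separating loci, or a directory (or
#' explicit vector of paths) with one file per locus, each holding that
#' locus's tree multiset (one Newick per line).
#'
#' @param paths one file, one directory, or a character vector of
#'   per-locus files.
#' @param taxonMap optional named character vector or path to a
#'   two-column map file (see [readTaxonMap()]).
#' @return a [GeneTreeData-class] object.
#' @export
readGeneTrees <- function(paths, taxonMap = NULL) {
  if (is.character(taxonMap) && length(taxonMap) == 1L && file.exists(taxonMap) &&
      is.null(names(taxonMap)))
    taxonMap <- readTaxonMap(taxonMap)
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, full.names = TRUE))
  if (!length(paths)) stop("no gene-tree files found")
  for (p in paths) if (!file.exists(p)) stop(sprintf("file not found: '%s'", p))
  loci <- list()
  if (length(paths) == 1L) {
    lines <- trimws(readLines(paths, warn = FALSE))
    cur <- character(0)
    flush <- function() {
      if (length(cur)) loci[[length(loci) + 1L]] <<- as.list(cur)
      cur <<- character(0)
    }
    for (ln in lines) {
      if (startsWith(ln, "#locus")) flush()
      else if (nzchar(ln) && !startsWith(ln, "#")) cur <- c(cur, ln)
    }
    flush()
  } else {
    for (p in paths) {
      lines <- trimws(readLines(p, warn = FALSE))
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      if (!length(lines)) stop(sprintf("empty locus file '%s'", p))
      loci[[length(loci) + 1L]] <- as.list(lines)
    }
  }
  if (!length(loci)) stop("no loci found in input")
  makeGeneTreeData(loci, taxonMap)
}
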