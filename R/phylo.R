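#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with an upfront syntax check that
#' reports the character position of unbalanced parentheses or a missing
#' terminating semicolon.
#'
#' @param text Newick string (single tree).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' (string ends at position %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf(
      "malformed Newick: missing terminating ';' at position %d", length(chars)
    ))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick: ape could not parse the string")
  tr
}

#' Write a tree as Newick text
#'
#' @param tree An [ape::phylo] object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Set every branch length to one
#'
#' Branch lengths from heterogeneous sources are not comparable (and are
#' sometimes absent), so analyses here run on cladograms with unit branch
#' lengths.
#'
#' @param tree An [ape::phylo] object.
#' @return Tree with `edge.length` all equal to 1.
#' @export
unit_branch_lengths <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Prune a tree to a taxon set
#'
#' Induced subtree on the retained tips with degree-2 internal nodes
#' suppressed.
#'
#' @param tree An [ape::phylo] object.
#' @param taxa Character vector of tip labels to keep.
#' @return Pruned [ape::phylo].
#' @export
prune_to_taxa <- function(tree, taxa) {
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) == 0) stop("prune_to_taxa(): no requested taxon is a tip of the tree")
  ape::keep.tip(tree, keep)
}

#' Faith's phylogenetic diversity of a species set
#'
#' Total branch length of the minimal rooted subtree spanning the set:
#' the union of the root-to-tip paths of the species, with shared branches
#' counted once (the rooted variant of Faith's PD).
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param species_set Character vector of tip labels (subset of the tips).
#' @return Summed branch length; 0 for the empty set.
#' @export
faith_pd <- function(tree, species_set) {
  species_set <- unique(species_set)
  if (length(species_set) == 0) return(0)
  miss <- setdiff(species_set, tree$tip.label)
  if (length(miss) > 0) {
    stop("faith_pd(): not tips of the tree: ", paste(miss, collapse = ", "))
  }
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  used <- logical(nrow(tree$edge))
  for (tip in match(species_set, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- edge_of[node]
      if (used[e]) break
      used[e] <- TRUE
      node <- parent_of[node]
    }
  }
  sum(tree$edge.length[used])
}

# tip indices descending from the child node of each edge
edge_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  tips_below <- vector("list", nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) tips_below[[tree$edge[e, 2]]])
}

#' Per-branch ranges and phylogenetic weighted endemism
#'
#' Generalizes weighted endemism from species to tree branches: each branch's
#' range is the union of the occupied-cell sets of its descendant tips, and
#' the branch contributes `length / |range|` to every cell of that range. A
#' cell's phylogenetic weighted endemism (PWE) is the sum of those
#' contributions, so each recorded branch contributes exactly its length
#' across the landscape.
#'
#' @param tree Rooted [ape::phylo]; tips are species ids; branch lengths used
#'   as weights (unit lengths for supertrees assembled here).
#' @param ranges Tibble `species_id`, `cell_id` (see [species_ranges()]).
#' @return List with `cells` (tibble `cell_id`, `pwe`) and `branches`
#'   (tibble `edge`, `child`, `length`, `n_cells`, `endemism` = length /
#'   n_cells; `n_cells = 0` for branches with no recorded descendant).
#' @export
pwe <- function(tree, ranges) {
  stopifnot(all(c("species_id", "cell_id") %in% names(ranges)))
  cells_of <- split(ranges$cell_id, ranges$species_id)
  desc <- edge_descendant_tips(tree)
  nE <- nrow(tree$edge)
  branch_cells <- lapply(seq_len(nE), function(e) {
    labs <- tree$tip.label[desc[[e]]]
    sort(unique(unlist(cells_of[labs], use.names = FALSE)))
  })
  n_cells <- vapply(branch_cells, length, integer(1))
  lens <- tree$edge.length
  if (is.null(lens)) stop("pwe(): tree has no branch lengths")
  contrib_cells <- unlist(branch_cells, use.names = FALSE)
  contrib_w <- rep(ifelse(n_cells > 0, lens / pmax(n_cells, 1L), 0), n_cells)
  cell_pwe <- tapply(contrib_w, contrib_cells, sum)
  cells <- tibble::tibble(
    cell_id = as.integer(names(cell_pwe)),
    pwe = as.numeric(cell_pwe)
  ) |> dplyr::arrange(.data$cell_id)
  branches <- tibble::tibble(
    edge = seq_len(nE),
    child = tree$edge[, 2],
    length = lens,
    n_cells = n_cells,
    endemism = ifelse(n_cells > 0, lens / pmax(n_cells, 1L), NA_real_)
  )
  list(cells = cells, branches = branches, branch_cells = branch_cells)
}

#' Share of evolutionary lineages protected
#'
#' A branch counts as protected when its range (union of descendant-tip
#' cells) touches at least one PA-overlapping cell. The headline share is in
#' branch length; the branch-count share is reported alongside. Branches
#' with no recorded descendant are excluded from both numerator and
#' denominator.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param ranges Tibble `species_id`, `cell_id`.
#' @param pa_cells Integer vector of PA-overlapping cell ids (see
#'   [cells_overlapping()]).
#' @return Tibble with `prop_length`, `prop_count`, `protected_length`,
#'   `total_length`, `protected_branches`, `total_branches`.
#' @export
lineage_protection <- function(tree, ranges, pa_cells) {
  pw <- pwe(tree, ranges)
  recorded <- pw$branches$n_cells > 0
  prot <- vapply(
    pw$branch_cells, function(cs) length(cs) > 0 && any(cs %in% pa_cells),
    logical(1)
  )
  total_len <- sum(pw$branches$length[recorded])
  prot_len <- sum(pw$branches$length[recorded & prot])
  tibble::tibble(
    prop_length = if (total_len > 0) prot_len / total_len else 0,
    prop_count = if (sum(recorded) > 0) sum(prot & recorded) / sum(recorded) else 0,
    protected_length = prot_len,
    total_length = total_len,
    protected_branches = sum(prot & recorded),
    total_branches = sum(recorded)
  )
}
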