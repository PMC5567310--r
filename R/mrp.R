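#' Matrix representation with parsimony (MRP) encoding
#'
#' Baum-Ragan coding of a set of source trees: every non-root internal node
#' of every source tree becomes one binary character in which the node's
#' descendant tips score 1, the other taxa of that tree score 0, and taxa
#' absent from that tree score `?`. Unresolved polytomies contribute one
#' character per *resolved* internal node only; star trees contribute none.
#'
#' @param source_trees A list of [ape::phylo] objects (or a `multiPhylo`),
#'   each with at least 3 tips.
#' @return An `mrp_matrix`: character matrix (taxa x characters) over
#'   `{"0","1","?"}` with a `provenance` attribute (source tree and node per
#'   character).
#' @export
mrp_encode <- function(source_trees) {
  if (inherits(source_trees, "phylo")) source_trees <- list(source_trees)
  stopifnot(length(source_trees) >= 1)
  for (tr in source_trees) {
    if (length(tr$tip.label) < 3) {
      stop("mrp_encode(): every source tree needs at least 3 tips")
    }
  }
  taxa <- sort(unique(unlist(lapply(source_trees, function(t) t$tip.label))))
  cols <- list()
  prov <- list()
  for (ti in seq_along(source_trees)) {
    tr <- source_trees[[ti]]
    ntip <- length(tr$tip.label)
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
    internal <- setdiff(unique(tr$edge[, 1]), root)
    if (length(internal) == 0) next
    desc <- edge_descendant_tips(tr)
    child_nodes <- tr$edge[, 2]
    for (nd in internal) {
      e <- match(nd, child_nodes)
      clade <- tr$tip.label[desc[[e]]]
      col <- rep("?", length(taxa))
      names(col) <- taxa
      col[tr$tip.label] <- "0"
      col[clade] <- "1"
      cols[[length(cols) + 1L]] <- col
      prov[[length(prov) + 1L]] <- c(tree = ti, node = nd)
    }
  }
  m <- if (length(cols) == 0) {
    matrix(character(0), nrow = length(taxa), ncol = 0,
           dimnames = list(taxa, NULL))
  } else {
    do.call(cbind, cols)
  }
  structure(m, provenance = do.call(rbind, prov), class = c("mrp_matrix", class(m)))
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat(sprintf("<mrp_matrix> %d taxa x %d characters\n", nrow(x), ncol(x)))
  invisible(x)
}

# tip-state bitmasks for the two-state alphabet: 1 = state 0, 2 = state 1,
# 3 = {0,1} (missing / '?')
mrp_tip_masks <- function(tree, matrix) {
  taxa <- rownames(matrix)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra) > 0) {
    stop("fitch_score(): matrix taxa missing from the tree: ",
         paste(extra, collapse = ", "))
  }
  nchar_ <- ncol(matrix)
  ntip <- length(tree$tip.label)
  masks <- matrix(3L, nrow = ntip, ncol = nchar_)
  idx <- match(taxa, tree$tip.label)
  if (nchar_ > 0) {
    mm <- matrix(3L, nrow = length(taxa), ncol = nchar_)
    mm[matrix == "0"] <- 1L
    mm[matrix == "1"] <- 2L
    masks[idx, ] <- mm
  }
  masks
}

#' Fitch parsimony score
#'
#' Minimum number of state changes required by a tree for each binary
#' character, summed (optionally with per-character weights). `?` entries
#' are fully ambiguous; taxa present in the tree but absent from the matrix
#' are treated as all-`?`. Polytomies are scored exactly (two-state
#' majority-state rule, which coincides with Fitch's set operations on
#' binary nodes).
#'
#' @param tree An [ape::phylo]; tips must include every matrix taxon.
#' @param matrix An [mrp_encode()] matrix (or any character matrix over
#'   `{"0","1","?"}` with taxa as rownames).
#' @param weights Optional per-character positive weights (default 1).
#' @return Weighted parsimony length (numeric scalar).
#' @export
fitch_score <- function(tree, matrix, weights = NULL) {
  nchar_ <- ncol(matrix)
  if (nchar_ == 0) return(0)
  if (is.null(weights)) weights <- rep(1, nchar_)
  stopifnot(length(weights) == nchar_)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  masks <- rbind(
    mrp_tip_masks(tree, matrix),
    matrix(0L, nrow = nnode - ntip, ncol = nchar_)
  )
  post <- ape::reorder.phylo(tree, "postorder")
  changes <- numeric(nchar_)
  parents <- unique(post$edge[, 1]) # postorder: children resolved first
  kids_of <- split(post$edge[, 2], factor(post$edge[, 1], levels = parents))
  for (p in parents) {
    kids <- kids_of[[as.character(p)]]
    km <- masks[kids, , drop = FALSE]
    c0 <- colSums(km == 1L | km == 3L)
    c1 <- colSums(km == 2L | km == 3L)
    best <- pmax(c0, c1)
    changes <- changes + (length(kids) - best)
    mask <- integer(nchar_)
    mask[c0 == best] <- 1L
    mask[c1 == best] <- mask[c1 == best] + 2L
    masks[p, ] <- mask
  }
  sum(changes * weights)
}

mrp_hamming <- function(matrix) {
  taxa <- rownames(matrix)
  n <- nrow(matrix)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  num <- matrix(NA_real_, n, ncol(matrix))
  num[matrix == "0"] <- 0
  num[matrix == "1"] <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(num[i, ]) & !is.na(num[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(num[i, ok] != num[j, ok]) else 0.5
    }
  }
  stats::as.dist(d)
}

nni_hill_climb <- function(tree, matrix, weights) {
  score <- fitch_score(tree, matrix, weights)
  repeat {
    nbrs <- phangorn::nni(tree)
    sc <- vapply(nbrs, fitch_score, numeric(1), matrix = matrix, weights = weights)
    k <- which.min(sc)
    if (sc[k] < score) {
      tree <- nbrs[[k]]
      score <- sc[k]
    } else {
      return(list(tree = tree, score = score))
    }
  }
}

#' Parsimony-ratchet supertree search
#'
#' Heuristic maximum-parsimony search over the MRP matrix. Starting from a
#' neighbour-joining tree on MRP Hamming distances, the search alternates
#' NNI hill-climbing under perturbed character weights (a random 25% of
#' characters upweighted to 2) with hill-climbing under the original
#' weights, keeping the best tree seen. The result is never worse than the
#' starting tree and is an NNI-local optimum under the original weights;
#' runs are deterministic for a fixed seed.
#'
#' @param matrix An [mrp_encode()] matrix with at least 4 taxa.
#' @param iterations Number of ratchet iterations (default 200).
#' @param seed RNG seed for the weight perturbations.
#' @param prop_upweight Share of characters perturbed each iteration.
#' @param upweight Perturbed weight.
#' @return A `supertree` object: list with `tree` (unrooted [ape::phylo],
#'   unit branch lengths), `score` (parsimony length), and `log` (tibble of
#'   iteration and incumbent score).
#' @export
ratchet_search <- function(matrix, iterations = 200, seed = 1,
                           prop_upweight = 0.25, upweight = 2) {
  if (iterations < 1) stop("ratchet_search(): iterations must be >= 1")
  taxa <- rownames(matrix)
  if (length(taxa) < 4) stop("ratchet_search(): need at least 4 taxa")
  set.seed(seed)
  nchar_ <- ncol(matrix)
  w <- rep(1, nchar_)
  start <- ape::unroot(ape::nj(mrp_hamming(matrix)))
  start$edge.length <- rep(1, nrow(start$edge))
  best <- nni_hill_climb(start, matrix, w)
  log <- list(tibble::tibble(iteration = 0L, score = best$score))
  for (it in seq_len(iterations)) {
    wp <- w
    idx <- sample.int(nchar_, max(1L, ceiling(prop_upweight * nchar_)))
    wp[idx] <- upweight
    pert <- nni_hill_climb(best$tree, matrix, wp)
    cand <- nni_hill_climb(pert$tree, matrix, w)
    if (cand$score < best$score) best <- cand
    log[[length(log) + 1L]] <- tibble::tibble(iteration = it, score = best$score)
  }
  tree <- best$tree
  tree$edge.length <- rep(1, nrow(tree$edge))
  structure(
    list(tree = tree, score = best$score, log = dplyr::bind_rows(log)),
    class = "supertree"
  )
}

#' @export
print.supertree <- function(x, ...) {
  cat(sprintf(
    "<supertree> %d tips, parsimony score %g after %d ratchet iterations\n",
    length(x$tree$tip.label), x$score, max(x$log$iteration)
  ))
  invisible(x)
}

#' Export an MRP matrix
#'
#' Writes the matrix as relaxed PHYLIP or NEXUS for external parsimony
#' software.
#'
#' @param matrix An [mrp_encode()] matrix.
#' @param path Output file.
#' @param format `"phylip"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_mrp <- function(matrix, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  taxa <- rownames(matrix)
  rows <- apply(matrix, 1, paste, collapse = "")
  if (format == "phylip") {
    lines <- c(
      sprintf("%d %d", nrow(matrix), ncol(matrix)),
      sprintf("%s  %s", taxa, rows)
    )
  } else {
    lines <- c(
      "#NEXUS", "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(matrix), ncol(matrix)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
      "  MATRIX",
      sprintf("    %s  %s", taxa, rows),
      "  ;", "END;"
    )
  }
  writeLines(lines, path)
  invisible(path)
}
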