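# Shared fixtures and independent oracles.

toy_tree <- function() read_newick("((A:1,B:1):1,C:1);")

toy_ranges <- function() {
  tibble::tibble(
    species_id = c("A", "B", "B", "C", "C"),
    cell_id = c(1L, 1L, 2L, 2L, 3L)
  )
}

small_config <- function(seed = 1, n_species = 60, env_nx = 40, env_ny = 40, ...) {
  world_config(n_species = n_species, env_nx = env_nx, env_ny = env_ny,
               seed = seed, ...)
}

# Brute-force minimal-change count for one binary character on a tree:
# enumerate all 0/1 assignments to internal nodes and ambiguous tips.
fitch_bruteforce <- function(tree, column) {
  nnode <- max(tree$edge)
  fixed <- rep(NA_integer_, nnode)
  known <- names(column)[column != "?"]
  fixed[match(known, tree$tip.label)] <- as.integer(column[known])
  free <- which(is.na(fixed))
  A <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  full <- matrix(rep(fixed, each = nrow(A)), nrow(A), nnode)
  full[, free] <- A
  changes <- rep(0L, nrow(A))
  for (e in seq_len(nrow(tree$edge))) {
    changes <- changes + (full[, tree$edge[e, 1]] != full[, tree$edge[e, 2]])
  }
  min(changes)
}

random_mrp_column <- function(taxa, p_missing = 0.2) {
  col <- sample(c("0", "1", "?"), length(taxa), replace = TRUE,
                prob = c((1 - p_missing) / 2, (1 - p_missing) / 2, p_missing))
  names(col) <- taxa
  col
}

# Tie-corrected Kruskal-Wallis, written out from the rank-sum formula.
kw_hand <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  R <- tapply(r, g, sum)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  t <- table(x)
  H <- H / (1 - sum(t^3 - t) / (N^3 - N))
  list(H = unname(H), p = stats::pchisq(H, length(R) - 1, lower.tail = FALSE))
}

# Mann-Whitney U with tie-corrected normal approximation (no continuity
# correction), written out from the rank formulas.
mw_hand <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  t <- table(c(x, y))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1))))
  z <- (U - n1 * n2 / 2) / sigma
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  list(U = unname(U), p = p)
}

# quartet topology from a unit-branch cophenetic matrix via the
# four-point condition; returns the pair split off with `a`
quartet_split <- function(tree, q) {
  d <- ape::cophenetic.phylo(tree)[q, q]
  s <- c(ab = d[1, 2] + d[3, 4], ac = d[1, 3] + d[2, 4], ad = d[1, 4] + d[2, 3])
  names(which.min(s))
}
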