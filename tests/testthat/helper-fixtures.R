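# Shared fixtures and independent oracles. Oracles deliberately share no
# code with the package: PD/RPD/PE are computed by explicit root-to-tip
# path enumeration, distances by an all-pairs scan.

tiny_grid <- function(n_rows = 4, n_cols = 4, cell_size = 1) {
  pr_grid(origin_x = 0, origin_y = n_rows * cell_size,
          cell_size = cell_size, n_rows = n_rows, n_cols = n_cols)
}

# The worked three-taxon tree ((A:1,B:1):1,C:2); used across metric tests.
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Brute-force Faith PD: union of all edges on root-to-tip paths.
pd_brute <- function(tree, species) {
  if (length(species) == 0) return(0)
  tips <- match(species, tree$tip.label)
  edges_on_path <- integer(0)
  for (tip in tips) {
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      edges_on_path <- c(edges_on_path, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[unique(edges_on_path)])
}

# Brute-force PE for one cell: every edge on a present species' root path
# contributes length / (number of assemblage cells holding any of its
# descendant tips).
pe_brute <- function(tree, pres, cell) {
  species_here <- colnames(pres)[pres[cell, ] == 1]
  if (length(species_here) == 0) return(0)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    # descendant tips of this edge by walking down
    desc <- tree$edge[e, 2]
    repeat {
      kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
      new <- union(desc, kids)
      if (length(new) == length(desc)) break
      desc <- new
    }
    tips <- tree$tip.label[desc[desc <= length(tree$tip.label)]]
    tips <- intersect(tips, colnames(pres))
    if (length(tips) == 0) next
    occupied <- which(rowSums(pres[, tips, drop = FALSE]) > 0)
    if (!(cell %in% occupied)) next
    total <- total + tree$edge.length[e] / length(occupied)
  }
  total
}

# Random tree + assemblage fixture on a small grid.
random_fixture <- function(seed, max_tips = 8, max_dim = 5) {
  set.seed(seed)
  n_tips <- sample(2:max_tips, 1)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  nr <- sample(2:max_dim, 1); nc <- sample(2:max_dim, 1)
  g <- tiny_grid(nr, nc)
  masks <- lapply(seq_len(n_tips), function(i) {
    v <- matrix(rbinom(nr * nc, 1, 0.4), nr, nc)
    pr_mask(g, v)
  })
  names(masks) <- tree$tip.label
  list(tree = tree, masks = masks, grid = g)
}

# Persistence fixture with random counts in [0, T].
random_persistence <- function(seed, S = 6, T = 20, nr = 8, nc = 8) {
  set.seed(seed)
  g <- tiny_grid(nr, nc)
  maps <- lapply(seq_len(S), function(s)
    lapply(seq_len(T), function(t)
      pr_mask(g, matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.9)), nr, nc))))
  names(maps) <- sprintf("s%02d", seq_len(S))
  build_persistence(maps)
}

# Small synthetic world shared by slower tests (30 slices, 30x30 grid).
small_world_config <- function(seed = 11) {
  sim_config(seed = seed, n_rows = 30, n_cols = 30,
             core_rows = 11:20, core_cols = 11:20,
             S_indicator = 5, S_focal = 10,
             start_age = 310, end_age = 20, step = 10,
             n_occurrences = 60, pa_fraction = 0.15)
}
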