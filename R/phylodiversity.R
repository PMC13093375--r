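# Branch index of a rooted tree: edges x tips incidence (which tips
# descend from each edge) and edge lengths. Root-inclusive: every edge on
# the path from a tip to the root is indexed.
branch_index <- function(tree) {
  ntip <- length(tree$tip.label)
  E <- nrow(tree$edge)
  B <- matrix(FALSE, E, ntip, dimnames = list(NULL, tree$tip.label))
  # postorder so children are filled before their parent edge
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chl <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chl]])
  }
  for (e in seq_len(E)) B[e, desc[[tree$edge[e, 2]]]] <- TRUE
  list(B = B, lengths = tree$edge.length, tips = tree$tip.label)
}

#' Faith's phylogenetic diversity of one assemblage
#'
#' Sum of the branch lengths of every branch whose descendant tip set
#' intersects the assemblage — the root-inclusive spanning definition,
#' so the full tip set returns the tree's total branch length.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param cell_species Character vector of species (must all be tips).
#' @return PD value (0 for the empty set).
#' @export
faith_pd <- function(tree, cell_species) {
  if (length(cell_species) == 0) return(0)
  missing <- setdiff(cell_species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  bi <- branch_index(tree)
  on <- bi$B[, cell_species, drop = FALSE]
  sum(bi$lengths[rowSums(on) > 0])
}

#' Replace all branch lengths by their mean
#'
#' The comparison tree for relative PD: identical topology, every branch
#' set to `total_length / n_branches`, so total length is preserved and
#' the full assemblage has RPD exactly 1.
#'
#' @param tree A `phylo` with branch lengths.
#' @return The equal-branch-length tree.
#' @export
equalize_branches <- function(tree) {
  tree$edge.length <- rep(sum(tree$edge.length) / length(tree$edge.length),
                          length(tree$edge.length))
  tree
}

#' Build a cell-by-species assemblage matrix from stacked range masks
#'
#' Stacks per-species distribution masks into a presence matrix over the
#' reporting extent, and computes per-species range sizes (occupied cell
#' counts) over the — possibly larger — endemism extent, mirroring the
#' study design where diversity maps are clipped to the focal bounding
#' box but range sizes for phylogenetic endemism span the full species
#' distributions.
#'
#' @param species_masks Named list of `pr_mask` layers on one grid.
#' @param extent Reporting extent: `NULL` (whole grid) or
#'   `list(rows = <int>, cols = <int>)`.
#' @param pe_extent Endemism extent over which range sizes are counted:
#'   `NULL` (whole grid) or a `list(rows, cols)`; must contain every
#'   occupied cell you want counted.
#' @return A `pr_assemblage`: `grid`, `species`, `cells` (data frame
#'   `row`, `col`), presence matrix `pres` (cells x species), matrix
#'   `pres_pe` over the endemism extent, and `range_sizes`.
#' @export
build_assemblages <- function(species_masks, extent = NULL,
                              pe_extent = NULL) {
  stopifnot(length(species_masks) > 0, !is.null(names(species_masks)))
  grid <- species_masks[[1]]$grid
  for (m in species_masks) stop_if_grid_mismatch(grid, m$grid, "mask")
  sub_cells <- function(ext) {
    rows <- if (is.null(ext)) seq_len(grid$n_rows) else ext$rows
    cols <- if (is.null(ext)) seq_len(grid$n_cols) else ext$cols
    expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  }
  cells <- sub_cells(extent)
  cells_pe <- sub_cells(pe_extent)
  pres_at <- function(cl) {
    out <- vapply(species_masks, function(m) {
      v <- m$values[cbind(cl$row, cl$col)]
      v[is.na(v)] <- 0
      v
    }, numeric(nrow(cl)))
    matrix(out, nrow = nrow(cl),
           dimnames = list(NULL, names(species_masks)))
  }
  pres <- pres_at(cells)
  pres_pe <- pres_at(cells_pe)
  structure(list(grid = grid, species = names(species_masks),
                 cells = cells, pres = pres, pres_pe = pres_pe,
                 range_sizes = colSums(pres_pe)),
            class = "pr_assemblage")
}

# Place a per-cell vector of an assemblage back onto the grid as a
# raster (cells outside the reporting extent are nodata).
assemblage_raster <- function(assemblage, values, variable) {
  m <- matrix(NA_real_, assemblage$grid$n_rows, assemblage$grid$n_cols)
  m[cbind(assemblage$cells$row, assemblage$cells$col)] <- values
  pr_raster(assemblage$grid, m, variable)
}

#' Species richness surface
#'
#' @param assemblage A `pr_assemblage`.
#' @return `pr_raster` of per-cell presence sums.
#' @export
species_richness <- function(assemblage) {
  assemblage_raster(assemblage, rowSums(assemblage$pres), "SR")
}

# Cells x branches presence indicator for a tip subset of the tree.
edge_presence <- function(pres, bi) {
  tips <- intersect(colnames(pres), bi$tips)
  M <- pres[, tips, drop = FALSE]
  (M %*% t(bi$B[, tips, drop = FALSE] * 1)) > 0
}

#' Faith PD surface
#'
#' @param tree Rooted `phylo`; tips must cover the species used (species
#'   absent from the tree are dropped with a message).
#' @param assemblage A `pr_assemblage`.
#' @return `pr_raster` of per-cell PD (root-inclusive).
#' @export
pd_surface <- function(tree, assemblage) {
  bi <- branch_index(tree)
  dropped <- setdiff(assemblage$species, bi$tips)
  if (length(dropped))
    message("species without tree tips excluded from PD: ",
            paste(dropped, collapse = ", "))
  P <- edge_presence(assemblage$pres, bi)
  assemblage_raster(assemblage, drop(P %*% bi$lengths), "PD")
}

#' Relative phylogenetic diversity surface
#'
#' Per-cell ratio of PD on the original tree to PD on the equal-branch
#' comparison tree ([equalize_branches()]). Cells with no species are
#' nodata. Values below 1 flag assemblages of unusually short branches
#' (recent radiations), above 1 unusually long branches.
#'
#' @inheritParams pd_surface
#' @return `pr_raster` of per-cell RPD.
#' @export
relative_pd <- function(tree, assemblage) {
  pd_o <- pd_surface(tree, assemblage)
  pd_e <- pd_surface(equalize_branches(tree), assemblage)
  v <- pd_o$values / pd_e$values
  v[!is.na(pd_e$values) & pd_e$values == 0] <- NA  # empty cells
  pr_raster(assemblage$grid, v, "RPD")
}

#' Phylogenetic endemism surface
#'
#' Per cell, the sum over branches present in the cell of branch length
#' divided by the branch's range — the number of cells (over the
#' endemism extent) occupied by at least one descendant tip. Summed over
#' the full endemism extent, PE equals the total branch length of the
#' subtree of occurring species (every branch contributes
#' `L_b * range_b / range_b`).
#'
#' @inheritParams pd_surface
#' @return `pr_raster` of per-cell PE.
#' @export
phylogenetic_endemism <- function(tree, assemblage) {
  bi <- branch_index(tree)
  P <- edge_presence(assemblage$pres, bi)
  Ppe <- edge_presence(assemblage$pres_pe, bi)
  range_b <- colSums(Ppe)
  w <- ifelse(range_b > 0, bi$lengths / range_b, 0)
  if (any(P[, range_b == 0]))
    stop("internal error: branch with zero range present in a cell")
  assemblage_raster(assemblage, drop(P %*% w), "PE")
}

#' Graft an unsequenced taxon onto an ultrametric tree
#'
#' Attaches a new tip on the stem branch of its hypothesized sister
#' species (or clade) at depth `attach_age` before present, emulating
#' the addition of taxa without sequence data whose branch lengths are
#' calibrated by the age of their sister group. Ultrametricity is
#' preserved: the new tip's branch length equals `attach_age`.
#'
#' @param tree Ultrametric rooted `phylo`.
#' @param new_tip Label of the new tip (must not already exist).
#' @param sister A tip label, or a character vector of tips defining a
#'   clade (attachment is on that clade's stem branch).
#' @param attach_age Age (Myr before present) of the attachment point;
#'   must lie on the sister's stem branch: greater than the sister
#'   node's age and at most its parent's age.
#' @return The enlarged `phylo`.
#' @export
graft_taxon <- function(tree, new_tip, sister, attach_age) {
  if (new_tip %in% tree$tip.label)
    stop("tip '", new_tip, "' already present")
  missing <- setdiff(sister, tree$tip.label)
  if (length(missing))
    stop("sister taxa not in tree: ", paste(missing, collapse = ", "))
  node <- if (length(sister) == 1) match(sister, tree$tip.label) else
    ape::getMRCA(tree, sister)
  depths <- ape::node.depth.edgelength(tree)
  tree_height <- max(depths[seq_along(tree$tip.label)])
  node_age <- tree_height - depths[node]
  stem_edge <- match(node, tree$edge[, 2])
  if (is.na(stem_edge)) stop("cannot graft onto the root")
  parent_age <- node_age + tree$edge.length[stem_edge]
  if (attach_age <= node_age || attach_age > parent_age)
    stop(sprintf(
      "attach_age %.6g outside the sister stem branch (%.6g, %.6g]",
      attach_age, node_age, parent_age))
  out <- phytools::bind.tip(tree, new_tip, edge.length = attach_age,
                            where = node, position = attach_age - node_age)
  validate_tree(out)
}

#' Rescale a metric layer to \[0, 1\]
#'
#' Divides by the maximum non-nodata value, so the richest cell is
#' exactly 1 (the reporting convention for all four diversity metrics).
#' An all-zero layer is returned unchanged with a warning.
#'
#' @param layer A `pr_raster` with at least one non-nodata cell.
#' @return The scaled `pr_raster`.
#' @export
normalize_metric <- function(layer) {
  v <- layer$values[!is.na(layer$values)]
  if (length(v) == 0) stop("layer has no non-nodata cells")
  mx <- max(v)
  if (mx == 0) {
    warning("all-zero layer left unchanged by normalize_metric")
    return(layer)
  }
  pr_raster(layer$grid, layer$values / mx, paste0(layer$variable, "_scaled"))
}

#' All four diversity surfaces, raw and 0-1 scaled
#'
#' @inheritParams pd_surface
#' @return List with elements `SR`, `PD`, `RPD`, `PE` (raw
#'   `pr_raster`s) and `scaled` (same metrics rescaled by their maxima).
#' @export
diversity_maps <- function(tree, assemblage) {
  raw <- list(SR = species_richness(assemblage),
              PD = pd_surface(tree, assemblage),
              RPD = relative_pd(tree, assemblage),
              PE = phylogenetic_endemism(tree, assemblage))
  c(raw, list(scaled = lapply(raw, normalize_metric)))
}
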