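test_that("Faith PD on the worked tree matches hand computation", {
  tr <- worked_tree()  # ((A:1,B:1):1,C:2)
  expect_equal(faith_pd(tr, character(0)), 0)
  expect_equal(faith_pd(tr, c("A", "B")), 3)   # A, B and their stem
  expect_equal(faith_pd(tr, "C"), 2)
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("PD is monotone and matches picante on random assemblages", {
  skip_if_not_installed("picante")
  set.seed(20)
  tr <- ape::rphylo(10, 1, 0)
  tr$tip.label <- paste0("t", 1:10)
  comm <- matrix(rbinom(50, 1, 0.5), 5, 10,
                 dimnames = list(NULL, tr$tip.label))
  comm[1, ] <- 1
  ours <- apply(comm, 1, function(r)
    faith_pd(tr, colnames(comm)[r == 1]))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  ref[rowSums(comm) == 0] <- 0
  expect_equal(unname(ours), ref)
  # adding a species never decreases PD
  for (i in 2:5) {
    sp <- colnames(comm)[comm[i, ] == 1]
    extra <- setdiff(colnames(comm), sp)
    if (length(extra))
      expect_gte(faith_pd(tr, c(sp, extra[1])), faith_pd(tr, sp))
  }
})

test_that("equalize_branches preserves topology and total length", {
  tr <- worked_tree()
  eq <- equalize_branches(tr)
  expect_equal(eq$edge.length, rep(1.25, 4))
  expect_equal(sum(eq$edge.length), sum(tr$edge.length))
  expect_identical(eq$edge, tr$edge)
  expect_identical(equalize_branches(eq)$edge.length, eq$edge.length)
  set.seed(2); big <- ape::rphylo(20, 1, 0)
  expect_equal(sum(equalize_branches(big)$edge.length),
               sum(big$edge.length), tolerance = 1e-12)
})

test_that("assemblages stack masks and count ranges over the PE extent", {
  g <- tiny_grid(4, 4)
  all_cells <- pr_mask(g, matrix(1, 4, 4))
  ten <- matrix(0, 4, 4); ten[, 1:3] <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  sp10 <- pr_mask(g, ten)
  asm_full <- build_assemblages(list(wide = all_cells, ten = sp10))
  expect_equal(unname(asm_full$range_sizes), c(16, 10))
  expect_equal(asm_full$pres[, "wide"], rep(1, 16))
  # reporting extent clipped to 2x2, PE extent still the whole grid
  asm_clip <- build_assemblages(list(wide = all_cells, ten = sp10),
                                extent = list(rows = 1:2, cols = 1:2))
  expect_equal(nrow(asm_clip$pres), 4)
  expect_equal(unname(asm_clip$range_sizes), c(16, 10))
})

test_that("richness is the per-cell presence sum", {
  g <- tiny_grid(2, 2)
  m1 <- pr_mask(g, matrix(c(1, 1, 0, 0), 2, 2))
  m2 <- pr_mask(g, matrix(c(1, 0, 0, 0), 2, 2))
  m3 <- pr_mask(g, matrix(c(1, 0, 0, 1), 2, 2))
  sr <- species_richness(build_assemblages(list(a = m1, b = m2, c = m3)))
  expect_equal(sr$values, matrix(c(3, 1, 0, 1), 2, 2))
})

test_that("RPD is the ratio to the equal-branch tree", {
  tr <- worked_tree()
  g <- tiny_grid(1, 3)
  masks <- list(A = pr_mask(g, matrix(c(1, 1, 0), 1, 3)),
                B = pr_mask(g, matrix(c(1, 0, 0), 1, 3)),
                C = pr_mask(g, matrix(c(1, 0, 1), 1, 3)))
  asm <- build_assemblages(masks)
  rpd <- relative_pd(tr, asm)
  expect_equal(rpd$values[1, 1], 1)          # full assemblage
  # {C}: root path is the single 2-unit edge; equalized path 1.25
  expect_equal(rpd$values[1, 3], 2 / 1.25)
  # {A}: PD 2 (tip + stem, two edges), equalized 2 * 1.25
  expect_equal(rpd$values[1, 2], 0.8)
  # equal-branch input tree gives RPD 1 everywhere occupied
  eq <- equalize_branches(tr)
  expect_equal(unname(relative_pd(eq, asm)$values[1, ]), c(1, 1, 1))
})

test_that("phylogenetic endemism divides branches by their ranges", {
  # single endemic on a star tree: PE = full root-to-tip length
  star <- ape::read.tree(text = "(A:3,B:3,C:3);")
  g <- tiny_grid(2, 2)
  masks <- list(A = pr_mask(g, matrix(c(1, 0, 0, 0), 2, 2)),
                B = pr_mask(g, matrix(c(0, 1, 1, 0), 2, 2)),
                C = pr_mask(g, matrix(0, 2, 2)))
  asm <- build_assemblages(masks)
  pe <- phylogenetic_endemism(star, asm)
  expect_equal(pe$values[1, 1], 3)        # endemic to one cell
  expect_equal(pe$values[2, 1], 1.5)      # B occupies 2 cells: 3/2
  expect_equal(pe$values[1, 2], 1.5)
  expect_equal(pe$values[2, 2], 0)
})

test_that("PE sums to the occurring subtree length over the PE extent", {
  for (s in 1:100) {
    fx <- random_fixture(seed = 400 + s)
    asm <- build_assemblages(fx$masks)
    pe <- phylogenetic_endemism(fx$tree, asm)
    occurring <- names(which(colSums(asm$pres) > 0))
    expect_equal(sum(pe$values), faith_pd(fx$tree, occurring),
                 tolerance = 1e-9)
  }
})

test_that("all four metrics match brute-force oracles on random fixtures", {
  for (s in 1:100) {
    fx <- random_fixture(seed = 200 + s)
    asm <- build_assemblages(fx$masks)
    pres <- asm$pres
    sr <- species_richness(asm)
    pd <- pd_surface(fx$tree, asm)
    rpd <- relative_pd(fx$tree, asm)
    pe <- phylogenetic_endemism(fx$tree, asm)
    eq_tree <- fx$tree
    eq_tree$edge.length <- rep(sum(fx$tree$edge.length) /
                                 length(fx$tree$edge.length),
                               length(fx$tree$edge.length))
    for (cell in seq_len(nrow(pres))) {
      rc <- c(asm$cells$row[cell], asm$cells$col[cell])
      here <- colnames(pres)[pres[cell, ] == 1]
      expect_equal(sr$values[rc[1], rc[2]], length(here))
      pd_exp <- pd_brute(fx$tree, here)
      expect_equal(pd$values[rc[1], rc[2]], pd_exp, tolerance = 1e-12)
      if (length(here))
        expect_equal(rpd$values[rc[1], rc[2]],
                     pd_exp / pd_brute(eq_tree, here), tolerance = 1e-12)
      else expect_true(is.na(rpd$values[rc[1], rc[2]]))
      expect_equal(pe$values[rc[1], rc[2]], pe_brute(fx$tree, pres, cell),
                   tolerance = 1e-12)
    }
  }
})

test_that("star trees with equal branches make PD proportional to SR", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  set.seed(30)
  g <- tiny_grid(3, 3)
  masks <- lapply(1:4, function(i) pr_mask(g, matrix(rbinom(9, 1, 0.6), 3, 3)))
  names(masks) <- star$tip.label
  asm <- build_assemblages(masks)
  sr <- species_richness(asm); pd <- pd_surface(star, asm)
  expect_equal(pd$values, sr$values * 2)
})

test_that("grafting preserves ultrametricity and the worked example", {
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  out <- graft_taxon(cherry, "C", "A", attach_age = 1)
  expect_equal(sort(out$tip.label), c("A", "B", "C"))
  expect_equal(sum(out$edge.length), 5)
  d <- ape::node.depth.edgelength(out)[1:3]
  expect_lt(diff(range(d)), 1e-9)
  # A and C now join at age 1
  expect_equal(ape::dist.nodes(out)[match("A", out$tip.label),
                                    match("C", out$tip.label)], 2)
  # grafting onto a clade stem at its full stem age
  tr <- worked_tree()
  out2 <- graft_taxon(tr, "D", c("A", "B"), attach_age = 2)
  expect_equal(length(out2$tip.label), 4)
  d2 <- ape::node.depth.edgelength(out2)[1:4]
  expect_lt(diff(range(d2)), 1e-9)
  expect_error(graft_taxon(tr, "A", "B", 0.5), "already present")
  expect_error(graft_taxon(tr, "E", "A", 5), "stem branch")
  expect_error(graft_taxon(tr, "E", "A", 0), "stem branch")
})

test_that("normalize_metric rescales by the maximum", {
  g <- tiny_grid(1, 3)
  layer <- pr_raster(g, matrix(c(2, 5, 10), 1, 3))
  expect_equal(normalize_metric(layer)$values, matrix(c(0.2, 0.5, 1), 1, 3))
  same <- pr_raster(g, matrix(3, 1, 3))
  expect_equal(normalize_metric(same)$values, matrix(1, 1, 3))
  zero <- pr_raster(g, matrix(0, 1, 3))
  expect_warning(out <- normalize_metric(zero), "all-zero")
  expect_equal(out$values, zero$values)
})

test_that("diversity_maps produces scaled variants peaking at 1", {
  fx <- random_fixture(seed = 77)
  dm <- diversity_maps(fx$tree, build_assemblages(fx$masks))
  for (m in c("SR", "PD", "PE"))
    expect_equal(max(dm$scaled[[m]]$values, na.rm = TRUE), 1)
})
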