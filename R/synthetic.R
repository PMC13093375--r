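#' Configuration for the synthetic world
#'
#' The generator plants a known ground truth: a rectangular "stable core"
#' inside which the temporal climate anomaly is small
#' (`anomaly_sd_inside`) and outside which it is large
#' (`anomaly_sd_outside`). That variance asymmetry *is* the planted
#' stability signal every downstream stage is expected to recover.
#' Climate is expressed in dimensionless synthetic units: both variables
#' (labelled BIO1 and BIO12) ramp linearly from `gradient_range[1]` to
#' `gradient_range[2]` across the grid (BIO1 over columns, BIO12 over
#' rows), so climate space maps affinely onto the grid and the set of
#' cells matching the core's climate is exactly the core rectangle.
#'
#' Defaults describe the study conditions: a 100 x 100 grid of 4.5 km
#' cells, 60 paleo slices (610 to 20 kyr BP at 10 kyr steps), 10
#' stability-indicator species and 40 focal-clade species, anomaly SD 0.2
#' inside versus 2.0 outside a 30 x 30 core.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_rows,n_cols,cell_size Grid dimensions and cell edge (km).
#' @param start_age,end_age,step Paleo time axis in kyr BP; the number of
#'   slices is `(start_age - end_age) / step + 1`.
#' @param S_indicator Number of forest-stability indicator species (the
#'   clade-independent species whose stacked hindcasts define forest
#'   stability).
#' @param S_focal Number of focal-clade species used for the diversity
#'   metrics.
#' @param core_rows,core_cols Integer ranges of the planted stable core.
#' @param anomaly_sd_inside,anomaly_sd_outside Temporal climate noise SD
#'   inside/outside the core (synthetic climate units); inside must not
#'   exceed outside.
#' @param niche_breadth Gaussian niche kernel SD (climate units).
#' @param indicator_jitter Half-width of the uniform jitter applied to
#'   indicator species' optima around the core's mean climate.
#' @param focal_optimum_sd Scale of focal species' niche-optimum offsets
#'   from the core climate (half-normal magnitudes).
#' @param n_occurrences Occurrence records sampled per species.
#' @param pa_fraction Fraction of the grid covered by protected areas.
#' @param truth_threshold Suitability cutoff defining a species' true
#'   range.
#' @return A `pr_sim_config` list.
#' @export
sim_config <- function(seed = 1, n_rows = 100, n_cols = 100,
                       cell_size = 4.5,
                       start_age = 610, end_age = 20, step = 10,
                       S_indicator = 10, S_focal = 40,
                       core_rows = 36:65, core_cols = 36:65,
                       anomaly_sd_inside = 0.2, anomaly_sd_outside = 2.0,
                       niche_breadth = 1.5, indicator_jitter = 0.3,
                       focal_optimum_sd = 1.5,
                       n_occurrences = 200, pa_fraction = 0.15,
                       truth_threshold = 0.5,
                       gradient_range = c(0, 10)) {
  if (anomaly_sd_inside > anomaly_sd_outside)
    stop("anomaly_sd_inside must not exceed anomaly_sd_outside ",
         "(the inside<outside asymmetry is the planted stability signal)")
  ages <- make_time_axis(start_age, end_age, step)
  grid <- pr_grid(origin_x = 0, origin_y = n_rows * cell_size,
                  cell_size = cell_size, n_rows = n_rows, n_cols = n_cols)
  stopifnot(all(core_rows %in% seq_len(n_rows)),
            all(core_cols %in% seq_len(n_cols)),
            pa_fraction > 0, pa_fraction < 1,
            truth_threshold > 0, truth_threshold < 1)
  structure(list(seed = as.integer(seed), grid = grid,
                 ages = ages, T = length(ages),
                 start_age = start_age, end_age = end_age, step = step,
                 S_indicator = S_indicator, S_focal = S_focal,
                 core_rows = core_rows, core_cols = core_cols,
                 anomaly_sd_inside = anomaly_sd_inside,
                 anomaly_sd_outside = anomaly_sd_outside,
                 niche_breadth = niche_breadth,
                 indicator_jitter = indicator_jitter,
                 focal_optimum_sd = focal_optimum_sd,
                 n_occurrences = n_occurrences,
                 pa_fraction = pa_fraction,
                 truth_threshold = truth_threshold,
                 gradient_range = gradient_range),
            class = "pr_sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are
#' rejected so typos fail loudly. Two-element `core_rows`/`core_cols`
#' entries are expanded to inclusive ranges.
#'
#' @param path YAML file path.
#' @return A `pr_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("core_rows", "core_cols"))
    if (!is.null(y[[k]]) && length(y[[k]]) == 2)
      y[[k]] <- seq(y[[k]][1], y[[k]][2])
  do.call(sim_config, y)
}

# Deterministic derivation of per-stage seeds from the master seed, so
# stages are individually rerunnable. Offsets are fixed per stage.
stage_seed <- function(config, stage) {
  offs <- c(climate = 1L, phylogeny = 2L, species = 3L,
            protected_areas = 4L, forest = 5L, enm = 6L, scenarios = 7L)
  config$seed * 101L + offs[[stage]]
}

#' Build a strictly decreasing paleo time axis
#'
#' @param start_age,end_age Oldest and youngest slice ages (kyr BP);
#'   `start_age > end_age > 0`.
#' @param step Slice spacing (kyr); must divide `start_age - end_age`
#'   exactly (no silent truncation).
#' @return Strictly decreasing numeric vector of ages from `start_age` to
#'   `end_age` inclusive. The reference configuration (2580, 20, 10)
#'   yields 257 slices.
#' @export
make_time_axis <- function(start_age, end_age, step) {
  if (!(start_age > end_age) || !(end_age > 0))
    stop("need start_age > end_age > 0")
  if (step <= 0) stop("step must be positive")
  if ((start_age - end_age) %% step != 0)
    stop("(start_age - end_age) must be divisible by step")
  seq(start_age, end_age, by = -step)
}

# The fixed spatial climate gradient (no noise): BIO1 ramps over columns,
# BIO12 over rows, both across gradient_range at cell centers.
gradient_layers <- function(config) {
  g <- config$grid
  lo <- config$gradient_range[1]; hi <- config$gradient_range[2]
  colv <- lo + (hi - lo) * (seq_len(g$n_cols) - 0.5) / g$n_cols
  rowv <- lo + (hi - lo) * (seq_len(g$n_rows) - 0.5) / g$n_rows
  list(BIO1 = pr_raster(g, matrix(colv, g$n_rows, g$n_cols, byrow = TRUE),
                        "BIO1"),
       BIO12 = pr_raster(g, matrix(rowv, g$n_rows, g$n_cols), "BIO12"))
}

#' Planted stable-core mask
#'
#' @param config A `pr_sim_config`.
#' @return `pr_mask` with 1 inside the configured core rectangle.
#' @export
core_mask <- function(config) {
  g <- config$grid
  v <- matrix(0, g$n_rows, g$n_cols)
  v[config$core_rows, config$core_cols] <- 1
  pr_mask(g, v, role = "study_area")
}

# Per-cell anomaly SD field.
anomaly_sd_field <- function(config) {
  g <- config$grid
  sd <- matrix(config$anomaly_sd_outside, g$n_rows, g$n_cols)
  sd[config$core_rows, config$core_cols] <- config$anomaly_sd_inside
  sd
}

#' Simulate a paleoclimate history with a planted stable core
#'
#' Each slice's BIO1 and BIO12 are the fixed spatial gradient plus an
#' independent zero-mean Gaussian temporal anomaly whose per-cell SD is
#' `anomaly_sd_inside` within the core and `anomaly_sd_outside`
#' elsewhere. Contemporary layers are the gradient plus one further
#' anomaly draw. Anomalies are temporally independent: the stability
#' statistic responds only to variance structure, and independence keeps
#' analytic expectations available.
#'
#' @param config A `pr_sim_config`.
#' @return List with `stack` (fields `grid`, `ages`, `layers`: per slice
#'   a named list of `pr_raster`s) and `contemporary` (named list of
#'   `pr_raster`s).
#' @export
simulate_climate_history <- function(config) {
  set.seed(stage_seed(config, "climate"))
  g <- config$grid
  grad <- gradient_layers(config)
  sdf <- anomaly_sd_field(config)
  draw <- function(var) {
    noise <- matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
    pr_raster(g, grad[[var]]$values + noise * sdf, var)
  }
  layers <- lapply(config$ages, function(a)
    list(BIO1 = draw("BIO1"), BIO12 = draw("BIO12")))
  contemporary <- list(BIO1 = draw("BIO1"), BIO12 = draw("BIO12"))
  list(stack = structure(list(grid = g, ages = config$ages,
                              layers = layers),
                         class = "pr_timestack"),
       contemporary = contemporary)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Ultrametric tree with tips labelled `sp_001`, `sp_002`, ... and branch
#' lengths in Myr. Fully reproducible from the seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (events/Myr).
#' @return An `ape::phylo` object.
#' @export
simulate_phylogeny <- function(n_tips, seed = 1, birth = 0.5) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- sprintf("sp_%03d", seq_len(n_tips))
  tr
}

# Gaussian suitability kernel of a species over a climate slice.
kernel_suitability <- function(optimum, breadth, layers) {
  d2 <- (layers$BIO1$values - optimum[1])^2 +
        (layers$BIO12$values - optimum[2])^2
  exp(-0.5 * d2 / breadth^2)
}

#' Simulate niche-structured species and their occurrence records
#'
#' Every species has a Gaussian suitability kernel in (BIO1, BIO12)
#' around its niche optimum. Indicator species (the forest-stability
#' proxies) get optima jittered tightly around the core's mean climate.
#' Focal-clade species get optima offset from the core climate by
#' half-normal magnitudes in a random direction; when a phylogeny is
#' supplied, offsets are ranked by terminal branch length (longest branch
#' = smallest offset), concentrating evolutionarily distinct lineages in
#' the stable core — the museum pattern the analysis is designed to
#' detect. Occurrences are cell centers sampled without replacement with
#' probability proportional to contemporary suitability. A species' true
#' range on any slice is the set of cells whose suitability exceeds
#' `truth_threshold` (see [true_range_mask()]).
#'
#' @param config A `pr_sim_config`.
#' @param climate Output of [simulate_climate_history()].
#' @param phylogeny Optional `phylo` with `S_focal` tips providing focal
#'   species names and branch-length-ranked offsets.
#' @return List with `truth` (named list per species: `species`, `kind`,
#'   `niche_optimum`, `niche_breadth`, `range_contemporary` mask) and
#'   `occurrences` (named list of `pr_occurrences`).
#' @export
simulate_species <- function(config, climate, phylogeny = NULL) {
  set.seed(stage_seed(config, "species"))
  grad <- gradient_layers(config)
  core_clim <- c(mean(grad$BIO1$values[config$core_rows, config$core_cols]),
                 mean(grad$BIO12$values[config$core_rows, config$core_cols]))
  n_ind <- config$S_indicator; n_foc <- config$S_focal
  ind_names <- sprintf("ind_%03d", seq_len(n_ind))
  foc_names <- if (!is.null(phylogeny)) {
    if (length(phylogeny$tip.label) != n_foc)
      stop("phylogeny must have S_focal tips")
    phylogeny$tip.label
  } else sprintf("sp_%03d", seq_len(n_foc))

  optima <- matrix(NA_real_, n_ind + n_foc, 2)
  for (i in seq_len(n_ind))
    optima[i, ] <- core_clim +
      stats::runif(2, -config$indicator_jitter, config$indicator_jitter)

  # Half-normal offset magnitudes by rank; rank 1 (smallest offset) goes
  # to the tip with the longest terminal branch when a tree is supplied.
  mags <- config$focal_optimum_sd *
    stats::qnorm(0.5 + 0.5 * (seq_len(n_foc) - 0.5) / n_foc)
  rank_order <- if (!is.null(phylogeny)) {
    term <- terminal_branch_lengths(phylogeny)[foc_names]
    order(order(-term))  # rank of each species by descending branch length
  } else sample(seq_len(n_foc))
  theta <- stats::runif(n_foc, 0, 2 * pi)
  for (i in seq_len(n_foc))
    optima[n_ind + i, ] <- core_clim +
      mags[rank_order[i]] * c(cos(theta[i]), sin(theta[i]))

  species <- c(ind_names, foc_names)
  kinds <- c(rep("indicator", n_ind), rep("focal", n_foc))
  g <- config$grid
  cc <- cell_centers(g)
  truth <- vector("list", length(species)); names(truth) <- species
  occ <- vector("list", length(species)); names(occ) <- species
  for (i in seq_along(species)) {
    suit <- kernel_suitability(optima[i, ], config$niche_breadth,
                               climate$contemporary)
    rng <- pr_mask(g, (suit >= config$truth_threshold) * 1, role = "range")
    if (!any(rng$values == 1))
      stop("species ", species[i], " has an empty contemporary true range")
    truth[[i]] <- structure(
      list(species = species[i], kind = kinds[i],
           niche_optimum = optima[i, ], niche_breadth = config$niche_breadth,
           range_contemporary = rng),
      class = "pr_species_truth")
    p <- as.vector(t(suit))  # row-major to match cell_centers order
    eligible <- which(p > 0)
    if (length(eligible) < config$n_occurrences)
      stop("requested ", config$n_occurrences,
           " occurrences but only ", length(eligible),
           " cells have positive suitability for ", species[i])
    pick <- sample(eligible, config$n_occurrences, prob = p[eligible])
    pts <- as.matrix(cc[pick, c("x", "y")])
    dimnames(pts) <- list(NULL, c("x", "y"))
    occ[[i]] <- structure(list(species = species[i], points = pts,
                               n_unique = nrow(pts),
                               modelable = nrow(pts) > 10),
                          class = "pr_occurrences")
  }
  list(truth = truth, occurrences = occ)
}

terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  idx <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' True range mask of a species on an arbitrary climate slice
#'
#' @param species_truth One element of `simulate_species()$truth`.
#' @param layers Named list of climate `pr_raster`s (BIO1, BIO12).
#' @param truth_threshold Suitability cutoff (defaults to 0.5).
#' @return A `pr_mask`.
#' @export
true_range_mask <- function(species_truth, layers, truth_threshold = 0.5) {
  suit <- kernel_suitability(species_truth$niche_optimum,
                             species_truth$niche_breadth, layers)
  pr_mask(layers$BIO1$grid, (suit >= truth_threshold) * 1, role = "range")
}

#' Simulate protected areas as random non-overlapping rectangles
#'
#' Rectangles are placed uniformly at random (rejecting overlaps) until
#' the covered fraction is within 0.02 of `pa_fraction`. At least one
#' rectangle is always placed.
#'
#' @param config A `pr_sim_config`.
#' @param max_tries Bound on placement attempts before giving up.
#' @return A `pr_mask` with role `"protected_area"`.
#' @export
simulate_protected_areas <- function(config, max_tries = 20000) {
  set.seed(stage_seed(config, "protected_areas"))
  g <- config$grid
  n_cells <- g$n_rows * g$n_cols
  target <- config$pa_fraction * n_cells
  tol <- 0.02 * n_cells
  cover <- matrix(0, g$n_rows, g$n_cols)
  covered <- 0
  tries <- 0
  while ((covered < target - tol || covered == 0) && tries < max_tries) {
    tries <- tries + 1
    budget <- max(1, floor(target + tol - covered))
    max_dim <- max(1L, min(15L, floor(sqrt(budget)),
                           g$n_rows, g$n_cols))
    h <- sample.int(max_dim, 1); w <- sample.int(max_dim, 1)
    r0 <- sample.int(g$n_rows - h + 1L, 1)
    c0 <- sample.int(g$n_cols - w + 1L, 1)
    patch <- cover[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    if (any(patch == 1)) next
    cover[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1
    covered <- covered + h * w
  }
  if (covered < target - tol)
    stop("could not reach protected-area fraction ", config$pa_fraction,
         " within ", max_tries, " placement attempts")
  pr_mask(g, cover, role = "protected_area")
}

#' Simulate a contemporary tree-density layer
#'
#' Tree stem density (stems per square km, emulating a global tree
#' density product) peaks where the long-term mean climate matches the
#' core forest climate, with an envelope twice as broad as the species
#' niches — contemporary forest extends well beyond the stable core, as
#' in the study region. Density reflects the integrated forest
#' distribution (the smooth climate surface) with independent
#' observation noise, not the single contemporary anomaly realization:
#' standing forest is an outcome of decades-to-centuries of growth, so
#' coupling it to one simulated weather draw would be artificial.
#'
#' @param config A `pr_sim_config`.
#' @param climate Output of [simulate_climate_history()] (unused beyond
#'   grid checks; kept so the stage signature matches the others).
#' @param peak_density Stem density at the forest optimum (stems/km^2).
#' @param noise_sd SD of additive observation noise (stems/km^2).
#' @return A `pr_raster` labelled `"tree_density"`.
#' @export
simulate_tree_density <- function(config, climate, peak_density = 80000,
                                  noise_sd = 2000) {
  set.seed(stage_seed(config, "forest"))
  grad <- gradient_layers(config)
  core_clim <- c(mean(grad$BIO1$values[config$core_rows, config$core_cols]),
                 mean(grad$BIO12$values[config$core_rows, config$core_cols]))
  suit <- kernel_suitability(core_clim, 2 * config$niche_breadth, grad)
  g <- config$grid
  v <- peak_density * suit +
    matrix(stats::rnorm(g$n_rows * g$n_cols, sd = noise_sd),
           g$n_rows, g$n_cols)
  v[v < 0] <- 0
  pr_raster(g, v, "tree_density")
}

#' Generate the full synthetic world
#'
#' Runs every generator stage off one master seed: climate history,
#' Yule phylogeny over the focal clade, indicator + focal species with
#' occurrences, tree density, and protected areas.
#'
#' @param config A `pr_sim_config`.
#' @return List with `config`, `climate`, `phylogeny`, `species`
#'   (truth + occurrences), `tree_density`, `protected_areas`, `core`.
#' @export
simulate_world <- function(config = sim_config()) {
  climate <- simulate_climate_history(config)
  phylogeny <- simulate_phylogeny(config$S_focal,
                                  seed = stage_seed(config, "phylogeny"))
  species <- simulate_species(config, climate, phylogeny)
  list(config = config,
       climate = climate,
       phylogeny = phylogeny,
       species = species,
       tree_density = simulate_tree_density(config, climate),
       protected_areas = simulate_protected_areas(config),
       core = core_mask(config))
}
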