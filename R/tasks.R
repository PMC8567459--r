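# Category-structure fixtures, trial protocols, and synthetic training-set
# generators for the simulated experiments.

fr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "famres")
  if (!nzchar(path)) stop("bundled fixture not found: ", file)
  path
}

read_fixture <- function(file) {
  utils::read.csv(fr_extdata(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Category structure container
#'
#' @param stimuli Numeric matrix, one stimulus per row.
#' @param labels Character labels (or `NA` for unsupervised tasks).
#' @param block_size Number of trials per block.
#' @param n_blocks Default number of training blocks.
#' @param block_composition Integer vector of stimulus row indices making up
#'   one block (copies allowed); presented in random order within each block.
#' @param name Structure name.
#' @return An object of class `category_structure`.
#' @export
category_structure <- function(stimuli, labels, block_composition,
                               n_blocks = 1L, name = "structure") {
  stimuli <- as.matrix(stimuli)
  stopifnot(length(labels) == nrow(stimuli))
  structure(list(stimuli = stimuli, labels = as.character(labels),
                 block_composition = as.integer(block_composition),
                 block_size = length(block_composition),
                 n_blocks = as.integer(n_blocks), name = name),
            class = "category_structure")
}

#' Deterministic randomized trial stream for a structure
#'
#' Each block presents the structure's block composition in an independent
#' uniform random order.
#'
#' @param struct A [category_structure()].
#' @param n_blocks Number of blocks (defaults to the structure's).
#' @param seed Integer seed.
#' @return List with `X` (trial stimuli), `label`, `block`.
#' @export
trial_stream <- function(struct, n_blocks = NULL, seed = 1L) {
  if (is.null(n_blocks)) n_blocks <- struct$n_blocks
  idx <- withr_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b)
      sample(struct$block_composition)))
  })
  list(X = struct$stimuli[idx, , drop = FALSE],
       label = struct$labels[idx],
       block = rep(seq_len(n_blocks), each = struct$block_size))
}

# Evaluate `expr` under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- SHJ problems --------------------------------------------------------

shj_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_fixture("shj_truth_tables.csv")
    cache
  }
})

#' The six classic three-dimensional binary category structures
#'
#' Eight stimuli at the corners of a cube (spacing one unit per dimension),
#' split 4/4 into categories A and B. Type I is one-dimensional, Type II the
#' exclusive-or of the first two structure dimensions, Type IV a
#' linearly-separable majority rule, Type VI three-bit parity, and Types III
#' and V rule-plus-exception structures from the bundled truth tables.
#' Blocks present two copies of each stimulus (16 trials).
#'
#' @param type One of `"I" ... "VI"`.
#' @param mapping Permutation of 1:3 assigning structure dimensions to
#'   physical dimensions.
#' @param spacing Per-physical-dimension stimulus spacing.
#' @param n_blocks Default number of training blocks.
#' @return A [category_structure()].
#' @export
shj_structure <- function(type = c("I", "II", "III", "IV", "V", "VI"),
                          mapping = 1:3, spacing = c(1, 1, 1),
                          n_blocks = 8L) {
  type <- match.arg(type)
  mapping <- as.integer(mapping)
  if (length(mapping) != 3L || !identical(sort(mapping), 1:3))
    stop("`mapping` must permute 1:3")
  bits <- as.matrix(expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1))
  struct_bits <- bits[, mapping, drop = FALSE]
  tab <- shj_tables()
  a_set <- tab[tab$type == type, c("b1", "b2", "b3")]
  key <- function(m) apply(m, 1L, paste0, collapse = "")
  labels <- ifelse(key(struct_bits) %in% key(as.matrix(a_set)), "A", "B")
  stimuli <- sweep(bits, 2L, spacing, `*`)
  colnames(stimuli) <- paste0("dim", 1:3)
  category_structure(stimuli, labels,
                     block_composition = rep(seq_len(8L), 2L),
                     n_blocks = n_blocks,
                     name = paste0("shj_", type))
}

## ---- condensation vs. filtration -----------------------------------------

#' Condensation and filtration category structures
#'
#' The eight-stimulus unit-grid ring with either an axis-parallel boundary
#' (filtration: a single dimension separates the categories) or a diagonal
#' boundary (condensation: both dimensions are needed). All four conditions
#' share the same coordinates; only the labels differ, and the two
#' condensation categories are slightly further apart than the filtration
#' ones. Blocks present all eight stimuli.
#'
#' @param condition Which boundary to use.
#' @param n_blocks Default number of training blocks.
#' @return A [category_structure()].
#' @export
condensation_filtration_structure <- function(
    condition = c("filtration_dim1", "filtration_dim2",
                  "condensation_A", "condensation_B"),
    n_blocks = 15L) {
  condition <- match.arg(condition)
  fix <- read_fixture("condensation_filtration_stimuli.csv")
  xy <- as.matrix(fix[, c("x", "y")])
  labels <- switch(condition,
    filtration_dim1 = ifelse(xy[, 1] <= 2.5, "A", "B"),
    filtration_dim2 = ifelse(xy[, 2] <= 2.5, "A", "B"),
    condensation_A = ifelse(xy[, 1] - xy[, 2] < 0, "A", "B"),
    condensation_B = ifelse(xy[, 1] + xy[, 2] < 5, "A", "B"))
  category_structure(xy, labels, block_composition = seq_len(8L),
                     n_blocks = n_blocks, name = condition)
}

## ---- biconditional discrimination ----------------------------------------

#' Biconditional (exclusive-or) discrimination structure
#'
#' Four stimuli at the corners of a unit square with exclusive-or labels
#' (diagonal corners share a label), embedded in three dimensions with the
#' unused dimension at zero. The separable pairing varies dimensions 1 and 3;
#' the integral pairing varies dimensions 1 and 2. Fifteen blocks of all four
#' stimuli.
#'
#' @param kind Which dimension pairing carries the variation.
#' @param n_blocks Default number of training blocks.
#' @return A [category_structure()].
#' @export
biconditional_structure <- function(kind = c("separable_pairing",
                                             "integral_pairing"),
                                    n_blocks = 15L) {
  kind <- match.arg(kind)
  dims <- if (kind == "separable_pairing") c(1L, 3L) else c(1L, 2L)
  corners <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5)))
  stimuli <- matrix(0, 4L, 3L)
  stimuli[, dims] <- corners
  colnames(stimuli) <- paste0("dim", 1:3)
  labels <- ifelse(corners[, 1] * corners[, 2] > 0, "A", "B")
  category_structure(stimuli, labels, block_composition = seq_len(4L),
                     n_blocks = n_blocks, name = paste0("biconditional_",
                                                        kind))
}

## ---- free classification -------------------------------------------------

#' Six-stimulus free-classification set with its critical partitions
#'
#' Returns the bundled two-dimensional six-stimulus configuration together
#' with the three critical bipartitions: grouping by overall similarity, by
#' one-dimensional similarity, and by one-dimensional identity (exact value
#' matches on one dimension). All other partitions of the six stimuli are
#' classified `"other"`.
#'
#' @param stimuli Optional replacement coordinate table (matrix with columns
#'   x, y), e.g. a different transcription of the figure.
#' @return List with `structure` (a [category_structure()] of unlabeled
#'   stimuli) and `critical` (named list of canonical assignment vectors).
#' @export
free_classification_structure <- function(stimuli = NULL) {
  fix <- read_fixture("free_classification_stimuli.csv")
  xy <- if (is.null(stimuli)) as.matrix(fix[, c("x", "y")]) else
    as.matrix(stimuli)
  crit <- list(
    overall_similarity = canonical_partition(fix$os),
    onedim_similarity = canonical_partition(fix$odsim),
    onedim_identity = canonical_partition(fix$odid))
  struct <- category_structure(xy, rep(NA_character_, nrow(xy)),
                               block_composition = seq_len(nrow(xy)),
                               n_blocks = 1L, name = "free_classification")
  list(structure = struct, critical = crit)
}

#' Classify a partition as one of the critical types
#'
#' @param z Assignment vector over the six stimuli.
#' @param critical Named list from [free_classification_structure()].
#' @return The matching critical-partition name, or `"other"`.
#' @export
partition_type <- function(z, critical) {
  z <- canonical_partition(z)
  for (nm in names(critical))
    if (identical(z, critical[[nm]])) return(nm)
  "other"
}

## ---- dimensional learning / Garner ---------------------------------------

#' Four-by-four discrimination-training grid
#'
#' Sixteen stimuli factorially crossing four values on each of two
#' dimensions (unit spacing, centered at zero). Training labels come in
#' three flavors: a one-dimensional boundary at the median of dimension 1 or
#' 2, or a two-dimensional four-quadrant labeling. Each training stimulus is
#' presented 20 times. Also enumerates the 24 neighboring same-different
#' test pairs, marking the dimension of difference and whether the pair
#' crosses the median boundary of its dimension.
#'
#' @param training `"1d_dim1"`, `"1d_dim2"`, or `"2d"`.
#' @param spacing Grid spacing.
#' @return List with `structure`, `pairs` (data frame of neighbor pairs),
#'   and `stimuli`.
#' @export
discrimination_grid <- function(training = c("1d_dim1", "1d_dim2", "2d"),
                                spacing = 1) {
  training <- match.arg(training)
  vals <- (c(1, 2, 3, 4) - 2.5) * spacing
  grid <- as.matrix(expand.grid(x = vals, y = vals))
  labels <- switch(training,
    "1d_dim1" = ifelse(grid[, 1] < 0, "A", "B"),
    "1d_dim2" = ifelse(grid[, 2] < 0, "A", "B"),
    "2d" = paste0(ifelse(grid[, 1] < 0, "L", "R"),
                  ifelse(grid[, 2] < 0, "D", "U")))
  struct <- category_structure(grid, labels,
                               block_composition = seq_len(16L),
                               n_blocks = 20L,
                               name = paste0("discrimination_", training))
  pairs <- NULL
  for (i in seq_len(16L)) for (j in seq_len(16L)) {
    if (j <= i) next
    diffd <- which(abs(grid[i, ] - grid[j, ]) > 1e-9)
    if (length(diffd) == 1L &&
        abs(grid[i, diffd] - grid[j, diffd]) <= spacing + 1e-9) {
      crosses <- grid[i, diffd] * grid[j, diffd] < 0
      pairs <- rbind(pairs, data.frame(i = i, j = j, dim = diffd,
                                       crosses_boundary = crosses))
    }
  }
  list(structure = struct, pairs = pairs, stimuli = grid)
}

#' Garner filtering and baseline tasks
#'
#' Training: a two-by-two stimulus square on dimensions 1 and 2 (unit
#' spacing), labeled by dimension 1, presented for nine blocks. Test tasks
#' live on dimensions 1 and 3 (the novel dimension) with doubled spacing:
#' the filtering task presents all four test stimuli classified by the
#' target dimension 1; each baseline task presents the two-stimulus subset
#' at a fixed value of the novel dimension. Garner interference is baseline
#' accuracy minus filtering accuracy.
#'
#' @param train_spacing Spacing of the training square.
#' @param n_blocks Training blocks.
#' @return List with `training`, `filtering`, `baselines` (list of two
#'   structures).
#' @export
garner_tasks <- function(train_spacing = 1, n_blocks = 9L) {
  half <- train_spacing / 2
  tr <- as.matrix(expand.grid(d1 = c(-half, half), d2 = c(-half, half)))
  training <- category_structure(
    cbind(tr, d3 = 0), ifelse(tr[, 1] < 0, "A", "B"),
    block_composition = seq_len(4L), n_blocks = n_blocks,
    name = "garner_training")
  test_half <- train_spacing  # doubled spacing at test
  te <- as.matrix(expand.grid(d1 = c(-test_half, test_half),
                              d3 = c(-test_half, test_half)))
  test_stim <- cbind(te[, 1], 0, te[, 2])
  colnames(test_stim) <- c("d1", "d2", "d3")
  filtering <- category_structure(
    test_stim, ifelse(te[, 1] < 0, "A", "B"),
    block_composition = seq_len(4L), n_blocks = n_blocks,
    name = "garner_filtering")
  baselines <- lapply(c(-test_half, test_half), function(v) {
    keep <- which(abs(te[, 2] - v) < 1e-9)
    # two copies per block so baseline blocks match filtering blocks in
    # trial count (blocks are fixed-length, stimuli cycle)
    category_structure(
      test_stim[keep, , drop = FALSE],
      ifelse(te[keep, 1] < 0, "A", "B"),
      block_composition = rep(seq_along(keep), 2L), n_blocks = n_blocks,
      name = paste0("garner_baseline_", ifelse(v < 0, "low", "high")))
  })
  list(training = training, filtering = filtering, baselines = baselines)
}

## ---- synthetic Gaussian training sets ------------------------------------

#' Generate Gaussian cluster training data
#'
#' Draws seeded Gaussian samples for a list of cluster specifications; each
#' cluster is tagged with its own context (the convention used when training
#' the full hierarchy on category exemplars).
#'
#' @param spec List of cluster specs: each a list with `mean`, `cov`, `n`,
#'   and optionally `context`.
#' @param seed Integer seed.
#' @return List with `X`, `context`, `cluster` (generating index), and the
#'   generating `spec`.
#' @export
generate_cluster_training <- function(spec, seed = 1L) {
  for (s in spec) if (!is_spd(as.matrix(s$cov)))
    stop("cluster covariances must be SPD")
  withr_seed(seed, {
    xs <- list(); ctx <- character(0); gen <- integer(0)
    for (i in seq_along(spec)) {
      s <- spec[[i]]
      d <- length(s$mean)
      ch <- chol_spd(as.matrix(s$cov))
      pts <- matrix(stats::rnorm(s$n * d), s$n, d) %*% ch
      pts <- sweep(pts, 2L, as.numeric(s$mean), `+`)
      xs[[i]] <- pts
      ctx <- c(ctx, rep(if (is.null(s$context)) paste0("ctx", i)
                        else s$context, s$n))
      gen <- c(gen, rep(i, s$n))
    }
    list(X = do.call(rbind, xs), context = ctx, cluster = gen, spec = spec)
  })
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Preset synthetic training regimes
#'
#' `"six_axis_aligned"`: six clusters of 30 points, three elongated
#' horizontally and three vertically (axis ratio 10:1).
#' `"ten_axis_aligned"`: the same recipe with five clusters per orientation.
#' `"six_rotated"`: the six-cluster preset rotated 45 degrees.
#'
#' The default wide standard deviation (0.1) places the generated clusters
#' at the scale the model's fixed top-level prior expects for cluster
#' covariances (the prior-predictive cluster standard deviation is roughly
#' 0.02-0.12), so that training informs the covariance *shape* rather than
#' fighting the prior's scale.
#'
#' @param preset Preset name.
#' @param n_per_cluster Points per cluster (30 by default).
#' @param sd_wide Wide standard deviation (narrow is `sd_wide / 10`).
#' @param center_range Cluster centers are drawn uniformly in
#'   `[-center_range, center_range]` per dimension.
#' @param seed Integer seed (controls cluster centers and draws).
#' @return As [generate_cluster_training()].
#' @export
training_preset <- function(preset = c("six_axis_aligned",
                                       "ten_axis_aligned", "six_rotated"),
                            n_per_cluster = 30L, sd_wide = 0.1,
                            center_range = 0.4, seed = 1L) {
  preset <- match.arg(preset)
  n_each <- if (preset == "ten_axis_aligned") 5L else 3L
  centers <- withr_seed(seed + 1000L, {
    matrix(stats::runif(2L * 2L * n_each, -center_range, center_range),
           ncol = 2L)
  })
  sds <- rbind(matrix(rep(c(sd_wide, sd_wide / 10), n_each),
                      ncol = 2L, byrow = TRUE),
               matrix(rep(c(sd_wide / 10, sd_wide), n_each),
                      ncol = 2L, byrow = TRUE))
  spec <- lapply(seq_len(2L * n_each), function(i)
    list(mean = centers[i, ], cov = diag(sds[i, ]^2), n = n_per_cluster))
  out <- generate_cluster_training(spec, seed)
  if (preset == "six_rotated") {
    r <- rotation2(pi / 4)
    out$X <- out$X %*% t(r)
    out$spec <- lapply(out$spec, function(s) {
      s$mean <- drop(r %*% s$mean)
      s$cov <- r %*% s$cov %*% t(r)
      s
    })
  }
  out
}
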