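test_that("the six problem types are balanced and have their defining
           structure", {
  for (ty in c("I", "II", "III", "IV", "V", "VI")) {
    s <- shj_structure(ty)
    expect_identical(as.integer(table(s$labels)), c(4L, 4L))
    expect_identical(nrow(s$stimuli), 8L)
    expect_identical(s$block_size, 16L)  # two copies per block
  }
  # Type I depends only on the first structure dimension
  s1 <- shj_structure("I")
  expect_true(all(tapply(s1$labels, s1$stimuli[, 1], function(l)
    length(unique(l)) == 1L)))
  # Type II: exclusive-or of the first two dimensions
  s2 <- shj_structure("II")
  expect_true(all((s2$stimuli[, 1] == s2$stimuli[, 2]) ==
                    (s2$labels == s2$labels[1])))
  # Type VI: flipping any single bit flips the label
  s6 <- shj_structure("VI")
  key <- apply(s6$stimuli, 1L, paste, collapse = "")
  lab <- setNames(s6$labels, key)
  for (i in 1:8) for (d in 1:3) {
    flipped <- s6$stimuli[i, ]
    flipped[d] <- 1 - flipped[d]
    expect_false(lab[[paste(flipped, collapse = "")]] == s6$labels[i])
  }
  # dimension mapping permutes which physical dimension is relevant
  sm <- shj_structure("I", mapping = c(3, 1, 2))
  expect_true(all(tapply(sm$labels, sm$stimuli[, 3], function(l)
    length(unique(l)) == 1L)))
})

test_that("condensation and filtration share coordinates and differ only in
           boundary orientation", {
  conds <- c("filtration_dim1", "filtration_dim2", "condensation_A",
             "condensation_B")
  structs <- lapply(conds, condensation_filtration_structure)
  for (s in structs) expect_identical(as.integer(table(s$labels)), c(4L, 4L))
  for (s in structs[-1])
    expect_identical(s$stimuli, structs[[1]]$stimuli)
  # filtration: a single dimension separates the categories
  f1 <- structs[[1]]
  expect_true(max(f1$stimuli[f1$labels == "A", 1]) <
                min(f1$stimuli[f1$labels == "B", 1]))
  # condensation: neither dimension alone separates them
  c1 <- structs[[3]]
  for (d in 1:2)
    expect_true(max(c1$stimuli[c1$labels == "A", d]) >
                  min(c1$stimuli[c1$labels == "B", d]))
  # condensation categories are further apart than filtration ones
  sepn <- function(s) {
    ma <- colMeans(s$stimuli[s$labels == "A", ])
    mb <- colMeans(s$stimuli[s$labels == "B", ])
    sqrt(sum((ma - mb)^2))
  }
  expect_gt(sepn(structs[[3]]), sepn(structs[[1]]))
  expect_gt(sepn(structs[[4]]), sepn(structs[[2]]))
})

test_that("biconditional structures are exclusive-or squares embedded in
           three dimensions", {
  for (kind in c("separable_pairing", "integral_pairing")) {
    b <- biconditional_structure(kind)
    expect_identical(dim(b$stimuli), c(4L, 3L))
    varying <- which(apply(b$stimuli, 2L, function(v) length(unique(v))) > 1)
    expect_length(varying, 2L)
    xy <- b$stimuli[, varying]
    # diagonal corners share labels
    expect_identical(b$labels[xy[, 1] * xy[, 2] > 0][1],
                     b$labels[xy[, 1] * xy[, 2] > 0][2])
    # all adjacent (side) distances equal
    d <- as.matrix(dist(xy))
    sides <- sort(d[upper.tri(d)])[1:4]
    expect_equal(max(sides) - min(sides), 0)
  }
  expect_identical(unname(
    which(apply(biconditional_structure("separable_pairing")$stimuli, 2L,
                function(v) length(unique(v))) > 1)), c(1L, 3L))
})

test_that("free-classification critical partitions are distinct 3/3 splits
           and identity groups exact values", {
  task <- free_classification_structure()
  expect_identical(nrow(task$structure$stimuli), 6L)
  keys <- vapply(task$critical, paste, character(1), collapse = "-")
  expect_identical(anyDuplicated(keys), 0L)
  for (z in task$critical)
    expect_identical(as.integer(table(z)), c(3L, 3L))
  idz <- task$critical$onedim_identity
  x <- task$structure$stimuli[, 1]
  for (g in 1:2)
    expect_length(unique(x[idz == g]), 1L)
  # everything else is typed "other"
  all_parts <- enumerate_partitions(6)
  types <- vapply(all_parts, partition_type, character(1),
                  critical = task$critical)
  expect_identical(sum(types == "other"), 200L)  # Bell(6) - 3
})

test_that("Garner tasks share target-dimension values with doubled test
           spacing", {
  g <- garner_tasks(train_spacing = 1)
  expect_identical(nrow(g$training$stimuli), 4L)
  expect_identical(nrow(g$filtering$stimuli), 4L)
  # target dimension values identical between filtering and each baseline
  for (b in g$baselines)
    expect_identical(sort(unique(b$stimuli[, 1])),
                     sort(unique(g$filtering$stimuli[, 1])))
  # test spacing is double the training spacing
  expect_equal(diff(sort(unique(g$filtering$stimuli[, 1]))),
               2 * diff(sort(unique(g$training$stimuli[, 1]))))
  # baselines have no variation on the novel dimension
  for (b in g$baselines)
    expect_length(unique(b$stimuli[, 3]), 1L)
})

test_that("the discrimination grid enumerates 24 neighbor pairs and labels
           quadrants", {
  for (tr in c("1d_dim1", "1d_dim2", "2d")) {
    g <- discrimination_grid(tr)
    expect_identical(nrow(g$structure$stimuli), 16L)
    expect_identical(nrow(g$pairs), 24L)
    expect_identical(sum(g$pairs$dim == 1), 12L)
  }
  g1 <- discrimination_grid("1d_dim1")
  expect_true(all(tapply(g1$structure$labels,
                         g1$structure$stimuli[, 1] < 0,
                         function(l) length(unique(l)) == 1L)))
  expect_length(unique(discrimination_grid("2d")$structure$labels), 4L)
  # crossing pairs straddle the median boundary on their dimension
  cr <- g1$pairs[g1$pairs$crosses_boundary & g1$pairs$dim == 1, ]
  expect_true(all(g1$stimuli[cr$i, 1] * g1$stimuli[cr$j, 1] < 0))
})

test_that("synthetic cluster training is reproducible and matches its
           generator", {
  spec <- list(list(mean = c(0, 0), cov = diag(c(1, 0.01)), n = 30),
               list(mean = c(2, 2), cov = diag(c(0.01, 1)), n = 30))
  a <- generate_cluster_training(spec, seed = 5)
  b <- generate_cluster_training(spec, seed = 5)
  expect_identical(a$X, b$X)
  expect_identical(as.integer(table(a$cluster)), c(30L, 30L))
  # sample covariance close to the generator (loose Monte-Carlo check)
  s1 <- cov(a$X[a$cluster == 1, ])
  expect_equal(s1[1, 1], 1, tolerance = 0.4)
  expect_lt(abs(s1[2, 2] - 0.01), 0.01)
  # rotated preset equals the unrotated preset rotated 45 degrees
  plain <- training_preset("six_axis_aligned", n_per_cluster = 5, seed = 2)
  rot <- training_preset("six_rotated", n_per_cluster = 5, seed = 2)
  r45 <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2)
  expect_equal(rot$X, plain$X %*% t(r45))
  expect_identical(nrow(training_preset("ten_axis_aligned",
                                        n_per_cluster = 3, seed = 1)$X),
                   30L)
})

test_that("trial streams are deterministic in the seed and block-complete", {
  s <- shj_structure("IV")
  a <- trial_stream(s, n_blocks = 3, seed = 7)
  b <- trial_stream(s, n_blocks = 3, seed = 7)
  expect_identical(a$X, b$X)
  expect_identical(a$label, b$label)
  # each block contains exactly the block composition
  for (bl in 1:3) {
    rows <- a$X[a$block == bl, ]
    counts <- table(apply(rows, 1L, paste, collapse = ","))
    expect_true(all(counts == 2L))
  }
})
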