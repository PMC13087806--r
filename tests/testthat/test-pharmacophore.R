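test_that("an acceptor at the sphere center satisfies the acceptor point", {
  points <- default_pharmacophore()
  m <- mol_parse("c1ccncc1")  # pyridine: one acceptor nitrogen
  coords <- matrix(0, nrow(m$atoms), 3)
  n_idx <- which(m$atoms$elem == "N")
  coords[n_idx, ] <- c(34.7400, 4.8230, -70.2390)
  p <- pose(m, coords)
  res <- check_pharmacophore(p, points["HBA"])
  expect_true(res$points$satisfied[1])
  expect_equal(res$points$min_distance[1], 0)
})

test_that("the sphere boundary is inclusive and radius + 0.01 fails", {
  pt <- pharmacophore_point("HBA", c(0, 0, 0), radius = 0.7)
  m <- mol_parse("c1ccncc1")
  n_idx <- which(m$atoms$elem == "N")
  at <- function(d) {
    coords <- matrix(50, nrow(m$atoms), 3)
    coords[n_idx, ] <- c(d, 0, 0)
    check_pharmacophore(pose(m, coords), list(pt))$overall
  }
  expect_true(at(0.7))          # inclusive boundary
  expect_false(at(0.71))        # just outside
})

test_that("a two-atom donor/acceptor pose satisfies both points", {
  points <- default_pharmacophore()
  m <- mol_parse("NCCOC")  # amine N donor, ether O acceptor
  fa <- nahdesign:::.feature_atoms(m)
  coords <- matrix(0, nrow(m$atoms), 3)
  coords[fa$HBA[1], ] <- points$HBA$center + c(0.3, 0, 0)  # dist 0.3 < 0.7
  coords[fa$HBD[1], ] <- points$HBD$center + c(0, 0.5, 0)  # dist 0.5 < 1.0
  res <- check_pharmacophore(pose(m, coords), points)
  expect_true(res$overall)
  expect_equal(res$points$min_distance,
               c(0.3, 0.5), tolerance = 1e-12)
})

test_that("poses without atoms of a required class fail that point", {
  m <- mol_parse("CCCC")  # no donors, no acceptors
  p <- pose(m, matrix(0, nrow(m$atoms), 3))
  res <- check_pharmacophore(p)
  expect_false(any(res$points$satisfied))
  expect_false(res$overall)
  expect_true(all(is.na(res$points$min_distance)))
})

test_that("checking is invariant under rigid-body transforms", {
  gp <- generate_poses(15, satisfied_fraction = 0.5, seed = 21)
  points <- default_pharmacophore()
  for (k in seq_along(gp$poses)) {
    rot <- random_rotation(k)
    tra <- c(5, -3, 12) * k
    moved_pose <- rigid_transform(gp$poses[[k]], rot, tra)
    moved_points <- lapply(points, rigid_transform, rotation = rot,
                           translation = tra)
    expect_equal(check_pharmacophore(moved_pose, moved_points)$overall,
                 check_pharmacophore(gp$poses[[k]], points)$overall)
  }
})

test_that("poses written as SDF read back with the same verdicts", {
  gp <- generate_poses(6, satisfied_fraction = 0.5, seed = 4)
  path <- withr::local_tempfile(fileext = ".sdf")
  blocks <- vapply(seq_along(gp$poses), function(i) {
    p <- gp$poses[[i]]
    m <- p$mol
    m$atoms$x <- p$coordinates[, 1]
    m$atoms$y <- p$coordinates[, 2]
    m$atoms$z <- p$coordinates[, 3]
    nahdesign:::.mol_to_molblock(m, title = sprintf("pose%02d", i))
  }, character(1))
  writeLines(blocks, path)
  back <- read_poses(path)
  expect_length(back, length(gp$poses))
  orig <- vapply(gp$poses, function(p) check_pharmacophore(p)$overall,
                 logical(1))
  again <- vapply(back, function(p) check_pharmacophore(p)$overall,
                  logical(1))
  expect_identical(again, orig)
})
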