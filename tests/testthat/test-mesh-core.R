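test_that("surface_mesh validates faces", {
  v <- diag(3)
  expect_s3_class(surface_mesh(v, rbind(c(1, 2, 3))), "surface_mesh")
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(surface_mesh(rbind(v, c(1, 1, 1)),
                            rbind(c(1, 2, 3), c(3, 2, 1))), "duplicate")
})

test_that("OBJ round trip preserves coordinates and connectivity", {
  set.seed(1)
  v <- matrix(rnorm(300, sd = 50), 100, 3)
  f <- t(replicate(60, sample.int(100, 3)))
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  f <- f[!duplicated(key), ]
  mesh <- surface_mesh(v, f)
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_identical(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
})

test_that("single-triangle OBJ reads as p=3, t=1", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  mesh <- read_mesh(path)
  expect_equal(n_vertices(mesh), 3)
  expect_equal(n_faces(mesh), 1)
  expect_equal(mesh$faces, rbind(c(1L, 2L, 3L)))
})

test_that("quad faces raise a parse error naming the face", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             path)
  expect_error(read_mesh(path), "face 1 has 4 vertices")
})

test_that("PLY ASCII and binary round trips are lossless", {
  mesh <- icosphere(1)
  for (binary in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, path, binary = binary)
    back <- read_mesh(path)
    expect_identical(back$faces, mesh$faces)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-9)
  }
})

test_that("OBJ faces with texture/normal slots parse to vertex indices", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1/1 2/2/1 3//2"), path)
  expect_equal(read_mesh(path)$faces, rbind(c(1L, 2L, 3L)))
})

test_that("mass matrix conserves total area", {
  tri <- single_triangle(1)
  mm <- compute_mass_matrix(tri)
  expect_equal(total_mass(mm), sqrt(3) / 4, tolerance = 1e-12)

  for (mesh in list(icosphere(1),
                    generate_head("sagittal", 0.3, noise = 0.5, seed = 2,
                                  subdivisions = 2)$mesh)) {
    mm <- compute_mass_matrix(mesh)
    expect_equal(total_mass(mm), sum(face_areas(mesh)), tolerance = 5e-3)
    expect_true(all(mm$M@x >= 0))
    expect_lt(max(abs(mm$M - Matrix::t(mm$M))), 1e-12)
  }
})

test_that("off-diagonal mass entries exist only on mesh edges", {
  mesh <- icosphere(1)
  mm <- compute_mass_matrix(mesh)
  M <- as.matrix(mm$M)
  edges <- mesh_edges(mesh)
  allowed <- matrix(FALSE, nrow(M), ncol(M))
  diag(allowed) <- TRUE
  allowed[edges] <- TRUE
  allowed[edges[, 2:1]] <- TRUE
  expect_true(all(M[!allowed] == 0))
})

test_that("face-area partition agrees with a dense nearest-element oracle", {
  # one icosahedron face, classified by brute force at a much denser grid:
  # nearest of the six element centers (3 vertices, 3 edge midpoints), then
  # the same PSD edge-lumping rule applied independently
  ico <- icosphere(0)
  f <- ico$faces[1, ]
  A <- ico$vertices[f[1], ]; B <- ico$vertices[f[2], ]; C <- ico$vertices[f[3], ]
  ctrs <- rbind(A, B, C, (A + B) / 2, (B + C) / 2, (C + A) / 2)
  n <- 80
  counts <- numeric(6)
  for (i in 0:n) {
    for (j in 0:(n - i)) {
      w <- c(i, j, n - i - j) / n
      p <- w[1] * A + w[2] * B + w[3] * C
      d <- rowSums((ctrs - rep(p, each = 6))^2)
      counts[which.min(d)] <- counts[which.min(d)] + 1
    }
  }
  fr <- counts / sum(counts)           # v1 v2 v3 e12 e23 e31 shares
  E <- c(fr[4] + fr[6], fr[4] + fr[5], fr[5] + fr[6])
  s <- min(1, (fr[1:3] + E / 2) / (1.5 * E))
  oracle_v <- fr[1] + (1 - s) * E[1] / 2
  oracle_e <- s * fr[4]
  mm <- compute_mass_matrix(ico)
  area <- face_areas(ico)[1]
  # every icosahedron face is congruent and partitions identically, so the
  # per-face vertex share is the vertex weight divided by its 5 incident faces
  vertex_share <- Matrix::diag(mm$M)[f[1]] / 5 / area
  edge_share <- mm$M[f[1], f[2]] / 2 / area
  expect_lt(abs(vertex_share - oracle_v), 0.01)
  expect_lt(abs(edge_share - oracle_e), 0.01)
})

test_that("the mass matrix is positive semidefinite", {
  for (mesh in list(icosphere(1), grid_mesh(5))) {
    mm <- compute_mass_matrix(mesh)
    ev <- eigen(as.matrix(mm$M), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
})

test_that("interior grid vertices get equal weight by symmetry", {
  mesh <- grid_mesh(6)
  mm <- compute_mass_matrix(mesh)
  d <- Matrix::diag(mm$M)
  v <- mesh$vertices
  interior <- which(v[, 1] > 0 & v[, 1] < 5 & v[, 2] > 0 & v[, 2] < 5)
  expect_gt(length(interior), 4)
  expect_lt(diff(range(d[interior])), 1e-10)
})

test_that("stretch_mass_matrix replicates channels per the index formula", {
  a <- 2.5
  expect_equal(as.matrix(stretch_mass_matrix(matrix(a, 1, 1))),
               diag(rep(a, 3)), ignore_attr = TRUE)
  expect_equal(as.matrix(stretch_mass_matrix(diag(4))), diag(12),
               ignore_attr = TRUE)
  set.seed(9)
  M <- matrix(rnorm(16), 4, 4)
  M <- M + t(M)
  M3 <- as.matrix(stretch_mass_matrix(M))
  for (i in 1:4) {
    for (j in 1:4) {
      for (ci in 1:3) {
        for (cj in 1:3) {
          expected <- if (ci == cj) M[i, j] else 0
          expect_identical(M3[3 * (i - 1) + ci, 3 * (j - 1) + cj], expected)
        }
      }
    }
  }
})

test_that("mirroring is an isometric involution that restores labels", {
  scan <- generate_head("coronal", 0.3, noise = 0.3, seed = 4,
                        subdivisions = 2)
  m1 <- mirror_scan(scan)
  expect_true(m1$mirrored)
  expect_false(identical(m1$landmarks$name[m1$landmarks$x ==
                                             m1$landmarks$x], NULL))
  # isometry: pairwise distances preserved
  idx <- c(1, 10, 50, 100)
  d0 <- as.matrix(dist(scan$mesh$vertices[idx, ]))
  d1 <- as.matrix(dist(m1$mesh$vertices[idx, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # involution
  m2 <- mirror_scan(m1)
  expect_false(m2$mirrored)
  expect_lt(max(abs(m2$mesh$vertices - scan$mesh$vertices)), 1e-9)
  expect_equal(m2$landmarks$name, scan$landmarks$name)
  expect_equal(landmark_coords(m2$landmarks), landmark_coords(scan$landmarks),
               tolerance = 1e-9)
})

test_that("mirroring a symmetric head reproduces it and keeps normals outward", {
  scan <- generate_head("control", 0.3, noise = 0, seed = 5, subdivisions = 2)
  plane <- list(point = c(0, 0, 0), normal = c(1, 0, 0))
  mir <- mirror_scan(scan, plane = plane)
  # vertex sets coincide after re-sorting (exact bilateral symmetry)
  map <- template_symmetry_map(scan$mesh)
  expect_lt(max(abs(mir$mesh$vertices[map, ] - scan$mesh$vertices)), 1e-9)
  # winding stays outward on the (star-shaped) head: normal . radial > 0
  fn <- face_normals(mir$mesh)
  v <- mir$mesh$vertices
  ctr <- (v[mir$mesh$faces[, 1], ] + v[mir$mesh$faces[, 2], ] +
            v[mir$mesh$faces[, 3], ]) / 3
  ctr <- ctr - matrix(colMeans(v), nrow(ctr), 3, byrow = TRUE)
  expect_true(all(rowSums(fn * ctr) > 0))
  # left/right landmark names swapped back into schema order
  expect_equal(mir$landmarks$name, scan$landmarks$name)
})

test_that("submesh extraction maps indices back to parent coordinates", {
  mesh <- icosphere(1)
  p <- n_vertices(mesh)
  full <- extract_submesh(mesh, seq_len(p))
  expect_equal(full$mesh$vertices, mesh$vertices)
  expect_identical(full$mesh$faces, mesh$faces)
  expect_identical(full$index_map, seq_len(p))

  mask <- which(mesh$vertices[, 3] > 0)
  sub <- extract_submesh(mesh, mask)
  expect_equal(n_vertices(sub$mesh), length(mask))
  expect_true(all(sub$mesh$faces >= 1 & sub$mesh$faces <= length(mask)))
  expect_equal(sub$mesh$vertices, mesh$vertices[sub$index_map, ])
  # faces fully inside the mask only
  orig_faces <- matrix(sub$index_map[sub$mesh$faces], ncol = 3)
  expect_true(all(orig_faces %in% mask))
  expect_error(extract_submesh(mesh, integer(0)), "empty")
})

test_that("vertex mask files round trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_vertex_mask(c(3L, 1L, 8L), path)
  expect_identical(read_vertex_mask(path), c(3L, 1L, 8L))
})

test_that("compiled closest-point kernel matches a dense sampling oracle", {
  mesh <- icosphere(0)
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 1.5), 10, 3)
  res <- closest_on_mesh(pts, mesh)
  for (i in seq_len(nrow(pts))) {
    d_oracle <- min(vapply(seq_len(n_faces(mesh)), function(f) {
      fv <- mesh$faces[f, ]
      oracle_point_tri_dist(pts[i, ], mesh$vertices[fv[1], ],
                            mesh$vertices[fv[2], ], mesh$vertices[fv[3], ],
                            n = 60)
    }, numeric(1)))
    # the kernel is exact, the oracle samples: kernel <= oracle, gap bounded
    # by the oracle's grid resolution
    expect_lte(res$distance[i], d_oracle + 1e-9)
    expect_lt(d_oracle - res$distance[i], 5e-3)
  }
})
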