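test_that("default geometry meshes to a valid tagged triangulation", {
  o <- buildGeometry(geometryParams())
  mesh <- generateMesh(o, targetH = 3e-4)
  expect_gt(nrow(mesh@cells), 5000)
  a <- graftflow:::triangleAreas(mesh@nodes, mesh@cells)
  expect_true(all(a > 0))
  ## closed boundary: every boundary node belongs to exactly two edges
  deg <- table(as.vector(mesh@boundaryEdges))
  expect_true(all(deg == 2))
  ## area consistency with the outline polygon
  polyA <- graftflow:::polygonArea(graftflow:::outlinePolygon(o))
  expect_lt(abs(meshArea(mesh) / polyA - 1), 0.005)
  expect_setequal(unique(mesh@boundaryTag),
                  c("LAD_INLET", "GRAFT_INLET", "OUTLET", "WALL"))
  expect_setequal(unique(stats::na.omit(mesh@wallRegion)),
                  c("LAD_WALL_PROX", "LAD_WALL_DIST", "GRAFT_WALL",
                    "ANASTOMOSIS"))
})

test_that("halving the target size grows the cell count about fourfold", {
  o <- buildGeometry(geometryParams())
  n1 <- nrow(generateMesh(o, targetH = 6e-4)@cells)
  n2 <- nrow(generateMesh(o, targetH = 3e-4)@cells)
  expect_gt(n2 / n1, 4 * 0.7)
  expect_lt(n2 / n1, 4 * 1.3)
})

test_that("full occlusion drops the LAD inlet without a topology jump", {
  m1 <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 1)), 6e-4)
  m99 <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 0.9999)), 6e-4)
  expect_false("LAD_INLET" %in% m1@boundaryTag)
  expect_true("LAD_INLET" %in% m99@boundaryTag)
  expect_lt(abs(meshArea(m1) / meshArea(m99) - 1), 1e-3)
})

test_that("near-wall layers respect the refinement factor", {
  mesh <- generateMesh(buildGeometry(geometryParams()), targetH = 6e-4,
                       refineWall = 4)
  ## first off-wall layer of the straight LAD: distance from the bottom wall
  yb <- sort(unique(round(mesh@nodes[mesh@nodes[, 1] < 1e-3, 2], 12)))
  expect_lte(yb[2] - yb[1], 6e-4 / 4 + 1e-9)
})

test_that("quality floor is enforced", {
  o <- buildGeometry(geometryParams())
  expect_error(generateMesh(o, targetH = 6e-4, qualityFloor = 0.9),
               "quality")
})

test_that("mesh round-trips through VTK and plain-text formats", {
  mesh <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 0.5)),
                       targetH = 1e-3)
  fv <- tempfile(fileext = ".vtk"); ft <- tempfile(fileext = ".txt")
  writeMeshVTK(mesh, fv); writeMeshTxt(mesh, ft)
  for (m2 in list(readMeshVTK(fv), readMeshTxt(ft))) {
    expect_identical(m2@nodes, mesh@nodes)
    expect_identical(unname(m2@cells), unname(mesh@cells))
    expect_identical(unname(m2@boundaryEdges), unname(mesh@boundaryEdges))
    expect_identical(unname(m2@boundaryTag), mesh@boundaryTag)
    expect_identical(unname(m2@wallRegion), mesh@wallRegion)
  }
  unlink(c(fv, ft))
})

test_that("channel mesh carries inlet, outlet and wall tags", {
  mesh <- channelMesh(4.5e-3, 0.01, targetH = 5e-4)
  expect_setequal(unique(mesh@boundaryTag), c("LAD_INLET", "OUTLET", "WALL"))
  expect_equal(meshArea(mesh), 4.5e-3 * 0.01, tolerance = 1e-12)
})
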