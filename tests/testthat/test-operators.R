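## Discrete operator identities on a small structured mesh.

opsFixture <- function() {
  mesh <- channelMesh(1e-3, 2e-3, targetH = 2.5e-4, refineWall = 1)
  list(mesh = mesh, ops = assembleOperators(mesh, fluidProps()))
}

test_that("diffusion operator annihilates constants on interior nodes", {
  fx <- opsFixture()
  interior <- setdiff(seq_len(nrow(fx$mesh@nodes)),
                      unique(as.vector(fx$mesh@boundaryEdges)))
  r <- as.vector(fx$ops$K %*% rep(1, nrow(fx$mesh@nodes)))
  expect_lt(max(abs(r[interior])), 1e-15)
  ## and is symmetric positive semidefinite
  expect_lt(max(abs(fx$ops$K - Matrix::t(fx$ops$K))), 1e-18)
  set.seed(1)
  z <- rnorm(nrow(fx$mesh@nodes))
  expect_gte(as.numeric(z %*% (fx$ops$K %*% z)), -1e-18)
})

test_that("discrete divergence vanishes for constant and linear solenoidal fields", {
  fx <- opsFixture()
  n <- nrow(fx$mesh@nodes)
  divOf <- function(u, v)
    as.vector(fx$ops$Dx %*% u + fx$ops$Dy %*% v)
  expect_lt(max(abs(divOf(rep(0.3, n), rep(-0.1, n)))), 1e-16)
  ## u = (x, -y): elementwise divergence zero
  d <- divOf(fx$mesh@nodes[, 1], -fx$mesh@nodes[, 2])
  expect_lt(max(abs(d)), 1e-12)
})

test_that("lumped mass sums to the domain area", {
  fx <- opsFixture()
  expect_equal(sum(fx$ops$MLgeo), meshArea(fx$mesh), tolerance = 1e-12)
})

test_that("divergence is the negative transpose of the gradient up to boundary terms", {
  fx <- opsFixture()
  interior <- setdiff(seq_len(nrow(fx$mesh@nodes)),
                      unique(as.vector(fx$mesh@boundaryEdges)))
  ## int phi_i dx u + int u dx phi_i = boundary integral = 0 for interior i:
  ## check on a smooth field against Dx and its transpose
  x <- fx$mesh@nodes[, 1]; y <- fx$mesh@nodes[, 2]
  u <- sin(1000 * x) * cos(800 * y)
  lhs <- as.vector((fx$ops$Dx + Matrix::t(fx$ops$Dx)) %*% u)
  ## rows of Dx + Dx^t are exact integrals of d/dx(phi_i u_h): zero away from
  ## the boundary up to quadrature differences of the two bilinear forms
  scale <- max(abs(as.vector(fx$ops$Dx %*% u)))
  expect_lt(max(abs(lhs[interior])) / scale, 0.05)
})

test_that("degenerate triangles are rejected at assembly", {
  mesh <- channelMesh(1e-3, 2e-3, targetH = 5e-4, refineWall = 1)
  mesh@nodes[mesh@cells[1, 2], ] <- mesh@nodes[mesh@cells[1, 1], ]
  expect_error(assembleOperators(mesh, fluidProps()), "singular|degenerate")
})
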