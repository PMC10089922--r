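# synthetic PDB fixtures are written on the fly
write_toy_pdb <- function(coords, path, elements = NULL, resno = NULL) {
  n <- nrow(coords)
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(resno)) resno <- seq_len(n)
  atom_names <- ifelse(seq_len(n) == 1, "CB", "CA")
  lines <- sprintf(
    "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), atom_names, resno, coords[, 1], coords[, 2], coords[, 3],
    elements)
  writeLines(c(lines, "END"), path)
  path
}

toy_structure <- function(coords, ...) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  parse_structure(write_toy_pdb(coords, path, ...))
}

test_that("PDB parsing extracts atoms, elements and residues", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0))
  st <- toy_structure(xyz, elements = c("C", "N", "S"), resno = c(29, 30, 31))
  expect_identical(nrow(st), 3L)
  expect_equal(st$x, xyz[, 1])
  expect_equal(st$vdw, c(1.70, 1.55, 1.80))
  # residue lookup via sequence number
  expect_identical(find_attachment(st, 29, "CB"), 1L)
  expect_error(find_attachment(st, 99, "CB"), "not found")
})

test_that("free-space accessible volumes are spherical around the anchor", {
  st <- toy_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  pars <- dye_parameters(linker_length_A = 10, linker_width_A = 2,
                         dye_radii_A = 1, grid_spacing_A = 0.9)
  av <- compute_av(st, 1, pars, model = "AV1")
  expect_lt(sqrt(sum((av$mean_position - av$attachment)^2)), 1e-6)
  rad <- sqrt(rowSums(sweep(av$points, 2, av$attachment)^2))
  expect_lte(max(rad), 10 + 1e-9)
  expect_equal(sum(av$weights), 1)
})

test_that("a plane wall halves the volume with the hemisphere centroid", {
  wall <- as.matrix(expand.grid(x = 1.1, y = seq(-14, 14, 1.0),
                                z = seq(-14, 14, 1.0)))
  st <- toy_structure(rbind(c(0, 0, 0), wall))
  st$vdw[-1] <- 0.1
  pars <- dye_parameters(linker_length_A = 10, linker_width_A = 2,
                         dye_radii_A = 1, grid_spacing_A = 0.9)
  av <- compute_av(st, 1, pars, model = "AV1")
  # allowed half-space x <= 0: centroid of a hemisphere is 3R/8 inward
  expect_lt(abs(av$mean_position[1] - (-3 * 10 / 8)), 0.8)
  expect_lt(abs(av$mean_position[2]), 0.2)
  # ACV: contact fraction 0 is the identity; 1 moves mass to the shell
  expect_identical(compute_acv(av, contact_fraction = 0), av)
  acv <- compute_acv(av, shell_A = 3, contact_fraction = 1)
  expect_gt(acv$mean_position[1], av$mean_position[1])
  # half-contact reweighting equals a direct reweighting oracle
  acv5 <- compute_acv(av, shell_A = 3, contact_fraction = 0.5)
  contact <- av$surface_clearance - mean(av$radii) <= 3
  w <- av$weights
  w[contact] <- w[contact] / sum(w[contact]) * 0.5
  w[!contact] <- w[!contact] / sum(w[!contact]) * 0.5
  expect_lt(max(abs(colSums(av$points * w) - acv5$mean_position)), 1e-6)
})

test_that("buried attachments raise an empty-cloud error", {
  shell <- as.matrix(expand.grid(x = seq(-3, 3, 1), y = seq(-3, 3, 1),
                                 z = seq(-3, 3, 1)))
  shell <- shell[rowSums(shell^2) > 0, ]
  st <- toy_structure(rbind(c(0, 0, 0), shell))
  st$vdw[-1] <- 2.5
  pars <- dye_parameters(linker_length_A = 8, linker_width_A = 2,
                         dye_radii_A = 1, grid_spacing_A = 1)
  expect_error(compute_av(st, 1, pars, model = "AV1"), "buried")
})

test_that("model distances equal the brute-force pair sums", {
  set.seed(10)
  mkcloud <- function(center, n) {
    pts <- sweep(matrix(rnorm(n * 3, 0, 3), n, 3), 2, center, "+")
    w <- runif(n); w <- w / sum(w)
    structure(list(points = pts, weights = w, attachment = center,
                   mean_position = colSums(pts * w), spacing = 1,
                   model = "AV1", radii = 1, surface_clearance = Inf,
                   contact_fraction = NA, flavor = "AV"),
              class = "av_cloud")
  }
  cd <- mkcloud(c(0, 0, 0), 400)
  ca <- mkcloud(c(60, 0, 0), 500)
  md <- model_distances(cd, ca, 65)
  # brute force double loop
  sE <- 0; sR <- 0
  for (i in seq_len(400)) {
    R <- sqrt(colSums((t(ca$points) - cd$points[i, ])^2))
    sE <- sE + sum(cd$weights[i] * ca$weights / (1 + (R / 65)^6))
    sR <- sR + sum(cd$weights[i] * ca$weights * R)
  }
  expect_lt(abs(md$E_mean - sE) / sE, 1e-9)
  expect_lt(abs(md$R_mean - sR) / sR, 1e-9)
  expect_equal(md$R_E, 65 * (1 / md$E_mean - 1)^(1 / 6))
  # two point masses at 50/80 A
  cp <- structure(list(points = rbind(c(50, 0, 0), c(80, 0, 0)),
                       weights = c(0.5, 0.5), attachment = c(65, 0, 0),
                       mean_position = c(65, 0, 0), spacing = 1,
                       model = "AV1", radii = 1, surface_clearance = Inf,
                       contact_fraction = NA, flavor = "AV"),
                  class = "av_cloud")
  orig <- structure(list(points = matrix(0, 1, 3), weights = 1,
                         attachment = c(0, 0, 0),
                         mean_position = c(0, 0, 0), spacing = 1,
                         model = "AV1", radii = 1, surface_clearance = Inf,
                         contact_fraction = NA, flavor = "AV"),
                    class = "av_cloud")
  md2 <- model_distances(orig, cp, 65)
  eref <- mean(distance_to_efficiency(c(50, 80), 65))
  expect_equal(md2$E_mean, eref, tolerance = 1e-12)
  # degenerate point clouds: all three distances coincide
  pt2 <- structure(list(points = matrix(c(65, 0, 0), 1), weights = 1,
                        attachment = c(65, 0, 0),
                        mean_position = c(65, 0, 0), spacing = 1,
                        model = "AV1", radii = 1, surface_clearance = Inf,
                        contact_fraction = NA, flavor = "AV"),
                   class = "av_cloud")
  md3 <- model_distances(orig, pt2, 65)
  expect_equal(md3$R_mp, 65)
  expect_equal(md3$R_mean, 65)
  expect_equal(md3$R_E, 65)
})

test_that("accessible volumes are invariant under rigid-body motion", {
  wall <- as.matrix(expand.grid(x = 2, y = seq(-12, 12, 1.2),
                                z = seq(-12, 12, 1.2)))
  base <- rbind(c(0, 0, 0), wall)
  st1 <- toy_structure(base)
  # rotate 90 degrees about z and translate
  rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  st2 <- toy_structure(sweep(base %*% t(rot), 2, c(5, -3, 2), "+"))
  pars <- dye_parameters(linker_length_A = 8, linker_width_A = 2,
                         dye_radii_A = 1, grid_spacing_A = 0.8)
  av1 <- compute_av(st1, 1, pars, model = "AV1")
  av2 <- compute_av(st2, 1, pars, model = "AV1")
  d1 <- sqrt(sum((av1$mean_position - av1$attachment)^2))
  d2 <- sqrt(sum((av2$mean_position - av2$attachment)^2))
  expect_lt(abs(d1 - d2), 0.3)
  expect_lt(abs(nrow(av1$points) - nrow(av2$points)) /
              nrow(av1$points), 0.05)
})

test_that("model-experiment comparison reports deviations and RMSD", {
  cmp <- compare_model_experiment(R_exp = c(65, 80), R_av = c(66, 78))
  expect_equal(unname(cmp$rmsd["AV"]), sqrt((1 + 4) / 2), tolerance = 1e-12)
  expect_equal(unname(cmp$n_within_band["AV"]), 2L)
  cmp0 <- compare_model_experiment(c(60, 70), c(60, 70))
  expect_equal(unname(cmp0$rmsd["AV"]), 0)
  cmp2 <- compare_model_experiment(c(65, 80), c(68, 84), R_acv = c(66, 81))
  expect_lt(cmp2$rmsd["ACV"], cmp2$rmsd["AV"])
})
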