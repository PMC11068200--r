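# Structural descriptors: pLDDT, hydrogen bonds, salt bridges, secondary
# structure, solvent accessibility.

make_struct <- function(resno, resid, elety, element, xyz, b = 90) {
  structure(
    data.frame(resno = resno, resid = resid, elety = elety,
               element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b = b, stringsAsFactors = FALSE),
    class = c("psd_structure", "data.frame"),
    incomplete_backbone = integer(0))
}

test_that("mean pLDDT averages CA B-factors and flags missing CA", {
  st <- generate_structure("AG", architecture = "extended",
                           plddt = c(80, 90))
  expect_equal(mean_plddt(st), 85)
  st70 <- generate_structure("AG", architecture = "extended", plddt = 70)
  expect_equal(mean_plddt(st70), 70)   # boundary: not strictly below 70
  expect_error(mean_plddt(st[0, ]), "empty")
  noca <- st[!(st$resno == 2 & st$elety == "CA"), ]
  expect_warning(m <- mean_plddt(noca), "without CA")
  expect_equal(m, 80)
})

test_that("hydrogen bonds require 2.5-3.2 A between polar heavy atoms", {
  at <- function(d) make_struct(
    resno = c(1, 2), resid = c("A", "A"), elety = c("N", "O"),
    element = c("N", "O"), xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(count_hbonds(at(3.0), 1),
               c(backbone = 1L, sidechain = 0L))
  expect_equal(count_hbonds(at(2.4), 1)[["backbone"]], 0L)
  expect_equal(count_hbonds(at(3.3), 1)[["backbone"]], 0L)
})

test_that("hydrogen-bond counting is symmetric across residues", {
  # residue 1 side-chain OG to residue 2 backbone N at 3.0 A
  st <- make_struct(
    resno = c(1, 1, 2, 2),
    resid = c("S", "S", "A", "A"),
    elety = c("CA", "OG", "N", "CA"),
    element = c("C", "O", "N", "C"),
    xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  expect_equal(count_hbonds(st, 1),
               c(backbone = 0L, sidechain = 1L))
  expect_equal(count_hbonds(st, 2),
               c(backbone = 1L, sidechain = 0L))
})

test_that("salt bridges need D/E carboxylate to K/R nitrogen under 4 A", {
  st <- function(d, code = "D", oname = "OD1") make_struct(
    resno = c(1, 2), resid = c(code, "K"), elety = c(oname, "NZ"),
    element = c("O", "N"), xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_true(has_salt_bridge(st(3.5), 1))
  expect_false(has_salt_bridge(st(4.0), 1))   # strictly under 4.0
  expect_true(has_salt_bridge(st(3.9, "E", "OE2"), 1))
  # asparagine never qualifies, whatever the geometry
  stn <- make_struct(
    resno = c(1, 2), resid = c("N", "K"), elety = c("OD1", "NZ"),
    element = c("O", "N"), xyz = rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_false(has_salt_bridge(stn, 1))
})

test_that("ideal helix interiors are H; extended chains have none", {
  hel <- generate_structure(strrep("A", 15), architecture = "helix")
  ss <- assign_secondary_structure(hel)
  expect_true(all(ss[3:12] == "H"))
  ext <- generate_structure(strrep("A", 15), architecture = "extended")
  expect_false(any(assign_secondary_structure(ext) == "H"))
  two <- generate_structure("AG", architecture = "extended")
  expect_equal(unname(assign_secondary_structure(two)), c("-", "-"))
})

test_that("single-atom SASA matches the analytic sphere area", {
  one <- make_struct(1, "G", "CA", "C", cbind(0, 0, 0))
  expect_equal(atom_sasa(one), 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  # two equal spheres at distance d: accessible area = 2*pi*R^2 + pi*R*d each
  d <- 2.0; R <- 1.70 + 1.4
  two <- make_struct(c(1, 2), c("G", "G"), c("CA", "CA"), c("C", "C"),
                     rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(atom_sasa(two), rep(2 * pi * R^2 + pi * R * d, 2),
               tolerance = 0.02 * 4 * pi * R^2)
})

test_that("relative accessibility ranks buried below exposed residues", {
  hel <- generate_structure(strrep("A", 21), architecture = "helix")
  tri <- generate_structure("AAA", architecture = "extended")
  rsa_hel <- suppressWarnings(relative_solvent_accessibility(hel))
  rsa_tri <- suppressWarnings(relative_solvent_accessibility(tri))
  expect_lt(rsa_hel[["11"]], rsa_tri[["2"]])
  # a fully isolated residue is at least as exposed as the normalization max
  iso <- generate_structure(strrep("G", 10), architecture = "extended")
  iso1 <- iso[iso$resno == 5, ]
  attr(iso1, "incomplete_backbone") <- integer(0)
  expect_gt(suppressWarnings(relative_solvent_accessibility(iso1)), 1)
})

test_that("accessibility is invariant under rigid motion", {
  st <- generate_structure("ADKEG", architecture = "helix")
  r1 <- suppressWarnings(relative_solvent_accessibility(st))
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(st[, c("x", "y", "z")]) %*% Rz
  st2 <- st
  st2$x <- xyz[, 1] + 5; st2$y <- xyz[, 2] - 3; st2$z <- xyz[, 3] + 1
  r2 <- suppressWarnings(relative_solvent_accessibility(st2))
  # equality up to the angular discretization of the test-point sphere
  expect_equal(unname(r2), unname(r1), tolerance = 0.03)
})
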