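single_atom <- function(element = "C", x = 0, y = 0, z = 0,
                        chain = "A", resno = 1L) {
  tibble::tibble(chain = chain, residue_index = as.integer(resno),
                 residue_name = "G", atom_name = element,
                 element = element, x = x, y = y, z = z)
}

test_that("an isolated atom recovers the analytic sphere area", {
  analytic <- 4 * pi * (1.70 + 3)^2
  a960 <- shrake_rupley(single_atom())$sasa
  expect_lt(abs(a960 - analytic) / analytic, 0.01)
  a10k <- shrake_rupley(single_atom(), n_sphere_points = 10000L)$sasa
  expect_lt(abs(a10k - analytic) / analytic, 0.002)
})

test_that("SASA is invariant under rigid rotation and translation", {
  set.seed(31)
  atoms <- dplyr::bind_rows(
    single_atom("C", 0, 0, 0), single_atom("N", 2.5, 0.4, -1),
    single_atom("O", -1, 3, 0.5), single_atom("P", 1, 1, 4))
  base <- shrake_rupley(atoms)$sasa

  theta <- 0.73; phi <- 1.2
  Rz <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(phi), -sin(phi), 0, sin(phi), cos(phi)),
               3, byrow = TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  moved <- atoms
  moved$x <- xyz[, 1] + 17.3
  moved$y <- xyz[, 2] - 5.9
  moved$z <- xyz[, 3] + 101
  expect_equal(shrake_rupley(moved)$sasa, base, tolerance = 1e-6)
})

test_that("strict interior test: coincident atoms do not occlude each other", {
  two <- dplyr::bind_rows(single_atom("C"), single_atom("C"))
  a <- shrake_rupley(two)$sasa
  expect_equal(a, rep(4 * pi * 4.7^2, 2), tolerance = 1e-9)
})

test_that("an atom engulfed by a larger expanded sphere has zero area", {
  atoms <- dplyr::bind_rows(
    single_atom("O"),                      # radius 1.52 + 3 = 4.52
    single_atom("P", x = 0.1))             # radius 1.80 + 3 = 4.80
  a <- shrake_rupley(atoms)$sasa
  expect_equal(a[1], 0)
  expect_gt(a[2], 0)
})

test_that("growing the probe never exposes more of a two-atom system", {
  atoms <- dplyr::bind_rows(single_atom("C"), single_atom("C", x = 3.0))
  buried_frac <- vapply(c(0, 1.4, 3, 5), function(pr) {
    a <- shrake_rupley(atoms, probe_radius = pr)$sasa
    1 - sum(a) / (2 * 4 * pi * (1.70 + pr)^2)
  }, numeric(1))
  expect_true(all(diff(buried_frac) >= -1e-12))
})

test_that("unknown elements require an explicit radius", {
  odd <- single_atom("other")
  expect_error(shrake_rupley(odd), class = "probeval_validation_error")
  ok <- shrake_rupley(odd, radii = c(default_vdw_radii, other = 2.0))
  expect_equal(ok$sasa, 4 * pi * 5^2, tolerance = 1e-9)
})

test_that("relative accessibility is 1 in isolation and ~0 when enclosed", {
  one <- single_atom()
  acc <- residue_accessibility(one)
  expect_equal(acc$relative_sasa, 1.0)

  # two residues far beyond any mutual occlusion distance
  two <- dplyr::bind_rows(single_atom(resno = 1L),
                          single_atom("N", x = 50, resno = 2L))
  acc2 <- residue_accessibility(two)
  expect_equal(acc2$relative_sasa, c(1.0, 1.0))

  # residue buried under a dense shell of phosphorus atoms
  pts <- probeval:::golden_spiral_points(200) * 4.0
  shell <- tibble::tibble(chain = "A", residue_index = 2L,
                          residue_name = "G", atom_name = "P",
                          element = "P", x = pts[, 1], y = pts[, 2],
                          z = pts[, 3])
  buried <- dplyr::bind_rows(single_atom(resno = 1L), shell)
  acc3 <- residue_accessibility(buried)
  expect_lt(acc3$relative_sasa[acc3$residue_index == 1L], 0.01)
})

test_that("reactivity-accessibility correlation matches the closed form", {
  react <- c(0.1, 0.4, 0.2, 0.8, 0.6)
  sasa <- c(0.2, 0.5, 0.1, 0.9, 0.4)
  acc <- tibble::tibble(chain = "A", residue_index = 1:5,
                        residue_name = "G", absolute_sasa = sasa * 100,
                        relative_sasa = sasa)
  prof <- make_profile(react)
  res <- reactivity_accessibility_correlation(prof, acc, "all")
  hand <- sum((react - mean(react)) * (sasa - mean(sasa))) /
    sqrt(sum((react - mean(react))^2) * sum((sasa - mean(sasa))^2))
  expect_equal(res$r, hand)
  expect_equal(res$n, 5L)

  ident <- reactivity_accessibility_correlation(make_profile(sasa), acc, "all")
  expect_equal(ident$r, 1.0)
  anti <- reactivity_accessibility_correlation(make_profile(1 - sasa), acc, "all")
  expect_equal(anti$r, -1.0)
})

test_that("correlation subsets respect structure, ranks and numbering offset", {
  set.seed(41)
  L <- 40
  sasa <- runif(L)
  react <- runif(L)
  acc <- tibble::tibble(chain = "A", residue_index = 1:L,
                        residue_name = "G", absolute_sasa = sasa,
                        relative_sasa = sasa)
  prof <- make_profile(react)
  st <- make_structure(paste0(strrep(".", 20), strrep("(", 9), "..",
                              strrep(")", 9)))
  paired_res <- reactivity_accessibility_correlation(prof, acc, "paired", st)
  expect_equal(paired_res$n, 18L)
  unpaired_res <- reactivity_accessibility_correlation(prof, acc, "unpaired", st)
  expect_equal(unpaired_res$n, 22L)
  expect_error(reactivity_accessibility_correlation(prof, acc, "paired"),
               class = "probeval_validation_error")

  top <- reactivity_accessibility_correlation(prof, acc, "top10")
  expect_equal(top$n, 4L)  # ceiling(10% of 40)
  bottom <- reactivity_accessibility_correlation(prof, acc, "bottom90")
  expect_equal(bottom$n, 36L)

  # unresolved residues are simply absent and excluded
  short <- acc[1:10, ]
  expect_equal(reactivity_accessibility_correlation(prof, short, "all")$n, 10L)

  # numbering offset: residue 886 maps to profile position 887 at +1
  off_acc <- tibble::tibble(chain = "A", residue_index = 885:889,
                            residue_name = "G",
                            absolute_sasa = sasa[1:5], relative_sasa = sasa[1:5])
  long <- make_profile(c(rep(0.5, 885), 0.6, 0.9, 0.7, rep(0.5, 2)))
  mapped <- reactivity_accessibility_correlation(long, off_acc, "all",
                                                 offset = 1L)
  expect_equal(mapped$n, 5L)

  expect_error(
    reactivity_accessibility_correlation(make_profile(react[1:2]), acc[1:2, ], "all"),
    class = "probeval_degenerate_data_error")
  flat <- make_profile(rep(0.5, L))
  expect_error(reactivity_accessibility_correlation(flat, acc, "all"),
               class = "probeval_degenerate_data_error")
})
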