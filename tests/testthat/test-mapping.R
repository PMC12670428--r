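test_that("forward mapping places beads at mass-weighted centers", {
  tpl <- build_template("CER_NS")
  # degenerate geometry: all atoms at one point -> all beads there
  xyz <- matrix(2, nrow(tpl$atoms), 3)
  fr <- template_atoms_frame(tpl, xyz)
  cg <- map_frame(fr, assignment = c(CER_NS = "CER_NS"))
  expect_equal(nrow(cg), nrow(tpl$beads))
  expect_true(all(abs(cg$x - 2) < 1e-12 & abs(cg$z - 2) < 1e-12))
  # bead masses equal template bead masses; total mass conserved
  expect_equal(sort(cg$mass), sort(tpl$beads$mass))
  expect_equal(sum(cg$mass), sum(element_mass(tpl$atoms$element)))
})

test_that("two equal-mass atoms map to their midpoint", {
  tpl <- new_cg_template(
    "DIMER",
    tibble::tibble(index = 1L, bead = "TAIL", role = "tail", chain = "acyl"),
    tibble::tibble(atom = c("C1", "C2"), element = "C", bead_index = 1L),
    tibble::tibble(i = integer(), j = integer(), term = character()),
    tibble::tibble(i = integer(), j = integer(), k = integer(), term = character()))
  fr <- tibble::tibble(molecule = 1L, resname = "DIM", atom = c("C1", "C2"),
                       element = "C", x = 0, y = 0, z = c(0, 1))
  attr(fr, "box") <- c(5, 5, 5)
  cg <- map_frame(fr, registry = list(DIMER = tpl), assignment = c(DIM = "DIMER"))
  expect_equal(cg$z, 0.5)
})

test_that("an all-trans chain maps to equally spaced TAIL beads", {
  # 18 carbons, 0.127 nm z-rise per carbon -> 6 TAIL beads 0.381 nm apart
  seqs <- tail_bead_sequence(18)
  tpl <- new_cg_template(
    "ALK18",
    tibble::tibble(index = 1:6, bead = seqs$bead, role = "tail", chain = "acyl"),
    tibble::tibble(atom = sprintf("C%d", 1:18), element = "C",
                   bead_index = rep(1:6, each = 3)),
    tibble::tibble(i = 1:5, j = 2:6, term = "TAIL-TAIL"),
    tibble::tibble(i = 1:4, j = 2:5, k = 3:6, term = "TAIL-TAIL-TAIL"))
  fr <- tibble::tibble(molecule = 1L, resname = "ALK", atom = sprintf("C%d", 1:18),
                       element = "C", x = 1, y = 1, z = (0:17) * 0.127)
  attr(fr, "box") <- c(10, 10, 10)
  cg <- map_frame(fr, registry = list(ALK18 = tpl), assignment = c(ALK = "ALK18"))
  expect_equal(diff(cg$z), rep(3 * 0.127, 5))
  # center-of-mass preservation
  expect_equal(sum(cg$z * cg$mass) / sum(cg$mass), mean((0:17) * 0.127),
               tolerance = 1e-12)
  # permutation invariance to atom order within groups
  perm <- sample(nrow(fr))
  fr2 <- fr[perm, ]
  attr(fr2, "box") <- c(10, 10, 10)
  cg2 <- map_frame(fr2, registry = list(ALK18 = tpl), assignment = c(ALK = "ALK18"))
  expect_equal(cg2$z, cg$z)
})

test_that("mapping detects missing atoms and broken molecules", {
  tpl <- build_template("WATER")
  fr <- template_atoms_frame(tpl, matrix(1, nrow(tpl$atoms), 3),
                             resname = "SOL")
  cg <- map_frame(fr, assignment = c(SOL = "WATER"))
  expect_equal(nrow(cg), 1)
  # drop an atom -> error naming the molecule
  fr_miss <- fr[-1, ]
  attr(fr_miss, "box") <- c(10, 10, 10)
  expect_error(map_frame(fr_miss, assignment = c(SOL = "WATER")), "molecule 1")
  # straddle the boundary: error without unwrap, healed with unwrap
  fr_split <- fr
  fr_split$z <- rep(c(0.1, 0.1, 0.1, 9.9, 9.9, 9.9), 2)
  attr(fr_split, "box") <- c(10, 10, 10)
  expect_error(map_frame(fr_split, assignment = c(SOL = "WATER")), "broken")
  cg2 <- map_frame(fr_split, assignment = c(SOL = "WATER"), unwrap = TRUE)
  expect_equal(cg2$z %% 10, 0, tolerance = 1e-9)
})

test_that("water mapping clusters by proximity", {
  # four waters at square corners -> one bead at the center
  sq <- tibble::tibble(molecule = 1:4, x = c(0, 0, 1, 1), y = c(0, 1, 0, 1), z = 0)
  b <- map_water(sq)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$x, b$y, b$z), c(0.5, 0.5, 0))
  expect_false(b$partial)
  # two well-separated tight clusters of four -> one bead per cluster
  cl <- tibble::tibble(
    molecule = 1:8,
    x = c(0, 0.1, 0, 0.1, 5, 5.1, 5, 5.1),
    y = c(0, 0, 0.1, 0.1, 5, 5, 5.1, 5.1), z = 0)
  b2 <- map_water(cl)
  expect_equal(nrow(b2), 2)
  expect_equal(sort(round(b2$x, 2)), c(0.05, 5.05))
  # empty input -> empty output; remainder flagged partial
  expect_equal(nrow(map_water(sq[0, ])), 0)
  b3 <- map_water(dplyr::bind_rows(sq, sq[1, ] |> dplyr::mutate(molecule = 9L, x = 9)))
  expect_true(any(b3$partial) && sum(b3$n_waters) == 5)
})

test_that("bonded samples use the minimum image and bounded angles", {
  tpl <- new_cg_template(
    "TRI",
    tibble::tibble(index = 1:3, bead = "TAIL", role = "tail", chain = "acyl"),
    tibble::tibble(atom = c("C1", "C2", "C3"), element = "C", bead_index = 1:3),
    tibble::tibble(i = 1:2, j = 2:3, term = "TAIL-TAIL"),
    tibble::tibble(i = 1L, j = 2L, k = 3L, term = "TAIL-TAIL-TAIL"))
  fr <- cg_frame(tibble::tibble(
    molecule = 1L, species = "TRI", bead = "TAIL", bead_index = 1:3,
    mass = 42, x = 1, y = 1, z = c(0.1, 4.9, 4.7)), box = c(5, 5, 5))
  s <- bonded_samples(fr, tpl)
  # bead 1-2 straddle the boundary: 0.2 nm = 2 A, not 4.8 nm
  expect_equal(s$value[s$kind == "bond"], c(2, 2), tolerance = 1e-9)
  # collinear triple -> 180 degrees
  expect_equal(s$value[s$kind == "angle"], 180, tolerance = 1e-9)
  # fixed geometry repeated over frames -> identical samples
  s2 <- bonded_samples(list(fr, fr), tpl)
  expect_equal(nrow(s2), 2 * nrow(s))
  expect_equal(unique(round(s2$value[s2$kind == "bond"], 9)), 2)
})
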