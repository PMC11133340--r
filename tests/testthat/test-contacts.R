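# contact_analysis: shortest distances, contact maps, axial ligands,
# polar contacts, layer classification.

test_that("min_distance finds the closest retained atom pair", {
  s1 <- fixture_spec(list(
    custom_placement("A", 1, "UNL",
      list(list(name = "C1", element = "C", position = c(0, 0, 0)))),
    custom_placement("A", 2, "UNL",
      list(list(name = "C1", element = "C", position = c(3, 4, 0))))))
  # map the UNL code so the residues become sites
  path <- tempfile(fileext = ".cif")
  make_fixture(s1, path)
  inv <- extract_pigments(read_structure(path), c(UNL = "OTHER"))
  cp <- min_distance(inv$sites[[1]], inv$sites[[2]])
  expect_equal(cp$min_distance, 5, tolerance = 1e-9)
  expect_equal(min_distance(inv$sites[[1]], inv$sites[[1]])$min_distance, 0)
  expect_true(cp$min_distance == min_distance(inv$sites[[2]],
                                              inv$sites[[1]])$min_distance)
})

test_that("phytol-tail atoms are excluded by default but includable", {
  # chlorophyll with a phytol carbon C5 reaching towards the carotenoid
  chl <- chl_placement("A", 601, c(0, 0, 0), c(0, 0, 1))
  chl$extra_atoms <- list(list(name = "C5", element = "C",
                               position = c(4, 0, 0)))
  car <- carotenoid_placement("A", 615, c(6, 0, 0), c(0, 1, 0), n_atoms = 2)
  inv <- inventory_from_spec(fixture_spec(list(chl, car)))
  chl_site <- inv$sites[[which(site_kinds(inv) == "CHL_A")]]
  car_site <- inv$sites[[which(site_kinds(inv) == "ALX")]]
  without <- min_distance(chl_site, car_site)            # Mg/NB/ND only
  with_tail <- min_distance(chl_site, car_site, include_phytol = TRUE)
  expect_equal(with_tail$min_distance, 2, tolerance = 1e-9)
  expect_gt(without$min_distance, 4.9)
  expect_equal(with_tail$atom_a, "C5")
})

test_that("contact_map matches a brute-force scan and sorts ascending", {
  set.seed(9)
  placements <- c(
    lapply(1:6, function(i)
      chl_placement("A", 600 + i, runif(3, 0, 25), c(0, 0, 1))),
    lapply(1:4, function(i)
      carotenoid_placement("A", 614 + i, runif(3, 0, 25), rnorm(3))))
  inv <- inventory_from_spec(fixture_spec(placements))
  for (thr in c(3, 5, 12)) {
    cm <- contact_map(inv, threshold = thr)
    # brute force over all carotenoid x chl pairs
    cars <- sites_of_kind(inv, c("ALX", "ACAR", "CRO", "MON"))
    chls <- sites_of_kind(inv, c("CHL_A", "CHL_C"))
    expected <- 0L
    for (ca in cars) for (ch in chls)
      if (min_distance(ca, ch)$min_distance < thr) expected <- expected + 1L
    expect_equal(nrow(cm), expected)
    if (nrow(cm) > 1) expect_true(!is.unsorted(cm$min_distance))
  }
  # planted single contact at 4.0 A
  pair <- fixture_spec(list(
    chl_placement("B", 601, c(0, 0, 0), c(0, 0, 1)),
    carotenoid_placement("B", 615, c(4, 0, 1), c(0, 0, 1), n_atoms = 3,
                         spacing = 1.0)))
  cm1 <- contact_map(inventory_from_spec(pair), threshold = 5)
  expect_equal(nrow(cm1), 1)
  expect_equal(cm1$min_distance, 4, tolerance = 1e-9)
  # empty inventory
  empty <- structure(list(sites = list(), naming_map = NULL,
                          skipped = data.frame()),
                     class = "pigment_inventory")
  expect_equal(nrow(contact_map(empty)), 0)
})

test_that("axial_ligand assigns the nearest qualifying heavy atom", {
  spec <- fixture_spec(list(
    chl_placement("A", 601, c(0, 0, 0), c(1, 0, 0)),
    custom_placement("P", 93, "HIS",
      list(list(name = "NE2", element = "N", position = c(0, 0, 2.2)))),
    custom_placement("W", 501, "HOH",
      list(list(name = "O", element = "O", position = c(0, 0, -3.0))))))
  path <- tempfile(fileext = ".cif")
  make_fixture(spec, path)
  model <- read_structure(path)
  inv <- extract_pigments(model, fixture_code_map())
  la <- axial_ligand(inv$sites[[1]], model)
  expect_equal(la$ligand_resname, "HIS")
  expect_equal(la$ligand_atom, "NE2")
  expect_equal(la$distance, 2.2, tolerance = 1e-9)
  # tighter cutoff than 2.2 -> unassigned
  la2 <- axial_ligand(inv$sites[[1]], model, cutoff = 2.0)
  expect_equal(la2$ligand_resname, "unassigned")
  expect_true(is.na(la2$distance))

  # exhaustive nearest-neighbour oracle over random ligand fields
  set.seed(31)
  for (rep in 1:5) {
    pos <- matrix(runif(15, -4, 4), ncol = 3)
    lig <- lapply(seq_len(nrow(pos)), function(i)
      custom_placement("P", i, "GLY",
        list(list(name = "N", element = "N", position = pos[i, ]))))
    sp <- fixture_spec(c(list(chl_placement("A", 601, c(0, 0, 0),
                                            c(0, 0, 1))), lig))
    pth <- tempfile(fileext = ".cif")
    make_fixture(sp, pth)
    mdl <- read_structure(pth)
    iv <- extract_pigments(mdl, fixture_code_map())
    d <- sqrt(rowSums(pos^2))
    got <- axial_ligand(iv$sites[[1]], mdl, cutoff = 3.5)
    if (min(d) <= 3.5) {
      expect_equal(got$distance, min(d), tolerance = 1e-9)
      expect_equal(got$ligand_resnum, which.min(d))
    } else {
      expect_equal(got$ligand_resname, "unassigned")
    }
  }
})

test_that("polar_contacts reports N/O pairs within the cutoff only", {
  spec <- fixture_spec(list(
    custom_placement("A", 231, "GLU", list(
      list(name = "OE1", element = "O", position = c(0, 0, 0)),
      list(name = "CD", element = "C", position = c(0, 1.2, 0)))),
    custom_placement("B", 250, "SER", list(
      list(name = "OG", element = "O", position = c(2.8, 0, 0)),
      list(name = "CB", element = "C", position = c(2.8, 1.5, 0)))),
    custom_placement("B", 238, "LYS", list(
      list(name = "NZ", element = "N", position = c(6, 0, 0))))))
  path <- tempfile(fileext = ".cif")
  make_fixture(spec, path)
  model <- read_structure(path)
  pc <- polar_contacts(model, "A:231", c("B:250", "B:238"), d_max = 3.5)
  expect_equal(nrow(pc), 1)            # carbons and the 6 A NZ excluded
  expect_equal(pc$distance, 2.8, tolerance = 1e-9)
  expect_equal(pc$atom_a, "OE1"); expect_equal(pc$atom_b, "OG")
  # no N/O in selection -> empty result, bad selection -> error
  pc0 <- polar_contacts(model, "A:231:CD", "B:250:CB", d_max = 5)
  expect_equal(nrow(pc0), 0)
  expect_error(polar_contacts(model, "Z:999", "B:250"), "selection error")
  expect_error(polar_contacts(model, "A231", "B:250"), "selection error")
})

test_that("classify_layers recovers planted sheets and needs a hint for sidedness", {
  # two flat sheets at z = 0 and 20 with a wide in-plane scatter
  set.seed(5)
  placements <- c(
    lapply(1:10, function(i)
      chl_placement("A", 600 + i, c(runif(1, 0, 60), runif(1, 0, 60), 0),
                    c(0, 0, 1))),
    lapply(1:7, function(i)
      chl_placement("A", 620 + i, c(runif(1, 0, 60), runif(1, 0, 60), 20),
                    c(0, 0, 1))))
  inv <- inventory_from_spec(fixture_spec(placements))
  expect_warning(ly <- classify_layers(inv), "hint")
  expect_equal(sort(unname(ly$counts)), c(7, 10))
  expect_equal(abs(ly$axis[3]), 1, tolerance = 1e-6)
  expect_equal(abs(ly$split_point), 10, tolerance = 0.5)

  oriented <- classify_layers(inv, stromal_direction = c(0, 0, 1))
  tab <- oriented$table
  z_of <- function(layer) {
    ids <- tab$site_id[tab$layer == layer]
    resnos <- as.integer(sub(".*:", "", ids))
    unique(ifelse(resnos <= 610, 0, 20))
  }
  expect_equal(z_of("stromal"), 20)
  expect_equal(z_of("lumenal"), 0)
  flipped <- classify_layers(inv, stromal_direction = c(0, 0, -1))
  expect_equal(sum(flipped$table$layer == "stromal"), 10)

  # degenerate: all Mg in one plane with no normal spread -> error
  flat <- inventory_from_spec(fixture_spec(lapply(1:5, function(i)
    chl_placement("A", 600 + i, c(5 * i, 2 * i, 0), c(0, 0, 1)))))
  expect_error(suppressWarnings(classify_layers(flat, axis = c(0, 0, 1))),
               "degenerate")
  one <- inventory_from_spec(fixture_spec(list(
    chl_placement("A", 601, c(0, 0, 0), c(0, 0, 1)))))
  expect_error(classify_layers(one), "at least 2")
})

test_that("layer partition is invariant under global rotation and translation", {
  spec <- two_layer_spec(n_low = 9, n_high = 6, seed = 23)
  inv <- inventory_from_spec(spec)
  base <- suppressWarnings(classify_layers(inv))
  # rotate all coordinates by a fixed rotation + translate
  th <- 0.7; ph <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  Q <- Rx %*% Rz; tr <- c(100, -50, 30)
  rotated <- fixture_spec(lapply(spec$placements, function(p) {
    q <- chl_placement(p$chain_id, p$residue_number,
                       as.numeric(Q %*% p$mg_position + tr),
                       as.numeric(Q %*% p$dipole_direction))
    q$planted_layer <- p$planted_layer
    q
  }), noise_sigma = spec$noise_sigma, seed = spec$seed)
  inv_r <- inventory_from_spec(rotated)
  rot <- suppressWarnings(classify_layers(inv_r))
  split <- function(a) {
    m <- a$table$layer == a$table$layer[1]
    sort(c(sum(m), sum(!m)))
  }
  expect_equal(split(base), split(rot))
  # same residues grouped together
  grp <- function(a) {
    resno <- as.integer(sub(".*:", "", a$table$site_id))
    same_as_first <- a$table$layer == a$table$layer[order(resno)[1]]
    sort(resno[same_as_first])
  }
  expect_equal(grp(base), grp(rot))
})
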