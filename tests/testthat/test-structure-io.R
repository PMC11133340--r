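# structure_io: parsing, altloc resolution, extraction, census.

test_that("fixture files round-trip through both formats within 0.001 A", {
  spec <- fixture_spec(list(
    chl_placement("A", 601, c(1.2345, -2.5, 7.875), c(0, 0, 1)),
    chl_placement("A", 602, c(12.5, 3.25, -4.125), c(0.6, 0.8, 0)),
    chl_placement("B", 610, c(-5, 18.75, 2.5), c(1, 0, 0), kind = "CHL_C"),
    carotenoid_placement("B", 615, c(0, 0, 30), c(0, 1, 0))))
  for (fmt in c("mmcif", "pdb")) {
    path <- tempfile(fileext = if (fmt == "mmcif") ".cif" else ".pdb")
    make_fixture(spec, path, format = fmt)
    model <- read_structure(path)
    inv <- extract_pigments(model, fixture_code_map())
    expect_length(inv$sites, 4)
    expect_equal(sort(site_kinds(inv)),
                 sort(c("CHL_A", "CHL_A", "CHL_C", "ALX")))
    for (p in spec$placements[1:3]) {
      site <- inv$sites[[which(site_ids_of(inv) ==
        paste(p$chain_id, eetnet:::kind_to_code[[p$kind]],
              p$residue_number, sep = ":"))]]
      # mmCIF fixtures are near-lossless; PDB is limited to 3 decimals,
      # i.e. at worst 0.0005 A per coordinate — both within 0.001 A
      expect_lt(max(abs(site$mg_position - p$mg_position)), 0.001)
    }
  }
})

test_that("degenerate and malformed inputs raise parse/format errors", {
  empty <- tempfile(fileext = ".cif")
  file.create(empty)
  expect_error(read_structure(empty), "empty")
  expect_error(read_structure(tempfile(fileext = ".cif")), "not found")
  junk <- tempfile()
  writeLines("not a structure at all", junk)
  expect_error(read_structure(junk), "format error")
  # truncated mmCIF loop: token count not divisible by the column count
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.group_PDB",
               "_atom_site.Cartn_x", "HETATM 1.0", "HETATM"), bad)
  expect_error(read_structure(bad), "parse error")
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties to smallest id", {
  pdb <- tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "HETATM", 1, "MG", "A", "CLA", "A", 601, 0, 0, 0, 0.4, 0, "MG"),
    sprintf(fmt, "HETATM", 2, "MG", "B", "CLA", "A", 601, 9, 9, 9, 0.6, 0, "MG"),
    sprintf(fmt, "HETATM", 3, "NB", "A", "CLA", "A", 601, 0, 0, -1, 0.4, 0, "N"),
    sprintf(fmt, "HETATM", 4, "NB", "B", "CLA", "A", 601, 9, 9, 8, 0.6, 0, "N"),
    sprintf(fmt, "HETATM", 5, "ND", "", "CLA", "A", 601, 9, 9, 10, 1.0, 0, "N"),
    # second residue: equal occupancies -> altloc A wins
    sprintf(fmt, "HETATM", 6, "MG", "B", "CLA", "A", 602, 5, 0, 0, 0.5, 0, "MG"),
    sprintf(fmt, "HETATM", 7, "MG", "A", "CLA", "A", 602, 4, 0, 0, 0.5, 0, "MG"),
    "END")
  writeLines(lines, pdb)
  m <- read_structure(pdb)
  r601 <- m$atoms[m$atoms$residue_number == 601, ]
  expect_equal(nrow(r601), 3)            # B conformer + altloc-free ND
  expect_equal(r601$x[r601$name == "MG"], 9)
  r602 <- m$atoms[m$atoms$residue_number == 602, ]
  expect_equal(r602$x, 4)
  # determinism: re-reading gives byte-identical census output
  # residue 602 is Mg-only (no NB/ND) and is skipped with a warning
  inv1 <- suppressWarnings(extract_pigments(m, default_code_map()))
  inv2 <- suppressWarnings(extract_pigments(read_structure(pdb),
                                            default_code_map()))
  c1 <- tempfile(fileext = ".csv"); c2 <- tempfile(fileext = ".csv")
  write_census(pigment_census(inv1), c1)
  write_census(pigment_census(inv2), c2)
  expect_identical(readLines(c1), readLines(c2))
})

test_that("chlorophylls missing Mg/NB/ND are skipped with a warning, not a crash", {
  pdb <- tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "HETATM", 1, "MG", "", "CLA", "A", 601, 0, 0, 0, 1, 0, "MG"),
    sprintf(fmt, "HETATM", 2, "NB", "", "CLA", "A", 601, 0, 0, -1, 1, 0, "N"),
    sprintf(fmt, "HETATM", 3, "ND", "", "CLA", "A", 601, 0, 0, 1, 1, 0, "N"),
    # 602 lacks ND
    sprintf(fmt, "HETATM", 4, "MG", "", "CLA", "A", 602, 8, 0, 0, 1, 0, "MG"),
    sprintf(fmt, "HETATM", 5, "NB", "", "CLA", "A", 602, 8, 0, -1, 1, 0, "N"),
    "END")
  writeLines(lines, pdb)
  m <- read_structure(pdb)
  expect_warning(inv <- extract_pigments(m, default_code_map()), "skipped")
  expect_length(inv$sites, 1)
  expect_equal(inv$skipped$residue_number, 602)
  expect_match(inv$skipped$missing, "ND")
})

test_that("extraction honours code and naming maps; empty map set gives empty inventory", {
  spec <- fixture_spec(list(
    chl_placement("A", 601, c(0, 0, 0), c(0, 0, 1)),
    chl_placement("A", 602, c(9, 0, 0), c(0, 0, 1)),
    chl_placement("B", 603, c(18, 0, 0), c(0, 1, 0)),
    chl_placement("B", 610, c(27, 0, 0), c(1, 0, 0), kind = "CHL_C")))
  inv <- inventory_from_spec(spec)
  expect_equal(sum(site_kinds(inv) == "CHL_A"), 3)
  expect_equal(sum(site_kinds(inv) == "CHL_C"), 1)

  path <- tempfile(fileext = ".cif")
  make_fixture(spec, path)
  model <- read_structure(path)
  named <- extract_pigments(model, fixture_code_map(),
                            naming_map = c(A = "ACPII-1", B = "ACPII-2"))
  labels <- vapply(named$sites, `[[`, character(1), "display_label")
  expect_true("a601_ACPII-1" %in% labels)
  expect_true("c610_ACPII-2" %in% labels)

  none <- extract_pigments(model, c(XYZ = "OTHER"))
  expect_length(none$sites, 0)
  expect_error(extract_pigments(model, character()), "non-empty")
})

test_that("census counts partition the sites and totals split pigments from lipids", {
  spec <- fixture_spec(c(
    lapply(1:5, function(i)
      chl_placement("A", 600 + i, c(8 * i, 0, 0), c(0, 0, 1))),
    list(carotenoid_placement("A", 615, c(0, 5, 0), c(1, 0, 0)),
         carotenoid_placement("A", 616, c(0, 10, 0), c(1, 0, 0)),
         custom_placement("L", 701, "LMG",
           list(list(name = "C1", element = "C", position = c(0, 0, 40)))))))
  inv <- inventory_from_spec(spec)
  cen <- pigment_census(inv)
  expect_equal(cen$counts[["CHL_A"]], 5)
  expect_equal(cen$counts[["ALX"]], 2)
  expect_equal(cen$counts[["LMG"]], 1)
  expect_equal(cen$total_pigments, 7)
  expect_equal(cen$total_lipids, 1)
  expect_equal(sum(cen$counts), length(inv$sites))

  # property: conservation holds over random fixtures
  for (seed in 1:5) {
    inv_r <- inventory_from_spec(random_chl_spec(10, seed))
    expect_equal(sum(pigment_census(inv_r)$counts), length(inv_r$sites))
  }

  empty <- structure(list(sites = list(), naming_map = NULL,
                          skipped = data.frame()),
                     class = "pigment_inventory")
  cen0 <- pigment_census(empty)
  expect_true(all(cen0$counts == 0))
  expect_equal(cen0$total_pigments + cen0$total_lipids, 0)
})

test_that("census writers emit CSV and JSON", {
  inv <- inventory_from_spec(random_chl_spec(4, 1))
  cen <- pigment_census(inv)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_census(cen, csv)
  write_census(cen, js)
  tab <- read.csv(csv)
  expect_equal(tab$count[tab$kind == "CHL_A"], 4)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$counts$CHL_A, 4)
  expect_equal(parsed$total_pigments, 4)
})

test_that("profiles load code and naming maps and reject unknown kinds", {
  prof <- read_profile(system.file("extdata", "profiles", "fixture.json",
                                   package = "eetnet"))
  expect_equal(unname(prof$code_map[["CLA"]]), "CHL_A")
  expect_equal(unname(prof$code_map[["ALX"]]), "ALX")
  tmpl <- read_profile(system.file("extdata", "profiles",
                                   "8wb4_template.json", package = "eetnet"))
  expect_true(all(c("CLA", "KC1", "KC2") %in% names(tmpl$code_map)))
  bad <- tempfile(fileext = ".json")
  writeLines('{"code_map": {"ZZZ": "NOT_A_KIND"}}', bad)
  expect_error(read_profile(bad), "unknown kind")
})
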