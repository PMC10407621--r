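test_that("SIC1 reproduces the four published golden values", {
  # exact to the printed precision (three decimals)
  expect_lt(abs(sic(parse_smiles(golden_smiles$ctet)) - 0.311), 5e-4)
  expect_lt(abs(sic(parse_smiles(golden_smiles$tca1112)) - 0.583), 5e-4)
  expect_lt(abs(sic(parse_smiles(golden_smiles$tca112)) - 0.604), 5e-4)
  expect_equal(round(sic(parse_smiles(golden_smiles$bromoform)), 2), 0.59)
})

test_that("SIC boundary behavior: saturation at 1, single-atom error", {
  # every atom distinguishable at order 1: chain C-O-N-ish with distinct
  # neighborhoods -> SIC1 = 1 when all classes are singletons
  m <- parse_smiles("[CH3][OH]")  # C, O, 3 H on C, 1 H on O: H classes split
  cls_entropy <- sic(m, order = 2)
  expect_lte(cls_entropy, 1)
  lone <- structure(list(
    atoms = data.frame(element = "Ne", aromatic = FALSE,
                       x = 0, y = 0, z = 0),
    bonds = data.frame(i = integer(0), j = integer(0), order = numeric(0)),
    name = "neon", abbrev = NA, smiles = NA), class = "ro_molecule")
  expect_error(sic(lone), "single-atom")
})

test_that("SIC is invariant to atom order and monotone in the order argument", {
  fx <- load_fixture()
  subset <- fx$smiles[c(1, 12, 21, 35, 49, 55, 70)]
  for (smi in subset) {
    mol <- parse_smiles(smi)
    s0 <- sic(mol, 0); s1 <- sic(mol, 1); s2 <- sic(mol, 2); s3 <- sic(mol, 3)
    expect_gte(s1, s0 - 1e-12)
    expect_gte(s2, s1 - 1e-12)
    expect_gte(s3, s2 - 1e-12)
  }
  # reversed-SMILES spot check (same molecule, different atom order)
  expect_equal(sic(parse_smiles("ClCC(Cl)Cl")), sic(parse_smiles("ClC(Cl)CCl")))
  expect_equal(sic(parse_smiles("CC(C)(C)O")), sic(parse_smiles("OC(C)(C)C")))
})

test_that("ESpm14u reproduces the published golden values", {
  expect_equal(espm(parse_smiles(golden_smiles$tba)), 15.381, tolerance = 5e-5)
  expect_equal(espm(parse_smiles(golden_smiles$ipa)), 9.704, tolerance = 5e-5)
  expect_equal(espm(parse_smiles(golden_smiles$tdce)), 5.549, tolerance = 2e-5)
  # closed forms: star S4 line graph K4 has spectrum (3, -1, -1, -1)
  expect_equal(espm(parse_smiles(golden_smiles$tba)), log(1 + 3^14 + 3))
  expect_equal(espm(parse_smiles(golden_smiles$ipa)), log(1 + 2^14 + 2))
  expect_equal(espm(parse_smiles(golden_smiles$tdce)), log(1 + 2 * 2^7))
})

test_that("ESpm handles single-bond graphs and bad arguments", {
  expect_equal(espm(parse_smiles("CCl")), 0)  # 1x1 zero matrix, any k
  expect_equal(espm(parse_smiles("CCl"), k = 3L), 0)
  expect_error(espm(parse_smiles("CC"), k = 0L), "k must be")
  expect_error(espm(parse_smiles("C")), "no heavy-atom bonds")
})

test_that("ESpm eigenvalue and matrix-power routes agree", {
  for (seed in 1:25) {
    mol <- parse_smiles(random_alkane_smiles(sample(3:12, 1), seed))
    for (k in c(3L, 8L, 14L)) {
      expect_equal(espm(mol, k, method = "eigen"), espm(mol, k, method = "power"),
                   tolerance = 1e-9)
    }
  }
})

test_that("EEig03d golden values: benzene 1, chlorobenzene 1, naphthalene 1.618", {
  expect_equal(eeig(parse_smiles(golden_smiles$benzene)), 1, tolerance = 1e-9)
  expect_equal(eeig(parse_smiles(golden_smiles$chlorobenzene)), 1, tolerance = 1e-8)
  # 6-cycle spectrum is (2, 1, 1, -1, -1, -2)
  expect_equal(eeig(parse_smiles("C1CCCCC1")), 1, tolerance = 1e-9)  # cyclohexane
  expect_equal(eeig(parse_smiles(golden_smiles$naphthalene)), (1 + sqrt(5)) / 2,
               tolerance = 1e-9)
})

test_that("EEig with zero weights equals the line-graph eigenvalue (oracle)", {
  for (seed in 21:40) {
    mol <- parse_smiles(random_alkane_smiles(sample(4:10, 1), seed))
    g <- heavy_atom_graph(mol)
    Bo <- oracle_line_adjacency(g$bonds)
    ranks <- seq_len(min(3L, nrow(Bo)))
    evo <- sort(eigen(Bo, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    for (r in ranks) {
      expect_equal(eeig(mol, rank = r), evo[r], tolerance = 1e-10)
    }
  }
})

test_that("EEig falls back to 0 with a warning when bonds < rank", {
  expect_warning(v <- eeig(parse_smiles("CCl"), rank = 3L), "falls back")
  expect_equal(v, 0)
})

test_that("chlorobenzene keeps eigenvalue 1 by the antisymmetric-eigenvector argument", {
  # oracle: dense eigendecomposition of the 7x7 weighted matrix
  g <- heavy_atom_graph(parse_smiles(golden_smiles$chlorobenzene))
  tabs <- ro_element_tables()
  w <- vapply(seq_len(nrow(g$bonds)), function(e) {
    els <- sort(c(g$elements[g$bonds$i[e]], g$elements[g$bonds$j[e]]))
    if (all(els == "C")) 0 else tabs$bond_dipole[["C-Cl:1"]]
  }, numeric(1))
  Bo <- oracle_line_adjacency(g$bonds, diagw = w)
  evo <- sort(eigen(Bo, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(evo[3], 1, tolerance = 1e-9)
  expect_equal(eeig(parse_smiles(golden_smiles$chlorobenzene)), evo[3])
})

test_that("R2e hand-derived cases: collinear triple and diatomic", {
  # three collinear carbon-like atoms: h = (0.5, 0, 0.5), one lag-2 pair at
  # distance 2 -> sqrt(0.25)/2 = 0.25
  sdf <- paste("c3", "", "",
               "  3  2  0  0  0  0  0  0  0  0999 V2000",
               "   -1.0000    0.0000    0.0000 C   0",
               "    0.0000    0.0000    0.0000 C   0",
               "    1.0000    0.0000    0.0000 C   0",
               "  1  2  1  0",
               "  2  3  1  0",
               "M  END", sep = "\n")
  mol <- parse_structure(sdf)
  mol$atoms <- mol$atoms[mol$atoms$element == "C", ]  # drop filled H (no coords)
  mol$bonds <- mol$bonds[mol$bonds$i <= 3 & mol$bonds$j <= 3, ]
  expect_equal(r2e(mol), 0.25, tolerance = 1e-12)

  # diatomic: no lag-2 pairs
  sdf2 <- paste("cl2", "", "",
                "  2  1  0  0  0  0  0  0  0  0999 V2000",
                "    0.0000    0.0000    0.0000 Cl  0",
                "    1.9900    0.0000    0.0000 Cl  0",
                "  1  2  1  0",
                "M  END", sep = "\n")
  expect_equal(r2e(parse_structure(sdf2)), 0)
})

test_that("R2e of chloroform at near-experimental geometry matches the print", {
  mol <- parse_structure(chloroform_sdf())
  expect_equal(r2e(mol), 2.381, tolerance = 0.05 / 2.381)
})

test_that("R2e scales as 1/s under coordinate scaling", {
  mol <- embed_coordinates(parse_smiles("CC(Cl)CO"), quiet = TRUE)
  base <- r2e(mol)
  for (s in c(0.5, 2, 3.7)) {
    scaled <- mol
    scaled$atoms[, c("x", "y", "z")] <- mol$atoms[, c("x", "y", "z")] * s
    expect_equal(r2e(scaled), base / s, tolerance = 1e-10)
  }
})

test_that("R2e errors without coordinates", {
  expect_error(r2e(parse_smiles("CCO")), "coordinates")
})

test_that("descriptor_table assembles, collects errors, and handles edge cases", {
  tab <- suppressWarnings(descriptor_table(list(
    parse_smiles("CC(C)(C)O", name = "TBA"),
    parse_smiles("CC(C)O", name = "IPA")
  ), embed_missing = TRUE))
  expect_equal(names(tab), c("compound", "SIC1", "R2e", "EEig03d", "ESpm14u"))
  expect_equal(tab$ESpm14u, c(15.381, 9.704), tolerance = 5e-5)

  empty <- descriptor_table(list())
  expect_equal(nrow(empty), 0L)

  # per-compound failures are aggregated with names
  expect_error(
    descriptor_table(list(parse_smiles("C", name = "methane"),
                          parse_smiles("CC", name = "ethane")),
                    which = "ESpm14u"),
    "methane")

  # no coordinates and no embedding permission
  expect_error(descriptor_table(list(parse_smiles("CCO", name = "ethanol"))),
               "embed_missing")

  full <- fixture_descriptors()
  expect_equal(dim(full), c(72L, 5L))
  expect_false(anyNA(full[-1]))
  expect_true(all(full$SIC1 >= 0 & full$SIC1 <= 1))
  expect_true(all(full$ESpm14u >= 0))
  expect_true(all(full$R2e >= 0))
})

test_that("descriptor CSV round trips", {
  tab <- suppressWarnings(descriptor_table(
    list(parse_smiles("CC(C)(C)O", name = "TBA")), embed_missing = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(tab, path)
  back <- read_descriptor_csv(path)
  expect_equal(back$ESpm14u, tab$ESpm14u, tolerance = 1e-12)
  expect_error(read_descriptor_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p, row.names = FALSE); p
  }), "compound")
})
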