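test_that("Kier shape indices match the path-enumeration oracle", {
  # hand values: n-pentane kappa3 = 4, n-hexane kappa3 = 16/3
  expect_equal(kier_shape_index(parse_smiles("CCCCC"), 3), 4.0)
  expect_equal(kier_shape_index(parse_smiles("CCCCCC"), 3), 16 / 3)
  expect_error(kier_shape_index(parse_smiles("CCC"), 3),
               class = "qf_descriptor_undefined")

  lib <- gen_molecule_set(30, max_atoms = 12, seed = 21)
  for (rec in lib$records) {
    mol <- rec$molecule
    a <- heavy_atom_count(mol)
    for (m in 1:3) {
      p <- path_count_oracle(mol, m)
      if (p == 0) {
        expect_error(kier_shape_index(mol, m),
                     class = "qf_descriptor_undefined")
        next
      }
      expected <- switch(m,
        a * (a - 1)^2 / p^2,
        (a - 1) * (a - 2)^2 / p^2,
        if (a %% 2 == 1) (a - 1) * (a - 3)^2 / p^2
        else (a - 3) * (a - 2)^2 / p^2)
      expect_equal(kier_shape_index(mol, m), expected, tolerance = 1e-10)
    }
  }
})

test_that("Balaban index matches hand values and the literal formula", {
  expect_equal(balaban_index(parse_smiles("CC")), 1.0)
  expect_equal(balaban_index(parse_smiles("CCC")), 4 / sqrt(6),
               tolerance = 1e-9)
  expect_equal(balaban_index(parse_smiles("C1CC1")), 2.25)
  expect_equal(balaban_index(parse_smiles("C")), 0)

  lib <- gen_molecule_set(50, max_atoms = 12, seed = 13)
  for (rec in lib$records) {
    mol <- rec$molecule
    expect_equal(balaban_index(mol), balaban_oracle(mol),
                 tolerance = 1e-10)
  }
})

test_that("information-content indices follow the entropy definition", {
  o2 <- parse_smiles("O=O")
  expect_equal(information_content(o2, "IC", 0), 0)
  expect_equal(information_content(o2, "SIC", 0), 0)

  methane <- parse_smiles("C")
  expect_equal(information_content(methane, "IC", 0), 0.7219281,
               tolerance = 1e-6)
  expect_equal(information_content(methane, "SIC", 0), 0.3109175,
               tolerance = 1e-6)
  expect_equal(information_content(methane, "CIC", 0), 1.6,
               tolerance = 1e-6)

  # bond orders only matter for the bonding variant: C4H8 isomers with
  # identical composition share IC0 but differ in BIC1
  butene <- parse_smiles("C=CCC")
  cyclobutane <- parse_smiles("C1CCC1")
  expect_equal(information_content(butene, "IC", 0),
               information_content(cyclobutane, "IC", 0))
  expect_false(isTRUE(all.equal(
    information_content(butene, "BIC", 1),
    information_content(cyclobutane, "BIC", 1))))

  # SIC in [0,1] and IC + CIC = log2(n atoms) exactly
  lib <- gen_molecule_set(25, max_atoms = 10, seed = 17)
  for (rec in lib$records) {
    mol <- rec$molecule
    n <- total_atom_count(mol)
    for (ord in 0:2) {
      sic <- information_content(mol, "SIC", ord)
      expect_gte(sic, 0); expect_lte(sic, 1)
      expect_equal(information_content(mol, "IC", ord) +
                     information_content(mol, "CIC", ord),
                   log2(n), tolerance = 1e-12)
    }
  }
})

test_that("constitutional descriptors report composition", {
  d <- constitutional_descriptors(parse_smiles("C"))
  expect_equal(unname(d["avg_atom_weight"]), 16.043 / 5, tolerance = 1e-4)
  single <- new_molecule("Catom", "C", NULL, explicit_h = 0L)
  expect_equal(unname(constitutional_descriptors(single)["avg_atom_weight"]),
               12.011)
  benz <- constitutional_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(unname(benz["n_rings"]), 1)
  expect_equal(unname(benz["n_C"]), 6)
})

test_that("Zefirov charges follow electronegativity equalization", {
  # homonuclear molecules carry zero charge everywhere
  for (smi in c("CC", "O=O", "CCCC")) {
    q <- zefirov_charges(parse_smiles(smi))
    hv <- q[q$element != "H", "charge"]
    if (smi %in% c("O=O")) expect_true(all(abs(hv) < 1e-12))
  }
  # HCl hand value: q_H = (sqrt(S_H S_Cl) - S_H) / (2.08 sqrt(S_H))
  q <- zefirov_charges(parse_smiles("Cl"))
  s_h <- 2.592; s_cl <- 3.475
  smol <- sqrt(s_h * s_cl)
  expect_equal(q$charge[q$element == "H"],
               (smol - s_h) / (2.08 * sqrt(s_h)), tolerance = 1e-9)
  expect_equal(q$charge[q$element == "H"], 0.122, tolerance = 5e-3)

  # charges sum to the net formal charge
  lib <- gen_molecule_set(50, max_atoms = 10, seed = 19)
  for (rec in lib$records) {
    expect_lt(abs(sum(zefirov_charges(rec$molecule)$charge)), 1e-8)
  }
  ion <- parse_smiles("[NH4+]")
  expect_equal(sum(zefirov_charges(ion)$charge), 1, tolerance = 1e-8)
})

test_that("charge extrema respect the element filter", {
  mol <- parse_smiles("CCCC")
  q <- zefirov_charges(mol)
  expect_error(charge_extrema(q, "O", "max"),
               class = "qf_descriptor_undefined")
  fake <- external_charges(parse_smiles("CCC"), c(-0.3, 0.1, 0.2))
  expect_equal(charge_extrema(fake, NULL, "min"), -0.3)
  expect_equal(charge_extrema(fake, NULL, "max"), 0.2)
  # brute-force scan agreement on random charge sets
  set.seed(4)
  for (i in 1:20) {
    m <- parse_smiles("CCOCN")
    ch <- stats::rnorm(nrow(m$atoms))
    cs <- external_charges(m, ch)
    for (el in c("C", "O", "N")) {
      sel <- ch[m$atoms$element == el]
      expect_equal(charge_extrema(cs, el, "max"), max(sel))
      expect_equal(charge_extrema(cs, el, "min"), min(sel))
    }
  }
})

test_that("SASA reproduces analytic spheres and converges with sampling", {
  lone <- new_molecule("Catom", "C", NULL, explicit_h = 0L,
                       coords = matrix(0, 1, 3))
  s <- shrake_rupley_sasa(lone)
  expect_equal(attr(s, "tmsa"), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)

  apart <- new_molecule("far", c("C", "C"),
                        data.frame(a1 = 1, a2 = 2, order = 1),
                        explicit_h = 0L,
                        coords = rbind(c(0, 0, 0), c(100, 0, 0)))
  s2 <- shrake_rupley_sasa(apart)
  expect_equal(attr(s2, "tmsa"), 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-9)

  # overlapping spheres: coarse lattice within 2% of a dense one
  touching <- new_molecule("pair", c("C", "O"),
                           data.frame(a1 = 1, a2 = 2, order = 1),
                           explicit_h = 0L,
                           coords = rbind(c(0, 0, 0), c(1.4, 0, 0)))
  coarse <- attr(shrake_rupley_sasa(touching, n_points = 960), "tmsa")
  dense <- attr(shrake_rupley_sasa(touching, n_points = 10000), "tmsa")
  expect_equal(coarse, dense, tolerance = 0.02)
  expect_true(all(shrake_rupley_sasa(touching)$area >= 0))
  expect_error(shrake_rupley_sasa(parse_smiles("CC")), "coordinates")
})

test_that("CPSA descriptors follow their summation definitions", {
  set.seed(7)
  # explicit-hydrogen ethanol-like chain with fake 3D coordinates
  mol <- new_molecule("etoh", c("C", "C", "O", "H"),
                      data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4),
                                 order = 1),
                      explicit_h = c(3L, 2L, 0L, 0L),
                      coords = rbind(c(0, 0, 0), c(1.5, 0, 0),
                                     c(2.2, 1.1, 0), c(3.1, 1.0, 0.3)))
  q <- zefirov_charges(mol)
  s <- shrake_rupley_sasa(mol)
  d <- cpsa_descriptors(mol, q, s)
  qs <- q$charge[1:4]; ar <- s$area
  expect_equal(unname(d["PPSA1"]), sum(ar[qs > 0]))
  expect_equal(unname(d["PPSA2"]), sum(qs[qs > 0]) * sum(ar[qs > 0]))
  expect_equal(unname(d["HASA"]), ar[3])
  expect_equal(unname(d["FHASA"]), ar[3] / sum(ar))
  expect_equal(unname(d["HACA1"]), qs[3] * ar[3])
  expect_equal(unname(d["HACA2"]), qs[3] * ar[3] / sqrt(sum(ar)))
  # the O-H hydrogen is the only donor hydrogen
  expect_equal(unname(d["HDCA1"]), qs[4] * ar[4])
  expect_equal(unname(d["HDCA2"]), qs[4] * ar[4] / sqrt(sum(ar)))

  # no N/O: acceptor terms vanish; all-positive charges make PPSA1 = TMSA
  hydrocarbon <- new_molecule("prop", c("C", "C", "C"),
                              data.frame(a1 = c(1, 2), a2 = c(2, 3),
                                         order = 1),
                              explicit_h = 0L,
                              coords = rbind(c(0, 0, 0), c(1.5, 0, 0),
                                             c(3, 0, 0)))
  sh <- shrake_rupley_sasa(hydrocarbon)
  dh <- cpsa_descriptors(hydrocarbon,
                         external_charges(hydrocarbon, c(0.1, 0.2, 0.3)),
                         sh)
  expect_equal(unname(dh[c("HASA", "FHASA", "HACA1", "HACA2")]),
               rep(0, 4))
  expect_equal(unname(dh["PPSA1"]), unname(dh["TMSA"]))
})

test_that("computed descriptors are invariant under atom reindexing", {
  lib <- gen_molecule_set(10, max_atoms = 10, seed = 23)
  set.seed(31)
  for (rec in lib$records) {
    mol <- rec$molecule
    n <- nrow(mol$atoms)
    if (n < 3) next
    perm <- sample(n)
    pmol <- permute_molecule(mol, perm)
    expect_equal(balaban_index(pmol), balaban_index(mol),
                 tolerance = 1e-10)
    for (ord in 0:2) {
      expect_equal(information_content(pmol, "BIC", ord),
                   information_content(mol, "BIC", ord),
                   tolerance = 1e-10)
    }
    expect_equal(sort(zefirov_charges(pmol)$charge),
                 sort(zefirov_charges(mol)$charge), tolerance = 1e-10)
    expect_equal(constitutional_descriptors(pmol),
                 constitutional_descriptors(mol))
  }
})

test_that("descriptor matrices attach external columns with provenance", {
  lib <- gen_molecule_set(3, max_atoms = 8, seed = 2)
  lib <- compound_library(lib$records[1:3])
  dm <- compute_descriptors(lib)
  expect_s3_class(dm, "qf_descmat")
  expect_true(all(attr(dm, "provenance") == "computed"))

  ext <- data.frame(compound_id = dm$compound_id,
                    LUMO_AM1 = c(-0.3, -0.1, -0.5),
                    heat_formation_AM1 = c(12, 8, -3))
  dm2 <- attach_external_descriptors(dm, ext)
  expect_equal(setdiff(names(dm2), names(dm)),
               c("LUMO_AM1", "heat_formation_AM1"))
  expect_equal(unname(attr(dm2, "provenance")[c("LUMO_AM1")]), "external")
  expect_equal(dm2$LUMO_AM1, ext$LUMO_AM1)

  # missing id flagged, duplicate name rejected
  dm3 <- attach_external_descriptors(dm, ext[-2, ])
  expect_equal(attr(dm3, "incomplete"), dm$compound_id[2])
  expect_error(attach_external_descriptors(dm2, ext), "duplicate")

  # CSV round trip preserves values and provenance
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(dm2, path)
  back <- read_descriptors(path)
  expect_equal(back$LUMO_AM1, dm2$LUMO_AM1)
  expect_equal(attr(back, "provenance")[["LUMO_AM1"]], "external")
})

test_that("undefined descriptors surface as NA in the matrix", {
  lib <- compound_library(list(
    compound_record("propane", parse_smiles("CCC", id = "propane")),
    compound_record("hexane", parse_smiles("CCCCCC", id = "hexane"))))
  dm <- compute_descriptors(lib)
  expect_true(is.na(dm$kappa3[dm$compound_id == "propane"]))
  expect_false(is.na(dm$kappa3[dm$compound_id == "hexane"]))
  expect_false("kappa3" %in% descriptor_names(dm, complete_only = TRUE))
})
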