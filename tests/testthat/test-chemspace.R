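smi_file <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}

test_that("load_molecules canonicalizes, assigns ids and reports bad lines", {
  m <- load_molecules(smi_file("c1ccccc1 benz"), role = "accessible")
  expect_equal(nrow(m), 1L)
  expect_equal(m$id, "benz")
  expect_equal(m$smiles, canonical_smiles("C1=CC=CC=C1"))
  expect_gt(m$mw, 78)

  expect_error(load_molecules(smi_file(character(0)), role = "substituent"),
               "zero valid records")
  expect_error(load_molecules(tempfile(), role = "substituent"), "not found")

  msg <- capture_messages(
    m2 <- load_molecules(smi_file(c("CCO a", "C1CC bad", "CN b", "CO c")),
                         role = "substituent")
  )
  expect_equal(nrow(m2), 3L)
  fails <- attr(m2, "failures")
  expect_equal(fails$line, 2L)
  expect_match(paste(msg, collapse = ""), "unparseable")

  expect_error(
    load_molecules(smi_file(c("CCO x", "CN x")), role = "substituent"),
    "duplicate"
  )
})

test_that("substituent MW filter is strict and order-preserving", {
  mols <- data.frame(id = c("a", "b", "c"), smiles = c("CN", "CCO", "CCCCN"),
                     mw = c(31.06, 200.0, 150.0))
  kept <- filter_substituents(mols, mw_limit = 200)
  expect_equal(kept$id, c("a", "c"))  # exactly 200 excluded
  expect_equal(nrow(filter_substituents(mols, mw_limit = 0)), 0L)
  ma <- load_molecules(smi_file("CN methylamine"), role = "substituent")
  expect_equal(nrow(filter_substituents(ma, 200)), 1L)
  expect_equal(ma$mw, 31.06, tolerance = 1e-3)
})

test_that("amide template turns benzoic acid + methylamine into N-methylbenzamide", {
  cores <- load_molecules(smi_file("OC(=O)c1ccccc1 bz"), "accessible")
  subs <- load_molecules(smi_file("CN ma"), "substituent")
  prod <- enumerate_products(cores, subs,
                             templates = reaction_templates("amide"))
  expect_equal(nrow(prod), 1L)
  # expected product canonicalized independently from a hand-built SMILES
  expect_equal(prod$smiles, canonical_smiles("O=C(NC)c1ccccc1"))
  expect_equal(prod$core_id, "bz")
  expect_equal(prod$substituent_id, "ma")
  expect_equal(prod$reaction_id, "amide")
  # condensation bookkeeping: product MW = acid + amine - water
  expect_equal(prod$mw, cores$mw + subs$mw - 18.0153, tolerance = 0.01)
})

test_that("pairs lacking a reactive handle yield no products", {
  benzene <- load_molecules(smi_file("c1ccccc1 b"), "accessible")
  subs <- load_molecules(smi_file(c("CN ma", "CCO et", "CCBr eb")),
                         "substituent")
  expect_equal(nrow(enumerate_products(benzene, subs)), 0L)
})

test_that("ether coupling runs in both orientations and products dedup", {
  phenol <- load_molecules(smi_file("Oc1ccccc1 ph"), "accessible")
  subs <- load_molecules(smi_file(c("CI mei", "ClCc1ccccc1 bzc")),
                         "substituent")
  prod <- enumerate_products(phenol, subs,
                             templates = reaction_templates("ether"))
  expect_setequal(prod$smiles,
                  canonical_smiles(c("COc1ccccc1", "C(Oc1ccccc1)c1ccccc1")))
  # reverse orientation: core alkyl halide + substituent alcohol
  bzc_core <- load_molecules(smi_file("ClCc1ccccc1 bzc"), "accessible")
  meoh <- load_molecules(smi_file("CO me"), "substituent")
  prod2 <- enumerate_products(bzc_core, meoh,
                              templates = reaction_templates("ether"))
  expect_equal(prod2$smiles, canonical_smiles("COCc1ccccc1"))

  # two substituent records that canonicalize to the same alcohol -> one product
  dup <- load_molecules(smi_file(c("CCO e1", "OCC e2")), "substituent")
  acid <- load_molecules(smi_file("OC(=O)c1ccccc1 bz"), "accessible")
  pr <- enumerate_products(acid, dup, templates = reaction_templates("ester"))
  expect_equal(nrow(pr), 1L)
})

test_that("enumeration is deterministic and order-invariant as a set", {
  cores <- load_molecules(smi_file(c("OC(=O)c1ccccc1 bz", "Oc1ccccc1 ph")),
                          "accessible")
  subs <- load_molecules(
    smi_file(c("CN ma", "CCO et", "CI mei", "NCCO ea")), "substituent")
  p1 <- enumerate_products(cores, subs)
  p2 <- enumerate_products(cores[2:1, ], subs[c(3, 1, 4, 2), ])
  expect_setequal(p1$smiles, p2$smiles)
  expect_identical(p1$smiles, enumerate_products(cores, subs)$smiles)
})

test_that("all_sites converts every arm of a tetra-acid core at once", {
  tcpp <- load_molecules(
    system.file("extdata", "cores.smi", package = "solucover"),
    "accessible")
  tcpp <- tcpp[tcpp$id == "tcpp", ]
  ma <- load_molecules(smi_file("CN ma"), "substituent")
  full <- enumerate_products(tcpp, ma, templates = reaction_templates("amide"),
                             site_mode = "all_sites")
  expect_equal(nrow(full), 1L)
  # four condensations: MW = core + 4 * (amine - water)
  expect_equal(full$mw, tcpp$mw + 4 * (ma$mw - 18.0153), tolerance = 0.02)
  mono <- enumerate_products(tcpp, ma, templates = reaction_templates("amide"),
                             site_mode = "single_site")
  expect_gte(nrow(mono), 1L)
  expect_true(all(mono$mw < full$mw))
  expect_equal(unique(round(mono$mw, 2)),
               round(tcpp$mw + ma$mw - 18.0153, 2))
})

test_that("build_molspace merges duplicates with accessible role winning", {
  acc <- load_molecules(smi_file(c("CCO a1", "CN a2")), "accessible")
  gen <- load_molecules(smi_file(c("OCC g1", "CCCCN g2", "CCN g3")),
                        "generated")
  sp <- build_molspace(acc, gen, nbits = 1024)
  expect_equal(sp$nmol, 4L)  # ethanol merged
  merged <- sp$molecules
  eth <- merged[merged$smiles == canonical_smiles("CCO"), ]
  expect_equal(eth$role, "accessible")
  expect_error(build_molspace(acc[0, ], gen[0, ]), "empty union")
  # no two molecules share a canonical SMILES
  expect_false(anyDuplicated(merged$smiles) > 0)
})
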