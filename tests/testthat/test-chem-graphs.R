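test_that("SMILES parsing produces correct atom/bond tables", {
  m <- fixtureMols()
  expect_equal(nrow(atoms(m$ethane)), 2)
  expect_equal(nrow(bonds(m$ethane)), 1)

  bz <- m$benzene
  expect_equal(nrow(atoms(bz)), 6)
  expect_equal(nrow(bonds(bz)), 6)
  expect_true(all(atoms(bz)$aromatic))
  expect_true(all(atoms(bz)$inRing))
  expect_true(all(bonds(bz)$type == "aromatic"))

  expect_equal(nrow(atoms(m$sodium)), 1)
  expect_equal(atoms(m$sodium)$charge, 1)
  expect_true(any(atoms(m$alanine)$chirality != "none"))
})

test_that("unparsable or empty SMILES raise named errors", {
  expect_error(parseSmiles("C("), "C\\(")
  expect_error(parseSmiles(""), "empty")
  expect_error(parseSmiles(character()), "non-empty")
})

test_that("re-parsing the canonical SMILES gives an isomorphic molecule", {
  for (m in fixtureMols()) {
    m2 <- parseSmiles(canonicalSmiles(m))[[1]]
    expect_equal(nrow(atoms(m2)), nrow(atoms(m)))
    expect_equal(nrow(bonds(m2)), nrow(bonds(m)))
    expect_equal(sort(atoms(m2)$element), sort(atoms(m)$element))
    expect_identical(canonicalSmiles(m2), canonicalSmiles(m))
  }
})

test_that("atom-bond graph doubles each bond into directed edges", {
  m <- fixtureMols()
  g <- buildAtomBondGraph(m$ethane)
  expect_equal(nrow(nodeFeatures(g)), 2)
  expect_equal(ncol(edgeIndex(g)), 2)

  gb <- buildAtomBondGraph(m$benzene)
  expect_equal(ncol(edgeIndex(gb)), 12)
  aromCol <- which(dtafuse:::.BOND_TYPES == "aromatic")
  expect_true(all(edgeFeatures(gb)[, aromCol] == 1))

  # edge count = 2 x bond count over the random pool
  pool <- syntheticMolPool(60)
  for (mol in utils::head(pool$mols, 50)) {
    g <- buildAtomBondGraph(mol)
    expect_equal(ncol(edgeIndex(g)), 2 * nrow(bonds(mol)))
    e <- edgeIndex(g)
    if (ncol(e)) {
      expect_true(all(e[1, ] != e[2, ]))
      expect_setequal(paste(e[1, ], e[2, ]), paste(e[2, ], e[1, ]))
    }
  }
})

test_that("provider shape mismatches are rejected", {
  m <- fixtureMols()$benzene
  bad <- list(name = "bad", dim = 8L,
              embed = function(mol) matrix(0, 3, 8))
  expect_error(buildAtomBondGraph(m, bad), "6 atoms")
  g <- buildAtomBondGraph(m, fallbackAtomProvider(8, 1))
  expect_equal(dim(nodeFeatures(g)), c(6L, 8L))
})

test_that("pharmacophore decomposition matches hand enumeration", {
  m <- fixtureMols()
  cases <- list(
    # smiles key, expected ring units, acyclic units, undirected unit edges
    list("ethane", 0, 1, 0),
    list("benzene", 1, 0, 0),
    list("toluene", 1, 1, 1),
    list("biphenyl", 2, 1, 2),
    list("naphthalene", 2, 0, 1),
    list("aspirin", 1, 7, 9)
  )
  for (cs in cases) {
    g <- buildPharmacophoreGraph(m[[cs[[1]]]])
    kinds <- vapply(pharmUnits(g), `[[`, character(1), "kind")
    expect_equal(sum(kinds == "ring"), cs[[2]], label = cs[[1]])
    expect_equal(sum(kinds == "acyclic_bond"), cs[[3]], label = cs[[1]])
    expect_equal(ncol(edgeIndex(g)) / 2, cs[[4]], label = cs[[1]])
  }
})

test_that("unit bond sets partition the bonds and atoms are covered", {
  pool <- syntheticMolPool(200)
  mols <- c(fixtureMols(), pool$mols)
  for (mol in mols) {
    units <- decomposePharmUnits(mol)
    allBonds <- unlist(lapply(units, `[[`, "bonds"))
    expect_equal(sort(allBonds), seq_len(nrow(bonds(mol))))  # no bond twice
    covered <- unique(unlist(lapply(units, `[[`, "atoms")))
    expect_setequal(covered, seq_len(nrow(atoms(mol))))
    for (u in units) {
      if (u$kind == "ring") {
        expect_true(all(bonds(mol)$inRing[u$bonds]))
      } else if (length(u$bonds)) {
        expect_length(u$bonds, 1)
        expect_length(u$atoms, 2)
      } else {
        expect_length(u$atoms, 1)  # degenerate isolated atom
      }
    }
  }
})

test_that("pharmacophore adjacency is symmetric, loop-free and by shared atoms", {
  pool <- syntheticMolPool(200)
  for (mol in pool$mols) {
    g <- buildPharmacophoreGraph(mol)
    e <- edgeIndex(g)
    if (ncol(e) == 0) next
    expect_true(all(e[1, ] != e[2, ]))
    expect_setequal(paste(e[1, ], e[2, ]), paste(e[2, ], e[1, ]))
    units <- pharmUnits(g)
    for (k in seq_len(ncol(e)))
      expect_gt(length(intersect(units[[e[1, k]]]$atoms,
                                 units[[e[2, k]]]$atoms)), 0)
  }
})

test_that("unit features are invariant to SMILES atom reordering", {
  spellings <- list(
    toluene = c("Cc1ccccc1", "c1ccc(C)cc1", "c1cc(C)ccc1"),
    biphenyl = c("c1ccccc1-c2ccccc2", "c1ccc(-c2ccccc2)cc1"),
    pyridine = c("c1ccncc1", "n1ccccc1", "c1cccnc1")
  )
  for (sp in spellings) {
    mols <- parseSmiles(sp)
    feats <- lapply(mols, function(m) {
      f <- nodeFeatures(buildPharmacophoreGraph(m))
      f[do.call(order, as.data.frame(f)), , drop = FALSE]  # canonical order
    })
    for (k in seq_along(feats)[-1])
      expect_equal(feats[[k]], feats[[1]], tolerance = 1e-12)
  }
})

test_that("benzene ring unit features record size and aromaticity", {
  m <- fixtureMols()
  units <- decomposePharmUnits(m$benzene)
  f <- featurizePharmNode(units[[1]], m$benzene)
  expect_equal(unname(f["atom_count"]), 6)
  expect_equal(unname(f["aromatic_fraction"]), 1)
  expect_equal(unname(f["ring_flag"]), 1)

  fe <- featurizePharmNode(decomposePharmUnits(m$ethane)[[1]], m$ethane)
  expect_equal(unname(fe["atom_count"]), 2)
  expect_equal(unname(fe["ring_flag"]), 0)
})

test_that("same SMILES yields bit-identical graphs across calls", {
  g1 <- buildAtomBondGraph(parseSmiles("CC(=O)Oc1ccccc1C(=O)O")[[1]],
                           fallbackAtomProvider(16, 3))
  g2 <- buildAtomBondGraph(parseSmiles("CC(=O)Oc1ccccc1C(=O)O")[[1]],
                           fallbackAtomProvider(16, 3))
  expect_identical(nodeFeatures(g1), nodeFeatures(g2))
  expect_identical(edgeIndex(g1), edgeIndex(g2))
  p1 <- buildPharmacophoreGraph(parseSmiles("Cc1ccccc1")[[1]])
  p2 <- buildPharmacophoreGraph(parseSmiles("Cc1ccccc1")[[1]])
  expect_identical(nodeFeatures(p1), nodeFeatures(p2))
})

test_that("graphs serialize to JSON with nodes, edges and features", {
  g <- buildAtomBondGraph(fixtureMols()$toluene)
  js <- jsonlite::fromJSON(graphToJSON(g))
  expect_equal(js$class, "AtomBondGraph")
  expect_equal(dim(js$node_features), dim(nodeFeatures(g)))
  expect_equal(js$edge_index, unname(edgeIndex(g)))
})
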