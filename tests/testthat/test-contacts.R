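minimal_pdb_text <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "END", sep = "\n")

test_that("PDB parsing extracts atom records with coordinates", {
  m <- parse_structure(minimal_pdb_text)
  expect_equal(nrow(m), 2)
  expect_equal(m$atom, c("N", "CA"))
  expect_equal(m$x, c(11.104, 11.639))
  expect_equal(model_chains(m), "A")
  expect_error(parse_structure("HEADER  NOTHING\nEND"), "no ATOM")
  bad <- sub("11.104", "xx.xxx", minimal_pdb_text, fixed = TRUE)
  expect_error(parse_structure(bad), "line 1")
})

test_that("write/parse round trip preserves coordinates to 3 decimals", {
  m <- gen_toy_complex(data.frame(
    donor_resname = c("LYS", "ARG"), donor_atom = c("NZ", "NH1"),
    acceptor_resname = c("SER", "ASP"), acceptor_atom = c("OG", "OD1"),
    distance = c(3.44, 2.875)))
  tf <- tempfile(fileext = ".pdb")
  write_structure(m, tf)
  back <- parse_structure(tf)
  unlink(tf)
  expect_equal(nrow(back), nrow(m))
  for (col in c("x", "y", "z")) {
    expect_equal(back[[col]], m[[col]], tolerance = 1e-9)
  }
  expect_equal(measure_distance(back, "A/1/NZ", "B/1/OG"), 3.44,
               tolerance = 1e-3)
})

test_that("distances are Euclidean", {
  m <- structure_model(data.frame(
    chain = c("A", "A", "B"), resname = "GLY", resno = c(1, 1, 1),
    atom = c("N", "CA", "N"),
    x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 0)))
  expect_equal(measure_distance(m, "A/1/N", "B/1/N"), 0)
  expect_equal(measure_distance(m, "A/1/CA", "B/1/N"), 5) # 3-4-5 triangle
  expect_error(measure_distance(m, "A/9/N", "B/1/N"), "resolve")
})

test_that("hydrogen bonds are detected inside the cutoff only", {
  close <- toy_pair_model(2.9)
  hb <- find_hbonds(close, "A", "B", cutoff = 3.5)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$donor_atom, "NZ")
  expect_equal(hb$acceptor_atom, "OG")
  expect_equal(hb$class, "side-side")
  far <- toy_pair_model(4.0)
  expect_equal(nrow(find_hbonds(far, "A", "B", cutoff = 3.5)), 0)
  expect_equal(nrow(find_hbonds(toy_pair_model(10), "A", "B")), 0)
  expect_error(find_hbonds(close, "A", "Z"), "chain")
})

test_that("swapping chains keeps the bond set and distances", {
  m <- toy_pair_model(3.2)
  ab <- find_hbonds(m, "A", "B")
  ba <- find_hbonds(m, "B", "A")
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(ab$distance), sort(ba$distance))
})

test_that("hydrogen bonds are a subset of interface residue pairs", {
  m <- gen_toy_complex(data.frame(
    donor_resname = c("LYS", "SER", "ARG"),
    donor_atom = c("NZ", "OG", "NH2"),
    acceptor_resname = c("SER", "GLU", "ASP"),
    acceptor_atom = c("OG", "OE1", "OD1"),
    distance = c(2.9, 3.3, 5.5)))
  cutoff <- 3.5
  hb <- find_hbonds(m, "A", "B", cutoff)
  ir <- interface_residues(m, "A", "B", cutoff)
  hb_pairs <- paste(hb$donor_resno, hb$acceptor_resno)
  ir_pairs <- paste(ir$resno_a, ir$resno_b)
  expect_true(all(hb_pairs %in% ir_pairs))
  expect_equal(nrow(ir), 2) # the 5.5 A pair is beyond the cutoff
})

test_that("interface report classifies and flags residues", {
  m <- toy_pair_model(3.0)
  ir <- interface_residues(m, "A", "B", cutoff = 3.5,
                           flag_residues = c(1, 177))
  expect_equal(nrow(ir), 1)
  expect_equal(ir$class, "side-side")
  expect_true(ir$flagged)
  # tight cutoff empties the report
  expect_equal(nrow(interface_residues(m, "A", "B", cutoff = 0.1)), 0)
})

test_that("reactive-site loop candidates carry the basic residues", {
  # knottin-like toy: cysteines at 5,15,30,40,45,55; Lys31/Arg32 sit in the
  # 31..39 inter-cysteine segment, Lys49 in 46..54
  chars <- rep("A", 60)
  chars[c(5, 15, 30, 40, 45, 55)] <- "C"
  chars[31] <- "K"; chars[32] <- "R"; chars[49] <- "K"
  s <- paste(chars, collapse = "")
  loops <- reactive_loop_candidates(s)
  expect_equal(nrow(loops), 2)
  expect_equal(loops$label, c("A", "B"))
  expect_equal(loops$basic_residues[[1]], c(31, 32))
  expect_equal(loops$basic_residues[[2]], 49)
})

test_that("secondary structure constrains loop candidates", {
  chars <- rep("A", 20)
  chars[c(6, 15)] <- "K"
  s <- paste(chars, collapse = "")
  # all-helix: no coil segments, no loops
  expect_equal(nrow(reactive_loop_candidates(
    s, ss = paste(rep("H", 20), collapse = ""))), 0)
  # coil stretch around residue 15 only
  ss <- paste(c(rep("H", 10), rep("-", 10)), collapse = "")
  loops <- reactive_loop_candidates(s, ss = ss)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$basic_residues[[1]], 15)
  expect_error(reactive_loop_candidates(s, ss = "H"), "length")
  # no basic residues, no loops
  expect_equal(nrow(reactive_loop_candidates(
    paste(rep("A", 20), collapse = ""))), 0)
})

test_that("reported distances obey the triangle inequality", {
  m <- gen_toy_complex(data.frame(
    donor_resname = c("LYS", "HIS"), donor_atom = c("NZ", "ND1"),
    acceptor_resname = c("SER", "GLU"), acceptor_atom = c("OG", "OE1"),
    distance = c(3, 7)))
  refs <- list("A/1/NZ", "B/1/OG", "A/2/ND1", "B/2/OE1")
  for (i in 1:3) for (j in (i + 1):4) for (k in seq_along(refs)) {
    if (k == i || k == j) next
    dij <- measure_distance(m, refs[[i]], refs[[j]])
    expect_lte(dij, measure_distance(m, refs[[i]], refs[[k]]) +
                    measure_distance(m, refs[[k]], refs[[j]]) + 1e-9)
  }
})
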