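test_that("synthetic PDB fixtures round-trip through the loader", {
  res <- synth_complex(data.frame(kind = "hbond", distance = 3.0,
                                  angle = 160, residue_name = "ALA"))
  cx <- load_complex(res$path, list(resid = "LIG"))
  expect_s3_class(cx, "lig_complex")
  expect_gt(nrow(cx$ligand), 0)
  # coordinates agree to the PDB format's fixed precision
  expect_equal(cx$ligand$x, round(res$complex$ligand$x, 3))
  expect_equal(cx$protein$z, round(res$complex$protein$z, 3))
})

test_that("ligand selector must match exactly one non-water group", {
  res <- synth_complex()
  expect_error(load_complex(res$path, list(resid = "XYZ")),
               "candidates")
  # waters are excluded, so a water selector finds nothing
  lines <- readLines(res$path)
  hoh <- "HETATM 9999  O   HOH A 950      10.000  10.000  10.000  1.00 20.00           O"
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[lines != "END"], hoh, "END"), f)
  expect_error(load_complex(f, list(resid = "HOH")), "candidates")
  # and the real ligand still loads with the water present
  expect_no_error(load_complex(f, list(resid = "LIG")))
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60 11.00           N",
    "ATOM      3  CA  ALA A   1       2.000   0.000   0.000  1.00 12.00           C",
    "HETATM    4  C1  LIG A  90      10.000   0.000   0.000  1.00 20.00           C",
    "END"), f)
  cx <- load_complex(f, list(resid = "LIG"))
  n_rows <- cx$protein[cx$protein$elety == "N", ]
  expect_equal(nrow(n_rows), 1)
  expect_equal(n_rows$x, 1.0)  # the 0.60-occupancy B copy
})

test_that("planted hydrogen bonds are classified by distance and angle", {
  # near-linear N-H...O at 3.14 A: strong
  r1 <- synth_complex(data.frame(kind = "hbond", distance = 3.14,
                                 angle = 165, residue_name = "ASN"))
  hb1 <- detect_hbonds(r1$complex)
  expect_equal(nrow(hb1), 1)
  expect_equal(hb1$strength_class, "strong")
  expect_equal(hb1$distance, 3.14, tolerance = 1e-9)
  expect_equal(hb1$angle, 165, tolerance = 1e-6)
  expect_equal(hb1$residue, "Asn2")

  # long, highly non-linear O-H...O at 3.81 A / 102.05 deg: weak only
  r2 <- synth_complex(data.frame(kind = "hbond", distance = 3.81,
                                 angle = 102.05, residue_name = "ASN",
                                 element = "O"))
  hb2 <- detect_hbonds(r2$complex)
  expect_equal(nrow(hb2), 1)
  expect_equal(hb2$strength_class, "weak")
  expect_equal(hb2$angle, 102.05, tolerance = 1e-6)

  # beyond every cutoff: nothing
  r3 <- synth_complex(data.frame(kind = "hbond", distance = 6.0,
                                 angle = 165, residue_name = "ASN"))
  expect_equal(nrow(detect_hbonds(r3$complex)), 0)
})

test_that("halogen bonds require the sigma-hole geometry", {
  r1 <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                 angle = 172.68, residue_name = "VAL"))
  xb <- detect_halogen_bonds(r1$complex)
  expect_equal(nrow(xb), 1)
  expect_equal(xb$distance, 3.0, tolerance = 1e-9)
  expect_equal(xb$angle, 172.68, tolerance = 1e-6)

  r2 <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                 angle = 90, residue_name = "VAL"))
  expect_equal(nrow(detect_halogen_bonds(r2$complex)), 0)

  # fluorine is excluded by default
  r3 <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                 angle = 172, residue_name = "VAL",
                                 element = "F"))
  expect_equal(nrow(detect_halogen_bonds(r3$complex)), 0)
  expect_equal(nrow(detect_halogen_bonds(r3$complex,
                                         halogens = c("F", "Cl", "Br",
                                                      "I"))), 1)
})

test_that("hydrophobic contacts respect apolar typing and the cutoff", {
  r1 <- synth_complex(data.frame(kind = "hydrophobic", distance = 3.9,
                                 angle = NA, residue_name = "LEU"))
  hp <- detect_hydrophobic(r1$complex)
  expect_equal(nrow(hp), 1)
  expect_equal(hp$res_name, "LEU")
  expect_equal(hp$distance, 3.9, tolerance = 1e-9)

  r2 <- synth_complex(data.frame(kind = "hydrophobic", distance = 4.5,
                                 angle = NA, residue_name = "LEU"))
  expect_equal(nrow(detect_hydrophobic(r2$complex)), 0)

  # polarizing the planted carbon (bond an O to it) removes the contact
  cx <- r1$complex
  ci <- which(cx$ligand$elety == "C1")
  o <- cx$ligand[ci, ]
  o$elety <- "OX"; o$element <- "O"; o$x <- o$x + 1.3
  o$eleno <- max(cx$ligand$eleno) + 1
  cx$ligand <- rbind(cx$ligand, o)
  expect_equal(nrow(detect_hydrophobic(cx)), 0)
})

test_that("measure_geometry is pure geometry", {
  res <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                  angle = 172.68, residue_name = "VAL"))
  g <- measure_geometry(res$complex, "ligand:BR1", "protein:2:O")
  expect_equal(g$distance, 3.0, tolerance = 1e-9)
  g2 <- measure_geometry(res$complex, "ligand:C1", "ligand:BR1",
                         "protein:2:O")
  expect_equal(g2$angle, 172.68, tolerance = 1e-6)
  expect_error(measure_geometry(res$complex, "ligand:NOPE",
                                "protein:2:O"), "not found")

  # unit-separated synthetic pair and a collinear triple
  cx <- res$complex
  cx$ligand <- data.frame(eleno = 1:3, elety = c("C1", "C2", "C3"),
                          element = "C", resid = "LIG", chain = "A",
                          resno = 900, insert = "",
                          x = c(0, 1, 2), y = 0, z = 0, o = 1, b = 0,
                          stringsAsFactors = FALSE)
  expect_equal(measure_geometry(cx, "ligand:C1", "ligand:C2")$distance, 1)
  expect_equal(measure_geometry(cx, "ligand:C1", "ligand:C2",
                                "ligand:C3")$angle, 180)
})

test_that("boundary plants at cutoff +/- 1e-3 flip detection", {
  eps <- 1e-3
  # hydrophobic distance boundary (4.0)
  inb <- synth_complex(data.frame(kind = "hydrophobic",
                                  distance = 4.0 - eps, angle = NA,
                                  residue_name = "LEU"))
  out <- synth_complex(data.frame(kind = "hydrophobic",
                                  distance = 4.0 + eps, angle = NA,
                                  residue_name = "LEU"))
  expect_equal(nrow(detect_hydrophobic(inb$complex)), 1)
  expect_equal(nrow(detect_hydrophobic(out$complex)), 0)
  # halogen distance boundary (3.8) and angle boundary (140)
  ind <- synth_complex(data.frame(kind = "halogen_bond",
                                  distance = 3.8 - eps, angle = 170,
                                  residue_name = "VAL"))
  outd <- synth_complex(data.frame(kind = "halogen_bond",
                                   distance = 3.8 + eps, angle = 170,
                                   residue_name = "VAL"))
  expect_equal(nrow(detect_halogen_bonds(ind$complex)), 1)
  expect_equal(nrow(detect_halogen_bonds(outd$complex)), 0)
  ina <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                  angle = 140 + 1e-3,
                                  residue_name = "VAL"))
  outa <- synth_complex(data.frame(kind = "halogen_bond", distance = 3.0,
                                   angle = 140 - 1e-3,
                                   residue_name = "VAL"))
  expect_equal(nrow(detect_halogen_bonds(ina$complex)), 1)
  expect_equal(nrow(detect_halogen_bonds(outa$complex)), 0)
  # hbond strong/weak distance boundary (3.6) and weak envelope (4.1)
  s <- synth_complex(data.frame(kind = "hbond", distance = 3.6 - eps,
                                angle = 150, residue_name = "ASN"))
  w <- synth_complex(data.frame(kind = "hbond", distance = 3.6 + eps,
                                angle = 150, residue_name = "ASN"))
  n <- synth_complex(data.frame(kind = "hbond", distance = 4.1 + eps,
                                angle = 150, residue_name = "ASN"))
  expect_equal(detect_hbonds(s$complex)$strength_class, "strong")
  expect_equal(detect_hbonds(w$complex)$strength_class, "weak")
  expect_equal(nrow(detect_hbonds(n$complex)), 0)
})

test_that("grid neighbour search matches the all-pairs oracle", {
  set.seed(7)
  for (rep in 1:5) {
    a <- matrix(runif(60, -20, 20), ncol = 3)
    b <- matrix(runif(1500, -20, 20), ncol = 3)
    cutoff <- runif(1, 2, 6)
    got <- ligandscape:::grid_pairs(a, b, cutoff)
    want <- brute_pairs(a, b, cutoff)
    key <- function(df) sort(paste(df$i, df$j))
    expect_identical(key(got), key(want))
  }
})

test_that("detection is invariant under rigid motion", {
  plants <- data.frame(kind = c("hbond", "halogen_bond", "hydrophobic"),
                       distance = c(3.14, 3.0, 3.9),
                       angle = c(165, 172.68, NA),
                       residue_name = c("ASN", "VAL", "LEU"))
  cx <- synth_complex(plants)$complex
  before <- detect_contacts(cx)
  set.seed(11)
  rot <- rotation_matrix(runif(1, 0, pi), runif(1, 0, pi),
                         runif(1, 0, pi))
  after <- detect_contacts(transform_complex(cx, rot, c(5, -3, 12)))
  expect_equal(nrow(after), nrow(before))
  expect_equal(after$distance, before$distance, tolerance = 1e-6)
  expect_equal(after$angle, before$angle, tolerance = 1e-6)
  expect_equal(after$residue, before$residue)
})

test_that("contacts collapse into binding fingerprints", {
  contacts <- data.frame(
    kind = "hydrophobic",
    ligand_atom = c("A/LIG900/C1", "A/LIG900/C2", "A/LIG900/C3"),
    partner_atom = c("A/VAL66/CG1", "A/VAL66/CG2", "A/ILE174/CD1"),
    res_name = c("VAL", "VAL", "ILE"), res_no = c(66, 66, 174),
    chain = "A", residue = c("Val66", "Val66", "Ile174"),
    distance = c(3.5, 3.8, 3.9), angle = NA_real_,
    strength_class = "strong", angle_basis = "explicit_h",
    stringsAsFactors = FALSE)
  fp <- contacts_to_fingerprint(contacts, "residue", "count")
  expect_equal(fp$entries[["Val66"]], 2)
  expect_equal(fp$entries[["Ile174"]], 1)

  fp0 <- contacts_to_fingerprint(contacts[0, ])
  expect_length(fp0$entries, 0)

  dw <- contacts
  dw$distance <- 2.0
  dw$residue <- "Val66"
  dw <- dw[1:2, ]
  fpw <- contacts_to_fingerprint(dw, "residue", "distance_weight")
  expect_equal(unname(fpw$entries), 1.0)  # 1/2 + 1/2
})

test_that("contact reports serialize to TSV and JSON", {
  res <- synth_complex(data.frame(kind = "hbond", distance = 3.1,
                                  angle = 160, residue_name = "ASN"))
  contacts <- detect_hbonds(res$complex)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(contacts, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(contacts))
  expect_equal(back$distance, contacts$distance, tolerance = 1e-6)
  js <- withr::local_tempfile(fileext = ".json")
  write_contacts(contacts, js)
  expect_equal(jsonlite::read_json(js)[[1]]$residue, "Asn2")
})
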