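test_that("fingerprint alignment fills missing keys with zero", {
  al <- align_fingerprints(binding_fingerprint(c(A = 1)),
                           binding_fingerprint(c(B = 2)))
  expect_equal(al$keys, c("A", "B"))
  expect_equal(al$P, c(1, 0))
  expect_equal(al$Q, c(0, 2))

  same <- align_fingerprints(binding_fingerprint(c(B = 2, A = 1)),
                             binding_fingerprint(c(A = 3, B = 4)))
  expect_equal(same$P, c(1, 2))
  expect_equal(same$Q, c(3, 4))

  both <- align_fingerprints(binding_fingerprint(numeric(0)),
                             binding_fingerprint(numeric(0)))
  expect_length(both$P, 0)
  expect_length(both$keys, 0)
})

test_that("rmsd_bm evaluates the root-mean-square mode deviation", {
  p <- binding_fingerprint(c(A = 1, B = 2, C = 3))
  expect_equal(rmsd_bm(p, p), 0)
  q <- binding_fingerprint(c(A = 4, B = 2, C = 3))
  expect_equal(rmsd_bm(p, q), sqrt(3))       # sqrt(9/3), hand evaluation
  expect_equal(rmsd_bm(q, p), rmsd_bm(p, q)) # symmetric
  expect_equal(rmsd_bm(binding_fingerprint(c(K = -5)),
                       binding_fingerprint(c(K = -7))), 2)
  expect_error(rmsd_bm(binding_fingerprint(numeric(0)),
                       binding_fingerprint(numeric(0))),
               "no interactions")
})

test_that("mode distances match hand-computed values", {
  p <- binding_fingerprint(c(a = 1, b = -2))
  q <- binding_fingerprint(c(a = 0, b = 0))
  expect_equal(mode_distance(p, q, "manhattan"), 3)
  expect_equal(mode_distance(p, q, "euclidean"), sqrt(5))
  expect_equal(mode_distance(p, q, "additive"), -1)
  expect_error(mode_distance(p, q, "chebyshev"))
})

test_that("rmsd_bm equals euclidean / sqrt(n) on random fingerprints", {
  set.seed(101)
  for (rep in 1:30) {
    p <- random_fp(sample(2:8, 1))
    q <- random_fp(sample(2:8, 1))
    n <- length(union(names(p$entries), names(q$entries)))
    expect_equal(rmsd_bm(p, q),
                 mode_distance(p, q, "euclidean") / sqrt(n),
                 tolerance = 1e-12)
  }
})

test_that("metric axioms hold for manhattan and euclidean; additive is
           antisymmetric and bounded by manhattan", {
  set.seed(202)
  for (rep in 1:30) {
    p <- random_fp(); q <- random_fp(); r <- random_fp()
    for (m in c("manhattan", "euclidean")) {
      expect_equal(mode_distance(p, q, m), mode_distance(q, p, m))
      expect_equal(mode_distance(p, p, m), 0)
      expect_lte(mode_distance(p, r, m),
                 mode_distance(p, q, m) + mode_distance(q, r, m) + 1e-9)
    }
    expect_equal(mode_distance(p, q, "additive"),
                 -mode_distance(q, p, "additive"))
    expect_lte(abs(mode_distance(p, q, "additive")),
               mode_distance(p, q, "manhattan") + 1e-12)
  }
})

test_that("keys rank by mean magnitude with lexicographic ties", {
  fp <- binding_fingerprint(c(Met163 = -9, Leu45 = -7))
  expect_equal(rank_keys(list(fp)), c("Met163", "Leu45"))

  tie <- list(binding_fingerprint(c(B = -4, A = 2)),
              binding_fingerprint(c(B = 2, A = -4)))
  expect_equal(rank_keys(tie), c("A", "B"))  # equal means: lexicographic

  set.seed(303)
  fps <- lapply(1:5, function(i) {
    e <- setNames(runif(4, -3, 0), c("Val66", "Ile174", "His115",
                                     "Lys68"))
    e["Met163"] <- -20  # dominates every ligand
    binding_fingerprint(e, ligand_id = paste0("l", i))
  })
  expect_equal(rank_keys(fps)[1], "Met163")
  # sorting oracle over the mean |strength| matrix
  keys <- sort(unique(unlist(lapply(fps, function(f) names(f$entries)))))
  mm <- sapply(fps, function(f) abs(f$entries[keys]))
  expect_equal(rank_keys(fps), keys[order(-rowMeans(mm), keys)])
})

test_that("packaged energy tables ingest with the printed row counts", {
  ck2a <- load_packaged_tables("ck2a")
  pim1 <- load_packaged_tables("pim1")
  rio1 <- load_packaged_tables("rio1")
  expect_equal(nrow(ck2a), 40)
  expect_equal(nrow(pim1), 10)
  expect_equal(nrow(rio1), 10)
  expect_setequal(unique(ck2a$series),
                  c("none", "ribose", "deoxyribose", "difluoro"))
  # spot values from the printed tables
  expect_equal(pim1$hbond[pim1$ligand == "4,5,6,7-tetrabromo-"], -4.00)
  expect_equal(ck2a$binding_affinity[ck2a$id == "4567-tetraI_difluoro"],
               -9.59)
})

test_that("energy table ingestion validates schema and cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ligand,e_protein_ligand,e_total,steric,vdw,hbond",
               "x,-1,-2,-3,-4,-5"), f)
  expect_error(ingest_energy_table(f), "binding affinity")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0("ligand,e_protein_ligand,e_total,steric,vdw,",
                      "hbond,binding_affinity"),
               "x,-1,-2,-3,-4,-5,oops"), g)
  expect_error(ingest_energy_table(g), "row 1")

  # Unicode minus signs parse as negatives
  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0("Glycone,Ligand,E_protein-ligand,E_total,Steric,",
                      "van der Waals,Hydrogen Bond,Binding Affinity"),
               "ribose,\"5,6-dibromo-\",−71.53,−69.37,-69.68,-19.98,-1.85,−7.16"),
             h)
  tab <- ingest_energy_table(h)
  expect_equal(tab$e_protein_ligand, -71.53)
  expect_equal(tab$binding_affinity, -7.16)
  expect_equal(tab$id, "56-diBr_ribose")
  expect_equal(tab$series, "ribose")
})

test_that("series extrema recover the printed optima", {
  ck2a <- load_packaged_tables("ck2a")
  best <- series_extremum(ck2a, series = "difluoro",
                          field = "binding_affinity", mode = "min")
  expect_equal(best$ligand, "4567-tetraI_difluoro")
  expect_equal(best$value, -9.59)

  rio1 <- load_packaged_tables("rio1")
  best_r <- series_extremum(rio1, field = "binding_affinity",
                            mode = "min")
  expect_equal(best_r$name, "4,5,6,7-tetrabromo-")
  expect_equal(best_r$value, -9.45)

  one <- ck2a[1, ]
  expect_equal(series_extremum(one, mode = "min")$value,
               series_extremum(one, mode = "max")$value)
  expect_error(series_extremum(ck2a, series = "nope"), "no records")
})

test_that("heatmaps reproduce ingested energies exactly and normalize", {
  ck2a <- load_packaged_tables("ck2a")
  hm <- build_heatmap(ck2a)
  expect_equal(dim(hm), c(4, 40))
  expect_equal(unname(unclass(hm)["steric", "4567-tetraBr_none"]), -66.69)
  expect_equal(unname(unclass(hm)["hbond", "56-diI-47-diCl_ribose"]),
               -4.86)
  expect_equal(as.numeric(unclass(hm)[, ck2a$id[7]]),
               as.numeric(ck2a[7, c("e_protein_ligand", "steric", "vdw",
                                    "hbond")]))

  single <- build_heatmap(list(binding_fingerprint(c(Val66 = -3,
                                                     Leu45 = -1),
                                                   ligand_id = "x")))
  expect_equal(dim(single), c(2, 1))

  pr <- build_heatmap(ck2a, normalization = "per_row")
  expect_true(all(abs(apply(abs(unclass(pr)), 1, max) - 1) < 1e-12))
})

test_that("heatmap CSV round trip is bit-exact", {
  ck2a <- load_packaged_tables("ck2a")
  hm <- build_heatmap(ck2a, normalization = "per_row")
  f <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(hm, f)
  back <- read_heatmap_csv(f, normalization = "per_row")
  expect_identical(unname(unclass(back)), unname(unclass(hm)))
  expect_equal(dimnames(back), dimnames(hm))
})

test_that("heatmap construction rejects ragged input", {
  expect_error(build_heatmap(data.frame(id = "x", steric = 1)),
               "lacks column")
})
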