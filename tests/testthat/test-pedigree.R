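test_that("pedigree files load, reorder, and reject cycles", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "A,,", "B,0,", "C,A,B"), path)
  ped <- load_pedigree(path)
  expect_s3_class(ped, "pedigree_table")
  expect_equal(nrow(ped), 3L)
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 2L)  # two founders

  # offspring listed before its parents: same table after reordering
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "C,A,B", "A,,", "B,,"), path2)
  ped2 <- load_pedigree(path2)
  expect_equal(ped2[order(ped2$animal), ], ped[order(ped$animal), ],
               ignore_attr = TRUE)

  # cycle A -> C -> A
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "A,C,", "C,A,"), path3)
  expect_error(load_pedigree(path3), "cycle")

  # undefined parent: dialect chooses error or founder insertion
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "A,Z,"), path4)
  expect_error(load_pedigree(path4, on_missing_parent = "error"), "never defined")
  expect_equal(nrow(load_pedigree(path4, on_missing_parent = "insert")), 2L)

  # round-trip through the writer
  out <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, out)
  expect_equal(load_pedigree(out), ped, ignore_attr = TRUE)
})

test_that("inbreeding matches closed forms and the tabular oracle", {
  # full-sib mating: F = 0.25
  f <- inbreeding_coefficients(fullsib_ped())
  expect_equal(unname(f[["E"]]), 0.25)
  expect_equal(unname(f[c("A", "B", "C", "D")]), rep(0, 4))

  # parent-offspring mating: F = 0.25
  po <- pedigree_table(c("A", "B", "C", "D"), c(NA, NA, "A", "A"),
                       c(NA, NA, "B", "C"))
  expect_equal(unname(inbreeding_coefficients(po)[["D"]]), 0.25)

  # random 200-animal pedigree vs diagonal of the tabular A
  ped <- random_ped(200, seed = 7)
  f <- inbreeding_coefficients(ped)
  A <- relationship_matrix(ped)
  expect_lt(max(abs(unname(f) - (diag(A) - 1))), 1e-12)
})

test_that("relationship matrix has textbook entries and is positive definite", {
  A <- relationship_matrix(trio_ped())
  expect_equal(A["A", "B"], 0)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["C", "C"], 1)
  expect_equal(relationship_matrix(fullsib_ped())["E", "E"], 1.25)

  ped <- random_ped(100, seed = 3)
  ev <- eigen(relationship_matrix(ped), symmetric = TRUE, only.values = TRUE)
  expect_gt(min(ev$values), 0)

  expect_error(relationship_matrix(random_ped(60, seed = 1), max_animals = 50),
               "refused")
})

test_that("sparse A-inverse matches Henderson closed forms and inverts A", {
  Ai <- as.matrix(a_inverse(trio_ped()))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2.0))
  expect_equal(Ai["A", "B"], 0.5)
  expect_equal(Ai["A", "C"], -1.0)
  expect_equal(Ai["B", "C"], -1.0)

  # founders only -> identity
  fo <- pedigree_table(c("A", "B", "C"), c(NA, NA, NA), c(NA, NA, NA))
  expect_equal(as.matrix(a_inverse(fo)), diag(3), ignore_attr = TRUE)

  # product with the tabular A is the identity
  ped <- random_ped(200, seed = 11)
  A <- relationship_matrix(ped)
  Ai <- a_inverse(ped)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(A)))), 1e-8)
})

test_that("pedigree identities hold across random pedigrees", {
  for (seed in 1:5) {
    ped <- random_ped(150, seed = seed)
    f <- inbreeding_coefficients(ped)
    A <- relationship_matrix(ped)
    expect_lt(max(abs(unname(f) - (diag(A) - 1))), 1e-12)
    expect_lt(max(abs(as.matrix(a_inverse(ped, f) %*% A) - diag(nrow(A)))), 1e-8)
  }
})

test_that("adding an unrelated founder changes no existing F or relationship", {
  ped <- random_ped(80, seed = 5)
  A <- relationship_matrix(ped)
  f <- inbreeding_coefficients(ped)
  df <- as.data.frame(ped)
  ped2 <- pedigree_table(c(df$animal, "NEW"), c(df$sire, NA), c(df$dam, NA))
  A2 <- relationship_matrix(ped2)
  f2 <- inbreeding_coefficients(ped2)
  expect_equal(f2[names(f)], f)
  expect_equal(A2[rownames(A), colnames(A)], A)
  expect_equal(unname(A2["NEW", rownames(A)]), rep(0, nrow(A)))
})
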