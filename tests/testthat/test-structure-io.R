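test_that("PDB round trip preserves chains, numbering and coordinates", {
  g <- fx_supercoiled()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_assembly(g$assembly, f)
  back <- read_assembly(f)
  expect_s3_class(back, "hook_assembly")
  expect_length(back, 26L)
  expect_identical(names(back), names(g$assembly))
  for (ch in names(back)) {
    expect_identical(back[[ch]]$resno, g$assembly[[ch]]$resno)
    expect_lt(max(abs(back[[ch]]$ca - g$assembly[[ch]]$ca)), 1e-3)
  }
})

test_that("a minimal single-chain file parses into one subunit", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       7.000   8.000   9.500  1.00  0.00           C",
    "HETATM    4  O   HOH B   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  asm <- read_assembly(f)
  expect_length(asm, 1L)
  expect_identical(asm[["A"]]$resno, 1:3)
  expect_equal(unname(asm[["A"]]$ca[3L, ]), c(7, 8, 9.5))
})

test_that("unparseable and empty inputs raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", f)
  expect_error(read_assembly(f))
  expect_error(read_assembly(tempfile()), "not found")
})

test_that("write_table produces CSV with metadata sidecar and JSON", {
  d <- data.frame(a = 1:3, b = c(1.5, 2.5, 3.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(d, f, "csv", meta = list(units = "Angstrom"))
  expect_identical(utils::read.csv(f)$a, 1:3)
  expect_identical(jsonlite::read_json(paste0(f, ".meta.json"))$units, "Angstrom")
  fj <- withr::local_tempfile(fileext = ".json")
  write_table(d, fj, "json")
  expect_length(jsonlite::read_json(fj), 3L)
})

test_that("domain assignment is a partial partition with the expected ranges", {
  g <- fx_supercoiled()
  sub <- g$assembly[[1L]]
  # FlgE layout on a toy subunit numbered like the hook protein
  toy <- hookjoint:::new_subunit("X", data.frame(
    resno = 1:402, resid = "ALA", elety = "CA",
    x = seq(0, 40.1, by = 0.1), y = 0, z = seq(0, 401) * 0.05))
  asg <- assign_domains(toy, flge_domains())
  expect_identical(asg$D0c, c(1:71, 358:402))
  expect_length(asg$D0c, 116L)
  expect_length(asg$unassigned, 0L)
  expect_identical(sort(c(asg$D0c, asg$D1, asg$D2)), 1:402)

  # empty definition set leaves everything unassigned
  asg0 <- assign_domains(sub, domain_set())
  expect_identical(asg0$unassigned, sub$resno)

  # partition property on the synthetic domain set
  asg2 <- assign_domains(sub, g$truth$domains)
  expect_identical(length(asg2$unassigned) +
                     sum(lengths(asg2[names(g$truth$domains)])),
                   length(sub$resno))
})

test_that("overlapping domain ranges are rejected", {
  expect_error(domain_set(A = c(1, 10), B = c(5, 20)), "overlap")
  expect_error(domain_set(A = c(10, 5)))
})
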