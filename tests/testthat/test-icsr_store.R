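test_that("normalized TSV reader joins detail rows and maps unknown codes", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "database\treport_id\tversion\tsex\tage_group\tweight_band\treporter\tserious\thistory_text",
    "FAERS\tA\t1\tM\t18-64\t50TO100\tHCP\tYES\t",
    "FAERS\tB\t1\tbogus\t\t\t\t\t",
    "FAERS\tC\t2\tF\t65-85\tGT100\tNONHCP\tNO\thistory of glioma"),
    file.path(dir, "reports.tsv"))
  writeLines(c(
    "report_id\tversion\tdrug_seq\tverbatim_name\tgeneric_name\trole",
    "A\t1\t1\tAvastin\tBEVACIZUMAB\tPS",
    "A\t1\t2\tTemodar\tTEMOZOLOMIDE\tC",
    "B\t1\t1\tlomustine\tLOMUSTINE\tSS",
    "C\t2\t1\tGliadel\tCARMUSTINE\tweird"),
    file.path(dir, "drugs.tsv"))
  writeLines(c(
    "report_id\tversion\tpt",
    "A\t1\tDEEP VEIN THROMBOSIS",
    "A\t1\tPULMONARY EMBOLISM",
    "B\t1\tNAUSEA"),
    file.path(dir, "reactions.tsv"))
  writeLines(c(
    "report_id\tversion\tindication_text",
    "A\t1\tGlioblastoma",
    "B\t1\tGlioma",
    "C\t2\tAstrocytoma"),
    file.path(dir, "indications.tsv"))
  paths <- file.path(dir, c("reports.tsv", "drugs.tsv", "reactions.tsv",
                            "indications.tsv"))
  s <- read_normalized(paths[1], paths[2], paths[3], paths[4])

  expect_equal(n_reports(s), 3)
  expect_equal(table(s$drugs$report_id)[["A"]], 2L)
  # unknown codes collapse to UNK; unknown roles to concomitant
  expect_equal(s$reports$sex, c("M", "UNK", "F"))
  expect_equal(s$drugs$role[s$drugs$report_id == "C"], "C")
  # two PTs for one report stay two reaction rows
  expect_equal(sum(s$reactions$report_id == "A"), 2)

  # empty drugs file -> empty drugs table, reports intact
  writeLines("report_id\tversion\tdrug_seq\tverbatim_name\tgeneric_name\trole",
             file.path(dir, "nodrugs.tsv"))
  s2 <- read_normalized(paths[1], file.path(dir, "nodrugs.tsv"), paths[3],
                        paths[4])
  expect_equal(nrow(s2$drugs), 0)
  expect_equal(n_reports(s2), 3)

  # missing required column is a format error naming the column
  writeLines(c("report_id\tversion\tdrug_seq\tverbatim_name\trole",
               "A\t1\t1\tx\tPS"), file.path(dir, "badcol.tsv"))
  expect_error(read_normalized(paths[1], file.path(dir, "badcol.tsv"),
                               paths[3], paths[4]),
               "generic_name")

  # duplicate (report_id, version, drug_seq) is a format error
  writeLines(c("report_id\tversion\tdrug_seq\tverbatim_name\tgeneric_name\trole",
               "A\t1\t1\tx\tX\tPS", "A\t1\t1\ty\tY\tPS"),
             file.path(dir, "dupseq.tsv"))
  expect_error(read_normalized(paths[1], file.path(dir, "dupseq.tsv"),
                               paths[3], paths[4]),
               "duplicate")
})

test_that("deduplication keeps the latest version, is idempotent, warns on ties", {
  s <- quick_set(drugs = list("BEVACIZUMAB", "BEVACIZUMAB", "TEMOZOLOMIDE"),
                 pts = list("NAUSEA", "HEADACHE", "FATIGUE"))
  s$reports$report_id <- c("X", "X", "Y")
  s$reports$version <- c(1L, 3L, 1L)
  s$drugs$report_id <- c("X", "X", "Y"); s$drugs$version <- c(1L, 3L, 1L)
  s$reactions$report_id <- c("X", "X", "Y"); s$reactions$version <- c(1L, 3L, 1L)
  s$indications$report_id <- c("X", "X", "Y"); s$indications$version <- c(1L, 3L, 1L)

  d <- deduplicate(s)
  expect_equal(d$reports$report_id, c("X", "Y"))
  expect_equal(d$reports$version, c(3L, 1L))
  expect_equal(d$reactions$pt, c("HEADACHE", "FATIGUE"))
  expect_identical(deduplicate(d), d)  # idempotent

  # tie on (id, version): last-read record kept, warning emitted
  t <- s
  t$reports$version <- c(2L, 2L, 1L)
  t$reports$sex <- c("M", "F", "UNK")
  expect_warning(dt <- deduplicate(t), "tied versions")
  expect_equal(nrow(dt$reports), 2)
  expect_equal(dt$reports$sex[dt$reports$report_id == "X"], "F")
})

test_that("deduplicated size equals the number of distinct case ids", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    ids <- sprintf("C%02d", sample(1:25, n, replace = TRUE))
    vers <- sample(1:4, n, replace = TRUE)
    keep <- !duplicated(paste(ids, vers))  # avoid tie-warning noise
    ids <- ids[keep]; vers <- vers[keep]
    s <- quick_set(drugs = vector("list", length(ids)),
                   versions = as.integer(vers))
    s$reports$report_id <- ids
    s$indications$report_id <- ids
    d <- deduplicate(s)
    expect_equal(nrow(d$reports), length(unique(ids)))
    expect_identical(deduplicate(d), d)
  }
})

test_that("FAERS dialect round-trips a generated set and maps fields", {
  cfg <- synthetic_config(n_reports = 150, seed = 5, duplicate_prob = 0.1)
  s <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_faers_ascii(s, dir)
  r <- read_faers_ascii(file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
                        file.path(dir, "REAC.txt"), file.path(dir, "INDI.txt"))
  expect_same_reports(s, r)
  expect_equal(r$drugs$generic_name, s$drugs$generic_name)
  expect_equal(r$drugs$role, s$drugs$role)
  expect_equal(r$reactions$pt, s$reactions$pt)
  expect_equal(r$indications$indication_text, s$indications$indication_text)

  # blank sex -> UNK, role_cod I (interacting) -> concomitant
  demo <- c("caseid$caseversion$sex$age$wt$occp_cod", "Z1$1$$44$$MD")
  drug <- c("caseid$caseversion$drugname$prod_ai$role_cod",
            "Z1$1$Avastin$BEVACIZUMAB$I")
  reac <- c("caseid$caseversion$pt", "Z1$1$NAUSEA")
  indi <- c("caseid$caseversion$indi_pt", "Z1$1$Glioma")
  f <- function(x, n) { p <- file.path(dir, n); writeLines(x, p); p }
  m <- read_faers_ascii(f(demo, "D2.txt"), f(drug, "G2.txt"),
                        f(reac, "R2.txt"), f(indi, "I2.txt"))
  expect_equal(m$reports$sex, "UNK")
  expect_equal(m$reports$age_group, "18-64")
  expect_equal(m$reports$reporter, "HCP")
  expect_equal(m$drugs$role, "C")

  # undelimitable line carries its line number
  bad <- c("caseid$caseversion$sex$age$wt$occp_cod", "Z1$1$$44", "Z2$1$M$50$70$MD")
  expect_error(read_faers_ascii(f(bad, "DB.txt"), f(drug, "G2.txt"),
                                f(reac, "R2.txt"), f(indi, "I2.txt")),
               "line 2")
})

test_that("writing a two-case set reproduces the golden FAERS files", {
  dir <- withr::local_tempdir()
  write_faers_ascii(golden_two_case_set(), dir)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "INDI.txt")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(system.file("extdata", "faers_golden", f,
                                           package = "pvsignal")),
                     label = f)
  }
})
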