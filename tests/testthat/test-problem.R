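# Problem-specification dialect: parsing, validation, parameter mapping.

test_that("parsing the viral fixture cross-links all tables", {
  expect_s4_class(viralProblem, "ProblemSpec")
  par <- parameterTable(viralProblem)
  expect_equal(sum(par$estimate), 2)
  expect_setequal(par$parameter_id[par$estimate], c("beta_cf", "beta_cc"))
  expect_equal(nrow(conditionTable(viralProblem)), 1)
  expect_equal(nrow(measurementTable(viralProblem)), 16)
  expect_equal(nrow(statisticTable(viralProblem)), 2)
  expect_length(validateProblem(viralProblem)$code, 0)
})

test_that("a missing required column is a schema error naming table and column", {
  dir <- file.path(tempdir(), "broken-schema")
  makeGaussianToy(dir)
  tab <- read.delim(file.path(dir, "parameters.tsv"), sep = "\t",
                    colClasses = "character", check.names = FALSE)
  tab$prior_kind <- NULL
  write.table(tab, file.path(dir, "parameters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  err <- tryCatch(parseProblem(file.path(dir, "problem.yaml")),
                  problemSchemaError = function(e) e)
  expect_s3_class(err, "problemSchemaError")
  expect_match(conditionMessage(err), "parameter_table: prior_kind")
  expect_equal(err$report$code, "MISSING_COLUMN")
})

test_that("a missing file is an I/O error naming the path", {
  err <- tryCatch(parseProblem(file.path(tempdir(), "nowhere.yaml")),
                  problemIOError = function(e) e)
  expect_s3_class(err, "problemIOError")
  expect_match(conditionMessage(err), "nowhere.yaml")
})

test_that("a dangling condition reference is a link error naming the id", {
  dir <- file.path(tempdir(), "broken-link")
  makeGaussianToy(dir)
  tab <- read.delim(file.path(dir, "measurements.tsv"), sep = "\t",
                    colClasses = "character", check.names = FALSE)
  tab$condition_id[1] <- "c99"
  write.table(tab, file.path(dir, "measurements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  err <- tryCatch(parseProblem(file.path(dir, "problem.yaml")),
                  problemLinkError = function(e) e)
  expect_s3_class(err, "problemLinkError")
  expect_match(conditionMessage(err), "c99")
  # non-strict parsing defers the same defect to the validator
  rep <- validateProblem(parseProblem(file.path(dir, "problem.yaml"),
                                      strict = FALSE))
  expect_equal(rep$code, "DANGLING_CONDITION")
})

test_that("validator flags inverted and non-positive prior bounds", {
  prob <- toyProblem
  par <- prob@parameters
  par$prior_kind[1] <- "uniform"
  par$prior_arg1[1] <- 2
  par$prior_arg2[1] <- 1
  prob@parameters <- par
  rep <- validateProblem(prob)
  expect_equal(rep$code, "PRIOR_BOUNDS")

  par$prior_kind[1] <- "log10-uniform"
  par$scale[1] <- "log10"
  par$prior_arg1[1] <- 0
  par$prior_arg2[1] <- 100
  prob@parameters <- par
  rep <- validateProblem(prob)
  expect_equal(rep$code, "PRIOR_POSITIVITY")
})

test_that("sampleSpace reports bounds on the sampling scale, estimated rows only", {
  prob <- toyProblem
  par <- prob@parameters
  par$prior_kind[1] <- "uniform"
  par$prior_arg1[1] <- 0.1
  par$prior_arg2[1] <- 10
  prob@parameters <- par
  sp <- sampleSpace(prob)
  expect_equal(nrow(sp), 1)  # estimate = FALSE rows excluded
  expect_equal(sp$lower, 0.1)
  expect_equal(sp$upper, 10)
  expect_equal(sp$scale, "lin")

  par$prior_kind[1] <- "log10-uniform"
  par$scale[1] <- "log10"
  par$prior_arg1[1] <- 1e-3
  par$prior_arg2[1] <- 1e3
  prob@parameters <- par
  sp <- sampleSpace(prob)
  expect_equal(sp$lower, -3)
  expect_equal(sp$upper, 3)
  expect_equal(sp$scale, "log10")
})

test_that("mapParameters writes values, back-transforms log10 scale, and is pure", {
  doc <- mapParameters(toyProblem, c(0.3))
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(doc, "//Param[@name='theta']"), "value"), "0.3")

  doc <- mapParameters(viralProblem, c(-2, -1))
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(doc, "//Param[@name='beta_cf']"), "value"), "0.01")
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(doc, "//Param[@name='beta_cc']"), "value"), "0.1")

  before <- as.character(modelDocument(viralProblem))
  d1 <- as.character(mapParameters(viralProblem, c(-1.5, -0.5)))
  d2 <- as.character(mapParameters(viralProblem, c(-1.5, -0.5)))
  expect_identical(d1, d2)                                    # deterministic
  expect_identical(as.character(modelDocument(viralProblem)), before)  # pure
})

test_that("mapParameters rejects wrong arity and unknown conditions", {
  expect_error(mapParameters(toyProblem, c(1, 2)), "one entry per")
  expect_error(mapParameters(toyProblem, 1, conditionId = "cX"),
               "unknown condition")
})

test_that("write-parse round trip preserves the problem", {
  dir <- file.path(tempdir(), "roundtrip")
  writeProblem(viralProblem, dir)
  again <- parseProblem(file.path(dir, "problem.yaml"))
  expect_true(tissueABC:::problemsEqual(viralProblem, again))
  # and once more through a second cycle
  dir2 <- file.path(tempdir(), "roundtrip2")
  writeProblem(again, dir2)
  expect_true(tissueABC:::problemsEqual(
    again, parseProblem(file.path(dir2, "problem.yaml"))))
})

test_that("condition overrides are applied before parameter mapping", {
  prob <- viralProblem
  con <- prob@conditions
  con[["Param[@name='p_prod']/@value"]] <- "2.5"
  prob@conditions <- con
  doc <- mapParameters(prob, c(-2, -1), conditionId = "c0")
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(doc, "//Param[@name='p_prod']"), "value"), "2.5")
})

test_that("gridded-array references are read and validated", {
  dir <- file.path(tempdir(), "gridref")
  makeGaussianToy(dir)
  m <- matrix(1:6 / 7, 2, 3)
  write.table(m, file.path(dir, "obs.csv"), sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tab <- read.delim(file.path(dir, "measurements.tsv"), sep = "\t",
                    colClasses = "character", check.names = FALSE)
  tab <- rbind(tab, data.frame(observable_id = "grid", condition_id = "c0",
                               time = "0", value = "", data_ref = "obs.csv",
                               replicate_id = ""))
  write.table(tab, file.path(dir, "measurements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prob <- parseProblem(file.path(dir, "problem.yaml"))
  expect_length(validateProblem(prob)$code, 0)
  expect_equal(readGriddedArray(prob, "obs.csv"), unname(m),
               ignore_attr = TRUE)
  # a row with both value and data_ref violates the exactly-one rule
  prob@measurements$value[2] <- 1
  expect_equal(validateProblem(prob)$code, "MEASUREMENT_VALUE_XOR")
})
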