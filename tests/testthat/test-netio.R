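test_that("build_network preserves records while collapsing the simple graph", {
  # path graph
  db <- structure(list(
    ages = character(0), receptors = data.frame(), references = character(0),
    interactions = data.frame(source = c("A", "B"), target = c("B", "C"),
                              stringsAsFactors = FALSE)
  ), class = "curated_database")
  net <- build_network(db)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$records), 2)
  expect_setequal(net$adj[["B"]], c("A", "C"))

  # duplicate edge + self-loop: kept in records, absent from adjacency
  db$interactions <- data.frame(source = c("A", "A", "C"), target = c("B", "B", "C"),
                                stringsAsFactors = FALSE)
  net <- build_network(db)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$records), 3)
  expect_equal(net$adj[["A"]], "B")
  expect_equal(net$adj[["C"]], character(0))
  expect_lte(sum(lengths(net$adj)) / 2, nrow(net$records))
})

test_that("node identifiers are trimmed but compared case-sensitively", {
  net <- molecular_network(data.frame(source = c(" CML", "cml"),
                                      target = c("RAGE ", "RAGE"),
                                      stringsAsFactors = FALSE))
  expect_setequal(net$nodes, c("CML", "cml", "RAGE"))
  expect_setequal(net$adj[["RAGE"]], c("CML", "cml"))
})

test_that("CSV/TSV edge lists are read with header sniffing and SIF-order fallback", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,interaction_type",
               "AGE,RAGE,binds", "AGE,TRPV1,activates", "CML,RAGE,binds"), f)
  db <- suppressMessages(read_database(f))
  expect_s3_class(db, "curated_database")
  expect_equal(nrow(db$interactions), 3)
  expect_equal(db$interactions$interaction_type[2], "activates")
  expect_length(db$ages, 0)
  expect_equal(nrow(db$receptors), 0)

  # headerless: first three columns in SIF order (source, type, target)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AGE\tbinds\tRAGE", "AGE\tactivates\tTRPV1"), f2)
  db2 <- suppressMessages(read_database(f2))
  expect_equal(db2$interactions$target, c("RAGE", "TRPV1"))
  expect_equal(db2$interactions$interaction_type, c("binds", "activates"))
})

test_that("empty interaction input is a schema error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("source,target,interaction_type", f)
  expect_error(suppressMessages(read_database(f)), "schema error")
  expect_error(read_database(withr::local_tempfile()), "not found")
})

test_that("workbook dialect parses the curated sheet layout", {
  # synthesize a workbook in the curated-database layout (sheets: ages,
  # receptors, AGE-TRPV1, analysis, reference) at test time
  f <- withr::local_tempfile(fileext = ".xlsx")
  py <- sprintf('
import openpyxl
wb = openpyxl.Workbook()
ws = wb.active; ws.title = "ages"
ws.append(["identifier"]); [ws.append([x]) for x in ["CML", "pentosidine", "MG-H1"]]
ws = wb.create_sheet("receptors")
ws.append(["identifier", "class"])
ws.append(["RAGE", "immunoglobulin"]); ws.append(["SR-A", "scavenger"])
ws = wb.create_sheet("AGE-TRPV1")
ws.append(["source", "interaction_type", "target", "provenance"])
for row in [["CML", "binds", "RAGE", "PMID:1"], ["CML", "activates", "TRPV1", "PMID:2"],
            ["pentosidine", "binds", "SR-A", "PMID:3"]]:
    ws.append(row)
ws = wb.create_sheet("analysis"); ws.append(["nodes", 5])
ws = wb.create_sheet("reference"); ws.append(["citation"]); ws.append(["PMID:1"])
ws = wb.create_sheet("scratchpad"); ws.append(["ignored"])
wb.save("%s")
', f)
  status <- suppressWarnings(system2("python", "-", input = py, stderr = FALSE))
  skip_if(status != 0, "no python/openpyxl available to synthesize a workbook")

  expect_warning(db <- suppressMessages(read_database(f)), "scratchpad")
  expect_equal(db$ages, c("CML", "pentosidine", "MG-H1"))
  expect_equal(db$receptors$identifier, c("RAGE", "SR-A"))
  expect_equal(nrow(db$interactions), 3)
  expect_equal(db$interactions$target, c("RAGE", "TRPV1", "SR-A"))
  expect_equal(db$interactions$provenance, c("PMID:1", "PMID:2", "PMID:3"))
  expect_equal(db$references, "PMID:1")
  net <- build_network(db)
  expect_setequal(net$adj[["CML"]], c("RAGE", "TRPV1"))
})

test_that("SIF round-trips preserve nodes and simple adjacency", {
  withr::local_seed(42)
  for (i in 1:10) {
    net <- random_connected_net()
    f <- withr::local_tempfile(fileext = ".sif")
    write_sif(net, f)
    back <- read_sif(f)
    expect_setequal(back$nodes, net$nodes)
    expect_equal(back$adj[sort(names(back$adj))], net$adj[sort(names(net$adj))])
  }
  # isolated nodes survive as single-field lines
  net <- molecular_network(data.frame(source = "a", target = "b"), nodes = "z")
  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, f)
  expect_setequal(read_sif(f)$nodes, c("a", "b", "z"))
})

test_that("malformed SIF lines are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a\tbinds\tb", "c\tbinds"), f)
  expect_error(read_sif(f), "line 2")
})

test_that("GraphML export contains one node element per node", {
  net <- generate_afirnet_like(1)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  doc <- xml2::read_xml(f)
  n_nodes <- length(xml2::xml_find_all(doc, "//*[local-name() = 'node']"))
  expect_equal(n_nodes, 145)
})
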