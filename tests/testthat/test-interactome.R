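test_that("biogrid-style parsing maps vocabulary and keeps only bait rows", {
  path <- writeBiogridFixture()
  expect_message(rec <- parseBiogridExport(path, bait = "INSR"),
                 "dropped 7 row")
  expect_equal(nrow(rec), 3L)            # hand count: 3 bait-incident rows
  expect_setequal(rec$partnerId, c("IRS1", "SHC1", "GRB10"))
  expect_equal(rec$experimentType[rec$partnerId == "IRS1"],
               "yeast-two-hybrid")
  expect_equal(rec$throughput[rec$partnerId == "IRS1"], "low")
  expect_equal(rec$experimentType[rec$partnerId == "GRB10"],
               "crystal-structure-reconstituted-complex")
  expect_true(all(rec$partnerId != "INSR"))
})

test_that("biogrid parsing fails usefully on malformed input", {
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(x = 1, y = 2), bad, sep = "\t",
                     row.names = FALSE)
  expect_error(parseBiogridExport(bad), "interactor A symbol")

  empty <- tempfile(fileext = ".tsv")
  writeLines("Official Symbol Interactor A\tOfficial Symbol Interactor B\tExperimental System\tThroughput",
             empty)
  expect_warning(rec <- parseBiogridExport(empty), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("string-style parsing normalises scores and deduplicates on max", {
  path <- writeStringFixture()
  rec <- parseStringExport(path, bait = "INSR")
  expect_setequal(rec$partnerId, c("IGF1R", "CAV1", "IRS1"))
  expect_equal(rec$combinedScore[rec$partnerId == "IGF1R"], 0.999)
  # duplicate (INSR, CAV1) rows at 420 and 615: max kept
  expect_equal(rec$combinedScore[rec$partnerId == "CAV1"], 0.615)

  unit <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(protein1 = "INSR", protein2 = "IRS1",
                                combined_score = "0.42"),
                     unit, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(parseStringExport(unit)$combinedScore, 0.42)

  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(protein1 = c("INSR", "INSR"),
                                protein2 = c("IRS1", "CAV1"),
                                combined_score = c("900", "n/a")),
                     bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseStringExport(bad), "line 2")
})

test_that("merge takes the union of partners and flags string-only ones", {
  bg <- data.frame(partnerId = c("IRS1", "IRS1"),
                   experimentType = c("yeast-two-hybrid", "affinity-capture-MS"),
                   throughput = c("low", "high"),
                   sourceDb = "biogrid-style", stringsAsFactors = FALSE)
  st <- data.frame(partnerId = c("IRS1", "CAV1"),
                   combinedScore = c(0.95, 0.6), stringsAsFactors = FALSE)
  merged <- mergeNetworks(bg, st)
  expect_setequal(unique(merged$partnerId), c("IRS1", "CAV1"))
  expect_equal(sum(merged$partnerId == "IRS1"), 2L)   # no synthetic record added
  cav <- merged[merged$partnerId == "CAV1", ]
  expect_equal(cav$experimentType, "other")
  expect_equal(cav$sourceDb, "string-style")
  expect_equal(attr(merged, "stringOnly"), "CAV1")
  expect_equal(unname(attr(merged, "stringScore")["IRS1"]), 0.95)

  emptyB <- bg[0, ]; emptyS <- st[0, ]
  expect_equal(nrow(mergeNetworks(emptyB, emptyS)), 0L)
})

test_that("evidence scoring respects the printed band ranges", {
  one <- scoreInteraction("yeast-two-hybrid")
  expect_equal(one$band, "low")
  expect_lte(one$score, 0.3)
  expect_gte(one$score, 0.1)

  two <- scoreInteraction(c("affinity-capture-MS", "kinase-activity"))
  expect_equal(two$band, "medium")
  expect_gte(two$score, 0.4)
  expect_lte(two$score, 0.6)

  five <- scoreInteraction(c("affinity-capture-MS", "yeast-two-hybrid",
                             "affinity-capture-immunoblot", "kinase-activity",
                             "crystal-structure-reconstituted-complex"))
  expect_equal(five$band, "high")
  expect_gte(five$score, 0.7)

  expect_error(scoreInteraction(character(0)), "evidence")

  stringOnly <- data.frame(experimentType = "other",
                           sourceDb = "string-style")
  expect_equal(scoreInteraction(stringOnly)$score, 0.1)
})

test_that("scores stay inside bands and never decrease with more evidence", {
  ranges <- list(low = c(0.1, 0.3), medium = c(0.4, 0.6), high = c(0.7, 0.9))
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:14, 1)
    ev <- sample(apmsTimeCourse:::.EXPERIMENT_TYPES, n, replace = TRUE)
    sc <- scoreInteraction(ev)
    expectedBand <- if (n == 1) "low" else if (n <= 3) "medium" else "high"
    expect_equal(sc$band, expectedBand)
    expect_gte(sc$score, ranges[[sc$band]][1])
    expect_lte(sc$score, ranges[[sc$band]][2])
    extra <- sample(apmsTimeCourse:::.EXPERIMENT_TYPES, 1)
    expect_gte(scoreInteraction(c(ev, extra))$score, sc$score)
  }
})

test_that("spoke network assigns rings from bands and stays bait-centred", {
  scored <- data.frame(
    partnerId = c("AAA", "BBB", "CCC"),
    score = c(0.8, 0.5, 0.2), band = c("high", "medium", "low"),
    nodeSize = c(5L, 2L, 1L), throughputBorder = c("low", "high", "low"),
    stringsAsFactors = FALSE)
  net <- buildSpokeNetwork(scored, "INSR")
  nd <- as.data.frame(interactomeNodes(net))
  expect_equal(nd$ring[match(c("AAA", "BBB", "CCC"), nd$partnerId)],
               c(1L, 2L, 3L))
  expect_error(buildSpokeNetwork(rbind(scored, scored[1, ]), "INSR"),
               "duplicate")
  single <- buildSpokeNetwork(scored[1, ], "INSR")
  expect_equal(length(single), 1L)
})

test_that("a full fixture interactome is bait-incident and deterministic", {
  fix <- simulateInteractomeFixture(20, seed = 5)
  net <- buildInteractome(fix$biogridPath, fix$stringPath, bait = "INSR")
  expect_equal(length(net), 20L)

  # every edge in the emitted table touches the bait
  d <- tempfile(); dir.create(d)
  writeNetwork(net, file.path(d, "net"))
  edges <- read.delim(file.path(d, "net_edges.tsv"))
  expect_equal(nrow(edges), 20L)
  expect_true(all(edges$from == "INSR" | edges$to == "INSR"))

  # bands match the fixture's planted expectations
  nd <- as.data.frame(interactomeNodes(net))
  m <- merge(nd, fix$truth, by = "partnerId")
  expect_equal(m$band, m$expectedBand)

  # identical inputs -> byte-identical node/edge tables
  writeNetwork(buildInteractome(fix$biogridPath, fix$stringPath),
               file.path(d, "net2"))
  expect_identical(readLines(file.path(d, "net_nodes.tsv")),
                   readLines(file.path(d, "net2_nodes.tsv")))
  expect_identical(readLines(file.path(d, "net_edges.tsv")),
                   readLines(file.path(d, "net2_edges.tsv")))
})

test_that("network round-trips through the node/edge tables", {
  fix <- simulateInteractomeFixture(12, seed = 9)
  net <- buildInteractome(fix$biogridPath, fix$stringPath)
  prefix <- file.path(tempfile(), "net"); dir.create(dirname(prefix))
  writeNetwork(net, prefix)
  back <- readNetwork(prefix)
  expect_equal(as.data.frame(interactomeNodes(back)),
               as.data.frame(interactomeNodes(net)))
  expect_equal(baitId(back), baitId(net))

  # score formatting survives serialisation unchanged
  nd <- read.delim(paste0(prefix, "_nodes.tsv"))
  expect_true(all(nd$score %in% c(0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)))

  # empty network: header-only tables
  empty <- buildSpokeNetwork(
    data.frame(partnerId = character(), score = numeric(),
               band = character(), nodeSize = integer(),
               throughputBorder = character()), "INSR")
  p2 <- file.path(tempfile(), "empty"); dir.create(dirname(p2))
  writeNetwork(empty, p2)
  expect_equal(length(readLines(paste0(p2, "_nodes.tsv"))), 1L)
})
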