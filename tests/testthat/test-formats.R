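makeMatrix <- function(pairs, mode = "per-bin", width = 7, N = 10000L) {
  new("CoFrequencyMatrix", pairs = pairs, mode = mode, width = width,
      level = "term", N = N)
}

test_that("co-frequency files are canonical and round-trip exactly", {
  path <- withr::local_tempfile()
  writeCofrequencyFile(makeMatrix(data.frame(id_x = 1L, id_y = 2L, count = 150L)),
                       path)
  expect_identical(readLines(path), "1\t2\t150")

  writeCofrequencyFile(makeMatrix(data.frame(id_x = integer(), id_y = integer(),
                                             count = integer())), path)
  expect_identical(file.size(path), 0)

  withr::with_seed(7, {
    pr <- allPairsFixture(40L, 500L)
  })
  m <- makeMatrix(pr)
  writeCofrequencyFile(m, path)
  bytes1 <- readBin(path, "raw", file.size(path))
  back <- readCofrequencyFile(path, mode = "per-bin", width = 7, N = 10000L)
  expect_identical(pairCounts(back), pairCounts(m))
  writeCofrequencyFile(back, path)
  expect_identical(readBin(path, "raw", file.size(path)), bytes1)
})

test_that("malformed count files are rejected with a line number", {
  path <- withr::local_tempfile()
  writeLines(c("1\t2\t5", "3\t4"), path)
  expect_error(readCofrequencyFile(path), "line 2")
  writeLines(c("1\t2\t5", "1\tx\t7"), path)
  expect_error(readCofrequencyFile(path), "line 2")
  writeLines(c("1\t2\t5", "1\t2\t7"), path)
  expect_error(readCofrequencyFile(path), "duplicate pair at line 2")
  writeLines("2\t1\t5", path)
  expect_error(readCofrequencyFile(path), "id_x >= id_y")
})

test_that("singleton files round-trip and stay sorted", {
  path <- withr::local_tempfile()
  s <- new("SingletonCounts", counts = data.frame(id = 5L, count = 42L),
           mode = "per-patient", width = Inf, level = "term", N = 100L)
  writeSingletonFile(s, path)
  expect_identical(readLines(path), "5\t42")

  s2 <- new("SingletonCounts",
            counts = data.frame(id = c(3L, 1L, 2L), count = c(7L, 9L, 8L)),
            mode = "per-bin", width = 7, level = "term", N = 100L)
  writeSingletonFile(s2, path)
  back <- readSingletonFile(path, mode = "per-bin", width = 7, N = 100L)
  expect_identical(singletonCounts(back)$id, 1:3)
  expect_identical(singletonCounts(back)$count, c(9L, 8L, 7L))

  writeSingletonFile(new("SingletonCounts",
                         counts = data.frame(id = integer(), count = integer()),
                         mode = "per-bin", width = 7, level = "term", N = 0L),
                     path)
  expect_identical(length(readLines(path)), 0L)
})

test_that("dictionary files round-trip with cross-file consistency checks", {
  # hand-built hydrocephalus-style fixture: 3 terms -> 2 concepts -> 2 CUIs,
  # term->concept many-to-many
  lex <- new("Lexicon",
             terms = data.frame(term_id = 1:3,
                                term = c("hydrocephalus", "shunt",
                                         "communicating hydrocephalus"),
                                stringsAsFactors = FALSE),
             stopWords = c("with", "the"), nameHomonyms = "parker",
             minLength = 4L,
             dropped = data.frame(term = character(), term_id = integer(),
                                  reason = character(), stringsAsFactors = FALSE))
  cm <- new("ConceptMap",
            termConcept = data.frame(term_id = c(1L, 1L, 2L, 3L),
                                     concept_id = c(11L, 12L, 11L, 12L)),
            concepts = data.frame(concept_id = c(11L, 12L),
                                  string = c("Hydrocephalus", "Communicating Hydrocephalus"),
                                  cui = c("C0020255", "C0009093"),
                                  stringsAsFactors = FALSE),
            semanticGroup = data.frame(concept_id = integer(), group = character(),
                                       stringsAsFactors = FALSE),
            suppressedPairs = data.frame(term_id = integer(), concept_id = integer()),
            ingredientMap = data.frame(concept_id = integer(), ingredient_id = integer()))
  dir <- withr::local_tempdir()
  paths <- writeDictionaries(lex, cm, dir)
  back <- readDictionaries(as.list(paths))
  expect_identical(lexiconTerms(back$lexicon), lexiconTerms(lex))
  expect_identical(termConceptMap(back$conceptMap), termConceptMap(cm))
  expect_identical(conceptTable(back$conceptMap), conceptTable(cm))
  # many-to-many: term 1 maps to two concepts, concept 11 has two terms
  tc <- termConceptMap(back$conceptMap)
  expect_identical(sum(tc$term_id == 1L), 2L)
  expect_identical(sum(tc$concept_id == 11L), 2L)

  # duplicated CUI under two concept IDs violates injectivity
  writeLines(c("11\tC0020255", "12\tC0020255"), file.path(dir, "concept_cui.tsv"))
  expect_error(readDictionaries(as.list(paths)), "one-to-one")

  # dangling term_id in File 3
  paths2 <- writeDictionaries(lex, cm, dir)
  writeLines("99\t11", file.path(dir, "term_concept_map.tsv"))
  expect_error(readDictionaries(as.list(paths2)), "absent from File 1: 99")

  # empty stop-word file -> empty set
  writeDictionaries(lex, cm, dir)
  writeLines(character(), file.path(dir, "stop_words.txt"))
  back2 <- readDictionaries(as.list(paths))
  expect_identical(back2$lexicon@stopWords, character())
})

test_that("decode substitutes strings or CUIs and refuses unknown IDs", {
  path <- withr::local_tempfile()
  writeLines("1\t2\t150", path)
  dec <- decodeCounts(path, c("1" = "shunt", "2" = "hydrocephalus"))
  expect_identical(dec, data.frame(x = "shunt", y = "hydrocephalus",
                                   count = 150L, stringsAsFactors = FALSE))
  dec2 <- decodeCounts(path, c("1" = "C0036442", "2" = "C0020255"))
  expect_identical(dec2$x, "C0036442")
  expect_error(decodeCounts(path, c("1" = "shunt")), "unknown ID.*2")

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_identical(nrow(decodeCounts(empty, c("1" = "a"))), 0L)

  writeLines("5\t9", path)
  dec3 <- decodeCounts(path, c("5" = "fever"))
  expect_identical(dec3, data.frame(x = "fever", count = 9L,
                                    stringsAsFactors = FALSE))
})

test_that("a full export manifest comprises 28 co-frequency and 16 singleton files", {
  mf <- exportManifest()
  expect_identical(sum(mf$type == "cofreq"), 28L)
  expect_identical(sum(mf$type == "singleton"), 16L)
  expect_identical(anyDuplicated(mf$filename), 0L)
})
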