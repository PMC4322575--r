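test_that("lexicon building applies the suppression rules with reasons", {
  lex <- buildLexicon(data.frame(term = c("clip", "myocardial infarction"),
                                 term_id = c(1L, 2L)))
  expect_setequal(lexiconTerms(lex)$term_id, c(1L, 2L))  # "clip" has 4 chars

  lex2 <- buildLexicon(data.frame(term = c("mi", "pneumonia"), term_id = c(3L, 4L)))
  expect_identical(lexiconTerms(lex2)$term_id, 4L)
  expect_identical(droppedTerms(lex2)$reason, "short")

  lex3 <- buildLexicon(data.frame(term = c("parker", "pneumonia"), term_id = c(5L, 6L)),
                       nameHomonyms = "Parker")
  expect_identical(droppedTerms(lex3)$reason, "name_homonym")

  lex4 <- buildLexicon(data.frame(term = c("with", "pneumonia"), term_id = c(7L, 8L)),
                       stopWords = "with")
  expect_identical(droppedTerms(lex4)$reason, "stop_word")

  expect_error(buildLexicon(data.frame(term = c("Chest Pain", "chest pain"),
                                       term_id = c(1L, 2L))),
               "conflicting IDs")
})

test_that("dictionary matching is case-insensitive and maximal-munch", {
  lex <- buildLexicon(data.frame(term = "chest pain", term_id = 7L))
  m <- annotateNote("pt denies CHEST Pain", lex)
  expect_identical(m$term_id, 7L)
  expect_identical(substr("pt denies CHEST Pain", m$start, m$end), "CHEST Pain")

  expect_identical(nrow(annotateNote("", lex)), 0L)

  # longest match wins over a nested shorter term: brute-force enumeration of
  # every candidate (position, term) cover confirms the maximal-munch choice
  lex2 <- buildLexicon(data.frame(term = c("myocardial infarction", "infarction"),
                                  term_id = c(2L, 8L)))
  text <- "myocardial infarction"
  toks <- c("myocardial", "infarction")
  candidates <- list(list(at = 1L, len = 2L, id = 2L), list(at = 2L, len = 1L, id = 8L))
  # leftmost-first, longest-first greedy over the enumerated candidates
  chosen <- integer(); i <- 1L
  while (i <= length(toks)) {
    here <- Filter(function(c) c$at == i, candidates)
    if (length(here)) {
      best <- here[[which.max(vapply(here, `[[`, integer(1), "len"))]]
      chosen <- c(chosen, best$id); i <- i + best$len
    } else i <- i + 1L
  }
  expect_identical(annotateNote(text, lex2)$term_id, chosen)
  expect_identical(chosen, 2L)
})

test_that("matching is insertion-order independent and idempotent", {
  entries <- data.frame(term = c("chest pain", "pain", "acute chest pain"),
                        term_id = c(1L, 2L, 3L))
  text <- "acute chest pain and more pain"
  a <- annotateNote(text, buildLexicon(entries))
  b <- annotateNote(text, buildLexicon(entries[c(3, 1, 2), ]))
  expect_identical(a, b)
  expect_identical(a$term_id, c(3L, 2L))  # maximal munch then later "pain"
  expect_identical(annotateNote(text, buildLexicon(entries)), a)
})

test_that("negation and section flagging follow the trigger-window rules", {
  lex <- buildLexicon(data.frame(term = c("myocardial infarction", "pneumonia",
                                          "diabetes"),
                                 term_id = 1:3))
  flag1 <- function(text) {
    m <- annotateNote(text, lex)
    flagMentions(text, m)
  }
  f <- flag1("myocardial infarction was ruled out")
  expect_true(f$negated)

  f2 <- flag1("no evidence of pneumonia")
  expect_true(f2$negated)

  f3 <- flag1("patient has pneumonia")
  expect_false(f3$negated)

  f4 <- flag1("FAMILY HISTORY: diabetes")
  expect_true(f4$family_history)

  # a later section marker closes the family-history section
  f5 <- flag1("FAMILY HISTORY: none. ASSESSMENT: diabetes poorly controlled")
  expect_false(f5$family_history)

  f6 <- flag1("PAST MEDICAL HISTORY: diabetes")
  expect_true(f6$history)
  expect_false(f6$family_history)
})

test_that("negation window is bounded", {
  lex <- buildLexicon(data.frame(term = "pneumonia", term_id = 1L))
  far <- paste("no evidence of anything remarkable in this lengthy",
               "radiology report mentioning pneumonia")
  m <- flagMentions(far, annotateNote(far, lex))
  expect_false(m$negated)  # trigger is more than 6 tokens away
})

test_that("concept mapping applies suppression, ambiguity and ingredient rules", {
  cm <- new("ConceptMap",
            termConcept = data.frame(term_id = c(10L, 10L, 11L, 12L),
                                     concept_id = c(101L, 102L, 103L, 104L)),
            concepts = data.frame(concept_id = c(101L, 102L, 103L, 104L, 200L),
                                  string = c("device concept", "peptide drug",
                                             "some drug", "a disease", "ingredient"),
                                  cui = sprintf("C%07d", c(101, 102, 103, 104, 200)),
                                  stringsAsFactors = FALSE),
            semanticGroup = data.frame(concept_id = c(101L, 102L, 103L, 104L, 200L),
                                       group = c("device", "drug", "drug",
                                                 "disease", "drug"),
                                       stringsAsFactors = FALSE),
            suppressedPairs = data.frame(term_id = 10L, concept_id = 102L),
            ingredientMap = data.frame(concept_id = 103L, ingredient_id = 200L))
  mentions <- data.frame(term_id = c(10L, 11L, 12L, 99L))

  out <- mapToConcepts(mentions, cm, level = "concept")
  # term 10: suppressed pair removes 102, leaving the device 101
  expect_identical(out$concept_id[out$term_id == 10L], 101L)
  # term 11: drug normalized to its ingredient
  expect_identical(out$concept_id[out$term_id == 11L], 200L)
  # term 99 has no mapping: dropped
  expect_false(99L %in% out$term_id)

  # group restriction: only unambiguous drug/disease terms survive
  res <- mapToConcepts(mentions, cm, level = "concept",
                       restrictToGroups = c("drug", "disease"))
  expect_setequal(res$term_id, c(11L, 12L))  # 10 maps to a device

  expect_identical(mapToConcepts(mentions, cm, level = "term"), mentions)
})

test_that("annotation over synthetic text recovers the ground truth exactly", {
  corp <- generateCorpus(simulationConfig(nPatients = 12L, vocabularySize = 60L,
                                          plantedPairs = list(c(10, 20, 0.4)),
                                          seed = 77L))
  lex <- syntheticLexicon(60L)
  ann <- annotateCorpus(corpusNotes(corp), lex, level = "term", triggers = NULL)
  expect_identical(ann$ids, corpusGroundTruth(corp))
})

test_that("no emitted mention violates the lexicon suppression invariants", {
  lex <- buildLexicon(data.frame(term = c("chest pain", "cough", "mi", "weber"),
                                 term_id = 1:4),
                      stopWords = "cough", nameHomonyms = "weber")
  m <- annotateNote("mi cough weber chest pain", lex)
  expect_identical(m$term_id, 1L)
})
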