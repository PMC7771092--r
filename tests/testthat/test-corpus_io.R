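toy_ont <- function() parse_obo(c(
  "[Term]", "id: OBT:000001", "name: habitat", "",
  "[Term]", "id: OBT:000002", "name: liver", 'synonym: "hepatic organ" EXACT []',
  'synonym: "liver tissue" RELATED []', "is_a: OBT:000001", "",
  "[Term]", "id: OBT:000003", "name: soil", "alt_id: OBT:999999",
  "is_a: OBT:000001"))

test_that("read_standoff parses mentions, multi-referent and discontinuous spans", {
  txt <- "liver of the cow. rich soil nearby."
  a1 <- c("T1\tHabitat 0 5\tliver",
          "T2\tHabitat 23 27\tsoil",
          "T3\tHabitat 0 5;13 16\tliver cow")
  a2 <- c("N1\tOntoBiotope Annotation:T1 Referent:OBT:000002",
          "N2\tOntoBiotope Annotation:T1 Referent:OBT:000003",
          "N3\tOntoBiotope Annotation:T2 Referent:OBT:000003")
  r <- read_standoff(txt, a1, a2, doc_id = "d1")
  expect_equal(nrow(r$mentions), 3)
  expect_equal(r$mentions$surface[r$mentions$mention_id == "T3"], "liver cow")
  expect_equal(nrow(r$mentions$spans[r$mentions$mention_id == "T3"][[1]]), 2)
  t1 <- r$gold$concept_id[r$gold$mention_id == "T1"]
  expect_setequal(t1, c("OBT:000002", "OBT:000003"))
  expect_error(read_standoff(txt, a1, "N9\tX Annotation:T99 Referent:OBT:000002"),
               "T99")
  expect_error(read_standoff(txt, "T1\tHabitat 5 0\tx"), "offsets")
  # type filter drops mentions and their gold rows
  r2 <- read_standoff(txt, c(a1, "T4\tPhenotype 28 34\tnearby"), a2,
                      types = "Phenotype")
  expect_equal(r2$mentions$mention_id, "T4")
  expect_equal(nrow(r2$gold), 0)
})

test_that("labels_as_examples covers every concept, synonyms optional", {
  ont <- toy_ont()
  ex0 <- labels_as_examples(ont, include_synonyms = FALSE)
  expect_equal(nrow(ex0), 3)
  expect_setequal(ex0$target_concept, ont$ids)
  ex1 <- labels_as_examples(ont, include_synonyms = TRUE)
  expect_equal(sum(ex1$target_concept == "OBT:000002"), 3)  # label + 2 synonyms
  expect_true(all(ex1$provenance == "weak"))
  expect_setequal(unique(ex1$target_concept), ont$ids)  # 100% coverage
  # stop-word filtering cannot empty an example
  ex2 <- labels_as_examples(ont, stopwords = c("habitat", "liver", "soil",
                                               "hepatic", "organ", "tissue"))
  expect_true(all(vapply(ex2$tokens, length, 1L) > 0))
})

test_that("assemble_training expands gold pairs and appends weak examples", {
  ont <- toy_ont()
  words <- c("liver", "soil", "liver", "soil", "liver")
  txt <- ""
  a1 <- character(0)
  for (i in 1:5) {
    a1 <- c(a1, sprintf("T%d\tHabitat %d %d\t%s", i, nchar(txt),
                        nchar(txt) + nchar(words[[i]]), words[[i]]))
    txt <- paste0(txt, words[[i]], " . ")
  }
  a2 <- vapply(1:5, function(i) {
    sprintf("N%d\tOntoBiotope Annotation:T%d Referent:OBT:%06d", i, i,
            if (i %% 2 == 1) 2 else 3)
  }, character(1))
  corpus <- read_standoff(txt, a1, a2)
  std <- assemble_training(corpus, ont, mode = "standard")
  expect_equal(nrow(std), 5)
  expect_true(all(std$provenance == "gold"))

  # one mention with two gold concepts -> two examples
  corpus2 <- read_standoff("liver", "T1\tHabitat 0 5\tliver",
                           c("N1\tOntoBiotope Annotation:T1 Referent:OBT:000002",
                             "N2\tOntoBiotope Annotation:T1 Referent:OBT:000003"))
  expect_equal(nrow(assemble_training(corpus2, ont, "standard")), 2)

  # alt_id resolves to canonical concept
  corpus3 <- read_standoff("soil", "T1\tHabitat 0 4\tsoil",
                           "N1\tOntoBiotope Annotation:T1 Referent:OBT:999999")
  expect_equal(assemble_training(corpus3, ont, "standard")$target_concept,
               "OBT:000003")

  both <- assemble_training(corpus, ont, mode = "standard+weak",
                            include_synonyms = FALSE)
  expect_equal(nrow(both), 5 + 3)
  expect_setequal(unique(both$target_concept), ont$ids)

  bad <- corpus
  bad$gold$concept_id[1] <- "OBT:777777"
  expect_error(assemble_training(bad, ont, "standard"), "OBT:777777")
})

test_that("prediction writing is byte-exact and round-trips through read_standoff", {
  preds <- data.frame(mention_id = c("T2", "T7"),
                      concept_id = c("OBT:001480", "OBT:000002"))
  lines <- write_predictions(preds)
  expect_equal(lines[1], "N1\tOntoBiotope Annotation:T2 Referent:OBT:001480")
  expect_equal(write_predictions(preds[0, ]), character(0))

  txt <- "ab cd ef gh"
  a1 <- c("T2\tHabitat 0 2\tab", "T7\tHabitat 3 5\tcd")
  r <- read_standoff(txt, a1, lines)
  expect_equal(r$gold[order(r$gold$mention_id), c("mention_id", "concept_id")],
               preds[order(preds$mention_id), ],
               ignore_attr = TRUE)
})
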