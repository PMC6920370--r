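test_that("dominant predicate handles carriers, controls and the sex-reversal family pattern", {
  ped <- trioPed()
  expect_true(fitsDominant(c(fat = 0, mot = 0, c1 = 1), ped))
  expect_false(fitsDominant(c(fat = 1, mot = 0, c1 = 1), ped))
  expect_false(fitsDominant(c(fat = 0, mot = 0, c1 = 0), ped))
  # missing never violates, but affecteds must have observed support
  expect_true(fitsDominant(c(fat = NA, mot = 0, c1 = 1), ped))
  expect_false(fitsDominant(c(fat = 0, mot = 0, c1 = NA), ped))
  # six carriers incl. four recorded-unaffected relatives: fails at 0 flips
  ped5 <- dsdPed()
  g5 <- c(fat = 0, mot = 1, p1 = 1, p2 = 1, sis = 1, bro = 0,
          aunt = 1, uncle = 1)
  expect_false(fitsDominant(g5, ped5))
})

test_that("recessive predicate requires hom affecteds with carrier parents", {
  ped <- quartetPed()
  expect_true(fitsRecessiveHom(c(fat = 1, mot = 1, s1 = 2, s2 = 2), ped))
  expect_false(fitsRecessiveHom(c(fat = 1, mot = 1, s1 = 1, s2 = 2), ped))
  expect_false(fitsRecessiveHom(c(fat = 0, mot = 1, s1 = 2, s2 = 2), ped))
  # unaffected hom sib kills it
  ped3 <- Pedigree("F1", within(pedMembers(quartetPed()), {
    affection[id == "s2"] <- "unaffected"
  }))
  expect_false(fitsRecessiveHom(c(fat = 1, mot = 1, s1 = 2, s2 = 2), ped3))
})

test_that("X-linked predicate distinguishes hemizygote codings and female carriers", {
  ped <- quartetPed()   # two affected sons
  expect_true(fitsXLinked(c(fat = 0, mot = 1, s1 = 1, s2 = 2), ped))
  expect_false(fitsXLinked(c(fat = 1, mot = 1, s1 = 1, s2 = 1), ped))
  # carrier mother het is fine; affected female het is not
  pedF <- Pedigree("F1", within(pedMembers(quartetPed()), {
    sex[id == "s1"] <- "female"
  }))
  expect_false(fitsXLinked(c(fat = 0, mot = 1, s1 = 1, s2 = 1), pedF))
  expect_true(fitsXLinked(c(fat = 0, mot = 1, s1 = 2, s2 = 1), pedF))
})

test_that("de novo predicate constrains parents and all unaffecteds", {
  ped <- trioPed()
  expect_true(fitsDeNovo(c(fat = 0, mot = 0, c1 = 1), ped))
  expect_false(fitsDeNovo(c(fat = 1, mot = 0, c1 = 1), ped))
  expect_false(fitsDeNovo(c(fat = 0, mot = 0, c1 = 0), ped))
  # shared apparent de novo in two affected sibs passes
  ped4 <- quartetPed()
  expect_true(fitsDeNovo(c(fat = 0, mot = 0, s1 = 1, s2 = 1), ped4))
  # no sequenced parent pair -> error
  pedNP <- Pedigree("F1", data.frame(
    id = "solo", fatherId = NA_character_, motherId = NA_character_,
    sex = "male", affection = "affected", labelConfidence = "soft",
    sequenced = TRUE, stringsAsFactors = FALSE))
  expect_error(fitsDeNovo(c(solo = 1), pedNP), "both parents")
})

test_that("de novo predicate matches a truth table over all trio genotypes", {
  ped <- trioPed()
  for (f in c(0, 1, 2, NA)) for (m in c(0, 1, 2, NA))
    for (c in c(0, 1, 2, NA)) {
      g <- c(fat = f, mot = m, c1 = c)
      expect_equal(fitsDeNovo(g, ped),
                   oracleDeNovo(g, list(c("c1", "fat", "mot")),
                                c("fat", "mot")),
                   info = paste(f, m, c))
    }
})

test_that("compound-het pairs require trans phase and clean controls", {
  ped <- quartetPed()
  G <- rbind(v1 = c(fat = 1, mot = 0, s1 = 1, s2 = 1),
             v2 = c(fat = 0, mot = 1, s1 = 1, s2 = 1))
  pr <- fitsCompoundHet(G, ped)
  expect_equal(nrow(pr), 1)
  expect_false(pr$phaseUnknown)
  # both variants on the paternal side: cis, no pair
  Gc <- rbind(v1 = c(fat = 1, mot = 0, s1 = 1, s2 = 1),
              v2 = c(fat = 1, mot = 0, s1 = 1, s2 = 1))
  expect_equal(nrow(fitsCompoundHet(Gc, ped)), 0)
  # an unaffected carrying both members of a pair excludes it
  ped5 <- Pedigree("F1", rbind(pedMembers(quartetPed()), data.frame(
    id = "s3", fatherId = "fat", motherId = "mot", sex = "female",
    affection = "unaffected", labelConfidence = "soft", sequenced = TRUE)))
  Gu <- rbind(v1 = c(fat = 1, mot = 0, s1 = 1, s2 = 1, s3 = 1),
              v2 = c(fat = 0, mot = 1, s1 = 1, s2 = 1, s3 = 1))
  expect_equal(nrow(fitsCompoundHet(Gu, ped5)), 0)
})

test_that("without parental genotypes all het pairs return phase-unknown", {
  ped <- Pedigree("F1", data.frame(
    id = c("s1", "s2"), fatherId = NA_character_, motherId = NA_character_,
    sex = c("male", "female"), affection = c("affected", "affected"),
    labelConfidence = "soft", sequenced = TRUE, stringsAsFactors = FALSE))
  G <- matrix(1, 4, 2, dimnames = list(paste0("v", 1:4), c("s1", "s2")))
  pr <- fitsCompoundHet(G, ped)
  expect_equal(nrow(pr), choose(4, 2))     # exhaustive pair enumeration
  expect_true(all(pr$phaseUnknown))
})

test_that("cross-family exclusion removes variants seen in any other family", {
  fams <- c(a1 = "FA", a2 = "FA", b1 = "FB", c1 = "FC")
  expect_equal(crossFamilyExclude(c(a1 = 1, a2 = 2, b1 = 0, c1 = 0),
                                  fams, "FA"), "keep")
  expect_equal(crossFamilyExclude(c(a1 = 1, a2 = 0, b1 = 1, c1 = 0),
                                  fams, "FA"), "remove")
  expect_equal(crossFamilyExclude(c(a1 = 1, a2 = 0, b1 = NA, c1 = 1),
                                  fams, "FA"), "remove")
  expect_equal(crossFamilyExclude(c(a1 = 1, a2 = 0, b1 = NA, c1 = NA),
                                  fams, "FA"), "keep")
})

test_that("every filter matches the brute-force oracle on random small cohorts", {
  for (seed in 1:200) {
    cs <- randomFamilyCase(seed, nVariants = 15)
    ctx <- oracleContext(cs$ped)
    if (!length(ctx$aff)) next
    for (i in seq_len(nrow(cs$geno))) {
      g <- cs$geno[i, ]
      expect_equal(unname(fitsDominant(g, cs$ped)),
                   oracleDominant(g, ctx$aff, ctx$unaff))
      expect_equal(unname(fitsRecessiveHom(g, cs$ped)),
                   oracleRecessiveHom(g, ctx$aff, ctx$unaff,
                                      ctx$parentsOfAff))
      expect_equal(unname(fitsXLinked(g, cs$ped)),
                   oracleXLinked(g, ctx$affM, ctx$affF, ctx$unM, ctx$unF))
      if (length(ctx$trios))
        expect_equal(unname(fitsDeNovo(g, cs$ped)),
                     oracleDeNovo(g, ctx$trios, ctx$unaff))
    }
  }
})

test_that("run_segregation recovers a planted recessive variant and is decreasing", {
  sim <- simulateCohort(fastConfig("recessive_hom", seed = 21))
  tr <- truthManifest(sim)
  ped <- pedigreesOf(sim)[[tr$targetFamily]]
  seg <- runSegregation(cohortOf(sim), ped, annotations = annotationsOf(sim))
  expect_true(tr$causalKeys %in% seg$results$recessive_hom$key)
  nv <- nrow(variantTable(cohortOf(sim)))
  expect_true(all(seg$counts <= nv))
  # a variant failing all models is absent from every output
  allKeys <- unlist(lapply(seg$results, function(r)
    if ("key" %in% names(r)) r$key else c(r$key1, r$key2)))
  G <- genoMatrix(cohortOf(sim))
  fam <- intersect(sequencedIds(ped), colnames(G))
  absent <- which(rowSums(G[, fam, drop = FALSE] >= 1, na.rm = TRUE) == 0)[1]
  expect_false(variantKeys(cohortOf(sim))[absent] %in% allKeys)
})

test_that("empty variant stream produces empty outputs and zero counts", {
  co <- toyCohort(matrix(numeric(), 0, 3,
                         dimnames = list(NULL, c("fat", "mot", "c1"))))
  seg <- runSegregation(co, trioPed(), models = c("dominant", "de_novo"))
  expect_equal(unname(seg$counts), c(0L, 0L))
  expect_equal(nrow(seg$results$dominant), 0)
})

test_that("the relabeling search finds a single wrongly-recorded carrier at k = 1", {
  # one affected carrier recorded as unaffected
  ped <- quartetPed()
  ped@members$affection[pedMembers(ped)$id == "s2"] <- "unaffected"
  G <- rbind(v = c(fat = 0, mot = 0, s1 = 1, s2 = 1))
  co <- toyCohort(G, sampleFamily = setNames(rep("F1", 4), colnames(G)))
  out <- misclassificationSearch(co, ped, models = "dominant", maxFlips = 2,
                                 applyAnnotationFilters = FALSE)
  expect_equal(nrow(out), 1)
  expect_equal(out$minFlips, 1L)
  expect_equal(out$flipSets[[1]][[1]], "s2")
})

test_that("the sex-reversal configuration resolves at the oracle's minimal flip count", {
  ped <- dsdPed()
  carriers <- c("mot", "p1", "p2", "sis", "aunt", "uncle")
  g <- setNames(as.numeric(pedMembers(ped)$id %in% carriers),
                pedMembers(ped)$id)
  co <- toyCohort(rbind(g), sampleFamily = setNames(rep("F5", 8), names(g)))
  # exhaustive oracle over all 2^6 assignments of the six soft members
  soft <- c("fat", "mot", "sis", "bro", "aunt", "uncle")
  best <- Inf
  bestSets <- list()
  for (mask in 0:(2^6 - 1)) {
    flip <- soft[bitwAnd(mask, 2^(0:5)) > 0]
    labels <- affectionLabels(ped)
    labels[flip] <- ifelse(labels[flip] == "affected", "unaffected",
                           "affected")
    ok <- oracleDominant(g, names(labels)[labels == "affected"],
                         names(labels)[labels == "unaffected"])
    if (ok && length(flip) < best) { best <- length(flip); bestSets <- list() }
    if (ok && length(flip) == best) bestSets <- c(bestSets, list(sort(flip)))
  }
  expect_equal(best, 4)   # aunt, uncle, mother, sister must become affected
  out <- misclassificationSearch(co, ped, models = "dominant", maxFlips = 4,
                                 applyAnnotationFilters = FALSE)
  expect_equal(out$minFlips, 4L)
  expect_equal(lapply(out$flipSets[[1]], sort), bestSets)
})

test_that("search at zero flips equals plain segregation and respects the cap", {
  sim <- simulateCohort(fastConfig("dominant", seed = 30))
  tr <- truthManifest(sim)
  ped <- pedigreesOf(sim)[[tr$targetFamily]]
  seg <- runSegregation(cohortOf(sim), ped, models = "dominant",
                        annotations = annotationsOf(sim))
  out <- misclassificationSearch(cohortOf(sim), ped,
                                 annotations = annotationsOf(sim),
                                 models = "dominant", maxFlips = 0)
  ann <- alignAnnotations(annotationsOf(sim), seg$results$dominant$key)
  expected <- seg$results$dominant$key[
    !raredx:::.dbRemove(ann) & raredx:::.voteDeleterious(ann)]
  expect_setequal(out$key, expected)
  expect_true(all(out$minFlips == 0))
  expect_error(misclassificationSearch(cohortOf(sim), ped, maxFlips = 8,
                                       cap = 10), "cap")
})
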