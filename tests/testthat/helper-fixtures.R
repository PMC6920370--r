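## Shared fixtures and independent brute-force oracles. The oracles inspect
## the genotype table directly with explicit loops; they never call the
## package's vectorized filter code.

toyCohort <- function(geno, chrom = "chr1", startPos = 100,
                      sampleFamily = NULL) {
  nv <- nrow(geno)
  v <- data.frame(chrom = rep(chrom, length.out = nv),
                  pos = seq(startPos, by = 10, length.out = nv),
                  ref = rep("A", nv), alt = rep("G", nv),
                  stringsAsFactors = FALSE)
  GenotypeCohort(v, geno,
                 sampleFamily = if (is.null(sampleFamily)) character()
                 else sampleFamily)
}

trioPed <- function(familyId = "F1", childAffected = TRUE) {
  Pedigree(familyId, data.frame(
    id = c("fat", "mot", "c1"),
    fatherId = c(NA, NA, "fat"), motherId = c(NA, NA, "mot"),
    sex = c("male", "female", "male"),
    affection = c("unaffected", "unaffected",
                  if (childAffected) "affected" else "unaffected"),
    labelConfidence = "soft", sequenced = TRUE, stringsAsFactors = FALSE))
}

quartetPed <- function(familyId = "F1") {
  Pedigree(familyId, data.frame(
    id = c("fat", "mot", "s1", "s2"),
    fatherId = c(NA, NA, "fat", "fat"), motherId = c(NA, NA, "mot", "mot"),
    sex = c("male", "female", "male", "male"),
    affection = c("unaffected", "unaffected", "affected", "affected"),
    labelConfidence = "soft", sequenced = TRUE, stringsAsFactors = FALSE))
}

## Fam5-1-like structure: twin probands (firm), mother, father, sister,
## brother, aunt, uncle (soft). Carrier pattern set by tests.
dsdPed <- function(familyId = "F5") {
  Pedigree(familyId, data.frame(
    id = c("fat", "mot", "p1", "p2", "sis", "bro", "aunt", "uncle"),
    fatherId = c(NA, NA, "fat", "fat", "fat", "fat", NA, NA),
    motherId = c(NA, NA, "mot", "mot", "mot", "mot", NA, NA),
    sex = c("male", "female", "female", "female", "female", "male",
            "female", "male"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected", "unaffected", "unaffected"),
    labelConfidence = c("soft", "soft", "firm", "firm", "soft", "soft",
                        "soft", "soft"),
    sequenced = TRUE, stringsAsFactors = FALSE))
}

## ---- per-variant segregation oracles (direct genotype-table loops) ----

.oCarries <- function(x) !is.na(x) && x >= 1

oracleDominant <- function(g, aff, unaff) {
  anyObs <- FALSE
  for (a in aff) {
    if (!is.na(g[[a]]) && g[[a]] == 0) return(FALSE)
    if (.oCarries(g[[a]])) anyObs <- TRUE
  }
  if (!anyObs) return(FALSE)
  for (u in unaff) if (.oCarries(g[[u]])) return(FALSE)
  TRUE
}

oracleRecessiveHom <- function(g, aff, unaff, parentsOfAff) {
  anyObs <- FALSE
  for (a in aff) {
    if (!is.na(g[[a]]) && g[[a]] != 2) return(FALSE)
    if (!is.na(g[[a]]) && g[[a]] == 2) anyObs <- TRUE
  }
  if (!anyObs) return(FALSE)
  for (u in unaff) if (!is.na(g[[u]]) && g[[u]] == 2) return(FALSE)
  for (p in parentsOfAff) if (!is.na(g[[p]]) && g[[p]] == 0) return(FALSE)
  TRUE
}

oracleXLinked <- function(g, affM, affF, unM, unF) {
  anyObs <- FALSE
  for (a in affM) {
    if (!is.na(g[[a]]) && g[[a]] == 0) return(FALSE)
    if (.oCarries(g[[a]])) anyObs <- TRUE
  }
  for (a in affF) {
    if (!is.na(g[[a]]) && g[[a]] != 2) return(FALSE)
    if (!is.na(g[[a]]) && g[[a]] == 2) anyObs <- TRUE
  }
  if (!anyObs) return(FALSE)
  for (u in unM) if (.oCarries(g[[u]])) return(FALSE)
  for (u in unF) if (!is.na(g[[u]]) && g[[u]] == 2) return(FALSE)
  TRUE
}

oracleDeNovo <- function(g, trios, unaff) {
  # trios: list of c(child, father, mother)
  anyObs <- FALSE
  for (t in trios) {
    if (!is.na(g[[t[1]]]) && g[[t[1]]] == 0) return(FALSE)
    if (.oCarries(g[[t[1]]])) anyObs <- TRUE
    if (.oCarries(g[[t[2]]])) return(FALSE)
    if (.oCarries(g[[t[3]]])) return(FALSE)
  }
  if (!anyObs) return(FALSE)
  for (u in unaff) if (.oCarries(g[[u]])) return(FALSE)
  TRUE
}

## compound-het pair oracle: G is variants x samples, keys as rownames
oracleCompoundHet <- function(G, aff, unaff, trios) {
  keys <- rownames(G)
  out <- list()
  isHetAll <- function(i) {
    obs <- FALSE
    for (a in aff) {
      x <- G[i, a]
      if (!is.na(x) && x != 1) return(FALSE)
      if (!is.na(x) && x == 1) obs <- TRUE
    }
    obs
  }
  for (i in seq_len(nrow(G))) for (j in seq_len(nrow(G))) {
    if (j <= i) next
    if (!isHetAll(i) || !isHetAll(j)) next
    ok <- TRUE
    for (u in unaff)
      if (.oCarries(G[i, u]) && .oCarries(G[j, u])) ok <- FALSE
    if (ok && length(trios)) {
      for (t in trios) {
        pf <- function(x) is.na(G[x, t[2]]) || G[x, t[2]] >= 1
        pm <- function(x) is.na(G[x, t[3]]) || G[x, t[3]] >= 1
        if (!((pf(i) && pm(j)) || (pm(i) && pf(j)))) ok <- FALSE
      }
    }
    if (ok) out[[length(out) + 1]] <- c(keys[i], keys[j])
  }
  out
}

## random small family + genotypes for the filter-vs-oracle property
randomFamilyCase <- function(seed, nVariants = 20) {
  set.seed(seed)
  shape <- sample(c("trio", "quartet", "ext"), 1)
  if (shape == "trio") {
    ids <- c("fat", "mot", "c1", "c2")
    fa <- c(NA, NA, "fat", "fat"); mo <- c(NA, NA, "mot", "mot")
    sex <- c("male", "female", sample(c("male", "female"), 2, TRUE))
  } else if (shape == "quartet") {
    ids <- c("fat", "mot", "s1", "s2", "s3")
    fa <- c(NA, NA, rep("fat", 3)); mo <- c(NA, NA, rep("mot", 3))
    sex <- c("male", "female", sample(c("male", "female"), 3, TRUE))
  } else {
    ids <- c("gf", "gm", "fat", "mot", "c1", "c2", "u1", "u2")
    fa <- c(NA, NA, NA, "gf", "fat", "fat", "gf", NA)
    mo <- c(NA, NA, NA, "gm", "mot", "mot", "gm", NA)
    sex <- c("male", "female", "male", "female",
             sample(c("male", "female"), 2, TRUE), "male", "female")
  }
  repeat {
    affc <- sample(c("affected", "unaffected", "unknown"), length(ids),
                   replace = TRUE, prob = c(0.4, 0.45, 0.15))
    if (any(affc == "affected")) break
  }
  ped <- Pedigree("FR", data.frame(
    id = ids, fatherId = fa, motherId = mo, sex = sex, affection = affc,
    labelConfidence = "soft", sequenced = TRUE, stringsAsFactors = FALSE))
  G <- matrix(sample(c(0, 1, 2, NA), nVariants * length(ids), replace = TRUE,
                     prob = c(0.55, 0.25, 0.12, 0.08)),
              nVariants, length(ids), dimnames = list(NULL, ids))
  list(ped = ped, geno = G)
}

oracleContext <- function(ped, labels = NULL) {
  m <- pedMembers(ped)
  if (is.null(labels)) labels <- affectionLabels(ped)
  seqd <- m$id[m$sequenced]
  aff <- seqd[labels[seqd] == "affected"]
  unaff <- seqd[labels[seqd] == "unaffected"]
  sex <- setNames(m$sex, m$id)
  trios <- list()
  for (a in aff) {
    fa <- m$fatherId[m$id == a]; mo <- m$motherId[m$id == a]
    if (!is.na(fa) && fa %in% seqd && !is.na(mo) && mo %in% seqd)
      trios[[length(trios) + 1]] <- c(a, fa, mo)
  }
  parents <- unique(unlist(lapply(aff, function(a)
    c(m$fatherId[m$id == a], m$motherId[m$id == a]))))
  parents <- parents[!is.na(parents) & parents %in% seqd]
  list(aff = aff, unaff = unaff, sex = sex, trios = trios,
       parentsOfAff = parents,
       affM = aff[sex[aff] == "male"], affF = aff[sex[aff] == "female"],
       unM = unaff[sex[unaff] == "male"], unF = unaff[sex[unaff] == "female"])
}

## small fast generator settings for unit tests
fastConfig <- function(scenario, seed, ...) {
  scenarioConfig(scenario, seed = seed, nDecoys = 2000,
                 nBackgroundGenes = 60, ...)
}
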