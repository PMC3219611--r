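test_that("normalized identity follows the length-normalization formula", {
  expect_equal(normalized_identity(100, 70, 70, 70), 100)
  expect_equal(normalized_identity(90, 80, 100, 100), 72)
  expect_equal(normalized_identity(100, 50, 50, 200), 25)
  expect_error(normalized_identity(50, 10, 0, 10), "positive")
  # never exceeds the raw identity
  set.seed(1)
  for (i in 1:50) {
    la <- sample(50:200, 1L); lb <- sample(50:200, 1L)
    al <- sample(seq_len(min(la, lb)), 1L)
    pid <- runif(1, 0, 100)
    ni <- normalized_identity(pid, al, la, lb)
    expect_lte(ni, pid + 1e-12)
    expect_gte(ni, 0)
  }
})

test_that("built-in pairwise backend matches exhaustive re-alignment", {
  set.seed(7)
  mkprot <- function(n) paste(sample(c("A","C","D","E","F","G","H","I","K","L"),
                                     n, TRUE), collapse = "")
  pa <- vapply(1:5, function(i) mkprot(40L), "")
  pb <- c(pa[1:3], vapply(1:2, function(i) mkprot(35L), ""))
  calls <- list(
    A = structure(data.frame(genome_id = "A", gene_id = paste0("a", 1:5),
                             protein = pa, stringsAsFactors = FALSE)),
    B = structure(data.frame(genome_id = "B", gene_id = paste0("b", 1:5),
                             protein = pb, stringsAsFactors = FALSE))
  )
  sc <- pair_scores(calls, floor = 0, prefilter = "none")
  # oracle: align each pair independently with the same scoring scheme
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (r in seq_len(nrow(sc))) {
    i <- match(sc$gene_id_a[r], calls$A$gene_id)
    j <- match(sc$gene_id_b[r], calls$B$gene_id)
    a <- Biostrings::pairwiseAlignment(pa[i], pb[j], type = "global",
                                       substitutionMatrix = BLOSUM62,
                                       gapOpening = 10, gapExtension = 0.5)
    nm <- Biostrings::nmatch(a); nmm <- Biostrings::nmismatch(a)
    expect_equal(sc$pct_identity[r], 100 * nm / (nm + nmm))
    expect_equal(sc$aln_len[r], nm + nmm)
  }
  # identical proteins across genomes score 100 normalized
  ident <- sc[sc$gene_id_a == "a1" & sc$gene_id_b == "b1", ]
  expect_equal(ident$norm_identity, 100)
})

test_that("seed prefilter finds the same ortholog pairs as exhaustive search", {
  sim <- simulate_gmv(n_genomes = 3L, n_families = 25L, e = 0, seed = 11)
  ex <- pair_scores(sim$calls, prefilter = "none")
  se <- pair_scores(sim$calls, prefilter = "seed")
  key <- function(x) sort(paste(x$gene_id_a, x$gene_id_b))
  # every above-floor ortholog pair found exhaustively is found with seeding
  expect_true(all(key(ex) %in% key(se)) || all(key(se) %in% key(ex)))
  m <- merge(ex, se, by = c("gene_id_a", "gene_id_b"))
  expect_equal(m$norm_identity.x, m$norm_identity.y)
})

test_that("unrelated random proteins fall below the identity floor", {
  set.seed(42)
  aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")
  mkprot <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  calls <- list(
    A = data.frame(genome_id = "A", gene_id = paste0("a", 1:4),
                   protein = vapply(1:4, function(i) mkprot(100L), ""),
                   stringsAsFactors = FALSE),
    B = data.frame(genome_id = "B", gene_id = paste0("b", 1:4),
                   protein = vapply(1:4, function(i) mkprot(100L), ""),
                   stringsAsFactors = FALSE)
  )
  sc <- pair_scores(calls, floor = 30, prefilter = "none")
  expect_equal(nrow(sc), 0L)
})

test_that("pan-RBH assembly recovers unambiguous families and voids ties", {
  # 3 genomes x 2 clean families
  genes <- list(G1 = c("G1_g1", "G1_g2"), G2 = c("G2_g1", "G2_g2"),
                G3 = c("G3_g1", "G3_g2"))
  mkrow <- function(a, b, ga, gb, s)
    data.frame(gene_id_a = a, gene_id_b = b, genome_a = ga, genome_b = gb,
               pct_identity = NA_real_, aln_len = NA_integer_,
               len_a = NA_integer_, len_b = NA_integer_, norm_identity = s,
               stringsAsFactors = FALSE)
  sc <- rbind(
    mkrow("G1_g1", "G2_g1", "G1", "G2", 90), mkrow("G1_g1", "G3_g1", "G1", "G3", 88),
    mkrow("G2_g1", "G3_g1", "G2", "G3", 91),
    mkrow("G1_g2", "G2_g2", "G1", "G2", 80), mkrow("G1_g2", "G3_g2", "G1", "G3", 82),
    mkrow("G2_g2", "G3_g2", "G2", "G3", 85),
    mkrow("G1_g1", "G2_g2", "G1", "G2", 40)   # weak cross-family hit
  )
  calls <- lapply(genes, function(g)
    data.frame(genome_id = sub("_.*", "", g[1L]), gene_id = g,
               stringsAsFactors = FALSE))
  os <- ortholog_sets(sc, calls)
  expect_equal(length(unique(os$sets$set_id)), 2L)
  expect_setequal(canonical_sets(os), brute_pan_rbh(sc, genes))

  # an exact best-hit tie (paralog) voids the family
  sc2 <- rbind(sc, mkrow("G1_g1", "G2_g2", "G1", "G2", 90))
  sc2 <- sc2[!(sc2$gene_id_a == "G1_g1" & sc2$gene_id_b == "G2_g2" &
                 sc2$norm_identity == 40), ]
  os2 <- ortholog_sets(sc2, calls)
  expect_setequal(canonical_sets(os2), brute_pan_rbh(sc2, genes))
  expect_false(any(grepl("G1_g1", canonical_sets(os2))))

  # a family missing from one genome yields no set
  sc3 <- sc[!(sc$gene_id_a == "G1_g2" & sc$gene_id_b == "G2_g2"), ]
  os3 <- ortholog_sets(sc3, calls)
  expect_equal(length(canonical_sets(os3)), 1L)
})

test_that("pan-RBH assembly equals exhaustive tuple search on random instances", {
  for (trial in 1:20) {
    ng <- sample(2:4, 1L)
    inst <- random_score_table(ng, sample(2:6, 1L), seed = 500 + trial)
    calls <- lapply(names(inst$genes), function(g)
      data.frame(genome_id = g, gene_id = inst$genes[[g]],
                 stringsAsFactors = FALSE))
    names(calls) <- names(inst$genes)
    os <- ortholog_sets(inst$scores, calls)
    expect_setequal(canonical_sets(os), brute_pan_rbh(inst$scores, inst$genes))
  }
})

test_that("set composition is independent of genome input order", {
  inst <- random_score_table(3L, 5L, seed = 321)
  calls <- lapply(names(inst$genes), function(g)
    data.frame(genome_id = g, gene_id = inst$genes[[g]],
               stringsAsFactors = FALSE))
  names(calls) <- names(inst$genes)
  os1 <- ortholog_sets(inst$scores, calls)
  perm <- rev(seq_along(calls))
  os2 <- ortholog_sets(inst$scores[sample(nrow(inst$scores)), ], calls[perm])
  expect_setequal(canonical_sets(os1), canonical_sets(os2))
})

test_that("emitted sets respect the identity floor", {
  sim <- simulate_gmv(n_genomes = 3L, n_families = 12L, e = 0, seed = 5)
  sc <- pair_scores(sim$calls, floor = 30)
  os <- ortholog_sets(sc, sim$calls)
  expect_true(all(os$summary$min_identity >= 30))
})

test_that("precomputed pairwise TSV backend round-trips through disk", {
  sim <- simulate_gmv(n_genomes = 3L, n_families = 8L, e = 0, seed = 9)
  sc <- pair_scores(sim$calls)
  tsv <- tempfile(fileext = ".tsv")
  write_pair_scores(sc, tsv)
  sc2 <- pair_scores(sim$calls, backend = "precomputed",
                     precomputed = read_pair_scores(tsv))
  expect_equal(sc2[order(sc2$gene_id_a, sc2$gene_id_b), ]$norm_identity,
               sc[order(sc$gene_id_a, sc$gene_id_b), ]$norm_identity)
  # unknown genes in the table warn and are dropped
  extra <- read_pair_scores(tsv)
  extra[1L, "gene_id_a"] <- "nosuchgene"
  expect_warning(pair_scores(sim$calls, backend = "precomputed",
                             precomputed = extra), "unknown genes")
})
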