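# Variant effect annotation, artifact filtering, recurrence ranking.

test_that("SNP effects follow the codon table, strand-aware", {
  tg <- tiny_genome()
  # + strand CDS 101..109 = ATG GCT TAA; 106 is the third base of codon GCT
  v <- data.frame(strain = "m1", contig = "chr", pos = 106L,
                  ref = substr(tg$genome[["chr"]], 106, 106), alt = "A")
  stopifnot(v$ref == "T")
  ann <- annotate_effect(v, tg$genes, tg$genome)
  expect_equal(ann$effect, "synonymous")   # GCT and GCA both encode Ala
  expect_equal(ann$gene_id, "gplus")

  # 104 is the first base of codon GCT; G->A gives ACT (Ala -> Thr)
  v2 <- data.frame(strain = "m1", contig = "chr", pos = 104L,
                   ref = "G", alt = "A")
  expect_equal(annotate_effect(v2, tg$genes, tg$genome)$effect,
               "nonsynonymous")

  # a single-nucleotide insertion inside any CDS is a frameshift
  base <- substr(tg$genome[["chr"]], 103, 103)
  v3 <- data.frame(strain = "m1", contig = "chr", pos = 103L,
                   ref = base, alt = paste0(base, "G"))
  expect_equal(annotate_effect(v3, tg$genes, tg$genome)$effect, "frameshift")

  # a 3-nt insertion is in-frame
  v4 <- data.frame(strain = "m1", contig = "chr", pos = 103L,
                   ref = base, alt = paste0(base, "GGG"))
  expect_equal(annotate_effect(v4, tg$genes, tg$genome)$effect,
               "inframe_indel")

  # outside every CDS: intergenic
  v5 <- data.frame(strain = "m1", contig = "chr", pos = 50L,
                   ref = substr(tg$genome[["chr"]], 50, 50), alt = "N")
  v5$alt <- setdiff(c("A", "C", "G", "T"), v5$ref)[1]
  expect_equal(annotate_effect(v5, tg$genes, tg$genome)$effect, "intergenic")

  # ref allele disagreeing with the genome is an input inconsistency
  v6 <- data.frame(strain = "m1", contig = "chr", pos = 104L,
                   ref = "T", alt = "A")
  expect_error(annotate_effect(v6, tg$genes, tg$genome), "mismatch")
})

test_that("effect annotation agrees with the full-CDS translation oracle", {
  cfg <- small_config(seed = 12)
  g <- gen_bgc_genome(cfg)
  genome <- as.character(g$genome)
  genes <- g$genes
  set.seed(13)
  n_checked <- 0
  for (i in 1:300) {
    gi <- genes[sample(nrow(genes), 1), ]
    if (gi$end - gi$start + 1 > 300 && runif(1) < 0.5) next  # favour short CDS
    pos <- sample(gi$start:gi$end, 1)
    ref <- substr(genome[[gi$contig]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- data.frame(strain = "m", contig = gi$contig, pos = pos,
                    ref = ref, alt = alt)
    got <- annotate_effect(v, genes, genome)$effect
    want <- oracle_snp_effect(v, gi, genome)
    expect_equal(got, want,
                 label = sprintf("effect at %s:%d %s>%s (%s strand)",
                                 gi$contig, pos, ref, alt, gi$strand))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("effect calls are invariant under reverse-complementing the genome", {
  tg <- tiny_genome()
  L <- nchar(tg$genome[["chr"]])
  rc <- c(chr = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tg$genome[["chr"]]))))
  genes_rc <- tg$genes
  genes_rc$start <- L - tg$genes$end + 1L
  genes_rc$end <- L - tg$genes$start + 1L
  genes_rc$strand <- ifelse(tg$genes$strand == "+", "-", "+")

  set.seed(14)
  for (i in 1:40) {
    g <- tg$genes[sample(2, 1), ]
    pos <- sample(g$start:g$end, 1)
    ref <- substr(tg$genome[["chr"]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- data.frame(strain = "m", contig = "chr", pos = pos,
                    ref = ref, alt = alt)
    comp <- function(x) as.character(Biostrings::complement(
      Biostrings::DNAString(x)))
    v_rc <- data.frame(strain = "m", contig = "chr", pos = L - pos + 1L,
                       ref = comp(ref), alt = comp(alt))
    expect_equal(annotate_effect(v, tg$genes, tg$genome)$effect,
                 annotate_effect(v_rc, genes_rc, rc)$effect)
  }
})

make_screen_fixture <- function() {
  # three genes: an ordinary one, an IS element, a short hypothetical
  genes <- flag_gene_models(data.frame(
    gene_id = c("gene_a", "is_1", "hyp_1"),
    contig = "c", strand = "+",
    start = c(100L, 1000L, 2000L), end = c(400L, 1900L, 2200L),
    product = c("kinase", "IS family transposase", "hypothetical protein")))
  genes
}

test_that("artifact filtering requires recurrence AND a flagged gene", {
  genes <- make_screen_fixture()
  v <- data.frame(
    strain = c("m1", "m2", "m3",  # identical substitution in an IS gene
               "m1",              # unique variant in the same IS gene
               "m1", "m2"),       # identical substitution in an unflagged gene
    contig = "c",
    pos = c(1500L, 1500L, 1500L, 1600L, 200L, 200L),
    ref = "A", alt = "T",
    gene_id = c("is_1", "is_1", "is_1", "is_1", "gene_a", "gene_a"),
    effect = "nonsynonymous")

  kept <- filter_artifacts(v, genes)
  log <- attr(kept, "removal_log")
  # the recurrent IS-gene substitution is removed from all three strains
  expect_equal(nrow(log), 3L)
  expect_true(all(log$pos == 1500L))
  # the strain-unique IS-gene variant is kept
  expect_true(any(kept$pos == 1600L))
  # recurrence in an unflagged gene is kept under AND semantics ...
  expect_equal(sum(kept$pos == 200L), 2L)
  # ... and removed under the OR sensitivity mode
  kept_or <- filter_artifacts(v, genes, mode = "either")
  expect_false(any(kept_or$pos == 200L))
})

test_that("artifact filtering never removes a strain-unique variant", {
  genes <- make_screen_fixture()
  set.seed(15)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    v <- data.frame(
      strain = sprintf("m%d", sample(5, n, replace = TRUE)),
      contig = "c",
      pos = sample(c(150L, 1500L, 2100L), n, replace = TRUE),
      ref = sample(c("A", "G"), n, replace = TRUE), alt = "T",
      effect = "nonsynonymous")
    v$gene_id <- c("gene_a", "is_1", "hyp_1")[match(v$pos,
                                                    c(150L, 1500L, 2100L))]
    kept <- filter_artifacts(v, genes)
    key <- paste(v$contig, v$pos, v$ref, v$alt)
    uniq_keys <- names(which(vapply(split(v$strain, key),
                                    function(s) length(unique(s)),
                                    integer(1)) == 1))
    kept_key <- paste(kept$contig, kept$pos, kept$ref, kept$alt)
    expect_true(all(uniq_keys %in% kept_key))
  }
})

test_that("recurrence ranking counts distinct complete-loss strains per gene", {
  ph <- data.frame(strain = c(sprintf("L%d", 1:7), "R1", "W1"),
                   phenotype = c(rep("ina_lost", 7), "ina_reduced",
                                 "wild_type"))
  v <- data.frame(
    strain = c("L1", "L2", "L3", "L4", "L5",   # five strains hit geneA
               "L1",                           # second hit, same strain
               "L6", "L7",                     # two strains hit geneB
               "R1", "W1",                     # non-lost strains hit geneC
               "L1"),                          # synonymous hit in geneB
    contig = "c", pos = 1:11, ref = "A", alt = "T",
    gene_id = c(rep("geneA", 6), "geneB", "geneB", "geneC", "geneC",
                "geneB"),
    effect = c(rep("nonsynonymous", 5), "frameshift", "nonsynonymous",
               "nonsynonymous", "nonsynonymous", "nonsynonymous",
               "synonymous"))

  hits <- recurrently_hit_genes(v, ph, min_strains = 2)
  expect_equal(hits$gene_id, c("geneA", "geneB"))
  expect_equal(hits$n_strains, c(5L, 2L))

  # no variants: empty ranking
  empty <- recurrently_hit_genes(v[0, ], ph, min_strains = 2)
  expect_equal(nrow(empty), 0L)

  # reduced strains are counted only when requested
  hits2 <- recurrently_hit_genes(v, ph, min_strains = 1,
                                 include_reduced = TRUE)
  expect_true("geneC" %in% hits2$gene_id)
  expect_equal(hits2$n_strains[hits2$gene_id == "geneC"], 1L)
})

test_that("recurrence ranking matches brute force and ignores labels/order", {
  set.seed(16)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    v <- data.frame(
      strain = sprintf("s%d", sample(6, n, replace = TRUE)),
      contig = "c", pos = seq_len(n), ref = "A", alt = "T",
      gene_id = sprintf("g%d", sample(5, n, replace = TRUE)),
      effect = sample(c("nonsynonymous", "synonymous", "frameshift",
                        "intergenic"), n, replace = TRUE))
    ph <- data.frame(strain = sprintf("s%d", 1:6),
                     phenotype = sample(c("ina_lost", "wild_type"), 6,
                                        replace = TRUE))
    hits <- recurrently_hit_genes(v, ph, min_strains = 1)

    # brute-force nested counting over (gene, strain)
    lost <- ph$strain[ph$phenotype == "ina_lost"]
    cand <- c("nonsynonymous", "nonsense", "frameshift", "inframe_indel")
    want <- list()
    for (g in unique(v$gene_id)) {
      s <- unique(v$strain[v$gene_id == g & v$effect %in% cand &
                             v$strain %in% lost])
      if (length(s) >= 1) want[[g]] <- length(s)
    }
    expect_equal(nrow(hits), length(want))
    for (g in names(want)) {
      expect_equal(hits$n_strains[hits$gene_id == g], want[[g]])
    }

    # invariance under strain relabeling and row order
    perm <- sample(nrow(v))
    relab <- setNames(sprintf("x%d", sample(6)), sprintf("s%d", 1:6))
    v2 <- v[perm, ]
    v2$strain <- unname(relab[v2$strain])
    ph2 <- ph; ph2$strain <- unname(relab[ph2$strain])
    hits2 <- recurrently_hit_genes(v2, ph2, min_strains = 1)
    expect_equal(hits2$gene_id, hits$gene_id)
    expect_equal(hits2$n_strains, hits$n_strains)
  }
})
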