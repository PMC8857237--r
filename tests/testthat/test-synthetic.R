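# Generator determinism, planted-truth recovery, and model calibration.

test_that("generator configuration is strict and seeded", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(1, not_a_knob = 2), "unknown generator")
  expect_error(generator_config(1, target_ids = c("A", "A")), "distinct")
  expect_error(generator_config(1, mutation_lambda = 0), "positive")
  cfg <- generator_config(3, n_unique = 10L)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_unique, 10L)
  expect_equal(cfg$n_genomes, 19L)
})

test_that("identical config and seed give identical bundles", {
  b1 <- gen_funnel_fixture(small_config(seed = 21))
  b2 <- gen_funnel_fixture(small_config(seed = 21))
  expect_identical(b1$pa$occupancy, b2$pa$occupancy)
  expect_identical(b1$expression, b2$expression)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$assays, b2$assays)

  # and byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_gt(length(f1), 5)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }

  b3 <- gen_funnel_fixture(small_config(seed = 22))
  expect_false(identical(b1$expression$count, b3$expression$count))
})

test_that("the pan-genome plants exactly the clade-unique clusters", {
  cfg <- small_config(seed = 23)
  pa <- gen_pangenome(cfg)
  got <- unique_to_clade(pa, cfg$target_ids)
  expect_setequal(got, unname(attr(pa, "unique_tags")))
  expect_length(got, cfg$n_unique)

  # distractor categories never leak through the filter
  cat <- attr(pa, "category")
  hit_rows <- rownames(pa$occupancy)[match(got, pa$occupancy[, "VT1065"])]
  expect_true(all(cat[match(hit_rows, rownames(pa$occupancy))] == "unique"))

  # permuting genome columns leaves the recovered set unchanged
  perm <- pa_matrix(pa$occupancy[, sample(ncol(pa$occupancy))])
  expect_setequal(unique_to_clade(perm, cfg$target_ids), unname(got))

  # n_unique = 0 means nothing passes
  pa0 <- gen_pangenome(small_config(seed = 23, n_unique = 0L))
  expect_length(unique_to_clade(pa0, cfg$target_ids), 0)
})

test_that("expression generation forces the chosen zeros and calibrates NB mass", {
  cfg <- small_config(seed = 24)
  ids <- sprintf("g%04d", 1:2000)
  expr <- gen_expression(cfg, ids, unique_gene_ids = ids[1:100],
                         protect_ids = ids[1:10])
  zero_ids <- attr(expr, "zero_ids")
  expect_length(zero_ids, cfg$n_zero_expression)
  expect_true(all(expr$tpm[expr$gene_id %in% zero_ids] == 0))
  expect_false(any(zero_ids %in% ids[1:10]))
  expect_equal(sum(expr$tpm), 1e6, tolerance = 1e-6)
  expect_equal(expr$tpm == 0, expr$count == 0)

  expect_error(gen_expression(small_config(seed = 1,
                                           n_zero_expression = 9L),
                              ids[1:20], unique_gene_ids = ids[1:5]),
               "exceeds")

  # NB mass at zero matches the stated parameters (3-sigma band)
  cfg2 <- small_config(seed = 25, nb_mean = 2, nb_size = 1,
                       n_zero_expression = 0L)
  e2 <- gen_expression(cfg2, ids)
  p0 <- (1 / (1 + 2))^1
  emp <- mean(e2$count == 0)
  expect_lt(abs(emp - p0), 3 * sqrt(p0 * (1 - p0) / length(ids)))
})

test_that("the generated genome carries the planted cluster template", {
  g <- gen_bgc_genome(small_config(seed = 26))
  res <- call_bgc_core(g$genes)
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$n_core, 5L)
  expect_setequal(res$core_genes, unname(g$focal_genes))

  # the causal pair is the PKS and NRPS genes, adjacent on the contig
  pks <- g$genes[g$genes$gene_id == g$causal_gene_ids[1], ]
  nrps <- g$genes[g$genes$gene_id == g$causal_gene_ids[2], ]
  expect_equal(pks$product_class, "T1-PKS")
  expect_equal(nrps$product_class, "NRPS")
  expect_lt(abs(nrps$start - pks$end), 300)

  # every CDS is a clean ORF: in frame and stop-free except the terminator
  genome <- as.character(g$genome)
  for (i in sample(nrow(g$genes), 10)) {
    gi <- g$genes[i, ]
    cds <- substr(genome[[gi$contig]], gi$start, gi$end)
    d <- Biostrings::DNAString(cds)
    if (gi$strand == "-") d <- Biostrings::reverseComplement(d)
    aa <- as.character(Biostrings::translate(d))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }

  # with an extra planted cluster the genome carries ten core genes
  g2 <- gen_bgc_genome(small_config(seed = 26, n_extra_clusters = 1L))
  res2 <- call_bgc_core(g2$genes)
  expect_length(res2$core_genes, 10L)
  expect_equal(nrow(res2$regions), 2L)

  # stripping the signature domains removes every region
  bare <- g$genes
  bare$domains <- ""
  expect_equal(nrow(call_bgc_core(bare)$regions), 0L)
})

test_that("mutant generation plants causal hits, artifacts, and Poisson load", {
  cfg <- small_config(seed = 27)
  g <- gen_bgc_genome(cfg)
  mut <- gen_mutants(cfg, g$genome, g$genes, g$causal_gene_ids)
  v <- annotate_effect(mut$variants, g$genes, g$genome)

  # wild-type and reduced strains never receive causal hits
  lost <- mut$phenotypes$strain[mut$phenotypes$phenotype == "ina_lost"]
  in_causal <- v[!is.na(v$gene_id) & v$gene_id %in% g$causal_gene_ids, ]
  expect_true(all(in_causal$strain %in% lost))
  expect_setequal(unique(in_causal$strain), lost)

  # every planted causal hit is a candidate-effect variant
  expect_true(all(in_causal$effect %in%
                    c("nonsynonymous", "frameshift", "inframe_indel")))

  # artifact filtering removes the planted artifacts but no causal hit
  kept <- filter_artifacts(v, g$genes)
  log <- attr(kept, "removal_log")
  removed_keys <- unique(paste(log$contig, log$pos, log$ref, log$alt,
                               sep = ":"))
  expect_setequal(removed_keys, mut$truth$artifact_keys)
  kept_causal <- kept[!is.na(kept$gene_id) &
                        kept$gene_id %in% g$causal_gene_ids, ]
  expect_equal(nrow(kept_causal), nrow(in_causal))

  # recurrence ranking recovers exactly the two planted genes
  hits <- recurrently_hit_genes(kept, mut$phenotypes, min_strains = 2)
  expect_setequal(hits$gene_id, g$causal_gene_ids)
  expect_equal(sort(hits$n_strains, decreasing = TRUE),
               sort(unname(cfg$causal_split), decreasing = TRUE))
})

test_that("background mutation load is Poisson with the configured mean", {
  cfg <- small_config(seed = 28, n_lost = 0L, n_reduced = 0L, n_wt = 400L,
                      n_artifact_variants = 0L)
  g <- gen_bgc_genome(cfg)
  mut <- gen_mutants(cfg, g$genome, g$genes)
  n <- mut$truth$n_background
  expect_length(n, 400L)
  se <- sqrt(cfg$mutation_lambda / length(n))
  expect_lt(abs(mean(n) - cfg$mutation_lambda), 3 * se)
})

test_that("droplet assays follow the Poisson activation model", {
  cfg <- small_config(seed = 29)

  # a zero spectrum never freezes anything
  ts0 <- spectrum_model(cfg)
  ts0$k_per_cfu <- 0
  a0 <- gen_droplet_assay(cfg, true_spectrum = ts0)
  expect_true(all(a0$assay$frozen == 0))
  expect_true(all(a0$control$frozen == 0))

  # empirical unfrozen fraction matches the Poisson void probability
  cfg2 <- small_config(seed = 30, n_drops = 2000L, n_replicates = 1L,
                       n_dilutions = 1L)
  sim <- gen_droplet_assay(cfg2)
  a <- sim$assay
  for (i in seq_len(nrow(a))) {
    k <- sim$true_spectrum$k_per_cfu[
      sim$true_spectrum$temperature_c == a$temperature_c[i]]
    p_unfrozen <- exp(-k * a$cfu_per_drop[i])
    se <- sqrt(p_unfrozen * (1 - p_unfrozen) / a$n_drops[i])
    emp <- 1 - a$frozen[i] / a$n_drops[i]
    expect_lt(abs(emp - p_unfrozen), 3 * se + 1e-12)
  }

  # a non-monotone spectrum is rejected
  bad <- spectrum_model(cfg)
  bad$k_per_cfu[6] <- bad$k_per_cfu[11] * 2
  expect_error(gen_droplet_assay(cfg, true_spectrum = bad), "non-decreasing")
})

test_that("the spectrum estimator recovers the generating spectrum", {
  cfg <- small_config(seed = 31, n_drops = 300L, n_replicates = 3L)
  sim <- gen_droplet_assay(cfg, strain = "s")
  est <- spectrum_from_assay(sim$assay)
  truth <- sim$true_spectrum

  # delta-method standard error of the droplet-number-weighted estimator
  pooled <- aggregate(cbind(n_drops, frozen) ~ temperature_c +
                        dilution_factor + cfu_per_drop, sim$assay, sum)
  for (t in est$temperature_c) {
    k_true <- truth$k_per_cfu[truth$temperature_c == t]
    pt <- pooled[pooled$temperature_c == t, ]
    inf <- pt$frozen > 0 & pt$frozen < pt$n_drops
    if (!any(inf) || k_true == 0) next
    pt <- pt[inf, ]
    p_unfrozen <- exp(-k_true * pt$cfu_per_drop)
    var_d <- (1 - p_unfrozen) / (pt$n_drops * p_unfrozen) /
      pt$cfu_per_drop^2
    w <- pt$n_drops
    se <- sqrt(sum(w^2 * var_d)) / sum(w)
    k_hat <- est$k_per_cfu[est$temperature_c == t]
    expect_lt(abs(k_hat - k_true), 3 * se,
              label = sprintf("spectrum recovery at %d degC", t))
  }
})
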