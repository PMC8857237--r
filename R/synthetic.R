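# Seeded synthetic-data generator: every pipeline input can be produced in
# memory with the statistical structure the analysis assumes, including the
# replay fixture whose planted truth reproduces the published funnel stage
# structure (fixture parameters live in inst/extdata/in_paper.yaml, not in
# pipeline logic).

generator_defaults <- function() {
  list(
    # pan-genome
    n_genomes = 19L,
    target_ids = c("VT1065", "BAM-582"),
    reference_id = "VT1065",
    n_core = 1200L,
    n_shell = 600L,
    n_unique = 60L,
    n_target_partial = 25L,
    n_near_unique = 25L,
    # expression
    nb_mean = 200,
    nb_size = 5,
    n_zero_expression = 3L,
    # genome / BGC template
    n_background_genes = 60L,
    n_extra_clusters = 0L,
    # mutant screen
    mutation_lambda = 4,
    n_lost = 7L,
    n_reduced = 2L,
    n_wt = 1L,
    causal_split = c(t1pks = 5L, nrps = 2L),
    n_artifact_variants = 3L,
    background_disjoint = TRUE,
    # droplet assay protocol
    n_drops = 30L,
    n_dilutions = 6L,
    n_replicates = 3L,
    start_cfu_per_ml = 1e8,
    drop_volume_ul = 20,
    temperature_grid = seq(-2, -12),
    # freezing spectrum model
    spectrum_onset = -4,
    spectrum_log_slope = 0.7,
    spectrum_k_onset = 1e-7
  )
}

#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults matching the study
#' protocol (19 genomes with two target strains, six tenfold dilutions from
#' 10^8 CFU/ml, thirty 20-uL droplets, three replicates, a mean UV mutation
#' load of 4, seven complete-loss and two reduced mutants split 5/2 across
#' the two causal genes). Identical `(seed, parameters)` produce identical
#' outputs. Unknown parameter names are rejected.
#'
#' @param seed Integer seed (mandatory); all randomness in the generator
#'   flows from it.
#' @param ... Overrides of the defaults; see `generator_defaults()` in the
#'   package source for the full list.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, ...) {
  if (missing(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is mandatory", call. = FALSE)
  }
  defaults <- generator_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, dots)
  cfg$seed <- as.integer(seed)
  if (length(cfg$target_ids) != 2 ||
      cfg$target_ids[1] == cfg$target_ids[2]) {
    stop("target_ids must be 2 distinct genome ids", call. = FALSE)
  }
  if (!cfg$reference_id %in% cfg$target_ids) {
    stop("reference_id must be one of target_ids", call. = FALSE)
  }
  counts <- c(cfg$n_core, cfg$n_shell, cfg$n_unique, cfg$n_target_partial,
              cfg$n_near_unique, cfg$n_zero_expression, cfg$n_lost,
              cfg$n_reduced, cfg$n_wt, cfg$n_artifact_variants)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$mutation_lambda <= 0) {
    stop("mutation_lambda must be positive", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Path to / contents of the in-study replay fixture configuration
#'
#' The replay fixture encodes, as generator parameters, the stage structure
#' of the published funnel (2993 clade-unique genes of which 7 are
#' unexpressed, 10 biosynthetic core genes among two clusters, seven
#' complete-loss mutants split 5/2 over the two causal genes). The values
#' live in a versioned YAML file shipped with the package.
#'
#' @param seed Integer seed for the bundle.
#' @return A `generator_config` built from the YAML file.
#' @export
in_paper_config <- function(seed) {
  path <- system.file("extdata", "in_paper.yaml", package = "linafunnel",
                      mustWork = TRUE)
  vals <- yaml::read_yaml(path)
  vals$fixture_version <- NULL
  if (!is.null(vals$causal_split)) {
    vals$causal_split <- unlist(vals$causal_split)
  }
  do.call(generator_config, c(list(seed = seed), vals))
}

# ---- sequence helpers -------------------------------------------------------

NON_STOP_CODONS <- local({
  code <- c(Biostrings::GENETIC_CODE)
  names(code)[code != "*"]
})

random_cds <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, len_nt / 3 - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- genome with planted biosynthetic cluster ------------------------------

cluster_gene_specs <- function(prefix = "") {
  # the five-gene template: accessory transferase + epimerase/dehydratase,
  # an intergenic gap, then the PKS-NRPS-thioesterase operon
  list(
    list(key = paste0(prefix, "pptase"), len = 720,
         product = "4'-phosphopantetheinyl transferase",
         class = "biosynthetic-additional", domains = "PPTASE"),
    list(key = paste0(prefix, "epim_dh"), len = 930,
         product = "NAD-dependent epimerase/dehydratase",
         class = "biosynthetic-additional", domains = "EPIM_DH",
         gap_after = 182),
    list(key = paste0(prefix, "t1pks"), len = 5100,
         product = "type I polyketide synthase",
         class = "T1-PKS", domains = "KS,AT,DH,KR,ACP"),
    list(key = paste0(prefix, "nrps"), len = 6300,
         product = "non-ribosomal peptide synthetase",
         class = "NRPS", domains = "C,A,PCP,C,A,PCP"),
    list(key = paste0(prefix, "te"), len = 750,
         product = "thioesterase", class = "biosynthetic-additional",
         domains = "TE")
  )
}

extra_cluster_specs <- function(idx) {
  p <- sprintf("x%d_", idx)
  list(
    list(key = paste0(p, "pks_a"), len = 3000,
         product = "polyketide synthase", class = "T1-PKS",
         domains = "KS,AT,ACP"),
    list(key = paste0(p, "nrps_a"), len = 3000,
         product = "non-ribosomal peptide synthetase", class = "NRPS",
         domains = "C,A,PCP"),
    list(key = paste0(p, "pks_b"), len = 3600,
         product = "polyketide synthase", class = "T1-PKS",
         domains = "KS,DH,KR,ACP"),
    list(key = paste0(p, "nrps_b"), len = 2700,
         product = "non-ribosomal peptide synthetase", class = "NRPS",
         domains = "C,A,PCP"),
    list(key = paste0(p, "te"), len = 660,
         product = "thioesterase", class = "biosynthetic-additional",
         domains = "TE")
  )
}

#' Generate a reference genome carrying a planted PKS-NRPS cluster
#'
#' Emits one contig containing the five-gene biosynthetic template
#' (phosphopantetheinyl transferase, epimerase/dehydratase, an intergenic gap,
#' then the T1-PKS, NRPS, and thioesterase genes), flanked by short
#' hypothetical genes, embedded among `n_background_genes` housekeeping CDSs
#' and two insertion-sequence elements. `n_extra_clusters` additional
#' five-core-gene clusters can be planted elsewhere on the contig (the replay
#' fixture uses one, so that the genome carries ten core genes in total).
#'
#' @param config A [generator_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes` (gene
#'   models with domains/products/flags), `unique_gene_ids` (genes planted as
#'   clade-unique), `shared_gene_ids`, `causal_gene_ids` (T1-PKS and NRPS
#'   locus tags), and `focal_genes` (named locus tags of the template).
#' @export
gen_bgc_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed + 101L, {
    ref <- gsub("[^A-Za-z0-9]", "", config$reference_id)
    nbg <- config$n_background_genes
    bg_lens <- 3 * sample(200:400, nbg, replace = TRUE)

    specs <- list()
    add_bg <- function(specs, n, from) {
      if (n <= 0) return(specs)
      for (j in seq_len(n)) {
        i <- from + j - 1
        if (i > nbg) break
        specs[[length(specs) + 1]] <- list(
          key = sprintf("bg%03d", i), len = bg_lens[i],
          product = "conserved protein", class = "other", domains = "",
          strand = if (i %% 3 == 0) "-" else "+")
      }
      specs
    }
    is_spec <- function(i) {
      list(key = sprintf("is%d", i), len = 903,
           product = "IS family transposase", class = "IS", domains = "",
           mobile_element_type = "insertion sequence:ISLsp1")
    }
    hyp_spec <- function(i, len) {
      list(key = sprintf("hyp%d", i), len = len,
           product = "hypothetical protein", class = "hypothetical",
           domains = "")
    }

    specs <- add_bg(specs, 15, 1)
    specs[[length(specs) + 1]] <- is_spec(1)
    specs <- add_bg(specs, 10, 16)
    specs[[length(specs) + 1]] <- hyp_spec(1, 240)
    specs <- c(specs, cluster_gene_specs())
    specs[[length(specs) + 1]] <- hyp_spec(2, 450)
    specs <- add_bg(specs, 12, 26)
    if (config$n_extra_clusters > 0) {
      for (k in seq_len(config$n_extra_clusters)) {
        xtr <- extra_cluster_specs(k)
        # a spacer beyond the merge window keeps each planted cluster a
        # separate region regardless of how many background genes remain
        xtr[[1]]$gap_before <- 12000L
        specs <- c(specs, xtr)
        specs <- add_bg(specs, 6, 38 + (k - 1) * 6)
      }
    }
    used_bg <- if (config$n_extra_clusters > 0) {
      min(nbg, 37 + config$n_extra_clusters * 6)
    } else min(nbg, 37)
    specs[[length(specs) + 1]] <- is_spec(2)
    specs <- add_bg(specs, nbg - used_bg, used_bg + 1)

    # lay genes along the contig
    seqs <- character(0)
    rows <- vector("list", length(specs))
    pos <- 1L
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      if (!is.null(sp$gap_before)) {
        seqs <- c(seqs, random_nt(sp$gap_before))
        pos <- pos + sp$gap_before
      }
      gap <- sample(80:220, 1)
      seqs <- c(seqs, random_nt(gap))
      pos <- pos + gap
      cds <- random_cds(sp$len)
      strand <- if (is.null(sp$strand)) "+" else sp$strand
      seqs <- c(seqs, if (strand == "+") cds else revcomp(cds))
      rows[[i]] <- data.frame(
        key = sp$key,
        gene_id = NA_character_, contig = "contig_1", strand = strand,
        start = pos, end = pos + sp$len - 1L,
        product = sp$product, product_class = sp$class,
        domains = sp$domains,
        mobile_element_type = if (is.null(sp$mobile_element_type))
          NA_character_ else sp$mobile_element_type)
      pos <- pos + sp$len
      extra_gap <- if (is.null(sp$gap_after)) 0L else sp$gap_after
      if (extra_gap > 0) {
        seqs <- c(seqs, random_nt(extra_gap))
        pos <- pos + extra_gap
      }
    }
    seqs <- c(seqs, random_nt(150))
    genes <- do.call(rbind, rows)
    genes$gene_id <- sprintf("%s_%05d", ref, seq_len(nrow(genes)) * 5L)

    genome <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
    names(genome) <- "contig_1"

    unique_classes <- c("T1-PKS", "NRPS", "biosynthetic-additional",
                        "hypothetical")
    unique_ids <- genes$gene_id[genes$product_class %in% unique_classes]
    shared_ids <- setdiff(genes$gene_id, unique_ids)
    focal <- genes$gene_id[match(c("pptase", "epim_dh", "t1pks", "nrps", "te"),
                                 genes$key)]
    names(focal) <- c("pptase", "epim_dh", "t1pks", "nrps", "te")
    genes$key <- NULL
    list(genome = genome,
         genes = flag_gene_models(genes),
         unique_gene_ids = unique_ids,
         shared_gene_ids = shared_ids,
         causal_gene_ids = unname(focal[c("t1pks", "nrps")]),
         focal_genes = focal)
  })
}

# ---- pan-genome -------------------------------------------------------------

#' Generate a pan-genome presence/absence matrix with planted clade-unique genes
#'
#' Plants `n_unique` clusters present in both target genomes and absent
#' everywhere else, among distractors: core clusters (all genomes), shell
#' clusters (random genome subsets, never a subset of the targets),
#' target-partial clusters (exactly one target, nothing else), and
#' near-unique clusters (both targets plus exactly one non-target).
#'
#' @param config A [generator_config()].
#' @param catalog Optional list with `unique` and `core` character vectors of
#'   reference-genome locus tags that must name the first planted clusters of
#'   each category (used to tie the matrix to a generated genome).
#' @return A [pa_matrix()]; attributes `"unique_tags"`, `"genome_ids"` record
#'   the planted truth.
#' @export
gen_pangenome <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(catalog)) {
    if (length(catalog$unique) > config$n_unique ||
        length(catalog$core) > config$n_core) {
      stop("catalog larger than configured cluster counts", call. = FALSE)
    }
  }
  withr::with_seed(config$seed + 202L, {
    n_other <- config$n_genomes - 2L
    others <- sprintf("LSP%02d", seq_len(n_other))
    genomes <- c(config$reference_id,
                 setdiff(config$target_ids, config$reference_id), others)
    targets <- config$target_ids

    n_all <- config$n_unique + config$n_core + config$n_shell +
      config$n_target_partial + config$n_near_unique
    category <- rep(c("unique", "core", "shell", "partial", "near"),
                    c(config$n_unique, config$n_core, config$n_shell,
                      config$n_target_partial, config$n_near_unique))
    present <- matrix(FALSE, n_all, length(genomes),
                      dimnames = list(NULL, genomes))
    present[category == "unique", targets] <- TRUE
    present[category == "core", ] <- TRUE
    for (i in which(category == "shell")) {
      repeat {
        k <- sample(2:(length(genomes) - 1), 1)
        sub <- sample(genomes, k)
        if (!all(sub %in% targets)) break
      }
      present[i, sub] <- TRUE
    }
    ip <- which(category == "partial")
    present[cbind(ip, match(targets[1 + (seq_along(ip) %% 2)], genomes))] <- TRUE
    for (i in which(category == "near")) {
      present[i, c(targets, sample(others, 1))] <- TRUE
    }

    # interleave categories so row order carries no signal
    ord <- sample(n_all)
    present <- present[ord, , drop = FALSE]
    category <- category[ord]

    occupancy <- matrix(NA_character_, n_all, length(genomes),
                        dimnames = list(sprintf("group_%05d", seq_len(n_all)),
                                        genomes))
    for (g in genomes) {
      idx <- which(present[, g])
      prefix <- gsub("[^A-Za-z0-9]", "", g)
      # counter offset keeps these clear of genome locus tags (which use
      # low numbers), so catalog substitution cannot create duplicates
      occupancy[idx, g] <- sprintf("%s_%05d", prefix,
                                   10000L + seq_along(idx) * 5L)
    }
    # tie planted reference tags to the genome catalog
    if (!is.null(catalog)) {
      iu <- which(category == "unique")
      occupancy[iu[seq_along(catalog$unique)], config$reference_id] <-
        catalog$unique
      ic <- which(category == "core")
      occupancy[ic[seq_along(catalog$core)], config$reference_id] <-
        catalog$core
    }
    annotation <- c(unique = "clade-restricted protein",
                    core = "conserved protein",
                    shell = "accessory protein",
                    partial = "strain-specific protein",
                    near = "near-clade protein")[category]
    pa <- pa_matrix(occupancy, unname(annotation))
    attr(pa, "unique_tags") <- occupancy[category == "unique",
                                         config$reference_id]
    attr(pa, "category") <- category
    pa
  })
}

# ---- expression -------------------------------------------------------------

#' Generate a negative-binomial expression table with planted zero-expression genes
#'
#' Counts are drawn from NB(`nb_mean`, `nb_size`); effective lengths are
#' uniform on 300-6000 nt. Exactly `n_zero_expression` of the clade-unique
#' genes are forced to zero counts, sampled outside `protect_ids` (the replay
#' fixture protects the biosynthetic core genes, which the study found
#' expressed).
#'
#' @param config A [generator_config()].
#' @param gene_ids All gene ids the table should cover.
#' @param unique_gene_ids The clade-unique subset from which the
#'   zero-expression genes are drawn.
#' @param protect_ids Genes that must never be forced to zero.
#' @return An [expression_table()]; attribute `"zero_ids"` records the
#'   planted zero-expression genes.
#' @export
gen_expression <- function(config, gene_ids, unique_gene_ids = gene_ids,
                           protect_ids = character()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_zero_expression > length(unique_gene_ids)) {
    stop("n_zero_expression exceeds the number of unique genes",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 303L, {
    n <- length(gene_ids)
    counts <- stats::rnbinom(n, mu = config$nb_mean, size = config$nb_size)
    lengths <- round(stats::runif(n, 300, 6000))
    eligible <- setdiff(unique_gene_ids, protect_ids)
    if (config$n_zero_expression > length(eligible)) {
      stop("n_zero_expression exceeds the eligible unique genes",
           call. = FALSE)
    }
    zero_ids <- sample(eligible, config$n_zero_expression)
    counts[match(zero_ids, gene_ids)] <- 0L
    # a forced-zero table must still normalise
    if (all(counts == 0)) counts[which.max(!gene_ids %in% zero_ids)] <- 1L
    expr <- expression_table(gene_ids, counts, lengths)
    attr(expr, "zero_ids") <- zero_ids
    expr
  })
}

# ---- mutants ----------------------------------------------------------------

snp_candidates <- function(base) setdiff(c("A", "C", "G", "T"), base)

# construct a guaranteed-missense SNP inside a CDS, strand-aware
make_missense_snp <- function(gene, genome_seq, code) {
  n_codons <- (gene$end - gene$start + 1) %/% 3
  cds <- substr(genome_seq, gene$start, gene$end)
  if (gene$strand == "-") cds <- revcomp(cds)
  for (try in 1:50) {
    ci <- sample(2:(n_codons - 1), 1)      # skip start and stop codons
    cp <- sample(1:3, 1)
    codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    mbase <- substr(codon, cp, cp)
    for (alt_m in sample(snp_candidates(mbase))) {
      alt_codon <- codon
      substr(alt_codon, cp, cp) <- alt_m
      if (code[[alt_codon]] != code[[codon]] && code[[alt_codon]] != "*") {
        off <- (ci - 1) * 3 + cp - 1       # 0-based mRNA offset
        if (gene$strand == "+") {
          pos <- gene$start + off
          ref <- mbase; alt <- alt_m
        } else {
          pos <- gene$end - off
          ref <- as.character(Biostrings::complement(
            Biostrings::DNAString(mbase)))
          alt <- as.character(Biostrings::complement(
            Biostrings::DNAString(alt_m)))
        }
        return(list(pos = pos, ref = ref, alt = alt))
      }
    }
  }
  stop("could not construct a missense SNP in ", gene$gene_id, call. = FALSE)
}

make_indel <- function(gene, genome_seq, kind) {
  if (kind == "insertion") {
    pos <- sample(gene$start:(gene$end - 1L), 1)
    ref <- substr(genome_seq, pos, pos)
    list(pos = pos, ref = ref, alt = paste0(ref, sample(c("A", "C", "G", "T"), 1)))
  } else {
    pos <- sample(gene$start:(gene$end - 2L), 1)
    ref <- substr(genome_seq, pos, pos + 1L)
    list(pos = pos, ref = substr(genome_seq, pos, pos + 1L),
         alt = substr(genome_seq, pos, pos))
  }
}

#' Simulate UV-mutant variant sets with planted causal hits and artifacts
#'
#' Each strain receives a Poisson(`mutation_lambda`) number of background
#' candidate-effect variants (missense SNPs and single-nucleotide indels) at
#' random CDS positions. Complete-loss strains additionally receive causal
#' hits per `causal_split`: the first group hits the T1-PKS gene with one or
#' two missense SNPs or a single-nucleotide insertion, the second hits the
#' NRPS gene with one missense SNP. `n_artifact_variants` identical
#' substitutions are planted inside insertion-sequence genes across two or
#' more strains, emulating recurrent sequencing artifacts.
#'
#' Within the complete-loss strains, background variants are placed in
#' per-strain disjoint gene pools (`background_disjoint`), so that at desk
#' scale — where the gene count is far below a real genome's — no background
#' gene recurs across phenotype-positive strains, mirroring the study's
#' observation that only the two causal genes were recurrently hit.
#'
#' @param config A [generator_config()].
#' @param genome Contig sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param genes Flagged gene models (see [flag_gene_models()]).
#' @param causal_gene_ids Length-2 vector: the T1-PKS-like and NRPS-like
#'   gene ids receiving causal hits.
#' @return List with `variants` (strain, contig, pos, ref, alt, origin),
#'   `phenotypes` (strain, phenotype), and `truth` (per-strain background
#'   counts, causal hit table, artifact keys).
#' @export
gen_mutants <- function(config, genome, genes,
                        causal_gene_ids = character()) {
  stopifnot(inherits(config, "generator_config"))
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  need_causal <- config$n_lost > 0
  if (need_causal && length(causal_gene_ids) != 2) {
    stop("causal_gene_ids must name 2 genes when n_lost > 0", call. = FALSE)
  }
  if (need_causal && !all(causal_gene_ids %in% genes$gene_id)) {
    stop("causal genes absent from gene models: ",
         paste(setdiff(causal_gene_ids, genes$gene_id), collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(config$seed + 404L, {
    code <- c(Biostrings::GENETIC_CODE)
    strains <- c(sprintf("UV%03d", seq_len(config$n_lost + config$n_reduced)),
                 if (config$n_wt > 0) sprintf("WT%04d", seq_len(config$n_wt)))
    phenotype <- c(rep("ina_lost", config$n_lost),
                   rep("ina_reduced", config$n_reduced),
                   rep("wild_type", config$n_wt))
    phenotypes <- data.frame(strain = strains, phenotype = phenotype)

    eligible <- genes[!genes$gene_id %in% causal_gene_ids &
                        !genes$is_insertion_sequence, , drop = FALSE]
    lost_idx <- which(phenotype == "ina_lost")
    pool_of <- rep(list(seq_len(nrow(eligible))), length(strains))
    if (config$background_disjoint && length(lost_idx) > 0) {
      shuffled <- sample(nrow(eligible))
      blocks <- split(shuffled,
                      rep(seq_along(lost_idx), length.out = length(shuffled)))
      for (j in seq_along(lost_idx)) pool_of[[lost_idx[j]]] <- blocks[[j]]
    }

    rows <- list()
    n_background <- integer(length(strains))
    add <- function(strain, gene, v, origin) {
      rows[[length(rows) + 1]] <<- data.frame(
        strain = strain, contig = gene$contig, pos = v$pos,
        ref = v$ref, alt = v$alt, origin = origin)
    }
    for (s in seq_along(strains)) {
      nb <- stats::rpois(1, config$mutation_lambda)
      n_background[s] <- nb
      if (nb > 0) {
        gidx <- sample(pool_of[[s]], nb, replace = TRUE)
        types <- sample(c("snp", "insertion", "deletion"), nb, replace = TRUE,
                        prob = c(0.7, 0.15, 0.15))
        for (j in seq_len(nb)) {
          g <- eligible[gidx[j], ]
          v <- if (types[j] == "snp") {
            make_missense_snp(g, genome[[g$contig]], code)
          } else {
            make_indel(g, genome[[g$contig]], types[j])
          }
          add(strains[s], g, v, "background")
        }
      }
    }

    causal <- NULL
    if (need_causal) {
      pks <- genes[genes$gene_id == causal_gene_ids[1], ]
      nrps <- genes[genes$gene_id == causal_gene_ids[2], ]
      split1 <- config$causal_split[[1]]
      modes <- sample(c("snp1", "snp2", "ins"), split1, replace = TRUE)
      causal <- list()
      for (s in seq_len(config$n_lost)) {
        if (s <= split1) {
          g <- pks
          hits <- switch(modes[s],
                         snp1 = list(make_missense_snp(g, genome[[g$contig]], code)),
                         snp2 = list(make_missense_snp(g, genome[[g$contig]], code),
                                     make_missense_snp(g, genome[[g$contig]], code)),
                         ins = list(make_indel(g, genome[[g$contig]], "insertion")))
        } else {
          g <- nrps
          hits <- list(make_missense_snp(g, genome[[g$contig]], code))
        }
        for (v in hits) add(strains[s], g, v, "causal")
        causal[[length(causal) + 1]] <- data.frame(
          strain = strains[s], gene_id = g$gene_id, n_hits = length(hits))
      }
      causal <- do.call(rbind, causal)
    }

    artifact_keys <- character(0)
    is_genes <- genes[genes$is_insertion_sequence, , drop = FALSE]
    if (config$n_artifact_variants > 0 && nrow(is_genes) > 0 &&
        length(strains) >= 2) {
      for (k in seq_len(config$n_artifact_variants)) {
        g <- is_genes[sample(nrow(is_genes), 1), ]
        pos <- sample(g$start:g$end, 1)
        ref <- substr(genome[[g$contig]], pos, pos)
        alt <- sample(snp_candidates(ref), 1)
        n_sh <- sample(2:min(4, length(strains)), 1)
        for (s in sample(strains, n_sh)) {
          add(s, g, list(pos = pos, ref = ref, alt = alt), "artifact")
        }
        artifact_keys <- c(artifact_keys,
                           paste(g$contig, pos, ref, alt, sep = ":"))
      }
    }

    variants <- if (length(rows) > 0) {
      do.call(rbind, rows)
    } else {
      data.frame(strain = character(), contig = character(), pos = integer(),
                 ref = character(), alt = character(), origin = character())
    }
    variants <- variants[!duplicated(variants[c("strain", "contig", "pos",
                                                "ref", "alt")]), ]
    variants <- variants[order(variants$strain, variants$contig,
                               variants$pos), ]
    rownames(variants) <- NULL
    list(variants = variants, phenotypes = phenotypes,
         truth = list(n_background = stats::setNames(n_background, strains),
                      causal = causal, artifact_keys = artifact_keys))
  })
}

# ---- droplet assays ---------------------------------------------------------

#' Model freezing spectrum implied by a generator configuration
#'
#' \eqn{K(\Theta) = K_{onset} \cdot 10^{b (\Theta_{onset} - \Theta)}} for
#' \eqn{\Theta \le \Theta_{onset}}, zero above the onset: a log-linear
#' cumulative spectrum of the shape seen in droplet-freezing assays.
#'
#' @param config A [generator_config()].
#' @return Data frame `temperature_c`, `k_per_cfu` over the config's grid.
#' @export
spectrum_model <- function(config) {
  t <- config$temperature_grid
  k <- ifelse(t <= config$spectrum_onset,
              config$spectrum_k_onset *
                10^(config$spectrum_log_slope * (config$spectrum_onset - t)),
              0)
  data.frame(temperature_c = t, k_per_cfu = k)
}

#' Simulate a droplet-freezing dilution assay from a known spectrum
#'
#' Uses the stochastic-nucleation model that underlies the cumulative-K
#' estimator: the number of INPs active at or above \eqn{\Theta} in a droplet
#' with \eqn{A} CFU is Poisson\eqn{(K(\Theta) A)}, so the droplet is frozen at
#' \eqn{\Theta} with probability \eqn{1 - e^{-K(\Theta) A}}. Each droplet's
#' freezing temperature is drawn by thresholding one exponential deviate
#' against the cumulative \eqn{K(\Theta) A} curve, which couples the draws
#' across temperatures and guarantees cumulative frozen counts.
#'
#' @param config A [generator_config()] (protocol: dilutions, droplets,
#'   replicates, starting concentration).
#' @param true_spectrum Data frame `temperature_c`, `k_per_cfu`
#'   (non-decreasing as temperature falls); defaults to
#'   [spectrum_model()]`(config)`.
#' @param strain Strain label for the output.
#' @param seed_offset Increment applied to the config seed, so different
#'   strains in one bundle get independent draws.
#' @return List with `assay` (long assay data frame), `control` (water
#'   control: same protocol, nothing freezes above -12 degC), and
#'   `true_spectrum`.
#' @export
gen_droplet_assay <- function(config, true_spectrum = NULL,
                              strain = "synthetic", seed_offset = 0L) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(true_spectrum)) true_spectrum <- spectrum_model(config)
  ord <- order(-true_spectrum$temperature_c)
  temps <- true_spectrum$temperature_c[ord]
  k <- true_spectrum$k_per_cfu[ord]
  if (any(k < 0) || is.unsorted(k)) {
    stop("true_spectrum must be non-negative and non-decreasing with cooling",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 505L + seed_offset, {
    dil <- 10^(seq_len(config$n_dilutions) - 1)
    a0 <- config$start_cfu_per_ml * config$drop_volume_ul / 1000
    rows <- list()
    for (r in seq_len(config$n_replicates)) {
      for (d in dil) {
        a <- a0 / d
        u <- stats::rexp(config$n_drops)
        frozen <- vapply(k * a, function(ka) sum(u <= ka), numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          strain = strain, replicate = r, dilution_factor = d,
          cfu_per_drop = a, temperature_c = temps,
          n_drops = config$n_drops, frozen = as.integer(frozen))
      }
    }
    assay <- do.call(rbind, rows)
    control <- assay[assay$replicate == 1 & assay$dilution_factor == 1, ]
    control$strain <- "water_control"
    control$cfu_per_drop <- 1
    control$frozen <- 0L
    rownames(assay) <- rownames(control) <- NULL
    list(assay = assay, control = control, true_spectrum = true_spectrum)
  })
}

# ---- full fixture bundle ----------------------------------------------------

#' Generate a complete input bundle for the whole pipeline
#'
#' One call produces every input the analysis consumes — presence/absence
#' matrix, expression table, annotated genome, per-mutant variants with
#' phenotypes, and droplet assays — with planted truth recorded in `truth`.
#' Under the shipped replay configuration ([in_paper_config()]) the planted
#' truth reproduces the published funnel stage structure.
#'
#' @param config A [generator_config()], e.g. from [in_paper_config()].
#' @return A `funnel_bundle` list: `pa`, `expression`, `genome`, `genes`,
#'   `variants`, `phenotypes`, `assays` (named list per strain), `control`,
#'   `truth`, `config`.
#' @export
gen_funnel_fixture <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  g <- gen_bgc_genome(config)
  core_expected <- call_bgc_core(g$genes)$core_genes
  pan <- gen_pangenome(config, catalog = list(unique = g$unique_gene_ids,
                                              core = g$shared_gene_ids))
  unique_tags <- attr(pan, "unique_tags")
  ref_tags <- pan$occupancy[, config$reference_id]
  ref_tags <- ref_tags[!is.na(ref_tags)]
  expr <- gen_expression(config, gene_ids = unname(ref_tags),
                         unique_gene_ids = unique_tags,
                         protect_ids = core_expected)
  mut <- gen_mutants(config, g$genome, g$genes,
                     causal_gene_ids = g$causal_gene_ids)

  wt <- gen_droplet_assay(config, strain = "wild_type", seed_offset = 0L)
  assays <- list(wild_type = wt$assay)
  true_k <- spectrum_model(config)
  for (i in seq_len(nrow(mut$phenotypes))) {
    st <- mut$phenotypes$strain[i]
    ph <- mut$phenotypes$phenotype[i]
    if (ph == "wild_type") next
    ts <- true_k
    ts$k_per_cfu <- if (ph == "ina_lost") 0 else ts$k_per_cfu * 1e-3
    assays[[st]] <- gen_droplet_assay(config, true_spectrum = ts, strain = st,
                                      seed_offset = i)$assay
  }

  structure(list(
    pa = pan, expression = expr, genome = g$genome, genes = g$genes,
    variants = mut$variants, phenotypes = mut$phenotypes,
    assays = assays, control = wt$control,
    truth = list(unique_tags = unique_tags,
                 zero_ids = attr(expr, "zero_ids"),
                 core_expected = core_expected,
                 causal_gene_ids = g$causal_gene_ids,
                 focal_genes = g$focal_genes,
                 causal = mut$truth$causal,
                 artifact_keys = mut$truth$artifact_keys,
                 n_background = mut$truth$n_background,
                 true_spectrum = true_k),
    config = config
  ), class = "funnel_bundle")
}

#' @export
print.funnel_bundle <- function(x, ...) {
  cat("Synthetic funnel bundle (seed", x$config$seed, ")\n")
  cat("  pan-genome:", nrow(x$pa$occupancy), "clusters x",
      ncol(x$pa$occupancy), "genomes\n")
  cat("  expression:", nrow(x$expression), "genes\n")
  cat("  genome:", sum(Biostrings::width(x$genome)), "nt,",
      nrow(x$genes), "genes\n")
  cat("  mutants:", nrow(x$phenotypes), "strains,",
      nrow(x$variants), "variants\n")
  invisible(x)
}
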