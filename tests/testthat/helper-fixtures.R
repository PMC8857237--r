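# Shared fixture builders for the test suite. Everything is generated in
# code; seeds are fixed so the suite is deterministic.

small_config <- function(seed = 42, ...) {
  base <- list(n_core = 30L, n_shell = 20L, n_unique = 25L,
               n_target_partial = 5L, n_near_unique = 5L,
               n_zero_expression = 2L, n_background_genes = 12L,
               nb_mean = 50, nb_size = 5,
               n_lost = 4L, n_reduced = 1L, n_wt = 1L,
               causal_split = c(t1pks = 2L, nrps = 2L),
               n_artifact_variants = 2L)
  args <- utils::modifyList(base, list(...))
  do.call(generator_config, c(list(seed = seed), args))
}

# one assay row per temperature for a single physical series
make_series <- function(strain, replicate, dilution, a, temps, n0, frozen) {
  data.frame(strain = strain, replicate = replicate,
             dilution_factor = dilution, cfu_per_drop = a,
             temperature_c = temps, n_drops = n0, frozen = frozen)
}

# random valid single-strain assay: cumulative frozen counts by construction
random_assay <- function(n_dilutions = 3, n_reps = 2, n_temps = 6, n0 = 30) {
  temps <- seq(-2, by = -1, length.out = n_temps)
  rows <- list()
  for (d in 10^(seq_len(n_dilutions) - 1)) {
    for (r in seq_len(n_reps)) {
      frozen <- sort(sample(0:n0, n_temps, replace = TRUE))
      rows[[length(rows) + 1]] <-
        make_series("s", r, d, 2e6 / d, temps, n0, frozen)
    }
  }
  do.call(rbind, rows)
}

# a gene-model table mirroring the five-gene biosynthetic template
template_genes <- function(contig = "ctg") {
  data.frame(
    gene_id = c("pptase", "epim_dh", "t1pks", "nrps", "te"),
    contig = contig, strand = "+",
    start = c(1000, 2000, 3200, 8500, 15000),
    end = c(1720, 2930, 8300, 14800, 15750),
    product = c("phosphopantetheinyl transferase",
                "NAD-dependent epimerase/dehydratase",
                "type I polyketide synthase",
                "non-ribosomal peptide synthetase", "thioesterase"),
    domains = c("PPTASE", "EPIM_DH", "KS,AT,DH,KR,ACP",
                "C,A,PCP,C,A,PCP", "TE"))
}

# tiny genome with one + strand and one - strand CDS for effect tests:
# + strand CDS 101..109 is ATG GCT TAA
tiny_genome <- function() {
  set.seed(7)
  left <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  plus_cds <- "ATGGCTTAA"
  mid <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  # - strand gene: mRNA ATG GAT TCC TAA -> genomic revcomp
  minus_mrna <- "ATGGATTCCTAA"
  minus_cds <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(minus_mrna)))
  right <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  seq <- paste0(left, plus_cds, mid, minus_cds, right)
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    contig = "chr", strand = c("+", "-"),
    start = c(101L, 150L), end = c(109L, 161L),
    product = "protein", domains = "")
  list(genome = c(chr = seq), genes = flag_gene_models(genes))
}

# brute-force oracle: classify a SNP by translating the full mutated CDS
oracle_snp_effect <- function(variant, gene, genome) {
  seq <- genome[[variant$contig]]
  if (variant$pos < gene$start || variant$pos > gene$end) return("intergenic")
  mutated <- seq
  substr(mutated, variant$pos, variant$pos) <- variant$alt
  get_prot <- function(s) {
    cds <- substr(s, gene$start, gene$end)
    d <- Biostrings::DNAString(cds)
    if (gene$strand == "-") d <- Biostrings::reverseComplement(d)
    # literal codon-by-codon translation: a start-codon change is classified
    # like any other codon change, matching the per-codon rule under test
    as.character(Biostrings::translate(d, genetic.code =
                                         Biostrings::getGeneticCode("11"),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "solve"))
  }
  p_ref <- get_prot(seq)
  p_alt <- get_prot(mutated)
  if (p_ref == p_alt) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  if (substr(p_alt, i, i) == "*") "nonsense" else "nonsynonymous"
}
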