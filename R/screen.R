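# UV-mutant screen: variant effect annotation, artifact filtering,
# recurrence ranking.

CANDIDATE_EFFECTS <- c("nonsynonymous", "nonsense", "frameshift",
                       "inframe_indel")

#' Classify variant kind from allele lengths
#'
#' @param ref,alt Reference and alternate allele strings (VCF convention:
#'   indels are anchored at the base before the event).
#' @return `"snp"`, `"insertion"`, or `"deletion"`.
#' @export
variant_kind <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
  ifelse(nchar(ref) == nchar(alt), "snp",
         ifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
}

#' Build gene models with artifact-relevant flags
#'
#' Derives the two flags used by the artifact filter: a gene is an insertion
#' sequence when its `mobile_element_type` is set or its product mentions a
#' transposase/insertion sequence, and a short hypothetical when its product
#' contains "hypothetical" and its CDS is shorter than `short_nt`.
#'
#' @param genes Data frame with `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `product`, and optionally `mobile_element_type` and `domains`.
#' @param short_nt CDS-length cutoff (nt) for the short-hypothetical flag;
#'   default 300.
#' @return The input with logical columns `is_insertion_sequence` and
#'   `is_short_hypothetical` added (recomputed if present).
#' @export
flag_gene_models <- function(genes, short_nt = 300) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end", "product")
                %in% names(genes)))
  met <- if ("mobile_element_type" %in% names(genes)) {
    !is.na(genes$mobile_element_type) & nzchar(genes$mobile_element_type)
  } else FALSE
  genes$is_insertion_sequence <- met |
    grepl("transposase|insertion sequence", genes$product, ignore.case = TRUE)
  len <- genes$end - genes$start + 1
  genes$is_short_hypothetical <-
    grepl("hypothetical", genes$product, ignore.case = TRUE) & len < short_nt
  genes
}

locate_gene <- function(contig, pos, genes) {
  # first containing CDS in start order; NA when intergenic
  hits <- which(genes$contig == contig & genes$start <= pos & genes$end >= pos)
  if (length(hits) == 0) NA_integer_ else hits[which.min(genes$start[hits])]
}

#' Annotate coding effects of variants
#'
#' Locates each variant's containing CDS (strand-aware), translates the
#' reference and mutated codon with the standard bacterial genetic code, and
#' classifies: SNPs as `synonymous`, `nonsynonymous`, or `nonsense`; indels
#' as `frameshift` when the length change is not a multiple of three, else
#' `inframe_indel`; variants outside every CDS as `intergenic`.
#'
#' @param variants Data frame with `strain`, `contig`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param genes Gene-model data frame (`gene_id`, `contig`, `strand`,
#'   `start`, `end`; CDS lengths must be multiples of three).
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences.
#' @return `variants` with columns `kind`, `gene_id`, and `effect` added.
#' @export
annotate_effect <- function(variants, genes, genome) {
  stopifnot(all(c("strain", "contig", "pos", "ref", "alt")
                %in% names(variants)))
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  badlen <- (genes$end - genes$start + 1) %% 3 != 0
  if (any(badlen)) {
    stop("CDS length not a multiple of 3 for: ",
         paste(genes$gene_id[badlen], collapse = ", "), call. = FALSE)
  }
  code <- Biostrings::getGeneticCode("11")
  n <- nrow(variants)
  kind <- variant_kind(variants$ref, variants$alt)
  gene_id <- character(n)
  effect <- character(n)
  for (i in seq_len(n)) {
    ctg <- variants$contig[i]
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    if (!ctg %in% names(genome)) {
      stop("variant contig not in genome: ", ctg, call. = FALSE)
    }
    obs <- substr(genome[[ctg]], pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      stop(sprintf("ref allele mismatch at %s:%d (VCF says %s, genome has %s)",
                   ctg, pos, ref, obs), call. = FALSE)
    }
    gi <- locate_gene(ctg, pos, genes)
    if (is.na(gi)) {
      gene_id[i] <- NA_character_
      effect[i] <- "intergenic"
      next
    }
    gene_id[i] <- genes$gene_id[gi]
    if (kind[i] != "snp") {
      effect[i] <- if (abs(nchar(alt) - nchar(ref)) %% 3 != 0) {
        "frameshift"
      } else {
        "inframe_indel"
      }
      next
    }
    # strand-aware codon lookup
    if (genes$strand[gi] == "+") {
      off <- pos - genes$start[gi]          # 0-based offset on the mRNA
      base <- alt
    } else {
      off <- genes$end[gi] - pos
      base <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
    }
    cds <- substr(genome[[ctg]], genes$start[gi], genes$end[gi])
    if (genes$strand[gi] == "-") {
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    }
    cstart <- (off %/% 3L) * 3L + 1L
    ref_codon <- substr(cds, cstart, cstart + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, off %% 3L + 1L, off %% 3L + 1L) <- base
    aa_ref <- code[[ref_codon]]
    aa_alt <- code[[alt_codon]]
    effect[i] <- if (aa_ref == aa_alt) {
      "synonymous"
    } else if (aa_alt == "*") {
      "nonsense"
    } else {
      "nonsynonymous"
    }
  }
  variants$kind <- kind
  variants$gene_id <- gene_id
  variants$effect <- effect
  variants
}

#' Remove putative sequencing-artifact variants
#'
#' A variant is discarded when the identical event (same contig, position,
#' ref, and alt) occurs in two or more strains *and* its containing gene is
#' flagged as an insertion sequence or a short hypothetical gene — recurrence
#' in such repeat-prone or low-confidence loci is treated as a mapping or
#' sequencing artifact rather than independent mutation. With
#' `mode = "either"` recurrence alone (or flagged location alone) suffices,
#' for sensitivity analysis.
#'
#' @param variants Annotated variant data frame (see [annotate_effect()];
#'   needs `strain`, `contig`, `pos`, `ref`, `alt`, `gene_id`).
#' @param genes Flagged gene models (see [flag_gene_models()]).
#' @param mode `"both"` (default: recurrence AND flagged gene) or `"either"`.
#' @return Kept variants; attribute `"removal_log"` holds the removed rows.
#' @export
filter_artifacts <- function(variants, genes, mode = c("both", "either")) {
  mode <- match.arg(mode)
  stopifnot(all(c("is_insertion_sequence", "is_short_hypothetical")
                %in% names(genes)))
  if (nrow(variants) == 0) {
    attr(variants, "removal_log") <- variants
    return(variants)
  }
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt,
               sep = ":")
  n_strains <- vapply(split(variants$strain, key),
                      function(s) length(unique(s)), integer(1))
  recurrent <- n_strains[key] >= 2
  flagged_genes <- genes$gene_id[genes$is_insertion_sequence |
                                   genes$is_short_hypothetical]
  in_flagged <- !is.na(variants$gene_id) &
    variants$gene_id %in% flagged_genes
  drop <- if (mode == "both") recurrent & in_flagged else
    recurrent | in_flagged
  kept <- variants[!drop, , drop = FALSE]
  attr(kept, "removal_log") <- variants[drop, , drop = FALSE]
  kept
}

#' Rank genes by independent mutation recurrence among phenotype-positive mutants
#'
#' For each gene, counts the distinct complete-loss mutant strains carrying
#' at least one candidate-effect variant (nonsynonymous, nonsense,
#' frameshift, or in-frame indel) in it, and returns the genes reaching
#' `min_strains`, sorted by strain count (descending) then gene id.
#'
#' @param variants Annotated (and typically artifact-filtered) variants.
#' @param phenotypes Data frame `strain`, `phenotype` with phenotype one of
#'   `ina_lost`, `ina_reduced`, `wild_type`.
#' @param min_strains Minimum number of independent strains (default 2).
#' @param include_reduced Also count `ina_reduced` strains (default FALSE).
#' @param effects Effect classes that count as candidate hits.
#' @return Data frame `gene_id`, `n_strains`, `strains`, `variants`.
#' @export
recurrently_hit_genes <- function(variants, phenotypes, min_strains = 2,
                                  include_reduced = FALSE,
                                  effects = CANDIDATE_EFFECTS) {
  stopifnot(all(c("gene_id", "effect", "strain") %in% names(variants)),
            all(c("strain", "phenotype") %in% names(phenotypes)),
            !anyDuplicated(phenotypes$strain))
  keep_ph <- c("ina_lost", if (include_reduced) "ina_reduced")
  pos_strains <- phenotypes$strain[phenotypes$phenotype %in% keep_ph]
  v <- variants[variants$strain %in% pos_strains &
                  variants$effect %in% effects &
                  !is.na(variants$gene_id), , drop = FALSE]
  if (nrow(v) == 0) {
    return(data.frame(gene_id = character(), n_strains = integer(),
                      strains = character(), variants = character()))
  }
  per_gene <- split(v, v$gene_id)
  out <- do.call(rbind, lapply(per_gene, function(g) {
    data.frame(gene_id = g$gene_id[1],
               n_strains = length(unique(g$strain)),
               strains = paste(sort(unique(g$strain)), collapse = ","),
               variants = paste(sprintf("%s:%d:%s>%s", g$contig, g$pos,
                                        g$ref, g$alt), collapse = ","))
  }))
  out <- out[out$n_strains >= min_strains, , drop = FALSE]
  out <- out[order(-out$n_strains, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
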