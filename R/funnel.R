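# Pan-genome candidate funnel: clade-uniqueness, expression, BGC-core tagging.

#' Construct a gene presence/absence matrix
#'
#' The container mirrors the Roary `gene_presence_absence.csv` summary: one
#' row per gene cluster, one column per genome, each non-absent cell holding
#' that genome's locus tag for the cluster. Absence is `NA`.
#'
#' @param occupancy Character matrix (clusters x genomes) with dimnames; `NA`
#'   or `""` cells mean the cluster is absent from that genome.
#' @param annotation Optional character vector of product annotations, one
#'   per cluster.
#' @return A `pa_matrix` object.
#' @export
pa_matrix <- function(occupancy, annotation = NULL) {
  stopifnot(is.matrix(occupancy), !is.null(rownames(occupancy)),
            !is.null(colnames(occupancy)))
  if (anyDuplicated(colnames(occupancy))) {
    stop("genome ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(rownames(occupancy))) {
    stop("gene cluster ids must be unique", call. = FALSE)
  }
  occupancy[!is.na(occupancy) & !nzchar(occupancy)] <- NA_character_
  if (is.null(annotation)) annotation <- rep(NA_character_, nrow(occupancy))
  stopifnot(length(annotation) == nrow(occupancy))
  structure(list(occupancy = occupancy, annotation = annotation),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("Presence/absence matrix:", nrow(x$occupancy), "gene clusters x",
      ncol(x$occupancy), "genomes\n")
  invisible(x)
}

#' Genes unique to a target clade
#'
#' Selects gene clusters by their occupancy pattern over the genomes: with
#' `mode = "all"` (default) a cluster qualifies when it is present in *every*
#' target genome and absent from *every* other genome; `mode = "any"` relaxes
#' the first condition to presence in at least one target.
#'
#' @param pa A [pa_matrix()].
#' @param target_ids Genome ids forming the clade of interest; must be a
#'   non-empty proper subset of the matrix's genomes.
#' @param mode `"all"` or `"any"`.
#' @param reference Genome whose locus tags name the returned genes; defaults
#'   to the first target.
#' @return Character vector of reference-genome locus tags of the qualifying
#'   clusters (cluster ids are used for clusters absent from the reference,
#'   which can only occur under `mode = "any"`).
#' @export
unique_to_clade <- function(pa, target_ids, mode = c("all", "any"),
                            reference = target_ids[1]) {
  mode <- match.arg(mode)
  stopifnot(inherits(pa, "pa_matrix"))
  genomes <- colnames(pa$occupancy)
  unknown <- setdiff(c(target_ids, reference), genomes)
  if (length(unknown) > 0) {
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(target_ids) == 0 || length(target_ids) >= length(genomes)) {
    stop("target_ids must be a non-empty proper subset of the genomes",
         call. = FALSE)
  }
  present <- !is.na(pa$occupancy)
  in_target <- present[, target_ids, drop = FALSE]
  in_other <- present[, setdiff(genomes, target_ids), drop = FALSE]
  hit <- if (mode == "all") {
    rowSums(in_target) == length(target_ids) & rowSums(in_other) == 0
  } else {
    rowSums(in_target) > 0 & rowSums(in_other) == 0
  }
  tags <- pa$occupancy[hit, reference]
  ifelse(is.na(tags), rownames(pa$occupancy)[hit], tags)
}

#' Transcripts-per-million normalisation
#'
#' `tpm_i = 1e6 * (count_i / length_i) / sum_j(count_j / length_j)`; the
#' result sums to one million by construction.
#'
#' @param counts Non-negative integer vector of mapped-read counts.
#' @param lengths Positive numeric vector of effective gene lengths (nt).
#' @return Numeric vector of TPM values.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) {
    stop("all counts are zero: TPM is undefined", call. = FALSE)
  }
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Assemble an expression table
#'
#' @param gene_id Character vector of gene ids (locus tags).
#' @param count Raw mapped-read counts.
#' @param length Effective lengths in nucleotides (annotated CDS length).
#' @return Data frame `gene_id`, `count`, `length`, `tpm`.
#' @export
expression_table <- function(gene_id, count, length) {
  stopifnot(!anyDuplicated(gene_id))
  data.frame(gene_id = as.character(gene_id), count = count,
             length = length, tpm = tpm(count, length))
}

#' Expressed genes at a TPM threshold
#'
#' @param expr An [expression_table()].
#' @param threshold Genes with `tpm > threshold` are called expressed;
#'   the default 0 counts any mapped read as evidence of expression.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(expr, threshold = 0) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expr)))
  expr$gene_id[expr$tpm > threshold]
}

#' Default biosynthetic signature-domain table
#'
#' A gene is tagged core when it carries a standalone signature domain (a
#' ketosynthase, KS), a complete condensation/adenylation didomain (C and A
#' together), a thioesterase (TE) immediately adjacent to a core gene, or an
#' accessory domain (4'-phosphopantetheinyl transferase, PPTASE; NAD-dependent
#' epimerase/dehydratase, EPIM_DH) within the clustering window of a core
#' gene. Edit the returned list to change the rule.
#'
#' @return List with elements `standalone`, `pairs`, `adjacent`, `proximal`.
#' @export
bgc_signature <- function() {
  list(standalone = "KS",
       pairs = list(c("C", "A")),
       adjacent = "TE",
       proximal = c("PPTASE", "EPIM_DH"))
}

parse_domains <- function(domains) {
  if (is.list(domains)) {
    lapply(domains, as.character)
  } else {
    strsplit(ifelse(is.na(domains), "", as.character(domains)), ",[ ]?")
  }
}

#' Tag biosynthetic core genes and cluster them into regions
#'
#' A simplified stand-in for a full biosynthetic-gene-cluster scan: genes are
#' tagged core from their annotated domain content alone (see
#' [bgc_signature()]), then core genes whose pairwise genomic gaps are at
#' most `window_nt` are merged into regions.
#'
#' @param genes Gene-model data frame with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `domains` (comma-separated domain labels or a
#'   list column).
#' @param window_nt Merge distance in nucleotides (default 10 kb); also the
#'   reach of the `proximal` accessory rule.
#' @param signature Signature table as returned by [bgc_signature()].
#' @return List with `core_genes` (character vector) and `regions` (data
#'   frame `contig`, `start`, `end`, `n_core`, `core_genes`,
#'   `member_genes` — all genes falling inside the region span).
#' @export
call_bgc_core <- function(genes, window_nt = 10000,
                          signature = bgc_signature()) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "domains")
                %in% names(genes)))
  if (any(genes$start > genes$end)) {
    stop("gene intervals must have start <= end", call. = FALSE)
  }
  genes <- genes[order(genes$contig, genes$start), ]
  if (nrow(genes) > 1) {
    same <- genes$contig[-1] == genes$contig[-nrow(genes)]
    if (any(same & genes$start[-1] <= genes$end[-nrow(genes)])) {
      warning("overlapping gene intervals; processed in start order")
    }
  }
  doms <- parse_domains(genes$domains)
  primary <- vapply(doms, function(d) {
    any(d %in% signature$standalone) ||
      any(vapply(signature$pairs, function(p) all(p %in% d), logical(1)))
  }, logical(1))

  gap_to_primary <- function(i) {
    js <- which(primary & genes$contig == genes$contig[i])
    if (length(js) == 0) return(Inf)
    min(pmax(0, pmax(genes$start[i] - genes$end[js],
                     genes$start[js] - genes$end[i])))
  }
  core <- primary
  for (i in which(!primary)) {
    d <- doms[[i]]
    if (any(d %in% signature$adjacent)) {
      # immediate genomic neighbour (either side, same contig) is core
      idx <- which(genes$contig == genes$contig[i])
      p <- match(i, idx)
      nb <- idx[c(p - 1, p + 1)]
      nb <- nb[!is.na(nb)]
      if (any(primary[nb]) && gap_to_primary(i) <= window_nt) core[i] <- TRUE
    }
    if (!core[i] && any(d %in% signature$proximal) &&
        gap_to_primary(i) <= window_nt) {
      core[i] <- TRUE
    }
  }

  regions <- NULL
  ci <- which(core)
  if (length(ci) > 0) {
    new_region <- c(TRUE, genes$contig[ci[-1]] != genes$contig[ci[-length(ci)]] |
                      genes$start[ci[-1]] - genes$end[ci[-length(ci)]] > window_nt)
    grp <- cumsum(new_region)
    regions <- do.call(rbind, lapply(split(ci, grp), function(ix) {
      s <- min(genes$start[ix]); e <- max(genes$end[ix])
      inside <- genes$contig == genes$contig[ix[1]] &
        genes$start >= s & genes$end <= e
      data.frame(contig = genes$contig[ix[1]], start = s, end = e,
                 n_core = length(ix),
                 core_genes = paste(genes$gene_id[ix], collapse = ","),
                 member_genes = paste(genes$gene_id[inside], collapse = ","))
    }))
    rownames(regions) <- NULL
  } else {
    regions <- data.frame(contig = character(), start = integer(),
                          end = integer(), n_core = integer(),
                          core_genes = character(),
                          member_genes = character())
  }
  list(core_genes = genes$gene_id[core], regions = regions)
}

#' Run the candidate-gene funnel
#'
#' Composes the three filters into nested stage sets: genes unique to the
#' target clade; of those, the expressed ones; of those, the biosynthetic
#' core genes; and, when a mutant screen's recurrently hit genes are
#' supplied, the screen-supported survivors.
#'
#' @param pa A [pa_matrix()].
#' @param target_ids Target clade genome ids (see [unique_to_clade()]).
#' @param expr An [expression_table()] keyed by reference-genome locus tags.
#' @param genes Gene-model data frame for the reference genome (see
#'   [call_bgc_core()]); may cover only part of the genome.
#' @param screen_hits Optional character vector of recurrently hit gene ids
#'   (e.g. `recurrently_hit_genes()$gene_id`).
#' @param tpm_threshold,uniqueness,window_nt,signature Filter parameters,
#'   passed through and echoed into the report.
#' @return A `candidate_report`: list with `stage_sets`, `stage_counts`, and
#'   `parameters`.
#' @export
run_funnel <- function(pa, target_ids, expr, genes, screen_hits = NULL,
                       tpm_threshold = 0, uniqueness = c("all", "any"),
                       window_nt = 10000, signature = bgc_signature()) {
  uniqueness <- match.arg(uniqueness)
  uniq <- unique_to_clade(pa, target_ids, mode = uniqueness)
  unmatched <- setdiff(uniq, expr$gene_id)
  if (length(unmatched) > 0) {
    stop("gene ids missing from the expression table: ",
         paste(utils::head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) sprintf(" (and %d more)",
                                            length(unmatched) - 5),
         call. = FALSE)
  }
  expressed <- intersect(uniq, expressed_genes(expr, tpm_threshold))
  bgc <- call_bgc_core(genes, window_nt = window_nt, signature = signature)
  core <- intersect(expressed, bgc$core_genes)
  stage_sets <- list(unique = uniq,
                     unique_expressed = expressed,
                     unique_expressed_core = core)
  if (!is.null(screen_hits)) {
    stage_sets$screen_supported <- intersect(core, screen_hits)
  }
  structure(list(
    stage_sets = stage_sets,
    stage_counts = vapply(stage_sets, length, integer(1)),
    regions = bgc$regions,
    parameters = list(target_ids = target_ids, uniqueness = uniqueness,
                      tpm_threshold = tpm_threshold, window_nt = window_nt,
                      signature = signature)
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate-gene funnel\n")
  for (s in names(x$stage_sets)) {
    cat(sprintf("  %-24s %6d genes\n", s, length(x$stage_sets[[s]])))
  }
  invisible(x)
}
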